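---
title: "Window-based differential methylation analysis with epidmr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based differential methylation analysis with epidmr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidmr)
```

## Scope and intended use

`epidmr` implements the analysis chain used in sperm MeDIP-Seq studies of
environmentally induced transgenerational disease: fixed 1-kb genome
windows are scored for differential read coverage between two groups of
animals (exposure lineage vs control, or diseased vs non-diseased), merged
into differential DNA methylation regions (DMRs), associated with nearby
genes, and compared across exposures and pathologies; a coexpression-style
module analysis relates genome-wide methylation patterns to sample traits,
and a histopathology module turns blinded observer abnormality counts into
binary disease calls. The pipeline starts from aligned read intervals (BED
or BAM) or from window-by-sample count matrices; trimming and alignment
are upstream concerns.

Because real studies of this kind require tens of millions of reads per
pool against a full mammalian genome, the package ships a synthetic-data
generator that reproduces the *statistical* structure the analysis
assumes — negative-binomial window counts with CpG-density-linked means,
library-size variation, planted group-specific shifts, latent-factor
correlated window blocks, and per-observer pathology counts — so every
stage can be exercised and validated end to end at desk scale.

## The window test

Each chromosome is tiled with consecutive windows `[0, w)`, `[w, 2w)`, ...
(default `w` = 1000 bp; the terminal partial window is kept and
length-corrected where normalization needs it). A fragment is counted into
every window it intersects after being extended 3' to the nominal fragment
length (default 250 bp); a containment mode, which assigns each fragment
to the single window holding its start, exists because it is exactly
invertible and anchors the round-trip tests.

Counts for window \(w\) in sample \(s\) are modeled as negative binomial
with mean \(\mu_{ws}\) and common dispersion \(\phi\), so that
\(\mathrm{Var} = \mu + \phi\mu^2\); \(\phi = 0\) degenerates to Poisson.
Library sizes are first equalized by scaling every sample to the
geometric-mean library size and rounding half-even. This deterministic
scaling is simpler than the quantile-adjusted pseudo-counts used by
edgeR's classic exact test; the trade-off is transparency and exact
reproducibility against a small loss of variance fidelity, and the type-I
error of the resulting test is verified by simulation (the null rejection
rate at 0.05 stays within [0.03, 0.07] in the acceptance suite).

For a window with equalized group sums \(s_A, s_B\) over \(n_A, n_B\)
samples, the test conditions on \(T = s_A + s_B\). Group sums are
\(NB(n_A\hat\mu, \phi/n_A)\) vs \(NB(n_B\hat\mu, \phi/n_B)\) with
\(\hat\mu = T/(n_A+n_B)\), and the two-sided p value sums the conditional
probabilities of all splits of \(T\) no more likely than the observed one
(ties included) — the same "less-likely outcomes" convention as edgeR's
exact test. At \(\phi = 0\) this is exactly the conditional binomial test,
which the test suite checks to \(10^{-12}\) by enumeration. \(T = 0\)
returns \(p = 1\) by convention.

The common dispersion is estimated either by pooled moments
(\(\max(0, \sum_w(v_w - m_w)/\sum_w m_w^2)\) after equalization) or, by
default, by maximizing the summed conditional NB log-likelihood over a
61-point log-spaced grid on \([10^{-4}, 10]\). The grid resolution
(~21% between neighbours) is adequate for calibration at conventional
thresholds but leaves residual error in the extreme tail
(\(p < 10^{-4}\)); validation scenarios that probe that tail therefore
use the simulation's known dispersion, which isolates the property under
test. Tagwise shrinkage and GLM-based testing are out of scope.

Fold changes are \(\log_2\big(((s_A + c)/L_A)/((s_B + c)/L_B)\big)\) with
prior count \(c = 0.5\) per group; false discovery control is
Benjamini–Hochberg over windows.

## DMR calling

Windows with \(p\) below the seed threshold (default \(10^{-6}\);
\(10^{-4}\) is the conventional relaxation when a comparison yields few
windows, e.g. sparse exposures or small disease groups) start a region.
Region edges then absorb any window with \(p < 0.1\) whose inter-edge gap
is at most 1000 bp, to a fixed point; intervening non-qualifying windows
are bridged and become members. "Within 1000 bp" is read inclusively, so
with 1-kb windows exactly one non-significant window can be bridged; this
is the most literal reading of the extension rule and is pinned down by an
exhaustive brute-force absorption oracle in the tests (1000 random
instances). Extension never crosses chromosome ends, and regions that
touch after extension merge, leftmost first, making the caller fully
deterministic.

A DMR is labeled by its most significant member window (p, q, log2
fold change), carries the member count, and gets CpG count and density
(CpGs per 100 bp) from the genome definition. Whether the published
analyses report window-level or region-level FDR is ambiguous; here q
values are window-level BH, reported at the DMR seed.

Planted-signal validation uses ten 40-window regions (alternating hyper-
and hypomethylation so the planted mass stays roughly library-balanced) on
a 10,000-window genome at \(\mu = 100\), \(\phi = 0.05\), 6 vs 6 samples:
sensitivity must reach 90% with at most 5% of called DMR windows outside
planted truth. The regions are deliberately wide: the extension rule
contributes ~0.4 null windows per DMR edge by construction, so the
false-window *rate* is only meaningful against a multi-window denominator.

## Gene association and DMR-set comparison

Genes are associated with a DMR when the gap between the interval and the
gene body is at most 10 kb (0 when overlapping), capturing distal and
proximal promoter regions. Distance is measured to the gene body rather
than the TSS, and strand is ignored — the anchoring used in the original
annotation is not recoverable, so the simpler symmetric rule is declared
and tested against an all-pairs oracle. All qualifying genes are retained.

DMR sets are compared three ways:

* **Venn region counts** merge all intervals into distinct genomic loci
  and label each locus by the subset of sets intersecting it by at least
  1 bp. Interval intersection (not shared gene or identical window id) is
  the declared overlap semantic.
* **Extended overlap** is asymmetric: each row DMR (called at the
  stringent threshold) counts as overlapping if it touches any window
  with \(p < 0.05\) in the column comparison's statistics, with the row
  set size as denominator. A set scored against its own statistics always
  gives 100% (every DMR contains its seed window), which is the built-in
  self-test. Shared planted signal between two synthetic exposures yields
  high extended overlap while disjoint signal stays low; the published
  full-depth percentages themselves require the archived sequencing data
  and are not reproduced at desk scale.
* **Chromosomal clusters** come from a sliding-window Poisson scan (2-Mb
  windows, 500-kb steps): window counts of DMR midpoints are tested
  against the genome-wide DMR density with BH correction at 0.05 and
  significant windows merge into cluster intervals. The original work
  reports clusters without describing a procedure, so this scan is a
  declared surrogate and is labeled as such in its output metadata.

## Methylation modules and trait correlation

Module detection follows the weighted-correlation-network recipe on the
windows with the highest coverage. Methods and results descriptions of
the ranking statistic differ in this literature (mean RPKM vs total
depth); mean RPKM across samples is the default and a total-depth mode is
available. Unsigned adjacency \(|r|^4\) (Pearson, soft power 4) feeds the
topological overlap matrix

\[
TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
               {\min(k_i, k_j) + 1 - a_{ij}},
\]

and windows are clustered by average linkage on \(1 - TOM\). Instead of
dynamic tree cut, the tree is cut statically at 0.99 of the maximum merge
height — a deliberate simplification whose recovery behaviour is tested
on planted two-block structure (within-block correlation 0.9, blocks of
50 windows, 20 samples: both blocks recovered with at least 95% membership
agreement, while pure noise stays at least 80% unassigned). Clusters below
30 windows are relabeled grey. Module eigengenes are first principal
components of the standardized member profiles, sign-oriented toward the
member mean; modules whose eigengene correlation distance falls below
0.25 are merged iteratively. Blocks larger than 15,000 windows are
rejected rather than split — reduce the selected window count instead.

Module–trait relationships are Pearson correlations between eigengenes
and numeric traits (binary exposure/disease indicators or continuous
covariates), with the Student-t p value
\(p = 2P\!\left(T_{n-2} \ge |r|\sqrt{n-2}/\sqrt{1-r^2}\right)\).

## Pathology classification

For each tissue the disease cutoff is the control-group mean abnormality
count plus two standard deviations (sample SD); a count qualifies only
when strictly greater. Control statistics are pooled across observers by
default (per-observer thresholds are a flag) — the original description
does not resolve which was used. An animal's tissue is diseased when at
least 2 of the 3 blinded observers qualify; animals with one diseased
tissue are "single disease", more than one "multiple disease". Group
frequencies are compared with a two-sided Fisher exact test implemented
by hypergeometric enumeration and checked exhaustively against an
independent enumeration for all margins up to 30.

## The synthetic generator and what passing means

All randomness descends from one explicit seed through derived
sub-streams; fixed seeds give bit-identical outputs, and the generator
never touches the caller's RNG state. Baseline window means are affine in
window CpG count (default `10 + 2 × CpGs`, giving means around 30 at a
CpG rate of 0.01/bp — a desk-scale stand-in for MeDIP coverage whose
per-window depth no study reports directly), library sizes vary around
their mean, planted DMRs multiply group-A means by \(2^{\mathrm{logFC}}\),
and module blocks share a per-sample lognormal latent factor that is also
exposed as a trait. Read placement back onto the genome is deterministic
(evenly spaced within each window) precisely so that containment
re-counting is an exact round trip.

The generator reproduces the distributional assumptions of the analysis,
not real methylomes: no sequence context, no fragment-length or GC
effects, no spatial correlation of methylation outside planted blocks, no
batch structure. Passing tests therefore demonstrates that the
implementation is correct and calibrated under its stated model, not that
the model captures every property of real sperm MeDIP-Seq data.

Problem sizes in the test and acceptance runs (2,000–10,000 windows,
6 vs 6 samples, 12–24 animals in the pathology arm) were chosen as the
smallest sizes at which the monitored rates are statistically stable.

## Numerical choices and edge cases

* Conditional p values cache the split distribution per window total, and
  numerically tied outcomes within a \(1+10^{-10}\) relative factor count
  as ties, keeping the two-sided rule stable under floating-point noise.
* Zero-variance windows correlate 0 in adjacency; zero-variance traits
  give `NA` with a warning rather than an error.
* Degenerate all-identical dissimilarity collapses to a single module.
* Empty DMR sets propagate as empty tables (header-only files, 0% overlap
  with a warning flag), never as errors.
* Coordinates are 0-based half-open internally and in BED output; GFF3 is
  converted at the boundary; 1-based positions appear only in external
  formats that require them.

## Limitations

Not implemented, by design: TMM or quantile normalization, tagwise
dispersion shrinkage, smoothing-based or region-statistic DMR callers,
dynamic tree cut and block-splitting for module detection, scale-free
topology fitting for the soft power, live annotation services, and any
image-based pathology scoring. These are either out of the analysis chain
being modeled or deliberately simplified variants documented above.
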