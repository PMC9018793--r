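#' Define a synthetic study design
#'
#' Captures everything the count simulator needs: samples and their
#' exposure/disease labels, two-group comparisons, expected library sizes,
#' planted DMRs (window ranges with a log2 effect applied to group A of one
#' comparison), the negative-binomial dispersion, the CpG-linked baseline
#' mean, and correlated window blocks driven by latent per-sample factors.
#'
#' @param samples data.frame with at least `sample_id`; any further columns
#'   (exposure, disease indicators) are carried as traits.
#' @param comparisons named list; each element `list(a = ids, b = ids)`
#'   with disjoint sample-id vectors.
#' @param library_size_targets expected total reads per sample (named, or
#'   recycled); converted to per-sample scale factors around their mean.
#' @param planted_dmrs data.frame with `comparison`, `first_window`,
#'   `last_window` (1-based window ordinals, inclusive) and `log2fc`;
#'   `NULL` for none.
#' @param dispersion NB dispersion phi >= 0 (`var = mu + phi * mu^2`);
#'   0 degenerates to Poisson.
#' @param baseline `c(intercept, per_cpg)`: window mean is
#'   `intercept + per_cpg * cpg_count`, an affine CpG-density link
#'   mimicking MeDIP coverage.
#' @param module_blocks list of `list(windows =, loading =, trait =)`:
#'   window sets sharing a multiplicative latent factor per sample,
#'   `exp(loading * z_s)` with `z_s ~ N(0, 1)`; the factor is exposed as a
#'   sample trait named `trait`.
#' @param seed integer RNG seed for the whole design.
#' @return a `study_design` object.
#' @export
study_design <- function(samples, comparisons,
                         library_size_targets = NULL,
                         planted_dmrs = NULL,
                         dispersion = 0.1,
                         baseline = c(intercept = 10, per_cpg = 2),
                         module_blocks = list(),
                         seed = 1L) {
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples),
            !anyDuplicated(samples$sample_id))
  if (dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(length(baseline) == 2, all(baseline >= 0), sum(baseline) > 0)
  if (length(comparisons) == 0 || is.null(names(comparisons))) {
    stop("comparisons must be a non-empty named list")
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    if (!all(c(cmp$a, cmp$b) %in% samples$sample_id)) {
      stop("comparison ", nm, " references unknown samples")
    }
    if (length(intersect(cmp$a, cmp$b))) {
      stop("comparison ", nm, ": groups must be disjoint")
    }
  }
  if (!is.null(planted_dmrs)) {
    stopifnot(all(c("comparison", "first_window", "last_window", "log2fc")
                  %in% names(planted_dmrs)))
    if (!all(planted_dmrs$comparison %in% names(comparisons))) {
      stop("planted DMR references an undefined comparison")
    }
    stopifnot(all(planted_dmrs$first_window >= 1),
              all(planted_dmrs$last_window >= planted_dmrs$first_window))
  }
  if (is.null(library_size_targets)) {
    library_size_targets <- rep(1, nrow(samples))
  }
  library_size_targets <- rep_len(library_size_targets, nrow(samples))
  stopifnot(all(library_size_targets > 0))
  structure(
    list(samples = samples, comparisons = comparisons,
         library_size_targets = stats::setNames(library_size_targets,
                                                samples$sample_id),
         planted_dmrs = planted_dmrs, dispersion = dispersion,
         baseline = baseline, module_blocks = module_blocks,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Simulate a window count matrix under a study design
#'
#' Per window `w` and sample `s`, counts are drawn from
#' `NB(mean = mu[w] * libfactor[s] * 2^effect * blockfactor, phi)` where
#' `mu[w]` is the CpG-linked baseline, `effect` applies at planted windows
#' to group-A samples of the affected comparison, and module-block windows
#' share a latent multiplicative factor per sample. `phi = 0` draws
#' Poisson counts.
#'
#' @param design a `study_design`.
#' @param grid a `window_grid` (supplies CpG counts and window number).
#' @return a `count_matrix`; latent block factors are attached as attribute
#'   `"latent_factors"` (samples x blocks) and the trait table as
#'   `"traits"`.
#' @export
simulate_counts <- function(design, grid) {
  stopifnot(inherits(design, "study_design"), inherits(grid, "window_grid"))
  nw <- nrow(grid)
  ids <- design$samples$sample_id
  ns <- length(ids)
  if (!is.null(design$planted_dmrs) &&
      any(design$planted_dmrs$last_window > nw)) {
    stop("planted DMR window index out of range for this grid")
  }
  mu0 <- design$baseline[[1]] + design$baseline[[2]] * grid$cpg_count
  libfac <- design$library_size_targets / mean(design$library_size_targets)

  with_seed(sub_seed(design$seed, "counts"), {
    logmu <- outer(log(pmax(mu0, 1e-8)), log(libfac), `+`)
    if (!is.null(design$planted_dmrs)) {
      for (i in seq_len(nrow(design$planted_dmrs))) {
        pd <- design$planted_dmrs[i, ]
        aff <- ids %in% design$comparisons[[pd$comparison]]$a
        w <- pd$first_window:pd$last_window
        logmu[w, aff] <- logmu[w, aff] + pd$log2fc * log(2)
      }
    }
    latent <- NULL
    if (length(design$module_blocks)) {
      latent <- matrix(rnorm(ns * length(design$module_blocks)), ns,
                       dimnames = list(ids, vapply(design$module_blocks,
                                                   function(b) b$trait, "")))
      for (k in seq_along(design$module_blocks)) {
        blk <- design$module_blocks[[k]]
        if (any(blk$windows < 1 | blk$windows > nw)) {
          stop("module block window index out of range")
        }
        logmu[blk$windows, ] <- logmu[blk$windows, ] +
          rep(blk$loading * latent[, k], each = length(blk$windows))
      }
    }
    mu <- exp(logmu)
    phi <- design$dispersion
    cnt <- if (phi == 0) {
      rpois(nw * ns, lambda = mu)
    } else {
      rnbinom(nw * ns, size = 1 / phi, mu = mu)
    }
    counts <- matrix(as.integer(cnt), nw, ns, dimnames = list(NULL, ids))
    cm <- count_matrix(counts)
    attr(cm, "latent_factors") <- latent
    traits <- design$samples[, setdiff(names(design$samples), "sample_id"),
                             drop = FALSE]
    rownames(traits) <- ids
    if (!is.null(latent)) traits <- cbind(traits, as.data.frame(latent))
    attr(cm, "traits") <- traits
    cm
  })
}

#' Turn a count matrix back into aligned fragments
#'
#' For every window and sample, places exactly `count[w, s]` fragments of
#' `fragment_length` bp fully inside the window at deterministic, evenly
#' spaced starts, so containment counting recovers the matrix exactly.
#'
#' @param counts a `count_matrix` over all grid windows.
#' @param grid a `window_grid`.
#' @param fragment_length fragment length in bp (`<=` every window length).
#' @return named list of read data.frames, one per sample.
#' @export
counts_to_reads <- function(counts, grid, fragment_length = 250L) {
  stopifnot(inherits(counts, "count_matrix"))
  len <- grid$end - grid$start
  if (any(fragment_length > len[counts$windows])) {
    stop("fragment_length exceeds a window length")
  }
  lapply(stats::setNames(seq_along(counts$sample_ids), counts$sample_ids),
         function(s) {
    k <- counts$counts[, s]
    nz <- which(k > 0)
    if (!length(nz)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0)))
    }
    reps <- k[nz]
    w <- counts$windows[nz]
    widx <- rep(w, reps)
    rank <- sequence(reps)
    n_in <- rep(reps, reps)
    slack <- grid$end[widx] - grid$start[widx] - fragment_length
    offset <- ifelse(n_in == 1, 0,
                     floor((rank - 1) * slack / pmax(n_in - 1, 1)))
    start <- grid$start[widx] + as.integer(offset)
    data.frame(chrom = grid$chrom[widx], start = start,
               end = start + as.integer(fragment_length),
               strand = "+", stringsAsFactors = FALSE)
  })
}

#' Simulate per-observer histopathology abnormality counts
#'
#' Controls draw abnormality counts from `Poisson(control_rate)` and cases
#' from `Poisson(control_rate + case_shift)`, independently per observer.
#'
#' @param n_control,n_case animals per lineage.
#' @param control_rate mean abnormality count in controls (>= 0).
#' @param case_shift additive mean shift in cases (>= 0).
#' @param n_observers blinded observers per section (>= 3 by default).
#' @param tissue tissue label for the records.
#' @param seed integer RNG seed.
#' @return data.frame of `PathologyRecord`s: `animal_id`, `lineage`,
#'   `tissue`, `observer`, `abnormality_count`.
#' @export
simulate_pathology <- function(n_control, n_case, control_rate, case_shift,
                               n_observers = 3L, tissue = "testis",
                               seed = 1L) {
  if (control_rate < 0 || case_shift < 0) stop("rates must be >= 0")
  stopifnot(n_observers >= 1L, n_control >= 1L, n_case >= 0L)
  animals <- c(sprintf("C%03d", seq_len(n_control)),
               if (n_case > 0) sprintf("E%03d", seq_len(n_case)))
  lineage <- rep(c("control", "exposure"), c(n_control, n_case))
  rate <- rep(c(control_rate, control_rate + case_shift),
              c(n_control, n_case))
  with_seed(seed, {
    df <- expand.grid(observer = paste0("obs", seq_len(n_observers)),
                      animal_id = animals, stringsAsFactors = FALSE)
    df$lineage <- rep(lineage, each = n_observers)
    df$tissue <- tissue
    df$abnormality_count <- rpois(nrow(df), rep(rate, each = n_observers))
    df[, c("animal_id", "lineage", "tissue", "observer",
           "abnormality_count")]
  })
}
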