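# Comparison of DMR sets across exposures and diseases: multiway Venn
# region counts over merged genomic loci, the asymmetric extended overlap
# (stringent rows against relaxed-threshold column windows), and a
# Poisson sliding-window scan for chromosomal DMR clusters.

#' Venn region counts for 2-7 DMR sets
#'
#' All intervals are merged into distinct genomic loci; each locus is
#' labeled by the subset of input sets intersecting it by >= 1 bp, and loci
#' are counted per subset pattern.
#'
#' @param sets named list (2-7 elements) of interval data.frames with
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame with `pattern` (set labels joined by `&`) and
#'   `n_loci`; per-set totals in attribute `"set_totals"`.
#' @export
venn_overlap <- function(sets) {
  if (length(sets) < 2 || length(sets) > 7) {
    stop("venn_overlap supports 2-7 sets")
  }
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  grs <- lapply(sets, as_granges0)
  loci <- GenomicRanges::reduce(do.call(c, unname(grs)))
  member <- vapply(grs, function(g)
    IRanges::overlapsAny(loci, g), logical(length(loci)))
  member <- matrix(member, nrow = length(loci),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), n_loci = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_loci, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_totals") <- colSums(member)
  out
}

#' Extended overlap of a stringent DMR set against relaxed windows
#'
#' A row DMR counts as overlapping iff its interval intersects at least one
#' window with `p < relaxed_p` in the column comparison's window
#' statistics. The percentage uses the row-set size as denominator; an
#' empty row set reports 0 with `empty_row_set = TRUE`.
#'
#' @param row_dmrs a `dmr_set` (called at the stringent threshold).
#' @param column_stats a `window_stats` table with genome coordinates.
#' @param relaxed_p relaxed threshold (default 0.05).
#' @return list with `count`, `percent`, `n_rows`, `empty_row_set`.
#' @export
extended_overlap <- function(row_dmrs, column_stats, relaxed_p = 0.05) {
  if (nrow(row_dmrs) == 0L) {
    warning("empty row DMR set; percent reported as 0")
    return(list(count = 0L, percent = 0, n_rows = 0L,
                empty_row_set = TRUE))
  }
  sig <- column_stats[column_stats$p_value < relaxed_p, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(list(count = 0L, percent = 0, n_rows = nrow(row_dmrs),
                empty_row_set = FALSE))
  }
  hit <- IRanges::overlapsAny(as_granges0(row_dmrs), as_granges0(sig))
  list(count = sum(hit), percent = 100 * sum(hit) / nrow(row_dmrs),
       n_rows = nrow(row_dmrs), empty_row_set = FALSE)
}

#' Extended-overlap matrix across comparisons
#'
#' Rows are stringent DMR sets, columns the corresponding window-statistic
#' tables scored at `relaxed_p` (the Fig. 3-style row-wise report).
#'
#' @param dmr_sets named list of `dmr_set`s.
#' @param stats_list named list of `window_stats` tables (same names).
#' @param relaxed_p relaxed column threshold.
#' @return list of matrices `count` and `percent` (rows x columns).
#' @export
extended_overlap_matrix <- function(dmr_sets, stats_list,
                                    relaxed_p = 0.05) {
  stopifnot(length(dmr_sets) >= 1,
            all(names(dmr_sets) %in% names(stats_list)))
  n <- length(dmr_sets)
  cnt <- matrix(NA_real_, n, length(stats_list),
                dimnames = list(names(dmr_sets), names(stats_list)))
  pct <- cnt
  for (r in names(dmr_sets)) {
    for (cc in names(stats_list)) {
      ov <- suppressWarnings(
        extended_overlap(dmr_sets[[r]], stats_list[[cc]], relaxed_p))
      cnt[r, cc] <- ov$count
      pct[r, cc] <- ov$percent
    }
  }
  list(count = cnt, percent = pct)
}

#' Sliding-window Poisson scan for chromosomal DMR clusters
#'
#' Overlapping genomic windows of `scan_window_bp` advanced by `step_bp`
#' are scored by the number of DMR midpoints they contain. Each score gets
#' a Poisson upper-tail p value under the genome-wide DMR density
#' (`lambda = n_dmrs / genome_bp * scan_window_bp`), BH-corrected across
#' scan windows; windows with `q <= alpha` are merged into cluster
#' intervals.
#'
#' @param dmrs a `dmr_set` (or any interval data.frame).
#' @param genome a `genome_def`.
#' @param scan_window_bp scan window width (default 2 Mb).
#' @param step_bp step between window starts (default 500 kb).
#' @param alpha FDR level for cluster candidates (default 0.05).
#' @return data.frame of merged cluster intervals with `chrom`, `start`,
#'   `end`, `n_dmrs`, `min_q`; scan parameters in attribute `"scan"`.
#' @export
cluster_scan <- function(dmrs, genome, scan_window_bp = 2e6,
                         step_bp = 5e5, alpha = 0.05) {
  validate_genome(genome)
  if (step_bp <= 0 || scan_window_bp < step_bp) {
    stop("need scan_window_bp >= step_bp > 0")
  }
  gsize <- sum(genome$chrom_lengths)
  if (gsize <= 0) stop("zero-length genome")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_dmrs = integer(0),
                      min_q = numeric(0))
  attr(empty, "scan") <- list(scan_window_bp = scan_window_bp,
                              step_bp = step_bp, alpha = alpha,
                              note = "surrogate cluster scan")
  if (nrow(dmrs) == 0L) return(empty)
  mid <- (dmrs$start + dmrs$end) / 2
  lambda <- nrow(dmrs) / gsize * scan_window_bp

  wins <- do.call(rbind, lapply(genome$chrom_names, function(ch) {
    len <- genome$chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + scan_window_bp, len))
  }))
  wins$count <- vapply(seq_len(nrow(wins)), function(i) {
    sum(dmrs$chrom == wins$chrom[i] & mid >= wins$start[i] &
          mid < wins$end[i])
  }, numeric(1))
  wins$p <- ppois(wins$count - 1, lambda, lower.tail = FALSE)
  wins$q <- bh_fdr(wins$p)
  cand <- wins[wins$q <= alpha & wins$count > 0, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cand$chrom, IRanges::IRanges(cand$start + 1, cand$end)))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr))
  out$n_dmrs <- vapply(seq_len(nrow(out)), function(i) {
    sum(dmrs$chrom == out$chrom[i] & mid >= out$start[i] &
          mid < out$end[i])
  }, numeric(1))
  out$min_q <- vapply(seq_len(nrow(out)), function(i) {
    min(cand$q[cand$chrom == out$chrom[i] & cand$start < out$end[i] &
                 cand$end > out$start[i]])
  }, numeric(1))
  attr(out, "scan") <- attr(empty, "scan")
  out
}

#' Per-chromosome DMR positions and cluster boxes for plotting
#'
#' Deterministic table backing an ideogram-style figure of genome-wide DMR
#' locations.
#'
#' @param dmrs a `dmr_set`.
#' @param genome a `genome_def`.
#' @param clusters optional output of [cluster_scan()].
#' @return list with `positions` (chrom, midpoint, sorted), `chromosomes`
#'   (name, length) and `clusters` (clipped to chromosome bounds).
#' @export
chromosome_plot_data <- function(dmrs, genome, clusters = NULL) {
  validate_genome(genome)
  pos <- data.frame(chrom = dmrs$chrom,
                    midpoint = (dmrs$start + dmrs$end) / 2)
  pos <- pos[order(pos$chrom, pos$midpoint), , drop = FALSE]
  rownames(pos) <- NULL
  chroms <- data.frame(chrom = genome$chrom_names,
                       length = as.numeric(genome$chrom_lengths))
  if (!is.null(clusters) && nrow(clusters)) {
    clusters$start <- pmax(clusters$start, 0)
    clusters$end <- pmin(clusters$end,
                         genome$chrom_lengths[clusters$chrom])
  }
  list(positions = pos, chromosomes = chroms, clusters = clusters)
}
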