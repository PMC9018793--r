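# DMR calling: windows below the seed p threshold start a region; the
# region edges then absorb any window below the extension threshold lying
# within the allowed inter-edge gap, to a fixed point; touching regions are
# merged. Bridged (non-qualifying) windows between absorbed edges become
# members.

#' Call differential DNA methylation regions from window statistics
#'
#' Seeds are windows with `p < seed_p`. Each region iteratively absorbs any
#' window with `p < extend_p` whose inter-edge gap to the region is at most
#' `max_gap_bp` (so with 1-kb windows and a 1000-bp gap, exactly one
#' non-qualifying window may be bridged and becomes a member). Extension
#' never crosses chromosomes. Regions that touch or overlap after
#' extension are merged.
#'
#' @param stats a `window_stats` data.frame with `chrom`, `start`, `end`,
#'   `p_value` (and optionally `q_value`, `log2fc`), sorted by genome
#'   position.
#' @param seed_p seed threshold (default 1e-6; use 1e-4 for sparse designs
#'   such as the glyphosate-style comparisons).
#' @param extend_p extension threshold (default 0.1); must be `>= seed_p`.
#' @param max_gap_bp maximal inter-edge gap for absorption (default 1000).
#' @param genome optional `genome_def` for CpG counts per DMR.
#' @return a `dmr_set` data.frame: `dmr_id`, `chrom`, `start`, `end`,
#'   `n_windows`, `seed_window`, `p_value` (min member p), `q_value` and
#'   `log2fc` (of the most significant window), `cpg_count`,
#'   `cpg_density` (CpGs per 100 bp), plus a `member_windows` list-column
#'   of member window ordinals.
#' @export
call_dmrs <- function(stats, seed_p = 1e-6, extend_p = 0.1,
                      max_gap_bp = 1000, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end", "p_value") %in% names(stats)))
  if (seed_p > extend_p) stop("seed_p must be <= extend_p")
  if (max_gap_bp < 0) stop("max_gap_bp must be >= 0")
  if (any(unlist(tapply(stats$start, stats$chrom, is.unsorted)))) {
    stop("stats must be sorted by (chrom, start)")
  }

  rows <- list()
  for (ch in unique(stats$chrom)) {
    idx <- which(stats$chrom == ch)
    st <- stats[idx, , drop = FALSE]
    elig <- which(st$p_value < extend_p)
    if (!length(elig)) next
    # chain eligible windows: consecutive eligible windows link when the
    # bp gap between their interval edges is <= max_gap_bp
    gap <- st$start[elig[-1]] - st$end[elig[-length(elig)]]
    chain <- cumsum(c(1L, as.integer(gap > max_gap_bp)))
    for (cid in unique(chain)) {
      members_e <- elig[chain == cid]
      if (!any(st$p_value[members_e] < seed_p)) next
      span <- range(members_e)
      mem <- span[1]:span[2]  # includes bridged windows
      best <- mem[which.min(st$p_value[mem])]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch,
        start = st$start[span[1]],
        end = st$end[span[2]],
        n_windows = length(mem),
        seed_window = if ("window" %in% names(st)) st$window[best] else
          idx[best],
        p_value = st$p_value[best],
        q_value = if ("q_value" %in% names(st)) st$q_value[best] else NA_real_,
        log2fc = if ("log2fc" %in% names(st)) st$log2fc[best] else NA_real_,
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$member_windows <- I(list(
        if ("window" %in% names(st)) st$window[mem] else idx[mem]))
    }
  }
  if (!length(rows)) {
    out <- data.frame(dmr_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_windows = integer(0), seed_window = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      log2fc = numeric(0), cpg_count = integer(0),
                      cpg_density = numeric(0))
    out$member_windows <- I(list())
    class(out) <- c("dmr_set", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(dmr_id = sprintf("DMR%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(genome)) {
    cd <- cpg_density(genome, out$chrom, out$start, out$end)
    out$cpg_count <- cd$cpg_count
    out$cpg_density <- cd$cpg_density
  } else {
    out$cpg_count <- NA_integer_
    out$cpg_density <- NA_real_
  }
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' CpG count and density of genomic intervals
#'
#' Counts CpG positions in `[start, end)` and reports density per 100 bp.
#'
#' @param genome a `genome_def`.
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @return data.frame with `cpg_count` and `cpg_density`.
#' @export
cpg_density <- function(genome, chrom, start, end) {
  validate_genome(genome)
  stopifnot(all(end > start))
  if (any(start < 0) || any(end > genome$chrom_lengths[chrom])) {
    stop("interval outside chromosome bounds")
  }
  n <- count_cpgs(genome, chrom, start, end)
  data.frame(cpg_count = n, cpg_density = 100 * n / (end - start))
}

#' Export a DMR table with a stable schema
#'
#' Deterministic (chrom, start) ordering; member window ordinals are
#' serialized as a comma-separated column so the file round-trips.
#'
#' @param dmrs a `dmr_set`.
#' @param comparison label recorded in the `comparison` column.
#' @return plain data.frame ready for writing.
#' @export
dmr_table <- function(dmrs, comparison = "comparison") {
  df <- as.data.frame(dmrs)
  df$member_windows <- vapply(
    dmrs$member_windows, function(w) paste(w, collapse = ","), "")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$comparison <- rep(comparison, nrow(df))
  rownames(df) <- NULL
  df
}

#' Write / read DMRs as TSV (full attributes) and BED
#'
#' @param dmrs a `dmr_set`.
#' @param path output path.
#' @param comparison label for the TSV `comparison` column.
#' @return invisibly, `path`.
#' @export
write_dmrs <- function(dmrs, path, comparison = "comparison") {
  write.table(dmr_table(dmrs, comparison), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_dmrs
#' @export
read_dmrs <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  mw <- lapply(strsplit(as.character(df$member_windows), ","),
               function(x) as.integer(x[nzchar(x)]))
  df$member_windows <- I(mw)
  class(df) <- c("dmr_set", "data.frame")
  df
}

#' @rdname write_dmrs
#' @export
write_dmr_bed <- function(dmrs, path) {
  df <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$dmr_id,
                   score = round(-log10(pmax(dmrs$p_value, 1e-300)), 3))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
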