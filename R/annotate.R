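# Interval-to-gene association within a distance threshold (default 10 kb,
# capturing distal and proximal promoter regions).

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Associate genomic intervals with gene models within a distance
#'
#' A gene is associated with an interval iff the bp gap between the
#' interval and the gene body is at most `max_distance` (0 when they
#' overlap). Chromosome mismatch is a non-association, not an error.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally an id column (`dmr_id` or `window`).
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @param max_distance maximal gap in bp (default 10000).
#' @return data.frame with `interval` (row index into `intervals`), `id`,
#'   `gene_id`, `symbol`, `distance`, sorted by interval, then distance,
#'   then gene id.
#' @export
associate_genes <- function(intervals, genes, max_distance = 10000) {
  stopifnot(max_distance >= 0)
  id <- if ("dmr_id" %in% names(intervals)) intervals$dmr_id else
    if ("window" %in% names(intervals)) as.character(intervals$window) else
      as.character(seq_len(nrow(intervals)))
  empty <- data.frame(interval = integer(0), id = character(0),
                      gene_id = character(0), symbol = character(0),
                      distance = numeric(0))
  if (nrow(intervals) == 0L || nrow(genes) == 0L) return(empty)
  qi <- as_granges0(intervals)
  gi <- as_granges0(genes)
  # widen queries so findOverlaps catches gap == max_distance, then compute
  # the exact gap
  pad <- max_distance + 1
  wide <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(pmax(intervals$start + 1 - pad, 1),
                     intervals$end + pad))
  # disjoint seqlevels are a legitimate non-association, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(wide, gi, ignore.strand = TRUE))
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- suppressWarnings(
    GenomicRanges::distance(qi[q], gi[s], ignore.strand = TRUE))
  keep <- !is.na(d) & d <= max_distance
  out <- data.frame(interval = q[keep], id = id[q[keep]],
                    gene_id = genes$gene_id[s[keep]],
                    symbol = genes$symbol[s[keep]],
                    distance = as.numeric(d[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$interval, out$distance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count associated genes per functional category
#'
#' Distinct associated genes are tallied by the supplied category map
#' (e.g. generalised protein-class groups); unmapped genes fall into
#' `"unknown"`.
#'
#' @param associations output of [associate_genes()].
#' @param category_map data.frame with `gene_id` and `category`.
#' @return data.frame with `category` and `n_genes` (all map categories
#'   present, zero-filled), plus `"unknown"` when needed.
#' @export
gene_category_counts <- function(associations, category_map) {
  stopifnot(all(c("gene_id", "category") %in% names(category_map)))
  cats <- unique(c(category_map$category, "unknown"))
  genes <- unique(associations$gene_id)
  assigned <- category_map$category[match(genes, category_map$gene_id)]
  assigned[is.na(assigned)] <- "unknown"
  tab <- table(factor(assigned, levels = cats))
  data.frame(category = names(tab), n_genes = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
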