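#' Generate a synthetic genome definition
#'
#' Draws CpG positions on each chromosome as a homogeneous point process:
#' the number of CpG sites is Binomial(length, `cpg_rate`) and positions are
#' a uniform sample without replacement. Coordinates are 0-based.
#'
#' @param n_chroms number of chromosomes (>= 1).
#' @param chrom_length length in bp of each chromosome; recycled to
#'   `n_chroms`.
#' @param cpg_rate per-bp CpG probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param chrom_names optional chromosome names (default `chr1`, `chr2`, ...).
#' @return an object of class `genome_def` with fields `chrom_names`,
#'   `chrom_lengths` (named integer vector) and `cpg_positions` (named list
#'   of sorted 0-based positions).
#' @examples
#' g <- generate_genome(2, 1e5, cpg_rate = 0.01, seed = 7)
#' lengths(g$cpg_positions)
#' @export
generate_genome <- function(n_chroms = 1L, chrom_length = 1e6, cpg_rate = 0.01,
                            seed = 1L, chrom_names = NULL) {
  if (n_chroms < 1L) stop("n_chroms must be >= 1")
  chrom_length <- rep_len(as.double(chrom_length), n_chroms)
  if (any(chrom_length <= 0)) stop("chromosome lengths must be positive")
  if (cpg_rate < 0 || cpg_rate >= 1) stop("cpg_rate must be in [0, 1)")
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chroms))
  stopifnot(length(chrom_names) == n_chroms, !anyDuplicated(chrom_names))

  cpg <- with_seed(seed, {
    lapply(seq_len(n_chroms), function(i) {
      n <- rbinom(1L, size = chrom_length[i], prob = cpg_rate)
      if (n == 0L) integer(0) else sort(sample.int(chrom_length[i], n)) - 1L
    })
  })
  names(cpg) <- chrom_names
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = stats::setNames(chrom_length, chrom_names),
      cpg_positions = cpg
    ),
    class = "genome_def"
  )
}

#' @export
print.genome_def <- function(x, ...) {
  cat("genome_def:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp,",
      format(sum(lengths(x$cpg_positions)), big.mark = ","), "CpG sites\n")
  invisible(x)
}

validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_def"))
  for (ch in genome$chrom_names) {
    p <- genome$cpg_positions[[ch]]
    if (length(p) &&
        (is.unsorted(p, strictly = TRUE) || p[1] < 0 ||
         p[length(p)] >= genome$chrom_lengths[[ch]])) {
      stop("CpG positions on ", ch,
           " must be strictly increasing and within the chromosome")
    }
  }
  invisible(genome)
}

#' Write genome files (chrom.sizes and CpG BED)
#'
#' @param genome a `genome_def`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  validate_genome(genome)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- file.path(dir, "genome.chrom.sizes")
  write.table(
    data.frame(chrom = genome$chrom_names,
               length = as.integer(genome$chrom_lengths)),
    sizes, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  bed <- file.path(dir, "cpg_sites.bed")
  cp <- data.frame(
    chrom = rep(genome$chrom_names, lengths(genome$cpg_positions)),
    start = unlist(genome$cpg_positions, use.names = FALSE)
  )
  cp$end <- cp$start + 1L
  write.table(cp, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(sizes = sizes, cpg_bed = bed))
}

#' Generate synthetic gene models
#'
#' Places non-degenerate gene intervals uniformly on the genome, with
#' lengths drawn from a gamma distribution (mean `mean_length`).
#'
#' @param genome a `genome_def`.
#' @param n_genes number of genes.
#' @param mean_length mean gene length in bp.
#' @param seed integer RNG seed.
#' @return data.frame with `gene_id`, `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
generate_gene_models <- function(genome, n_genes = 100L, mean_length = 5000,
                                 seed = 1L) {
  validate_genome(genome)
  stopifnot(n_genes >= 1L, mean_length >= 1)
  with_seed(seed, {
    chrom <- sample(genome$chrom_names, n_genes, replace = TRUE,
                    prob = genome$chrom_lengths / sum(genome$chrom_lengths))
    len <- pmax(200, round(stats::rgamma(n_genes, shape = 2,
                                         scale = mean_length / 2)))
    clen <- genome$chrom_lengths[chrom]
    len <- pmin(len, clen - 1)
    start <- floor(runif(n_genes) * (clen - len))
    df <- data.frame(
      gene_id = sprintf("GENE%05d", seq_len(n_genes)),
      symbol = sprintf("Gm%d", seq_len(n_genes)),
      chrom = chrom,
      start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    df[order(df$chrom, df$start), , drop = FALSE]
  })
}

#' Write gene models as GFF3
#'
#' @param genes gene-model data.frame (see [generate_gene_models()]).
#' @param path output GFF3 path.
#' @return invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$Name <- genes$symbol
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 features of type `gene` (all features if none are typed `gene`) or
#' BED records are returned as a 0-based half-open gene table.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @return data.frame with `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene")) {
    gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
  }
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    if ("name" %in% names(mc)) as.character(mc$name) else
      sprintf("GENE%05d", seq_along(gr))
  sym <- if ("Name" %in% names(mc)) as.character(mc$Name) else id
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(
    gene_id = id,
    symbol = sym,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

# Count CpG sites falling in [start, end) on one chromosome. Vectorized over
# intervals.
count_cpgs <- function(genome, chrom, start, end) {
  n <- length(start)
  out <- integer(n)
  for (ch in unique(chrom)) {
    pos <- genome$cpg_positions[[ch]]
    i <- which(chrom == ch)
    if (is.null(pos)) stop("unknown chromosome: ", ch)
    if (length(pos) == 0L) next
    out[i] <- findInterval(end[i] - 1L, pos) - findInterval(start[i] - 1L, pos)
  }
  out
}
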