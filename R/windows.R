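#' Tile a genome into fixed windows
#'
#' Each chromosome is tiled with consecutive windows `[0, w)`, `[w, 2w)`,
#' ...; a terminal partial window is retained. Window ordinals are row
#' numbers of the returned grid, in (chrom, start) order.
#'
#' @param genome a `genome_def`.
#' @param window_size window width in bp (default 1000, the DMR unit).
#' @return a `window_grid` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `cpg_count`, plus attributes `window_size`,
#'   `chrom_lengths` and `chrom_offsets` (0-based row offset of each
#'   chromosome's first window).
#' @export
make_windows <- function(genome, window_size = 1000L) {
  validate_genome(genome)
  if (window_size < 1) stop("window_size must be >= 1")
  window_size <- as.integer(window_size)
  pieces <- lapply(genome$chrom_names, function(ch) {
    len <- genome$chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + window_size, len)),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  grid$cpg_count <- count_cpgs(genome, grid$chrom, grid$start, grid$end)
  nper <- vapply(pieces, nrow, integer(1))
  attr(grid, "window_size") <- window_size
  attr(grid, "chrom_lengths") <- genome$chrom_lengths
  attr(grid, "chrom_offsets") <- stats::setNames(
    cumsum(c(0L, nper[-length(nper)])), genome$chrom_names)
  attr(grid, "n_windows_per_chrom") <- stats::setNames(nper,
                                                       genome$chrom_names)
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Window ordinal containing a genomic position
#'
#' @param grid a `window_grid`.
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return 1-based window ordinal(s) into `grid`.
#' @export
window_of <- function(grid, chrom, pos) {
  ws <- attr(grid, "window_size")
  off <- attr(grid, "chrom_offsets")
  nper <- attr(grid, "n_windows_per_chrom")
  if (any(!chrom %in% names(off))) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[!chrom %in% names(off)]), collapse = ", "))
  }
  idx <- pos %/% ws
  if (any(idx < 0 | idx >= nper[chrom])) stop("position outside chromosome")
  as.integer(off[chrom] + idx + 1L)
}

#' Construct a count matrix container
#'
#' @param counts windows x samples matrix of non-negative integers, with
#'   column names as sample ids.
#' @param library_sizes total counted fragments per sample; defaults to
#'   column sums (exact under single-assignment counting).
#' @param windows optional window ordinals for the rows (defaults to row
#'   numbers of the full grid).
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, library_sizes = colSums(counts),
                         windows = seq_len(nrow(counts))) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  }
  stopifnot(length(library_sizes) == ncol(counts),
            length(windows) == nrow(counts))
  structure(
    list(counts = counts,
         library_sizes = stats::setNames(as.double(library_sizes),
                                         colnames(counts)),
         sample_ids = colnames(counts),
         windows = as.integer(windows)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples; median library", stats::median(x$library_sizes), "\n")
  invisible(x)
}

#' Count aligned fragments per window per sample
#'
#' Fragments shorter than `extend_to` are first extended 3' (by strand when
#' present, else toward increasing coordinates) to `extend_to` bp, clipped
#' at chromosome ends. In `overlap` mode a fragment increments every window
#' it intersects; in `containment` mode only the window containing its
#' start, which makes counting single-assignment and exactly invertible.
#'
#' @param reads named list (one element per sample) of data.frames with
#'   `chrom`, `start`, `end` (0-based half-open) and optionally `strand`.
#' @param grid a `window_grid`.
#' @param mode `"overlap"` (default) or `"containment"`.
#' @param extend_to target fragment length in bp; 0 disables extension.
#' @return a `count_matrix`; `library_sizes` are fragments per sample.
#' @export
count_reads <- function(reads, grid, mode = c("overlap", "containment"),
                        extend_to = 250L) {
  mode <- match.arg(mode)
  if (extend_to < 0) stop("extend_to must be >= 0")
  ws <- attr(grid, "window_size")
  off <- attr(grid, "chrom_offsets")
  nper <- attr(grid, "n_windows_per_chrom")
  clen <- attr(grid, "chrom_lengths")
  nw <- nrow(grid)
  if (is.null(names(reads))) names(reads) <- paste0("S", seq_along(reads))

  counts <- matrix(0L, nw, length(reads),
                   dimnames = list(NULL, names(reads)))
  libs <- numeric(length(reads))
  for (s in seq_along(reads)) {
    r <- reads[[s]]
    libs[s] <- nrow(r)
    if (nrow(r) == 0L) next
    bad <- !r$chrom %in% names(off)
    if (any(bad)) {
      stop("sample ", names(reads)[s], ": reads on unknown chromosome(s): ",
           paste(utils::head(unique(r$chrom[bad]), 5), collapse = ", "))
    }
    start <- as.double(r$start)
    end <- as.double(r$end)
    if (any(start < 0 | end <= start | end > clen[r$chrom])) {
      stop("sample ", names(reads)[s], ": read outside chromosome bounds")
    }
    if (extend_to > 0) {
      strand <- if ("strand" %in% names(r)) as.character(r$strand) else
        rep("+", nrow(r))
      short <- (end - start) < extend_to
      fwd <- short & strand != "-"
      rev <- short & strand == "-"
      end[fwd] <- pmin(start[fwd] + extend_to, clen[r$chrom[fwd]])
      start[rev] <- pmax(end[rev] - extend_to, 0)
    }
    first <- off[r$chrom] + start %/% ws
    if (mode == "containment") {
      counts[, s] <- counts[, s] + tabulate(first + 1L, nbins = nw)
    } else {
      last <- off[r$chrom] + pmin((end - 1) %/% ws, nper[r$chrom] - 1)
      span <- as.integer(last - first + 1L)
      idx <- rep(as.integer(first), span) + sequence(span) - 1L
      counts[, s] <- counts[, s] + tabulate(idx + 1L, nbins = nw)
    }
  }
  count_matrix(counts, library_sizes = libs)
}

#' RPKM normalization of a window count matrix
#'
#' `rpkm[w, s] = counts[w, s] * 1e9 / (window_length_bp[w] *
#' library_size[s])`. Terminal partial windows use their true length.
#'
#' @param counts a `count_matrix`.
#' @param grid the `window_grid` the counts were made on (rows matched via
#'   the count matrix's `windows` field).
#' @return numeric matrix of RPKM values, same shape as the counts.
#' @export
rpkm <- function(counts, grid) {
  stopifnot(inherits(counts, "count_matrix"))
  zero <- counts$library_sizes <= 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(counts$sample_ids[zero], collapse = ", "))
  }
  len <- grid$end[counts$windows] - grid$start[counts$windows]
  out <- counts$counts * 1e9 /
    outer(as.double(len), unname(as.double(counts$library_sizes)))
  dimnames(out) <- list(NULL, counts$sample_ids)
  out
}

#' Drop windows with low total coverage
#'
#' Windows whose total count across samples is below `min_row_sum` are
#' removed; the retained rows keep their original window ordinals so later
#' stages can map back to genome coordinates.
#'
#' @param counts a `count_matrix`.
#' @param min_row_sum minimal total count across samples to keep a window.
#' @return a `count_matrix` restricted to the kept windows (library sizes
#'   unchanged).
#' @export
filter_low_coverage <- function(counts, min_row_sum = 10) {
  stopifnot(inherits(counts, "count_matrix"), min_row_sum >= 0)
  keep <- rowSums(counts$counts) >= min_row_sum
  count_matrix(counts$counts[keep, , drop = FALSE],
               library_sizes = counts$library_sizes,
               windows = counts$windows[keep])
}

#' Write / read a window count matrix as TSV
#'
#' Columns: `window_id`, `chrom`, `start`, `end`, then one column per
#' sample. Library sizes are carried in a `#library_sizes:` header line.
#'
#' @param counts a `count_matrix`.
#' @param grid the `window_grid` for coordinates.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_counts <- function(counts, grid, path) {
  w <- counts$windows
  df <- data.frame(window_id = w, chrom = grid$chrom[w],
                   start = grid$start[w], end = grid$end[w])
  df <- cbind(df, as.data.frame(counts$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes: ",
                    paste(counts$sample_ids, counts$library_sizes,
                          sep = "=", collapse = ",")), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  libs <- NULL
  if (startsWith(first, "#library_sizes:")) {
    kv <- strsplit(trimws(sub("^#library_sizes:", "", first)), ",")[[1]]
    parts <- strsplit(kv, "=")
    libs <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                            vapply(parts, `[`, "", 1L))
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("window_id", "chrom", "start", "end")
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  if (is.null(libs)) libs <- colSums(m)
  count_matrix(m, library_sizes = libs[colnames(m)],
               windows = df$window_id)
}

#' Write / read per-sample aligned fragments as BED6
#'
#' One BED6 file per sample: `chrom start end name score strand`.
#'
#' @param reads named list of read data.frames (see [count_reads()]).
#' @param dir output directory.
#' @return invisibly, named vector of file paths.
#' @export
write_reads_bed <- function(reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(reads)) {
    r <- reads[[s]]
    path <- file.path(dir, paste0(s, ".bed"))
    strand <- if ("strand" %in% names(r)) r$strand else rep("+", nrow(r))
    df <- data.frame(r$chrom, r$start, r$end,
                     name = if (nrow(r)) paste0("frag", seq_len(nrow(r)))
                     else character(0),
                     score = if (nrow(r)) 0L else integer(0),
                     strand = strand)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths[s] <- path
  }
  invisible(paths)
}

#' @param path a BED file of aligned fragments.
#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  out$strand <- if (ncol(df) >= 6) df[[6]] else "+"
  out
}

#' Read aligned fragments from BED or BAM/SAM
#'
#' BAM/SAM requires the Rsamtools package; only mapped primary alignments
#' at or above `min_mapq` are returned.
#'
#' @param path `.bed`, `.bam` or `.sam` file.
#' @param min_mapq minimal mapping quality for BAM/SAM records.
#' @return a read data.frame (`chrom`, `start`, `end`, `strand`).
#' @export
read_alignments <- function(path, min_mapq = 0L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    return(read_reads_bed(path))
  }
  if (!ext %in% c("bam", "sam")) stop("unsupported alignment format: ", ext)
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM/SAM requires the Rsamtools package")
  }
  if (ext == "sam") {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(
    flag = flag, mapqFilter = min_mapq,
    what = c("rname", "pos", "qwidth", "strand"))
  b <- Rsamtools::scanBam(path, param = prm)[[1]]
  keep <- !is.na(b$pos)
  data.frame(chrom = as.character(b$rname)[keep],
             start = b$pos[keep] - 1L,
             end = b$pos[keep] - 1L + b$qwidth[keep],
             strand = as.character(b$strand)[keep],
             stringsAsFactors = FALSE)
}
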