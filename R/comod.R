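# Coexpression-style module detection on methylation windows: unsigned
# correlation adjacency raised to a soft power, topological overlap,
# average-linkage clustering with a static height cut, module eigengenes,
# eigengene-correlation merging, and Pearson module-trait correlation with
# Student-t p values.

.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue")

module_labels_for <- function(k) {
  if (k <= length(.module_palette)) {
    .module_palette[seq_len(k)]
  } else {
    c(.module_palette, paste0("module", seq_len(k - length(.module_palette))))
  }
}

#' Select top windows by mean RPKM (or total depth)
#'
#' Windows are ranked by the mean RPKM across samples (default) or by the
#' total raw depth; ties break toward the lower genome ordinal. Used to
#' cap the window set entering module detection.
#'
#' @param mat windows x samples matrix (RPKM for `"mean_rpkm"`, raw counts
#'   for `"total_depth"`).
#' @param n_top number of windows to keep (1..nrow).
#' @param statistic ranking statistic.
#' @return integer row indices of the selected windows, in rank order.
#' @export
select_top_windows <- function(mat, n_top,
                               statistic = c("mean_rpkm", "total_depth")) {
  statistic <- match.arg(statistic)
  if (n_top <= 0) stop("n_top must be positive")
  if (n_top > nrow(mat)) stop("n_top exceeds the number of windows")
  score <- if (statistic == "mean_rpkm") rowMeans(mat) else rowSums(mat)
  order(-score, seq_len(nrow(mat)))[seq_len(n_top)]
}

#' Unsigned correlation adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power` over samples (Pearson); the diagonal is
#' 1 and zero-variance windows correlate 0 by convention.
#'
#' @param profiles windows x samples numeric matrix (>= 3 samples).
#' @param power soft-thresholding power (> 0; default 4).
#' @return symmetric adjacency matrix with unit diagonal.
#' @export
adjacency <- function(profiles, power = 4) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3) stop("adjacency needs at least 3 samples")
  if (power <= 0) stop("power must be positive")
  r <- suppressWarnings(cor(t(profiles)))
  r[!is.finite(r)] <- 0
  a <- abs(r)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivities `k_i = sum_{u != i} a_iu`, the shared-neighbor sum taken
#' over `u != i, j`; `TOM_ii = 1`.
#'
#' @param a symmetric adjacency matrix, entries in `[0, 1]`, unit diagonal.
#' @return the TOM matrix.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a), tol = 1e-8)) {
    stop("adjacency must be symmetric")
  }
  if (any(a < -1e-12 | a > 1 + 1e-12)) stop("adjacency entries must be in [0, 1]")
  k <- rowSums(a) - diag(a)
  shared <- a %*% a - 2 * a          # sum over u != i, j (unit diagonal)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  tom
}

#' @rdname tom_similarity
#' @export
tom_dissimilarity <- function(a) 1 - tom_similarity(a)

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' Cuts the average-linkage tree at `cut_height_frac` times the maximum
#' merge height (a static cut standing in for dynamic tree cut); clusters
#' smaller than `min_module_size` are relabeled `"grey"`; surviving
#' modules get color labels by decreasing size.
#'
#' @param diss square dissimilarity matrix (e.g. `1 - TOM`).
#' @param min_module_size minimal module size (default 30).
#' @param cut_height_frac static cut as a fraction of the maximum merge
#'   height (default 0.99).
#' @return a `module_assignment` list: `labels` (per window), `sizes`
#'   (non-grey), `hclust` (the tree).
#' @export
detect_modules <- function(diss, min_module_size = 30,
                           cut_height_frac = 0.99) {
  diss <- as.matrix(diss)
  stopifnot(nrow(diss) == ncol(diss), min_module_size >= 2)
  hc <- hclust(as.dist(diss), method = "average")
  hmax <- max(hc$height)
  cl <- if (hmax <= 0) {
    rep(1L, nrow(diss))  # degenerate: all identical
  } else {
    cutree(hc, h = cut_height_frac * hmax)
  }
  sz <- table(cl)
  big <- names(sz)[sz >= min_module_size]
  ord <- big[order(-sz[big], as.integer(big))]
  labels <- rep("grey", nrow(diss))
  cols <- module_labels_for(length(ord))
  for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- cols[i]
  structure(list(labels = labels,
                 sizes = stats::setNames(as.integer(sz[ord]), cols),
                 hclust = hc),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment:", length(x$sizes), "module(s);",
      sum(x$labels == "grey"), "grey of", length(x$labels), "windows\n")
  invisible(x)
}

#' Module eigengenes
#'
#' The first principal component of each module's standardized window
#' profiles, oriented so that its correlation with the member-mean profile
#' is non-negative, and scaled to unit variance.
#'
#' @param profiles windows x samples matrix.
#' @param labels per-window module labels (`"grey"` ignored).
#' @return samples x modules matrix of eigengenes.
#' @export
module_eigengene <- function(profiles, labels) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("eigengenes need more than one sample")
  stopifnot(length(labels) == nrow(profiles))
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey modules")
  eg <- matrix(NA_real_, ncol(profiles), length(mods),
               dimnames = list(colnames(profiles), mods))
  for (m in mods) {
    x <- profiles[labels == m, , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[!is.finite(xs)] <- 0
    v <- svd(xs, nu = 0, nv = 1)$v[, 1]
    ref <- colMeans(xs)
    if (sd(ref) > 0 && sd(v) > 0 && cor(v, ref) < 0) v <- -v
    eg[, m] <- if (sd(v) > 0) as.numeric(scale(v)) else v
  }
  eg
}

#' Merge modules with close eigengenes
#'
#' Modules whose eigengene correlation distance `1 - r` falls below
#' `merge_cut_height` are merged (single linkage over eigengene
#' dissimilarity), eigengenes are recomputed, and the step iterates to a
#' fixed point. Labels are reassigned by decreasing merged size.
#'
#' @param profiles windows x samples matrix.
#' @param labels per-window module labels.
#' @param merge_cut_height merge threshold on `1 - r` (default 0.25).
#' @return updated label vector (attribute `"eigengenes"` carries the
#'   final eigengene matrix).
#' @export
merge_close_modules <- function(profiles, labels, merge_cut_height = 0.25) {
  stopifnot(merge_cut_height > 0, merge_cut_height < 1)
  labels <- as.character(labels)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    eg <- module_eigengene(profiles, labels)[, mods, drop = FALSE]
    d <- 1 - cor(eg)
    hc <- hclust(as.dist(d), method = "single")
    grp <- cutree(hc, h = merge_cut_height * (1 - 1e-9))
    if (max(grp) == length(mods)) break  # nothing merged: fixed point
    merged <- labels
    for (g in unique(grp)) {
      members <- mods[grp == g]
      merged[labels %in% members] <- members[1]
    }
    # relabel by decreasing size
    sz <- sort(table(merged[merged != "grey"]), decreasing = TRUE)
    cols <- module_labels_for(length(sz))
    relab <- stats::setNames(cols, names(sz))
    labels <- ifelse(merged == "grey", "grey", relab[merged])
  }
  attr(labels, "eigengenes") <- if (length(setdiff(unique(labels), "grey")))
    module_eigengene(profiles, labels) else NULL
  labels
}

#' Student-t p value for a Pearson correlation
#'
#' `p = 2 P(T_{n-2} >= |r| sqrt(n-2) / sqrt(1-r^2))`; `|r| = 1` gives 0.
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @param n number of samples (>= 3).
#' @return two-sided p value(s).
#' @export
cor_pvalue_student <- function(r, n) {
  stopifnot(n >= 3, all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  p <- r  # preserve dim/dimnames
  rc <- pmin(1, pmax(-1, r))
  p[] <- ifelse(abs(rc) >= 1, 0,
                2 * pt(abs(rc) * sqrt(n - 2) / sqrt(1 - rc^2), df = n - 2,
                       lower.tail = FALSE))
  p
}

#' Module-trait Pearson correlations with Student p values
#'
#' @param eigengenes samples x modules matrix.
#' @param traits samples x traits numeric matrix or data.frame (binary
#'   indicators allowed). Zero-variance traits give `NA` with a warning.
#' @return a `module_trait_corr` list: matrices `r` and `p`
#'   (modules x traits) and `n` samples.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  eigengenes <- as.matrix(eigengenes)
  traits <- as.matrix(as.data.frame(traits))
  storage.mode(traits) <- "double"
  n <- nrow(eigengenes)
  stopifnot(nrow(traits) == n, n >= 3)
  novar <- apply(traits, 2L, sd) == 0
  if (any(novar)) {
    warning("zero-variance trait(s): ",
            paste(colnames(traits)[novar], collapse = ", "),
            "; correlation reported as NA")
  }
  r <- suppressWarnings(cor(eigengenes, traits))  # modules x traits
  p <- cor_pvalue_student(r, n)
  p[is.na(r)] <- NA_real_
  structure(list(r = r, p = p, n = n), class = "module_trait_corr")
}

#' @export
print.module_trait_corr <- function(x, ...) {
  cat("module_trait_corr:", nrow(x$r), "module(s) x", ncol(x$r),
      "trait(s), n =", x$n, "\n")
  invisible(x)
}

#' One-call module pipeline on a profile matrix
#'
#' Adjacency -> TOM dissimilarity -> static-cut average-linkage modules ->
#' eigengene merge. Inputs larger than `max_block_size` windows are
#' rejected (reduce `n_top` upstream); block splitting is out of scope.
#'
#' @param profiles windows x samples matrix (e.g. top RPKM windows).
#' @param power soft power (default 4).
#' @param min_module_size minimal module size (default 30).
#' @param merge_cut_height eigengene merge threshold (default 0.25).
#' @param cut_height_frac static tree-cut fraction (default 0.99).
#' @param max_block_size hard cap on windows per run (default 15000).
#' @return list with `labels`, `eigengenes`, `assignment` (pre-merge), and
#'   the `tom` dissimilarity.
#' @export
detect_methylation_modules <- function(profiles, power = 4,
                                       min_module_size = 30,
                                       merge_cut_height = 0.25,
                                       cut_height_frac = 0.99,
                                       max_block_size = 15000) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) > max_block_size) {
    stop("profile block of ", nrow(profiles), " windows exceeds ",
         max_block_size, "; select fewer top windows")
  }
  a <- adjacency(profiles, power = power)
  diss <- 1 - tom_similarity(a)
  asg <- detect_modules(diss, min_module_size = min_module_size,
                        cut_height_frac = cut_height_frac)
  labels <- if (length(asg$sizes)) {
    merge_close_modules(profiles, asg$labels,
                        merge_cut_height = merge_cut_height)
  } else {
    asg$labels
  }
  eg <- attr(labels, "eigengenes")
  list(labels = as.character(labels), eigengenes = eg,
       assignment = asg, tom_dissimilarity = diss)
}
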