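# Two-group negative-binomial exact test on genomic windows, in the edgeR
# tradition: condition on the window total and sum the probabilities of all
# splits no more likely than the observed one. Library sizes are equalized
# upstream by deterministic scaling to the geometric-mean library size.

#' Equalize library sizes by deterministic scaling
#'
#' Scales every sample's counts to the geometric-mean library size and
#' rounds half-even, giving integer pseudo-counts on a common scale.
#'
#' @param counts a `count_matrix`.
#' @return a list with `counts` (integer matrix), `common_lib` (the
#'   geometric-mean library size) and `windows`.
#' @export
equalize_libraries <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  libs <- counts$library_sizes
  if (any(libs <= 0)) {
    stop("zero library size for sample(s): ",
         paste(counts$sample_ids[libs <= 0], collapse = ", "))
  }
  common <- exp(mean(log(libs)))
  scaled <- sweep(counts$counts, 2L, common / libs, `*`)
  list(counts = round(scaled), common_lib = common,
       windows = counts$windows)
}

#' Conditional NB exact test for one window
#'
#' Given equalized group sums `sum_a`, `sum_b` over `n_a` and `n_b`
#' samples, conditions on `T = sum_a + sum_b`. The group sums are modeled
#' as `NB(n_a * mu, phi / n_a)` vs `NB(n_b * mu, phi / n_b)` with
#' `mu = T / (n_a + n_b)`; the two-sided p value sums the conditional
#' probabilities of all splits whose probability does not exceed the
#' observed one (ties included). `phi = 0` reduces to the conditional
#' binomial test. `T = 0` returns `p = 1` by convention.
#'
#' @param sum_a,sum_b non-negative group total counts (equal libraries).
#' @param n_a,n_b samples per group.
#' @param phi common NB dispersion (>= 0).
#' @return two-sided p value in `[0, 1]`.
#' @export
exact_test_window <- function(sum_a, sum_b, n_a, n_b, phi = 0) {
  if (sum_a < 0 || sum_b < 0) stop("group sums must be non-negative")
  if (phi < 0) stop("phi must be >= 0")
  stopifnot(n_a >= 1, n_b >= 1)
  tot <- sum_a + sum_b
  if (tot == 0) return(1)
  pmf <- split_pmf(tot, n_a, n_b, phi)
  conditional_p(pmf, sum_a + 1L)
}

# Unnormalized conditional pmf of sum_a over splits 0..tot.
split_pmf <- function(tot, n_a, n_b, phi) {
  k <- 0:tot
  mu <- tot / (n_a + n_b)
  if (phi == 0) {
    lp <- dpois(k, n_a * mu, log = TRUE) +
      dpois(tot - k, n_b * mu, log = TRUE)
  } else {
    lp <- dnbinom(k, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      dnbinom(tot - k, size = n_b / phi, mu = n_b * mu, log = TRUE)
  }
  exp(lp - max(lp))
}

# Two-sided "no more likely than observed" p from an unnormalized pmf and
# the 1-based index of the observed split. A small relative tolerance keeps
# numerically tied outcomes inside the rejection set.
conditional_p <- function(pmf, obs_idx) {
  thr <- pmf[obs_idx] * (1 + 1e-10)
  min(1, sum(pmf[pmf <= thr]) / sum(pmf))
}

#' Common NB dispersion estimate for a two-group count matrix
#'
#' `moments`: after library equalization, phi is the pooled
#' `(variance - mean) / mean^2` across windows, floored at zero.
#' `grid_cml`: phi maximizing the summed conditional NB log-likelihood
#' (given each window's within-group total) over a 61-point log-spaced grid
#' on `[1e-4, 10]`; requires replication in at least one group.
#'
#' @param counts a `count_matrix`.
#' @param group_a,group_b disjoint sample-id vectors.
#' @param method `"grid_cml"` (default) or `"moments"`.
#' @return a `dispersion_estimate` list: `phi`, `method`, `n_a`, `n_b`,
#'   `common_lib`.
#' @export
estimate_dispersion <- function(counts, group_a, group_b,
                                method = c("grid_cml", "moments")) {
  method <- match.arg(method)
  stopifnot(length(group_a) >= 1, length(group_b) >= 1,
            !length(intersect(group_a, group_b)))
  eq <- equalize_libraries(counts)
  ya <- eq$counts[, group_a, drop = FALSE]
  yb <- eq$counts[, group_b, drop = FALSE]
  phi <- if (method == "moments") {
    moments_phi(ya, yb)
  } else {
    if (ncol(ya) < 2 && ncol(yb) < 2) {
      stop("grid_cml needs replication in at least one group")
    }
    grid_cml_phi(list(ya, yb))
  }
  structure(list(phi = phi, method = method,
                 n_a = length(group_a), n_b = length(group_b),
                 common_lib = eq$common_lib),
            class = "dispersion_estimate")
}

moments_phi <- function(ya, yb) {
  num <- 0
  den <- 0
  for (y in list(ya, yb)) {
    if (ncol(y) < 2) next
    m <- rowMeans(y)
    v <- apply(y, 1L, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

# Summed conditional NB log-likelihood over a phi grid (counts rounded to
# integers; equal libraries assumed). For one group of n samples with row
# total z and size r = 1/phi per sample:
#   l = sum_i lgamma(y_i + r) - n * lgamma(r)
#       - [lgamma(z + n r) - lgamma(n r)]   (+ terms constant in phi)
grid_cml_phi <- function(groups, grid = 10^seq(-4, 1, length.out = 61)) {
  ll <- vapply(grid, function(phi) {
    r <- 1 / phi
    tot <- 0
    for (y in groups) {
      n <- ncol(y)
      if (n < 2) next
      z <- rowSums(y)
      tot <- tot + sum(lgamma(y + r)) - length(y) * lgamma(r) -
        sum(lgamma(z + n * r)) + nrow(y) * lgamma(n * r)
    }
    tot
  }, numeric(1))
  grid[which.max(ll)]
}

#' Log2 fold change between normalized group totals
#'
#' `log2(((sum_a + prior) / lib_a) / ((sum_b + prior) / lib_b))`, with a
#' prior count added to each group to damp zero totals.
#'
#' @param sum_a,sum_b group total counts.
#' @param lib_a,lib_b group total library sizes (> 0).
#' @param prior prior count per group (>= 0; default 0.5).
#' @return log2 fold change (A relative to B).
#' @export
logfc <- function(sum_a, sum_b, lib_a, lib_b, prior = 0.5) {
  stopifnot(all(lib_a > 0), all(lib_b > 0), prior >= 0)
  if (any(sum_a + prior == 0) || any(sum_b + prior == 0)) {
    stop("zero totals with zero prior leave the fold change undefined")
  }
  log2(((sum_a + prior) / lib_a) / ((sum_b + prior) / lib_b))
}

#' Benjamini-Hochberg q values
#'
#' Step-up false discovery rate adjustment (`stats::p.adjust`, method
#' `"BH"`) with input validation.
#'
#' @param p_values numeric p values in `[0, 1]`.
#' @return q values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-window differential methylation statistics
#'
#' Equalizes library sizes, runs the conditional NB exact test on every
#' window (caching the conditional distribution by window total), computes
#' log2 fold changes and BH q values. The common dispersion is either a
#' number or estimated by [estimate_dispersion()].
#'
#' @param counts a `count_matrix` (typically coverage-filtered).
#' @param group_a,group_b disjoint sample-id vectors present in the counts.
#' @param dispersion `"grid_cml"`, `"moments"`, or a non-negative number.
#' @param prior prior count per group for the fold change.
#' @param grid optional `window_grid`; adds `chrom`/`start`/`end` columns.
#' @return a `window_stats` data.frame: `window`, (`chrom`, `start`,
#'   `end`,) `mean_a`, `mean_b`, `log2fc`, `p_value`, `q_value`, with the
#'   dispersion used in attribute `"phi"`.
#' @export
test_all_windows <- function(counts, group_a, group_b,
                             dispersion = "grid_cml", prior = 0.5,
                             grid = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            all(c(group_a, group_b) %in% counts$sample_ids),
            !length(intersect(group_a, group_b)))
  phi <- if (is.numeric(dispersion)) {
    if (dispersion < 0) stop("dispersion must be >= 0")
    dispersion
  } else {
    estimate_dispersion(counts, group_a, group_b, method = dispersion)$phi
  }
  eq <- equalize_libraries(counts)
  ya <- eq$counts[, group_a, drop = FALSE]
  yb <- eq$counts[, group_b, drop = FALSE]
  na <- ncol(ya)
  nb <- ncol(yb)
  sa <- rowSums(ya)
  sb <- rowSums(yb)
  tot <- sa + sb

  p <- numeric(length(tot))
  for (tt in unique(tot)) {
    i <- which(tot == tt)
    if (tt == 0) {
      p[i] <- 1
      next
    }
    pmf <- split_pmf(tt, na, nb, phi)
    sp <- sort(pmf)
    cs <- cumsum(sp)
    norm <- cs[length(cs)]
    obs <- pmf[sa[i] + 1L]
    idx <- findInterval(obs * (1 + 1e-10), sp)
    p[i] <- pmin(1, cs[idx] / norm)
  }

  out <- data.frame(window = counts$windows)
  if (!is.null(grid)) {
    out$chrom <- grid$chrom[counts$windows]
    out$start <- grid$start[counts$windows]
    out$end <- grid$end[counts$windows]
  }
  out$mean_a <- sa / na
  out$mean_b <- sb / nb
  out$log2fc <- logfc(sa, sb, na * eq$common_lib, nb * eq$common_lib,
                      prior = prior)
  out$p_value <- p
  out$q_value <- bh_fdr(p)
  attr(out, "phi") <- phi
  attr(out, "groups") <- list(a = group_a, b = group_b)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Write / read a window statistics table as TSV
#'
#' @param stats a `window_stats` data.frame with genome coordinates.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_window_stats <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  class(out) <- c("window_stats", "data.frame")
  out
}
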