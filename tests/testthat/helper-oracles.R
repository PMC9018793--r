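# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive: enumeration and
# repeated-scan fixed points, kept separate from the package's own
# algorithms.

# window-statistics table on a regular 1-kb grid (single or multi chrom)
stats_df <- function(p, chrom = "chr1", window_size = 1000,
                     last_end = NULL) {
  n <- length(p)
  chrom <- rep_len(chrom, n)
  start <- numeric(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- (seq_along(i) - 1) * window_size
  }
  end <- start + window_size
  if (!is.null(last_end)) end[n] <- last_end
  data.frame(chrom = chrom, start = start, end = end,
             window = seq_len(n), p_value = p)
}

# Brute-force DMR caller: grow every seed region by exhaustive repeated
# absorption of eligible windows within the gap, then merge touching
# regions; returns per-region member window sets.
brute_dmrs <- function(st, seed_p, extend_p, max_gap) {
  regions <- data.frame(
    chrom = st$chrom, start = st$start, end = st$end
  )[st$p_value < seed_p, , drop = FALSE]
  if (!nrow(regions)) return(list())
  elig <- which(st$p_value < extend_p)
  repeat {
    before <- paste(regions$chrom, regions$start, regions$end,
                    collapse = ";")
    for (r in seq_len(nrow(regions))) {
      for (j in elig) {
        if (st$chrom[j] != regions$chrom[r]) next
        if (st$start[j] >= regions$start[r] &&
            st$end[j] <= regions$end[r]) next
        gap <- max(st$start[j] - regions$end[r],
                   regions$start[r] - st$end[j])
        if (gap <= max_gap) {
          regions$start[r] <- min(regions$start[r], st$start[j])
          regions$end[r] <- max(regions$end[r], st$end[j])
        }
      }
    }
    # merge touching/overlapping regions per chromosome
    regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
    keep <- regions[1, , drop = FALSE]
    for (r in seq_len(nrow(regions))[-1]) {
      last <- nrow(keep)
      if (regions$chrom[r] == keep$chrom[last] &&
          regions$start[r] <= keep$end[last]) {
        keep$end[last] <- max(keep$end[last], regions$end[r])
      } else {
        keep <- rbind(keep, regions[r, , drop = FALSE])
      }
    }
    regions <- keep
    if (identical(before, paste(regions$chrom, regions$start, regions$end,
                                collapse = ";"))) {
      break
    }
  }
  lapply(seq_len(nrow(regions)), function(r) {
    which(st$chrom == regions$chrom[r] & st$start >= regions$start[r] &
            st$end <= regions$end[r])
  })
}

# two-sided conditional binomial exact test (enumeration oracle)
binom_exact_p <- function(k, tot, n_a, n_b) {
  if (tot == 0) return(1)
  pr <- dbinom(0:tot, tot, n_a / (n_a + n_b))
  min(1, sum(pr[pr <= pr[k + 1] * (1 + 1e-10)]))
}

# two-sided Fisher p by direct choose() enumeration (independent of dhyper)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1)
  pr <- exp(logp)
  obs <- pr[match(a, k)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# brute-force TOM by direct triple summation
tom_oracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sh <- 0
    for (u in seq_len(n)) if (u != i && u != j) sh <- sh + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (sh + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# brute-force interval/gene association by all-pairs gap computation
assoc_oracle <- function(intervals, genes, max_distance) {
  out <- NULL
  for (i in seq_len(nrow(intervals))) for (g in seq_len(nrow(genes))) {
    if (intervals$chrom[i] != genes$chrom[g]) next
    gap <- max(genes$start[g] - intervals$end[i],
               intervals$start[i] - genes$end[g], 0)
    if (gap <= max_distance) {
      out <- rbind(out, data.frame(interval = i,
                                   gene_id = genes$gene_id[g],
                                   distance = gap))
    }
  }
  if (is.null(out)) {
    out <- data.frame(interval = integer(0), gene_id = character(0),
                      distance = numeric(0))
  }
  out[order(out$interval, out$distance, out$gene_id), , drop = FALSE]
}

# a 6v6 two-group synthetic comparison with optional planted regions
synth_comparison <- function(n_windows = 2000, mu = 30, phi = 0.1,
                             planted = NULL, seed = 1,
                             chrom_length = n_windows * 1000,
                             cpg_rate = 0.01) {
  g <- generate_genome(1, chrom_length, cpg_rate, seed = 101)
  grid <- make_windows(g, 1000)
  ids <- sprintf("s%02d", 1:12)
  des <- study_design(
    data.frame(sample_id = ids),
    list(cmp = list(a = ids[1:6], b = ids[7:12])),
    planted_dmrs = planted, dispersion = phi,
    baseline = c(intercept = mu, per_cpg = 0), seed = seed)
  cm <- simulate_counts(des, grid)
  list(genome = g, grid = grid, counts = cm, ids = ids,
       a = ids[1:6], b = ids[7:12])
}

# planted-block profile matrix for module detection: each block shares a
# latent factor with loading sqrt(r), so within-block correlation ~ r
planted_blocks <- function(n_blocks = 2, block_size = 50, n_samples = 20,
                           within_r = 0.9, n_noise = 0, seed = 1) {
  set.seed(seed)
  factors <- matrix(rnorm(n_samples * n_blocks), n_samples)
  profiles <- NULL
  labels <- integer(0)
  for (b in seq_len(n_blocks)) {
    e <- matrix(rnorm(block_size * n_samples), block_size)
    x <- sqrt(within_r) * matrix(factors[, b], block_size, n_samples,
                                 byrow = TRUE) + sqrt(1 - within_r) * e
    profiles <- rbind(profiles, x)
    labels <- c(labels, rep(b, block_size))
  }
  if (n_noise > 0) {
    profiles <- rbind(profiles,
                      matrix(rnorm(n_noise * n_samples), n_noise))
    labels <- c(labels, rep(0L, n_noise))
  }
  list(profiles = profiles, block = labels, factors = factors)
}
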