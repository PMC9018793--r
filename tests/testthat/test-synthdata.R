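test_that("genome generation follows the point-process contract", {
  # rate zero: no CpG sites
  g0 <- generate_genome(1, 10000, cpg_rate = 0, seed = 1)
  expect_identical(lengths(g0$cpg_positions)[[1]], 0L)

  # fixed-seed determinism
  g1 <- generate_genome(2, 1e5, cpg_rate = 0.01, seed = 7)
  g2 <- generate_genome(2, 1e5, cpg_rate = 0.01, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(
    g1$cpg_positions,
    generate_genome(2, 1e5, cpg_rate = 0.01, seed = 8)$cpg_positions))

  # CpG count concentrates around the binomial mean (within 5 SD)
  g3 <- generate_genome(1, 1e6, cpg_rate = 0.01, seed = 3)
  n_cpg <- length(g3$cpg_positions[[1]])
  sdv <- sqrt(1e6 * 0.01 * 0.99)
  expect_lt(abs(n_cpg - 10000), 5 * sdv)

  # positions strictly increasing and in range
  p <- g3$cpg_positions[[1]]
  expect_true(all(diff(p) > 0))
  expect_true(p[1] >= 0 && p[length(p)] < 1e6)

  expect_error(generate_genome(0, 1e4), "n_chroms")
  expect_error(generate_genome(1, -5), "positive")
  expect_error(generate_genome(1, 1e4, cpg_rate = 1.5), "cpg_rate")
})

test_that("simulated counts match their target moments", {
  g <- generate_genome(1, 5e7, cpg_rate = 0.001, seed = 2)
  grid <- make_windows(g, 1000)
  ids <- c("a1", "b1")
  des <- study_design(data.frame(sample_id = ids),
                      list(cmp = list(a = "a1", b = "b1")),
                      dispersion = 0, baseline = c(5, 0), seed = 4)
  cm <- simulate_counts(des, grid)
  # phi = 0, mu = 5: Poisson mean within 5 SD over 50,000 windows
  for (s in 1:2) {
    m <- mean(cm$counts[, s])
    expect_lt(abs(m - 5), 5 * sqrt(5 / nrow(grid)))
  }

  # NB moments: var = mu + phi mu^2 within 5 SE at n = 50,000
  des2 <- study_design(data.frame(sample_id = ids),
                       list(cmp = list(a = "a1", b = "b1")),
                       dispersion = 0.2, baseline = c(50, 0), seed = 9)
  x <- as.double(simulate_counts(des2, grid)$counts[, 1])
  target_var <- 50 + 0.2 * 50^2
  dev2 <- (x - mean(x))^2
  se_var <- sd(dev2) / sqrt(length(x))
  expect_lt(abs(var(x) - target_var), 5 * se_var)

  # determinism
  expect_identical(simulate_counts(des, grid)$counts,
                   simulate_counts(des, grid)$counts)
})

test_that("planted effects shift group means by the requested fold", {
  g <- generate_genome(1, 2e6, cpg_rate = 0.01, seed = 11)
  grid <- make_windows(g, 1000)
  ids <- sprintf("s%02d", 1:12)
  planted <- data.frame(comparison = "cmp", first_window = 501,
                        last_window = 700, log2fc = 1)
  des <- study_design(data.frame(sample_id = ids),
                      list(cmp = list(a = ids[1:6], b = ids[7:12])),
                      planted_dmrs = planted, dispersion = 0,
                      baseline = c(50, 0), seed = 5)
  cm <- simulate_counts(des, grid)
  w <- 501:700
  ratio <- mean(cm$counts[w, ids[1:6]]) / mean(cm$counts[w, ids[7:12]])
  # 1200 planted draws per group at mu = 50: ratio within ~3 SE of 2
  expect_lt(abs(ratio - 2), 0.1)
  off <- 1:500
  ratio0 <- mean(cm$counts[off, ids[1:6]]) / mean(cm$counts[off, ids[7:12]])
  expect_lt(abs(ratio0 - 1), 0.05)

  expect_error(simulate_counts(
    study_design(data.frame(sample_id = ids),
                 list(cmp = list(a = ids[1:6], b = ids[7:12])),
                 planted_dmrs = data.frame(comparison = "cmp",
                                           first_window = 1,
                                           last_window = 99999,
                                           log2fc = 1),
                 seed = 5), grid),
    "out of range")
})

test_that("counts -> reads -> counts is an exact round trip", {
  g <- generate_genome(2, 5e4, cpg_rate = 0.01, seed = 6)
  grid <- make_windows(g, 1000)
  ids <- c("x1", "x2", "y1")
  des <- study_design(data.frame(sample_id = ids),
                      list(cmp = list(a = c("x1", "x2"), b = "y1")),
                      dispersion = 0.3, baseline = c(8, 1), seed = 13)
  cm <- simulate_counts(des, grid)
  reads <- counts_to_reads(cm, grid, fragment_length = 250)
  back <- count_reads(reads, grid, mode = "containment", extend_to = 0)
  expect_identical(unname(back$counts), unname(cm$counts))
  expect_identical(unname(back$library_sizes), unname(colSums(cm$counts)))

  # forced placement: 3 fragments of 250 bp inside window [0, 1000)
  one <- count_matrix(matrix(c(3L, 0L), 2, 1,
                             dimnames = list(NULL, "s")),
                      windows = 1:2)
  grid2 <- make_windows(generate_genome(1, 2000, 0, seed = 1), 1000)
  r <- counts_to_reads(one, grid2, 250)$s
  expect_equal(nrow(r), 3)
  expect_true(all(r$start >= 0 & r$end <= 1000))

  # zero matrix -> empty read set
  zero <- count_matrix(matrix(0L, 2, 1, dimnames = list(NULL, "s")),
                       windows = 1:2)
  expect_equal(nrow(counts_to_reads(zero, grid2, 250)$s), 0)

  expect_error(counts_to_reads(one, grid2, 1500), "fragment_length")
})

test_that("pathology simulator produces the stated distributions", {
  # zero control rate: all control counts zero
  rec0 <- simulate_pathology(5, 5, control_rate = 0, case_shift = 3,
                             seed = 2)
  expect_true(all(rec0$abnormality_count[rec0$lineage == "control"] == 0))
  expect_gt(sum(rec0$abnormality_count[rec0$lineage == "exposure"]), 0)

  # determinism
  expect_identical(simulate_pathology(4, 4, 2, 3, seed = 5),
                   simulate_pathology(4, 4, 2, 3, seed = 5))

  # no shift: case and control counts identically distributed
  rec <- simulate_pathology(600, 600, control_rate = 3, case_shift = 0,
                            seed = 8)
  ks <- suppressWarnings(
    stats::ks.test(rec$abnormality_count[rec$lineage == "control"],
                   rec$abnormality_count[rec$lineage == "exposure"]))
  expect_gt(ks$p.value, 0.001)

  expect_error(simulate_pathology(5, 5, -1, 0), "rates")
})
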