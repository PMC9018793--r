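test_that("exact test at phi = 0 matches the conditional binomial", {
  # small enumeration here; the full T <= 40 sweep lives in the
  # acceptance suite
  for (np in list(c(1, 1), c(3, 3), c(2, 5))) {
    for (tot in c(1, 2, 6, 12)) {
      for (k in 0:tot) {
        expect_equal(exact_test_window(k, tot - k, np[1], np[2], phi = 0),
                     binom_exact_p(k, tot, np[1], np[2]),
                     tolerance = 1e-12)
      }
    }
  }
  # symmetric mode case: counts (3,3) at 1v1 sit at the binomial mode
  expect_equal(exact_test_window(3, 3, 1, 1, 0), 1)
  # (6,0) at 1v1: p = 2/2^6
  expect_equal(exact_test_window(6, 0, 1, 1, 0), 0.03125)
  # equal sums with equal group sizes always give p = 1
  expect_equal(exact_test_window(25, 25, 4, 4, 0.3), 1)
  # T = 0 convention
  expect_equal(exact_test_window(0, 0, 3, 3, 0.1), 1)
  expect_error(exact_test_window(-1, 3, 1, 1), "non-negative")
})

test_that("exact test is symmetric under group swap at equal sizes", {
  for (phi in c(0, 0.05, 0.4)) {
    for (split in list(c(11, 4), c(0, 9), c(30, 17))) {
      expect_equal(exact_test_window(split[1], split[2], 5, 5, phi),
                   exact_test_window(split[2], split[1], 5, 5, phi),
                   tolerance = 1e-12)
    }
  }
})

test_that("log fold change follows its definition", {
  expect_equal(logfc(20, 10, 1e6, 1e6, prior = 0), 1)
  expect_equal(logfc(15, 15, 1e6, 1e6, prior = 0), 0)
  expect_equal(logfc(0, 15, 1e6, 1e6, prior = 0.5), log2(0.5 / 15.5))
  # unequal libraries normalize before the ratio
  expect_equal(logfc(20, 10, 2e6, 1e6, prior = 0), 0)
  expect_error(logfc(0, 0, 1e6, 1e6, prior = 0), "undefined")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.08 / 3, 0.8))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # step-up invariants on random input
  set.seed(1)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("dispersion estimators recover simulated truth", {
  # zero within-group variance floors the moments estimate at 0
  cmz <- count_matrix(matrix(rep(c(10L, 7L), each = 3), 1, 6, byrow = TRUE,
                             dimnames = list(NULL, sprintf("s%d", 1:6))),
                      library_sizes = rep(100, 6))
  dz <- estimate_dispersion(cmz, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                            method = "moments")
  expect_equal(dz$phi, 0)

  # Poisson data: moments estimate near zero
  sim <- synth_comparison(n_windows = 5000, mu = 40, phi = 0, seed = 31,
                          chrom_length = 5e6, cpg_rate = 0)
  dp <- estimate_dispersion(sim$counts, sim$a, sim$b, method = "moments")
  expect_lte(dp$phi, 0.02)

  # NB truth phi = 0.2 recovered by the conditional-likelihood grid
  sim2 <- synth_comparison(n_windows = 5000, mu = 50, phi = 0.2, seed = 32,
                           chrom_length = 5e6, cpg_rate = 0)
  dg <- estimate_dispersion(sim2$counts, sim2$a, sim2$b,
                            method = "grid_cml")
  expect_gte(dg$phi, 0.1)
  expect_lte(dg$phi, 0.4)

  expect_error(
    estimate_dispersion(count_matrix(matrix(c(3L, 5L), 1, 2,
                                            dimnames = list(NULL,
                                                            c("a", "b"))),
                                     library_sizes = c(10, 10)),
                        "a", "b", method = "grid_cml"),
    "replication")
})

test_that("null simulation keeps type-I error near nominal", {
  sim <- synth_comparison(n_windows = 2000, mu = 30, phi = 0.1, seed = 41)
  st <- test_all_windows(sim$counts, sim$a, sim$b,
                         dispersion = "grid_cml")
  expect_gt(mean(st$p_value < 0.05), 0.03)
  expect_lt(mean(st$p_value < 0.05), 0.07)
  # q values respect the step-up structure
  expect_true(all(st$q_value >= st$p_value - 1e-12))
})

test_that("label permutation leaves the null p distribution unchanged", {
  sim <- synth_comparison(n_windows = 2000, mu = 30, phi = 0.1, seed = 43)
  st <- test_all_windows(sim$counts, sim$a, sim$b, dispersion = 0.1)
  perm <- c(sim$a[1:3], sim$b[1:3])
  st_perm <- test_all_windows(sim$counts, perm,
                              setdiff(sim$ids, perm), dispersion = 0.1)
  ks <- suppressWarnings(stats::ks.test(st$p_value, st_perm$p_value))
  expect_gt(ks$p.value, 0.001)
})

test_that("planted windows at a 4-fold shift are overwhelmingly detected", {
  planted <- data.frame(comparison = "cmp", first_window = 901,
                        last_window = 1000, log2fc = 2)
  sim <- synth_comparison(n_windows = 2000, mu = 100, phi = 0.05,
                          planted = planted, seed = 47)
  st <- test_all_windows(sim$counts, sim$a, sim$b, dispersion = 0.05)
  expect_gte(mean(st$p_value[901:1000] < 1e-4), 0.9)
  # direction of the fold change matches the planted shift
  expect_true(all(st$log2fc[901:1000] > 0))
})

test_that("window p-value ranking agrees with edgeR's exact test", {
  # independent cross-check against the reference NB exact test; the
  # implementations differ in library equalization, so agreement is
  # assessed on ranking, not identity
  sim <- synth_comparison(n_windows = 500, mu = 50, phi = 0.1, seed = 53,
                          chrom_length = 5e5)
  st <- test_all_windows(sim$counts, sim$a, sim$b, dispersion = 0.1)
  # columns are s01..s12 with the first six forming group a
  dge <- edgeR::DGEList(counts = sim$counts$counts,
                        lib.size = unname(sim$counts$library_sizes),
                        group = rep(c("a", "b"), each = 6))
  dge$common.dispersion <- 0.1
  et <- edgeR::exactTest(dge, pair = c("b", "a"))
  expect_gt(cor(st$p_value, et$table$PValue, method = "spearman"), 0.95)
})
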