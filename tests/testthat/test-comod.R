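test_that("top-window selection ranks by mean with genome-order ties", {
  m <- matrix(c(5, 3, 9, 5, 3, 9), 3, 2)
  expect_equal(select_top_windows(m, 3), c(3L, 1L, 2L))
  expect_equal(select_top_windows(m, 2), c(3L, 1L))
  # tie on the mean: lower ordinal wins
  tie <- matrix(c(4, 7, 4), 3, 1)
  expect_equal(select_top_windows(tie, 2), c(2L, 1L))
  # total-depth mode ranks by row sums
  m2 <- matrix(c(1, 10, 0, 9), 2, 2)
  expect_equal(select_top_windows(m2, 1, statistic = "total_depth"), 2L)
  expect_error(select_top_windows(m, 0), "positive")
  expect_error(select_top_windows(m, 9), "exceeds")
})

test_that("unsigned adjacency raises |cor| to the soft power", {
  x <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(-1, -2, -3, -4))
  a <- adjacency(x, power = 4)
  expect_equal(a[1, 2], 1)        # identical direction
  expect_equal(a[1, 3], 1)        # anti-correlated, unsigned
  expect_true(all(diag(a) == 1))
  # |cor|^power in general (cor 0.5 -> 0.0625 analogue on a random pair)
  set.seed(100)
  y <- matrix(rnorm(20), 2, 10)
  ay <- adjacency(y, power = 4)
  expect_equal(ay[1, 2], abs(cor(y[1, ], y[2, ]))^4)
  # zero-variance window correlates 0 by convention
  z <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5))
  az <- adjacency(z, power = 4)
  expect_equal(az[1, 2], 0)
  expect_equal(diag(az), c(1, 1))
  expect_error(adjacency(x[, 1:2]), "3 samples")
})

test_that("TOM matches closed forms and the brute-force formula", {
  # 2-node closed form: TOM12 = a
  for (aa in c(0.2, 0.5, 0.9)) {
    a2 <- matrix(c(1, aa, aa, 1), 2, 2)
    expect_equal(tom_similarity(a2)[1, 2], aa, tolerance = 1e-12)
  }
  # complete graph with all a = 1 -> all TOM = 1
  ones <- matrix(1, 5, 5)
  expect_true(all(abs(tom_similarity(ones) - 1) < 1e-12))
  # identity adjacency maps to identity TOM
  expect_equal(tom_similarity(diag(4)), diag(4))
  # random 10-node matrices agree with direct summation to 1e-12
  set.seed(101)
  for (rep in 1:5) {
    r <- matrix(runif(100), 10, 10)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-12)
    tom <- tom_similarity(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("planted correlation blocks are recovered as modules", {
  pb <- planted_blocks(n_blocks = 2, block_size = 50, n_samples = 20,
                       within_r = 0.9, seed = 5)
  res <- detect_methylation_modules(pb$profiles, power = 4,
                                    min_module_size = 30)
  mods <- setdiff(unique(res$labels), "grey")
  expect_equal(length(mods), 2)
  # >= 95% membership agreement with the planted partition
  tab <- table(pb$block, res$labels)
  agreement <- sum(apply(tab, 1, max)) / length(pb$block)
  expect_gte(agreement, 0.95)
  # determinism
  res2 <- detect_methylation_modules(pb$profiles, power = 4,
                                     min_module_size = 30)
  expect_identical(res$labels, res2$labels)
})

test_that("independent noise stays mostly grey", {
  set.seed(6)
  noise <- matrix(rnorm(100 * 20), 100, 20)
  res <- detect_methylation_modules(noise, power = 4, min_module_size = 30)
  expect_gte(mean(res$labels == "grey"), 0.8)
  # min size above n: everything grey
  asg <- detect_modules(1 - tom_similarity(adjacency(noise[1:10, ])),
                        min_module_size = 20)
  expect_true(all(asg$labels == "grey"))
})

test_that("eigengenes follow the stated orientation and closed forms", {
  prof <- matrix(rep(c(1, 3, 2, 5, 4), each = 4), 4, 5, byrow = FALSE)
  # all members share one profile: eigengene is that profile standardized
  labels <- rep("blue", 4)
  eg <- module_eigengene(prof, labels)
  expect_equal(unname(eg[, "blue"]),
               as.numeric(scale(c(1, 3, 2, 5, 4))), tolerance = 1e-10)
  # negating every member leaves correlation with member mean >= 0
  eg_neg <- module_eigengene(-prof, labels)
  ref <- colMeans(t(scale(t(-prof))))
  expect_gte(cor(eg_neg[, "blue"], ref), 0)
  # 2-window module: eigengene ~ standardized average (rank-1 + noise)
  set.seed(7)
  base <- rnorm(12)
  two <- rbind(base + rnorm(12, sd = 0.05), base + rnorm(12, sd = 0.05))
  eg2 <- module_eigengene(two, rep("m", 2))
  avg <- scale(colMeans(t(scale(t(two)))))
  expect_gt(abs(cor(eg2[, 1], avg)), 0.999)
  expect_error(module_eigengene(prof[, 1, drop = FALSE], labels),
               "one sample")
})

test_that("eigengene merging respects the cut height and is idempotent", {
  set.seed(8)
  f <- rnorm(30)
  mk_block <- function(fac, n, noise) {
    t(replicate(n, fac + rnorm(30, sd = noise)))
  }
  # two modules driven by near-identical factors (eigengene r ~ 0.95)
  close1 <- mk_block(f, 40, 0.3)
  close2 <- mk_block(f + rnorm(30, sd = 0.15), 40, 0.3)
  far <- mk_block(rnorm(30), 40, 0.3)
  prof <- rbind(close1, close2, far)
  labels <- rep(c("blue", "brown", "turquoise"), each = 40)
  eg0 <- module_eigengene(prof, labels)
  expect_gt(cor(eg0[, "blue"], eg0[, "brown"]), 0.75)  # distance < 0.25
  merged <- merge_close_modules(prof, labels, merge_cut_height = 0.25)
  expect_equal(length(setdiff(unique(merged), "grey")), 2)
  # the far module stays apart
  again <- merge_close_modules(prof, as.character(merged),
                               merge_cut_height = 0.25)
  expect_equal(as.character(again), as.character(merged))
})

test_that("correlation p values match the Student-t formula", {
  expect_equal(cor_pvalue_student(0, 10), 1)
  expect_equal(cor_pvalue_student(1, 10), 0)
  expect_equal(cor_pvalue_student(-1, 10), 0)
  # n = 5, r = 0.9 -> t = 3.576, p ~ 0.0374
  expect_equal(cor_pvalue_student(0.9, 5), 0.03738607, tolerance = 1e-3)
  # cross-check against cor.test over a range
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(12)
    y <- rnorm(12)
    ct <- stats::cor.test(x, y)
    expect_equal(cor_pvalue_student(cor(x, y), 12), ct$p.value,
                 tolerance = 1e-10)
  }
})

test_that("module-trait correlation flags the trait-linked block", {
  pb <- planted_blocks(n_blocks = 2, block_size = 50, n_samples = 20,
                       within_r = 0.9, seed = 10)
  res <- detect_methylation_modules(pb$profiles, power = 4,
                                    min_module_size = 30)
  traits <- data.frame(linked = pb$factors[, 1],
                       noise_trait = rnorm(20))
  mtc <- module_trait_correlation(res$eigengenes, traits)
  best <- which.max(abs(mtc$r[, "linked"]))
  expect_gte(abs(mtc$r[best, "linked"]), 0.8)
  expect_lt(mtc$p[best, "linked"], 0.01)
  # zero-variance trait reported as NA with a warning
  expect_warning(
    m2 <- module_trait_correlation(res$eigengenes,
                                   data.frame(flat = rep(1, 20))),
    "zero-variance")
  expect_true(all(is.na(m2$r)))
})
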