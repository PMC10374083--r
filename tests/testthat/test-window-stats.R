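test_that("Hudson F_ST: worked values, bounds, exclusions", {
  # one site, 8/10 vs 2/10
  expect_equal(hudson_fst(8, 2, 10, 10), (0.36 - 2 * 0.16 / 9) / 0.68)
  # fixed difference is maximal differentiation
  expect_equal(hudson_fst(10, 0, 10, 10), 1)
  # identical frequency vectors: estimator is non-positive (about 0)
  set.seed(1)
  counts <- rbinom(200, 100, 0.5)
  expect_lte(hudson_fst(counts, counts, 100, 100), 0)
  # identically fixed sites are uninformative; alone they give NA
  expect_true(is.na(hudson_fst(c(0, 10), c(0, 10), 10, 10)))
  # and they do not perturb the estimate of informative sites
  expect_equal(hudson_fst(c(8, 0), c(2, 0), 10, 10), hudson_fst(8, 2, 10, 10))
  expect_error(hudson_fst(11, 2, 10, 10), "counts")
  # sampled identical populations drift to 0 as sample size grows
  set.seed(2)
  p <- runif(500, 0.1, 0.9)
  big <- hudson_fst(rbinom(500, 1000, p), rbinom(500, 1000, p), 1000, 1000)
  expect_lt(abs(big), 0.005)
})

test_that("PBS: worked triples and relabeling equivariance", {
  # no differentiation anywhere: all branches zero
  expect_equal(unlist(pbs(0, 0, 0)), c(pbs_a = 0, pbs_b = 0, pbs_c = 0))
  # differentiation specific to population A
  res <- pbs(0.2, 0.2, 0)
  expect_equal(res$pbs_a, -log(0.8))
  expect_equal(res$pbs_b, 0)
  expect_equal(res$pbs_c, 0)
  # symmetric triple splits branch length equally
  sym <- pbs(0.1, 0.1, 0.1)
  expect_equal(unlist(sym), rep(-log(0.9) / 2, 3), ignore_attr = TRUE)
  # relabeling the populations permutes the output accordingly
  a <- pbs(0.3, 0.1, 0.2)   # pairs: AB, AC, BC
  b_focal <- pbs(0.3, 0.2, 0.1)  # pairs: BA, BC, AC
  expect_equal(b_focal$pbs_a, a$pbs_b)
  expect_equal(b_focal$pbs_b, a$pbs_a)
  expect_equal(b_focal$pbs_c, a$pbs_c)
  # F_ST of 1 maps to an infinite branch, flagged
  expect_warning(res_inf <- pbs(1, 0.2, 0.1), "infinite")
  expect_true(is.infinite(res_inf$pbs_a))
})

test_that("branch scores clamp, normalize to one, and flag negatives", {
  bs <- branch_scores(data.frame(a = 0.2, b = 0.2, c = 0.2))
  expect_equal(unlist(bs$score), c(a = 1 / 3, b = 1 / 3, c = 1 / 3))
  expect_false(bs$had_negative)
  # clamp then normalize
  bs2 <- branch_scores(data.frame(a = -0.02, b = 0.05, c = 0.05))
  expect_equal(unlist(bs2$score), c(a = 0, b = 0.5, c = 0.5))
  expect_true(bs2$had_negative)
  expect_equal(unlist(bs2$pbs_raw), c(a = -0.02, b = 0.05, c = 0.05))
  # all evolution on one branch
  bs3 <- branch_scores(data.frame(a = 0.22314, b = 0, c = 0))
  expect_equal(unlist(bs3$score), c(a = 1, b = 0, c = 0))
  # all-zero clamped triple gives missing scores
  bs4 <- branch_scores(data.frame(a = -0.1, b = -0.2, c = 0))
  expect_true(all(is.na(bs4$score)))
  # scores sum to one and are invariant to positive rescaling
  set.seed(3)
  m <- matrix(rnorm(30, 0.1, 0.2), ncol = 3)
  sc <- branch_scores(m)$score
  sums <- rowSums(sc)
  expect_equal(sums[!is.na(sums)], rep(1, sum(!is.na(sums))))
  sc_scaled <- branch_scores(m * 7)$score
  expect_equal(sc, sc_scaled)
  expect_error(branch_scores(matrix(1, 2, 2)), "3-column")
})

test_that("f_D: worked sums, symmetry null, missing handling", {
  # no excess sharing when recipient mirrors its sister
  p1 <- c(0.1, 0.6, 0.3)
  expect_equal(f_d(p1, p1, c(1, 0.5, 0.2), c(0, 0.1, 0)), 0)
  # complete donor sharing
  expect_equal(f_d(0, 1, 1, 0), 1)
  # two-site hand evaluation: numerator 0.5, denominator 2
  expect_equal(f_d(c(0, 0), c(0.5, 0), c(1, 1), c(0, 0)), 0.25)
  # missing frequencies drop the site
  expect_equal(f_d(c(0, NA), c(0.5, 0.2), c(1, 0.3), c(0, 0)),
               f_d(0, 0.5, 1, 0))
  # zero denominator (no derived alleles in recipient or donor) is missing
  expect_true(is.na(f_d(0.2, 0, 0, 0)))
})

test_that("regression: exact fit, null coverage, collinearity abort", {
  # exact line recovered with zero residuals
  d <- data.frame(f_d = 2 * (1:5), recomb = 1:5)
  # summary.lm warns on an exactly perfect fit; that is the point here
  fit <- suppressWarnings(
    fit_introgression_model(d, terms = "recomb", fd_threshold = -Inf))
  expect_equal(fit$estimate, 2)
  expect_equal(fit$n, 5)
  # independent predictor: slope CI covers zero
  set.seed(11)
  d2 <- data.frame(f_d = rnorm(1000, 0.2, 0.1), recomb = runif(1000))
  fit2 <- fit_introgression_model(d2, terms = "recomb")
  expect_lt(abs(fit2$estimate), 2.1 * fit2$se)
  # f_D filter excludes non-positive windows and logs the count
  d3 <- data.frame(f_d = c(-0.5, 0, 0.2, 0.4, 0.6, 0.1), recomb = 1:6)
  fit3 <- fit_introgression_model(d3, terms = "recomb")
  expect_equal(attr(fit3, "filter_counts")[["used"]], 4L)
  expect_equal(attr(fit3, "filter_counts")[["dropped_fd_filter"]], 2L)
  # machine-precision collinearity aborts with a diagnostic
  d4 <- data.frame(f_d = rnorm(10, 1), a = 1:10, b = 2 * (1:10))
  expect_error(
    fit_introgression_model(d4, terms = c("a", "b"), joint = TRUE),
    "collinear")
  # joint fit returns one row per term
  d5 <- data.frame(f_d = rnorm(50, 1), a = rnorm(50), b = rnorm(50))
  fit5 <- fit_introgression_model(d5, terms = c("a", "b"), joint = TRUE,
                                  fd_threshold = -Inf)
  expect_equal(nrow(fit5), 2)
  expect_error(fit_introgression_model(d[1:2, ], terms = "recomb",
                                       fd_threshold = -Inf), "too few")
})
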