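test_that("recipient mean fitness matches the direct product and expansion", {
  p <- p_default
  expect_identical(mean_fitness(0, p), 1)
  expect_identical(mean_fitness(0, p, "approx"), 1)
  # b = 2: one pair, two direct effects
  expect_equal(mean_fitness(2, p), 0.99^2 * 1.001, tolerance = 1e-15)
  # b = 60: 1 + 60 s + 1770 eps_w
  expect_equal(mean_fitness(60, p, "approx"), 1 - 0.6 + 1.77)
  # exact exceeds the expansion by the higher-order epistatic terms; at
  # these deliberately large illustration effects the gap is order one
  expect_gt(mean_fitness(60, p), mean_fitness(60, p, "approx"))
  expect_lt(abs(mean_fitness(60, p) - mean_fitness(60, p, "approx")), 1.2)
  # additive toggle coincides with the first-order expansion
  expect_equal(mean_fitness(60, p, "exact", combine = "additive"),
               mean_fitness(60, p, "approx"))
})

test_that("single-allele selection coefficients follow the three classes", {
  p <- p_default
  expect_equal(sigma_allele("new", 0, p, "approx"), p$s)
  expect_equal(sigma_allele("new", 0, p, "exact"), p$s, tolerance = 1e-12)
  expect_equal(sigma_allele("ancestral", 1, p, "approx"), -p$s)
  expect_equal(sigma_allele("new", 30, p, "approx"), p$s + 30 * p$eps_b)
  expect_equal(sigma_allele("ancestral", 30, p, "approx"),
               -p$s - 29 * p$eps_w)
  expect_equal(sigma_allele("replacement", 30, p, "approx"),
               29 * (p$eps_b - p$eps_w))
  # eps_b = eps_w: replacement alleles are neutral to first order
  p_eq <- selection_params(-0.01, 5e-4, 5e-4)
  expect_equal(sigma_allele("replacement", 25, p_eq, "approx"), 0)
  expect_lt(abs(sigma_allele("replacement", 25, p_eq, "exact")), 1e-6)
  # the single-allele kinds reduce to single-allele compositions
  for (b in c(5L, 20L)) {
    expect_equal(sigma_allele("new", b, p, "exact"),
                 sigma_haplotype(haplotype_composition(x_new = 1), b, p))
  }
  expect_error(sigma_allele("ancestral", 0, p), "impossible composition")
  expect_error(sigma_allele("replacement", 0, p), "impossible composition")
})

test_that("haplotype selection coefficient: zero size, reductions, regimes", {
  # sigma_I = 0 when x = 0, any parameters, both modes
  for (mode in c("exact", "approx")) {
    expect_identical(
      sigma_haplotype(haplotype_composition(), 60, p_default, mode), 0)
    expect_identical(
      sigma_haplotype(haplotype_composition(), 0, random_params(3), mode), 0)
  }
  # single new allele reduces to sigma_allele in both modes
  comp1 <- haplotype_composition(x_new = 1)
  for (mode in c("exact", "approx")) {
    expect_equal(sigma_haplotype(comp1, 40, p_default, mode),
                 sigma_allele("new", 40, p_default, mode))
  }
  # 40 new alleles against b = 60 with s = 0: 0.78 - 0.24 = 0.54
  expect_equal(
    sigma_haplotype(haplotype_composition(40), 60, p_s1, "approx"), 0.54)
  # composition exceeding recipient divergence is rejected
  expect_error(
    sigma_haplotype(haplotype_composition(0, 10, 5), 12, p_default),
    "invalid composition")
})

test_that("fraction form equals the composition form on the integer lattice", {
  p <- p_default
  for (x in c(2L, 10L, 20L)) {
    for (f in c(0, 0.5, 1)) {
      if (f * x > 60) next
      comp <- haplotype_composition(x_new = (1 - f) * x, x_ancestral = f * x)
      expect_equal(sigma_fraction(x, f, 60, p),
                   sigma_haplotype(comp, 60, p, "approx"),
                   tolerance = 1e-12,
                   label = sprintf("x=%d f=%g", x, f))
    }
  }
  # x = 20, f = 1/2 equals the (10, 10, 0) composition
  expect_equal(sigma_fraction(20, 0.5, 60, p),
               sigma_haplotype(haplotype_composition(10, 10), 60, p, "approx"))
  # f = 0 reduces to the new-alleles-only form
  expect_equal(sigma_fraction(15, 0, 60, p),
               p$s * 15 + (p$eps_w / 2) * (15^2 - 15) + p$eps_b * 15 * 60)
  # f = 1, x = b: all recipient substitutions reverted; to first order this
  # is minus the mean-fitness excess over the ancestor
  b <- 30L
  expect_equal(sigma_fraction(b, 1, b, p),
               -(mean_fitness(b, p, "approx") - 1), tolerance = 1e-12)
  expect_error(sigma_fraction(10, 1.2, 60, p), "f must lie")
  expect_error(sigma_fraction(80, 1, 60, p), "invalid composition")
})

test_that("new-only and all-replacement limits expose both printed forms", {
  p <- selection_params(s = -0.01, eps_w = 1e-3, eps_b = -1e-4)
  expect_equal(sigma_new_only(12, 60, p), sigma_fraction(12, 0, 60, p))
  expect_equal(sigma_new_only(12, 60, p, form = "printed"),
               -0.01 * 12 + 1e-3 * 144 - 1e-4 * 12 * 60)
  # all-replacement reduction: x (b - x)(eps_b - eps_w)
  expect_identical(sigma_late_replacement(0, 500, p), 0)
  p_eq <- selection_params(0, 5e-4, 5e-4)
  for (x in c(1, 7, 100)) {
    expect_identical(sigma_late_replacement(x, 500, p_eq), 0)
  }
  expect_equal(sigma_late_replacement(5, 500, p), 5 * 495 * (-1.1e-3))
  expect_equal(sigma_late_replacement(5, 500, p, form = "printed"),
               5 * 500 * -1e-4)
  # the reduction tracks the exact all-replacement model
  exact <- sigma_haplotype(haplotype_composition(x_replacement = 5), 500,
                           selection_params(0, 1e-3, -1e-4), "approx")
  expect_equal(sigma_late_replacement(5, 500,
                                      selection_params(0, 1e-3, -1e-4)),
               exact, tolerance = 1e-12)
  expect_error(sigma_late_replacement(10, 5, p), "x <= b")
})

test_that("critical size: closed form, special cases, degenerate landscape", {
  # weak incompatibilities: minimum at 1% of recipient divergence
  p <- selection_params(s = 0, eps_w = 1e-4, eps_b = -1e-6)
  expect_equal(critical_size(0, 1000, p), 10)
  expect_equal(critical_size(0, 1000, p) / 1000, 0.01)
  # eps_b = -eps_w: the minimum sits at b itself
  expect_equal(critical_size(0, 200, selection_params(0, 1e-4, -1e-4)), 200)
  # f = 1/2 and f = 1 give b for any admissible epistasis pair
  grid <- expand.grid(b = c(20L, 60L, 200L), ew = c(1e-4, 1e-3),
                      eb = c(-1e-6, -1e-4))
  for (i in seq_len(nrow(grid))) {
    p_i <- selection_params(0, grid$ew[i], grid$eb[i])
    expect_equal(critical_size(0.5, grid$b[i], p_i), grid$b[i],
                 label = sprintf("f=1/2 row %d", i))
    expect_equal(critical_size(1, grid$b[i], p_i), grid$b[i],
                 label = sprintf("f=1 row %d", i))
  }
  # both epistasis parameters positive: critical size negative, all
  # introgression favored
  p_pos <- selection_params(0, 1e-4, 1e-5)
  expect_lt(critical_size(0, 100, p_pos), 0)
  for (x in c(1, 5, 50, 200)) {
    expect_gt(sigma_fraction(x, 0, 100, p_pos), 0)
  }
  # zero denominator flagged
  expect_error(critical_size(0.5, 100, selection_params(0, 1e-4, 1e-4)),
               "degenerate")
})

test_that("fraction form is unimodal with minimum at the critical size", {
  for (seed in 1:5) {
    set.seed(seed)
    b <- sample(40:200, 1)
    f <- stats::runif(1, 0, 0.45)
    p <- selection_params(0, stats::runif(1, 1e-5, 1e-3),
                          -stats::runif(1, 1e-6, 1e-4))
    xstar <- critical_size(f, b, p)
    xs <- seq(0.5, min(xstar * 2.5, b / max(f, 1e-9)), length.out = 80)
    sig <- sigma_fraction(xs, f, b, p)
    left <- xs < xstar - 1e-6
    right <- xs > xstar + 1e-6
    expect_true(all(diff(sig[left]) < 0),
                label = sprintf("decreasing left of x* (seed %d)", seed))
    expect_true(all(diff(sig[right]) > 0),
                label = sprintf("increasing right of x* (seed %d)", seed))
  }
})

test_that("exact and approximate modes agree to second order in the effects", {
  grid <- random_composition_grid(40)
  for (k in seq_along(grid)) {
    g <- grid[[k]]
    p <- random_params(seed = k, max_effect = 1e-3)
    ex <- sigma_haplotype(g$comp, g$b, p, "exact")
    ap <- sigma_haplotype(g$comp, g$b, p, "approx")
    bound <- (n_terms_haploid(g$comp, g$b) * 1e-3)^2
    expect_lt(abs(ex - ap), bound + 1e-15)
  }
})

test_that("multiplicative and additive fitness composition agree to first order", {
  comp <- haplotype_composition(10, 5, 2)
  p <- selection_params(-1e-4, 1e-5, -1e-5)
  mult <- sigma_haplotype(comp, 30, p, "exact", combine = "multiplicative")
  add <- sigma_haplotype(comp, 30, p, "exact", combine = "additive")
  expect_lt(abs(mult - add), 1e-5)
})
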