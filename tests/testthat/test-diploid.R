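test_that("diploid reductions: haploid limit, zero size, h = f neutrality", {
  p <- p_default
  # fully dominant direct and epistatic effects with only new alleles: the
  # heterozygous carrier behaves like a haploid carrier
  d_dom <- dominance_params(h = 1, a1 = 1, a2 = 1)
  for (x in c(1L, 8L, 25L)) {
    comp <- haplotype_composition(x_new = x)
    expect_equal(sigma_diploid(comp, 60, p, d_dom, "approx"),
                 sigma_haplotype(comp, 60, p, "approx"),
                 tolerance = 1e-12, label = sprintf("x=%d", x))
  }
  # zero-size haplotype is exactly neutral in both modes
  for (mode in c("exact", "approx")) {
    expect_identical(
      sigma_diploid(haplotype_composition(), 60, p,
                    dominance_params(0.3, 0.1, 0.9), mode), 0)
  }
  # h = f: direct effects cancel; finite-difference derivative in s is zero
  d_half <- dominance_params(h = 0.5, a1 = 0.25, a2 = 0.5)
  eps <- 1e-6
  s_lo <- selection_params(-0.01 - eps, 1e-3, -1e-4)
  s_hi <- selection_params(-0.01 + eps, 1e-3, -1e-4)
  dsig <- (sigma_diploid_approx(20, 0.5, 60, s_hi, d_half) -
             sigma_diploid_approx(20, 0.5, 60, s_lo, d_half)) / (2 * eps)
  expect_lt(abs(dsig), 1e-10)
  # and h = f = 0 as well (new alleles, fully recessive direct effects)
  d0 <- dominance_params(h = 0, a1 = 0.25, a2 = 0.5)
  dsig0 <- (sigma_diploid_approx(20, 0, 60, s_hi, d0) -
              sigma_diploid_approx(20, 0, 60, s_lo, d0)) / (2 * eps)
  expect_lt(abs(dsig0), 1e-10)
})

test_that("dosage-additive special case equals a1 = 1/4, a2 = 1/2", {
  p <- p_default
  d_add <- dominance_params(h = 0.5, a1 = 0.25, a2 = 0.5)
  grid <- expand.grid(x = c(2, 10, 30), f = c(0, 0.25, 0.5, 1),
                      b = c(30L, 60L))
  for (i in seq_len(nrow(grid))) {
    expect_equal(
      sigma_diploid_additive(grid$x[i], grid$f[i], grid$b[i], p, h = 0.5),
      sigma_diploid_approx(grid$x[i], grid$f[i], grid$b[i], p, d_add),
      label = sprintf("row %d", i))
  }
  expect_identical(sigma_diploid_additive(0, 0.5, 60, p), 0)
  # cross-background term condenses to (eps_b/2) x (1-f) (b - x f / 2)
  p_eb <- selection_params(0, 0, -1e-4)
  x <- 18; f <- 0.4; b <- 60L
  expect_equal(sigma_diploid_additive(x, f, b, p_eb, h = 0.5),
               (p_eb$eps_b / 2) * x * (1 - f) * (b - x * f / 2))
  # f = 0, h = 1/2 hand reduction: sx/2 + (eps_w/2)(x^2/4 - x/4) + (eps_b/2) x b
  p2 <- p_default
  x <- 12; b <- 60L
  expect_equal(sigma_diploid_additive(x, 0, b, p2, h = 0.5),
               p2$s * x / 2 + (p2$eps_w / 2) * (x^2 / 4 - x / 4) +
                 (p2$eps_b / 2) * x * b)
})

test_that("recessive epistasis selects harder against mixed haplotypes", {
  # with positive within-background epistasis, recessive epistasis silences
  # the new interactions the haplotype brings while the removal of existing
  # ones persists
  p <- p_default
  d_rec <- dominance_params(h = 0.5, a1 = 0, a2 = 0)
  d_dom <- dominance_params(h = 0.5, a1 = 1, a2 = 1)
  grid <- expand.grid(x = c(5L, 20L, 40L), f = c(0.25, 0.5, 0.75),
                      b = c(60L, 100L))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; f <- grid$f[i]; b <- grid$b[i]
    comp <- haplotype_composition(x_new = round((1 - f) * x),
                                  x_ancestral = round(f * x))
    s_rec <- sigma_diploid(comp, b, p, d_rec, "exact")
    s_dom <- sigma_diploid(comp, b, p, d_dom, "exact")
    expect_lte(s_rec, s_dom + 1e-12,
               label = sprintf("x=%d f=%g b=%d", x, f, b))
  }
})

test_that("diploid approximation refuses replacement alleles; exact handles them", {
  p <- p_default
  d <- dominance_params(0.5, 0.25, 0.5)
  comp <- haplotype_composition(2, 2, 2)
  expect_error(sigma_diploid(comp, 30, p, d, "approx"),
               "unsupported composition")
  expect_true(is.finite(sigma_diploid(comp, 30, p, d, "exact")))
})

test_that("diploid exact and approximate modes agree to second order", {
  d <- dominance_params(h = 0.5, a1 = 0.25, a2 = 0.5)
  grid <- random_composition_grid(25, seed = 99)
  for (k in seq_along(grid)) {
    g <- grid[[k]]
    if (g$comp$x_replacement > 0) next   # approx form excludes replacement
    p <- random_params(seed = 1000 + k, max_effect = 1e-3)
    ex <- sigma_diploid(g$comp, g$b, p, d, "exact")
    ap <- sigma_diploid(g$comp, g$b, p, d, "approx")
    bound <- (n_terms_haploid(g$comp, g$b) * 1e-3)^2
    expect_lt(abs(ex - ap), bound + 1e-15)
  }
})
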