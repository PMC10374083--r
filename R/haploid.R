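# Haploid fitness of an introgressing haplotype.
#
# The recipient population B has fixed b derived substitutions since the
# common ancestor. A rare haplotype from donor population A carries x_A
# donor-background derived alleles and overwrites x_B of the recipient's
# substitutions. Fitness is a product over direct effects (1+s) and pairwise
# epistatic effects: (1+eps_w) for pairs fixed in the same background,
# (1+eps_b) for cross-background pairs. The carrier therefore holds
# x_A + (b - x_B) derived alleles; the small-effect approximation expands the
# products to first order.

# generalized "n choose 2", valid for real n (used by sweep grids where
# x_A = (1-f)*x need not be integral)
pairs2 <- function(n) n * (n - 1) / 2

#' Mean fitness of the recipient population
#'
#' Fitness of the average (haplotype-free) recipient individual relative to
#' the common ancestor: `b` direct effects and `choose(b, 2)` pairwise
#' within-background interactions.
#'
#' @param b Number of derived substitutions fixed in the recipient.
#' @param params A [selection_params()] object.
#' @param mode `"exact"` for the multiplicative product
#'   `(1+s)^b (1+eps_w)^choose(b,2)`, `"approx"` for its first-order
#'   expansion `1 + b s + choose(b,2) eps_w`.
#' @param combine Fitness composition rule for exact mode: `"multiplicative"`
#'   (default, the tested contract) or `"additive"` (fitness is one plus the
#'   sum of all effects; coincides with `mode = "approx"`).
#' @return Scalar fitness (dimensionless, ancestor = 1).
#' @examples
#' mean_fitness(60, selection_params())
#' @export
mean_fitness <- function(b, params, mode = c("exact", "approx"),
                         combine = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  b <- check_divergence(b)
  stopifnot(inherits(params, "selection_params"))
  if (mode == "approx" || combine == "additive") {
    1 + b * params$s + pairs2(b) * params$eps_w
  } else {
    (1 + params$s)^b * (1 + params$eps_w)^pairs2(b)
  }
}

# Exact-product carrier fitness and selection coefficient for real-valued
# x_A, x_B (counts enter only through factor multiplicities, so the product
# form extends smoothly off the integer lattice). Shared by the public
# count-based interface and the sweep engine.
sigma_haploid_core <- function(x_A, x_B, b, params,
                               mode = "exact", combine = "multiplicative") {
  s <- params$s; ew <- params$eps_w; eb <- params$eps_b
  if (mode == "approx") {
    return(s * (x_A - x_B) +
             (ew / 2) * (x_A^2 - x_A - x_B * (2 * b - x_B - 1)) +
             eb * x_A * (b - x_B))
  }
  n_s <- x_A + (b - x_B)                       # direct factors in carrier
  n_w <- pairs2(x_A) + pairs2(b - x_B)         # same-background pairs
  n_b <- x_A * (b - x_B)                       # cross-background pairs
  if (combine == "additive") {
    w_i <- 1 + s * n_s + ew * n_w + eb * n_b
    w_bar <- 1 + s * b + ew * pairs2(b)
  } else {
    w_i <- (1 + s)^n_s * (1 + ew)^n_w * (1 + eb)^n_b
    w_bar <- (1 + s)^b * (1 + ew)^pairs2(b)
  }
  w_i / w_bar - 1
}

#' Effective selection coefficient of an introgressing haplotype (haploid)
#'
#' Relative fitness of a rare carrier versus the recipient population mean,
#' minus one. Exact mode builds the carrier fitness as the product over
#' `(1+s)` per derived allele carried, `(1+eps_w)` per same-background pair
#' and `(1+eps_b)` per cross-background pair, divided by [mean_fitness()];
#' approximate mode uses the first-order expansion
#' `s(x_A - x_B) + (eps_w/2)(x_A^2 - x_A - x_B(2b - x_B - 1)) +
#' eps_b x_A (b - x_B)`.
#'
#' @param comp A [haplotype_composition()].
#' @param b Recipient divergence (substitution count).
#' @param params A [selection_params()] object.
#' @inheritParams mean_fitness
#' @return Scalar selection coefficient (dimensionless).
#' @examples
#' p <- selection_params(s = 0, eps_w = 1e-3, eps_b = -1e-4)
#' sigma_haplotype(haplotype_composition(x_new = 40), b = 60, p,
#'                 mode = "approx")  # 0.54
#' @export
sigma_haplotype <- function(comp, b, params, mode = c("exact", "approx"),
                            combine = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  stopifnot(inherits(comp, "haplotype_composition"),
            inherits(params, "selection_params"))
  b <- check_divergence(b)
  check_composition_vs_b(comp, b)
  if (comp$x == 0) return(0)   # empty haplotype: carrier is the resident
  sigma_haploid_core(comp$x_A, comp$x_B, b, params, mode, combine)
}

#' Selection coefficient of a single introgressing allele
#'
#' The three allele classes reduce to single-allele compositions: a new
#' allele adds one direct effect and `b` cross-background interactions
#' (`s + b eps_b` to first order); an ancestral allele removes a direct
#' effect and `b-1` within-background interactions (`-s - (b-1) eps_w`); a
#' replacement allele swaps `b-1` within-background interactions for
#' cross-background ones (`(b-1)(eps_b - eps_w)`), so it is neutral when
#' `eps_b = eps_w`.
#'
#' @param kind One of `"new"`, `"ancestral"`, `"replacement"`.
#' @inheritParams sigma_haplotype
#' @return Scalar selection coefficient.
#' @export
sigma_allele <- function(kind = c("new", "ancestral", "replacement"),
                         b, params, mode = c("exact", "approx")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  b <- check_divergence(b)
  stopifnot(inherits(params, "selection_params"))
  if (kind != "new" && b < 1) {
    stop(sprintf(
      "impossible composition: a %s allele requires at least one recipient substitution (b >= 1)",
      kind))
  }
  if (mode == "approx") {
    return(switch(kind,
                  new = params$s + b * params$eps_b,
                  ancestral = -params$s - (b - 1) * params$eps_w,
                  replacement = (b - 1) * (params$eps_b - params$eps_w)))
  }
  comp <- switch(kind,
                 new = haplotype_composition(x_new = 1),
                 ancestral = haplotype_composition(x_ancestral = 1),
                 replacement = haplotype_composition(x_replacement = 1))
  sigma_haplotype(comp, b, params, mode = "exact")
}

#' Haplotype selection coefficient in fraction-ancestral form
#'
#' First-order selection coefficient of a haplotype of size `x` whose
#' fraction `f` consists of ancestral alleles, the remainder new alleles
#' (replacement alleles assumed absent):
#' `(1-2f)(s x + (eps_w/2)(x^2 - x)) - x(eps_w f - eps_b(1-f))(b - x f)`.
#' Evaluated on real `x` and `f` without rounding; equals
#' [sigma_haplotype()] in approximate mode whenever `(1-f)x` and `f x` are
#' integers.
#'
#' @param x Haplotype size (number of alleles; real-valued allowed).
#' @param f Fraction of the haplotype carrying ancestral alleles, in \[0, 1\].
#' @inheritParams sigma_haplotype
#' @return Scalar selection coefficient.
#' @export
sigma_fraction <- function(x, f, b, params) {
  stopifnot(length(x) == 1 || length(f) == 1 || length(x) == length(f))
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  b <- check_divergence(b)
  stopifnot(inherits(params, "selection_params"))
  if (any(f * x > b + 1e-9)) {
    stop("invalid composition: f*x (ancestral alleles) exceeds divergence b")
  }
  s <- params$s; ew <- params$eps_w; eb <- params$eps_b
  (1 - 2 * f) * (s * x + (ew / 2) * (x^2 - x)) -
    x * (ew * f - eb * (1 - f)) * (b - x * f)
}

#' New-alleles-only limit of the haplotype selection coefficient
#'
#' Early in divergence a haplotype carries only new alleles (`f = 0`). The
#' canonical form is the `f = 0` reduction of [sigma_fraction()],
#' `s x + (eps_w/2)(x^2 - x) + eps_b x b`. A simplified variant dropping the
#' `-x` term and the factor 1/2 on the within-background pair count,
#' `s x + eps_w x^2 + eps_b x b`, is available as `form = "printed"`; it
#' overcounts within-haplotype pairs by roughly two-fold and is retained only
#' for comparison.
#'
#' @param x Haplotype size.
#' @param form `"canonical"` (default) or `"printed"`.
#' @inheritParams sigma_fraction
#' @return Scalar selection coefficient.
#' @export
sigma_new_only <- function(x, b, params, form = c("canonical", "printed")) {
  form <- match.arg(form)
  b <- check_divergence(b)
  stopifnot(inherits(params, "selection_params"))
  if (form == "canonical") {
    sigma_fraction(x, 0, b, params)
  } else {
    params$s * x + params$eps_w * x^2 + params$eps_b * x * b
  }
}

#' Late-divergence all-replacement limit
#'
#' When all `x` alleles on the haplotype are replacement alleles, the
#' first-order reduction of the haplotype selection coefficient is
#' `x (b - x)(eps_b - eps_w)` (`form = "reduction"`, default): each
#' replacement allele swaps within-background interactions with the `b - x`
#' untouched recipient substitutions for cross-background ones, and
#' within-haplotype pairs cancel against the removed recipient pairs. The
#' further-simplified linear form `x b eps_b` (`form = "printed"`) holds only
#' as a rough `x << b` magnitude guide; the two disagree even in sign
#' whenever `eps_w > |eps_b|`, so the reduction is the default. Both are
#' linear in `x` when `x << b`.
#'
#' @param x Number of replacement alleles (must satisfy `x <= b`).
#' @param form `"reduction"` (default) or `"printed"`.
#' @inheritParams sigma_fraction
#' @return Scalar selection coefficient.
#' @export
sigma_late_replacement <- function(x, b, params,
                                   form = c("reduction", "printed")) {
  form <- match.arg(form)
  b <- check_divergence(b)
  stopifnot(inherits(params, "selection_params"))
  if (any(x > b)) stop("all-replacement haplotype requires x <= b")
  if (form == "reduction") {
    x * (b - x) * (params$eps_b - params$eps_w)
  } else {
    x * b * params$eps_b
  }
}

#' Critical haplotype size (fitness minimum)
#'
#' With `eps_w > 0 > eps_b` the selection coefficient as a function of
#' haplotype size `x` is a downward-opening-then-recovering quadratic:
#' selection against the haplotype strengthens up to a critical size `x*`
#' and weakens beyond it. Setting the derivative of the fraction form to
#' zero with direct effects ignored (`s = 0`) and dropping the
#' `-(1-2f) eps_w / 2` offset (negligible against the `b`-proportional
#' numerator) gives
#' `x* = b (eps_w f - eps_b (1-f)) / (eps_w - 2 f (1-f)(eps_w + eps_b))`.
#' Special cases: `f = 0` gives `-b eps_b / eps_w`; `f = 1/2` and `f = 1`
#' both give `b`. When both epistasis parameters are positive the value is
#' negative: every haplotype size is favored. The exhaustive integer
#' minimizer ([argmin_size()]) may differ by O(1) alleles because of the
#' dropped offset term.
#'
#' @inheritParams sigma_fraction
#' @return Real-valued critical size `x*` (alleles).
#' @examples
#' critical_size(0, 1000, selection_params(s = 0, eps_w = 1e-4, eps_b = -1e-6))
#' @export
critical_size <- function(f, b, params) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  b <- check_divergence(b)
  stopifnot(inherits(params, "selection_params"))
  ew <- params$eps_w; eb <- params$eps_b
  denom <- ew - 2 * f * (1 - f) * (ew + eb)
  if (any(abs(denom) < .Machine$double.eps * max(1, abs(ew)))) {
    stop("degenerate landscape: critical-size denominator is zero")
  }
  b * (ew * f - eb * (1 - f)) / denom
}
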