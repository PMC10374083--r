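# Diploid carrier fitness. The haplotype is rare, so a carrier is
# heterozygous at every haplotype site: donor-background alleles (X_A) are
# heterozygous, and at each overwritten recipient site (X_B) the carrier
# still holds the recipient's derived allele on the homologous chromosome,
# also heterozygous. Untouched recipient substitutions (B \ X_B) remain
# homozygous. Direct effects scale by h when heterozygous; pairwise epistasis
# scales by a1 (het-het), a2 (het-hom), 1 (hom-hom).

# real-valued core, mirroring sigma_haploid_core
sigma_diploid_core <- function(x_A, x_B, x_rep, b, params, dom,
                               mode = "exact", combine = "multiplicative") {
  s <- params$s; ew <- params$eps_w; eb <- params$eps_b
  h <- dom$h; a1 <- dom$a1; a2 <- dom$a2
  if (mode == "approx") {
    # fraction form: requires x_rep = 0; x = x_A + x_B, f = x_B / x
    x <- x_A + x_B
    f <- if (x > 0) x_B / x else 0
    return(sigma_diploid_approx(x, f, b, params, dom))
  }
  # factor multiplicities in the carrier (Methods product form)
  n_hs  <- x_A + x_B                   # heterozygous direct effects
  n_s   <- b - x_B                     # homozygous recipient substitutions
  n_a1w <- pairs2(x_A) + pairs2(x_B)   # het-het same-background pairs
  n_a2w <- x_B * (b - x_B)             # het-hom within recipient background
  n_w   <- pairs2(b - x_B)             # hom-hom recipient pairs
  n_a1b <- x_A * x_B - x_rep           # het-het cross pairs (no self-locus)
  n_a2b <- x_A * (b - x_B)             # het-hom cross pairs
  facs <- c(1 + h * s, 1 + s, 1 + a1 * ew, 1 + a2 * ew, 1 + ew,
            1 + a1 * eb, 1 + a2 * eb)
  if (any(facs <= 0)) {
    stop("fitness factors must remain positive under the supplied dominance scaling")
  }
  ns <- c(n_hs, n_s, n_a1w, n_a2w, n_w, n_a1b, n_a2b)
  if (combine == "additive") {
    w_i <- 1 + sum((facs - 1) * ns)
    w_bar <- 1 + s * b + ew * pairs2(b)
  } else {
    w_i <- prod(facs^ns)
    w_bar <- (1 + s)^b * (1 + ew)^pairs2(b)
  }
  w_i / w_bar - 1
}

#' Diploid first-order selection coefficient in fraction form
#'
#' Small-effect approximation for a heterozygous carrier of a haplotype of
#' size `x` with ancestral fraction `f` (no replacement alleles):
#' `s x (h - f) + eps_w [a1 (x(x-1)/2 - x^2 f(1-f)) + a2 x f (b - x f) +
#' (x f / 2)(x f + 1 - 2 b)] + eps_b x (1-f) (a1 x f + a2 (b - x f))`.
#' When `h = f` the direct term vanishes: e.g. additive direct selection
#' (`h = 1/2`) with equal numbers of new and ancestral alleles (`f = 1/2`)
#' leaves only epistasis acting on the haplotype.
#'
#' @param x Haplotype size (real-valued allowed).
#' @param f Ancestral fraction in \[0, 1\].
#' @param b Recipient divergence.
#' @param params A [selection_params()] object.
#' @param dom A [dominance_params()] object.
#' @return Scalar selection coefficient.
#' @export
sigma_diploid_approx <- function(x, f, b, params, dom) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  stopifnot(inherits(params, "selection_params"),
            inherits(dom, "dominance_params"))
  s <- params$s; ew <- params$eps_w; eb <- params$eps_b
  h <- dom$h; a1 <- dom$a1; a2 <- dom$a2
  s * x * (h - f) +
    ew * (a1 * (x * (x - 1) / 2 - x^2 * f * (1 - f)) +
            a2 * x * f * (b - x * f) +
            (x * f / 2) * (x * f + 1 - 2 * b)) +
    eb * x * (1 - f) * (a1 * x * f + a2 * (b - x * f))
}

#' Effective selection coefficient of an introgressing haplotype (diploid)
#'
#' Exact mode multiplies, for a heterozygous carrier: `(1 + h s)` per
#' haplotype-site allele (both the donor-background alleles and the
#' still-present recipient alleles at overwritten sites), `(1 + s)` per
#' untouched recipient substitution, `(1 + a1 eps_w)` per het-het
#' same-background pair, `(1 + a2 eps_w)` per overwritten-by-untouched
#' recipient pair, `(1 + eps_w)` per untouched recipient pair,
#' `(1 + a1 eps_b)` per het-het cross-background pair (same-locus
#' replacement pairs excluded) and `(1 + a2 eps_b)` per donor-by-untouched
#' pair; the ratio to the (homozygous) population [mean_fitness()] minus one
#' is returned. Approximate mode uses [sigma_diploid_approx()] and requires
#' `x_replacement = 0`.
#'
#' @inheritParams sigma_haplotype
#' @param dom A [dominance_params()] object.
#' @return Scalar selection coefficient.
#' @examples
#' p <- selection_params()
#' d <- dominance_params(h = 0.5, a1 = 0.25, a2 = 0.5)
#' sigma_diploid(haplotype_composition(x_new = 20, x_ancestral = 10),
#'               b = 60, p, d)
#' @export
sigma_diploid <- function(comp, b, params, dom, mode = c("exact", "approx"),
                          combine = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  stopifnot(inherits(comp, "haplotype_composition"),
            inherits(params, "selection_params"),
            inherits(dom, "dominance_params"))
  b <- check_divergence(b)
  check_composition_vs_b(comp, b)
  if (comp$x == 0) return(0)
  if (mode == "approx" && comp$x_replacement > 0) {
    stop("unsupported composition: the diploid approximation assumes ",
         "x_replacement = 0")
  }
  sigma_diploid_core(comp$x_A, comp$x_B, comp$x_replacement, b, params, dom,
                     mode, combine)
}

#' Diploid selection coefficient under dosage-additive epistasis
#'
#' Special case of [sigma_diploid_approx()] with `a1 = 1/4`, `a2 = 1/2`
#' (each heterozygous allele contributes half dosage, so het-het pairs
#' interact at a quarter strength and het-hom pairs at half). The
#' cross-background term condenses to `(eps_b / 2) x (1-f) (b - x f / 2)`.
#'
#' @inheritParams sigma_diploid_approx
#' @param h Dominance of direct effects.
#' @return Scalar selection coefficient.
#' @export
sigma_diploid_additive <- function(x, f, b, params, h = 0.5) {
  sigma_diploid_approx(x, f, b, params,
                       dominance_params(h = h, a1 = 0.25, a2 = 0.5))
}
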