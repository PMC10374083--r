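#' Selection parameters for the introgression fitness model
#'
#' Bundles the three mean fitness effects the model works with: the direct
#' effect of a fixed substitution and the two classes of pairwise epistasis.
#' Alleles that fixed in the same genetic background have been co-filtered by
#' selection, so their mean interaction (`eps_w`) is expected positive;
#' alleles fixed in different backgrounds have never been tested together, so
#' their mean interaction (`eps_b`) is expected weakly negative
#' (incompatibility-like).
#'
#' @param s Mean direct fitness effect of a fixed substitution
#'   (dimensionless; typically negative). Default -0.01.
#' @param eps_w Mean pairwise epistatic effect between alleles fixed in the
#'   same background. Default 1e-3 (an order of magnitude larger than
#'   `|eps_b|` and positive).
#' @param eps_b Mean pairwise epistatic effect between alleles fixed in
#'   different backgrounds. Default -1e-4.
#'
#' @return An object of class `selection_params`.
#' @examples
#' selection_params(s = -0.01, eps_w = 1e-3, eps_b = -1e-4)
#' @export
selection_params <- function(s = -0.01, eps_w = 1e-3, eps_b = -1e-4) {
  stopifnot(length(s) == 1, length(eps_w) == 1, length(eps_b) == 1,
            is.finite(s), is.finite(eps_w), is.finite(eps_b))
  if (1 + s <= 0 || 1 + eps_w <= 0 || 1 + eps_b <= 0) {
    stop("fitness factors must remain positive: require 1+s > 0, ",
         "1+eps_w > 0 and 1+eps_b > 0")
  }
  structure(list(s = s, eps_w = eps_w, eps_b = eps_b),
            class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat(sprintf("selection_params: s=%g, eps_w=%g, eps_b=%g\n",
              x$s, x$eps_w, x$eps_b))
  invisible(x)
}

#' Dominance parameters for the diploid model
#'
#' A rare introgressed haplotype is carried heterozygous. Direct effects are
#' scaled by the dominance coefficient `h`; pairwise epistasis is scaled by
#' `a1` when both interacting derived alleles are heterozygous and by `a2`
#' when one is heterozygous and the other homozygous (homozygous pairs
#' interact at full strength).
#'
#' @param h Dominance of direct effects, in \[0, 1\]. Default 0.5 (additive).
#' @param a1 Heterozygous-heterozygous epistasis scaling. Default 0.25.
#' @param a2 Homozygous-heterozygous epistasis scaling. Default 0.5. The
#'   defaults are the dosage-additive case a1 = a2/2 = 1/4.
#'
#' @return An object of class `dominance_params`.
#' @export
dominance_params <- function(h = 0.5, a1 = 0.25, a2 = 0.5) {
  stopifnot(length(h) == 1, length(a1) == 1, length(a2) == 1,
            is.finite(h), is.finite(a1), is.finite(a2))
  if (h < 0 || h > 1) stop("h must lie in [0, 1]")
  if (a1 > a2) {
    # legal (dominance need not be dosage-monotone) but worth surfacing
    message("note: a1 > a2; heterozygous pairs interact more strongly than ",
            "mixed pairs")
  }
  structure(list(h = h, a1 = a1, a2 = a2), class = "dominance_params")
}

#' @export
print.dominance_params <- function(x, ...) {
  cat(sprintf("dominance_params: h=%g, a1=%g, a2=%g\n", x$h, x$a1, x$a2))
  invisible(x)
}

#' Composition of an introgressing haplotype
#'
#' Counts of the three allele classes a haplotype can carry: `x_new` (derived
#' in the donor only), `x_ancestral` (haplotype carries the ancestral variant
#' at a site where the recipient fixed a derived one) and `x_replacement`
#' (both populations fixed different derived variants). Derived totals:
#' `x = x_new + x_ancestral + x_replacement`, `x_A = x_new + x_replacement`
#' (donor-background derived alleles brought in), `x_B = x_ancestral +
#' x_replacement` (recipient substitutions overwritten).
#'
#' @param x_new,x_ancestral,x_replacement Non-negative integer counts.
#' @return An object of class `haplotype_composition` with fields
#'   `x_new`, `x_ancestral`, `x_replacement`, `x`, `x_A`, `x_B`.
#' @examples
#' haplotype_composition(x_new = 40)
#' @export
haplotype_composition <- function(x_new = 0, x_ancestral = 0,
                                  x_replacement = 0) {
  counts <- c(x_new = x_new, x_ancestral = x_ancestral,
              x_replacement = x_replacement)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("composition counts must be non-negative integers")
  }
  structure(list(x_new = as.integer(x_new),
                 x_ancestral = as.integer(x_ancestral),
                 x_replacement = as.integer(x_replacement),
                 x = as.integer(x_new + x_ancestral + x_replacement),
                 x_A = as.integer(x_new + x_replacement),
                 x_B = as.integer(x_ancestral + x_replacement)),
            class = "haplotype_composition")
}

#' @export
print.haplotype_composition <- function(x, ...) {
  cat(sprintf(
    "haplotype_composition: new=%d ancestral=%d replacement=%d (x=%d, x_A=%d, x_B=%d)\n",
    x$x_new, x$x_ancestral, x$x_replacement, x$x, x$x_A, x$x_B))
  invisible(x)
}

# validate recipient divergence b (number of substitutions fixed in the
# recipient since the common ancestor)
check_divergence <- function(b) {
  if (length(b) != 1 || !is.finite(b) || b < 0 || b != round(b)) {
    stop("divergence b must be a single non-negative integer")
  }
  as.integer(b)
}

# a composition is only meaningful against divergence b when the recipient
# substitutions it touches exist: x_B <= b
check_composition_vs_b <- function(comp, b) {
  if (comp$x_B > b) {
    stop(sprintf(
      "invalid composition: x_ancestral + x_replacement = %d exceeds b = %d",
      comp$x_B, b))
  }
  invisible(TRUE)
}
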