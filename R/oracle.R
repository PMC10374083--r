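# Brute-force fitness over explicit locus sets with per-locus direct effects
# and per-pair epistatic effects. This is the ground truth the closed forms
# are validated against: at zero effect variance it must reproduce the
# count-based products to machine precision, and with nonzero variance it
# checks the averaging assumption behind the closed forms.

# normal draw truncated so every fitness factor stays positive (1 + e > 0);
# effects are tiny so rejections are essentially never triggered
rnorm_trunc <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(1 + x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[1 + x[bad] <= 0]
  }
  x
}

#' Explicit donor/recipient genome pair
#'
#' Materializes the model's averaged parameters as explicit loci and pair
#' effects. The recipient carries `b` derived alleles at loci `1..b`; the
#' haplotype contributes `x_replacement` donor alleles at loci
#' `1..x_replacement` (overlapping recipient loci), removes the recipient
#' alleles at the next `x_ancestral` loci, and adds `x_new` donor alleles at
#' fresh loci. Direct effects are drawn around `s` and pair effects around
#' `eps_w` (same background) or `eps_b` (cross background), truncated so all
#' fitness factors stay positive; `effect_sd = 0` reproduces the means
#' exactly. Same-locus allele pairs at replacement sites carry no
#' interaction (a locus does not interact with itself).
#'
#' @inheritParams sigma_haplotype
#' @param effect_sd Standard deviation of the effect distributions (applied
#'   to direct and pairwise effects alike).
#' @param seed Optional integer seed for the effect draws.
#' @return An object of class `explicit_genome_pair` with fields `alleles`
#'   (data frame: id, background, locus, in_XB, s_i), `eps` (symmetric
#'   pair-effect matrix, same-locus entries NA), `comp`, `b`.
#' @export
explicit_genome_pair <- function(comp, b, params, effect_sd = 0,
                                 seed = NULL) {
  stopifnot(inherits(comp, "haplotype_composition"),
            inherits(params, "selection_params"))
  b <- check_divergence(b)
  check_composition_vs_b(comp, b)
  if (effect_sd < 0) stop("effect_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  x_rep <- comp$x_replacement; x_anc <- comp$x_ancestral; x_new <- comp$x_new
  # recipient alleles at loci 1..b; donor alleles overlap loci 1..x_rep and
  # occupy fresh loci b+1 .. b+x_new; loci x_rep+1 .. x_rep+x_anc are the
  # sites where the haplotype carries the ancestral variant
  alleles <- data.frame(
    background = c(rep("B", b), rep("A", x_rep + x_new)),
    locus = c(seq_len(b),
              if (x_rep > 0) seq_len(x_rep) else integer(),
              if (x_new > 0) b + seq_len(x_new) else integer()),
    stringsAsFactors = FALSE)
  alleles$in_XB <- alleles$background == "B" & alleles$locus <= comp$x_B
  n <- nrow(alleles)
  alleles$s_i <- rnorm_trunc(n, params$s, effect_sd)
  eps <- matrix(NA_real_, n, n)
  if (n >= 2) {
    within <- outer(alleles$background, alleles$background, "==")
    mean_mat <- ifelse(within, params$eps_w, params$eps_b)
    ut <- upper.tri(eps)
    mu <- mean_mat[ut]
    draws <- if (effect_sd == 0) mu else stats::rnorm(length(mu), mu, effect_sd)
    bad <- which(1 + draws <= 0)
    while (length(bad) > 0) {
      draws[bad] <- stats::rnorm(length(bad), mu[bad], effect_sd)
      bad <- bad[1 + draws[bad] <= 0]
    }
    eps[ut] <- draws
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    same_locus <- outer(alleles$locus, alleles$locus, "==")
    eps[same_locus] <- NA_real_
  }
  structure(list(alleles = alleles, eps = eps, comp = comp, b = b),
            class = "explicit_genome_pair")
}

#' Genotypes for the explicit pair
#'
#' `resident_genotype()` is the average recipient individual (all recipient
#' alleles, homozygous in the diploid case); `carrier_genotype()` is an
#' individual bearing the introgressed haplotype: donor alleles present
#' (heterozygous if diploid), recipient alleles at overwritten sites absent
#' (haploid) or heterozygous (diploid, the homologous chromosome still
#' carries them), remaining recipient alleles present/homozygous.
#'
#' @param pair An [explicit_genome_pair()].
#' @param diploid Logical; use heterozygous states.
#' @return Integer vector of per-allele states: 0 absent, 1 heterozygous,
#'   2 present/homozygous.
#' @export
carrier_genotype <- function(pair, diploid = FALSE) {
  al <- pair$alleles
  g <- integer(nrow(al))
  g[al$background == "A"] <- if (diploid) 1L else 2L
  g[al$background == "B" & !al$in_XB] <- 2L
  g[al$background == "B" & al$in_XB] <- if (diploid) 1L else 0L
  g
}

#' @rdname carrier_genotype
#' @export
resident_genotype <- function(pair, diploid = FALSE) {
  al <- pair$alleles
  ifelse(al$background == "B", 2L, 0L)
}

#' Fitness of an explicit genotype
#'
#' Product over present alleles of `(1 + s_i)` (scaled by `h` when
#' heterozygous under a diploid model) times the product over co-present
#' allele pairs of `(1 + eps_ij)` scaled by `a1` (het-het), `a2` (het-hom)
#' or 1 (hom-hom); same-locus pairs are skipped. The number of pair factors
#' evaluated is attached as attribute `n_pair_factors`.
#'
#' @param g Integer state vector as returned by [carrier_genotype()].
#' @param pair An [explicit_genome_pair()].
#' @param dom A [dominance_params()] object, or `NULL` for haploid (states
#'   must then avoid the heterozygous code).
#' @return Scalar fitness with attribute `n_pair_factors`.
#' @export
fitness_explicit <- function(g, pair, dom = NULL) {
  stopifnot(inherits(pair, "explicit_genome_pair"))
  if (length(g) != nrow(pair$alleles)) {
    stop("genotype length does not match the pair's allele set")
  }
  if (is.null(dom) && any(g == 1L)) {
    stop("haploid genotypes use only absent/present states")
  }
  present <- which(g > 0L)
  dscale <- if (is.null(dom)) rep(1, length(present)) else
    ifelse(g[present] == 1L, dom$h, 1)
  w <- prod(1 + dscale * pair$alleles$s_i[present])
  n_pairs <- 0L
  if (length(present) >= 2) {
    st <- g[present]
    eps <- pair$eps[present, present, drop = FALSE]
    keep <- upper.tri(eps) & !is.na(eps)   # NA marks same-locus pairs
    if (is.null(dom)) {
      scale <- matrix(1, nrow(eps), ncol(eps))
    } else {
      n_het <- outer(st == 1L, st == 1L, `+`)
      scale <- ifelse(n_het == 2L, dom$a1, ifelse(n_het == 1L, dom$a2, 1))
    }
    w <- w * prod(1 + (scale * eps)[keep])
    n_pairs <- sum(keep)
  }
  attr(w, "n_pair_factors") <- n_pairs
  w
}

#' Brute-force selection coefficient with effect-size variance
#'
#' Draws explicit per-locus and per-pair effects around the model means,
#' evaluates the carrier-versus-resident relative fitness exactly, and
#' repeats over replicates. With `effect_sd = 0` every replicate equals the
#' closed-form exact selection coefficient ([sigma_haplotype()] or
#' [sigma_diploid()]) to machine precision; with nonzero spread the mean
#' over replicates concentrates on the closed form, validating the
#' low-variance averaging the closed forms rely on.
#'
#' @inheritParams explicit_genome_pair
#' @param dom Optional [dominance_params()] for a diploid carrier.
#' @param n_rep Number of replicates; replicate `r` uses `seed + r - 1`.
#' @param seed Integer base seed.
#' @return List with `mean`, `sd`, and the per-replicate vector `sigma`.
#' @export
sigma_explicit <- function(comp, b, params, effect_sd = 0, seed = 1,
                           dom = NULL, n_rep = 1) {
  stopifnot(n_rep >= 1)
  diploid <- !is.null(dom)
  sig <- vapply(seq_len(n_rep), function(r) {
    pair <- explicit_genome_pair(comp, b, params, effect_sd,
                                 seed = seed + r - 1)
    w_i <- fitness_explicit(carrier_genotype(pair, diploid), pair, dom)
    w_bar <- fitness_explicit(resident_genotype(pair, diploid), pair, dom)
    as.numeric(w_i) / as.numeric(w_bar) - 1
  }, numeric(1))
  list(mean = mean(sig), sd = stats::sd(sig), sigma = sig)
}
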