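---
title: "Modeling selection on introgressing haplotypes and scanning for introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling selection on introgressing haplotypes and scanning for introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introsel)
```

## The model

A haplotype — a non-recombining block of the genome — introgresses from a
donor population A into a recipient population B that has fixed `b` derived
substitutions since their common ancestor. Fitness is relative to the
ancestor and multiplicative over effects: each derived allele contributes a
direct factor `(1 + s)`, each pair of derived alleles an epistatic factor.
The key asymmetry is between the two classes of pairwise epistasis:

* **within-background epistasis** `eps_w` — interactions among alleles that
  fixed in the same population. These have been filtered by selection as
  they fixed, so their mean is expected to be positive;
* **between-background epistasis** `eps_b` — interactions among alleles
  fixed in different populations. These have never been tested together, so
  their mean is expected to be weakly negative (the
  Dobzhansky–Muller-incompatibility expectation), typically an order of
  magnitude smaller than `eps_w`.

The recipient's mean fitness is `(1+s)^b (1+eps_w)^C(b,2)`: direct effects
accumulate linearly with divergence, pairwise interactions quadratically.
A haplotype carries three classes of sites — `x_new` alleles derived only
in the donor, `x_ancestral` sites where it restores the ancestral variant
over a recipient substitution, and `x_replacement` sites where both
populations fixed different derived variants. Writing
`x_A = x_new + x_replacement` and `x_B = x_ancestral + x_replacement`, a
carrier holds `x_A + (b - x_B)` derived alleles; its fitness is the product
over those direct effects, the same-background pairs within `x_A` and
within the untouched recipient set, and the `x_A (b - x_B)` cross pairs.
The effective selection coefficient is the carrier-to-mean fitness ratio
minus one (`sigma_haplotype()`, exact mode). Expanding to first order in
the effects gives the small-effect approximation

```
sigma ≈ s (x_A - x_B) + (eps_w/2) (x_A^2 - x_A - x_B (2b - x_B - 1)) + eps_b x_A (b - x_B)
```

and, with the ancestral fraction `f = x_ancestral / x` and no replacement
alleles, the fraction form implemented by `sigma_fraction()`. Because the
haplotype's own co-adapted interactions grow quadratically in `x` while its
incompatibilities grow only linearly in `b`, large blocks can be favored
early in divergence even when each allele is individually deleterious.

```{r single-alleles}
p <- selection_params(s = -0.01, eps_w = 1e-3, eps_b = -1e-4)
c(new = sigma_allele("new", 60, p, "approx"),
  ancestral = sigma_allele("ancestral", 60, p, "approx"),
  replacement = sigma_allele("replacement", 60, p, "approx"))
```

## The critical haplotype size

With `eps_w > 0 > eps_b` and direct effects ignored (`s = 0`), the fraction
form is a quadratic in `x` anchored at `sigma = 0` for `x = 0`: selection
against the haplotype strengthens up to a critical size

```
x* = b (eps_w f - eps_b (1 - f)) / (eps_w - 2 f (1 - f)(eps_w + eps_b))
```

and weakens beyond it. We implement the closed form without the
`-(1-2f) eps_w / 2` numerator offset that the literal derivative carries:
the offset is O(1) against the `b`-proportional numerator, and dropping it
is what makes the exact special cases hold (`f = 0` gives
`-b eps_b / eps_w`; `f = 1/2` and `f = 1` give `b`). The exhaustive integer
minimizer `argmin_size()` retains the offset implicitly and is documented
to differ by at most about one allele at `s = 0`.

```{r critical}
critical_size(0, 1000, selection_params(0, eps_w = 1e-4, eps_b = -1e-6))
argmin_size(0, 200, selection_params(0, 1e-4, -1e-4), x_max = 400)$x
```

## Diploid carriers and dominance of epistasis

A rare haplotype is always heterozygous, and at each overwritten site the
carrier still holds the recipient's derived allele on the homologous
chromosome. Direct effects scale by the dominance `h`; epistasis scales by
`a1` between two heterozygous derived alleles and `a2` between a
heterozygous and a homozygous one. The diploid exact product
(`sigma_diploid()`) therefore multiplies `(1 + h s)` over all haplotype-site
alleles, `(1 + s)` over untouched substitutions, and the seven pair classes
at their dominance-scaled strengths; replacement sites contribute one
donor-background and one recipient-background heterozygous allele whose
same-locus pair is excluded (a locus does not interact with itself). Under
dosage-additive epistasis each heterozygous allele carries half dosage, so
`a1 = 1/4` and `a2 = 1/2`; `sigma_diploid_additive()` is that substitution.
When `h = f` the direct terms cancel exactly and only epistasis acts.
Recessive epistasis (`a1 = a2 = 0`) silences the new interactions the
haplotype brings while the removal of existing recipient interactions
persists, which is why it selects against mixed haplotypes more strongly
than dominant epistasis does.

## The explicit-genome oracle

The closed forms average over effects; `sigma_explicit()` does not. It
materializes every locus and every pair with its own effect drawn around
the model means (normal, truncated so all fitness factors stay positive —
only the means and a "low variance" are assumed, so a truncated normal is
the minimal choice), evaluates carrier and resident fitness by brute-force
products, and repeats over replicates with seeds `seed + r - 1`. At
`effect_sd = 0` it must match the closed forms to machine precision — that
equivalence, over randomized compositions with `b ≤ 40`, `x ≤ 30`, is the
package's core correctness test. With nonzero spread the replicate mean
concentrates on the closed form, validating the averaging assumption for
unstructured interaction networks (highly structured networks are outside
the model's averaging assumption and out of scope).

## Parameter choices

The illustration defaults are `s = -0.01`, `eps_b = -1e-4`, and `eps_w`
one order of magnitude larger and positive (`1e-3`): within-background
interactions are selection-filtered upward and empirically an order of
magnitude stronger than untested cross-background ones, and `s` is set
larger than either epistatic effect. These values are deliberately large so
that curve shapes are visible at desk scale; conclusions should be read
from shapes, not magnitudes. Fitness composition is multiplicative by
default (`combine = "additive"` is exposed as a toggle; the two agree to
first order and the multiplicative form is the tested contract).
`sigma_fraction()` evaluates real-valued `x` without rounding; integer
consistency with the composition form is asserted only where both parts
are integral.

## The genome scan

The scan tests a prediction of the model on window data from four
populations related as (outgroup, (donor, (sister, focal))): introgression
from the donor into the focal population should avoid windows in which the
focal population has diverged most, and (at shallow divergence) should
concentrate in low-recombination windows.

* `hudson_fst()` — Hudson's ratio-of-averages estimator from per-site
  derived-allele counts. The estimator dialect is a package choice (the
  windowed-F_ST tooling a scan would normally use leaves the dialect
  open); it is well defined from counts, can be negative, and is recorded
  in output provenance. Sites fixed identically in both populations are
  0/0 and excluded; an all-uninformative window is missing, not 0.
* `pbs()` — branch lengths `T = -log(1 - F_ST)` apportioned as
  `PBS_A = (T_AB + T_AC - T_BC)/2` and cyclic permutations.
* `branch_scores()` — negative PBS values are clamped to 0 (they have no
  branch-length interpretation), then each window's triple is normalized to
  sum to one, reading as the proportion of evolution on each branch.
  Windows with any negative raw value are flagged so the stricter
  drop-them variant (`drop_negative_pbs = TRUE`) and the unclamped variant
  (`clamp = FALSE`) are both one switch away; "any negative" is read as
  any of the three branches.
* `f_d()` — the windowed introgression-proportion statistic from site
  frequencies, with the donor role at each site played by whichever of
  recipient/donor has the higher derived frequency (the standard dynamic
  denominator). Frequencies, not genotype likelihoods, are the input.
* `fit_introgression_model()` — OLS of `f_d` on window predictors,
  one single-predictor model per term by default (slopes reported per
  panel), restricted to windows with `f_d > 0`; two-sided t-test p-values,
  no multiple-testing correction; machine-precision collinearity aborts
  the fit rather than silently dropping a term.

Coordinates are 0-based half-open everywhere, declared in every output
header.

## The synthetic window generator

`simulate_scan()` generates the statistical structure the scan assumes,
desk-scale and analytically transparent — it is a frequency-mixing
generator, not a coalescent simulation. Ancestral site frequencies are
uniform on (0.05, 0.95); each branch applies Balding–Nichols drift (child
frequency Beta-distributed with mean the parent frequency and variance
scaled by the branch `F`); introgressed windows replace focal frequencies
by `(1 - alpha) p_focal + alpha p_donor`; counts are binomial at the
configured sample sizes. Two features mirror how such scans are actually
run. First, the focal and outgroup branches draw window-level `F` values
(gamma-distributed), creating the across-window branch-score heterogeneity
a real genome shows. Second, the F_ST panels are *separate, unadmixed*
draws for every population (`c_*_panel` columns) — the counterpart of
computing differentiation only from individuals without introgressed
ancestry — so branch scores are not shortened by the introgression being
scanned for, and panel sampling noise is independent of the f_D samples.

The preset (`preset_drosophila_like()`) emulates a shallow-divergence
scenario: branch `F` values of a few percent, introgression in ~20% of
windows at admixture proportion 0.7, recombination gamma-distributed with
mean 2 cM/Mb, and introgression probability decaying exponentially in
recombination rate (rate 1.5 per cM/Mb) and in focal-branch drift (rate 45
per unit `F`). The couplings are calibrated so that a 5000-window scan
recovers the target sign pattern with wide margins: negative f_D slopes on
recombination and on the focal branch score (p well below 0.05), and no
significant donor-branch slope. Setting both couplings to 0 is the null
configuration under which all slopes are non-significant.

What the generator does *not* emulate: linkage within windows (sites are
independent, which leaves the expectations of the site-sum statistics
unchanged but understates their window-to-window variance relative to real
LD), haplotype tract lengths, selection at linked sites, and ascertainment
of SNPs. Passing tests therefore show that the pipeline recovers the
structure it assumes, not that real data satisfy those assumptions.

```{r scan, eval = FALSE}
sim <- simulate_scan(preset_drosophila_like(seed = 1))
scan <- run_scan(sim$window_set)
fit_introgression_model(scan,
                        terms = c("recomb", "score_focal", "score_donor"))
```

## Numerical choices and degenerate inputs

* Exact products use real-valued factor multiplicities (generalized
  `n(n-1)/2` pair counts) so that sweep grids can evaluate fractional
  `(1-f) x`; on integer compositions this coincides with the combinatorial
  product.
* A zero-size haplotype returns exactly 0 (the carrier *is* the resident),
  short-circuited before any floating-point ratio.
* `critical_size()` refuses a zero denominator (degenerate landscape);
  compositions with `x_B > b` and F_ST counts above the sample size are
  errors, not NAs; an F_ST of 1 maps to an infinite PBS and is flagged.
* `argmin_size()` breaks ties toward the smaller haplotype.
* Sweep cells violating `f x ≤ b` are emitted with `status = "infeasible"`
  rather than dropped, so grid shapes are predictable.
* Generated drift `F` values are clipped to `[1e-4, 0.6]` and frequencies
  to `(1e-6, 1 - 1e-6)` before binomial sampling, keeping Beta and
  binomial parameters valid in the extreme tails.

Two printed simplifications of the haploid limits are ambiguous in the
field's shorthand, and both readings are exposed rather than silently
chosen: `sigma_new_only()` defaults to the `f = 0` reduction of the
fraction form (`(eps_w/2)(x^2 - x)`, consistent with the haplotype
approximation) with the doubled `eps_w x^2` variant as
`form = "printed"`, and `sigma_late_replacement()` defaults to the
all-replacement reduction `x (b - x)(eps_b - eps_w)` with the `x b eps_b`
magnitude guide as `form = "printed"`.

## Problem sizes

The test suite validates the closed forms against the brute-force oracle on
100 randomized compositions with `b ≤ 40`, `x ≤ 30` (the oracle is
quadratic in locus count, and these sizes already exercise every factor
class), sweeps figure regimes at `b ≤ 100`, `x ≤ 150`, and runs the scan
acceptance check at 5000 windows of 200 SNPs with samples of 20
chromosomes per population — the scale at which the regression's sign
pattern is stable across seeds while a full check stays comfortably within
a coffee break.

## Limitations

The model treats mean effects only (low-variance assumption), pairwise
epistasis only, a rare non-recombining haplotype (no trajectory dynamics,
no fixation probabilities), and at most two alleles per locus. The scan
statistics inherit the usual caveats of F_ST-derived branch lengths at
shallow divergence (sampling noise comparable to drift signal) and of f_D
with small samples (attenuation through the noisy dynamic denominator).
Recombination inside the haplotype, linkage maps, and coalescent realism
in the generator are explicitly out of scope.
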