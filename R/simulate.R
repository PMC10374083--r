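# Synthetic four-population window generator. Emulates the statistical
# structure the scan assumes: populations related as
# (outgroup, (donor, (sister, focal))), per-branch Balding-Nichols drift
# with window-level heterogeneity on the focal and outgroup branches,
# window-level introgression from donor into focal by frequency mixing, and
# heterogeneous recombination with introgression preferentially entering
# low-recombination, low-focal-drift windows. Frequency mixing (rather than
# coalescent simulation) keeps the generator analytically transparent;
# sites are independent within windows, which leaves the expectations of
# the site-sum statistics (F_ST, f_D) unaffected.

# Balding-Nichols drift: child frequency ~ Beta with mean p and variance
# p(1-p)F; vectorized over sites, F recycled per window
bn_drift <- function(p, f_drift) {
  shape1 <- p * (1 - f_drift) / f_drift
  shape2 <- (1 - p) * (1 - f_drift) / f_drift
  stats::rbeta(length(p), shape1, shape2)
}

#' Configuration for the synthetic scan generator
#'
#' Drift is parameterized per branch of the population tree
#' (O, (P3, (P1, P2))) by Balding-Nichols F values. The focal (P2) and
#' outgroup (O) branches use window-level F values drawn from gamma
#' distributions, creating the across-window PBS heterogeneity a real scan
#' shows; donor (P3), sister (P1) and the shared internal branch use fixed
#' F. A fraction of windows receives introgression: focal frequencies are
#' replaced by `(1-alpha) p2 + alpha p3`. The probability a window is
#' introgressed decays with its recombination rate and its focal-branch
#' drift (coupling strengths `couple_recomb`, `couple_focal`), producing
#' the negative recombination/introgression and focal-branch/introgression
#' relationships the scan is meant to recover.
#'
#' @param n_windows Number of windows.
#' @param sites_per_window SNPs per window (default 200).
#' @param n_hap Named sampled-chromosome counts (`p1`, `p2`, `p2_panel`,
#'   `p3`, `o`).
#' @param f_outgroup_mean,f_outgroup_shape Gamma mean/shape for the
#'   window-level outgroup-branch F.
#' @param f_internal F on the shared internal branch (root to the
#'   donor+focal clade ancestor).
#' @param f_donor F on the donor branch.
#' @param f_ooa F on the branch to the sister+focal ancestor.
#' @param f_sister F on the sister branch.
#' @param f_focal_mean,f_focal_shape Gamma mean/shape for the window-level
#'   focal-branch F.
#' @param intro_frac Expected fraction of windows carrying introgression.
#' @param alpha Admixture proportion mixed into focal frequencies in
#'   introgressed windows.
#' @param recomb_shape,recomb_mean Gamma shape/mean of per-window
#'   recombination rate (cM/Mb).
#' @param couple_recomb,couple_focal Exponential decay rates of the
#'   introgression probability in recombination rate and focal-branch F;
#'   set both to 0 for independence (null configuration).
#' @param seed Integer seed.
#' @return Object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_windows = 5000, sites_per_window = 200,
                       n_hap = c(p1 = 20, p2 = 20, p2_panel = 20,
                                 p3 = 20, p3_panel = 20,
                                 o = 20, o_panel = 20),
                       f_outgroup_mean = 0.10, f_outgroup_shape = 2,
                       f_internal = 0.05, f_donor = 0.01,
                       f_ooa = 0.03, f_sister = 0.02,
                       f_focal_mean = 0.05, f_focal_shape = 1.2,
                       intro_frac = 0.2, alpha = 0.7,
                       recomb_shape = 4, recomb_mean = 2,
                       couple_recomb = 1.5, couple_focal = 45,
                       seed = 1) {
  cfg <- list(n_windows = n_windows, sites_per_window = sites_per_window,
              n_hap = n_hap,
              f_outgroup_mean = f_outgroup_mean,
              f_outgroup_shape = f_outgroup_shape,
              f_internal = f_internal, f_donor = f_donor, f_ooa = f_ooa,
              f_sister = f_sister, f_focal_mean = f_focal_mean,
              f_focal_shape = f_focal_shape, intro_frac = intro_frac,
              alpha = alpha, recomb_shape = recomb_shape,
              recomb_mean = recomb_mean, couple_recomb = couple_recomb,
              couple_focal = couple_focal, seed = seed)
  fracs <- c(intro_frac, alpha)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  fixed_f <- c(f_internal, f_donor, f_ooa, f_sister)
  if (any(fixed_f <= 0 | fixed_f >= 1)) stop("branch F values must lie in (0, 1)")
  if (n_windows < 1 || sites_per_window < 1) stop("empty simulation")
  if (any(n_hap < 2)) stop("sample sizes must be at least 2")
  structure(cfg, class = "sim_config")
}

#' Generator preset emulating a shallow-divergence introgression scan
#'
#' Returns the default [sim_config()] with the supplied seed: four
#' populations at shallow divergence, introgression in a minority of
#' windows, concentrated in low-recombination, low-focal-drift windows. A
#' scan of the generated windows recovers negative f_D slopes on
#' recombination rate and on the focal branch score, and no significant
#' relationship with the donor branch score.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
preset_drosophila_like <- function(seed = 1) {
  sim_config(seed = seed)
}

#' Simulate a window table from a generator configuration
#'
#' Ancestral site frequencies are drawn uniformly in (0.05, 0.95), each
#' branch applies Balding-Nichols drift, introgressed windows mix donor
#' frequencies into the focal population, and per-site derived-allele
#' counts are drawn binomially at the configured sample sizes. The focal
#' panel counts (`c_p2_panel`) are drawn from the unadmixed focal
#' frequencies, emulating an F_ST panel restricted to individuals without
#' introgressed ancestry; `c_p2` is drawn from the admixed frequencies.
#'
#' @param config A [sim_config()].
#' @return List of class `introgression_sim`: `window_set` (a
#'   [window_set()]) and `truth` (data frame: `window_id`, `introgressed`,
#'   `f_focal`, `f_outgroup`, `recomb`).
#' @export
simulate_scan <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nw <- config$n_windows
  m <- config$sites_per_window
  total <- nw * m
  clip_f <- function(x) pmin(pmax(x, 1e-4), 0.6)
  f_focal_w <- clip_f(stats::rgamma(nw, shape = config$f_focal_shape,
                                    rate = config$f_focal_shape / config$f_focal_mean))
  f_out_w <- clip_f(stats::rgamma(nw, shape = config$f_outgroup_shape,
                                  rate = config$f_outgroup_shape / config$f_outgroup_mean))
  recomb <- stats::rgamma(nw, shape = config$recomb_shape,
                          rate = config$recomb_shape / config$recomb_mean)
  # introgression targets low-recombination, low-focal-drift windows
  w <- exp(-config$couple_recomb * recomb - config$couple_focal * f_focal_w)
  p_intro <- pmin(config$intro_frac * w / mean(w), 1)
  introgressed <- stats::rbinom(nw, 1, p_intro) == 1
  # site frequencies down the tree (O, (P3, (P1, P2)))
  clip_p <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  p0 <- stats::runif(total, 0.05, 0.95)
  per_site <- function(x) rep(x, each = m)
  p_o <- bn_drift(p0, per_site(f_out_w))
  p_int <- bn_drift(p0, config$f_internal)
  p_donor <- bn_drift(p_int, config$f_donor)
  p_ooa <- bn_drift(p_int, config$f_ooa)
  p_sister <- bn_drift(p_ooa, config$f_sister)
  p_focal <- bn_drift(p_ooa, per_site(f_focal_w))
  p_focal_adm <- ifelse(per_site(introgressed),
                        (1 - config$alpha) * p_focal +
                          config$alpha * p_donor,
                        p_focal)
  nh <- config$n_hap
  # panel counts are independent draws from the unadmixed frequencies,
  # emulating F_ST panels restricted to individuals without introgressed
  # ancestry (distinct individuals from the f_D samples)
  sites <- data.frame(
    window_id = per_site(seq_len(nw)),
    c_p1 = stats::rbinom(total, nh[["p1"]], clip_p(p_sister)),
    c_p2 = stats::rbinom(total, nh[["p2"]], clip_p(p_focal_adm)),
    c_p3 = stats::rbinom(total, nh[["p3"]], clip_p(p_donor)),
    c_o = stats::rbinom(total, nh[["o"]], clip_p(p_o)),
    c_p2_panel = stats::rbinom(total, nh[["p2_panel"]], clip_p(p_focal)),
    c_p3_panel = stats::rbinom(total, nh[["p3_panel"]], clip_p(p_donor)),
    c_o_panel = stats::rbinom(total, nh[["o_panel"]], clip_p(p_o)))
  win_len <- 10000L
  windows <- data.frame(
    window_id = seq_len(nw),
    chrom = "chrS",
    start = (seq_len(nw) - 1L) * win_len,
    end = seq_len(nw) * win_len,
    n_sites = m,
    recomb = recomb)
  truth <- data.frame(window_id = seq_len(nw), introgressed = introgressed,
                      f_focal = f_focal_w, f_outgroup = f_out_w,
                      recomb = recomb)
  structure(list(window_set = window_set(windows, sites, nh), truth = truth,
                 config = config),
            class = "introgression_sim")
}
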