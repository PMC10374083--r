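# Parameter-sweep engines: tidy long-format tables over haplotype size,
# divergence, ancestral fraction and composition, plus the numeric
# fitness-minimum locator. All sweeps are pure functions of their inputs.

#' Sweep the selection coefficient over size, divergence and composition
#'
#' Evaluates the haplotype selection coefficient over the Cartesian grid of
#' `x_grid`, `b_values` and `f_values`. Exact values use the product form
#' with real-valued factor multiplicities (`x_A = (1-f) x`, `x_B = f x`);
#' approximate values use the first-order fraction form. Grid cells that are
#' infeasible (`f x > b`: the haplotype would overwrite more substitutions
#' than exist) are emitted with `status = "infeasible"` and `NA` values
#' rather than dropped, so output shapes are predictable.
#'
#' @param x_grid Numeric vector of haplotype sizes.
#' @param b_values Integer vector of recipient divergences.
#' @param f_values Numeric vector of ancestral fractions in \[0, 1\].
#' @param params A [selection_params()] object.
#' @param dom Optional [dominance_params()]; when supplied the diploid model
#'   is swept.
#' @param mode `"both"` (default), `"exact"` or `"approx"`.
#' @return A long-format data frame with columns `x`, `b`, `f`, `status`,
#'   and `sigma_exact` / `sigma_approx` as requested.
#' @export
curve_sweep <- function(x_grid, b_values, f_values = 0, params,
                        dom = NULL, mode = c("both", "exact", "approx")) {
  mode <- match.arg(mode)
  stopifnot(length(x_grid) > 0, length(b_values) > 0, length(f_values) > 0,
            inherits(params, "selection_params"))
  if (any(f_values < 0 | f_values > 1)) stop("f values must lie in [0, 1]")
  grid <- expand.grid(x = x_grid, b = b_values, f = f_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$status <- ifelse(grid$f * grid$x > grid$b, "infeasible", "ok")
  ok <- grid$status == "ok"
  eval_one <- function(x, f, b, m) {
    x_A <- (1 - f) * x
    x_B <- f * x
    if (x == 0) return(0)
    if (is.null(dom)) {
      sigma_haploid_core(x_A, x_B, b, params, mode = m)
    } else {
      sigma_diploid_core(x_A, x_B, 0, b, params, dom, mode = m)
    }
  }
  if (mode %in% c("both", "exact")) {
    grid$sigma_exact <- NA_real_
    grid$sigma_exact[ok] <- mapply(eval_one, grid$x[ok], grid$f[ok],
                                   grid$b[ok], MoreArgs = list(m = "exact"))
  }
  if (mode %in% c("both", "approx")) {
    grid$sigma_approx <- NA_real_
    grid$sigma_approx[ok] <- mapply(eval_one, grid$x[ok], grid$f[ok],
                                    grid$b[ok], MoreArgs = list(m = "approx"))
  }
  grid
}

#' Sweep the selection coefficient over ternary compositions
#'
#' Enumerates all compositions `(x_new, x_ancestral, x_replacement)` summing
#' to `x_total` in steps of `step` and evaluates the exact (and optionally
#' approximate) haploid selection coefficient for each. Compositions that
#' would overwrite more recipient substitutions than exist
#' (`x_ancestral + x_replacement > b`) are flagged `infeasible`.
#'
#' @param x_total Total haplotype size.
#' @param b Recipient divergence.
#' @param params A [selection_params()] object.
#' @param step Grid step; must divide `x_total`.
#' @param mode `"both"` (default), `"exact"` or `"approx"`.
#' @return Data frame with columns `x_new`, `x_ancestral`, `x_replacement`,
#'   `status` and the requested sigma columns.
#' @export
ternary_sweep <- function(x_total, b, params, step = 1,
                          mode = c("both", "exact", "approx")) {
  mode <- match.arg(mode)
  b <- check_divergence(b)
  stopifnot(inherits(params, "selection_params"),
            x_total >= 0, step >= 1)
  if (x_total %% step != 0) stop("step must divide x_total")
  if (x_total == 0) {
    out <- data.frame(x_new = 0L, x_ancestral = 0L, x_replacement = 0L,
                      status = "ok")
    if (mode %in% c("both", "exact")) out$sigma_exact <- 0
    if (mode %in% c("both", "approx")) out$sigma_approx <- 0
    return(out)
  }
  vals <- seq(0L, x_total, by = step)
  grid <- expand.grid(x_new = vals, x_ancestral = vals,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$x_new + grid$x_ancestral <= x_total, , drop = FALSE]
  grid$x_replacement <- x_total - grid$x_new - grid$x_ancestral
  grid$status <- ifelse(grid$x_ancestral + grid$x_replacement > b,
                        "infeasible", "ok")
  eval_mode <- function(m) {
    vapply(seq_len(nrow(grid)), function(i) {
      if (grid$status[i] != "ok") return(NA_real_)
      comp <- haplotype_composition(grid$x_new[i], grid$x_ancestral[i],
                                    grid$x_replacement[i])
      sigma_haplotype(comp, b, params, mode = m)
    }, numeric(1))
  }
  if (mode %in% c("both", "exact")) grid$sigma_exact <- eval_mode("exact")
  if (mode %in% c("both", "approx")) grid$sigma_approx <- eval_mode("approx")
  rownames(grid) <- NULL
  grid
}

#' Integer haplotype size of strongest selection
#'
#' Exhaustively scans integer sizes `x` in `[0, x_max]` of the fraction-form
#' selection coefficient and returns the minimizer (ties broken toward the
#' smaller size). With `s = 0` this agrees with the closed-form
#' [critical_size()] to within about one allele (the closed form drops an
#' O(1) offset term).
#'
#' @inheritParams sigma_fraction
#' @param x_max Largest size scanned.
#' @return List with `x` (integer argmin), `sigma` (value at the minimum).
#' @export
argmin_size <- function(f, b, params, x_max) {
  stopifnot(x_max >= 1)
  b <- check_divergence(b)
  xs <- 0:x_max
  xs <- xs[f * xs <= b]   # respect the composition constraint
  sig <- vapply(xs, function(x) sigma_fraction(x, f, b, params), numeric(1))
  i <- which.min(sig)     # which.min takes the first (smallest x) on ties
  list(x = as.integer(xs[i]), sigma = sig[i])
}

#' Named figure-regime presets for [curve_sweep()] and [ternary_sweep()]
#'
#' Canonical illustration regimes: `fig2a` (new-alleles-only curves,
#' `f = 0`, `b` in 20/60/100), `fig2b` (size fixed sweep over `f`), `fig3`
#' and `s1` (ternary composition sweeps at `b = 60`, `x = 40`), `s5`
#' (diploid sweeps across dominance settings). Returns the sweep table(s)
#' for the named regime with all parameters recorded as attributes.
#'
#' @param preset One of `"fig2a"`, `"fig2b"`, `"fig3"`, `"s1"`, `"s5"`.
#' @return A data frame (or named list of data frames for `"s5"`).
#' @export
sweep_preset <- function(preset = c("fig2a", "fig2b", "fig3", "s1", "s5")) {
  preset <- match.arg(preset)
  p_fig <- selection_params(s = -0.01, eps_w = 1e-3, eps_b = -1e-4)
  p_s1 <- selection_params(s = 0, eps_w = 1e-3, eps_b = -1e-4)
  out <- switch(preset,
    fig2a = curve_sweep(0:150, c(20L, 60L, 100L), 0, p_fig),
    fig2b = curve_sweep(0:60, 60L, seq(0, 1, by = 0.25), p_fig),
    fig3 = ternary_sweep(40L, 60L, p_fig, step = 1),
    s1 = ternary_sweep(40L, 60L, p_s1, step = 1),
    s5 = {
      doms <- list(recessive = dominance_params(h = 0.5, a1 = 0, a2 = 0),
                   additive = dominance_params(h = 0.5, a1 = 0.25, a2 = 0.5),
                   dominant = dominance_params(h = 0.5, a1 = 1, a2 = 1))
      lapply(doms, function(d)
        curve_sweep(0:60, 60L, seq(0, 1, by = 0.25), p_fig, dom = d,
                    mode = "exact"))
    })
  attr(out, "preset") <- preset
  out
}
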