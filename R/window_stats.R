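# Per-window population-genetic statistics: Hudson F_ST from allele counts,
# the population branch statistic (PBS), clamped/normalized branch scores,
# the windowed f_D introgression statistic, and the f_D ~ predictors
# regression.

#' Hudson F_ST from per-site derived-allele counts
#'
#' Ratio-of-averages Hudson estimator. Per site with sample frequencies
#' `p_i`, `p_j` and sample sizes `n_i`, `n_j`, the numerator is
#' `(p_i - p_j)^2 - p_i(1-p_i)/(n_i - 1) - p_j(1-p_j)/(n_j - 1)` and the
#' denominator `p_i(1-p_j) + p_j(1-p_i)`; the window estimate is the sum of
#' numerators over the sum of denominators. Sites fixed identically in both
#' populations contribute 0/0 and are excluded from both sums; a window with
#' no informative site returns `NA`. The estimate may be negative.
#'
#' @param counts_i,counts_j Integer vectors of derived-allele counts per
#'   site.
#' @param n_i,n_j Sample sizes (number of sampled chromosomes), >= 2.
#' @return Scalar F_ST estimate, or `NA` if no site is informative.
#' @examples
#' hudson_fst(8, 2, 10, 10)  # 0.477...
#' @export
hudson_fst <- function(counts_i, counts_j, n_i, n_j) {
  stopifnot(length(counts_i) == length(counts_j), n_i >= 2, n_j >= 2)
  if (any(counts_i > n_i) || any(counts_j > n_j) ||
      any(counts_i < 0) || any(counts_j < 0)) {
    stop("counts must lie in [0, sample size]")
  }
  p_i <- counts_i / n_i
  p_j <- counts_j / n_j
  den <- p_i * (1 - p_j) + p_j * (1 - p_i)
  keep <- den > 0   # drops sites fixed identically in both populations
  if (!any(keep)) return(NA_real_)
  num <- (p_i - p_j)^2 - p_i * (1 - p_i) / (n_i - 1) -
    p_j * (1 - p_j) / (n_j - 1)
  sum(num[keep]) / sum(den[keep])
}

#' Population branch statistic from three pairwise F_ST values
#'
#' Transforms each F_ST to a branch-length scale, `T = -log(1 - F_ST)`, and
#' apportions it to the three populations:
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` and cyclic permutations. An F_ST of 1
#' maps to an infinite branch and is passed through as `Inf` with a warning.
#' All arguments are vectorized over windows.
#'
#' @param fst_ab,fst_ac,fst_bc Pairwise F_ST estimates for populations
#'   A, B, C.
#' @return Data frame with columns `pbs_a`, `pbs_b`, `pbs_c` (may be
#'   negative when the F_ST triple is non-treelike).
#' @examples
#' pbs(0.2, 0.2, 0)  # pbs_a = -log(0.8), pbs_b = pbs_c = 0
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  n <- max(length(fst_ab), length(fst_ac), length(fst_bc))
  fst_ab <- rep_len(fst_ab, n)
  fst_ac <- rep_len(fst_ac, n)
  fst_bc <- rep_len(fst_bc, n)
  if (any(stats::na.omit(c(fst_ab, fst_ac, fst_bc)) >= 1)) {
    warning("F_ST >= 1 maps to an infinite branch length")
  }
  t_ab <- -log(1 - fst_ab)
  t_ac <- -log(1 - fst_ac)
  t_bc <- -log(1 - fst_bc)
  data.frame(pbs_a = (t_ab + t_ac - t_bc) / 2,
             pbs_b = (t_ab + t_bc - t_ac) / 2,
             pbs_c = (t_ac + t_bc - t_ab) / 2)
}

#' Clamped, normalized branch scores
#'
#' Negative PBS values (not interpretable as branch lengths) are set to 0
#' when `clamp = TRUE`, then each window's triple is divided by its total so
#' the three scores sum to one and read as the proportion of evolution on
#' each branch. Windows whose clamped triple is all zero get `NA` scores.
#' Windows with any negative raw PBS are flagged (`had_negative`) so callers
#' can optionally exclude them.
#'
#' @param pbs_df Data frame (or 3-column matrix) of raw PBS triples, one row
#'   per window.
#' @param clamp Set negative PBS values to zero before normalizing.
#' @return List with `pbs_raw`, `pbs_clamped`, `score` (data frames, one row
#'   per window) and logical vector `had_negative`.
#' @export
branch_scores <- function(pbs_df, clamp = TRUE) {
  m <- as.matrix(pbs_df)
  if (ncol(m) != 3) stop("expected a 3-column PBS table")
  if (any(!is.finite(m[!is.na(m)]))) {
    stop("branch scores require finite PBS triples")
  }
  had_negative <- apply(m < 0, 1, any)
  clamped <- if (clamp) pmax(m, 0) else m
  tot <- rowSums(clamped)
  score <- clamped / ifelse(tot == 0 | is.na(tot), NA_real_, tot)
  colnames(score) <- colnames(clamped) <- colnames(m)
  list(pbs_raw = as.data.frame(m),
       pbs_clamped = as.data.frame(clamped),
       score = as.data.frame(score),
       had_negative = had_negative)
}

#' Windowed f_D introgression statistic
#'
#' Excess derived-allele sharing between recipient P2 and candidate donor
#' P3 relative to sister P1, under topology ((P1, P2), P3), outgroup O,
#' normalized by the maximal-sharing expectation. Per site,
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`; the
#' numerator sums `ABBA - BABA`, and the denominator is the same sum with
#' the donor role at each site played by whichever of P2/P3 has the higher
#' derived frequency. Sites with any missing frequency are dropped; a zero
#' denominator returns `NA`.
#'
#' @param p1,p2,p3,po Per-site derived-allele frequency vectors for sister,
#'   recipient, donor and outgroup populations.
#' @return Scalar f_D (at most 1; negative or unbounded-below values occur
#'   when there is no ABBA excess).
#' @export
f_d <- function(p1, p2, p3, po) {
  n <- length(p1)
  stopifnot(length(p2) == n, length(p3) == n, length(po) == n)
  keep <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(po))
  p1 <- p1[keep]; p2 <- p2[keep]; p3 <- p3[keep]; po <- po[keep]
  if (length(p1) == 0) return(NA_real_)
  num <- sum((1 - p1) * p2 * p3 * (1 - po) - p1 * (1 - p2) * p3 * (1 - po))
  pd <- pmax(p2, p3)
  den <- sum((1 - p1) * pd * pd * (1 - po) - p1 * (1 - pd) * pd * (1 - po))
  if (den == 0) return(NA_real_)
  num / den
}

#' Fit linear models of f_D on window predictors
#'
#' Ordinary least squares (Gaussian) fits of per-window `f_d` on window
#' predictors such as recombination rate or a branch score. By default each
#' predictor is fitted in its own single-predictor model (the way per-panel
#' slopes are usually reported); `joint = TRUE` fits one multiple
#' regression. Windows with `f_d` at or below `fd_threshold`, or with
#' missing values in any used column, are excluded and the exclusion counts
#' recorded. A design matrix that is collinear to machine precision aborts
#' with a diagnostic.
#'
#' @param windows Data frame with at least column `f_d` and the predictor
#'   columns.
#' @param terms Character vector of predictor column names.
#' @param fd_threshold Keep windows with `f_d` strictly greater than this
#'   (default 0); `-Inf` keeps all.
#' @param joint Fit all terms in a single model instead of one model per
#'   term.
#' @return Object of class `introgression_fit`: data frame with columns
#'   `model`, `term`, `estimate`, `se`, `t`, `p`, `n`, plus attribute
#'   `filter_counts`.
#' @export
fit_introgression_model <- function(windows, terms = c("recomb", "score_focal"),
                                    fd_threshold = 0, joint = FALSE) {
  stopifnot(is.data.frame(windows), "f_d" %in% names(windows),
            all(terms %in% names(windows)))
  n0 <- nrow(windows)
  used <- windows[, c("f_d", terms), drop = FALSE]
  complete <- stats::complete.cases(used)
  pass_fd <- !is.na(windows$f_d) & windows$f_d > fd_threshold
  keep <- complete & pass_fd
  filter_counts <- c(total = n0,
                     dropped_missing = sum(!complete),
                     dropped_fd_filter = sum(complete & !pass_fd),
                     used = sum(keep))
  dat <- used[keep, , drop = FALSE]
  fit_one <- function(term_set, label) {
    if (nrow(dat) < length(term_set) + 2) {
      stop("too few usable windows (", nrow(dat), ") for the regression")
    }
    mm <- stats::model.matrix(
      stats::reformulate(term_set), data = dat)
    if (qr(mm)$rank < ncol(mm)) {
      stop("predictors are collinear to machine precision (",
           paste(term_set, collapse = " + "), "); fit aborted")
    }
    fit <- stats::lm(stats::reformulate(term_set, response = "f_d"),
                     data = dat)
    cf <- summary(fit)$coefficients
    rows <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    data.frame(model = label, term = rownames(rows),
               estimate = rows[, 1], se = rows[, 2], t = rows[, 3],
               p = rows[, 4], n = nrow(dat), row.names = NULL)
  }
  res <- if (joint) {
    fit_one(terms, paste(terms, collapse = "+"))
  } else {
    do.call(rbind, lapply(terms, function(tm) fit_one(tm, tm)))
  }
  attr(res, "filter_counts") <- filter_counts
  class(res) <- c("introgression_fit", class(res))
  res
}

#' @export
print.introgression_fit <- function(x, ...) {
  fc <- attr(x, "filter_counts")
  cat(sprintf("f_D regression on %d windows (of %d; %d below f_D filter, %d missing)\n",
              fc[["used"]], fc[["total"]], fc[["dropped_fd_filter"]],
              fc[["dropped_missing"]]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
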