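# End-to-end window scan: container for window tables with per-site counts,
# and the pipeline that turns them into PBS branch scores and f_D.
#
# Population roles follow the four-population layout
# (outgroup, (donor, (sister, focal))): the focal recipient population (P2)
# receives introgression from the donor (P3); P1 is the focal population's
# non-introgressed sister, and O the outgroup. PBS is computed for the
# (focal, donor, outgroup) triple from an unadmixed focal panel, so branch
# lengths are not shortened by the introgression being scanned for.

#' Container for a set of genomic windows with per-site allele counts
#'
#' @param windows Data frame with columns `window_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `n_sites`, `recomb` (cM/Mb).
#' @param sites Data frame with one row per site: `window_id` plus
#'   derived-allele count columns `c_p1`, `c_p2`, `c_p3`, `c_o` (the full
#'   samples used for f_D) and `c_p2_panel`, `c_p3_panel`, `c_o_panel`
#'   (separate unadmixed panels used for F_ST, as a scan excluding admixed
#'   individuals from differentiation estimates would have).
#' @param sample_sizes Named integer vector with elements `p1`, `p2`,
#'   `p2_panel`, `p3`, `p3_panel`, `o`, `o_panel` (sampled chromosomes).
#' @return Object of class `window_set`.
#' @export
window_set <- function(windows, sites, sample_sizes) {
  req_w <- c("window_id", "chrom", "start", "end", "n_sites", "recomb")
  req_s <- c("window_id", "c_p1", "c_p2", "c_p3", "c_o",
             "c_p2_panel", "c_p3_panel", "c_o_panel")
  req_n <- c("p1", "p2", "p2_panel", "p3", "p3_panel", "o", "o_panel")
  if (!all(req_w %in% names(windows))) {
    stop("windows table missing columns: ",
         paste(setdiff(req_w, names(windows)), collapse = ", "))
  }
  if (!all(req_s %in% names(sites))) {
    stop("sites table missing columns: ",
         paste(setdiff(req_s, names(sites)), collapse = ", "))
  }
  if (!all(req_n %in% names(sample_sizes))) {
    stop("sample_sizes must name: ", paste(req_n, collapse = ", "))
  }
  bad <- which(windows$start >= windows$end)
  if (length(bad) > 0) {
    stop("start >= end in windows table row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(windows = windows, sites = sites,
                 sample_sizes = sample_sizes),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows, %d sites, sample sizes [%s]\n",
              nrow(x$windows), nrow(x$sites),
              paste(names(x$sample_sizes), x$sample_sizes, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Run the windowed introgression scan
#'
#' For every window: Hudson F_ST between the unadmixed focal panel, the
#' donor and the outgroup (all three pairs); the PBS triple for
#' (focal, donor, outgroup); clamped and normalized branch scores; and f_D
#' from the full-sample site frequencies under ((sister, focal), donor)
#' with the outgroup. Non-finite PBS triples (an F_ST of 1) are set to
#' missing.
#'
#' @param ws A [window_set()].
#' @param clamp Clamp negative PBS values to zero before normalizing
#'   (default TRUE, the main-line treatment).
#' @param drop_negative_pbs Drop windows where any raw PBS value is
#'   negative (the stricter filter variant); default FALSE (keep, flagged).
#' @return Data frame (class `introgression_scan`), one row per retained
#'   window: window columns, `fst_fd` (focal-donor), `fst_fo`, `fst_do`,
#'   `pbs_focal`, `pbs_donor`, `pbs_outgroup`, `score_focal`,
#'   `score_donor`, `score_outgroup`, `had_negative`, `f_d`. Attribute
#'   `filter_counts` records filtering; attribute `dialect` the estimator
#'   choices.
#' @export
run_scan <- function(ws, clamp = TRUE, drop_negative_pbs = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  ns <- ws$sample_sizes
  split_idx <- split(seq_len(nrow(ws$sites)), ws$sites$window_id)
  ids <- ws$windows$window_id
  per_window <- lapply(ids, function(id) {
    i <- split_idx[[as.character(id)]]
    st <- ws$sites[i, , drop = FALSE]
    c(fst_fd = hudson_fst(st$c_p2_panel, st$c_p3_panel,
                          ns[["p2_panel"]], ns[["p3_panel"]]),
      fst_fo = hudson_fst(st$c_p2_panel, st$c_o_panel,
                          ns[["p2_panel"]], ns[["o_panel"]]),
      fst_do = hudson_fst(st$c_p3_panel, st$c_o_panel,
                          ns[["p3_panel"]], ns[["o_panel"]]),
      f_d = f_d(st$c_p1 / ns[["p1"]], st$c_p2 / ns[["p2"]],
                st$c_p3 / ns[["p3"]], st$c_o / ns[["o"]]))
  })
  stats_df <- as.data.frame(do.call(rbind, per_window))
  pbs_df <- pbs(stats_df$fst_fd, stats_df$fst_fo, stats_df$fst_do)
  names(pbs_df) <- c("pbs_focal", "pbs_donor", "pbs_outgroup")
  n_infinite <- sum(!is.finite(as.matrix(pbs_df)) & !is.na(as.matrix(pbs_df)))
  if (n_infinite > 0) {
    pbs_df[!apply(is.finite(as.matrix(pbs_df)), 1, all), ] <- NA_real_
  }
  bs <- branch_scores(pbs_df, clamp = clamp)
  score <- bs$score
  names(score) <- c("score_focal", "score_donor", "score_outgroup")
  out <- cbind(ws$windows, stats_df["fst_fd"], stats_df["fst_fo"],
               stats_df["fst_do"], pbs_df, score,
               had_negative = bs$had_negative, f_d = stats_df$f_d)
  n0 <- nrow(out)
  if (drop_negative_pbs) {
    out <- out[!is.na(out$had_negative) & !out$had_negative, , drop = FALSE]
  }
  attr(out, "filter_counts") <- c(
    total = n0,
    infinite_pbs = n_infinite,
    negative_pbs = sum(bs$had_negative, na.rm = TRUE),
    dropped_negative = n0 - nrow(out),
    retained = nrow(out))
  attr(out, "dialect") <- c(fst = "hudson_ratio_of_averages",
                            pbs_clamp = clamp,
                            drop_negative_pbs = drop_negative_pbs)
  class(out) <- c("introgression_scan", class(out))
  out
}
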