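# Table readers/writers and the command-line entry point. All output files
# are TSV with '#'-prefixed provenance comment lines (key=value); window
# coordinates are 0-based half-open throughout.

provenance_header <- function(extra = character()) {
  c(sprintf("# introsel=%s",
            as.character(utils::packageVersion("introsel"))),
    "# coordinates=0-based_half-open",
    if (length(extra)) paste0("# ", names(extra), "=", unname(extra)))
}

#' Write a results table with a provenance header
#'
#' TSV with deterministic column order and '#'-prefixed `key=value`
#' provenance lines; an empty table yields a header-only file.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Named character vector of extra provenance entries
#'   (e.g. seed, estimator dialect).
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path, provenance = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a window table
#'
#' Reads a '#'-commented TSV of windows. Requires `chrom`, `start`, `end`
#' (0-based half-open); accepts either precomputed statistic columns
#' (`fst_*`, `f_d`) or none at all. Malformed rows are rejected with their
#' row numbers. Operations that need per-site counts work on a
#' [window_set()] instead; a plain window table with precomputed statistics
#' can go straight into [fit_introgression_model()].
#'
#' @param path Path to the TSV.
#' @return Validated data frame of windows.
#' @export
read_window_table <- function(path) {
  df <- read_tsv_commented(path)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("window table missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start >= df$end)
  if (length(bad) > 0) {
    stop("invalid coordinates (start >= end or non-numeric) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df
}

#' Write / read a window set (windows + per-site counts)
#'
#' Persists a [window_set()] as two TSVs, `<prefix>.windows.tsv` and
#' `<prefix>.sites.tsv`, with sample sizes recorded in the provenance
#' header; `read_window_set()` restores it.
#'
#' @param ws A [window_set()].
#' @param prefix Output path prefix.
#' @param provenance Extra provenance entries.
#' @return The prefix (write) or a `window_set` (read), invisibly/visibly.
#' @export
write_window_set <- function(ws, prefix, provenance = character()) {
  stopifnot(inherits(ws, "window_set"))
  prov <- c(provenance,
            stats::setNames(as.character(ws$sample_sizes),
                            paste0("n_", names(ws$sample_sizes))))
  write_results(ws$windows, paste0(prefix, ".windows.tsv"), prov)
  write_results(ws$sites, paste0(prefix, ".sites.tsv"), prov)
  invisible(prefix)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(prefix) {
  wpath <- paste0(prefix, ".windows.tsv")
  spath <- paste0(prefix, ".sites.tsv")
  header <- grep("^#", readLines(wpath, n = 50), value = TRUE)
  kv <- header[grepl("^# n_", header)]
  if (length(kv) == 0) stop("window set header lacks sample sizes (n_* keys)")
  keys <- sub("^# n_([^=]+)=.*$", "\\1", kv)
  vals <- as.integer(sub("^.*=", "", kv))
  windows <- read_window_table(wpath)
  sites <- read_tsv_commented(spath)
  window_set(windows, sites, stats::setNames(vals, keys))
}

# ---- command-line interface -------------------------------------------------

# minimal --flag value / --flag parser; returns named list
parse_flags <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(argv) && !startsWith(argv[i + 1], "--")) {
      out[[key]] <- argv[i + 1]
      i <- i + 2
    } else {
      out[[key]] <- TRUE   # bare switch
      i <- i + 1
    }
  }
  out
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

flag_chr <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.character(flags[[key]])
}

# merge YAML config defaults under explicit flags
apply_config <- function(flags) {
  if (is.null(flags$config)) return(flags)
  cfg <- yaml::read_yaml(flags$config)
  for (k in names(cfg)) {
    key <- gsub("_", "-", k)
    if (is.null(flags[[key]])) flags[[key]] <- cfg[[k]]
  }
  flags
}

cli_model_eval <- function(flags) {
  p <- selection_params(s = flag_num(flags, "s", -0.01),
                        eps_w = flag_num(flags, "eps-w", 1e-3),
                        eps_b = flag_num(flags, "eps-b", -1e-4))
  b <- flag_num(flags, "b", 60)
  comp <- haplotype_composition(flag_num(flags, "x-new", 0),
                                flag_num(flags, "x-ancestral", 0),
                                flag_num(flags, "x-replacement", 0))
  mode <- flag_chr(flags, "mode", "exact")
  ploidy <- flag_chr(flags, "ploidy", "haploid")
  sigma <- if (ploidy == "diploid") {
    d <- dominance_params(h = flag_num(flags, "h", 0.5),
                          a1 = flag_num(flags, "a1", 0.25),
                          a2 = flag_num(flags, "a2", 0.5))
    sigma_diploid(comp, b, p, d, mode = mode)
  } else {
    sigma_haplotype(comp, b, p, mode = mode)
  }
  row <- data.frame(s = p$s, eps_w = p$eps_w, eps_b = p$eps_b, b = b,
                    x_new = comp$x_new, x_ancestral = comp$x_ancestral,
                    x_replacement = comp$x_replacement, mode = mode,
                    ploidy = ploidy, sigma = sigma)
  message("model eval: ", paste(names(row), unlist(row), sep = "=",
                                collapse = " "))
  out <- flag_chr(flags, "out", "")
  if (nzchar(out)) {
    write_results(row, out, c(subcommand = "model_eval"))
  } else {
    utils::write.table(row, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  0L
}

cli_model_sweep <- function(flags) {
  preset <- flag_chr(flags, "preset", "")
  tab <- if (nzchar(preset)) {
    res <- sweep_preset(preset)
    if (is.data.frame(res)) res else {
      do.call(rbind, lapply(names(res), function(nm)
        cbind(dominance = nm, res[[nm]])))
    }
  } else {
    p <- selection_params(s = flag_num(flags, "s", -0.01),
                          eps_w = flag_num(flags, "eps-w", 1e-3),
                          eps_b = flag_num(flags, "eps-b", -1e-4))
    x_max <- flag_num(flags, "x-max", 100)
    curve_sweep(0:x_max, flag_num(flags, "b", 60),
                flag_num(flags, "f", 0), p)
  }
  prov <- c(subcommand = "model_sweep",
            preset = if (nzchar(preset)) preset else "custom")
  out <- flag_chr(flags, "out", "")
  if (nzchar(out)) {
    write_results(tab, out, prov)
  } else {
    utils::write.table(tab, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  0L
}

cli_simulate_scan <- function(flags) {
  seed <- as.integer(flag_num(flags, "seed", 1))
  cfg <- preset_drosophila_like(seed)
  for (key in c("n-windows", "sites-per-window", "intro-frac", "alpha")) {
    if (!is.null(flags[[key]])) {
      cfg[[gsub("-", "_", key)]] <- as.numeric(flags[[key]])
    }
  }
  sim <- simulate_scan(cfg)
  prefix <- flag_chr(flags, "out", "simulated_scan")
  prov <- c(subcommand = "simulate_scan", seed = as.character(seed))
  write_window_set(sim$window_set, prefix, prov)
  write_results(sim$truth, paste0(prefix, ".truth.tsv"), prov)
  message(sprintf("simulate scan: %d windows (%d introgressed) -> %s.*",
                  nrow(sim$truth), sum(sim$truth$introgressed), prefix))
  0L
}

cli_scan_run <- function(flags) {
  if (is.null(flags$windows)) stop("scan run requires --windows PREFIX")
  ws <- read_window_set(flags$windows)
  clamp <- is.null(flags[["no-clamp"]])
  drop_neg <- !is.null(flags[["drop-negative-pbs"]])
  fd_thr <- flag_num(flags, "fd-threshold", 0)
  scan <- run_scan(ws, clamp = clamp, drop_negative_pbs = drop_neg)
  fc <- attr(scan, "filter_counts")
  message("scan run: ", paste(names(fc), fc, sep = "=", collapse = " "))
  fit <- fit_introgression_model(
    scan, terms = c("recomb", "score_focal", "score_donor"),
    fd_threshold = fd_thr)
  prefix <- flag_chr(flags, "out", "scan")
  prov <- c(subcommand = "scan_run",
            fst_estimator = "hudson_ratio_of_averages",
            clamp = as.character(clamp),
            drop_negative_pbs = as.character(drop_neg),
            fd_threshold = as.character(fd_thr),
            stats::setNames(as.character(fc), paste0("filter_", names(fc))))
  write_results(as.data.frame(scan), paste0(prefix, ".scores.tsv"), prov)
  write_results(as.data.frame(fit), paste0(prefix, ".regression.tsv"), prov)
  0L
}

#' Command-line entry point
#'
#' Subcommands: `model eval` (single selection-coefficient evaluation),
#' `model sweep` (figure presets or free grids), `simulate scan` (synthetic
#' window generator) and `scan run` (PBS/branch-score/f_D scan plus
#' regression). A thin executable wrapper lives at
#' `system.file("cli", "introgression.R", package = "introsel")`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
run_cli <- function(argv) {
  status <- tryCatch({
    if (length(argv) < 2) stop("usage: introgression.R <model|simulate|scan> <subcommand> [--flags]")
    cmd <- paste(argv[1], argv[2])
    flags <- apply_config(parse_flags(argv[-(1:2)]))
    handler <- switch(cmd,
                      "model eval" = cli_model_eval,
                      "model sweep" = cli_model_sweep,
                      "simulate scan" = cli_simulate_scan,
                      "scan run" = cli_scan_run,
                      stop("unknown subcommand: ", cmd))
    handler(flags)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  as.integer(status)
}
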