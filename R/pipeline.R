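#' Two-sample t-test sample size via the normal approximation
#'
#' Total sample size needed to detect a mean difference `delta` between two
#' equal groups with common SD `sd`. The default method uses normal
#' quantiles: per-group `n = ceiling(2 * ((z_{1-alpha} + z_{power}) * sd /
#' delta)^2)` with the one-tailed alpha when `one_tailed = TRUE`, and the
#' total is twice that (at least 2). `method = "t"` instead solves the exact
#' noncentral-t power equation via [stats::power.t.test()].
#'
#' @param delta Positive mean difference (any units, e.g. minutes).
#' @param sd Positive common SD (same units).
#' @param power Target power in `(0, 1)`; default 0.80.
#' @param alpha Significance level in `(0, 1)`; default 0.05.
#' @param one_tailed Use a one-tailed test; default `FALSE`.
#' @param method `"normal"` (default) or `"t"`.
#' @return Total sample size (both groups combined).
#' @export
#' @examples
#' power_two_sample_t(24.6, 58, 0.80, 0.05, one_tailed = TRUE)  # 138
power_two_sample_t <- function(delta, sd, power = 0.80, alpha = 0.05,
                               one_tailed = FALSE, method = c("normal", "t")) {
  method <- match.arg(method)
  if (!(delta > 0) || !(sd > 0)) stop("delta and sd must be > 0", call. = FALSE)
  if (!(power > 0 && power < 1) || !(alpha > 0 && alpha < 1)) {
    stop("power and alpha must lie in (0, 1)", call. = FALSE)
  }
  if (method == "normal") {
    za <- stats::qnorm(1 - if (one_tailed) alpha else alpha / 2)
    zb <- stats::qnorm(power)
    per_group <- max(1L, as.integer(ceiling(2 * ((za + zb) * sd / delta)^2)))
  } else {
    pt <- stats::power.t.test(delta = delta, sd = sd, power = power,
                              sig.level = alpha,
                              alternative = if (one_tailed) "one.sided" else "two.sided")
    per_group <- max(1L, as.integer(ceiling(pt$n)))
  }
  2L * per_group
}

#' Pipeline configuration with the published default settings
#'
#' Defaults reproduce the analysis settings: 98% of calibration pairs kept
#' after trimming, an 11-hour (39600 s) predicted-marathon-time cut-off,
#' 100000 Monte Carlo samples per p-value, no extra name-model uncertainty,
#' a 0.05/0.95 cross-validation confidence threshold.
#'
#' @param path Optional JSON file of overrides.
#' @param ... Named overrides applied after the file.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(keep_frac = 0.98, max_predicted_seconds = 39600,
              n_sims = 100000L, epsilon = 0, threshold = 0.05, seed = 1L,
              marathon_event = "marathon")
  if (!is.null(path)) {
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Fit all four log-time models with Monte Carlo p-values
#'
#' Fits models 1-4 on an assigned cross-race dataset and attaches
#' parametric-bootstrap p-values to every reported (non-event,
#' non-intercept) term. Records without an assigned `prob_male` are dropped
#' with a message before fitting, matching the exclusion rule for athletes
#' whose sex no method could inform. Each (model, term) p-value gets its own
#' deterministic sub-seed derived from `config$seed`.
#'
#' @param data Cross-race data frame with `prob_male` assigned.
#' @param config A [pipeline_config()].
#' @return Named list `model1`..`model4`, each with elements `fit`,
#'   `pvalues` (named by term) and `table` (see [fit_table()]).
#' @export
run_all_models <- function(data, config = pipeline_config()) {
  drop <- is.na(data$prob_male)
  if (any(drop)) {
    message("excluding ", sum(drop), " record(s) with no sex probability")
    data <- data[!drop, , drop = FALSE]
  }
  out <- list()
  for (m in 1:4) {
    fit <- fit_latent_model(data, model_spec(m))
    terms <- names(fit$coefficients)
    terms <- terms[!grepl("^event:|^\\(Intercept\\)", terms)]
    pvals <- list()
    for (i in seq_along(terms)) {
      sub_seed <- (as.integer(config$seed) + 1000L * m + i) %% .Machine$integer.max
      pvals[[terms[i]]] <- monte_carlo_pvalues(fit, terms[i],
                                               n_sims = config$n_sims,
                                               seed = sub_seed)
    }
    out[[paste0("model", m)]] <- list(fit = fit, pvalues = pvals,
                                      table = fit_table(fit, pvals))
  }
  out
}

# ---- command-line interface -------------------------------------------------

.cli_parse <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE
      i <- i + 1L
    }
  }
  flags
}

.cli_num <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing required flag --", key, call. = FALSE)
    return(default)
  }
  as.numeric(v)
}

.cli_log <- function(level, threshold, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

.cli_simulate <- function(flags, seed, log_level) {
  out <- flags[["out"]]
  if (is.null(out)) stop("simulate needs --out DIR", call. = FALSE)
  cfg_truth <- if (!is.null(flags[["config"]])) {
    jsonlite::read_json(flags[["config"]], simplifyVector = TRUE)
  } else list()
  truth_args <- cfg_truth[intersect(names(cfg_truth),
                                    names(formals(synthetic_truth)))]
  truth_args$seed <- seed
  truth <- do.call(synthetic_truth, truth_args)
  year_rng <- (truth$race_year - truth$age_range[2] - 1):(truth$race_year - truth$age_range[1])
  tab <- generate_name_table(year_range = year_rng, seed = seed)
  athletes <- generate_athletes(truth, tab, seed = seed + 1L)
  results <- generate_race_results(athletes, truth, seed = seed + 2L)
  coverage <- if (!is.null(cfg_truth$lookup_coverage)) cfg_truth$lookup_coverage else 0.55
  lookup <- generate_lookup(athletes, coverage, seed = seed + 3L)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_race_results(results, file.path(out, "results.csv"))
  write_ssa_names(tab, file.path(out, "names"))
  utils::write.csv(lookup, file.path(out, "lookup.csv"), row.names = FALSE)
  write_truth(truth, file.path(out, "truth.json"))
  .cli_log("info", log_level, "wrote synthetic bundle (", nrow(results),
           " results, ", nrow(athletes), " athletes) to ", out)
  0L
}

.cli_build <- function(flags, log_level) {
  res_path <- flags[["results"]]
  out <- flags[["out"]]
  if (is.null(res_path) || is.null(out)) {
    stop("build needs --results FILE and --out DIR", call. = FALSE)
  }
  if (!file.exists(res_path)) stop("no such results file: ", res_path, call. = FALSE)
  results <- read_race_results(res_path)
  built <- build_cross_race(results,
                            keep_frac = .cli_num(flags, "keep-frac", 0.98),
                            max_predicted_seconds = .cli_num(flags, "max-predicted", 39600))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(built$records, file.path(out, "cross_race.csv"),
                   row.names = FALSE)
  writeLines(format_build_summary(built$summary),
             file.path(out, "build_summary.csv"))
  .cli_log("info", log_level, "cross-race dataset: ",
           built$summary$n_unique_rows, " unique rows, ",
           built$summary$n_outliers_discarded, " outliers discarded")
  0L
}

.cli_assign <- function(flags, log_level) {
  data_path <- flags[["data"]]
  names_dir <- flags[["names"]]
  out <- flags[["out"]]
  if (is.null(data_path) || is.null(names_dir) || is.null(out)) {
    stop("assign-sex needs --data FILE, --names DIR and --out DIR", call. = FALSE)
  }
  if (!file.exists(data_path)) stop("no such data file: ", data_path, call. = FALSE)
  data <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  tab <- read_ssa_names(names_dir)
  lookup <- if (!is.null(flags[["lookup"]])) read_lookup(flags[["lookup"]]) else NULL
  assigned <- assign_prob_male(data, lookup, tab,
                               epsilon = .cli_num(flags, "epsilon", 0))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(assigned, file.path(out, "cross_race_assigned.csv"),
                   row.names = FALSE)
  utils::write.csv(sex_assignment_summary(assigned),
                   file.path(out, "sex_summary.csv"), row.names = FALSE)
  cv <- cross_validate(lookup, tab,
                       assigned[assigned$gender_id == "non-binary", , drop = FALSE],
                       threshold = .cli_num(flags, "threshold", 0.05))
  writeLines(c(sprintf("n_compared,%d", cv$n_compared),
               sprintf("n_agree,%d", cv$n_agree),
               sprintf("agreement,%s", format(cv$agreement))),
             file.path(out, "cross_validation.txt"))
  .cli_log("info", log_level, "assigned probabilities; cross-validation ",
           cv$n_agree, "/", cv$n_compared)
  0L
}

.cli_fit <- function(flags, seed, log_level) {
  data_path <- flags[["data"]]
  out <- flags[["out"]]
  if (is.null(data_path) || is.null(out)) {
    stop("fit needs --data FILE and --out DIR", call. = FALSE)
  }
  if (!file.exists(data_path)) {
    stop("no such data file: ", data_path, " (run build/assign-sex first)",
         call. = FALSE)
  }
  data <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  if (!"prob_male" %in% names(data)) {
    stop("data has no prob_male column (run assign-sex first)", call. = FALSE)
  }
  cfg <- pipeline_config(seed = seed,
                         n_sims = as.integer(.cli_num(flags, "n-sims", 100000)))
  fits <- run_all_models(data, cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (m in names(fits)) {
    utils::write.csv(fits[[m]]$table, file.path(out, paste0(m, "_table.csv")),
                     row.names = FALSE)
  }
  qq <- residual_qq(fits$model4$fit, known_sex_only = TRUE)
  utils::write.csv(qq, file.path(out, "qq_model4.csv"), row.names = FALSE)
  .cli_log("info", log_level, "wrote model tables and Q-Q data to ", out)
  0L
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle: results, SSA-style
#' name files, lookup, ground-truth sidecar), `build` (cross-race dataset
#' plus summary), `assign-sex` (sex probabilities, assignment summary,
#' cross-validation report), `fit` (the four models with Monte Carlo
#' p-values plus Q-Q data), and `power` (sample-size calculator). Global
#' flags `--seed`, `--log-level` (debug/info/warn) and per-command flags as
#' documented in the subcommand errors. Run from a shell as e.g.
#' `Rscript -e 'racelatent::race_cli()' power --delta 24.6 --sd 58
#' --power 0.8 --alpha 0.05 --one-tailed`.
#'
#' @param argv Character vector of arguments (default: the command line).
#' @return Exit code, invisibly: 0 on success, 2 on usage error, 1 on
#'   runtime failure.
#' @export
race_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0L) {
      stop("usage: racelatent <simulate|build|assign-sex|fit|power> [flags]",
           call. = FALSE)
    }
    cmd <- argv[1L]
    flags <- .cli_parse(argv[-1L])
    seed <- as.integer(.cli_num(flags, "seed", 1))
    log_level <- if (!is.null(flags[["log-level"]])) flags[["log-level"]] else "info"
    if (!log_level %in% c("debug", "info", "warn")) {
      stop("--log-level must be debug, info or warn", call. = FALSE)
    }
    switch(cmd,
      power = {
        n <- power_two_sample_t(
          delta = .cli_num(flags, "delta"),
          sd = .cli_num(flags, "sd"),
          power = .cli_num(flags, "power", 0.80),
          alpha = .cli_num(flags, "alpha", 0.05),
          one_tailed = isTRUE(flags[["one-tailed"]]),
          method = if (isTRUE(flags[["t-test"]])) "t" else "normal")
        cat(n, "\n", sep = "")
        0L
      },
      simulate = .cli_simulate(flags, seed, log_level),
      build = .cli_build(flags, log_level),
      `assign-sex` = .cli_assign(flags, log_level),
      fit = .cli_fit(flags, seed, log_level),
      stop("unknown command: ", cmd, call. = FALSE)
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("usage|needs|unknown command|missing required|no such",
              conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}
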