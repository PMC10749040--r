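#' No-intercept least-squares slope
#'
#' Fits `marathon_time ~ 0 + event_time`, i.e. the slope minimizing
#' `sum((marathon_time - s * event_time)^2)`, whose closed form is
#' `sum(x * y) / sum(x^2)`. Used to convert any event's finish time into a
#' predicted marathon time.
#'
#' @param pairs Data frame (or list) with columns/elements `event_time` and
#'   `marathon_time`, both positive seconds.
#' @return The slope (marathon seconds per event second).
#' @export
#' @examples
#' fit_no_intercept(data.frame(event_time = c(1, 2), marathon_time = c(2, 5)))
fit_no_intercept <- function(pairs) {
  x <- pairs$event_time
  y <- pairs$marathon_time
  if (length(x) == 0L) stop("insufficient data: no pairs", call. = FALSE)
  if (length(x) != length(y)) stop("pair vectors differ in length", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) stop("times must be positive", call. = FALSE)
  sum(x * y) / sum(x * x)
}

#' Calibrate one event against the marathon
#'
#' Two-pass trimmed no-intercept regression. A first slope is fitted to all
#' shared (event time, marathon time) pairs; each pair's outlyingness is the
#' absolute residual divided by its time (marathon time by default); the
#' `ceiling(keep_frac * n)` pairs with the lowest ratios are retained and a
#' second no-intercept slope plus the Pearson correlation between event and
#' marathon times — the event's *marathon correlation* — are computed on
#' them.
#'
#' @param pairs Data frame with columns `event_time`, `marathon_time`.
#' @param keep_frac Fraction of pairs retained after trimming, in `(0, 1]`;
#'   default 0.98 (the 2% worst-fitting pairs are treated as outliers).
#' @param event Optional event id recorded in the result.
#' @param denominator Which time divides the residual: `"marathon"` (the
#'   predicted quantity; default) or `"event"`.
#' @param log_scale_cor If `TRUE`, the correlation is computed on log times
#'   instead of raw seconds.
#' @return An `event_calibration` object: list with `event`, `slope`,
#'   `marathon_correlation`, `n_shared`, `n_trimmed`.
#' @export
calibrate_event <- function(pairs, keep_frac = 0.98, event = NA_character_,
                            denominator = c("marathon", "event"),
                            log_scale_cor = FALSE) {
  denominator <- match.arg(denominator)
  n <- length(pairs$event_time)
  if (n < 2L) stop("insufficient data: need at least 2 pairs", call. = FALSE)
  if (!(keep_frac > 0 && keep_frac <= 1)) {
    stop("keep_frac must lie in (0, 1]", call. = FALSE)
  }
  s1 <- fit_no_intercept(pairs)
  denom <- if (denominator == "marathon") pairs$marathon_time else pairs$event_time
  ratio <- abs(pairs$marathon_time - s1 * pairs$event_time) / denom
  n_keep <- ceiling(keep_frac * n)
  keep <- order(ratio)[seq_len(n_keep)]
  kept <- list(event_time = pairs$event_time[keep],
               marathon_time = pairs$marathon_time[keep])
  slope <- fit_no_intercept(kept)
  corr <- if (log_scale_cor) {
    stats::cor(log(kept$event_time), log(kept$marathon_time))
  } else {
    stats::cor(kept$event_time, kept$marathon_time)
  }
  structure(list(event = event, slope = slope, marathon_correlation = corr,
                 n_shared = as.integer(n), n_trimmed = as.integer(n - n_keep)),
            class = "event_calibration")
}

#' @export
print.event_calibration <- function(x, ...) {
  cat(sprintf("Event calibration%s: slope %.5f, marathon correlation %.4f (n = %d, trimmed %d)\n",
              if (is.na(x$event)) "" else paste0(" [", x$event, "]"),
              x$slope, x$marathon_correlation, x$n_shared, x$n_trimmed))
  invisible(x)
}

#' Predicted marathon time for an event result
#'
#' @param calibration An [calibrate_event()] result.
#' @param event_time Positive finish time in seconds.
#' @return Predicted marathon time in seconds (`slope * event_time`).
#' @export
predict_marathon_time <- function(calibration, event_time) {
  stopifnot(inherits(calibration, "event_calibration"))
  if (any(event_time <= 0)) stop("event_time must be positive", call. = FALSE)
  calibration$slope * event_time
}

#' Build the one-record-per-athlete cross-race dataset
#'
#' Calibrates every event against the marathon using athletes who ran both
#' (the marathon's own calibration has slope 1 and correlation 1); for each
#' athlete (identified by normalized full name) keeps the single result from
#' the calibrated event with the highest marathon correlation — the marathon
#' itself always wins for athletes who ran it — and discards records whose
#' predicted marathon time exceeds `max_predicted_seconds` (default 39600 s,
#' the 11-hour marathon cut-off). Duplicate results within one (athlete,
#' event) collapse to the fastest time. Events sharing fewer than 2 athletes
#' with the marathon cannot be calibrated; their results are ineligible for
#' selection. Ties on correlation break by higher shared-athlete count, then
#' lexicographic event id.
#'
#' @param results Race-result data frame (`name`, `event`, `date`, `age`,
#'   `gender_id`, `time_seconds`, optionally `prob_male`).
#' @param keep_frac Trimming fraction passed to [calibrate_event()].
#' @param max_predicted_seconds Predicted-marathon-time cut-off in seconds.
#' @param marathon_event Event id of the marathon.
#' @param denominator,log_scale_cor Passed to [calibrate_event()].
#' @return List with `records` (the cross-race data frame, one row per
#'   athlete, with `predicted_marathon_time` and `marathon_correlation`
#'   appended) and `summary` (a `build_summary`: total results, outliers
#'   discarded, unique rows, plus per-event calibrations).
#' @export
build_cross_race <- function(results, keep_frac = 0.98,
                             max_predicted_seconds = 39600,
                             marathon_event = "marathon",
                             denominator = "marathon",
                             log_scale_cor = FALSE) {
  stopifnot(is.data.frame(results),
            all(c("name", "event", "time_seconds") %in% names(results)))
  if (!any(results$event == marathon_event)) {
    stop("insufficient data: no marathon results to calibrate against",
         call. = FALSE)
  }
  res <- results
  res$.key <- normalize_name(res$name)

  # one row per (athlete, event): fastest time
  res <- res[order(res$.key, res$event, res$time_seconds), , drop = FALSE]
  res <- res[!duplicated(res[c(".key", "event")]), , drop = FALSE]

  mar <- res[res$event == marathon_event, , drop = FALSE]
  mar_time <- mar$time_seconds
  names(mar_time) <- mar$.key

  events <- sort(unique(res$event))
  calibrations <- list()
  for (ev in events) {
    if (ev == marathon_event) {
      calibrations[[ev]] <- structure(
        list(event = ev, slope = 1, marathon_correlation = 1,
             n_shared = nrow(mar), n_trimmed = 0L),
        class = "event_calibration")
      next
    }
    sub <- res[res$event == ev, , drop = FALSE]
    shared <- sub$.key %in% names(mar_time)
    if (sum(shared) < 2L) next  # uncalibratable
    pairs <- list(event_time = sub$time_seconds[shared],
                  marathon_time = unname(mar_time[sub$.key[shared]]))
    calibrations[[ev]] <- calibrate_event(pairs, keep_frac = keep_frac,
                                          event = ev, denominator = denominator,
                                          log_scale_cor = log_scale_cor)
  }

  calibrated <- names(calibrations)
  eligible <- res$event %in% calibrated
  n_uncalibrated <- sum(!eligible)
  res <- res[eligible, , drop = FALSE]

  corr <- vapply(calibrations, `[[`, numeric(1), "marathon_correlation")
  nsh <- vapply(calibrations, `[[`, numeric(1), "n_shared")
  slope <- vapply(calibrations, `[[`, numeric(1), "slope")
  res$.corr <- corr[res$event]
  res$.nsh <- nsh[res$event]

  # per athlete: highest correlation, then larger shared-n, then event id
  ord <- order(res$.key, -res$.corr, -res$.nsh, res$event)
  res <- res[ord, , drop = FALSE]
  sel <- res[!duplicated(res$.key), , drop = FALSE]

  sel$predicted_marathon_time <- slope[sel$event] * sel$time_seconds
  outlier <- sel$predicted_marathon_time > max_predicted_seconds
  n_outliers <- sum(outlier)
  sel <- sel[!outlier, , drop = FALSE]

  sel$marathon_correlation <- sel$.corr
  keep_cols <- intersect(c("name", "event", "date", "age", "gender_id",
                           "prob_male", "time_seconds",
                           "predicted_marathon_time", "marathon_correlation"),
                         names(sel))
  records <- sel[, keep_cols, drop = FALSE]
  rownames(records) <- NULL

  summary <- structure(list(
    n_results = nrow(results),
    n_outliers_discarded = as.integer(n_outliers),
    n_unique_rows = nrow(records),
    n_uncalibrated_dropped = as.integer(n_uncalibrated),
    calibrations = calibrations
  ), class = "build_summary")
  list(records = records, summary = summary)
}

#' @export
print.build_summary <- function(x, ...) {
  cat("Cross-race dataset build summary\n")
  cat(sprintf("  Total no of race results in full data set  %d\n", x$n_results))
  cat(sprintf("  No of outliers discarded                   %d\n",
              x$n_outliers_discarded))
  cat(sprintf("  No of unique rows in cross-race data set   %d\n",
              x$n_unique_rows))
  if (x$n_uncalibrated_dropped > 0) {
    cat(sprintf("  (results in uncalibratable events, ineligible: %d)\n",
                x$n_uncalibrated_dropped))
  }
  invisible(x)
}

#' Format a build summary as plain text
#'
#' @param summary A `build_summary` from [build_cross_race()].
#' @return Character vector of report lines.
#' @export
format_build_summary <- function(summary) {
  stopifnot(inherits(summary, "build_summary"))
  c(sprintf("Total no of race results in full data set,%d", summary$n_results),
    sprintf("No of outliers discarded,%d", summary$n_outliers_discarded),
    sprintf("No of unique rows in cross-race data set,%d", summary$n_unique_rows))
}
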