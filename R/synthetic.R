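#' Ground truth for the synthetic race-result generator
#'
#' Holds the generative counterparts of every coefficient in the log-time
#' model: per-event log-mean finish times, the natal-female offset, linear
#' and quadratic age effects centred at age 40, the non-binary offset, the
#' signed natal-sex-within-non-binary offset (`beta_nbp`, zero by default so
#' hypothesis-test calibration runs under a true null), and the residual SD
#' of log time.
#'
#' Defaults mirror the final fitted model on the real data: 21 events
#' spanning 4 miles to the marathon, `beta_female = 0.12224`,
#' `beta_age = 0.00375`, `beta_age2 = 0.00012`, `beta_nb = 0.03225`,
#' `sigma = 0.20`, 85173 athletes of whom a fraction 166/85173 register
#' non-binary. Default event log-means follow a pace model of
#' `540 + 4 * miles` seconds per mile, giving a ~37 min 4-miler and a
#' ~4 h 42 min marathon, typical of mass-participation fields.
#'
#' @param event_log_means Named numeric vector of log-seconds per event;
#'   must include an event named `"marathon"`. `NULL` for the 21-event
#'   default.
#' @param beta_female Natal-female log-time offset.
#' @param beta_age Per-year log-time slope at age 40.
#' @param beta_age2 Per-year-squared curvature.
#' @param beta_nb Non-binary log-time offset.
#' @param beta_nbp Offset on the signed non-binary predictor (+1 natal-male
#'   non-binary, -1 natal-female non-binary); 0 is the null.
#' @param sigma Residual SD of log time (> 0).
#' @param frac_nonbinary Proportion registering non-binary, in `[0, 1]`.
#' @param n_athletes Number of athletes (>= 1).
#' @param race_year Calendar year in which all races take place.
#' @param age_range Inclusive integer age range athletes are drawn from,
#'   uniformly; default `c(18, 70)` (realized mean 44).
#' @param seed Default RNG seed used by the generators.
#' @return A `synthetic_truth` object (a list).
#' @export
synthetic_truth <- function(event_log_means = NULL,
                            beta_female = 0.12224,
                            beta_age = 0.00375,
                            beta_age2 = 0.00012,
                            beta_nb = 0.03225,
                            beta_nbp = 0,
                            sigma = 0.20,
                            frac_nonbinary = 166 / 85173,
                            n_athletes = 85173,
                            race_year = 2022,
                            age_range = c(18L, 70L),
                            seed = 1L) {
  if (is.null(event_log_means)) {
    miles <- seq(4, 26.2, length.out = 21)
    event_log_means <- log(miles * (540 + 4 * miles))
    names(event_log_means) <- c(sprintf("race%02d", 1:20), "marathon")
  }
  if (is.null(names(event_log_means)) || !"marathon" %in% names(event_log_means)) {
    stop("event_log_means must be named and include 'marathon'", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be > 0", call. = FALSE)
  }
  if (frac_nonbinary < 0 || frac_nonbinary > 1) {
    stop("frac_nonbinary must lie in [0, 1]", call. = FALSE)
  }
  n_athletes <- as.integer(n_athletes)
  if (is.na(n_athletes) || n_athletes < 1L) {
    stop("n_athletes must be >= 1", call. = FALSE)
  }
  age_range <- as.integer(age_range)
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2], age_range[1] >= 0L)
  structure(list(
    event_log_means = event_log_means,
    beta_female = beta_female, beta_age = beta_age, beta_age2 = beta_age2,
    beta_nb = beta_nb, beta_nbp = beta_nbp, sigma = sigma,
    frac_nonbinary = frac_nonbinary, n_athletes = n_athletes,
    race_year = as.integer(race_year), age_range = age_range,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

# Deterministic pseudo-name pools built from syllable grids.
.name_pool <- function(n, kind = c("given", "surname")) {
  kind <- match.arg(kind)
  if (kind == "given") {
    a <- c("al", "ber", "cas", "dor", "el", "fin", "gal", "har", "jor", "kel",
           "lan", "mar", "nor", "or", "pal", "quin", "ren", "sal", "tor", "vel")
    b <- c("an", "en", "in", "on", "ar", "is", "ia", "ey", "o", "a",
           "us", "elle", "ine", "ys", "eth")
  } else {
    a <- c("ash", "black", "cole", "dray", "elm", "ford", "gray", "hill",
           "kirk", "lake", "marsh", "north", "oak", "pier", "reed", "stone",
           "thorn", "under", "wells", "york")
    b <- c("by", "don", "field", "gate", "ham", "land", "man", "mont",
           "son", "ton", "wood", "worth")
  }
  pool <- as.vector(outer(a, b, paste0))
  if (n > length(pool)) {
    pool <- as.vector(outer(pool, c("", letters[1:10]), paste0))
  }
  if (n > length(pool)) stop("name pool exhausted", call. = FALSE)
  pool[seq_len(n)]
}

#' Generate a synthetic baby-name frequency table
#'
#' Emulates the SSA baby-name database structure the sex model consumes:
#' strongly male names (male share above 0.95), strongly female names
#' (below 0.05), ambiguous names, and rare names absent in some years.
#' Per-(name, year, sex) counts are Poisson draws around a log-normal
#' name-popularity level.
#'
#' @param n_names Number of distinct names (>= 4 so every category exists).
#' @param year_range Integer vector of birth years covered (nonempty).
#' @param seed RNG seed; fixed seed gives an identical table.
#' @param composition Named fractions of `male`, `female`, `ambiguous` and
#'   `rare` names; must sum to 1 with `male` and `female` positive.
#' @param exclusive If `TRUE`, strongly sexed names are fully sex-specific
#'   (male share exactly 1 or 0) instead of the default 0.995-0.999 /
#'   0.001-0.005 bands; useful for worlds where a name determines sex.
#' @return A [name_frequency_table()] with attribute `true_share` (the
#'   latent male share per name).
#' @export
generate_name_table <- function(n_names = 40,
                                year_range = 1950:2005,
                                seed = 1L,
                                composition = c(male = 0.3, female = 0.3,
                                                ambiguous = 0.25, rare = 0.15),
                                exclusive = FALSE) {
  n_names <- as.integer(n_names)
  if (is.na(n_names) || n_names < 4L) stop("n_names must be >= 4", call. = FALSE)
  year_range <- as.integer(year_range)
  if (length(year_range) == 0L) stop("year_range must be nonempty", call. = FALSE)
  stopifnot(all(c("male", "female", "ambiguous", "rare") %in% names(composition)),
            abs(sum(composition) - 1) < 1e-8,
            composition[["male"]] > 0, composition[["female"]] > 0)
  set.seed(as.integer(seed))

  counts <- pmax(floor(composition * n_names), c(1, 1, 0, 0))
  while (sum(counts) < n_names) {
    i <- which.max(composition * n_names - counts)
    counts[i] <- counts[i] + 1
  }
  while (sum(counts) > n_names) {
    i <- which.max(counts - composition * n_names)
    counts[i] <- counts[i] - 1
  }
  kind <- rep(names(counts), counts)
  nms <- sample(.name_pool(max(n_names, 8L), "given"), n_names)

  share <- numeric(n_names)
  share[kind == "male"] <- if (exclusive) 1 else
    runif(sum(kind == "male"), 0.995, 0.999)
  share[kind == "female"] <- if (exclusive) 0 else
    runif(sum(kind == "female"), 0.001, 0.005)
  share[kind == "ambiguous"] <- runif(sum(kind == "ambiguous"), 0.2, 0.8)
  share[kind == "rare"] <- runif(sum(kind == "rare"), 0.2, 0.8)
  popularity <- round(stats::rlnorm(n_names, log(800), 0.6)) + 20

  ny <- length(year_range)
  rows <- vector("list", n_names)
  for (i in seq_len(n_names)) {
    present <- if (kind[i] == "rare") runif(ny) < 0.6 else rep(TRUE, ny)
    m <- stats::rpois(ny, popularity[i] * share[i])
    f <- stats::rpois(ny, popularity[i] * (1 - share[i]))
    m[!present] <- 0
    f[!present] <- 0
    keep <- m + f > 0
    rows[[i]] <- data.frame(name = nms[i], year = year_range[keep],
                            male = m[keep], female = f[keep],
                            stringsAsFactors = FALSE)
  }
  out <- name_frequency_table(do.call(rbind, rows))
  ts <- share
  names(ts) <- normalize_name(nms)
  attr(out, "true_share") <- ts
  out
}

#' Generate synthetic athletes with known natal sex
#'
#' Natal sex is Bernoulli(0.5); gender identity is `non-binary` with
#' probability `truth$frac_nonbinary` independently of natal sex (both natal
#' sexes occur among non-binary athletes), otherwise equal to natal sex.
#' Ages are uniform integers on `truth$age_range`; birth year is
#' `race_year - age` or `race_year - age - 1` with a fair coin, so the
#' downstream two-candidate-year logic is exercised. Given names are drawn
#' proportionally to the sex-specific birth counts for the athlete's birth
#' year; a surname from a separate pool (made unique) completes the full
#' name, so every athlete has a distinct identity key.
#'
#' @param truth A [synthetic_truth()].
#' @param name_table A [name_frequency_table()] covering all sampled birth
#'   years.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return Data frame with columns `name`, `birth_year`, `age`, `natal_sex`
#'   (`male`/`female`), `gender_id` (`male`/`female`/`non-binary`).
#' @export
generate_athletes <- function(truth, name_table, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(name_table, "name_table"))
  set.seed(as.integer(seed))
  n <- truth$n_athletes
  natal <- sample(c("male", "female"), n, replace = TRUE)
  nb <- stats::runif(n) < truth$frac_nonbinary
  gender <- ifelse(nb, "non-binary", natal)
  ages <- seq(truth$age_range[1], truth$age_range[2])
  age <- ages[sample.int(length(ages), n, replace = TRUE)]
  birth_year <- truth$race_year - age - stats::rbinom(n, 1L, 0.5)

  yr_missing <- setdiff(unique(birth_year), unique(name_table$year))
  if (length(yr_missing)) {
    stop("name_table does not cover birth years: ",
         paste(sort(yr_missing), collapse = ", "), call. = FALSE)
  }

  given <- character(n)
  for (sx in c("male", "female")) {
    col <- if (sx == "male") "male" else "female"
    for (yr in unique(birth_year[natal == sx])) {
      rows <- which(natal == sx & birth_year == yr)
      tab <- name_table[name_table$year == yr & name_table[[col]] > 0, , drop = FALSE]
      if (nrow(tab) == 0L) {
        stop("no ", sx, " name counts for birth year ", yr, call. = FALSE)
      }
      given[rows] <- sample(tab$name, length(rows), replace = TRUE,
                            prob = tab[[col]])
    }
  }
  surname <- sample(.name_pool(240L, "surname"), n, replace = TRUE)
  full <- make.unique(paste(given, surname), sep = "")
  data.frame(name = full, birth_year = birth_year, age = age,
             natal_sex = natal, gender_id = gender, stringsAsFactors = FALSE)
}

# Linear predictor of log finish time for one athlete-event combination.
.log_time_mean <- function(truth, event, natal_sex, gender_id, age) {
  nb <- gender_id == "non-binary"
  truth$event_log_means[event] +
    truth$beta_female * (natal_sex == "female") +
    truth$beta_age * (age - 40) +
    truth$beta_age2 * (age - 40)^2 +
    truth$beta_nb * nb +
    truth$beta_nbp * ifelse(nb, ifelse(natal_sex == "male", 1, -1), 0)
}

#' Generate synthetic race results
#'
#' Each athlete runs `races_per_athlete` distinct events in the truth's race
#' year; with probability `marathon_frac` the marathon is among them (the
#' calibration step downstream needs athletes shared between each event and
#' the marathon). Log finish time is the event log-mean plus the
#' natal-female, age (centred at 40), quadratic-age, non-binary and signed
#' non-binary offsets, plus Gaussian noise with SD `truth$sigma`.
#'
#' @param athletes Output of [generate_athletes()].
#' @param truth A [synthetic_truth()].
#' @param events Named log-mean vector (default `truth$event_log_means`);
#'   must include `"marathon"`.
#' @param races_per_athlete Events per athlete (>= 1, at most the number of
#'   events); default 2 so total results ~ 2.2x unique athletes, as in the
#'   real cross-race source data.
#' @param marathon_frac Probability an athlete's event set includes the
#'   marathon; default 0.3.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return Data frame with columns `name`, `event`, `date` (ISO-8601),
#'   `age`, `gender_id`, `time_seconds`, carrying `truth` as an attribute.
#' @export
generate_race_results <- function(athletes, truth, events = truth$event_log_means,
                                  races_per_athlete = 2L, marathon_frac = 0.3,
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(names(events)) || !"marathon" %in% names(events)) {
    stop("events must include a 'marathon'", call. = FALSE)
  }
  k <- as.integer(races_per_athlete)
  if (is.na(k) || k < 1L) stop("races_per_athlete must be >= 1", call. = FALSE)
  k <- min(k, length(events))
  set.seed(as.integer(seed))
  n <- nrow(athletes)
  others <- setdiff(names(events), "marathon")

  run_mar <- stats::runif(n) < marathon_frac
  if (length(others) == 0L) run_mar <- rep(TRUE, n)
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (run_mar[i]) {
      ev_list[[i]] <- c("marathon",
                        if (k > 1L) sample(others, k - 1L) else character(0))
    } else {
      ev_list[[i]] <- if (k <= length(others)) sample(others, k) else
        c(sample(others, length(others)), "marathon")
    }
  }
  rep_idx <- rep(seq_len(n), lengths(ev_list))
  event <- unlist(ev_list, use.names = FALSE)
  m <- length(event)

  date <- as.Date(sprintf("%d-01-01", truth$race_year)) +
    sample(0:364, m, replace = TRUE)
  mu <- .log_time_mean(truth, event,
                       athletes$natal_sex[rep_idx], athletes$gender_id[rep_idx],
                       athletes$age[rep_idx])
  log_t <- mu + stats::rnorm(m, 0, truth$sigma)
  out <- data.frame(
    name = athletes$name[rep_idx],
    event = event,
    date = format(date, "%Y-%m-%d"),
    age = athletes$age[rep_idx],
    gender_id = athletes$gender_id[rep_idx],
    time_seconds = exp(log_t),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- truth
  out
}

#' Generate a partial natal-sex lookup table
#'
#' Emulates sex labels recovered from a results-history website: each
#' non-binary athlete independently receives their true natal sex as a label
#' with probability `coverage`; all other athletes are absent.
#'
#' @param athletes Output of [generate_athletes()].
#' @param coverage Labelling probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return Data frame with columns `name`, `natal_sex`.
#' @export
generate_lookup <- function(athletes, coverage, seed = 1L) {
  if (length(coverage) != 1L || is.na(coverage) || coverage < 0 || coverage > 1) {
    stop("coverage must lie in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  nb <- athletes[athletes$gender_id == "non-binary", , drop = FALSE]
  keep <- stats::runif(nrow(nb)) < coverage
  data.frame(name = nb$name[keep], natal_sex = nb$natal_sex[keep],
             stringsAsFactors = FALSE)
}

#' Read and write race-result CSV files
#'
#' The on-disk layout is a header CSV `name,event,date,age,gender_id,
#' time_seconds` with ISO-8601 dates.
#'
#' @param results Race-result data frame.
#' @param path CSV path.
#' @return `write_race_results` invisibly returns `path`;
#'   `read_race_results` returns the data frame.
#' @export
write_race_results <- function(results, path) {
  cols <- c("name", "event", "date", "age", "gender_id", "time_seconds")
  stopifnot(all(cols %in% names(results)))
  utils::write.csv(results[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_race_results
#' @export
read_race_results <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(name = "character", event = "character",
                                      date = "character", age = "integer",
                                      gender_id = "character",
                                      time_seconds = "numeric"))
  if (any(d$time_seconds <= 0) || any(d$age < 0)) {
    stop("race results must have positive times and nonnegative ages",
         call. = FALSE)
  }
  d
}

#' Serialize synthetic ground truth as a JSON sidecar
#'
#' Recovery tests read the generating parameters back from this file rather
#' than trusting in-memory state.
#'
#' @param truth A [synthetic_truth()].
#' @param path JSON path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns the
#'   reconstructed `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- unclass(truth)
  x$event_names <- names(x$event_log_means)
  x$event_log_means <- unname(x$event_log_means)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- x$event_log_means
  names(ev) <- x$event_names
  synthetic_truth(event_log_means = ev, beta_female = x$beta_female,
                  beta_age = x$beta_age, beta_age2 = x$beta_age2,
                  beta_nb = x$beta_nb, beta_nbp = x$beta_nbp, sigma = x$sigma,
                  frac_nonbinary = x$frac_nonbinary, n_athletes = x$n_athletes,
                  race_year = x$race_year, age_range = x$age_range,
                  seed = x$seed)
}
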