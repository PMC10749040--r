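#' Normalize an athlete name
#'
#' Case-folds, transliterates accented characters to ASCII, trims surrounding
#' whitespace and collapses internal runs of whitespace to a single space.
#' Normalized full names are the athlete identity key used for record
#' deduplication: two results with the same normalized full name are assumed
#' to belong to the same athlete.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @seealso [given_name()]
#' @export
#' @examples
#' normalize_name(c("  Ana  MARIA Silva ", "Zoë Quinn"))
normalize_name <- function(x) {
  x <- as.character(x)
  out <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  out[is.na(out)] <- x[is.na(out)]
  out <- gsub("[\"'^`~]", "", out)  # transliteration artifacts, apostrophes
  out <- tolower(trimws(out))
  gsub("[[:space:]]+", " ", out)
}

#' Extract the given name used for name-frequency lookup
#'
#' The first whitespace-separated token of the normalized name. Baby-name
#' frequency tables are keyed on given names, so sex probabilities are
#' computed from this token only.
#'
#' @inheritParams normalize_name
#' @return Character vector of normalized given names.
#' @export
given_name <- function(x) {
  sub(" .*$", "", normalize_name(x))
}

#' Construct a name-frequency table
#'
#' A name-frequency table maps (given name, birth year) to the number of
#' recorded male and female births, as in the US Social Security
#' Administration baby-name database. Absence of a (name, year) pair is
#' meaningful (the name was not recorded that year) and is distinct from an
#' explicit zero-count entry.
#'
#' @param df Data frame with columns `name`, `year`, `male`, `female`.
#'   Names are normalized; duplicate (name, year) rows are summed.
#' @return A `name_table` object (a data frame keyed on name and year).
#' @export
name_frequency_table <- function(df) {
  req <- c("name", "year", "male", "female")
  if (!all(req %in% names(df))) {
    stop("name table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    name = normalize_name(df$name),
    year = as.integer(df$year),
    male = as.numeric(df$male),
    female = as.numeric(df$female),
    stringsAsFactors = FALSE
  )
  if (any(df$male < 0 | df$female < 0)) {
    stop("name counts must be nonnegative", call. = FALSE)
  }
  key <- paste(df$name, df$year, sep = "\t")
  if (anyDuplicated(key)) {
    df <- aggregate(cbind(male, female) ~ name + year, data = df, FUN = sum)
    key <- paste(df$name, df$year, sep = "\t")
  }
  df <- df[order(df$name, df$year), c("name", "year", "male", "female")]
  rownames(df) <- NULL
  attr(df, "key") <- paste(df$name, df$year, sep = "\t")
  class(df) <- c("name_table", "data.frame")
  df
}

#' Read a directory of SSA-style baby-name files
#'
#' Expects the SSA `yobYYYY.txt` layout: one file per birth year, each line
#' `Name,M|F,count` with no header.
#'
#' @param dir Directory containing `yobYYYY.txt` files.
#' @param years Optional integer vector restricting which years to read.
#' @return A [name_frequency_table()] object.
#' @export
read_ssa_names <- function(dir, years = NULL) {
  files <- list.files(dir, pattern = "^yob[0-9]{4}\\.txt$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no yobYYYY.txt files found in ", dir, call. = FALSE)
  }
  yrs <- as.integer(sub("^yob([0-9]{4})\\.txt$", "\\1", basename(files)))
  if (!is.null(years)) {
    keep <- yrs %in% as.integer(years)
    files <- files[keep]
    yrs <- yrs[keep]
  }
  parts <- lapply(seq_along(files), function(i) {
    d <- utils::read.csv(files[i], header = FALSE,
                         col.names = c("name", "sex", "count"),
                         stringsAsFactors = FALSE)
    data.frame(name = d$name, year = yrs[i], sex = d$sex,
               count = as.numeric(d$count), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, parts)
  if (!all(long$sex %in% c("M", "F"))) {
    stop("SSA sex column must be M or F", call. = FALSE)
  }
  wide <- data.frame(
    name = long$name,
    year = long$year,
    male = ifelse(long$sex == "M", long$count, 0),
    female = ifelse(long$sex == "F", long$count, 0),
    stringsAsFactors = FALSE
  )
  name_frequency_table(wide)
}

#' Write a name-frequency table in the SSA yobYYYY layout
#'
#' One `yobYYYY.txt` file per year with lines `Name,M|F,count` (no header);
#' zero-count entries are omitted, matching the convention that absence means
#' the name was not recorded that year.
#'
#' @param table A [name_frequency_table()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ssa_names <- function(table, dir) {
  stopifnot(inherits(table, "name_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cap <- function(x) paste0(toupper(substring(x, 1L, 1L)), substring(x, 2L))
  paths <- character(0)
  for (yr in sort(unique(table$year))) {
    d <- table[table$year == yr, , drop = FALSE]
    lines <- c(
      sprintf("%s,M,%d", cap(d$name[d$male > 0]), as.integer(d$male[d$male > 0])),
      sprintf("%s,F,%d", cap(d$name[d$female > 0]), as.integer(d$female[d$female > 0]))
    )
    p <- file.path(dir, sprintf("yob%d.txt", yr))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Candidate birth years for an athlete
#'
#' An athlete aged `age_years` on race day was born in one of two calendar
#' years, depending on whether their birthday falls before or after the race
#' date within the year.
#'
#' @param age_years Nonnegative integer age on race day.
#' @param race_date Race date (`Date` or ISO-8601 string).
#' @return Integer vector of the two candidate years
#'   `c(race_year - age, race_year - age - 1)`. Vectorized inputs return a
#'   two-column matrix.
#' @export
#' @examples
#' candidate_birth_years(30, "2022-11-06")
candidate_birth_years <- function(age_years, race_date) {
  age_years <- as.integer(age_years)
  if (any(is.na(age_years)) || any(age_years < 0L)) {
    stop("age_years must be a nonnegative integer", call. = FALSE)
  }
  ry <- as.integer(format(as.Date(race_date), "%Y"))
  y1 <- ry - age_years
  if (length(y1) == 1L) c(y1, y1 - 1L) else cbind(y1, y1 - 1L, deparse.level = 0)
}

# Pooled (male, female) counts for given names over a set of years.
# Returns a list(male, female, seen) of vectors; `seen` marks names present
# (with positive total) in at least one of the years.
.pooled_counts <- function(names_norm, years_mat, table) {
  key <- attr(table, "key")
  m <- numeric(length(names_norm))
  f <- numeric(length(names_norm))
  seen <- logical(length(names_norm))
  for (j in seq_len(ncol(years_mat))) {
    idx <- match(paste(names_norm, years_mat[, j], sep = "\t"), key)
    hit <- !is.na(idx)
    m[hit] <- m[hit] + table$male[idx[hit]]
    f[hit] <- f[hit] + table$female[idx[hit]]
    seen <- seen | hit
  }
  list(male = m, female = f, seen = seen & (m + f) > 0)
}

#' Probability of being natal male from a given name
#'
#' Pools male and female birth counts for the athlete's given name over the
#' two candidate birth years and returns the male share
#' `sum(male) / sum(male + female)`. Pooling uses raw count sums, not the
#' mean of two per-year proportions. Returns `NA` (unassigned) when the name
#' is absent in both years or the pooled total is zero: absence is a value,
#' not an error.
#'
#' @param name Athlete name (full names allowed; the given name is the first
#'   token after normalization).
#' @param years Integer vector of candidate birth years, as returned by
#'   [candidate_birth_years()].
#' @param table A [name_frequency_table()].
#' @return Probability in `[0, 1]`, or `NA_real_` if unassignable.
#' @export
prob_male_from_name <- function(name, years, table) {
  stopifnot(inherits(table, "name_table"))
  g <- given_name(name)
  pc <- .pooled_counts(g, matrix(as.integer(years), nrow = 1), table)
  if (!pc$seen) return(NA_real_)
  pc$male / (pc$male + pc$female)
}

#' Read a partial natal-sex lookup table
#'
#' CSV with header `name,natal_sex`, `natal_sex` in `{male, female}` —
#' emulating sex labels recovered from an athlete's earlier binary-category
#' races.
#'
#' @param path CSV path.
#' @return Data frame with columns `name`, `natal_sex`.
#' @export
read_lookup <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "natal_sex") %in% names(d))) {
    stop("lookup table needs columns name, natal_sex", call. = FALSE)
  }
  if (nrow(d) > 0 && !all(d$natal_sex %in% c("male", "female"))) {
    stop("lookup natal_sex must be 'male' or 'female'", call. = FALSE)
  }
  d
}

#' Assign each record a probability of being natal male
#'
#' Implements the three-tier precedence declared > lookup > name model.
#' Athletes registered male or female get `prob_male` 1 or 0 (source
#' `declared`). Non-binary athletes are first matched (by normalized full
#' name) against the lookup table, which yields 0/1 labels (source `lookup`);
#' failing that, the given-name frequency model over the two candidate birth
#' years is used (source `name_model`); records no method can inform get
#' `prob_male = NA` and source `none`, and are flagged for exclusion.
#'
#' @param records Data frame with columns `name`, `gender_id` (one of
#'   `male`, `female`, `non-binary`), `age`, `date`.
#' @param lookup Optional data frame `name,natal_sex` (see [read_lookup()]).
#' @param table Optional [name_frequency_table()].
#' @param epsilon Extra-uncertainty shrinkage applied to name-model
#'   probabilities via [widen_uncertainty()]; default 0 (no widening).
#' @return `records` with columns `prob_male` and `prob_source`
#'   (`declared`, `lookup`, `name_model`, or `none`) appended.
#' @export
assign_prob_male <- function(records, lookup = NULL, table = NULL, epsilon = 0) {
  ok <- c("male", "female", "non-binary")
  if (!all(records$gender_id %in% ok)) {
    bad <- setdiff(unique(records$gender_id), ok)
    stop("unknown gender_id value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  prob <- rep(NA_real_, n)
  src <- rep("none", n)

  decl_m <- records$gender_id == "male"
  decl_f <- records$gender_id == "female"
  prob[decl_m] <- 1
  prob[decl_f] <- 0
  src[decl_m | decl_f] <- "declared"

  nb <- which(records$gender_id == "non-binary")
  if (length(nb)) {
    if (!is.null(lookup) && nrow(lookup) > 0) {
      idx <- match(normalize_name(records$name[nb]), normalize_name(lookup$name))
      hit <- !is.na(idx)
      prob[nb[hit]] <- ifelse(lookup$natal_sex[idx[hit]] == "male", 1, 0)
      src[nb[hit]] <- "lookup"
    }
    rest <- nb[src[nb] == "none"]
    if (length(rest) && !is.null(table)) {
      yrs <- candidate_birth_years(records$age[rest], records$date[rest])
      if (is.null(dim(yrs))) yrs <- matrix(yrs, nrow = 1)
      pc <- .pooled_counts(given_name(records$name[rest]), yrs, table)
      got <- pc$seen
      p <- pc$male[got] / (pc$male[got] + pc$female[got])
      prob[rest[got]] <- widen_uncertainty(p, epsilon)
      src[rest[got]] <- "name_model"
    }
  }
  records$prob_male <- prob
  records$prob_source <- src
  records
}

#' Summarize how non-binary athletes' sex probabilities were assigned
#'
#' Counts, among non-binary records, how many probabilities came from the
#' lookup table, from the name-frequency model, and how many could not be
#' assigned. The three counts sum to the number of non-binary records.
#'
#' @param records Output of [assign_prob_male()].
#' @return Data frame with columns `method`, `n`.
#' @export
sex_assignment_summary <- function(records) {
  nb <- records[records$gender_id == "non-binary", , drop = FALSE]
  data.frame(
    method = c("lookup", "name_model", "none", "total"),
    n = c(sum(nb$prob_source == "lookup"),
          sum(nb$prob_source == "name_model"),
          sum(nb$prob_source == "none"),
          nrow(nb)),
    stringsAsFactors = FALSE
  )
}

#' Cross-validate lookup labels against the name-frequency model
#'
#' Restricted to records that both carry a lookup label and receive a
#' name-model probability outside `[threshold, 1 - threshold]` (i.e. the
#' name model is confident), counts cases and agreements, where the name
#' model's call is the side of 0.5 its probability falls on.
#'
#' @param lookup Data frame `name,natal_sex`.
#' @param table A [name_frequency_table()].
#' @param records Data frame with `name`, `age`, `date` columns.
#' @param threshold Confidence threshold in `(0, 0.5)`; default 0.05.
#' @return List with `n_compared`, `n_agree`, and `agreement` (their ratio,
#'   `NaN` when nothing compared).
#' @export
cross_validate <- function(lookup, table, records, threshold = 0.05) {
  if (!(threshold > 0 && threshold < 0.5)) {
    stop("threshold must lie in (0, 0.5)", call. = FALSE)
  }
  if (is.null(lookup) || nrow(lookup) == 0L || nrow(records) == 0L) {
    return(list(n_compared = 0L, n_agree = 0L, agreement = NaN))
  }
  idx <- match(normalize_name(records$name), normalize_name(lookup$name))
  has <- which(!is.na(idx))
  if (!length(has)) return(list(n_compared = 0L, n_agree = 0L, agreement = NaN))
  yrs <- candidate_birth_years(records$age[has], records$date[has])
  if (is.null(dim(yrs))) yrs <- matrix(yrs, nrow = 1)
  pc <- .pooled_counts(given_name(records$name[has]), yrs, table)
  p <- ifelse(pc$seen, pc$male / (pc$male + pc$female), NA_real_)
  conf <- !is.na(p) & (p < threshold | p > 1 - threshold)
  pred_male <- p[conf] > 0.5
  label_male <- lookup$natal_sex[idx[has][conf]] == "male"
  n_comp <- sum(conf)
  n_agr <- sum(pred_male == label_male)
  list(n_compared = as.integer(n_comp), n_agree = as.integer(n_agr),
       agreement = if (n_comp > 0) n_agr / n_comp else NaN)
}

#' Widen a sex probability to absorb extra uncertainty
#'
#' Linear shrinkage of a probability toward 0.5:
#' `(1 - epsilon) * prob + epsilon / 2`. Models residual uncertainty the
#' name-frequency data cannot capture (e.g. athletes who changed their
#' name). `epsilon = 0` is the identity; 0.5 is a fixed point for any
#' epsilon.
#'
#' @param prob Probability vector in `[0, 1]`.
#' @param epsilon Shrinkage weight in `[0, 1]`.
#' @return Widened probabilities.
#' @export
#' @examples
#' widen_uncertainty(1, 0.2)  # 0.9
widen_uncertainty <- function(prob, epsilon) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(is.na(prob)) || any(prob < 0 | prob > 1)) {
    stop("prob must lie in [0, 1]", call. = FALSE)
  }
  (1 - epsilon) * prob + epsilon / 2
}
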