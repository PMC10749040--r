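# Shared fixtures and independent oracles, built in code at test time.

# 12-athlete constructed fixture for the cross-race builder: two non-marathon
# events of different marathon correlation, one gross calibration outlier
# (a6's marathon pair), one record whose predicted marathon time exceeds the
# 11-hour cut-off (a10), and one athlete who ran both non-marathon events but
# not the marathon (a12).
crossrace_fixture <- function() {
  row <- function(name, event, time) {
    data.frame(name = name, event = event, date = "2022-06-01", age = 40L,
               gender_id = "male", time_seconds = time,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("a1", "tenk", 2400), row("a1", "marathon", 9620),
    row("a2", "tenk", 2500), row("a2", "marathon", 10000),
    row("a3", "tenk", 2600), row("a3", "marathon", 10350),
    row("a4", "tenk", 2700), row("a4", "marathon", 10840),
    row("a5", "tenk", 2800), row("a5", "marathon", 11150),
    row("a6", "tenk", 3000), row("a6", "marathon", 30000),
    row("a7", "fourmile", 1200), row("a7", "marathon", 8400),
    row("a8", "fourmile", 1300), row("a8", "marathon", 9350),
    row("a9", "fourmile", 1400), row("a9", "marathon", 9600),
    row("a10", "tenk", 11000),
    row("a11", "fourmile", 1250),
    row("a12", "tenk", 2650), row("a12", "fourmile", 1280)
  )
}

# Brute-force oracle for the fixture: closed-form no-intercept slopes,
# explicit ratio ordering, and per-athlete selection enumerated directly.
crossrace_fixture_oracle <- function(keep_frac = 0.75) {
  tenk_e <- c(2400, 2500, 2600, 2700, 2800, 3000)
  tenk_m <- c(9620, 10000, 10350, 10840, 11150, 30000)
  fm_e <- c(1200, 1300, 1400)
  fm_m <- c(8400, 9350, 9600)
  s1 <- sum(tenk_e * tenk_m) / sum(tenk_e^2)
  ratio <- abs(tenk_m - s1 * tenk_e) / tenk_m
  keep <- order(ratio)[seq_len(ceiling(keep_frac * 6))]
  tenk_slope <- sum(tenk_e[keep] * tenk_m[keep]) / sum(tenk_e[keep]^2)
  tenk_cor <- stats::cor(tenk_e[keep], tenk_m[keep])
  fm_slope <- sum(fm_e * fm_m) / sum(fm_e^2)
  fm_cor <- stats::cor(fm_e, fm_m)
  list(
    tenk = list(slope = tenk_slope, cor = tenk_cor,
                trimmed_pair = setdiff(1:6, keep), n_trimmed = 6 - length(keep)),
    fourmile = list(slope = fm_slope, cor = fm_cor, n_trimmed = 0L),
    # a1..a9 ran the marathon -> marathon always selected; a10 tenk-only with
    # predicted time over 11 h -> discarded; a11 fourmile-only; a12 picks the
    # event with the higher marathon correlation.
    selected = c(a1 = "marathon", a2 = "marathon", a3 = "marathon",
                 a4 = "marathon", a5 = "marathon", a6 = "marathon",
                 a7 = "marathon", a8 = "marathon", a9 = "marathon",
                 a11 = "fourmile",
                 a12 = if (tenk_cor > fm_cor) "tenk" else "fourmile"),
    discarded = "a10",
    a10_predicted = tenk_slope * 11000
  )
}

# A small synthetic world exercising the whole path: athletes, one result
# each across two events, a partial lookup over non-binary athletes, and
# name-model probabilities for the rest.
small_world <- function(n = 300, frac_nb = 0.15, lookup_coverage = 0.5,
                        seed = 100, sigma = 0.20, beta_nbp = 0,
                        name_table = NULL, races_per_athlete = 1,
                        marathon_frac = 0.5) {
  ev <- c(race01 = log(4 * (540 + 16)),
          marathon = log(26.2 * (540 + 4 * 26.2)))
  truth <- synthetic_truth(event_log_means = ev, n_athletes = n,
                           frac_nonbinary = frac_nb, sigma = sigma,
                           beta_nbp = beta_nbp, seed = seed)
  if (is.null(name_table)) {
    name_table <- generate_name_table(year_range = 1951:2004, seed = 11)
  }
  athletes <- generate_athletes(truth, name_table, seed = seed)
  results <- generate_race_results(athletes, truth,
                                   races_per_athlete = races_per_athlete,
                                   marathon_frac = marathon_frac,
                                   seed = seed + 1)
  lookup <- generate_lookup(athletes, lookup_coverage, seed = seed + 2)
  assigned <- assign_prob_male(results, lookup, name_table)
  list(truth = truth, name_table = name_table, athletes = athletes,
       results = results, lookup = lookup,
       data = assigned[!is.na(assigned$prob_male), , drop = FALSE])
}

# Ordinary-least-squares oracle for the latent model with fully known sex:
# completes natal sex from degenerate prob_male and fits lm() directly.
ols_oracle <- function(data, model_id) {
  stopifnot(all(data$prob_male %in% c(0, 1)))
  natal <- ifelse(data$prob_male == 1, "male", "female")
  lat <- latent_covariates(data$gender_id, natal)
  df <- data.frame(y = log(data$time_seconds), event = factor(data$event),
                   age_c = data$age - 40)
  df$age_c2 <- df$age_c^2
  df$natal_female <- as.numeric(natal == "female")
  df$gender_female <- as.numeric(data$gender_id == "female")
  df$gender_nonbinary <- as.numeric(data$gender_id == "non-binary")
  df <- cbind(df, lat)
  form <- switch(model_id,
    y ~ event + age_c + age_c2 + natal_female + nb_predictor,
    y ~ event + age_c + age_c2 + gender_female + gender_nonbinary + nb_predictor,
    y ~ event + age_c + age_c2 + natal_female + is_nbm + is_nbf,
    y ~ event + age_c + age_c2 + natal_female + is_nb)
  stats::lm(form, data = df)
}

# Map lm() coefficient names onto fit_latent_model()'s naming.
match_ols_coefs <- function(lm_fit) {
  co <- stats::coef(lm_fit)
  names(co) <- sub("^event", "event:", names(co))
  co
}
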