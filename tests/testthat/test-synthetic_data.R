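test_that("generate_name_table produces all name categories, determinism, and errors", {
  expect_error(generate_name_table(n_names = 3), "n_names")
  expect_error(generate_name_table(year_range = integer(0)), "year_range")

  tab <- generate_name_table(n_names = 40, year_range = 1980:1990, seed = 3)
  agg <- aggregate(cbind(male, female) ~ name, data = tab, FUN = sum)
  share <- agg$male / (agg$male + agg$female)
  expect_true(any(share > 0.95))
  expect_true(any(share < 0.05))
  expect_true(any(share >= 0.05 & share <= 0.95))
  # rare names are absent in some years
  yrs_per_name <- table(tab$name)
  expect_true(any(yrs_per_name < length(1980:1990)))
  expect_true(all(tab$male >= 0 & tab$female >= 0))
  expect_true(all(tab$male == floor(tab$male)))

  tab2 <- generate_name_table(n_names = 40, year_range = 1980:1990, seed = 3)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  # male share is computable per (name, year) on a minimal table
  tiny <- generate_name_table(n_names = 4, year_range = 2000, seed = 1)
  expect_true(all(tiny$male / (tiny$male + tiny$female) >= 0))
})

test_that("generate_athletes respects the non-binary fraction and name-sex link", {
  tab <- generate_name_table(year_range = 1951:2004, seed = 11)

  t0 <- synthetic_truth(n_athletes = 400, frac_nonbinary = 0, seed = 5)
  a0 <- generate_athletes(t0, tab)
  expect_false(any(a0$gender_id == "non-binary"))
  expect_identical(a0$gender_id, a0$natal_sex)

  t1 <- synthetic_truth(n_athletes = 200, frac_nonbinary = 1, seed = 5)
  a1 <- generate_athletes(t1, tab)
  expect_true(all(a1$gender_id == "non-binary"))
  expect_setequal(unique(a1$natal_sex), c("male", "female"))

  # n=10000, frac=0.002: count inside the binomial 99% interval around 20
  t2 <- synthetic_truth(n_athletes = 10000, frac_nonbinary = 0.002, seed = 9)
  a2 <- generate_athletes(t2, tab)
  n_nb <- sum(a2$gender_id == "non-binary")
  expect_gte(n_nb, qbinom(0.005, 10000, 0.002))
  expect_lte(n_nb, qbinom(0.995, 10000, 0.002))

  # names are drawn conditionally on natal sex: strongly male given names
  # should overwhelmingly belong to natal-male athletes
  share <- attr(tab, "true_share")
  g <- given_name(a2$name)
  strong_m <- names(share)[share > 0.95]
  has_strong <- g %in% strong_m
  expect_gt(mean(a2$natal_sex[has_strong] == "male"), 0.97)

  # identity keys unique; birth year consistent with age and race year
  expect_false(anyDuplicated(normalize_name(a2$name)) > 0)
  expect_true(all(a2$birth_year %in% c(t2$race_year - a2$age,
                                       t2$race_year - a2$age - 1L)))
})

test_that("generate_race_results follows the generative log-time model", {
  tab <- generate_name_table(year_range = 1951:2004, seed = 11)

  # noise-free single-event case: natal male, age 40, binary -> exact time
  tr <- synthetic_truth(event_log_means = c(marathon = 9.5), sigma = 1e-12,
                        frac_nonbinary = 0, n_athletes = 50,
                        age_range = c(40L, 40L), seed = 2)
  ath <- generate_athletes(tr, tab)
  res <- generate_race_results(ath, tr, races_per_athlete = 1,
                               marathon_frac = 1)
  males <- res$gender_id == "male"
  expect_equal(res$time_seconds[males], rep(exp(9.5), sum(males)),
               tolerance = 1e-9)
  expect_equal(res$time_seconds[!males], rep(exp(9.5 + tr$beta_female),
                                             sum(!males)), tolerance = 1e-9)

  # error when the marathon is missing
  expect_error(generate_race_results(ath, tr, events = c(tenk = 8)),
               "marathon")

  # determinism
  tr2 <- synthetic_truth(n_athletes = 200, seed = 4)
  a2 <- generate_athletes(tr2, tab)
  r_a <- generate_race_results(a2, tr2)
  r_b <- generate_race_results(a2, tr2)
  expect_identical(r_a, r_b)

  # natal-sex log-time gap at fixed event and age matches beta_female
  tr3 <- synthetic_truth(event_log_means = c(marathon = 9.6),
                         beta_female = 0.12221, frac_nonbinary = 0,
                         n_athletes = 5000, age_range = c(40L, 40L), seed = 6)
  a3 <- generate_athletes(tr3, tab)
  r3 <- generate_race_results(a3, tr3, races_per_athlete = 1, marathon_frac = 1)
  gap <- mean(log(r3$time_seconds[a3$natal_sex == "female"])) -
    mean(log(r3$time_seconds[a3$natal_sex == "male"]))
  expect_lt(abs(gap - 0.12221), 3 * tr3$sigma * sqrt(4 / 5000))
})

test_that("generated moments match the generative formula", {
  tab <- generate_name_table(year_range = 1951:2004, seed = 11)
  tr <- synthetic_truth(n_athletes = 4000, frac_nonbinary = 0.01, seed = 12)
  ath <- generate_athletes(tr, tab)
  res <- generate_race_results(ath, tr, races_per_athlete = 1,
                               marathon_frac = 0.4)
  idx <- match(res$name, ath$name)
  nb <- ath$gender_id[idx] == "non-binary"
  mu <- tr$event_log_means[res$event] +
    tr$beta_female * (ath$natal_sex[idx] == "female") +
    tr$beta_age * (res$age - 40) + tr$beta_age2 * (res$age - 40)^2 +
    tr$beta_nb * nb
  resid <- log(res$time_seconds) - mu
  # per-event mean residual within 3 sigma / sqrt(n)
  for (ev in unique(res$event)) {
    r <- resid[res$event == ev]
    if (length(r) >= 30) {
      expect_lt(abs(mean(r)), 3 * tr$sigma / sqrt(length(r)))
    }
  }
  # residual SD recovers sigma within Monte Carlo error
  expect_lt(abs(sd(resid) - tr$sigma), 4 * tr$sigma / sqrt(2 * length(resid)))
})

test_that("generate_lookup covers non-binary athletes as specified", {
  tab <- generate_name_table(year_range = 1951:2004, seed = 11)
  tr <- synthetic_truth(n_athletes = 600, frac_nonbinary = 0.3, seed = 8)
  ath <- generate_athletes(tr, tab)
  nb <- ath[ath$gender_id == "non-binary", ]

  expect_equal(nrow(generate_lookup(ath, 0, seed = 1)), 0)

  full <- generate_lookup(ath, 1, seed = 1)
  expect_setequal(full$name, nb$name)
  expect_identical(full$natal_sex, nb$natal_sex[match(full$name, nb$name)])

  # coverage 0.55 on exactly 166 non-binary athletes: binomial 99% interval
  nb166 <- nb[seq_len(166), ]
  lk <- generate_lookup(nb166, 0.55, seed = 2)
  expect_gte(nrow(lk), qbinom(0.005, 166, 0.55))
  expect_lte(nrow(lk), qbinom(0.995, 166, 0.55))
  expect_error(generate_lookup(ath, 1.2), "coverage")
})

test_that("synthetic bundle round-trips through its file formats", {
  dir <- withr::local_tempdir()
  tab <- generate_name_table(n_names = 12, year_range = 1990:1993, seed = 5)
  tr <- synthetic_truth(n_athletes = 60, frac_nonbinary = 0.2, seed = 5,
                        race_year = 2022, age_range = c(29L, 31L))
  tab2 <- generate_name_table(n_names = 12, year_range = 1990:1994, seed = 5)

  write_ssa_names(tab, file.path(dir, "names"))
  back <- read_ssa_names(file.path(dir, "names"))
  expect_equal(as.data.frame(back), as.data.frame(tab)[c("name", "year", "male", "female")],
               ignore_attr = TRUE)

  ath <- generate_athletes(tr, tab2)
  res <- generate_race_results(ath, tr, races_per_athlete = 1)
  write_race_results(res, file.path(dir, "results.csv"))
  res2 <- read_race_results(file.path(dir, "results.csv"))
  expect_equal(res2$time_seconds, res$time_seconds, tolerance = 1e-12)
  expect_identical(res2$name, res$name)
  expect_identical(res2$date, res$date)

  write_truth(tr, file.path(dir, "truth.json"))
  tr2 <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr2$event_log_means, tr$event_log_means, tolerance = 1e-12)
  expect_equal(tr2$beta_female, tr$beta_female)
  expect_equal(tr2$frac_nonbinary, tr$frac_nonbinary)
})

test_that("synthetic_truth validates its invariants", {
  expect_error(synthetic_truth(sigma = 0), "sigma")
  expect_error(synthetic_truth(frac_nonbinary = 1.5), "frac_nonbinary")
  expect_error(synthetic_truth(n_athletes = 0), "n_athletes")
  expect_error(synthetic_truth(event_log_means = c(tenk = 8)), "marathon")
})
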