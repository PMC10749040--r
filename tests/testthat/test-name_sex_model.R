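test_that("candidate_birth_years does the two-year arithmetic", {
  expect_equal(candidate_birth_years(30, "2022-11-06"), c(1992L, 1991L))
  expect_equal(candidate_birth_years(0, "2022-01-01"), c(2022L, 2021L))
  expect_equal(candidate_birth_years(40, "1999-06-15"), c(1959L, 1958L))
  expect_error(candidate_birth_years(-1, "2022-01-01"), "nonnegative")
  m <- candidate_birth_years(c(30, 40), c("2022-11-06", "1999-06-15"))
  expect_equal(m, cbind(c(1992L, 1959L), c(1991L, 1958L)))
})

test_that("prob_male_from_name pools counts over the candidate years", {
  tab <- name_frequency_table(data.frame(
    name = c("alex", "alex", "bea", "bea", "casey", "casey", "drew"),
    year = c(1991, 1992, 1991, 1992, 1991, 1992, 1990),
    male = c(100, 100, 0, 0, 30, 10, 7),
    female = c(0, 0, 50, 40, 10, 30, 3)))

  expect_equal(prob_male_from_name("Alex", c(1992, 1991), tab), 1.0)
  # pooled counts, not averaged proportions: (30+10)/(40+40) = 0.5
  expect_equal(prob_male_from_name("casey", c(1992, 1991), tab), 0.5)
  expect_equal(prob_male_from_name("bea", c(1992, 1991), tab), 0.0)
  expect_true(is.na(prob_male_from_name("zelda", c(1992, 1991), tab)))
  # present in the table but absent in both candidate years -> unassigned
  expect_true(is.na(prob_male_from_name("drew", c(1992, 1991), tab)))
  # full names are reduced to the given name
  expect_equal(prob_male_from_name("Casey Stonewood", c(1992, 1991), tab), 0.5)
})

test_that("prob_male_from_name is invariant to scaling all counts", {
  base <- data.frame(name = rep(c("ab", "cd", "ef"), each = 2),
                     year = rep(c(2000, 2001), 3),
                     male = c(5, 7, 90, 80, 33, 0),
                     female = c(95, 93, 10, 30, 66, 12))
  t1 <- name_frequency_table(base)
  for (k in c(2, 10, 400)) {
    scaled <- base
    scaled$male <- scaled$male * k
    scaled$female <- scaled$female * k
    t2 <- name_frequency_table(scaled)
    for (nm in c("ab", "cd", "ef")) {
      expect_equal(prob_male_from_name(nm, c(2000, 2001), t2),
                   prob_male_from_name(nm, c(2000, 2001), t1))
    }
  }
})

test_that("assign_prob_male applies declared > lookup > name-model precedence", {
  tab <- name_frequency_table(data.frame(
    name = c("alex", "bea", "casey"), year = 1992,
    male = c(100, 0, 20), female = c(0, 50, 20)))
  recs <- data.frame(
    name = c("Alex One", "Bea Two", "Casey Three", "Alex Four", "Zed Five"),
    gender_id = c("male", "female", "non-binary", "non-binary", "non-binary"),
    age = 30L, date = "2022-06-01", stringsAsFactors = FALSE)
  lookup <- data.frame(name = c("Alex One", "Casey Three"),
                       natal_sex = c("female", "male"))

  out <- assign_prob_male(recs, lookup, tab)
  # declared beats a contradictory lookup entry
  expect_equal(out$prob_male[1], 1)
  expect_equal(out$prob_source[1], "declared")
  expect_equal(out$prob_male[2], 0)
  expect_equal(out$prob_source[2], "declared")
  # non-binary with lookup -> 0/1 from the label
  expect_equal(out$prob_male[3], 1)
  expect_equal(out$prob_source[3], "lookup")
  # non-binary without lookup -> name model
  expect_equal(out$prob_male[4], 1)
  expect_equal(out$prob_source[4], "name_model")
  # nothing knows this name -> flagged for exclusion
  expect_true(is.na(out$prob_male[5]))
  expect_equal(out$prob_source[5], "none")

  # adding a lookup never changes a declared assignment
  no_lookup <- assign_prob_male(recs, NULL, tab)
  decl <- out$prob_source == "declared"
  expect_identical(out$prob_male[decl], no_lookup$prob_male[decl])

  expect_error(assign_prob_male(transform(recs, gender_id = "other"), NULL, tab),
               "gender_id")

  s <- sex_assignment_summary(out)
  expect_equal(s$n[s$method == "total"],
               sum(s$n[s$method %in% c("lookup", "name_model", "none")]))
})

test_that("widen_uncertainty shrinks linearly toward 0.5", {
  expect_equal(widen_uncertainty(1.0, 0), 1.0)
  expect_equal(widen_uncertainty(1.0, 0.2), 0.9)
  for (eps in c(0, 0.1, 0.5, 1)) {
    expect_equal(widen_uncertainty(0.5, eps), 0.5)
  }
  expect_equal(widen_uncertainty(c(0, 0.25), 0.4), c(0.2, 0.35))
  expect_error(widen_uncertainty(0.5, 1.1), "epsilon")
  expect_error(widen_uncertainty(1.2, 0.1), "prob")
})

test_that("name normalization strips accents, case and extra tokens", {
  expect_equal(normalize_name("  Ana  MARIA  "), "ana maria")
  expect_equal(given_name("Ana Maria Silva"), "ana")
  expect_equal(given_name("Zoë Quinn"), "zoe")
})

test_that("cross_validate counts confident comparisons and agreements", {
  # empty lookup
  tab <- generate_name_table(year_range = 1990:1995, seed = 2)
  recs <- data.frame(name = "nobody", age = 30L, date = "2022-06-01")
  cv0 <- cross_validate(data.frame(name = character(0),
                                   natal_sex = character(0)), tab, recs)
  expect_equal(cv0$n_compared, 0L)
  expect_equal(cv0$n_agree, 0L)
  expect_error(cross_validate(NULL, tab, recs, threshold = 0.6), "threshold")

  # lookup and name model built from the same truth with sex-specific names
  # only: every confident comparison agrees
  strong <- generate_name_table(n_names = 20, year_range = 1951:2004, seed = 3,
                                composition = c(male = 0.5, female = 0.5,
                                                ambiguous = 0, rare = 0),
                                exclusive = TRUE)
  w <- small_world(n = 300, frac_nb = 0.3, lookup_coverage = 1, seed = 21,
                   name_table = strong)
  nbrec <- w$results[w$results$gender_id == "non-binary", ]
  cv <- cross_validate(w$lookup, strong, nbrec)
  expect_gt(cv$n_compared, 10)
  expect_equal(cv$n_agree, cv$n_compared)

  # default mixed name table: agreement at least 0.95
  w2 <- small_world(n = 1200, frac_nb = 0.15, lookup_coverage = 1, seed = 22)
  nb2 <- w2$results[w2$results$gender_id == "non-binary", ]
  cv2 <- cross_validate(w2$lookup, w2$name_table, nb2)
  expect_gt(cv2$n_compared, 30)
  expect_gte(cv2$agreement, 0.95)
})

test_that("name-model imputation at the 0.5 cut recovers ground truth", {
  strong <- generate_name_table(n_names = 24, year_range = 1951:2004, seed = 7,
                                composition = c(male = 0.5, female = 0.5,
                                                ambiguous = 0, rare = 0))
  agg <- aggregate(cbind(male, female) ~ name, data = strong, FUN = sum)
  expect_true(all(pmax(agg$male, agg$female) /
                    (agg$male + agg$female) > 0.99))

  truth <- synthetic_truth(n_athletes = 3000, frac_nonbinary = 0, seed = 13)
  ath <- generate_athletes(truth, strong)
  recs <- data.frame(name = ath$name, gender_id = "non-binary",
                     age = ath$age, date = sprintf("%d-07-01", truth$race_year))
  out <- assign_prob_male(recs, NULL, strong)
  ok <- !is.na(out$prob_male)
  imputed <- ifelse(out$prob_male[ok] > 0.5, "male", "female")
  expect_gte(mean(imputed == ath$natal_sex[ok]), 0.99)
})

test_that("SSA files and lookup CSVs read back correctly", {
  dir <- withr::local_tempdir()
  writeLines(c("Mary,F,7065", "John,M,9655", "Jo,F,12", "Jo,M,30"),
             file.path(dir, "yob1990.txt"))
  writeLines(c("Mary,F,6000", "John,M,9000"), file.path(dir, "yob1991.txt"))
  tab <- read_ssa_names(dir)
  expect_equal(prob_male_from_name("John", c(1990, 1991), tab), 1)
  expect_equal(prob_male_from_name("jo", c(1990, 1991), tab), 30 / 42)
  expect_true(is.na(prob_male_from_name("jo", c(1991, 1992), tab)))

  lk_path <- file.path(dir, "lookup.csv")
  writeLines(c("name,natal_sex", "Ann Example,female"), lk_path)
  lk <- read_lookup(lk_path)
  expect_equal(lk$natal_sex, "female")
  writeLines(c("name,natal_sex", "Ann Example,unknown"), lk_path)
  expect_error(read_lookup(lk_path), "natal_sex")
})
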