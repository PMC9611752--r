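test_that("person tables load from delimited text with column mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "RACE,SEX,AGE,NAT,EMP,INC,HLT",
    "White,Male,40,Native,Full-time,50000,2",
    "Black,Female,30,Native,Full-time,30000,3",
    "White,Female,55,Native,Full-time,70000,1"), path)
  map <- c(race = "RACE", sex = "SEX", age = "AGE", nativity = "NAT",
           employment = "EMP", income = "INC", health = "HLT")
  tab <- load_person_table(path, map)
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "dropped"), 0)

  # out-of-support health is dropped and counted
  writeLines(c(
    "race,sex,age,nativity,employment,income,health",
    "White,Male,40,Native,Full-time,50000,9",
    "Black,Female,30,Native,Full-time,30000,3"), path)
  expect_message(tab2 <- load_person_table(path), "dropped")
  expect_equal(nrow(tab2), 1)
  expect_equal(attr(tab2, "dropped"), 1)
  expect_error(load_person_table(path, map), "absent from file")
})

test_that("generator output round-trips through write and load", {
  pop <- generate_population(generator_config(n = 300, seed = 4), year = 2015)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  back <- load_person_table(path, year = 2015)
  expect_equal(nrow(back), nrow(pop))
  expect_equal(back$income, pop$income, tolerance = 1e-9)
  expect_identical(back$race, pop$race)
  expect_identical(back$health, as.integer(pop$health))
})

test_that("inclusion filters use inclusive age bounds and drop the right rows", {
  base <- data.frame(
    race = c("White", "White", "Black", "Multiracial", "White", "White", "White"),
    sex = "Male", age = c(24, 25, 65, 40, 66, 40, 40),
    nativity = c("Native", "Native", "Native", "Native", "Native",
                 "Foreign-born", "Native"),
    employment = c("Full-time", "Full-time", "Full-time", "Full-time",
                   "Full-time", "Full-time", "Part-time"),
    income = 50000, health = 3, stringsAsFactors = FALSE)
  tab <- person_table(base)
  kept <- apply_filters(tab, cohort_config())
  # rows 2 and 3 survive: ages 25 and 65 are retained, 24 and 66 excluded,
  # as are the multiracial, foreign-born and part-time rows
  expect_equal(kept$age, c(25, 65))
  at <- attr(kept, "attrition")
  expect_equal(unname(at[c("age", "race", "nativity", "employment")]),
               c(2L, 1L, 1L, 1L))
  # emptying filter is named
  young <- person_table(transform(base, age = 20))
  expect_error(apply_filters(young, cohort_config()), "'age' filter")
})

test_that("income coarse-graining uses the documented cutpoints", {
  f <- coarse_grain_income(c(0, 27499, 27500, 52499, 52500, 77499, 77500))
  expect_equal(as.character(f),
               c("Low", "Low", "Lower-Middle", "Lower-Middle",
                 "Upper-Middle", "Upper-Middle", "High"))
  expect_true(is.ordered(f))
  expect_error(coarse_grain_income(-5), ">= 0")
})

test_that("balanced mixture equals the empirical distribution in the identity case", {
  tab <- tiny_balanced_table()
  cfg <- cohort_config(n_resamples = 1, cell_size = 2, replace = FALSE,
                       seed = 9)
  tab$inc4 <- coarse_grain_income(tab$income)
  eff <- balanced_resample_mixture(tab, c("race", "sex"), "inc4", cfg)
  emp <- joint_dist_from_counts(
    data.frame(race = factor(tab$race), sex = factor(tab$sex),
               inc4 = tab$inc4))
  expect_equal(eff$dist$prob, emp$prob, tolerance = 1e-12)
  expect_equal(eff$predictor_marginal_flatness, 0, tolerance = 1e-12)
  # k identical replicates (full cells, no replacement) mix to the same thing
  cfg3 <- cohort_config(n_resamples = 3, cell_size = 2, replace = FALSE,
                        seed = 9)
  eff3 <- balanced_resample_mixture(tab, c("race", "sex"), "inc4", cfg3)
  expect_equal(eff3$dist$prob, emp$prob, tolerance = 1e-12)
})

test_that("balanced mixture is uniform over predictor cells and seed-reproducible", {
  pop <- generate_population(generator_config(n = 4000, seed = 2))
  pop$inc4 <- coarse_grain_income(pop$income)
  cfg <- cohort_config(n_resamples = 25, seed = 31)
  e1 <- balanced_resample_mixture(pop, c("race", "sex"), "inc4", cfg)
  e2 <- balanced_resample_mixture(pop, c("race", "sex"), "inc4", cfg)
  expect_identical(e1$dist$prob, e2$dist$prob) # bit-identical
  expect_lte(e1$predictor_marginal_flatness, 1e-9)
  cfg2 <- cfg; cfg2$seed <- 32L
  e3 <- balanced_resample_mixture(pop, c("race", "sex"), "inc4", cfg2)
  expect_false(identical(e1$dist$prob, e3$dist$prob))

  # an empty predictor cell is reported by name
  sub <- pop[!(pop$race == "Black" & pop$sex == "Female"), ]
  sub$race <- factor(sub$race, levels = c("White", "Black"))
  sub$sex <- factor(sub$sex, levels = c("Male", "Female"))
  expect_error(balanced_resample_mixture(sub, c("race", "sex"), "inc4", cfg),
               "Black:Female")
})

test_that("independent outcome yields vanishing effective information", {
  set.seed(77)
  n <- 8000
  df <- data.frame(
    race = sample(c("White", "Black"), n, TRUE, prob = c(0.8, 0.2)),
    sex = sample(c("Male", "Female"), n, TRUE),
    out = sample(letters[1:4], n, TRUE))
  eff <- balanced_resample_mixture(df, c("race", "sex"), "out",
                                   cohort_config(n_resamples = 40, seed = 5))
  expect_lt(mutual_information(eff$dist, c("race", "sex"), "out"), 0.005)
})

test_that("decade analysis runs the study triads and aggregates fractions", {
  pops <- lapply(1:3, function(y)
    generate_population(generator_config(n = 5000, seed = 100 + y),
                        year = 2010 + y))
  names(pops) <- 2011:2013
  cfg <- cohort_config(n_resamples = 20, seed = 8)
  res <- decade_analysis(pops, config = cfg)
  expect_s3_class(res, "decade_pid")
  expect_setequal(unique(res$atoms$triad),
                  c("race_sex_income", "race_income_health",
                    "race_sex_income_health"))
  expect_equal(nrow(res$wms), 9)
  expect_true(all(res$summary$sd_fraction >= 0))
  # single year: zero sd
  one <- decade_analysis(pops[1], config = cfg)
  expect_true(all(one$summary$sd_fraction == 0))
  # three-source triad cannot use the optimization-based method
  expect_error(
    decade_analysis(pops[1], triads = list(
      t3 = list(sources = list("race", "sex", "income"), target = "health")),
      config = cfg, method = "broja"),
    "exactly 2")
  # outputs round-trip to disk
  dir <- withr::local_tempdir()
  write_decade_results(res, dir, config = cfg)
  expect_true(file.exists(file.path(dir, "atoms.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  atoms <- utils::read.csv(file.path(dir, "atoms.csv"))
  expect_equal(nrow(atoms), nrow(res$atoms))
})
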