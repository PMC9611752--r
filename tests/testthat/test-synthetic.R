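test_that("generation is deterministic and satisfies record invariants", {
  cfg <- generator_config(n = 2000, seed = 123)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_true(all(p1$health %in% 1:5))
  expect_true(all(p1$income >= 0))
  expect_true(all(p1$age >= 25 & p1$age <= 65))
  # default tables pass the cohort filters unchanged
  expect_equal(nrow(apply_filters(p1, cohort_config())), nrow(p1))
  # a planted failing fraction is removed by the filters
  cfg_f <- generator_config(n = 2000, filter_fail_fraction = 0.2, seed = 5)
  pf <- generate_population(cfg_f)
  expect_lt(nrow(apply_filters(pf, cohort_config())), nrow(pf))
  expect_gt(nrow(apply_filters(pf, cohort_config())), 0.6 * nrow(pf))
})

test_that("config validation rejects degenerate settings", {
  expect_error(generator_config(n = 2), "at least 4")
  expect_error(generator_config(p_race = 0), "\\(0,1\\)")
  expect_error(generator_config(identity_coupling = 0.2, p_race = 0.1),
               "coupling")
  expect_error(generator_config(income_noise_sd = -1), ">= 0")
  expect_error(generate_population(
    generator_config(n = 5, p_race = 0.011, p_sex = 0.011,
                     identity_coupling = 0.01)), "degenerate")
})

test_that("all effects zero and zero noise give a constant, uninformative income", {
  cfg <- generator_config(n = 2000, main_effect_race = 0, main_effect_sex = 0,
                          shared_effect = 0, interaction_effect = 0,
                          parity_weight = 0, income_noise_sd = 0, seed = 2)
  pop <- generate_population(cfg)
  expect_equal(length(unique(pop$income)), 1)
  d <- joint_dist_from_counts(data.frame(
    race = pop$race, sex = pop$sex,
    income = coarse_grain_income(pop$income)))
  expect_warning(r <- pid_imin(d, list("race", "sex"), "income"), "constant")
  expect_true(all(r$atoms == 0))
})

test_that("the latent common cause couples the identities", {
  probs0 <- pidsect:::synthetic_cell_probs(
    generator_config(identity_coupling = 0))
  probs4 <- pidsect:::synthetic_cell_probs(
    generator_config(p_race = 0.5, p_sex = 0.5, identity_coupling = 0.4))
  expect_equal(sum(probs0), 1, tolerance = 1e-12)
  expect_equal(sum(probs4), 1, tolerance = 1e-12)
  expect_equal(probs0[["BW"]], 0.11 * 0.47, tolerance = 1e-12)
  expect_gt(probs4[["BW"]], 0.25) # positive association
  pop <- generate_population(
    generator_config(n = 20000, p_race = 0.5, p_sex = 0.5,
                     identity_coupling = 0.4, seed = 8))
  expect_gt(cor(pop$race == "Black", pop$sex == "Female"), 0.4)
})

test_that("planted ladder arithmetic is exact and weighting-sensitive", {
  cfg <- generator_config()
  pl <- planted_decomposition(cfg)
  expect_equal(pl$redundant_shift + pl$synergistic_shift,
               pl$conjunctive - pl$baseline, tolerance = 1e-12)
  # pure interaction: balanced synergistic shift is 2/3 of the cell shift
  cfg_i <- generator_config(p_race = 0.5, p_sex = 0.5,
                            main_effect_race = 0, main_effect_sex = 0,
                            shared_effect = 0, interaction_effect = -6000)
  pli <- planted_decomposition(cfg_i)
  expect_equal(pli$synergistic_shift, -4000, tolerance = 1e-12)
  ple <- planted_decomposition(cfg, weighting = "empirical")
  expect_false(isTRUE(all.equal(pl$baseline, ple$baseline)))
})

test_that("gate distributions are the exact uniform fixtures", {
  xor <- gate_distribution("xor")
  expect_equal(sum(xor$prob > 0), 4)
  expect_true(all(xor$prob[xor$prob > 0] == 0.25))
  rc <- gate_distribution("redundant_copy")
  expect_equal(sum(rc$prob > 0), 2)
  expect_true(all(rc$prob[rc$prob > 0] == 0.5))
  p3 <- gate_distribution("parity3")
  expect_equal(sum(p3$prob > 0), 8)
  expect_true(all(p3$prob[p3$prob > 0] == 0.125))
  expect_error(gate_distribution("nand"), "arg")
})

test_that("recovery report classifies well-separated regimes", {
  configs <- list(
    synergistic = generator_config(
      n = 12000, p_race = 0.5, p_sex = 0.5, identity_coupling = 0.02,
      main_effect_race = 0, main_effect_sex = 0, shared_effect = 0,
      interaction_effect = -12000, base_income = 50000,
      income_noise_sd = 4000, seed = 1),
    unique = generator_config(
      n = 12000, p_race = 0.5, p_sex = 0.5, identity_coupling = 0.02,
      main_effect_race = -12000, main_effect_sex = 0, shared_effect = 0,
      interaction_effect = 0, base_income = 50000,
      income_noise_sd = 4000, seed = 1))
  rep <- recovery_report(configs, n_seeds = 4,
                         cohort = cohort_config(n_resamples = 10))
  expect_equal(rep$dominant_mode,
               c("synergistic", "unique"))
  expect_true(all(rep$dominant_share == 1))
  expect_lt(abs(rep$recovered_interaction[1] - (-12000)),
            3 * rep$recovered_interaction_sd[1] + 1e-9)
})
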