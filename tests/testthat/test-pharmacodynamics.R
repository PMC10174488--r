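u87_model <- function() {
  cell_line_model("U87", cached_calibration("U87")$params,
                  builtin_drug_params("U87"))
}

test_that("Hill inhibition obeys its limiting identities", {
  expect_equal(transition_inhibition(0.11, 0, 0.1, 0.5), 0.11)
  expect_equal(transition_inhibition(0.11, 0.1, 0.1, 0.5), 0.055)
  expect_lt(transition_inhibition(0.11, 1e6, 0.1, 0.5), 1e-3)
  expect_gt(transition_inhibition(0.11, 1e6, 0.1, 0.5), 0)
  # strictly decreasing in dose
  doses <- 10^seq(-4, 2, length.out = 30)
  vals <- transition_inhibition(0.11, doses, 0.1, 0.5)
  expect_true(all(diff(vals) < 0))
})

test_that("death term is a saturating hyperbola with half-max at EC50_phi", {
  expect_equal(death_rate(0, 0.011, 0.4), 0)
  # PD0325901/U87 at its half-max death dose
  expect_equal(death_rate(0.40, 0.011, 0.40), 0.0055)
  expect_lt(death_rate(1e9, 0.011, 0.4), 0.011)
  doses <- 10^seq(-3, 2, length.out = 20)
  expect_true(all(diff(death_rate(doses, 0.011, 0.4)) > 0))
})

test_that("effective rates map each drug onto only its target state", {
  model <- u87_model()
  # empty assignment: base params, zero death
  eff <- effective_rates(model)
  expect_equal(unlist(eff$params), unlist(model$base))
  expect_equal(unlist(eff$death), c(phi1 = 0, phi2 = 0, phi3 = 0))

  # two-drug assignment decomposes into the single-drug calls
  doses <- c(PD0325901 = 0.3, Abemaciclib = 0.02)
  both <- effective_rates(model, doses)
  only_a <- effective_rates(model, doses["PD0325901"])
  only_b <- effective_rates(model, doses["Abemaciclib"])
  expect_equal(both$params$m1, only_a$params$m1)
  expect_equal(both$death$phi1, only_a$death$phi1)
  expect_equal(both$params$m2, only_b$params$m2)
  expect_equal(both$death$phi2, only_b$death$phi2)
  expect_equal(both$params$m3, model$base$m3)
  expect_equal(both$death$phi3, 0)

  # a drug at its transition EC50 (death negligible) halves the base rate
  weak_death <- cell_line_model("toy", transition_params(0.2, 0.2, 0.2),
                                list(drug_params("X", 2, ec50 = 0.5,
                                                 hill_n = 1, emax_phi = 1e-9,
                                                 ec50_phi = 1e3)))
  eff <- effective_rates(weak_death, c(X = 0.5))
  expect_equal(eff$params$m2, 0.1, tolerance = 1e-6)

  expect_error(effective_rates(model, c(Nonexistent = 1)), "not in model")
})

test_that("inconsistent user drug parameters are caught at rate assembly", {
  bad <- cell_line_model("toy", transition_params(0.5, 0.1, 0.1),
                         list(drug_params("harsh", 1, ec50 = 1e3,
                                          hill_n = 1, emax_phi = 0.9,
                                          ec50_phi = 1e-5)))
  expect_error(effective_rates(bad, c(harsh = 0.01)), "mi \\+ phii")
})

test_that("relative cell count is 1 without drug and scale invariant", {
  model <- u87_model()
  expect_identical(relative_cell_count(model), 1)
  expect_identical(relative_cell_count(model, c(PD0325901 = 0)), 1)
  # spot check one treated dose against the matrix-power oracle
  dose <- 0.1
  d <- model$drugs$PD0325901
  m <- unlist(model$base)
  m1_eff <- transition_inhibition(m[1], dose, d$ec50, d$hill_n)
  phi1 <- death_rate(dose, d$emax_phi, d$ec50_phi)
  x0 <- 100 * stationary_composition(model)
  A_treat <- oracle_matrix(c(m1_eff, m[2], m[3]), c(phi1, 0, 0))
  A_ctrl <- oracle_matrix(m)
  want <- sum(oracle_power_apply(A_treat, x0, 72)) /
    sum(oracle_power_apply(A_ctrl, x0, 72))
  expect_equal(relative_cell_count(model, c(PD0325901 = dose)), want,
               tolerance = 1e-12)
})

test_that("relative cell count decreases with dose and respects the arrest bound", {
  model <- u87_model()
  doses <- c(0, 10^seq(-3, 1, by = 1))
  curve <- predict_single_drug(model, "Abemaciclib", doses)
  expect_true(all(diff(curve) < 1e-12))
  expect_true(all(curve > 0))

  # pure arrest (no death): even a saturating dose cannot push the relative
  # count below the frozen-population bound 1 / control growth
  arrest_only <- cell_line_model("U87", model$base,
                                 list(drug_params("PD0325901", 1,
                                                  ec50 = 0.1, hill_n = 0.5,
                                                  emax_phi = 0)))
  ctrl_growth <- growth_eigensystem(model$base)$growth_factor^72
  lower_bound <- sum(100 * stationary_composition(model)) / 100 / ctrl_growth
  val <- relative_cell_count(arrest_only, c(PD0325901 = 1e6))
  expect_gte(val, lower_bound - 1e-9)
})
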