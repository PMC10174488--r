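test_that("hourly step handles frozen, dividing and mixed populations", {
  # zero rates: population frozen
  s <- step_population(population_state(10, 5, 5),
                       transition_params(0, 0, 0))
  expect_equal(s$x, c(10, 5, 5))
  expect_equal(s$t, 1L)

  # m3 = 1: every G2/M cell divides into two G0/G1 daughters
  s <- step_population(population_state(0, 0, 8),
                       transition_params(0, 0, 1))
  expect_equal(s$x, c(16, 0, 0))

  # generic step agrees with the explicit matrix-product oracle
  m <- c(0.0523, 0.1114, 0.1381)
  x0 <- c(60.2, 23.5, 16.3)
  s <- step_population(population_state(x0[1], x0[2], x0[3]),
                       transition_params(m[1], m[2], m[3]))
  expect_equal(s$x, drop(oracle_matrix(m) %*% x0), tolerance = 1e-14)
  # near-stationary input: one step preserves proportions closely
  expect_equal(s$x / sum(s$x), x0 / sum(x0), tolerance = 1e-2)
})

test_that("step rejects inconsistent rates and negative counts", {
  expect_error(transition_params(-0.1, 0, 0), "\\[0, 1\\]")
  expect_error(population_state(-1, 0, 0), "nonnegative")
  expect_error(step_population(population_state(1, 1, 1),
                               transition_params(0.6, 0, 0),
                               death_rates(0.5, 0, 0)),
               "retained fraction")
})

test_that("72-step simulation matches the independent matrix-power oracle", {
  m <- c(0.07, 0.15, 0.15)
  phi <- c(0.001, 0.002, 0.003)
  x0 <- c(58, 23, 19)
  traj <- simulate_population(transition_params(m[1], m[2], m[3]),
                              death_rates(phi[1], phi[2], phi[3]),
                              population_state(x0[1], x0[2], x0[3]),
                              horizon = 72)
  expect_equal(nrow(traj), 73L)
  want <- oracle_power_apply(oracle_matrix(m, phi), x0, 72)
  got <- unlist(traj[73, c("x_g0g1", "x_lateg1s", "x_g2m")], use.names = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
  # proportions sum to 1 at every step
  expect_equal(traj$p_g0g1 + traj$p_lateg1s + traj$p_g2m,
               rep(1, 73), tolerance = 1e-12)
})

test_that("simulation is linear in the initial condition", {
  p <- transition_params(0.05, 0.11, 0.14)
  t1 <- simulate_population(p, x0 = population_state(60, 24, 16), horizon = 40)
  t2 <- simulate_population(p, x0 = population_state(60 * 7.5, 24 * 7.5, 16 * 7.5),
                            horizon = 40)
  expect_equal(t2$total, 7.5 * t1$total, tolerance = 1e-12)
  expect_equal(t2$p_g0g1, t1$p_g0g1, tolerance = 1e-12)
})

test_that("total count is conserved when the division edge is blocked", {
  traj <- simulate_population(transition_params(0.3, 0.2, 0),
                              x0 = population_state(10, 20, 30), horizon = 50)
  expect_equal(traj$total, rep(60, 51), tolerance = 1e-12)
})

test_that("growing populations are monotone and converge to the eigenvector", {
  p <- transition_params(0.0523, 0.1114, 0.1381)
  traj <- simulate_population(p, x0 = population_state(90, 5, 5), horizon = 300)
  expect_true(all(diff(traj$total) >= -1e-12))
  eig <- growth_eigensystem(p)
  final_props <- unlist(traj[301, c("p_g0g1", "p_lateg1s", "p_g2m")],
                        use.names = FALSE)
  expect_equal(final_props, unname(eig$proportions), tolerance = 1e-8)
})

test_that("eigensystem gives the symmetric-cycle growth factor analytically", {
  # m = (1,1,1): a rigid 3-hour cycle with one division per traversal
  eig <- growth_eigensystem(transition_params(1, 1, 1))
  expect_equal(eig$growth_factor, 2^(1 / 3), tolerance = 1e-12)
  expect_equal(sum(eig$proportions), 1, tolerance = 1e-12)
})

test_that("blocked cycles report non-growing dynamics instead of failing", {
  eig <- growth_eigensystem(transition_params(0.1, 0, 0.1))
  expect_lte(eig$growth_factor, 1 + 1e-12)
  expect_identical(doubling_time(eig$growth_factor), Inf)
})

test_that("doubling time inverts the growth factor", {
  expect_equal(doubling_time(2), 1)
  expect_equal(doubling_time(2^(1 / 31.13)), 31.13, tolerance = 1e-12)
  expect_identical(doubling_time(0.99), Inf)
})

test_that("trajectory CSV export round-trips", {
  traj <- simulate_population(transition_params(0.05, 0.11, 0.14),
                              x0 = population_state(60, 24, 16), horizon = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read.csv(path)
  expect_equal(names(back), names(traj))
  expect_equal(back$total, traj$total, tolerance = 1e-12)
})
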