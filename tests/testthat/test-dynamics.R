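# Within-compartment replication dynamics (coupled logistic
# cross-replication with shared carrying capacity).

test_that("fixed points of the dynamics hold exactly", {
  K <- table1_matrix()
  dyn <- dynamics_config()

  empty <- replicate_compartment(c(H1 = 0, H2 = 0, P1 = 0), K, dyn, seed = 1)
  expect_identical(unname(empty$counts), c(0L, 0L, 0L))
  expect_identical(unname(empty$replicated), c(0L, 0L, 0L))

  # parasites cannot grow without host replicase
  par_only <- replicate_compartment(c(H1 = 0, H2 = 0, P1 = 50), K, dyn,
                                    seed = 1)
  expect_identical(unname(par_only$counts), c(0L, 0L, 50L))

  # a compartment exactly at carrying capacity does not change
  full <- replicate_compartment(c(H1 = 100, H2 = 0, P1 = 0), K, dyn, seed = 1)
  expect_identical(unname(full$counts), c(100L, 0L, 0L))
  expect_identical(sum(full$replicated), 0L)
})

test_that("species at zero stay at zero and states above capacity decay", {
  K <- table1_matrix()
  res <- integrate_compartment(c(H1 = 80, H2 = 0, P1 = 150), K)
  expect_identical(unname(res["H2"]), 0)
  expect_true(sum(res) < 230)           # decays toward capacity
  expect_true(all(res >= 0))
  expect_gte(sum(res), 100 - 1e-4)      # never undershoots the capacity
})

test_that("adaptive solver matches the fixed-step RK4 oracle", {
  # single-host growth example
  K1 <- coefficients_from_slots(c(k11H = 2.0))
  got <- integrate_compartment(c(H1 = 10), K1)
  want <- oracle_rk4(c(H1 = 10), unclass(K1), species_roles(K1))
  expect_lt(abs(got - want) / want, 1e-4)
  # and the discretized value agrees within rounding
  det <- replicate_compartment(c(H1 = 10), K1,
                               dynamics_config(rounding = "nearest"))
  expect_identical(unname(det$counts), as.integer(round(want)))

  # randomized three-species states with totals up to 2N
  set.seed(42)
  K <- table1_matrix()
  for (i in 1:3) {
    x <- setNames(random_compartment_state(), colnames(K))
    got <- integrate_compartment(x, K)
    want <- oracle_rk4(x, unclass(K), species_roles(K))
    keep <- want > 1e-8
    expect_lt(max(abs(got[keep] - want[keep]) / want[keep]), 1e-4)
  }
})

test_that("single-host growth saturates monotonically below capacity", {
  K <- coefficients_from_slots(c(k11H = 2.3))
  horizons <- c(0.02, 0.05, 0.1, 0.3, 1, 3)
  vals <- vapply(horizons, function(T)
    integrate_compartment(c(H1 = 5), K, dynamics_config(horizon = T)), 0)
  # non-decreasing within solver tolerance (values are O(100), rel_tol 1e-6)
  expect_true(all(diff(vals) >= -1e-3))
  expect_true(all(vals <= 100 + 1e-3))
})

test_that("final composition is insensitive to the horizon past saturation", {
  # growth saturates at capacity, so doubling the horizon changes nothing
  # measurable for the coefficient magnitudes of the study designs
  set.seed(7)
  K <- table1_matrix()
  for (i in 1:3) {
    x <- setNames(random_compartment_state(max_total = 120), colnames(K))
    a <- integrate_compartment(x, K, dynamics_config(horizon = 1))
    b <- integrate_compartment(x, K, dynamics_config(horizon = 10))
    expect_lt(max(abs(a - b)), 1e-3)
  }
})

test_that("stochastic rounding is unbiased in expectation", {
  target <- 10.37
  draws <- vapply(1:10000, function(s)
    replinet:::cpp_discretize(target, 0L, s)[1], 0L)
  se <- sqrt(0.37 * 0.63 / 10000)
  expect_lt(abs(mean(draws) - target), 3 * se)
  expect_true(all(draws %in% c(10L, 11L)))
  # deterministic mode rounds to nearest
  expect_identical(replinet:::cpp_discretize(10.37, 1L, 1)[1], 10L)
  expect_identical(replinet:::cpp_discretize(10.63, 1L, 1)[1], 11L)
})

test_that("unknown species and bad counts are configuration errors", {
  K <- coefficients_from_slots(c(k11H = 2.0))
  expect_error(replicate_compartment(c(X9 = 5), K), "not covered")
  expect_error(replicate_compartment(c(H1 = -3), K), ">= 0")
  expect_error(dynamics_config(carrying_capacity = 0), "carrying_capacity")
  expect_error(dynamics_config(horizon = -1), "horizon")
})

test_that("coefficient matrices validate their invariants", {
  expect_error(coefficient_matrix(matrix(-1, 1, 1), c(H1 = "host")), ">= 0")
  # parasites never act as replicase
  bad <- rbind(c(2, 5), c(1, 0))
  expect_error(coefficient_matrix(bad, c(H1 = "host", P1 = "parasite")),
               "replicase")
  K <- table1_matrix()
  expect_identical(unname(species_roles(K)),
                   c("host", "host", "parasite"))
  expect_identical(K["H1", "P1"], 6.7)  # host 1 replicates the parasite
  expect_identical(K["H2", "P1"], 0.0)  # host 2 is fully resistant
})

test_that("coefficient CSV round-trips", {
  K <- table1_matrix()
  f <- withr::local_tempfile(fileext = ".csv")
  write_coefficient_csv(K, f)
  K2 <- read_coefficient_csv(f)
  expect_equal(unclass(K2), unclass(K))
  expect_identical(species_roles(K2), species_roles(K))
})
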