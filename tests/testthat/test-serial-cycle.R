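# Serial replication cycle: culling, fusion-division, rounds, sustained-run
# criterion.

test_that("culling keeps exactly floor(C * S) compartments", {
  cfg <- cycle_config()  # C = 3000, S = 0.25
  pop <- matrix(1L, nrow = 3000, ncol = 1, dimnames = list(NULL, "H1"))
  culled <- cull(pop, cfg, seed = 3)
  expect_identical(nrow(culled), 3000L)           # compartment count fixed
  expect_identical(sum(rowSums(culled) > 0), 750L)

  # S = 1 keeps everything, S = 0 empties everything
  expect_identical(cull(pop, cycle_config(cull_rate = 1), seed = 1), pop)
  expect_identical(sum(cull(pop, cycle_config(cull_rate = 0), seed = 1)), 0L)
})

test_that("culling retains a fraction S of each species' total on average", {
  C <- 200
  cfg <- cycle_config(compartments = C, cull_rate = 0.25)
  set.seed(11)
  pop <- matrix(as.integer(rpois(2 * C, c(3, 7))), nrow = C, byrow = TRUE,
                dimnames = list(NULL, c("H1", "H2")))
  fracs <- vapply(1:1000, function(s) {
    colSums(cull(pop, cfg, seed = s)) / colSums(pop)
  }, c(0, 0))
  # retained compartments are a uniform subset, so the expected retained
  # fraction of each species' total is S; allow ~5 SEs for the unequal
  # per-compartment weights
  se <- sqrt(0.25 * 0.75 / C) / sqrt(1000)
  expect_lt(max(abs(rowMeans(fracs) - 0.25)), 5 * se)
})

test_that("fusion-division conserves global totals exactly", {
  set.seed(5)
  for (i in 1:50) {
    pop <- matrix(as.integer(rpois(40 * 3, 20)), nrow = 40,
                  dimnames = list(NULL, c("H1", "H2", "P1")))
    out <- fuse_divide(pop, times = 100, seed = i)
    expect_identical(colSums(out), colSums(pop))
    expect_identical(nrow(out), nrow(pop))
  }
  # two empty compartments stay empty
  empty <- matrix(0L, 2, 1, dimnames = list(NULL, "H1"))
  expect_identical(fuse_divide_once(empty, seed = 1), empty)
  expect_error(fuse_divide_once(empty[1, , drop = FALSE]), "two compartments")
})

test_that("fusion-division splits a pooled count as Binomial(n, 1/2)", {
  pop <- matrix(c(100L, 0L), nrow = 2, dimnames = list(NULL, "H1"))
  daughters <- vapply(1:10000, function(s)
    fuse_divide_once(pop, seed = s)[1, 1], 0L)
  expect_lt(abs(mean(daughters) - 50), 3 * 5 / sqrt(10000))
  expect_lt(abs(var(daughters) - 25), 2)
})

test_that("a round with A = 0 and S = 1 reduces to pure replication", {
  K <- coefficients_from_slots(c(k11H = 2.0))
  cfg <- cycle_config(compartments = 100, cull_rate = 1, fusion_divisions = 0)
  pop <- init_population(K, cfg)        # all compartments at capacity
  out <- run_round(pop, K, cfg, seed = 2)
  expect_identical(out$pop, pop)        # capacity is a fixed point
  expect_identical(sum(out$replicated), 0L)

  half <- pop
  half[, 1] <- 50L
  out2 <- run_round(half, K, cfg, seed = 2)
  expect_true(all(out2$pop[, 1] >= 99L))   # saturates within one round
  expect_identical(out2$replicated, out2$pop - half)
})

test_that("an empty population is absorbing", {
  K <- coefficients_from_slots(c(k11H = 2.6, k11P = 7.0))
  cfg <- small_cycle()
  pop <- matrix(0L, cfg$compartments, 2, dimnames = list(NULL, colnames(K)))
  out <- run_round(pop, K, cfg, seed = 9)
  expect_identical(sum(out$pop), 0L)
})

test_that("a strong single host ends round 1 above the compartment count", {
  K <- coefficients_from_slots(c(k11H = 2.6))
  cfg <- cycle_config()
  pop <- init_population(K, cfg)
  hits <- vapply(1:10, function(s) {
    out <- run_round(pop, K, cfg, seed = s)
    sum(out$pop) > cfg$compartments
  }, NA)
  expect_gte(sum(hits), 9)
})

test_that("the sustained criterion is strict in the compartment count", {
  cfg <- cycle_config()  # C = 3000
  expect_false(is_sustained(c(H1 = 0), cfg)[["H1"]])
  expect_false(is_sustained(c(H1 = 3000), cfg)[["H1"]])
  expect_true(is_sustained(c(H1 = 3001), cfg)[["H1"]])
})

test_that("initial fill gives equal shares up to the carrying capacity", {
  K2 <- coefficients_from_slots(c(k11H = 2, k11P = 7))
  pop2 <- init_population(K2, cycle_config(compartments = 10))
  expect_true(all(pop2 == 50L))
  K3 <- table1_matrix()
  pop3 <- init_population(K3, cycle_config(compartments = 10))
  expect_true(all(pop3 == 33L))
  expect_true(all(rowSums(pop3) <= 100))
})

test_that("runs are reproducible seed-for-seed", {
  K <- coefficients_from_slots(c(k11H = 2.3, k11P = 7.0))
  cfg <- small_cycle(rounds = 15)
  a <- run_simulation(K, cfg, seed = 77)
  b <- run_simulation(K, cfg, seed = 77)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_pop, b$final_pop)
  c <- run_simulation(K, cfg, seed = 78)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("a non-replicating founder is diluted to extinction", {
  K <- coefficients_from_slots(c(k11H = 0))
  out <- run_simulation(K, small_cycle(rounds = 20), seed = 4)
  expect_identical(out$trajectory[20, "H1"][[1]], 0L)
  expect_false(out$sustained_all)
})

test_that("trajectories export tidily", {
  K <- coefficients_from_slots(c(k11H = 2.3, k11P = 7.0))
  out <- run_simulation(K, small_cycle(rounds = 5), seed = 10)
  df <- trajectory_df(out)
  expect_identical(nrow(df), 10L)
  expect_identical(unique(df$role), c("host", "parasite"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(out, f)
  expect_identical(nrow(utils::read.csv(f)), 10L)
})
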