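# Sustainability sweeps over replication-coefficient grids.

test_that("built-in grids have the documented shapes and fixed values", {
  hh <- build_grid(topology_spec("hh"))
  expect_identical(nrow(hh), 256L)               # 4^4 combinations
  expect_true(all(sort(unique(hh$k11H)) == c(1.7, 2.0, 2.3, 2.6)))
  # the diagonal where hosts 1 and 2 are identical is flagged, not dropped
  expect_identical(sum(hh$identical_hosts), 16L)

  hp <- build_grid(topology_spec("hp"))
  expect_identical(nrow(hp), 54L)                # 6 host x 9 parasite values
  expect_true(all(c(0.2, 4.1) %in% hp$k11H))
  expect_true(all(c(7, 10, 20) %in% hp$k11P))

  asym <- build_grid(topology_spec("hhp_asym"))
  expect_identical(nrow(asym), 256L)
  K <- asym$K[[1]]
  expect_identical(K["H1", "P1"], 7.0)
  expect_identical(K["H2", "P1"], 0.1)
  sym <- build_grid(topology_spec("hhp_sym"))$K[[1]]
  expect_identical(sym["H2", "P1"], 7.0)

  h3 <- build_grid(topology_spec("hhh_condI"))
  expect_identical(nrow(h3), 512L)               # 2 x 4^4
  K3 <- h3$K[[1]]
  expect_identical(K3["H1", "H1"], 1.7)
  expect_identical(K3["H2", "H1"], 2.6)
  expect_identical(K3["H1", "H2"], 2.0)
  expect_identical(K3["H2", "H2"], 1.7)
  K3b <- build_grid(topology_spec("hhh_condII"))$K[[1]]
  expect_identical(K3b["H1", "H1"], 2.0)
  expect_identical(K3b["H2", "H1"], 1.7)

  # an intermediate asymmetry is expressible through overrides
  mid <- topology_spec("hhp_asym", fixed = list(k21P = 1.0))
  expect_identical(mid$fixed$k21P, 1.0)
})

test_that("the sustainable-HHP condition checks its three inequalities", {
  expect_true(check_hhp_condition(table1_matrix()))
  # symmetric parasite replication fails the strict first inequality
  sym <- coefficients_from_slots(c(k11H = 2.3, k21H = 2.3, k12H = 2.3,
                                   k22H = 2.0, k11P = 7.0, k21P = 7.0))
  expect_false(check_hhp_condition(sym))
  # vectorized over data-frame rows
  df <- data.frame(k11H = c(2.3, 2.0), k21H = c(2.3, 1.7),
                   k12H = c(2.3, 2.0), k22H = c(2.0, 1.8),
                   k11P = c(6.7, 5.0), k21P = c(0.0, 1.0))
  expect_identical(check_hhp_condition(df), c(TRUE, FALSE))
  # wrong topology is an error
  expect_error(check_hhp_condition(coefficients_from_slots(c(k11H = 2))),
               "HHP")
})

test_that("sweep tallies sum to the run count and reproduce per seed", {
  spec <- topology_spec("hp", grid_values = list(k11H = 2.3, k11P = 7.0))
  res <- run_sweep(spec, small_cycle(rounds = 5), seed = 3, n_runs = 6)
  expect_identical(sum(res$n), 6L)
  res2 <- run_sweep(spec, small_cycle(rounds = 5), seed = 3, n_runs = 6)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("a non-replicating cell is never sustained", {
  spec <- topology_spec("h", grid_values = list(k11H = 0))
  res <- run_sweep(spec, small_cycle(rounds = 10), seed = 2, n_runs = 5)
  counts <- sustained_counts(res)
  expect_identical(counts$n_sustained, 0L)
})

test_that("independent hosts exclude each other under competition", {
  # no cross-replication: two hosts only compete for compartment capacity
  spec <- topology_spec("hh", grid_values = list(
    k11H = 2.0, k22H = 2.0, k12H = 0, k21H = 0))
  res <- run_sweep(spec, cycle_config(), seed = 8, n_runs = 10)
  expect_identical(sustained_counts(res)$n_sustained, 0L)
})

test_that("cells passing the HHP condition outlast failing cells", {
  # matched asymmetric-HHP cells: passing cells must show a higher mean
  # sustained count than failing cells
  grid <- build_grid(topology_spec("hhp_asym"))
  pass <- vapply(grid$K, check_hhp_condition, NA)
  set.seed(31)
  pick_pass <- sample(grid$cell[pass], 3)
  pick_fail <- sample(grid$cell[!pass], 3)
  res <- run_sweep(topology_spec("hhp_asym"), cycle_config(), seed = 5,
                   cells = c(pick_pass, pick_fail), n_runs = 10)
  counts <- sustained_counts(res)
  mean_pass <- mean(counts$n_sustained[counts$cell %in% pick_pass])
  mean_fail <- mean(counts$n_sustained[counts$cell %in% pick_fail])
  expect_gt(mean_pass, mean_fail)
})

test_that("more compartments do not hurt host-parasite sustainability", {
  # raising the compartment number (with the fusion-division frequency
  # scaled proportionally) gives hosts more chances to escape parasites;
  # sustained counts on sampled host-parasite cells must not decrease
  cells_kp <- c(4.1, 7.0, 10.0)
  count_sustained <- function(C, seedbase) {
    cfg <- cycle_config(compartments = C,
                        fusion_divisions = scale_fusion_divisions(C))
    tot <- 0L
    for (i in seq_along(cells_kp)) {
      K <- coefficients_from_slots(c(k11H = 2.3, k11P = cells_kp[i]))
      for (r in 1:10)
        tot <- tot + run_simulation(K, cfg,
                                    seed = derive_seed(seedbase, i, r))$sustained_all
    }
    tot
  }
  expect_gte(count_sustained(10000, 56), count_sustained(3000, 55))
})

test_that("sweep results export as tidy CSV", {
  spec <- topology_spec("hp", grid_values = list(k11H = 2.3, k11P = 7.0))
  res <- run_sweep(spec, small_cycle(rounds = 3), seed = 1, n_runs = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(res, f)
  back <- utils::read.csv(f)
  expect_identical(sum(back$n), 3L)
  expect_true(all(c("state", "n") %in% names(back)))
})
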