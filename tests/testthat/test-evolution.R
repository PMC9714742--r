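# Evolutionary-transition simulator: appearance step, classification,
# maintained networks, predecessors.

test_that("the mutation step respects the species cap and needs replication", {
  cfg <- evolution_config()
  K <- table1_matrix()
  pop <- matrix(10L, 4, 3, dimnames = list(NULL, colnames(K)))
  repl <- matrix(50L, 4, 3)
  # three species present: no appearance, by the cap
  out <- mutation_step(pop, species_roles(K), K, repl, cfg, seed = 1)
  expect_identical(out$pop, pop)
  expect_identical(nrow(out$events), 0L)
  # zero replication counts: appearance probability is zero
  K1 <- coefficients_from_slots(c(k11H = 2))
  pop1 <- matrix(10L, 4, 1, dimnames = list(NULL, "H1"))
  out1 <- mutation_step(pop1, species_roles(K1), K1,
                        matrix(0L, 4, 1), cfg, seed = 2)
  expect_identical(out1$pop, pop1)
})

test_that("appearance fires at rate replications x per-replication rate", {
  K <- coefficients_from_slots(c(k11H = 2))
  roles <- species_roles(K)
  pop <- matrix(10L, 5, 1, dimnames = list(NULL, "H1"))
  repl <- matrix(0L, 5, 1)
  repl[1, 1] <- 10L  # p = min(1, 10 * 0.02) = 0.2 for a new host
  cfg <- evolution_config(parasite_from_host_rate = 0)
  fired <- vapply(1:10000, function(s) {
    nrow(mutation_step(pop, roles, K, repl, cfg, seed = s)$events) > 0
  }, NA)
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(mean(fired) - 0.2), 3 * se)
})

test_that("a new species enters with one copy in one firing compartment", {
  K <- coefficients_from_slots(c(k11H = 2))
  roles <- species_roles(K)
  pop <- matrix(10L, 20, 1, dimnames = list(NULL, "H1"))
  repl <- matrix(100L, 20, 1)  # p = 1 in every compartment
  cfg <- evolution_config(parasite_from_host_rate = 0)
  out <- mutation_step(pop, roles, K, repl, cfg, seed = 6)
  expect_identical(nrow(out$events), 1L)
  expect_identical(out$events$n_seeded, 1L)
  expect_identical(sum(out$pop) - sum(pop), 1L)
  # drawn coefficients lie in the configured ranges
  newid <- out$events$species_id
  expect_true(all(out$K[, newid] >= 1 & out$K[, newid] <= 3))

  # the alternative policy seeds every firing compartment
  cfg2 <- evolution_config(parasite_from_host_rate = 0,
                           seeding = "all_firing")
  out2 <- mutation_step(pop, roles, K, repl, cfg2, seed = 6)
  expect_identical(out2$events$n_seeded, 20L)
  expect_identical(sum(out2$pop) - sum(pop), 20L)
})

test_that("new parasites draw coefficients from the parasite range", {
  K <- coefficients_from_slots(c(k11H = 2))
  pop <- matrix(10L, 10, 1, dimnames = list(NULL, "H1"))
  repl <- matrix(1000L, 10, 1)
  cfg <- evolution_config(host_from_host_rate = 0)  # only parasites arise
  out <- mutation_step(pop, species_roles(K), K, repl, cfg, seed = 3)
  expect_identical(out$events$role, "parasite")
  newid <- out$events$species_id
  expect_true(out$K["H1", newid] >= 0 && out$K["H1", newid] <= 10)
  expect_identical(unname(out$K[newid, "H1"]), 0)  # never a replicase
})

test_that("network classification uses a strict 1000-copy threshold", {
  roles <- c(H1 = "host", P1 = "parasite")
  expect_identical(
    classify_network(c(H1 = 150000, P1 = 8000), roles)$label, "HP")
  expect_identical(
    classify_network(c(H1 = 1000, P1 = 900), roles)$label, "none")
  expect_identical(
    classify_network(c(H1 = 1001, P1 = 1000), roles)$label, "H")
})

test_that("with zero appearance rates the composition stays a single host", {
  cfg <- evolution_config(host_from_host_rate = 0,
                          parasite_from_host_rate = 0,
                          parasite_from_parasite_rate = 0, rounds = 30)
  log <- run_evolution(cfg, small_cycle(), seed = 5)
  expect_identical(nrow(log$species), 1L)
  expect_identical(log$species$role, "host")
})

test_that("concurrent species never exceed the cap", {
  cfg <- evolution_config(rounds = 120)
  log <- run_evolution(cfg, small_cycle(), seed = 21)
  per_round <- table(log$totals$round)
  expect_lte(max(per_round), 3L)
  expect_gt(nrow(log$species), 1L)  # appearances did happen
})

test_that("evolutionary runs are reproducible seed-for-seed", {
  cfg <- evolution_config(rounds = 60)
  a <- run_evolution(cfg, small_cycle(), seed = 13)
  b <- run_evolution(cfg, small_cycle(), seed = 13)
  expect_identical(a$totals, b$totals)
  expect_identical(a$coeffs, b$coeffs)
})

test_that("maintained networks and predecessors follow the timeline", {
  # hand-built log: H (1-150) -> HP (151-400) -> HHP (401-700)
  totals <- rbind(
    data.frame(round = 1:400, species_id = 1L, total = 50000L),
    data.frame(round = 151:700, species_id = 2L, total = 8000L),
    data.frame(round = 401:700, species_id = 3L, total = 5000L),
    data.frame(round = 401:700, species_id = 1L, total = 40000L))
  log <- structure(list(
    totals = totals[order(totals$round), ],
    species = data.frame(species_id = 1:3,
                         role = c("host", "parasite", "host"),
                         birth_round = c(0L, 150L, 400L)),
    coeffs = data.frame(replicase_id = c(1, 1, 3, 3, 1, 3),
                        template_id = c(1, 2, 3, 1, 3, 2),
                        k = c(2.0, 7.0, 1.5, 2.5, 1.9, 0.05)),
    extinct_round = NA_integer_, rounds = 1000L,
    config = evolution_config()), class = "evolution_log")
  m <- maintained_networks(log)
  expect_identical(m$label, c("H", "HP", "HHP"))
  expect_identical(m$length, c(150L, 250L, 300L))
  expect_identical(m$predecessor, c("none", "H", "HP"))
  expect_identical(m$predecessor_maintained, c("none", "H", "HP"))

  # trio coefficients are assembled with the elder host as host 1
  sets <- replinet:::hhp_slot_coefficients(log, m$ids[3])
  expect_identical(sets$k11H, 2.0)   # founder self-replication
  expect_identical(sets$k22H, 1.5)   # younger host self-replication
  expect_identical(sets$k11P, 7.0)
  expect_identical(sets$k21P, 0.05)
})

test_that("intervals at or below the maintenance window do not count", {
  totals <- data.frame(round = 1:100, species_id = 1L, total = 5000L)
  log <- structure(list(
    totals = totals,
    species = data.frame(species_id = 1L, role = "host", birth_round = 0L),
    coeffs = data.frame(replicase_id = 1, template_id = 1, k = 2),
    extinct_round = 100L, rounds = 1000L,
    config = evolution_config()), class = "evolution_log")
  expect_identical(nrow(maintained_networks(log)), 0L)  # 100 is not > 100
})

test_that("predecessor analysis aggregates over a batch", {
  cfg <- evolution_config(rounds = 40)
  b <- run_evolution_batch(3, cfg, small_cycle(), seed = 2)
  expect_identical(nrow(b$runs), 3L)
  expect_true(all(c("extinct", "extinct_round") %in% names(b$runs)))
  p <- predecessor_analysis(b)
  expect_true(is.data.frame(p))
})
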