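#' Serial replication cycle settings
#'
#' Fixed machinery of one run: `C` compartments go through rounds of
#' replication, culling (a random `floor(C * cull_rate)` compartments keep
#' their contents, the rest are replaced by empty ones), and `A` binomial
#' fusion-division events. Defaults are the study conditions: 3000
#' compartments, culling rate 0.25, 5000 fusion-divisions per round,
#' carrying capacity 100, 100 rounds.
#'
#' @param compartments `C`, number of compartments (constant throughout).
#' @param cull_rate `S` in `[0, 1]`; `floor(C * S)` compartments survive.
#' @param fusion_divisions `A`, fusion-division events per round.
#' @param rounds number of serial-cycle rounds.
#' @param dynamics a [dynamics_config()].
#' @param seed optional integer master seed for the run.
#' @return A list of class `cycle_config`.
#' @export
cycle_config <- function(compartments = 3000, cull_rate = 0.25,
                         fusion_divisions = 5000, rounds = 100,
                         dynamics = dynamics_config(), seed = NULL) {
  problems <- c(
    if (compartments < 1) "compartments must be >= 1",
    if (cull_rate < 0 || cull_rate > 1) "cull_rate must be in [0, 1]",
    if (fusion_divisions < 0) "fusion_divisions must be >= 0",
    if (rounds < 1) "rounds must be >= 1",
    if (!inherits(dynamics, "dynamics_config"))
      "dynamics must be a dynamics_config()")
  stop_fields(problems)
  structure(list(compartments = as.integer(compartments),
                 cull_rate = cull_rate,
                 fusion_divisions = as.integer(fusion_divisions),
                 rounds = as.integer(rounds), dynamics = dynamics,
                 seed = if (!is.null(seed)) draw_seed(seed)),
            class = "cycle_config")
}

n_culled_survivors <- function(cfg) {
  as.integer(floor(cfg$compartments * cfg$cull_rate))
}

#' Initial population for a run
#'
#' Every compartment receives equal shares of all founding species summing
#' to at most the carrying capacity: with `n` founders each gets
#' `floor(N / n)` copies.
#'
#' @param K a [coefficient_matrix()].
#' @param cfg a [cycle_config()].
#' @param founders ids of the founding species (default: all species of `K`).
#' @return Integer matrix `C x n_species` (compartments in rows), with one
#'   column per species of `K`.
#' @export
init_population <- function(K, cfg = cycle_config(),
                            founders = colnames(K)) {
  ids <- colnames(K)
  stopifnot(length(founders) >= 1, all(founders %in% ids))
  per <- floor(cfg$dynamics$carrying_capacity / length(founders))
  pop <- matrix(0L, nrow = cfg$compartments, ncol = length(ids),
                dimnames = list(NULL, ids))
  pop[, founders] <- as.integer(per)
  pop
}

check_population <- function(pop, K = NULL) {
  if (!is.matrix(pop) || !is.numeric(pop))
    stop("`pop` must be an integer matrix (compartments x species)",
         call. = FALSE)
  if (any(pop < 0)) stop("copy numbers must be >= 0", call. = FALSE)
  if (!is.null(K) && !identical(colnames(pop), colnames(K)))
    stop("population species do not match the coefficient matrix",
         call. = FALSE)
  storage.mode(pop) <- "integer"
  pop
}

#' Culling step
#'
#' `floor(C * S)` compartments, chosen uniformly without replacement, keep
#' their contents; all others are replaced by empty compartments. The total
#' number of compartments never changes.
#'
#' @param pop integer population matrix (compartments x species).
#' @param cfg a [cycle_config()].
#' @param seed optional integer seed.
#' @return The culled population matrix.
#' @export
cull <- function(pop, cfg = cycle_config(), seed = NULL) {
  pop <- check_population(pop)
  cpp_cull(pop, n_culled_survivors(cfg), draw_seed(seed))
}

#' Fusion-division step
#'
#' One event picks two distinct compartments uniformly at random, pools
#' their contents, and redistributes each species' copies between the two
#' daughters by a Binomial(n, 1/2) draw. Global totals of every species are
#' conserved exactly. `fuse_divide()` repeats the event `times` times with
#' independently drawn pairs.
#'
#' @param pop integer population matrix (compartments x species).
#' @param times number of fusion-division events.
#' @param seed optional integer seed.
#' @return The population matrix after the events.
#' @export
fuse_divide <- function(pop, times = 1, seed = NULL) {
  pop <- check_population(pop)
  if (nrow(pop) < 2)
    stop("fusion-division requires at least two compartments", call. = FALSE)
  cpp_fuse_divide(pop, as.integer(times), draw_seed(seed))
}

#' @rdname fuse_divide
#' @export
fuse_divide_once <- function(pop, seed = NULL) fuse_divide(pop, 1L, seed)

#' One full round of the serial cycle
#'
#' Applies replication to every compartment, then culling, then
#' `fusion_divisions` fusion-division events. Replication tallies are
#' recorded per compartment before culling (culling destroys compartments,
#' not the replication history that drives the mutation step).
#'
#' @param pop integer population matrix (compartments x species).
#' @param K a [coefficient_matrix()] with one column per population species.
#' @param cfg a [cycle_config()].
#' @param seed optional integer seed; sub-steps use seeds derived from it.
#' @return A list with `pop` (population after the round) and `replicated`
#'   (integer matrix of per-compartment replication counts).
#' @export
run_round <- function(pop, K, cfg = cycle_config(), seed = NULL) {
  require_complete(K)
  pop <- check_population(pop, K)
  seed <- draw_seed(seed)
  dyn <- cfg$dynamics
  rep_res <- cpp_replicate_population(pop, unclass_coeff(K), is_host(K),
                                      dyn$carrying_capacity, dyn$horizon,
                                      dyn$rel_tol, dyn$abs_tol,
                                      rounding_code(dyn),
                                      derive_seed(seed, 1))
  out <- cpp_cull(rep_res$pop, n_culled_survivors(cfg), derive_seed(seed, 2))
  if (cfg$fusion_divisions > 0)
    out <- cpp_fuse_divide(out, cfg$fusion_divisions, derive_seed(seed, 3))
  list(pop = out, replicated = rep_res$replicated)
}

#' Sustained-species criterion
#'
#' A species counts as sustained when its global total across all
#' compartments strictly exceeds the number of compartments `C` in the
#' final round.
#'
#' @param pop final-round population matrix, or a named vector of global
#'   totals.
#' @param cfg a [cycle_config()].
#' @param species optional subset of species ids.
#' @return Named logical vector.
#' @export
is_sustained <- function(pop, cfg = cycle_config(), species = NULL) {
  totals <- if (is.matrix(pop)) colSums(pop) else pop
  if (!is.null(species)) totals <- totals[species]
  totals > cfg$compartments
}

#' Run a full serial-cycle simulation
#'
#' Executes `cfg$rounds` rounds of replication, culling and fusion-division
#' from an equal-share initial fill and records per-species global totals
#' every round. The whole run consumes a single seeded random stream, so an
#' identical seed and configuration reproduce the outcome exactly.
#'
#' @param K a [coefficient_matrix()].
#' @param cfg a [cycle_config()]; `cfg$seed` seeds the run unless `seed` is
#'   given.
#' @param founders founding species ids (default: all species of `K`).
#' @param seed optional integer seed overriding `cfg$seed`.
#' @return An object of class `run_outcome`: list with `trajectory`
#'   (integer matrix rounds x species of global totals), `survivors`
#'   (named logical, sustained flag per founder), `sustained_all`,
#'   `final_pop`, `seed` and `config`.
#' @export
run_simulation <- function(K, cfg = cycle_config(), founders = colnames(K),
                           seed = NULL) {
  require_complete(K)
  seed <- draw_seed(seed %||% cfg$seed)
  pop <- init_population(K, cfg, founders)
  dyn <- cfg$dynamics
  res <- cpp_run_simulation(pop, unclass_coeff(K), is_host(K), cfg$cull_rate,
                            cfg$fusion_divisions, cfg$rounds,
                            dyn$carrying_capacity, dyn$horizon, dyn$rel_tol,
                            dyn$abs_tol, rounding_code(dyn), seed)
  traj <- res$trajectory
  colnames(traj) <- colnames(K)
  survivors <- is_sustained(res$pop, cfg)[founders]
  structure(list(trajectory = traj, survivors = survivors,
                 sustained_all = all(survivors), final_pop = res$pop,
                 seed = seed, config = cfg, roles = species_roles(K)),
            class = "run_outcome")
}

#' @export
print.run_outcome <- function(x, ...) {
  cat("Serial-cycle run:", nrow(x$trajectory), "rounds,",
      x$config$compartments, "compartments\n")
  cat("final totals:\n")
  print(x$trajectory[nrow(x$trajectory), ])
  cat(if (x$sustained_all) "all founders sustained\n" else
    "not all founders sustained\n")
  invisible(x)
}

#' Tidy per-round trajectory of a run
#'
#' @param outcome a `run_outcome` from [run_simulation()].
#' @return A tibble with columns `round`, `species_id`, `role`,
#'   `global_total`.
#' @export
trajectory_df <- function(outcome) {
  traj <- outcome$trajectory
  tibble::tibble(
    round = rep(seq_len(nrow(traj)), times = ncol(traj)),
    species_id = rep(colnames(traj), each = nrow(traj)),
    role = rep(unname(outcome$roles[colnames(traj)]), each = nrow(traj)),
    global_total = as.integer(traj))
}
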