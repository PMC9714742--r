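# Evolutionary-transition simulator: stochastic appearance of new hosts and
# parasites on top of the serial cycle, plus classification of the network
# timeline and maintained-network / predecessor statistics.

#' Evolutionary simulation settings
#'
#' New species appear immediately before the replication step, driven by the
#' previous round's replication tallies: for each (species, compartment) the
#' appearance probability is `min(1, replications * rate)`. A host parent
#' can spawn a new host (rate 0.02 per replication, from the replicase error
#' rate over a ~2000-nt host RNA; see [mutations_per_replication()]) or a
#' new parasite (0.001); a parasite parent spawns new parasites at 0.002.
#' All firings of one class in a round seed copies of the same new species,
#' whose replication coefficients are drawn uniformly: host coefficients
#' from `[1, 3]`, parasite coefficients from `[0, 10]`. The mutation step is
#' skipped entirely while the concurrent species count is at the cap
#' (default 3).
#'
#' @param host_from_host_rate,parasite_from_host_rate,parasite_from_parasite_rate
#'   appearance rates per replication event.
#' @param host_coeff_range,parasite_coeff_range ranges for newly drawn
#'   coefficients.
#' @param species_cap maximum number of concurrent species.
#' @param classification_threshold copies above which a species counts
#'   toward the network composition (strict).
#' @param maintenance_window a composition must persist strictly more than
#'   this many consecutive rounds to count as maintained.
#' @param founder_coefficient self-replication coefficient of the single
#'   founding host.
#' @param rounds rounds per evolutionary run.
#' @param seeding how a new species enters the population:
#'   `"single_compartment"` (one founding copy in one compartment chosen
#'   uniformly among the firing compartments; a lucky founder replicates
#'   from 1 to above 100 within its appearance round) or `"all_firing"`
#'   (one copy in every firing compartment).
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(host_from_host_rate = 0.02,
                             parasite_from_host_rate = 0.001,
                             parasite_from_parasite_rate = 0.002,
                             host_coeff_range = c(1, 3),
                             parasite_coeff_range = c(0, 10),
                             species_cap = 3,
                             classification_threshold = 1000,
                             maintenance_window = 100,
                             founder_coefficient = 2.0,
                             rounds = 1000,
                             seeding = c("single_compartment", "all_firing")) {
  seeding <- match.arg(seeding)
  rates <- c(host_from_host_rate, parasite_from_host_rate,
             parasite_from_parasite_rate)
  problems <- c(
    if (any(rates < 0 | rates > 1)) "appearance rates must be in [0, 1]",
    if (diff(host_coeff_range) < 0 || diff(parasite_coeff_range) < 0)
      "coefficient ranges must be ordered",
    if (species_cap < 1) "species_cap must be >= 1",
    if (rounds < 1) "rounds must be >= 1")
  stop_fields(problems)
  structure(list(host_from_host_rate = host_from_host_rate,
                 parasite_from_host_rate = parasite_from_host_rate,
                 parasite_from_parasite_rate = parasite_from_parasite_rate,
                 host_coeff_range = host_coeff_range,
                 parasite_coeff_range = parasite_coeff_range,
                 species_cap = as.integer(species_cap),
                 classification_threshold = classification_threshold,
                 maintenance_window = as.integer(maintenance_window),
                 founder_coefficient = founder_coefficient,
                 rounds = as.integer(rounds), seeding = seeding),
            class = "evolution_config")
}

role_chr <- function(code) c("host", "parasite")[code + 1L]

#' Mutation step of the evolutionary simulator
#'
#' Applies one appearance step to a population, given the replication
#' tallies of the previous round. Fires per (species, compartment) with
#' probability `min(1, replications * rate)`; each firing adds one copy of
#' the round's new species of that class to the firing compartment. At most
#' one new host type and one new parasite type arise per round, and nothing
#' happens while the concurrent species count is at `species_cap`.
#'
#' @param pop integer population matrix (compartments x species).
#' @param roles character vector of `"host"`/`"parasite"` per column of
#'   `pop`.
#' @param K [coefficient_matrix()] of the current species.
#' @param replicated integer matrix of the previous round's per-compartment
#'   replication counts (same shape as `pop`); all zeros (or round 1) make
#'   this a no-op.
#' @param cfg an [evolution_config()].
#' @param seed optional integer seed.
#' @return A list with the (possibly extended) `pop`, `roles`, `K`, and a
#'   tibble `events` describing any new species (`role`, `n_seeded`).
#' @export
mutation_step <- function(pop, roles, K, replicated,
                          cfg = evolution_config(), seed = NULL) {
  pop <- check_population(pop)
  storage.mode(replicated) <- "integer"
  res <- cpp_mutation_step(
    pop, as.integer(roles == "parasite"), unclass_coeff(K), replicated,
    cfg$host_from_host_rate, cfg$parasite_from_host_rate,
    cfg$parasite_from_parasite_rate,
    cfg$host_coeff_range[1], cfg$host_coeff_range[2],
    cfg$parasite_coeff_range[1], cfg$parasite_coeff_range[2],
    cfg$species_cap, as.integer(cfg$seeding == "all_firing"), draw_seed(seed))
  n_new <- length(res$new_roles)
  new_roles <- role_chr(res$new_roles)
  roles2 <- c(unname(roles), new_roles)
  ids <- colnames(pop) %||% default_ids(roles2[seq_len(ncol(pop))])
  if (n_new) {
    new_ids <- paste0(ifelse(new_roles == "host", "H", "P"), "new",
                      seq_len(n_new))
    ids <- c(ids, new_ids)
  }
  colnames(res$pop) <- ids
  dimnames(res$K) <- list(ids, ids)
  list(pop = res$pop, roles = setNames(roles2, ids),
       K = coefficient_matrix(res$K, setNames(roles2, ids)),
       events = tibble::tibble(species_id = if (n_new) ids[ncol(pop) + seq_len(n_new)] else character(),
                               role = new_roles,
                               n_seeded = as.integer(res$n_seeded)))
}

#' Classify a network composition
#'
#' The composition is the set of species whose global total strictly
#' exceeds the classification threshold, summarized as a topology label
#' (`"H"`, `"HP"`, `"HH"`, `"HHP"`, `"HPP"`, `"HHH"`, ... or `"none"`).
#'
#' @param x a population matrix (compartments x species) or a named vector
#'   of global totals.
#' @param roles named character vector of roles per species.
#' @param threshold classification threshold (strict; default 1000 copies).
#' @return A list with `ids` (character vector of member species) and
#'   `label`.
#' @export
classify_network <- function(x, roles, threshold = 1000) {
  totals <- if (is.matrix(x)) colSums(x) else x
  ids <- names(totals)[totals > threshold]
  list(ids = ids, label = composition_label(roles[ids]))
}

composition_label <- function(roles) {
  if (!length(roles)) return("none")
  paste0(strrep("H", sum(roles == "host")),
         strrep("P", sum(roles == "parasite")))
}

#' Run one evolutionary simulation
#'
#' Starts from a single self-replicating host filling every compartment to
#' capacity and iterates mutation, replication, culling and fusion-division
#' for `cfg$rounds` rounds (or until global extinction). Every coefficient
#' ever drawn, every appearance event and the per-round global total of
#' every living species are logged.
#'
#' @param cfg an [evolution_config()].
#' @param cycle a [cycle_config()] (its `rounds` is ignored in favour of
#'   `cfg$rounds`).
#' @param seed integer seed for the run.
#' @return An object of class `evolution_log`: tibbles `totals` (round,
#'   species_id, total), `species` (species_id, role, birth_round),
#'   `coeffs` (replicase_id, template_id, k), `events`, plus
#'   `extinct_round` (`NA` if the run survived), `rounds` and the configs.
#' @export
run_evolution <- function(cfg = evolution_config(), cycle = cycle_config(),
                          seed = NULL) {
  dyn <- cycle$dynamics
  res <- cpp_run_evolution(
    cycle$compartments, cycle$cull_rate, cycle$fusion_divisions, cfg$rounds,
    dyn$carrying_capacity, dyn$horizon, dyn$rel_tol, dyn$abs_tol,
    rounding_code(dyn), cfg$host_from_host_rate, cfg$parasite_from_host_rate,
    cfg$parasite_from_parasite_rate, cfg$host_coeff_range[1],
    cfg$host_coeff_range[2], cfg$parasite_coeff_range[1],
    cfg$parasite_coeff_range[2], cfg$species_cap, cfg$founder_coefficient,
    as.integer(cfg$seeding == "all_firing"), draw_seed(seed %||% cycle$seed))
  species <- tibble::as_tibble(res$species)
  species$role <- role_chr(species$role)
  events <- tibble::as_tibble(res$events)
  events$role <- role_chr(events$role)
  structure(list(totals = tibble::as_tibble(res$totals), species = species,
                 coeffs = tibble::as_tibble(res$coeffs), events = events,
                 extinct_round = res$extinct_round, rounds = cfg$rounds,
                 config = cfg, cycle = cycle),
            class = "evolution_log")
}

#' @export
print.evolution_log <- function(x, ...) {
  cat("Evolutionary run:", x$rounds, "rounds,", x$cycle$compartments,
      "compartments\n")
  cat(nrow(x$species), "species appeared;",
      if (is.na(x$extinct_round)) "population survived"
      else paste("global extinction at round", x$extinct_round), "\n")
  invisible(x)
}

# per-round composition keys (id sets above the classification threshold)
composition_timeline <- function(log) {
  n_rounds <- if (is.na(log$extinct_round)) log$rounds else log$extinct_round
  thr <- log$config$classification_threshold
  above <- log$totals[log$totals$total > thr, ]
  keys <- character(n_rounds)
  if (nrow(above)) {
    split_ids <- split(above$species_id, above$round)
    keys[as.integer(names(split_ids))] <-
      vapply(split_ids, function(v) paste(sort(v), collapse = ","), "")
  }
  keys
}

#' Maintained networks of an evolutionary run
#'
#' A maintained network is a maximal interval of rounds over which the set
#' of species above the classification threshold is identical (by species
#' id) and non-empty, lasting strictly more than the maintenance window.
#'
#' @param log an `evolution_log` from [run_evolution()].
#' @return A tibble with one row per maintained network: `label`, `ids`
#'   (comma-joined species ids), `start`, `end`, `length`,
#'   `predecessor` (composition label of the round immediately before the
#'   interval) and `predecessor_maintained` (label of the latest maintained
#'   network ending before the interval, `"none"` if there is none).
#' @export
maintained_networks <- function(log) {
  keys <- composition_timeline(log)
  r <- rle(keys)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  roles <- setNames(log$species$role, as.character(log$species$species_id))
  lab <- function(key) {
    if (key == "") "none"
    else composition_label(roles[strsplit(key, ",")[[1]]])
  }
  all_lab <- vapply(r$values, lab, "", USE.NAMES = FALSE)
  ok <- which(r$values != "" & r$lengths > log$config$maintenance_window)
  if (!length(ok))
    return(tibble::tibble(label = character(), ids = character(),
                          start = integer(), end = integer(),
                          length = integer(), predecessor = character(),
                          predecessor_maintained = character()))
  pred <- vapply(ok, function(i) if (i == 1L) "none" else all_lab[i - 1L], "")
  pred_m <- vapply(ok, function(i) {
    earlier <- ok[ok < i]
    if (length(earlier)) all_lab[max(earlier)] else "none"
  }, "")
  tibble::tibble(label = all_lab[ok], ids = r$values[ok],
                 start = start[ok], end = end[ok],
                 length = r$lengths[ok], predecessor = pred,
                 predecessor_maintained = pred_m)
}

# coefficient set of a maintained HHP trio, hosts ordered by birth round
# (the elder host is host 1; in the HP -> HHP route it is the
# parasite-susceptible partner of the established pair)
hhp_slot_coefficients <- function(log, ids) {
  ids <- as.integer(strsplit(ids, ",")[[1]])
  sp <- log$species[match(ids, log$species$species_id), ]
  hosts <- sp$species_id[sp$role == "host"]
  hosts <- hosts[order(sp$birth_round[sp$role == "host"])]
  par <- sp$species_id[sp$role == "parasite"]
  if (length(hosts) != 2 || length(par) != 1) return(NULL)
  co <- log$coeffs
  k <- function(j, i) {
    v <- co$k[co$replicase_id == j & co$template_id == i]
    if (length(v)) v[1] else NA_real_
  }
  data.frame(k11H = k(hosts[1], hosts[1]), k21H = k(hosts[2], hosts[1]),
             k12H = k(hosts[1], hosts[2]), k22H = k(hosts[2], hosts[2]),
             k11P = k(hosts[1], par), k21P = k(hosts[2], par))
}

#' Run a batch of evolutionary simulations
#'
#' Per-run seeds are derived deterministically from the master seed, so any
#' subset of runs is reproducible in isolation.
#'
#' @param n_runs number of independent runs.
#' @param cfg an [evolution_config()].
#' @param cycle a [cycle_config()].
#' @param seed master seed.
#' @param keep_logs keep the full `evolution_log` objects (memory-heavy for
#'   large batches; summaries are always kept).
#' @return An object of class `evolution_batch`: `runs` (tibble with
#'   `run`, `extinct`, `extinct_round`), `maintained` (all maintained
#'   networks with their predecessors), `hhp_sets` (coefficient sets of
#'   maintained HHP networks with `satisfies_condition` from
#'   [check_hhp_condition()]), and optionally `logs`.
#' @export
run_evolution_batch <- function(n_runs, cfg = evolution_config(),
                                cycle = cycle_config(), seed = 1,
                                keep_logs = FALSE) {
  runs <- vector("list", n_runs)
  maint <- vector("list", n_runs)
  hhp <- vector("list", n_runs)
  logs <- if (keep_logs) vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    log <- run_evolution(cfg, cycle, seed = derive_seed(seed, r))
    runs[[r]] <- data.frame(run = r, extinct = !is.na(log$extinct_round),
                            extinct_round = log$extinct_round)
    m <- maintained_networks(log)
    if (nrow(m)) {
      m$run <- r
      maint[[r]] <- m
      is_hhp <- which(m$label == "HHP")
      if (length(is_hhp)) {
        sets <- do.call(rbind, lapply(m$ids[is_hhp], hhp_slot_coefficients,
                                      log = log))
        sets$run <- r
        sets$start <- m$start[is_hhp]
        hhp[[r]] <- sets
      }
    }
    if (keep_logs) logs[[r]] <- log
  }
  maintained <- do.call(rbind, maint) %||%
    tibble::tibble(label = character(), run = integer())
  hhp_sets <- do.call(rbind, hhp)
  if (!is.null(hhp_sets))
    hhp_sets$satisfies_condition <- check_hhp_condition(hhp_sets)
  structure(list(runs = tibble::as_tibble(do.call(rbind, runs)),
                 maintained = tibble::as_tibble(maintained),
                 hhp_sets = if (!is.null(hhp_sets)) tibble::as_tibble(hhp_sets),
                 logs = logs, n_runs = n_runs, seed = seed,
                 config = cfg, cycle = cycle),
            class = "evolution_batch")
}

#' @export
print.evolution_batch <- function(x, ...) {
  cat("Evolutionary batch:", x$n_runs, "runs x", x$config$rounds, "rounds\n")
  cat(sprintf("extinct: %d/%d (%.3f)\n", sum(x$runs$extinct), x$n_runs,
              mean(x$runs$extinct)))
  if (nrow(x$maintained)) {
    cat("maintained networks:\n")
    print(maintained_network_counts(x))
  }
  invisible(x)
}

#' Counts of maintained networks by topology label
#'
#' @param batch an `evolution_batch`.
#' @return A tibble with `label` and `n` (number of runs in which at least
#'   one network of that label was maintained).
#' @export
maintained_network_counts <- function(batch) {
  if (!nrow(batch$maintained))
    return(tibble::tibble(label = character(), n = integer()))
  per_run <- unique(batch$maintained[, c("run", "label")])
  tab <- sort(table(per_run$label), decreasing = TRUE)
  tibble::tibble(label = names(tab), n = as.integer(tab))
}

#' Predecessors of maintained networks
#'
#' For each maintained network of the requested topology, tallies the
#' composition it arose from: either the classified composition of the
#' round immediately preceding the interval (default) or the latest
#' maintained network that ended before it.
#'
#' @param batch an `evolution_batch` (or a list of `evolution_log`s).
#' @param network topology label of interest (default `"HHP"`).
#' @param mode `"previous_composition"` or `"previous_maintained"`.
#' @return A tibble with `predecessor` and `n`, sorted by count.
#' @export
predecessor_analysis <- function(batch, network = "HHP",
                                 mode = c("previous_composition",
                                          "previous_maintained")) {
  mode <- match.arg(mode)
  if (!inherits(batch, "evolution_batch")) {
    maint <- do.call(rbind, lapply(batch, maintained_networks))
  } else maint <- batch$maintained
  if (is.null(maint) || !nrow(maint))
    return(tibble::tibble(predecessor = character(), n = integer()))
  col <- if (mode == "previous_composition") "predecessor"
         else "predecessor_maintained"
  sel <- maint[maint$label == network, ]
  tab <- sort(table(sel[[col]]), decreasing = TRUE)
  tibble::tibble(predecessor = names(tab), n = as.integer(tab))
}
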