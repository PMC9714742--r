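# Configuration loading, fixture generation, result serialization and run
# manifests.

#' Load a run configuration from YAML
#'
#' Recognized top-level keys: `compartments`, `cull_rate`,
#' `fusion_divisions`, `carrying_capacity`, `rounds`, `horizon`, `rel_tol`,
#' `abs_tol`, `rounding`, `seed`, plus an optional `topology` section
#' (`name`, `n_runs`, `grid_values`, `fixed`) or `evolution` section (any
#' [evolution_config()] argument). Omitted keys take the study defaults
#' (3000 compartments, culling rate 0.25, 5000 fusion-divisions, carrying
#' capacity 100). When `compartments` is changed and `fusion_divisions` is
#' not given, the fusion-division frequency is scaled proportionally to the
#' compartment number (keeping the published configuration pairs: 3000
#' compartments pair with 5000 events, 10000 with 16500).
#'
#' @param path YAML file path (an empty file yields all defaults).
#' @return A list with `cycle` (a [cycle_config()]) and, when present,
#'   `topology` (a [topology_spec()]) or `evolution` (an
#'   [evolution_config()]). Unknown or out-of-range keys raise a
#'   validation error listing the offending fields.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  known <- c("compartments", "cull_rate", "fusion_divisions",
             "carrying_capacity", "rounds", "horizon", "rel_tol", "abs_tol",
             "rounding", "seed", "topology", "evolution")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_fields(paste0("unknown key: ", unknown))
  C <- raw$compartments %||% 3000
  A <- raw$fusion_divisions %||% scale_fusion_divisions(C)
  dyn <- dynamics_config(
    carrying_capacity = raw$carrying_capacity %||% 100,
    horizon = raw$horizon %||% 1,
    rel_tol = raw$rel_tol %||% 1e-6,
    abs_tol = raw$abs_tol %||% 1e-9,
    rounding = raw$rounding %||% "stochastic")
  cycle <- cycle_config(compartments = C,
                        cull_rate = raw$cull_rate %||% 0.25,
                        fusion_divisions = A,
                        rounds = raw$rounds %||% 100,
                        dynamics = dyn, seed = raw$seed)
  out <- list(cycle = cycle)
  if (!is.null(raw$topology)) {
    tp <- raw$topology
    if (is.null(tp$name)) stop_fields("topology: `name` is required")
    out$topology <- topology_spec(tp$name, grid_values = tp$grid_values,
                                  fixed = tp$fixed, n_runs = tp$n_runs)
  }
  if (!is.null(raw$evolution))
    out$evolution <- do.call(evolution_config, raw$evolution)
  out
}

#' Fusion-division frequency scaled to the compartment number
#'
#' Keeps the average number of fusion-division events per compartment
#' constant when the compartment number changes, rounding down to a
#' multiple of 500 so that the published configuration pairs (3000/5000 and
#' 10000/16500) are reproduced exactly.
#'
#' @param compartments number of compartments `C`.
#' @return Integer fusion-division frequency `A`.
#' @export
scale_fusion_divisions <- function(compartments) {
  as.integer(floor(compartments * (5000 / 3000) / 500) * 500)
}

#' Generate small synthetic inputs
#'
#' Fixtures for tests and demonstrations, built so that the relevant
#' property holds by construction:
#' \describe{
#'   \item{`coefficient_matrix`}{a random HHP matrix with host coefficients
#'     in `[1, 3]` and parasite coefficients in `[0, 10]`.}
#'   \item{`fold_table`}{a triplicate fold table that inverts the
#'     estimator's normalization for a given (or random) coefficient
#'     matrix, so [estimate_coefficients()] recovers it exactly.}
#'   \item{`sequence_pair`}{two equal-length random RNA sequences at a
#'     prescribed Hamming distance.}
#'   \item{`s1data_like`}{a table of HHP coefficient sets shaped like an
#'     evolutionary-simulation export, with a prescribed number of rows
#'     satisfying [check_hhp_condition()].}
#' }
#'
#' @param kind one of `"coefficient_matrix"`, `"fold_table"`,
#'   `"sequence_pair"`, `"s1data_like"`.
#' @param path optional file to write (CSV, or FASTA for sequences).
#' @param seed optional integer seed.
#' @param K coefficient matrix for `"fold_table"` (random if omitted).
#' @param length,distance sequence length and Hamming distance for
#'   `"sequence_pair"`.
#' @param n,n_pass row counts for `"s1data_like"`.
#' @return The fixture object (invisibly `path`-annotated when written).
#' @export
make_fixture <- function(kind = c("coefficient_matrix", "fold_table",
                                  "sequence_pair", "s1data_like"),
                         path = NULL, seed = NULL, K = NULL,
                         length = 2000, distance = 7, n = 218, n_pass = 148) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  out <- switch(kind,
    coefficient_matrix = fixture_coeff_matrix(),
    fold_table = fixture_fold_table(K %||% fixture_coeff_matrix()),
    sequence_pair = fixture_sequence_pair(length, distance),
    s1data_like = fixture_s1data(n, n_pass))
  if (!is.null(path)) {
    switch(kind,
      coefficient_matrix = write_coefficient_csv(out, path),
      fold_table = utils::write.csv(out, path, row.names = FALSE),
      sequence_pair = seqinr::write.fasta(
        as.list(out), names = names(out), file.out = path, nbchar = 70),
      s1data_like = utils::write.csv(out, path, row.names = FALSE))
  }
  out
}

fixture_coeff_matrix <- function() {
  k <- matrix(0, 3, 3)
  k[1:2, 1:2] <- runif(4, 1, 3)
  k[1:2, 3] <- runif(2, 0, 10)
  coefficient_matrix(k, c(H1 = "host", H2 = "host", P1 = "parasite"))
}

# invert the estimator: self folds are the self coefficients, competitive
# folds are chosen so that k_ij = k_ii * v_ijj / v_iji reproduces K
fixture_fold_table <- function(K, n_replicates = 3) {
  roles <- species_roles(K)
  hosts <- names(roles)[roles == "host"]
  rows <- list()
  add <- function(i, j, h, fold) {
    for (r in seq_len(n_replicates))
      rows[[length(rows) + 1]] <<- data.frame(
        rna_I = i, rna_II = j, measured = h, replicate = r,
        conc_0h = 1, conc_1h = 10^fold)
  }
  for (i in hosts) {
    add(i, i, i, K[i, i])
    for (j in setdiff(names(roles), i)) {
      viji <- 0.8 * K[i, i]  # competition slows RNA I's own replication
      vijj <- K[i, j] * viji / K[i, i]
      if (vijj == 0) vijj <- 1e-12  # fold of an unreplicated template
      add(i, j, i, viji)
      add(i, j, j, vijj)
    }
  }
  df <- do.call(rbind, rows)
  df$fold <- fold_value(df$conc_0h, df$conc_1h)
  tibble::as_tibble(df)
}

fixture_sequence_pair <- function(length, distance) {
  stopifnot(distance <= length)
  bases <- c("A", "C", "G", "U")
  a <- sample(bases, length, replace = TRUE)
  b <- a
  pos <- sample.int(length, distance)
  for (p in pos) b[p] <- sample(setdiff(bases, a[p]), 1)
  c(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""))
}

fixture_s1data <- function(n, n_pass) {
  stopifnot(n_pass <= n)
  draw_one <- function(pass) {
    repeat {
      k <- list(k11H = runif(1, 1, 3), k21H = runif(1, 1, 3),
                k12H = runif(1, 1, 3), k22H = runif(1, 1, 3),
                k11P = runif(1, 0, 10), k21P = runif(1, 0, 10))
      ok <- check_hhp_condition(as.data.frame(k))
      if (ok == pass) return(as.data.frame(k))
    }
  }
  pass_flags <- sample(rep(c(TRUE, FALSE), c(n_pass, n - n_pass)))
  out <- do.call(rbind, lapply(pass_flags, draw_one))
  out$network <- seq_len(n)
  tibble::as_tibble(out[, c("network", "k11H", "k21H", "k12H", "k22H",
                            "k11P", "k21P")])
}

#' Write a run trajectory as tidy CSV
#'
#' @param outcome a `run_outcome` from [run_simulation()].
#' @param path CSV file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(outcome, path) {
  utils::write.csv(as.data.frame(trajectory_df(outcome)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a run outcome as JSON
#'
#' @param outcome a `run_outcome`.
#' @param path JSON file path.
#' @return Invisibly, `path`.
#' @export
write_outcome_json <- function(outcome, path) {
  jsonlite::write_json(list(
    seed = outcome$seed,
    survivors = as.list(outcome$survivors),
    sustained_all = outcome$sustained_all,
    final_totals = as.list(outcome$trajectory[nrow(outcome$trajectory), ])),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write an evolutionary run log
#'
#' Events and species metadata go to JSON, per-round totals to tidy CSV.
#'
#' @param log an `evolution_log`.
#' @param totals_csv,events_json output paths (either may be `NULL`).
#' @return Invisibly, a character vector of the written paths.
#' @export
write_evolution_log <- function(log, totals_csv = NULL, events_json = NULL) {
  written <- character()
  if (!is.null(totals_csv)) {
    utils::write.csv(as.data.frame(log$totals), totals_csv,
                     row.names = FALSE)
    written <- c(written, totals_csv)
  }
  if (!is.null(events_json)) {
    jsonlite::write_json(list(
      species = log$species, events = log$events, coeffs = log$coeffs,
      extinct_round = log$extinct_round, rounds = log$rounds),
      events_json, dataframe = "rows", pretty = TRUE, na = "null")
    written <- c(written, events_json)
  }
  invisible(written)
}

#' Run manifest
#'
#' Snapshot of everything that determines a run's outputs: the
#' configuration, the master seed, the package version and the derived
#' per-task seeds. Re-running a manifest with the same code version
#' reproduces every output.
#'
#' @param config a configuration list (e.g. from [load_config()]).
#' @param seed master seed.
#' @param tasks optional named vector of task indices whose derived seeds
#'   should be recorded.
#' @param outputs optional named list of output paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, tasks = NULL, outputs = NULL) {
  derived <- if (!is.null(tasks))
    setNames(vapply(tasks, function(t) derive_seed(seed, t), 0), names(tasks))
  structure(list(
    version = as.character(utils::packageVersion("replinet")),
    seed = seed, derived_seeds = derived, config = config,
    outputs = outputs), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE, na = "null")
  invisible(path)
}
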