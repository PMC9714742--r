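# Sustainability screens: coefficient grids per network topology, repeated
# runs per grid cell, tallies of full- and partial-survivor outcomes.

host_vals_main <- c(1.7, 2.0, 2.3, 2.6)
host_vals_ext <- c(0.2, 1.7, 2.0, 2.3, 2.6, 4.1)
parasite_vals <- c(0.2, 1.7, 2.0, 2.3, 2.6, 4.1, 7.0, 10.0, 20.0)

topology_registry <- function() {
  hh_free <- list(k11H = host_vals_main, k21H = host_vals_main,
                  k12H = host_vals_main, k22H = host_vals_main)
  hhh_free <- list(k33H = c(1.7, 2.6), k31H = host_vals_main,
                   k32H = host_vals_main, k13H = host_vals_main,
                   k23H = host_vals_main)
  list(
    h = list(hosts = 1, parasites = 0, n_runs = 100,
             free = list(k11H = host_vals_main), fixed = list()),
    hh = list(hosts = 2, parasites = 0, n_runs = 100,
              free = hh_free, fixed = list()),
    hp = list(hosts = 1, parasites = 1, n_runs = 100,
              free = list(k11H = host_vals_ext, k11P = parasite_vals),
              fixed = list()),
    hpp = list(hosts = 1, parasites = 2, n_runs = 100,
               free = list(k11H = host_vals_ext, k11P = parasite_vals,
                           k12P = parasite_vals),
               fixed = list()),
    hhp_sym = list(hosts = 2, parasites = 1, n_runs = 100, free = hh_free,
                   fixed = list(k11P = 7.0, k21P = 7.0)),
    hhp_asym = list(hosts = 2, parasites = 1, n_runs = 100, free = hh_free,
                    fixed = list(k11P = 7.0, k21P = 0.1)),
    hhh_condI = list(hosts = 3, parasites = 0, n_runs = 100, free = hhh_free,
                     fixed = list(k11H = 1.7, k21H = 2.6, k12H = 2.0,
                                  k22H = 1.7)),
    hhh_condII = list(hosts = 3, parasites = 0, n_runs = 100, free = hhh_free,
                      fixed = list(k11H = 2.0, k21H = 1.7, k12H = 2.0,
                                   k22H = 1.7)))
}

#' Topology specification for a sustainability sweep
#'
#' Built-in designs cover the study's two- and three-member networks. `hh`
#' grids all four host coefficients over \{1.7, 2.0, 2.3, 2.6\} (256 cells);
#' `hp` crosses the host axis (with extremes 0.2 and 4.1) with a parasite
#' axis up to 20; `hpp` adds a second independent parasite coefficient;
#' `hhp_sym`/`hhp_asym` grid the host coefficients with the parasite
#' replicated equally by both hosts (7.0/7.0) or mostly by host 1
#' (7.0/0.1); `hhh_condI`/`hhh_condII` fix the host-1/2 block at one
#' "low self- high cross-replication" or one "balanced" sustainable setting
#' and grid the five coefficients brought in by host 3.
#'
#' @param name one of `"h"`, `"hh"`, `"hp"`, `"hpp"`, `"hhp_sym"`,
#'   `"hhp_asym"`, `"hhh_condI"`, `"hhh_condII"`.
#' @param grid_values named list overriding the gridded values of free
#'   coefficient slots (e.g. `list(k21P = 1.0)` to move a slot into the
#'   fixed set, or a vector to re-grid it).
#' @param fixed named list overriding fixed slot values.
#' @param n_runs independent simulations per grid cell (default 100 for the
#'   main designs; supplementary-scale screens conventionally use 10).
#' @return A list of class `topology_spec`.
#' @export
topology_spec <- function(name, grid_values = NULL, fixed = NULL,
                          n_runs = NULL) {
  reg <- topology_registry()
  name <- match.arg(tolower(name), tolower(names(reg)))
  spec <- reg[[match(name, tolower(names(reg)))]]
  spec$name <- names(reg)[match(name, tolower(names(reg)))]
  if (!is.null(fixed)) spec$fixed <- modifyList(spec$fixed, as.list(fixed))
  if (!is.null(grid_values)) {
    for (slot in names(grid_values)) {
      v <- grid_values[[slot]]
      if (length(v) == 1) {  # a single value demotes the slot to fixed
        spec$free[[slot]] <- NULL
        spec$fixed[[slot]] <- v
      } else spec$free[[slot]] <- v
    }
  }
  if (!is.null(n_runs)) spec$n_runs <- as.integer(n_runs)
  if (any(lengths(spec$free) == 0))
    stop("empty grid: a free coefficient slot has no values", call. = FALSE)
  structure(spec, class = "topology_spec")
}

#' Enumerate the coefficient grid of a topology
#'
#' @param spec a [topology_spec()].
#' @return A tibble with one row per grid cell: the free-slot values, a
#'   `cell` index, `identical_hosts` (`TRUE` on the two-host diagonal where
#'   hosts 1 and 2 are interchangeable; conventionally omitted from
#'   two-host heat maps), and a list-column `K` of [coefficient_matrix()]
#'   objects.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "topology_spec"))
  cells <- if (length(spec$free)) {
    expand.grid(spec$free, KEEP.OUT.ATTRS = FALSE)
  } else data.frame(row.names = 1)  # everything fixed: a single cell
  if (!nrow(cells)) stop("empty coefficient grid", call. = FALSE)
  slots_list <- lapply(seq_len(nrow(cells)), function(r)
    c(as.list(cells[r, , drop = FALSE]), spec$fixed))
  K <- lapply(slots_list, coefficients_from_slots,
              n_hosts = spec$hosts, n_parasites = spec$parasites)
  all_slots <- function(slot) {
    vapply(slots_list, function(s) s[[slot]] %||% 0, 0)
  }
  identical_hosts <- if (spec$hosts == 2) {
    all_slots("k11H") == all_slots("k22H") &
      all_slots("k12H") == all_slots("k21H")
  } else rep(FALSE, nrow(cells))
  out <- tibble::as_tibble(cells)
  out$cell <- seq_len(nrow(out))
  out$identical_hosts <- identical_hosts
  out$K <- K
  out
}

#' Run a sustainability sweep
#'
#' For every grid cell, runs `n_runs` independent serial-cycle simulations
#' (with seeds derived deterministically from the master seed, the cell
#' index and the run index) and tallies outcomes by the exact set of
#' sustained species. The count of the full set reproduces the sustained-run
#' heat maps; partial sets give the remaining-replicator tallies.
#'
#' @param spec a [topology_spec()].
#' @param cfg a [cycle_config()].
#' @param seed master seed.
#' @param cells optional subset of cell indices to run.
#' @param n_runs overrides `spec$n_runs`.
#' @return A tibble of class `sweep_result`: one row per (cell, survivor
#'   set) with the free-slot values, `state` (sustained ids joined by `+`,
#'   or `"none"`) and count `n`; counts per cell sum to the number of runs.
#' @export
run_sweep <- function(spec, cfg = cycle_config(), seed = 1, cells = NULL,
                      n_runs = NULL) {
  grid <- build_grid(spec)
  if (!is.null(cells)) grid <- grid[grid$cell %in% cells, , drop = FALSE]
  n_runs <- as.integer(n_runs %||% spec$n_runs)
  stopifnot(n_runs >= 1)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    K <- grid$K[[g]]
    states <- character(n_runs)
    for (r in seq_len(n_runs)) {
      out <- run_simulation(K, cfg, seed = derive_seed(seed, grid$cell[g], r))
      s <- names(out$survivors)[out$survivors]
      states[r] <- if (length(s)) paste(s, collapse = "+") else "none"
    }
    tab <- table(states)
    row <- grid[g, setdiff(names(grid), "K"), drop = FALSE]
    res[[g]] <- tibble::as_tibble(cbind(
      row[rep(1, length(tab)), , drop = FALSE],
      data.frame(state = names(tab), n = as.integer(tab))))
  }
  out <- do.call(rbind, res)
  attr(out, "spec") <- spec
  attr(out, "n_runs") <- n_runs
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", class(out))
  out
}

#' Per-cell counts of fully sustained runs
#'
#' @param result a `sweep_result` from [run_sweep()].
#' @return A tibble with one row per cell and column `n_sustained`, the
#'   number of runs in which every founding species was sustained.
#' @export
sustained_counts <- function(result) {
  spec <- attr(result, "spec")
  ids <- c(if (spec$hosts) paste0("H", seq_len(spec$hosts)),
           if (spec$parasites) paste0("P", seq_len(spec$parasites)))
  full <- paste(ids, collapse = "+")
  cols <- setdiff(names(result), c("state", "n"))
  cells <- unique(result[, cols, drop = FALSE])
  n_full <- vapply(cells$cell, function(cl) {
    hit <- result$cell == cl & result$state == full
    if (any(hit)) sum(result$n[hit]) else 0L
  }, 0L)
  cells$n_sustained <- as.integer(n_full)
  cells
}

#' Check the sustainable-HHP parameter condition
#'
#' A two-host/one-parasite network tends to be sustainable when all three of
#' these hold: the two hosts have asymmetric parasite resistance
#' (`k11P > k21P`, host 2 resistant), the resistant host replicates the
#' susceptible host more than itself (`k21H > k22H`), and the susceptible
#' host receives at least as much replication as the resistant one
#' (`k11H + k21H >= k12H + k22H`).
#'
#' @param K an HHP [coefficient_matrix()] (species order host 1, host 2,
#'   parasite), or a data frame with columns `k11H`, `k21H`, `k12H`,
#'   `k22H`, `k11P`, `k21P` (one network per row).
#' @return Logical (one value per network).
#' @export
check_hhp_condition <- function(K) {
  if (inherits(K, "coeff_matrix")) {
    roles <- species_roles(K)
    if (sum(roles == "host") != 2 || sum(roles == "parasite") != 1)
      stop("`K` must describe an HHP network (two hosts, one parasite)",
           call. = FALSE)
    h <- names(roles)[roles == "host"]
    p <- names(roles)[roles == "parasite"]
    K <- data.frame(k11H = K[h[1], h[1]], k21H = K[h[2], h[1]],
                    k12H = K[h[1], h[2]], k22H = K[h[2], h[2]],
                    k11P = K[h[1], p], k21P = K[h[2], p])
  }
  need <- c("k11H", "k21H", "k12H", "k22H", "k11P", "k21P")
  if (!all(need %in% names(K)))
    stop("expected columns ", paste(need, collapse = ", "), call. = FALSE)
  unname(K$k11P > K$k21P & K$k21H > K$k22H &
           K$k11H + K$k21H >= K$k12H + K$k22H)
}

#' Write a sweep result as tidy CSV
#'
#' @param result a `sweep_result`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
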