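#' Within-compartment replication dynamics settings
#'
#' Controls the replication step of the serial cycle. Copy numbers in a
#' compartment follow the coupled logistic equations
#' \deqn{dH_i/dt = H_i \Big(\sum_j k_{ji}^H H_j\Big)\Big(1 - \frac{\sum_j H_j + \sum_h P_h}{N}\Big)}
#' \deqn{dP_h/dt = P_h \Big(\sum_j k_{jh}^P H_j\Big)\Big(1 - \frac{\sum_j H_j + \sum_h P_h}{N}\Big)}
#' with a carrying capacity `N` shared by all compartments and no
#' degradation term. The equations are integrated in continuous space over
#' `[0, horizon]` with an adaptive Dormand-Prince 5(4) solver and the result
#' is converted back to integer copy numbers.
#'
#' The dynamics saturate once the compartment reaches capacity (the
#' logistic factor vanishes), so the final composition is insensitive to the
#' horizon beyond saturation; the default of 1 model-time unit is past
#' saturation for all coefficient magnitudes used in the study designs.
#'
#' @param carrying_capacity `N`, maximum total copies per compartment.
#' @param horizon integration time per replication step (model time units).
#' @param rel_tol,abs_tol solver tolerances.
#' @param rounding how continuous solutions become integers: `"stochastic"`
#'   (floor plus a Bernoulli draw on the fractional part; unbiased in
#'   expectation) or `"nearest"` (deterministic, for exactly reproducible
#'   unit checks).
#' @return A list of class `dynamics_config`.
#' @export
dynamics_config <- function(carrying_capacity = 100, horizon = 1,
                            rel_tol = 1e-6, abs_tol = 1e-9,
                            rounding = c("stochastic", "nearest")) {
  rounding <- match.arg(rounding)
  problems <- c(
    if (!is.numeric(carrying_capacity) || carrying_capacity <= 0)
      "carrying_capacity must be > 0",
    if (!is.numeric(horizon) || horizon <= 0) "horizon must be > 0",
    if (rel_tol <= 0 || abs_tol <= 0) "solver tolerances must be > 0")
  stop_fields(problems)
  structure(list(carrying_capacity = carrying_capacity, horizon = horizon,
                 rel_tol = rel_tol, abs_tol = abs_tol, rounding = rounding),
            class = "dynamics_config")
}

rounding_code <- function(dynamics) {
  match(dynamics$rounding, c("stochastic", "nearest")) - 1L
}

check_counts <- function(counts, K) {
  ids <- colnames(K)
  if (is.null(names(counts))) {
    if (length(counts) != length(ids))
      stop("`counts` must be named or have one entry per species of `K`",
           call. = FALSE)
    names(counts) <- ids
  }
  unknown <- setdiff(names(counts), ids)
  if (length(unknown))
    stop("species not covered by the coefficient matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  full <- setNames(integer(length(ids)), ids)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("copy numbers must be >= 0", call. = FALSE)
  full
}

#' Continuous solution of the replication dynamics
#'
#' Integrates the within-compartment equations from an integer initial
#' condition and returns the continuous (un-rounded) copy numbers at the end
#' of the horizon. Used directly by solver-accuracy checks; simulations use
#' [replicate_compartment()], which also discretizes.
#'
#' @param counts named non-negative integer vector of copy numbers.
#' @param K a [coefficient_matrix()] covering all species in `counts`.
#' @param dynamics a [dynamics_config()].
#' @return Named numeric vector of continuous copy numbers.
#' @export
integrate_compartment <- function(counts, K, dynamics = dynamics_config()) {
  require_complete(K)
  counts <- check_counts(counts, K)
  cpp_integrate(as.numeric(counts), unclass_coeff(K), is_host(K),
                dynamics$carrying_capacity, dynamics$horizon,
                dynamics$rel_tol, dynamics$abs_tol)
}

#' Replicate one compartment
#'
#' Runs the replication step for a single compartment: continuous
#' integration of the logistic cross-replication dynamics followed by
#' conversion back to integer copy numbers. Species at zero stay at zero
#' (no spontaneous generation), parasites without a host do not grow, and a
#' compartment exactly at carrying capacity is a fixed point. If the initial
#' total exceeds the capacity (possible after fusion-division) the logistic
#' factor is negative and counts decay toward the capacity, never below 0.
#'
#' @inheritParams integrate_compartment
#' @param seed optional integer seed for the stochastic rounding draw.
#' @return A list with `counts` (new integer copy numbers) and `replicated`
#'   (`max(new - old, 0)` per species, consumed by the mutation step of the
#'   evolutionary simulator).
#' @export
replicate_compartment <- function(counts, K, dynamics = dynamics_config(),
                                  seed = NULL) {
  require_complete(K)
  counts <- check_counts(counts, K)
  res <- cpp_replicate_population(
    matrix(counts, nrow = 1, dimnames = list(NULL, names(counts))),
    unclass_coeff(K), is_host(K), dynamics$carrying_capacity,
    dynamics$horizon, dynamics$rel_tol, dynamics$abs_tol,
    rounding_code(dynamics), draw_seed(seed))
  list(counts = setNames(res$pop[1, ], names(counts)),
       replicated = setNames(res$replicated[1, ], names(counts)))
}

#' Expected mutations per replication event
#'
#' Converts a per-nucleotide error rate into the expected number of
#' mutations introduced by one replication of a template of the given
#' length; the product underlies the per-replication appearance rates used
#' by [evolution_config()] (e.g. 9.1e-6 per nt over a 2000-nt host RNA gives
#' about 0.02).
#'
#' @param per_nt_rate substitution rate per nucleotide per replication.
#' @param genome_length template length in nucleotides.
#' @return Expected mutations per replication.
#' @export
mutations_per_replication <- function(per_nt_rate = 9.1e-6,
                                      genome_length = 2000) {
  stopifnot(per_nt_rate >= 0, genome_length > 0)
  per_nt_rate * genome_length
}
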