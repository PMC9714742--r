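#' Replication-coefficient matrix
#'
#' A `coeff_matrix` holds the dimensionless replication coefficients of a
#' named species set: entry `K[j, i]` is the rate with which replicase
#' translated from host `j` copies template species `i` (`k_ji^H` for host
#' templates, `k_jh^P` for parasite templates). Only hosts translate
#' replicase, so parasite rows are identically zero.
#'
#' @param k numeric square matrix, rows = replicase species, columns =
#'   template species. Dimnames, if present, must agree; otherwise names are
#'   taken from `roles`.
#' @param roles character vector of `"host"`/`"parasite"`, one per species,
#'   optionally named with species ids. Unnamed roles are paired with the
#'   matrix columns in order.
#' @return A numeric matrix of class `coeff_matrix` with a `roles` attribute.
#' @examples
#' K <- coefficient_matrix(
#'   rbind(c(2.3, 2.3, 6.7),
#'         c(2.3, 2.0, 0.0),
#'         c(0,   0,   0)),
#'   roles = c(H1 = "host", H2 = "host", P1 = "parasite"))
#' @export
coefficient_matrix <- function(k, roles) {
  k <- as.matrix(k)
  if (nrow(k) != ncol(k)) stop("`k` must be square", call. = FALSE)
  n <- ncol(k)
  if (length(roles) != n)
    stop("`roles` must name one role per species", call. = FALSE)
  role_names <- names(roles)
  roles <- as.character(roles)
  if (!all(roles %in% c("host", "parasite")))
    stop("roles must be \"host\" or \"parasite\"", call. = FALSE)
  names(roles) <- role_names
  ids <- names(roles) %||% colnames(k) %||% default_ids(roles)
  if (is.null(names(roles))) names(roles) <- ids
  dimnames(k) <- list(ids, ids)
  validate_coefficients(k, roles)
  structure(k, roles = roles, class = c("coeff_matrix", "matrix", "array"))
}

default_ids <- function(roles) {
  idx <- stats::ave(seq_along(roles), roles, FUN = seq_along)
  paste0(ifelse(roles == "host", "H", "P"), idx)
}

validate_coefficients <- function(k, roles) {
  # NA marks a coefficient the estimator reported as missing
  if (any(k < 0, na.rm = TRUE) || any(is.infinite(k)))
    stop("replication coefficients must be finite and >= 0", call. = FALSE)
  par <- which(roles == "parasite")
  if (length(par) && any(k[par, , drop = FALSE] != 0, na.rm = TRUE))
    stop("parasites never act as replicase: parasite rows must be zero",
         call. = FALSE)
  if (anyDuplicated(names(roles)))
    stop("species ids must be unique", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.coeff_matrix <- function(x, ...) {
  roles <- attr(x, "roles")
  cat("Replication coefficients (", sum(roles == "host"), " hosts, ",
      sum(roles == "parasite"), " parasites)\n", sep = "")
  cat("rows = replicase, columns = template\n")
  print(unclass_coeff(x))
  invisible(x)
}

unclass_coeff <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

#' Species roles of a coefficient matrix
#' @param K a [coefficient_matrix()].
#' @return Named character vector of `"host"`/`"parasite"`.
#' @export
species_roles <- function(K) {
  r <- attr(K, "roles")
  if (is.null(r)) stop("`K` is not a coeff_matrix", call. = FALSE)
  r
}

is_host <- function(K) unname(species_roles(K) == "host")

# simulation entry points need every coefficient present
require_complete <- function(K) {
  if (anyNA(K))
    stop("coefficient matrix has missing (NA) entries; fill or drop them ",
         "before simulating", call. = FALSE)
  invisible(K)
}

#' Build a coefficient matrix from named slots
#'
#' Slot names follow the `k<j><i><class>` convention used throughout the
#' sweep designs: `k21H` is the rate with which host 2 replicates host 1 and
#' `k21P` the rate with which host 2 replicates parasite 1.
#'
#' @param slots named numeric vector or list (e.g. `c(k11H = 2, k11P = 7)`).
#' @param n_hosts,n_parasites species counts; inferred from the slot names
#'   when omitted.
#' @return A [coefficient_matrix()]. Slots not mentioned default to zero.
#' @export
coefficients_from_slots <- function(slots, n_hosts = NULL, n_parasites = NULL) {
  slots <- unlist(slots)
  m <- regmatches(names(slots),
                  regexec("^k([0-9])([0-9])([HP])$", names(slots)))
  bad <- names(slots)[lengths(m) == 0]
  if (length(bad))
    stop("unrecognized coefficient slots: ", paste(bad, collapse = ", "),
         call. = FALSE)
  j <- as.integer(vapply(m, `[`, "", 2L))
  i <- as.integer(vapply(m, `[`, "", 3L))
  cls <- vapply(m, `[`, "", 4L)
  n_hosts <- n_hosts %||% max(j, i[cls == "H"], 0L)
  n_parasites <- n_parasites %||% max(i[cls == "P"], 0L)
  ids <- c(if (n_hosts) paste0("H", seq_len(n_hosts)),
           if (n_parasites) paste0("P", seq_len(n_parasites)))
  roles <- setNames(rep(c("host", "parasite"), c(n_hosts, n_parasites)), ids)
  k <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in seq_along(slots)) {
    tmpl <- paste0(cls[s], i[s])
    k[paste0("H", j[s]), tmpl] <- slots[[s]]
  }
  coefficient_matrix(k, roles)
}

#' Read / write coefficient matrices as CSV
#'
#' The layout mirrors the estimated-coefficient table of the assay module:
#' one row per replicase species (with its role), one column per template
#' species. `read_coefficient_csv(write_coefficient_csv(K, f))` is the
#' identity.
#'
#' @param K a [coefficient_matrix()].
#' @param path file path.
#' @return `read_coefficient_csv` returns a [coefficient_matrix()];
#'   `write_coefficient_csv` invisibly returns `path`.
#' @export
write_coefficient_csv <- function(K, path) {
  roles <- species_roles(K)
  df <- data.frame(replicase = rownames(K), role = unname(roles),
                   unclass_coeff(K), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficient_csv
#' @export
read_coefficient_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("replicase", "role") %in% names(df)))
    stop("expected columns `replicase` and `role` in ", path, call. = FALSE)
  ids <- as.character(df$replicase)
  k <- as.matrix(df[, setdiff(names(df), c("replicase", "role")), drop = FALSE])
  rownames(k) <- ids
  k <- k[, ids, drop = FALSE]
  coefficient_matrix(k, setNames(as.character(df$role), ids))
}
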