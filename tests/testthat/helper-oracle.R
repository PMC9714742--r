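# Brute-force fixed-step RK4 integrator for the within-compartment dynamics,
# kept deliberately independent of the package's adaptive solver: plain R,
# fixed grid, no step control. Used as the numerical oracle.

oracle_rhs <- function(x, K, host, N) {
  g <- 1 - sum(x) / N
  r <- as.numeric(crossprod(K[host, , drop = FALSE], x[host]))
  x * r * g
}

oracle_rk4 <- function(x0, K, roles, N = 100, T = 1, dt = 1e-5) {
  host <- roles == "host"
  x <- as.numeric(x0)
  n <- ceiling(T / dt)
  dt <- T / n
  for (s in seq_len(n)) {
    k1 <- oracle_rhs(x, K, host, N)
    k2 <- oracle_rhs(x + dt / 2 * k1, K, host, N)
    k3 <- oracle_rhs(x + dt / 2 * k2, K, host, N)
    k4 <- oracle_rhs(x + dt * k3, K, host, N)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  setNames(x, names(x0))
}
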