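# Shared fixtures, built in code.

# estimated coefficients of the representative assay RNAs (two hosts, one
# parasite replicated only by host 1's replicase)
table1_matrix <- function() {
  coefficients_from_slots(c(k11H = 2.3, k21H = 2.3, k12H = 2.3, k22H = 2.0,
                            k11P = 6.7, k21P = 0.0))
}

# a small, fast serial-cycle configuration for tests whose conclusion does
# not depend on the study-scale compartment number
small_cycle <- function(rounds = 10, seed = NULL) {
  cycle_config(compartments = 200, fusion_divisions = 300, rounds = rounds,
               seed = seed)
}

random_compartment_state <- function(m = 3, max_total = 200) {
  repeat {
    x <- as.integer(runif(m, 0, max_total / m))
    if (sum(x) > 0 && x[1] > 0) return(x)  # at least one host present
  }
}
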