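`%||%` <- function(x, y) if (is.null(x)) y else x

# Seeds handed to the compiled engine. When the caller does not supply one we
# draw it from R's RNG, so set.seed() at the R level makes a whole session
# reproducible while the engine itself runs on its own stream.
draw_seed <- function(seed = NULL) {
  if (is.null(seed)) return(sample.int(2147483646L, 1L))
  seed <- as.numeric(seed)
  if (length(seed) != 1L || is.na(seed) || seed < 0 || seed >= 2^31)
    stop("`seed` must be a single integer in [0, 2^31)", call. = FALSE)
  seed
}

#' Derive a reproducible sub-stream seed
#'
#' Work units (grid cells, repeated runs) receive seeds that are pure
#' functions of the master seed and their indices, so results never depend
#' on execution order.
#'
#' @param master master seed (integer).
#' @param a,b work-unit indices (e.g. cell and run number).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, a, b = 0) {
  cpp_mix_seed(as.numeric(master), as.numeric(a), as.numeric(b))
}

stop_fields <- function(problems) {
  if (length(problems))
    stop("invalid configuration:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  invisible(TRUE)
}
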