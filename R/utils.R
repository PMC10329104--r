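#' @useDynLib metacontrolr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Classed error helper; class is one of "config", "invalid_parameter",
# "invalid_input", "key", "schema", "data", "degenerate", "spec".
mc_error <- function(msg, class) {
  stop(structure(class = c(paste0("metacontrolr_", class, "_error"),
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Seed the RNG if a seed is given; NULL consumes the ambient stream so a
# caller that seeded once can drive several sub-steps deterministically.
local_rng <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    mc_error("seed must be a single integer", "config")
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Deterministic per-stage / per-subject seed derivation from one master
# seed; stays below 2^31 - 1.
derive_seed <- function(master, stage, i = 0L) {
  m <- 2147483629
  as.integer((as.double(master) * 48271 + stage * 1299709 + i * 7919) %% m) + 1L
}
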