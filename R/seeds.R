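#' Derive a child seed from a master seed
#'
#' Every stochastic generator in the package is a pure function of (config,
#' seed). Sessions use one master seed; per-day and per-stream child seeds are
#' derived by hashing the master seed together with a stream label, so each
#' day/stream is independently reproducible. The hash is a 32-bit
#' multiply-add fold modulo 2^31 - 1 (a Mersenne prime), portable across
#' platforms.
#'
#' @param master_seed Integer master seed.
#' @param ... Stream labels (character or integer scalars), e.g.
#'   `derive_seed(1, "song", bird = 2, day = 3)`.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master_seed) %% m
  labels <- list(...)
  codes <- unlist(lapply(labels, function(x) {
    if (is.character(x)) utf8ToInt(x) else as.numeric(x)
  }), use.names = FALSE)
  for (c in codes) h <- (h * 69069 + c + 1) %% m
  as.integer(h %% (m - 1L) + 1L)
}

# Run `expr` under a local, seeded RNG without disturbing the caller's RNG
# state. All generators funnel through this.
with_stream_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
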