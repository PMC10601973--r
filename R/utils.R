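#' @keywords internal
"_PACKAGE"

# Round half away from zero at `digits` decimals. Base round() ties to even,
# which would print 0.125 as 0.12; report cells need 0.13-style rounding.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `expr` under a deterministic RNG sub-stream derived from a root
# seed and a vector of integer counters, leaving the caller's RNG state
# untouched. Splitting is by hashing, so streams keyed by (participant,
# trial) do not shift when other participants are added.
with_substream <- function(root_seed, counters, expr) {
  h <- as.double(root_seed %% 2147483647L)
  for (k in as.double(counters)) {
    h <- (h * 1103515245 + 12345 + k * 2654435761) %% 2147483647
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(h), kind = "Mersenne-Twister")
  expr
}

# Fixed-format numeric serialization so identical simulations produce
# byte-identical files on every platform.
fmt_num <- function(x, digits = 4) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out <- sub("\\.$", "", sub("0+$", "", out))
  out[is.na(x)] <- ""
  out
}
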