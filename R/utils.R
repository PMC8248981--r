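# internal helpers shared across modules

# single positive finite scalar
check_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    abort(sprintf("`%s` must be a finite %s number, got %s",
                  name, if (allow_zero) "non-negative" else "positive",
                  deparse(substitute(x))),
          class = "cdkflow_config_error")
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name),
          class = "cdkflow_config_error")
  }
  invisible(x)
}

# cylinder volume in fl (um^3) from radius and length in um
cylinder_volume <- function(radius_um, length_um) {
  pi * radius_um^2 * length_um
}

# seed the global RNG for one generator call, restoring the caller's stream
# when the calling function exits
use_substream <- function(seed, stream, envir = parent.frame()) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  if (is.null(old)) {
    do.call(on.exit, list(quote(rm(".Random.seed", envir = globalenv())),
                          add = TRUE), envir = envir)
  } else {
    do.call(on.exit,
            list(bquote(assign(".Random.seed", .(old), envir = globalenv())),
                 add = TRUE), envir = envir)
  }
  set.seed(substream_seed(seed, stream))
}

# derive a reproducible 32-bit sub-seed from a root seed and a stream label
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) + 1000003L * (h %% 1000L)) %% .Machine$integer.max
}

# centred moving average; window is forced odd, ends use shrunken windows
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
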