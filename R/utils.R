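# Small internal helpers.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of y over (possibly non-uniform) x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Strict local maxima of a vector over a centered window of `half` points on
# each side; ties never qualify. Returns integer indices.
local_maxima <- function(x, half = 2L) {
  n <- length(x)
  if (n < 2L * half + 1L) return(integer(0))
  idx <- integer(0)
  for (i in seq.int(half + 1L, n - half)) {
    win <- x[(i - half):(i + half)]
    if (x[i] > max(win[-(half + 1L)])) idx <- c(idx, i)
  }
  idx
}

# Centered running mean with edge shrinkage, used to stabilise tracer traces
# before local-maximum detection.
running_mean <- function(x, half = 1L) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Format doubles so that as.numeric() recovers them bit-exactly.
format_exact <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(structure(
    class = c("breathvoc_format_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
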