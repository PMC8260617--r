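# Internal helpers: seeded RNG streams and small numeric utilities.

# A private RNG stream. Draws advance the stream's own state and leave the
# caller's .Random.seed untouched, so independently seeded components stay
# reproducible no matter how they are interleaved.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  borrow <- function() {
    env$outer <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(as.integer(seed) %% .Machine$integer.max)
    else assign(".Random.seed", env$state, globalenv())
  }
  give_back <- function() {
    env$state <- get(".Random.seed", globalenv())
    if (is.null(env$outer)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", env$outer, globalenv())
  }
  wrap <- function(f) {
    force(f)
    function(...) {
      borrow()
      on.exit(give_back())
      f(...)
    }
  }
  list(runif  = wrap(stats::runif),
       rnorm  = wrap(stats::rnorm),
       rpois  = wrap(stats::rpois),
       sample = wrap(base::sample))
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483629)
}

.stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be positive", call. = FALSE)
  invisible(x)
}

# Rows of unit norm.
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Linear detrend of a vector (removes least-squares line).
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * (sum(t * x) / sum(t^2))
}

# Centered moving average of odd length with reflection padding at edges.
moving_average <- function(x, period) {
  if (period == 1L) return(x)
  h <- (period - 1L) %/% 2L
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[length(x) - seq_len(h)]))
  as.numeric(stats::filter(xp, rep(1 / period, period), sides = 2))[
    h + seq_along(x)]
}
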