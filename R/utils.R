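# internal numeric helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then restores
#' the previous global RNG state, so simulation functions are deterministic
#' without clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic per-cell sub-seed, kept below 2^31
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 1009 + 7919 * as.numeric(i)) %% 2147483647
}

# first time at which y crosses `level`, linearly interpolated.
# direction = "down": first crossing from above to <= level;
# direction = "up": first crossing from below to >= level.
# Returns NA if no crossing.
crossing_time <- function(t, y, level, direction = c("down", "up")) {
  direction <- match.arg(direction)
  hit <- if (direction == "down") y <= level else y >= level
  if (!any(hit)) return(NA_real_)
  i <- which(hit)[1L]
  if (i == 1L) return(t[1L])
  y0 <- y[i - 1L]; y1 <- y[i]
  if (y1 == y0) return(t[i])
  t[i - 1L] + (level - y0) / (y1 - y0) * (t[i] - t[i - 1L])
}

# trapezoidal integral of y over uniform spacing dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

odd_window <- function(k) {
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k + 1L else k
}
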