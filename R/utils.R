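# Seed scoping: every stochastic routine runs under its own seed and restores
# the caller's RNG state, so library generation, protocols and simulations are
# pure functions of their arguments.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed %% 2147483647L))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# deterministic per-participant / per-trial seed splitting (31-bit)
split_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

finite_diff_speed <- function(t, xy) {
  n <- length(t)
  if (n < 2L) stop("need >= 2 samples for a speed estimate", call. = FALSE)
  v <- numeric(n)
  # central differences at interior samples, one-sided at the ends
  dt_c <- t[3:n] - t[1:(n - 2L)]
  dxy <- xy[3:n, , drop = FALSE] - xy[1:(n - 2L), , drop = FALSE]
  v[2:(n - 1L)] <- sqrt(rowSums(dxy^2)) / dt_c
  v[1L] <- sqrt(sum((xy[2L, ] - xy[1L, ])^2)) / (t[2L] - t[1L])
  v[n] <- sqrt(sum((xy[n, ] - xy[n - 1L, ])^2)) / (t[n] - t[n - 1L])
  v
}

arc_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
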