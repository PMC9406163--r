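# Independent oracles and shared fixtures. Oracles use brute-force
# enumeration or generic numerical optimization and never call the package
# routines they check.

# exhaustive lag scan of the centered, globally normalized cross-correlation
brute_xcorr <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  n <- length(a)
  lags <- -(n - 1L):(n - 1L)
  vals <- vapply(lags, function(l) {
    j <- seq_len(n) + l
    ok <- j >= 1L & j <= n
    sum(a[ok] * b[j[ok]])
  }, numeric(1))
  list(value = max(vals) / sqrt(sum(a^2) * sum(b^2)),
       lag = lags[which.max(vals)])
}

# exhaustive enumeration of monotone warping paths (feasible up to ~6 points)
brute_dtw <- function(E, R) {
  cost <- function(i, j) sqrt(sum((E[i, ] - R[j, ])^2))
  rec <- function(i, j) {
    if (i == 1L && j == 1L) return(cost(1L, 1L))
    best <- Inf
    if (i > 1L) best <- min(best, rec(i - 1L, j))
    if (j > 1L) best <- min(best, rec(i, j - 1L))
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L))
    cost(i, j) + best
  }
  rec(nrow(E), nrow(R))
}

# numerical minimization of the similarity-superimposition residual over
# rotation angle, scale, translation and reflection; grid starts + Nelder-Mead
brute_procrustes_d <- function(E, R) {
  ss_e <- sum(sweep(E, 2L, colMeans(E))^2)
  obj <- function(par, mirror) {
    th <- par[1L]; b <- par[2L]; cx <- par[3L]; cy <- par[4L]
    Rm <- if (mirror) R %*% diag(c(1, -1)) else R
    Tr <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L)
    fit <- b * Rm %*% Tr
    sum((E[, 1L] - fit[, 1L] - cx)^2 + (E[, 2L] - fit[, 2L] - cy)^2)
  }
  best <- Inf
  for (mirror in c(FALSE, TRUE)) {
    for (th0 in seq(0, 2 * pi, length.out = 13L)[-13L]) {
      o <- stats::optim(c(th0, 1, 0, 0), obj, mirror = mirror,
                        control = list(maxit = 2000, reltol = 1e-14))
      best <- min(best, o$value)
    }
  }
  best / ss_e
}

# uniform arc-length resampling of a polyline
arc_resample <- function(xy, n) {
  seg <- sqrt(rowSums((xy[-1L, , drop = FALSE] -
                         xy[-nrow(xy), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  s <- seq(0, cs[length(cs)], length.out = n)
  cbind(approx(cs, xy[, 1L], xout = s)$y, approx(cs, xy[, 2L], xout = s)$y)
}

dist_to_polyline <- function(pts, path) {
  seg_a <- path[-nrow(path), , drop = FALSE]
  seg_b <- path[-1L, , drop = FALSE]
  apply(pts, 1L, function(p) {
    d <- Inf
    for (k in seq_len(nrow(seg_a))) {
      v <- seg_b[k, ] - seg_a[k, ]
      L2 <- sum(v^2)
      tt <- if (L2 == 0) 0 else max(0, min(1, sum((p - seg_a[k, ]) * v) / L2))
      d <- min(d, sum((p - seg_a[k, ] - tt * v)^2))
    }
    sqrt(d)
  })
}

make_shape <- function(vertices, id = "s1", label = "triangle") {
  structure(list(shape_id = id, n_vertices = nrow(vertices),
                 vertices = vertices, class_label = label),
            class = "sp_shape")
}

# a session whose reproduction is an exact copy of the exploration: the
# analytic fixed point of the scoring parameters
exact_copy_session <- function(library, spec, n_correct = NULL, seed = 3L) {
  prof <- participant_profile("healthy", scale_mean = 1, scale_sd = 0,
                              rotation_sd = 0, vertex_jitter_sd = 0,
                              path_noise_sd = 0, shape_confusion_prob = 0,
                              identification_error_prob = 0)
  ses <- simulate_session("H001", "passive", prof, spec, library, seed = seed)
  ses$trials <- lapply(ses$trials, function(tr) {
    tr$reproduction <- tr$exploration
    tr$reproduction$phase <- "reproduction"
    tr
  })
  if (!is.null(n_correct)) {
    for (i in seq_along(ses$trials)) {
      tr <- ses$trials[[i]]
      if (i > n_correct) {
        wrong <- setdiff(tr$plan$option_ids, tr$plan$shape_id)[1L]
        ses$trials[[i]]$identified_shape_id <- wrong
      } else {
        ses$trials[[i]]$identified_shape_id <- tr$plan$shape_id
      }
    }
  }
  ses
}

# one-factor table in the scoring parameter layout: oriented latent data are
# flipped back through the worse-is-higher sign convention for dtw/procrustes
one_factor_table <- function(n, lam, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  X <- vapply(seq_along(lam), function(i) {
    lam[i] * f + sqrt(1 - lam[i]^2) * rnorm(n)
  }, numeric(n))
  data.frame(xcorr_x = X[, 1], xcorr_y = X[, 2], dtw = -X[, 3],
             procrustes_d = -X[, 4], pct_identified = X[, 5])
}

# shared fixtures, computed once per run
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_library <- function() fixture("lib", generate_shape_library(seed = 42))

# coarse protocol for tests where millimetre-level sampling is irrelevant
quick_spec <- function(...) protocol_spec(sample_rate = 200, ...)

# the study-sized cohort under default profiles, used by the acceptance suite
default_cohort_table <- function() {
  fixture("cohort60_20", cohort_parameter_table(60, 20, seed = 1L))
}
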