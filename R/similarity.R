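as_path_matrix <- function(p) {
  if (inherits(p, "normalized_path")) return(cbind(p$x, p$y))
  if (is.matrix(p) && ncol(p) == 2L) return(p)
  stop("expected a normalized_path or a two-column matrix", call. = FALSE)
}

#' Normalized cross-correlation of two position signals
#'
#' Both signals are mean-centered, and the normalized cross-correlation
#' c(lag) = sum a(t) b(t+lag) / sqrt(sum a^2 * sum b^2) is evaluated over all
#' lags; the maximum is returned (its lag is attached as attribute `lag`).
#' With `lag = "zero"` only the zero-lag coefficient (the Pearson correlation)
#' is returned.
#'
#' @param a,b Equal-length numeric signals.
#' @param lag `"max"` (default) or `"zero"`.
#' @return Value in \[-1, 1\].
#' @export
cross_correlation <- function(a, b, lag = c("max", "zero")) {
  lag <- match.arg(lag)
  if (length(a) != length(b)) stop("signals must have equal length",
                                   call. = FALSE)
  if (length(a) < 2L) stop("signals must have length >= 2", call. = FALSE)
  a <- a - mean(a)
  b <- b - mean(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) stop("undefined correlation: constant signal",
                       call. = FALSE)
  if (lag == "zero") {
    return(sum(a * b) / denom)
  }
  # the open convolution of a with reversed b enumerates sum a(t) b(t+l)
  # for every lag l in -(n-1)..(n-1)
  cc <- stats::convolve(a, b, type = "open") / denom
  k <- which.max(cc)
  out <- cc[k]
  attr(out, "lag") <- length(b) - k
  out
}

#' Dynamic time warping distance between two paths
#'
#' Classic dynamic-programming alignment with Euclidean local cost (cm) and
#' the symmetric step set, no window; returns the accumulated cost along the
#' optimal warping path. Zero if and only if the sequences are equal after
#' collapsing consecutive duplicates.
#'
#' @param E,R `normalized_path` objects or two-column matrices (cm).
#' @return Non-negative accumulated distance (cm x samples).
#' @export
dtw_distance <- function(E, R) {
  e <- as_path_matrix(E)
  r <- as_path_matrix(R)
  if (nrow(e) < 1L || nrow(r) < 1L) stop("paths must have >= 1 point",
                                         call. = FALSE)
  dtw_distance_cpp(e[, 1L], e[, 2L], r[, 1L], r[, 2L])
}

#' Procrustes superimposition of a reproduction onto an exploration
#'
#' Finds the translation, rotation (reflection permitted) and scale that
#' optimally superimpose the reproduced path `R` onto the explored path `E`
#' in the least-squares sense, via the singular-value decomposition of the
#' centered cross-covariance. The dissimilarity `d` is the minimized residual
#' divided by the centered sum of squares of `E`, so it is invariant to any
#' similarity transform of either path; `scale` is the size of the
#' reproduction relative to the exploration (values above 1 mean the
#' reproduction was drawn too large).
#'
#' @param E,R Equal-length `normalized_path` objects or two-column matrices.
#' @return A `procrustes_result` with fields `d`, `scale`, `rotation`
#'   (degrees), `translation` (cm), `det` (sign of the fitted orthogonal
#'   transform; -1 marks a mirrored reproduction) and `b` (the fitted
#'   least-squares scale applied to `R`).
#' @export
procrustes_fit <- function(E, R) {
  e <- as_path_matrix(E)
  r <- as_path_matrix(R)
  if (nrow(e) != nrow(r)) stop("paths must have equal length", call. = FALSE)
  if (nrow(e) < 2L) stop("need >= 2 points", call. = FALSE)
  mu_e <- colMeans(e)
  mu_r <- colMeans(r)
  ec <- sweep(e, 2L, mu_e)
  rc <- sweep(r, 2L, mu_r)
  ss_e <- sum(ec^2)
  ss_r <- sum(rc^2)
  if (ss_e <= 1e-12 || ss_r <= 1e-12) {
    stop("degenerate configuration: zero-variance path", call. = FALSE)
  }
  M <- crossprod(rc, ec)            # 2x2 cross-covariance
  sv <- svd(M)
  Tm <- sv$u %*% t(sv$v)            # orthogonal map applied to R
  trace_s <- sum(sv$d)
  b <- trace_s / ss_r
  d <- 1 - trace_s^2 / (ss_e * ss_r)
  d <- max(d, 0)
  structure(list(
    d = d,
    scale = sqrt(ss_r / ss_e),
    b = b,
    rotation = atan2(Tm[1L, 2L], Tm[1L, 1L]) * 180 / pi,
    det = sign(det(Tm)),
    translation = as.numeric(mu_e - b * (mu_r %*% Tm))
  ), class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf(
    "Procrustes fit: d = %.4g, scale (R/E) = %.3f, rotation = %.1f deg%s\n",
    x$d, x$scale, x$rotation, if (x$det < 0) " (mirrored)" else ""))
  invisible(x)
}

score_trial <- function(trial, cfg, n_samples, xcorr_lag) {
  expl <- withCallingHandlers(
    segment_phase(trial$exploration, cfg),
    warning = function(w) invokeRestart("muffleWarning"))
  repr <- withCallingHandlers(
    segment_phase(trial$reproduction, cfg),
    warning = function(w) invokeRestart("muffleWarning"))
  E <- time_normalize(expl, n_samples)
  R <- time_normalize(repr, n_samples)
  pf <- procrustes_fit(E, R)
  list(xcorr_x = as.numeric(cross_correlation(E$x, R$x, lag = xcorr_lag)),
       xcorr_y = as.numeric(cross_correlation(E$y, R$y, lag = xcorr_lag)),
       dtw = dtw_distance(E, R),
       procrustes_d = pf$d,
       procrustes_scale = pf$scale)
}

#' Score one session into its parameter record
#'
#' Per trial, both phases are segmented and time-normalized, and the
#' reproduction-accuracy parameters (per-axis cross-correlation, dynamic time
#' warping, Procrustes dissimilarity and scale) are computed; identification
#' correctness and certainty are recorded. Trials whose segmentation fails are
#' dropped and counted; the session record holds the mean of each parameter
#' over the valid trials and the percentage of correctly identified shapes.
#'
#' @param session A `session`.
#' @param cfg A [segmentation_config()].
#' @param n_samples Time-normalization length (default 1000).
#' @param xcorr_lag Cross-correlation mode, `"max"` (default) or `"zero"`.
#' @return One-row `data.frame`: participant_id, group, condition, xcorr_x,
#'   xcorr_y, dtw, procrustes_d, procrustes_scale, pct_identified,
#'   certainty_mean, n_valid_trials.
#' @export
score_session <- function(session, cfg = segmentation_config(),
                          n_samples = 1000L, xcorr_lag = "max") {
  vals <- list()
  correct <- logical(0)
  certainty <- integer(0)
  for (trial in session$trials) {
    res <- tryCatch(score_trial(trial, cfg, n_samples, xcorr_lag),
                    error = function(e) NULL)
    if (is.null(res)) next
    vals[[length(vals) + 1L]] <- res
    correct <- c(correct, trial$identified_shape_id == trial$plan$shape_id)
    certainty <- c(certainty, trial$certainty)
  }
  if (length(vals) == 0L) {
    stop("no valid trials in session ", session$participant_id, call. = FALSE)
  }
  agg <- function(f) mean(vapply(vals, `[[`, numeric(1), f))
  data.frame(
    participant_id = session$participant_id,
    group = session$group,
    condition = session$condition,
    xcorr_x = agg("xcorr_x"),
    xcorr_y = agg("xcorr_y"),
    dtw = agg("dtw"),
    procrustes_d = agg("procrustes_d"),
    procrustes_scale = agg("procrustes_scale"),
    pct_identified = 100 * mean(correct),
    certainty_mean = mean(certainty),
    n_valid_trials = length(vals),
    stringsAsFactors = FALSE
  )
}

#' Score a list of sessions into a parameter table
#'
#' @param sessions List of `session` objects.
#' @inheritParams score_session
#' @return A `data.frame` with one row per session (participant x condition).
#' @export
score_sessions <- function(sessions, cfg = segmentation_config(),
                           n_samples = 1000L, xcorr_lag = "max") {
  do.call(rbind, lapply(sessions, score_session, cfg = cfg,
                        n_samples = n_samples, xcorr_lag = xcorr_lag))
}
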