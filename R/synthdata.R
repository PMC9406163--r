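#' Participant simulation profile
#'
#' Describes how a simulated participant distorts reproductions and errs at
#' identification. Group defaults encode the modelled cohorts: both groups
#' overestimate reproduction size by the same mean scale (1.41), while the
#' stroke profile carries larger rotation/jitter/path noise, more frequent
#' shape confusion and identification errors, and slightly lower answer
#' certainty. Self-paced exploration speed averages 0.04 m/s in both groups.
#'
#' @param group `"healthy"` or `"stroke"`; selects the default parameter set.
#' @param scale_mean,scale_sd Reproduction size ratio distribution (unitless).
#' @param rotation_sd SD of the reproduction rotation, degrees.
#' @param vertex_jitter_sd Per-vertex, per-coordinate jitter SD, cm.
#' @param path_noise_sd SD of smoothed along-path noise, cm.
#' @param smoothing_window Path-noise smoothing window, seconds.
#' @param shape_confusion_prob Probability of reproducing the wrong shape.
#' @param identification_error_prob Probability of a wrong identification on a
#'   correctly reproduced trial.
#' @param certainty_levels Probability vector over certainty ratings 0..3.
#' @param active_speed_mean,active_speed_sd Self-paced exploration speed, m/s.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(group = c("healthy", "stroke"),
                                scale_mean = 1.41,
                                scale_sd = NULL, rotation_sd = NULL,
                                vertex_jitter_sd = NULL, path_noise_sd = NULL,
                                smoothing_window = 0.1,
                                shape_confusion_prob = NULL,
                                identification_error_prob = NULL,
                                certainty_levels = NULL,
                                active_speed_mean = 0.04,
                                active_speed_sd = 0.01) {
  group <- match.arg(group)
  def <- if (group == "healthy") {
    list(scale_sd = 0.15, rotation_sd = 5, vertex_jitter_sd = 0.3,
         path_noise_sd = 0.15, shape_confusion_prob = 0.05,
         identification_error_prob = 0.35,
         certainty_levels = c(0.05, 0.15, 0.39, 0.41))
  } else {
    list(scale_sd = 0.20, rotation_sd = 9, vertex_jitter_sd = 0.6,
         path_noise_sd = 0.30, shape_confusion_prob = 0.15,
         identification_error_prob = 0.50,
         certainty_levels = c(0.08, 0.20, 0.37, 0.35))
  }
  p <- list(
    group = group, scale_mean = scale_mean,
    scale_sd = scale_sd %||% def$scale_sd,
    rotation_sd = rotation_sd %||% def$rotation_sd,
    vertex_jitter_sd = vertex_jitter_sd %||% def$vertex_jitter_sd,
    path_noise_sd = path_noise_sd %||% def$path_noise_sd,
    smoothing_window = smoothing_window,
    shape_confusion_prob = shape_confusion_prob %||% def$shape_confusion_prob,
    identification_error_prob =
      identification_error_prob %||% def$identification_error_prob,
    certainty_levels = certainty_levels %||% def$certainty_levels,
    active_speed_mean = active_speed_mean, active_speed_sd = active_speed_sd
  )
  class(p) <- "participant_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  sds <- c(p$scale_sd, p$rotation_sd, p$vertex_jitter_sd, p$path_noise_sd,
           p$active_speed_sd)
  if (any(sds < 0)) stop("profile SDs must be >= 0", call. = FALSE)
  probs <- c(p$shape_confusion_prob, p$identification_error_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]",
                                       call. = FALSE)
  if (length(p$certainty_levels) != 4L ||
      abs(sum(p$certainty_levels) - 1) > 1e-8 || any(p$certainty_levels < 0)) {
    stop("certainty_levels must be a probability vector over ratings 0..3",
         call. = FALSE)
  }
  if (p$scale_mean <= 0 || p$active_speed_mean <= 0) {
    stop("scale_mean and active_speed_mean must be positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.participant_profile <- function(x, ...) {
  cat("Participant profile (", x$group, "): scale ", x$scale_mean, " (SD ",
      x$scale_sd, "), rotation SD ", x$rotation_sd, " deg, jitter ",
      x$vertex_jitter_sd, " cm, P(confusion) ", x$shape_confusion_prob,
      ", P(id error) ", x$identification_error_prob, "\n", sep = "")
  invisible(x)
}

new_trajectory <- function(phase, t, x, y, truncated = FALSE) {
  stopifnot(length(t) >= 2L, all(diff(t) > 0),
            all(is.finite(t)), all(is.finite(x)), all(is.finite(y)))
  structure(list(phase = phase, t = t, x = x, y = y, truncated = truncated),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory (", x$phase, "): ", length(x$t), " samples over ",
      sprintf("%.2f", x$t[length(x$t)] - x$t[1L]), " s",
      if (isTRUE(x$truncated)) " [truncated]", "\n", sep = "")
  invisible(x)
}

# minimum-jerk position fraction and its peak-speed constant:
# f(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5, max f' = 1.875 at tau = 1/2
min_jerk_fraction <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# sample grid at the nominal rate plus the exact vertex-passage times, so the
# recorded polyline contains every corner and its chord length equals the
# true arc length
traversal_grid <- function(T_total, rate, corner_times) {
  t <- seq(0, T_total, by = 1 / rate)
  if (t[length(t)] < T_total) t <- c(t, T_total)
  ct <- corner_times[corner_times > 1e-9 & corner_times < T_total - 1e-9]
  t <- sort(c(t, ct))
  t[c(TRUE, diff(t) > 1e-9)]
}

# vertex-passage times of a minimum-jerk traversal: solve P f(t/T) = s_k
min_jerk_corner_times <- function(cum_s, P, T_total) {
  inner <- cum_s[cum_s > 1e-9 & cum_s < P - 1e-9]
  vapply(inner, function(sk) {
    T_total * stats::uniroot(function(tau) min_jerk_fraction(tau) - sk / P,
                             c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}

# linear interpolation of a polyline (cm) at arc positions s (cm)
path_at_arc <- function(path, s) {
  seg <- sqrt(rowSums((path[-1L, , drop = FALSE] -
                         path[-nrow(path), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cs[length(cs)])
  cbind(stats::approx(cs, path[, 1L], xout = s)$y,
        stats::approx(cs, path[, 2L], xout = s)$y)
}

#' Simulate the robot-driven (passive) exploration of a shape
#'
#' The robot traces the closed shape path with a bell-shaped (minimum-jerk)
#' speed profile. The traversal duration is set so the peak tangential speed
#' equals `spec$passive_peak_speed` (for a minimum-jerk profile the peak speed
#' is 1.875 P / T with P the perimeter), and speed is zero at both endpoints.
#'
#' @param shape A shape from the library.
#' @param spec A [protocol_spec()].
#' @return A `trajectory` (time in s, positions in m) sampled at
#'   `spec$sample_rate`.
#' @export
simulate_passive_exploration <- function(shape, spec = protocol_spec()) {
  path <- shape_path(shape)
  P_m <- shape_perimeter(shape) / 100
  if (P_m <= 0) stop("degenerate shape: zero perimeter", call. = FALSE)
  T_total <- 1.875 * P_m / spec$passive_peak_speed
  P_cm <- shape_perimeter(shape)
  cum_s <- c(0, cumsum(side_lengths(shape$vertices)))
  t <- traversal_grid(T_total, spec$sample_rate,
                      min_jerk_corner_times(cum_s, P_cm, T_total))
  s_cm <- P_cm * min_jerk_fraction(t / T_total)
  xy <- path_at_arc(path, s_cm) / 100
  new_trajectory("exploration", t, xy[, 1L], xy[, 2L])
}

# smoothed, endpoint-anchored lateral noise in cm; clipped if clip is finite
lateral_noise <- function(n, sd_cm, window_s, rate, clip = Inf) {
  if (sd_cm <= 0 || n < 3L) return(numeric(n))
  k <- max(1L, round(window_s * rate))
  raw <- stats::rnorm(n + 2L * k)
  sm <- stats::filter(raw, rep(1 / (2L * k + 1L), 2L * k + 1L), sides = 2L)
  sm <- as.numeric(sm[(k + 1L):(k + n)])
  sm[is.na(sm)] <- 0
  if (stats::sd(sm) > 0) sm <- sm / stats::sd(sm) * sd_cm
  ramp <- max(2L, round(0.2 * rate))
  env <- pmin(1, (seq_len(n) - 1L) / ramp, (n - seq_len(n)) / ramp)
  pmin(pmax(sm * env, -clip), clip)
}

# unit normals of a polyline at given arc positions
path_normals <- function(path, s) {
  seg <- path[-1L, , drop = FALSE] - path[-nrow(path), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  cs <- c(0, cumsum(len))
  idx <- pmin(findInterval(pmax(s, 0), cs, rightmost.closed = TRUE),
              nrow(seg))
  idx[idx < 1L] <- 1L
  tang <- seg[idx, , drop = FALSE] / len[idx]
  cbind(-tang[, 2L], tang[, 1L])
}

#' Simulate self-paced (active) exploration inside the haptic corridor
#'
#' The participant traverses the shape once at per-side speeds drawn from a
#' truncated normal distribution. The stiff virtual walls are represented
#' purely kinematically: lateral deviation from the shape boundary is clipped
#' to the zero-force corridor half-width. Trajectories exceeding the
#' exploration time limit are truncated and flagged.
#'
#' @param shape A shape.
#' @param profile A [participant_profile()].
#' @param spec A [protocol_spec()].
#' @param seed Integer seed for this trial.
#' @return A `trajectory` in meters.
#' @export
simulate_active_exploration <- function(shape, profile, spec = protocol_spec(),
                                        seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  path <- shape_path(shape)
  seg_cm <- side_lengths(shape$vertices)
  v <- stats::rnorm(length(seg_cm), profile$active_speed_mean,
                    profile$active_speed_sd)
  bad <- which(v <= 1e-3)
  while (length(bad) > 0L && profile$active_speed_sd > 0) {
    v[bad] <- stats::rnorm(length(bad), profile$active_speed_mean,
                           profile$active_speed_sd)
    bad <- which(v <= 1e-3)
  }
  v[v <= 1e-3] <- profile$active_speed_mean
  seg_t <- (seg_cm / 100) / v
  cum_t <- c(0, cumsum(seg_t))
  cum_s <- c(0, cumsum(seg_cm))
  T_total <- cum_t[length(cum_t)]
  truncated <- T_total > spec$active_time_limit
  T_end <- min(T_total, spec$active_time_limit)
  t <- traversal_grid(T_end, spec$sample_rate, cum_t)
  s_cm <- stats::approx(cum_t, cum_s, xout = t)$y
  base <- path_at_arc(path, s_cm)
  nrm <- path_normals(path, s_cm)
  dev <- lateral_noise(length(t), profile$path_noise_sd,
                       profile$smoothing_window, spec$sample_rate,
                       clip = spec$corridor_half_width)
  xy <- (base + nrm * dev) / 100
  new_trajectory("exploration", t, xy[, 1L], xy[, 2L], truncated = truncated)
}

#' Simulate the contralateral reproduction of an explored shape
#'
#' With probability `shape_confusion_prob` the participant reproduces a
#' different library shape. The (possibly confused) shape is distorted by a
#' similarity transform (random scale and rotation about the start point) and
#' per-vertex jitter, then traversed with a minimum-jerk profile within the
#' reproduction time limit, with smoothed path noise added away from the
#' anchored endpoints. The trajectory starts and ends at the start point.
#'
#' @param explored The explored shape.
#' @param profile A [participant_profile()].
#' @param spec A [protocol_spec()].
#' @param seed Integer seed for this trial.
#' @param library Optional `shape_library`; required for shape confusion.
#' @return A `trajectory` in meters, with attribute fields `confused` and
#'   `reproduced_shape_id` stored in the returned object.
#' @export
simulate_reproduction <- function(explored, profile, spec = protocol_spec(),
                                  seed = 1L, library = NULL) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  source_shape <- explored
  confused <- FALSE
  if (!is.null(library) && length(library) > 1L &&
      stats::runif(1) < profile$shape_confusion_prob) {
    confused <- TRUE
    others <- setdiff(names(library), explored$shape_id)
    source_shape <- library[[sample(others, 1L)]]
  }
  b <- stats::rnorm(1, profile$scale_mean, profile$scale_sd)
  while (b <= 0.05) b <- stats::rnorm(1, profile$scale_mean, profile$scale_sd)
  th <- stats::rnorm(1, 0, profile$rotation_sd) * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  v <- source_shape$vertices %*% t(R) * b
  if (profile$vertex_jitter_sd > 0 && nrow(v) > 1L) {
    # the start vertex stays anchored at the origin
    v[-1L, ] <- v[-1L, ] + matrix(stats::rnorm(2L * (nrow(v) - 1L), 0,
                                               profile$vertex_jitter_sd),
                                  ncol = 2L)
  }
  path <- rbind(v, v[1L, , drop = FALSE])
  P_cm <- arc_length(path)
  T_total <- min(1.875 * (P_cm / 100) / spec$reproduction_peak_speed,
                 spec$reproduction_time_limit)
  cum_sr <- c(0, cumsum(sqrt(rowSums((path[-1L, , drop = FALSE] -
                                        path[-nrow(path), , drop = FALSE])^2))))
  t <- traversal_grid(T_total, spec$sample_rate,
                      min_jerk_corner_times(cum_sr, P_cm, T_total))
  s_cm <- P_cm * min_jerk_fraction(t / T_total)
  base <- path_at_arc(path, s_cm)
  if (profile$path_noise_sd > 0) {
    nrm <- path_normals(path, s_cm)
    dev <- lateral_noise(length(t), profile$path_noise_sd,
                         profile$smoothing_window, spec$sample_rate)
    base <- base + nrm * dev
  }
  out <- new_trajectory("reproduction", t, base[, 1L] / 100, base[, 2L] / 100)
  out$confused <- confused
  out$reproduced_shape_id <- source_shape$shape_id
  out
}

#' Simulate the six-option identification response
#'
#' The true shape is chosen with probability `1 - identification_error_prob`,
#' reduced to a quarter of that when the trial's reproduction was
#' shape-confused. Erroneous answers pick a distractor with 2:1 weight in
#' favour of distractors of the same polygon class. Certainty is drawn from
#' the profile's rating distribution and shifted one level down with
#' probability 0.5 on erroneous answers.
#'
#' @param plan A trial plan from [build_protocol()].
#' @param reproduced_ok Logical; FALSE when the reproduction was confused.
#' @param profile A [participant_profile()].
#' @param seed Integer seed.
#' @param library The `shape_library` (for distractor class lookups).
#' @return List with `shape_id` (the answer) and `certainty` (0..3).
#' @export
simulate_identification <- function(plan, reproduced_ok, profile, seed = 1L,
                                    library = NULL) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  p_correct <- (1 - profile$identification_error_prob) *
    if (reproduced_ok) 1 else 0.25
  correct <- stats::runif(1) < p_correct
  if (correct) {
    answer <- plan$shape_id
  } else {
    distract <- setdiff(plan$option_ids, plan$shape_id)
    w <- rep(1, length(distract))
    if (!is.null(library)) {
      true_class <- library[[plan$shape_id]]$class_label
      same <- vapply(distract, function(id) {
        library[[id]]$class_label == true_class
      }, logical(1))
      w[same] <- 2
    }
    answer <- sample(distract, 1L, prob = w)
  }
  cert <- sample(0:3, 1L, prob = profile$certainty_levels)
  if (!correct && stats::runif(1) < 0.5) cert <- max(0L, cert - 1L)
  list(shape_id = answer, certainty = as.integer(cert))
}

# per-participant heterogeneity: a latent ability scales every noise source
# and shifts the error probabilities, inducing the shared variance that the
# one-factor analysis downstream is meant to recover
personalize_profile <- function(profile, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ability <- stats::rnorm(1)
  m <- exp(0.35 * (-ability))
  shift_logit <- function(p, d) stats::plogis(stats::qlogis(min(max(p, 1e-6),
                                                                1 - 1e-6)) + d)
  p <- profile
  p$rotation_sd <- profile$rotation_sd * m
  p$vertex_jitter_sd <- profile$vertex_jitter_sd * m
  p$path_noise_sd <- profile$path_noise_sd * m
  p$scale_sd <- profile$scale_sd * m
  p$scale_mean <- max(0.2, profile$scale_mean + 0.05 * stats::rnorm(1))
  p$identification_error_prob <-
    shift_logit(profile$identification_error_prob, -0.6 * ability)
  p$shape_confusion_prob <-
    shift_logit(profile$shape_confusion_prob, -0.6 * ability)
  p$active_speed_mean <- max(0.01, profile$active_speed_mean +
                               0.005 * stats::rnorm(1))
  p$ability <- ability
  p
}

#' Simulate one complete session (one participant, one condition)
#'
#' @param participant_id Character id.
#' @param condition `"passive"` or `"active"`.
#' @param profile A (possibly personalized) [participant_profile()].
#' @param spec A [protocol_spec()]; its `rng_seed` is re-derived per
#'   participant so shape orders differ across participants.
#' @param library A `shape_library`.
#' @param seed Integer participant seed; trial seeds are split from it by
#'   counter so the session is reproducible under any trial reordering.
#' @return An object of class `session`.
#' @export
simulate_session <- function(participant_id, condition, profile,
                             spec = protocol_spec(), library, seed = 1L) {
  pspec <- spec
  pspec$rng_seed <- split_seed(seed, 1L)
  plans <- build_protocol(library, pspec, condition)
  trials <- lapply(plans, function(plan) {
    shp <- library[[plan$shape_id]]
    tseed <- split_seed(seed, 2L, plan$trial_index)
    exploration <- if (condition == "passive") {
      simulate_passive_exploration(shp, spec)
    } else {
      simulate_active_exploration(shp, profile, spec, seed = tseed)
    }
    reproduction <- simulate_reproduction(shp, profile, spec,
                                          seed = split_seed(tseed, 3L),
                                          library = library)
    idresp <- simulate_identification(plan, !isTRUE(reproduction$confused),
                                      profile, seed = split_seed(tseed, 4L),
                                      library = library)
    list(plan = plan, exploration = exploration, reproduction = reproduction,
         identified_shape_id = idresp$shape_id, certainty = idresp$certainty)
  })
  structure(list(participant_id = participant_id, group = profile$group,
                 condition = condition, trials = trials, seed = seed),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  ok <- vapply(x$trials, function(tr) {
    tr$identified_shape_id == tr$plan$shape_id
  }, logical(1))
  cat("Session ", x$participant_id, " (", x$group, ", ", x$condition, "): ",
      length(x$trials), " trials, ", sum(ok), " identified correctly\n",
      sep = "")
  invisible(x)
}

#' Simulate a two-group cohort over both task conditions
#'
#' Per participant, noise parameters are jittered around the group defaults
#' through a latent ability (see the methods vignette), and one session per
#' condition is generated.
#'
#' @param n_healthy,n_stroke Group sizes.
#' @param healthy_profile,stroke_profile Group base profiles.
#' @param spec A [protocol_spec()].
#' @param library A `shape_library`; defaults to the seed-42 library.
#' @param seed Master seed.
#' @param conditions Conditions to simulate (default both).
#' @return A list of `session` objects (participants x conditions).
#' @export
simulate_cohort <- function(n_healthy, n_stroke,
                            healthy_profile = participant_profile("healthy"),
                            stroke_profile = participant_profile("stroke"),
                            spec = protocol_spec(),
                            library = generate_shape_library(),
                            seed = 1L,
                            conditions = c("passive", "active")) {
  stopifnot(n_healthy >= 0L, n_stroke >= 0L, n_healthy + n_stroke >= 1L)
  groups <- c(rep("healthy", n_healthy), rep("stroke", n_stroke))
  ids <- c(sprintf("H%03d", seq_len(n_healthy)),
           sprintf("S%03d", seq_len(n_stroke)))
  sessions <- list()
  for (i in seq_along(ids)) {
    base <- if (groups[i] == "healthy") healthy_profile else stroke_profile
    pseed <- split_seed(seed, 100L, i)
    prof <- personalize_profile(base, pseed)
    for (cond in conditions) {
      cseed <- split_seed(pseed, if (cond == "passive") 1L else 2L)
      sessions[[length(sessions) + 1L]] <-
        simulate_session(ids[i], cond, prof, spec, library, seed = cseed)
    }
  }
  sessions
}
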