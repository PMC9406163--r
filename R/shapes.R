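#' Protocol specification for one assessment condition
#'
#' Bundles the task-protocol constants: number of scored and practice trials,
#' number of on-screen identification options, phase time limits, the width of
#' the zero-force corridor used in the active condition, the peak speed of the
#' robot-driven (passive) traversal, and the position sample rate.
#'
#' @param n_trials Number of scored trials per condition (default 15).
#' @param n_practice Number of practice trials, generated but never scored
#'   (default 5).
#' @param n_options Number of shapes shown at identification (default 6).
#' @param reproduction_time_limit Reproduction phase limit, seconds (default 15).
#' @param active_time_limit Active exploration limit, seconds (default 30).
#' @param corridor_half_width Half-width of the zero-force corridor, cm
#'   (default 0.1, i.e. a 0.2 cm corridor).
#' @param passive_peak_speed Peak hand speed of the robot-driven traversal,
#'   m/s (default 0.67).
#' @param reproduction_peak_speed Peak hand speed assumed for the simulated
#'   reproduction traversal, m/s (default 0.25).
#' @param sample_rate Position sampling rate, Hz (default 1000).
#' @param rng_seed Integer seed attached to protocol randomization.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_trials = 15L, n_practice = 5L, n_options = 6L,
                          reproduction_time_limit = 15, active_time_limit = 30,
                          corridor_half_width = 0.1, passive_peak_speed = 0.67,
                          reproduction_peak_speed = 0.25,
                          sample_rate = 1000, rng_seed = 1L) {
  spec <- list(
    n_trials = as.integer(n_trials), n_practice = as.integer(n_practice),
    n_options = as.integer(n_options),
    reproduction_time_limit = reproduction_time_limit,
    active_time_limit = active_time_limit,
    corridor_half_width = corridor_half_width,
    passive_peak_speed = passive_peak_speed,
    reproduction_peak_speed = reproduction_peak_speed,
    sample_rate = sample_rate, rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "protocol_spec"
  validate_protocol_spec(spec)
  spec
}

validate_protocol_spec <- function(spec) {
  stopifnot(spec$n_trials >= 1L, spec$n_practice >= 1L, spec$n_options >= 2L)
  lims <- c(spec$reproduction_time_limit, spec$active_time_limit,
            spec$corridor_half_width, spec$passive_peak_speed,
            spec$reproduction_peak_speed, spec$sample_rate)
  if (any(!is.finite(lims)) || any(lims <= 0)) {
    stop("all protocol limits, speeds and rates must be positive", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Protocol: ", x$n_trials, " trials (+", x$n_practice, " practice), ",
      x$n_options, " identification options\n", sep = "")
  cat("  passive peak speed ", x$passive_peak_speed, " m/s, corridor +/-",
      x$corridor_half_width, " cm, ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

side_lengths <- function(vertices) {
  v2 <- rbind(vertices[-1L, , drop = FALSE], vertices[1L, , drop = FALSE])
  sqrt(rowSums((v2 - vertices)^2))
}

# segment-intersection test for the simple-polygon invariant; proper crossings
# only (shared endpoints of adjacent sides are fine)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(vertices) {
  n <- nrow(vertices)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1L], 1L)))
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent around the closure
      if (segments_cross(vertices[idx[i, 1L], ], vertices[idx[i, 2L], ],
                         vertices[idx[j, 1L], ], vertices[idx[j, 2L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

shape_is_valid <- function(shape, side_min, side_max, workspace_radius) {
  v <- shape$vertices
  if (any(abs(v[1L, ]) > 1e-12)) return("first vertex not at the start point")
  s <- side_lengths(v)
  if (any(s < side_min - 1e-9) || any(s > side_max + 1e-9)) {
    return("side length outside bounds")
  }
  if (any(sqrt(rowSums(v^2)) > workspace_radius + 1e-9)) {
    return("vertex outside workspace")
  }
  if (!polygon_is_simple(v)) return("polygon self-intersects")
  TRUE
}

new_shape <- function(shape_id, vertices, class_label) {
  structure(list(shape_id = shape_id, n_vertices = nrow(vertices),
                 vertices = vertices, class_label = class_label),
            class = "sp_shape")
}

#' @export
print.sp_shape <- function(x, ...) {
  cat("Shape ", x$shape_id, " (", x$class_label, "): sides ",
      paste(sprintf("%.2f", side_lengths(x$vertices)), collapse = ", "),
      " cm\n", sep = "")
  invisible(x)
}

# one candidate polygon: star-shaped around a sampled interior centre, then
# translated so the traversal start lies at the origin
random_polygon <- function(n, side_min, side_max, workspace_radius) {
  r_lo <- side_min / (2 * sin(pi / n)) * 0.8
  r_hi <- min(side_max / (2 * sin(pi / n)), workspace_radius / 2)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, r_lo, r_hi)
  v <- cbind(rad * cos(ang), rad * sin(ang))
  sweep(v, 2L, v[1L, ])
}

#' Generate a procedural polygon shape library
#'
#' Builds a library of simple polygons (triangles, tetragons, pentagons) by
#' seeded rejection sampling. Every shape starts at the origin of a
#' start-point-centered frame (the physical start point sits 20 cm in front of
#' the shoulder), every side length falls within the protocol bounds, the
#' polygon is simple, and all vertices stay inside the workspace.
#'
#' @param seed Integer RNG seed; the library is a pure function of its
#'   arguments.
#' @param n_per_class Shapes per polygon class (default 5, giving 15 shapes).
#' @param side_min,side_max Side-length bounds in cm (defaults 2.92 and 14.14).
#' @param workspace_radius Maximum vertex distance from the start point, cm.
#' @param max_rejections Rejection-sampling budget per shape before failing.
#' @return A list of shapes with class `shape_library`.
#' @examples
#' lib <- generate_shape_library(seed = 42)
#' range(unlist(lapply(lib, function(s) side_lengths_of(s))))
#' @export
generate_shape_library <- function(seed = 42L, n_per_class = 5L,
                                   side_min = 2.92, side_max = 14.14,
                                   workspace_radius = 25,
                                   max_rejections = 20000L) {
  if (!(side_min > 0 && side_min < side_max)) {
    stop("side bounds must satisfy 0 < side_min < side_max", call. = FALSE)
  }
  if (workspace_radius < side_min / (2 * sin(pi / 3))) {
    stop("workspace_radius too small to admit a minimum-side triangle",
         call. = FALSE)
  }
  old <- local_seed(as.integer(seed))
  on.exit(restore_seed(old), add = TRUE)
  classes <- c(triangle = 3L, tetragon = 4L, pentagon = 5L)
  lib <- list()
  k <- 0L
  for (cl in names(classes)) {
    n <- classes[[cl]]
    for (i in seq_len(n_per_class)) {
      ok <- FALSE
      last_reason <- "exhausted rejection budget"
      for (try in seq_len(max_rejections)) {
        v <- random_polygon(n, side_min, side_max, workspace_radius)
        k_try <- shape_is_valid(list(vertices = v), side_min, side_max,
                                workspace_radius)
        if (isTRUE(k_try)) { ok <- TRUE; break }
        last_reason <- k_try
      }
      if (!ok) {
        stop("shape generation failed (", last_reason, ") for class ", cl,
             call. = FALSE)
      }
      k <- k + 1L
      lib[[k]] <- new_shape(sprintf("%s_%02d", cl, i), v, cl)
    }
  }
  names(lib) <- vapply(lib, `[[`, "", "shape_id")
  attr(lib, "seed") <- as.integer(seed)
  attr(lib, "side_min") <- side_min
  attr(lib, "side_max") <- side_max
  attr(lib, "workspace_radius") <- workspace_radius
  class(lib) <- "shape_library"
  lib
}

#' @export
print.shape_library <- function(x, ...) {
  tab <- table(vapply(unclass(x), `[[`, "", "class_label"))
  cat("Shape library:", length(x), "shapes (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), seed",
      attr(x, "seed"), "\n")
  invisible(x)
}

#' Side lengths of a shape
#'
#' @param shape A shape from [generate_shape_library()].
#' @return Numeric vector of side lengths in cm (closed polygon).
#' @export
side_lengths_of <- function(shape) side_lengths(shape$vertices)

#' Closed traversal path of a shape
#'
#' Returns the vertex sequence closed back to the start point, the polyline
#' the robot (or the participant) traces.
#'
#' @param shape A shape.
#' @return Matrix of 2D points in cm; first row equals last row equals (0,0).
#' @export
shape_path <- function(shape) {
  rbind(shape$vertices, shape$vertices[1L, , drop = FALSE])
}

#' Perimeter of a shape (cm)
#' @param shape A shape.
#' @export
shape_perimeter <- function(shape) sum(side_lengths(shape$vertices))

#' Build the randomized trial protocol for one condition
#'
#' Draws a seeded random shape order (shapes repeat only when there are more
#' trials than library shapes) and, per trial, a seeded set of identification
#' options containing the explored shape exactly once.
#'
#' @param library A `shape_library`.
#' @param spec A [protocol_spec()].
#' @param condition `"passive"` or `"active"`.
#' @param practice Logical; build the (unscored) practice block instead.
#' @return A list of trial plans, each with `trial_index`, `shape_id`,
#'   `option_ids` and `condition`.
#' @export
build_protocol <- function(library, spec = protocol_spec(),
                           condition = c("passive", "active"),
                           practice = FALSE) {
  condition <- match.arg(condition)
  ids <- names(library)
  if (length(ids) < spec$n_options) {
    stop("library (", length(ids), " shapes) smaller than n_options (",
         spec$n_options, ")", call. = FALSE)
  }
  n <- if (practice) spec$n_practice else spec$n_trials
  seed <- spec$rng_seed + (if (condition == "active") 1L else 0L) +
    (if (practice) 10000L else 0L)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  order_ids <- if (n <= length(ids)) {
    sample(ids, n)
  } else {
    c(replicate(n %/% length(ids), sample(ids)),
      sample(ids, n %% length(ids)))
  }
  lapply(seq_len(n), function(i) {
    true_id <- order_ids[[i]]
    distract <- sample(setdiff(ids, true_id), spec$n_options - 1L)
    opts <- sample(c(true_id, distract))
    list(trial_index = i, shape_id = true_id, option_ids = opts,
         condition = condition, practice = practice)
  })
}
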