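fmt_num <- function(x) sprintf("%.9f", x)

trajectory_df <- function(trial_index, traj) {
  data.frame(trial_index = trial_index, phase = traj$phase,
             t_s = traj$t, x_m = traj$x, y_m = traj$y,
             stringsAsFactors = FALSE)
}

session_manifest <- function(session) {
  list(
    participant_id = session$participant_id,
    group = session$group,
    condition = session$condition,
    seed = session$seed,
    trials = lapply(session$trials, function(tr) {
      list(trial_index = tr$plan$trial_index,
           shape_id = tr$plan$shape_id,
           option_ids = tr$plan$option_ids,
           identified_shape_id = tr$identified_shape_id,
           certainty = tr$certainty,
           confused = isTRUE(tr$reproduction$confused),
           reproduced_shape_id = tr$reproduction$reproduced_shape_id %||%
             tr$plan$shape_id)
    })
  )
}

#' Write a session to disk
#'
#' Two layouts are supported. The bundled layout (default) writes a single
#' JSON document with the identification responses and the trajectory sample
#' arrays embedded. The directory layout writes a `session.json` manifest
#' plus one CSV per trajectory (columns `trial_index`, `phase`, `t_s`, `x_m`,
#' `y_m`). Both round-trip losslessly to 1e-9 m.
#'
#' @param session A `session`.
#' @param path File path (bundled) or directory path.
#' @param bundle Logical; write the single-file layout (default TRUE).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, bundle = TRUE) {
  man <- session_manifest(session)
  if (bundle) {
    man$trials <- lapply(seq_along(session$trials), function(i) {
      tr <- session$trials[[i]]
      m <- man$trials[[i]]
      m$exploration <- list(t_s = tr$exploration$t, x_m = tr$exploration$x,
                            y_m = tr$exploration$y)
      m$reproduction <- list(t_s = tr$reproduction$t, x_m = tr$reproduction$x,
                             y_m = tr$reproduction$y)
      m
    })
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(man, file.path(path, "session.json"),
                         auto_unbox = TRUE, digits = NA)
    for (tr in session$trials) {
      for (phase in c("exploration", "reproduction")) {
        df <- trajectory_df(tr$plan$trial_index, tr[[phase]])
        df$t_s <- fmt_num(df$t_s)
        df$x_m <- fmt_num(df$x_m)
        df$y_m <- fmt_num(df$y_m)
        utils::write.csv(df, file.path(path, sprintf("trial%02d_%s.csv",
                                                     tr$plan$trial_index,
                                                     phase)),
                         row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(path)
}

read_trajectory_csv <- function(file, phase) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("trial_index", "phase", "t_s", "x_m", "y_m")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop("trajectory file ", basename(file), " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("t_s", "x_m", "y_m")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("malformed value in ", basename(file), ", column ", col,
           ", line ", bad[1L] + 1L, call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(diff(df$t_s) <= 0)) {
    stop("non-monotone timestamps in ", basename(file), " at line ",
         which(diff(df$t_s) <= 0)[1L] + 2L, call. = FALSE)
  }
  new_trajectory(phase, df$t_s, df$x_m, df$y_m)
}

#' Read a session written by [write_session()]
#'
#' @param path Bundled JSON file or session directory.
#' @return A `session`.
#' @export
read_session <- function(path) {
  bundled <- !dir.exists(path)
  man <- jsonlite::read_json(if (bundled) path else
    file.path(path, "session.json"), simplifyVector = FALSE)
  for (f in c("participant_id", "group", "condition", "trials")) {
    if (is.null(man[[f]])) stop("session manifest lacks field ", f,
                                call. = FALSE)
  }
  trials <- lapply(man$trials, function(m) {
    opt <- unlist(m$option_ids)
    if (!m$identified_shape_id %in% opt) {
      stop("identified_shape_id not among option_ids for trial ",
           m$trial_index, call. = FALSE)
    }
    if (!m$certainty %in% 0:3) {
      stop("certainty outside 0..3 for trial ", m$trial_index, call. = FALSE)
    }
    grab <- function(phase) {
      if (bundled) {
        arr <- m[[phase]]
        tr <- new_trajectory(phase, unlist(arr$t_s), unlist(arr$x_m),
                             unlist(arr$y_m))
        if (any(diff(tr$t) <= 0)) {
          stop("non-monotone timestamps in trial ", m$trial_index,
               call. = FALSE)
        }
        tr
      } else {
        read_trajectory_csv(file.path(path, sprintf("trial%02d_%s.csv",
                                                    m$trial_index, phase)),
                            phase)
      }
    }
    repro <- grab("reproduction")
    repro$confused <- isTRUE(m$confused)
    repro$reproduced_shape_id <- m$reproduced_shape_id
    list(plan = list(trial_index = m$trial_index, shape_id = m$shape_id,
                     option_ids = opt, condition = man$condition),
         exploration = grab("exploration"), reproduction = repro,
         identified_shape_id = m$identified_shape_id,
         certainty = as.integer(m$certainty))
  })
  structure(list(participant_id = man$participant_id, group = man$group,
                 condition = man$condition, trials = trials,
                 seed = man$seed %||% NA_integer_),
            class = "session")
}

#' Write / read a shape library as JSON
#'
#' The document carries a header (seed and generation constraints) and one
#' record per shape with its id, class label and vertex list in cm.
#'
#' @param library A `shape_library`.
#' @param path JSON file path.
#' @return `path` invisibly / the `shape_library`.
#' @export
write_shape_library <- function(library, path) {
  doc <- list(
    header = list(seed = attr(library, "seed"),
                  side_min = attr(library, "side_min"),
                  side_max = attr(library, "side_max"),
                  workspace_radius = attr(library, "workspace_radius")),
    shapes = lapply(unclass(library), function(s) {
      list(shape_id = s$shape_id, class_label = s$class_label,
           vertices = apply(s$vertices, 1L, as.numeric, simplify = FALSE))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_library
#' @export
read_shape_library <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- lapply(doc$shapes, function(s) {
    v <- do.call(rbind, lapply(s$vertices, unlist))
    new_shape(s$shape_id, v, s$class_label)
  })
  names(lib) <- vapply(lib, `[[`, "", "shape_id")
  attr(lib, "seed") <- doc$header$seed
  attr(lib, "side_min") <- doc$header$side_min
  attr(lib, "side_max") <- doc$header$side_max
  attr(lib, "workspace_radius") <- doc$header$workspace_radius
  class(lib) <- "shape_library"
  lib
}

parameter_columns <- c("participant_id", "group", "condition", "xcorr_x",
                       "xcorr_y", "dtw", "procrustes_d", "procrustes_scale",
                       "pct_identified", "certainty_mean", "n_valid_trials")

#' Write / read the parameter table CSV
#'
#' One row per participant and condition, in the documented stable column
#' order (factor-score columns, when present, follow the core columns).
#'
#' @param table Parameter table.
#' @param path CSV path.
#' @export
write_parameter_table <- function(table, path) {
  extra <- setdiff(names(table), parameter_columns)
  utils::write.csv(table[, c(parameter_columns, extra)], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(parameter_columns, names(df))
  if (length(missing) > 0L) {
    stop("parameter table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write / read a fitted factor model as JSON
#' @param model A `factor_model`.
#' @param path JSON file path.
#' @export
write_factor_model <- function(model, path) {
  doc <- unclass(model)
  # named vectors go out as JSON objects so the names survive the round trip
  for (f in c("orientation", "loadings", "communalities", "healthy_means",
              "healthy_sds")) {
    doc[[f]] <- as.list(doc[[f]])
  }
  doc$correlation <- as.data.frame(model$correlation)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$correlation <- as.matrix(doc$correlation)
  rownames(doc$correlation) <- colnames(doc$correlation)
  for (f in c("orientation", "loadings", "communalities", "healthy_means",
              "healthy_sds")) {
    doc[[f]] <- unlist(doc[[f]])
  }
  structure(doc, class = "factor_model")
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with validated defaults.
#'
#' @param n_healthy,n_stroke Cohort sizes (defaults 60 and 20).
#' @param seed Master seed.
#' @param conditions Conditions to run (default both).
#' @param library_seed,n_per_class,side_min,side_max,workspace_radius Shape
#'   library arguments.
#' @param spec A [protocol_spec()].
#' @param segmentation A [segmentation_config()].
#' @param healthy_profile,stroke_profile Group base profiles.
#' @param n_samples Time-normalization length.
#' @param xcorr_lag Cross-correlation mode.
#' @param gamma Trimming/winsorizing proportion for the robust statistics.
#' @param confidence Confidence level for normative intervals.
#' @param output_dir Artifact directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_healthy = 60L, n_stroke = 20L, seed = 1L,
                            conditions = c("passive", "active"),
                            library_seed = 42L, n_per_class = 5L,
                            side_min = 2.92, side_max = 14.14,
                            workspace_radius = 25,
                            spec = protocol_spec(),
                            segmentation = segmentation_config(),
                            healthy_profile = participant_profile("healthy"),
                            stroke_profile = participant_profile("stroke"),
                            n_samples = 1000L, xcorr_lag = "max",
                            gamma = 0.2, confidence = 0.95,
                            output_dir = "sensproc_out") {
  stopifnot(n_healthy >= 0L, n_stroke >= 0L, n_healthy + n_stroke >= 1L,
            gamma >= 0, gamma < 0.5, confidence > 0, confidence < 1,
            n_samples >= 2L)
  conditions <- match.arg(conditions, c("passive", "active"),
                          several.ok = TRUE)
  cfg <- list(n_healthy = as.integer(n_healthy),
              n_stroke = as.integer(n_stroke), seed = as.integer(seed),
              conditions = conditions, library_seed = as.integer(library_seed),
              n_per_class = as.integer(n_per_class), side_min = side_min,
              side_max = side_max, workspace_radius = workspace_radius,
              spec = spec, segmentation = segmentation,
              healthy_profile = healthy_profile,
              stroke_profile = stroke_profile,
              n_samples = as.integer(n_samples), xcorr_lag = xcorr_lag,
              gamma = gamma, confidence = confidence,
              output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from JSON
#'
#' Scalar fields override the defaults of [pipeline_config()]; unknown keys
#' are rejected.
#'
#' @param path JSON file.
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("n_healthy", "n_stroke", "seed", "conditions", "library_seed",
               "n_per_class", "side_min", "side_max", "workspace_radius",
               "n_samples", "xcorr_lag", "gamma", "confidence", "output_dir")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, doc)
}

config_hash <- function(config) {
  flat <- jsonlite::toJSON(lapply(unclass(config), unclass),
                           auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(flat), f)
  unname(tools::md5sum(f))
}

#' Simulate and score a cohort, streaming one session at a time
#'
#' Identical simulation scheme to [simulate_cohort()] (same seeds, same
#' sessions) but each session is scored and discarded immediately, so cohorts
#' of arbitrary size fit in memory.
#'
#' @inheritParams simulate_cohort
#' @param cfg A [segmentation_config()].
#' @param n_samples,xcorr_lag Scoring options, see [score_session()].
#' @return Parameter table `data.frame`.
#' @export
cohort_parameter_table <- function(n_healthy, n_stroke,
                                   healthy_profile = participant_profile("healthy"),
                                   stroke_profile = participant_profile("stroke"),
                                   spec = protocol_spec(),
                                   library = generate_shape_library(),
                                   seed = 1L,
                                   conditions = c("passive", "active"),
                                   cfg = segmentation_config(),
                                   n_samples = 1000L, xcorr_lag = "max") {
  groups <- c(rep("healthy", n_healthy), rep("stroke", n_stroke))
  ids <- c(sprintf("H%03d", seq_len(n_healthy)),
           sprintf("S%03d", seq_len(n_stroke)))
  rows <- vector("list", length(ids) * length(conditions))
  k <- 0L
  for (i in seq_along(ids)) {
    base <- if (groups[i] == "healthy") healthy_profile else stroke_profile
    pseed <- split_seed(seed, 100L, i)
    prof <- personalize_profile(base, pseed)
    for (cond in conditions) {
      cseed <- split_seed(pseed, if (cond == "passive") 1L else 2L)
      ses <- simulate_session(ids[i], cond, prof, spec, library, seed = cseed)
      k <- k + 1L
      rows[[k]] <- score_session(ses, cfg, n_samples, xcorr_lag)
    }
  }
  do.call(rbind, rows)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates the configured cohort, scores every session, fits the one-factor
#' model per condition on the healthy rows, computes regression factor scores
#' for healthy participants and loading-weighted z scores for participants
#' with stroke, derives normative intervals and abnormality flags, and runs
#' the validation statistics (robust trimmed ANOVAs with classical
#' generalized-eta-squared companions, and factor-score group comparisons
#' with Hedges' g). All artifacts are written under `config$output_dir` with
#' a manifest recording the seed and a hash of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the parameter table, per-condition factor
#'   models, norms, flags and the stats report.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  existing <- file.path(out_dir, "manifest.json")
  if (file.exists(existing)) {
    old <- jsonlite::read_json(existing, simplifyVector = TRUE)
    if (!identical(old$config_hash, unname(hash))) {
      stop("output_dir holds artifacts from a different configuration ",
           "(hash mismatch); refusing to mix", call. = FALSE)
    }
  }

  say("stage simulate+score: ", config$n_healthy, " healthy + ",
      config$n_stroke, " stroke participants, conditions: ",
      paste(config$conditions, collapse = ", "))
  library <- generate_shape_library(config$library_seed, config$n_per_class,
                                    config$side_min, config$side_max,
                                    config$workspace_radius)
  write_shape_library(library, file.path(out_dir, "shape_library.json"))
  table <- cohort_parameter_table(
    config$n_healthy, config$n_stroke, config$healthy_profile,
    config$stroke_profile, config$spec, library, config$seed,
    config$conditions, config$segmentation, config$n_samples,
    config$xcorr_lag)
  say("  scored ", nrow(table), " sessions")

  models <- list(); norms <- list(); flags <- list()
  table$factor_score <- NA_real_
  for (cond in config$conditions) {
    say("stage factor (", cond, ")")
    hrows <- table$group == "healthy" & table$condition == cond
    srows <- table$group == "stroke" & table$condition == cond
    model <- fit_paf(table[hrows, ])
    models[[cond]] <- model
    write_factor_model(model, file.path(out_dir,
                                        paste0("factor_", cond, ".json")))
    hscores <- regression_factor_scores(model, table[hrows, ])
    table$factor_score[hrows] <- hscores
    nm <- compute_norms(table[hrows, ], hscores, config$confidence)
    norms[[cond]] <- nm
    utils::write.csv(as.data.frame(nm),
                     file.path(out_dir, paste0("norms_", cond, ".csv")),
                     row.names = FALSE)
    if (any(srows)) {
      table$factor_score[srows] <- weighted_z_factor_scores(model,
                                                            table[srows, ])
      fl <- flag_abnormal(nm, table[srows, ])
      flags[[cond]] <- data.frame(
        participant_id = table$participant_id[srows], fl,
        check.names = FALSE)
      utils::write.csv(flags[[cond]],
                       file.path(out_dir, paste0("flags_", cond, ".csv")),
                       row.names = FALSE)
    } else {
      say("  no stroke participants; skipping patient scores and flags")
    }
  }
  write_parameter_table(table, file.path(out_dir, "parameters.csv"))

  stats_report <- list()
  if (config$n_stroke > 0L && length(config$conditions) == 2L) {
    say("stage stats")
    long_of <- function(par) {
      data.frame(subject = table$participant_id, group = table$group,
                 condition = table$condition, value = table[[par]])
    }
    xl <- do.call(rbind, lapply(c("xcorr_x", "xcorr_y"), function(p) {
      d <- long_of(p)
      d$axis <- if (p == "xcorr_x") "X" else "Y"
      d
    }))
    stats_report$xcorr_anova <-
      bww_trim_anova(xl, gamma = config$gamma)
    stats_report$xcorr_eta2 <-
      split_plot_eta_squared(xl, within = c("condition", "axis"))
    for (par in c("dtw", "procrustes_d", "pct_identified",
                  "certainty_mean")) {
      d <- long_of(par)
      stats_report[[paste0(par, "_anova")]] <-
        bw_trim_anova(d, gamma = config$gamma)
      stats_report[[paste0(par, "_eta2")]] <- split_plot_eta_squared(d)
    }
    for (cond in config$conditions) {
      h <- table$factor_score[table$group == "healthy" &
                                table$condition == cond]
      s <- table$factor_score[table$group == "stroke" &
                                table$condition == cond]
      stats_report[[paste0("factor_", cond)]] <- group_comparison_t(h, s)
    }
    ser <- lapply(stats_report, function(x) {
      if (is.data.frame(x)) as.data.frame(x) else unclass(x)
    })
    jsonlite::write_json(ser, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  } else if (config$n_stroke == 0L) {
    say("stage stats skipped: no stroke group to compare")
  }

  manifest <- list(config_hash = unname(hash), seed = config$seed,
                   n_sessions = nrow(table),
                   conditions = config$conditions,
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  say("done: artifacts in ", out_dir)
  invisible(list(parameters = table, models = models, norms = norms,
                 flags = flags, stats = stats_report, manifest = manifest))
}
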