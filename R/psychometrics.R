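# The five parameters entering the one-factor model, with orientation signs:
# dtw and procrustes_d grow when performance worsens, so they are negated
# before factoring and the factor reads "higher = better ability".
factor_parameters <- function() {
  c(xcorr_x = 1, xcorr_y = 1, dtw = -1, procrustes_d = -1,
    pct_identified = 1)
}

oriented_matrix <- function(table, orientation = factor_parameters()) {
  pars <- names(orientation)
  missing <- setdiff(pars, names(table))
  if (length(missing) > 0L) {
    stop("parameter table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[, pars, drop = FALSE])
  sweep(X, 2L, orientation, `*`)
}

#' Fit the one-factor model by iterated principal-axis factoring
#'
#' Orients the five parameters so higher is better, standardizes them, and
#' runs iterated principal-axis factoring on their correlation matrix:
#' communalities start at the squared multiple correlations, and each
#' iteration eigendecomposes the reduced correlation matrix (communalities on
#' the diagonal), takes loadings as sqrt(largest eigenvalue) times the leading
#' eigenvector, and updates the communalities to the squared loadings, until
#' the largest communality change falls below `tol`. Loadings are sign-fixed
#' so their sum is positive.
#'
#' @param healthy_table Parameter table rows of the normative cohort.
#' @param tol Convergence tolerance on communalities (default 1e-6).
#' @param max_iter Iteration cap (default 200); non-convergence is flagged,
#'   not fatal.
#' @return An object of class `factor_model`: loadings, communalities,
#'   eigenvalues of the raw correlation matrix (for the scree check), the
#'   normative means/SDs of the oriented parameters, the correlation matrix,
#'   and convergence information.
#' @export
fit_paf <- function(healthy_table, tol = 1e-6, max_iter = 200L) {
  orientation <- factor_parameters()
  X <- oriented_matrix(healthy_table, orientation)
  if (nrow(X) < 10L) stop("need >= 10 normative rows to fit the factor model",
                          call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant parameter column: ", names(orientation)[sds == 0][1L],
         call. = FALSE)
  }
  R <- stats::cor(X)
  Rinv <- tryCatch(solve(R), error = function(e) {
    off <- abs(R); diag(off) <- 0
    pair <- which(off == max(off), arr.ind = TRUE)[1L, ]
    stop("singular correlation matrix (collinear pair: ",
         colnames(R)[pair[1L]], ", ", colnames(R)[pair[2L]], ")",
         call. = FALSE)
  })
  eig_raw <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  paf <- paf_correlation(R, smc = 1 - 1 / diag(Rinv), tol = tol,
                         max_iter = max_iter)
  loadings <- paf$loadings
  structure(list(
    parameter_names = names(orientation),
    orientation = orientation,
    loadings = loadings,
    communalities = loadings^2,
    eigenvalues = eig_raw,
    healthy_means = colMeans(X),
    healthy_sds = sds,
    correlation = R,
    converged = paf$converged,
    n_iterations = paf$n_iterations,
    n = nrow(X)
  ), class = "factor_model")
}

#' Iterated principal-axis factoring of a correlation matrix
#'
#' The one-factor iteration underlying [fit_paf()], exposed for direct use on
#' a correlation matrix: starting from the supplied communalities (squared
#' multiple correlations by default), repeatedly eigendecompose the reduced
#' correlation matrix, set loadings to sqrt(largest eigenvalue) times the
#' leading eigenvector, and update communalities to the squared loadings.
#'
#' @param R Positive-definite correlation matrix.
#' @param smc Initial communalities (default: squared multiple correlations).
#' @param tol Convergence tolerance on communalities.
#' @param max_iter Iteration cap.
#' @return List with `loadings` (sign-fixed so their sum is positive),
#'   `communalities`, `converged`, `n_iterations`.
#' @export
paf_correlation <- function(R, smc = NULL, tol = 1e-6, max_iter = 200L) {
  if (is.null(smc)) smc <- 1 - 1 / diag(solve(R))
  h2 <- smc
  converged <- FALSE
  iter <- 0L
  loadings <- rep(0, ncol(R))
  repeat {
    iter <- iter + 1L
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- sqrt(max(e$values[1L], 0)) * e$vectors[, 1L]
    h2_new <- pmin(lam^2, 1)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    loadings <- lam
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (sum(loadings) < 0) loadings <- -loadings
  names(loadings) <- colnames(R)
  list(loadings = loadings, communalities = loadings^2,
       converged = converged, n_iterations = iter)
}

#' @export
print.factor_model <- function(x, ...) {
  cat("One-factor model (principal-axis factoring, n =", x$n, ")\n")
  print(round(rbind(loading = x$loadings, communality = x$communalities), 3))
  cat("raw-correlation eigenvalues:",
      paste(sprintf("%.2f", x$eigenvalues), collapse = ", "), "\n")
  if (!x$converged) cat("WARNING: communalities did not converge\n")
  invisible(x)
}

#' Regression-method factor scores for the normative cohort
#'
#' Scores are Z R^-1 lambda with Z the oriented, standardized parameter
#' matrix of the fitting cohort, R its correlation matrix and lambda the
#' loadings. By construction the scores have mean zero over the fitting
#' cohort and variance lambda' R^-1 lambda (at most 1).
#'
#' @param model A `factor_model`.
#' @param healthy_table The table the model was fitted on (or any table
#'   standardized against the model's normative constants).
#' @return Numeric vector of factor scores.
#' @export
regression_factor_scores <- function(model, healthy_table) {
  X <- oriented_matrix(healthy_table, model$orientation)
  Z <- sweep(sweep(X, 2L, model$healthy_means), 2L, model$healthy_sds, `/`)
  as.numeric(Z %*% solve(model$correlation, model$loadings))
}

#' Loading-weighted z factor scores for patients
#'
#' Each parameter is oriented and standardized against the normative cohort's
#' mean and SD; the score is the loading-weighted mean of these z-scores
#' (weights = the factor loadings, divided by their sum). Zero equals mean
#' normative performance; negative scores mean worse-than-normal performance.
#'
#' @param model A `factor_model` carrying the normative constants.
#' @param patient_table Parameter table rows to score.
#' @return Numeric vector of factor scores.
#' @export
weighted_z_factor_scores <- function(model, patient_table) {
  X <- oriented_matrix(patient_table, model$orientation)
  Z <- sweep(sweep(X, 2L, model$healthy_means), 2L, model$healthy_sds, `/`)
  as.numeric(Z %*% model$loadings / sum(model$loadings))
}

#' Normative means and confidence intervals
#'
#' Per parameter (raw scale) and for the factor score: the normative mean, SD
#' and the t-based confidence interval of the mean, plus the direction in
#' which performance is worse.
#'
#' @param healthy_table Normative parameter table.
#' @param factor_scores Factor scores of the same rows (regression method).
#' @param confidence Confidence level (default 0.95).
#' @return A `data.frame` of class `cohort_norms` with columns parameter,
#'   mean, sd, ci_low, ci_high, n, worse_direction.
#' @export
compute_norms <- function(healthy_table, factor_scores,
                          confidence = 0.95) {
  cols <- c("xcorr_x", "xcorr_y", "dtw", "procrustes_d", "pct_identified")
  worse <- c(xcorr_x = "low", xcorr_y = "low", dtw = "high",
             procrustes_d = "high", pct_identified = "low",
             factor_score = "low")
  vals <- c(lapply(cols, function(p) healthy_table[[p]]),
            list(factor_scores))
  names(vals) <- c(cols, "factor_score")
  rows <- lapply(names(vals), function(p) {
    x <- vals[[p]]
    n <- length(x)
    if (n < 3L) stop("need n >= 3 for normative intervals", call. = FALSE)
    m <- mean(x)
    s <- stats::sd(x)
    half <- stats::qt((1 + confidence) / 2, df = n - 1L) * s / sqrt(n)
    data.frame(parameter = p, mean = m, sd = s, ci_low = m - half,
               ci_high = m + half, n = n, worse_direction = worse[[p]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_norms", "data.frame")
  attr(out, "confidence") <- confidence
  out
}

#' Flag abnormal performance against normative intervals
#'
#' A value is flagged when it falls outside the normative confidence interval
#' on the worse side only: below `ci_low` where lower is worse, above
#' `ci_high` where higher is worse.
#'
#' @param norms A `cohort_norms` table.
#' @param record A one-row parameter record (with `factor_score` column) or a
#'   multi-row table.
#' @return Logical matrix (rows = records, columns = parameters).
#' @export
flag_abnormal <- function(norms, record) {
  flags <- sapply(seq_len(nrow(norms)), function(i) {
    p <- norms$parameter[i]
    if (!p %in% names(record)) {
      stop("record lacks column ", p, call. = FALSE)
    }
    v <- record[[p]]
    if (norms$worse_direction[i] == "low") v < norms$ci_low[i]
    else v > norms$ci_high[i]
  })
  flags <- matrix(flags, nrow = nrow(as.data.frame(record)),
                  dimnames = list(NULL, norms$parameter))
  flags
}
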