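#' Trimmed mean
#'
#' Drops `floor(gamma * n)` observations from each tail and averages the rest.
#'
#' @param x Numeric sample.
#' @param gamma Trimming proportion in \[0, 0.5).
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(x, gamma = 0.2) {
  stopifnot(gamma >= 0, gamma < 0.5)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1L) stop("empty sample", call. = FALSE)
  g <- floor(gamma * n)
  if (n - 2L * g < 1L) stop("no observations left after trimming",
                            call. = FALSE)
  xs <- sort(x)
  mean(xs[(g + 1L):(n - g)])
}

winsorize <- function(x, gamma = 0.2) {
  n <- length(x)
  g <- floor(gamma * n)
  if (g == 0L) return(x)
  xs <- sort(x)
  lo <- xs[g + 1L]
  hi <- xs[n - g]
  pmin(pmax(x, lo), hi)
}

label_strength <- function(r) {
  a <- abs(r)
  if (a < 0.30) "negligible" else if (a < 0.50) "low"
  else if (a <= 0.70) "moderate" else "high"
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' CI = tanh(atanh(r) +/- z_crit / sqrt(n - 3)).
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs.
#' @param confidence Confidence level (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
fisher_z_ci <- function(r, n, confidence = 0.95) {
  zc <- stats::qnorm((1 + confidence) / 2)
  tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
}

#' Winsorized correlation with Fisher-z confidence interval
#'
#' Winsorizes each variable marginally (each tail's `floor(gamma * n)`
#' extremes are replaced by the adjacent retained value), computes the Pearson
#' correlation of the winsorized pairs, tests it with
#' T = r_w sqrt((n-2)/(1-r_w^2)) on n - 2g - 2 degrees of freedom, and builds
#' the confidence interval by the Fisher z' transformation with n pairs.
#' Strength labels use the 0.30 / 0.50 / 0.70 convention.
#'
#' @param x,y Paired numeric samples.
#' @param gamma Winsorization proportion per tail (default 0.2).
#' @param confidence Confidence level (default 0.95).
#' @return An object of class `wincor_result`: `r_w`, `n`, `gamma`, `ci_low`,
#'   `ci_high`, `statistic`, `df`, `p`, `strength_label`.
#' @export
winsorized_correlation <- function(x, y, gamma = 0.2, confidence = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  g <- floor(gamma * n)
  if (n < 2L * g + 3L) stop("need n >= 2g + 3 pairs", call. = FALSE)
  xw <- winsorize(x, gamma)
  yw <- winsorize(y, gamma)
  if (stats::sd(xw) == 0 || stats::sd(yw) == 0) {
    stop("zero winsorized variance", call. = FALSE)
  }
  r <- stats::cor(xw, yw)
  Tstat <- r * sqrt((n - 2) / (1 - r^2))
  df <- n - 2L * g - 2L
  p <- 2 * stats::pt(-abs(Tstat), df)
  ci <- fisher_z_ci(r, n, confidence)
  structure(list(r_w = r, n = n, gamma = gamma, ci_low = ci[1L],
                 ci_high = ci[2L], statistic = Tstat, df = df, p = p,
                 strength_label = label_strength(r)),
            class = "wincor_result")
}

#' @export
print.wincor_result <- function(x, ...) {
  cat(sprintf("Winsorized correlation (gamma = %.2f): r_w = %.2f (%.2f %.2f), n = %d, p = %.3f [%s]\n",
              x$gamma, x$r_w, x$ci_low, x$ci_high, x$n, x$p,
              x$strength_label))
  invisible(x)
}

# Johansen-type approximate-df test of C mu = 0 given trimmed-mean estimates,
# a block-diagonal covariance V of those estimates, and per-group effective
# sizes h_j; blocks[[j]] gives the index set of group j inside mu.
johansen_test <- function(C, mu, V, h, blocks) {
  C <- matrix(C, ncol = length(mu))
  q <- nrow(C)
  CVC <- C %*% V %*% t(C)
  inv <- solve(CVC)
  Q <- as.numeric(t(C %*% mu) %*% inv %*% (C %*% mu))
  Rm <- V %*% t(C) %*% inv %*% C
  A <- 0
  for (j in seq_along(h)) {
    Qj <- matrix(0, length(mu), length(mu))
    diag(Qj)[blocks[[j]]] <- 1
    M <- Rm %*% Qj
    A <- A + (sum(diag(M %*% M)) + sum(diag(M))^2) / (h[j] - 1)
  }
  A <- A / 2
  cval <- q + 2 * A - 6 * A / (q + 2)
  Fstat <- Q / cval
  df2 <- if (A > 1e-12) q * (q + 2) / (3 * A) else Inf
  p <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  list(Q = Fstat, df1 = q, df2 = df2, p = p)
}

# wide per-group matrices (subjects x within-cells) from a long table
split_plot_wide <- function(data, value, between, within, subject) {
  data <- as.data.frame(data)
  req <- c(value, between, subject, within)
  missing <- setdiff(req, names(data))
  if (length(missing) > 0L) {
    stop("data lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cells <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  cell_levels <- levels(cells)
  groups <- unique(as.character(data[[between]]))
  out <- list()
  for (gname in groups) {
    sub <- data[data[[between]] == gname, ]
    subs <- unique(as.character(sub[[subject]]))
    W <- matrix(NA_real_, length(subs), length(cell_levels),
                dimnames = list(subs, cell_levels))
    cc <- as.character(interaction(sub[within], drop = FALSE,
                                   lex.order = TRUE))
    for (i in seq_len(nrow(sub))) {
      W[as.character(sub[[subject]][i]), cc[i]] <- sub[[value]][i]
    }
    if (anyNA(W)) {
      bad <- rownames(W)[which(rowSums(is.na(W)) > 0)][1L]
      stop("subject ", bad, " lacks a value for some within-cell",
           call. = FALSE)
    }
    out[[gname]] <- W
  }
  out
}

# trimmed cell means, Winsorized covariance of the trimmed means, and the
# Johansen tests for each contrast of a between x within design
trim_split_plot_engine <- function(wide, contrasts, gamma) {
  J <- length(wide)
  K <- ncol(wide[[1L]])
  mu <- numeric(0)
  V_blocks <- list()
  h <- numeric(J)
  blocks <- list()
  pos <- 0L
  for (j in seq_len(J)) {
    W <- wide[[j]]
    n_j <- nrow(W)
    g_j <- floor(gamma * n_j)
    h[j] <- n_j - 2L * g_j
    if (h[j] < 2L) stop("group ", names(wide)[j],
                        " too small after trimming", call. = FALSE)
    mu <- c(mu, apply(W, 2L, trimmed_mean, gamma = gamma))
    Wwin <- apply(W, 2L, winsorize, gamma = gamma)
    Sw <- stats::cov(Wwin)
    V_blocks[[j]] <- (n_j - 1) * Sw / (h[j] * (h[j] - 1))
    blocks[[j]] <- pos + seq_len(K)
    pos <- pos + K
  }
  V <- matrix(0, J * K, J * K)
  for (j in seq_len(J)) V[blocks[[j]], blocks[[j]]] <- V_blocks[[j]]
  res <- lapply(contrasts, johansen_test, mu = mu, V = V, h = h,
                blocks = blocks)
  out <- do.call(rbind, lapply(names(res), function(e) {
    data.frame(effect = e, Q = res[[e]]$Q, df1 = res[[e]]$df1,
               df2 = res[[e]]$df2, p = res[[e]]$p, stringsAsFactors = FALSE)
  }))
  attr(out, "trimmed_means") <- mu
  out
}

between_contrast_rows <- function(J) {
  # successive-difference contrasts spanning the between main effect
  C <- matrix(0, J - 1L, J)
  for (i in seq_len(J - 1L)) { C[i, i] <- 1; C[i, i + 1L] <- -1 }
  C
}

#' Robust between-within (split-plot) ANOVA on trimmed means
#'
#' Johansen-type tests on 20% trimmed cell means with Winsorized covariance
#' estimates, for a design with one between-subject factor and one
#' within-subject factor: the robust analogue of a two-way split-plot ANOVA.
#'
#' @param data Long-format data frame.
#' @param value,between,within,subject Column names.
#' @param gamma Trimming proportion (default 0.2).
#' @return A `robust_anova` data frame with one row per effect (`between`,
#'   `within`, `between:within`): Q (F-like statistic), df1, df2, p.
#' @export
bw_trim_anova <- function(data, value = "value", between = "group",
                          within = "condition", subject = "subject",
                          gamma = 0.2) {
  wide <- split_plot_wide(data, value, between, within, subject)
  J <- length(wide)
  K <- ncol(wide[[1L]])
  if (J < 2L) stop("need >= 2 between-subject groups", call. = FALSE)
  CJ <- between_contrast_rows(J)
  CK <- between_contrast_rows(K)
  oneJ <- matrix(1 / J, 1L, J)
  oneK <- matrix(1 / K, 1L, K)
  contrasts <- list(
    between = kronecker(CJ, oneK),
    within = kronecker(oneJ, CK),
    `between:within` = kronecker(CJ, CK)
  )
  out <- trim_split_plot_engine(wide, contrasts, gamma)
  attr(out, "gamma") <- gamma
  class(out) <- c("robust_anova", "data.frame")
  out
}

#' Robust between-within-within ANOVA on trimmed means
#'
#' Extension of [bw_trim_anova()] to one between-subject factor and two
#' crossed within-subject factors; returns all seven effects.
#'
#' @param data Long-format data frame.
#' @param value,between,within1,within2,subject Column names.
#' @param gamma Trimming proportion (default 0.2).
#' @return A `robust_anova` data frame with rows `between`, `within1`,
#'   `within2`, `between:within1`, `between:within2`, `within1:within2`,
#'   `between:within1:within2`.
#' @export
bww_trim_anova <- function(data, value = "value", between = "group",
                           within1 = "condition", within2 = "axis",
                           subject = "subject", gamma = 0.2) {
  wide <- split_plot_wide(data, value, between, c(within1, within2), subject)
  J <- length(wide)
  if (J < 2L) stop("need >= 2 between-subject groups", call. = FALSE)
  K1 <- length(unique(as.data.frame(data)[[within1]]))
  K2 <- length(unique(as.data.frame(data)[[within2]]))
  if (ncol(wide[[1L]]) != K1 * K2) {
    stop("incomplete within-cells", call. = FALSE)
  }
  CJ <- between_contrast_rows(J)
  C1 <- between_contrast_rows(K1)
  C2 <- between_contrast_rows(K2)
  oneJ <- matrix(1 / J, 1L, J)
  one1 <- matrix(1 / K1, 1L, K1)
  one2 <- matrix(1 / K2, 1L, K2)
  contrasts <- list(
    between = kronecker(CJ, kronecker(one1, one2)),
    within1 = kronecker(oneJ, kronecker(C1, one2)),
    within2 = kronecker(oneJ, kronecker(one1, C2)),
    `between:within1` = kronecker(CJ, kronecker(C1, one2)),
    `between:within2` = kronecker(CJ, kronecker(one1, C2)),
    `within1:within2` = kronecker(oneJ, kronecker(C1, C2)),
    `between:within1:within2` = kronecker(CJ, kronecker(C1, C2))
  )
  out <- trim_split_plot_engine(wide, contrasts, gamma)
  attr(out, "gamma") <- gamma
  class(out) <- c("robust_anova", "data.frame")
  out
}

#' @export
print.robust_anova <- function(x, ...) {
  cat("Robust trimmed-mean ANOVA (gamma =", attr(x, "gamma"), ")\n")
  df <- as.data.frame(x)
  df$Q <- round(df$Q, 3)
  df$df2 <- round(df$df2, 1)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Independent-samples comparison with Hedges' g
#'
#' Pooled-variance two-sided t-test plus the bias-corrected standardized mean
#' difference g = (mean_x - mean_y) / s_pooled * J, with
#' J = 1 - 3 / (4 (n_x + n_y - 2) - 1).
#'
#' @param x,y Independent numeric samples.
#' @return An `effect_size` list: `g`, `t`, `df`, `p`, `mean_diff`.
#' @export
group_comparison_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("need >= 2 observations per group",
                               call. = FALSE)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  Jc <- 1 - 3 / (4 * (nx + ny - 2) - 1)
  g <- (mean(x) - mean(y)) / sqrt(sp2) * Jc
  structure(list(g = g, t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(x) - mean(y)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("t(%g) = %.2f, p = %.3f, Hedges' g = %.2f\n",
              x$df, x$t, x$p, x$g))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Generalized eta squared from a sums-of-squares decomposition
#'
#' eta^2_G = SS_effect / (SS_effect + sum of all error/subject-variance SS),
#' the Olejnik-Algina formulation for designs in which all factors are
#' manipulated.
#'
#' @param ss_effect Effect sum of squares.
#' @param ss_errors Numeric vector of all error-term sums of squares.
#' @return Value in \[0, 1\].
#' @export
generalized_eta_squared <- function(ss_effect, ss_errors) {
  if (ss_effect < 0 || any(ss_errors < 0)) {
    stop("sums of squares must be non-negative", call. = FALSE)
  }
  denom <- ss_effect + sum(ss_errors)
  if (denom <= 0) stop("zero denominator", call. = FALSE)
  ss_effect / denom
}

#' Classical split-plot decomposition with generalized eta squared
#'
#' Fits the classical (untrimmed) split-plot ANOVA with `aov` error strata
#' and returns each effect's SS together with eta^2_G computed against the
#' pooled error terms of all strata. Companion effect sizes for the robust
#' trimmed tests, which do not decompose into sums of squares.
#'
#' @param data Long-format data frame.
#' @param value,between,within,subject Column names; `within` may name one or
#'   two columns.
#' @return Data frame with columns effect, ss, eta2_g.
#' @export
split_plot_eta_squared <- function(data, value = "value", between = "group",
                                   within = "condition",
                                   subject = "subject") {
  d <- as.data.frame(data)
  d$.y <- d[[value]]
  d$.g <- factor(d[[between]])
  d$.s <- factor(d[[subject]])
  wn <- paste0(".w", seq_along(within))
  for (i in seq_along(within)) d[[wn[i]]] <- factor(d[[within[i]]])
  wterm <- paste(wn, collapse = "*")
  fml <- stats::as.formula(paste0(".y ~ .g*", wterm,
                                  " + Error(.s/(", wterm, "))"))
  fit <- stats::aov(fml, data = d)
  ss_eff <- c(); ss_err <- c()
  for (stratum in summary(fit)) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") {
        ss_err <- c(ss_err, tab[i, "Sum Sq"])
      } else {
        ss_eff[terms[i]] <- tab[i, "Sum Sq"]
      }
    }
  }
  pretty <- names(ss_eff)
  pretty <- gsub("\\.g", between, pretty)
  for (i in seq_along(within)) {
    pretty <- gsub(paste0("\\.w", i), within[i], pretty)
  }
  data.frame(effect = pretty, ss = unname(ss_eff),
             eta2_g = vapply(ss_eff, generalized_eta_squared,
                             numeric(1), ss_errors = ss_err),
             stringsAsFactors = FALSE, row.names = NULL)
}
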