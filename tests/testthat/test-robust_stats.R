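test_that("trimmed mean drops the stated tails and keeps equivariance", {
  expect_equal(trimmed_mean(1:10, 0.2), 5.5)   # g = 2, mean of 3..8
  x <- rnorm(37)
  expect_equal(trimmed_mean(x, 0), mean(x))
  expect_equal(trimmed_mean(rep(4.2, 9), 0.2), 4.2)
  expect_equal(trimmed_mean(3 * x + 1, 0.2), 3 * trimmed_mean(x, 0.2) + 1)
  # breakdown: making an already-trimmed value more extreme changes nothing
  y <- 1:10
  y[10] <- 1e6
  expect_equal(trimmed_mean(y, 0.2), 5.5)
})

test_that("winsorized correlation matches a hand-winsorized Pearson oracle", {
  set.seed(41)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 50)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 30, 9)
  g <- 2L                                     # floor(0.2 * 10)
  xs <- sort(x); ys <- sort(y)
  xw <- pmin(pmax(x, xs[g + 1L]), xs[10L - g])
  yw <- pmin(pmax(y, ys[g + 1L]), ys[10L - g])
  got <- winsorized_correlation(x, y, gamma = 0.2)
  expect_equal(got$r_w, cor(xw, yw))
  expect_equal(got$df, 10L - 2L * g - 2L)

  a <- rnorm(25); b <- rnorm(25)
  expect_equal(winsorized_correlation(a, b, gamma = 0)$r_w, cor(a, b))
})

test_that("winsorized correlation is invariant to increasing affine maps", {
  set.seed(42)
  x <- rt(30, 3); y <- x + rt(30, 3)
  r0 <- winsorized_correlation(x, y)$r_w
  expect_equal(winsorized_correlation(2 * x + 3, y)$r_w, r0)
  expect_equal(winsorized_correlation(x, -y)$r_w, -r0)
  expect_error(winsorized_correlation(x[1:2], y[1:2]), "pairs")
})

test_that("fisher-z intervals reproduce the printed normative correlations", {
  expect_equal(round(fisher_z_ci(0.52, 20), 2), c(0.10, 0.78))
  expect_equal(round(fisher_z_ci(0.65, 20), 2), c(0.29, 0.85))
})

test_that("strength labels follow the 0.30/0.50/0.70 convention", {
  set.seed(43)
  mk <- function(rho) {
    x <- rnorm(400)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(400)
    winsorized_correlation(x, y)$strength_label
  }
  expect_equal(mk(0.10), "negligible")
  expect_equal(mk(0.42), "low")
  expect_equal(mk(0.62), "moderate")
  expect_equal(mk(0.93), "high")
})

sim_split_plot <- function(n_per_group, shift_b = 0, rdist = rnorm) {
  n <- 2L * n_per_group
  data.frame(subject = rep(seq_len(n), each = 2L),
             group = rep(rep(c("a", "b"), each = n_per_group), each = 2L),
             condition = rep(c("c1", "c2"), n),
             value = rdist(2L * n) +
               rep(c(0, shift_b), each = 2L * n_per_group))
}

test_that("untrimmed split-plot test agrees with the classical ANOVA oracle", {
  set.seed(44)
  d <- sim_split_plot(200)
  robust <- bw_trim_anova(d, gamma = 0)
  fit <- summary(aov(value ~ group * condition + Error(subject / condition),
                     data = transform(d, subject = factor(subject))))
  p_between <- fit[[1L]][[1L]]["group", "Pr(>F)"]
  p_within <- fit[[2L]][[1L]]["condition", "Pr(>F)"]
  expect_equal(robust$p[robust$effect == "between"], p_between,
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(robust$p[robust$effect == "within"], p_within,
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("between-effect p falls monotonically with a group shift", {
  shifts <- c(0, 0.5, 1)
  ps <- sapply(1:40, function(s) {
    set.seed(s)
    base <- sim_split_plot(20)
    vapply(shifts, function(sh) {
      d <- base
      d$value <- d$value + ifelse(d$group == "b", sh, 0)
      bw_trim_anova(d)$p[1L]
    }, numeric(1))
  })
  med <- apply(ps, 1L, median)
  expect_true(all(diff(med) < 0))
})

test_that("trimmed split-plot test keeps type-I error under heavy tails", {
  set.seed(45)
  rej <- mean(replicate(1000, {
    d <- sim_split_plot(30, rdist = function(n) rt(n, 3))
    bw_trim_anova(d)$p[1L] < 0.05
  }))
  expect_lte(rej, 0.08)
})

test_that("unbalanced within-cells are rejected naming the subject", {
  d <- sim_split_plot(10)
  d <- d[-2L, ]
  expect_error(bw_trim_anova(d), "subject 1")
})

test_that("three-way test collapses to the two-way test when one factor is idle", {
  set.seed(46)
  d <- sim_split_plot(25, shift_b = 0.4)
  # an (almost) idle second within factor: exact duplication makes its
  # contrast covariance singular, so the duplicate carries negligible noise
  dY <- transform(d, axis = "Y")
  dY$value <- dY$value + rnorm(nrow(dY), sd = 1e-6)
  d2 <- rbind(transform(d, axis = "X"), dY)
  two <- bw_trim_anova(d)
  three <- bww_trim_anova(d2)
  expect_equal(three$Q[three$effect == "between"],
               two$Q[two$effect == "between"], tolerance = 1e-4)
  expect_equal(three$p[three$effect == "within1"],
               two$p[two$effect == "within"], tolerance = 1e-4)
  expect_error(bww_trim_anova(d2[-1L, ]), "within-cell")
})

test_that("hedges g applies the small-sample correction to the pooled difference", {
  set.seed(47)
  x <- rnorm(10, 1); y <- rnorm(10)
  got <- group_comparison_t(x, y)
  sp <- sqrt(((10 - 1) * var(x) + (10 - 1) * var(y)) / 18)
  expect_equal(got$g, (mean(x) - mean(y)) / sp * (1 - 3 / 71))
  expect_equal(got$p, t.test(x, y, var.equal = TRUE)$p.value)

  same <- rnorm(12)
  self <- group_comparison_t(same, same)
  expect_equal(self$g, 0)
  expect_equal(self$p, 1)
  expect_error(group_comparison_t(c(1, 1, 1), c(1, 1, 1)), "variance")
})

test_that("holm adjustment is step-down, monotone and capped", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(48)
  p <- runif(12)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # never more lenient than Bonferroni on the smallest p
  expect_equal(min(adj), min(pmin(p * 12, 1)))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("generalized eta squared matches a hand-worked split-plot table", {
  d <- data.frame(subject = rep(1:4, each = 2),
                  group = rep(c("a", "a", "b", "b"), each = 2),
                  condition = rep(c("c1", "c2"), 4),
                  value = c(1, 3, 2, 4, 5, 9, 6, 8))
  # manual decomposition: grand mean 4.75
  ss_group <- 4 * ((2.5 - 4.75)^2 + (7 - 4.75)^2)            # 40.5
  ss_cond <- 4 * ((3.5 - 4.75)^2 + (6 - 4.75)^2)             # 12.5
  cells <- c(1.5, 3.5, 5.5, 8.5)
  ss_cells <- 2 * sum((cells - 4.75)^2)
  ss_int <- ss_cells - ss_group - ss_cond                    # 0.5
  ss_subj <- 2 * sum((c(2, 3, 7, 7) - rep(c(2.5, 7), each = 2))^2)  # 1
  ss_tot <- sum((d$value - 4.75)^2)                          # 55.5
  ss_err <- ss_tot - ss_cells - ss_subj                      # 1

  res <- split_plot_eta_squared(d)
  expect_equal(res$ss[res$effect == "group"], ss_group)
  expect_equal(res$ss[res$effect == "condition"], ss_cond)
  expect_equal(res$ss[res$effect == "group:condition"], ss_int)
  expect_equal(res$eta2_g[res$effect == "group"],
               ss_group / (ss_group + ss_subj + ss_err))
  expect_equal(res$eta2_g[res$effect == "condition"],
               ss_cond / (ss_cond + ss_subj + ss_err))
  expect_true(all(res$eta2_g >= 0 & res$eta2_g <= 1))

  expect_equal(generalized_eta_squared(3, 7), 0.3)   # one-way reduction
  expect_error(generalized_eta_squared(-1, 2), "non-negative")
  expect_error(generalized_eta_squared(0, 0), "denominator")
})
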