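fake_cells <- function(n = 4, seed = 20) {
  set.seed(seed)
  expand.grid(subject_id = paste0("S", seq_len(n)),
              orientation = c("ccw", "cw"),
              amount = c(5, 10, 20, 40),
              KEEP.OUT.ATTRS = FALSE) |>
    transform(value = round(rnorm(n * 8, 0.4, 0.15), 3))
}

test_that("repeated-measures ANOVA matches the multivariate-model oracle", {
  skip_if_not_installed("car")
  d <- fake_cells(n = 6)
  res <- rm_anova_2x4(d)

  # build subject x 8 matrix ordered orientation x amount
  Y <- t(sapply(split(d, d$subject_id), function(s)
    s$value[order(s$orientation, s$amount)]))
  idata <- expand.grid(amount = factor(c(5, 10, 20, 40)),
                       orientation = factor(c("ccw", "cw")))
  idata <- idata[order(idata$orientation, idata$amount), ]
  fit <- lm(Y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~ orientation * amount,
                   type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  for (eff in c("orientation", "amount", "orientation:amount")) {
    mine <- res[res$effect == eff, ]
    expect_equal(mine$F, uni[eff, "F value"], tolerance = 1e-8)
    expect_equal(mine$df_num, uni[eff, "num Df"])
    expect_equal(mine$df_den, uni[eff, "den Df"])
    expect_equal(mine$p_uncorrected, uni[eff, "Pr(>F)"], tolerance = 1e-8)
  }
  gg <- s$pval.adjustments
  for (eff in c("amount", "orientation:amount")) {
    mine <- res[res$effect == eff, ]
    expect_equal(mine$epsilon_gg, unname(gg[eff, "GG eps"]),
                 tolerance = 1e-8)
    expect_equal(mine$p_gg, unname(gg[eff, "Pr(>F[GG])"]), tolerance = 1e-8)
  }
  mau <- s$sphericity.tests
  for (eff in c("amount", "orientation:amount")) {
    mine <- res[res$effect == eff, ]
    expect_equal(mine$mauchly_W, unname(mau[eff, "Test statistic"]),
                 tolerance = 1e-8)
    expect_equal(mine$mauchly_p, unname(mau[eff, "p-value"]),
                 tolerance = 1e-8)
  }
})

test_that("ANOVA degenerate and two-level identities hold", {
  d <- fake_cells()
  d$value <- 0.4
  res <- rm_anova_2x4(d)
  expect_equal(res$F, rep(0, 3))

  # two-level effect: epsilon is 1 and F equals the paired t squared
  set.seed(5)
  Y <- cbind(rnorm(8, 1), rnorm(8, 1.4))
  res1 <- rm_anova_oneway(Y)
  expect_equal(res1$epsilon_gg, 1)
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(res1$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res1$p, tt$p.value, tolerance = 1e-8)

  dmiss <- fake_cells()[-1, ]
  expect_error(rm_anova_2x4(dmiss), "missing cells")
})

test_that("Greenhouse-Geisser epsilon matches the eigenvalue formula", {
  # compound symmetry: perfect sphericity
  S <- matrix(0.3, 4, 4); diag(S) <- 1
  expect_equal(gg_epsilon(S), 1)

  # all contrast variance in one direction: the 1/(k-1) lower bound
  a <- c(3, -1, -1, -1)
  expect_equal(gg_epsilon(outer(a, a)), 1 / 3)

  # random SPD matrices against the eigenvalue formula on the
  # contrast-projected covariance
  set.seed(6)
  for (k in c(3, 4, 5)) {
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k)
    C <- contr.helmert(k)
    C <- t(sweep(C, 2, sqrt(colSums(C^2)), "/"))
    lam <- eigen(C %*% S %*% t(C), symmetric = TRUE, only.values = TRUE)$values
    oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(gg_epsilon(S), oracle, tolerance = 1e-10)
  }
})

test_that("planned contrasts run ordered one-tailed tests with Bonferroni", {
  # strictly decreasing profile, subject-varying magnitude: all contrasts hit
  Y <- outer(c(1, 1.2, 0.9, 1.1, 1.05), c(0.6, 0.55, 0.4, 0.2))
  colnames(Y) <- c(5, 10, 20, 40)
  pc <- planned_contrasts(Y)
  expect_equal(nrow(pc$paired), 3)
  expect_true(all(pc$paired$p_raw < 0.01))
  expect_true(all(pc$vs_zero$p_raw < 1e-4))

  # oracle check of one paired contrast
  set.seed(7)
  Y2 <- matrix(rnorm(20, 0.4, 0.1), 5, 4,
               dimnames = list(NULL, c(5, 10, 20, 40)))
  pc2 <- planned_contrasts(Y2)
  d <- Y2[, 2] - Y2[, 3]
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(pc2$paired$t[2], t_oracle, tolerance = 1e-12)
  expect_equal(pc2$paired$p_raw[2], pt(t_oracle, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pc2$paired$effect_r,
               sqrt(pc2$paired$t^2 / (pc2$paired$t^2 + pc2$paired$df)))
  # Bonferroni caps at 1 and never decreases p
  expect_true(all(pc2$paired$p_bonferroni <= 1))
  expect_true(all(pc2$paired$p_bonferroni >= pc2$paired$p_raw))
  high <- planned_contrasts(-Y)  # reversed ordering: p near 1
  expect_true(all(high$paired$p_bonferroni == 1))
})

test_that("trial regression equals closed-form OLS", {
  ident <- trial_regression(1:10, 1:10 * 1.0)
  expect_equal(ident$r, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)

  set.seed(8)
  x <- rnorm(60, 0, 7); y <- 0.219 * x + rnorm(60, 0, 3)
  fit <- trial_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y) - slope_oracle * mean(x),
               tolerance = 1e-10)
  expect_equal(fit$r, cor(x, y), tolerance = 1e-12)
  expect_equal(fit$df, 58)
  # slope CI covers the generating coefficient
  se_slope <- sqrt(sum(residuals(lm(y ~ x))^2) / 58 / sxx)
  expect_lt(abs(fit$slope - 0.219), 3 * se_slope)

  # independent data: small correlation, large p
  set.seed(9)
  y0 <- rnorm(60)
  fit0 <- trial_regression(x, y0)
  expect_lt(abs(fit0$r), 0.25)
  expect_gt(fit0$p, 0.05)

  expect_error(trial_regression(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(trial_regression(1:2, 1:2), "at least 3")
})

test_that("within-subject correlations aggregate with raw means", {
  agg <- aggregate_within_subject_r(c(0.2, 0.3, 0.25))
  expect_equal(agg$mean, 0.25)
  expect_equal(agg$se, sd(c(0.2, 0.3, 0.25)) / sqrt(3))
  expect_equal(agg$df, 2)

  same <- aggregate_within_subject_r(c(0.3, 0.3, 0.3, 0.3))
  expect_equal(same$se, 0)
  expect_equal(same$p_raw, 0)  # positive constant effect
})

test_that("half-normal Bayes factor matches quadrature and behaves monotonically", {
  bf <- dienes_bayes_factor(0.252, 0.039, 0.5)
  # independent fine-grid trapezoid oracle
  theta <- seq(0, 2.5, by = 1e-4)
  f <- dnorm(0.252, theta, 0.039) * 2 * dnorm(theta, 0, 0.5)
  marg <- sum((f[-1] + f[-length(f)]) / 2) * 1e-4
  oracle <- marg / dnorm(0.252, 0, 0.039)
  expect_equal(bf$B, oracle, tolerance = 1e-4)

  # zero observed effect: evidence favours the null (closed form)
  b0 <- dienes_bayes_factor(0, 0.039, 0.5)
  expect_lt(b0$B, 1)
  expect_equal(b0$B, 0.039 / sqrt(0.039^2 + 0.5^2), tolerance = 1e-6)

  # monotone in the sample mean at fixed SE
  grid <- seq(0, 1, by = 0.1)
  Bs <- sapply(grid, function(m) dienes_bayes_factor(m, 0.1, 0.5)$B)
  expect_true(all(diff(Bs) > 0))

  # shrinking SE: diverges for a positive mean, stays below 1 at zero mean
  ses <- c(0.2, 0.1, 0.05, 0.02, 0.01)
  Bpos <- sapply(ses, function(s) dienes_bayes_factor(0.3, s, 0.5)$B)
  expect_true(all(diff(Bpos) > 0))
  expect_gt(Bpos[length(Bpos)], 1e10)
  Bnull <- sapply(ses, function(s) dienes_bayes_factor(0, s, 0.5)$B)
  expect_true(all(Bnull < 1))

  expect_error(dienes_bayes_factor(0.2, 0), "se must be")
})

test_that("Shapiro-Wilk screen flags bimodal cells and tolerates minimal n", {
  set.seed(10)
  gauss <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:11), each = 4 * 40),
    amount = rep(rep(c(5, 10, 20, 40), each = 40), 11),
    value = rnorm(11 * 4 * 40, 0.4, 0.2))
  scr <- unimodality_screen(gauss)
  expect_equal(scr$n_tested, 44)
  expect_gte(scr$n_tenable / scr$n_tested, 0.9)

  bim <- data.frame(subject_id = "A", amount = 10,
                    value = c(rnorm(25, 0, 0.01), rnorm(25, 1, 0.01)))
  expect_lt(unimodality_screen(bim)$table$p[1], 0.05)

  tiny <- data.frame(subject_id = "A", amount = 5, value = c(0.1, 0.5, 0.2))
  expect_equal(unimodality_screen(tiny)$n_tested, 1)

  const <- data.frame(subject_id = "A", amount = 5, value = rep(0.4, 5))
  out <- unimodality_screen(const)
  expect_match(out$table$note[1], "constant")
  expect_true(is.na(out$table$p[1]))
})

test_that("Masson-Loftus normalisation removes subject offsets only", {
  one <- matrix(rnorm(9), 1)
  expect_equal(masson_loftus_normalize(one), one)

  X2 <- rbind(a = 1:9, b = 1:9 + 5)
  norm2 <- masson_loftus_normalize(X2)
  expect_equal(norm2[1, ], norm2[2, ])               # offset removed
  expect_equal(unname(diff(norm2[1, ])), rep(1, 8))  # pattern intact

  set.seed(11)
  X <- matrix(rnorm(45), 5, 9)
  norm <- masson_loftus_normalize(X)
  expect_equal(colMeans(norm), colMeans(X), tolerance = 1e-12)
  expect_equal(rowMeans(norm), rep(mean(X), 5), tolerance = 1e-12)
  oracle <- X - (rowMeans(X) - mean(X))
  expect_equal(norm, oracle, tolerance = 1e-15)

  Xna <- X; Xna[2, 3] <- NA
  expect_error(masson_loftus_normalize(Xna), "complete")
})
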