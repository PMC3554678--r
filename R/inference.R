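#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor for repeated-measures degrees of
#' freedom, computed from the covariance matrix of the repeated measures:
#' with an orthonormal contrast basis C, epsilon =
#' tr(C S C')^2 / ((k - 1) tr((C S C')^2)). Equals 1 under compound symmetry
#' and attains its lower bound 1/(k - 1) for maximal non-sphericity; the
#' returned value is clamped to [1/(k - 1), 1] against rounding.
#'
#' @param S Covariance matrix (k x k) of the k repeated measures, or a
#'   subject x level score matrix from which the covariance is taken.
#' @return Epsilon in [1/(k - 1), 1].
#' @export
gg_epsilon <- function(S) {
  if (!isSymmetric(unname(as.matrix(S)), tol = 1e-8))
    S <- stats::cov(S)
  S <- as.matrix(S)
  k <- ncol(S)
  stopifnot(k >= 2L)
  C <- orthonormal_contrasts(k)
  E <- C %*% S %*% t(C)
  denom <- (k - 1) * sum(E * E)
  if (denom <= 0) return(1 / (k - 1))  # singular: report the lower bound
  eps <- sum(diag(E))^2 / denom
  min(max(eps, 1 / (k - 1)), 1)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of orthonormal contrasts of the repeated
#' measures is proportional to the identity, using the standard chi-square
#' approximation.
#'
#' @param scores Subject x variable matrix of repeated-measure scores, with
#'   one column per level (or per within-cell contrast, already transformed:
#'   set `transformed = TRUE`).
#' @param transformed If `TRUE`, `scores` are already contrast-transformed
#'   (k - 1 columns); otherwise an orthonormal contrast basis is applied.
#' @param p_orig Number of original repeated measures the contrasts were
#'   taken from (defaults to one more than the number of contrasts); enters
#'   the second-order term of the chi-square approximation.
#' @return List with `W`, `chisq`, `df`, `p`.
#' @export
mauchly_test <- function(scores, transformed = FALSE, p_orig = NULL) {
  Y <- as.matrix(scores)
  n <- nrow(Y)
  if (!transformed) {
    k <- ncol(Y)
    if (k < 3L) return(list(W = 1, chisq = 0, df = 0L, p = 1))
    if (is.null(p_orig)) p_orig <- k
    Y <- Y %*% t(orthonormal_contrasts(k))
  }
  pp <- ncol(Y)
  if (pp < 2L) return(list(W = 1, chisq = 0, df = 0L, p = 1))
  if (is.null(p_orig)) p_orig <- pp + 1L
  S <- stats::cov(Y)
  W <- det(S) / (sum(diag(S)) / pp)^pp
  df <- as.integer(pp * (pp + 1) / 2 - 1)
  if (!is.finite(W) || W <= 0 || n - 1L < pp) {
    # singular covariance (too few subjects for the number of contrasts):
    # the test statistic is undefined
    return(list(W = NA_real_, chisq = NA_real_, df = df, p = NA_real_))
  }
  # chi-square approximation with the second-order Box correction
  nd <- n - 1
  rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * nd)
  w2 <- (pp + 2) * (pp - 1) * (pp - 2) *
    (2 * pp^3 + 6 * pp^2 + 3 * p_orig + 2) / (288 * (nd * pp * rho)^2)
  chisq <- -nd * rho * log(W)
  pr1 <- stats::pchisq(chisq, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(chisq, df + 4, lower.tail = FALSE)
  list(W = W, chisq = chisq, df = df, p = pr1 + w2 * (pr2 - pr1))
}

#' Two-way repeated-measures ANOVA (orientation x amount)
#'
#' Full within-subject decomposition for a complete, balanced
#' subject x factor A x factor B table of cell scores, with each effect
#' tested against its own effect-by-subject interaction. For every
#' multi-level effect, Mauchly's test and the Greenhouse-Geisser epsilon are
#' computed on the effect's contrast-transformed scores; the reported `p`
#' uses GG-corrected degrees of freedom whenever Mauchly rejects sphericity
#' at `alpha` (epsilon and both p-values are always reported). Two-level
#' effects have epsilon 1 and need no correction.
#'
#' @param data Data frame with columns `subject_id`, the two factor columns
#'   and `value` (one row per subject x cell; replicates are averaged).
#' @param factors Character vector of the two within-subject factor columns.
#' @param alpha Significance level of Mauchly's test that triggers the
#'   GG correction.
#' @return Data frame with one row per effect (A, B, A:B): `F`, `df_num`,
#'   `df_den`, `p_uncorrected`, `mauchly_W`, `mauchly_p`, `epsilon_gg`,
#'   `df_num_gg`, `df_den_gg`, `p_gg`, `sphericity_corrected`, `p`.
#' @export
rm_anova_2x4 <- function(data, factors = c("orientation", "amount"),
                         alpha = 0.05) {
  stopifnot(all(c("subject_id", factors, "value") %in% names(data)))
  fa <- factor(data[[factors[1]]])
  fb <- factor(data[[factors[2]]])
  subj <- factor(data$subject_id)
  a <- nlevels(fa); b <- nlevels(fb); n <- nlevels(subj)
  if (n < 3L) stop("need at least 3 subjects")
  cell <- tapply(data$value, list(subj, fa, fb), mean)
  if (anyNA(cell)) stop("missing cells: design must be complete and balanced")

  grand <- mean(cell)
  m_a <- apply(cell, 2, mean); m_b <- apply(cell, 3, mean)
  m_s <- apply(cell, 1, mean)
  m_as <- apply(cell, c(1, 2), mean); m_bs <- apply(cell, c(1, 3), mean)
  m_ab <- apply(cell, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_as <- b * sum((m_as - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- a * sum((m_bs - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  resid <- cell
  for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(b))
    resid[i, j, l] <- cell[i, j, l] - m_as[i, j] - m_bs[i, l] - m_ab[j, l] +
      m_s[i] + m_a[j] + m_b[l] - grand
  ss_abs <- sum(resid^2)

  effect_row <- function(name, ss_eff, df_eff, ss_err, df_err, scores) {
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    F <- if (ms_err > 0) ms_eff / ms_err else 0
    mt <- mauchly_test(scores, transformed = TRUE, p_orig = a * b)
    eps <- if (ncol(scores) > 1L) gg_epsilon_transformed(scores) else 1
    p_unc <- stats::pf(F, df_eff, df_err, lower.tail = FALSE)
    p_gg <- stats::pf(F, eps * df_eff, eps * df_err, lower.tail = FALSE)
    corrected <- isTRUE(mt$p < alpha)
    data.frame(effect = name, F = F, df_num = df_eff, df_den = df_err,
               p_uncorrected = p_unc,
               mauchly_W = mt$W, mauchly_p = mt$p,
               epsilon_gg = eps,
               df_num_gg = eps * df_eff, df_den_gg = eps * df_err,
               p_gg = p_gg, sphericity_corrected = corrected,
               p = if (corrected) p_gg else p_unc)
  }

  ca <- orthonormal_contrasts(a); cb <- orthonormal_contrasts(b)
  y_as <- matrix(m_as, n, a) %*% t(ca)
  y_bs <- matrix(m_bs, n, b) %*% t(cb)
  # subject x (a*b) scores with factor A varying slowest, matching
  # kronecker(ca, cb) column order
  y_cell <- t(apply(cell, 1, function(x) as.vector(t(x))))
  cab <- kronecker(ca, cb)
  y_abs <- y_cell %*% t(cab)

  out <- rbind(
    effect_row(factors[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), y_as),
    effect_row(factors[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1), y_bs),
    effect_row(paste(factors, collapse = ":"), ss_ab, (a - 1) * (b - 1),
               ss_abs, (a - 1) * (b - 1) * (n - 1), y_abs)
  )
  rownames(out) <- NULL
  out
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA for a single k-level factor, with Mauchly's test and
#' the Greenhouse-Geisser correction handled as in [rm_anova_2x4()].
#'
#' @param scores Subject x level matrix of cell means.
#' @param alpha Mauchly significance level triggering the GG correction.
#' @return One-row data frame in the [rm_anova_2x4()] format.
#' @export
rm_anova_oneway <- function(scores, alpha = 0.05) {
  Y <- as.matrix(scores)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3L) stop("need at least 3 subjects")
  grand <- mean(Y)
  m_c <- colMeans(Y); m_s <- rowMeans(Y)
  ss_c <- n * sum((m_c - grand)^2)
  ss_err <- sum((Y - outer(m_s, rep(1, k)) -
                   outer(rep(1, n), m_c) + grand)^2)
  df_c <- k - 1; df_err <- (k - 1) * (n - 1)
  F <- if (ss_err > 0) (ss_c / df_c) / (ss_err / df_err) else 0
  Yt <- Y %*% t(orthonormal_contrasts(k))
  mt <- mauchly_test(Yt, transformed = TRUE, p_orig = k)
  eps <- if (k > 2L) gg_epsilon_transformed(Yt) else 1
  p_unc <- stats::pf(F, df_c, df_err, lower.tail = FALSE)
  p_gg <- stats::pf(F, eps * df_c, eps * df_err, lower.tail = FALSE)
  corrected <- isTRUE(mt$p < alpha)
  data.frame(effect = "condition", F = F, df_num = df_c, df_den = df_err,
             p_uncorrected = p_unc, mauchly_W = mt$W, mauchly_p = mt$p,
             epsilon_gg = eps, df_num_gg = eps * df_c,
             df_den_gg = eps * df_err, p_gg = p_gg,
             sphericity_corrected = corrected,
             p = if (corrected) p_gg else p_unc)
}

#' Planned one-tailed contrasts over pooled amounts
#'
#' Tests the a-priori ordering that the measure decreases with increasing
#' amount of manipulation: sequential paired one-tailed t-tests between
#' neighbouring amounts (5 vs 10, 10 vs 20, 20 vs 40; Bonferroni family
#' size 3), plus one-sample one-tailed t-tests of each amount against 0
#' (family size 4). Effect sizes are r = sqrt(t^2 / (t^2 + df)).
#'
#' @param cells Subject x amount matrix of pooled cell means (columns
#'   ordered by increasing amount) or a pooled long table as from
#'   [cell_means()].
#' @return List with data frames `paired` and `vs_zero`.
#' @export
planned_contrasts <- function(cells) {
  if (is.data.frame(cells) && "amount" %in% names(cells))
    cells <- cells_to_matrix(cells, "amount")
  Y <- as.matrix(cells)
  if (nrow(Y) < 3L) stop("need at least 3 subjects")
  k <- ncol(Y)
  paired <- do.call(rbind, lapply(seq_len(k - 1L), function(i) {
    ttest_row(sprintf("%s > %s", colnames(Y)[i], colnames(Y)[i + 1L]),
              one_sample_t(Y[, i] - Y[, i + 1L]), family = k - 1L)
  }))
  vs_zero <- do.call(rbind, lapply(seq_len(k), function(i) {
    ttest_row(sprintf("%s > 0", colnames(Y)[i]),
              one_sample_t(Y[, i]), family = k)
  }))
  list(paired = paired, vs_zero = vs_zero)
}

# one-tailed one-sample t against 0 ("greater"); tolerates zero variance
one_sample_t <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  se <- stats::sd(x) / sqrt(n)
  t <- if (se > 0) mean(x) / se
       else if (mean(x) == 0) 0 else sign(mean(x)) * Inf
  list(t = t, df = n - 1L, p = stats::pt(t, n - 1L, lower.tail = FALSE))
}

ttest_row <- function(label, tt, family) {
  data.frame(contrast = label, t = tt$t, df = tt$df,
             p_raw = tt$p,
             p_bonferroni = min(1, family * tt$p),
             tail = "greater",
             effect_r = sqrt(tt$t^2 / (tt$t^2 + tt$df)))
}

#' Trial-by-trial regression of probe on feedback percepts
#'
#' Ordinary least squares predicting the perceived pointing direction of
#' probe trials from the perceived pointing direction of the immediately
#' preceding feedback trials, within one subject (optionally restricted to a
#' single absolute amount of manipulation). Positive slopes indicate that
#' the internally attributed error component carries over into the next
#' internal sensory prediction.
#'
#' @param feedback_ppd,probe_ppd Paired percepts (degrees); probe trial i
#'   followed feedback trial i.
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   directional positivity hypothesis.
#' @return List with `r`, `slope`, `intercept`, `df`, `p`, `n`.
#' @export
trial_regression <- function(feedback_ppd, probe_ppd,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  ok <- is.finite(feedback_ppd) & is.finite(probe_ppd)
  x <- feedback_ppd[ok]; y <- probe_ppd[ok]
  if (length(x) < 3L) stop("need at least 3 valid trial pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in predictor or response")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  r <- stats::cor(x, y)
  df <- length(x) - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- if (alternative == "two.sided") 2 * stats::pt(-abs(tval), df)
       else stats::pt(tval, df, lower.tail = FALSE)
  list(r = r, slope = slope, intercept = unname(stats::coef(fit)[1L]),
       df = df, p = p, n = length(x))
}

#' Aggregate within-subject correlation coefficients
#'
#' Arithmetic mean and standard error of raw per-subject correlation
#' coefficients (no Fisher transform), with a one-sample one-tailed t-test
#' against 0 and an optional Bonferroni family size.
#'
#' @param r Numeric vector of per-subject correlation coefficients.
#' @param family Bonferroni family size for the corrected p-value.
#' @return List with `mean`, `se`, `n`, `t`, `df`, `p_raw`, `p_bonferroni`.
#' @export
aggregate_within_subject_r <- function(r, family = 1L) {
  r <- r[is.finite(r)]
  n <- length(r)
  if (n < 3L) stop("need at least 3 subjects")
  tt <- one_sample_t(r)
  list(mean = mean(r), se = stats::sd(r) / sqrt(n), n = n,
       t = tt$t, df = tt$df, p_raw = tt$p,
       p_bonferroni = min(1, family * tt$p))
}

#' Half-normal-prior Bayes factor for a directional effect
#'
#' Evidence ratio for a directional hypothesis against the point null,
#' following the Dienes calculator convention: the likelihood of the
#' observed sample mean, Normal(theta, se), is integrated against a
#' half-normal prior on theta >= 0 with mode 0 and standard deviation
#' `prior_sd`, and divided by the likelihood at theta = 0. Values above 1
#' favour the directional hypothesis, below 1 the null; 3 and 1/3 mark
#' substantial evidence. The integral is evaluated with
#' [stats::integrate()] at a relative tolerance of 1e-8.
#'
#' @param sample_mean Observed mean effect.
#' @param se Standard error of the mean (> 0).
#' @param prior_sd Standard deviation of the half-normal prior (> 0);
#'   default 0.5, suitable for correlation-scale effects.
#' @return List with `B`, `sample_mean`, `se`, `prior_sd`,
#'   `prior_shape = "half-normal(0, prior_sd)"`.
#' @export
dienes_bayes_factor <- function(sample_mean, se, prior_sd = 0.5) {
  if (!is.finite(se) || se <= 0) stop("se must be > 0")
  if (prior_sd <= 0) stop("prior_sd must be > 0")
  marginal <- stats::integrate(
    function(theta) stats::dnorm(sample_mean, theta, se) *
      2 * stats::dnorm(theta, 0, prior_sd),
    lower = 0, upper = Inf, rel.tol = 1e-8)$value
  null_lik <- stats::dnorm(sample_mean, 0, se)
  list(B = marginal / null_lik,
       sample_mean = sample_mean, se = se, prior_sd = prior_sd,
       prior_shape = "half-normal(0, prior_sd)")
}

#' Shapiro-Wilk unimodality screen of per-trial weights
#'
#' Applies the Shapiro-Wilk test to the distribution of per-trial relative
#' visual weights in every subject x amount cell. A tenable null
#' (p >= alpha, uncorrected) indicates a normal - hence unimodal -
#' distribution, i.e. continuous rather than dichotomous (all-or-none)
#' error attribution on single trials. Constant cells cannot be tested and
#' are reported with a note.
#'
#' @param measures Per-trial weight table from [trial_measures()] (pooled or
#'   unpooled; cells are subject x amount).
#' @param alpha Tenability threshold (uncorrected), default 0.05.
#' @return List with `table` (subject, amount, n, W, p, note), `n_tested`,
#'   `n_tenable`.
#' @export
unimodality_screen <- function(measures, alpha = 0.05) {
  cells <- split(measures$value,
                 list(measures$subject_id, measures$amount), drop = TRUE)
  rows <- lapply(names(cells), function(nm) {
    v <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    base <- data.frame(subject_id = parts[1L], amount = as.numeric(parts[2L]),
                       n = length(v))
    if (length(v) < 3L) stop("need at least 3 trials per cell")
    if (stats::sd(v) == 0)
      return(cbind(base, W = NA_real_, p = NA_real_,
                   note = "constant sample: not testable"))
    sw <- stats::shapiro.test(v)
    cbind(base, W = unname(sw$statistic), p = sw$p.value, note = "")
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       n_tested = sum(tab$note == ""),
       n_tenable = sum(tab$p >= alpha, na.rm = TRUE))
}

#' Masson-Loftus within-subject normalisation
#'
#' Removes between-subject offsets from a subject x condition score table:
#' each score has the deviation of its subject's mean from the grand mean
#' subtracted, X_ij - (M_i - GM). Condition means are unchanged; variability
#' across subjects then reflects within-subject variability only, which is
#' the appropriate error-bar basis for within-subject designs.
#'
#' @param X Complete subject x condition numeric matrix (or data frame).
#' @return Matrix of normalised scores with the same dimensions.
#' @export
masson_loftus_normalize <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("table must be complete")
  X - (rowMeans(X) - mean(X))
}

# orthonormal basis of contrasts (rows) orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  t(C)
}

gg_epsilon_transformed <- function(Yt) {
  E <- stats::cov(Yt)
  d <- ncol(Yt)
  denom <- d * sum(E * E)
  if (denom <= 0) return(1 / d)
  eps <- sum(diag(E))^2 / denom
  min(max(eps, 1 / d), 1)
}
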