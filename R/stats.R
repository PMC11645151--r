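#' Two-group comparison
#'
#' The study-level comparison layer: Welch (default) or pooled t test and
#' Mann-Whitney U for continuous phenotypes, chi-squared or Fisher's exact
#' test for categorical ones. All tests are two-sided. The Mann-Whitney test
#' is exact for group sizes up to 8 without ties and otherwise uses the
#' normal approximation with tie correction.
#'
#' @param values Numeric (t, mannwhitney) or categorical (chi2, fisher)
#'   outcome vector.
#' @param groups Two-level grouping vector.
#' @param test One of "t", "mannwhitney", "chi2", "fisher".
#' @param pooled Logical; use the pooled-variance t test instead of Welch.
#' @return List with `statistic`, `p`, `effect` (mean difference, median
#'   difference, or odds ratio as appropriate) and `test`.
#' @export
group_compare <- function(values, groups,
                          test = c("t", "mannwhitney", "chi2", "fisher"),
                          pooled = FALSE) {
  test <- match.arg(test)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required, got ", nlevels(groups))
  g1 <- levels(groups)[1L]; g2 <- levels(groups)[2L]
  if (test %in% c("t", "mannwhitney")) {
    x <- values[groups == g1]; y <- values[groups == g2]
    if (length(x) < 2L || length(y) < 2L)
      stop("each group needs n >= 2 for ", test)
    if (test == "t") {
      ht <- stats::t.test(x, y, var.equal = pooled)
      return(list(statistic = unname(ht$statistic), p = ht$p.value,
                  effect = mean(x) - mean(y), test = ht$method))
    }
    exact <- max(length(x), length(y)) <= 8 &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    return(list(statistic = unname(ht$statistic), p = ht$p.value,
                effect = stats::median(x) - stats::median(y),
                test = ht$method))
  }
  tab <- table(values, groups)
  if (nrow(tab) < 2L) stop("categorical outcome has a single level")
  if (test == "chi2") {
    ht <- suppressWarnings(stats::chisq.test(tab))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         effect = NA_real_, test = ht$method)
  } else {
    ht <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ht$p.value,
         effect = if (!is.null(ht$estimate)) unname(ht$estimate) else NA_real_,
         test = ht$method)
  }
}

#' Covariate-adjusted (least-squares) group means
#'
#' Ordinary least squares of the outcome on a group indicator plus
#' covariates; adjusted means are the model predictions for each group at
#' the covariate grand means, with 95% CIs from the model error variance.
#' With no covariates the adjusted means equal the raw group means.
#'
#' @param outcome Numeric outcome.
#' @param group Two-level grouping vector.
#' @param covariates Optional data frame / matrix of numeric covariates.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `means` (data frame: group, estimate, lower, upper),
#'   `difference` (estimate, lower, upper, p for group 2 minus group 1), and
#'   the fitted `model`.
#' @export
adjusted_means <- function(outcome, group, covariates = NULL,
                           conf_level = 0.95) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  X <- stats::model.matrix(~group)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    C <- as.matrix(as.data.frame(covariates))
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, outcome)
  n <- length(outcome); pdim <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - pdim)
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- fit$coefficients
  cov_means <- if (pdim > 2L) colMeans(X[, -(1:2), drop = FALSE]) else numeric(0)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - pdim)
  row_for <- function(glev) {
    cc <- c(1, as.numeric(glev == levels(group)[2L]), cov_means)
    est <- sum(cc * beta)
    se <- sqrt(sigma2 * drop(t(cc) %*% XtXinv %*% cc))
    c(estimate = est, lower = est - tq * se, upper = est + tq * se)
  }
  means <- t(vapply(levels(group), row_for, numeric(3)))
  dbeta <- beta[2L]
  dse <- sqrt(sigma2 * XtXinv[2L, 2L])
  pval <- 2 * stats::pt(abs(dbeta / dse), df = n - pdim, lower.tail = FALSE)
  list(means = data.frame(group = levels(group), means,
                          row.names = NULL),
       difference = c(estimate = unname(dbeta),
                      lower = unname(dbeta - tq * dse),
                      upper = unname(dbeta + tq * dse),
                      p = unname(pval)),
       model = list(coefficients = beta, sigma2 = sigma2,
                    df = n - pdim))
}

#' Spearman rank correlation, with optional covariate-adjusted companion
#'
#' Rank correlation using average ranks for ties; the p-value is the t
#' approximation t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#' When covariates are supplied, a companion linear regression of y on x
#' plus the covariates is reported, computed either on ranks or on the raw
#' scale.
#'
#' @param x,y Numeric vectors (n >= 3 complete pairs).
#' @param covariates Optional data frame of adjustment covariates.
#' @param adjust_scale "rank" or "raw": scale on which the companion
#'   adjusted regression is run.
#' @return List with `rho`, `p`, `n`, and (when covariates are given)
#'   `adjusted` (slope of x, lower, upper, p; plus the scale used).
#' @export
spearman_cor <- function(x, y, covariates = NULL,
                         adjust_scale = c("rank", "raw")) {
  adjust_scale <- match.arg(adjust_scale)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant vector: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  out <- list(rho = rho, p = p, n = n)
  if (!is.null(covariates)) {
    C <- as.data.frame(covariates)[keep, , drop = FALSE]
    if (adjust_scale == "rank") {
      dat <- data.frame(.y = ry, .x = rx,
                        lapply(C, rank))
    } else {
      dat <- data.frame(.y = y, .x = x, C)
    }
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)[".x", ]
    out$adjusted <- list(slope = sm[".x", "Estimate"],
                         lower = ci[[1L]], upper = ci[[2L]],
                         p = sm[".x", "Pr(>|t|)"],
                         scale = adjust_scale)
  }
  out
}

#' Asymptotic two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution evaluated at
#' sqrt(n_eff) D with effective size n_eff = n_a n_b / (n_a + n_b).
#'
#' @param a,b Numeric samples (each n >= 1).
#' @return List with `D`, `p`, and the sample sizes.
#' @export
ks_2sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty")
  z <- c(a, b)
  e <- c(rep(1 / na, na), rep(-1 / nb, nb))
  ord <- order(z)
  zs <- z[ord]
  cum <- cumsum(e[ord])
  last_of_run <- c(diff(zs) != 0, TRUE)
  D <- max(abs(cum[last_of_run]))
  ne <- na * nb / (na + nb)
  lam <- sqrt(ne) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  list(D = D, p = min(1, max(0, p)), n_a = na, n_b = nb)
}

#' Single-cell quality-control filter
#'
#' Keeps cells with between 500 and 5,000 detected genes (inclusive) and a
#' mitochondrial fraction below 50%.
#'
#' @param genes_detected Integer vector of detected gene counts per cell.
#' @param mito_fraction Mitochondrial read fraction per cell, in [0, 1].
#' @return List with `kept` (indices), and `summary` (counts: input, kept,
#'   low_genes, high_genes, high_mito).
#' @export
scrna_qc_filter <- function(genes_detected, mito_fraction) {
  if (length(genes_detected) != length(mito_fraction))
    stop("inputs differ in length")
  if (any(genes_detected < 0)) stop("gene counts must be >= 0")
  if (any(mito_fraction < 0 | mito_fraction > 1))
    stop("mito_fraction must lie in [0, 1]")
  low <- genes_detected < 500
  high <- genes_detected > 5000
  mito <- mito_fraction >= 0.5
  keep <- !(low | high | mito)
  list(kept = which(keep),
       summary = c(input = length(keep), kept = sum(keep),
                   low_genes = sum(low), high_genes = sum(high),
                   high_mito = sum(mito)))
}

#' Square-root-transformed group regression
#'
#' For right-skewed nonnegative outcomes (e.g. tissue metabolite
#' abundances): OLS of sqrt(outcome) on group and covariates, with the group
#' effect, CI and p reported on the square-root scale.
#'
#' @inheritParams adjusted_means
#' @return List with `effect` (estimate, lower, upper, p on the sqrt scale)
#'   and the underlying [adjusted_means()] result on sqrt(outcome).
#' @export
sqrt_regression <- function(outcome, group, covariates = NULL,
                            conf_level = 0.95) {
  if (any(outcome < 0)) stop("outcome must be nonnegative for sqrt transform")
  am <- adjusted_means(sqrt(outcome), group, covariates, conf_level)
  list(effect = am$difference, adjusted_means = am$means, model = am$model)
}

#' Power of the two-sided two-sample t test
#'
#' Exact power via the noncentral t distribution with
#' df = n1 + n2 - 2 and noncentrality delta / (sd sqrt(1/n1 + 1/n2)).
#' Handles unequal group sizes (e.g. 28 vs 12 participants for an 88 nm
#' difference in GBM width at SD 78 nm).
#'
#' @param n1,n2 Group sizes (each >= 2).
#' @param delta True mean difference.
#' @param sd Common standard deviation, > 0.
#' @param alpha Two-sided significance level, in (0, 1).
#' @return Power as a probability.
#' @examples
#' ttest_power(28, 12, delta = 88, sd = 78)
#' @export
ttest_power <- function(n1, n2, delta, sd, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("both group sizes must be >= 2")
  if (sd <= 0) stop("sd must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- delta / (sd * sqrt(1 / n1 + 1 / n2))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
}
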