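#' Two-sample t-test from printed summary statistics
#'
#' Reconstructs the two-sample t from group means, standard deviations and
#' sizes, as printed in cohort demographics tables. Pooled-variance and
#' Welch (Satterthwaite) variants are both available because published
#' tables are not always consistent about which was used.
#'
#' @param m1,s1,n1 mean, sd, n of group 1.
#' @param m2,s2,n2 mean, sd, n of group 2.
#' @param variant "pooled" (default) or "welch".
#' @return list `t`, `df`, `p` (two-tailed).
#' @export
two_sample_t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), the
#' convention that matches published demographics tables reporting e.g.
#' sex-by-group counts.
#'
#' @param a,b,c,d cell counts: rows are groups, columns the binary variable,
#'   i.e. matrix(c(a, c, b, d), 2).
#' @return list `chi2`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m <- matrix(c(a, c, b, d), 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all table margins must be positive")
  res <- stats::chisq.test(m, correct = FALSE)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the covariates
#' (plus intercept), with df = n - k - 2 and a two-tailed p from the t
#' transform. With no covariates this reduces to the plain Pearson
#' correlation.
#'
#' @param x,y numeric vectors, one value per subject.
#' @param covariates data.frame (or matrix) of per-subject covariate columns;
#'   NULL or zero columns for a plain correlation.
#' @return list `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  k <- 0L
  sx0 <- stats::sd(x); sy0 <- stats::sd(y)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Z <- as.matrix(as.data.frame(covariates))
    if (nrow(Z) != n) stop("covariates must have one row per subject")
    k <- ncol(Z)
    if (n <= k + 2) stop("need n > number of covariates + 2")
    X <- cbind(1, Z)
    x <- stats::lm.fit(X, x)$residuals
    y <- stats::lm.fit(X, y)$residuals
  }
  if (stats::sd(x) <= 1e-10 * max(sx0, 1e-30) ||
      stats::sd(y) <= 1e-10 * max(sy0, 1e-30))
    stop("zero residual variance")
  r <- stats::cor(x, y)
  df <- n - k - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df), df = df, n = n)
}

#' Regression of cognitive change on cluster thinning
#'
#' OLS of the change in MoCA on the mean thinning of the significant
#' clusters, adjusting for age and sex. Reports the overall r-squared and
#' per-term coefficients with raw p-values, plus an optional Bonferroni
#' column over the cluster terms.
#'
#' @param delta_moca numeric vector of MoCA change per subject.
#' @param cluster_thinning matrix/data.frame of per-cluster mean thinning
#'   (subjects x clusters).
#' @param age,sex covariate vectors (sex as a 0/1 indicator).
#' @param bonferroni if TRUE, add a `p_bonf` column over the cluster terms.
#' @return A `regression_result`: list with `r2`, `p_model`, `coefficients`
#'   (term, beta, se, t, p), `n`, `df`.
#' @export
delta_moca_regression <- function(delta_moca, cluster_thinning, age, sex,
                                  bonferroni = FALSE) {
  ct <- as.matrix(cluster_thinning)
  if (is.null(colnames(ct)))
    colnames(ct) <- paste0("cluster", seq_len(ncol(ct)))
  n <- length(delta_moca)
  if (nrow(ct) != n || length(age) != n || length(sex) != n)
    stop("all inputs must have one row/value per subject")
  if (n <= ncol(ct) + 3) stop("too few subjects for the model")
  dat <- data.frame(delta_moca = delta_moca, ct, age = age, sex = sex)
  X <- stats::model.matrix(~ ., data = dat[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X))
    stop("collinear predictors in MoCA regression")
  fit <- stats::lm(delta_moca ~ ., data = dat)
  s <- summary(fit)
  coefs <- data.frame(term = rownames(s$coefficients),
                      beta = s$coefficients[, 1], se = s$coefficients[, 2],
                      t = s$coefficients[, 3], p = s$coefficients[, 4],
                      row.names = NULL)
  if (bonferroni) {
    coefs$p_bonf <- NA_real_
    cl <- coefs$term %in% colnames(ct)
    coefs$p_bonf[cl] <- pmin(coefs$p[cl] * sum(cl), 1)
  }
  fstat <- s$fstatistic
  p_model <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(r2 = s$r.squared, p_model = unname(p_model),
                 coefficients = coefs, n = n, df = fit$df.residual),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("regression: n = %d, r2 = %.3f, model p = %.4g\n",
              x$n, x$r2, x$p_model))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Group comparison table from a clinical table
#'
#' Convenience wrapper producing demographics-table statistics (two-sample t
#' per numeric variable, chi-square for sex) between the PD and HC groups of
#' a clinical table.
#'
#' @param clinical a `clinical_table` (see [gen_clinical]).
#' @param variables numeric columns to compare.
#' @param variant t-test variant, see [two_sample_t_from_summary].
#' @return data.frame `variable`, `mean_pd`, `sd_pd`, `mean_hc`, `sd_hc`,
#'   `statistic`, `p`.
#' @export
clinical_group_table <- function(clinical,
                                 variables = c("age", "moca_t1", "moca_t2",
                                               "asyn", "abeta42", "ttau",
                                               "ptau181"),
                                 variant = "pooled") {
  pd <- clinical[clinical$group == "PD", ]
  hc <- clinical[clinical$group == "HC", ]
  rows <- lapply(variables, function(v) {
    x <- pd[[v]]; y <- hc[[v]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    tt <- two_sample_t_from_summary(mean(x), stats::sd(x), length(x),
                                    mean(y), stats::sd(y), length(y),
                                    variant = variant)
    data.frame(variable = v, mean_pd = mean(x), sd_pd = stats::sd(x),
               mean_hc = mean(y), sd_hc = stats::sd(y),
               statistic = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  sx <- chi2_2x2(sum(pd$sex == 1), sum(pd$sex == 0),
                 sum(hc$sex == 1), sum(hc$sex == 0))
  rbind(out, data.frame(variable = "sex", mean_pd = mean(pd$sex),
                        sd_pd = NA, mean_hc = mean(hc$sex), sd_hc = NA,
                        statistic = sx$chi2, p = sx$p))
}
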