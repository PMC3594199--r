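#' Rank transformation with average ranks for ties
#'
#' Network property distributions are often non-normal; rank transformation
#' permits parametric analysis on the ranks. Ties receive the average of the
#' ranks they span; missing values are excluded from ranking but keep their
#' positions (returned as `NA`).
#'
#' @param x numeric vector.
#' @return Numeric vector of ranks `1..n_nonmissing` (average for ties).
#' @export
rank_transform <- function(x) {
  rank(x, ties.method = "average", na.last = "keep")
}

#' Rank-transform ANCOVA for a group effect
#'
#' Fits a linear model of the rank-transformed response on the covariates
#' plus the two-level group factor, and tests the group term added last
#' (partial F against the covariates-only model). The full model's F test
#' is reported as well. Only the response is rank-transformed; covariates
#' enter untransformed.
#'
#' @param response numeric vector (network property values).
#' @param group two-level factor (or coercible).
#' @param covariates data.frame of covariates (e.g. grey-matter volume, age,
#'   sex), or `NULL` for a plain one-way comparison on ranks.
#' @param rank_response if `FALSE`, analyse the raw response.
#' @return List with `F`, `df1`, `df2`, `p` for the group term, plus
#'   `full_model_F`, `full_model_p`, `n`, `covariates`.
#' @export
ancova_group <- function(response, group, covariates = NULL,
                         rank_response = TRUE) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly two levels")
  dat <- data.frame(.y = if (rank_response) rank_transform(response) else
    response, .group = group)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(response)) {
      stop("covariates must have one row per subject")
    }
    cov_names <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  rhs_cov <- if (length(cov_names)) paste(cov_names, collapse = " + ") else "1"
  full <- stats::lm(stats::as.formula(paste(".y ~", rhs_cov, "+ .group")),
                    data = dat)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("singular design; collinear terms: ", paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(stats::as.formula(paste(".y ~", rhs_cov)), data = dat)
  cmp <- stats::anova(reduced, full)
  fs <- summary(full)$fstatistic
  list(F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2], p = cmp$`Pr(>F)`[2],
       full_model_F = unname(fs[1]),
       full_model_p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
       n = n, covariates = cov_names)
}

#' Levene test of equality of variance between groups
#'
#' Brown-Forsythe variant by default: an ANOVA on absolute deviations from
#' the group medians. Both groups constant (zero spread) is a degenerate
#' case reported with `p = NA` and `status = "degenerate"`.
#'
#' @param values numeric vector.
#' @param group two-level factor (or coercible).
#' @param center `"median"` (robust, default) or `"mean"`.
#' @return List with `statistic`, `df1`, `df2`, `p`, `status`.
#' @export
levene_check <- function(values, group, center = c("median", "mean")) {
  center <- match.arg(center)
  group <- factor(group)
  ok <- stats::complete.cases(values, group)
  values <- values[ok]
  group <- droplevels(group[ok])
  centers <- tapply(values, group, if (center == "median") stats::median
                    else mean)
  dev <- abs(values - centers[group])
  if (all(dev == 0)) {
    return(list(statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p = NA_real_, status = "degenerate"))
  }
  lt <- car::leveneTest(values ~ group, center = if (center == "median")
    stats::median else mean)
  list(statistic = lt$`F value`[1], df1 = lt$Df[1], df2 = lt$Df[2],
       p = lt$`Pr(>F)`[1], status = "ok")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values; adjusted values never fall below the raw ones
#' and are capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with confidence interval
#'
#' Pearson r with a two-sided t-test p-value and a Fisher-z 95% confidence
#' interval.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @param conf_level confidence level (default 0.95).
#' @return List with `r`, `p`, `ci` (length 2), `n`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        conf.level = conf_level)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = sum(ok))
}

#' Partial Spearman correlation by rank residualization
#'
#' All variables are rank-transformed (average ranks for ties); the x and y
#' ranks are each residualized on the covariate ranks by least squares, and
#' the Pearson correlation of the residuals is reported with a t-based
#' p-value on `n - 2 - k` degrees of freedom (`k` covariates). With no
#' covariates this reduces exactly to the plain Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame (or `NULL`); rows with any missing value
#'   among x, y, covariates are dropped.
#' @param conf_level confidence level for the Fisher-z interval.
#' @return List with `rho`, `p`, `ci`, `n`, `covariates`.
#' @export
partial_spearman <- function(x, y, covariates = NULL, conf_level = 0.95) {
  dat <- data.frame(x = x, y = y)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k <- ncol(dat) - 2L
  ranks <- as.data.frame(lapply(dat, rank_transform))
  if (k > 0) {
    zmat <- as.matrix(ranks[, -(1:2), drop = FALSE])
    rx <- stats::lsfit(zmat, ranks$x)$residuals
    ry <- stats::lsfit(zmat, ranks$y)$residuals
  } else {
    rx <- ranks$x
    ry <- ranks$y
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  z <- atanh(rho)
  se <- 1 / sqrt(n - 3 - k)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rho = rho, p = p, ci = tanh(c(z - q * se, z + q * se)), n = n,
       covariates = if (k > 0) names(dat)[-(1:2)] else character(0))
}

#' Forward comparison of nested regression models
#'
#' Starting from a base predictor set, adds one stage of predictors at a
#' time and reports each model's adjusted R^2 together with partial F tests
#' between nested pairs of models (every later model against every earlier
#' one). The response is rank-transformed by default (average ranks for
#' ties).
#'
#' @param response numeric vector (e.g. a cognitive score).
#' @param stages named list of data.frames; stage `i` predictors are added
#'   cumulatively to stages `1..i-1`.
#' @param rank_response rank-transform the response first (default `TRUE`).
#' @return List with `models` (data.frame: stage, predictors, df_model,
#'   adj_r_squared) and `comparisons` (data.frame: model_a, model_b,
#'   F_change, df1, df2, p_change), plus `n`.
#' @export
forward_model_comparison <- function(response, stages, rank_response = TRUE) {
  if (!is.list(stages) || length(stages) < 2L) {
    stop("`stages` must be a list of at least two predictor stages")
  }
  if (is.null(names(stages)) || any(names(stages) == "")) {
    names(stages) <- paste0("model_", seq_along(stages))
  }
  preds <- do.call(cbind, lapply(stages, as.data.frame))
  dat <- data.frame(.y = if (rank_response) rank_transform(response) else
    response, preds)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  ncols <- vapply(stages, ncol, integer(1))
  cum <- cumsum(ncols)
  fits <- lapply(seq_along(stages), function(i) {
    stats::lm(.y ~ ., data = dat[, c(1L, 1L + seq_len(cum[i])),
                                 drop = FALSE])
  })
  models <- data.frame(
    stage = seq_along(stages),
    name = names(stages),
    n_predictors = cum,
    adj_r_squared = vapply(fits, function(f) summary(f)$adj.r.squared,
                           numeric(1))
  )
  pairs <- which(upper.tri(diag(length(stages))), arr.ind = TRUE)
  comparisons <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]
    b <- pairs[r, 2]
    cmp <- stats::anova(fits[[a]], fits[[b]])
    data.frame(model_a = names(stages)[a], model_b = names(stages)[b],
               F_change = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
               p_change = cmp$`Pr(>F)`[2])
  }))
  list(models = models, comparisons = comparisons, n = n)
}
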