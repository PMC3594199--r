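test_that("rank transform averages ties and preserves missing positions", {
  expect_equal(rank_transform(c(3, 1, 3)), c(2.5, 1, 2.5))
  expect_equal(rank_transform(c(2, 5, 9, 11)), c(1, 2, 3, 4))
  expect_equal(rank_transform(c(4, NA, 2)), c(2, NA, 1))
  # sort-and-average oracle on a seeded vector with ties
  set.seed(5)
  x <- sample(1:6, 30, replace = TRUE)
  oracle <- sapply(x, function(v) mean(which(sort(x) == v)))
  expect_equal(rank_transform(x), oracle)
})

test_that("rank ANCOVA finds nothing when the response ignores the group", {
  v <- rnorm(20)
  response <- c(v, v)                       # identical in both groups
  group <- rep(c("a", "b"), each = 20)
  covs <- data.frame(age = c(rnorm(20), rnorm(20)))
  covs$age <- rep(covs$age[1:20], 2)        # covariates matched as well
  a <- ancova_group(response, group, covs)
  expect_lt(a$F, 1e-10)
  expect_gt(a$p, 0.999)
})

test_that("rank ANCOVA detects a two-SD group shift with high power", {
  set.seed(77)
  hits <- 0
  for (i in 1:20) {
    g <- rep(c("ctrl", "pat"), each = 50)
    y <- rnorm(100) + ifelse(g == "pat", 2, 0)
    covs <- data.frame(age = rnorm(100), vol = rnorm(100))
    if (ancova_group(y, g, covs)$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("ANCOVA F and p match an explicit normal-equations computation", {
  set.seed(31)
  n <- 24
  group <- factor(rep(c("a", "b"), each = n / 2))
  covs <- data.frame(vol = rnorm(n), age = rnorm(n))
  y <- rnorm(n) + 0.8 * (group == "b") + 0.3 * covs$vol
  res <- ancova_group(y, group, covs)
  # oracle: hat matrices from scratch on the ranked response
  ry <- rank(y)
  X_full <- cbind(1, covs$vol, covs$age, as.integer(group == "b"))
  X_red <- X_full[, 1:3]
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% ry)
    sum((ry - X %*% beta)^2)
  }
  rss_f <- rss(X_full)
  rss_r <- rss(X_red)
  df2 <- n - ncol(X_full)
  F_oracle <- (rss_r - rss_f) / (rss_f / df2)
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(F_oracle, 1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, df2)
})

test_that("singular designs are rejected with the collinear term named", {
  n <- 20
  group <- rep(c("a", "b"), each = n / 2)
  covs <- data.frame(x1 = rnorm(n))
  covs$x2 <- 2 * covs$x1
  expect_error(ancova_group(rnorm(n), group, covs), "singular|collinear")
})

test_that("the Levene check separates equal from unequal spread", {
  set.seed(41)
  g <- rep(c("a", "b"), each = 100)
  same <- c(rnorm(100), rnorm(100))
  expect_gt(levene_check(same, g)$p, 0.05)
  diff <- c(rnorm(100), rnorm(100, sd = 10))
  expect_lt(levene_check(diff, g)$p, 0.001)
  const <- rep(c(1, 2), each = 100)
  res <- levene_check(const, g)
  expect_identical(res$status, "degenerate")
  expect_true(is.na(res$p))
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.013), 0.013)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(51)
  p <- runif(40)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # direct step-up computation
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * 40 / seq_len(40))))
  expect_equal(adj[o], pmin(stepup, 1))
})

test_that("Pearson CI reproduces the Fisher-z interval around r = 0.48", {
  # construct data with sample correlation exactly 0.48 at n = 36
  set.seed(61)
  n <- 36
  z1 <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ z1))
  y <- 0.48 * z1 + sqrt(1 - 0.48^2) * scale(e)[, 1]
  res <- pearson_with_ci(z1, y)
  expect_equal(res$r, 0.48, tolerance = 1e-10)
  z <- atanh(0.48)
  ci_oracle <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  expect_equal(res$ci, ci_oracle, tolerance = 1e-6)
  expect_equal(round(res$ci, 2), c(0.18, 0.70))
  t_oracle <- 0.48 * sqrt((n - 2) / (1 - 0.48^2))
  expect_equal(res$p, 2 * pt(t_oracle, n - 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_lt(abs(res$p - 0.003), 0.0005)
})

test_that("Pearson CI handles perfect correlation without crashing", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(res$r, 1.0)
  expect_lt(res$p, 1e-10)
})

test_that("partial Spearman with no covariates is plain Spearman", {
  set.seed(71)
  x <- rnorm(25)
  y <- rnorm(25) + 0.5 * x
  res <- partial_spearman(x, y)
  expect_equal(res$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("partial Spearman fully adjusts away a covariate-driven link", {
  set.seed(72)
  z <- rnorm(200)
  x <- rnorm(200)
  y <- exp(z)                    # monotone function of the covariate only
  res <- partial_spearman(x, y, data.frame(z = z))
  expect_lt(abs(res$rho), 0.12)
  expect_gt(res$p, 0.05)
})

test_that("partial Spearman equals the explicit residualization oracle", {
  set.seed(73)
  n <- 18
  x <- rnorm(n)
  y <- rnorm(n)
  covs <- data.frame(a = rnorm(n), b = sample(1:3, n, replace = TRUE))
  res <- partial_spearman(x, y, covs)
  rx <- rank(x)
  ry <- rank(y)
  Z <- cbind(1, rank(covs$a), rank(covs$b))
  resid_on <- function(v) v - Z %*% solve(t(Z) %*% Z, t(Z) %*% v)
  oracle <- oracle_pearson(as.vector(resid_on(rx)),
                           as.vector(resid_on(ry)))
  expect_equal(res$rho, oracle, tolerance = 1e-10)
})

test_that("partial Spearman approaches plain Spearman when covariates are noise", {
  set.seed(74)
  x <- rnorm(300)
  y <- 0.6 * x + rnorm(300)
  covs <- data.frame(u = rnorm(300), v = rnorm(300))
  plain <- partial_spearman(x, y)$rho
  part <- partial_spearman(x, y, covs)$rho
  expect_equal(part, plain, tolerance = 0.05)
})

test_that("forward model comparison matches the RSS-based closed form", {
  set.seed(81)
  n <- 30
  base <- data.frame(gv = rnorm(n), hv = rnorm(n))
  lam <- rnorm(n)
  y <- 5 + 2 * lam + rnorm(n)
  res <- forward_model_comparison(y, list(volumes = base,
                                          lambda = data.frame(lam = lam)))
  ry <- rank(y)
  f1 <- lm(ry ~ gv + hv, data = base)
  f2 <- lm(ry ~ gv + hv + lam, data = cbind(base, lam = lam))
  expect_equal(res$models$adj_r_squared,
               c(summary(f1)$adj.r.squared, summary(f2)$adj.r.squared))
  rss1 <- sum(residuals(f1)^2)
  rss2 <- sum(residuals(f2)^2)
  F_oracle <- (rss1 - rss2) / (rss2 / (n - 4))
  expect_equal(res$comparisons$F_change, F_oracle, tolerance = 1e-10)
  expect_equal(res$comparisons$p_change,
               pf(F_oracle, 1, n - 4, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("pure-noise predictors do not inflate adjusted R-squared", {
  set.seed(82)
  deltas <- replicate(300, {
    n <- 38
    base <- data.frame(v = rnorm(n))
    y <- rnorm(n) + base$v
    res <- forward_model_comparison(y, list(base = base,
                                            noise = data.frame(z = rnorm(n))))
    diff(res$models$adj_r_squared)
  })
  expect_lt(mean(deltas), 0.01)    # centred near zero, not systematically up
})

test_that("a true added predictor is usually detected at n = 38", {
  set.seed(83)
  ps <- replicate(60, {
    n <- 38
    base <- data.frame(v = rnorm(n))
    lam <- rnorm(n)
    y <- 0.6 * lam + 0.4 * base$v + rnorm(n)
    forward_model_comparison(y, list(base = base,
                                     lambda = data.frame(lam = lam))
                             )$comparisons$p_change
  })
  expect_lt(median(ps), 0.05)
})

test_that("non-nested or malformed stage lists are rejected", {
  expect_error(forward_model_comparison(rnorm(10),
                                        list(a = data.frame(x = rnorm(10)))),
               "at least two")
})
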