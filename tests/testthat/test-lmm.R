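test_that("predictor standardization centres, scales, and squares latitude", {
  d <- data.frame(latitude = c(0, 10, 20), size = c(1, 10, 100),
                  vegetation = c("closed", "open", "semi-open"),
                  realm = c("Afrotropical", "Nearctic", "Palearctic"))
  std <- standardize_predictors(d)
  expect_equal(std$data$lat_std, c(-1, 0, 1))
  expect_equal(std$data$lat2, c(1, 0, 1))
  expect_equal(mean(std$data$size_std), 0)
  expect_equal(stats::sd(std$data$size_std), 1)
  expect_equal(levels(std$data$vegetation)[1], "closed")
  expect_equal(levels(std$data$realm)[1], "Afrotropical")

  # standardizing already-standardized data is a fixed point
  d2 <- d; d2$latitude <- std$data$lat_std; d2$size <- 10^std$data$size_std
  std2 <- standardize_predictors(d2)
  expect_equal(std2$data$lat_std, std$data$lat_std, tolerance = 1e-12)

  d3 <- d; d3$size <- 5
  expect_error(standardize_predictors(d3), "zero-variance")
  std_abs <- standardize_predictors(transform(d, latitude = -latitude),
                                    abs_latitude = TRUE)
  expect_equal(std_abs$data$lat_std, c(-1, 0, 1))
})

test_that("lmm_loglik reduces to independent normal densities when variance collapses", {
  set.seed(1)
  n <- 30
  X <- cbind(1, rnorm(n))
  beta <- c(0.5, -1)
  y <- drop(X %*% beta) + rnorm(n)
  gr <- rep(letters[1:5], each = 6)
  ll <- lmm_loglik(y, X, gr, list(beta = beta, sigma2_study = 0, sigma2_resid = 1.3))
  expect_equal(ll, sum(stats::dnorm(y, drop(X %*% beta), sqrt(1.3), log = TRUE)),
               tolerance = 1e-10)
  # single observation limit
  ll1 <- lmm_loglik(2, matrix(1), "g", list(beta = 0, sigma2_study = 0, sigma2_resid = 1))
  expect_equal(ll1, stats::dnorm(2, log = TRUE))
  # rho -> 0: spatial correlation vanishes
  xy <- cbind(runif(n), runif(n))
  ll_sp <- lmm_loglik(y, X, gr, list(beta = beta, sigma2_study = 0.4,
                                     sigma2_resid = 1.3, rho = 1e-8),
                      coords = xy, coord_type = "euclidean")
  ll_id <- lmm_loglik(y, X, gr, list(beta = beta, sigma2_study = 0.4,
                                     sigma2_resid = 1.3))
  expect_equal(ll_sp, ll_id, tolerance = 1e-6)
  expect_error(lmm_loglik(y, X, gr, list(beta = beta, sigma2_study = -1,
                                         sigma2_resid = 1)), ">= 0")
})

test_that("lmm_loglik matches the dense multivariate-normal oracle", {
  set.seed(22)
  n <- 50
  gr <- rep(paste0("s", 1:10), each = 5)
  X <- cbind(1, rnorm(n), rnorm(n))
  beta <- c(0.3, 1.1, -0.7)
  y <- rnorm(n, drop(X %*% beta), 1.5)
  xy <- cbind(rnorm(n), rnorm(n))
  for (rho in list(NULL, 2)) {
    mine <- lmm_loglik(y, X, gr, list(beta = beta, sigma2_study = 0.8,
                                      sigma2_resid = 1.2, rho = rho),
                       coords = xy, coord_type = "euclidean")
    oracle <- dense_mvn_loglik(y, X, beta, gr, 0.8, 1.2, rho, xy)
    expect_equal(mine, oracle, tolerance = 1e-8)
  }
})

test_that("REML equals ML when the fixed-effect design is empty", {
  set.seed(4)
  y <- rnorm(12)
  gr <- rep(c("a", "b", "c"), each = 4)
  X0 <- matrix(numeric(0), nrow = 12, ncol = 0)
  p <- list(beta = numeric(0), sigma2_study = 0.5, sigma2_resid = 1)
  expect_equal(lmm_loglik(y, X0, gr, p, reml = TRUE),
               lmm_loglik(y, X0, gr, p, reml = FALSE))
})

test_that("fit_lmm recovers OLS when the grouping variance is absent", {
  set.seed(8)
  n <- 120
  gr <- rep(paste0("s", 1:12), each = 10)
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)  # no study effect in truth
  f <- fit_lmm(y, X, gr)
  ols <- stats::lm.fit(X, y)$coefficients
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-4)
  expect_lt(f$sigma2_study, 0.05)
})

test_that("REML variance components match ANOVA method-of-moments on balanced data", {
  set.seed(15)
  n_g <- 12; m <- 8
  gr <- rep(paste0("g", 1:n_g), each = m)
  b <- rnorm(n_g, 0, 1.2)
  y <- 3 + b[as.integer(factor(gr))] + rnorm(n_g * m, 0, 0.9)
  X <- matrix(1, n_g * m, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_lmm(y, X, gr, reml = TRUE)
  gm <- tapply(y, gr, mean)
  msw <- sum((y - gm[gr])^2) / (n_g * (m - 1))
  msb <- m * sum((gm - mean(y))^2) / (n_g - 1)
  expect_equal(f$sigma2_resid, msw, tolerance = 1e-5)
  expect_equal(f$sigma2_study, (msb - msw) / m, tolerance = 1e-5)
})

test_that("fit_lmm agrees with nlme on coefficients and likelihood", {
  set.seed(7)
  n_st <- 12; m <- 8; n <- n_st * m
  gr <- rep(sprintf("s%02d", 1:n_st), each = m)
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  y <- simulate_response(X, gr, c(0.5, 1, -0.6), sigma_study = 0.8,
                         sigma_resid = 1, seed = 11)
  d <- data.frame(y = y, x1 = x1, x2 = x2, g = gr)
  for (method in c("ML", "REML")) {
    f <- fit_lmm(y, X, gr, reml = method == "REML")
    nm <- nlme::lme(y ~ x1 + x2, random = ~1 | g, data = d, method = method)
    expect_equal(f$logLik, as.numeric(stats::logLik(nm)), tolerance = 1e-6)
    expect_equal(unname(f$beta), unname(nlme::fixef(nm)), tolerance = 1e-5)
    if (method == "REML")
      expect_equal(unname(f$se), unname(sqrt(diag(stats::vcov(nm)))),
                   tolerance = 1e-5)
  }
})

test_that("the spatial fit matches nlme's corExp structure", {
  set.seed(3)
  n_st <- 10; m <- 10; n <- n_st * m
  gr <- rep(sprintf("s%02d", 1:n_st), each = m)
  xy <- cbind(px = rnorm(n, rep(1:n_st, each = m) * 10, 1), py = rnorm(n))
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n))
  y <- simulate_response(X, gr, c(0.2, 0.7), sigma_study = 0.6,
                         sigma_resid = 1, rho = 2, coords = xy,
                         coord_type = "euclidean", seed = 5)
  f <- fit_lmm(y, X, gr, coords = xy, spatial = TRUE,
               coord_type = "euclidean")
  d <- data.frame(y = y, x1 = X[, 2], g = gr, px = xy[, 1], py = xy[, 2])
  nm <- nlme::lme(y ~ x1, random = ~1 | g, data = d, method = "ML",
                  correlation = nlme::corExp(form = ~px + py | g))
  expect_equal(f$logLik, as.numeric(stats::logLik(nm)), tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(nlme::fixef(nm)), tolerance = 1e-4)
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(-100, k = 3, n = 20), 206 + 24 / 16)
  expect_equal(aicc(-50, k = 0, n = 30), 100)
  expect_equal(aicc(-100, k = 3, n = 1e9), -2 * -100 + 6, tolerance = 1e-6)
  expect_error(aicc(-10, k = 5, n = 6), "n <= k \\+ 1")
  expect_equal(aicc(fake_fit(-100, 3, 20)), 207.5)
})

test_that("model ranking produces normalized Akaike weights", {
  f1 <- fake_fit(-100, 3, 50)  # AICc 206.52
  f2 <- fake_fit(-101, 3, 50)  # dAICc = 2
  tab <- rank_models(list(a = f1, b = f2))
  expect_equal(tab$dAICc, c(0, 2))
  expect_equal(round(tab$weight, 4), c(0.7311, 0.2689))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)

  tab2 <- rank_models(list(a = f1, b = f1))
  expect_equal(tab2$weight, c(0.5, 0.5))
  expect_equal(rank_models(list(only = f1))$weight, 1)
  expect_error(rank_models(list(a = f1, b = fake_fit(n = 49))), "sample sizes")

  # non-converged fits are excluded from the weight normalization
  tab3 <- rank_models(list(a = f1, b = f2, c = fake_fit(-90, 3, 50, converged = FALSE)))
  expect_true(is.na(tab3$weight[tab3$model == "c"]))
  expect_equal(sum(tab3$weight, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  x <- drop(scale(stats::rnorm(50))) * sqrt(2)  # var(X beta) = 2 with beta = 1
  fit <- structure(list(X = cbind(x), beta = 1, sigma2_study = 1,
                        sigma2_resid = 1), class = "lmm_fit")
  r2 <- r2_marginal_conditional(fit)
  expect_equal(r2$R2_marginal, 0.5)
  expect_equal(r2$R2_conditional, 0.75)

  fit0 <- structure(list(X = cbind(x), beta = 0, sigma2_study = 1,
                         sigma2_resid = 1), class = "lmm_fit")
  expect_equal(r2_marginal_conditional(fit0)$R2_marginal, 0)

  fitc <- structure(list(X = cbind(x), beta = 1, sigma2_study = 1,
                         sigma2_resid = 1e-12), class = "lmm_fit")
  expect_equal(r2_marginal_conditional(fitc)$R2_conditional, 1, tolerance = 1e-6)
})

test_that("marginal Wald tests give t = estimate/se and joint F for factors", {
  set.seed(30)
  n_st <- 15; m <- 12; n <- n_st * m
  gr <- rep(sprintf("s%02d", 1:n_st), each = m)
  d <- data.frame(
    x = rnorm(n),
    veg = factor(sample(c("closed", "open", "semi-open"), n, TRUE),
                 levels = c("closed", "open", "semi-open"))
  )
  X <- build_design(~ x + veg, d)
  y <- simulate_response(X, gr, c(0, 1, -1.2, -0.5), 1, 1, seed = 31)
  f <- fit_lmm(y, X, gr, reml = TRUE)
  tst <- marginal_tests(f)
  co <- attr(tst, "coefficients")
  expect_equal(co$t, unname(f$beta / f$se))
  expect_equal(tst$df_den, rep(f$n - ncol(X) - n_st + 1L, 2))
  expect_equal(tst$df_num[tst$term == "veg"], 2)
  # single-coefficient term: F = t^2
  expect_equal(tst$F[tst$term == "x"], co$t[co$coefficient == "x"]^2,
               tolerance = 1e-10)
  # a single-level factor cannot be fitted
  d$bad <- factor("only")
  expect_error(fit_lmm(y, build_design(~ x + bad, d), gr), "contrasts|rank")
})

test_that("fitted coefficients recover simulated truth within Wald error", {
  set.seed(77)
  n_st <- 25; m <- 10; n <- n_st * m
  gr <- rep(sprintf("s%02d", 1:n_st), each = m)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(0.5, 1, -0.8)
  bad <- 0
  for (i in 1:10) {
    y <- simulate_response(X, gr, beta, sigma_study = 1, sigma_resid = 1,
                           seed = 1000 + i)
    f <- fit_lmm(y, X, gr, reml = TRUE)
    bad <- bad + sum(abs(f$beta - beta) > 3 * f$se)
  }
  expect_lte(bad, 2)  # ~0.3% expected rate over 30 intervals
})
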