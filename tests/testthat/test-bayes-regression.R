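test_that("fixed-variance ridge Gibbs matches the closed-form solution", {
  set.seed(10)
  for (rep in 1:5) {
    n <- sample(25:50, 1); p <- sample(4:12, 1)
    X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    dimnames(X) <- list(paste0("s", 1:n), paste0("x", 1:p))
    y <- as.numeric(X %*% rnorm(p) + rnorm(n))
    s2e <- 1; s2b <- 0.5
    fit <- gibbs_fit(y, list(B = X), "ridge",
                     model_config(n_iter = 6000, burn_in = 1000, thin = 2,
                                  seed = rep),
                     control = list(sigma2_e = s2e, sigma2_beta = s2b,
                                    update_sigma2_e = FALSE,
                                    update_prior = FALSE))
    oracle <- solve(crossprod(X) + diag(s2e / s2b, p),
                    crossprod(X, y - mean(y)))
    z <- vapply(seq_len(p), function(j)
      (mean(fit$beta$B[, j]) - oracle[j]) / mc_se(fit$beta$B[, j]), 0)
    expect_lt(max(abs(z)), 6)
    expect_gte(mean(abs(z) < 3), 0.9)
  }
})

test_that("intercept-only posterior matches the Gaussian conjugate form", {
  set.seed(11)
  n <- 60
  y <- rnorm(n, mean = 5, sd = 2)
  X0 <- matrix(0, n, 1, dimnames = list(paste0("s", 1:n), "null"))
  fit <- gibbs_fit(y, list(B = X0), "ridge",
                   model_config(n_iter = 8000, burn_in = 1000, thin = 2,
                                seed = 1),
                   control = list(sigma2_e = 4, update_sigma2_e = FALSE,
                                  update_beta = FALSE, update_prior = FALSE))
  # with flat prior, mu | y ~ N(ybar, sigma2e / n)
  expect_lt(abs(mean(fit$mu) - mean(y)) / mc_se(fit$mu), 4)
  expect_equal(sd(fit$mu), sqrt(4 / n), tolerance = 0.1)
})

test_that("residual-variance draws follow the scaled-inverse-chi-square", {
  set.seed(12)
  n <- 80
  y <- rnorm(n, 2, 1.5)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", 1:n), paste0("x", 1:4)))
  beta_fix <- c(0.5, -0.2, 0, 0.1)
  fit <- gibbs_fit(y, list(B = X), "ridge",
                   model_config(n_iter = 12000, burn_in = 2000, thin = 2,
                                seed = 2),
                   control = list(mu = 2, beta = list(beta_fix),
                                  update_mu = FALSE, update_beta = FALSE,
                                  update_prior = FALSE))
  sse <- sum((y - 2 - X %*% beta_fix)^2)
  draws <- sort(fit$sigma2_e)
  theo <- sse / stats::qchisq(stats::ppoints(length(draws)), df = n - 2,
                              lower.tail = FALSE)
  expect_gt(cor(draws, sort(theo)), 0.99)
  # location agreement too, not just linearity
  expect_equal(median(draws), sse / stats::qchisq(0.5, n - 2),
               tolerance = 0.05)
})

test_that("draw bookkeeping and determinism hold", {
  set.seed(13)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(paste0("s", 1:n), paste0("x", 1:5)))
  y <- rnorm(n)
  cfg <- model_config(n_iter = 25000, burn_in = 5000, thin = 10, seed = 3)
  fit <- gibbs_fit(y, list(B = X), "ridge", cfg)
  expect_identical(n_draws(fit), 2000L)      # (25000 - 5000) / 10
  expect_true(all(fit$sigma2_e > 0))
  expect_true(all(fit$sigma2_beta[, "B"] > 0))

  fit2 <- gibbs_fit(y, list(B = X), "ridge", cfg)
  expect_identical(fit$beta, fit2$beta)
  expect_identical(fit$loglik, fit2$loglik)

  tr <- traces(fit)
  expect_identical(nrow(tr), 2000L)
  expect_true(all(c("mu", "sigma2_e", "sigma2_beta.B", "loglik") %in% names(tr)))
})

test_that("input contracts are enforced", {
  y <- rnorm(10)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("x", 1:5)))
  expect_error(gibbs_fit(y, list(), "ridge"), "non-empty")
  expect_error(gibbs_fit(c(y[-1], NA), list(B = X), "ridge"), "non-finite")
  expect_error(gibbs_fit(y, list(B = X[, 0]), "ridge"), "p = 0")
  expect_error(gibbs_fit(y[1:2], list(B = X[1:2, ]), "ridge"), "at least 3")
  expect_error(model_config(n_iter = 100, burn_in = 200), "burn_in")
  expect_error(model_config(lambda_shape = 0))
})

test_that("prediction is the posterior-mean plug-in", {
  set.seed(14)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(paste0("s", 1:n), paste0("x", 1:8)))
  y <- as.numeric(X %*% rnorm(8) * 0.5 + rnorm(n))
  fit <- gibbs_fit(y, list(B = X), "ridge",
                   model_config(n_iter = 3000, burn_in = 500, thin = 2, seed = 4))
  # all-zero design predicts the posterior-mean intercept
  X0 <- matrix(0, 3, 8, dimnames = list(NULL, colnames(X)))
  expect_equal(predict(fit, list(B = X0)), rep(mean(fit$mu), 3))
  # single-sample prediction equals the dot product by hand
  x1 <- X[1, , drop = FALSE]
  expect_equal(predict(fit, list(B = x1)),
               mean(fit$mu) + sum(x1 * colMeans(fit$beta$B)))
  # in-sample predictions correlate with y under signal
  expect_gt(cor(predict(fit, list(B = X)), y), 0)
  # column mismatch is an error
  Xbad <- X; colnames(Xbad) <- paste0("z", 1:8)
  expect_error(predict(fit, list(B = Xbad)), "do not match")
})

test_that("DIC accounting is internally consistent", {
  set.seed(15)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("x", 1:6)))
  y <- as.numeric(X %*% rnorm(6) + rnorm(n))
  cfg <- model_config(n_iter = 4000, burn_in = 1000, thin = 2, seed = 5)
  fit <- gibbs_fit(y, list(B = X), "ridge", cfg)
  d1 <- compute_dic(fit, y, list(B = X))
  d2 <- compute_dic(gibbs_fit(y, list(B = X), "ridge", cfg), y, list(B = X))
  expect_identical(d1$dic, d2$dic)            # same seed, same DIC
  expect_equal(d1$dic, d1$Dbar + d1$pD)
  expect_gt(d1$pD, 0)                          # Jensen-type property
  short <- gibbs_fit(y, list(B = X), "ridge",
                     model_config(n_iter = 30, burn_in = 20, thin = 2, seed = 1))
  expect_error(compute_dic(short, y, list(B = X)), "at least 10")
})

test_that("lasso shrinks null coefficients harder than ridge when sparse", {
  set.seed(16)
  wins <- 0
  for (seed in 1:3) {
    n <- 150; p <- 120
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("x", 1:p)))
    beta <- numeric(p); beta[1:5] <- 2
    y <- as.numeric(X %*% beta + rnorm(n))
    cfg <- model_config(n_iter = 3000, burn_in = 500, thin = 2, seed = seed)
    br <- colMeans(gibbs_fit(y, list(B = X), "ridge", cfg)$beta$B)
    bl <- colMeans(gibbs_fit(y, list(B = X), "lasso", cfg)$beta$B)
    if (mean(abs(bl[-(1:5)])) < mean(abs(br[-(1:5)]))) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("variance partition recovers structure and normalizes", {
  set.seed(17)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(paste0("s", 1:n), paste0("x", 1:10)))
  y <- as.numeric(X %*% rnorm(10) + rnorm(n))
  fit <- gibbs_fit(y, list(B = X), "ridge",
                   model_config(n_iter = 3000, burn_in = 500, thin = 2, seed = 6))
  vp <- variance_partition(fit, list(B = X))
  expect_identical(vp$component, c("B", "residual"))
  expect_true(all(vp$estimate >= 0))
  # percentages are component means over the draw-averaged total
  expect_equal(sum(vp$estimate) / attr(vp, "total") * 100, sum(vp$percentage),
               tolerance = 1e-9)

  # a null fit (all beta frozen at zero) attributes everything to residual
  fit0 <- gibbs_fit(y, list(B = X), "ridge",
                    model_config(n_iter = 2000, burn_in = 500, thin = 2, seed = 7),
                    control = list(update_beta = FALSE, update_prior = FALSE))
  vp0 <- variance_partition(fit0, list(B = X))
  expect_equal(vp0$estimate[1], 0)
  expect_equal(vp0$percentage[2], 100)
})
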