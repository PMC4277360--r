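#' MCMC model configuration
#'
#' Sampler schedule and hyperparameters for [gibbs_fit()].  The default
#' schedule (25,000 cycles, 5,000 burn-in, thinning 10) retains 2,000 draws
#' and is the documented default for final fits; cross-validation helpers
#' expose a reduced desk-scale schedule.  The variance priors are scaled
#' inverse chi-square with degrees of belief `nu = -2` and scale `S = 0`,
#' i.e. flat (improper) priors whose conditional posteriors remain proper
#' as long as n and every ridge-block p exceed 2.  The lasso regularization
#' parameter lambda^2 carries a Gamma(0.001, 0.001) prior.
#'
#' @param n_iter total MCMC cycles.
#' @param burn_in cycles discarded before sampling starts.
#' @param thin sampling interval after burn-in.
#' @param nu,S degrees of belief and scale of the scaled-inverse-chi-square
#'   priors on the residual and ridge-block variances.
#' @param lambda_shape,lambda_rate Gamma prior on the lasso lambda^2.
#' @param seed optional integer seed applied just before sampling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_iter = 25000, burn_in = 5000, thin = 10,
                         nu = -2, S = 0,
                         lambda_shape = 0.001, lambda_rate = 0.001,
                         seed = NULL) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            lambda_shape > 0, lambda_rate > 0, S >= 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), nu = nu, S = S,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "model_config")
}

#' Fit the whole-genome regression model by Gibbs sampling
#'
#' Samples from the posterior of `y = mu + sum_b X_b beta_b + e` where each
#' explanatory block carries either a Gaussian ("ridge") prior with one
#' common variance `sigma2_beta` per block, or a double-exponential
#' ("lasso") prior represented as a scale mixture of normals with one
#' variance `tau2_j * sigma2_e` per coefficient and a block-level
#' regularization parameter `lambda2`.  Updates are single-site Gibbs steps
#' in fixed column order: mu, each beta_j, the lasso tau2/lambda2, the ridge
#' sigma2_beta, then sigma2_e from its scaled-inverse-chi-square full
#' conditional.  A Gaussian log-likelihood is stored per retained draw for
#' DIC computation.
#'
#' @param y numeric phenotype vector.
#' @param blocks named list of design matrices, all row-aligned with `y`.
#' @param priors character vector (recycled) giving `"ridge"` or `"lasso"`
#'   per block.
#' @param config a [model_config()].
#' @param control list of expert options used mainly by validation tests:
#'   initial values `mu`, `sigma2_e`, `sigma2_beta`, `lambda2`, `beta`
#'   (list per block) and switches `update_mu`, `update_beta`,
#'   `update_sigma2_e`, `update_prior` to freeze parts of the chain at
#'   known values; `store_tau2` (default `TRUE`) controls whether
#'   per-coefficient lasso variances are kept.
#' @return An object of class `posterior_fit` holding the thinned draws of
#'   mu, the per-block coefficient vectors, sigma2_e, per-ridge-block
#'   sigma2_beta, per-lasso-block lambda2 and tau2, and the per-draw
#'   log-likelihood.
#' @export
gibbs_fit <- function(y, blocks, priors = "ridge", config = model_config(),
                      control = list()) {
  stopifnot(is.numeric(y), inherits(config, "model_config"))
  if (!is.list(blocks) || length(blocks) == 0) stop("blocks must be a non-empty list")
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    names(blocks) <- paste0("block", seq_along(blocks))
  blocks <- lapply(blocks, as.matrix)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(y))) stop("non-finite values in y")
  for (b in blocks) {
    if (nrow(b) != n) stop("all blocks must be row-aligned with y")
    if (ncol(b) == 0) stop("empty (p = 0) blocks are not allowed")
    if (!all(is.finite(b))) stop("non-finite values in a design block")
  }
  priors <- rep_len(match.arg(priors, c("ridge", "lasso"), several.ok = TRUE),
                    length(blocks))

  ctl <- list(mu = mean(y), sigma2_e = var(y) / 2,
              sigma2_beta = NULL, lambda2 = NULL, beta = NULL,
              update_mu = TRUE, update_beta = TRUE,
              update_sigma2_e = TRUE, update_prior = TRUE,
              store_tau2 = TRUE)
  ctl[names(control)] <- control

  # the flat (nu = -2, S = 0) variance priors stay proper only when the
  # conditional degrees of freedom n + nu and p + nu are positive
  if (isTRUE(ctl$update_sigma2_e) && n + config$nu <= 0)
    stop("n too small for the residual-variance prior")
  if (isTRUE(ctl$update_prior))
    for (i in seq_along(blocks))
      if (priors[i] == "ridge" && ncol(blocks[[i]]) + config$nu <= 0)
        stop("ridge blocks need p > ", -config$nu, " columns")

  p <- vapply(blocks, ncol, 0L)
  prior_code <- ifelse(priors == "lasso", 1L, 0L)
  vy <- max(var(y), 1e-8)
  sigma2b0 <- rep(if (is.null(ctl$sigma2_beta)) vy / (2 * max(p, 1)) else
    ctl$sigma2_beta, length.out = length(blocks))
  # lambda^2 starts at its rough equilibrium magnitude for a block explaining
  # about half the phenotypic variance (E[tau2] = 2/lambda2, block variance
  # ~ p * tau2 * sigma2_e); starting at O(1) leaves short chains stranded in
  # an overfitted mode
  lambda20 <- if (is.null(ctl$lambda2)) 2 * pmax(p, 1) else
    rep(ctl$lambda2, length.out = length(blocks))
  beta0 <- if (is.null(ctl$beta)) lapply(p, numeric) else lapply(ctl$beta, as.numeric)
  tau20 <- lapply(seq_along(p), function(i) rep(2 / lambda20[i], p[i]))

  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- gibbs_sampler_cpp(as.numeric(y), blocks, prior_code,
                           config$n_iter, config$burn_in, config$thin,
                           config$nu, config$S,
                           config$lambda_shape, config$lambda_rate,
                           ctl$mu, beta0, ctl$sigma2_e,
                           sigma2b0, lambda20, tau20,
                           isTRUE(ctl$update_mu), isTRUE(ctl$update_beta),
                           isTRUE(ctl$update_sigma2_e), isTRUE(ctl$update_prior),
                           isTRUE(ctl$store_tau2))

  bn <- names(blocks)
  beta <- raw$beta
  names(beta) <- bn
  for (i in seq_along(beta)) colnames(beta[[i]]) <- colnames(blocks[[i]])
  tau2 <- raw$tau2
  names(tau2) <- bn
  colnames(raw$sigma2_beta) <- bn
  colnames(raw$lambda2) <- bn

  structure(list(mu = raw$mu,
                 beta = beta,
                 sigma2_e = raw$sigma2_e,
                 sigma2_beta = raw$sigma2_beta,
                 lambda2 = raw$lambda2,
                 tau2 = tau2,
                 loglik = raw$loglik,
                 priors = setNames(priors, bn),
                 block_cols = lapply(blocks, colnames),
                 n = n,
                 config = config),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit: %d draws, n = %d, blocks: %s\n",
              length(x$mu), x$n,
              paste(sprintf("%s[%s, p=%d]", names(x$priors), x$priors,
                            vapply(x$block_cols, length, 0L)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of retained posterior draws
#' @param fit a `posterior_fit`.
#' @export
n_draws <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  length(fit$mu)
}

#' Posterior-mean plug-in prediction
#'
#' Predicts phenotypes for new samples as `posterior-mean mu +
#' sum_b X_new_b %*% posterior-mean beta_b`.
#'
#' @param object a `posterior_fit`.
#' @param blocks_new named list of design matrices whose columns match the
#'   training blocks.
#' @param ... unused.
#' @return Numeric vector of predicted phenotypic values.
#' @export
predict.posterior_fit <- function(object, blocks_new, ...) {
  stopifnot(is.list(blocks_new), length(blocks_new) == length(object$beta))
  if (is.null(names(blocks_new))) names(blocks_new) <- names(object$beta)
  yhat <- rep(mean(object$mu), nrow(as.matrix(blocks_new[[1]])))
  for (b in names(object$beta)) {
    Xb <- as.matrix(blocks_new[[b]])
    if (!identical(colnames(Xb), object$block_cols[[b]]))
      stop("columns of block '", b, "' do not match the training design")
    yhat <- yhat + as.numeric(Xb %*% colMeans(object$beta[[b]]))
  }
  yhat
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with Dbar the posterior mean of the deviance
#' (-2 log-likelihood over the retained draws) and pD = Dbar - D(theta_hat),
#' the deviance evaluated at the posterior means of mu, all coefficients and
#' sigma2_e (the standard plug-in for hierarchical Gaussian regression).
#'
#' @param fit a `posterior_fit` (at least 10 retained draws).
#' @param y training phenotype vector.
#' @param blocks training design blocks.
#' @return List with `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
compute_dic <- function(fit, y, blocks) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (n_draws(fit) < 10) stop("need at least 10 retained draws for DIC")
  Dbar <- mean(-2 * fit$loglik)
  yhat <- predict(fit, blocks)
  s2 <- mean(fit$sigma2_e)
  n <- length(y)
  ll_hat <- -0.5 * n * log(2 * pi * s2) - 0.5 * sum((y - yhat)^2) / s2
  Dhat <- -2 * ll_hat
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Block-wise variance partition from posterior samples
#'
#' For every retained draw t and block b the fitted contribution
#' `g_b = X_b beta_b^(t)` is computed and its sample variance across
#' individuals taken; the posterior mean and SD of these per-draw variances
#' estimate the variance explained by each block.  The total is the
#' per-draw sum of all block variances plus sigma2_e, averaged over draws,
#' and percentages are component posterior means over that total.
#'
#' @param fit a `posterior_fit`.
#' @param blocks the training design blocks.
#' @return An object of class `variance_partition`: a data.frame with one
#'   row per component (each block, then the residual) and columns
#'   `component`, `estimate`, `post_sd`, `percentage`, plus a `total`
#'   attribute.
#' @export
variance_partition <- function(fit, blocks) {
  stopifnot(inherits(fit, "posterior_fit"), is.list(blocks),
            length(blocks) == length(fit$beta))
  if (is.null(names(blocks))) names(blocks) <- names(fit$beta)
  m <- n_draws(fit)
  Vb <- matrix(0, m, length(blocks),
               dimnames = list(NULL, names(fit$beta)))
  for (b in names(fit$beta)) {
    Xb <- as.matrix(blocks[[b]])
    if (!identical(colnames(Xb), fit$block_cols[[b]]))
      stop("columns of block '", b, "' do not match the training design")
    G <- Xb %*% t(fit$beta[[b]])            # n x m fitted contributions
    Vb[, b] <- apply(G, 2, var)
  }
  total_draws <- rowSums(Vb) + fit$sigma2_e
  total <- mean(total_draws)
  est <- c(colMeans(Vb), residual = mean(fit$sigma2_e))
  sds <- c(apply(Vb, 2, sd), residual = sd(fit$sigma2_e))
  out <- data.frame(component = names(est),
                    estimate = unname(est),
                    post_sd = unname(sds),
                    percentage = unname(est) / total * 100,
                    stringsAsFactors = FALSE)
  structure(out, total = total, class = c("variance_partition", "data.frame"))
}

#' @export
print.variance_partition <- function(x, digits = 3, ...) {
  cat("Variance partition (posterior means)\n")
  cat(sprintf("  %-12s %-18s %s\n", "Component", "Estimate", "Percentage"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %-18s %d\n", x$component[i],
                sprintf("%.*g (%.*g)", digits, x$estimate[i], digits, x$post_sd[i]),
                round(x$percentage[i])))
  }
  cat(sprintf("  %-12s %.*g\n", "Total", digits, attr(x, "total")))
  invisible(x)
}

#' Extract MCMC traces
#'
#' Returns the scalar-parameter chains as a data.frame (one row per
#' retained draw) for convergence inspection via trace plots.
#'
#' @param fit a `posterior_fit`.
#' @return data.frame with columns `draw`, `mu`, `sigma2_e`, per-ridge-block
#'   `sigma2_beta.*`, per-lasso-block `lambda2.*`, and `loglik`.
#' @export
traces <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  out <- data.frame(draw = seq_len(n_draws(fit)), mu = fit$mu,
                    sigma2_e = fit$sigma2_e)
  for (b in names(fit$priors)) {
    if (fit$priors[[b]] == "ridge")
      out[[paste0("sigma2_beta.", b)]] <- fit$sigma2_beta[, b]
    else
      out[[paste0("lambda2.", b)]] <- fit$lambda2[, b]
  }
  out$loglik <- fit$loglik
  out
}
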