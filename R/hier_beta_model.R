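# Bayesian hierarchical beta regression for a mode share outcome.
#
# Likelihood: y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi), the mean-precision
# parameterization, with logit(mu_i) linear in standardized covariates.
# City-level slopes vary by country and their country-specific values are
# moderated by national covariates (by default, log GDP per capita):
#
#   logit(mu_i) = alpha_{j(i)} + sum_k beta_{j(i),k} x_{ik}
#   alpha_j ~ Normal(alpha0 + sum_m delta_m z_{jm}, sigma_alpha)
#   beta_jk ~ Normal(gamma0_k + sum_m in moderators gamma1_km z_{jm}, tau_k)

#' Beta log-density in the mean-precision parameterization
#'
#' Log density of Beta(y; mu * phi, (1 - mu) * phi): mean mu in (0, 1) and
#' precision phi > 0, so Var(y) = mu (1 - mu) / (1 + phi).
#'
#' @param y Observed share, strictly inside (0, 1).
#' @param mu Mean parameter in (0, 1).
#' @param phi Precision, > 0.
#' @return Log density (vectorized over arguments of common length).
#' @export
beta_logpdf <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly in (0, 1)")
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly in (0, 1)")
  if (any(phi <= 0)) stop("phi must be > 0")
  a <- mu * phi
  b <- (1 - mu) * phi
  lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * log(y) + (b - 1) * log1p(-y)
}

#' Model specification for one outcome
#'
#' @param outcome `"walk"` or `"cycle"`.
#' @param city_covariates Ordered subset of the seven city covariates
#'   (`ln_density`, `B`, `terrain`, `tmin`, `tmin2`, `tmax`, `precip`).
#' @param country_covariates Ordered subset of `gas_price`, `ln_gdp_pc`,
#'   `dependency_ratio`, entering the country-intercept regression.
#' @param moderators Country covariates moderating the city slopes
#'   (default `ln_gdp_pc` only).
#' @param prior_scales Named list of SDs for the normal priors: `intercept`
#'   and `delta` (default 2), `gamma0` and `gamma1` (default 1), and the
#'   half-normal scales `tau` and `sigma_alpha` (default 1).
#' @param phi_rate Rate of the exponential prior on the precision phi
#'   (default 0.1).
#' @param chains,adapt,warmup,iter,thin Sampler settings; `iter` is the
#'   number of kept draws per chain after thinning.
#' @param seed Integer master seed; per-chain RNG seeds are derived from it.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome = c("walk", "cycle"),
                       city_covariates = CITY_COVARIATES,
                       country_covariates = COUNTRY_COVARIATES,
                       moderators = "ln_gdp_pc",
                       prior_scales = list(),
                       phi_rate = 0.1,
                       chains = 2, adapt = 1500, warmup = 2500,
                       iter = 500, thin = 10, seed = 1L) {
  outcome <- match.arg(outcome)
  stopifnot(length(city_covariates) > 0,
            !anyDuplicated(city_covariates),
            all(city_covariates %in% CITY_COVARIATES),
            all(country_covariates %in% COUNTRY_COVARIATES),
            all(moderators %in% country_covariates))
  ps <- modifyList(list(intercept = 2, delta = 2, gamma0 = 1, gamma1 = 1,
                        tau = 1, sigma_alpha = 1), prior_scales)
  if (any(unlist(ps) <= 0) || phi_rate <= 0) {
    stop("prior scales and phi_rate must be > 0")
  }
  structure(list(outcome = outcome, city_covariates = city_covariates,
                 country_covariates = country_covariates,
                 moderators = moderators, prior_scales = ps,
                 phi_rate = phi_rate, chains = chains, adapt = adapt,
                 warmup = warmup, iter = iter, thin = thin,
                 seed = as.integer(seed)),
            class = "model_spec")
}

jags_model_string <- function(has_country, n_mod) {
  mod_term <- if (n_mod > 0) " + inprod(g1[k,], zmod[j,])" else ""
  cty_term <- if (has_country) " + inprod(delta, Z[j,])" else ""
  g1_block <- if (n_mod > 0) paste0(
    "    for (m in 1:Mmod) { g1[k,m] ~ dnorm(0, prec_g1) }\n") else ""
  delta_block <- if (has_country) paste0(
    "  for (m in 1:M) { delta[m] ~ dnorm(0, prec_delta) }\n") else ""
  paste0(
"model {
  for (i in 1:N) {
    logit(mu[i]) <- alpha[cc[i]] + inprod(beta[cc[i],], X[i,])
    y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
  }
  for (j in 1:J) {
    alpha[j] ~ dnorm(a0", cty_term, ", prec_a)
    for (k in 1:K) {
      beta[j,k] ~ dnorm(g0[k]", mod_term, ", prec_b[k])
    }
  }
  for (k in 1:K) {
    g0[k] ~ dnorm(0, prec_g0)
", g1_block,
"    tau[k] ~ dnorm(0, prec_tau) T(0,)
    prec_b[k] <- 1 / (tau[k] * tau[k])
  }
", delta_block,
"  a0 ~ dnorm(0, prec_a0)
  sigma_alpha ~ dnorm(0, prec_sa) T(0,)
  prec_a <- 1 / (sigma_alpha * sigma_alpha)
  phi ~ dexp(phi_rate)
}")
}

#' Fit the hierarchical beta regression
#'
#' Draws from the posterior of the full hierarchical model by MCMC (Gibbs /
#' Metropolis via JAGS), using a centered parameterization of the country
#' level so that the slope hyper-means are updated by conjugate samplers.
#' Split-chain potential-scale-reduction (Rhat) and effective sample sizes
#' are computed for every hyperparameter; the fit aborts when any Rhat
#' exceeds 1.05 (disable via `check_convergence = FALSE` for exploratory
#' runs) and warns when any effective size falls below 100.
#'
#' @param spec A [model_spec()].
#' @param design A [build_design()] result.
#' @param shares Numeric vector of outcome shares, row-aligned with
#'   `design$X`, strictly inside (0, 1) (apply [shrink_boundary()] first).
#' @param check_convergence Abort on Rhat > 1.05 (default `TRUE`).
#' @param quiet Suppress JAGS progress output.
#' @return A `posterior_draws` object: matrices/arrays of joint draws of
#'   `alpha` (draws x countries), `beta` (draws x countries x covariates),
#'   `gamma0`, `gamma1`, `delta`, `tau`, `phi`, `alpha0`, `sigma_alpha`,
#'   plus the design registry, country index, and diagnostics.
#' @export
fit_hier_beta <- function(spec, design, shares, check_convergence = TRUE,
                          quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(design, "design_matrix"))
  y <- shares
  if (length(y) != nrow(design$X)) {
    stop("shares must be row-aligned with the design matrix")
  }
  ok <- !is.na(y)
  bad <- which(!ok)
  y <- y[ok]
  if (any(y <= 0 | y >= 1)) {
    stop("non-finite likelihood: shares at 0 or 1 in rows ",
         paste(utils::head(which(shares <= 0 | shares >= 1), 5),
               collapse = ", "),
         "; apply shrink_boundary() first")
  }
  X <- design$X[ok, spec$city_covariates, drop = FALSE]
  cc <- design$country_index[ok]
  keep_j <- sort(unique(cc))
  jmap <- match(cc, keep_j)
  Z <- design$Z[keep_j, spec$country_covariates, drop = FALSE]
  zmod <- design$Z[keep_j, spec$moderators, drop = FALSE]
  J <- length(keep_j)
  K <- ncol(X)
  M <- ncol(Z)
  Mmod <- ncol(zmod)

  ps <- spec$prior_scales
  dat <- list(y = y, X = X, cc = jmap, N = length(y), J = J, K = K,
              prec_g0 = 1 / ps$gamma0^2, prec_tau = 1 / ps$tau^2,
              prec_a0 = 1 / ps$intercept^2, prec_sa = 1 / ps$sigma_alpha^2,
              phi_rate = spec$phi_rate)
  if (M > 0) {
    dat$Z <- Z; dat$M <- M; dat$prec_delta <- 1 / ps$delta^2
  }
  if (Mmod > 0) {
    dat$zmod <- zmod; dat$Mmod <- Mmod; dat$prec_g1 <- 1 / ps$gamma1^2
  }

  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = (spec$seed * 1000L + ch) %% .Machine$integer.max,
         phi = 10, a0 = qlogis(mean(y)))
  })
  monitors <- c("alpha", "beta", "g0", "tau", "phi", "a0", "sigma_alpha")
  if (M > 0) monitors <- c(monitors, "delta")
  if (Mmod > 0) monitors <- c(monitors, "g1")

  run <- function() {
    jm <- rjags::jags.model(
      textConnection(jags_model_string(M > 0, Mmod)),
      data = dat, inits = inits, n.chains = spec$chains,
      n.adapt = spec$adapt, quiet = quiet)
    update(jm, spec$warmup, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = spec$iter * spec$thin,
                        thin = spec$thin, progress.bar = "none")
  }
  samp <- if (quiet) suppressMessages(run()) else run()

  hyper_pat <- "^(g0|g1|tau|phi|a0|sigma_alpha|delta)"
  hyper <- grep(hyper_pat, coda::varnames(samp), value = TRUE)
  rhat <- vapply(hyper, function(v) {
    split_rhat(sapply(samp, function(ch) as.numeric(ch[, v])))
  }, numeric(1))
  ess <- coda::effectiveSize(samp[, hyper, drop = FALSE])
  diagnostics <- data.frame(parameter = hyper, rhat = rhat,
                            ess = as.numeric(ess[hyper]),
                            stringsAsFactors = FALSE, row.names = NULL)
  if (check_convergence && any(rhat > 1.05, na.rm = TRUE)) {
    worst <- diagnostics[which.max(diagnostics$rhat), ]
    stop("convergence failure: split-chain Rhat = ",
         round(worst$rhat, 3), " for ", worst$parameter,
         " (gate: 1.05); increase warmup/iter")
  }
  if (any(ess < 100)) {
    warning("low effective sample size (< 100) for: ",
            paste(names(ess)[ess < 100], collapse = ", "))
  }

  m <- as.matrix(samp)  # draws x params, chains stacked
  D <- nrow(m)
  pick <- function(stub, dims) {
    cols <- grep(paste0("^", stub, "(\\[|$)"), colnames(m), value = TRUE)
    a <- m[, cols, drop = FALSE]
    if (is.null(dims)) return(as.numeric(a))
    if (length(dims) == 1) return(a)
    # JAGS names are column-major: stub[j,k]
    array(a, dim = c(D, dims))
  }
  draws <- structure(list(
    outcome = spec$outcome,
    alpha = pick("alpha", J),
    beta = pick("beta", c(J, K)),
    gamma0 = pick("g0", K),
    gamma1 = if (Mmod > 0) pick("g1", c(K, Mmod)) else NULL,
    delta = if (M > 0) pick("delta", M) else NULL,
    tau = pick("tau", K),
    phi = pick("phi", NULL),
    alpha0 = pick("a0", NULL),
    sigma_alpha = pick("sigma_alpha", NULL),
    covariates = spec$city_covariates,
    country_covariates = spec$country_covariates,
    moderators = spec$moderators,
    country_ids = design$country_ids[keep_j],
    z_country = design$Z[keep_j, , drop = FALSE],
    registry = design$registry,
    n_draws = D,
    diagnostics = diagnostics,
    dropped_rows = bad,
    spec = spec
  ), class = "posterior_draws")
  colnames(draws$gamma0) <- spec$city_covariates
  colnames(draws$tau) <- spec$city_covariates
  if (!is.null(draws$delta)) colnames(draws$delta) <- spec$country_covariates
  if (!is.null(draws$gamma1)) {
    dimnames(draws$gamma1) <- list(NULL, spec$city_covariates,
                                   spec$moderators)
  }
  draws
}

#' Split-chain potential scale reduction factor
#'
#' Classic Rhat computed after splitting each chain in half, so within-chain
#' trends register as apparent non-convergence.
#'
#' @param x Matrix of draws, one column per chain.
#' @return Scalar Rhat (NA when the parameter is constant).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- floor(n / 2)
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[(n - h + 1):n, , drop = FALSE])
  m <- ncol(halves)
  cm <- colMeans(halves)
  W <- mean(apply(halves, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- h * stats::var(cm)
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Logit-scale linear predictor for one design row
#'
#' alpha_j + sum_k beta_jk x_k, evaluated for every posterior draw. Under
#' the centered parameterization the country intercept alpha_j already
#' carries the country-covariate contribution sum_m delta_m z_m(j) (delta
#' enters as the prior mean of alpha_j), so no separate delta term is added.
#'
#' @param draws A `posterior_draws` object.
#' @param x Named numeric vector of standardized city covariates (names must
#'   cover the fitted covariates; missing names default to 0).
#' @param country_id Country identifier present in the fit.
#' @return Numeric vector, one value per draw.
#' @export
linear_predictor <- function(draws, x, country_id) {
  j <- match(country_id, draws$country_ids)
  if (is.na(j)) stop("unknown country '", country_id, "'")
  xv <- setNames(numeric(length(draws$covariates)), draws$covariates)
  if (length(x) > 0) {
    if (is.null(names(x))) {
      if (length(x) != length(xv)) stop("unnamed x must match covariates")
      xv[] <- x
    } else {
      unknown <- setdiff(names(x), draws$covariates)
      if (length(unknown) > 0) {
        stop("covariate(s) not in model: ", paste(unknown, collapse = ", "))
      }
      xv[names(x)] <- x
    }
  }
  eta <- draws$alpha[, j] + as.numeric(draws$beta[, j, ] %*% xv)
  eta
}

#' Posterior predictive mode share
#'
#' Per draw, mu = inverse-logit(linear predictor). Optionally adds beta
#' observation noise around each draw's mu.
#'
#' @inheritParams linear_predictor
#' @param sample_beta Draw a beta realization per posterior draw instead of
#'   returning the mean mu.
#' @return Numeric vector of predicted shares, one per draw.
#' @export
posterior_predict <- function(draws, x, country_id, sample_beta = FALSE) {
  mu <- plogis(linear_predictor(draws, x, country_id))
  if (sample_beta) {
    mu <- rbeta(length(mu), mu * draws$phi, (1 - mu) * draws$phi)
  }
  mu
}

#' Total data log-likelihood under the fitted model
#'
#' Sums [beta_logpdf()] over rows for a single parameter draw; used for
#' deterministic likelihood checks.
#'
#' @param draws A `posterior_draws` object.
#' @param draw Index of the posterior draw to evaluate.
#' @param design The `design_matrix` used in fitting.
#' @param shares Outcome shares aligned with the design (boundary-shrunk).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(draws, draw, design, shares) {
  ok <- !is.na(shares)
  X <- design$X[ok, draws$covariates, drop = FALSE]
  jm <- match(design$country_ids[design$country_index[ok]], draws$country_ids)
  b <- matrix(draws$beta[draw, , ], nrow = length(draws$country_ids),
              dimnames = list(NULL, draws$covariates))
  eta <- draws$alpha[draw, jm] + rowSums(X * b[jm, , drop = FALSE])
  sum(beta_logpdf(shares[ok], plogis(eta), draws$phi[draw]))
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Hierarchical beta regression posterior (", x$outcome, " share)\n",
      sep = "")
  cat("  draws: ", x$n_draws, "; countries: ", length(x$country_ids),
      "; city covariates: ", paste(x$covariates, collapse = ", "), "\n",
      sep = "")
  cat("  max Rhat: ", round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
      "; min ESS: ", round(min(x$diagnostics$ess), 1), "\n", sep = "")
  invisible(x)
}
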