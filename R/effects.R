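# One-SD marginal effects on the percentage-point scale.
#
# A covariate's effect in country j is the change in the predicted mode
# share when that covariate moves from the reference profile (all
# standardized covariates at 0, i.e. the pooled mean city) to +1 pooled SD,
# holding everything else fixed: 100 * (invlogit(eta1) - invlogit(eta0)).
# Minimum temperature is perturbed on the raw degree-Celsius scale so that
# its linear and squared columns move coherently.

# Standardized profiles (x0, x1) for a +1 SD perturbation of `covariate`.
effect_profiles <- function(draws, covariate) {
  covs <- draws$covariates
  x0 <- setNames(numeric(length(covs)), covs)
  x1 <- x0
  if (covariate == "tmin" && "tmin2" %in% covs) {
    rt <- draws$registry
    m_t <- rt$mean[rt$covariate == "tmin"]
    s_t <- rt$sd[rt$covariate == "tmin"]
    m_t2 <- rt$mean[rt$covariate == "tmin2"]
    s_t2 <- rt$sd[rt$covariate == "tmin2"]
    x0["tmin"] <- 0
    x0["tmin2"] <- (m_t^2 - m_t2) / s_t2
    x1 <- x0
    x1["tmin"] <- 1
    x1["tmin2"] <- ((m_t + s_t)^2 - m_t2) / s_t2
  } else {
    x1[covariate] <- 1
  }
  list(x0 = x0, x1 = x1)
}

# Per-draw effect (share-fraction scale) of +1 SD of `covariate` in country
# index j. Handles both city covariates (country-specific slope) and country
# covariates (single coefficient delta).
effect_draws_j <- function(draws, covariate, j) {
  if (covariate %in% draws$covariates) {
    pr <- effect_profiles(draws, covariate)
    b <- draws$beta[, j, , drop = FALSE]
    b <- matrix(b, nrow = draws$n_draws,
                dimnames = list(NULL, draws$covariates))
    eta0 <- draws$alpha[, j] + as.numeric(b %*% pr$x0)
    eta1 <- draws$alpha[, j] + as.numeric(b %*% pr$x1)
  } else if (covariate %in% draws$country_covariates) {
    eta0 <- draws$alpha[, j]
    eta1 <- eta0 + draws$delta[, covariate]
  } else {
    stop("covariate '", covariate, "' not in fitted model")
  }
  plogis(eta1) - plogis(eta0)
}

summarize_effect <- function(e, covariate, country) {
  data.frame(covariate = covariate, country = country,
             effect = 100 * mean(e),
             lower = 100 * unname(quantile(e, 0.025)),
             upper = 100 * unname(quantile(e, 0.975)),
             stringsAsFactors = FALSE)
}

#' One-SD marginal effect for a covariate in one country
#'
#' @param draws A `posterior_draws` object.
#' @param covariate A fitted city or country covariate name.
#' @param country_id Country identifier.
#' @return A one-row data.frame: `covariate`, `country`, `effect`
#'   (percentage points of mode share per +1 pooled SD), `lower`, `upper`
#'   (95% posterior interval).
#' @export
marginal_effect <- function(draws, covariate, country_id) {
  j <- match(country_id, draws$country_ids)
  if (is.na(j)) stop("unknown country '", country_id, "'")
  summarize_effect(effect_draws_j(draws, covariate, j), covariate, country_id)
}

# Draws x countries matrix of per-draw effects (fraction scale).
effect_draws_all <- function(draws, covariate) {
  em <- vapply(seq_along(draws$country_ids), function(j) {
    effect_draws_j(draws, covariate, j)
  }, numeric(draws$n_draws))
  matrix(em, nrow = draws$n_draws)
}

#' Median-country marginal effect
#'
#' Computes the per-draw effect in every country, takes the cross-country
#' median within each draw, and summarizes the resulting posterior.
#'
#' @inheritParams marginal_effect
#' @return A one-row data.frame as in [marginal_effect()], with country
#'   `"median-country"`.
#' @export
median_country_effect <- function(draws, covariate) {
  if (length(draws$country_ids) < 1) stop("no countries in draws")
  em <- effect_draws_all(draws, covariate)
  med <- apply(em, 1, median)
  summarize_effect(med, covariate, "median-country")
}

#' Cross-level moderation of a city slope by a national covariate
#'
#' Two complementary views of how a city covariate's effect varies with a
#' national covariate (income by default): (a) the model's own moderation
#' coefficient gamma1 for that (covariate, moderator) pair; (b) a
#' descriptive unweighted least-squares regression of the posterior-mean
#' country effects (percentage points) on the standardized moderator, with
#' its 95% confidence interval.
#'
#' @inheritParams marginal_effect
#' @param moderator A country covariate (default `"ln_gdp_pc"`).
#' @return A list with `gamma1` (NULL, with a warning, when the moderator is
#'   not in the model) and `descriptive` (slope, CI, R-squared, `degenerate`
#'   flag when residual degrees of freedom are 0).
#' @export
moderation_summary <- function(draws, covariate, moderator = "ln_gdp_pc") {
  g1 <- NULL
  if (covariate %in% draws$covariates && moderator %in% draws$moderators) {
    gd <- draws$gamma1[, covariate, moderator]
    g1 <- data.frame(covariate = covariate, moderator = moderator,
                     mean = mean(gd),
                     lower = unname(quantile(gd, 0.025)),
                     upper = unname(quantile(gd, 0.975)),
                     stringsAsFactors = FALSE)
  } else {
    warning("moderator '", moderator, "' not in model for covariate '",
            covariate, "'; returning descriptive regression only")
  }
  e_mean <- 100 * colMeans(effect_draws_all(draws, covariate))
  z <- draws$z_country[, moderator]
  J <- length(e_mean)
  if (J < 2) stop("need at least 2 countries for the descriptive regression")
  fitlm <- lm(e_mean ~ z)
  degenerate <- stats::df.residual(fitlm) == 0
  ci <- if (degenerate) c(NA_real_, NA_real_) else confint(fitlm)["z", ]
  desc <- data.frame(
    covariate = covariate, moderator = moderator,
    slope = unname(coef(fitlm)["z"]),
    lower = unname(ci[1]), upper = unname(ci[2]),
    r_squared = summary(fitlm)$r.squared,
    degenerate = degenerate,
    stringsAsFactors = FALSE)
  list(gamma1 = g1, descriptive = desc,
       country_effects = data.frame(country = draws$country_ids,
                                    effect = e_mean, z_moderator = z,
                                    stringsAsFactors = FALSE))
}

#' Ordered effect table for one or both outcomes
#'
#' Median-country one-SD effects for every fitted city and country
#' covariate, ordered by the absolute effect size (ties broken
#' lexicographically by covariate name), together with the per-country
#' effect distributions behind them.
#'
#' @param walk_draws `posterior_draws` for the walk share (or NULL).
#' @param cycle_draws `posterior_draws` for the cycle share (or NULL).
#' @return A list with `table` (outcome, covariate, effect, lower, upper)
#'   and `country_effects` (outcome, covariate, country, effect).
#' @export
effect_table <- function(walk_draws = NULL, cycle_draws = NULL) {
  inputs <- list(walk = walk_draws, cycle = cycle_draws)
  present <- !vapply(inputs, is.null, logical(1))
  if (!any(present)) stop("at least one outcome's draws required")
  if (!all(present)) {
    warning("draws available for ", paste(names(inputs)[present]),
            " only; emitting a single-outcome table")
  }
  rows <- list()
  ceff <- list()
  for (oc in names(inputs)[present]) {
    dr <- inputs[[oc]]
    covs <- c(dr$covariates, dr$country_covariates)
    tab <- do.call(rbind, lapply(covs, function(k) {
      cbind(outcome = oc, median_country_effect(dr, k))
    }))
    tab <- tab[order(-abs(tab$effect), tab$covariate), ]
    rows[[oc]] <- tab
    ceff[[oc]] <- do.call(rbind, lapply(dr$covariates, function(k) {
      data.frame(outcome = oc, covariate = k, country = dr$country_ids,
                 effect = 100 * colMeans(effect_draws_all(dr, k)),
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       country_effects = do.call(rbind, c(ceff,
                                          list(make.row.names = FALSE))))
}
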