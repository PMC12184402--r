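# Single-draw fake posteriors make every effect computable by hand.

two_country_draws <- function(D = 1, alpha_val = 0, slope = 0,
                              slope_cov = "ln_density", registry = NULL,
                              delta = NULL) {
  alpha <- matrix(alpha_val, D, 2, dimnames = list(NULL, c("AA", "BB")))
  beta <- array(0, c(D, 2, 7))
  k <- match(slope_cov, CITY_COVARIATES)
  beta[, , k] <- slope
  fake_draws(alpha, beta, registry %||% default_registry(),
             z_country = matrix(c(-1, 1, -1, 1, -1, 1), 2, 3,
                                dimnames = list(NULL, COUNTRY_COVARIATES)),
             delta = delta)
}

test_that("marginal effects reproduce the logistic closed form", {
  # zero slope, any baseline: zero effect
  dr0 <- two_country_draws(alpha_val = -1.2, slope = 0)
  expect_equal(marginal_effect(dr0, "ln_density", "AA")$effect, 0)

  # slope 0.1 at baseline mu = 0.5
  dr <- two_country_draws(alpha_val = 0, slope = 0.1)
  eff <- marginal_effect(dr, "ln_density", "AA")
  expect_equal(eff$effect, 100 * (plogis(0.1) - 0.5), tolerance = 1e-9)
  expect_equal(eff$lower, eff$effect)  # single draw: degenerate interval
  expect_equal(eff$upper, eff$effect)

  # link curvature: the same slope moves shares more at mu = 0.5 than at
  # mu = 0.05
  dr05 <- two_country_draws(alpha_val = qlogis(0.05), slope = 0.1)
  expect_gt(marginal_effect(dr, "ln_density", "AA")$effect,
            marginal_effect(dr05, "ln_density", "AA")$effect)

  expect_error(marginal_effect(dr, "nightlights", "AA"), "not in fitted")
})

test_that("effect sign and small-slope approximation hold", {
  for (slope in c(-0.05, -0.01, 0.002, 0.03, 0.05)) {
    for (base_mu in c(0.1, 0.5, 0.8)) {
      dr <- two_country_draws(alpha_val = qlogis(base_mu), slope = slope)
      eff <- marginal_effect(dr, "ln_density", "AA")$effect
      expect_equal(sign(eff), sign(slope))
      approx <- 100 * slope * base_mu * (1 - base_mu)
      expect_lt(abs(eff - approx) / abs(approx), 0.05)
    }
  }
})

test_that("temperature effects move the linear and squared terms together", {
  reg <- default_registry()
  D <- 1
  alpha <- matrix(0, 1, 2, dimnames = list(NULL, c("AA", "BB")))
  beta <- array(0, c(1, 2, 7))
  b_lin <- 0.2; b_sq <- -0.1
  beta[, , match("tmin", CITY_COVARIATES)] <- b_lin
  beta[, , match("tmin2", CITY_COVARIATES)] <- b_sq
  dr <- fake_draws(alpha, beta, reg,
                   z_country = matrix(0, 2, 3,
                     dimnames = list(NULL, COUNTRY_COVARIATES)))
  m_t <- reg$mean[reg$covariate == "tmin"]
  s_t <- reg$sd[reg$covariate == "tmin"]
  m_t2 <- reg$mean[reg$covariate == "tmin2"]
  s_t2 <- reg$sd[reg$covariate == "tmin2"]
  z2_0 <- (m_t^2 - m_t2) / s_t2
  z2_1 <- ((m_t + s_t)^2 - m_t2) / s_t2
  want <- 100 * (plogis(b_lin * 1 + b_sq * z2_1) - plogis(b_sq * z2_0))
  expect_equal(marginal_effect(dr, "tmin", "AA")$effect, want,
               tolerance = 1e-9)
  # and differs from a naive single-column perturbation
  naive <- 100 * (plogis(b_lin) - 0.5)
  expect_false(isTRUE(all.equal(want, naive)))
})

test_that("country covariates act through their single coefficient", {
  delta <- matrix(c(0.3, -0.1, 0.05), 1, 3, byrow = TRUE,
                  dimnames = list(NULL, COUNTRY_COVARIATES))
  dr <- two_country_draws(alpha_val = qlogis(0.2), delta = delta)
  eff <- marginal_effect(dr, "gas_price", "AA")$effect
  expect_equal(eff, 100 * (plogis(qlogis(0.2) + 0.3) - 0.2),
               tolerance = 1e-9)
})

test_that("median-country effects follow the median definition", {
  # all countries identical: median equals the common effect
  dr <- two_country_draws(alpha_val = 0, slope = 0.1)
  expect_equal(median_country_effect(dr, "ln_density")$effect,
               marginal_effect(dr, "ln_density", "AA")$effect)

  # 3 countries engineered to per-draw effects 1, 2, 9 percentage points
  alpha <- matrix(0, 1, 3, dimnames = list(NULL, c("AA", "BB", "CC")))
  slopes <- vapply(c(1, 2, 9) / 100,
                   function(e) qlogis(0.5 + e) - 0, numeric(1))
  beta <- array(0, c(1, 3, 7))
  beta[1, , 1] <- slopes
  dr3 <- fake_draws(alpha, beta, default_registry(),
                    z_country = matrix(0, 3, 3,
                      dimnames = list(NULL, COUNTRY_COVARIATES)))
  expect_equal(median_country_effect(dr3, "ln_density")$effect, 2,
               tolerance = 1e-9)

  # the median lies between the per-country extremes in every draw
  set.seed(21)
  D <- 50
  alphaR <- matrix(rnorm(D * 3, -2, 0.3), D, 3,
                   dimnames = list(NULL, c("AA", "BB", "CC")))
  betaR <- array(rnorm(D * 3 * 7, 0, 0.1), c(D, 3, 7))
  drR <- fake_draws(alphaR, betaR, default_registry(),
                    z_country = matrix(0, 3, 3,
                      dimnames = list(NULL, COUNTRY_COVARIATES)))
  em <- 100 * sapply(1:3, function(j) {
    modeshift:::effect_draws_j(drR, "ln_density", j)
  })
  med <- apply(em, 1, median)
  expect_true(all(med >= apply(em, 1, min) & med <= apply(em, 1, max)))
})

test_that("moderation summaries expose both model and descriptive views", {
  # countries' effects exactly linear in z_gdp: R^2 = 1, slope recovered
  J <- 6
  z <- seq(-1, 1, length.out = J)
  alpha <- matrix(0, 1, J, dimnames = list(NULL, paste0("C", 1:J)))
  beta <- array(0, c(1, J, 7))
  slope_per_z <- 0.08
  beta[1, , 1] <- slope_per_z * z
  zc <- cbind(gas_price = rep(0, J), ln_gdp_pc = z,
              dependency_ratio = rep(0, J))
  dr <- fake_draws(alpha, beta, default_registry(), z_country = zc)
  ms <- moderation_summary(dr, "ln_density")
  expect_equal(ms$descriptive$r_squared, 1, tolerance = 1e-6)
  # effects are ~ linear in the slope for small slopes: slope of the
  # percentage-point effects on z approximates 100 * 0.25 * slope_per_z
  expect_equal(ms$descriptive$slope, 100 * 0.25 * slope_per_z,
               tolerance = 0.02)
  expect_false(ms$descriptive$degenerate)

  # two countries: zero residual degrees of freedom -> degenerate flag
  dr2 <- two_country_draws(alpha_val = 0, slope = 0.1)
  ms2 <- suppressWarnings(moderation_summary(dr2, "ln_density"))
  expect_true(ms2$descriptive$degenerate)

  # moderator absent from the model: gamma1 view omitted with a warning
  dr_nm <- dr
  dr_nm$moderators <- character(0)
  dr_nm$gamma1 <- NULL
  expect_warning(ms3 <- moderation_summary(dr_nm, "ln_density"),
                 "not in model")
  expect_null(ms3$gamma1)
  expect_false(is.null(ms3$descriptive))
})

test_that("effect tables are ordered by absolute median-country effect", {
  J <- 2
  alpha <- matrix(0, 1, J, dimnames = list(NULL, c("AA", "BB")))
  beta <- array(0, c(1, J, 7))
  # engineered ordering: terrain (negative, largest), ln_density, B
  beta[1, , match("terrain", CITY_COVARIATES)] <- -0.3
  beta[1, , match("ln_density", CITY_COVARIATES)] <- 0.2
  beta[1, , match("B", CITY_COVARIATES)] <- 0.1
  zc <- matrix(0, J, 3, dimnames = list(NULL, COUNTRY_COVARIATES))
  drw <- fake_draws(alpha, beta, default_registry(), z_country = zc)
  et <- suppressWarnings(effect_table(walk_draws = drw))
  walk_tab <- et$table[et$table$outcome == "walk", ]
  expect_equal(walk_tab$covariate[1:3], c("terrain", "ln_density", "B"))
  # remaining covariates all have zero effect: ties break lexicographically
  zero_rows <- walk_tab$covariate[walk_tab$effect == 0]
  expect_equal(zero_rows, sort(zero_rows))
  # single-outcome call warns but still returns a walk table
  expect_warning(effect_table(walk_draws = drw), "walk")
  expect_error(effect_table(), "at least one")
})
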