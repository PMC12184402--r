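# Shared fixtures, built once per test run.

the <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(the$tiny)) {
    the$tiny <- make_fixture("tiny", file.path(tempdir(), "ms-tiny"))
  }
  the$tiny
}

small_fixture <- function() {
  if (is.null(the$small)) {
    the$small <- make_fixture("small", file.path(tempdir(), "ms-small"))
  }
  the$small
}

# A quick, ungated fit on the tiny fixture, reused by several tests.
tiny_fit <- function() {
  if (is.null(the$tiny_fit)) {
    fx <- tiny_fixture()
    design <- build_design(fx$cities_df, fx$countries_df)
    tab <- suppressWarnings(mode_share_table(fx$cities_df))
    tab <- tab[match(design$city_ids, tab$city_id), ]
    y <- shrink_boundary(tab$share_reg_walk,
                         sum(!tab$reg_denominator_zero))
    spec <- model_spec("walk", seed = 42, adapt = 200, warmup = 200,
                       iter = 150, thin = 1)
    the$tiny_fit <- list(
      design = design, shares = y,
      draws = suppressWarnings(
        fit_hier_beta(spec, design, y, check_convergence = FALSE)))
  }
  the$tiny_fit
}

# Hand-built posterior draws with fully known parameters, for closed-form
# effect and scenario checks without running the sampler.
fake_draws <- function(alpha, beta, registry, z_country,
                       covariates = CITY_COVARIATES,
                       country_covariates = COUNTRY_COVARIATES,
                       moderators = "ln_gdp_pc",
                       delta = NULL, gamma1 = NULL, phi = 50,
                       outcome = "walk") {
  D <- nrow(alpha)
  J <- ncol(alpha)
  K <- length(covariates)
  stopifnot(all(dim(beta) == c(D, J, K)))
  dimnames(beta)[[3]] <- covariates
  g0 <- matrix(colMeans(matrix(beta, D * J, K)), D, K, byrow = TRUE,
               dimnames = list(NULL, covariates))
  if (is.null(delta)) {
    delta <- matrix(0, D, length(country_covariates),
                    dimnames = list(NULL, country_covariates))
  }
  if (is.null(gamma1)) {
    gamma1 <- array(0, c(D, K, length(moderators)),
                    dimnames = list(NULL, covariates, moderators))
  }
  structure(list(
    outcome = outcome, alpha = alpha, beta = beta, gamma0 = g0,
    gamma1 = gamma1, delta = delta,
    tau = matrix(0.1, D, K, dimnames = list(NULL, covariates)),
    phi = rep(phi, D), alpha0 = rowMeans(alpha),
    sigma_alpha = rep(0.1, D),
    covariates = covariates, country_covariates = country_covariates,
    moderators = moderators,
    country_ids = colnames(alpha) %||% paste0("K", seq_len(J)),
    z_country = z_country, registry = registry,
    n_draws = D,
    diagnostics = data.frame(parameter = "phi", rhat = 1, ess = D),
    spec = list(seed = 1L)
  ), class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_registry <- function() {
  data.frame(
    covariate = c(CITY_COVARIATES, COUNTRY_COVARIATES),
    mean = c(8, 5, 1, 5, 125, 23, 800, 1, 9, 55),
    sd = c(1, 6, 1, 10, 180, 5, 400, 0.4, 1, 12),
    stringsAsFactors = FALSE)
}

# A minimal hand-written city table (3 cities, 2 countries).
manual_cities <- function() {
  validate_city_table(data.frame(
    city_id = c("a1", "a2", "b1"),
    country_id = c("AA", "AA", "BB"),
    population = c(1e5, 2e5, 3e5),
    km_walk_within = c(10, 20, 2),
    km_cycle_within = c(5, 1, 1),
    km_carmoto_within = c(85, 160, 7),
    km_transit_within = c(50, 100, 10),
    km_walk_inout = c(4, NA, 0),
    km_cycle_inout = c(2, NA, 0),
    km_carmoto_inout = c(30, NA, 0),
    km_transit_inout = c(20, NA, 0),
    trips_walk_within = c(10, 20, 2),
    trips_cycle_within = c(2, 1, 1),
    trips_carmoto_within = c(9, 16, 1),
    trips_transit_within = c(6, 12, 1),
    trips_walk_inout = c(2, NA, 0),
    trips_cycle_inout = c(1, NA, 0),
    trips_carmoto_inout = c(3, NA, 0),
    trips_transit_inout = c(2, NA, 0),
    road_km = c(200, 400, 100),
    bikeway_km = c(10, 40, 0),
    density = c(exp(7), exp(8), exp(9)),
    terrain = c(0.5, 1.5, 0.1),
    tmin_c = c(-5, 3, 12),
    tmax_c = c(20, 25, 30),
    precip_mm = c(600, 900, 1200),
    stringsAsFactors = FALSE))
}

manual_countries <- function() {
  data.frame(country_id = c("AA", "BB"),
             gas_price_usd_l = c(0.8, 1.4),
             gdp_pc_usd = c(5000, 40000),
             dependency_ratio = c(60, 50),
             stringsAsFactors = FALSE)
}
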