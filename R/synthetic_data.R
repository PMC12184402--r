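# Synthetic multilevel data with known ground truth.
#
# The generator draws countries with correlated national covariates, nests
# cities inside them, and produces walk and cycle regression shares from the
# assumed beta/logit data-generating process with country-varying slopes
# moderated by national income. It exists so that every downstream stage
# (design construction, fitting, effects, scenarios) can be tested for
# parameter recovery without the proprietary source data.

#' Ground-truth configuration for the synthetic generator
#'
#' Defaults emulate the structure of the real study population: many
#' countries, tens of cities per country, walk shares around a few percent
#' and cycle shares around one percent of non-transit km, right-skewed
#' positive covariates, and roughly 30% of cities reporting in/out-bound
#' travel. Hyper-coefficients are on the logit scale per one pooled SD.
#'
#' @param n_countries Number of countries.
#' @param cities_per_country Cities per country (scalar or length
#'   `n_countries`).
#' @param hyper_intercepts Logit-scale global intercepts, named `walk`,
#'   `cycle`.
#' @param hyper_slopes List with `walk` and `cycle`: named length-7 vectors
#'   of slope hyper-means gamma0 over the city covariates.
#' @param moderation List with `walk` and `cycle`: named length-7 vectors
#'   gamma1, the effect of standardized ln GDP per capita on each slope.
#' @param country_var_slopes List with `walk` and `cycle`: between-country
#'   slope SDs tau (length 7, >= 0).
#' @param country_coefs List with `walk` and `cycle`: named length-3 vectors
#'   over `gas_price`, `ln_gdp_pc`, `dependency_ratio`.
#' @param sigma_alpha Between-country intercept SD (around the hyper
#'   intercept plus country-covariate terms).
#' @param precision Beta precision phi per outcome (named `walk`, `cycle`).
#' @param inout_fraction Probability that a city reports in/out-bound
#'   volumes (default 0.301).
#' @param seed Master seed; per-stage substreams are derived from it.
#' @return A `truth_config` list.
#' @export
truth_config <- function(n_countries = 121,
                         cities_per_country = 96,
                         hyper_intercepts = c(walk = -3.6, cycle = -4.4),
                         hyper_slopes = list(
                           walk = c(ln_density = 0.30, B = 0.15,
                                    terrain = -0.05, tmin = 0.10,
                                    tmin2 = -0.08, tmax = -0.12,
                                    precip = -0.03),
                           cycle = c(ln_density = 0.10, B = 0.15,
                                     terrain = -0.30, tmin = 0.08,
                                     tmin2 = -0.05, tmax = 0.00,
                                     precip = -0.02)),
                         moderation = list(
                           walk = c(ln_density = 0.20, B = 0, terrain = 0,
                                    tmin = 0, tmin2 = 0, tmax = 0,
                                    precip = 0),
                           cycle = c(ln_density = 0.10, B = 0, terrain = 0,
                                     tmin = 0, tmin2 = 0, tmax = 0,
                                     precip = 0)),
                         country_var_slopes = list(
                           walk = rep(0.15, 7), cycle = rep(0.15, 7)),
                         country_coefs = list(
                           walk = c(gas_price = 0.30, ln_gdp_pc = -0.10,
                                    dependency_ratio = 0.05),
                           cycle = c(gas_price = 0.25, ln_gdp_pc = 0.15,
                                     dependency_ratio = -0.05)),
                         sigma_alpha = 0.4,
                         precision = c(walk = 50, cycle = 30),
                         inout_fraction = 0.301,
                         seed = 1L) {
  stopifnot(n_countries >= 1, all(cities_per_country >= 1),
            all(precision > 0),
            all(unlist(country_var_slopes) >= 0),
            inout_fraction >= 0, inout_fraction <= 1)
  for (oc in c("walk", "cycle")) {
    stopifnot(length(hyper_slopes[[oc]]) == 7,
              length(moderation[[oc]]) == 7,
              length(country_var_slopes[[oc]]) == 7,
              length(country_coefs[[oc]]) == 3)
  }
  if (length(cities_per_country) == 1) {
    cities_per_country <- rep(cities_per_country, n_countries)
  }
  stopifnot(length(cities_per_country) == n_countries)
  structure(list(
    n_countries = n_countries, cities_per_country = cities_per_country,
    hyper_intercepts = hyper_intercepts, hyper_slopes = hyper_slopes,
    moderation = moderation, country_var_slopes = country_var_slopes,
    country_coefs = country_coefs, sigma_alpha = sigma_alpha,
    precision = precision, inout_fraction = inout_fraction,
    seed = as.integer(seed)
  ), class = "truth_config")
}

# Deterministic substream seed per generation stage.
substream <- function(seed, stage) {
  (as.integer(seed) * 131L + stage * 7919L) %% 2147483646L + 1L
}

country_codes <- function(n) {
  l1 <- LETTERS[(seq_len(n) - 1) %/% 26 + 1]
  l2 <- LETTERS[(seq_len(n) - 1) %% 26 + 1]
  paste0(l1, l2)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate national covariates
#'
#' Gasoline prices are normal (truncated positive), GDP per capita is
#' log-normal, and the dependency ratio is normal truncated positive with a
#' negative correlation with income (poorer countries tend to be younger).
#'
#' @param cfg A [truth_config()].
#' @return A country table as returned by [read_country_table()].
#' @export
generate_countries <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  set.seed(substream(cfg$seed, 1L))
  n <- cfg$n_countries
  ln_gdp <- rnorm(n, 9, 1)                     # median ~ $8100/cap
  gas <- rtrunc_norm(n, 1.0, 0.4, 0.05)        # USD / liter
  dep <- rtrunc_norm(n, 55 - 8 * (ln_gdp - 9), 10, 5)
  data.frame(country_id = country_codes(n),
             gas_price_usd_l = gas,
             gdp_pc_usd = exp(ln_gdp),
             dependency_ratio = dep,
             stringsAsFactors = FALSE)
}

#' Generate cities from the assumed data-generating process
#'
#' For each city, raw covariates are drawn (log-normal density, half-normal
#' terrain, normal temperatures, gamma precipitation, zero-inflated-gamma
#' bikeway provision truncated to \[0, 100\]); the pooled standardized design
#' is computed internally; country slopes are drawn as beta_jk ~
#' Normal(gamma0_k + gamma1_k z_gdp(j), tau_k); the walk and cycle regression
#' shares are drawn from Beta(mu phi, (1 - mu) phi) independently per
#' outcome, with joint draws violating walk + cycle <= 1 rejected and
#' redrawn; and total annual km/trips are allocated to modes consistent with
#' the drawn shares, with a configured fraction of cities splitting volumes
#' into within-boundary and in/out-bound components.
#'
#' @param cfg A [truth_config()].
#' @param countries Output of [generate_countries()] (or a compatible table).
#' @return A list with `cities` (validated city table) and `truth` (ground
#'   truth: per-country intercepts and slopes, hyper-parameters, the internal
#'   registry, and the rejection count).
#' @export
generate_cities <- function(cfg, countries) {
  stopifnot(inherits(cfg, "truth_config"), nrow(countries) >= 1)
  set.seed(substream(cfg$seed, 2L))
  J <- nrow(countries)
  nj <- cfg$cities_per_country
  if (length(nj) == 1) nj <- rep(nj, J)
  N <- sum(nj)
  cidx <- rep(seq_len(J), nj)

  # Raw covariates
  density <- rlnorm(N, log(3000), 1)
  terrain <- abs(rnorm(N, 0, 1))
  tmin <- rnorm(N, 5, 10)
  tmax <- tmin + rtrunc_norm(N, 18, 4, 2)
  precip <- rgamma(N, shape = 2, scale = 400)
  road_km <- rlnorm(N, log(500), 0.8)
  B <- ifelse(runif(N) < 0.35, 0, rgamma(N, shape = 1.5, scale = 6))
  B <- pmin(B, 100)
  bikeway_km <- B / 100 * road_km
  population <- rlnorm(N, log(1.5e5), 1)

  # Standardize internally against the generated pooled sample
  rawX <- cbind(ln_density = log(density), B = B, terrain = terrain,
                tmin = tmin, tmin2 = tmin^2, tmax = tmax, precip = precip)
  muX <- colMeans(rawX)
  sdX <- apply(rawX, 2, sd)
  X <- sweep(sweep(rawX, 2, muX), 2, sdX, "/")
  rawZ <- cbind(gas_price = countries$gas_price_usd_l,
                ln_gdp_pc = log(countries$gdp_pc_usd),
                dependency_ratio = countries$dependency_ratio)
  muZ <- colMeans(rawZ)
  sdZ <- apply(rawZ, 2, sd)
  if (J == 1) sdZ[] <- 1
  Z <- sweep(sweep(rawZ, 2, muZ), 2, sdZ, "/")
  z_gdp <- Z[, "ln_gdp_pc"]

  # Country-level truth and city shares per outcome
  truth <- list(config = cfg, registry = data.frame(
    covariate = c(colnames(rawX), colnames(rawZ)),
    mean = c(muX, muZ), sd = c(sdX, sdZ), stringsAsFactors = FALSE),
    z_gdp = z_gdp, country_id = countries$country_id)
  mu <- list()
  for (oc in c("walk", "cycle")) {
    g0 <- cfg$hyper_slopes[[oc]]
    g1 <- cfg$moderation[[oc]]
    tau <- cfg$country_var_slopes[[oc]]
    beta_j <- sapply(seq_len(7), function(k) {
      rnorm(J, g0[k] + g1[k] * z_gdp, tau[k])
    })
    beta_j <- matrix(beta_j, nrow = J, dimnames = list(NULL, names(g0)))
    alpha_j <- rnorm(J, cfg$hyper_intercepts[[oc]] +
                       as.numeric(Z %*% cfg$country_coefs[[oc]]),
                     cfg$sigma_alpha)
    eta <- alpha_j[cidx] + rowSums(X * beta_j[cidx, , drop = FALSE])
    mu[[oc]] <- plogis(eta)
    truth[[oc]] <- list(alpha = alpha_j, beta = beta_j,
                        gamma0 = g0, gamma1 = g1, tau = tau,
                        delta = cfg$country_coefs[[oc]],
                        phi = cfg$precision[[oc]],
                        sigma_alpha = cfg$sigma_alpha)
  }
  s_walk <- rbeta(N, mu$walk * cfg$precision["walk"],
                  (1 - mu$walk) * cfg$precision["walk"])
  s_cycle <- rbeta(N, mu$cycle * cfg$precision["cycle"],
                   (1 - mu$cycle) * cfg$precision["cycle"])
  rejections <- 0L
  while (any(bad <- s_walk + s_cycle > 1)) {
    rejections <- rejections + sum(bad)
    s_walk[bad] <- rbeta(sum(bad), mu$walk[bad] * cfg$precision["walk"],
                         (1 - mu$walk[bad]) * cfg$precision["walk"])
    s_cycle[bad] <- rbeta(sum(bad), mu$cycle[bad] * cfg$precision["cycle"],
                          (1 - mu$cycle[bad]) * cfg$precision["cycle"])
  }
  truth$share_rejections <- rejections

  # Volumes: total effective km over the regression denominator, allocated
  # by the drawn shares; transit added via a separate descriptive share.
  km_total <- population * rlnorm(N, log(4000), 0.4)
  km_walk <- s_walk * km_total
  km_cycle <- s_cycle * km_total
  km_car <- (1 - s_walk - s_cycle) * km_total
  transit_ratio <- rbeta(N, 2, 6)               # transit / (transit + rest)
  km_transit <- km_total * transit_ratio / (1 - transit_ratio)

  trip_len <- c(walk = 1.0, cycle = 3.0, car_moto = 10.0, transit = 8.0)
  jitter <- function() exp(rnorm(N, 0, 0.1))
  trips <- list(walk = km_walk / (trip_len["walk"] * jitter()),
                cycle = km_cycle / (trip_len["cycle"] * jitter()),
                car_moto = km_car / (trip_len["car_moto"] * jitter()),
                transit = km_transit / (trip_len["transit"] * jitter()))

  inout <- runif(N) < cfg$inout_fraction
  rho <- runif(N, 0.1, 0.4)  # effective-km fraction occurring in/out-bound
  split_io <- function(total) {
    within <- ifelse(inout, (1 - rho) * total, total)
    io <- ifelse(inout, 2 * rho * total, NA_real_)
    list(within = within, inout = io)
  }
  km <- list(walk = split_io(km_walk), cycle = split_io(km_cycle),
             carmoto = split_io(km_car), transit = split_io(km_transit))
  tr <- list(walk = split_io(trips$walk), cycle = split_io(trips$cycle),
             carmoto = split_io(trips$car_moto),
             transit = split_io(trips$transit))

  cities <- data.frame(
    city_id = sprintf("%s-%04d", countries$country_id[cidx],
                      unlist(lapply(nj, seq_len))),
    country_id = countries$country_id[cidx],
    population = population,
    stringsAsFactors = FALSE)
  for (s in names(km)) cities[[paste0("km_", s, "_within")]] <- km[[s]]$within
  for (s in names(km)) cities[[paste0("km_", s, "_inout")]] <- km[[s]]$inout
  for (s in names(tr)) {
    cities[[paste0("trips_", s, "_within")]] <- tr[[s]]$within
  }
  for (s in names(tr)) cities[[paste0("trips_", s, "_inout")]] <- tr[[s]]$inout
  cities$road_km <- road_km
  cities$bikeway_km <- bikeway_km
  cities$density <- density
  cities$terrain <- terrain
  cities$tmin_c <- tmin
  cities$tmax_c <- tmax
  cities$precip_mm <- precip

  list(cities = validate_city_table(cities), truth = truth)
}

#' Write a named fixture dataset to disk
#'
#' Presets: `tiny` (3 countries x 5 cities, seed 101), `small` (10 x 20,
#' seed 202), `recovery` (30 x 40, seed 303; between-country slope SD 0.15
#' with income moderation of the density slopes). Writes `cities.csv`,
#' `countries.csv`, and a `truth.json` sidecar recording the configuration
#' and all drawn ground-truth parameters. Byte-stable for a given preset.
#'
#' @param name Preset label.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths plus the in-memory dataset.
#' @export
make_fixture <- function(name = c("tiny", "small", "recovery"),
                         dir = tempfile("fixture")) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = truth_config(n_countries = 3, cities_per_country = 5, seed = 101L),
    small = truth_config(n_countries = 10, cities_per_country = 20,
                         seed = 202L),
    recovery = truth_config(n_countries = 30, cities_per_country = 40,
                            seed = 303L))
  countries <- generate_countries(cfg)
  gen <- generate_cities(cfg, countries)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(cities = file.path(dir, "cities.csv"),
                countries = file.path(dir, "countries.csv"),
                truth = file.path(dir, "truth.json"))
  write_city_table(gen$cities, paths$cities)
  write_country_table(countries, paths$countries)
  tr <- gen$truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(cities_df = gen$cities, countries_df = countries,
                          truth_obj = gen$truth)))
}
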