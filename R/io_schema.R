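#' @importFrom stats sd median quantile rnorm rbeta rgamma rlnorm runif
#'   plogis qlogis dbeta integrate coef confint lm setNames rexp var
#'   df.residual update
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Mode labels and covariate names
#'
#' `MODES` are the four transport modes of the CSV contract;
#' `CITY_COVARIATES` and `COUNTRY_COVARIATES` are the canonical covariate
#' orderings used by the design matrix and model.
#' @export
MODES <- c("walk", "cycle", "car_moto", "transit")
MODE_STEM <- c(walk = "walk", cycle = "cycle", car_moto = "carmoto",
               transit = "transit")

#' @rdname MODES
#' @export
CITY_COVARIATES <- c("ln_density", "B", "terrain", "tmin", "tmin2", "tmax",
                     "precip")

#' @rdname MODES
#' @export
COUNTRY_COVARIATES <- c("gas_price", "ln_gdp_pc", "dependency_ratio")

city_cols_mandatory <- function() {
  c("city_id", "country_id", "population",
    paste0("km_", MODE_STEM, "_within"),
    paste0("trips_", MODE_STEM, "_within"),
    "road_km", "bikeway_km", "density", "terrain", "tmin_c", "tmax_c",
    "precip_mm")
}

city_cols_inout <- function() {
  c(paste0("km_", MODE_STEM, "_inout"), paste0("trips_", MODE_STEM, "_inout"))
}

#' Read and validate a city table
#'
#' Reads the comma-separated city contract: one row per city with annual
#' travel volumes (km and trips) by mode, split into within-boundary and
#' optional in/out-bound components, plus infrastructure (road and bikeway
#' km) and geography covariates (density, terrain, monthly temperature
#' extremes, precipitation).
#'
#' The in/out-bound columns are optional as a block: a file may omit them
#' entirely, and an individual city may leave all of them empty. Such cities
#' are flagged `inout_reported = FALSE` and their effective distances use the
#' within-boundary volumes only.
#'
#' @param path Path to a cities CSV file.
#' @return A `data.frame` of validated city records with a logical
#'   `inout_reported` column. Invalid rows abort with row-indexed messages.
#' @export
read_city_table <- function(path) {
  if (!file.exists(path)) stop("city table not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_city_table(raw)
}

#' Validate an in-memory city table
#'
#' Applies the full schema contract (see [read_city_table()]) to a data
#' frame, normalizing the optional in/out-bound block and attaching the
#' `inout_reported` flag.
#'
#' @param raw A data.frame with the cities CSV columns.
#' @return The validated city table.
#' @export
validate_city_table <- function(raw) {
  mand <- city_cols_mandatory()
  missing_cols <- setdiff(mand, names(raw))
  if (length(missing_cols) > 0) {
    stop("city table schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  io <- city_cols_inout()
  have_io <- io %in% names(raw)
  if (any(have_io) && !all(have_io)) {
    stop("city table schema error: in/out-bound columns must be present as ",
         "a block; missing: ", paste(io[!have_io], collapse = ", "))
  }
  if (!any(have_io)) for (cl in io) raw[[cl]] <- NA_real_

  num_cols <- setdiff(c(mand, io), c("city_id", "country_id"))
  for (cl in num_cols) {
    v <- raw[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad) > 0) {
        stop("city table parse error: non-numeric value in column '", cl,
             "', row ", bad[1])
      }
      raw[[cl]] <- conv
    }
  }

  if (anyDuplicated(raw$city_id)) {
    dup <- raw$city_id[duplicated(raw$city_id)][1]
    stop("city table uniqueness error: duplicate city_id '", dup, "'")
  }

  fail_rows <- function(cond, what) {
    if (any(cond)) {
      stop("city table invariant violation: ", what, " in row ",
           which(cond)[1])
    }
  }
  nonneg <- c(setdiff(num_cols, c("density", "tmin_c", "tmax_c")))
  for (cl in nonneg) {
    fail_rows(!is.na(raw[[cl]]) & raw[[cl]] < 0, paste0("negative ", cl))
  }
  fail_rows(is.na(raw$density) | raw$density <= 0, "density")
  fail_rows(raw$tmax_c < raw$tmin_c, "tmax_c < tmin_c")

  io_na <- is.na(as.matrix(raw[, io]))
  partial <- rowSums(io_na) > 0 & rowSums(io_na) < length(io)
  fail_rows(partial, "partial in/out-bound block (must be all-present or all-absent)")
  raw$inout_reported <- rowSums(io_na) == 0

  class(raw) <- c("city_table", "data.frame")
  raw
}

#' Read and validate a country table
#'
#' @param path Path to a countries CSV with columns `country_id`,
#'   `gas_price_usd_l`, `gdp_pc_usd`, `dependency_ratio`.
#' @return A validated `data.frame`, one row per country.
#' @export
read_country_table <- function(path) {
  if (!file.exists(path)) stop("country table not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_id", "gas_price_usd_l", "gdp_pc_usd", "dependency_ratio")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("country table schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$country_id)) {
    stop("country table uniqueness error: duplicate country_id")
  }
  if (any(raw$gas_price_usd_l < 0)) stop("country table: negative gas price")
  if (any(raw$gdp_pc_usd <= 0)) stop("country table: gdp_pc_usd must be > 0")
  if (any(raw$dependency_ratio < 0)) {
    stop("country table: negative dependency_ratio")
  }
  raw
}

#' Write city / country tables in the canonical dialect
#'
#' @param x A city or country table.
#' @param path Output path.
#' @export
write_city_table <- function(x, path) {
  x$inout_reported <- NULL
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_city_table
#' @export
write_country_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Effective annual distance (or trips) for a mode
#'
#' Effective volume counts the full within-boundary volume plus 50% of the
#' in/out-bound volume, following greenhouse-gas reporting convention for
#' trips that cross the city boundary. Cities that do not report in/out-bound
#' travel contribute their within-boundary volume only.
#'
#' @param cities A city table (one or more rows).
#' @param mode One of `"walk"`, `"cycle"`, `"car_moto"`, `"transit"`.
#' @param what `"km"` or `"trips"`.
#' @return Numeric vector, one value per city.
#' @export
effective_km <- function(cities, mode, what = c("km", "trips")) {
  what <- match.arg(what)
  if (!mode %in% MODES) {
    stop("unknown mode '", mode, "'; must be one of ",
         paste(MODES, collapse = ", "))
  }
  stem <- MODE_STEM[[mode]]
  within <- cities[[paste0(what, "_", stem, "_within")]]
  inout <- cities[[paste0(what, "_", stem, "_inout")]]
  if (is.null(inout)) inout <- rep(NA_real_, length(within))
  within + 0.5 * ifelse(is.na(inout), 0, inout)
}

#' Mode shares under the regression and descriptive denominators
#'
#' The regression outcome is the share of effective km made by walking or
#' cycling with public transportation excluded from the denominator (walk +
#' cycle + car/motorcycle), because the substitution of interest is between
#' active travel and private motor vehicles. Descriptive shares include
#' transit in the denominator and are computed for both km and trips.
#'
#' @param cities A city table.
#' @return A `data.frame` with columns `city_id`, `share_reg_walk`,
#'   `share_reg_cycle`, `share_km_<mode>`, `share_trip_<mode>`, and a logical
#'   `reg_denominator_zero` marking cities excluded from model fitting.
#' @export
mode_share_table <- function(cities) {
  km <- sapply(MODES, function(m) effective_km(cities, m, "km"))
  km <- matrix(km, nrow = nrow(cities),
               dimnames = list(NULL, MODES))
  tr <- sapply(MODES, function(m) effective_km(cities, m, "trips"))
  tr <- matrix(tr, nrow = nrow(cities), dimnames = list(NULL, MODES))

  reg_den <- km[, "walk"] + km[, "cycle"] + km[, "car_moto"]
  des_den_km <- reg_den + km[, "transit"]
  des_den_tr <- rowSums(tr)

  out <- data.frame(city_id = cities$city_id, stringsAsFactors = FALSE)
  out$share_reg_walk <- ifelse(reg_den > 0, km[, "walk"] / reg_den, NA_real_)
  out$share_reg_cycle <- ifelse(reg_den > 0, km[, "cycle"] / reg_den, NA_real_)
  for (m in MODES) {
    out[[paste0("share_km_", m)]] <-
      ifelse(des_den_km > 0, km[, m] / des_den_km, NA_real_)
    out[[paste0("share_trip_", m)]] <-
      ifelse(des_den_tr > 0, tr[, m] / des_den_tr, NA_real_)
  }
  out$reg_denominator_zero <- reg_den <= 0
  if (any(out$reg_denominator_zero)) {
    warning(sum(out$reg_denominator_zero),
            " city(ies) with all-zero regression denominator excluded from ",
            "model fitting")
  }
  out
}

#' Per-record mode shares
#'
#' Convenience wrapper over [mode_share_table()] for a single denominator
#' convention.
#'
#' @param cities A city table.
#' @param denominator `"regression"` (walk + cycle + car/moto effective km,
#'   transit excluded) or `"descriptive"` (all four modes).
#' @return A data.frame of shares; regression shares cover walk and cycle,
#'   descriptive shares cover all modes (km basis).
#' @export
mode_shares <- function(cities, denominator = c("regression", "descriptive")) {
  denominator <- match.arg(denominator)
  tab <- suppressWarnings(mode_share_table(cities))
  if (denominator == "regression") {
    tab[, c("city_id", "share_reg_walk", "share_reg_cycle",
            "reg_denominator_zero")]
  } else {
    tab[, c("city_id", paste0("share_km_", MODES))]
  }
}

#' Compress boundary shares into the open unit interval
#'
#' The beta likelihood has open support (0, 1); observed shares that are
#' exactly 0 or 1 are compressed with the sample-size-aware transformation
#' y' = (y (n - 1) + 0.5) / n, where n is the number of modelled cities.
#' Interior values are left untouched.
#'
#' @param y Numeric vector of shares in \[0, 1\].
#' @param n Number of modelled observations.
#' @return Shares strictly inside (0, 1).
#' @export
shrink_boundary <- function(y, n = length(y)) {
  if (n < 1) stop("n must be >= 1")
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("shares must lie in [0, 1]")
  at_edge <- !is.na(y) & (y == 0 | y == 1)
  y[at_edge] <- (y[at_edge] * (n - 1) + 0.5) / n
  y
}

#' Build the standardized design matrix
#'
#' Transforms raw covariates (natural log of density and of GDP per capita;
#' bikeway provision B = 100 x bikeway km / road km; the square of the raw
#' minimum temperature, formed before standardization) and standardizes every
#' covariate against the pooled global sample, so that slopes are per one
#' worldwide standard deviation. The (mean, SD) registry needed to map
#' between raw and standardized units is retained.
#'
#' Cities with `road_km = 0` (B undefined) are excluded with a warning.
#'
#' @param cities A validated city table.
#' @param countries A validated country table covering every `country_id`
#'   in `cities`.
#' @return A `design_matrix` object: `X` (cities x 7 standardized city
#'   covariates), `Z` (countries x 3 standardized country covariates),
#'   `registry` (covariate, mean, sd), `country_index` mapping each city row
#'   to a row of `Z`, plus id vectors and the `kept` filter.
#' @export
build_design <- function(cities, countries) {
  orphan <- setdiff(unique(cities$country_id), countries$country_id)
  if (length(orphan) > 0) {
    stop("linkage error: city country_id(s) not in country table: ",
         paste(orphan, collapse = ", "))
  }
  kept <- cities$road_km > 0
  if (any(!kept)) {
    warning(sum(!kept), " city(ies) with road_km = 0 excluded (B undefined)")
  }
  cc <- cities[kept, , drop = FALSE]

  raw <- cbind(
    ln_density = log(cc$density),
    B = 100 * cc$bikeway_km / cc$road_km,
    terrain = cc$terrain,
    tmin = cc$tmin_c,
    tmin2 = cc$tmin_c^2,
    tmax = cc$tmax_c,
    precip = cc$precip_mm
  )
  mu <- colMeans(raw)
  sdv <- apply(raw, 2, sd)
  if (any(sdv <= 0)) {
    stop("degenerate covariate (zero SD): ",
         paste(colnames(raw)[sdv <= 0], collapse = ", "))
  }
  X <- sweep(sweep(raw, 2, mu), 2, sdv, "/")

  used <- countries[countries$country_id %in% cc$country_id, , drop = FALSE]
  used <- used[order(used$country_id), , drop = FALSE]
  rawZ <- cbind(
    gas_price = used$gas_price_usd_l,
    ln_gdp_pc = log(used$gdp_pc_usd),
    dependency_ratio = used$dependency_ratio
  )
  muZ <- colMeans(rawZ)
  sdZ <- apply(rawZ, 2, sd)
  if (nrow(used) == 1) sdZ[] <- 1  # single-country designs carry raw scale
  if (any(sdZ <= 0)) sdZ[sdZ <= 0] <- 1
  Z <- sweep(sweep(rawZ, 2, muZ), 2, sdZ, "/")

  registry <- data.frame(
    covariate = c(colnames(raw), colnames(rawZ)),
    mean = c(mu, muZ),
    sd = c(sdv, sdZ),
    stringsAsFactors = FALSE
  )

  structure(list(
    X = X,
    Z = Z,
    registry = registry,
    country_index = match(cc$country_id, used$country_id),
    country_ids = used$country_id,
    city_ids = cc$city_id,
    kept = kept,
    raw_B = raw[, "B"]
  ), class = "design_matrix")
}

#' Map standardized design columns back to raw units
#'
#' Round-trip companion of [build_design()]: multiplies by the registry SD
#' and adds back the mean.
#'
#' @param design A `design_matrix`.
#' @return Matrix of raw-unit city covariates (ln_density, B, terrain, tmin,
#'   tmin2, tmax, precip).
#' @export
unstandardize_design <- function(design) {
  reg <- design$registry
  reg <- reg[match(colnames(design$X), reg$covariate), ]
  sweep(sweep(design$X, 2, reg$sd, "*"), 2, reg$mean, "+")
}

#' Registry lookup
#' @param design A `design_matrix`.
#' @param covariate Covariate name.
#' @return Named vector `c(mean, sd)`.
#' @export
registry_entry <- function(design, covariate) {
  reg <- design$registry
  i <- match(covariate, reg$covariate)
  if (is.na(i)) stop("covariate '", covariate, "' not in registry")
  c(mean = reg$mean[i], sd = reg$sd[i])
}

#' Pooled descriptive statistics
#'
#' Pools effective km and trips across cities (weighting by volume, not
#' averaging city shares) under the descriptive denominator (transit
#' included), and reports the walk:cycle ratios for trips and km.
#'
#' @param cities A city table.
#' @return A list with `km_share` and `trip_share` (named by mode) and
#'   `walk_cycle_ratio` (named vector `trips`, `km`).
#' @export
aggregate_descriptives <- function(cities) {
  if (nrow(cities) == 0) stop("empty city table")
  km <- sapply(MODES, function(m) sum(effective_km(cities, m, "km")))
  tr <- sapply(MODES, function(m) sum(effective_km(cities, m, "trips")))
  list(
    km_share = km / sum(km),
    trip_share = tr / sum(tr),
    walk_cycle_ratio = c(trips = unname(tr["walk"] / tr["cycle"]),
                         km = unname(km["walk"] / km["cycle"]))
  )
}

#' Urban population coverage
#'
#' @param dataset_population Total population of the covered cities.
#' @param world_urban_population World urban population.
#' @return Coverage in percent.
#' @export
urban_coverage <- function(dataset_population, world_urban_population) {
  if (world_urban_population <= 0) {
    stop("world_urban_population must be > 0")
  }
  100 * dataset_population / world_urban_population
}
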