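# Counterfactual bikeway-provision scenarios.
#
# Every city's provision B (km of bicycle facility per 100 km of road) is
# raised to a floor B*; cities already above the floor do not change. The
# predicted walk and cycle share changes are propagated, per posterior draw,
# into added active km, displaced motorized km, CO2 reductions (as a percent
# of baseline private-vehicle emissions), and monetized health benefits,
# with equal-tailed 95% posterior uncertainty intervals.

#' Scenario configuration
#'
#' @param B_grid Floors to sweep, in km of bikeway per 100 km of road
#'   (default 1..50).
#' @param d_walk,d_cycle Km of motorized travel displaced per added km of
#'   walking / cycling (central assumption 1 and 1; literature ranges run
#'   1.0-3.1 for walking and 0.8-2.1 for cycling).
#' @param emission_factor Grams CO2 per km of car/motorcycle travel. The
#'   default 170 g/km is a configurable placeholder for a global fleet
#'   average; CO2 percentage reductions are insensitive to it when it is a
#'   single global constant.
#' @param health_walk,health_cycle USD of health benefit per km of walking /
#'   cycling. The defaults (0.50, 0.25) are documented placeholders; any
#'   per-km valuation can be supplied.
#' @param cap_displacement Cap displaced km at each city's baseline
#'   motorized km (default TRUE; cap events are counted).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(B_grid = 1:50, d_walk = 1, d_cycle = 1,
                            emission_factor = 170,
                            health_walk = 0.50, health_cycle = 0.25,
                            cap_displacement = TRUE) {
  stopifnot(all(B_grid >= 0), d_walk > 0, d_cycle > 0, emission_factor >= 0,
            health_walk >= 0, health_cycle >= 0)
  structure(list(B_grid = B_grid, d_walk = d_walk, d_cycle = d_cycle,
                 emission_factor = emission_factor,
                 health_walk = health_walk, health_cycle = health_cycle,
                 cap_displacement = cap_displacement),
            class = "scenario_config")
}

#' Copenhagen-level bikeway provision
#'
#' The benchmark floor of ~44.3 km of bicycle facility per 100 km of road.
#' @export
B_COPENHAGEN <- 44.3

#' Preset scenario floor
#'
#' @param preset `"copenhagen"` (B* = 44.3) or `"percentile95"` (the 95th
#'   percentile of observed provision in `cities`).
#' @param cities City table (needed for `percentile95`).
#' @return A single floor value.
#' @export
preset_floor <- function(preset = c("copenhagen", "percentile95"),
                         cities = NULL) {
  preset <- match.arg(preset)
  if (preset == "copenhagen") return(B_COPENHAGEN)
  if (is.null(cities)) stop("percentile95 preset needs the city table")
  ok <- cities$road_km > 0
  unname(quantile(100 * cities$bikeway_km[ok] / cities$road_km[ok], 0.95))
}

#' Apply a provision floor
#'
#' Cities already at or above the floor keep their provision: the floor is a
#' minimum level, so the counterfactual provision is max(B, B*).
#'
#' @param B Observed provision (vectorized).
#' @param B_star Floor.
#' @return Counterfactual provision.
#' @export
apply_floor <- function(B, B_star) {
  if (any(B < 0) || any(B_star < 0)) stop("provision must be non-negative")
  pmax(B, B_star)
}

#' New bikeway construction required by a floor
#'
#' Sum over cities of max(0, B*/100 x road km - existing bikeway km).
#' Deterministic in the data (no posterior draws involved).
#'
#' @param cities City table.
#' @param B_star Floor.
#' @return Km of new bicycle facility.
#' @export
required_construction <- function(cities, B_star) {
  ok <- cities$road_km > 0
  if (any(!ok)) warning(sum(!ok), " city(ies) with road_km = 0 excluded")
  sum(pmax(0, B_star / 100 * cities$road_km[ok] - cities$bikeway_km[ok]))
}

#' Predicted mode-share changes under a provision floor
#'
#' Per posterior draw and city: the B column is recomputed under the floor
#' and re-standardized with the ORIGINAL registry (the counterfactual city
#' is measured on the factual world's scale), the linear predictor is
#' re-evaluated for both outcomes, and the share differences are returned.
#' Cities at or above the floor change by exactly zero.
#'
#' @param walk_draws,cycle_draws `posterior_draws` for the two outcomes
#'   (either may be NULL; its delta matrix is then zero).
#' @param design The factual `design_matrix`.
#' @param B_star Floor.
#' @return A list of draws-by-cities matrices `dshare_walk`,
#'   `dshare_cycle`, plus the city ids and the per-city kept filter.
#' @export
shift_shares <- function(walk_draws, cycle_draws, design, B_star) {
  sB <- registry_entry(design, "B")
  zB0 <- design$X[, "B"]
  B_raw <- design$raw_B
  zB1 <- (apply_floor(B_raw, B_star) - sB["mean"]) / sB["sd"]
  dz <- zB1 - zB0

  avail <- Filter(Negate(is.null), list(walk_draws, cycle_draws))
  if (length(avail) == 0) stop("at least one outcome's draws required")
  # outcomes are fitted separately and may carry different draw counts;
  # subsample the larger posterior evenly so draws align row-wise
  D <- min(vapply(avail, function(d) d$n_draws, numeric(1)))
  one_outcome <- function(dr) {
    if (is.null(dr)) {
      return(matrix(0, nrow = D, ncol = nrow(design$X)))
    }
    idx <- if (dr$n_draws == D) seq_len(D) else
      round(seq(1, dr$n_draws, length.out = D))
    jm <- match(design$country_ids[design$country_index], dr$country_ids)
    if (anyNA(jm)) {
      warning(sum(is.na(jm)), " city(ies) in countries absent from the ",
              "posterior skipped (zero change)")
    }
    N <- nrow(design$X)
    d_out <- matrix(0, D, N)
    X <- design$X[, dr$covariates, drop = FALSE]
    kb <- match("B", dr$covariates)
    if (is.na(kb)) return(d_out)
    for (j in seq_along(dr$country_ids)) {
      rows <- which(jm == j)
      if (length(rows) == 0) next
      b <- matrix(dr$beta[, j, ], nrow = dr$n_draws,
                  dimnames = list(NULL, dr$covariates))[idx, , drop = FALSE]
      eta0 <- dr$alpha[idx, j] + b %*% t(X[rows, , drop = FALSE])
      eta1 <- eta0 + outer(b[, kb], dz[rows])
      d_out[, rows] <- plogis(eta1) - plogis(eta0)
    }
    d_out
  }
  list(dshare_walk = one_outcome(walk_draws),
       dshare_cycle = one_outcome(cycle_draws),
       city_ids = design$city_ids)
}

# Baseline volumes needed by the accounting, aligned with a design matrix.
scenario_baseline <- function(cities, design) {
  idx <- match(design$city_ids, cities$city_id)
  cc <- cities[idx, , drop = FALSE]
  km_walk <- effective_km(cc, "walk")
  km_cycle <- effective_km(cc, "cycle")
  km_car <- effective_km(cc, "car_moto")
  km_transit <- effective_km(cc, "transit")
  list(reg_den = km_walk + km_cycle + km_car,
       km_car = km_car, km_transit = km_transit)
}

#' Displacement, emissions, and health accounting for one floor
#'
#' Per draw: added active km = share change x the city's baseline
#' regression-denominator km (total travel is held fixed; shares reallocate
#' it). Displaced motorized km = d_walk x added walk km + d_cycle x added
#' cycle km, split across car/motorcycle and transit in proportion to their
#' baseline km; only the car/motorcycle portion saves CO2. The percent CO2
#' reduction is relative to baseline car/motorcycle emissions. Health
#' benefits are per-km multipliers on the added active km.
#'
#' @param shifts Output of [shift_shares()].
#' @param cities City table (for baseline volumes).
#' @param design The factual design (city alignment).
#' @param config A [scenario_config()].
#' @return A list of per-draw aggregate vectors: `dkm_walk`, `dkm_cycle`,
#'   `displaced_km`, `displaced_car_km`, `co2_pct`, `health_usd`,
#'   `walk_share_of_co2`, and the scalar `cap_count`.
#' @export
displace_and_account <- function(shifts, cities, design, config) {
  base <- scenario_baseline(cities, design)
  T_i <- base$reg_den
  dkm_w <- sweep(shifts$dshare_walk, 2, T_i, "*")
  dkm_c <- sweep(shifts$dshare_cycle, 2, T_i, "*")
  disp <- config$d_walk * dkm_w + config$d_cycle * dkm_c
  cap_count <- 0L
  if (config$cap_displacement) {
    cap_i <- base$km_car + base$km_transit
    over <- sweep(disp, 2, cap_i, ">")
    cap_count <- sum(over)
    if (cap_count > 0) {
      capped <- sweep(disp, 2, cap_i, pmin)
      scale <- ifelse(disp > 0, capped / disp, 1)
      disp <- capped
      dkm_w_disp <- config$d_walk * dkm_w * scale
      dkm_c_disp <- config$d_cycle * dkm_c * scale
    } else {
      dkm_w_disp <- config$d_walk * dkm_w
      dkm_c_disp <- config$d_cycle * dkm_c
    }
  } else {
    dkm_w_disp <- config$d_walk * dkm_w
    dkm_c_disp <- config$d_cycle * dkm_c
  }
  mot <- base$km_car + base$km_transit
  p_car <- ifelse(mot > 0, base$km_car / mot, 0)
  disp_car <- sweep(disp, 2, p_car, "*")
  ef <- config$emission_factor
  base_co2 <- sum(base$km_car) * ef
  co2_saved <- rowSums(disp_car) * ef
  co2_pct <- if (base_co2 > 0) 100 * co2_saved / base_co2 else
    rep(0, nrow(disp))
  disp_car_walk <- rowSums(sweep(dkm_w_disp, 2, p_car, "*"))
  disp_car_total <- rowSums(disp_car)
  list(
    dkm_walk = rowSums(dkm_w),
    dkm_cycle = rowSums(dkm_c),
    displaced_km = rowSums(disp),
    displaced_car_km = disp_car_total,
    co2_pct = co2_pct,
    health_usd = config$health_walk * rowSums(dkm_w) +
      config$health_cycle * rowSums(dkm_c),
    walk_share_of_co2 = ifelse(disp_car_total != 0,
                               disp_car_walk / disp_car_total, NA_real_),
    cap_count = cap_count
  )
}

ui_row <- function(v) {
  c(mean = mean(v), lo = unname(quantile(v, 0.025)),
    hi = unname(quantile(v, 0.975)))
}

#' Sweep scenario floors
#'
#' Runs shift -> displace -> account for every floor in the grid and
#' summarizes each aggregate with its posterior mean and equal-tailed 95%
#' uncertainty interval.
#'
#' @param walk_draws,cycle_draws Posterior draws for the outcomes.
#' @param design The factual `design_matrix`.
#' @param cities City table.
#' @param config A [scenario_config()].
#' @return A `data.frame`, one row per floor: `B_star`, mean/lo/hi for
#'   `dkm_walk`, `dkm_cycle`, `co2_pct`, `health_usd`, plus
#'   `walk_share_of_co2_mean` and the deterministic `new_bikeway_km`.
#' @export
sweep_scenario <- function(walk_draws, cycle_draws, design, cities,
                           config = scenario_config()) {
  if (is.null(walk_draws) && is.null(cycle_draws)) {
    stop("at least one outcome's draws required")
  }
  rows <- lapply(config$B_grid, function(B_star) {
    sh <- shift_shares(walk_draws, cycle_draws, design, B_star)
    acc <- displace_and_account(sh, cities, design, config)
    out <- c(B_star = B_star)
    for (f in c("dkm_walk", "dkm_cycle", "co2_pct", "health_usd")) {
      v <- ui_row(acc[[f]])
      names(v) <- paste(f, c("mean", "lo", "hi"), sep = "_")
      out <- c(out, v)
    }
    wsc <- acc$walk_share_of_co2
    out <- c(out,
             walk_share_of_co2_mean = mean(wsc[is.finite(wsc)]),
             new_bikeway_km = required_construction(
               cities[cities$city_id %in% design$city_ids, ], B_star))
    out
  })
  as.data.frame(do.call(rbind, rows))
}
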