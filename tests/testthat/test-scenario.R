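# Scenario engine checks on hand-built cities and fake posteriors.

scenario_world <- function(D = 1, b_B = 0.2, alpha_val = qlogis(0.03),
                           b_B_cycle = b_B / 2) {
  cities <- manual_cities()
  countries <- manual_countries()
  design <- suppressWarnings(build_design(cities, countries))
  mk <- function(bB, outcome) {
    alpha <- matrix(alpha_val, D, 2, dimnames = list(NULL, c("AA", "BB")))
    beta <- array(0, c(D, 2, 7))
    beta[, , match("B", CITY_COVARIATES)] <- bB
    fake_draws(alpha, beta, design$registry,
               z_country = design$Z, outcome = outcome)
  }
  list(cities = cities, countries = countries, design = design,
       walk = mk(b_B, "walk"), cycle = mk(b_B_cycle, "cycle"))
}

test_that("provision floors are max-based and idempotent", {
  expect_equal(apply_floor(50, 44.3), 50)
  expect_equal(apply_floor(10, 44.3), 44.3)
  expect_equal(apply_floor(44.3, 44.3), 44.3)
  expect_equal(apply_floor(apply_floor(c(3, 70), 44.3), 44.3),
               apply_floor(c(3, 70), 44.3))
  expect_error(apply_floor(-1, 5), "non-negative")
})

test_that("required construction is the per-city shortfall sum", {
  one <- manual_cities()[1, ]  # road 200, bikeway 10
  expect_equal(required_construction(one, 44.3), 0.443 * 200 - 10)
  above <- one
  above$bikeway_km <- 150
  expect_equal(required_construction(above, 44.3), 0)
  expect_equal(required_construction(manual_cities(), 0), 0)
})

test_that("share shifts are zero when the floor binds nowhere", {
  w <- scenario_world()
  # manual cities have B = 5, 10, 0
  sh <- shift_shares(w$walk, w$cycle, w$design, 0)
  expect_true(all(sh$dshare_walk == 0))
  sh2 <- shift_shares(w$walk, w$cycle, w$design, 4)
  # only the B = 0 city moves
  expect_equal(sh2$dshare_walk[, 1:2, drop = FALSE], matrix(0, 1, 2))
  expect_gt(sh2$dshare_walk[, 3], 0)

  wz <- scenario_world(b_B = 0, b_B_cycle = 0)
  shz <- shift_shares(wz$walk, wz$cycle, wz$design, 44.3)
  expect_true(all(shz$dshare_walk == 0) && all(shz$dshare_cycle == 0))
})

test_that("a single city/draw shift matches hand computation", {
  w <- scenario_world(b_B = 0.25)
  B_star <- 20
  sh <- shift_shares(w$walk, w$cycle, w$design, B_star)
  rB <- registry_entry(w$design, "B")
  # city a1: B = 5 -> 20
  dz <- (20 - 5) / rB[["sd"]]
  eta0 <- qlogis(0.03) + 0.25 * w$design$X[1, "B"]
  want <- plogis(eta0 + 0.25 * dz) - plogis(eta0)
  expect_equal(sh$dshare_walk[1, 1], unname(want), tolerance = 1e-12)
})

test_that("displacement splits proportionally and conserves km", {
  w <- scenario_world(b_B = 0.3)
  cfg <- scenario_config(B_grid = 30, d_walk = 1.0, d_cycle = 1.0)
  sh <- shift_shares(w$walk, w$cycle, w$design, 30)
  acc <- displace_and_account(sh, w$cities, w$design, cfg)
  # conservation before capping
  expect_equal(acc$displaced_km,
               cfg$d_walk * acc$dkm_walk + cfg$d_cycle * acc$dkm_cycle,
               tolerance = 1e-9)
  expect_equal(acc$cap_count, 0L)

  # proportional car/transit split: city-by-city check
  base_car <- effective_km(w$cities, "car_moto")
  base_tr <- effective_km(w$cities, "transit")
  p_car <- base_car / (base_car + base_tr)
  T_i <- effective_km(w$cities, "walk") + effective_km(w$cities, "cycle") +
    base_car
  disp_i <- (sh$dshare_walk + sh$dshare_cycle)[1, ] * T_i
  expect_equal(acc$displaced_car_km, sum(disp_i * p_car), tolerance = 1e-9)

  # non-unit ratios break conservation exactly as configured
  cfg2 <- scenario_config(B_grid = 30, d_walk = 3.1, d_cycle = 0.8)
  acc2 <- displace_and_account(sh, w$cities, w$design, cfg2)
  expect_equal(acc2$displaced_km,
               3.1 * acc2$dkm_walk + 0.8 * acc2$dkm_cycle,
               tolerance = 1e-9)

  # zero emission factor and zero health multipliers null the accounts
  cfg0 <- scenario_config(B_grid = 30, emission_factor = 0,
                          health_walk = 0, health_cycle = 0)
  acc0 <- displace_and_account(sh, w$cities, w$design, cfg0)
  expect_equal(acc0$co2_pct, 0)
  expect_equal(acc0$health_usd, 0)
  expect_gt(acc0$displaced_km, 0)
})

test_that("one-city all-car world gives the closed-form CO2 percent", {
  cities <- manual_cities()[1, ]
  cities$km_cycle_within <- 0
  cities$km_transit_within <- 0
  cities$km_cycle_inout <- 0
  cities$km_transit_inout <- 0
  cities <- validate_city_table(as.data.frame(cities))
  base_car <- effective_km(cities, "car_moto")
  T_i <- effective_km(cities, "walk") + base_car
  design <- structure(list(city_ids = "a1"), class = "design_matrix")
  dshare <- 0.004
  shifts <- list(dshare_walk = matrix(dshare), dshare_cycle = matrix(0),
                 city_ids = "a1")
  acc <- displace_and_account(shifts, cities, design,
                              scenario_config(B_grid = 30,
                                              emission_factor = exp(1)))
  a_km <- dshare * T_i
  expect_equal(acc$co2_pct, 100 * a_km / base_car, tolerance = 1e-12)
  expect_equal(acc$health_usd, 0.5 * a_km)
})

test_that("displacement capping binds at baseline motorized km", {
  w <- scenario_world(b_B = 5, alpha_val = qlogis(0.4))  # huge shift
  cfg <- scenario_config(B_grid = 50, d_walk = 3, d_cycle = 3)
  sh <- shift_shares(w$walk, w$cycle, w$design, 50)
  acc <- displace_and_account(sh, w$cities, w$design, cfg)
  expect_gt(acc$cap_count, 0)
  uncapped <- displace_and_account(
    sh, w$cities, w$design,
    scenario_config(B_grid = 50, d_walk = 3, d_cycle = 3,
                    cap_displacement = FALSE))
  expect_lte(acc$displaced_km, uncapped$displaced_km)
})

test_that("sweep output is monotone for positive slopes and well-formed", {
  set.seed(31)
  D <- 40
  w <- scenario_world(D = D, b_B = 0.2)
  # jitter draws but keep every B slope positive
  w$walk$beta[, , match("B", CITY_COVARIATES)] <-
    abs(rnorm(D * 2, 0.2, 0.05))
  w$cycle$beta[, , match("B", CITY_COVARIATES)] <-
    abs(rnorm(D * 2, 0.1, 0.03))
  cfg <- scenario_config(B_grid = seq(1, 50, by = 7))
  res <- sweep_scenario(w$walk, w$cycle, w$design, w$cities, cfg)
  expect_equal(nrow(res), length(cfg$B_grid))
  for (col in c("dkm_walk_mean", "dkm_cycle_mean", "co2_pct_mean",
                "health_usd_mean", "new_bikeway_km")) {
    expect_true(all(diff(res[[col]]) >= -1e-12), info = col)
  }
  # interval sanity
  expect_true(all(res$co2_pct_lo <= res$co2_pct_mean + 1e-12))
  expect_true(all(res$co2_pct_mean <= res$co2_pct_hi + 1e-12))

  # floor 0 row is exactly zero everywhere
  res0 <- sweep_scenario(w$walk, w$cycle, w$design, w$cities,
                         scenario_config(B_grid = 0))
  expect_equal(res0$dkm_walk_mean, 0)
  expect_equal(res0$co2_pct_hi, 0)
  expect_equal(res0$new_bikeway_km, 0)

  # single-draw posterior: degenerate intervals
  w1 <- scenario_world(D = 1, b_B = 0.2)
  r1 <- sweep_scenario(w1$walk, w1$cycle, w1$design, w1$cities,
                       scenario_config(B_grid = 25))
  expect_equal(r1$dkm_walk_lo, r1$dkm_walk_mean)
  expect_equal(r1$dkm_walk_hi, r1$dkm_walk_mean)

  # outcomes with unequal draw counts align by even subsampling
  w3 <- scenario_world(D = 3, b_B = 0.2)
  w2 <- scenario_world(D = 2, b_B = 0.1)
  shm <- shift_shares(w3$walk, w2$cycle, w3$design, 30)
  expect_equal(nrow(shm$dshare_walk), 2)
  expect_equal(nrow(shm$dshare_cycle), 2)
  # constant-parameter draws: subsampling changes nothing
  expect_equal(shm$dshare_walk[1, ], shm$dshare_walk[2, ])

  # result invariant to city ordering
  perm <- c(3, 1, 2)
  dperm <- w$design
  dperm$X <- w$design$X[perm, ]
  dperm$country_index <- w$design$country_index[perm]
  dperm$city_ids <- w$design$city_ids[perm]
  dperm$raw_B <- w$design$raw_B[perm]
  res_p <- sweep_scenario(w$walk, w$cycle, dperm, w$cities, cfg)
  expect_equal(res_p, res, tolerance = 1e-12)
})

test_that("preset floors resolve to Copenhagen or the 95th percentile", {
  expect_equal(preset_floor("copenhagen"), 44.3)
  cities <- manual_cities()
  expect_equal(preset_floor("percentile95", cities),
               unname(quantile(c(5, 10, 0), 0.95)))
})
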