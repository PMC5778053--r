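test_that("zero rise and zero SEC is a fixed point of the step", {
  est <- tiny_world()
  st <- initial_state(est$dem, est$subsites, est$frame, zonation_bands(),
                      zero_scenario(), engine = "slamm", cfg = zero_rates())
  st2 <- sim_step(st, 10)
  expect_identical(st2$z$values, st$z$values)
  expect_identical(st2$veg$values, st$veg$values)
  expect_equal(st2$year, st$year + 10)
})

test_that("one band of rise retrogresses every class one step seaward", {
  # five cells at the midpoints of the five equal-width bands, plus water
  bands <- strip_bands(0.3)
  w <- strip_world(c(-2, -0.45, -0.15, 0.15, 0.45, 0.75))
  veg0 <- classify_grid(w$dem, w$subsites, w$frame, bands)
  expect_equal(veg0$values[1, ], class_rank(
    c("open_water", "mudflat", "mangrove", "mixed", "saltmarsh",
      "casuarina")))
  scn <- slr_scenario(c(2000, 2010), c(0, 0.3)) # exactly one band width
  st <- initial_state(w$dem, w$subsites, w$frame, bands, scn,
                      engine = "slamm", cfg = zero_rates(), veg = veg0)
  st <- sim_step(st, 10)
  expect_equal(st$veg$values[1, ], class_rank(
    c("open_water", "open_water", "mudflat", "mangrove", "mixed",
      "saltmarsh")))
  # water never becomes vegetated even if elevations later permit it
  expect_equal(st$veg$values[1, 1], class_rank("open_water"))
})

test_that("SEC matching the rise rate leaves vegetation unchanged", {
  est <- tiny_world()
  rate <- 3 # mm/yr
  scn <- linear_scenario(rate, 2000:2100)
  st <- initial_state(est$dem, est$subsites, est$frame, zonation_bands(),
                      scn, engine = "slamm", cfg = flat_rates(rate))
  run <- sim_run(st, 2100, dt = 10)
  final <- run$final_state
  expect_identical(final$veg$values, st$veg$values)
  total <- anomaly_at(scn, 2100)
  ok <- !st$z$nodata_mask
  expect_equal(final$z$values[ok], st$z$values[ok] + total,
               tolerance = 1e-12)
})

test_that("runs record areas per step, conserve area, and are deterministic", {
  est <- tiny_world()
  scn <- make_scenarios(years = 1997:2100)$projection
  st <- initial_state(est$dem, est$subsites, est$frame, zonation_bands(),
                      scn, engine = "slamm")
  run <- sim_run(st, 2097, dt = 10)
  expect_equal(sort(unique(run$areas$year)), seq(1997, 2097, by = 10))
  totals <- dplyr::summarise(dplyr::group_by(run$areas, year),
                             total = sum(area_ha))
  unmasked_ha <- sum(!est$dem$nodata_mask) * est$dem$cell_size^2 / 1e4
  expect_equal(totals$total, rep(unmasked_ha, nrow(totals)))
  # determinism
  st2 <- initial_state(est$dem, est$subsites, est$frame, zonation_bands(),
                       scn, engine = "slamm")
  run2 <- sim_run(st2, 2097, dt = 10)
  expect_identical(run2$areas, run$areas)
  # degenerate run: already at the horizon
  run0 <- sim_run(st, 1997)
  expect_equal(nrow(run0$areas), 7)
  expect_equal(run0$areas$area_ha, area_by_class(st$veg)$area_ha)
})

test_that("with zero SEC and slamm policy open water area never shrinks", {
  est <- tiny_world()
  scn <- make_scenarios(total_rise_by_2100 = 0.6, years = 2000:2100)$projection
  st <- initial_state(est$dem, est$subsites, est$frame, zonation_bands(),
                      scn, engine = "slamm", cfg = zero_rates())
  run <- sim_run(st, 2100, dt = 10)
  ow <- run$areas$area_ha[run$areas$class == "open_water"]
  expect_true(all(diff(ow) >= 0))
  # a pointwise-dominating scenario floods at least as much
  scn_hi <- make_scenarios(total_rise_by_2100 = 0.9,
                           years = 2000:2100)$projection
  st_hi <- initial_state(est$dem, est$subsites, est$frame, zonation_bands(),
                         scn_hi, engine = "slamm", cfg = zero_rates())
  run_hi <- sim_run(st_hi, 2100, dt = 10)
  ow_hi <- run_hi$areas$area_ha[run_hi$areas$class == "open_water"]
  expect_true(all(ow_hi - ow >= 0))
})

test_that("initial vegetation follows the engine's intended mode", {
  est <- tiny_world()
  bands <- zonation_bands()
  mapped <- make_initial_veg(est$dem, est$subsites, est$frame, bands,
                             perturbation = 0.3, seed = 2)
  scn <- zero_scenario()
  st_slamm <- initial_state(est$dem, est$subsites, est$frame, bands, scn,
                            engine = "slamm", veg = mapped)
  st_cm1 <- initial_state(est$dem, est$subsites, est$frame, bands, scn,
                          engine = "cm1")
  st_cm2 <- initial_state(est$dem, est$subsites, est$frame, bands, scn,
                          engine = "cm2",
                          covariates = make_covariates(covariate_recipe(
                            start_year = 2000, end_year = 2100)))
  # slamm keeps the map, the comparison engines classify from the DEM
  expect_identical(st_slamm$veg$values, mapped$values)
  expect_identical(st_cm1$veg$values, st_cm2$veg$values)
  expect_false(identical(st_cm1$veg$values, mapped$values))
  # a map exactly consistent with zonation makes the modes agree
  clean <- make_initial_veg(est$dem, est$subsites, est$frame, bands)
  st_consistent <- initial_state(est$dem, est$subsites, est$frame, bands,
                                 scn, engine = "slamm", veg = clean)
  expect_identical(st_consistent$veg$values, st_cm1$veg$values)
})

test_that("stepping beyond the scenario is a range error; cm2 needs covariates", {
  est <- tiny_world()
  scn <- zero_scenario(2000:2020)
  st <- initial_state(est$dem, est$subsites, est$frame, zonation_bands(),
                      scn, engine = "slamm")
  expect_error(sim_run(st, 2030), "range error")
  expect_error(initial_state(est$dem, est$subsites, est$frame,
                             zonation_bands(), scn, engine = "cm2"),
               "covariate")
})

test_that("cm1 builds a channel-bank levee behind which flooding onsets", {
  # channel-bank strip: elevation constant, distance to channel increasing,
  # so near-channel cells out-accrete distant cells
  z <- rep(0.05, 12)
  w <- strip_world(c(-2, z), gt = 1.2, salt_boundary = 0.66)
  scn <- slr_scenario(2000:2100, 0.009 * (0:100), "fast-linear")
  st <- initial_state(w$dem, w$subsites, w$frame, zonation_bands(), scn,
                      engine = "cm1",
                      cfg = cm1_sec_config(k = 20, l = 1, m = 0.05))
  run <- sim_run(st, 2100, dt = 10)
  zfin <- run$final_state$z$values[1, -1]
  expect_true(all(diff(zfin) <= 1e-12)) # accretion decays away from channel
  fin <- run$final_state$veg$values[1, -1]
  # the bank keeps pace; flooding onsets landward of it
  expect_gte(fin[1], class_rank("mudflat"))
  expect_equal(fin[12], class_rank("open_water"))
  expect_gt(fin[1], fin[12])
})
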