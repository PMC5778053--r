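test_that("percent area difference is signed and guards undefined ratios", {
  pad <- percent_area_difference(c(saltmarsh = 108.5, mangrove = 75,
                                   mixed = 50, mudflat = 0),
                                 c(saltmarsh = 100, mangrove = 100,
                                   mixed = 50, mudflat = 0))
  expect_equal(pad$pct_diff, c(8.5, -25, 0, 0))
  # observed zero with modelled presence is reported NA, never infinite
  pad2 <- percent_area_difference(c(casuarina = 3), c(casuarina = 0))
  expect_true(is.na(pad2$pct_diff))
})

test_that("overlap matrix equals a brute-force tally and rows sum to one", {
  # 2x2 toy: all modelled saltmarsh, observed half saltmarsh half mangrove
  m <- vegetation_grid(matrix(class_rank("saltmarsh"), 2, 2), 10)
  o <- vegetation_grid(matrix(class_rank(c("saltmarsh", "mangrove",
                                           "saltmarsh", "mangrove")), 2, 2),
                       10)
  O <- overlap_matrix(m, o)
  expect_equal(O["saltmarsh", "saltmarsh"], 0.5)
  expect_equal(O["saltmarsh", "mangrove"], 0.5)
  expect_true(all(is.na(O["mangrove", ])))

  # identical maps give an identity overlap on present classes
  v <- random_veg(12, 12, seed = 21)
  Oi <- overlap_matrix(v, v)
  expect_equal(diag(Oi)[!is.na(diag(Oi))],
               rep(1, sum(!is.na(diag(Oi)))), ignore_attr = TRUE)

  # disjoint single-class maps put all mass off-diagonal
  a <- vegetation_grid(matrix(class_rank("mangrove"), 3, 3), 10)
  b <- vegetation_grid(matrix(class_rank("upland"), 3, 3), 10)
  expect_equal(overlap_matrix(a, b)["mangrove", "upland"], 1)
  expect_equal(disagreement_fraction(a, b), 1)

  # random maps vs brute force
  for (seed in 1:5) {
    x <- random_veg(10, 10, seed = seed)
    y <- random_veg(10, 10, seed = seed + 100)
    O <- overlap_matrix(x, y)
    for (i in 1:7) {
      ni <- sum(x$values == i)
      if (ni == 0) next
      expect_equal(sum(O[i, ]), 1)
      for (j in 1:7) {
        expect_equal(O[i, j], sum(x$values == i & y$values == j) / ni)
      }
    }
    expect_equal(disagreement_fraction(x, y), mean(x$values != y$values))
  }
})

test_that("the 10% rule is strict and monotone in its threshold", {
  v <- validity_check(c(a = 1.7, b = 8.5, c = -25, d = 94))
  expect_equal(v$valid, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(attr(v, "overall_valid"))
  expect_true(attr(validity_check(c(1.7, 8.5)), "overall_valid"))
  expect_false(validity_check(c(x = 10))$valid) # exactly 10 is invalid
  # monotone: everything valid at t1 < t2 is valid at t2
  diffs <- c(-12, -9.99, 0, 5, 9.99, 10, 15)
  for (t1 in c(5, 10)) for (t2 in c(10, 20)) {
    if (t1 >= t2) next
    v1 <- validity_check(diffs, t1)$valid
    v2 <- validity_check(diffs, t2)$valid
    expect_true(all(v2[v1]))
  }
})

test_that("agreement_report bundles areas, overlap and validity", {
  est <- tiny_world()
  obs <- make_initial_veg(est$dem, est$subsites, est$frame,
                          perturbation = 0.1, seed = 3)
  mod <- make_initial_veg(est$dem, est$subsites, est$frame)
  rep <- agreement_report(mod, obs)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 7)
  expect_equal(rep$disagreement, disagreement_fraction(mod, obs))
  g <- glance(rep)
  expect_true(is.logical(g$overall_valid))
})

test_that("pathway-less parameters give exactly zero sensitivity rows", {
  est <- tiny_world()
  scn <- make_scenarios(years = 2000:2100)$projection
  cov <- make_covariates(covariate_recipe(start_year = 2000,
                                          end_year = 2100), scn)
  base <- list(dem = est$dem, subsites = est$subsites, frame = est$frame,
               bands = zonation_bands(), scenario = scn, engine = "cm2",
               cfg = cm2_sec_config(b_rain = 0), covariates = cov)
  tab <- sensitivity_analysis(base, c("cm2_rain", "historic_trend"),
                              0.1, 2050, dt = 25)
  nz <- tab$pct_change[!is.na(tab$pct_change)]
  expect_true(all(nz == 0))
  expect_error(
    sensitivity_analysis(base, "sec_mangrove", 0.1, 2050, dt = 25),
    "configuration error")
  expect_error(
    sensitivity_analysis(base, "no_such_knob", 0.1, 2050, dt = 25),
    "configuration error")
})

test_that("sensitivity responds linearly to first order on a linear pathway", {
  # fine-grained ramp (1 mm elevation increments) so flooded area responds
  # continuously to the perturbed total rise
  w <- strip_world(-0.7 + (seq_len(2500) - 0.5) * 0.001)
  scn <- linear_scenario(10, 2000:2100)
  base <- list(dem = w$dem, subsites = w$subsites, frame = w$frame,
               bands = zonation_bands(), scenario = scn, engine = "slamm",
               cfg = zero_rates())
  t1 <- sensitivity_analysis(base, "slr_by_2100", 0.1, 2100, dt = 50)
  t2 <- sensitivity_analysis(base, "slr_by_2100", 0.2, 2100, dt = 50)
  p1 <- t1$pct_change[t1$direction == "+" & t1$class == "open_water"]
  p2 <- t2$pct_change[t2$direction == "+" & t2$class == "open_water"]
  expect_gt(p1, 0)
  expect_equal(unname(p2 / p1), 2, tolerance = 0.02) # doubled dose
  head <- sensitivity_headline(t1)
  expect_equal(tail(head$class, 4), c("minimum", "maximum", "mean", "sd"))
})

test_that("model comparison degenerates to equality under identical physics", {
  est <- tiny_world()
  scn <- make_scenarios(years = 2000:2100)$projection
  cov <- make_covariates(covariate_recipe(start_year = 2000,
                                          end_year = 2100), scn)
  configs <- list(
    slamm = zero_rates(),
    cm1 = cm1_sec_config(k = 0),
    cm2 = cm2_sec_config(intercept = 0, b_time = 0, b_rain = 0, b_wl6 = 0,
                         b_dist = 0, b_soi = 0, b_msl = 0))
  cmp <- compare_models(est$dem, est$subsites, est$frame, zonation_bands(),
                        scn, 2100, configs = configs, covariates = cov,
                        policies = list(slamm = "boundary_free",
                                        cm1 = "boundary_free",
                                        cm2 = "boundary_free"))
  expect_true(all(cmp$disagreement$fraction == 0))
  expect_true(all(cmp$deltas$delta_ha == 0))
  # disagreement equals a brute-force mismatch count
  g1 <- cmp$runs$slamm$grids[["2100"]]
  g2 <- cmp$runs$cm1$grids[["2100"]]
  expect_equal(cmp$disagreement$fraction[cmp$disagreement$year == 2100][1],
               mean(g1$values != g2$values))
})

test_that("cm1 can prograde where the slamm engine cannot", {
  est <- tiny_world()
  scn <- linear_scenario(1, 2000:2100) # slow rise, strong sediment supply
  cmp <- compare_models(est$dem, est$subsites, est$frame, zonation_bands(),
                        scn, 2100,
                        configs = list(slamm = zero_rates(),
                                       cm1 = cm1_sec_config(k = 15, l = 2,
                                                            m = 0.002)))
  fin <- function(e) {
    a <- cmp$runs[[e]]$areas
    a$area_ha[a$year == 2100 & a$class == "mangrove"]
  }
  expect_gt(fin("cm1"), fin("slamm"))
})
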