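#' Build the initial coupled elevation-vegetation state
#'
#' The SLAMM-style engine starts from a supplied vegetation map when one is
#' given (the mapped distribution is the best estimate of time zero); the
#' comparison engines, and any engine without a map, derive the initial
#' vegetation from the DEM through the zonation bands.
#'
#' @param dem An [elevation_grid()].
#' @param subsites A [subsite_map()].
#' @param frame A [tidal_frame()].
#' @param bands A [zonation_bands()].
#' @param scenario An [slr_scenario()] forcing curve.
#' @param engine `"slamm"`, `"cm1"` or `"cm2"`.
#' @param cfg Engine configuration (defaults per engine, see
#'   [slamm_sec_config()]).
#' @param veg Optional [vegetation_grid()] initial map (used by `slamm`).
#' @param policy A [succession_policy()]; defaults to `"slamm"` for the
#'   slamm engine and `"boundary_free"` for cm1/cm2.
#' @param covariates Covariate series tibble (required by `cm2`; see
#'   [make_covariates()]).
#' @param dist A [distance_field()]; derived from the initial open-water
#'   cells when absent and needed.
#' @param start_year Defaults to the scenario's first year.
#' @return A `wetland_state`.
#' @export
initial_state <- function(dem, subsites, frame, bands, scenario,
                          engine = c("slamm", "cm1", "cm2"), cfg = NULL,
                          veg = NULL, policy = NULL, covariates = NULL,
                          dist = NULL, start_year = NULL) {
  engine <- match.arg(engine)
  if (is.null(cfg)) cfg <- default_sec_config(engine)
  if (is.null(policy)) {
    policy <- succession_policy(if (engine == "slamm") "slamm"
                                else "boundary_free")
  }
  if (is.null(start_year)) start_year <- min(scenario$year)
  if (engine == "slamm" && !is.null(veg)) {
    check_same_geometry(dem, veg)
  } else {
    veg <- classify_grid(dem, subsites, frame, bands)
  }
  if (is.null(dist) && engine %in% c("cm1", "cm2")) {
    water <- !veg$nodata_mask & veg$values == class_rank("open_water")
    dist <- distance_field(water, dem$cell_size)
  }
  if (engine == "cm2" && is.null(covariates)) {
    stop("configuration error: the cm2 engine needs a covariate series",
         call. = FALSE)
  }
  structure(list(year = start_year, z = dem, veg = veg, subsites = subsites,
                 frame = frame, bands = bands, scenario = scenario,
                 engine = engine, cfg = cfg, policy = policy,
                 covariates = covariates, dist = dist,
                 start_year = start_year),
            class = "wetland_state")
}

covariates_at <- function(covariates, year) {
  if (is.null(covariates)) {
    stop("input error: no covariate series supplied", call. = FALSE)
  }
  rng <- range(covariates$year)
  if (year < rng[1] || year > rng[2]) {
    stop("input error: covariates do not cover year ", year, call. = FALSE)
  }
  cols <- c("rain_prev_month_mm", "waterlevel_6mo_m", "soi_3mo", "msl_m")
  out <- lapply(cols, function(cl) {
    if (is.null(covariates[[cl]])) return(NULL)
    stats::approx(covariates$year, covariates[[cl]], xout = year)$y
  })
  names(out) <- cols
  out
}

# per-cell SEC rate field (mm/yr) from the pre-step classification and
# elevation, under the frame holding the current (risen) sea level
rate_field <- function(state, frame) {
  codes <- state$veg$values
  z <- state$z$values
  switch(state$engine,
    slamm = {
      if (!state$cfg$proportional) {
        r <- matrix(NA_real_, nrow(codes), ncol(codes))
        ok <- !state$veg$nodata_mask
        r[ok] <- slamm_rate(codes[ok], cfg = state$cfg)
        r[!ok] <- 0
        r
      } else {
        r <- matrix(0, nrow(codes), ncol(codes))
        for (k in seq_len(nrow(frame))) {
          s <- frame$subsite_id[k]
          in_s <- !state$veg$nodata_mask & state$subsites$values == s
          if (!any(in_s)) next
          r[in_s] <- slamm_rate(codes[in_s], z[in_s], frame$gt_m[k],
                                frame$msl_offset_m[k],
                                frame$salt_boundary_m[k], state$cfg,
                                state$bands)
        }
        r
      }
    },
    cm1 = {
      gtm <- frame_field(frame, state$subsites, "gt_m")
      mslm <- frame_field(frame, state$subsites, "msl_offset_m")
      saltm <- frame_field(frame, state$subsites, "salt_boundary_m")
      r <- cm1_rate(z, state$dist$dist_channel, gtm, mslm, saltm, state$cfg)
      r[is.na(r)] <- 0
      r
    },
    cm2 = {
      cov <- covariates_at(state$covariates, state$year)
      t_days <- (state$year - state$start_year) * 365.25
      d <- if (state$cfg$distance == "channel") state$dist$dist_channel
           else state$dist$dist_mouth
      r <- cm2_rate(t_days, cov, d, state$cfg)
      if (!is.matrix(r)) r <- matrix(r, nrow(codes), ncol(codes))
      r
    }
  )
}

#' Advance the coupled state one time step
#'
#' Operator splitting, in the order sea level, then elevation, then
#' vegetation: (1) every subsite's local mean sea level rises by the
#' scenario anomaly increment over the step; (2) the substrate is advanced
#' by the engine's SEC rate field, computed from the pre-step
#' classification; (3) every cell is reclassified against the new frame and
#' the succession policy arbitrates against the previous class.
#'
#' @param state A `wetland_state` from [initial_state()].
#' @param dt Step length (years, > 0); decadal steps are the conventional
#'   resolution.
#' @return The advanced `wetland_state`.
#' @export
sim_step <- function(state, dt) {
  stopifnot(inherits(state, "wetland_state"), dt > 0)
  year2 <- state$year + dt
  danom <- anomaly_at(state$scenario, year2) -
    anomaly_at(state$scenario, state$year)
  frame2 <- state$frame
  frame2$msl_offset_m <- frame2$msl_offset_m + danom
  frame2 <- rebuild_frame(state$frame, frame2)
  rates <- rate_field(state, frame2)
  z2 <- advance_elevation(state$z, rates, dt)
  proposed <- classify_grid(z2, state$subsites, frame2, state$bands)
  codes2 <- apply_succession(state$veg$values, proposed$values, state$policy)
  veg2 <- vegetation_grid(codes2, state$veg$cell_size, state$veg$origin,
                          state$veg$nodata_mask)
  state$year <- year2
  state$frame <- frame2
  state$z <- z2
  state$veg <- veg2
  state
}

#' Run a simulation through a scenario
#'
#' Iterates [sim_step()] from the state's current year to `end_year`,
#' recording the per-class area table at every step (and optionally the
#' vegetation rasters). Runs are deterministic given their inputs.
#'
#' @inheritParams sim_step
#' @param end_year Final year; must lie within the scenario span.
#' @param dt Step length in years (default 10); a shorter final step is
#'   taken if the horizon is not a multiple of `dt`.
#' @param keep_grids Keep the per-step vegetation grids (needed by
#'   map-comparison statistics).
#' @return A `wetland_run`: list with `areas` (tibble `year`, `class`,
#'   `area_ha`), `grids` (named list or `NULL`), `final_state`, and `meta`.
#' @export
sim_run <- function(state, end_year, dt = 10, keep_grids = FALSE) {
  areas <- list(dplyr::mutate(area_by_class(state$veg), year = state$year,
                              .before = 1))
  grids <- if (keep_grids) stats::setNames(list(state$veg),
                                           as.character(state$year))
  while (state$year < end_year - 1e-9) {
    step_len <- min(dt, end_year - state$year)
    state <- sim_step(state, step_len)
    areas[[length(areas) + 1L]] <-
      dplyr::mutate(area_by_class(state$veg), year = state$year, .before = 1)
    if (keep_grids) grids[[as.character(state$year)]] <- state$veg
  }
  structure(list(
    areas = dplyr::bind_rows(areas),
    grids = grids,
    final_state = state,
    meta = list(engine = state$engine,
                scenario = attr(state$scenario, "label", exact = TRUE),
                policy = state$policy$mode,
                start_year = state$start_year, end_year = state$year,
                total_slr_m = anomaly_at(state$scenario, state$year) -
                  anomaly_at(state$scenario, state$start_year))
  ), class = "wetland_run")
}

#' @export
print.wetland_run <- function(x, ...) {
  cat(sprintf("<wetland_run> engine %s, %s, %g-%g (%.3f m SLR)\n",
              x$meta$engine, x$meta$scenario, x$meta$start_year,
              x$meta$end_year, x$meta$total_slr_m))
  print(tidyr::pivot_wider(x$areas, names_from = "class",
                           values_from = "area_ha"))
  invisible(x)
}

#' Tidy methods for simulation results
#'
#' `tidy()` returns the per-step class-area table in long form; `glance()`
#' returns a one-row run summary.
#'
#' @param x A `wetland_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wetland_run <- function(x, ...) x$areas

#' @rdname tidy.wetland_run
#' @export
glance.wetland_run <- function(x, ...) {
  final <- x$areas[x$areas$year == x$meta$end_year, ]
  wide <- stats::setNames(as.list(final$area_ha),
                          paste0("final_", final$class, "_ha"))
  tibble::tibble(engine = x$meta$engine, scenario = x$meta$scenario,
                 policy = x$meta$policy, start_year = x$meta$start_year,
                 end_year = x$meta$end_year,
                 total_slr_m = x$meta$total_slr_m, !!!wide)
}
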