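#' Recipe for a synthetic barrier estuary
#'
#' Generates the structure the analysis assumes without any external data:
#' a meandering channel incised into a cross-shore floodplain ramp, an
#' along-channel attenuating tide partitioned into subsites, and seeded
#' Gaussian microtopography. The seed fixes all randomness, so the
#' generators are pure functions of the recipe.
#'
#' The defaults describe a small wave-dominated barrier estuary: a
#' 1.2 km x 2 km grid at 10 m resolution, a 1.2 m great diurnal range at
#' the mouth decaying to roughly 0.4 m at the head (eight subsites), a salt
#' boundary at 0.55 of the local tide range, a gentle floodplain ramp
#' capped by a low backing plateau (so rising seas squeeze the upper
#' intertidal zone against terrestrial land), and a 2.1 mm/yr historic
#' sea-level trend.
#'
#' @param nrow,ncol Grid shape; rows run along the channel, row 1 is the
#'   mouth (northernmost).
#' @param cell_size Cell edge (m).
#' @param meander_amplitude,meander_wavelength Channel sinusoid (m).
#' @param channel_width Channel width (m).
#' @param channel_depth Incision depth below the mouth low-tide level (m).
#' @param floodplain_slope Cross-shore slope (m/m).
#' @param plateau_elev Elevation cap of the backing floodplain (m).
#' @param n_subsites Number of along-channel subsites.
#' @param gt_mouth Great diurnal range at the mouth (m).
#' @param attenuation Fractional tide-range loss per km along channel.
#' @param salt_boundary_frac Salt boundary as a fraction of local `gt`.
#' @param noise_sd Microtopography standard deviation (m).
#' @param msl_offset Local mean sea level above the height datum (m).
#' @param historic_trend_mm_yr Historic sea-level trend (mm/yr).
#' @param datum_correction_m Height-to-tidal-datum correction (m).
#' @param seed Integer seed fixing all randomness.
#' @return An `estuary_recipe` list.
#' @export
estuary_recipe <- function(nrow = 120, ncol = 200, cell_size = 10,
                           meander_amplitude = 250,
                           meander_wavelength = 1600,
                           channel_width = 60, channel_depth = 2,
                           floodplain_slope = 0.004, plateau_elev = 1.4,
                           n_subsites = 8, gt_mouth = 1.2,
                           attenuation = 0.6, salt_boundary_frac = 0.55,
                           noise_sd = 0.02, msl_offset = 0,
                           historic_trend_mm_yr = 2.1,
                           datum_correction_m = 0.05, seed = 1) {
  r <- as.list(environment())
  if (r$floodplain_slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (r$attenuation < 0 || r$attenuation >= 1) {
    stop("attenuation must be in [0, 1)", call. = FALSE)
  }
  structure(r, class = "estuary_recipe")
}

#' Generate the synthetic estuary world
#'
#' Builds the DEM (cross-shore ramp from below low-tide level at the
#' channel banks to the backing plateau, plus channel incision and seeded
#' microtopography), the along-channel subsite partition with
#' `gt(s) = gt_mouth * (1 - attenuation)^km(s)`, the tidal frame, and the
#' frozen distance fields derived from the channel mask. Deterministic per
#' seed.
#'
#' @param recipe An [estuary_recipe()].
#' @return A list: `dem` ([elevation_grid()]), `subsites` ([subsite_map()]),
#'   `frame` ([tidal_frame()]), `dist` ([distance_field()]), `channel`
#'   (logical matrix), and the `recipe`.
#' @export
make_estuary <- function(recipe) {
  stopifnot(inherits(recipe, "estuary_recipe"))
  r <- recipe
  rows <- seq_len(r$nrow); cols <- seq_len(r$ncol)
  along_m <- (rows - 0.5) * r$cell_size
  centre_col <- (r$ncol + 1) / 2 +
    (r$meander_amplitude / r$cell_size) *
    sin(2 * pi * along_m / r$meander_wavelength)
  cross_m <- abs(outer(centre_col, cols, function(cc, j) j - cc)) * r$cell_size
  channel <- cross_m <= r$channel_width / 2
  a_mouth <- r$gt_mouth / 2
  bank <- pmax(cross_m - r$channel_width / 2, 0) # first arg keeps dims
  z <- pmin(-1.2 * a_mouth + r$floodplain_slope * bank, r$plateau_elev)
  z[channel] <- -a_mouth - r$channel_depth
  if (r$noise_sd > 0) {
    z <- z + withr::with_seed(r$seed, {
      matrix(stats::rnorm(r$nrow * r$ncol, sd = r$noise_sd), r$nrow, r$ncol)
    })
  }
  z <- z + r$msl_offset
  dem <- elevation_grid(z, r$cell_size)

  km <- along_m / 1000
  bin <- pmin(r$n_subsites,
              1L + floor(km / (max(km) * 1.0000001) * r$n_subsites))
  ids <- matrix(rep(as.integer(bin), r$ncol), r$nrow, r$ncol)
  subsites <- subsite_map(ids, r$cell_size)

  km_mid <- vapply(seq_len(r$n_subsites),
                   function(s) mean(km[bin == s]), numeric(1))
  gt <- r$gt_mouth * (1 - r$attenuation)^km_mid
  frame <- build_frame(
    subsites,
    tibble::tibble(subsite_id = seq_len(r$n_subsites),
                   msl_offset_m = r$msl_offset,
                   gt_m = gt,
                   salt_boundary_m = r$salt_boundary_frac * gt),
    historic_trend_mm_yr = r$historic_trend_mm_yr,
    datum_correction_m = r$datum_correction_m)

  intertidal <- !channel & (z - r$msl_offset) < max(frame$salt_boundary_m)
  if (!any(intertidal)) {
    stop("recipe error: the recipe produces an empty intertidal zone",
         call. = FALSE)
  }
  list(dem = dem, subsites = subsites, frame = frame,
       dist = distance_field(channel, r$cell_size),
       channel = channel, recipe = recipe)
}

#' Generate an initial vegetation map, optionally perturbed
#'
#' Classifies the DEM through the zonation bands, then swaps a seeded
#' fraction of the intertidal cells (mudflat..casuarina) to an adjacent
#' class — mimicking the disagreement between a photo-interpreted map and
#' pure elevation zonation, with known ground truth.
#'
#' @inheritParams classify_grid
#' @param perturbation Fraction of intertidal cells to swap, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [vegetation_grid()].
#' @export
make_initial_veg <- function(dem, subsites, frame, bands = zonation_bands(),
                             perturbation = 0, seed = 1) {
  stopifnot(perturbation >= 0, perturbation <= 1)
  veg <- classify_grid(dem, subsites, frame, bands)
  if (perturbation == 0) return(veg)
  codes <- veg$values
  swappable <- which(!veg$nodata_mask & codes >= class_rank("mudflat") &
                       codes <= class_rank("casuarina"))
  n_swap <- round(perturbation * length(swappable))
  if (n_swap > 0) {
    withr::with_seed(seed, {
      pick <- sample(swappable, n_swap)
      dir <- sample(c(-1L, 1L), n_swap, replace = TRUE)
      prop <- codes[pick] + dir
      # reflect at the ends of the swappable range so swaps stay intertidal
      prop[prop < class_rank("mudflat")] <- class_rank("mangrove")
      prop[prop > class_rank("casuarina")] <- class_rank("saltmarsh")
      codes[pick] <- prop
    })
  }
  vegetation_grid(codes, veg$cell_size, veg$origin, veg$nodata_mask)
}

#' Build the scenario pair used by the analyses
#'
#' A pure-acceleration (quadratic) projection curve reaching
#' `total_rise_by_2100` at the final year, plus a linear historic curve at
#' the stated trend — the forcing shapes the validation and comparison
#' procedures assume. Tabulated at every year so any step interval lands on
#' the curve.
#'
#' @param total_rise_by_2100 Total rise of the projection curve (m).
#' @param historic_trend_mm_yr Linear historic trend (mm/yr).
#' @param years Year vector (default 1997:2100).
#' @param label Label of the projection scenario.
#' @return List of two [slr_scenario()]s: `projection`, `historic`.
#' @export
make_scenarios <- function(total_rise_by_2100 = 0.9,
                           historic_trend_mm_yr = 2.1,
                           years = 1997:2100, label = "A1FI-95CI-like") {
  stopifnot(total_rise_by_2100 >= 0)
  t0 <- years[1]; tn <- years[length(years)]
  frac <- (years - t0) / (tn - t0)
  list(
    projection = slr_scenario(years, total_rise_by_2100 * frac^2, label),
    historic = slr_scenario(years,
                            historic_trend_mm_yr * (years - t0) / 1000,
                            "historic-linear")
  )
}

#' Recipe and generator for CM2 covariate series
#'
#' Seeded synthetic stand-ins for the site records the linear covariate
#' engine consumes: Gaussian monthly-rainfall values, a sinusoidal SOI with
#' a stated ENSO-like period, and water level and mean sea level tied to a
#' scenario anomaly (plus seeded noise on the water level).
#'
#' @param start_year,end_year Span of the series.
#' @param rain_mean,rain_sd Previous-month rainfall distribution (mm).
#' @param soi_amplitude,soi_period SOI sinusoid (index units, years).
#' @param wl_noise_sd Water-level noise sd (m).
#' @param seed Integer seed.
#' @return A `covariate_recipe` list.
#' @export
covariate_recipe <- function(start_year = 1997, end_year = 2100,
                             rain_mean = 90, rain_sd = 30,
                             soi_amplitude = 8, soi_period = 4,
                             wl_noise_sd = 0.03, seed = 1) {
  structure(as.list(environment()), class = "covariate_recipe")
}

#' @rdname covariate_recipe
#' @param recipe A `covariate_recipe`.
#' @param scenario Optional [slr_scenario()]; when given, water level and
#'   MSL follow its anomaly.
#' @return `make_covariates()`: a tibble `year`, `rain_prev_month_mm`,
#'   `waterlevel_6mo_m`, `soi_3mo`, `msl_m`.
#' @export
make_covariates <- function(recipe, scenario = NULL) {
  stopifnot(inherits(recipe, "covariate_recipe"))
  r <- recipe
  years <- seq(r$start_year, r$end_year)
  n <- length(years)
  anom <- if (is.null(scenario)) rep(0, n) else {
    anomaly_at(scenario, pmin(pmax(years, min(scenario$year)),
                              max(scenario$year)))
  }
  withr::with_seed(r$seed, {
    rain <- pmax(0, stats::rnorm(n, r$rain_mean, r$rain_sd))
    wl_noise <- if (r$wl_noise_sd > 0) stats::rnorm(n, 0, r$wl_noise_sd)
                else numeric(n)
  })
  tibble::tibble(
    year = years,
    rain_prev_month_mm = rain,
    waterlevel_6mo_m = anom + wl_noise,
    soi_3mo = r$soi_amplitude * sin(2 * pi * (years - years[1]) /
                                      r$soi_period),
    msl_m = anom
  )
}
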