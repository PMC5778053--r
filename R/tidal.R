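#' Per-subsite tidal datums
#'
#' A tidal frame carries, for each subsite of the estuary, the local tidal
#' parameters that control inundation: the local mean sea level offset
#' relative to the height datum (`msl_offset_m`), the great diurnal tide
#' range (`gt_m`, MHHW to MLLW), and the salt boundary elevation
#' (`salt_boundary_m`, upper limit of tidally influenced wetland, stored
#' relative to local MSL so it attenuates with the subsite). Two global
#' quantities ride along as attributes: the historic sea-level trend (mm/yr)
#' and a height-to-tidal-datum correction (m).
#'
#' In a barrier estuary the tide attenuates as it propagates upstream, so
#' `gt_m` is typically non-increasing with along-channel distance; a frame
#' built by [make_estuary()] always has that structure.
#'
#' @param table Data frame with columns `subsite_id`, `msl_offset_m`,
#'   `gt_m`, `salt_boundary_m` (one row per subsite).
#' @param historic_trend_mm_yr Historic linear sea-level trend (mm/yr).
#' @param datum_correction_m Height-datum to tidal-datum shift (m).
#' @return A `tidal_frame` tibble.
#' @export
tidal_frame <- function(table, historic_trend_mm_yr = 0,
                        datum_correction_m = 0) {
  table <- tibble::as_tibble(table)
  need <- c("subsite_id", "msl_offset_m", "gt_m", "salt_boundary_m")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("tidal table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  table <- dplyr::arrange(table[need], .data$subsite_id)
  if (any(table$gt_m <= 0)) stop("gt_m must be > 0", call. = FALSE)
  if (any(table$salt_boundary_m <= 0)) {
    stop("salt_boundary_m must be > 0", call. = FALSE)
  }
  if (anyDuplicated(table$subsite_id)) {
    stop("duplicate subsite_id rows", call. = FALSE)
  }
  structure(table,
            class = c("tidal_frame", class(tibble::tibble())),
            historic_trend_mm_yr = historic_trend_mm_yr,
            datum_correction_m = datum_correction_m)
}

frame_attr <- function(frame, which) attr(frame, which, exact = TRUE)

rebuild_frame <- function(frame, table) {
  tidal_frame(table,
              historic_trend_mm_yr = frame_attr(frame, "historic_trend_mm_yr"),
              datum_correction_m = frame_attr(frame, "datum_correction_m"))
}

#' Bind a subsite table to a subsite map
#'
#' Validates that the per-subsite parameter table covers every subsite id
#' present on the map, so a cell-level lookup can never miss.
#'
#' @param subsites A [subsite_map()].
#' @param table Per-subsite parameter table (see [tidal_frame()]).
#' @inheritParams tidal_frame
#' @return A `tidal_frame`.
#' @export
build_frame <- function(subsites, table, historic_trend_mm_yr = 0,
                        datum_correction_m = 0) {
  frame <- tidal_frame(table, historic_trend_mm_yr, datum_correction_m)
  missing_ids <- setdiff(seq_len(subsites$n_subsites), frame$subsite_id)
  if (length(missing_ids)) {
    stop("configuration error: no tidal parameters for subsite(s) ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  frame
}

#' Collapse a frame to a single global tidal range
#'
#' The no-attenuation control: every subsite receives the parameters of the
#' reference subsite, which defaults to the most seaward one (the subsite
#' with the largest tide range — the value an open-coast gauge would
#' supply to a run that ignores attenuation).
#'
#' @param frame A [tidal_frame()].
#' @param reference Subsite id to broadcast; default the largest-`gt_m` row.
#' @return A `tidal_frame` with uniform parameters.
#' @export
global_frame <- function(frame, reference = NULL) {
  if (is.null(reference)) reference <- frame$subsite_id[which.max(frame$gt_m)]
  ref <- frame[frame$subsite_id == reference, ]
  if (nrow(ref) != 1L) stop("reference subsite not found", call. = FALSE)
  out <- frame
  out$msl_offset_m <- ref$msl_offset_m
  out$gt_m <- ref$gt_m
  out$salt_boundary_m <- ref$salt_boundary_m
  rebuild_frame(frame, out)
}

# parameter value per cell, via the cell's subsite id
frame_field <- function(frame, subsites, column) {
  v <- rep(NA_real_, max(frame$subsite_id))
  v[frame$subsite_id] <- frame[[column]]
  m <- matrix(v[subsites$values], nrow(subsites$values))
  m
}

#' Convert between inundation frequency and elevation
#'
#' Under a single-constituent sinusoidal tide of amplitude `gt/2`, a surface
#' at elevation `z` (relative to local MSL) is submerged for a fraction
#' `f = acos(z / (gt/2)) / pi` of the time, and conversely the elevation
#' flooded a fraction `f` of the time is `z = (gt/2) * cos(pi * f)`. This is
#' the bridge between the ecological description of zonation ("flooded less
#' than 25% of the time") and elevation bands; it is isolated here so a
#' harmonic-sum tide could replace it.
#'
#' @param f Inundation fraction in `(0, 1]`.
#' @param gt Great diurnal tide range (m).
#' @return Elevation (m relative to local MSL) / inundation fraction.
#' @export
#' @examples
#' exceedance_elevation(0.5, 1.2) # local MSL
#' frequency_at(0, 1.2)
exceedance_elevation <- function(f, gt) {
  if (any(f <= 0 | f > 1)) {
    stop("domain error: inundation fraction must be in (0, 1]", call. = FALSE)
  }
  (gt / 2) * cospi(f) # cospi is exact at half-integers: f = 0.5 is MSL

}

#' @rdname exceedance_elevation
#' @param z Elevation (m relative to local MSL), within `[-gt/2, gt/2]`.
#' @export
frequency_at <- function(z, gt) {
  a <- gt / 2
  if (any(abs(z) > a + 1e-12)) {
    stop("domain error: elevation outside the tidal range", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, z / a))) / pi
}

#' Back-step a tidal frame to an earlier sea level
#'
#' Retrospective runs need an elevation surface representative of an earlier
#' year. Rather than editing the DEM, the local mean sea level of every
#' subsite is lowered by `rate * years` (the extrapolated sea-level rise
#' over the period of retrospection) — equivalent to raising all land
#' relative to the sea by the same amount. All other parameters are
#' unchanged.
#'
#' @param frame A [tidal_frame()].
#' @param rate_mm_yr Historic sea-level trend (mm/yr).
#' @param years Length of the retrospection period (>= 0).
#' @return The back-stepped `tidal_frame`.
#' @export
#' @examples
#' f <- tidal_frame(data.frame(subsite_id = 1, msl_offset_m = 0, gt_m = 1.2,
#'                             salt_boundary_m = 0.66))
#' backstep_datum(f, 2.1, 48)$msl_offset_m # -0.1008 m
backstep_datum <- function(frame, rate_mm_yr, years) {
  if (years < 0) {
    stop("domain error: backstepping requires years >= 0", call. = FALSE)
  }
  out <- frame
  out$msl_offset_m <- out$msl_offset_m - rate_mm_yr * years / 1000
  rebuild_frame(frame, out)
}

#' Sea-level rise scenarios
#'
#' A scenario is a monotone series of sea-level anomaly (m) by year,
#' starting at zero. [slr_scenario()] builds one from vectors or a
#' two-column table; [anomaly_at()] interpolates it linearly at any year in
#' its span.
#'
#' @param years Strictly increasing integer years.
#' @param anomaly_m Non-decreasing anomalies (m), zero in the first year.
#' @param label Scenario label (e.g. `"A1FI-95CI"`).
#' @return A `slr_scenario` tibble with columns `year`, `anomaly_m`.
#' @export
slr_scenario <- function(years, anomaly_m, label = "scenario") {
  if (length(years) != length(anomaly_m) || length(years) < 1L) {
    stop("years and anomaly_m must be equal-length, non-empty", call. = FALSE)
  }
  if (any(diff(years) <= 0)) {
    stop("scenario years must be strictly increasing", call. = FALSE)
  }
  if (abs(anomaly_m[1]) > 1e-12) {
    stop("scenario anomaly must be zero at the start year", call. = FALSE)
  }
  if (any(diff(anomaly_m) < -1e-12)) {
    stop("scenario anomaly must be non-decreasing", call. = FALSE)
  }
  structure(tibble::tibble(year = years, anomaly_m = anomaly_m),
            class = c("slr_scenario", class(tibble::tibble())),
            label = label)
}

#' @rdname slr_scenario
#' @param scenario An `slr_scenario`.
#' @param year Year(s) within the scenario span.
#' @export
anomaly_at <- function(scenario, year) {
  rng <- range(scenario$year)
  if (any(year < rng[1] | year > rng[2])) {
    stop("range error: year outside the scenario span ", rng[1], "-", rng[2],
         call. = FALSE)
  }
  if (nrow(scenario) == 1L) return(rep(scenario$anomaly_m, length(year)))
  stats::approx(scenario$year, scenario$anomaly_m, xout = year)$y
}
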