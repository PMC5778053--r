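#' Elevation zonation bands
#'
#' Vegetation classes occupy elevation bands tiling the interval from the
#' bottom of the tidal frame to above the salt boundary. The intertidal
#' bands are defined by inundation-frequency bounds and converted to
#' elevations through [exceedance_elevation()], so band widths scale with
#' the local tide range: mudflat where inundation is near-permanent
#' (50-100%), mangrove where it is high (25-50%), mixed mangrove-saltmarsh
#' where moderate (12.5-25%), saltmarsh where low (< 12.5%) up to the salt
#' boundary. Above the salt boundary sit casuarina forest and then upland,
#' with widths expressed as fractions of the tide range so every between-band
#' gap scales linearly with `gt`.
#'
#' Alternatively, explicit elevation bounds (m relative to local MSL) can be
#' supplied for the five classes mudflat..casuarina; these are fixed
#' elevations and do not scale with the tide range.
#'
#' All band intervals are half-open and lower-inclusive, `[lower, upper)`,
#' which resolves boundary ties deterministically (a cell exactly at local
#' MSL is mangrove).
#'
#' @param freq_bounds Named numeric vector giving the inundation frequency
#'   at the *lower* elevation bound of mudflat, mangrove, mixed and
#'   saltmarsh (defaults `c(mudflat = 1, mangrove = 0.5, mixed = 0.25,
#'   saltmarsh = 0.125)`); must be strictly decreasing.
#' @param casuarina_width_gt,upland_width_gt Width of the casuarina band and
#'   of the (reconstruction-only) upland band, as fractions of `gt`.
#' @param elevations Optional data frame `class`, `lower_m`, `upper_m` with
#'   one row for each of mudflat, mangrove, mixed, saltmarsh, casuarina;
#'   bands must tile without gaps or overlaps.
#' @return A `zonation_bands` object.
#' @export
zonation_bands <- function(freq_bounds = c(mudflat = 1, mangrove = 0.5,
                                           mixed = 0.25, saltmarsh = 0.125),
                           casuarina_width_gt = 0.25,
                           upland_width_gt = 0.25,
                           elevations = NULL) {
  if (!is.null(elevations)) {
    elevations <- tibble::as_tibble(elevations)
    need <- c("mudflat", "mangrove", "mixed", "saltmarsh", "casuarina")
    elevations <- elevations[match(need, elevations$class), ]
    if (anyNA(elevations$class)) {
      stop("configuration error: explicit bands need rows for ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    gaps <- elevations$lower_m[-1] - elevations$upper_m[-nrow(elevations)]
    if (any(abs(gaps) > 1e-9) || any(elevations$upper_m <= elevations$lower_m)) {
      stop("configuration error: bands must tile without gaps or overlaps",
           call. = FALSE)
    }
  } else {
    if (any(diff(freq_bounds) >= 0) || length(freq_bounds) != 4L) {
      stop("configuration error: freq_bounds must be 4 strictly decreasing values",
           call. = FALSE)
    }
  }
  structure(list(freq_bounds = freq_bounds,
                 casuarina_width_gt = casuarina_width_gt,
                 upland_width_gt = upland_width_gt,
                 elevations = elevations),
            class = "zonation_bands")
}

# Classification breaks (m rel. local MSL): lower bounds of
# mudflat, mangrove, mixed, saltmarsh, casuarina, upland.
class_breaks <- function(bands, gt, salt_boundary) {
  if (!is.null(bands$elevations)) {
    e <- bands$elevations
    brk <- c(e$lower_m, e$upper_m[nrow(e)])[1:6]
  } else {
    brk <- c(exceedance_elevation(bands$freq_bounds, gt),
             salt_boundary,
             salt_boundary + bands$casuarina_width_gt * gt)
  }
  if (any(diff(brk) <= 0)) {
    stop("configuration error: zonation bands overlap for gt = ", gt,
         " (salt boundary below the saltmarsh lower bound?)", call. = FALSE)
  }
  unname(brk)
}

# Reconstruction bands for all 7 classes: open_water and upland get
# finite pseudo-bounds so veg_to_dem can place them.
recon_breaks <- function(bands, gt, salt_boundary) {
  brk <- class_breaks(bands, gt, salt_boundary)
  c(brk[1] - gt / 2, brk, brk[6] + bands$upland_width_gt * gt)
}

#' Classify elevation into vegetation classes
#'
#' `classify_elevation()` maps elevations (relative to local MSL) to class
#' codes for a single tide range; `classify_grid()` classifies a whole DEM,
#' looking up each cell's tide parameters through its subsite. Elevation
#' below the lowest band is open water; at or above the upland lower bound
#' is upland. Classification is monotone in elevation.
#'
#' @param z_rel Elevation(s), m relative to local MSL.
#' @param gt Great diurnal tide range (m).
#' @param salt_boundary Salt boundary elevation (m above local MSL).
#' @param bands A [zonation_bands()].
#' @return Integer class codes (see [wetland_classes()]).
#' @export
classify_elevation <- function(z_rel, gt, salt_boundary, bands = zonation_bands()) {
  brk <- class_breaks(bands, gt, salt_boundary)
  codes <- findInterval(z_rel, brk) + 1L
  codes[is.na(z_rel)] <- NA_integer_
  codes
}

#' @rdname classify_elevation
#' @param dem An [elevation_grid()].
#' @param subsites A [subsite_map()] on the same geometry.
#' @param frame A [tidal_frame()].
#' @export
classify_grid <- function(dem, subsites, frame, bands = zonation_bands()) {
  check_same_geometry(dem, subsites)
  codes <- matrix(NA_integer_, nrow(dem$values), ncol(dem$values))
  for (k in seq_len(nrow(frame))) {
    s <- frame$subsite_id[k]
    in_s <- !dem$nodata_mask & !subsites$nodata_mask & subsites$values == s
    if (!any(in_s)) next
    z_rel <- dem$values[in_s] - frame$msl_offset_m[k]
    codes[in_s] <- classify_elevation(z_rel, frame$gt_m[k],
                                      frame$salt_boundary_m[k], bands)
  }
  vegetation_grid(codes, dem$cell_size, dem$origin,
                  dem$nodata_mask | subsites$nodata_mask)
}

#' Succession policies and the per-cell succession rule
#'
#' The SLAMM-style rule forces a cell to pass through the predefined class
#' sequence in the seaward (retrogression) direction only: a transition
#' toward a less frequently inundated class (progradation) is refused and
#' the cell keeps its previous class, and open water can never convert to
#' any vegetated class (it is absorbing). The boundary-free rule used by
#' the comparison engines accepts whatever the elevation bands propose in
#' either direction.
#'
#' @param mode `"slamm"` or `"boundary_free"`.
#' @return A `succession_policy` object.
#' @export
succession_policy <- function(mode = c("slamm", "boundary_free")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, allow_progradation = mode == "boundary_free"),
            class = "succession_policy")
}

#' @rdname succession_policy
#' @param prev,proposed Integer class codes (vectors or matrices).
#' @param policy A `succession_policy`.
#' @return `apply_succession()`: the resulting class codes, same shape as
#'   the inputs.
#' @export
apply_succession <- function(prev, proposed, policy) {
  stopifnot(inherits(policy, "succession_policy"))
  if (policy$allow_progradation) return(proposed)
  # refuse landward moves; open_water (rank 1) is automatically absorbing
  pmin(prev, proposed)
}

# per-cell matrices of class-band lower/upper bounds (absolute elevation)
band_bound_fields <- function(veg, subsites, frame, bands) {
  nr <- nrow(veg$values)
  lower <- upper <- matrix(NA_real_, nr, ncol(veg$values))
  for (k in seq_len(nrow(frame))) {
    s <- frame$subsite_id[k]
    brk <- recon_breaks(bands, frame$gt_m[k], frame$salt_boundary_m[k])
    if (any(diff(brk) <= 0)) {
      stop("configuration error: zero-width band for subsite ", s,
           call. = FALSE)
    }
    in_s <- !veg$nodata_mask & subsites$values == s
    codes <- veg$values[in_s]
    lower[in_s] <- brk[codes] + frame$msl_offset_m[k]
    upper[in_s] <- brk[codes + 1L] + frame$msl_offset_m[k]
  }
  list(lower = lower, upper = upper)
}

#' Reconstruct an elevation surface from a vegetation map
#'
#' The vegetation preprocessor: when no historic DEM exists, an elevation
#' surface is built from a mapped vegetation distribution by assigning each
#' class its band bounds and linearly interpolating between them. Within
#' each contiguous same-class region, elevation runs from the class lower
#' bound at the region edge adjacent to a more seaward (lower-ranked) class
#' to the upper bound at the edge adjacent to a more landward class, along
#' the distance-to-seaward-edge axis. Regions with no usable pair of edges
#' (including single cells) sit at the band midpoint.
#'
#' @param veg A [vegetation_grid()].
#' @param subsites A [subsite_map()] on the same geometry.
#' @param frame A [tidal_frame()].
#' @param bands A [zonation_bands()].
#' @return An [elevation_grid()] whose classification reproduces `veg` on
#'   region interiors.
#' @export
veg_to_dem <- function(veg, subsites, frame, bands = zonation_bands()) {
  check_same_geometry(veg, subsites)
  bounds <- band_bound_fields(veg, subsites, frame, bands)
  frac <- matrix(0.5, nrow(veg$values), ncol(veg$values))
  codes <- veg$values
  codes_na <- codes
  sea_adj <- land_adj <- matrix(FALSE, nrow(codes), ncol(codes))
  nb <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (d in nb) {
    shifted <- shift_matrix(codes_na, d[1], d[2])
    sea_adj <- sea_adj | (!is.na(shifted) & !is.na(codes_na) & shifted < codes_na)
    land_adj <- land_adj | (!is.na(shifted) & !is.na(codes_na) & shifted > codes_na)
  }
  for (cl in sort(unique(codes[!veg$nodata_mask]))) {
    m <- !veg$nodata_mask & codes == cl
    lab <- EBImage::bwlabel(ifelse(m, 1, 0))
    for (r in seq_len(max(lab))) {
      cells <- lab == r
      sea <- cells & sea_adj
      land <- cells & land_adj
      if (!any(sea) || !any(land)) next # band midpoint fallback
      dsea <- EBImage::distmap(ifelse(sea, 0, 1))
      dland <- EBImage::distmap(ifelse(land, 0, 1))
      tot <- dsea + dland
      f <- ifelse(tot == 0, 0.5, dsea / tot)
      frac[cells] <- f[cells]
    }
  }
  z <- bounds$lower + frac * (bounds$upper - bounds$lower)
  elevation_grid(z, veg$cell_size, veg$origin, veg$nodata_mask)
}

# shift a matrix by (dr, dc), padding with NA
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(m[0][1], nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}
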