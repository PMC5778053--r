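# Shared fixtures, all generated in code.

# Small estuary for fast end-to-end tests.
tiny_recipe <- function(...) {
  args <- utils::modifyList(
    list(nrow = 40, ncol = 60, cell_size = 10, meander_amplitude = 60,
         meander_wavelength = 350, channel_width = 40,
         floodplain_slope = 0.012, noise_sd = 0.02, seed = 42),
    list(...))
  do.call(estuary_recipe, args)
}

tiny_world <- function(...) make_estuary(tiny_recipe(...))

# One-subsite, one-row strip world with explicit equal-width bands; cells
# placed at the midpoints of mudflat..casuarina plus one open-water cell.
strip_bands <- function(w = 0.3) {
  zonation_bands(elevations = tibble::tibble(
    class = c("mudflat", "mangrove", "mixed", "saltmarsh", "casuarina"),
    lower_m = w * (-2:2),
    upper_m = w * (-1:3)
  ))
}

strip_world <- function(z, gt = 1.2, salt_boundary = 0.66, msl = 0,
                        cell = 10) {
  zm <- matrix(z, nrow = 1)
  list(
    dem = elevation_grid(zm, cell),
    subsites = subsite_map(matrix(1L, 1, length(z)), cell),
    frame = tidal_frame(tibble::tibble(
      subsite_id = 1L, msl_offset_m = msl, gt_m = gt,
      salt_boundary_m = salt_boundary))
  )
}

zero_rates <- function() {
  slamm_sec_config(rates = c(open_water = 0, mudflat = 0, mangrove = 0,
                             mixed = 0, saltmarsh = 0, casuarina = 0,
                             upland = 0))
}

flat_rates <- function(r) {
  slamm_sec_config(rates = c(open_water = r, mudflat = r, mangrove = r,
                             mixed = r, saltmarsh = r, casuarina = r,
                             upland = r))
}

zero_scenario <- function(years = 2000:2100) {
  slr_scenario(years, rep(0, length(years)), "no-rise")
}

linear_scenario <- function(rate_mm_yr, years) {
  slr_scenario(years, rate_mm_yr * (years - years[1]) / 1000, "linear")
}

random_veg <- function(nr = 10, nc = 10, cell = 10, seed = 1) {
  withr::with_seed(seed, {
    vegetation_grid(matrix(sample.int(7L, nr * nc, replace = TRUE), nr, nc),
                    cell)
  })
}
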