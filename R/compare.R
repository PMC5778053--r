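#' Run and compare the three SEC engines on one world
#'
#' Runs each configured engine on the same grid, tidal frame, bands and
#' scenario (rates and parameters applied consistently, as a fair
#' comparison requires), then derives per-year cross-engine area deltas and
#' pairwise class-map disagreement fractions.
#'
#' By default the slamm engine pairs with the slamm succession policy and a
#' supplied vegetation map when one is given, while cm1/cm2 run
#' boundary-free from the DEM — the modes in which each engine is meant to
#' be used. `policies` can force a common policy for controlled contrasts.
#'
#' @inheritParams initial_state
#' @param end_year Final year of each run.
#' @param configs Named list of engine configurations; names select the
#'   engines (subset of `"slamm"`, `"cm1"`, `"cm2"`). `NULL` entries get
#'   engine defaults.
#' @param dt Step length (years).
#' @param policies Optional named list of policy modes overriding the
#'   engine defaults (e.g. `list(slamm = "boundary_free")`).
#' @return A `model_comparison`: list with `runs` (named list of
#'   [sim_run()] results), `areas` (long tibble with an `engine` column),
#'   `deltas` (pairwise per-year, per-class area differences) and
#'   `disagreement` (pairwise per-year map disagreement fractions).
#' @export
compare_models <- function(dem, subsites, frame, bands, scenario, end_year,
                           configs = list(slamm = NULL, cm1 = NULL,
                                          cm2 = NULL),
                           veg = NULL, covariates = NULL, dt = 10,
                           policies = NULL) {
  engines <- names(configs)
  stopifnot(all(engines %in% c("slamm", "cm1", "cm2")))
  runs <- purrr::imap(configs, function(cfg, engine) {
    pol <- if (!is.null(policies[[engine]])) {
      succession_policy(policies[[engine]])
    }
    state <- initial_state(dem, subsites, frame, bands, scenario,
                           engine = engine, cfg = cfg, veg = veg,
                           policy = pol, covariates = covariates)
    sim_run(state, end_year, dt = dt, keep_grids = TRUE)
  })
  areas <- dplyr::bind_rows(
    purrr::imap(runs, ~ dplyr::mutate(.x$areas, engine = .y, .before = 1)))
  pairs <- if (length(engines) > 1) {
    utils::combn(engines, 2, simplify = FALSE)
  } else list()
  deltas <- dplyr::bind_rows(purrr::map(pairs, function(p) {
    a <- runs[[p[1]]]$areas
    b <- runs[[p[2]]]$areas
    dplyr::mutate(
      dplyr::inner_join(a, b, by = c("year", "class"),
                        suffix = c("_a", "_b")),
      pair = paste(p, collapse = "-"),
      delta_ha = .data$area_ha_a - .data$area_ha_b)
  }))
  disagreement <- dplyr::bind_rows(purrr::map(pairs, function(p) {
    years <- intersect(names(runs[[p[1]]]$grids), names(runs[[p[2]]]$grids))
    tibble::tibble(
      pair = paste(p, collapse = "-"),
      year = as.numeric(years),
      fraction = purrr::map_dbl(years, function(y) {
        disagreement_fraction(runs[[p[1]]]$grids[[y]],
                              runs[[p[2]]]$grids[[y]])
      }))
  }))
  structure(list(runs = runs, areas = areas, deltas = deltas,
                 disagreement = disagreement),
            class = "model_comparison")
}

#' @rdname tidy.wetland_run
#' @export
tidy.model_comparison <- function(x, ...) x$areas

#' @rdname tidy.wetland_run
#' @export
glance.model_comparison <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$runs, glance))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> engines: %s\n",
              paste(names(x$runs), collapse = ", ")))
  print(glance(x))
  invisible(x)
}
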