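#' One-at-a-time sensitivity analysis
#'
#' Re-runs a simulation with each named parameter varied by plus and minus
#' a fixed fraction (default 10%) while all other parameters stay at their
#' base values, and reports the percent change in each vegetation class's
#' final-year area. Both directions are stored; the conventional headline
#' table ([sensitivity_headline()]) uses the +10% run, a convention fixed
#' here so results are reproducible.
#'
#' Perturbations are multiplicative, so a parameter with no model pathway
#' (a zero coefficient, or the historic trend in a forward run driven by a
#' scenario curve) produces an exactly zero row.
#'
#' Recognised parameter names: `"slr_by_2100"` (scales the scenario
#' anomaly), `"gt"`, `"salt_boundary"`, `"navd88_mtl"` (shifts local MSL by
#' a fraction of the datum correction), `"historic_trend"`,
#' `"sec_<class>"` (a SLAMM class rate), `"cm1_k"`, `"cm1_l"`, `"cm1_m"`,
#' and `"cm2_<coef>"` with coef one of `intercept`, `time`, `rain`, `wl6`,
#' `dist`, `soi`, `msl`.
#'
#' @param base Named list of arguments for [initial_state()] (`dem`,
#'   `subsites`, `frame`, `bands`, `scenario`, `engine`, and optionally
#'   `cfg`, `veg`, `policy`, `covariates`, `dist`, `start_year`).
#' @param parameters Character vector of parameter names to perturb.
#' @param perturbation Fractional perturbation (default 0.10).
#' @param end_year Final year of each run.
#' @param dt Step length (years).
#' @return A `sensitivity_table` tibble: `parameter`, `class`, `direction`
#'   (`"+"`/`"-"`), `pct_change` (`NA` where the base class area is zero),
#'   with the perturbation size as an attribute.
#' @export
sensitivity_analysis <- function(base, parameters, perturbation = 0.1,
                                 end_year, dt = 10) {
  final_areas <- function(b) {
    state <- do.call(initial_state, b)
    run <- sim_run(state, end_year, dt = dt)
    a <- run$areas[run$areas$year == run$meta$end_year, ]
    stats::setNames(a$area_ha, as.character(a$class))
  }
  base_a <- final_areas(base)
  rows <- purrr::flatten(purrr::map(parameters, function(p) {
    purrr::map(c(1, -1), function(sgn) {
      pert <- final_areas(perturb_parameter(base, p, sgn * perturbation))
      tibble::tibble(
        parameter = p,
        class = factor(names(base_a), levels = wetland_classes()),
        direction = if (sgn > 0) "+" else "-",
        pct_change = ifelse(base_a > 0, 100 * (pert - base_a) / base_a,
                            NA_real_)
      )
    })
  }))
  structure(dplyr::bind_rows(rows),
            class = c("sensitivity_table", class(tibble::tibble())),
            perturbation = perturbation)
}

perturb_parameter <- function(base, parameter, delta) {
  b <- base
  scale1 <- function(x) x * (1 + delta)
  if (parameter == "slr_by_2100") {
    s <- b$scenario
    b$scenario <- slr_scenario(s$year, scale1(s$anomaly_m),
                               attr(s, "label", exact = TRUE))
  } else if (parameter == "gt") {
    f <- b$frame; f$gt_m <- scale1(f$gt_m); b$frame <- rebuild_frame(b$frame, f)
  } else if (parameter == "salt_boundary") {
    f <- b$frame; f$salt_boundary_m <- scale1(f$salt_boundary_m)
    b$frame <- rebuild_frame(b$frame, f)
  } else if (parameter == "navd88_mtl") {
    f <- b$frame
    f$msl_offset_m <- f$msl_offset_m +
      delta * frame_attr(b$frame, "datum_correction_m")
    b$frame <- rebuild_frame(b$frame, f)
  } else if (parameter == "historic_trend") {
    attr(b$frame, "historic_trend_mm_yr") <-
      scale1(frame_attr(b$frame, "historic_trend_mm_yr"))
  } else if (grepl("^sec_", parameter)) {
    cl <- sub("^sec_", "", parameter)
    cfg <- b$cfg %||% default_sec_config(b$engine)
    if (!inherits(cfg, "slamm_sec_config") || !cl %in% names(cfg$rates)) {
      stop("configuration error: parameter '", parameter,
           "' not addressable in this configuration", call. = FALSE)
    }
    cfg$rates[cl] <- scale1(cfg$rates[cl])
    b$cfg <- cfg
  } else if (grepl("^cm1_", parameter)) {
    fld <- sub("^cm1_", "", parameter)
    cfg <- b$cfg %||% default_sec_config(b$engine)
    if (!inherits(cfg, "cm1_sec_config") || !fld %in% c("k", "l", "m")) {
      stop("configuration error: parameter '", parameter,
           "' not addressable in this configuration", call. = FALSE)
    }
    cfg[[fld]] <- scale1(cfg[[fld]])
    b$cfg <- cfg
  } else if (grepl("^cm2_", parameter)) {
    fld <- sub("^cm2_", "", parameter)
    fld <- if (fld == "intercept") "intercept" else paste0("b_", fld)
    cfg <- b$cfg %||% default_sec_config(b$engine)
    if (!inherits(cfg, "cm2_sec_config") || is.null(cfg[[fld]])) {
      stop("configuration error: parameter '", parameter,
           "' not addressable in this configuration", call. = FALSE)
    }
    cfg[[fld]] <- scale1(cfg[[fld]])
    b$cfg <- cfg
  } else {
    stop("configuration error: unknown parameter '", parameter, "'",
         call. = FALSE)
  }
  b
}

#' @rdname sensitivity_analysis
#' @param x A `sensitivity_table`.
#' @param direction Which perturbation direction the headline uses.
#' @return `sensitivity_headline()`: a wide tibble, classes as rows and
#'   parameters as columns, with `minimum`, `maximum`, `mean` and `sd`
#'   summary rows appended.
#' @export
sensitivity_headline <- function(x, direction = "+") {
  wide <- tidyr::pivot_wider(
    x[x$direction == direction, c("parameter", "class", "pct_change")],
    names_from = "parameter", values_from = "pct_change")
  num <- wide[-1]
  summarise_rows <- function(fun, label) {
    tibble::tibble(class = label,
                   !!!purrr::map(num, ~ fun(.x[is.finite(.x)])))
  }
  wide$class <- as.character(wide$class)
  dplyr::bind_rows(
    wide,
    summarise_rows(min, "minimum"),
    summarise_rows(max, "maximum"),
    summarise_rows(mean, "mean"),
    summarise_rows(stats::sd, "sd")
  )
}
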