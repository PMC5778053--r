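#' Percent area difference between modelled and observed class areas
#'
#' The headline agreement statistic: `100 * (modeled - observed) / observed`
#' per class. It is directional — a negative value is an underestimate of
#' the observed extent — and is not symmetric under swapping the two maps
#' except at zero. Classes observed at zero area but modelled as present
#' have an undefined ratio and are reported as `NA`, never as infinity.
#'
#' @param modeled,observed Class-area tables as returned by
#'   [area_by_class()] (tibbles `class`, `area_ha`), or named vectors of
#'   areas.
#' @return A tibble `class`, `modeled_ha`, `observed_ha`, `pct_diff`.
#' @export
#' @examples
#' percent_area_difference(c(saltmarsh = 108.5), c(saltmarsh = 100))
percent_area_difference <- function(modeled, observed) {
  as_area_tbl <- function(x, nm) {
    if (is.numeric(x) && !is.null(names(x))) {
      x <- tibble::tibble(class = names(x), area_ha = unname(x))
    }
    stats::setNames(tibble::tibble(class = as.character(x$class),
                                   area = x$area_ha), c("class", nm))
  }
  out <- dplyr::full_join(as_area_tbl(modeled, "modeled_ha"),
                          as_area_tbl(observed, "observed_ha"),
                          by = "class")
  out$pct_diff <- dplyr::case_when(
    out$observed_ha > 0 ~ 100 * (out$modeled_ha - out$observed_ha) /
      out$observed_ha,
    out$modeled_ha == 0 ~ 0,
    TRUE ~ NA_real_
  )
  out
}

#' Overlap matrix between two co-registered class maps
#'
#' `O[i, j]` is the fraction of the cells modelled as class `i` that lie
#' within observed class `j`; each non-empty row sums to one, and the
#' diagonal entry is the "correspondence" of a class (the fraction of its
#' modelled extent that is mapped as the same class). Rows for classes with
#' no modelled cells are `NA`.
#'
#' @param modeled,observed Co-registered [vegetation_grid()]s.
#' @return A 7 x 7 matrix, rows = modelled classes, columns = observed.
#' @export
overlap_matrix <- function(modeled, observed) {
  check_same_geometry(modeled, observed)
  k <- length(wetland_classes())
  ok <- !modeled$nodata_mask & !observed$nodata_mask
  counts <- table(factor(modeled$values[ok], levels = seq_len(k)),
                  factor(observed$values[ok], levels = seq_len(k)))
  counts <- matrix(as.numeric(counts), k, k,
                   dimnames = list(modeled = wetland_classes(),
                                   observed = wetland_classes()))
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Fraction of cells on which two class maps disagree
#'
#' @param a,b Co-registered [vegetation_grid()]s.
#' @return Fraction in `[0, 1]` over jointly unmasked cells.
#' @export
disagreement_fraction <- function(a, b) {
  check_same_geometry(a, b)
  ok <- !a$nodata_mask & !b$nodata_mask
  mean(a$values[ok] != b$values[ok])
}

#' The 10% validity rule
#'
#' A class prediction is statistically valid when its absolute percent area
#' difference is strictly less than the threshold; the run as a whole is
#' valid when every class with a defined difference is valid. Undefined
#' differences (zero observed area) are reported as `NA` flags.
#'
#' @param pct_diff Tibble from [percent_area_difference()], or a numeric
#'   vector of percent differences.
#' @param threshold Percent threshold (default 10, strict `<`).
#' @return Tibble `class`, `pct_diff`, `valid`, with the overall flag in
#'   attribute `overall_valid`.
#' @export
#' @examples
#' validity_check(c(mangrove = 1.7, saltmarsh = 8.5))
validity_check <- function(pct_diff, threshold = 10) {
  if (is.numeric(pct_diff)) {
    pct_diff <- tibble::tibble(
      class = if (is.null(names(pct_diff))) as.character(seq_along(pct_diff))
              else names(pct_diff),
      pct_diff = unname(pct_diff))
  }
  valid <- abs(pct_diff$pct_diff) < threshold
  out <- tibble::tibble(class = pct_diff$class, pct_diff = pct_diff$pct_diff,
                        valid = valid)
  structure(out, overall_valid = all(out$valid[!is.na(out$valid)]))
}

#' Full agreement report between a modelled and an observed map
#'
#' Bundles the per-class areas, percent area differences, overlap matrix
#' and validity flags into one object with [tidy()]/[glance()] methods.
#'
#' @param modeled,observed Co-registered [vegetation_grid()]s.
#' @param threshold Validity threshold (percent, strict).
#' @return An `agreement_report`.
#' @export
agreement_report <- function(modeled, observed, threshold = 10) {
  pad <- percent_area_difference(area_by_class(modeled),
                                 area_by_class(observed))
  val <- validity_check(pad, threshold)
  structure(list(
    areas = dplyr::mutate(pad, valid = val$valid),
    overlap = overlap_matrix(modeled, observed),
    disagreement = disagreement_fraction(modeled, observed),
    threshold = threshold,
    overall_valid = attr(val, "overall_valid", exact = TRUE)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> overall %s (|pct| < %g%%), disagreement %.1f%%\n",
              if (isTRUE(x$overall_valid)) "VALID" else "NOT valid",
              x$threshold, 100 * x$disagreement))
  print(x$areas)
  invisible(x)
}

#' @rdname tidy.wetland_run
#' @export
tidy.agreement_report <- function(x, ...) x$areas

#' @rdname tidy.wetland_run
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(overall_valid = x$overall_valid,
                 threshold = x$threshold,
                 disagreement = x$disagreement,
                 n_valid = sum(x$areas$valid, na.rm = TRUE),
                 n_classes = sum(!is.na(x$areas$valid)))
}
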