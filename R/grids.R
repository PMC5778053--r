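#' The ordered wetland class set
#'
#' Classes are ordered from most- to least-frequently inundated. The integer
#' code of a class is its rank in this order, so "landward of" is simply a
#' larger code and succession direction is an integer comparison.
#'
#' @return Character vector of the seven class names, in rank order:
#'   `open_water < mudflat < mangrove < mixed < saltmarsh < casuarina < upland`.
#' @export
#' @examples
#' wetland_classes()
wetland_classes <- function() {
  c("open_water", "mudflat", "mangrove", "mixed", "saltmarsh",
    "casuarina", "upland")
}

#' @rdname wetland_classes
#' @param class Character vector of class names.
#' @return `class_rank()`: integer codes (rank in the inundation order).
#' @export
class_rank <- function(class) {
  rank <- match(class, wetland_classes())
  if (anyNA(rank) && !anyNA(class)) {
    bad <- setdiff(unique(class), wetland_classes())
    stop("unknown wetland class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rank
}

class_factor <- function(codes) {
  factor(wetland_classes()[codes], levels = wetland_classes())
}

new_grid <- function(values, cell_size, origin, nodata_mask, subclass) {
  if (!is.matrix(values)) stop("grid values must be a matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  if (!identical(dim(nodata_mask), dim(values))) {
    stop("nodata_mask dimensions do not match values", call. = FALSE)
  }
  nodata_mask <- nodata_mask | is.na(values)
  values[nodata_mask] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata_mask = nodata_mask),
    class = c(subclass, "wetland_grid")
  )
}

#' Raster grids of elevation and vegetation
#'
#' An `elevation_grid` holds substrate elevation in metres above a fixed
#' height datum; a `vegetation_grid` holds integer class codes from
#' [wetland_classes()]; a `subsite_map` holds contiguous small-integer
#' subsite identifiers used to look up local tidal parameters. All three
#' share the raster convention that row 1 is the northernmost row, and a
#' local metric coordinate frame with `origin` at the lower-left corner.
#' Nodata cells are `NA` and are propagated, never imputed.
#'
#' @param values Numeric matrix of elevations (m above datum).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric `(x, y)` of the lower-left corner (m, local frame).
#' @param nodata_mask Optional logical matrix; `TRUE` marks nodata. `NA`
#'   values are always masked.
#' @return An object of class `elevation_grid`, `vegetation_grid` or
#'   `subsite_map`.
#' @export
elevation_grid <- function(values, cell_size, origin = c(0, 0),
                           nodata_mask = NULL) {
  g <- new_grid(values, cell_size, origin, nodata_mask, "elevation_grid")
  if (any(!is.finite(g$values[!g$nodata_mask]))) {
    stop("elevation values must be finite where not masked", call. = FALSE)
  }
  g
}

#' @rdname elevation_grid
#' @param codes Integer matrix of class codes (1..7) or character matrix of
#'   class names.
#' @export
vegetation_grid <- function(codes, cell_size, origin = c(0, 0),
                            nodata_mask = NULL) {
  if (is.character(codes)) {
    codes <- matrix(class_rank(codes), nrow(codes), ncol(codes))
  }
  storage.mode(codes) <- "integer"
  g <- new_grid(codes, cell_size, origin, nodata_mask, "vegetation_grid")
  storage.mode(g$values) <- "integer"
  ok <- g$values[!g$nodata_mask]
  if (length(ok) && (min(ok) < 1L || max(ok) > length(wetland_classes()))) {
    stop("vegetation codes must be members of wetland_classes()",
         call. = FALSE)
  }
  g
}

#' @rdname elevation_grid
#' @param ids Integer matrix of subsite identifiers, contiguous `1..n`.
#' @export
subsite_map <- function(ids, cell_size, origin = c(0, 0),
                        nodata_mask = NULL) {
  storage.mode(ids) <- "integer"
  g <- new_grid(ids, cell_size, origin, nodata_mask, "subsite_map")
  storage.mode(g$values) <- "integer"
  present <- sort(unique(g$values[!g$nodata_mask]))
  if (length(present) && !identical(present, seq_len(max(present)))) {
    stop("subsite ids must be contiguous 1..n_subsites", call. = FALSE)
  }
  g$n_subsites <- if (length(present)) max(present) else 0L
  g
}

#' @export
print.wetland_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells, %g m resolution, %d masked\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$cell_size,
              sum(x$nodata_mask)))
  invisible(x)
}

#' @export
dim.wetland_grid <- function(x) dim(x$values)

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

check_same_geometry <- function(a, b) {
  if (!same_geometry(a, b)) {
    stop("grids do not share shape and cell size", call. = FALSE)
  }
  invisible(TRUE)
}

#' Tabulate class areas of a vegetation grid
#'
#' Area bookkeeping used by every evaluation stage:
#' `area(class) = count(class) * cell_size^2 / 10000` hectares. Masked cells
#' are excluded, so the per-class areas always sum to the unmasked area.
#'
#' @param veg A [vegetation_grid()].
#' @return A tibble with one row per class (all seven classes, zero-area
#'   classes included): `class`, `area_ha`.
#' @export
#' @examples
#' v <- vegetation_grid(matrix(3L, 3, 3), cell_size = 10)
#' area_by_class(v) # 9 mangrove cells of 100 m2 = 0.09 ha
area_by_class <- function(veg) {
  stopifnot(inherits(veg, "vegetation_grid"))
  counts <- tabulate(veg$values[!veg$nodata_mask],
                     nbins = length(wetland_classes()))
  tibble::tibble(
    class = factor(wetland_classes(), levels = wetland_classes()),
    area_ha = counts * veg$cell_size^2 / 1e4
  )
}

#' @export
as_tibble.wetland_grid <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    value = as.vector(x$values)
  )
  # row 1 is the northernmost row; y increases northwards from the origin
  out$x <- x$origin[1] + (out$col - 0.5) * x$cell_size
  out$y <- x$origin[2] + (nr - out$row + 0.5) * x$cell_size
  if (inherits(x, "vegetation_grid")) {
    out$class <- class_factor(out$value)
  }
  out
}
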