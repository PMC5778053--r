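#' Read and write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, optionally
#' `NODATA_value`) followed by `nrows` whitespace-separated rows, first row
#' northernmost. Values are written with 17 significant digits so a
#' write/read cycle reproduces doubles bit-identically.
#'
#' @param path File path.
#' @return `read_ascii_grid()`: an [elevation_grid()]. Use
#'   [as_vegetation_grid()] / [as_subsite_map()] to reinterpret integer-coded
#'   rasters.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  hdr <- list()
  i <- 1L
  for (key in expected) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2L || tolower(tok[1]) != key) {
      stop(sprintf("malformed ESRI ASCII header: expected '%s', found '%s'",
                   key, if (length(tok)) tok[1] else ""), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(val)) {
      stop(sprintf("malformed ESRI ASCII header: non-numeric value for '%s'",
                   key), call. = FALSE)
    }
    hdr[[key]] <- val
    i <- i + 1L
  }
  nodata <- NULL
  tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
  if (length(tok) == 2L && tolower(tok[1]) == "nodata_value") {
    nodata <- as.numeric(tok[2])
    i <- i + 1L
  }
  body <- lines[seq.int(i, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) {
    stop(sprintf("dimension error: expected %d data rows, found %d",
                 hdr$nrows, length(body)), call. = FALSE)
  }
  rows <- lapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != hdr$ncols) {
      stop(sprintf("dimension error: row with %d values, expected %d columns",
                   length(v), hdr$ncols), call. = FALSE)
    }
    v
  })
  values <- do.call(rbind, rows)
  if (!is.null(nodata)) values[values == nodata] <- NA_real_
  elevation_grid(values, cell_size = hdr$cellsize,
                 origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' @rdname read_ascii_grid
#' @param grid A grid object ([elevation_grid()], [vegetation_grid()] or
#'   [subsite_map()]).
#' @param nodata_value Number written for masked cells (default -9999).
#' @export
write_ascii_grid <- function(grid, path, nodata_value = -9999) {
  stopifnot(inherits(grid, "wetland_grid"))
  v <- grid$values
  fmt <- function(x) {
    out <- vapply(x, function(xx) {
      if (is.na(xx)) return(sprintf("%.17g", nodata_value))
      if (xx == round(xx) && abs(xx) < 2^31) sprintf("%d", as.integer(xx))
      else sprintf("%.17g", xx)
    }, character(1))
    paste(out, collapse = " ")
  }
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", grid$origin[2]),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata_value)
  )
  body <- vapply(seq_len(nrow(v)), function(r) fmt(v[r, ]), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reinterpret an integer-coded raster
#'
#' @param grid An [elevation_grid()] whose values are integer codes.
#' @return A [vegetation_grid()] or [subsite_map()] on the same geometry.
#' @export
as_vegetation_grid <- function(grid) {
  vegetation_grid(matrix(as.integer(grid$values), nrow(grid$values)),
                  grid$cell_size, grid$origin, grid$nodata_mask)
}

#' @rdname as_vegetation_grid
#' @export
as_subsite_map <- function(grid) {
  subsite_map(matrix(as.integer(grid$values), nrow(grid$values)),
              grid$cell_size, grid$origin, grid$nodata_mask)
}
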