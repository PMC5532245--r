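#' Construct a land-cover grid
#'
#' A land-cover grid is a categorical raster of integer land-cover codes at
#' one accounting epoch, in either the 44-code CORINE nomenclature or the
#' 14-class SEEA nomenclature. Code 0 marks nodata cells; nodata cells take
#' no part in any area tally.
#'
#' @param codes Integer matrix of land-cover codes; 0 = nodata.
#' @param cell_area_km2 Area of one cell in square kilometres (> 0). A
#'   100 m cell is 0.01 km2.
#' @param epoch Epoch label, e.g. `"2000"`.
#' @param nomenclature `"corine"` or `"seea"`.
#' @return A `land_cover_grid` object.
#' @examples
#' g <- land_cover_grid(matrix(2L, 3, 3), cell_area_km2 = 0.01,
#'                      epoch = "2000", nomenclature = "seea")
#' area_by_class(g)
#' @export
land_cover_grid <- function(codes, cell_area_km2, epoch = "",
                            nomenclature = c("seea", "corine")) {
  nomenclature <- match.arg(nomenclature)
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  storage.mode(codes) <- "integer"
  if (!is.numeric(cell_area_km2) || length(cell_area_km2) != 1 ||
      is.na(cell_area_km2) || cell_area_km2 <= 0)
    stop("`cell_area_km2` must be a single positive number")
  present <- unique(codes[codes != 0L])
  valid <- switch(nomenclature,
                  seea = 1:14,
                  corine = read_class_mapping()$corine_code)
  bad <- setdiff(present, valid)
  if (length(bad))
    stop("invalid ", nomenclature, " codes in grid: ",
         paste(sort(bad), collapse = ", "))
  structure(list(codes = codes, cell_area_km2 = as.numeric(cell_area_km2),
                 epoch = as.character(epoch), nomenclature = nomenclature),
            class = "land_cover_grid")
}

#' @export
print.land_cover_grid <- function(x, ...) {
  nclass <- length(unique(x$codes[x$codes != 0L]))
  cat(sprintf(
    "<land_cover_grid> %d x %d cells (%s), epoch %s, %.4g km2/cell, %d classes, %d nodata\n",
    nrow(x$codes), ncol(x$codes), x$nomenclature,
    if (nzchar(x$epoch)) x$epoch else "?", x$cell_area_km2,
    nclass, sum(x$codes == 0L)))
  invisible(x)
}

#' Reclassify a CORINE grid to the 14 SEEA classes
#'
#' Applies a CORINE-to-SEEA class mapping cell-wise. Nodata cells (code 0)
#' pass through; shape, cell size and the nodata mask are preserved.
#'
#' @param grid A `land_cover_grid` in CORINE nomenclature.
#' @param mapping A `class_mapping`; defaults to the packaged mapping.
#' @return A `land_cover_grid` in SEEA nomenclature.
#' @examples
#' g <- land_cover_grid(matrix(c(312L, 211L, 0L, 511L), 2, 2),
#'                      cell_area_km2 = 0.01, nomenclature = "corine")
#' aggregate_classes(g)$codes
#' @export
aggregate_classes <- function(grid, mapping = read_class_mapping()) {
  stopifnot(inherits(grid, "land_cover_grid"))
  if (grid$nomenclature != "corine")
    stop("grid is already in SEEA nomenclature; aggregation must start ",
         "from CORINE codes")
  codes <- grid$codes
  present <- unique(codes[codes != 0L])
  unknown <- setdiff(present, mapping$corine_code)
  if (length(unknown)) {
    n_bad <- sum(codes %in% unknown)
    stop("unmapped CORINE code(s) ", paste(sort(unknown), collapse = ", "),
         " in ", n_bad, " cell(s)")
  }
  lut <- integer(max(mapping$corine_code) + 1L)  # lut[code + 1]
  lut[mapping$corine_code + 1L] <- mapping$seea_code
  out <- codes
  nz <- codes != 0L
  out[nz] <- lut[codes[nz] + 1L]
  land_cover_grid(out, grid$cell_area_km2, grid$epoch, "seea")
}

#' Area per SEEA class
#'
#' Tallies classified area by class: cell count times cell area. All 14
#' classes are reported; classes absent from the grid get 0.
#'
#' @param grid A `land_cover_grid` in SEEA nomenclature.
#' @return Named numeric vector of length 14 (names `"1"`..`"14"`),
#'   areas in km2.
#' @export
area_by_class <- function(grid) {
  stopifnot(inherits(grid, "land_cover_grid"))
  if (grid$nomenclature != "seea")
    stop("area_by_class() requires a SEEA-nomenclature grid; ",
         "aggregate_classes() first")
  counts <- tabulate(grid$codes[grid$codes != 0L], nbins = 14L)
  stats::setNames(counts * grid$cell_area_km2, as.character(1:14))
}

#' Read a land-cover grid from a plain-text or TIFF file
#'
#' The plain-text format has a four-line header (`ncols`, `nrows`,
#' `cellsize_m`, `nodata`) followed by `nrows` rows of whitespace-separated
#' integer codes. Cells equal to the declared nodata value become 0.
#' For `.tif`/`.tiff` files the first band is read as integers via the
#' `tiff` package and `cellsize_m` must be supplied (no georeferencing is
#' interpreted).
#'
#' @param path File path.
#' @param epoch Epoch label for the grid.
#' @param nomenclature `"seea"` or `"corine"`.
#' @param cellsize_m Cell size in metres, required for TIFF input.
#' @return A `land_cover_grid`.
#' @seealso [write_grid()]
#' @export
read_grid <- function(path, epoch = "", nomenclature = c("seea", "corine"),
                      cellsize_m = NULL) {
  nomenclature <- match.arg(nomenclature)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF grids")
    if (is.null(cellsize_m))
      stop("`cellsize_m` must be given for TIFF input")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    codes <- matrix(as.integer(img), nrow(img), ncol(img))
    codes[is.na(codes) | codes < 0L] <- 0L
    return(land_cover_grid(codes, (cellsize_m / 1000)^2, epoch, nomenclature))
  }
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines[1:4], value = TRUE)
    if (!length(ln)) stop("grid header missing '", key, "'")
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(hdr("ncols")); nrows <- as.integer(hdr("nrows"))
  cellsize <- hdr("cellsize_m"); nodata <- as.integer(hdr("nodata"))
  vals <- as.integer(scan(text = paste(lines[-(1:4)], collapse = "\n"),
                          quiet = TRUE))
  if (length(vals) != ncols * nrows)
    stop("grid body has ", length(vals), " values, expected ", ncols * nrows)
  codes <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  codes[codes == nodata] <- 0L
  land_cover_grid(codes, (cellsize / 1000)^2, epoch, nomenclature)
}

#' Write a land-cover grid in the plain-text grid format
#'
#' @param grid A `land_cover_grid`.
#' @param path Output path.
#' @param nodata Nodata value written in place of code 0.
#' @return `path`, invisibly.
#' @seealso [read_grid()]
#' @export
write_grid <- function(grid, path, nodata = -9999L) {
  stopifnot(inherits(grid, "land_cover_grid"))
  codes <- grid$codes
  codes[codes == 0L] <- as.integer(nodata)
  hdr <- c(paste("ncols", ncol(codes)),
           paste("nrows", nrow(codes)),
           paste("cellsize_m", format(sqrt(grid$cell_area_km2) * 1000)),
           paste("nodata", nodata))
  body <- apply(codes, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# shared precondition for grid-pair operations: same shape, cell size,
# nodata mask. A cell nodata in one epoch but classified in the other is
# an error (it would be an unexplained flow), not a transition.
check_grid_pair <- function(g0, g1) {
  stopifnot(inherits(g0, "land_cover_grid"), inherits(g1, "land_cover_grid"))
  if (g0$nomenclature != "seea" || g1$nomenclature != "seea")
    stop("both grids must be in SEEA nomenclature")
  if (!identical(dim(g0$codes), dim(g1$codes)))
    stop("grid shapes differ: ", paste(dim(g0$codes), collapse = "x"),
         " vs ", paste(dim(g1$codes), collapse = "x"))
  if (abs(g0$cell_area_km2 - g1$cell_area_km2) > 1e-12)
    stop("grid cell areas differ")
  discord <- sum((g0$codes == 0L) != (g1$codes == 0L))
  if (discord > 0L)
    stop("nodata masks differ in ", discord, " cell(s)")
  invisible(TRUE)
}
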