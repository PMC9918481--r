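#' Study domains of tiled rectangular districts
#'
#' A study domain is a rectangular extent in planar kilometre coordinates,
#' partitioned into non-overlapping district polygons. All coordinates in the
#' package are planar km (no geographic CRS), so Euclidean distances between
#' cluster locations are exact.
#'
#' @param n_x,n_y Number of districts along the x (east-west) and y
#'   (south-north) axes.
#' @param cell_km Side length of each district in km.
#' @return An object of class `study_domain`: a list with `xmin`, `ymin`,
#'   `xmax`, `ymax` (extent, km), `districts` (a list of `list(id, ring)`
#'   where `ring` is a closed counter-clockwise coordinate matrix), and
#'   `crs_note = "planar_km"`. District ids run row-major from 0, starting at
#'   the south-west corner.
#' @examples
#' dom <- generate_domain(4, 4, 25)
#' domain_extent(dom)
#' @export
generate_domain <- function(n_x, n_y, cell_km) {
  if (length(n_x) != 1L || length(n_y) != 1L || length(cell_km) != 1L)
    stop("n_x, n_y and cell_km must be scalars")
  if (!is.finite(n_x) || !is.finite(n_y) || n_x < 1 || n_y < 1 ||
      n_x != round(n_x) || n_y != round(n_y))
    stop("n_x and n_y must be positive integers")
  if (!is.finite(cell_km) || cell_km <= 0)
    stop("cell_km must be positive")
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  districts <- vector("list", n_x * n_y)
  id <- 0L
  for (iy in seq_len(n_y)) {
    y0 <- (iy - 1L) * cell_km; y1 <- iy * cell_km
    for (ix in seq_len(n_x)) {
      x0 <- (ix - 1L) * cell_km; x1 <- ix * cell_km
      ring <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
      districts[[id + 1L]] <- list(id = id, ring = ring)
      id <- id + 1L
    }
  }
  structure(
    list(xmin = 0, ymin = 0, xmax = n_x * cell_km, ymax = n_y * cell_km,
         districts = districts, crs_note = "planar_km"),
    class = "study_domain")
}

#' @rdname generate_domain
#' @param domain A `study_domain`.
#' @return `domain_extent()` returns `c(xmin, ymin, xmax, ymax)`.
#' @export
domain_extent <- function(domain) {
  stopifnot(inherits(domain, "study_domain"))
  c(xmin = domain$xmin, ymin = domain$ymin,
    xmax = domain$xmax, ymax = domain$ymax)
}

#' @export
print.study_domain <- function(x, ...) {
  cat(sprintf(
    "study_domain: extent [%g, %g] x [%g, %g] km, %d districts (%s)\n",
    x$xmin, x$xmax, x$ymin, x$ymax, length(x$districts), x$crs_note))
  invisible(x)
}

#' Polygon area by the shoelace formula
#'
#' Signed area is positive for counter-clockwise rings; the absolute value is
#' returned. Used for domain validity checks and as a test oracle.
#'
#' @param ring A closed two-column coordinate matrix (first row == last row).
#' @return Area in km^2.
#' @export
polygon_area <- function(ring) {
  stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 4)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Validate that districts tile the domain extent
#'
#' Checks that the district areas sum to the extent area (gap/overlap
#' tolerance 1e-9 km^2) and that every ring is closed.
#'
#' @param domain A `study_domain`.
#' @param tol Area tolerance in km^2.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_domain <- function(domain, tol = 1e-9) {
  stopifnot(inherits(domain, "study_domain"))
  if (domain$xmax <= domain$xmin || domain$ymax <= domain$ymin)
    stop("domain extent must have positive width and height")
  areas <- vapply(domain$districts, function(d) polygon_area(d$ring), 0)
  extent_area <- (domain$xmax - domain$xmin) * (domain$ymax - domain$ymin)
  if (abs(sum(areas) - extent_area) > tol)
    stop("districts do not tile the extent: area mismatch ",
         format(abs(sum(areas) - extent_area)))
  closed <- vapply(domain$districts, function(d)
    all(d$ring[1, ] == d$ring[nrow(d$ring), ]), TRUE)
  if (!all(closed)) stop("unclosed district ring(s)")
  invisible(TRUE)
}
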