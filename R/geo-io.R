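#' Read and write rasters as ESRI ASCII grids
#'
#' Surfaces and covariate layers are stored in the plain-text ESRI ASCII
#' grid format (`.asc`: a six-line header — ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value — followed by rows north to south),
#' which round-trips values, transform and nodata cells exactly at the
#' written precision and is readable by standard GIS tooling.
#'
#' @param path File path.
#' @param grid A `covariate_grid`.
#' @param nodata Sentinel written for missing cells (default -9999).
#' @param digits Significant digits written (default 17: lossless for
#'   doubles).
#' @return `read_raster()` returns a `covariate_grid`; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path, n = 6)
  hdr <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop("not an ESRI ASCII grid (missing header keys; expected ",
         paste(need, collapse = ", "), "): ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  v <- scan(path, skip = 6, quiet = TRUE)
  if (length(v) != vals[["ncols"]] * vals[["nrows"]])
    stop("raster payload size mismatch in ", path)
  m <- matrix(v, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
              byrow = TRUE)
  m[m == nodata] <- NA_real_
  covariate_grid(m, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
                 cell = vals[["cellsize"]],
                 name = sub("\\.asc$", "", basename(path)))
}

#' @rdname read_raster
#' @export
write_raster <- function(grid, path, nodata = -9999, digits = 17) {
  stopifnot(inherits(grid, "covariate_grid"))
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata, " as a real value")
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$xmin, digits = 17)),
    paste("yllcorner", format(grid$ymin, digits = 17)),
    paste("cellsize", format(grid$cell, digits = 17)),
    paste("NODATA_value", nodata)), con)
  writeLines(apply(v, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")), con)
  invisible(path)
}

#' Read and write district polygons as GeoJSON
#'
#' Districts are exchanged as a GeoJSON `FeatureCollection` of `Polygon`
#' features with a `district_id` property, in planar-km coordinates.
#'
#' @param path File path.
#' @param domain A `study_domain` (written) / returned on read, with the
#'   extent recovered from the polygon bounding box.
#' @return `read_districts()` returns a `study_domain`; `write_districts()`
#'   returns `path` invisibly.
#' @export
read_districts <- function(path) {
  if (!file.exists(path)) stop("no such district file: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", path)
  districts <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature with district_id ", f$properties$district_id,
           " is not a Polygon")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    if (nrow(ring) < 4 || !all(ring[1, ] == ring[nrow(ring), ]))
      stop("invalid (unclosed or degenerate) ring in feature with district_id ",
           f$properties$district_id)
    list(id = as.integer(f$properties$district_id), ring = ring)
  })
  allxy <- do.call(rbind, lapply(districts, `[[`, "ring"))
  structure(list(xmin = min(allxy[, 1]), ymin = min(allxy[, 2]),
                 xmax = max(allxy[, 1]), ymax = max(allxy[, 2]),
                 districts = districts, crs_note = "planar_km"),
            class = "study_domain")
}

#' @rdname read_districts
#' @export
write_districts <- function(domain, path) {
  stopifnot(inherits(domain, "study_domain"))
  features <- lapply(domain$districts, function(d) {
    coords <- lapply(seq_len(nrow(d$ring)),
                     function(i) c(d$ring[i, 1], d$ring[i, 2]))
    list(type = "Feature",
         properties = list(district_id = d$id),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write cluster tables as CSV
#'
#' @param clusters Cluster data frame.
#' @param path File path.
#' @return `read_clusters()` returns the data frame; `write_clusters()`
#'   returns `path` invisibly.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.csv(clusters, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("no such cluster file: ", path)
  utils::read.csv(path)
}

#' Point-in-polygon test by ray casting
#'
#' Even-odd rule with a horizontal ray; points exactly on an edge are
#' resolved by the half-open convention of the crossing test (a vertex
#' belongs to the edge going upward through it), so a set of polygons that
#' tile the plane assigns boundary points to exactly one polygon.
#'
#' @param points Two-column coordinate matrix.
#' @param ring Closed polygon ring matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(points, ring) {
  points <- as.matrix(points)
  px <- points[, 1]; py <- points[, 2]
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    x1 <- ring[e, 1]; y1 <- ring[e, 2]
    x2 <- ring[e + 1, 1]; y2 <- ring[e + 1, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- xint > px[crosses]
      inside[crosses] <- xor(inside[crosses], flip)
    }
  }
  inside
}

#' District zonal means of a prediction surface
#'
#' Averages the unmasked cells of a surface within each district, assigning
#' each cell by its centre (point-in-polygon; a cell centre on a shared
#' boundary is counted in exactly one district by the ray-casting half-open
#' rule, with the first matching district winning any residual tie).
#'
#' @param surface A `prediction_surface` or a single `covariate_grid`.
#' @param domain A `study_domain` (or list of `list(id, ring)` districts).
#' @param which For a `prediction_surface`, summarize the `"mean"` or
#'   `"sd"` layer.
#' @return Data frame with `district_id`, `mean`, `n_cells`; `mean` is `NA`
#'   (with a warning) for a district containing no cells.
#' @export
zonal_mean <- function(surface, domain, which = "mean") {
  grid <- if (inherits(surface, "prediction_surface")) surface[[which]]
          else surface
  stopifnot(inherits(grid, "covariate_grid"))
  districts <- if (inherits(domain, "study_domain")) domain$districts
               else domain
  centers <- grid_cell_centers(grid)
  vals <- as.vector(t(grid$values))
  unassigned <- !is.na(vals)
  out <- data.frame(district_id = integer(), mean = numeric(),
                    n_cells = integer())
  assigned <- rep(FALSE, length(vals))
  for (d in districts) {
    cand <- which(unassigned & !assigned)
    inside <- cand[points_in_polygon(centers[cand, , drop = FALSE], d$ring)]
    assigned[inside] <- TRUE
    mu <- if (length(inside)) mean(vals[inside]) else NA_real_
    if (!length(inside))
      warning("district ", d$id, " contains no unmasked cells")
    out <- rbind(out, data.frame(district_id = d$id, mean = mu,
                                 n_cells = length(inside)))
  }
  out
}
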