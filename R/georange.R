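#' Define a latitude-longitude analysis grid
#'
#' All range rasters in an analysis share one grid. Cells are
#' `resolution`-degree squares in longitude/latitude; areas are computed on
#' the sphere (authalic radius, default 6371 km), not in planar units, because
#' ranges spanning many latitudes would otherwise be badly biased. Rows of the
#' raster matrices index latitude bands from south to north, columns index
#' longitude bands from west to east.
#'
#' @param lon_min,lon_max,lat_min,lat_max grid bounds in degrees.
#' @param resolution cell size in degrees; bounds must be whole multiples.
#' @param earth_radius sphere radius in km.
#' @return a `grid_spec` object.
#' @examples
#' grid_spec(resolution = 1)
#' @export
grid_spec <- function(lon_min = -180, lon_max = 180, lat_min = -90, lat_max = 90,
                      resolution = 0.5, earth_radius = 6371) {
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  if (lat_min < -90 || lat_max > 90 || lat_min >= lat_max) {
    stop("latitude bounds must satisfy -90 <= lat_min < lat_max <= 90", call. = FALSE)
  }
  if (lon_min >= lon_max || lon_max - lon_min > 360) {
    stop("longitude bounds must satisfy lon_min < lon_max, span <= 360", call. = FALSE)
  }
  n_lon <- (lon_max - lon_min) / resolution
  n_lat <- (lat_max - lat_min) / resolution
  if (abs(n_lon - round(n_lon)) > 1e-8 || abs(n_lat - round(n_lat)) > 1e-8) {
    stop("grid bounds must be whole multiples of the resolution", call. = FALSE)
  }
  structure(
    list(lon_min = lon_min, lon_max = lon_max, lat_min = lat_min,
         lat_max = lat_max, resolution = resolution, earth_radius = earth_radius,
         n_lon = as.integer(round(n_lon)), n_lat = as.integer(round(n_lat))),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g deg, lon [%g, %g], lat [%g, %g], %d x %d cells\n",
              x$resolution, x$lon_min, x$lon_max, x$lat_min, x$lat_max,
              x$n_lat, x$n_lon))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

grid_lon_centers <- function(grid) {
  grid$lon_min + (seq_len(grid$n_lon) - 0.5) * grid$resolution
}
grid_lat_centers <- function(grid) {
  grid$lat_min + (seq_len(grid$n_lat) - 0.5) * grid$resolution
}

#' Spherical cell areas of a grid
#'
#' The area of a cell in latitude band \eqn{[\phi_1, \phi_2]} with longitude
#' width \eqn{\Delta\lambda} is \eqn{R^2 \Delta\lambda (\sin\phi_2 -
#' \sin\phi_1)}; summed over a globe-covering grid this recovers
#' \eqn{4\pi R^2}.
#'
#' @param grid a [grid_spec()].
#' @return an `n_lat x n_lon` matrix of areas in km^2 (rows south to north).
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  phi1 <- (grid$lat_min + (seq_len(grid$n_lat) - 1) * grid$resolution) * pi / 180
  phi2 <- phi1 + grid$resolution * pi / 180
  dlam <- grid$resolution * pi / 180
  band <- grid$earth_radius^2 * dlam * (sin(phi2) - sin(phi1))
  matrix(band, nrow = grid$n_lat, ncol = grid$n_lon)
}

#' Construct a presence raster for one species
#'
#' @param species species label.
#' @param grid a [grid_spec()].
#' @param presence logical `n_lat x n_lon` matrix (rows south to north).
#' @return a `range_raster` object.
#' @export
range_raster <- function(species, grid, presence) {
  stopifnot(inherits(grid, "grid_spec"), is.logical(presence))
  if (!identical(dim(presence), c(grid$n_lat, grid$n_lon))) {
    stop("presence matrix is ", paste(dim(presence), collapse = "x"),
         " but grid is ", grid$n_lat, "x", grid$n_lon, call. = FALSE)
  }
  structure(list(species = species, grid = grid, presence = presence),
            class = "range_raster")
}

#' @export
print.range_raster <- function(x, ...) {
  cat(sprintf("<range_raster> %s: %d of %d cells, %.0f km^2\n", x$species,
              sum(x$presence), length(x$presence),
              sum(cell_areas(x$grid)[x$presence])))
  invisible(x)
}

# even-odd point-in-polygon for one polygon (outer ring + optional holes),
# with antimeridian handling: rings are unwrapped to a continuous longitude
# band and points tested at lon, lon - 360, lon + 360
points_in_polygon <- function(rings, pts) {
  if (is.matrix(rings)) rings <- list(rings)
  bnd <- do.call(rbind, lapply(rings, function(r) {
    r <- as.matrix(r)[, 1:2, drop = FALSE]
    lon <- ((r[, 1] + 180) %% 360) - 180
    dl <- diff(lon)
    shift <- cumsum(c(0, ifelse(dl > 180, -360, ifelse(dl < -180, 360, 0))))
    rbind(cbind(lon + shift, r[, 2]), c(NA, NA))
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  inside <- rep(FALSE, nrow(pts))
  for (off in c(-360, 0, 360)) {
    shifted <- cbind(pts[, 1] + off, pts[, 2])
    inside <- inside | mgcv::in.out(bnd, shifted)
  }
  inside
}

# a species geometry is a list of polygons; each polygon a list of rings
# (first outer, rest holes); a bare matrix is promoted to one polygon
as_geometry <- function(g) {
  if (is.matrix(g) || is.data.frame(g)) return(list(list(as.matrix(g))))
  if (is.list(g) && length(g) > 0 && (is.matrix(g[[1]]) || is.data.frame(g[[1]]))) {
    return(list(lapply(g, as.matrix)))
  }
  lapply(g, function(p) lapply(p, as.matrix))
}

#' Rasterize polygon ranges onto a grid
#'
#' Converts lon/lat polygons (WGS84 degrees) into a presence raster. Under the
#' `"center"` rule a cell is present when its center falls inside the polygon
#' (even-odd rule, so holes are excluded); under `"any"` a cell is present
#' when any point of a 4x4 sub-lattice of the cell falls inside, an
#' approximation to any-overlap. Polygons crossing the antimeridian are
#' handled by unwrapping longitudes.
#'
#' @param geometry a ring matrix (lon, lat columns), a list of ring matrices
#'   (one polygon with holes), or a list of such polygons (multi-polygon).
#' @param grid a [grid_spec()].
#' @param species species label for the resulting raster.
#' @param rule `"center"` or `"any"`.
#' @return a `range_raster`; error if no cell is covered (a species whose
#'   range misses the grid must be excluded, not kept as an empty range).
#' @export
rasterize_range <- function(geometry, grid, species = "species", rule = c("center", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(grid, "grid_spec"))
  polys <- as_geometry(geometry)
  if (length(polys) == 0) stop("empty polygon set", call. = FALSE)

  lon <- grid_lon_centers(grid)
  lat <- grid_lat_centers(grid)
  if (rule == "center") {
    pts <- cbind(rep(lon, each = grid$n_lat), rep(lat, times = grid$n_lon))
    inside <- rep(FALSE, nrow(pts))
    for (p in polys) inside <- inside | points_in_polygon(p, pts)
    presence <- matrix(inside, nrow = grid$n_lat, ncol = grid$n_lon)
  } else {
    k <- 4L
    off <- ((seq_len(k) - 0.5) / k - 0.5) * grid$resolution
    presence <- matrix(FALSE, grid$n_lat, grid$n_lon)
    for (ox in off) {
      for (oy in off) {
        pts <- cbind(rep(lon + ox, each = grid$n_lat), rep(lat + oy, times = grid$n_lon))
        inside <- rep(FALSE, nrow(pts))
        for (p in polys) inside <- inside | points_in_polygon(p, pts)
        presence <- presence | matrix(inside, grid$n_lat, grid$n_lon)
      }
    }
  }
  if (!any(presence)) {
    stop("polygon covers no grid cell (range outside grid?): ", species, call. = FALSE)
  }
  range_raster(species, grid, presence)
}

#' Threshold a probability-of-occurrence grid into a presence raster
#'
#' Converts modelled occurrence probabilities (Aquamaps-style) into presence
#' by `probability >= cutoff`. The cutoff is configurable; 0.5 is the default.
#'
#' @param prob numeric `n_lat x n_lon` matrix with values in \[0, 1\].
#' @param grid a [grid_spec()].
#' @param species species label.
#' @param cutoff probability cutoff in \[0, 1\].
#' @return a `range_raster`.
#' @export
threshold_probability <- function(prob, grid, species = "species", cutoff = 0.5) {
  stopifnot(is.numeric(prob), inherits(grid, "grid_spec"))
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    stop("probabilities outside [0, 1]", call. = FALSE)
  }
  prob[is.na(prob)] <- 0
  range_raster(species, grid, matrix(prob >= cutoff, grid$n_lat, grid$n_lon))
}

#' Range area in km^2
#'
#' @param r a `range_raster`.
#' @return total spherical area of present cells; error on an empty range
#'   (such species must be excluded upstream).
#' @export
range_area <- function(r) {
  stopifnot(inherits(r, "range_raster"))
  if (!any(r$presence)) {
    stop("empty range for species ", r$species, call. = FALSE)
  }
  sum(cell_areas(r$grid)[r$presence])
}

#' Range overlap index O
#'
#' The area occupied jointly by a species pair (intersection of their ranges)
#' divided by the area of the species with the smaller range: 0 means no
#' overlap, 1 complete overlap (co-occurrence throughout, or one range nested
#' inside the other).
#'
#' @param a,b `range_raster` objects on the same grid, both non-empty.
#' @return O in \[0, 1\].
#' @export
overlap_index <- function(a, b) {
  stopifnot(inherits(a, "range_raster"), inherits(b, "range_raster"))
  if (!same_grid(a$grid, b$grid)) stop("rasters are on different grids", call. = FALSE)
  ca <- cell_areas(a$grid)
  area_a <- sum(ca[a$presence])
  area_b <- sum(ca[b$presence])
  if (area_a == 0 || area_b == 0) stop("empty range", call. = FALSE)
  sum(ca[a$presence & b$presence]) / min(area_a, area_b)
}

#' Range symmetry index S
#'
#' The smaller of the two range areas divided by the sum of both: S lies in
#' (0, 0.5], with 0.5 meaning equal-sized ranges. Low S between young sisters
#' is the signature of peripatric speciation (a small peripheral isolate).
#'
#' @inheritParams overlap_index
#' @return S in (0, 0.5].
#' @export
symmetry_index <- function(a, b) {
  stopifnot(inherits(a, "range_raster"), inherits(b, "range_raster"))
  if (!same_grid(a$grid, b$grid)) stop("rasters are on different grids", call. = FALSE)
  ca <- cell_areas(a$grid)
  area_a <- sum(ca[a$presence])
  area_b <- sum(ca[b$presence])
  if (area_a == 0 || area_b == 0) stop("empty range", call. = FALSE)
  min(area_a, area_b) / (area_a + area_b)
}

#' Classify a pair as sympatric or allopatric
#'
#' Allopatric when the overlap index is below the threshold, sympatric when
#' greater than or equal to it; the default 0.05 absorbs small errors in
#' occurrence data. Vectorized over `o`.
#'
#' @param o overlap index values in \[0, 1\].
#' @param threshold classification threshold in (0, 1).
#' @return character vector of `"allopatric"` / `"sympatric"`.
#' @examples
#' classify_overlap(c(0, 0.02, 0.05, 0.16, 1))
#' @export
classify_overlap <- function(o, threshold = 0.05) {
  if (any(is.na(o)) || any(o < 0 | o > 1)) {
    stop("overlap index must lie in [0, 1]", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)", call. = FALSE)
  ifelse(o < threshold, "allopatric", "sympatric")
}

#' Pairwise overlap records
#'
#' Computes areas, intersection area, overlap O, symmetry S and the
#' sympatry/allopatry classification for species pairs on a shared grid.
#'
#' @param rasters named list of `range_raster` objects sharing one grid.
#' @param pairs optional two-column data frame (`species_a`, `species_b`);
#'   defaults to all unordered pairs.
#' @param threshold classification threshold passed to [classify_overlap()].
#' @return a tibble with one row per pair: `species_a`, `species_b`,
#'   `area_a`, `area_b`, `intersection_area` (km^2), `overlap`, `symmetry`,
#'   `classification`.
#' @export
pairwise_overlap <- function(rasters, pairs = NULL, threshold = 0.05) {
  stopifnot(is.list(rasters), length(rasters) >= 2)
  nm <- vapply(rasters, function(r) r$species, character(1))
  names(rasters) <- nm
  grid <- rasters[[1]]$grid
  for (r in rasters) {
    if (!same_grid(r$grid, grid)) stop("rasters are on different grids", call. = FALSE)
  }
  if (is.null(pairs)) {
    idx <- utils::combn(nm, 2)
    pairs <- tibble::tibble(species_a = idx[1, ], species_b = idx[2, ])
  }
  ca <- cell_areas(grid)
  area <- vapply(rasters, function(r) sum(ca[r$presence]), numeric(1))
  purrr::pmap_dfr(pairs[, c("species_a", "species_b")], function(species_a, species_b) {
    a <- rasters[[species_a]]; b <- rasters[[species_b]]
    inter <- sum(ca[a$presence & b$presence])
    o <- inter / min(area[species_a], area[species_b])
    tibble::tibble(
      species_a = species_a, species_b = species_b,
      area_a = unname(area[species_a]), area_b = unname(area[species_b]),
      intersection_area = inter, overlap = o,
      symmetry = min(area[species_a], area[species_b]) /
        (area[species_a] + area[species_b]),
      classification = classify_overlap(o, threshold)
    )
  })
}

#' Stacked species richness
#'
#' @param rasters list of `range_raster` objects on a shared grid.
#' @return integer `n_lat x n_lon` matrix of per-cell species counts, with the
#'   grid attached as attribute `grid`.
#' @export
range_richness <- function(rasters) {
  stopifnot(is.list(rasters), length(rasters) >= 1)
  grid <- rasters[[1]]$grid
  rich <- matrix(0L, grid$n_lat, grid$n_lon)
  for (r in rasters) {
    if (!same_grid(r$grid, grid)) stop("rasters are on different grids", call. = FALSE)
    rich <- rich + r$presence
  }
  attr(rich, "grid") <- grid
  rich
}

#' Read species range polygons from GeoJSON
#'
#' Expects a FeatureCollection with one feature per species (Polygon or
#' MultiPolygon geometry, WGS84 lon/lat) and the species name stored in a
#' feature property.
#'
#' @param file path to a GeoJSON file.
#' @param species_key name of the property holding the species label.
#' @return a named list of geometries suitable for [rasterize_range()].
#' @export
read_ranges_geojson <- function(file, species_key = "species") {
  gj <- jsonlite::read_json(file)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  out <- list()
  for (ft in gj$features) {
    sp <- ft$properties[[species_key]]
    if (is.null(sp)) stop("feature without property '", species_key, "'", call. = FALSE)
    geom <- ft$geometry
    polys <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates, function(p) lapply(p, ring_mat)),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    out[[as.character(sp)]] <- polys
  }
  out
}

#' Write / read a grid matrix as headed CSV
#'
#' The dialect is a plain numeric CSV preceded by comment lines carrying the
#' grid definition (`# lon_min=...` etc.); row 1 is the southernmost band.
#'
#' @param mat numeric or logical `n_lat x n_lon` matrix.
#' @param grid a [grid_spec()].
#' @param file output path.
#' @export
write_grid_csv <- function(mat, grid, file) {
  stopifnot(inherits(grid, "grid_spec"))
  hdr <- sprintf("# %s=%.10g",
                 c("lon_min", "lon_max", "lat_min", "lat_max", "resolution", "earth_radius"),
                 c(grid$lon_min, grid$lon_max, grid$lat_min, grid$lat_max,
                   grid$resolution, grid$earth_radius))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(mat * 1, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_grid_csv
#' @param logical_values read the matrix back as logical (presence) rather
#'   than numeric.
#' @return `read_grid_csv()` returns a list with elements `matrix` and `grid`.
#' @export
read_grid_csv <- function(file, logical_values = FALSE) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, regmatches(hdr, regexec("^# *([a-z_]+)=([-0-9.eE+]+)", hdr)))
  vals <- as.numeric(kv[, 3])
  names(vals) <- kv[, 2]
  grid <- grid_spec(vals[["lon_min"]], vals[["lon_max"]], vals[["lat_min"]],
                    vals[["lat_max"]], vals[["resolution"]], vals[["earth_radius"]])
  mat <- as.matrix(utils::read.csv(text = lines[!grepl("^#", lines)], header = FALSE))
  dimnames(mat) <- NULL
  if (logical_values) mat <- mat > 0
  if (!identical(dim(mat), c(grid$n_lat, grid$n_lon))) {
    stop("matrix dimensions do not match grid header", call. = FALSE)
  }
  list(matrix = mat, grid = grid)
}
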