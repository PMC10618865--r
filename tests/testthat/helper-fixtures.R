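# fixtures are built in code; nothing is read from disk

# balanced ultrametric tree with 2^k tips, unit edge lengths
balanced_tree <- function(n_tip, edge_len = 1) {
  tr <- ape::stree(n_tip, "balanced")
  tr$edge.length <- rep(edge_len, nrow(tr$edge))
  tr
}

# raster from linear cell indices (column-major over the n_lat x n_lon grid)
make_raster <- function(grid, cells, species = "sp") {
  m <- matrix(FALSE, grid$n_lat, grid$n_lon)
  m[cells] <- TRUE
  range_raster(species, grid, m)
}

random_raster <- function(grid, species = "sp", p = 0.3) {
  m <- matrix(stats::runif(grid$n_lat * grid$n_lon) < p, grid$n_lat, grid$n_lon)
  if (!any(m)) m[sample.int(length(m), 1)] <- TRUE
  range_raster(species, grid, m)
}

# independent oracle: naive double loop over every cell, collecting each
# member cell's area before summing (column-major, matching R's layout)
naive_pair_indices <- function(a, b) {
  ca <- cell_areas(a$grid)
  av <- bv <- iv <- numeric(0)
  for (j in seq_len(ncol(ca))) {
    for (i in seq_len(nrow(ca))) {
      if (a$presence[i, j]) av <- c(av, ca[i, j])
      if (b$presence[i, j]) bv <- c(bv, ca[i, j])
      if (a$presence[i, j] && b$presence[i, j]) iv <- c(iv, ca[i, j])
    }
  }
  area_a <- sum(av); area_b <- sum(bv); inter <- sum(iv)
  list(overlap = inter / min(area_a, area_b),
       symmetry = min(area_a, area_b) / (area_a + area_b))
}

# ultrametric tree with exactly k cherries, joined by recursive bisection so
# no cherry sits more than ceiling(log2(k)) + 1 splits below the root
cherry_scaffold <- function(k) {
  build <- function(idx) {
    if (length(idx) == 1) {
      return(list(str = sprintf("(a%d:1,b%d:1)", idx, idx), h = 1))
    }
    half <- length(idx) %/% 2
    L <- build(idx[seq_len(half)])
    R <- build(idx[seq.int(half + 1, length(idx))])
    h <- max(L$h, R$h) + 1
    list(str = sprintf("(%s:%g,%s:%g)", L$str, h - L$h, R$str, h - R$h), h = h)
  }
  t <- build(seq_len(k))
  ape::read.tree(text = paste0(t$str, ";"))
}

# spherical area of a lon/lat rectangle, km^2
rect_area_sphere <- function(lon1, lon2, lat1, lat2, R = 6371) {
  R^2 * (lon2 - lon1) * pi / 180 * (sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
}

rect_ring <- function(lon1, lon2, lat1, lat2) {
  cbind(c(lon1, lon2, lon2, lon1, lon1), c(lat1, lat1, lat2, lat2, lat1))
}
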