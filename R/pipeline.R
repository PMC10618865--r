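#' Pipeline run configuration
#'
#' @param tree path to a Newick chronogram.
#' @param ranges path to range data: a directory of presence/probability grid
#'   CSVs (one per species, named `<species>.csv`, in the [write_grid_csv()]
#'   dialect) or a GeoJSON FeatureCollection of polygons.
#' @param traits path to a trait CSV (`species`, `max_length_cm`,
#'   `max_depth_m`, `habitat`, `piscivory`); optional.
#' @param out output directory for result CSVs and the run manifest.
#' @param overlap_threshold sympatry threshold on the overlap index.
#' @param grid a [grid_spec()] used when rasterizing polygons.
#' @param prob_cutoff cutoff for probability-of-occurrence grids.
#' @param n_perm permutations/simulations for the signal tests (>= 100).
#' @param mantel_mode `"plain"` or `"phylo-weighted"`.
#' @param species_key GeoJSON property holding the species name.
#' @param seed integer seed for all stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(tree, ranges, traits = NULL, out = "sympatree-run",
                       overlap_threshold = 0.05, grid = grid_spec(),
                       prob_cutoff = 0.5, n_perm = 1000,
                       mantel_mode = c("plain", "phylo-weighted"),
                       species_key = "species", seed = 1L) {
  mantel_mode <- match.arg(mantel_mode)
  if (overlap_threshold <= 0 || overlap_threshold >= 1) {
    stop("overlap_threshold must be in (0, 1)", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  structure(
    list(tree = tree, ranges = ranges, traits = traits, out = out,
         overlap_threshold = overlap_threshold, grid = grid,
         prob_cutoff = prob_cutoff, n_perm = as.integer(n_perm),
         mantel_mode = mantel_mode, species_key = species_key,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a flat key=value run configuration file
#'
#' @param file path to a flat `key=value` text file; recognized keys mirror
#'   the arguments of [run_config()], with the grid given as `grid_lon_min`,
#'   `grid_lat_min`, ..., `grid_resolution`.
#' @return a `run_config`.
#' @export
read_run_config <- function(file) {
  kv <- read_flat_config(file)
  g <- grid_spec(
    lon_min = kv$grid_lon_min %||% -180, lon_max = kv$grid_lon_max %||% 180,
    lat_min = kv$grid_lat_min %||% -90, lat_max = kv$grid_lat_max %||% 90,
    resolution = kv$grid_resolution %||% 0.5
  )
  run_config(
    tree = kv$tree, ranges = kv$ranges, traits = kv$traits,
    out = kv$out %||% "sympatree-run",
    overlap_threshold = kv$overlap_threshold %||% 0.05, grid = g,
    prob_cutoff = kv$prob_cutoff %||% 0.5, n_perm = kv$n_perm %||% 1000,
    mantel_mode = kv$mantel_mode %||% "plain",
    species_key = kv$species_key %||% "species", seed = kv$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_rasters <- function(cfg) {
  if (dir.exists(cfg$ranges)) {
    files <- list.files(cfg$ranges, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) stop("no grid CSVs in ", cfg$ranges, call. = FALSE)
    rasters <- lapply(files, function(f) {
      sp <- sub("\\.csv$", "", basename(f))
      g <- read_grid_csv(f)
      m <- g$matrix
      if (all(m %in% c(0, 1))) {
        range_raster(sp, g$grid, m > 0)
      } else {
        threshold_probability(m, g$grid, sp, cutoff = cfg$prob_cutoff)
      }
    })
    names(rasters) <- vapply(rasters, function(r) r$species, character(1))
    rasters
  } else if (grepl("\\.(geojson|json)$", cfg$ranges)) {
    geoms <- read_ranges_geojson(cfg$ranges, cfg$species_key)
    rasters <- lapply(names(geoms), function(sp) {
      rasterize_range(geoms[[sp]], cfg$grid, species = sp)
    })
    names(rasters) <- names(geoms)
    rasters
  } else {
    stop("ranges path not found: ", cfg$ranges, call. = FALSE)
  }
}

# all-species overlap and symmetry matrices via one cross-product
overlap_matrices <- function(rasters) {
  grid <- rasters[[1]]$grid
  ca <- as.vector(cell_areas(grid))
  M <- vapply(rasters, function(r) as.vector(r$presence) * sqrt(ca),
              numeric(length(ca)))
  inter <- crossprod(M)
  area <- diag(inter)
  mins <- outer(area, area, pmin)
  O <- inter / mins
  S <- mins / outer(area, area, `+`)
  diag(O) <- 1
  diag(S) <- 0.5
  list(overlap = O, symmetry = S, area = area)
}

welch_row <- function(name, res) {
  if (inherits(res, "welch_result")) {
    tibble::tibble(test = name, t_statistic = res$t_statistic, df = res$df,
                   p_value = res$p_value, n_a = res$n_a, n_b = res$n_b,
                   mean_a = res$mean_a, mean_b = res$mean_b, note = NA_character_)
  } else {
    tibble::tibble(test = name, t_statistic = NA_real_, df = NA_real_,
                   p_value = NA_real_, n_a = NA_integer_, n_b = NA_integer_,
                   mean_a = NA_real_, mean_b = NA_real_, note = as.character(res))
  }
}

#' Run the full sympatry analysis pipeline
#'
#' Reads a chronogram, ranges and traits; prunes species without usable range
#' data; extracts sister pairs; builds the pair table; and writes to `out`:
#' `pair_table.csv`, `summaries.csv` (both median variants),
#' `habitat_crosstab.csv`, `tests.csv` (Welch's t contrasts by class and
#' habitat stratum), `regressions.csv` (age-range correlations),
#' `signal.csv` (Blomberg's K, Fritz's D, Mantel tests), `richness.csv`, and
#' `manifest.json` recording versions, seed, configuration hash and every
#' exclusion count. Runs are deterministic for fixed inputs and seed.
#'
#' @param cfg a [run_config()] or path to a flat config file.
#' @return invisibly, a list with the in-memory results and file paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$tree, cfg$ranges, cfg$traits)) {
    if (!is.null(p) && !file.exists(p) && !dir.exists(p)) {
      stop("input not found: ", p, call. = FALSE)
    }
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)

  tree <- read_timetree(cfg$tree)
  rasters <- load_rasters(cfg)
  traits <- if (!is.null(cfg$traits)) readr::read_csv(cfg$traits, show_col_types = FALSE) else NULL

  n_input <- length(tree$tip.label)
  usable <- intersect(tree$tip.label,
                      names(rasters)[vapply(rasters, function(r) any(r$presence), logical(1))])
  n_excluded <- n_input - length(usable)
  if (n_excluded > 0) {
    message(n_excluded, " species trimmed from the tree (no usable range)")
  }
  tree_used <- if (n_excluded > 0) prune_timetree(tree, usable) else tree
  rasters <- rasters[tree_used$tip.label]

  pairs <- sister_pairs(tree_used)
  pair_table <- build_pair_table(pairs, rasters, traits,
                                 threshold = cfg$overlap_threshold)

  summaries <- dplyr::bind_rows(
    dplyr::mutate(summarize_pairs(pair_table), variant = "all_pairs"),
    tryCatch(dplyr::mutate(summarize_pairs(pair_table, drop_depth_missing = TRUE),
                           variant = "depth_complete"),
             error = function(e) NULL)
  )
  crosstab <- habitat_crosstab(pair_table)

  by_class <- function(col) {
    a <- pair_table[[col]][pair_table$classification %in% "allopatric"]
    s <- pair_table[[col]][pair_table$classification %in% "sympatric"]
    tryCatch(welch_t(s, a), error = function(e) conditionMessage(e))
  }
  tests <- dplyr::bind_rows(
    welch_row("depth_contrast_sympatric_vs_allopatric", by_class("contrast_depth")),
    welch_row("length_contrast_sympatric_vs_allopatric", by_class("contrast_length")),
    welch_row("depth_contrast_same_vs_mixed_habitat",
              tryCatch(habitat_stratified_test(pair_table, "depth"),
                       error = function(e) conditionMessage(e))),
    welch_row("length_contrast_same_vs_mixed_habitat",
              tryCatch(habitat_stratified_test(pair_table, "length"),
                       error = function(e) conditionMessage(e)))
  )

  reg_of <- function(x, y) {
    fit <- tryCatch(arc_regression(pair_table, x, y), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    tibble::tibble(response = y, predictor = x, slope = fit$slope,
                   intercept = fit$intercept, r = fit$r,
                   r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n)
  }
  regressions <- dplyr::bind_rows(
    reg_of("node_age", "overlap"),
    reg_of("node_age", "symmetry"),
    reg_of("overlap", "symmetry")
  )

  # phylogenetic signal on the full (range-usable) tree
  signal <- NULL
  om <- overlap_matrices(rasters)
  Dphy <- ape::cophenetic.phylo(tree_used)[tree_used$tip.label, tree_used$tip.label]
  sig_rows <- list()
  if (!is.null(traits)) {
    cont <- list(max_length_cm = "log", max_depth_m = "log")
    for (nm in names(cont)) {
      if (!nm %in% names(traits)) next
      v <- setNames(traits[[nm]], traits$species)
      v <- v[tree_used$tip.label]
      keep <- names(v)[!is.na(v)]
      if (length(keep) < 4) next
      if (length(keep) < length(v)) {
        message(length(v) - length(keep), " species dropped from K test of ", nm)
      }
      tr <- if (length(keep) < length(v)) prune_timetree(tree_used, keep) else tree_used
      res <- blomberg_k(tr, log(v[keep]), n_perm = cfg$n_perm, seed = cfg$seed)
      sig_rows[[paste0("K_", nm)]] <- tibble::tibble(
        test = "blomberg_k", variable = nm, statistic = res$statistic,
        p_name = "p", p_value = res$p_values$p, n = res$n, n_perm = res$n_perm)
    }
    for (nm in intersect(c("habitat", "piscivory"), names(traits))) {
      v <- traits[[nm]]
      v <- if (nm == "habitat") as.numeric(v == "reef") else as.numeric(v)
      v <- setNames(v, traits$species)[tree_used$tip.label]
      keep <- names(v)[!is.na(v)]
      if (length(keep) < 4 || length(unique(v[keep])) < 2) next
      tr <- if (length(keep) < length(v)) prune_timetree(tree_used, keep) else tree_used
      res <- tryCatch(fritz_d(tr, v[keep], n_sim = cfg$n_perm, seed = cfg$seed),
                      error = function(e) NULL)
      if (is.null(res)) next
      sig_rows[[paste0("D_", nm)]] <- tibble::tibble(
        test = "fritz_d", variable = nm, statistic = res$statistic,
        p_name = names(res$p_values), p_value = unlist(res$p_values),
        n = res$n, n_perm = res$n_perm)
    }
    # K for range size
    v <- log(om$area[tree_used$tip.label])
    res <- blomberg_k(tree_used, v, n_perm = cfg$n_perm, seed = cfg$seed)
    sig_rows[["K_range"]] <- tibble::tibble(
      test = "blomberg_k", variable = "range_area_km2", statistic = res$statistic,
      p_name = "p", p_value = res$p_values$p, n = res$n, n_perm = res$n_perm)
  }
  for (nm in c("overlap", "symmetry")) {
    m <- if (nm == "overlap") 1 - om$overlap else 0.5 - om$symmetry
    diag(m) <- 0
    res <- phylo_mantel(m, Dphy, n_perm = cfg$n_perm, seed = cfg$seed,
                        tree = tree_used, mode = cfg$mantel_mode)
    sig_rows[[paste0("mantel_", nm)]] <- tibble::tibble(
      test = paste0("mantel_", cfg$mantel_mode), variable = nm,
      statistic = res$statistic, p_name = "p", p_value = res$p_values$p,
      n = res$n, n_perm = res$n_perm)
  }
  signal <- dplyr::bind_rows(sig_rows)

  rich <- range_richness(rasters)

  paths <- list(
    pair_table = file.path(cfg$out, "pair_table.csv"),
    summaries = file.path(cfg$out, "summaries.csv"),
    habitat_crosstab = file.path(cfg$out, "habitat_crosstab.csv"),
    tests = file.path(cfg$out, "tests.csv"),
    regressions = file.path(cfg$out, "regressions.csv"),
    signal = file.path(cfg$out, "signal.csv"),
    richness = file.path(cfg$out, "richness.csv"),
    manifest = file.path(cfg$out, "manifest.json")
  )
  readr::write_csv(pair_table, paths$pair_table)
  readr::write_csv(summaries, paths$summaries)
  readr::write_csv(crosstab, paths$habitat_crosstab)
  readr::write_csv(tests, paths$tests)
  readr::write_csv(regressions, paths$regressions)
  if (!is.null(signal) && nrow(signal) > 0) readr::write_csv(signal, paths$signal)
  write_grid_csv(rich, rasters[[1]]$grid, paths$richness)

  cfg_flat <- cfg[setdiff(names(cfg), "grid")]
  cfg_flat$grid <- unclass(cfg$grid)
  manifest <- list(
    package = "sympatree",
    package_version = as.character(utils::packageVersion("sympatree")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = cfg_flat,
    config_hash = rlang::hash(cfg_flat),
    counts = list(
      species_input = n_input,
      species_with_range = length(usable),
      species_excluded_no_range = n_excluded,
      pairs = nrow(pair_table),
      pairs_excluded_no_range = sum(!is.na(pair_table$excluded_reason) &
                                      pair_table$excluded_reason == "no_range"),
      pairs_missing_depth_contrast = sum(is.na(pair_table$contrast_depth))
    )
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  invisible(list(pair_table = pair_table, summaries = summaries,
                 habitat_crosstab = crosstab, tests = tests,
                 regressions = regressions, signal = signal, richness = rich,
                 manifest = manifest, paths = paths))
}
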