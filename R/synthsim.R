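#' Configuration for the synthetic-data generator
#'
#' Defaults describe a clade of the size and age structure the analysis is
#' designed for: ~123 extant species arising under a birth-death process at
#' rates giving a crown age of a few tens of Ma, ranges on a 1-degree grid
#' over the latitudinal band where most marine fish diversity lies, and an
#' allopatry-dominant mix of speciation modes with moderate post-speciation
#' range drift. See the methods vignette for the rationale behind each value.
#'
#' @param n_tips number of extant species to simulate.
#' @param birth_rate,death_rate speciation/extinction rates (events/Ma).
#' @param speciation_mode `"sympatric"`, `"allopatric"`, `"peripatric"`, or
#'   `"mixed"` (modes drawn per node from `mode_probs`).
#' @param mode_probs named probabilities for `"mixed"`; must sum to 1.
#' @param drift_rate expected boundary-cell changes per Ma per lineage.
#' @param peripheral_fraction fraction of the parent range budded off to the
#'   daughter under peripatry, in (0, 0.5).
#' @param bm_sigma2 Brownian trait variance per Ma (log-trait scale).
#' @param mk_rates named `q01`, `q10` transition rates per Ma for binary
#'   traits.
#' @param root_fraction fraction of grid cells in the ancestral seed range.
#' @param grid a [grid_spec()] for the simulated rasters.
#' @param seed integer seed for all randomness downstream.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tips = 123, birth_rate = 0.08, death_rate = 0.02,
                       speciation_mode = c("mixed", "sympatric", "allopatric", "peripatric"),
                       mode_probs = c(sympatric = 0.25, allopatric = 0.5, peripatric = 0.25),
                       drift_rate = 2, peripheral_fraction = 0.1,
                       bm_sigma2 = 0.02, mk_rates = c(q01 = 0.05, q10 = 0.05),
                       root_fraction = 0.1,
                       grid = grid_spec(-180, 180, -60, 60, resolution = 1),
                       seed = 1L) {
  speciation_mode <- match.arg(speciation_mode)
  stopifnot(n_tips >= 2, birth_rate > death_rate, death_rate >= 0,
            drift_rate >= 0, bm_sigma2 >= 0, all(mk_rates >= 0),
            root_fraction > 0, root_fraction <= 1)
  if (peripheral_fraction <= 0 || peripheral_fraction >= 0.5) {
    stop("peripheral_fraction must be in (0, 0.5)", call. = FALSE)
  }
  if (speciation_mode != "mixed") {
    mode_probs <- setNames(as.numeric(names(mode_probs) == speciation_mode) * 0,
                           names(mode_probs))
    mode_probs[speciation_mode] <- 1
  }
  if (abs(sum(mode_probs) - 1) > 1e-8) stop("mode_probs must sum to 1", call. = FALSE)
  structure(
    list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
         death_rate = death_rate, speciation_mode = speciation_mode,
         mode_probs = mode_probs, drift_rate = drift_rate,
         peripheral_fraction = peripheral_fraction, bm_sigma2 = bm_sigma2,
         mk_rates = mk_rates, root_fraction = root_fraction, grid = grid,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a birth-death chronogram conditioned on tip count
#'
#' Forward constant-rate birth-death simulation starting from the two root
#' lineages; the present is fixed at the moment the (`n_tips` + 1)-th extant
#' lineage would arise, and extinct lineages are pruned, leaving exactly
#' `n_tips` extant tips. Under pure birth this makes the expected root age
#' \eqn{\sum_{k=2}^{n} 1/(\lambda k)}. Runs in which the clade dies out are
#' discarded and re-drawn.
#'
#' @param n_tips number of surviving tips.
#' @param birth_rate,death_rate rates per lineage per Ma (birth > death).
#' @param seed integer seed.
#' @param max_retries attempts before giving up when extinction keeps
#'   terminating the clade.
#' @return an ultrametric `phylo` with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate, death_rate = 0, seed = 1L,
                          max_retries = 1000L) {
  stopifnot(n_tips >= 2, birth_rate > death_rate, death_rate >= 0)
  tr <- with_seed(seed, {
    res <- NULL
    for (try in seq_len(max_retries)) {
      res <- bd_forward_once(n_tips, birth_rate, death_rate)
      if (!is.null(res)) break
    }
    res
  })
  if (is.null(tr)) {
    stop("could not condition on ", n_tips, " survivors after ", max_retries,
         " attempts", call. = FALSE)
  }
  tr
}

bd_forward_once <- function(n_tips, b, d) {
  # lineage records; ids index the vectors
  parent <- c(0L, 0L)
  t_birth <- c(0, 0)
  t_death <- c(NA_real_, NA_real_)
  alive <- c(TRUE, TRUE)
  kids <- list(integer(0), integer(0))
  t_now <- 0
  repeat {
    n_alive <- sum(alive)
    if (n_alive == 0) return(NULL)
    t_now <- t_now + stats::rexp(1, (b + d) * n_alive)
    is_birth <- runif(1) < b / (b + d)
    if (is_birth && n_alive == n_tips) break  # present reached
    who <- which(alive)
    who <- if (length(who) == 1) who else sample(who, 1)
    if (is_birth) {
      alive[who] <- FALSE
      t_death[who] <- t_now
      id1 <- length(parent) + 1L
      id2 <- id1 + 1L
      parent <- c(parent, who, who)
      t_birth <- c(t_birth, t_now, t_now)
      t_death <- c(t_death, NA, NA)
      alive <- c(alive, TRUE, TRUE)
      kids[[who]] <- c(id1, id2)
      kids[[id1]] <- integer(0)
      kids[[id2]] <- integer(0)
    } else {
      alive[who] <- FALSE
      t_death[who] <- t_now
    }
    if (length(parent) > 100 * n_tips + 1000) return(NULL)  # runaway extinction churn
  }
  present <- t_now
  nwk_of <- function(id) {
    end <- if (alive[id]) present else t_death[id]
    len <- end - t_birth[id]
    if (length(kids[[id]]) == 2) {
      sprintf("(%s,%s):%.12g", nwk_of(kids[[id]][1]), nwk_of(kids[[id]][2]), len)
    } else {
      sprintf("x%d:%.12g", id, len)
    }
  }
  txt <- sprintf("(%s,%s);", nwk_of(1L), nwk_of(2L))
  full <- ape::read.tree(text = txt)
  survivors <- paste0("x", which(alive & vapply(kids, length, 1L) == 0))
  if (length(survivors) != n_tips) return(NULL)
  tr <- if (length(full$tip.label) == length(survivors)) full else ape::keep.tip(full, survivors)
  tr$tip.label <- paste0("t", seq_along(tr$tip.label))
  tr
}

# --- range evolution on the grid ------------------------------------------

neighbor_shift <- function(m, wrap_lon) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-nr, , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], if (wrap_lon) m[, 1] else FALSE)
  right <- cbind(if (wrap_lon) m[, nc] else FALSE, m[, -nc, drop = FALSE])
  up | down | left | right
}

drift_range <- function(pres, n_steps, wrap_lon) {
  for (s in seq_len(n_steps)) {
    add_cand <- neighbor_shift(pres, wrap_lon) & !pres
    rem_cand <- pres & neighbor_shift(!pres, wrap_lon)
    do_add <- if (sum(pres) <= 1) TRUE else if (!any(add_cand)) FALSE else runif(1) < 0.5
    if (do_add && any(add_cand)) {
      idx <- which(add_cand)
      pres[if (length(idx) == 1) idx else sample(idx, 1)] <- TRUE
    } else if (any(rem_cand) && sum(pres) > 1) {
      idx <- which(rem_cand)
      pres[if (length(idx) == 1) idx else sample(idx, 1)] <- FALSE
    }
  }
  pres
}

# order presence cells along the range's longer bounding-box axis (ties to
# longitude), returning cell indices sorted by (axis coordinate, other axis)
ordered_cells <- function(pres) {
  cells <- which(pres, arr.ind = TRUE)
  ext_lat <- diff(range(cells[, 1]))
  ext_lon <- diff(range(cells[, 2]))
  if (ext_lat > ext_lon) {
    ord <- order(cells[, 1], cells[, 2])
  } else {
    ord <- order(cells[, 2], cells[, 1])
  }
  which(pres)[ord]  # linear indices in axis order
}

split_allopatric <- function(pres, areas) {
  cells <- ordered_cells(pres)
  ca <- cumsum(areas[cells])
  k <- which(ca >= ca[length(ca)] / 2)[1]
  if (k >= length(cells)) k <- length(cells) - 1L
  p1 <- p2 <- pres & FALSE
  p1[cells[seq_len(k)]] <- TRUE
  p2[cells[seq.int(k + 1, length(cells))]] <- TRUE
  list(p1, p2)
}

split_peripatric <- function(pres, areas, fraction) {
  cells <- ordered_cells(pres)
  if (runif(1) < 0.5) cells <- rev(cells)
  ca <- cumsum(areas[cells])
  k <- max(1L, sum(ca <= ca[length(ca)] * fraction))
  if (k >= length(cells)) k <- length(cells) - 1L
  bud <- core <- pres & FALSE
  bud[cells[seq_len(k)]] <- TRUE
  core[cells[seq.int(k + 1, length(cells))]] <- TRUE
  list(core = core, bud = bud)
}

#' Simulate range evolution along a tree
#'
#' The root ancestor receives a contiguous rectangular seed range covering
#' `root_fraction` of the grid. At each speciation node a mode is drawn:
#' under sympatric speciation both daughters inherit the full parental range;
#' under allopatric (vicariant) speciation the range is bisected along its
#' longer axis at the area-median line; under peripatric speciation one
#' daughter buds off a `peripheral_fraction` block at a randomly chosen range
#' edge and the other keeps the remainder. Between events each lineage's
#' boundary drifts: a Poisson(`drift_rate` x branch length) number of steps,
#' each adding or removing one frontier cell (never emptying the range).
#'
#' @param tree an ultrametric `phylo` (typically from [simulate_tree()]).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `rasters` (named list of `range_raster`) and `truth`
#'   (tibble of `node`, `mode` for every internal node).
#' @export
simulate_ranges <- function(tree, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tree, "phylo"))
  grid <- cfg$grid
  areas <- cell_areas(grid)
  wrap <- (grid$lon_max - grid$lon_min) >= 360
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L

  # centered rectangular seed range
  total <- grid$n_lat * grid$n_lon
  n_seed <- max(4L, round(cfg$root_fraction * total))
  nr <- min(grid$n_lat, max(2L, round(sqrt(n_seed * grid$n_lat / grid$n_lon))))
  nc <- min(grid$n_lon, max(2L, ceiling(n_seed / nr)))
  r0 <- floor((grid$n_lat - nr) / 2)
  c0 <- floor((grid$n_lon - nc) / 2)
  seed_range <- matrix(FALSE, grid$n_lat, grid$n_lon)
  seed_range[r0 + seq_len(nr), c0 + seq_len(nc)] <- TRUE

  kids <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- setNames(tree$edge.length, tree$edge[, 2])
  ranges <- vector("list", n_tip + tree$Nnode)
  ranges[[root]] <- seed_range
  modes <- character(tree$Nnode)
  names(modes) <- as.character(root - 1L + seq_len(tree$Nnode))
  node_cells <- integer(tree$Nnode)
  names(node_cells) <- names(modes)

  visit <- function(nd) {
    ch <- kids[[as.character(nd)]]
    pres <- ranges[[nd]]
    mode <- sample(names(cfg$mode_probs), 1, prob = cfg$mode_probs)
    if (sum(pres) < 2 && mode != "sympatric") mode <- "sympatric"  # unsplittable
    modes[as.character(nd)] <<- mode
    node_cells[as.character(nd)] <<- sum(pres)
    alloc <- switch(mode,
      sympatric = list(pres, pres),
      allopatric = split_allopatric(pres, areas),
      peripatric = {
        sp <- split_peripatric(pres, areas, cfg$peripheral_fraction)
        if (runif(1) < 0.5) list(sp$core, sp$bud) else list(sp$bud, sp$core)
      }
    )
    for (i in 1:2) {
      n_steps <- stats::rpois(1, cfg$drift_rate * edge_len[[as.character(ch[i])]])
      ranges[[ch[i]]] <<- drift_range(alloc[[i]], n_steps, wrap)
      if (ch[i] > n_tip) visit(ch[i])
    }
  }
  if (!ape::is.binary(tree)) stop("range simulation requires a binary tree", call. = FALSE)
  with_seed(seed, visit(root))

  rasters <- lapply(seq_len(n_tip), function(i) {
    range_raster(tree$tip.label[i], grid, ranges[[i]])
  })
  names(rasters) <- tree$tip.label
  truth <- tibble::tibble(node = as.integer(names(modes)), mode = unname(modes),
                          n_cells = unname(node_cells))
  list(rasters = rasters, truth = truth)
}

#' Simulate a Brownian-motion trait
#'
#' @param tree a `phylo` with branch lengths (Ma).
#' @param sigma2 variance accrued per Ma.
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector over tips; tip covariance equals shared path
#'   length times `sigma2`.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = 1L) {
  stopifnot(sigma2 >= 0)
  pre <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  val <- numeric(n_tip + tree$Nnode)
  val[n_tip + 1L] <- root_value
  incr <- with_seed(seed, rnorm(nrow(pre$edge), 0, sqrt(sigma2 * pre$edge.length)))
  for (e in seq_len(nrow(pre$edge))) {
    val[pre$edge[e, 2]] <- val[pre$edge[e, 1]] + incr[e]
  }
  setNames(val[seq_len(n_tip)], tree$tip.label)
}

#' Simulate a two-state Markov trait
#'
#' Continuous-time Markov chain with rates `q01` (0 to 1) and `q10` (1 to 0)
#' run along every branch.
#'
#' @param tree a `phylo` with branch lengths.
#' @param q01,q10 transition rates per Ma (not both 0).
#' @param root_state state at the root (0 or 1).
#' @param seed integer seed.
#' @return named 0/1 vector over tips.
#' @export
simulate_binary <- function(tree, q01, q10, root_state = 0, seed = 1L) {
  stopifnot(q01 >= 0, q10 >= 0, root_state %in% c(0, 1))
  pre <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  st <- integer(n_tip + tree$Nnode)
  st[n_tip + 1L] <- root_state
  with_seed(seed, {
    for (e in seq_len(nrow(pre$edge))) {
      s <- st[pre$edge[e, 1]]
      t_rem <- pre$edge.length[e]
      repeat {
        rate <- if (s == 0) q01 else q10
        if (rate == 0) break
        w <- stats::rexp(1, rate)
        if (w > t_rem) break
        s <- 1L - s
        t_rem <- t_rem - w
      }
      st[pre$edge[e, 2]] <- s
    }
  })
  setNames(st[seq_len(n_tip)], tree$tip.label)
}

#' Generate a complete synthetic dataset
#'
#' Wires the tree, range and trait simulators under one seed and (optionally)
#' writes the dataset in the same plain-text formats the analysis pipeline
#' reads, guaranteeing an end-to-end round trip: `tree.nwk`, per-species
#' presence grids `grids/<species>.csv`, `traits.csv`, `truth.csv` and the
#' configuration as a flat `config.txt`. Continuous traits are generated as
#' geometric Brownian motion (Brownian on the log scale) around field-typical
#' values of maximum body length (cm) and maximum depth (m); habitat
#' (reef/nonreef) and piscivory evolve as two-state Markov chains.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory to write the dataset into.
#' @param tree optional user-supplied ultrametric `phylo` (e.g. a balanced
#'   tree for calibration designs with an exact cherry count); by default a
#'   birth-death tree is simulated from `cfg`.
#' @return a `synth_scenario` list: `tree`, `rasters`, `traits` (tibble),
#'   `truth`, `config`, and `dir` when written.
#' @export
make_scenario <- function(cfg = sim_config(), dir = NULL, tree = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(tree)) {
    tree <- simulate_tree(cfg$n_tips, cfg$birth_rate, cfg$death_rate, seed = cfg$seed)
  } else {
    validate_timetree(tree)
  }
  rng <- simulate_ranges(tree, cfg, seed = cfg$seed + 1L)
  length_log <- simulate_bm(tree, cfg$bm_sigma2, root_value = log(60), seed = cfg$seed + 2L)
  depth_log <- simulate_bm(tree, cfg$bm_sigma2, root_value = log(100), seed = cfg$seed + 3L)
  habitat <- simulate_binary(tree, cfg$mk_rates[["q01"]], cfg$mk_rates[["q10"]],
                             seed = cfg$seed + 4L)
  piscivory <- simulate_binary(tree, cfg$mk_rates[["q01"]], cfg$mk_rates[["q10"]],
                               seed = cfg$seed + 5L)
  traits <- tibble::tibble(
    species = tree$tip.label,
    max_length_cm = exp(length_log),
    max_depth_m = exp(depth_log),
    habitat = ifelse(habitat == 1, "reef", "nonreef"),
    piscivory = as.integer(piscivory)
  )
  out <- structure(
    list(tree = tree, rasters = rng$rasters, traits = traits,
         truth = rng$truth, config = cfg, dir = dir),
    class = "synth_scenario"
  )
  if (!is.null(dir)) {
    dir.create(file.path(dir, "grids"), recursive = TRUE, showWarnings = FALSE)
    write_timetree(tree, file.path(dir, "tree.nwk"))
    for (r in rng$rasters) {
      write_grid_csv(r$presence, cfg$grid, file.path(dir, "grids", paste0(r$species, ".csv")))
    }
    readr::write_csv(traits, file.path(dir, "traits.csv"))
    readr::write_csv(rng$truth, file.path(dir, "truth.csv"))
    write_flat_config(sim_config_flat(cfg), file.path(dir, "config.txt"))
  }
  out
}

#' @export
print.synth_scenario <- function(x, ...) {
  cat(sprintf("<synth_scenario> %d tips, %d rasters, mode = %s, seed = %d\n",
              length(x$tree$tip.label), length(x$rasters),
              x$config$speciation_mode, x$config$seed))
  invisible(x)
}

sim_config_flat <- function(cfg) {
  list(
    n_tips = cfg$n_tips, birth_rate = cfg$birth_rate, death_rate = cfg$death_rate,
    speciation_mode = cfg$speciation_mode,
    mode_prob_sympatric = unname(cfg$mode_probs[["sympatric"]]),
    mode_prob_allopatric = unname(cfg$mode_probs[["allopatric"]]),
    mode_prob_peripatric = unname(cfg$mode_probs[["peripatric"]]),
    drift_rate = cfg$drift_rate, peripheral_fraction = cfg$peripheral_fraction,
    bm_sigma2 = cfg$bm_sigma2, q01 = cfg$mk_rates[["q01"]], q10 = cfg$mk_rates[["q10"]],
    root_fraction = cfg$root_fraction,
    grid_lon_min = cfg$grid$lon_min, grid_lon_max = cfg$grid$lon_max,
    grid_lat_min = cfg$grid$lat_min, grid_lat_max = cfg$grid$lat_max,
    grid_resolution = cfg$grid$resolution, seed = cfg$seed
  )
}

# flat key=value config files (read back by the pipeline)
write_flat_config <- function(x, file) {
  writeLines(paste0(names(x), "=", vapply(x, as.character, character(1))), file)
  invisible(file)
}

read_flat_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[#\\[]", trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}
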