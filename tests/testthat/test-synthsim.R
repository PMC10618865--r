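small_grid <- function() grid_spec(0, 60, 0, 30, 1)

test_that("tree simulation conditions on tip count and is seed-reproducible", {
  tr <- simulate_tree(16, 1, 0, seed = 1)
  expect_equal(length(tr$tip.label), 16)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::all.equal.phylo(tr, simulate_tree(16, 1, 0, seed = 1),
                                   use.edge.length = TRUE))

  chry <- simulate_tree(2, 1, 0, seed = 2)
  expect_equal(length(chry$tip.label), 2)
  expect_gt(max(ape::node.depth.edgelength(chry)), 0)

  bd <- simulate_tree(20, 0.3, 0.1, seed = 3)
  expect_equal(length(bd$tip.label), 20)
  expect_true(ape::is.ultrametric(bd, tol = 1e-8))
})

test_that("Yule root ages match the analytic expectation", {
  # stopping just before the (n+1)-th speciation makes
  # E[root age] = sum_{k=2}^{n} 1/(lambda k)
  set.seed(100)
  ages <- replicate(2000, {
    tr <- simulate_tree(16, 1, 0, seed = sample.int(1e7, 1))
    max(ape::node.depth.edgelength(tr))
  })
  expected <- sum(1 / (2:16))
  expect_lt(abs(mean(ages) - expected) / expected, 0.05)
})

test_that("drift-free speciation modes produce their defining geometries", {
  tr <- balanced_tree(16)
  cfg_a <- sim_config(n_tips = 16, speciation_mode = "allopatric", drift_rate = 0,
                      grid = small_grid(), root_fraction = 0.5, seed = 5)
  ra <- simulate_ranges(tr, cfg_a)
  ta <- build_pair_table(sister_pairs(tr), ra$rasters)
  expect_equal(ta$overlap, rep(0, 8))
  expect_equal(ta$classification, rep("allopatric", 8))

  cfg_s <- sim_config(n_tips = 16, speciation_mode = "sympatric", drift_rate = 0,
                      grid = small_grid(), seed = 5)
  rs <- simulate_ranges(tr, cfg_s)
  ts <- build_pair_table(sister_pairs(tr), rs$rasters)
  expect_equal(ts$overlap, rep(1, 8))
  expect_equal(ts$symmetry, rep(0.5, 8))

  cfg_p <- sim_config(n_tips = 8, speciation_mode = "peripatric", drift_rate = 0,
                      peripheral_fraction = 0.1,
                      grid = grid_spec(0, 120, 0, 60, 0.5), root_fraction = 1,
                      seed = 6)
  trp <- balanced_tree(8)
  rp <- simulate_ranges(trp, cfg_p)
  tp <- build_pair_table(sister_pairs(trp), rp$rasters)
  # every ancestor kept >= 10 cells, so each bud is at most the target fraction
  expect_true(all(rp$truth$n_cells >= 10))
  expect_true(all(tp$symmetry <= 0.1 + 1e-9))
  expect_true(all(tp$overlap == 0))
})

test_that("range simulation respects the seed and never empties a range", {
  tr <- simulate_tree(12, 1, 0, seed = 7)
  cfg <- sim_config(n_tips = 12, drift_rate = 10, grid = small_grid(), seed = 8)
  r1 <- simulate_ranges(tr, cfg)
  r2 <- simulate_ranges(tr, cfg)
  expect_identical(lapply(r1$rasters, `[[`, "presence"),
                   lapply(r2$rasters, `[[`, "presence"))
  expect_true(all(vapply(r1$rasters, function(r) sum(r$presence), 0L) >= 1))
  expect_equal(nrow(r1$truth), tr$Nnode)
})

test_that("classification accuracy degrades with drift", {
  tr <- balanced_tree(32)
  acc <- vapply(c(0, 2, 5, 10, 20), function(dr) {
    cfg <- sim_config(n_tips = 32, speciation_mode = "mixed",
                      mode_probs = c(sympatric = 0.5, allopatric = 0.5, peripatric = 0),
                      drift_rate = dr, grid = small_grid(), root_fraction = 0.5,
                      seed = 11)
    rng <- simulate_ranges(tr, cfg)
    tb <- build_pair_table(sister_pairs(tr), rng$rasters)
    truth <- rng$truth$mode[match(sister_pairs(tr)$node, rng$truth$node)]
    mean(tb$classification == ifelse(truth == "sympatric", "sympatric", "allopatric"))
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_lt(unname(coef(stats::lm(acc ~ c(0, 2, 5, 10, 20)))[2]), 0)
})

test_that("Brownian traits have the covariance the tree implies", {
  chry <- read_timetree(text = "(A:2,B:2);")
  diffs <- vapply(1:8000, function(i) {
    v <- simulate_bm(chry, sigma2 = 1.5, seed = i)
    v[["A"]] - v[["B"]]
  }, numeric(1))
  expect_lt(abs(var(diffs) - 2 * 1.5 * 2) / (2 * 1.5 * 2), 0.05)

  tr <- balanced_tree(16)
  expect_identical(simulate_bm(tr, 1, 3, seed = 5), simulate_bm(tr, 1, 3, seed = 5))
  expect_equal(unname(simulate_bm(tr, 0, 7, seed = 5)), rep(7, 16))
})

test_that("binary traits follow the two-state Markov process", {
  tr <- balanced_tree(16)
  expect_equal(unname(simulate_binary(tr, 0, 0, root_state = 1, seed = 1)),
               rep(1L, 16))

  # no-change probability on a single branch is exp(-q t)
  star <- ape::stree(2000, "star")
  star$edge.length <- rep(3, nrow(star$edge))
  st <- simulate_binary(star, q01 = 0.4, q10 = 0, root_state = 0, seed = 2)
  p_nochange <- mean(st == 0)
  expect_lt(abs(p_nochange - exp(-0.4 * 3)), 3 * sqrt(0.3 * 0.7 / 2000) + 0.02)

  # symmetric rates on long branches approach the 50/50 stationary state
  star$edge.length <- rep(100, nrow(star$edge))
  st2 <- simulate_binary(star, 0.5, 0.5, seed = 3)
  expect_lt(abs(mean(st2) - 0.5), 3 * sqrt(0.25 / 2000) + 0.02)
})

test_that("full scenarios are reproducible and label every internal node", {
  cfg <- sim_config(n_tips = 16, grid = small_grid(), seed = 12)
  sc <- make_scenario(cfg)
  expect_setequal(sc$tree$tip.label, names(sc$rasters))
  expect_setequal(sc$tree$tip.label, sc$traits$species)
  expect_equal(nrow(sc$truth), sc$tree$Nnode)
  sc2 <- make_scenario(cfg)
  expect_identical(sc$traits, sc2$traits)
  expect_identical(lapply(sc$rasters, `[[`, "presence"),
                   lapply(sc2$rasters, `[[`, "presence"))
})

test_that("mixed scenarios recover planted mode proportions", {
  tr <- cherry_scaffold(40)
  cfg <- sim_config(n_tips = 80, speciation_mode = "mixed",
                    mode_probs = c(sympatric = 0.7, allopatric = 0.3, peripatric = 0),
                    drift_rate = 0, grid = grid_spec(-180, 180, -60, 60, 1),
                    seed = 13)
  rng <- simulate_ranges(tr, cfg)
  pairs <- sister_pairs(tr)
  expect_equal(nrow(pairs), 40)
  tb <- build_pair_table(pairs, rng$rasters)
  truth <- rng$truth$mode[match(pairs$node, rng$truth$node)]
  expect_equal(tb$classification,
               ifelse(truth == "sympatric", "sympatric", "allopatric"))
  prop <- mean(tb$classification == "sympatric")
  expect_lt(abs(prop - 0.7), 3 * sqrt(0.7 * 0.3 / 40))
})

test_that("scenario directories round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_tips = 8, grid = grid_spec(0, 30, 0, 15, 1), seed = 14)
  sc <- make_scenario(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "tree.nwk")))
  tr <- read_timetree(file.path(dir, "tree.nwk"), tol = 1e-4)
  expect_setequal(tr$tip.label, sc$tree$tip.label)
  gfile <- file.path(dir, "grids", paste0(sc$tree$tip.label[1], ".csv"))
  back <- read_grid_csv(gfile, logical_values = TRUE)
  expect_equal(back$matrix, sc$rasters[[sc$tree$tip.label[1]]]$presence)
  cfg_back <- sympatree:::read_flat_config(file.path(dir, "config.txt"))
  expect_equal(cfg_back$seed, 14)
  expect_equal(cfg_back$n_tips, 8)
})

test_that("simulated Brownian traits calibrate Blomberg's K near 1", {
  set.seed(15)
  ks <- replicate(60, {
    tr <- simulate_tree(32, 1, 0, seed = sample.int(1e7, 1))
    x <- simulate_bm(tr, 1, seed = sample.int(1e7, 1))
    blomberg_k(tr, x, n_perm = 9, seed = 1)$statistic
  })
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
})
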