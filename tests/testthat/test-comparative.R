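make_traits <- function(species, length_cm = NULL, depth_m = NULL,
                        habitat = NULL, piscivory = NULL) {
  tibble::tibble(
    species = species,
    max_length_cm = length_cm %||% rep(NA_real_, length(species)),
    max_depth_m = depth_m %||% rep(NA_real_, length(species)),
    habitat = habitat %||% rep(NA_character_, length(species)),
    piscivory = piscivory %||% rep(NA_integer_, length(species))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pair table reproduces hand-computed indices on a 6-tip scenario", {
  tr <- read_timetree(text = "(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,(E:2,F:2):1);")
  g <- grid_spec(0, 12, 40, 41, 1)  # single latitude band: equal cell areas
  idx <- function(cols) cols  # n_lat = 1 so linear index = column
  rasters <- list(
    make_raster(g, idx(1:4), "A"),   # 4 cells
    make_raster(g, idx(3:4), "B"),   # 2 cells, 2 shared -> O = 1
    make_raster(g, idx(5:8), "C"),   # 4 cells
    make_raster(g, idx(7:10), "D"),  # 4 cells, 2 shared -> O = 0.5
    make_raster(g, idx(11:12), "E"), # disjoint pair
    make_raster(g, idx(1:2), "F")
  )
  traits <- make_traits(LETTERS[1:6],
                        length_cm = c(10, 30, 50, 50, 20, 80),
                        depth_m = c(100, 150, 200, 260, NA, 40),
                        habitat = c("reef", "reef", "reef", "nonreef", "nonreef", "nonreef"))
  tb <- build_pair_table(sister_pairs(tr), rasters, traits)
  ab <- tb[tb$species_a == "A", ]
  expect_equal(ab$overlap, 1)
  expect_equal(ab$symmetry, 2 / 6)
  expect_equal(ab$classification, "sympatric")
  expect_equal(ab$contrast_length, 20)
  expect_equal(ab$habitat_combo, "same-reef")
  cd <- tb[tb$species_a == "C", ]
  expect_equal(cd$overlap, 0.5)
  expect_equal(cd$symmetry, 0.5)
  expect_equal(cd$habitat_combo, "mixed")
  ef <- tb[tb$species_a == "E", ]
  expect_equal(ef$overlap, 0)
  expect_equal(ef$classification, "allopatric")
  expect_true(is.na(ef$contrast_depth))
  expect_equal(ef$habitat_combo, "same-nonreef")
})

test_that("pairs without range data are excluded with a logged reason", {
  tr <- read_timetree(text = "((A:1,B:1):1,(C:2,(D:1,E:1):1):0);")
  g <- grid_spec(0, 10, 0, 10, 1)
  rasters <- list(make_raster(g, 1:5, "D"), make_raster(g, 3:8, "E"))
  expect_message(
    tb <- build_pair_table(sister_pairs(tr), rasters),
    "excluded: no range"
  )
  ab <- tb[tb$species_a == "A", ]
  expect_equal(ab$excluded_reason, "no_range")
  expect_true(is.na(ab$overlap))
  de <- tb[tb$species_a == "D", ]
  expect_true(is.na(de$excluded_reason))
  expect_gt(de$overlap, 0)
})

test_that("identical ranges and traits give the degenerate record", {
  tr <- read_timetree(text = "(A:1,B:1);")
  g <- grid_spec(0, 10, 0, 10, 1)
  rasters <- list(make_raster(g, 1:10, "A"), make_raster(g, 1:10, "B"))
  traits <- make_traits(c("A", "B"), length_cm = c(30, 30), depth_m = c(50, 50))
  tb <- build_pair_table(sister_pairs(tr), rasters, traits)
  expect_equal(tb$overlap, 1)
  expect_equal(tb$symmetry, 0.5)
  expect_equal(tb$contrast_length, 0)
  expect_equal(tb$contrast_depth, 0)
})

test_that("age-range regression matches lm and is shift-equivariant", {
  tb <- tibble::tibble(node_age = c(1, 2, 3, 4, 6), overlap = c(0.1, 0.3, 0.2, 0.6, 0.9))
  r <- arc_regression(tb, "node_age", "overlap")
  ref <- stats::lm(overlap ~ node_age, tb)
  expect_equal(r$slope, unname(coef(ref)[2]))
  expect_equal(r$p_value, summary(ref)$coefficients[2, 4])
  expect_equal(r$r^2, r$r_squared)

  shifted <- dplyr::mutate(tb, overlap = overlap + 5)
  r2 <- arc_regression(shifted, "node_age", "overlap")
  expect_equal(r2$slope, r$slope)
  expect_equal(r2$r, r$r)
  expect_equal(r2$intercept, r$intercept + 5)

  const <- tibble::tibble(node_age = 1:5, overlap = rep(0.4, 5))
  rc <- arc_regression(const, "node_age", "overlap")
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)

  exact <- tibble::tibble(node_age = 1:6, overlap = 2 * (1:6))
  re <- arc_regression(exact, "node_age", "overlap")
  expect_equal(re$r, 1)
  expect_lt(re$p_value, 1e-10)

  expect_error(arc_regression(tb[1:2, ], "node_age", "overlap"), "at least 3")
})

test_that("age-range regression recovers a planted slope", {
  set.seed(90)
  hits <- replicate(200, {
    age <- runif(40, 0, 18)
    y <- 0.02 * age + rnorm(40, 0, 0.1)
    r <- arc_regression(tibble::tibble(node_age = age, overlap = y))
    se <- summary(r$fit)$coefficients[2, 2]
    abs(r$slope - 0.02) <= 2 * se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Welch's t matches the textbook formula", {
  r <- welch_t(c(1, 2, 3), c(2, 4, 6))
  t_manual <- (2 - 4) / sqrt(1 / 3 + 4 / 3)
  df_manual <- (1 / 3 + 4 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2)
  expect_equal(r$t_statistic, t_manual, tolerance = 1e-12)
  expect_equal(r$df, df_manual, tolerance = 1e-12)

  set.seed(91)
  for (i in 1:200) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 1)
    got <- welch_t(a, b)
    tt <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
    dd <- (var(a) / length(a) + var(b) / length(b))^2 /
      ((var(a) / length(a))^2 / (length(a) - 1) + (var(b) / length(b))^2 / (length(b) - 1))
    expect_equal(got$t_statistic, tt, tolerance = 1e-12)
    expect_equal(got$df, dd, tolerance = 1e-12)
    expect_lte(got$df, length(a) + length(b) - 2)
    swapped <- welch_t(b, a)
    expect_equal(swapped$t_statistic, -got$t_statistic, tolerance = 1e-12)
    expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
  }
  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(c(1), c(1, 2)), ">= 2")
})

test_that("summaries reproduce planted class proportions and medians", {
  tb <- tibble::tibble(
    node_age = rep(c(1, 3), c(28, 12)),
    symmetry = rep(c(0.4, 0.2), c(28, 12)),
    overlap = rep(c(0.9, 0.01), c(28, 12)),
    classification = rep(c("sympatric", "allopatric"), c(28, 12)),
    contrast_depth = c(rep(10, 27), NA, rep(5, 12))
  )
  s <- summarize_pairs(tb)
  expect_equal(sum(s$proportion), 1)
  expect_equal(s$proportion[s$classification == "sympatric"], 0.7)
  expect_equal(s$n[s$classification == "allopatric"], 12L)
  expect_equal(s$median_symmetry, c(0.2, 0.4))

  s2 <- summarize_pairs(tb, drop_depth_missing = TRUE)
  expect_equal(s2$n[s2$classification == "sympatric"], 27L)

  tri <- tibble::tibble(node_age = 1:3, symmetry = c(0.1, 0.2, 0.3),
                        overlap = c(1, 1, 1), classification = rep("sympatric", 3),
                        contrast_depth = 1:3)
  expect_equal(summarize_pairs(tri)$median_symmetry, 0.2)
})

test_that("excluded pairs never enter summaries or tests", {
  tb <- tibble::tibble(
    node_age = 1:4, symmetry = c(0.3, 0.3, NA, 0.4), overlap = c(1, 0, NA, 1),
    classification = c("sympatric", "allopatric", NA, "sympatric"),
    contrast_depth = c(1, 2, 3, 4), excluded_reason = c(NA, NA, "no_range", NA)
  )
  s <- summarize_pairs(tb)
  expect_equal(sum(s$n), 3L)
})

test_that("habitat-stratified test detects planted effects at the right rate", {
  strat_table <- function(same, mixed) {
    tibble::tibble(
      classification = "sympatric",
      habitat_combo = rep(c("same-reef", "mixed"), c(length(same), length(mixed))),
      contrast_depth = c(same, mixed),
      contrast_length = NA_real_
    )
  }
  set.seed(92)
  power <- replicate(200, {
    t <- strat_table(rnorm(15, 50, 5), rnorm(15, 10, 5))
    habitat_stratified_test(t, "depth")$p_value < 0.01
  })
  expect_gte(mean(power), 0.95)

  type1 <- replicate(200, {
    t <- strat_table(rnorm(15, 20, 5), rnorm(15, 20, 5))
    habitat_stratified_test(t, "depth")$p_value < 0.05
  })
  expect_lt(abs(mean(type1) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))

  all_same <- strat_table(rnorm(10, 20, 5), numeric(0))
  expect_error(habitat_stratified_test(all_same, "depth"), "mixed-habitat")
})

test_that("tidy and glance methods return the documented columns", {
  tb <- tibble::tibble(node_age = c(1, 2, 3, 5), overlap = c(0.1, 0.4, 0.2, 0.8))
  r <- arc_regression(tb)
  expect_named(tidy(r), c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(glance(r)$nobs, 4L)

  w <- welch_t(c(1, 2, 3), c(4, 5, 7))
  expect_equal(tidy(w)$statistic, w$t_statistic)
  expect_equal(glance(w)$n_a, 3L)

  tr <- balanced_tree(8)
  k <- blomberg_k(tr, setNames(rnorm(8), tr$tip.label), n_perm = 49, seed = 1)
  expect_equal(tidy(k)$statistic, rep(k$statistic, 1))
  expect_equal(glance(k)$statistic_name, "K")
})
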