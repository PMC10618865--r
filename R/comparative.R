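#' Assemble the per-pair analysis table
#'
#' Joins sister pairs with range rasters and trait data into one record per
#' pair: overlap O, symmetry S, the sympatry/allopatry classification, and
#' trait contrasts (absolute differences between the two species, since sign
#' has no meaning for an unordered pair). Pairs for which either species lacks
#' range data are retained with `excluded_reason = "no_range"` and NA indices;
#' a pair missing a trait value loses only that trait's contrast. All
#' exclusions are reported via `message()`, never silent.
#'
#' @param pairs tibble from [sister_pairs()].
#' @param rasters named list of `range_raster` objects (names = species).
#' @param traits data frame with columns `species`, `max_length_cm`,
#'   `max_depth_m`, `habitat` (`"reef"`/`"nonreef"`), `piscivory` (0/1);
#'   any trait column may be absent or contain NAs.
#' @param threshold overlap threshold for [classify_overlap()].
#' @return a tibble with columns `species_a`, `species_b`, `node_age`,
#'   `direct`, `area_a`, `area_b`, `intersection_area`, `overlap`, `symmetry`,
#'   `classification`, `contrast_length`, `contrast_depth`, `habitat_combo`
#'   (`"same-reef"`, `"same-nonreef"`, `"mixed"`), `excluded_reason`.
#' @export
build_pair_table <- function(pairs, rasters, traits = NULL, threshold = 0.05) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  nm <- vapply(rasters, function(r) r$species, character(1))
  names(rasters) <- nm

  trait_of <- function(sp, col) {
    if (is.null(traits) || !col %in% names(traits)) return(NA_real_)
    v <- traits[[col]][match(sp, traits$species)]
    if (length(v) == 0) NA else v
  }

  recs <- purrr::pmap_dfr(
    pairs[, c("species_a", "species_b", "node_age", "direct")],
    function(species_a, species_b, node_age, direct) {
      rec <- tibble::tibble(
        species_a = species_a, species_b = species_b,
        node_age = node_age, direct = direct,
        area_a = NA_real_, area_b = NA_real_, intersection_area = NA_real_,
        overlap = NA_real_, symmetry = NA_real_,
        classification = NA_character_,
        contrast_length = NA_real_, contrast_depth = NA_real_,
        habitat_combo = NA_character_, excluded_reason = NA_character_
      )
      a <- rasters[[species_a]]
      b <- rasters[[species_b]]
      if (is.null(a) || is.null(b) || !any(a$presence) || !any(b$presence)) {
        rec$excluded_reason <- "no_range"
      } else {
        ca <- cell_areas(a$grid)
        rec$area_a <- sum(ca[a$presence])
        rec$area_b <- sum(ca[b$presence])
        rec$intersection_area <- sum(ca[a$presence & b$presence])
        rec$overlap <- rec$intersection_area / min(rec$area_a, rec$area_b)
        rec$symmetry <- min(rec$area_a, rec$area_b) / (rec$area_a + rec$area_b)
        rec$classification <- classify_overlap(rec$overlap, threshold)
      }
      la <- trait_of(species_a, "max_length_cm"); lb <- trait_of(species_b, "max_length_cm")
      da <- trait_of(species_a, "max_depth_m"); db <- trait_of(species_b, "max_depth_m")
      rec$contrast_length <- abs(la - lb)
      rec$contrast_depth <- abs(da - db)
      if (!is.null(traits) && "habitat" %in% names(traits)) {
        ha <- traits$habitat[match(species_a, traits$species)]
        hb <- traits$habitat[match(species_b, traits$species)]
        rec$habitat_combo <- dplyr::case_when(
          is.na(ha) | is.na(hb) ~ NA_character_,
          ha == "reef" & hb == "reef" ~ "same-reef",
          ha != hb ~ "mixed",
          TRUE ~ "same-nonreef"
        )
      }
      rec
    }
  )

  n_norange <- sum(!is.na(recs$excluded_reason) & recs$excluded_reason == "no_range")
  if (n_norange > 0) {
    message(n_norange, " pair(s) excluded: no range data")
  }
  n_nodepth <- sum(is.na(recs$contrast_depth))
  if (!is.null(traits) && n_nodepth > 0) {
    message(n_nodepth, " pair(s) lack a depth contrast (missing max_depth_m)")
  }
  recs
}

#' Age-range correlation regression
#'
#' Ordinary least squares of a range index (overlap or symmetry) on sister
#' pair node age, over pairs with range data. Under allopatric speciation
#' with independent range drift, overlap should increase with node age; under
#' sympatric speciation young pairs should already overlap. Both r and r^2
#' are reported.
#'
#' @param table pair table from [build_pair_table()] (or any data frame with
#'   the two columns).
#' @param x,y column names for predictor and response.
#' @return an `arc_regression` object (slope, intercept, r, r_squared,
#'   p_value, n, and the underlying `lm` fit).
#' @export
arc_regression <- function(table, x = "node_age", y = c("overlap", "symmetry")) {
  y <- if (length(y) > 1) y[1] else y
  dat <- tibble::tibble(x = table[[x]], y = table[[y]])
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 3) stop("need at least 3 pairs with data", call. = FALSE)
  fit <- stats::lm(y ~ x, data = dat)
  # degenerate inputs (constant or exactly collinear y) are legitimate here;
  # lm's perfect-fit warning is expected noise for them
  sm <- suppressWarnings(summary(fit))
  r <- suppressWarnings(cor(dat$x, dat$y))
  if (is.na(r)) r <- 0  # constant response
  structure(
    list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
         r = r, r_squared = r^2,
         p_value = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_,
         n = nrow(dat), x = x, y = y, fit = fit, data = dat),
    class = "arc_regression"
  )
}

#' @export
print.arc_regression <- function(x, ...) {
  cat(sprintf("<arc_regression> %s ~ %s: slope = %.4g, r = %.4g, r^2 = %.4g, p = %.4g, n = %d\n",
              x$y, x$x, x$slope, x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test,
#' \eqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}, with
#' Welch-Satterthwaite (fractional) degrees of freedom and a two-tailed p.
#'
#' @param a,b numeric vectors (each >= 2 values with nonzero variance).
#' @return a `welch_result` object.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) stop("both groups have zero variance", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(
    list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b)),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.4f, df = %.4f, p = %.4g (n = %d, %d)\n",
              x$t_statistic, x$df, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Summarize the pair table by sympatry class
#'
#' Counts and proportions of sympatric vs allopatric pairs, plus per-class
#' medians of node age and range symmetry, over pairs with range data.
#'
#' @param table pair table from [build_pair_table()].
#' @param drop_depth_missing also exclude pairs lacking a depth contrast
#'   before computing medians (the two variants can differ when trait
#'   coverage is incomplete; both are reported by [run_pipeline()]).
#' @return a tibble with one row per classification: `classification`, `n`,
#'   `proportion`, `median_node_age`, `median_symmetry`.
#' @export
summarize_pairs <- function(table, drop_depth_missing = FALSE) {
  dat <- dplyr::filter(table, !is.na(.data$classification))
  if (drop_depth_missing) dat <- dplyr::filter(dat, !is.na(.data$contrast_depth))
  if (nrow(dat) == 0) stop("no classified pairs to summarize", call. = FALSE)
  dat |>
    dplyr::group_by(.data$classification) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_node_age = stats::median(.data$node_age),
      median_symmetry = stats::median(.data$symmetry),
      .groups = "drop"
    ) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n), .after = "n")
}

#' Habitat cross-tabulation of pairs
#'
#' @param table pair table from [build_pair_table()].
#' @return tibble of counts and within-class proportions by `classification`
#'   and `habitat_combo`.
#' @export
habitat_crosstab <- function(table) {
  dat <- dplyr::filter(table, !is.na(.data$classification), !is.na(.data$habitat_combo))
  dat |>
    dplyr::count(.data$classification, .data$habitat_combo) |>
    dplyr::group_by(.data$classification) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Trait contrasts between habitat strata of sympatric pairs
#'
#' Welch's t-test of a trait contrast between sympatric pairs whose members
#' share a habitat type (reef-reef or nonreef-nonreef) and sympatric pairs of
#' mixed habitat. Larger contrasts in same-habitat pairs are consistent with
#' niche partitioning along the tested axis.
#'
#' @param table pair table from [build_pair_table()].
#' @param trait which contrast to test: `"depth"` or `"length"`.
#' @return a `welch_result` (group a = same habitat, group b = mixed).
#' @export
habitat_stratified_test <- function(table, trait = c("depth", "length")) {
  trait <- match.arg(trait)
  col <- if (trait == "depth") "contrast_depth" else "contrast_length"
  dat <- dplyr::filter(table, .data$classification == "sympatric",
                       !is.na(.data$habitat_combo), !is.na(.data[[col]]))
  same <- dat[[col]][dat$habitat_combo %in% c("same-reef", "same-nonreef")]
  mixed <- dat[[col]][dat$habitat_combo == "mixed"]
  if (length(same) < 2) stop("empty or degenerate stratum: same-habitat", call. = FALSE)
  if (length(mixed) < 2) stop("empty or degenerate stratum: mixed-habitat", call. = FALSE)
  welch_t(same, mixed)
}
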