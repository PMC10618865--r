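#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an age-range correlation fit
#'
#' @param x an `arc_regression` object.
#' @param ... ignored.
#' @return one row per model term with estimate, std.error, statistic,
#'   p.value.
#' @export
tidy.arc_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", x$x),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidy.arc_regression
#' @export
glance.arc_regression <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r_squared, slope = x$slope,
                 p.value = x$p_value, nobs = x$n)
}

#' Tidy a Welch t-test result
#'
#' @param x a `welch_result`.
#' @param ... ignored.
#' @export
tidy.welch_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_a - x$mean_b, estimate1 = x$mean_a, estimate2 = x$mean_b,
    statistic = x$t_statistic, parameter = x$df, p.value = x$p_value,
    method = "Welch two-sample t-test"
  )
}

#' @rdname tidy.welch_result
#' @export
glance.welch_result <- function(x, ...) {
  tibble::tibble(statistic = x$t_statistic, parameter = x$df,
                 p.value = x$p_value, n_a = x$n_a, n_b = x$n_b)
}

#' Tidy a phylogenetic-signal result
#'
#' @param x a `signal_result` (from [blomberg_k()], [fritz_d()] or
#'   [phylo_mantel()]).
#' @param ... ignored.
#' @return one row per p-value with the statistic repeated.
#' @export
tidy.signal_result <- function(x, ...) {
  tibble::tibble(
    statistic_name = x$statistic_name, statistic = x$statistic,
    p_name = names(x$p_values), p.value = unlist(x$p_values, use.names = FALSE),
    n = x$n, n_perm = x$n_perm, seed = x$seed
  )
}

#' @rdname tidy.signal_result
#' @export
glance.signal_result <- function(x, ...) {
  tibble::tibble(statistic_name = x$statistic_name, statistic = x$statistic,
                 p.value = x$p_values[[1]], n = x$n, n_perm = x$n_perm)
}

#' Tidy a PGLS-OU fit
#'
#' @param x a `pgls_ou` object.
#' @param ... ignored.
#' @export
tidy.pgls_ou <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope),
    statistic = c(NA_real_, x$t_statistic),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname tidy.pgls_ou
#' @export
glance.pgls_ou <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, logLik = x$loglik, nobs = x$n,
                 p.value = x$p_value)
}

#' Write a set of signal results to CSV
#'
#' @param results named list of `signal_result` objects.
#' @param file output path.
#' @export
write_signal_csv <- function(results, file) {
  rows <- purrr::imap_dfr(results, function(r, nm) {
    dplyr::mutate(tidy(r), test = nm, .before = 1)
  })
  readr::write_csv(rows, file)
  invisible(file)
}
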