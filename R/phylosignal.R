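#' @importFrom stats cor lm.fit optimize pt rnorm runif sd setNames var
NULL

# accept a named vector or a two-column data frame (species, value) and
# return a vector aligned to the tree's tips; errors list missing species
align_trait <- function(tree, x, what = "trait") {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    x <- setNames(x[[2]], x[[1]])
  }
  if (is.null(names(x))) stop(what, " must be named by species", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing) > 0) {
    stop(what, " missing for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[tree$tip.label]
}

new_signal_result <- function(statistic_name, statistic, p_values, n_perm,
                              seed, n, extra = list()) {
  structure(
    c(list(statistic_name = statistic_name, statistic = statistic,
           p_values = p_values, n_perm = n_perm, seed = seed, n = n), extra),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("<signal_result> %s = %.4g (n = %d, %d permutations/simulations)\n",
              x$statistic_name, x$statistic, x$n, x$n_perm))
  for (nm in names(x$p_values)) cat(sprintf("  %s = %.4g\n", nm, x$p_values[[nm]]))
  invisible(x)
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts by the pruning recursion (each raw contrast divided
#' by its expected standard deviation); thin wrapper that validates coverage
#' of the tip set before delegating to [ape::pic()].
#'
#' @param tree a binary `phylo` object.
#' @param x named numeric vector (or species/value data frame) covering all
#'   tips.
#' @return numeric vector of n - 1 standardized contrasts.
#' @export
phylo_pic <- function(tree, x) {
  x <- align_trait(tree, x)
  if (!ape::is.binary(tree)) stop("tree must be binary for contrasts", call. = FALSE)
  ape::pic(x, tree)
}

#' Blomberg's K for a continuous trait
#'
#' K compares the observed ratio of tip variance to phylogenetically
#' corrected variance against its Brownian-motion expectation:
#' \deqn{K = \frac{MSE_0 / MSE}{(\mathrm{tr}\,V - n / \mathbf{1}'V^{-1}\mathbf{1}) / (n-1)}}
#' where \eqn{V} is the tree's covariance matrix, \eqn{MSE_0} the mean squared
#' deviation of tips from the phylogenetically weighted mean and \eqn{MSE} the
#' GLS mean squared error. K = 1 is the Brownian expectation; K < 1 means less
#' similarity among relatives than Brownian motion predicts.
#'
#' Significance is assessed by permuting trait values across tips: the
#' observed variance of independent contrasts is compared to the permuted
#' distribution, one-tailed toward low contrast variance (signal = less
#' variance among contrasts than permuted data), with the observed value
#' included in both numerator and denominator so p > 0 always.
#'
#' @param tree an ultrametric binary `phylo` (>= 4 tips).
#' @param x named numeric trait (or species/value data frame).
#' @param n_perm number of tip-label permutations.
#' @param seed integer seed for the permutations.
#' @return a `signal_result` with `statistic` = K and `p_values$p`.
#' @export
blomberg_k <- function(tree, x, n_perm = 1000, seed = 1L) {
  x <- align_trait(tree, x)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips", call. = FALSE)
  if (var(x) == 0) stop("trait has zero variance; K undefined", call. = FALSE)

  V <- ape::vcv(tree)
  Vinv <- solve(V)
  one <- rep(1, n)
  ahat <- sum(Vinv %*% x) / sum(Vinv)
  dev <- x - ahat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- drop(t(dev) %*% Vinv %*% dev) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vinv)) / (n - 1)
  k <- (mse0 / mse) / expected

  btree <- if (ape::is.binary(tree)) tree else ape::multi2di(tree)
  obs_stat <- mean(ape::pic(x, btree)^2)
  perm_stat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    xp <- setNames(sample(x), names(x))
    mean(ape::pic(xp, btree)^2)
  }, numeric(1)))
  p <- (1 + sum(perm_stat <= obs_stat)) / (1 + n_perm)

  new_signal_result("K", k, list(p = p), n_perm, seed, n,
                    extra = list(mse0 = mse0, mse = mse))
}

# sum over internal nodes of the absolute difference between the two
# child-clade estimates, with nodal estimates by the unweighted
# average-of-children recursion (binary trees)
sister_clade_d <- function(tree_post, tip_values) {
  n_tip <- length(tree_post$tip.label)
  n_all <- n_tip + tree_post$Nnode
  val <- numeric(n_all)
  val[seq_len(n_tip)] <- tip_values
  parent <- tree_post$edge[, 1]
  child <- tree_post$edge[, 2]
  d <- 0
  # postorder: children are finalized before their parent appears as child
  for (e in seq.int(1, length(parent), by = 2)) {
    p <- parent[e]
    c1 <- child[e]
    c2 <- child[e + 1]
    val[p] <- (val[c1] + val[c2]) / 2
    d <- d + abs(val[c1] - val[c2])
  }
  d
}

# tip values of one or more Brownian simulations (unit rate, root 0),
# columns = replicates
bm_tips <- function(tree, n_sim) {
  pre <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  val <- matrix(0, n_all, n_sim)
  incr <- matrix(rnorm(nrow(pre$edge) * n_sim), nrow(pre$edge), n_sim) *
    sqrt(pre$edge.length)
  for (e in seq_len(nrow(pre$edge))) {
    val[pre$edge[e, 2], ] <- val[pre$edge[e, 1], ] + incr[e, ]
  }
  val[seq_len(n_tip), , drop = FALSE]
}

#' Fritz's D for a binary trait
#'
#' Measures phylogenetic dispersion of a two-state character. The observed
#' sum of sister-clade differences \eqn{d_{obs}} (nodal values by the
#' average-of-children recursion) is scaled between its expectation under a
#' random shuffle of tip states (D = 1) and under Brownian motion thresholded
#' at the observed prevalence (D = 0):
#' \deqn{D = (d_{obs} - \bar d_{BM}) / (\bar d_{random} - \bar d_{BM})}
#' D < 0 indicates stronger clumping than Brownian motion, D > 1
#' overdispersion. Two simulation-tail probabilities are returned:
#' `p_d_gt_0`, the probability of a \eqn{d} as large as observed under the
#' Brownian model (small = D significantly above 0), and `p_d_lt_1`, the
#' probability of a \eqn{d} as small as observed under the random model
#' (small = D significantly below 1).
#'
#' @param tree a binary `phylo` (>= 4 tips).
#' @param x binary (0/1) named trait with both states present.
#' @param n_sim number of permutations and Brownian simulations.
#' @param seed integer seed.
#' @return a `signal_result` with `statistic` = D and `p_values$p_d_gt_0`,
#'   `p_values$p_d_lt_1`.
#' @export
fritz_d <- function(tree, x, n_sim = 1000, seed = 1L) {
  x <- align_trait(tree, x)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1", call. = FALSE)
  k1 <- sum(x == 1)
  if (k1 == 0 || k1 == n) stop("trait is monomorphic; D undefined", call. = FALSE)
  if (!ape::is.binary(tree)) stop("tree must be binary", call. = FALSE)

  post <- ape::reorder.phylo(tree, "postorder")
  d_obs <- sister_clade_d(post, x)

  sims <- with_seed(seed, {
    d_rand <- vapply(seq_len(n_sim), function(i) sister_clade_d(post, sample(x)),
                     numeric(1))
    tips <- bm_tips(tree, n_sim)
    d_bm <- vapply(seq_len(n_sim), function(i) {
      z <- tips[, i]
      st <- as.numeric(rank(-z, ties.method = "random") <= k1)
      sister_clade_d(post, st)
    }, numeric(1))
    list(d_rand = d_rand, d_bm = d_bm)
  })
  d_rand <- sims$d_rand
  d_bm <- sims$d_bm

  D <- (d_obs - mean(d_bm)) / (mean(d_rand) - mean(d_bm))
  p_gt0 <- (1 + sum(d_bm >= d_obs)) / (1 + n_sim)
  p_lt1 <- (1 + sum(d_rand <= d_obs)) / (1 + n_sim)
  new_signal_result("D", D, list(p_d_gt_0 = p_gt0, p_d_lt_1 = p_lt1),
                    n_sim, seed, n,
                    extra = list(d_obs = d_obs, d_bm_mean = mean(d_bm),
                                 d_random_mean = mean(d_rand)))
}

# restricted log-likelihood of the GLS fit y ~ X under correlation V
# (constants dropped); returns fit components for reuse
reml_fit <- function(y, X, V) {
  n <- nrow(X)
  p <- ncol(X)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(rll = -Inf))
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- drop(crossprod(r, Vi_r)) / (n - p)
  rll <- -0.5 * ((n - p) * log(max(s2, .Machine$double.xmin)) + logdetV +
                   determinant(XtViX, logarithm = TRUE)$modulus)
  list(rll = as.numeric(rll), beta = beta, s2 = s2, XtViX = XtViX)
}

#' Phylogenetic GLS regression with an Ornstein-Uhlenbeck error model
#'
#' Fits y ~ x by generalized least squares with error correlation
#' \eqn{V_{ij} = \exp(-\alpha d_{ij})}, where \eqn{d_{ij}} is the patristic
#' distance between tips. The decay rate \eqn{\alpha} is estimated by
#' maximizing the restricted likelihood over 50 log-spaced values spanning
#' `[1e-4, 1e2] / tree height`, followed by derivative-free local refinement;
#' as \eqn{\alpha \to \infty} the fit converges to ordinary least squares.
#'
#' @param tree a `phylo` object.
#' @param y,x named numeric traits (or species/value data frames).
#' @param alpha optional fixed decay rate; `NULL` (default) estimates it.
#' @return a `pgls_ou` object with elements `slope`, `intercept`,
#'   `t_statistic`, `p_value` (two-tailed, df = n - 2), `alpha`, `loglik`,
#'   `n`, and the profile `grid`.
#' @export
pgls_ou <- function(tree, y, x, alpha = NULL) {
  y <- align_trait(tree, y, "y")
  x <- align_trait(tree, x, "x")
  n <- length(y)
  if (sd(x) == 0) stop("design is singular: x has zero variance", call. = FALSE)
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  h <- max(ape::node.depth.edgelength(tree))
  X <- cbind(intercept = 1, slope = x)

  fit_at <- function(a) reml_fit(y, X, exp(-a * D))

  if (is.null(alpha)) {
    grid_alpha <- exp(seq(log(1e-4), log(1e2), length.out = 50)) / h
    rll <- vapply(grid_alpha, function(a) fit_at(a)$rll, numeric(1))
    best <- which.max(rll)
    lo <- grid_alpha[max(1, best - 1)]
    hi <- grid_alpha[min(length(grid_alpha), best + 1)]
    opt <- optimize(function(la) fit_at(exp(la))$rll,
                    interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-8)
    alpha_hat <- exp(opt$maximum)
    if (fit_at(alpha_hat)$rll < rll[best]) alpha_hat <- grid_alpha[best]
    grid_tbl <- tibble::tibble(alpha = grid_alpha, rll = rll)
  } else {
    alpha_hat <- alpha
    grid_tbl <- tibble::tibble(alpha = numeric(), rll = numeric())
  }

  fit <- fit_at(alpha_hat)
  se <- sqrt(pmax(fit$s2, 0) * diag(solve(fit$XtViX)))
  tstat <- fit$beta[2] / se[2]
  structure(
    list(slope = unname(fit$beta[2]), intercept = unname(fit$beta[1]),
         se_slope = unname(se[2]), t_statistic = unname(tstat),
         p_value = 2 * pt(-abs(tstat), df = n - 2),
         alpha = alpha_hat, loglik = fit$rll, n = n, grid = grid_tbl),
    class = "pgls_ou"
  )
}

#' @export
print.pgls_ou <- function(x, ...) {
  cat(sprintf("<pgls_ou> slope = %.4g (t = %.3f, p = %.4g), alpha = %.4g, n = %d\n",
              x$slope, x$t_statistic, x$p_value, x$alpha, x$n))
  invisible(x)
}

check_dist_matrix <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(what, " must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop(what, " must be symmetric", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) stop(what, " must have zero diagonal", call. = FALSE)
  invisible(m)
}

# proximity-weighted permutation: labels are assigned preferring
# phylogenetically nearby positions (Lapointe-Garland style)
weighted_permutation <- function(Dphy, scale) {
  n <- nrow(Dphy)
  w <- exp(-Dphy / scale)
  perm <- integer(n)
  remaining <- seq_len(n)
  for (i in sample.int(n)) {
    pr <- w[i, remaining]
    j <- if (length(remaining) == 1) remaining else {
      remaining[sample.int(length(remaining), 1, prob = pr)]
    }
    perm[i] <- j
    remaining <- setdiff(remaining, j)
  }
  perm
}

#' (Partial) Mantel test with optional phylogenetically informed permutations
#'
#' Regresses the vectorized upper triangle of `dist_y` on that of `dist_x`
#' (both residualized on `dist_z` when given) and reports the squared
#' correlation R^2. Significance comes from simultaneous row/column
#' permutations of `dist_y`; p is the proportion of permutations with R^2 at
#' least as large as observed, with the observed included so p > 0. In
#' `mode = "phylo-weighted"` (requires `tree`) permuted labels are drawn with
#' probability decaying in patristic distance, concentrating exchanges among
#' close relatives.
#'
#' @param dist_y,dist_x square symmetric matrices, zero diagonal, same label
#'   order (checked via dimnames when present).
#' @param dist_z optional control matrix for the partial test.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tree optional `phylo` used by the weighted mode.
#' @param mode `"plain"` or `"phylo-weighted"`.
#' @return a `signal_result` with `statistic` = R^2 and `p_values$p`; the
#'   permutation mode is recorded in `$mode`.
#' @export
phylo_mantel <- function(dist_y, dist_x, dist_z = NULL, n_perm = 1000,
                         seed = 1L, tree = NULL,
                         mode = c("plain", "phylo-weighted")) {
  mode <- match.arg(mode)
  check_dist_matrix(dist_y, "dist_y")
  check_dist_matrix(dist_x, "dist_x")
  if (nrow(dist_y) != nrow(dist_x)) stop("matrix sizes differ", call. = FALSE)
  if (!is.null(dimnames(dist_y)) && !is.null(dimnames(dist_x)) &&
      !identical(rownames(dist_y), rownames(dist_x))) {
    stop("dist_y and dist_x labels do not match", call. = FALSE)
  }
  if (!is.null(dist_z)) {
    check_dist_matrix(dist_z, "dist_z")
    if (nrow(dist_z) != nrow(dist_y)) stop("matrix sizes differ", call. = FALSE)
  }
  n <- nrow(dist_y)
  ut <- upper.tri(dist_y)
  xv <- dist_x[ut]
  zv <- if (!is.null(dist_z)) dist_z[ut] else NULL
  residualize <- function(v) {
    if (is.null(zv)) v else lm.fit(cbind(1, zv), v)$residuals
  }
  xr <- residualize(xv)
  r2_of <- function(ym) {
    yr <- residualize(ym[ut])
    suppressWarnings(cor(yr, xr)^2)
  }
  r2_obs <- r2_of(dist_y)

  if (mode == "phylo-weighted" && is.null(tree)) {
    stop("phylo-weighted mode requires `tree`", call. = FALSE)
  }
  perms <- with_seed(seed, {
    if (mode == "phylo-weighted") {
      Dphy <- ape::cophenetic.phylo(tree)
      if (!is.null(rownames(dist_y))) Dphy <- Dphy[rownames(dist_y), rownames(dist_y)]
      scale <- mean(Dphy[upper.tri(Dphy)])
      replicate(n_perm, weighted_permutation(Dphy, scale), simplify = FALSE)
    } else {
      replicate(n_perm, sample.int(n), simplify = FALSE)
    }
  })
  r2_perm <- vapply(perms, function(p) r2_of(dist_y[p, p]), numeric(1))
  r2_perm[is.na(r2_perm)] <- 0
  p <- (1 + sum(r2_perm >= r2_obs)) / (1 + n_perm)
  new_signal_result("R2", r2_obs, list(p = p), n_perm, seed, n,
                    extra = list(mode = mode, partial = !is.null(dist_z)))
}
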