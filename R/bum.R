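#' Beta-uniform mixture log-likelihood
#'
#' Density `f(x | a, lambda) = lambda + (1 - lambda) * a * x^(a - 1)` on
#' `(0, 1]`: a uniform component of weight `lambda` (null p-values) plus
#' a decreasing Beta(a, 1) component capturing enrichment near zero.
#'
#' @param p_values p-values in `(0, 1]` (zero is rejected: the density
#'   diverges there when `a < 1`).
#' @param a beta shape in `(0, 1]`.
#' @param lam uniform mixing weight in `[0, 1]`.
#' @return the log-likelihood.
#' @export
bum_loglik <- function(p_values, a, lam) {
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (a <= 0 || a > 1) stop("'a' must be in (0, 1]")
  if (lam < 0 || lam > 1) stop("'lam' must be in [0, 1]")
  sum(log(lam + (1 - lam) * a * p_values^(a - 1)))
}

# vectorized over a grid; x validated by the caller
.bum_ll_grid <- function(x, a_grid, lam_grid) {
  xa <- outer(x, a_grid - 1, `^`)  # n x na: x^(a-1)
  ll <- matrix(0, length(a_grid), length(lam_grid))
  for (j in seq_along(lam_grid)) {
    lam <- lam_grid[j]
    dens <- lam + (1 - lam) * sweep(xa, 2, a_grid, `*`)
    ll[, j] <- colSums(log(dens))
  }
  ll
}

#' Fit the beta-uniform mixture to a group's empirical p-values
#'
#' Maximum likelihood over the constrained box `a` in (0,1], `lambda` in
#' \[0,1\], via a coarse grid followed by local refinement from the top
#' grid points (the likelihood surface has a boundary ridge at
#' `lambda -> 1`). The fitted mixture yields
#' `pi_ub = lambda_hat + (1 - lambda_hat) * a_hat`, an upper bound on
#' the fraction of p-values generated under the null; `1 - pi_ub` is a
#' conservative lower bound on the accelerated fraction.
#'
#' @param p_values empirical p-values in `(0, 1]`.
#' @param grid_n coarse grid resolution per axis (default 50).
#' @return object of class `bum_fit`: `lambda_hat`, `a_hat`, `loglik`,
#'   `pi_ub`, `prop_accel` (`1 - pi_ub`), `n`, `boundary`.
#' @export
fit_bum <- function(p_values, grid_n = 50) {
  x <- as.numeric(p_values)
  if (any(x <= 0) || any(x > 1)) stop("p-values must lie in (0, 1]")
  if (length(x) < 20)
    warning("fewer than 20 p-values; mixture fit will be unstable")
  if (length(unique(x)) == 1)
    warning("degenerate fit: all p-values identical")
  a_grid <- seq(0.02, 1, length.out = grid_n)
  lam_grid <- seq(0, 1, length.out = grid_n)
  ll <- .bum_ll_grid(x, a_grid, lam_grid)
  ord <- order(ll, decreasing = TRUE)[1:3]
  f <- function(par) -bum_loglik(x, par[1], par[2])
  best <- NULL
  for (k in ord) {
    i <- (k - 1) %% grid_n + 1
    j <- (k - 1) %/% grid_n + 1
    o <- tryCatch(
      optim(c(a_grid[i], lam_grid[j]), f, method = "L-BFGS-B",
            lower = c(1e-4, 0), upper = c(1, 1),
            control = list(factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  a_hat <- best$par[1]; lam_hat <- best$par[2]
  pi_ub <- lam_hat + (1 - lam_hat) * a_hat
  structure(list(lambda_hat = lam_hat, a_hat = a_hat,
                 loglik = -best$value, pi_ub = pi_ub,
                 prop_accel = 1 - pi_ub, n = length(x),
                 boundary = a_hat >= 1 - 1e-8 || lam_hat <= 1e-8 ||
                   lam_hat >= 1 - 1e-8),
            class = "bum_fit")
}

#' Profile-region confidence interval for the null upper bound
#'
#' Retains every `(a*, lambda*)` pair whose log-likelihood is within the
#' chi-square(2 df) quantile of the maximum,
#' `2 * (l(a_hat, lambda_hat) - l(a*, lambda*)) <= chisq_{2, 1-alpha}`
#' (5.991 at the 0.95 level), on a fine grid refined fourfold around the
#' retained region, and returns the range of
#' `pi_ub* = lambda* + (1 - lambda*) a*` over that set. The MLE pair is
#' always retained, so the interval contains `pi_ub`.
#'
#' @param p_values the p-values the fit was computed on.
#' @param fit the [fit_bum()] MLE on those p-values.
#' @param level confidence level (default 0.95).
#' @param grid_n initial grid resolution per axis (default 200).
#' @return numeric `c(lo, hi)`.
#' @export
bum_confidence_interval <- function(p_values, fit, level = 0.95,
                                    grid_n = 200) {
  x <- as.numeric(p_values)
  thr <- stats::qchisq(level, df = 2)
  pass1 <- .bum_ci_scan(x, fit$loglik, thr,
                        a_lo = 1e-4, a_hi = 1, l_lo = 0, l_hi = 1,
                        n = grid_n)
  if (is.null(pass1))
    stop("no grid point satisfied the profile region; use a finer grid")
  # refine fourfold inside the retained bounding box (one cell margin)
  step_a <- (1 - 1e-4) / (grid_n - 1)
  step_l <- 1 / (grid_n - 1)
  pass2 <- .bum_ci_scan(
    x, fit$loglik, thr,
    a_lo = max(1e-4, pass1$a_rng[1] - step_a),
    a_hi = min(1, pass1$a_rng[2] + step_a),
    l_lo = max(0, pass1$l_rng[1] - step_l),
    l_hi = min(1, pass1$l_rng[2] + step_l),
    n = 4 * grid_n)
  pi_star <- c(pass1$pi_rng, pass2$pi_rng, fit$pi_ub)
  c(min(pi_star), max(pi_star))
}

.bum_ci_scan <- function(x, ll_hat, thr, a_lo, a_hi, l_lo, l_hi, n) {
  a_grid <- seq(a_lo, a_hi, length.out = n)
  lam_grid <- seq(l_lo, l_hi, length.out = n)
  ll <- .bum_ll_grid(x, a_grid, lam_grid)
  keep <- 2 * (ll_hat - ll) <= thr
  if (!any(keep)) return(NULL)
  idx <- which(keep, arr.ind = TRUE)
  a_k <- a_grid[idx[, 1]]
  l_k <- lam_grid[idx[, 2]]
  pi_k <- l_k + (1 - l_k) * a_k
  list(a_rng = range(a_k), l_rng = range(l_k), pi_rng = range(pi_k))
}

#' Expected number of accelerated elements in a group
#'
#' @param fit a [fit_bum()] result.
#' @param n_elements number of elements in the group (>= 1).
#' @return `(1 - pi_ub) * n_elements`, unrounded.
#' @export
accelerated_count <- function(fit, n_elements) {
  if (n_elements < 1) stop("'n_elements' must be >= 1")
  (1 - fit$pi_ub) * n_elements
}
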