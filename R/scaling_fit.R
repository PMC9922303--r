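# scale factors are searched on a log grid within these bounds
.scale_bounds <- c(1e-4, 1e3)

#' Fit the null model: one global branch-length scale
#'
#' Maximizes the likelihood of a group's concatenated alignment over a
#' single scaling factor `r` applied to every branch of the reference
#' tree, all other reference parameters fixed. `r` is interpreted as the
#' relative substitution rate of the group in all lineages. Bounded 1-D
#' optimization on the log scale.
#'
#' @param group_aln concatenated alignment of the group's elements.
#' @param ref a [reference_model()].
#' @return object of class `group_fit_null`: fields `r`, `loglik`,
#'   `convergence_warning`, `n_sites`.
#' @export
fit_global_scale <- function(group_aln, ref) {
  ld <- prepare_likelihood_data(group_aln, ref$tree)
  fit_global_scale_ld(ld, ref, gtr_eigen(ref$gtr))
}

fit_global_scale_ld <- function(ld, ref, eig) {
  nedge <- length(ld$brlen)
  freq <- ref$gtr$freq
  cr <- ref$rates$rates
  f <- function(logr)
    -loglik_prepared(ld, eig, freq, cr, rep(exp(logr), nedge))
  opt <- optimize(f, interval = log(.scale_bounds), tol = 1e-8)
  r <- exp(opt$minimum)
  warn <- r <= .scale_bounds[1] * 1.001 || r >= .scale_bounds[2] * 0.999
  structure(list(r = r, loglik = -opt$objective,
                 convergence_warning = warn,
                 n_sites = ld$nsites, signature = ld$signature),
            class = "group_fit_null")
}

#' Fit the alternative model: foreground and background scales
#'
#' Jointly maximizes the likelihood over two scaling factors, `r1` for
#' foreground branches and `r2` for background branches, with all other
#' reference parameters fixed. Optimization is bounded L-BFGS-B on the
#' log scale with multiple starts around the null fit's scale (the
#' likelihood can be flat in `r1` for short foregrounds), and the
#' alternative log-likelihood never falls below the null's because the
#' null point is among the starts.
#'
#' @param group_aln concatenated alignment of the group's elements.
#' @param ref a [reference_model()].
#' @param fg a [define_foreground()] branch scaling map.
#' @param null optional pre-computed [fit_global_scale()] result for the
#'   same alignment (computed if missing).
#' @return object of class `group_fit_alt`: fields `r1`, `r2`, `loglik`,
#'   `scaling`, `null`.
#' @export
fit_two_scales <- function(group_aln, ref, fg, null = NULL) {
  ld <- prepare_likelihood_data(group_aln, ref$tree)
  fit_two_scales_ld(ld, ref, fg, gtr_eigen(ref$gtr), null)
}

fit_two_scales_ld <- function(ld, ref, fg, eig, null = NULL) {
  if (!inherits(fg, "branch_scaling"))
    stop("'fg' must be a branch_scaling map from define_foreground()")
  if (fg$n_edge != length(ld$brlen))
    stop("branch scaling map does not match the reference tree")
  if (is.null(null)) null <- fit_global_scale_ld(ld, ref, eig)
  freq <- ref$gtr$freq
  cr <- ref$rates$rates
  is_fg <- fg$class == "foreground"
  sc <- numeric(length(is_fg))
  f <- function(par) {
    sc[is_fg] <- exp(par[1])
    sc[!is_fg] <- exp(par[2])
    -loglik_prepared(ld, eig, freq, cr, sc)
  }
  lb <- log(.scale_bounds[1]); ub <- log(.scale_bounds[2])
  lr <- log(null$r)
  starts <- list(c(lr, lr), c(lr + log(2), lr), c(lr - log(2), lr))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lb), ub)
    o <- tryCatch(
      optim(s, f, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || -best$value < null$loglik) {
    # fall back to the null point; the models are nested
    best <- list(par = c(lr, lr), value = -null$loglik)
  }
  r1 <- exp(best$par[1]); r2 <- exp(best$par[2])
  structure(list(r1 = r1, r2 = r2, loglik = -best$value,
                 scaling = set_scales(fg, r1, r2), null = null,
                 n_sites = ld$nsites, signature = ld$signature),
            class = "group_fit_alt")
}

#' Group-level likelihood ratio test for accelerated evolution
#'
#' The statistic is twice the log-likelihood difference between the
#' two-scale alternative and the single-scale null, clipped at zero
#' (nesting guarantees non-negativity analytically; tiny negatives are
#' numerical noise). The p-value is the upper tail of the chi-square
#' distribution with one degree of freedom, appropriate at the group
#' level where alignment data are plentiful. A group is called
#' accelerated when the null is rejected and `r1 > r2`.
#'
#' @param null a [fit_global_scale()] result.
#' @param alt a [fit_two_scales()] result on the same alignment.
#' @param m number of tests in the batch for Bonferroni adjustment
#'   (default 1).
#' @return object of class `lrt_result`: `stat`, `p`, `p_bonferroni`,
#'   `accelerated` (direction flag `r1 > r2`), `fold` (`r1/r2`).
#' @export
group_lrt <- function(null, alt, m = 1) {
  if (!inherits(null, "group_fit_null") || !inherits(alt, "group_fit_alt"))
    stop("'null' and 'alt' must be fit_global_scale / fit_two_scales fits")
  if (!identical(null$signature, alt$signature))
    stop("null and alternative fits come from different alignments")
  stat <- max(0, 2 * (alt$loglik - null$loglik))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(stat = stat, p = p,
                 p_bonferroni = min(1, m * p),
                 accelerated = alt$r1 > alt$r2,
                 fold = alt$r1 / alt$r2,
                 r_null = null$r, r1 = alt$r1, r2 = alt$r2),
            class = "lrt_result")
}

#' Bonferroni adjustment with an explicit test count
#'
#' @param p_values numeric p-values in `[0,1]`.
#' @param m number of tests; may exceed `length(p_values)` when some
#'   tests failed upstream. Defaults to the number of p-values.
#' @return adjusted p-values `min(1, m * p)`, order preserved.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values))
    stop("'m' must be at least the number of p-values")
  pmin(1, m * p_values)
}
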