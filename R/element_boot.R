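#' Element-level likelihood ratio statistic
#'
#' The same two-scale versus one-scale comparison as the group-level
#' test, applied to one element's alignment. At element scale the
#' chi-square approximation is unreliable, so the statistic is meant to
#' be converted into an empirical p-value against a parametric-bootstrap
#' null distribution (see [simulate_group_null()]).
#'
#' @param elem_aln a single element's alignment.
#' @param ref a [reference_model()].
#' @param fg a [define_foreground()] map.
#' @param min_informative minimum informative sites (default 50); the
#'   element must pass this filter first.
#' @param min_species species threshold for an informative site
#'   (default 5).
#' @return the clipped likelihood ratio statistic (numeric).
#' @export
element_lrt <- function(elem_aln, ref, fg, min_informative = 50,
                        min_species = 5) {
  if (count_informative_sites(elem_aln, min_species) < min_informative)
    stop("element has fewer than ", min_informative,
         " informative sites; apply filter_elements() first")
  element_lrt_ld(prepare_likelihood_data(elem_aln, ref$tree), ref, fg,
                 gtr_eigen(ref$gtr))
}

element_lrt_ld <- function(ld, ref, fg, eig) {
  null <- fit_global_scale_ld(ld, ref, eig)
  alt <- fit_two_scales_ld(ld, ref, fg, eig, null)
  max(0, 2 * (alt$loglik - null$loglik))
}

#' Parametric-bootstrap null statistics for a group
#'
#' Builds the empirical null distribution of the element-level statistic
#' for one group. For each of `B` replicates, an element length is drawn
#' with replacement from the group's observed element lengths, an
#' alignment of that length is simulated under the reference model with
#' every branch scaled by the group's null-model scale (the H0 fit
#' calibrates the bootstrap), and the element-level statistic is
#' computed on it. Reproducible given `seed`.
#'
#' @param group either a list of element alignments or an integer vector
#'   of element lengths.
#' @param ref a [reference_model()].
#' @param null_scale the group's fitted global scale (from
#'   [fit_global_scale()]).
#' @param fg the [define_foreground()] map used for the element tests.
#' @param B number of bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return numeric vector of `B` null statistics.
#' @export
simulate_group_null <- function(group, ref, null_scale, fg, B = 10000,
                                seed = 1) {
  if (B < 1) stop("'B' must be >= 1")
  lengths <- if (is.list(group)) vapply(group, ncol, 0L) else
    as.integer(group)
  if (!length(lengths)) stop("empty group")
  eig <- gtr_eigen(ref$gtr)
  set.seed(derive_seed(seed, 0L, 2L))
  picked <- sample(lengths, B, replace = TRUE)
  stats <- numeric(B)
  for (b in seq_len(B)) {
    a <- simulate_alignment(ref, null_scale, picked[b],
                            seed = derive_seed(seed, b, 3L))
    ld <- prepare_likelihood_data(a, ref$tree)
    stats[b] <- element_lrt_ld(ld, ref, fg, eig)
  }
  stats
}

#' Empirical p-value against a bootstrap null distribution
#'
#' Uses the pseudocount convention `p = (1 + #\{null >= stat\}) / (1 + B)`
#' so that p-values lie in `[1/(B+1), 1]` and never equal zero — the
#' beta-uniform mixture density is ill-behaved at zero.
#'
#' @param stat observed statistic(s).
#' @param null_stats numeric vector of `B` null statistics.
#' @return empirical p-value(s), same length as `stat`.
#' @export
empirical_pvalue <- function(stat, null_stats) {
  B <- length(null_stats)
  if (B < 1) stop("empty null distribution")
  vapply(stat, function(s) (1 + sum(null_stats >= s)) / (1 + B), 0)
}
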