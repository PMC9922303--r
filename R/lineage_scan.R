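#' Bayesian information criterion
#'
#' `BIC = -2 l + k log(n)`; lower values indicate better fit. For the
#' two-scale alternative model `k = 2` (the two scaling factors) and `n`
#' is the number of columns in the concatenated alignment — columns are
#' the independent observations in the likelihood.
#'
#' @param loglik maximized log-likelihood `l`.
#' @param k number of free parameters.
#' @param n sample size (>= 1).
#' @return the BIC value.
#' @export
bic <- function(loglik, k, n) {
  if (n < 1) stop("'n' must be >= 1")
  -2 * loglik + k * log(n)
}

#' Scan nested foreground clades for the lineage of acceleration
#'
#' Fits the two-scale alternative model once per candidate foreground —
#' the focal tip and every ancestor clade short of the root (see
#' [enumerate_focal_clades()]) — and ranks candidates by BIC with
#' `k = 2` and `n` the number of alignment columns. The best-fit
#' foreground is the candidate with minimum BIC; ties break toward the
#' smaller (tip-ward) clade, the most parsimonious foreground.
#'
#' @param group_aln concatenated group alignment.
#' @param ref a [reference_model()].
#' @param focal_tip tip label the candidate clades must contain.
#' @return object of class `lineage_scan`: a data.frame with one row per
#'   candidate (`candidate_label`, `clade_tips`, `r1`, `r2`, `loglik`,
#'   `k`, `n`, `bic`, `is_best`) plus attributes `candidates` and
#'   `fits`.
#' @export
scan_lineages <- function(group_aln, ref, focal_tip) {
  ld <- prepare_likelihood_data(group_aln, ref$tree)
  eig <- gtr_eigen(ref$gtr)
  null <- fit_global_scale_ld(ld, ref, eig)
  cands <- enumerate_focal_clades(ref$tree, focal_tip)
  fits <- vector("list", length(cands))
  rows <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    fg <- define_foreground(ref$tree, cands[[i]])
    fit <- fit_two_scales_ld(ld, ref, fg, eig, null)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      candidate_label = names(cands)[i],
      clade_tips = paste(cands[[i]], collapse = ","),
      r1 = fit$r1, r2 = fit$r2, loglik = fit$loglik,
      k = 2L, n = ld$nsites,
      bic = bic(fit$loglik, 2, ld$nsites),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$is_best <- seq_len(nrow(out)) == which.min(out$bic)
  structure(out, candidates = cands, fits = fits, null = null,
            class = c("lineage_scan", "data.frame"))
}
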