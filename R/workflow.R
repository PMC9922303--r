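as_element_list <- function(x) {
  if (is.matrix(x)) list(x) else x
}

#' Group-level acceleration test over a batch of groups
#'
#' For each group: concatenate its elements, fit the single-scale null
#' and the two-scale alternative, and run the group-level LRT; p-values
#' are Bonferroni-adjusted with an explicit test count `m`.
#'
#' @param groups named list; each entry is a list of element alignments
#'   (or a single concatenated alignment).
#' @param ref a [reference_model()].
#' @param foreground foreground tip labels (passed to
#'   [define_foreground()]).
#' @param m Bonferroni test count (default: number of groups).
#' @return data.frame with one row per group: group, n_elements,
#'   n_columns, r_null, r1, r2, fold, lrt_stat, p, p_bonferroni,
#'   direction.
#' @export
run_group_test <- function(groups, ref, foreground, m = length(groups)) {
  fg <- define_foreground(ref$tree, foreground)
  eig <- gtr_eigen(ref$gtr)
  rows <- lapply(names(groups), function(g) {
    elems <- as_element_list(groups[[g]])
    concat <- concatenate_group(elems)
    ld <- prepare_likelihood_data(concat, ref$tree)
    null <- fit_global_scale_ld(ld, ref, eig)
    alt <- fit_two_scales_ld(ld, ref, fg, eig, null)
    lrt <- group_lrt(null, alt, m = m)
    data.frame(group = g, n_elements = length(elems),
               n_columns = ncol(concat), r_null = null$r,
               r1 = alt$r1, r2 = alt$r2, fold = lrt$fold,
               lrt_stat = lrt$stat, p = lrt$p,
               p_bonferroni = lrt$p_bonferroni,
               direction = ifelse(alt$r1 > alt$r2, "r1>r2", "r1<=r2"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Element-level bootstrap p-values and mixture estimate per group
#'
#' For each group passing the group-level significance gate: compute the
#' element-level statistic for every element, build the
#' parametric-bootstrap null calibrated by the group's null-model scale,
#' convert statistics to empirical p-values, fit the beta-uniform
#' mixture, and report the accelerated fraction lower bound with its
#' profile confidence interval and the implied accelerated-element
#' count.
#'
#' @param groups named list of element-alignment lists.
#' @param ref a [reference_model()].
#' @param foreground foreground tip labels.
#' @param B bootstrap replicates (default 10000). Below 100 a warning is
#'   issued (interval estimates become unreliable).
#' @param seed integer master seed.
#' @param gate require group-level significance before the element
#'   analysis (default TRUE); `force = TRUE` overrides.
#' @param alpha significance level for the gate (on Bonferroni-adjusted
#'   p, default 0.05).
#' @param m Bonferroni test count for the gate.
#' @param force analyze all groups regardless of the gate.
#' @return list with `groups` (mixture summary data.frame), `elements`
#'   (per-element data.frame), `group_test` (the [run_group_test()]
#'   table) and `skipped` (gated-out group names).
#' @export
run_element_mixture <- function(groups, ref, foreground, B = 10000,
                                seed = 1, gate = TRUE, alpha = 0.05,
                                m = length(groups), force = FALSE) {
  if (B < 100) warning("B < 100: empirical p-values and the mixture ",
                       "confidence interval will be unreliable")
  gt <- run_group_test(groups, ref, foreground, m = m)
  fg <- define_foreground(ref$tree, foreground)
  eig <- gtr_eigen(ref$gtr)
  elem_rows <- list()
  grp_rows <- list()
  skipped <- character()
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    ok <- !gate || force ||
      (gt$p_bonferroni[gt$group == g] < alpha &&
         gt$direction[gt$group == g] == "r1>r2")
    if (!ok) {
      skipped <- c(skipped, g)
      next
    }
    elems <- as_element_list(groups[[gi]])
    stats <- vapply(elems, function(a)
      element_lrt_ld(prepare_likelihood_data(a, ref$tree), ref, fg, eig),
      0)
    nulls <- simulate_group_null(elems, ref,
                                 null_scale = gt$r_null[gt$group == g],
                                 fg = fg, B = B,
                                 seed = derive_seed(seed, gi, 10L))
    pvals <- empirical_pvalue(stats, nulls)
    fit <- fit_bum(pvals)
    ci <- bum_confidence_interval(pvals, fit)
    elem_rows[[g]] <- data.frame(
      group = g,
      element_id = if (!is.null(names(elems))) names(elems) else
        sprintf("%s_%05d", g, seq_along(elems)),
      length = vapply(elems, ncol, 0L),
      lrt_stat = stats, p_empirical = pvals,
      stringsAsFactors = FALSE)
    grp_rows[[g]] <- data.frame(
      group = g, n = length(elems),
      lambda_hat = fit$lambda_hat, a_hat = fit$a_hat,
      pi_ub = fit$pi_ub, prop_accel = fit$prop_accel,
      ci_lo = ci[1], ci_hi = ci[2],
      n_accel = accelerated_count(fit, length(elems)),
      stringsAsFactors = FALSE)
  }
  list(groups = if (length(grp_rows)) do.call(rbind, grp_rows) else NULL,
       elements = if (length(elem_rows)) do.call(rbind, elem_rows) else
         NULL,
       group_test = gt, skipped = skipped)
}

#' Foreground-lineage BIC scan over a batch of groups
#'
#' @param groups named list of element-alignment lists (or concatenated
#'   alignments).
#' @param ref a [reference_model()].
#' @param focal_tip tip the candidate clades must contain.
#' @return data.frame: one row per group x candidate with a `group`
#'   column prepended to the [scan_lineages()] table.
#' @export
run_lineage_scan <- function(groups, ref, focal_tip) {
  rows <- lapply(names(groups), function(g) {
    concat <- concatenate_group(as_element_list(groups[[g]]))
    sc <- scan_lineages(concat, ref, focal_tip)
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          as.data.frame(sc))
  })
  do.call(rbind, rows)
}

#' Write a result table as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_result_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
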