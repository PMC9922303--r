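# Deterministic 31-bit sub-seed stream: one stream per (seed, index,
# stage) so element counts can change without perturbing earlier
# elements. Lehmer-style mixing keeps everything below 2^31.
derive_seed <- function(seed, index = 0L, stage = 0L) {
  m <- 2147483647
  a <- ((as.double(seed) %% m) * 69621 + as.double(index) * 1999 +
          as.double(stage) * 268435399 + 1) %% m
  a <- (a * 48271) %% m
  a <- (a * 48271) %% m
  as.integer(a)
}

#' Simulate an alignment under the reference model with branch scaling
#'
#' Columns are independent: each draws a Gamma rate category, a root
#' state from the stationary frequencies, and then evolves down the tree
#' through `P(rate * scale * branch_length)` on every branch. No indels
#' or missing data are simulated.
#'
#' @param ref a [reference_model()].
#' @param scaling optional [branch_scaling()] map (or single scale).
#' @param length number of columns (bp).
#' @param seed optional integer seed; given the same seed the output is
#'   identical.
#' @return an alignment matrix over the tree's tips.
#' @export
simulate_alignment <- function(ref, scaling = NULL, length, seed = NULL) {
  if (length < 1) stop("'length' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tree <- ref$tree
  eig <- gtr_eigen(ref$gtr)
  sc <- edge_scales(scaling, nrow(tree$edge))
  cr <- ref$rates$rates
  K <- ref$rates$K
  ntot <- n_tips(tree) + tree$Nnode
  cats <- sample.int(K, length, replace = TRUE)
  states <- matrix(0L, ntot, length)
  states[root_node(tree), ] <- sample.int(4, length, replace = TRUE,
                                          prob = ref$gtr$freq)
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t0 <- tree$edge.length[e] * sc[e]
    for (k in seq_len(K)) {
      cols <- which(cats == k)
      if (!length(cols)) next
      P <- eig$U %*% (exp(eig$eigval * t0 * cr[k]) * eig$Uinv)
      P[P < 0] <- 0
      ps <- states[pa, cols]
      out <- integer(length(cols))
      for (s in 1:4) {
        j <- which(ps == s)
        if (length(j))
          out[j] <- sample.int(4, length(j), replace = TRUE, prob = P[s, ])
      }
      states[ch, cols] <- out
    }
  }
  m <- matrix(c("A", "C", "G", "T")[states[seq_len(n_tips(tree)), ,
                                           drop = FALSE]],
              n_tips(tree), length)
  rownames(m) <- tree$tip.label
  as_alignment(m)
}

# the eight accelerated-lineage cases used in the validation scenarios
.case_tips <- list(
  "1" = "human",
  "2" = c("human", "chimp"),
  "3" = c("human", "chimp", "gorilla"),
  "4" = c("human", "chimp", "gorilla", "orangutan"),
  "5" = "chimp",
  "6" = "gorilla",
  "7" = "orangutan",
  "8" = "macaque"
)

#' Tip set of a simulation case
#'
#' Cases 1-8 name the accelerated lineage: human; Hominini (human,
#' chimp); human+chimp+gorilla; the ape clade; chimp; gorilla;
#' orangutan; macaque.
#'
#' @param case integer 1..8.
#' @return character vector of tip labels.
#' @export
scenario_case_tips <- function(case) {
  tips <- .case_tips[[as.character(case)]]
  if (is.null(tips)) stop("'case' must be an integer in 1..8")
  tips
}

#' Simulation scenario configuration
#'
#' Scenario 1: every element fully accelerated. Scenario 2: a fraction
#' `L` of each element's columns accelerated (contiguous leading
#' segment). Scenario 3: a fraction `M` of the elements accelerated, the
#' rest evolving under the unscaled reference model.
#'
#' @param scenario 1, 2 or 3.
#' @param case accelerated-lineage case 1..8 (see
#'   [scenario_case_tips()]); ignored when `tips` is given.
#' @param fold true foreground/background rate ratio `r1/r2` (> 0).
#' @param n_elements number of elements.
#' @param element_length element length in bp (default 200, the median
#'   ChIP-seq peak alignment length this setting emulates).
#' @param L scenario-2 within-element accelerated fraction in (0,1].
#' @param M scenario-3 accelerated-element fraction in (0,1].
#' @param seed integer master seed.
#' @param tips optional explicit accelerated-clade tip labels.
#' @return object of class `sim_scenario_config`.
#' @export
sim_scenario_config <- function(scenario, case = 1, fold, n_elements,
                                element_length = 200, L = NULL, M = NULL,
                                seed = 1, tips = NULL) {
  if (!scenario %in% 1:3) stop("'scenario' must be 1, 2 or 3")
  if (fold <= 0) stop("'fold' must be positive")
  if (n_elements < 1 || element_length < 1)
    stop("element count and length must be positive")
  if (scenario == 2 && (is.null(L) || !is.null(M)))
    stop("scenario 2 requires 'L' (and no 'M')")
  if (scenario == 3 && (is.null(M) || !is.null(L)))
    stop("scenario 3 requires 'M' (and no 'L')")
  if (scenario == 1 && (!is.null(L) || !is.null(M)))
    stop("scenario 1 takes neither 'L' nor 'M'")
  if (!is.null(L) && (L <= 0 || L > 1)) stop("'L' must be in (0, 1]")
  if (!is.null(M) && (M <= 0 || M > 1)) stop("'M' must be in (0, 1]")
  if (is.null(tips)) tips <- scenario_case_tips(case)
  structure(list(scenario = scenario, case = case, tips = tips,
                 fold = fold, n_elements = as.integer(n_elements),
                 element_length = as.integer(element_length),
                 L = L, M = M, seed = as.integer(seed)),
            class = "sim_scenario_config")
}

#' Generate a simulated element group with its truth record
#'
#' @param config a [sim_scenario_config()].
#' @param ref a [reference_model()].
#' @return list with `elements` (named list of alignments), `truth`
#'   (data.frame: element_id, accelerated, scaled_columns), `foreground`
#'   (the accelerated-clade [branch_scaling()] map) and `config`.
#' @export
make_scenario <- function(config, ref) {
  if (!inherits(config, "sim_scenario_config"))
    stop("'config' must be a sim_scenario_config")
  fg <- define_foreground(ref$tree, config$tips)
  scaled <- set_scales(fg, config$fold, 1)
  n <- config$n_elements
  len <- config$element_length
  ids <- sprintf("elem_%05d", seq_len(n))
  n_accel <- switch(as.character(config$scenario),
                    "1" = n, "2" = n, "3" = ceiling(n * config$M))
  elements <- vector("list", n)
  scaled_cols <- integer(n)
  accel <- logical(n)
  for (i in seq_len(n)) {
    s <- derive_seed(config$seed, i)
    if (config$scenario == 1) {
      elements[[i]] <- simulate_alignment(ref, scaled, len, seed = s)
      scaled_cols[i] <- len; accel[i] <- TRUE
    } else if (config$scenario == 2) {
      nsc <- as.integer(ceiling(len * config$L))
      a <- simulate_alignment(ref, scaled, nsc, seed = s)
      if (nsc < len) {
        b <- simulate_alignment(ref, NULL, len - nsc,
                                seed = derive_seed(config$seed, i, 1))
        a <- as_alignment(cbind(a, b[rownames(a), , drop = FALSE]))
      }
      elements[[i]] <- a
      scaled_cols[i] <- nsc; accel[i] <- TRUE
    } else {
      if (i <= n_accel) {
        elements[[i]] <- simulate_alignment(ref, scaled, len, seed = s)
        scaled_cols[i] <- len; accel[i] <- TRUE
      } else {
        elements[[i]] <- simulate_alignment(ref, NULL, len, seed = s)
        scaled_cols[i] <- 0L; accel[i] <- FALSE
      }
    }
    attr(elements[[i]], "element_id") <- ids[i]
  }
  names(elements) <- ids
  list(elements = elements,
       truth = data.frame(element_id = ids, accelerated = accel,
                          scaled_columns = scaled_cols,
                          stringsAsFactors = FALSE),
       foreground = fg, config = config)
}

#' Weighted fold-of-increase estimate for partial acceleration
#'
#' When only a fraction of the data is accelerated, the group-average
#' fold of increase is `fraction * fold + (1 - fraction)`; applying this
#' to a fitted `r1/r2` gives the weighted estimate used to summarize
#' scenario 2 (fraction = `L`) and scenario 3 (fraction = `M`).
#'
#' @param fold_hat estimated (or true) fold `r1/r2` (> 0).
#' @param fraction accelerated fraction in (0, 1].
#' @return the weighted fold.
#' @export
weighted_fold_estimate <- function(fold_hat, fraction) {
  if (any(fraction <= 0) || any(fraction > 1))
    stop("'fraction' must be in (0, 1]")
  if (any(fold_hat <= 0)) stop("'fold_hat' must be positive")
  fraction * fold_hat + (1 - fraction)
}
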