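#' Reference phylogenetic model
#'
#' The calibrated backbone that every acceleration test scales: a fixed
#' rooted tree with fitted branch lengths, GTR exchangeabilities and
#' stationary frequencies, and a discrete-Gamma site-rate model. It is
#' normally fitted once on the concatenation of all elements, under the
#' assumption that most elements are not accelerated.
#'
#' @param tree postorder `phylo` tree with branch lengths.
#' @param gtr a [gtr_params()] object.
#' @param rates a [discretize_gamma()] model.
#' @param loglik optional log-likelihood at the fitted optimum.
#' @return object of class `reference_model`.
#' @export
reference_model <- function(tree, gtr, rates, loglik = NA_real_) {
  structure(list(tree = as_postorder_tree(tree), gtr = gtr, rates = rates,
                 loglik = loglik),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("Reference model:", n_tips(x$tree), "taxa,",
      nrow(x$tree$edge), "branches\n")
  cat("  tree length:", format(sum(x$tree$edge.length), digits = 4),
      "subs/site\n")
  cat("  GTR rates:", paste(format(x$gtr$rates, digits = 3),
                            collapse = " "), "\n")
  cat("  base freq:", paste(format(x$gtr$freq, digits = 3),
                            collapse = " "), "\n")
  cat("  Gamma shape:", format(x$rates$alpha, digits = 4), "with",
      x$rates$K, "categories\n")
  if (is.finite(x$loglik))
    cat("  log-likelihood:", format(x$loglik, digits = 10), "\n")
  invisible(x)
}

#' Fit the reference model to a concatenated alignment
#'
#' Jointly estimates branch lengths, GTR parameters and the gamma shape
#' by maximum likelihood on a fixed topology, delegating the optimization
#' to [phangorn::optim.pml()] (cycles of coordinate-wise updates until
#' the log-likelihood improvement falls below tolerance). The fitted
#' parameters are returned as a [reference_model()] usable with the
#' package's own likelihood engine, which matches `pml` likelihoods on
#' identical parameters.
#'
#' @param concat concatenated alignment matrix (all elements).
#' @param topology `phylo` tree giving the fixed topology; its branch
#'   lengths are used as starting values.
#' @param K gamma categories (default 4).
#' @return a [reference_model()] with `loglik` set.
#' @export
fit_reference_model <- function(concat, topology, K = 4) {
  topology <- as_postorder_tree(topology)
  if (!is.matrix(concat)) concat <- as_alignment(concat)
  pd <- phangorn::phyDat(concat, type = "DNA")
  if (attr(pd, "nr") < 2)
    stop("degenerate data: fewer than 2 distinct site patterns")
  start <- topology
  start$edge.length[start$edge.length < 1e-8] <- 1e-8
  # pml optimizes on the unrooted tree anyway; unroot explicitly and
  # restore the rooted topology afterwards
  start <- ape::unroot(start)
  fit <- phangorn::pml(start, pd, k = K, shape = 1)
  fit <- phangorn::optim.pml(fit, model = "GTR", optEdge = TRUE,
                             optGamma = TRUE, rearrangement = "none",
                             control = phangorn::pml.control(trace = 0))
  gtr <- gtr_params(rates = fit$Q, freq = fit$bf)
  tree <- restore_rooted_lengths(topology, fit$tree)
  reference_model(tree, gtr, discretize_gamma(fit$shape, K),
                  loglik = as.numeric(stats::logLik(fit)))
}

# optim.pml works on the unrooted tree (the likelihood of a reversible
# model is root-invariant); copy its fitted lengths back onto the rooted
# topology by matching tip splits. The merged edge across the root is
# split between the two root children in proportion to the starting
# lengths — any split yields the same likelihood (pulley principle).
restore_rooted_lengths <- function(rooted, fitted) {
  rooted <- as_postorder_tree(rooted)
  tips <- sort(rooted$tip.label)
  ref_tip <- tips[1]
  split_key <- function(tree, edge_child) {
    labs <- tree$tip.label[descendant_tips_generic(tree, edge_child)]
    if (ref_tip %in% labs) labs <- setdiff(tips, labs)
    paste(sort(labs), collapse = "|")
  }
  fit_keys <- vapply(fitted$edge[, 2], function(ch)
    split_key(fitted, ch), "")
  out <- rooted
  root <- root_node(rooted)
  root_edges <- which(rooted$edge[, 1] == root)
  for (e in seq_len(nrow(rooted$edge))) {
    key <- split_key(rooted, rooted$edge[e, 2])
    hit <- which(fit_keys == key)
    if (e %in% root_edges) next
    if (length(hit) != 1)
      stop("could not match fitted branch for split: ", key)
    out$edge.length[e] <- fitted$edge.length[hit[1]]
  }
  # both root edges define the same split; share the fitted length
  key <- split_key(rooted, rooted$edge[root_edges[1], 2])
  hit <- which(fit_keys == key)
  if (!length(hit))
    stop("could not match the root-spanning branch")
  total <- fitted$edge.length[hit[1]]
  w <- rooted$edge.length[root_edges]
  w <- if (sum(w) > 0) w / sum(w) else rep(0.5, 2)
  out$edge.length[root_edges] <- total * w
  out
}

# descendant tip indices that also works for unrooted ape trees
descendant_tips_generic <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[pa]] <- c(desc[[pa]], desc[[ch]])
  }
  sort(desc[[node]])
}

#' Serialize a reference model to a versioned JSON text file
#' @param model a [reference_model()].
#' @param path output path.
#' @export
write_reference_model <- function(model, path) {
  obj <- list(format = "groupacc-reference-model",
              version = 1L,
              newick = ape::write.tree(model$tree),
              gtr_rates = unname(model$gtr$rates),
              base_freq = unname(model$gtr$freq),
              gamma_shape = model$rates$alpha,
              gamma_categories = model$rates$K,
              loglik = model$loglik)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized reference model
#' @param path file written by [write_reference_model()].
#' @return a [reference_model()].
#' @export
read_reference_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "groupacc-reference-model"))
    stop("not a groupacc reference model file: ", path)
  reference_model(parse_newick(obj$newick),
                  gtr_params(obj$gtr_rates, obj$base_freq),
                  discretize_gamma(obj$gamma_shape, obj$gamma_categories),
                  loglik = if (is.null(obj$loglik)) NA_real_ else
                    as.numeric(obj$loglik))
}
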