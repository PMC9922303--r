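#' Parse a rooted newick tree with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is
#' rooted, has unique tip labels, carries a branch length on every edge,
#' and is stored in canonical postorder so that branch identifiers
#' (postorder edge indices; equivalently the child node of each edge) are
#' deterministic and serializable. The topology and rooting are taken
#' as-is; no re-rooting is performed, because foreground/background
#' partitions depend on the given root.
#'
#' @param text newick string.
#' @return a postorder-sorted `phylo` object.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick string: ", substr(text, 1, 60))
  as_postorder_tree(tree)
}

#' Read a newick tree from a file
#' @param path path to a newick file.
#' @return a postorder-sorted `phylo` object.
#' @export
read_tree_file <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

# validate and canonicalize any phylo object
as_postorder_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      any(!is.finite(tree$edge.length)))
    stop("every branch must carry a finite branch length")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::reorder.phylo(tree, "postorder")
}

n_tips <- function(tree) length(tree$tip.label)
root_node <- function(tree) n_tips(tree) + 1L

# tip indices (1..ntip) descending from each node, computed by one
# postorder pass over the edge matrix
descendant_tips <- function(tree, node) {
  ntip <- n_tips(tree)
  if (node <= ntip) return(node)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[pa]] <- c(desc[[pa]], desc[[ch]])
  }
  sort(desc[[node]])
}

#' Branch scaling map: foreground/background classes and their scales
#'
#' Assigns every branch of a postorder tree to the foreground or the
#' background class and records the multiplicative scale applied to each
#' class. Branch order follows the tree's postorder edge list.
#'
#' @param tree postorder `phylo` tree.
#' @param foreground_edges integer indices (postorder) of foreground
#'   edges.
#' @param scales named numeric vector `c(foreground=, background=)`,
#'   both positive.
#' @return object of class `branch_scaling`.
#' @export
branch_scaling <- function(tree, foreground_edges = integer(),
                           scales = c(foreground = 1, background = 1)) {
  nedge <- nrow(tree$edge)
  if (length(foreground_edges) &&
      (any(foreground_edges < 1) || any(foreground_edges > nedge)))
    stop("foreground edge index out of range")
  if (any(scales <= 0)) stop("scales must be positive")
  cls <- rep("background", nedge)
  cls[foreground_edges] <- "foreground"
  structure(list(class = cls,
                 scales = c(foreground = unname(scales["foreground"]),
                            background = unname(scales["background"])),
                 n_edge = nedge),
            class = "branch_scaling")
}

# per-edge multiplicative scales, postorder
edge_scales <- function(scaling, nedge) {
  if (is.null(scaling)) return(rep(1, nedge))
  if (inherits(scaling, "branch_scaling")) {
    if (scaling$n_edge != nedge)
      stop("branch scaling map does not match this tree")
    return(unname(scaling$scales[scaling$class]))
  }
  if (is.numeric(scaling) && length(scaling) == 1) return(rep(scaling, nedge))
  if (is.numeric(scaling) && length(scaling) == nedge) return(scaling)
  stop("invalid branch scaling specification")
}

set_scales <- function(scaling, r1, r2) {
  scaling$scales <- c(foreground = r1, background = r2)
  scaling
}

#' Define the foreground lineage from a tip or monophyletic clade
#'
#' The foreground comprises the stem branch of the clade's most recent
#' common ancestor plus every branch inside the clade; all remaining
#' branches are background. A single tip yields exactly its terminal
#' branch. Non-monophyletic tip sets are rejected, naming the extra tips
#' that break monophyly.
#'
#' @param tree postorder `phylo` tree.
#' @param clade_tips character vector of tip labels (one or more).
#' @return a [branch_scaling()] map with unit scales.
#' @export
define_foreground <- function(tree, clade_tips) {
  tree <- as_postorder_tree(tree)
  idx <- match(clade_tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip(s): ", paste(clade_tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1) {
    mrca <- idx
  } else {
    mrca <- ape::getMRCA(tree, clade_tips)
    got <- descendant_tips(tree, mrca)
    extra <- setdiff(got, idx)
    if (length(extra))
      stop("tip set is not monophyletic; the clade also contains: ",
           paste(tree$tip.label[extra], collapse = ", "))
  }
  clade_nodes <- if (mrca <= n_tips(tree)) mrca else
    c(mrca, clade_descendant_nodes(tree, mrca))
  fg <- which(tree$edge[, 2] %in% clade_nodes)
  if (!length(fg)) stop("foreground cannot be the whole tree (root clade)")
  branch_scaling(tree, fg)
}

# all nodes (tips and internals) strictly below 'node'
clade_descendant_nodes <- function(tree, node) {
  nedge <- nrow(tree$edge)
  below <- logical(n_tips(tree) + tree$Nnode)
  below[node] <- TRUE
  for (e in rev(seq_len(nedge))) {  # preorder: parents before children
    if (below[tree$edge[e, 1]]) below[tree$edge[e, 2]] <- TRUE
  }
  setdiff(which(below), node)
}

#' Enumerate nested foreground candidates containing a focal tip
#'
#' Candidate foregrounds are the focal tip itself followed by the clades
#' of each of its ancestors up to, but excluding, the root — i.e. all
#' proper monophyletic clades containing the focal lineage, ordered
#' tip-to-root and therefore nested.
#'
#' @param tree postorder `phylo` tree.
#' @param focal_tip tip label.
#' @return named list (`M1`, `M2`, ...) of tip-label vectors.
#' @export
enumerate_focal_clades <- function(tree, focal_tip) {
  tree <- as_postorder_tree(tree)
  tip <- match(focal_tip, tree$tip.label)
  if (is.na(tip)) stop("unknown tip: ", focal_tip)
  parent_of <- integer(n_tips(tree) + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  out <- list(tree$tip.label[tip])
  node <- parent_of[tip]
  while (node != root_node(tree) && node != 0L) {
    out <- c(out, list(tree$tip.label[descendant_tips(tree, node)]))
    node <- parent_of[node]
  }
  names(out) <- paste0("M", seq_along(out))
  out
}

#' Synthetic ten-primate fixture tree
#'
#' A hand-curated rooted tree of the ten primates used throughout the
#' package's simulations (human, chimp, gorilla, orangutan, macaque,
#' baboon, marmoset, tarsier, mouse lemur, bushbaby), with plausible
#' branch lengths in expected substitutions per site. This is a synthetic
#' stand-in for a genome-alignment-calibrated model, shipped so that all
#' examples and tests run without downloads.
#'
#' @return a postorder `phylo` tree with 10 tips.
#' @export
synthetic_primate_tree <- function() {
  read_tree_file(system.file("extdata", "primate10_synthetic.nh",
                             package = "groupacc", mustWork = TRUE))
}

#' Synthetic primate reference model
#'
#' The [synthetic_primate_tree()] equipped with mammal-like GTR
#' exchangeabilities, AT-rich stationary frequencies and moderate
#' among-site rate variation (Gamma shape 2, four categories). Used as
#' the default generating model for simulations and examples.
#'
#' @param alpha gamma shape (default 2).
#' @param K rate categories (default 4).
#' @return a [reference_model()].
#' @export
synthetic_reference_model <- function(alpha = 2, K = 4) {
  reference_model(
    tree = synthetic_primate_tree(),
    gtr = gtr_params(rates = c(1.3, 5.0, 0.9, 1.2, 5.5, 1.0),
                     freq = c(0.30, 0.20, 0.20, 0.30)),
    rates = discretize_gamma(alpha, K)
  )
}
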