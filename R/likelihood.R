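# IUPAC-aware tip partial likelihoods. Gaps and full ambiguities are
# missing data (all-ones partials); partial ambiguities restrict to the
# consistent states. Rows = A,C,G,T.
iupac_partials <- local({
  tab <- list(
    A = c(1,0,0,0), C = c(0,1,0,0), G = c(0,0,1,0), T = c(0,0,0,1),
    U = c(0,0,0,1),
    R = c(1,0,1,0), Y = c(0,1,0,1), S = c(0,1,1,0), W = c(1,0,0,1),
    K = c(0,0,1,1), M = c(1,1,0,0),
    B = c(0,1,1,1), D = c(1,0,1,1), H = c(1,1,0,1), V = c(1,1,1,0),
    N = c(1,1,1,1), "-" = c(1,1,1,1), "?" = c(1,1,1,1), "." = c(1,1,1,1)
  )
  m <- matrix(1, 4, 256)
  for (ch in names(tab)) {
    m[, utf8ToInt(ch) + 1L] <- tab[[ch]]
    lo <- tolower(ch)
    if (lo != ch) m[, utf8ToInt(lo) + 1L] <- tab[[ch]]
  }
  m
})

#' Construct an element alignment
#'
#' An alignment is a character matrix with one row per taxon (rownames
#' are taxon labels) over the DNA alphabet plus gaps and IUPAC ambiguity
#' codes. All rows have equal length.
#'
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix with rownames.
#' @param id optional element identifier stored as an attribute.
#' @return character matrix of class `tfbs_alignment`.
#' @export
as_alignment <- function(seqs, id = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    n <- nchar(seqs)
    if (length(unique(n)) != 1) stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment rows must carry unique taxon names")
  bad <- setdiff(unique(as.vector(m)),
                 c(strsplit("ACGTURYSWKMBDHVN-?.", "")[[1]],
                   strsplit("acgturyswkmbdhvn", "")[[1]]))
  if (length(bad))
    stop("characters outside the DNA/IUPAC alphabet: ",
         paste(bad, collapse = " "))
  structure(m, class = c("tfbs_alignment", class(m)), element_id = id)
}

#' Read a multi-FASTA alignment
#' @param path FASTA file; record names must match tree tip labels.
#' @param id optional element id (defaults to the file name).
#' @return a [as_alignment()] matrix.
#' @export
read_alignment_fasta <- function(path, id = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  as_alignment(setNames(as.character(x), names(x)), id = id)
}

#' Write an alignment as multi-FASTA
#' @param aln alignment matrix.
#' @param path output path.
#' @param header optional comment lines (e.g. recording the seed) written
#'   as `;`-prefixed lines before the records.
#' @export
write_alignment_fasta <- function(aln, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("; ", header), con)
  for (i in seq_len(nrow(aln))) {
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  }
  invisible(path)
}

# Site-pattern compression + tip partials, reusable across likelihood
# evaluations on the same alignment/tree pair.
prepare_likelihood_data <- function(aln, tree) {
  tree <- as_postorder_tree(tree)
  if (!is.matrix(aln)) aln <- as_alignment(aln)
  if (ncol(aln) == 0) stop("empty alignment")
  extra <- setdiff(rownames(aln), tree$tip.label)
  if (length(extra))
    stop("alignment taxa not in tree: ", paste(extra, collapse = ", "))
  key <- apply(aln, 2, paste, collapse = "\r")
  upat <- !duplicated(key)
  idx <- match(key, key[upat])
  wt <- tabulate(idx, nbins = sum(upat))
  sub <- aln[, upat, drop = FALSE]
  ntip <- n_tips(tree)
  npat <- ncol(sub)
  tip_part <- array(1, dim = c(4, npat, ntip))
  for (i in seq_len(nrow(sub))) {
    t_i <- match(rownames(sub)[i], tree$tip.label)
    codes <- utf8ToInt(paste(sub[i, ], collapse = "")) + 1L
    tip_part[, , t_i] <- iupac_partials[, codes, drop = FALSE]
  }
  list(tree = tree, parent = tree$edge[, 1], child = tree$edge[, 2],
       brlen = tree$edge.length, tip_part = tip_part, wt = as.numeric(wt),
       npat = npat, nsites = ncol(aln), ntip = ntip, nint = tree$Nnode,
       signature = paste(ncol(aln), npat,
                         format(sum(wt * seq_len(npat)), digits = 15),
                         sep = ":"))
}

# fast path used by every fit: eigensystem precomputed, per-edge scales
loglik_prepared <- function(ld, eig, freq, cat_rates, scale) {
  cpp_alignment_loglik(ld$parent, ld$child, ld$brlen, scale,
                       eig$U, eig$Uinv, eig$eigval, freq, cat_rates,
                       as.numeric(ld$tip_part), ld$wt, ld$npat, ld$ntip,
                       ld$nint)
}

#' Alignment log-likelihood under GTR+Gamma with branch scaling
#'
#' Felsenstein pruning over site patterns, mixing the discrete-Gamma
#' rate categories with equal weights at the column level. Each branch
#' length is multiplied by the scale of its foreground/background class
#' before computing transition probabilities. Gaps, `N` and IUPAC
#' ambiguity codes are marginalized as missing data, as are taxa absent
#' from the alignment.
#'
#' @param aln alignment matrix (taxa x sites).
#' @param tree postorder `phylo` tree; alignment taxa must be a subset of
#'   its tips.
#' @param gtr a [gtr_params()] object.
#' @param rates a [discretize_gamma()] model.
#' @param scaling optional [branch_scaling()] map (or a single scale
#'   applied to all branches); default no scaling.
#' @return the log-likelihood (a finite value `<= 0`).
#' @export
alignment_log_likelihood <- function(aln, tree, gtr, rates,
                                     scaling = NULL) {
  ld <- prepare_likelihood_data(aln, tree)
  eig <- gtr_eigen(gtr)
  sc <- edge_scales(scaling, length(ld$brlen))
  loglik_prepared(ld, eig, gtr$freq, rates$rates, sc)
}
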