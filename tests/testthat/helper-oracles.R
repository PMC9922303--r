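# Independent oracles and small fixtures shared across tests.

# Exhaustive sum-over-internal-state likelihood: feasible up to ~5 tips.
# Deliberately naive and independent of the pruning engine.
brute_force_loglik <- function(aln, tree, gtr, rates) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  code <- c(A = 1, C = 2, G = 3, T = 4)
  total <- 0
  for (col in seq_len(ncol(aln))) {
    lik <- 0
    for (k in seq_len(rates$K)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        transition_matrix(gtr, tree$edge.length[e] * rates$rates[k]))
      sk <- 0
      for (combo in seq_len(4^nint) - 1) {
        st <- integer(ntip + nint)
        st[seq_len(ntip)] <- code[aln[tree$tip.label, col]]
        for (j in seq_len(nint))
          st[ntip + j] <- (combo %/% 4^(j - 1)) %% 4 + 1
        pr <- gtr$freq[st[ntip + 1]]
        for (e in seq_len(nrow(tree$edge)))
          pr <- pr * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
        sk <- sk + pr
      }
      lik <- lik + sk / rates$K
    }
    total <- total + log(lik)
  }
  unname(total)
}

random_gtr <- function() {
  gtr_params(rates = exp(runif(6, -1, 1)),
             freq = as.numeric(rmultinom(1, 400, rep(0.25, 4)) + 1))
}

random_columns_alignment <- function(taxa, n = 16) {
  m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * n,
                     replace = TRUE),
              length(taxa), n, dimnames = list(taxa, NULL))
  as_alignment(m)
}

fixture_ref <- function() synthetic_reference_model()

set_scales_test <- function(fg, r1, r2) {
  fg$scales <- c(foreground = r1, background = r2)
  fg
}

# brute-force per-base interval oracles (0-based half-open BED logic)
covered_bases <- function(df, chrom, lo, hi) {
  pos <- lo:(hi - 1)
  hit <- rep(FALSE, length(pos))
  rows <- df[df$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(rows)))
    hit <- hit | (pos >= rows$start[r] & pos < rows$end[r])
  pos[hit]
}

k_of_n_bases <- function(factor_list, chrom, lo, hi, k) {
  pos <- lo:(hi - 1)
  cnt <- rep(0L, length(pos))
  for (df in factor_list)
    cnt <- cnt + (pos %in% covered_bases(df, chrom, lo, hi))
  pos[cnt >= k]
}

random_bed <- function(n, chrom = "chr1", span = 1000, seed_width = 50) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(seed_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             name = NA_character_, score = NA_real_,
             stringsAsFactors = FALSE)
}
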