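test_that("newick parsing validates structure and rejects bad input", {
  tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(nrow(tr$edge), 4)

  expect_error(parse_newick("((A:0.1,A:0.2):0.05,C:0.3);"), "duplicate")
  expect_error(parse_newick("((A:0.1,B):0.05,C:0.3);"), "branch length")
  expect_error(parse_newick("not a tree"), "malformed")

  fx <- synthetic_primate_tree()
  expect_length(fx$tip.label, 10)
  expect_true(all(c("human", "chimp", "gorilla", "orangutan", "macaque",
                    "baboon", "marmoset", "tarsier", "mouse_lemur",
                    "bushbaby") %in% fx$tip.label))
})

test_that("GTR rate matrix satisfies conservation and detailed balance", {
  # Jukes-Cantor limit
  Q <- gtr_rate_matrix(gtr_params())
  expect_equal(unname(Q[row(Q) != col(Q)]), rep(1 / 3, 12))
  expect_equal(unname(diag(Q)), rep(-1, 4))

  set.seed(71)
  for (i in 1:20) {
    g <- random_gtr()
    Q <- gtr_rate_matrix(g)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_lt(max(abs(outer(g$freq, rep(1, 4)) * Q -
                        t(outer(g$freq, rep(1, 4)) * Q))), 1e-10)
    expect_equal(-sum(g$freq * diag(Q)), 1, tolerance = 1e-12)
  }
  expect_error(gtr_params(freq = c(-0.1, 0.4, 0.35, 0.35)), "positive")
  expect_error(gtr_params(rates = c(0, 1, 1, 1, 1, 1)), "positive")
})

test_that("transition matrices match closed forms and CTMC laws", {
  jc <- gtr_params()
  expect_equal(transition_matrix(jc, 0), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # Jukes-Cantor closed form at t = 0.3
  P <- transition_matrix(jc, 0.3)
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-0.4), 4),
               tolerance = 1e-10)
  expect_equal(unname(P[row(P) != col(P)]),
               rep(0.25 - 0.25 * exp(-0.4), 12), tolerance = 1e-10)

  set.seed(5)
  for (i in 1:10) {
    g <- random_gtr()
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    P1 <- transition_matrix(g, t1)
    expect_lt(max(abs(rowSums(P1) - 1)), 1e-12)
    expect_true(all(P1 >= 0 & P1 <= 1))
    # Chapman-Kolmogorov
    expect_equal(transition_matrix(g, t1 + t2), P1 %*%
                   transition_matrix(g, t2), tolerance = 1e-10)
    # ergodic limit: every row converges to the stationary frequencies
    Pinf <- transition_matrix(g, 1e6)
    expect_equal(unname(Pinf), matrix(g$freq, 4, 4, byrow = TRUE),
                 tolerance = 1e-8)
  }
  expect_error(transition_matrix(jc, -0.1), ">= 0")
})

test_that("discrete-Gamma categories have unit mean and correct bins", {
  for (alpha in c(0.2, 1, 2, 7)) {
    rm <- discretize_gamma(alpha, 4)
    expect_equal(mean(rm$rates), 1, tolerance = 1e-10)
    expect_true(all(diff(rm$rates) > 0))
    expect_equal(rm$probs, rep(0.25, 4))
  }
  # exponential case: top bin mean is 1 + log(4) by direct integration
  rm1 <- discretize_gamma(1, 4)
  expect_equal(rm1$rates[4], 1 + log(4), tolerance = 1e-6)
  # rate homogeneity limit
  expect_equal(discretize_gamma(1e6, 4)$rates, rep(1, 4),
               tolerance = 1e-2)
  expect_error(discretize_gamma(0), "positive")
  expect_error(discretize_gamma(-1), "positive")
})

test_that("pruning equals the exhaustive enumeration oracle", {
  set.seed(42)
  topologies <- c("(A:0.12,B:0.3);",
                  "((A:0.1,B:0.2):0.07,C:0.3);",
                  "((A:0.1,B:0.2):0.05,(C:0.15,D:0.3):0.08);",
                  "(((A:0.1,B:0.2):0.05,C:0.15):0.04,D:0.3);",
                  "(((A:0.1,B:0.2):0.05,(C:0.1,D:0.2):0.03):0.04,E:0.25);",
                  "((((A:0.1,B:0.2):0.05,C:0.1):0.03,D:0.2):0.04,E:0.25);")
  for (nwk in topologies) {
    tr <- parse_newick(nwk)
    g <- random_gtr()
    rm <- discretize_gamma(exp(runif(1, -0.5, 1)), 4)
    aln <- random_columns_alignment(tr$tip.label, 16)
    expect_equal(alignment_log_likelihood(aln, tr, g, rm),
                 brute_force_loglik(aln, tr, g, rm), tolerance = 1e-9)
  }
})

test_that("missing data, ordering and degenerate inputs follow the
           marginalization conventions", {
  jc <- gtr_params()
  rm <- discretize_gamma(1, 4)
  tr0 <- parse_newick("(A:0.0,B:0.0);")
  one <- as_alignment(c(A = "A", B = "A"))
  expect_equal(alignment_log_likelihood(one, tr0, jc, rm), log(0.25))

  tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
  gapcol <- as_alignment(c(A = "-", B = "N", C = "?"))
  expect_equal(alignment_log_likelihood(gapcol, tr, jc, rm), 0)

  # partial ambiguity marginalizes over consistent states only
  g <- gtr_params(c(1.2, 3, 0.7, 1.1, 4, 1), c(0.3, 0.2, 0.25, 0.25))
  amb <- as_alignment(c(A = "R", B = "A", C = "G"))
  by_hand <- log(exp(alignment_log_likelihood(
    as_alignment(c(A = "A", B = "A", C = "G")), tr, g, rm)) +
      exp(alignment_log_likelihood(
        as_alignment(c(A = "G", B = "A", C = "G")), tr, g, rm)))
  expect_equal(alignment_log_likelihood(amb, tr, g, rm), by_hand,
               tolerance = 1e-10)

  # invariance to column order and to taxon row order
  set.seed(9)
  aln <- random_columns_alignment(c("A", "B", "C"), 30)
  ll <- alignment_log_likelihood(aln, tr, g, rm)
  expect_equal(alignment_log_likelihood(
    as_alignment(aln[, sample(30)]), tr, g, rm), ll, tolerance = 1e-12)
  expect_equal(alignment_log_likelihood(
    as_alignment(aln[c("C", "A", "B"), ]), tr, g, rm), ll,
    tolerance = 1e-12)
  expect_lte(ll, 0)

  # taxa absent from the alignment are missing data
  sub <- as_alignment(aln[c("A", "B"), ])
  expect_lt(alignment_log_likelihood(sub, tr, g, rm), 0)

  expect_error(alignment_log_likelihood(
    as_alignment(c(A = "A", Z = "C")), tr, g, rm), "not in tree")
  expect_error(alignment_log_likelihood(
    matrix(character(), 3, 0, dimnames = list(c("A", "B", "C"), NULL)),
    tr, g, rm), "empty")
})

test_that("branch scaling is equivalent to rescaling the tree and
           pattern compression is exact", {
  set.seed(12)
  tr <- parse_newick("((A:0.1,B:0.2):0.05,(C:0.15,D:0.3):0.08);")
  g <- random_gtr()
  rm <- discretize_gamma(0.8, 4)
  aln <- random_columns_alignment(tr$tip.label, 40)
  for (cc in c(0.3, 1, 2.5)) {
    sc <- branch_scaling(tr, integer(),
                         scales = c(foreground = cc, background = cc))
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * cc
    expect_equal(alignment_log_likelihood(aln, tr, g, rm, sc),
                 alignment_log_likelihood(aln, tr2, g, rm),
                 tolerance = 1e-10)
  }
  # duplicated columns share one computation: likelihood is additive
  rep3 <- as_alignment(aln[, rep(1:40, 3)])
  expect_equal(alignment_log_likelihood(rep3, tr, g, rm),
               3 * alignment_log_likelihood(aln, tr, g, rm),
               tolerance = 1e-9)
})

test_that("the engine agrees with an independent implementation on the
           ten-primate model", {
  ref <- fixture_ref()
  aln <- simulate_alignment(ref, NULL, 300, seed = 77)
  pd <- phangorn::phyDat(aln, type = "DNA")
  fit <- phangorn::pml(ref$tree, pd, bf = ref$gtr$freq,
                       Q = unname(ref$gtr$rates),
                       shape = ref$rates$alpha, k = 4)
  expect_equal(alignment_log_likelihood(aln, ref$tree, ref$gtr,
                                        ref$rates),
               as.numeric(stats::logLik(fit)), tolerance = 1e-8)
})
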