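test_that("BED parsing validates coordinates with line numbers", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300\tFOXP2", "chr2\t5\t10\tNANOG\t7.5"), f)
  bed <- read_bed(f)
  expect_equal(bed$end - bed$start, c(200L, 5L))
  expect_equal(bed$name, c("FOXP2", "NANOG"))
  expect_equal(bed$score, c(NA, 7.5))

  writeLines("chr1\t300\t100", f)
  expect_error(read_bed(f), "line 1.*start >= end")
  writeLines(c("chr1\t1\t2\tok", "chr1\tx\t2"), f)
  expect_error(read_bed(f), "line 2.*non-numeric")
  writeLines(character(), f)
  expect_equal(nrow(read_bed(f)), 0)
})

test_that("exclusion uses half-open overlap: one shared base drops, an
           abutting interval survives", {
  iv <- data.frame(chrom = "chr1", start = c(100L, 500L),
                   end = c(300L, 600L), name = NA, score = NA)
  ex1 <- data.frame(chrom = "chr1", start = 299L, end = 400L,
                    name = NA, score = NA)
  expect_equal(exclude_regions(iv, ex1)$start, 500L)
  ex2 <- data.frame(chrom = "chr1", start = 300L, end = 400L,
                    name = NA, score = NA)
  expect_equal(nrow(exclude_regions(iv, ex2)), 2)
  expect_identical(exclude_regions(iv, iv[0, ]), iv)
})

test_that("abutting random intervals never overlap (per-base oracle)", {
  set.seed(202)
  for (r in 1:10) {
    iv <- random_bed(8)
    ex <- random_bed(8)
    kept <- exclude_regions(iv, ex)
    exbase <- covered_bases(ex, "chr1", 0, 1100)
    manual <- vapply(seq_len(nrow(iv)), function(i)
      !any(seq(iv$start[i], iv$end[i] - 1) %in% exbase), TRUE)
    expect_equal(kept$start, iv$start[manual])
  }
})

maf_text <- c(
  "##maf version=1",
  "a score=1.0",
  "s hg.chr1 10 8 + 1000 ACG-TACGT",
  "s pt.chr5 20 9 + 900  ACGCTACGA",
  "s gg.chr2 30 8 + 800  AC--TACGG",
  "",
  "a score=2.0",
  "s hg.chr1 22 4 + 1000 TTTT",
  "s pt.chr5 40 4 + 900  TCTT")

test_that("MAF extraction restricts to reference positions, drops
           reference gaps and stitches blocks", {
  f <- tempfile(fileext = ".maf")
  writeLines(maf_text, f)
  maf <- read_maf(f)
  expect_setequal(maf$species, c("hg", "pt", "gg"))

  # the reference row spells ACG-TACGT with a gap: 8 reference bases
  a <- extract_element_alignment(maf, list(chrom = "chr1", start = 10,
                                           end = 18))
  expect_equal(ncol(a), 8)
  expect_equal(paste(a["hg", ], collapse = ""), "ACGTACGT")
  expect_equal(paste(a["pt", ], collapse = ""), "ACGTACGA")
  expect_equal(paste(a["gg", ], collapse = ""), "AC-TACGG")
})

test_that("MAF extraction agrees with a naive per-position oracle and
           handles missing species and coverage gaps", {
  f <- tempfile(fileext = ".maf")
  writeLines(maf_text, f)
  maf <- read_maf(f)

  # naive oracle: reference position -> column characters
  lookup <- function(pos) {
    for (b in maf$blocks) {
      if (b$chrom[1] != "chr1") next
      ref <- strsplit(b$text[1], "")[[1]]
      rp <- b$start[1] + cumsum(ref != "-") - 1L
      hit <- which(ref != "-" & rp == pos)
      if (length(hit)) {
        col <- setNames(rep("N", length(maf$species)), maf$species)
        for (r in seq_len(nrow(b)))
          col[b$species[r]] <- toupper(strsplit(b$text[r], "")[[1]][hit])
        return(col)
      }
    }
    NULL
  }

  # a window spanning both blocks plus an uncovered gap [18, 22)
  a <- extract_element_alignment(maf, list(chrom = "chr1", start = 12,
                                           end = 26))
  covered <- Filter(function(p) !is.null(lookup(p)), 12:25)
  expect_equal(ncol(a), length(covered))
  for (j in seq_along(covered)) {
    expect_equal(a[maf$species, j], lookup(covered[j]),
                 ignore_attr = TRUE)
  }
  # species absent from the second block are all-missing there
  a2 <- extract_element_alignment(maf, list(chrom = "chr1", start = 22,
                                            end = 26))
  expect_true(all(a2["gg", ] == "N"))
  expect_error(extract_element_alignment(maf,
                                         list(chrom = "chr9", start = 0,
                                              end = 5)),
               "not covered")
})

test_that("informative-site counting and the element filter behave
           exactly at their boundaries", {
  taxa <- paste0("t", 1:10)
  col_k <- function(k) c(rep("A", k), rep("-", 10 - k))
  aln5 <- as_alignment(matrix(col_k(5), 10, 1,
                              dimnames = list(taxa, NULL)))
  aln4 <- as_alignment(matrix(col_k(4), 10, 1,
                              dimnames = list(taxa, NULL)))
  expect_equal(count_informative_sites(aln5, 5), 1)
  expect_equal(count_informative_sites(aln4, 5), 0)
  allgap <- as_alignment(matrix("-", 10, 20,
                                dimnames = list(taxa, NULL)))
  expect_equal(count_informative_sites(allgap, 5), 0)

  mk <- function(ninf) as_alignment(matrix(
    c(rep(col_k(10), ninf), rep(col_k(2), 60 - ninf)), 10, 60,
    dimnames = list(taxa, NULL)))
  elems <- list(e49 = mk(49), e50 = mk(50), e60 = mk(60))
  kept <- filter_elements(elems, min_informative = 50)
  expect_named(kept, c("e50", "e60"))
  expect_named(filter_elements(elems, min_informative = 0),
               c("e49", "e50", "e60"))
})

test_that("composite 2-of-3 and intersection groups match the per-base
           oracle", {
  pou <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                    name = NA, score = NA)
  nan <- data.frame(chrom = "chr1", start = 200L, end = 400L,
                    name = NA, score = NA)
  res <- define_composite_groups(
    list(POU5F1 = pou, NANOG = nan),
    list(list(name = "POU5F1-NANOG", type = "intersection",
              factors = c("POU5F1", "NANOG"))))
  expect_equal(res$composites[["POU5F1-NANOG"]][, c("start", "end")],
               data.frame(start = 200L, end = 300L),
               ignore_attr = TRUE)

  set.seed(303)
  for (r in 1:8) {
    facs <- list(BDP1 = random_bed(6), BRF1 = random_bed(6),
                 POLR3G = random_bed(6))
    res <- define_composite_groups(
      facs, list(list(name = "PolIII", type = "k_of_n",
                      factors = names(facs), k = 2)))
    got <- covered_bases(res$composites$PolIII, "chr1", 0, 1200)
    want <- k_of_n_bases(facs, "chr1", 0, 1200, 2)
    expect_equal(got, want)
    # factor intervals overlapping the composite left their groups
    for (fac in names(facs)) {
      pruned <- res$factors[[fac]]
      if (!nrow(pruned)) next
      for (i in seq_len(nrow(pruned)))
        expect_false(any(seq(pruned$start[i], pruned$end[i] - 1) %in%
                           got))
    }
  }
  expect_error(define_composite_groups(
    list(A = random_bed(2)),
    list(list(name = "x", type = "k_of_n", factors = c("A", "B"),
              k = 2))), "unknown factor")
})

test_that("cross-group overlap removal drops both offenders and keeps
           within-group overlaps", {
  gX <- data.frame(chrom = "chr1", start = c(0L, 50L, 500L),
                   end = c(100L, 120L, 600L), name = NA, score = NA)
  gY <- data.frame(chrom = "chr1", start = c(90L, 700L),
                   end = c(200L, 800L), name = NA, score = NA)
  out <- remove_multigroup_overlaps(list(X = gX, Y = gY))
  # X[0,100) and X[50,120) overlap Y[90,200): all three removed;
  # within-group overlap between the two X intervals alone is fine
  expect_equal(out$X$start, 500L)
  expect_equal(out$Y$start, 700L)
  disjoint <- list(A = data.frame(chrom = "chr1", start = 0L, end = 10L,
                                  name = NA, score = NA),
                   B = data.frame(chrom = "chr1", start = 10L, end = 20L,
                                  name = NA, score = NA))
  expect_identical(remove_multigroup_overlaps(disjoint), disjoint)

  set.seed(404)
  for (r in 1:5) {
    gs <- list(A = random_bed(6), B = random_bed(6))
    out <- remove_multigroup_overlaps(gs)
    basesB <- covered_bases(gs$B, "chr1", 0, 1200)
    manual <- vapply(seq_len(nrow(gs$A)), function(i)
      !any(seq(gs$A$start[i], gs$A$end[i] - 1) %in% basesB), TRUE)
    expect_equal(out$A$start, gs$A$start[manual])
  }
})

test_that("group concatenation preserves columns and likelihood
           additivity", {
  ref <- fixture_ref()
  elems <- lapply(1:3, function(i)
    simulate_alignment(ref, NULL, 200, seed = 600 + i))
  concat <- concatenate_group(elems)
  expect_equal(ncol(concat), 600)
  expect_equal(attr(concat, "boundaries"), c(200L, 400L, 600L))
  expect_identical(concatenate_group(elems[1])[, ], elems[[1]][, ])
  ll_sum <- sum(vapply(elems, function(a)
    alignment_log_likelihood(a, ref$tree, ref$gtr, ref$rates), 0))
  expect_equal(alignment_log_likelihood(concat, ref$tree, ref$gtr,
                                        ref$rates),
               ll_sum, tolerance = 1e-8)
  bad <- elems
  rownames(bad[[2]])[1] <- "other"
  expect_error(concatenate_group(bad), "taxon set")
})
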