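# All interval arithmetic is BED-style: 0-based, half-open [start, end).
# Internally converted to 1-based closed GRanges, so abutting BED
# intervals never overlap.

bed_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_bed <- function(gr, name = NA_character_) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = name, score = NA_real_,
             stringsAsFactors = FALSE)
}

#' Read a BED3+ file of genomic intervals
#'
#' Columns: chrom, start, end, optional name (used as the factor/group
#' label) and score. Coordinates are 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, name, score.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < 3)
      stop("BED parse error at line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop("BED parse error at line ", i, ": non-numeric coordinates")
    if (start < 0)
      stop("BED parse error at line ", i, ": negative coordinate")
    if (start >= end)
      stop("BED parse error at line ", i, ": start >= end")
    data.frame(chrom = f[1], start = start, end = end,
               name = if (length(f) >= 4) f[4] else NA_character_,
               score = if (length(f) >= 5)
                 suppressWarnings(as.numeric(f[5])) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Drop intervals overlapping an exclusion set
#'
#' Any interval overlapping (by at least 1 bp) any exclusion interval —
#' UTRs, CDSs, previously identified accelerated regions — is removed
#' outright; survivors are kept intact, never trimmed. Abutting
#' half-open intervals do not overlap.
#'
#' @param intervals,exclusions BED data.frames ([read_bed()] layout).
#' @return the filtered intervals data.frame.
#' @export
exclude_regions <- function(intervals, exclusions) {
  if (!nrow(intervals) || !nrow(exclusions)) return(intervals)
  hits <- GenomicRanges::findOverlaps(bed_to_granges(intervals),
                                      bed_to_granges(exclusions))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) intervals[-drop, , drop = FALSE] else intervals
}

#' Read a MAF genome-alignment file
#'
#' Minimal parser for block-based MAF: each `a` line opens a block whose
#' `s` lines carry src (species.chrom), start, size, strand, srcSize and
#' the aligned text. The first `s` line of each block is the reference.
#'
#' @param path MAF file path.
#' @return object of class `maf`: list of blocks plus the union species
#'   set.
#' @export
read_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && nrow(cur)) c(blocks, list(cur)) else blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- data.frame(species = character(), chrom = character(),
                        start = integer(), size = integer(),
                        strand = character(), src_size = integer(),
                        text = character(), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7) stop("malformed MAF 's' line: ", ln)
      src <- strsplit(f[2], ".", fixed = TRUE)[[1]]
      cur <- rbind(cur, data.frame(
        species = src[1],
        chrom = if (length(src) > 1)
          paste(src[-1], collapse = ".") else NA_character_,
        start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE))
    }
  }
  blocks <- flush(cur, blocks)
  structure(list(blocks = blocks,
                 species = unique(unlist(lapply(blocks,
                                                function(b) b$species)))),
            class = "maf")
}

#' Extract one element's alignment from a MAF source
#'
#' Restricts the genome alignment to reference positions in
#' `[start, end)` of the interval. Columns where the reference carries a
#' gap are excluded (elements are defined in reference coordinates), so
#' the result has at most `end - start` columns. Species missing from a
#' covering block contribute `N` (missing data); positions covered by no
#' block are skipped. Blocks are stitched in reference order.
#'
#' @param source a [read_maf()] object.
#' @param interval one BED row (list or 1-row data.frame with chrom,
#'   start, end, optionally name).
#' @return an element alignment over the MAF's species set.
#' @export
extract_element_alignment <- function(source, interval) {
  if (!inherits(source, "maf")) stop("'source' must be a read_maf() object")
  chrom <- as.character(interval$chrom)
  lo <- as.integer(interval$start)
  hi <- as.integer(interval$end)
  species <- source$species
  ref_sp <- source$blocks[[1]]$species[1]
  covering <- Filter(function(b) {
    b$species[1] == ref_sp && b$chrom[1] == chrom &&
      b$start[1] < hi && (b$start[1] + b$size[1]) > lo
  }, source$blocks)
  if (!length(covering)) {
    on_chrom <- any(vapply(source$blocks,
                           function(b) b$chrom[1] == chrom, TRUE))
    if (!on_chrom)
      stop("interval chromosome ", chrom, " not covered by the MAF source")
    # covered chromosome but a gap in coverage: zero-column element
    m <- matrix(character(), length(species), 0,
                dimnames = list(species, NULL))
    return(structure(m, class = c("tfbs_alignment", class(m))))
  }
  covering <- covering[order(vapply(covering, function(b) b$start[1], 0L))]
  cols <- list()
  pos_seen <- integer()
  for (b in covering) {
    ref_chars <- strsplit(b$text[1], "")[[1]]
    is_base <- ref_chars != "-"
    ref_pos <- b$start[1] + cumsum(is_base) - 1L  # 0-based ref position
    keep <- which(is_base & ref_pos >= lo & ref_pos < hi &
                    !(ref_pos %in% pos_seen))
    if (!length(keep)) next
    pos_seen <- c(pos_seen, ref_pos[keep])
    block_rows <- matrix("N", length(species), length(keep))
    rownames(block_rows) <- species
    for (r in seq_len(nrow(b))) {
      ch <- strsplit(b$text[r], "")[[1]]
      block_rows[b$species[r], ] <- toupper(ch[keep])
    }
    cols[[length(cols) + 1]] <-
      block_rows[, order(ref_pos[keep]), drop = FALSE]
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(character(), length(species), 0, dimnames = list(species, NULL))
  as_alignment(m, id = if (!is.null(interval$name) &&
                           !is.na(interval$name))
    as.character(interval$name) else NULL)
}

#' Count informative alignment sites
#'
#' An informative site is a column with unambiguous bases (A, C, G or T)
#' in at least `min_species` species. This screens out low-quality,
#' gap-dominated alignment columns.
#'
#' @param aln alignment matrix.
#' @param min_species species threshold (default 5, i.e. at least five
#'   of ten primates).
#' @return number of informative columns.
#' @export
count_informative_sites <- function(aln, min_species = 5) {
  if (min_species < 1) stop("'min_species' must be >= 1")
  if (!ncol(aln)) return(0L)
  unamb <- matrix(toupper(aln) %in% c("A", "C", "G", "T"), nrow(aln))
  sum(colSums(unamb) >= min_species)
}

#' Filter element alignments on informative-site count
#'
#' @param elements named list of element alignments (one group), or a
#'   named list of such lists (several groups).
#' @param min_informative minimum informative sites (default 50).
#' @param min_species species threshold per site (default 5).
#' @return the same structure with failing elements removed.
#' @export
filter_elements <- function(elements, min_informative = 50,
                            min_species = 5) {
  if (length(elements) && is.list(elements[[1]]) &&
      !is.matrix(elements[[1]])) {
    return(lapply(elements, filter_elements,
                  min_informative = min_informative,
                  min_species = min_species))
  }
  keep <- vapply(elements, function(a)
    count_informative_sites(a, min_species) >= min_informative, TRUE)
  elements[keep]
}

#' Build composite element groups from co-bound regions
#'
#' Two rule types. `k_of_n`: genomic regions covered, at base level, by
#' peaks of at least `k` of the named factors (e.g. regions bound by at
#' least two of the three Pol III factors); maximal runs of sufficient
#' coverage become the composite members. `intersection`: the base-level
#' intersection of all named factors' peaks. Source-factor intervals
#' overlapping a composite member are removed from their factor groups,
#' so the remaining factor groups are exclusive.
#'
#' @param factor_intervals named list of BED data.frames, one per
#'   factor.
#' @param rules list of rules, each a list with `name`, `type`
#'   (`"k_of_n"` or `"intersection"`), `factors` (character) and, for
#'   `k_of_n`, `k`.
#' @return list with `composites` (named list of BED data.frames) and
#'   `factors` (the pruned source groups).
#' @export
define_composite_groups <- function(factor_intervals, rules) {
  for (rule in rules) {
    unknown <- setdiff(rule$factors, names(factor_intervals))
    if (length(unknown))
      stop("unknown factor(s) in rule '", rule$name, "': ",
           paste(unknown, collapse = ", "))
  }
  composites <- list()
  pruned <- factor_intervals
  for (rule in rules) {
    grl <- lapply(factor_intervals[rule$factors], function(df)
      GenomicRanges::reduce(bed_to_granges(df)))
    if (identical(rule$type, "k_of_n")) {
      k <- rule$k
      cov <- GenomicRanges::coverage(do.call(c, unname(grl)))
      sl <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
      gr <- GenomicRanges::GRanges(sl)
    } else if (identical(rule$type, "intersection")) {
      gr <- Reduce(GenomicRanges::intersect, grl)
    } else {
      stop("unknown rule type: ", rule$type)
    }
    composites[[rule$name]] <- granges_to_bed(gr, name = rule$name)
    for (fac in rule$factors) {
      df <- pruned[[fac]]
      if (!nrow(df) || !length(gr)) next
      hits <- GenomicRanges::findOverlaps(bed_to_granges(df), gr)
      drop <- unique(S4Vectors::queryHits(hits))
      if (length(drop)) pruned[[fac]] <- df[-drop, , drop = FALSE]
    }
  }
  list(composites = composites, factors = pruned)
}

#' Remove elements overlapping another group
#'
#' Any element overlapping (by at least 1 bp) an element of a different
#' group is removed from all groups; within-group overlaps are left
#' untouched. The result is a set of mutually non-overlapping groups.
#'
#' @param groups named list of BED data.frames.
#' @return the same list with cross-group-overlapping rows removed.
#' @export
remove_multigroup_overlaps <- function(groups) {
  tags <- rep(names(groups), vapply(groups, nrow, 0L))
  if (!length(tags)) return(groups)
  all_df <- do.call(rbind, groups)
  gr <- bed_to_granges(all_df)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  bad <- unique(q[tags[q] != tags[s]])
  keep <- !(seq_along(tags) %in% bad)
  split_keep <- split(keep, factor(tags, levels = names(groups)))
  out <- groups
  for (g in names(groups))
    out[[g]] <- groups[[g]][split_keep[[g]], , drop = FALSE]
  out
}

#' Concatenate a group's element alignments
#'
#' Columns are concatenated in element order; all elements must share
#' the same taxon set (rows are reordered to the first element's order).
#' Element boundaries are recorded in the `boundaries` attribute for
#' provenance.
#'
#' @param elements list of element alignments.
#' @return a single concatenated alignment.
#' @export
concatenate_group <- function(elements) {
  if (!length(elements)) stop("empty group")
  taxa <- rownames(elements[[1]])
  mats <- lapply(elements, function(a) {
    if (!setequal(rownames(a), taxa))
      stop("elements do not share a common taxon set")
    a[taxa, , drop = FALSE]
  })
  out <- as_alignment(do.call(cbind, mats))
  attr(out, "boundaries") <- cumsum(vapply(mats, ncol, 0L))
  out
}
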