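---
title: "Pooling-based detection of lineage-specific accelerated evolution"
author: "groupacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling-based detection of lineage-specific accelerated evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupacc)
```

## The problem

Comparative genomics has catalogued a few thousand individually striking
accelerated elements — conserved regions whose substitution rate jumped
in one lineage. Most regulatory sequence, however, is not strongly
conserved, and acceleration in it is expected to be *weak*: too little
alignment data per element, and too heavy a multiple-testing burden, for
element-by-element scans to see anything. `groupacc` takes the opposite
route: it pools hundreds or thousands of functionally related elements
(canonically, ChIP-seq binding-site peaks of one transcription factor)
and asks whether the *group* evolves faster in a foreground lineage than
in the background.

Two estimators are provided:

1. a **group-level likelihood ratio test** on the concatenated group
   alignment, and
2. a **phylogenetic mixture estimate** of *how many* elements in a
   significant group are accelerated, built from element-level
   statistics calibrated by parametric bootstrapping.

## The model

Everything rests on a **reference model**: a fixed rooted tree with
branch lengths $b_e$ (expected substitutions per site), a GTR
substitution matrix $Q$ (six exchangeabilities, four stationary
frequencies, normalized to unit mean rate at stationarity) and a
discrete-Gamma site-rate model with shape $\alpha$ and $K = 4$
equal-probability categories whose rates are bin means, so the mean
rate is exactly 1. The reference model is fitted once, by maximum
likelihood on the concatenation of *all* elements
(`fit_reference_model()`, delegating the standard GTR+Gamma
optimization to `phangorn::optim.pml` and mapping the fitted lengths
back onto the rooted topology, which is likelihood-invariant for a
reversible model). The premise is that most elements are *not*
accelerated, so this backbone captures baseline binding-site evolution.

Acceleration is modelled purely through **branch-length scaling**. A
foreground lineage — a tip, or a monophyletic clade including its stem
branch — splits the branches into foreground and background classes.
Under the null $H_0$ a single scale $r$ multiplies every branch; under
the alternative $H_a$ the foreground gets $r_1$ and the background
$r_2$. All other parameters stay frozen at the reference fit. The
likelihood is computed by Felsenstein pruning over compressed site
patterns with gaps and IUPAC codes marginalized as missing data, mixing
the four Gamma categories with equal weights at each column.

The group-level statistic is $2(\ell_a - \ell_0)$, clipped at zero
(the models are nested; negative values are optimizer noise), referred
to $\chi^2_1$ — defensible at group scale where a concatenation holds
$10^4$–$10^6$ columns — and Bonferroni-adjusted across the groups
tested in a batch. A group is called accelerated when the null is
rejected *and* $r_1 > r_2$.

## Counting accelerated elements

The same two-scale-versus-one-scale statistic applied to a single
200 bp element does *not* follow $\chi^2_1$; with less than one
expected foreground substitution per element the statistic is discrete
and conservative. The package therefore calibrates element statistics
by a **group-level parametric bootstrap**: the group's $H_0$ fit
supplies a global scale, `B` alignments of lengths resampled from the
group's element lengths are simulated under that calibrated model, and
each element's statistic is converted to an empirical p-value with the
pseudocount convention $p = (1 + \#\{\text{null} \ge s\})/(1 + B)$,
which keeps $p > 0$.

A **beta-uniform mixture** is then fitted to the group's p-values,
density $f(x \mid a, \lambda) = \lambda + (1-\lambda)\,a\,x^{a-1}$ on
$(0, 1]$ with $a \in (0,1]$ so the beta part is decreasing (enrichment
near zero). Because the true alternative density is non-negative at
$x = 1$, $\hat\pi_{ub} = \hat\lambda + (1-\hat\lambda)\hat a = \hat f(1)$
upper-bounds the null fraction, and $1 - \hat\pi_{ub}$ is a
*conservative lower bound* on the accelerated fraction;
multiplying by the group size gives the accelerated-element count. A
95% confidence interval comes from the 2-degree-of-freedom profile
region $2(\ell(\hat a,\hat\lambda) - \ell(a^\star,\lambda^\star)) \le
\chi^2_{2,0.95} = 5.991$, scanned on a grid (200×200, refined fourfold
around the retained region) and mapped through
$\pi^\star_{ub} = \lambda^\star + (1-\lambda^\star)a^\star$. A
1-df profile on the scalar $\pi_{ub}$ would be narrower; the 2-df joint
region is implemented as specified for the method.

## When did acceleration happen?

A group detected with a human foreground may really have accelerated
anywhere on the path from the human tip to the root. `scan_lineages()`
fits $H_a$ once per nested candidate foreground — the focal tip, then
each ancestor clade short of the root (seven candidates, M1–M7, on the
ten-primate tree) — and ranks them by
$\mathrm{BIC} = -2\ell + k\log n$ with $k = 2$ and $n$ the number of
alignment columns. The **minimum** BIC wins; ties break toward the
smaller, tip-ward clade (the most parsimonious foreground). Columns,
not columns × taxa, are counted as observations because columns are the
independent units in the likelihood.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_species` | 5 | unambiguous bases required for an informative site |
| `min_informative` | 50 | informative sites required to keep an element |
| `B` | 10,000 | bootstrap replicates per group |
| `m` | batch size | Bonferroni test count, recorded explicitly |
| scale bounds | $[10^{-4}, 10^3]$ | box for all scale optimizations (log grid, multi-start) |
| `element_length` | 200 bp | simulator default, the median binding-site alignment length this emulates |

## The simulator and what it does (not) cover

`simulate_alignment()` draws each column independently: a Gamma
category, a root state from the stationary frequencies, then
transitions $P(\text{rate}\times\text{scale}\times b_e)$ down the tree.
Three scenarios reproduce the validation designs: (1) every element
fully accelerated; (2) a fraction `L` of each element's columns
accelerated — placed as a contiguous leading segment, mimicking a
motif; placement is immaterial to an i.i.d.-column likelihood; (3) a
fraction `M` of elements accelerated. Eight cases place the
acceleration on human, Hominini, human–chimp–gorilla, the ape clade,
chimp, gorilla, orangutan or macaque. Randomness flows from one master
seed through per-element derived streams, so enlarging a batch never
perturbs existing elements.

The shipped ten-primate tree and GTR+Gamma parameters are a *synthetic*
backbone with plausible magnitudes (hand-set branch lengths, mammal-like
exchangeabilities, $\alpha = 2$); they are not calibrated to any genome
alignment. The simulator draws no indels, no missing species, no
alignment error, no GC-biased gene conversion and no rate
autocorrelation along the sequence. Passing tests therefore demonstrate
the statistical machinery under the model's own assumptions — not
robustness to real-alignment pathologies, which the informative-site
and element-length filters only partially address.

## Numerical choices

* Scale fits are bounded in $[10^{-4}, 10^3]$ on the log scale; the
  two-scale fit starts from the null solution and from half/double it,
  because the likelihood is nearly flat in $r_1$ for short foregrounds.
  The alternative can never fall below the null (the null point is a
  candidate), so clipping the LRT statistic at zero only removes noise.
* The mixture fit uses a 50×50 grid then box-constrained refinement;
  the surface has a boundary ridge at $\lambda \to 1$ that local
  optimization alone can miss.
* Empirical p-values are floored at $1/(B+1)$; the beta density would
  diverge at 0 for $a < 1$.
* Invariant alignments drive scales to the lower bound and are reported
  with a convergence warning; degenerate concatenations (fewer than two
  site patterns) are rejected outright.

## Design choices made where the design was open

* **Stem branch belongs to the foreground clade.** A rate change on the
  branch leading to a clade is part of that clade's history; testing a
  single tip then reduces to exactly its terminal branch.
* **Partially ambiguous IUPAC codes** are fully marginalized over their
  consistent states, the standard phylogenetic convention.
* **Best BIC = minimum BIC.** The criterion's definition makes lower
  values better; descriptions of picking the "highest" value conflict
  with that form and are resolved in favour of the standard convention.
* **Scenario-2 summary.** The two-scale model fitted uniformly over
  mosaic columns estimates the *column-weighted average* fold
  $L \cdot (r_1/r_2) + (1 - L)$; the weighted-fold formula
  (`weighted_fold_estimate()`) applied to the true fold is therefore
  the quantity the fitted fold should be compared against, and that is
  how the package's own validation states scenario-2 recovery.
* **Bootstrap calibration uses the group's $H_0$ scale**, not the
  alternative fit — even though accelerated elements inflate that
  scale slightly, which makes the resulting p-values conservative for
  heavily accelerated groups.
* **Composite groups** ("bound by at least two of three factors") are
  defined at base level: maximal runs covered by at least *k* reduced
  factor peak sets. Base-level logic is deterministic and matches a
  per-base counting oracle.
* **The element analysis is gated** on group-level significance by
  default (with an override), since element counts are only sought in
  groups already showing acceleration.

## Validation scale and known limitations

The test-suite simulations run at desk scale — groups of 300–500
elements of 100–200 bp, 50–200 replicate groups for size checks,
$B = 999$ bootstrap replicates — rather than the $10^4$-element,
$B = 10^4$ design the framework targets; these sizes were chosen so
the full suite exercises every code path while remaining quick to run,
and they leave Monte-Carlo noise of a few percent in the reported
rates.

Two statistical caveats are worth stating plainly, because the
package's own validation quantifies both:

* $1 - \hat\pi_{ub}$ is a *bound*, not an unbiased estimate. With a
  weak per-element signal it undershoots the true accelerated
  fraction. With a very strong per-element signal the empirical
  p-values of accelerated elements pile up at the $1/(B+1)$ floor — an
  atom the smooth $a x^{a-1}$ component cannot represent — and the
  maximum-likelihood trade-off can *overshoot* the true count by
  tens of percent even though the bootstrap null is perfectly
  calibrated. The estimate is most accurate in the intermediate regime
  the mixture model was designed for; the confidence interval does not
  capture this misspecification error.
* The group-level $\chi^2_1$ approximation is excellent for
  concatenations of kilobases but conservative per element; that is
  precisely why element-level inference goes through the bootstrap.

Out of scope by design: codon models, more than two rate classes,
multiple rate shifts per tree, indel/turnover simulation, selection
versus gBGC attribution, and enrichment analyses downstream of the
counts.
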