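---
title: "Testing differential clustering of positively selected sites in paralogous proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential clustering of positively selected sites in paralogous proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selclust)
```

## The question

When a gene duplicates, the two copies can divide the ancestral job between
them (subfunctionalization) or one can acquire a new job
(neofunctionalization). Either way, positive selection — an excess of
amino-acid-changing substitutions, detected per site by codon site models
such as PAML's M8 with Bayes Empirical Bayes (BEB) posteriors — is expected
to act on *different regions* of the two paralogs. Reproductive proteins,
such as the abalone sperm acrosomal proteins lysin and sp18 and their
recently recognized paralogs, are a canonical setting: both copies evolve
fast, and the question is whether their selected sites occupy distinct
parts of the molecule.

`selclust` turns that question into three complementary hypothesis tests,
given (a) a pairwise protein alignment of the paralogs, (b) per-paralog
lists of selected alignment columns with BEB posteriors, and (c) a shared
C-alpha structure for one paralog:

1. a **multi-category runs test** for clustering along the alignment,
2. a **plane-partition chi-square** for uneven placement across the
   structure, and
3. a **nearest-selected-site affiliation chi-square** for paralog-specific
   spatial clusters.

## Test 1: the multi-category runs test

Every selected column is labelled `A_ONLY`, `B_ONLY`, or `BOTH` and read
off in alignment order; this is the data string. Its number of **runs** —
maximal blocks of one category, i.e. the number of adjacent category
changes plus one — is the statistic: sites clustered by paralog produce
few long runs.

The null is parametric and simulated. With alignment length $L$ and
marginal selected fractions $\hat p_A = |A|/L$ and $\hat p_B = |B|/L$ (a
`BOTH` column counts in each paralog's fraction, since it is a selected
site in each), every replicate draws, for each of the $L$ columns,
independent Bernoulli indicators for selection in each paralog, discards
unselected columns, and counts runs. The p-value is the fraction of
replicates with **at most** the observed number of runs — one-sided
toward clustering — with no pseudo-count, so the minimum attainable
p-value is $1/\texttt{n\_reps}$'s floor of zero and the replicate count
is always reported alongside. A replicate whose string is empty scores 0
runs, below any observable count; at realistic selected fractions this is
vanishingly rare and errs conservative. The `exclude_both` variant drops
`BOTH` columns from both the observed and the simulated strings.

**Calibration, measured, not assumed.** The test suite simulates the
test's own null: when the bootstrap replicates are generated at the *true*
selection probabilities, rejection at $\alpha = 0.05$ sits inside the
exact binomial band around 5% — the machinery is correct. But the test as
defined plugs the *observed* fractions into the null, which re-centers
every replicate on the observed site composition and removes the
between-dataset variation in site counts from the null distribution. The
measured consequence (500 null datasets, $\alpha = 0.05$) is an empirical
size far below nominal — effectively under 1%. The test is therefore
**conservative**: its significant results are trustworthy, but it
sacrifices power relative to a null conditioned on the true proportions,
which are of course unavailable in practice. Users should read
non-significant results accordingly.

## Test 2: plane-of-best-fit partition

A plane of best fit is computed through all C-alpha coordinates by
ordinary least squares of $z$ on $(x, y)$ — a plane fitted by linear
regression — and the structure is split into the two sides of the plane
("left"/"right"). For one paralog with $n$ selected sites mapped to
residues, the expected count on a side is (residues on that side ÷ total
residues) × $n$; a chi-square with 1 df compares observed to expected,
per paralog separately.

Two genuinely open design points are resolved as follows:

* **Response axis.** OLS of $z$ on $(x, y)$ depends on which coordinate
  is treated as the response, and the axis convention of the original
  deposited coordinates is not recoverable. We therefore also provide
  `method = "pca"`, the total-least-squares plane (normal = the
  smallest-variance principal axis through the centroid), which is
  rotation-invariant; the rigid-body invariance property in the test
  suite is stated and checked for this method. If the normal equations of
  the OLS fit are near-singular (points in a nearly vertical plane), the
  fit aborts and suggests the PCA route rather than returning an unstable
  answer.
* **The perpendicular plane** ("top"/"bottom") is under-determined —
  infinitely many planes are orthogonal to the fitted one. We take the
  plane through the centroid whose normal is the direction of maximal
  C-alpha variance *within* the fitted plane: the only coordinate-free
  choice, and the one that splits the molecule along its widest in-plane
  extent. Isotropic in-plane variance (no unique direction) is an error.

Residues exactly on a plane go to the second label; this is measure-zero
for real coordinates and only matters for synthetic exact-symmetry cases.
Sites selected in both paralogs are counted in each paralog's observed
vector, consistent with the neighbor test's counted-twice rule. Expected
side counts below 5 trigger the usual chi-square small-count warning.

## Test 3: nearest-selected-site affiliation

Each selected site becomes an instance at its residue's C-alpha
coordinate; a column selected in **both** paralogs contributes two
co-located instances, one per paralog. For every instance we find the
Euclidean-nearest other instance and ask whether it belongs to the same
paralog, tallying four cells (A→same, A→other, B→same, B→other). Two
rules govern the shared sites: a shared neighbor always counts as "same"
(it is under selection in the focal paralog too), and an instance's own
co-located twin is not an eligible neighbor (otherwise every shared site
would trivially match itself at distance zero). Distance ties break
deterministically: lower residue index, then paralog A before B.

The expected counts come from random labeling: with $n_A$ and $n_B$
instances, an A instance's nearest neighbor is any of the other
$n_A + n_B - 1$ instances with equal probability, so
$E[\text{A→same}] = n_A (n_A - 1) / (n_A + n_B - 1)$, and analogously for
the other cells; per-paralog totals are preserved. A chi-square over the
four cells with 3 df gives the p-value.

Nearest-neighbor outcomes are not independent, so the chi-square
reference distribution is an approximation. Our null simulations measure
its empirical size at roughly a quarter at nominal 5% — markedly
**anticonservative** — which is why `neighbor_test(..., null =
"permutation")` is provided: it shuffles paralog labels over the fixed
site positions (default 10,000 shuffles, seeded) and reports the fraction
of shuffles with a chi-square at least as large as observed. For
publication-grade inference we recommend the permutation p-value; the
chi-square p-value is retained as the default for continuity with the
test's original formulation.

## Mapping sites onto the structure

Alignment columns are 1-based; residue indices are 1-based and
chain-sequential (the first residue with a C-alpha atom is residue 1),
*not* author PDB numbering — an `offset` argument reconciles the two.
The ungapped reference row must match the structure sequence at ≥ 95%
identity (configurable); below that the mapping aborts naming the first
mismatch, because a silently wrong register would corrupt every
downstream count. Gap columns are unmapped and dropped from the spatial
tests with a logged count. In PDB input, alternate locations and
insertion codes are resolved first-occurrence-wins with a warning; NMR
ensembles are read one model at a time (default: the first model).

## The synthetic generator

`synthetic_spec()` + `generate_bundle()` produce a full testable dataset:

* **Chain.** `random_walk` (uniformly random step directions) or `helix`
  (radius 2.3 Å, 100° twist per residue, rise set so consecutive C-alpha
  spacing is exactly `bond_length`, default 3.8 Å — the observed mean
  C-alpha–C-alpha distance in proteins).
* **Sites.** Defaults emulate the study scale the tests were designed
  for: a 142-column alignment with marginal selected fractions 62/142 and
  30/142 (the mapped BEB site densities of an sp18-like paralog pair; the
  codon-model estimates of the *percentage of sites in the selected
  class* are a different, larger quantity and are not what the tests
  consume). Under `clustering = NULL` columns are selected by independent
  Bernoulli draws — *exactly* the runs-test null. With clustering, each
  paralog's per-residue probability decays as
  $\exp(-d_i/\texttt{decay\_length})$ from its focus residue, scaled to
  keep the expected count at $n \cdot p$ and capped at 1; with very tight
  clusters (small decay lengths) the cap bites and realized site counts
  fall below the nominal expectation — visible in the bundle and reported
  in every result.
* **Alignment.** Gapless; row B carries a substitution at every selected
  column, so divergent columns coincide with the selected union and the
  column→residue mapping is the identity. Gap handling is exercised
  separately in the i/o tests.

What the generator does **not** emulate: real protein compactness and
secondary structure (a random walk is not excluded-volume), correlated
selection between neighboring codons, posterior uncertainty in site
identification (posteriors are drawn from [0.75, 1] merely to pass the
threshold), or alignment error. Passing tests on synthetic bundles
therefore validate the *statistical machinery and its calibration under
the stated model*, not the biological fidelity of any particular dataset.

## Seeds, sizes, and numerical conventions

Every stochastic function takes a `seed` and restores the caller's RNG
state; identical seeds give byte-identical results, and reports echo all
seeds and flags. The BEB retention threshold is inclusive (posterior ≥
0.75 keeps the site). Simulation sizes used by the test suite and the
summary script — 1,000 bootstrap replicates per runs test (20,000 when
checking the null against exhaustive enumeration at $L = 3$), 500
datasets for size, 100 for power, 60 per arm for the neighbor-test
comparison — were chosen so that the binomial error of each estimated
rate is small relative to the effect being checked.

## Known limitations

* The runs test is conservative by construction (plug-in null); the
  neighbor test's chi-square p-value is anticonservative (dependent
  cells) — use the permutation option when it matters.
* The plane tests answer a coarse question (uneven split across one
  plane); they can miss clustering that is symmetric about the plane.
* No multiple-testing correction is applied across the seven reported
  p-values; the report carries the test count so users can correct as
  they see fit.
* Structures are reduced to C-alpha positions; side-chain geometry,
  accessibility and interfaces are out of scope.

## A worked synthetic example

```{r example}
spec <- synthetic_spec(
  seed = 5,
  clustering = list(focus_a = 1, focus_b = 142, decay_length = 2)
)
b <- generate_bundle(spec)
report <- run_all(b$structure, b$alignment, b$sites_a, b$sites_b,
                  n_reps = 1000, seed = 2)
report
```

The two paralogs' sites were planted in tight clusters at opposite ends
of the chain, and all three tests respond: the runs test sees few, long
runs; the neighbor test sees same-paralog nearest neighbors far in excess
of the random-labeling expectation.
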