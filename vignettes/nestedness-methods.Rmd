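---
title: "Methods: nestedness metrics, null models and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nestedness metrics, null models and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

avinest asks two questions of a species × sites abundance matrix: do
species-poor sites hold subsets of the species at species-rich sites
(taxonomic nestedness), and do small sites hold subsets of the *functional
traits* found at large sites (functional nestedness)? This vignette is the
package's own account of the models behind those questions, the conventions
and numerical choices we committed to, and what the test suite does and
does not demonstrate.

## The community matrix and its preparation

Internally species are always in rows. Cells are non-negative integer
abundances; presence means `cell > 0`. Two preparation rules are applied
before any metric:

* A species recorded nowhere carries no information for any nestedness or
  coverage computation, so all-zero species rows are dropped with a
  warning at data entry. All-zero *sites* are kept: a park with zero
  richness is an observation, and the pair terms of every metric already
  guard against zero fills.
* Waterbirds are removed before any group is formed, reflecting survey
  designs that census them separately; the five analysable groups are
  all, passerine, resident, insectivorous and omnivorous birds. Rarer
  partitions (carnivores, nectarivores, granivores, non-passerines,
  migrants) are refused rather than silently computed, because their
  species counts do not support a pairwise-overlap metric.

Every ordering in the package — packing by marginal totals, ordering sites
by park area — breaks ties by input order. Stable ties cost nothing and
make every number in a report reproducible across runs and platforms.

## NODF and WNODF

After packing (both margins sorted by decreasing marginal totals), each
ordered row pair with strictly decreasing totals contributes the percentage
of the poorer row's occupied cells that are "dominated" by the richer row:
shared presences for NODF, strictly larger matching abundances for WNODF,
always normalised by the poorer row's fill. Columns are treated the same
way, and the overall index is the mean over all `C(rows,2) + C(cols,2)`
pair terms, so overall, row and column components all live on `[0, 100]`.

Conventions we fixed, and why:

* **Strictly decreasing totals.** Equal marginal totals contribute a zero
  term. A community in which every species has the same incidence and
  every site the same richness has no nested structure to measure, and a
  strict inequality is what makes the checkerboard matrix score exactly 0.
* **Packing is part of the metric.** The default ordering sorts both
  margins by decreasing totals before computing, so the result is
  invariant to the order in which the data arrive; a `given` mode exists
  for sensitivity checks against externally imposed orders.
* **WNODF orders by abundance totals, not fills.** Marginal abundance sums
  decide both the packing and the decreasing-totals condition; fills enter
  only as pair-term denominators. This follows the quantitative metric's
  definition. It is worth knowing that vegan's weighted `nestednodf`
  instead packs by fill with abundance as tiebreak, so the two weighted
  variants legitimately disagree on some matrices; our binary NODF and
  vegan's agree exactly, and the test suite pins both facts (binary
  equivalence against vegan on random matrices; weighted equivalence
  against an independent brute-force pair enumeration).
* **Binary input to `wnodf()` is a degenerate case** — no cell can be
  strictly smaller than another occupied cell, so the score is 0 by
  construction — and triggers a warning rather than an error.

## Null models and the Monte-Carlo test

The four randomisations conserve increasingly much of the observed matrix
structure (N = grand total, F = occupied-cell count):

| model | placement rule | conserved exactly |
|-------|----------------|-------------------|
| `aa`  | N individuals uniform over all cells | N |
| `pp`  | cell probability `r_i c_j / N²` | N (marginals in expectation) |
| `ss`  | F cells chosen uniformly, one individual seeded in each, the rest uniform over those cells | N and F |
| `rc`  | uniform integer matrix with the observed marginals (Patefield's algorithm via `stats::r2dtable`) | all row and column sums |

The named models are glosses in the source literature; the concrete
algorithms above are each documented by their conservation contract, which
the test suite asserts on every generated matrix, so any one of them can be
swapped for an alternative sampler with the same contract. "ss" fixes
*total* fill; fixing each site's richness separately would be a stricter
variant that we did not implement.

The test recomputes the metric — including re-packing — on each of `n_sim`
null matrices (default 1000, the usual reporting convention with a 95%
interval) and summarises each component with a z-score, the 2.5th/97.5th
null percentiles, and an add-one two-sided p,
`p = 2·min(#{null ≥ obs}+1, #{null ≤ obs}+1)/(n_sim+1)` capped at 1. Two-
sided is deliberate: the same test must be able to report nestedness and
anti-nestedness (observed significantly *below* expectation indicates
species turnover), and the add-one correction keeps p away from zero. The
verdict is taken from the percentile interval; when the null distribution
degenerates (sd = 0) the z-score is reported as `NA` and the interval
decides alone. Replicate k of a test seeded with s uses seed `s + k`, and
the pipeline hands each test a non-overlapping seed block, so one integer
reproduces a whole report.

The choice of null model is not a technicality. The calibration suite
verifies that each model, tested against data generated under itself,
rejects at close to the nominal 5% rate; but against *observed* data the
lenient `aa` and the strict `rc` regularly return different verdicts for
the same matrix — the suite keeps a fixture demonstrating exactly that.
Reporting several models side by side is the honest presentation.

## Coleman's random placement and the one-third rule

If individuals fall into sites independently with probability equal to
relative area `a_j`, expected richness and its variance at each site have
closed forms (`E_j = S − Σ_i (1−a_j)^{n_i}`; the variance sums the
presence Bernoullis). The conventional decision rule rejects passive
sampling when more than 1/3 of sites fall outside `E_j ± 1 SD`; sites
exactly on the boundary count as within, reading "not within one SD"
strictly. Pooled abundances are taken from the analysed matrix, so each
bird group gets its own curve.

**Known limitation, measured by the calibration suite:** when per-site
richness is far from saturation its distribution under the model is close
to normal, so by construction roughly 32% of sites fall outside one SD —
barely below the 1/3 threshold — and the rule then rejects data the model
itself generated in about half of the replicates at the surveyed scale
(95 species, 17 log-uniform areas, pooled abundances near 90 per species).
The rule is well behaved only when large sites saturate (`E_j → S`,
`SD → 0`, observed pinned to the boundary): with ~100 individuals per
species and 50 species it is rarely triggered, which is the regime the
unit test demonstrates. The corresponding calibration check is asserted at
the conventional ≥ 90% self-consistency level at survey scale and is
expected to fail there; we keep it because it documents a real property of
the published decision rule rather than of this implementation. Treat a
rejection from sparse data as weak evidence.

## Coverage and rarefaction

Inventory completeness uses the singleton/doubleton coverage estimator
(`Ĉ = 1 − (f1/n)·[(n−1)f1/((n−1)f1 + 2f2)]`, with Ĉ = 1 when f1 = 0 and
Ĉ = 0 for an all-singleton sample), the exact hypergeometric rarefaction
curve, and Chao1-based extrapolation out to `2n` — the conventional
endpoint beyond which the extrapolation variance is no longer trustworthy.
Binomial coefficients are evaluated through `lchoose` so the curve is
stable at survey-sized n. The curve is computed on abundances pooled over
all sites per group, matching how completeness is usually reported for a
park system as a whole; per-park curves would need a different pooling
choice. Correctness is pinned three ways: closed-form hand values, vegan's
independent rarefaction, and an exhaustive enumeration of all subsamples
at tiny n.

## treeNODF: functional nestedness

Traits (body size in grams, wing length in millimetres, or any continuous
set) become a Gower distance — range-normalised mean absolute difference,
zero-range traits dropped with a warning, missing values excluded pairwise
— and UPGMA turns that into an ultrametric dendrogram. Nodes sit at half
the merge height so tip-to-tip cophenetic distances reproduce the merge
heights exactly; tie handling during agglomeration is `stats::hclust`'s
deterministic convention.

Each site is represented by its *branch set*: every branch on the paths
from its present species to the root (the root itself carries no branch).
With sites ordered by decreasing park area, a pair (u above v) with
`BL_u > BL_v > 0` scores `100 × length(intersection)/BL_v`. The
S.Fraction part of the pair term uses only the subtree spanned by species
present at *both* sites; since those branches are necessarily in the
intersection, the remainder (topoNODF) is non-negative and the
decomposition `treeNODF = S.Fraction + topoNODF` is additive by
construction (asserted to 1e-9 on every tested input). Two limiting cases
anchor the definition: on a star dendrogram branch sets reduce to species
sets, treeNODF collapses to the site-wise binary NODF in the same order
and topoNODF is exactly 0; and a site whose species are a strict subset of
a larger site's scores a full 100 pair term. treeNODF is computed on
presence–absence, as the tree-based metric is defined; abundance
information enters the analysis only through WNODF.

The `permRows` test re-orders sites uniformly at random (default 99
permutations) and reports a one-sided (greater) p per component — the
question is specifically whether the area ordering scores *higher* than
chance. With 99 permutations the p floor is exactly 0.01. The permutation
loop re-evaluates only the ordered-pair terms; branch sets, their pairwise
intersections and shared-subtree lengths are computed once per matrix,
which is what makes calibration studies with hundreds of permutation tests
cheap.

## The synthetic generator

`generate_community()` emulates the statistical shape of a multi-park bird
survey, and its defaults are the surveyed conditions: 95 species, 17
sites, areas log-uniform on 2–200 ha (a realistic span for urban parks,
chosen once), nestedness dial `theta = 0.75`, rank-decaying occupancy
(`prevalence_decay = 1`), mean extra abundance 6 per occupied cell at an
average-area site with negative-binomial overdispersion (size 1), and no
waterbirds (the species set models a community after waterbird exclusion).
Species i deterministically occupies the `k_i` largest sites
(`k_i = ceil(p_i · n_sites)` from its occupancy `p_i`); each cell follows
that area-threshold rule with probability theta and an occupancy-matched
Bernoulli otherwise, giving presence probability
`theta·[a_j ≥ t_i] + (1−theta)·p_i` exactly. At `theta = 1` a square
community has strictly decreasing marginals on both margins and NODF is
exactly 100; at `theta = 0` composition is area-independent, which is what
makes the generator usable for both power and type-I studies. Species left
unobserved by the mixture are seeded into the largest site so the species
count is exact. Traits are correlated log-normals through a Gaussian
copula.

What the generator does **not** emulate: spatial structure and
between-park distances, seasonal turnover (surveys are pooled), detection
error, and any trait–occupancy dependence (traits are independent of the
incidence process). Tests that pass on these communities therefore
demonstrate the correctness and calibration of the *methods*, not claims
about real bird data.

## Calibration evidence and problem sizes

The stochastic suite, all under fixed seeds, uses sizes chosen to keep the
full test run around two minutes while leaving each check statistically
meaningful:

* **Type-I error:** 200 matrices generated under each null model
  (12 species × 10 sites base community), each tested against the same
  model with 200 simulations; empirical rejection at the 95% interval
  stays within 5% ± 3 percentage points for all four models. The base
  community is sized so the NODF null distribution is effectively
  continuous — heavy ties at the interval boundary would make the test
  conservative.
* **Dial monotonicity:** mean NODF over 50 seeds is non-decreasing along
  `theta ∈ {0, 0.25, 0.5, 0.75, 1}` at the default 95 × 17 scale.
* **Power:** at `theta = 1` (20 species × 10 sites) the treeNODF
  permutation p sits at its 0.01 floor in ≥ 95% of seeds; at `theta = 0`
  the p-values over 200 replicate communities pass a Kolmogorov–Smirnov
  uniformity check at the 5% level.
* **Random placement self-consistency:** 200 communities generated by the
  placement model at survey scale — the honest negative result discussed
  above.

## Other design decisions and degenerate inputs

* Season replicates are assumed pre-summed into one matrix; the package
  takes a single abundance matrix as its unit of analysis.
* Spreadsheet sources are expected as CSV/TSV exports; the canonical
  interchange format is delimited text with site ids in the first row and
  species ids in the first column.
* `n_perm = 1` permutation tests, constant null distributions, single-site
  placement curves, `f2 = 0` extrapolation and all-flat trait tables all
  have defined behaviour (p = 1 on a tie, `NA` z with a CI-only verdict,
  sd = 0 with boundary-inclusive comparison, the f1-based Chao fallback,
  and a hard error respectively) — each is pinned by a unit test.
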