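---
title: "Partitioning species and taxonomic beta diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning species and taxonomic beta diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betataxa)
```

## The model

All analyses start from a binary site × species incidence matrix: a species
is present at a site iff it has at least one record there. Record counts are
used only by the coverage estimator; dissimilarity is incidence-based
throughout, because the data this package targets — species lists compiled
per ecoregion or survey unit from heterogeneous field campaigns — support
presence/absence far more reliably than relative abundance.

For any two sites, let `a` be the number of shared elements and `b`, `c` the
numbers exclusive to each. Total dissimilarity is the Jaccard complement,

$$\beta_{cc} = \frac{b + c}{a + b + c},$$

partitioned additively into a replacement (turnover) component and a
richness-difference component,

$$\beta_{-3} = \frac{2\min(b, c)}{a + b + c}, \qquad
  \beta_{rich} = \frac{|b - c|}{a + b + c}.$$

Since $(b + c) = 2\min(b,c) + |b - c|$ identically, $\beta_{cc} =
\beta_{-3} + \beta_{rich}$ holds exactly in rational arithmetic; the test
suite asserts it to 1e-12 in floating point. Both components are bounded by
$\beta_{cc}$, all three live in $[0, 1]$, and $\beta_{cc} = 1$ exactly when
nothing is shared.

### Taxonomic dissimilarity

The taxonomic variant applies the *same* partition to different elements:
each community's species set is expanded upward through the group's Linnaean
classification and pooled into a single set of (rank, name) pairs — species,
genera, subfamilies, families and so on, all together. With `Ta` taxa shared
and `Tb`, `Tc` exclusive,

$$\beta_{ccT} = 1 - \frac{T_a}{T_a + T_b + T_c},$$

and $\beta_{-3T}$, $\beta_{richT}$ follow by the same formulas. Pooling all
ranks into one set (rather than averaging per-rank dissimilarities) is a
deliberate choice: the quantity counts *taxa*, so a genus and a species
contribute equally, and the result is a single proportion of unshared taxa
with a direct reading. Per-rank step weights, as used in
taxonomic-distinctness frameworks, are intentionally out of scope.

Two structural details matter. Taxon identity is the (rank, name) *pair*, so
a name that appears at two ranks counts twice — homonymy across ranks is
rare but real. And hierarchies may be ragged: a blank cell means the rank is
not applicable to that lineage (not every bird family has named subfamilies)
and contributes no taxon. A consequence worth knowing: although on realistic
data $\beta_{ccT} \le \beta_{cc}$ essentially always (shared species drag
their whole lineages into the shared set), this is *not* a theorem under
ragged hierarchies — if shared species have shallow lineages and exclusive
species deep ones, the inequality can reverse. The package computes, it does
not enforce; the test suite contains an explicit counterexample documenting
this.

### Multiple-site aggregation

With $T$ sites the package summarizes all $T(T-1)/2$ pairs in one partition.
The default aggregates matching components:

$$\beta_{cc} = \frac{\sum (b+c)}{\sum (a+b+c)}, \quad
  \beta_{-3} = \frac{\sum 2\min(b,c)}{\sum (a+b+c)}, \quad
  \beta_{rich} = \frac{\sum |b-c|}{\sum (a+b+c)},$$

sums over pairs. This was chosen over an arithmetic mean of pairwise values
because it preserves exact additivity by construction, reduces to the
pairwise partition at $T = 2$, and weights pairs by their pooled richness
rather than equally. The pair-mean alternative is one `variant` switch away
(`multi_site_beta(..., variant = "pair-mean")`) as a sensitivity check;
both variants satisfy the $T = 2$ reduction, and the tests exercise both.
Contribution percentages are $100\,\beta_{-3}/\beta_{cc}$ and its
complement; they are reported as missing (never as zeros) when
$\beta_{cc} = 0$.

### Sample coverage

Inventory completeness per group × site uses the abundance-based sample
coverage estimator

$$\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2},$$

with `n` total records, `f1` singletons and `f2` doubletons. This estimator
was selected because those three quantities are exactly what a records
database provides; no abundance model has to be fitted. `f1 = 0` yields
coverage 1; the degenerate `n = 1, f1 = 1` cell yields 0 with a small-sample
warning. A resampling test (geometric abundances, 30 species, samples of
100, 1000 replicates) confirms the estimator's mean tracks the true expected
coverage to within 0.005.

## Downstream statistics

**NMDS.** Ordination minimizes Kruskal's stress-1 under monotone regression
of configuration distances on the input dissimilarities. The optimization is
delegated to `vegan::monoMDS` (global model, primary tie treatment — tied
dissimilarities share a fitted block); `beta_nmds()` contributes the
protocol around it: 2 dimensions, a metric-scaling start plus 50 random
restarts by default, 300 iterations per start, all randomness drawn from one
seed. Stress can therefore only improve with additional restarts, and
repeated runs at the same seed agree to better than 1e-6. Coordinates are
identified only up to rotation, reflection and translation — tests and users
should compare distances or stress, never raw axes. Inputs must be complete;
missing pairs are a hard error with advice to exclude or impute, because
silently dropping sites from an ordination changes its meaning.

**Correlations.** Species-level vs taxonomic dissimilarity across site pairs
is summarized by Pearson's r with the usual two-sided t-test on n − 2
degrees of freedom, treating the pairs as independent observations. They are
not — the 15 pairs of 6 sites share sites — so this p-value is optimistic; a
Mantel-style site-permutation p-value is available via the `permutations`
argument and recommended whenever the decision hinges on significance. The
parametric version remains the default for comparability with standard
practice in the beta-diversity literature.

## The synthetic generator

`community_design()` + `generate_occurrences()` produce multi-site
occurrence tables whose compositional ground truth is known exactly: a core
present at every site, per-site exclusive species, and "patchy" species
placed on weighted random subsets of 2 to T − 1 sites. The realized matching
components for every pair are returned as an attribute, which is what makes
the pipeline's primary end-to-end test possible — designed (a, b, c) in,
identical (a, b, c) back out through ingestion, incidence and partitioning.

Record counts follow a geometric-series rank-abundance model: within a site
the k-th ranked species has weight $\propto r^{k-1}$, and its count is drawn
as $1 + \mathrm{Poisson}(\lambda_k)$ with the $\lambda_k$ scaled so the
site's expected total matches `mean_records` per species. The added 1
guarantees every designed presence is realized (so ground truth is exact);
the Poisson tail produces the singletons and doubletons that the coverage
estimator needs. The closed form $E[f_1] = \sum_k e^{-\lambda_k}$ serves as
the oracle for the generator's own distributional test.

The bundled `hidalgo_like_designs()` preset fabricates four vertebrate-like
groups over six ecoregion-like sites, emulating the *shape* of a state-level
terrestrial vertebrate survey in central Mexico: per-site richness from
roughly 10 (amphibians in arid scrub) to 300 (birds in pine-oak forest),
group totals of 50–515 species, rank lists of ragged depth (5 ranks for
amphibians, 9 for reptiles and mammals, 15 for birds), and record totals in
the thousands. Core/exclusive/patchy counts are derived from the target
richness profile (core = half the poorest site's richness, exclusives ≈ 20%
of each site's, the remainder patchy with richness-weighted occupancy), and
the geometric ratio is steeper for species-poor groups (0.8 for amphibians
up to 0.97 for birds) so rare species occur at realistic rates at every
richness scale. What the preset does **not** emulate: real species
identities, spatial autocorrelation, environmental gradients, detection
bias, or any fit to real supplementary data — passing tests on it
demonstrates algebraic and pipeline correctness plus qualitative realism of
magnitudes, not fidelity to any particular empirical dataset.

## Numerical and policy choices

- Components `a`, `b`, `c` are exact integers; only the final ratios are
  doubles. Equality tests run at 1e-12.
- Undefined quantities (two empty communities, contributions at
  $\beta_{cc}=0$, pairs involving an empty site) propagate as `NA` with a
  classed warning — never as zeros, which would be silently wrong in means.
- Label matching trims, collapses internal whitespace and case-folds;
  original spellings are preserved in outputs. Duplicate (group, species,
  site) triples abort ingestion rather than being summed.
- Sites with no presences for a group are kept in the incidence matrix and
  flagged, so downstream stages can report rather than hide them.
- Full precision is written to all machine-readable CSVs; rounding (2
  decimals for completeness percentages) happens only at presentation.
- All pipeline randomness derives from one recorded seed; identical config
  and seed give byte-identical CSV outputs.

## Problem sizes in the test suite

The suite favours exact, desk-scale checks: 10,000 random component triples
for additivity; 1,000 random communities (universe 30, up to 20 elements)
against a brute-force double-loop oracle; the full four-group preset
(50–515 species per group, 6 sites) for end-to-end recovery and additivity
of every output; 1,000 resampling replicates for the coverage estimator;
200 lineages for the ragged-taxonomy rate check. The complete suite runs in
well under a minute on one core.

## Known limitations

- Taxonomic dissimilarity weights all ranks equally by pooling; it is a
  surrogate for, not an estimate of, phylogenetic beta diversity, and rank
  inflation (splitting one family into three) changes the answer.
- Abundance-weighted dissimilarity and Sørensen-family partitions are out of
  scope, as are richness extrapolation (Chao-type), rarefaction, and
  incidence-based coverage.
- The parametric correlation p-values inherit pseudo-replication from
  shared sites; use the permutation option for inference.
- XLSX sources must be exported to CSV/TSV before ingestion.
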