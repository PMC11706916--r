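---
title: "Classifying crop-processing stages from weed-seed attributes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying crop-processing stages from weed-seed attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropclass)
```

## The model

Traditional processing of free-threshing cereals and pulses is a fixed
sequence — threshing, winnowing, coarse sieving, fine sieving — and each
step partitions the accompanying weed seeds according to three physical
properties: size relative to the fine-sieve mesh (Big/Small), tendency to
remain in seed heads after threshing (Headed/Free), and aerodynamic
behaviour under winnowing (Heavy/Light). Six of the eight combinations
occur (`BHH, BFH, SHH, SHL, SFH, SFL`; big seeds are not light), and the
mix of these six categories in a sample is diagnostic of the stage it
derives from: winnowing by-products accumulate light seeds, coarse-sieve
by-products headed seeds, fine-sieve by-products small free seeds, and the
cleaned fine-sieve product retains big free heavy contaminants.

`attribute_transform()` maps a sample's classifiable weed counts to six
scores: taxon *i* with count $n_{is}$ out of classifiable total $N_s$
contributes $\sqrt{100\, n_{is}/N_s}$, summed within each attribute code.
Three properties matter:

* **compositional** — scores depend only on proportions, so differential
  sample volume cancels;
* **variance-damping** — the square root stops one hyper-abundant taxon
  from dominating the category score;
* **sum-of-roots** — the per-taxon roots are summed, so richness counts:
  two taxa at 50% each give $2\sqrt{50} \approx 14.14$, more than one
  taxon at 100% ($\sqrt{100} = 10$). A root-of-sum variant would destroy
  this richness sensitivity and is deliberately not offered; a unit test
  asserts against it.

The percentage base is classifiable weed seeds only: non-weed items and
weed taxa without a code are removed first (`drop_unclassified()`), so
that an uncodeable taxon changes no score. This base is fixed, not
configurable, to keep attribute matrices comparable across analyses.

## Discriminant classification

`fit_lda()` is a from-scratch linear discriminant analysis with a shared
within-group covariance. Choices that affect numbers:

* **Pooled covariance divisor $n-G$** (unbiased pooled estimator). This
  slightly affects posteriors relative to the $n$ divisor; in particular,
  duplicating a training set perturbs posteriors at order $G/n$ even
  though classifications are stable — the tests assert classification
  invariance exactly and posterior invariance to 1%.
* **Scalings** are eigenvectors of $W^{-1}B$ (computed via a Cholesky
  whitening of $W$, keeping the problem symmetric), normalised so the
  projected training data have unit within-group variance; there are
  $m=\min(G-1,p)$ of them.
* **Sign convention**: the sign of a discriminant function is arbitrary
  and differs between statistical programs, so each scaling is oriented
  to make its largest-magnitude loading positive. All downstream results
  (posteriors, classes, distances) are sign-invariant; only plot
  orientation is affected.
* **Posteriors** are computed in the sphered discriminant space,
  $p_k(x) \propto \pi_k \exp(-\tfrac12\lVert z(x)-\bar z_k\rVert^2)$ with
  a log-sum-exp guard. Because $m = \min(G-1, p)$ discriminants span every
  between-mean direction, this equals the full $p$-dimensional
  shared-covariance Gaussian posterior; the test suite checks the
  identity against an independent full-space oracle at 1e-10 and against
  `MASS::lda` label-for-label.
* **Priors** default to group-size proportions (matching the common
  statistics-library default, hence published outputs); `"uniform"` and
  explicit vectors are available.
* **Degeneracy**: a singular pooled covariance (e.g. an all-zero
  attribute column, common in small assemblages) triggers a diagonal
  ridge of `1e-8 * trace/p` with a warning naming any all-zero columns.
  The ridge is never applied to well-conditioned data, so it cannot
  perturb regular results.
* **Ties** in the posterior argmax break towards the lowest group index;
  with continuous scores this matters only for symmetric toy cases, but
  the rule is deterministic and tested.

`jones_classify()` fits on the four reference groups only and assigns each
archaeological sample to its most probable stage — appropriate when a
crop-processing origin is taken for granted. `charles_classify()` refits
with the archaeological samples included as group 5 and re-classifies
them among all five groups: samples that remain in group 5 are more like
each other than like any processing stage, which is the signal used to
screen for alternative taphonomic pathways (dung or turf burning). The
archaeological group enters the priors at its sample-size proportion, the
same convention as the four-group default; pass `priors = "uniform"` to
remove the size advantage of a large site assemblage.

`rerun_without_taxa()` supports the iterative workflow: remove a stated
taxon list (hay-meadow flora, putative dung flora), re-apply
`drop_unclassified()` and the minimum-seed filter — **the filter is
recomputed**, so samples can drop out of the comparison when their counts
fall below threshold; the change report marks them with `NA` — then
re-transform and re-classify, returning paired before/after results.

## Filters and screening

Two eligibility rules precede analysis, both caller-visible and logged:
a minimum number of items for the ternary plot (30 by default in the
published workflow; assemblage-dependent) and a minimum number of
classifiable weed seeds for the discriminant analysis (10 as an absolute
floor, 20 for richer assemblages). `filter_min_items()` implements both
bases and reports dropped samples, and is idempotent.

`classify_dominance()` screens mixed-crop assemblages: a sample is
labelled with the crop whose share of crop items reaches the threshold
(default 80%), with a wheat+barley union evaluated as "free-threshing
cereal" when neither cereal dominates alone, and "mixed" otherwise. The
denominator is crop items only (grain + rachis for cereals, seeds for
pulses); the published account does not state the denominator, so this
choice is explicit here and the crop-group sets are caller-supplied.

## Ternary plots

`triplot_proportions()` converts per-sample grain/rachis/weed totals to
percentages; `ternary_coordinates()` maps them into a unit-side triangle
with grain at the apex, rachis lower-left, weeds lower-right (the apex
assignment is a package convention — the published figures do not state
their orientation in text). `make_triplot()` draws the ethnographic panel
(symbols 1-4 by group) and the archaeological panel side by side,
monochrome by default, with optional highlighted-and-labelled samples;
absent highlight ids warn rather than error, and sub-30-item samples
warn because filtering is deliberately left to the caller.

## What the synthetic generator emulates — and what it does not

The package must be testable without the published supplementary data, so
`generate_reference()` / `generate_archaeological()` produce synthetic
assemblages. **The default profiles are this package's own**: they encode
only the qualitative enrichment logic of the attribute scheme (group 1
heavy in `SFL`/`SHL`, group 2 in `BHH`/`SHH`, group 3 in `SFH`/`SFL`,
group 4 in `BFH`/`BHH`), with 2 taxa per code, ~120 seeds per sample
(Poisson), and per-sample compositions drawn from a Dirichlet
(concentration 60 at the default "high" separation; 12 at "moderate") —
a compound multinomial, chosen over a plain multinomial to give the
overdispersion real samples show. Taxon richness (12 taxa) is a
placeholder: realistic per-group richness is unknown without the real
reference data. A green synthetic test therefore establishes that the
*machinery* is correct (transform identities, model algebra, recovery of
a planted structure at the stated separation); it does not establish that
real ethnographic groups are separable to the same degree, and the
published case-study numbers are only reproduced when a user supplies
the original data files (see `read_reference_set()` and the acceptance
test that remains red offline).

Contamination in `generate_archaeological()` mixes a stated fraction of
each sample's composition from an off-manifold profile (simultaneously
rich in `BFH` and `SHL`, a combination no processing stage produces),
standing in for dung-derived seed input. The recovery tests assert the
direction the screening method is built on: contaminated samples are
re-classified "archaeological" by the five-group method at a strictly
higher rate than uncontaminated ones.

## Known limitations

* The three-dimensional score plot is a static projection with an
  explicit camera (`theta`/`phi`); interactive rotation would need an
  HTML/WebGL backend, which an offline build cannot carry.
* The model applies to large-seeded free-threshing cereals and pulses;
  glume wheats, small-seeded cereals (millets) and weed-free crops
  (maize) are outside its domain, and the ternary plot is restricted to
  free-threshing material because grain and chaff separate at different
  stages in glume wheats.
* Attribute coding of taxa is user-supplied; the package does not infer
  codes from seed measurements, and the small/big or heavy/light cut-offs
  are assemblage-dependent judgements the analyst should vary and re-run.
* Dominance screening, the wider ecological criteria for dung derivation
  and correspondence analysis are out of scope beyond the taxon-removal
  re-run mechanics.
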