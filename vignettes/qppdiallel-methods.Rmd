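---
title: "Models and methods for quality-protein popcorn hybrid evaluation"
author: "qppdiallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quality-protein popcorn hybrid evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qppdiallel)
```

## The problem

Quality Protein Popcorn (QPP) breeding crosses *opaque-2* Quality Protein
Maize (QPM) donors into popcorn to raise kernel lysine while keeping
popability and expansion volume. At the intermediate stage of such a
program, a factorial set of hybrids (here 4 maternal x 12 paternal
inbreds, selfs excluded, reciprocals distinct: 44 crosses) is grown in a
generalized complete block design (GCBD) at two locations with six
replicate row-plots each, and the breeder must (i) partition phenotypic
variation into genetic and environmental components, (ii) assign
combining abilities to parents and crosses, (iii) collapse a dozen traits
into a single defensible ranking, (iv) read heterosis off the pedigree
structure, and (v) verify that protein quality survives popping. This
package implements that full analysis plus a simulator that reproduces
the design's statistical structure, so every stage is testable without
proprietary field data.

## Plot-level model and variance components

Each trait is analysed with the two-location model

$$y_{ijk} = \mu + \beta_i + \tau_j + (\beta\tau)_{ij} + \epsilon_{ijk},$$

where $\beta_i$ is the location effect, $\tau_j$ the treatment effect
(hybrid, maternal line, paternal line, or pedigree category, depending on
the question) and $(\beta\tau)_{ij}$ the location-by-treatment
interaction. Replicate row-plots within a location are absorbed into the
error stratum rather than modelled as their own blocks; with randomized
10-foot row units this costs little and keeps the expected-mean-square
algebra exact. Sums of squares are **Type II**, computed by explicit
residual-SS comparison of nested least-squares fits, which keeps degrees
of freedom honest when hybrids are missing from a location and reduces
to the sequential (Type I) decomposition on balanced data.

Treating $\tau$ and $(\beta\tau)$ as random, variance components come
from inverting the balanced expected mean squares
($E[\mathrm{MS}_t] = \sigma^2_e + n\sigma^2_{int} + nL\sigma^2_t$, etc.),
with $n$ the mean occupied-cell count for mildly unbalanced data, and
negative solutions clipped to zero (pre-clip values retained). EMS
inversion was chosen over REML deliberately: it is deterministic,
closed-form, and checkable against an algebraic oracle; a REML refinement
is a natural extension point. Heritability / repeatability is the
plot-basis ratio

$$H = \frac{\sigma^2_t}{\sigma^2_t + \sigma^2_{int} + \sigma^2_e},$$

the denominator being a design choice (the source analysis does not
define it); this choice bounds the ratio in $[0,1]$ and reproduces the
magnitude range seen in published popcorn trials (~0.02-0.45).

## Combining ability

With cell means $\bar y_{kl}$ for cross $k \times l$, general combining
abilities are deviations of a parent's average hybrid performance from
the grand mean, and specific combining ability is the remainder:

$$\hat s_{kl} = \bar y_{kl} - \hat\mu - \hat g_k - \hat g_l .$$

Two conventions deserve a note. First, the sign: positive GCA means an
above-average parent (the $\bar y - \mu$ form; printed equations
sometimes carry the opposite sign by typographic accident, but published
effect tables only close to zero under this convention). Second, the
estimator: effects are obtained from a joint additive least-squares fit
to the available cell means under sum-to-zero constraints. On a complete
grid this *equals* the marginal-mean formula; on the selfs-excluded 4x12
grid the missing diagonal would otherwise leave GCA sums and SCA
row/column sums a few percent off zero, whereas the constrained fit keeps
the zero-sum contracts and the reconstruction identity
$\hat\mu + \hat g_k + \hat g_l + \hat s_{kl} = \bar y_{kl}$ exact to
machine precision. Standard errors are contrast-based: each effect is a
linear combination of cell means whose variance is propagated from the
plot-level residual variance and per-cell replication; they are labelled
as such since a mixed-model fit would shrink differently.

## The rank-summation index

Hybrids are ranked by

$$X_h = \sum_{i=1}^{m}\left(\frac{y_{i,h}}{y_{i,\max}} - 1\right)^2 I_i
  \frac{\sigma_{i,h}}{\sigma_{i,\max}},$$

a weighted squared relative deviation from the best hybrid per trait,
scaled by the hybrid's relative within-trait variability and summed over
the $m = 10$ weighted traits. Smaller is better; a hybrid at the oriented
maximum of every weighted trait scores exactly zero. Default weights
$I_i$ (0-1 "selection intensities"): popability and expansion volume
0.85, ear weight 0.8, germination and 100-grain weight 0.7, vitreousness
and ears harvested 0.6, rot and ear length 0.5, rows per ear 0.4; days to
pollination and kernel size are recorded but unweighted. "Smaller is
better" traits (rot susceptibility) are complemented ($x \to 1-x$,
proportions only) *before* maxima are taken.

Resolved ambiguities, made once and kept:

* **sd-term placement.** The typeset formula is ambiguous between
  multiplying and dividing by $\sigma_{i,h}/\sigma_{i,\max}$. The
  multiplicative form is the default - a less homogeneous hybrid is
  penalized more, matching the stated intent of rewarding hybrid
  uniformity; the divisive variant is selectable
  (`ranking_variant: divisive`) for sensitivity analysis.
* **Maxima** are taken across the ranked hybrids, per trait, after
  orientation; $\sigma_{i,\max}$ includes all hybrids with $n \ge 1$.
* **Missing traits** receive the worst observed contribution for that
  trait (pessimistic imputation, flagged) so missing data are never
  rewarded.
* **Ties** share a rank position; display order among ties puts higher
  expansion volume first (it carries the top weight), but no hidden
  tie-break affects the reported totals or ranks.

The index satisfies checkable invariances: per-trait positive rescaling
changes nothing (both terms are ratios), zero-weight traits are inert,
and improving a hybrid toward the trait maximum can only lower its total.

## Pedigree heterosis categories

Each of the 44 crosses is assigned one of five ordered categories of
increasing genetic diversity from the inbreds' pedigrees: `pseudo_self`
(same QPM donor and same popcorn parent - sib lines of independent
descent), `same_popcorn`, `same_qpm`, `same_pool_hybrid` (all parents
distinct, popcorn parents from one heterotic pool), `complete_hybrid`.
The popcorn test dominates the QPM test when both partially hold because
the inbreds were back-crossed twice to the popcorn parent (~87.5%
popcorn genome). The trend test fits the plot-level model with category
as treatment, runs Tukey-Kramer HSD pairwise comparisons against the
residual variance (studentized-range p-values), and reports a
monotonicity flag: only an adjacent-category mean *decrease* larger than
0.25 pooled SEs of the difference clears the flag, since published
trends tolerate non-significant dips.

The default pedigree shipped with the package is a **synthetic
reconstruction**: the published pedigree table is available only as a
figure, so `make_default_pedigree()` encodes every constraint stated in
the accompanying text (three QPM donors x four popcorn parents; six sib
pairs; inbreds I9/I10 = CML154Q x P1; popcorn parents P2 and P3 sharing
a pool) and provably reproduces the published category memberships:
pseudo-self hybrids {5, 16, 31, 42} and same-pool hybrids
{3, 4, 10, 11, 14, 15, 21, 22} under the standard hybrid numbering
(maternal order I5, I6, I9, I10; paternal order I1..I12, selfs skipped).

## Correlations and path coefficients

Phenotypic correlations are pairwise-complete Pearson coefficients on
hybrid entry means pooled over locations (one value per hybrid per
trait), with two-sided t-test p-values and the star convention
`***` < 0.0001, `**` < 0.001, `*` < 0.05, `NS` otherwise. "Path
analysis" is deliberately simplified to standardized multiple regression
per outcome (coefficients solve $R_{xx}\,b = r_{xy}$): the quantities
reported by comparable analyses are the standardized coefficients, and a
full SEM adds fit machinery without changing them. The classical path
identity $r_{x y} = b_x + \sum_j r_{x j} b_j$ is enforced in tests to
1e-10.

## Protein-quality analytics

Fold changes are ratios of group means with delta-method SEs; lysine
share of protein is $100\,\mathrm{lys}/\mathrm{protein}$; popping
retention obeys the exact identity
$\mathrm{retention}/100 \cdot \mathrm{raw} + \mathrm{loss} =
\mathrm{raw}$ (losses may be negative - some residues rise after air or
microwave popping). Cross-method consistency is the Pearson correlation
of genotype means between treatment pairs per residue, flagged below
0.700. The dietary-requirement fraction takes the requirement (g/day) as
a *user input*, because the conventional 30 mg/kg/day figure and
published per-day values do not reconcile exactly.

Inheritance-mode classification uses two one-sided Welch tests: hybrid
vs. mid-parent (mid-parent SE = half the root-sum-square of parent SEs)
and hybrid vs. high parent. Not above mid = `additive`; above mid only =
`dominant`; above both = `over_dominant`; the contradictory quadrant
(above high but not above mid) and zero-variance exact ties =
`ambiguous`. $\alpha$ defaults to 0.05 with no multiplicity correction
across residues (trends are reported per residue); Benjamini-Hochberg
can be applied downstream by the user.

## What the simulator does and does not emulate

`simulate_diallel_trial()` draws maternal GCA, paternal GCA and SCA
effects i.i.d. normal with a specified cross-trait genetic correlation,
centers each effect vector to an exact zero sum (matching the
estimators' constraint and making recovery identifiable), adds
independent location, location-by-genotype and plot-error terms, and
truncates proportions to $[0,1]$, the vitreousness score to $[1,7]$ and
counts to $\ge 0$ (negligible at default magnitudes). Defaults encode
the emulated trial: 4 x 12 parents, 2 locations, 6 row-plots, and
per-trait components chosen once to put plot-basis heritabilities in the
published 0.02-0.45 range. The default genetic correlation is a
two-factor (agronomic / popcorn-quality) loading model - PSD by
construction - reproducing the signature negative expansion-volume vs.
yield-component correlations and positive EV-vitreousness/popability
correlations. The simulator does **not** model spatial field trend,
multi-year effects, non-Gaussian traits beyond truncation, or
genotype-specific error variances; correlation is imposed on genetic
effects only, with independent errors per trait, so a green recovery
test establishes estimator correctness under this stated world, not
robustness to field pathologies.

`simulate_amino_profiles()` sets the hybrid level at mid-parent
(`additive`), high parent (`dominant`) or high parent x 1.2
(`over_dominant`), multiplies popped treatments by per-method retention
factors, and applies relative Gaussian noise. Default parent levels were
set by an a priori power argument: with $n = 6$ replicates and 5%
relative noise, the one-sided Welch test separating mid-parent from high
parent has $\ge 95\%$ power only when the parental ratio is roughly 1.3
or larger, so the dominant-case default uses a 1.4x separation
(2.0 vs. 2.8 g/100 g, within the range of published hybrid-vs-popcorn
contrasts). With a smaller separation the stated recovery rate is not
achievable by *any* test at that replication - a detectability limit,
not a software one. Note also that an exactly-additive residue is
misclassified with probability $\alpha$ by construction, so per-call
recovery of a mixed mode map is expected near
$1 - \alpha \cdot (\text{share of additive and dominant residues})$,
about 96-97% at defaults.

## Numerical choices and degenerate inputs

* Zero-sum and reconstruction contracts are enforced to 1e-10; index
  decomposition to 1e-12.
* Negative variance-component solutions clip to 0 with the raw value
  kept for diagnostics; heritability with an all-zero denominator is an
  error, not NaN.
* A trait whose oriented maximum is nonpositive cannot be ranked
  relatively and is skipped with a warning.
* Tukey HSD with zero residual variance reports p = 0 for unequal means
  and p = 1 for equal means (boundary convention).
* Confounded designs (treatment indistinguishable from location) raise a
  degenerate-design error rather than returning 0-df sums of squares.

## Known limitations

EMS-based components are less efficient than REML under strong
unbalance; SEs are contrast-based, not model-based; the heterosis
categorizer is purely rule-based (no marker relatedness); the published
paternal kernel-size GCA column does not close to zero as printed and is
tracked as a known fixture anomaly rather than asserted.
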