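---
title: "Chronosequence methods: models, conventions, and design choices"
author: "metasucc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronosequence methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasucc)
```

`metasucc` analyses space-for-time ("chronosequence") stem inventories of
secondary forests: sites of different ages since abandonment, censused
once, interpreted as snapshots of one successional trajectory. This
vignette documents the statistical machinery, the conventions adopted
where several are defensible, and what the bundled synthetic landscape
does and does not emulate.

## The data model

A **stem record** is one censused individual: site, plot (upper or lower
slope; every site has exactly two 20 × 50 m plots), species code, stratum,
diameter (cm), life form. Strata follow the census protocol: *trees* are
woody non-climbers with DBH ≥ 5 cm, censused on the full plot (1000 m²);
*saplings* 1–5 cm DBH on one half plot (500 m²); *lianas* are woody
climbers ≥ 1 cm on the full plot; *seedlings* are small recent recruits
censused on twenty 1 m² subplots and carry no diameter. `validateStems()`
enforces these invariants row by row and reports (never silently drops)
offenders. Note the asymmetry: the liana *stratum* is reserved for
climbing life forms, but liana species legitimately appear in the
*seedling* stratum.

**Abundance matrices** (`AbundanceMatrix`) are unit × species count
matrices for one stratum or a pooled set of strata, at site level (plot
pairs pooled; the default for diversity, ordination and divergence
analyses) or plot level (the unit for landscape frequency analyses). All
units of the input stem table are retained as rows so matrices from
different strata align; species left without records by a filter are
dropped. Site-level matrices are exactly the sum of their two plot-level
rows, a property the test suite asserts as integer equality.

**Classification.** Sites are partitioned along two successional axes.
Stand-basal-area (SBA) classes use half-open intervals `[b, b')` — a site
at exactly 11 m²/ha falls in SBA-2 — with default edges 0, 11, 20 m²/ha
and an open-topped third class so no site is unassignable. Age classes
use the field's integer labels with both ends inclusive: edges
`c(2, 8, 18, 33)` produce "2–7 y", "8–17 y", "18–32 y". These conventions
reproduce balanced class sizes on integer ages and resolve the ambiguity
of whether a class printed as "1–11" includes its bounds.

When a measured stand basal area is unavailable, `siteBasalArea()`
computes Σ π(d/2)² over all stems ≥ 1 cm — saplings, trees and (by
default, switchable) lianas — scaled to m²/ha by the sampled area of each
stratum. The inclusive stem basis is a package choice; it is documented
here because field studies rarely state theirs.

## Diversity

Hill numbers ^qD = (Σ p_i^q)^{1/(1−q)} are implemented directly; the
order-1 case uses its analytic limit exp(−Σ p_i log p_i), never a
numerical approach to q = 1, so the profile is continuous and
tolerance-free. The suite cross-checks the implementation against an
independent Rényi-entropy route and property-tests the ordering
⁰D ≥ ¹D ≥ ²D and scale invariance on random vectors.

Individual-based rarefaction uses the exact hypergeometric expectation
evaluated with `lchoose()` in log space, so inventories of tens of
thousands of stems do not overflow. Sample-based accumulation curves use
the analytic expectation over site subsets (`method = "exact"`) or
averaged random orderings.

Metacommunity (γ) diversity is made comparable across classes holding
different numbers of sites by resampling: 12 sites are drawn without
replacement (with replacement available behind a flag), their counts
pooled, the Hill number evaluated, 1000 times; the 0.025 and 0.975
empirical quantiles (type-7 linear interpolation, the R default) are the
confidence limits. Twelve sites and 1000 iterations are the defaults
because they are the study design this package targets; both are
arguments.

## Similarity and the seedling-divergence comparison

The Ružička index 1 − Σmin/Σmax is the abundance-based Jaccard; on 0/1
vectors it reduces exactly to classical Jaccard (asserted in the tests).
The Chao–Jaccard abundance estimator corrects for unseen shared species:
with totals n, m and shared counts x_i, y_i,

U = Σ x_i/n + ((m−1)/m) · f₊₁/(2 f₊₂) · Σ_{y_i = 1} x_i/n,

V symmetric, both capped at 1, similarity U·V/(U + V − U·V). When a
correction denominator has f₊₂ = 0 it is replaced by 2(f₊₂ + 1), the
usual bias-correction convention; the uncorrected plug-in version is
available via `corrected = FALSE` for sensitivity checks. The
implementation is verified to 10⁻¹² against an independent transcription
of the published formulas, and its self-similarity on large paired
samples approaches 1 as singletons vanish. Morisita–Horn is provided as
an alternative index but excluded from default reports.

`seedlingDivergence()` scores every cross pair (seedling assemblage in
SBA class k) × (≥1 cm stem assemblage in SBA-1) with the Chao–Jaccard
estimator, after restricting both to canopy-capable species
(maximum-DBH class mid-value ≥ 7.5 cm, i.e. classes 5–10 cm and larger).
The 95% confidence interval across pairs is normal-theory
(mean ± 1.96 SE, pairs treated as independent) by default, with a
percentile bootstrap alternative; the sources this analysis follows
report confidence limits without naming a method, so the simpler
convention is the default.

## Ordination

`runNMDS()` minimizes Kruskal stress-1 with primary treatment of ties;
the isotonic-regression engine is `vegan::monoMDS` (model "global"), run
from `nStarts` random configurations plus one metric (principal
coordinates) start, with tightened stopping thresholds
(`smin = 1e-6`, `sfgrmin = 1e-8`). The metric start guarantees that
perfectly embeddable inputs are recovered at (numerically) zero stress.
The best solution is centred and PCA-rotated so axis 1 carries maximal
variance; when site ages are supplied, the sign of axis 1 is fixed so its
correlation with age is non-negative, making runs comparable. Convergence
is reported (not enforced) as the Procrustes RMSE between the two best
solutions being below 10⁻⁴. One caveat the tests document: at stress ≈ 0
the configuration is identified only up to a monotone distortion of
distances, so two exact solutions can legitimately differ by more than
that tolerance — the flag is a diagnostic for ordinary, noisy inputs.

Dimension choice follows a scree rule (smallest k with stress < 0.10,
capped at 4) when automated, with manual override; the frequent-species
sensitivity analysis refits the ordination keeping species above an
occurrence threshold (10/25/50% of units) and reports the absolute
Pearson correlation of sign-aligned axis-1 scores with the full fit
(reflection invariance makes the absolute value the meaningful summary;
its square is also reported).

## Permutation inference

All permutation p-values use p = (1 + #{perm ≥ obs})/(1 + N), so
p ≥ 1/(1+N) and identical seeds give identical p. The Mantel statistic is
the Pearson correlation of lower-triangle entries, with the null obtained
by simultaneously permuting rows and columns of one matrix; 999
permutations by default. For n ≤ 8 an exhaustive mode enumerates every
non-identity relabeling, which makes the p-value exactly the proportion
of all n! relabelings attaining the observed statistic — the suite checks
this against brute-force enumeration at n = 5 (Mantel) and against the 20
distinct two-group splits at n = 6 (PERMANOVA).

The Mantel correlogram cuts pair distances into classes (Sturges' rule
unless breaks are given), computes per class a Mantel statistic against
the class-membership indicator signed so that positive values mean
within-class compositional similarity, tests one-sided for positive
correlation, and applies progressive Holm correction (class k corrected
within the first k tests). Classes without pairs are dropped with a
warning; a class containing every pair has an undefined statistic and is
reported as NA.

PERMANOVA is one-factor by design (the grouping of interest here is a
single successional class factor). It is computed from the Gower-centred
inner-product matrix G = −½ J D² J: SS_model = tr(HGH) for the hat matrix
of the group design, pseudo-F = (SS_b/df_b)/(SS_w/df_w),
R² = SS_b/SS_total. This algebra reproduces classical one-way ANOVA F
exactly on Euclidean distances of 1-D data (asserted to 10⁻¹⁰) and
matches `vegan::adonis2` to the same precision. Because published
analyses of this design sometimes report df = 1 for three ordered
classes, both codings are supported: categorical (df = k−1, the default)
and a linear-contrast coding that scores ordered classes 1..k as a single
numeric term (df = 1).

## Succession regressions

Three two-parameter families relate community metrics to age, stand
basal area, or understory light: linear y = a + bx, power y = a·x^b,
exponential y = a·e^{bx}. Nonlinear fits start from the log-space linear
fit; a log-space-only mode (`fitMode = "loglog"`) is available because
either could stand behind a published table. R² is always computed on the
response scale (so families are comparable) and clamped at 0; p is the
F-test against the intercept-only model. Two numerical conventions
matter: (1) non-positive responses are excluded from power/exponential
fits with their count recorded — no +0.5 offset is added; (2) when the
log-space initialization already fits with essentially zero residual the
closed-form solution is returned directly, because `nls` refuses
zero-residual problems by design.

`selectSuccessionModel()` fits all applicable families and picks the
highest response-scale R² among those with p ≤ 0.05, returning an "ns"
marker when none qualifies. The selection rule is a package convention
(published tables report one chosen model per response without stating
the rule). A calibration caveat the tests quantify: on pure noise, "ns"
requires all three correlated F-tests to be non-significant at once, so
the family-wise rejection rate is ~15%, not the nominal 5% of a single
test. Model *selection* is exploratory summary, not inference.

## Landscape frequencies and effective diversity

F₁ and F₅% are computed per SBA class from plot-level matrices of all
stems ≥ 1 cm of all life forms: F₁ is the percentage of the class's plots
holding ≥ 1 individual, F₅% the percentage where the species holds ≥ 5%
(boundary inclusive) of all such stems; the all-life-forms denominator is
the default, a trees-only denominator sits behind a flag. Turnover
between classes is the percentage of species present in one class (F₁>0)
absent from the other, both directions. Rank-frequency curves sort
species by descending F₁ with alphabetical tie-breaking; the slope
summary is the linear slope of F₁ on rank over the **top decile of
ranks** (at least two). The head of the curve is where dominance
concentrates; a fit through the full tail of rare species measures tail
length rather than steepness and fails to track the evenness change the
curve itself displays.

The conservation calculation classifies species into maximum-DBH classes
1–5, 5–10, 10–20, 20–40, 40–80, >80 cm (expert label wins over observed
maximum; intervals lower-inclusive) and uses class mid-values 3, 7.5, 15,
30, 60 cm as conservative DBH_max estimates. The open >80 class has no
defined mid-value; 120 cm (1.5 × its lower bound) is the configurable
default, which at RST₃₀% sets the qualifying bar for emergents at 36 cm.
A species qualifies in an age class when ≥ 1 individual reaches
p × mid-value in ≥ `minPlots` plots (p = 0.10 and 0.30 by default;
`minPlots = 2` is the rarity variant). Scope is tree and shrub life forms
only — lianas and palms are excluded — and seedlings, having no diameter,
never qualify but do count toward species totals (switchable).
Reductions are reported to the integer percent. Raising p can only
shrink the qualifying set; the tests assert this as set inclusion.

## The synthetic metacommunity

The generator exists so every stage is testable end-to-end; it encodes
exactly the two assembly axes the analysis is designed to detect and as
little else as possible.

*Landscape.* 45 sites (15 per age band 2–7, 8–17, 18–32 y, so the age
classes are balanced by construction), two plots each, placed uniformly
on a 2 km square. Stand basal area follows a saturating curve
SBA(t) = 33·t/(t+11) m²/ha with lognormal site effects (sd 0.25), chosen
so the three SBA classes (0–11, 11–20, >20 m²/ha) receive similar numbers
of sites. Understory light declines as 100·e^{−0.086·SBA} %, putting
light near 7% under a 30 m²/ha canopy.

*Species pool.* 300 species; life forms drawn with realistic weights
(trees 46%, shrubs 25%, lianas 22%, palms 5%); 25% pioneers.
Colonization rates are lognormal across species (median 0.02
arrivals/plot/year, log-sd 1.2 — dispersal limitation spans orders of
magnitude), with pioneers boosted 8×. Shade tolerance is uniform on
disjoint ranges (pioneers 0.02–0.35, others 0.40–0.95), longevity 6–15 y
for pioneers versus 30–120 y, growth lognormal around 0.45 cm/y scaled by
(mid/15)^0.3 and 2.2× for pioneers; maximum-DBH classes are drawn with
life-form-dependent weights (shrubs small-statured, canopy trees large).

*Assembly.* Arrivals are Poisson (rate × site age) per plot; an arrival
establishes only where understory light at its arrival time exceeds the
species' regeneration requirement 30·(1 − tolerance) %, and then with
probability tolerance^(1 − light/100); survivors of an exponential
mortality hazard 1/longevity grow linearly, capped at 95% of DBH_max, and
are emitted with stratum inferred from diameter and life form (saplings
thinned by half for the half-plot census; establishments of the last two
years still below 1 cm become seedlings). The hard light requirement is
what makes pioneers *fail to regenerate* under a closed canopy rather
than merely establish less often — without it, thirty years of arrivals
at 10–25% light outweigh any establishment penalty and pioneer stocks
never decline.

The suite verifies the regime this produces rather than any fitted
number: tree species density rises monotonically with age, seedling
assemblages diverge monotonically from the initial (SBA-1) tree flora
across SBA classes, rank-frequency curves flatten with stand development,
and the RST₃₀% reduction shrinks from the youngest to the oldest age
class — all under one fixed seed, with the generator's defaults as the
study conditions.

*What it does not emulate:* no seed bank, resprouting, explicit
dispersers, gap dynamics, soil or topographic heterogeneity; seedling
height windows are represented only as a 2-year recency filter; the
optional spatial kernel (one exponential source per species, e-folding
250 m, off by default) creates short-range distance decay for testing the
correlogram but is not a mechanistic dispersal model. Passing tests
therefore certify the statistical machinery and its qualitative
sensitivity, not any quantitative fidelity to a real landscape.

A structureless null generator (counts i.i.d. Poisson with
species-specific means; no age, structure or spatial dependence) is used
to calibrate type-I error: over 200 replicates at n = 30 sites and 999
permutations, both the Mantel test and the PERMANOVA must reject in
3–7% of cases at α = 0.05.

## Problem sizes and degenerate inputs

The test suite runs the full landscape (45 sites, 300-species pool,
~10⁴ stems), 200-replicate permutation calibrations, and a 10⁵-draw
Monte-Carlo rarefaction oracle; the pipeline tests use reduced settings
(99 permutations, 30 γ iterations, 3 NMDS starts) — sizes chosen as
sensible defaults for a complete desk run of the method.

Degenerate inputs are handled explicitly rather than silently: two
all-zero assemblages have undefined dissimilarity (error); units without
individuals are dropped from dissimilarity matrices with a warning
(young sites may hold no stems ≥ 5 cm — a real feature of early
succession); a distance-class holding every pair yields an NA
correlogram entry; empty classes raise errors naming the class; and a
pipeline configuration lacking a seed for any stochastic stage is
refused before any computation.

## Known limitations

- One-factor PERMANOVA only; no partial Mantel, db-RDA or dispersion
  tests.
- No coverage-based rarefaction or asymptotic richness estimators
  (Chao1 and relatives) — the workflow this package implements uses
  size-based rarefaction and resampling only.
- The divergence CI treats pairwise similarities as independent although
  pairs share units; the bootstrap option does not remove that
  dependence. Interpret the intervals as descriptive.
- Chronosequence inference itself assumes space substitutes for time;
  nothing in the statistics can validate that assumption.
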