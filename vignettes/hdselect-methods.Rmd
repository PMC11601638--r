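---
title: "Hyperdimensional classification and backward feature elimination for microbial profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperdimensional classification and backward feature elimination for microbial profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdselect)
```

## The problem

Case/control metagenomic studies ask which microbial species separate
diseased from healthy individuals. Given a samples-by-species table of
relative abundances (percentages summing, with an *unclassified* remainder,
to 100 per sample), we want (i) a classifier that predicts the class of a
sample from its profile and (ii) a small subset of species that suffices
for that prediction — candidate biomarkers. `hdselect` implements both on
top of a vector-symbolic architecture (VSA), also called hyperdimensional
(HD) computing, together with the surrounding preprocessing and
differential-abundance statistics a practitioner needs to go from raw
MetaPhlAn-style tables to a ranked species shortlist.

## The vector-symbolic classifier

**Level hypervectors.** Every numeric value is represented by a bipolar
hypervector (entries in $\{-1,+1\}$) of dimensionality $d$ (default
10{,}000). The value range $[v_{\min}, v_{\max}]$ is quantized into $L$
uniform bins; bin 0 gets a uniform-random bipolar vector, and each
subsequent bin flips the sign of $N = \lfloor d/2/L \rfloor$ coordinates of
its predecessor. We draw the flipped coordinates without replacement from
positions never flipped before (pre-sampling $(L-1)N$ distinct indices and
revealing $N$ per step). This makes the geometry exact and testable:

$$\cos(\ell_i, \ell_j) = 1 - \frac{2N\,|i-j|}{d},$$

so adjacent levels are similar while distant levels decay linearly towards
quasi-orthogonality. A re-flipping scheme would only blur this monotone
decay, which is why the disjoint scheme is the default and the only one
implemented. Bins are half-open with the last bin closed, so $v_{\max}$
maps to level $L-1$; distinct values inside one bin share a level vector
by design. For presence/absence data we use $L = 2$ over $[0, 1]$: absence
maps to level 0, presence to level 1.

**Encoding and training.** A sample with $F$ feature values is encoded by
rotating (circularly shifting) the level vector of the $n$-th value by $n$
positions ($n = 0, \dots, F-1$; the first feature is unrotated) and
bundling — element-wise summing — the rotated vectors. Rotation tags
*which* feature a value belongs to; bundling superposes the tagged values
into one integer-valued hypervector. The rotation convention (index $i
\to (i+p) \bmod d$) is arbitrary but fixed; any bijective convention is
equivalent. A class hypervector is the bundle of all its training samples'
encodings, and prediction assigns the class whose hypervector has the
highest cosine similarity to the encoded sample, breaking exact ties
towards the lexicographically smallest label so that results are
deterministic. Bundles are kept as raw integer sums — no thresholding or
sign normalization — so that the retraining arithmetic below stays exact.

**Retraining.** Bundling many samples introduces crosstalk noise. The
error-mitigation loop revisits the training samples in dataset order;
every misclassified sample's encoding is immediately subtracted from the
wrongly predicted class vector and added to the true one. After each pass
the training error count is re-evaluated; the loop stops when the count
equals the previous pass's count (an exact integer comparison, no
tolerance) or after $R$ passes (default 10). Every update is logged, so a
class vector always equals its initial bundle plus/minus the exact
multiset of logged adjustment encodings — a property the test suite
replays verbatim. If bundling or retraining ever cancels a class vector to
the all-zero vector, cosine similarity is undefined and the package raises
an error naming the class rather than guessing.

**Evaluation.** Accuracy is correct predictions over total samples.
Cross-validation is stratified by class and seeded; the level registry is
built once per dataset from the global value range and shared across
folds, because levels encode *values*, not samples, and a per-fold
registry would make fold accuracies incomparable.

## Backward variable elimination

Starting from the full feature set $S$, the wrapper evaluates a $k$-fold
cross-validated model for every candidate subset $S \setminus \{f\}$ and
permanently removes the features whose candidate accuracy is within an
*uncertainty band* of the iteration best $ACC^{*}$: every candidate with
accuracy $\ge ACC^{*} (1 - u/100)$ and above the accuracy threshold $T$
falls in one iteration (multi-removal; a switch restores strict
single-removal with ties going to the earliest feature in the original
order). Defaults follow the study setting: $T = 0.60$, $u = 1$,
$k = 5$, $R = 10$.

Selection only starts if the full model reaches $T$, and the run ends
when:

* the iteration best falls below $T$;
* the iteration best falls below the previous iteration's best *by more
  than the uncertainty band*, i.e. $ACC^{*} < ACC^{*}_{\mathrm{prev}}
  (1 - u/100)$ — this check happens **before** any removal, so the
  stopping iteration leaves the surviving subset intact;
* fewer than two features remain (the only thinner candidate would be the
  empty set, on which no classifier can be built).

The ordering of the second rule was a genuinely open design point. Checked
*after* removal, the stopping iteration strips the last features that
caused the accuracy drop — precisely the informative ones. Checked before
removal and band-adjusted, the five-feature worked example in the
package's tests unfolds step for step (iteration bests 93% and 90%, both
one-feature models evaluated and rejected, features F1 and F4 surviving
with F2, F3, F5 bucketed in order), and on planted-biomarker simulations
the informative species survive reliably instead of being swept away in
the final iteration. The band-adjusted pre-removal check is therefore the
default and only behaviour.

Three further reporting conventions:

* `best_feature_set` is the globally best-accuracy subset evaluated at any
  point (ties: fewest features, then lexicographic) — the elimination path
  is greedy and noisy, so the final surviving set need not be the best one
  seen.
* The *sub-optimal* record is the evaluated subset with the fewest
  features whose accuracy is still strictly above a floor (default 70%) —
  the shortest usable biomarker panel, even if its accuracy trails the
  best model.
* `models_evaluated` counts fold-models, $k$ per distinct subset;
  candidates below $T$ are kept in the history, flagged, because
  discarding them silently would hide the evidence the stop rules act on.

Per-subset RNG seeds are derived from a rolling hash of the global seed
and the sorted feature subset, so evaluation order (or a parallel
schedule) cannot change any result, and repeated subsets are served from a
cache.

## Preprocessing and statistics

Multi-study tables are harmonized by keeping only species detected
(abundance $> 0$ in at least one sample) in every study; excluded species'
abundances are added to the per-sample unclassified remainder, so each
sample's total is conserved — an invariant every abundance-moving filter
in the package maintains. Two filters follow, in the pipeline's default
order: species whose maximum relative abundance never reaches 1% (the
criterion statistic is configurable between `max`, the most conservative
remover, and `mean`, since the choice is not uniquely determined by the
workflow the package follows), and species detected in strictly fewer
than 5% of samples. Binarization maps abundance $> 0$ to 1. Stratification
splits by biological sex or by the 65-year age boundary (age $\le 65$ is
*adult*, $> 65$ *senior*); samples with missing stratification values are
excluded and reported.

Differential abundance per species: prevalence (percentage of samples per
class with the species present), log2 fold change of mean relative
abundances (case over control; zero means yield flagged IEEE limit values
rather than errors), a two-sided Wilcoxon rank-sum test (exact when the
pooled size is under 50 without ties, otherwise the tie-corrected normal
approximation — `stats::wilcox.test`'s default behaviour), and
Benjamini–Hochberg adjustment via `stats::p.adjust` across the full
tested family by default (correcting only over a reported subset is
available but anti-conservative). A species is significant when both
$p \le 0.05$ and $\mathrm{FDR} \le 0.2$. Species constant across both
groups are degenerate for a rank test; their $p$ is set to 1 and flagged.

## The synthetic cohort generator

`simulate_profiles()` emulates the structure of a case/control cohort with
planted biomarkers: by default 60 case and 60 control samples over 30
species, of which 3 are informative with presence probability 0.8 in cases
versus 0.1 in controls, against a 0.5 background — prevalence contrasts of
the magnitude reported for real CRC-associated species. Present species
get log-normal magnitudes (heavy-tailed, like real relative abundances),
and each sample is renormalized so species plus an unclassified remainder
total exactly 100. Sex is uniform and age uniform over 28–84 years, the
range of the motivating cohorts; metadata carries no abundance effect
unless configured, so stratification tests have a known null. The
generator makes no attempt at ecological covariance between species or at
sequencing noise, so passing tests demonstrate the algorithmic contract —
planted-signal recovery, chance-level behaviour on nulls — not performance
on real microbiomes.

## Numerical choices and problem sizes

Hypervector arithmetic is integer-valued throughout; cosine similarities
are the only floating-point quantities, and all equalities the package
relies on (convergence, accounting, band membership) are computed on exact
integers or with explicit tolerances. The test suite exercises the
planted-recovery and null-guard studies at $d = 1024$, $L = 2$ across 10
seeds each, level-geometry checks at $d$ up to 10{,}000, and the
retraining/prediction contracts on dozens of small randomized instances —
sizes chosen so the full suite documents the behaviour at realistic signal
strengths while remaining convenient to run routinely. The retraining
inner loop (online per-sample updates) is implemented in C++ via Rcpp
because the selection wrapper trains thousands of fold-models per run; all
other numerics are vectorized base R.

## Known limitations

* The elimination wrapper is greedy: it cannot resurrect a removed
  feature, and with strongly redundant biomarkers it may legitimately
  retain fewer than all of them (any subset may already saturate
  accuracy). The sub-optimal record exists precisely to surface such
  minimal panels.
* Cross-validated accuracies on ~100-sample cohorts carry sampling noise
  of a few percentage points; the uncertainty band $u$ should not be set
  far below that noise level, or band membership becomes arbitrary.
* Forward selection, probabilistic outputs, compositional-data
  corrections (e.g. CLR) and covariate-adjusted tests are out of scope;
  covariates are handled by stratification only.
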