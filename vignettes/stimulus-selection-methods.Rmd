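---
title: "Model-based selection of affective stimuli: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based selection of affective stimuli: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Experiments on emotion routinely draw their stimuli from normative picture
databases in which every image carries mean ratings of pleasure/valence,
arousal and dominance (PAD), each on a 9-point scale, together with the
standard deviation and the number of raters behind each mean. Stimulus
groups for such experiments are commonly formed by ad-hoc cutoffs on one
dimension (e.g. "valence below 4 is negative"), which ignores the strong
correlations among the PAD dimensions — most notably the "U"-shaped
relation between valence and arousal — and often ignores dominance
entirely.

`affectselect` implements an alternative, fully data-driven workflow:

1. **Screen** the norms: merge stimuli normed twice, resolve the working
   dominance scale, remove robust outliers, remove stimuli whose norms are
   too imprecise.
2. **Cluster** the surviving stimuli in the 3-D PAD space with a
   parsimonious Gaussian mixture, selecting both the number of clusters
   and the covariance structure by BIC.
3. **Validate** the partition against baseline clusterers (k-means,
   hierarchical agglomeration) and under resampling (split-half,
   jack-knife).
4. **Select** equal numbers of representative stimuli per cluster, ranked
   by classification uncertainty.

Every removal and every decision is logged, because the screening rules
have an ethical function as well as a statistical one: robust outliers in
dominance tend to be the most distressing images.

## Screening rules

* **Duplicates.** Stimuli that appear under the same code with two rating
  rows (normed in different picture sets) are collapsed to one entry whose
  per-dimension mean is the unweighted average of the duplicate means. The
  merged standard deviation defaults to the exact pooled (combined-sample)
  sd computed from the duplicates' means, sds and rater counts, with the
  plain average available as an option; the merged rater count is the sum.
  Only the averaging of means is canonical; the sd convention is this
  package's declared choice and is logged with the merge.
* **Dominance.** Norm tables may carry two dominance variants collected
  with different instruments. The default policy keeps whichever variant
  has fewer missing values (ties prefer the first) and drops stimuli that
  lack it, counting them.
* **Robust outliers.** For each working dimension, values more than
  `mad_cutoff` (default 2.5) MADs from the median are removed, where
  MAD = `mad_constant` × median absolute deviation. The constant defaults
  to 1.4826, the usual Gaussian consistency factor; it is configurable
  because published analyses rarely print it. Exceedance is strict
  (`>`, not `>=`), another declared convention. The rule is affine
  invariant, and a zero MAD (degenerate scale) flags nothing and warns.
  Medians and MADs are computed on the sample that survives the dominance
  stage, and the union of per-dimension flags is removed in one step.
* **Precision.** A stimulus is kept only if, on every working dimension,
  the total width of the confidence interval for its population mean,
  `2 t((1+level)/2, n-1) sd / sqrt(n)`, is at most `ci_max_width` rating
  points (defaults: level 0.95, width 1.0). The Student-t margin is the
  default; at the typical 100 raters it differs from the normal margin by
  under 1%, and a `z` option exists for sensitivity checks.

Each stage attributes every removed code to exactly one reason, so the
report identity `n_out = n_in − merged − dropped − outliers − wide-CI`
holds by construction and is fuzz-tested.

Note that re-screening a screened table can, in principle, remove further
points: the median and MAD of the trimmed sample differ slightly from the
originals. The test suite asserts the weaker monotone property (a second
pass never removes more than the first) and uses a stricter-than-default
pass when it needs a base table that is stable under the default rule.

## The mixture model

Stimuli are modelled as draws from a k-component Gaussian mixture on the
PAD means. Each component covariance is factored as

$$\Sigma_g = \lambda_g D_g A_g D_g^\top,$$

with volume $\lambda_g > 0$, diagonal shape $A_g$ with $\det A_g = 1$,
and orthogonal orientation $D_g$. Constraining each factor to be equal
across components, varying, or fixed at the identity (spherical shape,
axis-aligned orientation) yields the ten three-dimensional families
EII … VVV. The family name plus $k$ determines the free-parameter count in
closed form (e.g. VEV with $k = 5$ in 3-D has $15 + 4 + 5 + 2 + 15 = 41$
parameters), verified in the tests against an independent reference
counter.

**EM.** The E-step computes responsibilities from the current parameters
through Cholesky-based log densities with a log-sum-exp guard. The M-step
updates weights and means in closed form and the covariances per family;
VEI and VEV tie the shape across components while volumes vary, which has
no closed form and uses an inner fixed-point iteration (tolerance 1e-8,
at most 100 inner steps). The observed log-likelihood is recorded every
iteration and is asserted non-decreasing in every test fit.

**Numerical choices.**

* *Initialisation* is a deterministic Ward-linkage agglomeration of the
  data cut at k, so fits are exactly reproducible run to run; an integer
  label vector can be supplied instead.
* *Convergence*: relative log-likelihood change below 1e-8 or 1000
  iterations.
* *Degeneracy*: a component weight falling below $1/(10n)$ or a
  covariance eigenvalue below $10^{-10}$ times the data variance scale
  raises a classed degenerate-fit error carrying the iteration trace,
  rather than silently regularising. During model selection such fits are
  recorded in the BIC surface as failed and excluded.
* *k = 1* uses the closed-form maximum-likelihood solution.

**Model selection.** The BIC is used in the mixture-modelling sign
convention $2\hat\ell - m\log n$ and maximised over the grid of
$k$ (default 1–9) × family (default all ten). Ties break toward fewer
components, then toward the more constrained family. The full surface is
returned for reporting, not only the winner.

**Classification.** Responsibilities give each stimulus a hard label
$\arg\max_g \tau_{ig}$ and an uncertainty $u_i = 1 - \max_g \tau_{ig}
\in [0, 1 - 1/k]$. A fitted model can classify data it was not fitted to,
which is what the split-half validation exploits.

## Baselines and validity indices

k-means (Lloyd's algorithm with `n_init` random starts, best
within-cluster sum of squares kept) and agglomerative hierarchical
clustering (single/average/complete/Ward linkage × Euclidean or
correlation distance) serve as comparison methods, with the usual
index battery: Calinski–Harabasz, Ball, Hartigan, a Simple Structure
Index, silhouette, Dunn, Handl's connectivity and the explained
dissimilarity $1 - W/TSS$. Two caveats are deliberate:

* Correlation distance on profiles of only three values is statistically
  unstable; it is provided because it is used in practice for exactly
  these data, and zero-variance profiles warn and get correlation 0.
* The "Simple Structure Index" exists in several variants; the one
  implemented here multiplies, per variable, the centroid contrast of the
  two extreme clusters, their relative total size, and the deviation of
  the extreme centroids from the grand mean, averaged over variables.
  Results that consume the SSI should be treated as convention-dependent.

The Hartigan index at the top of the scanned range needs $W_{k+1}$, so
the scan fits one extra k internally. The cophenetic correlation
(Pearson correlation between original and merge-height distances) equals
1 exactly on ultrametric inputs, which the tests verify on a constructed
triangle.

## Concordance and stability

Two partitions of the same stimuli are compared through their contingency
table: Variation of Information (natural logs), normalised by its
universal bound $\ln n$; the Adjusted Rand Index; and Cramér's φ from the
uncorrected Pearson χ², with empty rows/columns dropped. The VI
normalisation denominator is not canonical in the literature; $\ln n$ is
this package's declared choice. φ against a constant labeling (a single
cluster on either side) is reported as `NA` rather than an arbitrary
number, except in the trivial case where both partitions are the single
all-inclusive cluster.

Stability is assessed two ways:

* **Split-half**: the stimuli are split 50/50; each half gets its own
  BIC-selected model; each model predicts the other half; agreement
  between predicted and independently fitted labels is averaged over the
  two directions. Because ARI, VI and φ are label-invariant, no explicit
  label matching is needed.
* **Jack-knife**: a fraction (default 10%) of stimuli is deleted, model
  selection reruns, and the retained stimuli's labels are cross-tabulated
  against the full-data solution. The default repetition count is 2000
  (the "few thousand" scale); the test suite and the acceptance script
  use 50 repetitions with the model search restricted to the selected
  family over k = 2–7, which keeps a full stability run in the minutes
  range on one CPU without changing what is being measured.

## Exemplar selection

Usability bands use the 75th and 95th percentiles of uncertainty
(linear-interpolation quantiles, computed over the full classified sample
rather than per cluster — the convention of the reference uncertainty
plots): at or below the 75th percentile is `ok`, between the 75th and
95th `risky`, above `avoid`. Within each cluster stimuli are ranked by
ascending uncertainty with lexicographic code order as the tie-break
(bit-reproducible output), and the first `n_per_cluster` (default 20) are
selected; short clusters return all members with a warning.
`reclassify_codes()` redistributes an externally chosen stimulus list
over the clusters and the screening exclusion categories, with absent
codes counted as unaccounted for, so the counts always sum to the list
length.

## The synthetic norms generator

The licensed normative database cannot be redistributed, so the package
ships a generator whose default specification reproduces everything the
published analysis prints about the five-cluster solution: the five PAD
centroids (3.56, 5.18, 4.34), (7.27, 4.69, 5.96), (2.27, 5.87, 3.55),
(5.05, 3.31, 5.84), (6.44, 4.82, 5.90) and the mixing proportions
(.29, .08, .08, .18, .37). Within-cluster covariances are *not* printed
anywhere, so the defaults are a declared construction with the VEV
pattern the published model selected: one shared ellipsoidal shape
(long axis about twice the others), genuinely varying volumes (about a
3–4× spread), and per-component orientations that follow the local
tangent of the U-shaped valence–arousal curve, tilted into dominance for
the three high-dominance clusters so the marginal dominance spread
resembles real norms. Rating means are rejection-sampled into [1, 9]
(no boundary atoms that would distort medians), per-item rating sds are
uniform on 0.5–2.6 and rater counts integer-uniform on 90–110, matching
the database's published characteristics.

The geometry was fixed once, at design time, to satisfy two requirements
simultaneously: BIC recovers k = 5 with the VEV family at n = 849 in at
least 90% of seeds (a property the test suite asserts over 20 seeds),
and the robust screening rule reproduces the qualitative pattern of the
real data (no valence outliers, few dominance outliers at the low end,
a mid-single-digit percentage of wide-CI removals).

What the generator does **not** emulate, and what passing tests therefore
do not show about real data:

* Real norms are a fixed population, not mixture draws; their
  within-cluster spreads are wider and heavier-tailed than the synthetic
  components, so real classification uncertainties are substantially
  larger than the synthetic ones.
* The synthetic arousal marginal is clumpier than the real one; as a
  consequence a few percent of synthetic items trip the arousal MAD rule,
  where the real data yielded none. Screening tests that need an
  artifact-free base therefore construct one explicitly.
* Image content, themes and rater-level processes are out of scope; only
  codes and normative statistics are modelled.

`inject_artifacts()` plants duplicates (re-emitted codes with jittered
means), dominance outliers (displaced to the far scale end, 1.4 × the
2.5-MAD boundary away from the median, which errors if the displacement
would leave the rating scale) and wide-CI items (sd inflated so the 95%
CI at the item's own rater count spans 1.3 points), with a manifest that
the screening report must recover exactly — the inverse-bookkeeping
property the tests assert.

## Problem sizes

The test suite and the acceptance script run on one CPU in minutes using:
n = 849 samples for recovery (20 seeds over the full 10-family × k = 1–9
grid), 50 jack-knife and 20 split-half repetitions with the search
restricted to VEV over k = 2–7, n = 250–500 unimodal tables for the
screening bookkeeping checks, and brute-force enumeration of all 203 set
partitions of 6 items for the VI metric axioms. The jack-knife default of
2000 repetitions is available for production use.

## Known limitations

* Only three-dimensional data are supported; the four additional
  covariance families that are distinct only above 3-D are out of scope.
* No non-Gaussian mixtures, no Bayesian posterior sampling, no
  bootstrap (with-replacement) stability, no imputation of missing
  ratings.
* Published headline figures for the licensed database can only be
  recomputed by users who hold that database; point the option
  `affectselect.iaps_norms` at the file and the conditional block in the
  acceptance tests will run the reproduction.
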