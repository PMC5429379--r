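# affectselect

Cluster-based selection of representative stimuli from normative
affective rating databases.

## The problem

Emotion researchers build experimental stimulus sets from normed picture
databases in which every image carries mean ratings of pleasure/valence,
arousal and dominance (the PAD model), each on a 9-point scale, plus the
standard deviation and rater count behind every mean. Stimulus groups are
usually formed by hand — valence cutoffs, factorial crossings of
discretised dimensions, thematic picks — which silently assumes the PAD
dimensions are independent (they are strongly correlated, with a
"U"-shaped valence–arousal relation) and usually discards dominance.

`affectselect` replaces that with a reproducible pipeline:

1. **Screening** — merge duplicate norm entries (averaged means), resolve
   the working dominance scale, remove robust outliers (more than 2.5
   MADs from the median on any dimension, MAD scaled by 1.4826), and
   remove imprecise stimuli (95% CI for any dimension's mean wider than
   one rating point, Student-t margin). Every removal is attributed and
   logged.
2. **Model-based clustering** — a k-component Gaussian mixture on the PAD
   means, with component covariances factored as
   Σ_g = λ_g D_g A_g D_gᵀ (volume λ, det-1 diagonal shape A, orthogonal
   orientation D). Constraining each factor equal/varying/identity gives
   ten families (EII … VVV); EM fits every (k, family) pair and the BIC,
   2·loglik − m·log n (maximised), selects the model. Each stimulus gets
   a posterior responsibility vector, a hard label and an uncertainty
   u = 1 − max_g τ_g.
3. **Validation** — k-means and hierarchical baselines with the standard
   validity indices (Calinski–Harabasz, Ball, Hartigan, SSI, silhouette,
   Dunn, connectivity, explained dissimilarity, cophenetic correlation);
   partition concordance via Variation of Information (normalised by
   ln n), Adjusted Rand Index and Cramér's φ; stability by split-half
   cross-prediction and jack-knife deletion.
4. **Selection** — stimuli banded by global uncertainty percentiles
   (≤75th `ok`, 75th–95th `risky`, above `avoid`) and the n least
   uncertain stimuli per cluster exported as that cluster's
   representatives.

The licensed IAPS normative database is **not** bundled. A synthetic
generator (`default_iaps_spec()`, `sample_norms()`) emulates its
structure — the five published cluster centroids and mixing proportions,
VEV-patterned covariances, per-item sds of 0.5–2.6 and about 100 raters
per image — with known ground truth, so the entire pipeline is testable;
`inject_artifacts()` plants duplicates, outliers and wide-CI items that
screening must recover exactly.

## Worked example

```r
library(affectselect)

sn  <- sample_norms(default_iaps_spec(), n = 849, seed = 7)
scr <- run_screening(sn$table)
print(scr$report)
#> Screening report
#>   input stimuli:            849
#>   duplicate groups merged:  0 (0 rows removed)
#>   dominance variant 'dom1'; dropped for missing dominance: 0
#>   MAD outliers removed:     31 (valence 0, arousal 27, dominance 4)
#>   wide-CI removals:         95 (1 dim: 91, 2: 3, 3: 1)
#>   output stimuli:           723

X <- cbind(valence = scr$table$val_mean, arousal = scr$table$aro_mean,
           dominance = scr$table$dom_mean)
sel <- select_model(X)        # 10 families x k = 1..9, BIC-selected
print(sel$best)
#> Gaussian mixture: VEV, k = 5, n = 723
#>   loglik = -1521.1055  params = 41  BIC = -3312.1308
#>   mixing proportions: 0.368 0.306 0.076 0.184 0.066

cl <- classify(sel$best, X, codes = scr$table$code)
reps <- select_representatives(cl, selection_config(n_per_cluster = 20))
print(reps)
#> Stimulus selection: 100 exemplars over 5 clusters (<= 20 per cluster)
#>   uncertainty thresholds: ok <= 0.0006, risky <= 0.0421
```

The screening report shows each filtration stage and its removals (the
counts reconcile exactly with the output size). BIC picks a five-cluster
mixture of varying volume, equal shape and varying orientation — the
structure the generator encodes — and the selection step returns the 20
least-uncertain stimuli per cluster, banded by the 75th/95th uncertainty
percentiles. `write_table()` exports any of these objects as CSV, and
`run_pipeline(pipeline_config(...))` drives the whole sequence from a
norms file to artifacts plus a JSON run manifest. A thin command-line
wrapper lives at `inst/cli/affectselect.R`.

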