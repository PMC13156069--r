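---
title: "Substrate-specific effect prediction for transporter variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-specific effect prediction for transporter variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssep)
```

## The problem

Drug transporters of the SLC superfamily (OCT1, the MATEs, CNTs, OATPs)
carry genetic variants whose functional impact depends on the transported
substrate: the same amino-acid change can abolish uptake of one drug while
leaving another untouched, or even enhance it. Conventional variant effect
predictors (SIFT, PolyPhen-2, CADD, AlphaMissense, ...) assign one
substrate-agnostic score per variant and cannot represent this axis at all.
`ssep` implements a substrate-specific effect predictor: a regression model
that scores a *(variant, substrate)* pair, together with the profiling,
evaluation, feature-exploration and cohort-association machinery needed to
use and assess such scores.

## Data model

Activity is stored as percent of wildtype uptake (`uptake_pct_wt`; 100 =
wildtype). Sources quoting fold-changes are converted to this scale at
ingestion. Replicated measurements of one *(gene, variant, substrate)* key
are collapsed by the unweighted arithmetic mean
(`aggregate_measurements()`), with the replicate count retained. Variant
labels are canonical protein-level strings (`p.F244A`, `p.M420del`);
three-letter codes are accepted and canonicalised, and `parse_variant()` /
`format_variant()` round-trip exactly.

The regression target is `log10` of the uptake ratio relative to wildtype
(`target_transform()`): 100 %WT maps to 0, gains are positive, losses
negative, and ratios are clipped at `1e-3` so that complete loss of
function stays finite at −3. This scale makes variant, substrate and
interaction effects additive, matches the log display convention used for
uptake-ratio panels, and keeps the wildtype anchor at zero, which is also
where normalised deep-mutational-scanning (DMS) scores are anchored.

## Substrate-variability profiling

For every variant measured on at least two substrates, `profile_variant()`
reports:

* **span** Δ%WT = max − min across substrates (≥ 50 defines *high
  variability*);
* **span ratio** max/min (undefined when a substrate has zero uptake; such
  profiles are excluded from span-ratio rankings with a warning);
* **mixed directionality**: some substrate strictly above and some strictly
  below 100 %WT — values exactly at 100 count as neither direction;
* the sample (n−1) standard deviation, the statistical default since the
  underlying replicate counts are small.

`summarize_transporter()` aggregates these into per-gene fractions.
Percentages are displayed rounded half-up to integers
(`round_half_up()`); raw fractions are retained. The `log10(1 + x)`
transform (`log1p10()`) exists for presentation only and is never applied
to stored values.

## Feature bundles

Each *(variant, substrate, structure)* triple carries a blocked feature
vector (`feature_bundle()`):

| block | content | sees |
|---|---|---|
| `embedding` | fixed-length sequence embedding via a provider contract | variant |
| `insilico` | user-supplied panel of variant effect predictor scores | variant |
| `mutation` | Δhydropathy (Kyte–Doolittle), Δvolume (Zamyatnin Å³), Δcharge at pH 7, BLOSUM62 log-odds, indel flag | variant |
| `ligand` | molecular weight, kappa shape index, small-ring count, symmetric-atom count, heavy-atom count | substrate |
| `interaction` | min residue–ligand heavy-atom distance, contact count, binding-site flag | both |

Design choices that the literature leaves open, made once here:

* **Shape index.** The exact ligand shape descriptor used upstream is not
  published; we compute the Kier second kappa index
  κ₂ = (A−1)(A−2)²/P₂² from heavy-atom graph path counts, a standard
  topological shape measure, and document it as a stand-in.
* **Symmetric atoms** are heavy atoms whose canonical topological rank
  (iterative Morgan-style neighbourhood refinement seeded with element,
  degree and bond-order sum) is shared with at least one other atom —
  benzene scores 6, methane 0. Refinement can in principle merge distinct
  orbits on pathological regular graphs; for drug-like molecules it equals
  the automorphism partition.
* **Small rings** are rings of size ≤ 6 in a smallest-set-of-smallest-rings,
  selected greedily by GF(2) independence from the perceived ring set, so
  fused-ring envelopes are not double-counted.
* **Cutoffs.** Binding-site membership 5.0 Å, contacts 4.0 Å; both
  configurable, chosen as conventional protein–ligand proximity values.
* **Deletions** use the wildtype-removal convention: per-residue deltas are
  minus the wildtype property, with the BLOSUM62 stop/gap column as
  substitution score. This avoids undefined mutant lookups while keeping
  deletion descriptors on the same scales.
* **Charge at pH 7** assigns His +0.1 (partial protonation); Asp/Glu −1,
  Lys/Arg +1.

SMILES parsing and molecular weights come from ChemmineR/OpenBabel;
structures are consumed as standard PDB files via bio3d (docking and
structure prediction are out of scope — coordinates are inputs). Sequence
embeddings go through a provider contract (deterministic, fixed length).
The bundled fallback provider is a hash projection of 3-mer counts: it is
*not* a protein language model, but satisfies the contract offline, is
sensitive to single-residue changes, and keeps every downstream code path
testable without downloads. Precomputed embeddings can be supplied with
`table_embedding_provider()`.

A bundle is `full` only when every block, including at least one
interaction block, is present and finite; otherwise it is `partial` and is
routed to the UV (universal-variant) model, which is configured without
the missing blocks. This is how indels and variants without structural
coverage are scored.

## The model

Both routes (SNV for fully annotated missense variants, UV for the rest)
are multi-input feed-forward regressors: one affine encoder per block →
concatenation → dense trunk → scalar, trained with Adam on mean squared
error. The engine is deliberately plain matrix code: with a fixed seed the
training log and predictions are bit-stable on one CPU, and the degenerate
configuration (encoder width 0, no trunk, identity activation) is exactly
an affine map whose Adam fixed point is the least-squares solution — a
property the tests exploit as an analytic oracle.

Defaults (all in `model_config()`): per-block encoder width 32, trunk
(64, 32), ReLU, dropout 0.1, learning rate 10⁻³, batch = full data, max
500 epochs, early stopping with patience 20 on a held-out 15% split and
best-weight restoration. Architecture sizes are not dictated by the
problem; they are defaults for a grid search (`grid_search()`) that scores
each candidate by mean held-out Spearman ρ across repeated seeded runs
(default 5 repeats), breaking ties toward the smaller parameter count and
then grid order. Rank correlation is the selection metric because
rank-preserving predictions are what pharmacogenomic downstream use cares
about.

**Pretrain → fine-tune.** Pretraining uses the multi-substrate labelled
pairs (85/15 split). DMS data — dense single-reporter-substrate scores —
are first normalised by a monotone rank-quantile map onto the empirical
distribution of the pretraining targets, anchored so the
wildtype/synonymous class maps to 0 (`normalize_dms()`; the upstream
normalisation is unspecified, this one is distribution-matched by
construction). Fine-tuning (`fine_tune()`) continues optimisation of *all*
weights at a 10× lower learning rate on DMS bundles built with the
reporter substrate's ligand block, and reports held-out ρ before and after
so the benefit is measurable. Freezing policies were considered and
rejected for simplicity; at desk scale full fine-tuning at reduced rate is
stable.

**Score integration.** `predict_pair()` averages per-structure predictions
(unweighted) into one score per pair and records the count. Pairs with
mixed bundle completeness are routed by majority, ties to SNV; under the
SNV route only the full bundles contribute. A full bundle scored by the UV
route contributes only the blocks that route was trained on.

## Evaluation toolkit

* `spearman()`: average-rank ties; exact permutation p for n ≤ 8, t
  approximation above.
* `jonckheere_test()`: JT = Σ Mann–Whitney counts over ordered group pairs
  (ties ½); exact enumeration of group assignments for total n ≤ 10, else
  a tie-corrected normal approximation with continuity correction, which
  agrees with the exact tail within 0.02 on tie-free instances up to
  n = 10 (tested).
* `kruskal_wallis()`: tie-corrected H via `kruskal.test`, exact permutation
  p for total n ≤ 10.
* `roc_auc()`: Mann–Whitney form, ties ½ (cross-checked against pROC).
* `bin_activity()`: decreased < 50, increased > 200, strict boundaries
  (the canonical convention; an inclusive variant is a flag because both
  conventions appear in figure and text descriptions of such schemes).
  Threshold schemes 50/75 label reduced function (positive class below
  threshold), 125/150 gain of function (above).
* `rank_error()`: |rank(pred) − rank(obs)|/n — the definition is ours,
  since the quantity is otherwise only named in figure legends.
* `per_substrate_benchmark()` / `per_substrate_auc_summary()`: per-substrate
  |ρ| or AUC for every method over substrates with ≥ 10 variants, with a
  Kruskal–Wallis omnibus across methods, or mean ± SEM. For
  reduced-function thresholds, scores oriented as "higher = more activity"
  are negated before AUC so an informative method always scores above 0.5.

## Cohort association layer

Per-prescription daily dose is strength × quantity / duration-days;
a subject's maintenance dose is the **median** of their valid
per-prescription doses (mean available as an option) — the median is
robust to titration outliers in prescription sequences. Variants are
restricted to MAF < 0.05 (strict). The burden score is
Σ dosage × weight, with weights either substrate-specific predicted
activities, mean in-vitro activity, or damaging indicators.
`fit_dose_model()` is ordinary least squares of dose on burden adjusted
for age at prescription, sex, ethnic group and BMI, reporting the burden
coefficient (mg/day per unit burden) with a normal-theory 95% CI and
two-sided p.

Gene-level rare-variant tests: `burden_test()` is a score test of the
unweighted carrier count within the covariate-adjusted linear model;
`skat_style_test()` computes the variance-component statistic
Q = Σ w²(gᵀr)² on null residuals and combines the burden and
variance-component branches by a min-p omnibus under residual permutation
(default 1000 permutations). The analytic SKAT-O ρ-grid/Davies machinery
is intentionally not reproduced: the permutation omnibus is
exchangeability-valid, matches the analytic test's qualitative behaviour
(variance-component branch wins under bidirectional effects, burden branch
under unidirectional ones), and its Monte-Carlo resolution (≥ 1/(B+1)) is
adequate at desk scale.

Damaging-variant classification ships a direction-aware threshold table
(`default_damaging_thresholds()`) with common literature cutoffs per
predictor, fully overrideable; the substrate-specific score counts as
damaging at or below log10(0.5) — half of wildtype activity — because
lower scores mean lower transport. Note that a published CI of
[−2.3, 57.8] alongside p = 0.034 for a burden coefficient is internally
inconsistent with two-sided normal-theory inference; this package reports
standard two-sided tests, so users comparing against such figures should
check sidedness.

## Synthetic study conditions

All pipeline stages are testable offline through seeded generators with
planted truth (`simulate_activity()`, `simulate_features()`,
`simulate_dms()`, `simulate_cohort()`). The activity model is

log₁₀ activity = variant effect + substrate effect + variant×substrate
interaction + noise,

with defaults (variant mean −0.08, SD 0.2; substrate SD 0.08; interaction
SD 0.18; noise SD 0.08) chosen once so the three-bin scheme populates at
roughly 20% decreased / 70% neutral / 10% increased — the shape of curated
uptake panels. Under these defaults the high-variability fraction
(span ≥ 50) is substantially higher than in curated transporter panels;
the span statistic is sensitive to the number of substrates per variant
(8 here versus a handful in typical assays), which is worth remembering
when reading the profiling output on simulated tables. Feature blocks are
linear loadings on the planted latents plus noise, wired so that
substrate specificity is learnable only through blocks that see the
substrate (ligand, interaction) — which is exactly what the
ablation contrast measures. Cohorts draw Hardy–Weinberg genotypes at given
MAFs and generate dose as 1500 + 30·burden + covariate terms + N(0, 300²)
mg/day, an effect size and residual scale matching maintenance-dose
regression settings.

What passing these tests shows — and does not show: the model recovers
planted linear-in-latents structure from well-behaved features; real
embeddings, real chemistry and real dosing records are noisier, collinear
and confounded in ways the generators deliberately do not emulate
(no population structure, no prescription-text noise, no docking error).
The synthetic results validate the machinery, not transferability to any
particular transporter.

## Numerical and reproducibility notes

* One explicit seed drives everything; `child_seed()` splits it into
  independent streams, and `with_seed()` restores global RNG state, so no
  call leaks state. CLI reruns with the same seed are byte-identical.
* Exact permutation switches: Spearman at n ≤ 8; JT/KW at total n ≤ 10
  (full enumeration of group assignments; the 0.5-step lattice of tied JT
  statistics is handled by ≥-with-tolerance counting).
* Training runs full-batch by default at these problem sizes; minibatching
  is available and seeded. Non-finite losses abort with a diagnostic
  rather than returning garbage.
* Default test and acceptance problem sizes (40 variants × 8 substrates,
  5 seeds; cohorts of 500–5000 subjects, 100 replicates; 500 permutation
  nulls) are the package's chosen study conditions: large enough for the
  planted-effect contrasts to be stable, small enough to run on one CPU in
  minutes.

## Known limitations

* The fallback embedding carries only local k-mer composition; positional
  context beyond 3-mers is invisible to it.
* `prune_collinear()` is order-dependent by contract (the earlier column
  wins); permuting columns may change the kept set.
* The UV route shares no parameters with the SNV route; transfer between
  them happens only through the data.
* Exact analytic SKAT-O p-values (Davies' method) and kinetic parameters
  (K_m, V_max) are out of scope.
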