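---
title: "Methods: connectome-based prediction of depression severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based prediction of depression severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements:
the assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and
the numerical choices made where the method's usual description leaves
the design open.

## 1. The model

The quantity being predicted is depression severity as measured by a
psychometric scale (BDI, 0–63, or HDRS, 0–52), always modeled in
standardized units `z = (score − μ)/σ`. The predictor is the subject's
resting-state functional connectome: a symmetric 68×68 matrix of phase
locking values (PLV) in one EEG band (alpha, 8–13 Hz, is where such
effects are typically found), vectorized to 2278 edges in a fixed
row-major upper-triangle order.

CPM assumes each informative edge relates *linearly* to the standardized
score, screens edges by that marginal correlation, and compresses the
surviving edges into one or two sufficient statistics — the summed
z-edge strength of the positively correlated ("high depressive") and
negatively correlated ("low depressive") networks — before a low-capacity
regressor (linear ε-SVR) maps strength to score. The pipeline is
deliberately high-bias/low-variance: with ~10⁵ candidate edges and
~10² subjects, anything richer overfits.

Two leakage rules are absolute and enforced by construction inside
`cross_validate()` (and asserted in tests by replaying a fold manually):
edge standardization means/SDs, the selected edge set, and the SVR are
estimated on training folds only; test subjects and external cohorts
pass through those *frozen* parameters.

## 2. Score harmonization across scales

Training scores are Z-transformed with the training cohort's sample
moments. To score an HDRS cohort against a BDI-trained model, the BDI
moments are rescaled by the ratio of scale ranges (`52/63`, the "rule of
three"): `μ_eq = μ·52/63`, `σ_eq = σ·52/63`. Because both moments are
scaled by the same factor, proportionally equivalent raw scores map to
identical z-values — in particular z(0) is invariant, which is the exact
worked value the acceptance suite checks
(`(0 − 9.5207)/10.5064 = −0.9062` with the reference parameters). The
rescaling assumes the two scales are linearly comparable through their
ranges; that is an approximation the field accepts for harmonization,
not a psychometric equivalence claim.

## 3. Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `q` (FDR level) | 0.01 | — | Benjamini–Hochberg across all 2278 edge tests; strict enough that consensus networks stay small and stable |
| `k` (folds) | 5 | — | ~20 % held out per fold at n ≈ 120; 10 offered for the consistency check |
| `n_iterations` | 100 | — | fold-assignment noise averages out; 20 suffices for the synthetic tests and is used there for runtime |
| `n_perm` | 1000 | — | permutation-null resolution ~0.001; tests use 100–200 (resolution 0.005–0.01) for runtime |
| SVR `C`, `ε` | 1, 0.1 | z units | features are 1–2-D sums of z-scores; a linear kernel with default box constraint is the minimal assumption; both exposed everywhere |
| band edges | alpha 8–13 | Hz | canonical EEG bands (delta 1–4, theta 4–8, beta 13–30, gamma 30–45) |
| epoch rule | 40 s, ±100 µV, 4 epochs | s, µV | standard resting-state artifact screening; earliest surviving epochs kept (deterministic) |
| phase margin | 1 | s | analytic-signal boundary transients are discarded at each epoch end before PLV |

`feature_mode` selects the regressor input: `"pos"` or `"neg"` (one
tail's strength), `"combined"` (the summed index, positive − negative;
the default, since each tail tracks one end of a bimodal cohort and the
difference describes both), or `"both"` (two features, offered for
comparison — the method's usual description is ambiguous between one
SVR per tail and a joint model, so all variants are available).

## 4. The synthetic world

The generator states the conditions the analysis assumes; it is not
fitted to any dataset and its defaults are never moved to make a test
pass.

* **Cohort**: HC scores ~ N(1.6, 0.75²), MDD ~ N(22, 2.7²) in BDI units
  (the reference cohort's group moments), truncated to the scale range
  and rounded — BDI/HDRS are integer-valued, which adds variance 1/12
  that the moment tests account for. Demographics default to
  age ~ N(19, 0.6²) and gender ~ Bernoulli(0.4), matching that cohort.
* **Connectomes**: edge weight = 0.3 + s·0.1·z + N(0, 0.05), clipped to
  [0, 1], with s = +1 on 33 planted positive edges, −1 on 5 negative
  edges (locations uniform at random — the counts are stated by the
  reference analysis, the locations are not), 0 elsewhere. The constant
  0.3 baseline keeps default perturbations inside [0, 1] (z spans about
  −0.8 to +1.3 in a bimodal cohort, so planted weights stay within
  ~0.17–0.43). At these defaults the per-edge edge–score correlation is
  0.1/√(0.1² + 0.05²) ≈ 0.89 — strong by design, so recovery failures
  indicate implementation faults, not statistical bad luck.
* **Time series**: each region is a 10 Hz oscillator
  `A·cos(2π·10·t + θ_r(t))` plus white noise (amplitudes 20 and 5 µV,
  inside the ±100 µV artifact gate), where θ_r is a phase random walk
  (diffusion 2 rad²/s, i.e. a linewidth well inside the alpha band).
  The two regions of a planted edge mix a shared phase driver into
  their own with weight `w = clamp(0.5 + s·0.15·z, 0.02, 1)`, so PLV
  increases monotonically with w (w = 1 gives PLV ≈ 1, w = 0 the
  uncoupled floor). A region in several planted edges follows its first
  edge's driver — a simplification; the oscillator route is there to
  exercise the signal-processing chain, and the connectome generator is
  the primary statistical testbed.

What a green test does **not** establish: robustness to volume
conduction and source leakage, realistic artifacts (blinks, cardiac),
1/f background spectra, non-linear edge–score relationships, or the
performance attainable on real cohorts. The generator's linear planted
signal is exactly the structure CPM assumes, so end-to-end r values
near 1 are a correctness statement about the pipeline, not a
performance claim.

## 5. Numerical choices

* **Band-pass filter.** The usual choice is a zero-phase
  forward–backward order-4 Butterworth. No IIR filtering package is
  assumed here; instead the *squared magnitude response* of the order-4
  analog Butterworth band-pass is applied in the frequency domain —
  identical magnitude to the forward–backward design, exactly zero
  phase (any phase distortion would corrupt PLV). The difference is in
  boundary handling (circular rather than reflected), which the 1-s
  phase margin discards.
* **ε-SVR.** Solved as the standard dual QP with `quadprog`, with a
  relative diagonal jitter of 1e-6 to make the PSD dual matrix strictly
  positive definite. The offset b is then computed exactly as the
  minimizer of the convex piecewise-linear ε-insensitive loss at the
  fitted slope — more stable than averaging KKT conditions under
  jitter. An independent primal oracle (direct `optim()` minimization)
  bounds the QP solution's objective in the tests.
* **Degenerate cases.** Zero-variance edges are flagged, excluded from
  selection (BH runs across the non-degenerate edges), and map to z = 0
  when the standardization is applied. An empty selected network yields
  constant (zero) features; the fold then falls back to the dummy
  training-mean predictor, and `metrics()` records r = 0 for a constant
  prediction vector — without these conventions null-calibration runs
  would be undefined. Sample (n−1) SDs are used throughout.
* **Permutation p.** `p = (1 + #{null MAE ≤ observed}) / (1 + B)`: the
  add-one convention never returns 0, and counting ties as successes is
  conservative. (The inverse convention — counting nulls *greater* than
  the observed error — would reward bad models and is treated as a
  description error in the method's source.) Fold plans are reshuffled
  per permutation; each permutation repeats the full pipeline including
  selection.
* **Confounds.** Screening correlates the candidate with the scores
  (Pearson, or point-biserial for 0/1 variables — the same number as
  Pearson on the coding) and with every edge; the variable is flagged
  when |r| ≥ 0.15 with the score *or* p < 0.05 *or* any edge survives
  BH at 0.05 (the effect-size clause mirrors the practice of treating
  r ≈ 0.15 as "considerable" even at p ≈ 0.09). Flagged variables enter
  `select_edges()` as covariates, where the *edges* are residualized on
  them (semi-partial correlation, t-test on n − 2 − k df); the target
  scores are left untouched. `partial_corr()` itself is the full
  partial correlation (both variables residualized) with the
  n − k − 2 df t-test.
* **R².** 1 − SS_res/SS_tot on held-out data, so it can be negative;
  reported because a squared correlation would hide calibration error.
* **Seeds.** A single master seed fans out to fold plans, permutations,
  and bootstraps through a seeded sub-seed stream
  (`sample.int(2^31 − 1, n)`); fixed seed implies bit-identical output.
* **Consensus.** Intersection over *all* fold × iteration networks (the
  stricter of the two readings of "persist in all iterations");
  external validation freezes that network plus the full-training-set
  standardization.

## 6. Known limitations

Source reconstruction (inverse solutions, head models, parcellation) is
upstream and out of scope — the package starts at regional time series
or connectivity matrices. The PLV estimator is one value per epoch
(no sliding window); with 40-s epochs and a 1-s margin this is the
stable choice, but it cannot resolve within-epoch dynamics. The
cross-scale rule of three is a range-proportional approximation. The
within-cohort score Z-transformation uses the full training cohort
(as the reference procedure does) rather than refitting per fold; the
affine transform cannot leak edge information, but fold-level MAE is
expressed in cohort-level z units. Group-wise metrics on bimodal
cohorts are range-restricted and expectedly lower than pooled metrics —
that is a property of correlation under restriction, not a bug.
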