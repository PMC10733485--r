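---
title: "Joint channel-band-time feature optimization for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint channel-band-time feature optimization for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

Imagining a movement suppresses the mu (7–13 Hz) and beta (13–30 Hz)
rhythms over the contralateral sensorimotor cortex — event-related
desynchronization (ERD). A two-class motor-imagery decoder must therefore
find *where* (channels), *in which band*, and *when* within the epoch the
class contrast lives. The common spatial pattern (CSP) extracts optimal
variance-contrast features once those three choices are fixed; this package
optimizes the three choices jointly instead of fixing them a priori.

## Model and procedure

**Preprocessing.** Trials are common-average referenced and band-passed
4–40 Hz with a 5th-order Butterworth filter applied forward and backward
(zero phase). Whether the original protocol filtered causally is not
something the method depends on; we chose zero-phase because the pipeline
is offline and group delay would smear the time-window grid. The effective
magnitude order doubles; edges are handled by odd-symmetric extension of
three filter lengths with zero initial state.

**Channel ranking.** Each channel is scored by the Fisher discriminant
criterion of its segmented log-power (1 s segments, 50% overlap; segment
length is configurable because epoch lengths differ between recordings):
per segment φ = (m₁−m₂)²/(σ₁²+σ₂²), then the maximum over segments. Nested
channel modes (default top-16, top-32, all; modes wider than the montage
are dropped) are prefixes of the descending ranking, ties broken by channel
index. Ranking runs inside each training fold only — computing it once on
the full dataset would leak test labels through the channel choice.

**Views.** The band grid covers 4–40 Hz in 4 Hz bands stepped by 2 Hz
(17 bands); the time grid uses 2 s windows stepped by 0.5 s (5 windows on a
4 s epoch, 4 on 3.5 s). Sub-band filtering is applied to the full epoch
*before* windowing so that filter transients do not sit inside short
windows. For every (mode, window) view, one CSP filter pair (m = 1) per
band is fitted; features are f_p = log var(Z_p) with the biased 1/T
variance. CSP fitting trace-normalizes per-trial covariances (removing
inter-trial amplitude nuisance), averages per class, and shrinks toward
(trace/M)·I with intensity 0.05 — sample covariances of wide montages over
2 s windows are otherwise ill-conditioned; the original formulation is
silent on both points and we document them as our choices. Eigenvector
signs are fixed (largest-magnitude entry positive) for backend-independent
reproducibility.

**Joint selection.** With y ∈ {−1,+1} and per-view feature matrices
V_{s,t} (columns z-scored by training statistics — row selection under an
L2,1 penalty is scale-sensitive), the weight matrix U (rows = 2mk features,
columns = S·T views) solves

  min_U ½ Σ_{s,t} ‖V_{s,t} u_{s,t} − y‖² + λ ‖U‖₂,₁.

The smooth term decouples across views; the row penalty couples them and
zeroes whole rows, i.e. deselects a feature everywhere at once. We solve by
FISTA with step 1/L (L the largest view Gram eigenvalue), function-value
restart (the iterate is rejected in favour of a plain proximal step
whenever the accelerated step would increase the objective, making the
objective trace monotone), tolerance 1e-6 on the relative objective change,
and a 1000-iteration cap. λ is parameterized as a fraction of
λ_max = max_i ‖(V'y)_i‖₂ across views, the smallest penalty whose solution
is exactly zero — so the grid endpoint λ = 1 always selects nothing,
matching the method's published endpoint behaviour, independent of data
scale. Zero rows are detected at 1e-8 of the largest row norm.

A note on orientation: the method's published description indexes u_{s,t}
ambiguously; the only orientation consistent with "features selected across
views" is rows = features, columns = views, which is what we implement. Its
selection figure is drawn at band resolution (17 rows, not 2mk = 34);
`band_weight_profile()` provides that aggregation for reporting.

**Sparsification.** The surviving rows still carry one weight per view.
Restricted to non-zero rows (Q), each row's views are ranked by |weight|
(R); candidate sets keep each row's Ns strongest views, growing column by
column, zero-weight entries never entering. Ns is the *smallest* depth
attaining the maximum accuracy — accuracy retained with the fewest
features. The accuracy used here is inner cross-validation accuracy on the
training folds. The published description says "test accuracy"; evaluating
candidates on the outer fold would leak its labels into the feature choice,
so we use the stricter nested protocol and note that published absolute
accuracies obtained the optimistic way would be slightly higher.

**Hyperparameters.** λ ∈ {0, 0.1, …, 1} and Ns ∈ {1, …, S·T} are tuned by
stratified inner 5-fold CV on each outer training set: λ first (accuracy of
all non-zero-row features; the *largest* λ attaining the maximum, keeping
selection sparse without accuracy loss; λ values selecting nothing are
excluded), then Ns at that λ (smallest argmax). The final model re-solves
on the full training set at the chosen λ, sparsifies at the chosen Ns, and
trains an RBF-SVM (C = 1, kernel width 1/(p·var(X)), the common "scale"
heuristic; the original work does not state SVM settings). One master seed
drives every fold assignment; fitting and prediction are deterministic
given the model.

**Baselines.** CSP (broadband, full epoch), FBCSP with
mutual-information-based band selection (equal-frequency 8-bin histogram MI
per feature — the cited Parzen estimator is under-specified, and a
histogram plug-in is deterministic and sufficient for ranking; bands ranked
by mean feature MI, top 4 kept), SFBCSP (lasso on band features, penalty
fraction γ ∈ {0, 0.01, …, 1} of max|xᵀy|/n tuned by inner CV; solved by
glmnet), DFBCSP (Fisher score of the C3 anchor channel's whole-epoch log
band-power, top 4 bands — whether the original used segmented power is
unstated), and MSO (the multi-view selection at a single 0.5–2.5 s window
without the sparsification stage). All share the preprocessing, CSP
primitives, SVM, and — given one master seed — the outer fold assignment,
so per-seed comparisons are paired.

## The synthetic generator

`generate_trials()` emulates the physiology the method targets: per-channel
1/f background (spectral exponent 1, std 1), a shared common-mode trace
(std 0.5, removed by CAR), and at the active channels (defaults C3 and C4)
a 10–14 Hz oscillation synthesized by band-pass filtering white noise —
not a pure sinusoid, so within-band variance behaves as in real EEG. For
class 2 the oscillation amplitude is multiplied by `attenuation` (default
0.5) inside 0.5–2.5 s, with 100 ms raised-cosine ramps to avoid ringing
confounds in window selection. The oscillation std defaults to 3: a
prominent mu rhythm whose in-band power dominates the background, chosen so
that planted power ratios are directly measurable — with a weaker rhythm
the measured class-1/class-2 band-power ratio is visibly diluted below
1/attenuation² by in-band background and by zero-phase filter smearing at
the window edges (which is also why verification measures the ratio on the
central part of the window). The generator does not model volume
conduction, artifacts, or non-stationary background, so passing tests show
correct recovery of planted structure under idealized conditions, not
real-data performance; the published real-data accuracies are not
reproduced here.

`checkerboard_case()` is a fixed 20-trial, 6-channel fixture with the
planted channel/band/window known by construction, used in unit tests. Its
CSP check inspects the spatial *pattern* (composite covariance times
filter) rather than the filter, whose entries are rescaled by whitening.

## Numerical choices and degenerate inputs

- Sample windows are half-open, 0-based `[round(start·fs), round(end·fs))`,
  so stepped windows tile without duplicated samples.
- Zero-variance segments or projections raise errors naming the offending
  trial/channel/segment rather than propagating -Inf.
- Equal class covariances give all generalized eigenvalues exactly 0.5;
  singular composite covariances are rejected with advice to use
  shrinkage > 0.
- Accuracy ties during tuning are resolved with a 1e-12 tolerance before
  applying the largest-λ / smallest-Ns rules.
- λ = 1 (or any grid value selecting zero features in some inner fold) is
  excluded from the argmax; if every λ degenerates, fitting stops with an
  error rather than returning an empty model.

## Known limitations

- The two CSP feature rows of one band are strongly correlated, and a
  row-sparse penalty at the largest accuracy-preserving λ keeps one
  representative of such a pair, not both; recovery of a planted band is
  therefore assessed at band level (at least one of its rows selected),
  which matches the band-resolution reporting of the method's original
  selection figures.
- Verification problem sizes are the generator defaults (100 trials/class,
  20 channels; 20 benchmark seeds, 100 recovery seeds, 3 seeds for chance
  controls), chosen to keep the full suite at desk scale.
- Only two-class decoding is implemented; multi-class extensions,
  causal/online operation, and subject transfer are out of scope, as are
  loaders for the public competition recordings the method was originally
  evaluated on.
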