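---
title: "Phase-encoded somatotopic mapping: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-encoded somatotopic mapping: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

## The problem

In phase-encoded (traveling-wave) fMRI somatotopy, successive skin sites —
here the tips of the index through little fingers (d2–d5) — are stimulated
periodically. A cortical location that prefers one site responds each time
the stimulus sweeps past it, so its BOLD time series oscillates at the
sweep frequency, and the *phase* of that oscillation encodes the preferred
site. A map of phase across the cortical surface of the postcentral gyrus
is a map of the fingers in primary somatosensory cortex (S1).

`somatomap` implements the full analysis chain for such experiments on
triangulated surface patches, together with a synthetic-data module that
generates every input with known ground truth, so each stage can be tested
quantitatively without scanner data. The motivating application is the
comparison of hand maps between people with unilateral complex regional
pain syndrome (CRPS) and pain-free controls — area, location on a common
spherical surface, and functional geometry of the map, plus the
accompanying clinical-covariate statistics.

## Stimulation protocol and the forward model

The default `stim_protocol()` encodes the design: 4 fingers x 6 s + 6 s
rest per 30 s cycle, 12 cycles per run, 4 runs, TR = 2 s, 183 volumes per
run of which the first 3 are dummies. The stimulus frequency is therefore
1/30 Hz, which falls exactly on DFT bin 12 of the 180 retained samples
(frequency resolution 1/360 Hz). All of these are derived quantities, not
hard-coded constants.

The synthetic forward model (`simulate_bold()`) is deliberately minimal:

\[
y_v(t) = a_v \cos(2\pi f_{stim} t - \phi_v) + b\,t + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),
\]

a pure sinusoid at the stimulus frequency plus linear drift plus white
Gaussian noise. Since the analysis only ever interrogates the fundamental
frequency, a richer hemodynamic-response shape would change nothing
downstream except the constant phase offset, which is already captured by
the `hemodynamic_delay_s` parameter (default 5 s, i.e. a phase offset of
\(2\pi \cdot 5/30\)). The delay affects only the labelling of phases as
fingers, never a test statistic. What the generator does *not* emulate —
structured physiological noise, motion, vascular artifacts, inter-subject
anatomical variability — bounds what passing tests show: they validate the
estimators and their calibration, not robustness to every artifact of real
scanner data.

The default ground-truth "hand map" is a 20 mm x 10 mm band on a
40 mm x 40 mm flat patch with 1 % signal amplitude, matching the scale of
the S1 hand knob on a flattened patch. The default noise SD is a free
parameter of the simulation (real-map SNR is not something we can fix from
first principles) and is exposed rather than asserted.

## First-level analysis

`preprocess_runs()` discards dummy volumes, removes a per-run linear trend,
and raw-averages the four runs; `fourier_phase_map()` then takes the DFT
and keeps the complex coefficient at the stimulus bin. One numerical
choice deserves emphasis: the trend coefficients are estimated jointly
with the stimulus-frequency quadrature pair (only the trend is removed).
A plain detrend is slightly correlated with the stimulus cosine over a
finite window and would bias the recovered phase by order 1e-3 radians;
with the protected fit, a noiseless periodic response is recovered to
machine precision.

Significance of the periodic response is an F-ratio: power at the stimulus
bin over mean power across noise bins. Noise bins are all frequencies up
to Nyquist except (i) bins below 0.005 Hz, where slow movement artifacts
dominate (with the default protocol that is bin 1; bin 0, the mean, is
never tested), (ii) the stimulus bin itself, and (iii) its harmonics
(bins 24, 36, ..., 84). Each retained complex bin contributes two degrees
of freedom, giving F(2, 2K) with K = 82 noise bins; this df convention is
configurable in the sense that it is derived from the protocol, and the
choice of *mean* (rather than summed) noise power is documented here
because the literature leaves it unstated. Under white Gaussian noise the
resulting p-values are calibrated (the test suite checks 5 % nominal /
empirical agreement on 5000 null vertices).

### Cluster correction

Vertexwise thresholding at p < 0.01 is followed by a surface-based
cluster correction. Reference implementations of this step exist in
surface packages whose null-generation procedure is not documented; we
therefore state ours precisely. Clusters are connected components of
suprathreshold vertices; the cluster statistic is *surface area* (the sum
of face areas whose three vertices are all suprathreshold), not vertex
count, because meshes need not be uniform. The null distribution is Monte
Carlo: i.i.d. Gaussian maps, smoothed with the same number of
nearest-neighbour steps as the data (0 if the data were not smoothed),
standardized per vertex, thresholded at the matching Gaussian quantile;
the maximum cluster area per null map is recorded and
`corrected_p = (1 + #{null >= observed}) / (n_null + 1)`, so the smallest
attainable corrected p is `1/(n_null + 1)`. Hemispheres with no
suprathreshold response are returned as an explicit missing-map flag that
every downstream measure propagates (`NA` area, missing centroid) — maps
can genuinely be absent in patient data and the pipeline must not fail on
them.

The family-wise error calibration of this procedure is itself a test: 200
pure-noise first-level analyses on a 15 x 15 patch with a 199-sample null
give an empirical FWER at or below 0.01 plus two binomial standard
errors. These problem sizes (and the other calibration sizes quoted
below) were chosen as the smallest that make the Monte-Carlo error bands
meaningful.

### Finger labelling and cross-subject averaging

Phase minus the delay offset, expressed as a cycle fraction, maps
[0, 0.8) onto d2–d5 in stimulation order and [0.8, 1) onto rest (these
rest phases are the ones truncated from display). `cross_subject_average()`
normalizes each subject's complex response to unit amplitude before vector
averaging — a subject with a strong amplitude should not dominate the
group phase — and attaches a coherence-style F-ratio
\((n-1)A^2/(1-A^2)\) for display thresholding; for fully random phases the
group amplitude follows the Rayleigh-walk law \(\sqrt{\pi}/(2\sqrt{n})\),
which the tests verify at n = 17.

## Map measures

**Area.** `roi_area()` counts faces whose three vertices all belong to the
ROI. The all-vertices rule (rather than fractional faces) is deterministic
and unambiguous; it underestimates by a boundary band of at most one face
ring, identically across groups.

**Location.** Map centroids live on a common sphere (radius 100 mm, the
usual average-surface convention, configurable). The centroid is the
area-weighted mean of ROI vertex positions renormalized to the sphere;
weights are one third of adjacent face areas. An unweighted variant is
available (`weighted = FALSE`); on near-uniform meshes the two differ by
under half a degree. Group comparison of centroid *directions* uses the
Watson F test for a common Fisher (spherical Gaussian) population:

\[
F = (N-2)\,\frac{R_1 + R_2 - R}{N - R_1 - R_2},
\qquad df = (2,\ 2(N-2)),
\]

with \(R_1, R_2, R\) the within-group and pooled resultant lengths. The
test is rotation invariant, and under a shared Fisher distribution its
p-value is uniform (both are property tests; type-I error is checked to
0.05 ± 0.02 over 1000 simulations). As a complementary scalar measure,
`geodesic_distance()` gives the great-circle distance from the centroid to
a reference point; the reference (in application, a point in the concavity
of the central sulcus) is arbitrary, and two-group comparisons of
distances are unaffected by shifting it for both groups.

**Bayes factors from F statistics.** The published source formula for the
F-based Bayes factor used with such contrasts is not reproducible from the
text it appears in, so `bf_from_f()` is a pluggable interface with a
clearly documented default: a likelihood-ratio Bayes factor whose
alternative is pinned at the critical noncentrality of a level-`p0` test
(default `p0 = 0.05`, `ncp = df1 * qf(1 - p0, df1, df2)`). This default is
monotone increasing in F (monotone likelihood ratio of the noncentral F
family), satisfies `BF10 = 1/BF01` exactly, and equals 3.52 at the
α = 0.05 critical value for df (2, 50) — a calibration constant recorded
in the tests. We deliberately do not attempt to reproduce published BF
columns computed with the unavailable formula.

## Map geometry

`smooth_complex()` implements gentle nearest-neighbour averaging of the
complex values (vertex + 1-ring uniform mean). When a kernel width is
given instead of a step count, the step count is derived from the mean
squared edge length so the accumulated kernel is ≲ the requested FWHM and
is reported back; on the default 1 mm patch a 1.5 mm kernel is one step.

`phase_gradient()` fits, at each ROI vertex, a no-intercept plane to the
neighbour phase *differences* (wrapped to \((-\pi, \pi]\) — the circular
subtraction) against the 2-D offsets. On any affine phase field the fit
is exact at machine precision, and wrapping the field across 0/2π changes
nothing. Only in-ROI neighbours enter the fit: vertices outside the map
have zero amplitude and their phase is noise, and including them would
corrupt every band-edge gradient. Vertices with fewer than three usable
non-collinear neighbours are flagged undefined rather than extrapolated.

Gradient variability is summarized by the circular variance
\(1 - \bar{R}\) of gradient directions, and compared across a
within-subject factor (side) and between-subject factor (group) with the
Harrison–Kanji two-factor circular ANOVA in its high-concentration form:
resultant-based sums of squares, the \(1 + 3/(8\hat\kappa)\) correction,
and F reference distributions. \(\hat\kappa\) is estimated from the mean
*within-cell* resultant so a genuine factor effect does not masquerade as
low concentration. Its type-I error is ≈ 5 % (±3 points over 400 null
replicates at κ = 5, n = 20/cell) and its power for a π/2 side
separation exceeds 90 %.

One ambiguity is worth stating openly: the published analysis applies the
circular ANOVA "on the gradient variances", yet the test consumes angular
data while a circular variance is a linear quantity in [0, 1]. We expose
both readings — the default pathway feeds per-subject (per-hemisphere)
mean gradient *directions* to `harrison_kanji()`, which is the standard
use of the test; `variance_to_angle()` supports the literal pathway that
wraps variances onto the circle as \(2\pi v\). Neither is asserted as the
published intent.

Relations between map geometry and clinical covariates use the
circular–linear correlation \(r_{cl}\) (cosine/sine component
correlations), with `n * r_cl^2` referred to χ²(2). The statistic is `n`
times the squared correlation — we read the published "N r" as a
typographical truncation of the standard statistic. Null p-values are
uniform (KS-checked over 1000 replicates at n = 200).

## Group statistics

`pool_by_affected_side()` flips right-CRPS subjects so the affected side
is aligned across patients before pooling; controls receive a fixed,
documented pseudo-assignment (left hand) since they have no affected side.
Group tests are pooled-variance Student t tests (the published df of 33
for 17 + 18 subjects identifies Student, not Welch, pooling), with
default-prior JZS Bayes factors: the Cauchy prior scale is fixed at
\(\sqrt{2}/2 \approx 0.707\), the common analysis-software default, and
the marginal likelihood is computed by adaptive quadrature of the
noncentral-t density against the prior. The implementation is checked
against an independent fine-grid quadrature oracle to 3 significant
digits, and against the published cohort values: for the packaged
35-subject table, age gives t(33) = 0.19 and BF10 = 0.330, laterality
t(33) = 0.65 and BF10 = 0.384.

The 2 x 2 mixed ANOVA (side within, group between) uses the classical
error strata: group against between-subject error, side and side x group
against the within-subject residual; subjects missing either side are
dropped listwise with the count reported, mirroring how missing
hemispheres must be handled in application. On balanced data it agrees
with an explicit sums-of-squares oracle to 1e-9, and its group-effect
p-value is calibrated under label permutation.

`normality_log_pipeline()` codifies the normalization rule: Shapiro–Wilk
at α = 0.05, natural-log transform on rejection (only if all values are
positive — a nonpositive value is an error, never silently offset), and a
re-test. `fisher_z_compare()` compares affected- vs unaffected-side
correlations through Fisher's z, and `bh_critical_values()` reports the
Benjamini–Hochberg rank criticals `i*q/m` assigned back in original test
order, with the step-up pass/fail decision. The pressure-pain severity
score is the normalized threshold difference
\((PPT_{unaff} - PPT_{aff}) / (PPT_{unaff} + PPT_{aff}) \in [-1, 1]\);
the plain difference is available by flag because the published algebra
for this score is not legible in the source text.

## Worked example

```{r example, eval = FALSE}
pr <- stim_protocol()
patch <- make_flat_patch(41, 41, 1)
truth <- ground_truth_phase_map(patch, pr)          # 20 x 10 mm band
bold <- simulate_bold(truth, pr, noise_sd = 0.5, seed = 1)
series <- preprocess_runs(bold, pr)
pm <- fourier_phase_map(series, pr)
cc <- cluster_correct(pm, patch, n_null = 999, seed = 2)
roi_area(patch, cc$roi)
table(phase_to_finger(pm, pr)[cc$roi$vertex_indices])
```

## Known limitations

* The forward model has no hemodynamic convolution, physiological noise
  spectrum, or motion; calibration results transfer to real data only to
  the extent that residual noise is approximately white at non-excluded
  frequencies.
* The cluster-correction null assumes the data's spatial correlation is
  matched by the stated nearest-neighbour smoothing; a data-adaptive
  smoothness estimate is not implemented.
* The Harrison–Kanji high-concentration decomposition loses power below
  κ ≈ 2 (a warning is raised); no exact small-κ variant is provided.
* Gradient computation is restricted to flat patches; cortical flattening
  itself, surface reconstruction and registration are out of scope — the
  synthetic module supplies already-flattened or spherical meshes on a
  common topology.
* Simulation sizes in the test suite (e.g. 200 null analyses for the FWER
  check, 1000 replicates for p-uniformity) are the package's chosen
  calibration sizes; the corresponding Monte-Carlo error bands are stated
  next to each assertion.
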