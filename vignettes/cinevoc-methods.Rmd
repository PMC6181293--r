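---
title: "Classifying films from cinema-air chemistry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying films from cinema-air chemistry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinevoc)
```

`cinevoc` turns raw cinema exhaust-air traces — one mixing-ratio time series
per compound, plus a ticket-sales metadata table — into a per-class
assessment of whether crowd-emitted chemistry predicts a film's age
classification. This vignette explains each model in the chain, the
parameters that matter, and the choices made where the design was genuinely
open.

## The one-box room model

A screening room of volume $V$ flushed with fresh outside air at rate $Q$
and holding an audience emitting a compound at total rate $S(t)$ obeys the
well-mixed mass balance

$$\frac{dC}{dt} = \frac{Q}{V}\bigl(C_{\mathrm{in}} - C\bigr) + \frac{S(t)}{V},$$

with $C$ the room (and exhaust-duct) mixing ratio and $C_{\mathrm{in}}$ that
of the inflowing air. With constant $S$, the solution is exponential
relaxation from the initial value $C_0$ toward the steady state
$C_{\mathrm{in}} + S/Q$ with time constant $\tau = V/Q$. The measured rooms
have $V = 6500\,$m$^3$ and $Q = 1300\,$m$^3$/h, so $\tau = 5$ h — much longer
than a film, which is why a screening shows a quasi-linear rise rather than a
plateau.

**Per-person form.** Peak mixing ratios scale with the audience size $N$
(known from ticket sales), so each screening's trace is divided by $N$ before
fitting and the fitted emission rate $E$ is per person (ppb·m³/h). Viewers
under 12 can be discounted (children emit less isoprene); the generator
models this with a configurable child emission factor (default 0.5).

**Fitting.** With $C_{\mathrm{in}}$ held fixed the constant-emission solution
is *linear* in $(E/Q,\ C_0 - C_{\mathrm{in}})$ through the basis functions
$1 - e^{-t/\tau}$ and $e^{-t/\tau}$, so the least-squares problem is solved
exactly by linear algebra — no iterative optimizer, no convergence
diagnostics. The physical bound $E \ge 0$ is imposed by the constrained
solution (if the unconstrained optimum has $E < 0$, the bound is active and
$C_0$ is refit alone — the KKT solution); `allow_negative_E` lifts the bound
for deposition-dominated compounds.

**Why $C_{\mathrm{in}}$ is never co-fitted.** Inside one screening window
$C_{\mathrm{in}}$ and $E/Q$ multiply the *same* basis function
$1 - e^{-t/\tau}$: only their sum is estimable. $C_{\mathrm{in}}$ must come
from outside the window — the room configuration (default), or the median of
a pre-entry baseline window (`estimate_inflow()`, opt-in via
`baseline_minutes`). The baseline estimator is deliberately *not* the
default: with $\tau = 5$ h and back-to-back screenings the pre-entry air
still carries the previous audience's excess, so the baseline median
overstates $C_{\mathrm{in}}$; the model family is invariant to that shift
*except* through the $E \ge 0$ bound, which then clamps otherwise good fits.
Fit quality is reported as the RMS misfit and logged per
(screening, compound) in the feature table's audit attribute.

**Preprocessing order.** Slice the screening window (closed interval
$[\mathrm{start}, \mathrm{end}]$, boundary samples included — fixed here once
so sample counts are reproducible), interpolate missing samples linearly when
a gap is at most 3 steps (longer gaps exclude the screening rather than
invent data), trim the final 5 minutes (the exit transient: for isoprene a
spike from the audience standing up), divide by $N$, fit, subtract. The fit
uses the full trimmed window including the entry rise. The residual series —
measured minus modelled — is the object everything downstream consumes.

## Peak features

The residual series carries peaks and valleys that recur at the same scene in
every screening of a film. Features (per screening × compound):

| group | features | notes |
|---|---|---|
| moments | sd, skewness, excess kurtosis | population moments; all-constant input maps skewness/kurtosis to 0 rather than NaN |
| sums | $\sum r^+$, $\sum r^-$ | overall measure of change |
| counts | peaks per film-minute, two rules | all peaks (1 step up/down) and robust peaks (≥ 3 strictly increasing then ≥ 3 strictly decreasing steps) |
| occurrence | first robust peak apex as fraction of film length | sentinel 1.0 when no robust peak exists, keeping the feature bounded and defined |
| top peaks | 5 highest and 5 widest robust peaks | sorted descending, zero-padded; ties broken by earlier apex |

Steps must be *strictly* monotone: plateaus break a run (determinism on tied
samples). Peak width is the elapsed time from the start of the monotone rise
to the end of the monotone fall, extended outward beyond the qualifying 3
steps while monotonicity holds — width is not defined by any half-height
convention, which a residual (sign-changing) trace does not support.

The canonical descriptor list counts 20 items; the modelling feature set has
18. The two dropped by default are the sums of the top-5 heights and of the
top-5 widths, because they are exact linear functions of included features —
dropping them loses no information. The alternative 18-variant
(`feature_variant = "drop_counts"`) keeps the sums and drops the two peak
counts instead, and `"full"` keeps all 20; which pair is dropped changes the
ensemble's inputs only marginally since both variants span nearly the same
information.

## Evaluation design

Instances are screenings (one feature vector per screening × compound), and a
separate model is built per compound. Films — not screenings — are the unit
of train/test splitting, because screenings of one film share its scene
schedule; splitting screenings would leak film identity into the test set.

One film per class is chosen as the test set; the rest of its class trains.
Test eligibility requires ≥ 8 screenings, *except* in the class containing
the configured always-together pair (default: the two films measured only
once, The Counselor and Machete Kills). There the pair forms one joint test
option — pooled scoring, since one screening each cannot be evaluated
separately — and every remaining film of that class is an option regardless
of its count: when the pair trains, some other film of the class must be
tested. With the measured film list this yields $2 \times 3 \times 2 \times 2
= 24$ combinations.

Each training set fits one multiclass ensemble of 500 randomized trees with 6
candidate variables per split ($\lfloor 18/3 \rfloor$; a `ranger` probability
forest). Per-class scores are one-vs-rest: the class's probability column
against the binary is-this-class labels of the test screenings.

* **ROC AUC** is computed in the Mann–Whitney form (midranks; ties get half
  credit), the exact pairwise ordering probability.
* **PRC curves** are computed at every distinct threshold — the same
  confusion counts as the ROC curve, preserving their one-to-one
  correspondence — and precision is linearly interpolated onto a fixed
  101-point recall grid so curves from different combinations can be
  averaged point-wise; the best precision is kept where several thresholds
  share a recall. At small test sizes the early-recall end of a PR curve is
  upward-biased (an artifact of precision at few predictions, visible in the
  random-score simulation in the test suite); the bias vanishes with size.
* A (combination, class) AUC whose test set lacks positives or negatives is
  *missing*, excluded from the class mean with the count logged — imputing
  0.5 would bias the summary toward randomness.

Reproducibility: a master seed in the configuration; per-combination (and
per-shuffle) training seeds are derived deterministically from it, so every
result table is a pure function of (input files, config, seed).

## Permutation test

Under the null that film labels carry no information, each training film is
assigned a uniformly random permutation of the existing labels (class
distribution retained; all screenings of a film move together; test labels
never shuffled). Fifty shuffles per combination retrain and rescore, and the
pooled p-value is

$$p = \frac{b + 1}{n + 1},$$

where $b$ counts permuted AUCs $\ge$ their combination's original AUC and $n$
is the total number of permuted values. The add-one form cannot return 0
(the observed labelling is itself one permutation); the raw fraction $b/n$
is available as a variant, and ties count against the original
(conservative). Per-film p-values restrict the pool to the combinations whose
test set contains the film. No correction across compounds is applied by
default — the analysis screens for candidate compounds rather than asserting
family-wise significance.

A property worth knowing: pooling exceedances over 24 combinations that share
films makes the null distribution of $p$ *concentrated around 0.5* rather
than exactly uniform — each combination contributes a partially independent
exceedance fraction, and their average is less dispersed than a single
uniform draw. The test is therefore conservative in both tails (it will not
over-reject at conventional levels), which the null-calibration test in the
suite measures directly.

## The synthetic-study generator

The generator exists so that every stage — file parsing through permutation
p-values — is testable end to end without measurement files. It emulates:

* **Room physics:** traces are the exact stepwise one-box response to
  piecewise-constant emission, so the preprocessing model is *correctly
  specified* for null films — parameter recovery is exact up to noise.
* **Population structure:** per class, films, screenings per film, audience
  sizes (uniform 20–120), optional under-12 fraction.
* **Film and class identity:** each film has a fixed scene schedule of
  emission bursts (Poisson 10/h, boxcar 1–3 min) shared by all its
  screenings — peaks recur at the same time in every screening; the class
  sets the schedule's amplitude statistics (gamma, CV 25%).
* **The campaign's shape:** `study_spec_campaign()` mirrors the measured
  film list (11 films, screening counts 18/33, 10/12/13, 2/8/34, 1/1/3), so
  the split enumerator reproduces the 24 combinations on generated metadata.
* **Nuisance structure:** per-person baseline emission (150 ppb·m³/h),
  end-of-film exit burst (removed by the 5-min trim by construction),
  additive Gaussian measurement noise (default 0.02 ppb on the raw trace),
  and back-to-back scheduling with 30-min gaps so consecutive screenings
  start from an un-flushed room.

Default magnitudes are calibrated to the measured isoprene phenomenology: a
per-person rise of a few hundredths of a ppb over a screening, residual
peaks of roughly 0.002–0.01 ppb per person, and on the order of ten
discernible residual peaks per film. One consequence of the 5-h residence
time discovered while designing the generator: a burst's excess does not
decay within a film, so with very few events the detrended residual is
dominated by each film's cumulative event pattern rather than by class
amplitude; at realistic event rates the class signal dominates.

What the generator does **not** emulate: compound-specific physiology beyond
per-person rates, genre structure within a class, ventilation-system checks
or cleaning emissions (real QC exclusions enter as metadata flags), drifts or
calibration error in the instrument, or audience heterogeneity beyond the
under-12 split. Passing the recovery tests therefore shows the pipeline is
correct and sensitive under its own assumptions — not that real cinema data
meet those assumptions.

## Numerical conventions and degenerate inputs

* All-constant residuals: moments and peak features 0, first-peak occurrence 1.
* Flat-zero traces fit $E = 0$ with zero misfit (not an error).
* AUC/PRC with an absent class: `NA` plus a warning, never silently 0.5.
* Equal heights or widths: the earlier apex ranks first; fewer than 5 peaks:
  zero-padding.
* Series too short for a peak: zero peaks with a warning, not an error.
* Timestamps are naive local time (UTC+1) throughout; no timezone math.

## Problem sizes used by the test suite

Unit tests run on small studies (2 films per class, 3–4 screenings, 40–50-min
films) for speed; the end-to-end recovery checks use the full default study
(2–3 films per class, 10 screenings per film, 90–120-min films) once with a
5×-amplitude separation and twenty structureless replicates for the null
calibration of the permutation p-values — sizes chosen to estimate each
quantity to the precision its assertion needs.

## Known limitations

* With only 1–2 training films per class, class probabilities for an unseen
  film interpolate between neighbouring classes; per-class AUC for a single
  study draw is volatile even when class separation is large. This mirrors
  the smallness of the measured campaign (11 films) rather than a fixable
  implementation detail.
* The FSK-16 class of the measured list (three films, five screenings) is
  structurally hard to evaluate; missing-AUC handling matters most there.
* The pooled permutation p-value is conservative (see above); per-film
  p-values pool fewer combinations and are closer to uniform under the null.
* The box model assumes constant ventilation and perfect mixing; neither
  multi-zone flow nor temperature effects are represented.
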