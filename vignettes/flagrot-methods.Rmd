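---
title: "Rotational kinematics of uniflagellate cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational kinematics of uniflagellate cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagrot)
```

## The problem

Uniflagellate *Chlamydomonas reinhardtii* cells (the *uni1* mutant) do not
swim forward: under a coverslip they rotate in place, driven by the beat of
their single flagellum. Marker-less pose estimators such as DeepLabCut can
track three landmarks per video frame — the flagellar tip, the flagellar
base, and the posterior end of the cell body — each with a confidence score
("likelihood"). `flagrot` turns those per-frame landmark coordinates into
the quantities a motility study needs:

* the **body angle** $\theta_b(t)$: the planar angle of the posterior
  $\to$ base vector (the body axis);
* the **flagellar angle** $\theta_f(t)$: the signed angle from the body
  axis to the base $\to$ tip vector;
* the **cumulative angle** $\Theta(t)$: the unwrapped body angle, whose
  least-squares slope is the signed angular velocity $\omega$ and whose
  sign classifies rotation as counterclockwise (CCW, positive) or
  clockwise (CW);
* the **beat frequency** $f_{beat}$ and **rotational frequency** $f_{rot}$,
  from FFT power-spectrum peaks of $\theta_f$ and $\theta_b$;
* cohort summaries: direction counts, box statistics of frequencies over
  the top-$k$ fastest CCW rotators, and percent reductions between a live
  and a demembranated (detergent-extracted, ATP-reactivated) condition.

## Coordinate convention

Image files put the origin top-left with y increasing downward. The reader
negates y once at import, so every internal angle follows the mathematical
convention and *on-screen counterclockwise motion gives a positive
cumulative slope*. The writer negates back, making
`read_dlc_csv(write_dlc_csv(x))` the identity; numbers are formatted with
the shortest decimal string that parses back to the identical double, so
the round trip is bitwise. One caveat is deliberate: whether the
microscope's optical train inserts a mirror between specimen and camera is
a property of the instrument, not the file. The convention encoded here is
"CCW on screen = positive"; mapping that to handedness above the coverslip
is the experimenter's responsibility.

## Likelihood masking

Frames are masked, never deleted: each angle's validity mask requires a
minimum likelihood (default 0.95, the conventional pose-confidence cutoff)
for **exactly the landmarks that angle consumes** — base and posterior for
the body angle; all three for the flagellar angle, which uses the body-axis
vector as its reference. An angle is unreliable precisely when one of its
own inputs is; filtering on other landmarks would discard good data or keep
bad. Zero-length landmark vectors (below `degenerate_eps`, default
$10^{-9}$ px) mark a frame invalid rather than raising an error, since a
tracker glitch should cost one frame, not the cell.

## Unwrapping and the slope fit

Wrapped angles live in $(-\pi, \pi]$, with the boundary mapping to $+\pi$.
Unwrapping accumulates `wrap_to_pi` increments over valid samples only,
starting at zero. This assumes less than half a turn between consecutive
valid samples — at 200 fps and a few Hz of rotation the margin is roughly
twenty-fold. Valid samples separated by more than `max_gap_frames`
(default 5) contribute a **zero** increment: rotation is never extrapolated
across a tracking gap. The bias is conservative (long gaps can only shrink
$|\Theta|$) and quantifiable from the gap census.

The angular velocity is the ordinary-least-squares slope of $\Theta$
against time, computed in closed form as
$\widehat\omega = \mathrm{cov}(t, \Theta)/\mathrm{var}(t)$ over valid
samples. Direction is the sign of $\widehat\omega$ outside a dead band
$\pm\omega_{min}$ (default 0.05 rad/s): a noise-only track should be
*indeterminate*, not a coin flip. Set `omega_min = 0` to force a CW/CCW
call on every cell, as a study that classifies every video would. Tracks
with fewer than `min_valid_fraction` (default 0.5) valid frames are also
indeterminate regardless of slope. Slope-based calls can be corrected by a
visual-inspection override table; overrides replace the label, flag the
cell, and leave $\widehat\omega$ untouched so the correction is auditable.

## Spectral estimation

Two representations are used, because the two signals have different
structure:

* the flagellar angle oscillates about a mean, so the **mean-removed real
  signal** has a clean line at $f_{beat}$; the one-sided power spectrum is
  scaled so total power equals the signal's variance (Parseval);
* the body angle of a rotating cell is a ramp; wrapped, it is a sawtooth
  whose harmonics smear the spectrum. The **unit-complex signal**
  $e^{i\theta_b(t)}$ of a uniform rotation is a pure complex exponential,
  so its magnitude spectrum (positive- and negative-frequency magnitudes
  summed per $|f|$ bin) peaks exactly at $|f_{rot}|$ with no windowing.

No window is applied by default — on long records the rectangular window
gives maximal peak sharpness — with Hann available as a switch for
leakage-limited spectra. Gaps are handled by analyzing the **longest
contiguous valid run** rather than interpolating: fabricated samples would
bias the very frequencies being measured, and minute-long records leave
ample contiguous data at realistic dropout rates.

Manual peak reading is replaced by an automated rule: local maxima inside a
band prior (beat 10–100 Hz, rotation 0.2–20 Hz — the observed median
frequencies sit comfortably inside both) qualify if their topological
prominence reaches `min_prominence_fraction` (default 0.1) of the
spectrum's *reference power*. The reference is the maximum spectral
component anywhere, **including the DC magnitude measured before the DC bin
is zeroed**. This detail carries the noise rejection: a non-rotating cell's
unit-complex signal is a stationary phasor whose entire energy is the DC
component (a constant's DFT is exactly a delta at zero), so in-band noise
bins — whose prominence is always comparable to the largest of them — can
never reach a tenth of it, and the cell is reported as "no estimate" rather
than given a fabricated frequency. Referencing the in-band maximum instead
would make the rule self-satisfying on pure noise. When two or more
qualifying peaks lie within 20% power of the winner the estimate is flagged
`ambiguous`, marking spectra where a manual reading could have differed.

`pick_peak` reports the winning **bin** frequency, so it can be checked
against an exhaustive in-band argmax. The estimator wrappers refine that
bin by the two-bin amplitude ratio
$\delta = a_{k+1}/(a_k + a_{k+1})$ (sign flipped when the left neighbour is
larger), with $a$ the amplitude ($\sqrt{\text{power}}$ for power spectra,
the magnitude itself for unit-complex spectra). For a single spectral line
under a rectangular window this recovers the sub-bin offset exactly in the
small-angle limit. It matters on dropout-shortened segments: at a 5%
per-frame dropout rate the longest run of a minute-long record is a few
hundred frames, the bin width is of order 1 Hz, and a 1.7 Hz rotation
estimated to the nearest bin would carry up to 40% quantization error;
interpolation reduces the median error to the order of $10^{-2}$ Hz.

## Cohort summaries

Direction summaries report CCW/CW/indeterminate counts and the clockwise
percentage among directed cells, rounded to one decimal. Frequency
summaries follow the convention of characterizing the top-$k$ (default 10)
fastest CCW rotators per condition, with ties at the cut broken by cell id
so the subset is deterministic; `all_cells = TRUE` lifts the restriction
for exploratory use. Box statistics use linear-interpolation quantiles
(R type 7 — the common default; no single rule is canonical, so the choice
is documented for reproducibility) and whiskers at the extreme data values
within 1.5 IQR of the quartiles. Percent reductions between conditions are
recomputed from the medians reported in the same summary, so the output is
internally consistent by construction.

## The synthetic generator

`simulate_track` emulates the statistical structure the analysis assumes:

$$\Theta_b(t) = \Theta_0 + 2\pi f_{rot} t + w\sin(2\pi f_{beat} t), \qquad
\theta_f(t) = \mu + A\sin(2\pi f_{beat} t)$$

with the base fixed at `center` (adsorbed cells rotate with little
translation), posterior at distance `body_len` behind it, and tip at
`flag_len` along the body axis rotated by $\theta_f$ — so the kinematics
stage recovers $\theta_f$ and $\Theta_b$ *exactly* on noise-free output.
Defaults: 200 fps, 12,607 frames (about a minute), body 40 px and flagellum
45 px (a ~10 µm cell at 4.14 px/µm), beat amplitude 0.6 rad, body-angle
wobble 0.05 rad at the beat frequency (so rotation spectra contain a
realistic beat satellite and peak picking is actually exercised), 1 px
Gaussian localization noise, 5% likelihood dropout. Dropout frames get all
likelihoods below the 0.95 threshold and a large tip displacement (uniform
in a disc of radius five flagellar lengths), mirroring the tip-specific
failure mode that motivates the likelihood filter. Draws happen in a fixed
order under a locally seeded RNG: identical seeds give bitwise-identical
tracks and exported CSVs, and the caller's RNG state is untouched.

`simulate_cohort` draws per-cell frequencies log-normally around the
condition presets (live: beat 67.1 Hz, rotation 4.3 Hz, CW probability
2/46; demembranated: 46.5 Hz, 1.7 Hz, 10/56) with relative s.d. `jitter`
(default 0.15). Log-normal jitter has positive support and preserves the
median — the summary statistic the cohort comparison uses. Beat draws at or
above Nyquist are redrawn (well under 1% of draws at defaults; the median
shift is negligible). Per-cell seeds are `base_seed + index`.

What the generator does **not** emulate — and therefore what passing tests
do not certify about real data: flagellar waveform shape (only the
base–tip chord angle is modeled, not curvature along the flagellum), cell
translation and hydrodynamic wall effects, autocorrelated tracker errors
(DeepLabCut failures cluster in time; dropout here is i.i.d.),
likelihood-versus-error correlation beyond the dropout dichotomy,
non-stationary beating (fatigue, ATP depletion in reactivated models), and
any optical-parity question. Parameter-recovery results certify the
pipeline's arithmetic under its own model assumptions, not the biology.

## Problem sizes and numerical choices

The bundled analysis scripts and the validation suite use cohorts of 20
cells per condition at full record length, a 100-cell-per-preset recovery
study under noise (1 px, 5% dropout, 15% jitter), and 10,000-draw
parameter-only checks of the mixing fractions and medians — sizes at which
binomial and median sampling error are small enough to be informative while
a complete run stays in the tens of seconds. Other conventions collected
in one place: angles wrap to $(-\pi, \pi]$ with the boundary at $+\pi$;
spectra need at least 16 samples; unwrapping and slope fits need at least
2 valid samples; the percent-reduction reference must be positive; spectral
ties resolve to the lowest frequency and top-$k$ ties to the smaller cell
id; all tabular output is plain CSV/JSON.

## Known limitations

Direction is a 2-D call on the camera plane; out-of-plane wobble appears
as amplitude modulation and is not modeled. The longest-run gap policy
discards data when dropout is heavy and shortens the spectral record (the
sub-bin interpolation compensates for resolution, not for SNR). The
prominence rule can still return a spurious peak for noise spectra whose
dominant component happens to lie in-band with few bins; per-cell
`ambiguous` and no-estimate flags are surfaced precisely so such cells can
be audited the way the original visual inspection audited direction calls.
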