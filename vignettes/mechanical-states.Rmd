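---
title: "Inferring mechanical states of intestinal muscle from diameter and pressure maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mechanical states of intestinal muscle from diameter and pressure maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(motimech)
```

## The problem

Isolated segments of colon propel fluid content through coordinated activity
of the circular muscle: rhythmic, non-propulsive myogenic "ripples" driven by
pacemaker cells, and distension-evoked neurogenic peristalsis in which an
anterogradely propagating contraction is preceded, further anally, by active
relaxation (descending inhibition). Neither a diameter recording nor a
pressure recording alone can say whether the muscle at a given place and time
is actively contracting, actively relaxing, or being passively pushed around
by content. The joint trajectory of the two signals can.

motimech implements that joint analysis. Its inputs are spatiotemporal maps:
a diameter map (DMap) extracted from video of the preparation, a pressure map
(PMap) from a multi-sensor manometry catheter, and optionally an admittance
map (IMap) from an impedance catheter, which stands in for internal diameter
when video is impossible (e.g. in vivo). Maps are co-registered into a
composite map and analysed three ways:

1. **Orbit analysis.** At a chosen location, the paired (diameter, pressure)
   samples trace an orbit. Its near-linear phases are "steady states" of the
   muscle and are classified by the signs of their pressure and diameter
   changes.
2. **State decoding.** Every sample of the composite map is classified into
   one of twelve mechanical states with Gaussian derivative emissions and a
   hidden Markov model, then clustered into maps of active excitation and
   active inhibition.
3. **Hill mechanics.** During contractions that start isotonic and end
   isometric, pooled (pressure, shortening-velocity) pairs are fitted with
   Hill's rectangular hyperbola $(P+a)(V+b) = C$.

## The twelve-state alphabet

A phase is described by the zero-banded sign of its pressure change, the sign
of its diameter change, and — where diameter is steady — whether the lumen is
occluded (collapsed onto the catheter) or distended:

```{r}
mechanical_states()
```

Isometric, auxotonic and isotonic contractions reflect muscle excitation;
auxotonic and isotonic relaxations reflect active inhibition (isotonic
relaxation is interpreted as active, inhibitory-neuron-driven dilation).
Same-signed simultaneous changes are passive (content-driven), and a steady
sample is quiescent, occluded or distended. The sign lookup is total over its
18 inputs and its image has exactly 12 states — `state_from_signs()` is the
single source of truth used by the orbit classifier, the HMM decoder and the
synthetic generator's ground truth.

`cluster_states()` simplifies a 12-state map into three classes: the three
contraction states (excited muscle), the two active relaxations (inhibited
muscle), and everything else. Isometric relaxation is deliberately *not*
clustered as active inhibition: it is excitation wearing off in an occluded
segment.

## Map handling

Maps are stored on strictly increasing position (cm) and time (s) axes with
units fixed to mm, mmHg, cm and s; conversions (1 mmHg = 0.133322 kPa) happen
only at reporting boundaries. The exchange format is self-describing
tab-separated text with `nan` for missing cells, chosen over binary formats
for diffability and language neutrality.

Three preprocessing steps matter:

* **Resampling** (`resample()`) is bilinear, exact on linear fields and
  bounded by the source extremes; composite construction resamples to the
  coarser of the two grids, since nothing is gained by upsampling the worse
  instrument. Any stencil touching a missing cell yields a missing cell.
* **Baseline drift removal** (`remove_baseline_drift()`) subtracts a
  per-position running *median* (default window 120 s). The median is
  preferred to a mean because contraction transients are large, one-sided and
  short relative to the window; a 2-s pressure pulse passes through
  untouched while slow sensor drift is removed.
* **Clock alignment** (`align()`) fits an affine mapping
  $t_B = \alpha t_A + \beta$ by least squares over order-paired sync events
  (LED flashes visible in both recordings). An affine rather than pure-offset
  model absorbs clock-rate drift; a fitted $|\alpha - 1| > 0.05$ is flagged
  as a clock-rate anomaly. On noiseless affine event pairs the recovery is
  exact to rounding.

## Orbit segmentation and classification

Orbits are sampled pointwise along any space–time path by bilinear
interpolation. Segmentation into near-linear phases uses recursive
endpoint-split (greatest-deviation bisection) polyline simplification,
performed in per-axis-normalised orbit space — each axis divided by its
robust 5th–95th percentile range so that a millimetre of diameter and a mmHg
of pressure are commensurable. The default tolerance of 0.05 normalised units
reproduces by construction what an experienced eye calls "a straight piece of
orbit"; segments shorter than `min_len` (default 5 samples) are absorbed into
neighbours, and adjacent segments with identical sign classification merge.

Classification applies zero bands `eps_P`, `eps_D` to the phase totals.
Recordings do not define "no change" exactly, so the default bands are 3
robust (MAD-based) standard deviations of the sample-to-sample changes
(`default_zero_bands()`): a phase must move at least 3 noise-sigmas to count
as moving. A phase classified (0, 0) takes its lumen flag from its own mean
diameter, never from its neighbours.

## The emission model and the HMM decoder

The decoder works on the smoothed temporal derivatives of diameter and
pressure (Gaussian kernel, `sigma_t` default 0.5 s, then central
differences). Emissions are Gaussian: a state with pressure sign $s_P$ has
derivative mean $s_P\,\kappa\,\hat\sigma_{dP}$, where $\hat\sigma_{dP}$ is
the pooled robust scale (1.4826 × MAD, variance floor $10^{-6}$) of the
pressure-derivative field, and likewise for diameter. The offset $\kappa = 2$
means a sample must sit about two pooled SDs out on a Gaussian tail before a
moving state is favoured — the same "which tail does the sample fall on"
logic as the orbit zero bands, made probabilistic.

The occlusion boundary $\theta$ is estimated from the pooled diameters with a
two-component Gaussian mixture (EM, 100 iterations, components initialised by
hard assignment to the 10th/90th percentiles); $\theta$ is the
equal-posterior point between the component means. When the components
overlap (means closer than one pooled SD) the boundary falls back to the data
midrange, and for a degenerate constant field the decoder assigns the lumen
by a configurable default flag. Occlusion enters the emission as *soft*
evidence, $\log\sigma(\mp(D-\theta)/s)$ with softness $s$ equal to the
smaller component SD, only for the six steady-diameter states; a hard
threshold would flicker between occluded and distended labels whenever
$D \approx \theta$.

Decoding is Viterbi over the 12 states, run independently at each position
(the method defines no spatial coupling, and observed transitions occur
directly between many state pairs, so the transition matrix is uniform off
the diagonal with self-probability `p_stay` = 0.95 and no graph
restrictions). As `p_stay` falls to uniform the decoder reduces to per-sample
maximum-emission classification; raising it buys temporal persistence —
a single-sample derivative blip is absorbed at `p_stay` = 0.99 and labelled
at 0.5. Transition probabilities are fixed, not learned: decoding, not
Baum–Welch, is the task.

## Hill force–velocity fitting

Shortening velocity is $V = -\,dD/dt$ (positive while the muscle shortens),
estimated with the same smoothed central differences. Pairs are pooled over
user-chosen windows spanning isotonic-to-isometric contractions; lengthening
samples are excluded by default. The number of pooled windows is
configurable — reports of this analysis in the literature used of the order
of 8–10 episodes.

Expanding $(P+a)(V+b)=C$ gives the exact linearisation
$PV = (C - ab) - aV - bP$, solved by OLS. On noiseless hyperbola points this
is exact to rounding and serves as the independent oracle in the tests. On
noisy data, however, the velocity noise sits on both sides of the regression
(in $PV$ and in the regressor $V$), and the resulting errors-in-variables
bias can push the linear solution arbitrarily far off — even past the
hyperbola pole $P = -a$, where a Levenberg–Marquardt refinement started there
cannot recover. `fit_hill()` therefore also builds profile seed candidates
(for each $a$ on a log-spaced grid relative to the pressure span, $(C, b)$
follow by OLS of $V$ on $1/(P+a)$), takes the best seed by velocity-space
RMS, and runs a single Levenberg–Marquardt pass from it, kept only if it does
not worsen the RMS. With this, 100 replicates of 200 points carrying velocity
noise of 5% of the velocity range recover $P_{max}$ with relative bias below
2%, while noiseless recovery remains exact ($\le 10^{-6}$ relative).

The pressure unit of the constants is the unit of the input map (mmHg
internally); printed reports echo kPa as well, since published values of the
small offset constant $a$ appear in hectopascal-scale units while pressures
are quoted in mmHg — the fit makes no attempt to guess which was intended and
carries both.

## The impedance bridge

Inverse impedance (admittance) is proportional to internal cross-sectional
area while the conductance of the content is constant; with a circular lumen,
$D_{int} = 2\sqrt{kG/\pi}$. The proportionality constant can be supplied from
a calibration or estimated by least squares against a CSA proxy
(`estimate_admittance_scale()`). Agreement between impedance-derived and
video-derived diameter is quantified by pooled Pearson correlation over all
paired samples at the |r|-maximising integer lag within ±2 s
(`correlate_maps()`); the lag search absorbs residual clock misalignment, and
pooling (rather than per-channel averaging) is used and reported as such.

## The synthetic generator

`generate_dataset()` is a rule-based kinematic generator, not a fluid
solver: its purpose is ground-truth labels that are unambiguous by
construction. The diameter and pressure fields are prescribed analytically;
labels come from applying `state_from_signs()` to the noiseless derivative
signs with exact zero bands, so generator and classifier are consistent by
construction.

The emulated preparation is a 20 cm closed segment sampled at 1 cm and
0.25 s (the spatial pitch of a high-resolution manometry catheter and the
frame interval of 4 fps video) for 600 s. An oral region (5 cm) lies
occluded on the 3.2 mm catheter and carries 0.1 Hz isometric pressure
ripples (amplitude 6 mmHg) — myogenic activity. From 6 cm, a peristaltic
wave is launched every 90 s travelling anally at 0.5 cm/s as a rigidly
translating profile: a 2 cm leading dilation (resting 9 mm up to the
distended 12 mm at constant pressure: isotonic relaxation), a 2 cm
contraction ramp (diameter falls to occlusion while pressure rises:
auxotonic contraction), a 1 cm occluded plateau (pressure peaks at +25 mmHg
then decays: isometric contraction then relaxation), and a 3 cm recovery
(back to resting diameter at baseline pressure: isotonic relaxation). The
last 4 cm are permanently distended; each wave arrival there raises and
releases pressure at constant diameter (passive isometric pressure
increase/decrease at the closed end). No quantitative wave speeds or ripple
frequencies have been published for this preparation; these defaults were
chosen once as plausible for isolated distal colon, give at least five full
waves per run, and are stated in every report. Ramps use cubic smoothsteps,
which keeps the travelling profile's sampled luminal volume
($\sum \mathrm{CSA}\,dx$, circular cross-section) conserved frame-to-frame
to well within 2% during pure propulsion. Measurement noise is additive
Gaussian on diameter (SD 0.05 mm) and pressure (SD 0.3 mmHg) and
multiplicative lognormal (SD 2%) on admittance.

What the generator does *not* emulate: antiperistalsis, wave-speed and
interval variability, longitudinal muscle movement, wall-thickness dynamics,
content conductivity changes, optical artefacts beyond band silhouettes.
Passing the pipeline tests on this data therefore demonstrates internal
consistency of the method — correct state recovery when the modelled
assumptions hold — not performance on real recordings.

```{r, fig.height = 4}
ds <- generate_dataset(synth_params(duration = 300))
plot(ds$truth$states)
```

## Pipeline performance on synthetic data

With noise-free fields, Viterbi decoding recovers the ground-truth label at
more than 95% of non-transition samples (samples whose true label is constant
within ±1.5 s, the support of the derivative smoother; labels *at* phase
boundaries are ill-defined at sample resolution). At a derivative
signal-to-noise ratio of 3 — noise SDs chosen so the noiseless derivative
field's SD is three times the noise-induced derivative SD
(`derivative_snr_noise()`) — recovery stays above 80%. These two figures are
recomputed by the test suite on every run.

```{r}
par0 <- synth_params(noise = list(diameter_sd = 0, pressure_sd = 0), seed = 1)
ds0 <- generate_dataset(par0)
cm0 <- composite_map(ds0$dmap, ds0$pmap)
sm0 <- decode_states(cm0, fit_emission_model(cm0))
mean(sm0$codes == ds0$truth$states$codes)
```

## Video extraction

Diameters are read off each frame as the largest contiguous run of
below-threshold pixels per image column (the preparation is assumed straight
along one image axis; the largest-run rule rejects detached shadows and the
ruler ticks). The default threshold is an Otsu-style bimodal histogram
split, so extraction is invariant to affine intensity rescaling of
well-separated frames; a manual threshold covers uneven lighting. Columns
within 2 px of the frame border are excluded as boundary artifacts. Pixel
calibration comes from ruler marks at known spacing via the *median*
inter-mark gap. The round trip through `render_frames()` and `build_dmap()`
recovers a diameter map to within one pixel (0.1 mm at the default
calibration), which bounds the quantisation error of the whole video
pathway.

## Problem sizes and numerical choices

The test suite and the acceptance analyses run the generator at its default
600 s × 20 cm geometry (about 50,000 samples per field, within the
10⁴–10⁵-sample regime the method targets) and smaller geometries where only
geometry matters. Remaining numerical choices: derivative variance floors
(10⁻⁶) keep noiseless fields from producing zero emission widths; the
occlusion softness is floored at 10⁻³ mm; `log(sigmoid)` is evaluated in a
numerically stable branch form; segmentation tie-breaks send a short segment
into its shorter neighbour; missing observations contribute a flat emission
so the HMM bridges them by persistence.

## Known limitations

* The HMM is 1-D in time per position; no spatial coupling of labels.
* Orbit paths are sampled pointwise; no averaging across an oblique line's
  width.
* The video module assumes a straight preparation; curved-midline geometry
  is out of scope.
* Compliance/stiffness estimation is deliberately absent: those require
  quasi-static conditions that moving preparations do not provide.
* Published single-number results for real rabbit recordings (e.g. an
  impedance-vs-diameter correlation of 0.85) cannot be reproduced here
  because the raw recordings are not deposited; the package's validation is
  property-based on synthetic data instead.
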