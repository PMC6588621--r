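---
title: "Quantifying prawn camouflage to fish vision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prawn camouflage to fish vision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prawnvision)
```

## The question and the modelling chain

Chameleon prawns (*Hippolyte varians*) occur as green and red colour types on
two intertidal seaweeds, green sea lettuce and red dulse. `prawnvision`
quantifies how well each colour type is concealed from predatory fish, and
how concealment changes when prawns slowly change colour or behaviourally
choose a substrate. "Concealment" is always defined through a receiver: a
reflectance spectrum is converted to the quantum catches of a fish's cone
classes, and the separability of two stimuli is expressed in units of just
noticeable differences (JNDs) under the receptor-noise-limited (RNL) model
of colour discrimination.

The chain is:

1. **Calibration** — raw camera images are linearised with grey-standard
   response curves and equalised against two in-frame reflectance standards,
   yielding reflectance-scaled multispectral stacks.
2. **Camera to cone catches** — ROI means in camera colour space are mapped
   to predator cone-catch space with a fitted polynomial transform (or, for
   spectra, catches are computed by direct integration).
3. **Discrimination and hue** — pairs of cone-catch records are compared
   with the RNL model; hue ratios summarise position on the green-red axis.
4. **Statistics** — group means with standard errors, and an exact binomial
   test for the substrate-choice experiment.

Every stage can be fed by the synthetic-data generator, which emits ground
truth alongside its data, so the whole chain is testable end to end without
the original photographs.

## Visual systems

Two fish models ship with the package:

* **Pollack** (dichromat): single cones at 436 nm (SWS) and double cones at
  521 nm; cone ratio 0.70:1 (shortest to longest).
* **Two-spotted goby** (trichromat): single cones at 456 nm (SWS), double
  cones at 531 nm (MWS) and 553 nm (LWS); cone ratio 0.72:1:0.60.

Both use a 50% ocular-media transmission cutoff at 410 nm and a
noise-to-signal ratio $\nu = 0.05$ for the most abundant cone class. Each
double-cone member is treated as an independent channel. Weber fractions
follow $\omega_i = \nu / \sqrt{\eta_i}$ with abundances $\eta_i$ normalised
so the most abundant class has $\eta = 1$:

```{r}
weber_fractions(pollack())
weber_fractions(goby())
```

Only the pigment peak wavelengths are available for these species, so
channel sensitivities use the standard A1 visual-pigment template
(Govardovskii-type alpha plus beta band) parameterised by the peak; this is
the conventional choice in RNL modelling when full microspectrophotometric
curves are not published. The ocular media are modelled as a logistic curve
with its 50% point at the cutoff and a 10-90% rise over ~30 nm; only the
50% point is constrained by data, and the JND results are insensitive to
the exact slope because both modelled species share the same curve. A note
on channel naming: the pollack 521 nm double-cone channel is the *long*
channel of that dichromat and is stored as `LWS` (the hue ratio divides by
it), although it is sometimes labelled MWS; both labels are accepted in the
shipped YAML configs.

## Cone catches and their normalisation

For receptor $i$ with sensitivity $S_i(\lambda)$, ocular transmission
$T(\lambda)$, illuminant $I(\lambda)$ and reflectance $R(\lambda)$:

$$q_i = \frac{\int R\, I\, T\, S_i \, d\lambda}{\int I\, T\, S_i \,
d\lambda}$$

The denominator (von Kries normalisation to the illuminant's own catch)
makes a flat reflectance $c$ map to $q_i = c$ in every channel under *any*
positive illuminant, and makes all downstream statistics independent of the
illuminant's absolute scale — only reflectance contrast matters. This is
required for grey standards to behave as anchors and is the convention the
flat-spectrum identity tests enforce. Illumination defaults to the CIE D65
daylight table (shipped at 10 nm, interpolated). All integrals use the
trapezoid rule on a 1 nm grid from 400-700 nm; the grid covers the
photography pass band (420-680 nm), every receptor peak, and the 410 nm
cutoff, with padding for stable integration. The integration step is an
assumption (no finer structure exists in any shipped spectrum); halving it
changes catches at the 5th decimal.

## Receptor-noise discrimination

Receptor contrasts are log catch ratios, $\Delta f_i = \ln(q_i^a / q_i^b)$
(the standard log-linear receptor code; the linear small-contrast form
differs only at higher contrasts and is not offered). For Weber fractions
$\omega_i$:

$$\Delta S_{di} = \frac{|\Delta f_1 - \Delta f_2|}
{\sqrt{\omega_1^2 + \omega_2^2}}, \qquad
\Delta S_{tri} = \sqrt{\frac{\omega_1^2 (\Delta f_2 - \Delta f_3)^2 +
\omega_2^2 (\Delta f_1 - \Delta f_3)^2 + \omega_3^2 (\Delta f_1 - \Delta
f_2)^2}{(\omega_1\omega_2)^2 + (\omega_1\omega_3)^2 +
(\omega_2\omega_3)^2}}$$

$\Delta S$ is in JND units; values below 1 are predicted indiscriminable.
The closed forms are verified in the test suite against an independently
derived quadratic form (the noise-weighted Mahalanobis distance restricted
to the achromatic-invariant subspace), which agrees to $10^{-10}$ on random
inputs. $\Delta S$ is symmetric, invariant to common scaling of both
records, zero exactly when all $\Delta f_i$ are equal, and linear along a
contrast ray.

```{r}
p <- pollack()
jnd(cone_catch_record("a", c(SWS = 0.50, LWS = 0.50)),
    cone_catch_record("b", c(SWS = 0.55, LWS = 0.45)), p)
```

## Calibration

`fit_linearisation()` fits a monotone pixel-to-reflectance response from
eight grey standards (2-99% reflectance). Because the true response family
of a given camera is unknown, three candidates are compared by leave-one-out
cross-validation in reflectance units — a power law, a log-log quadratic
(admitted only when monotone on the sample hull), and a monotone Hyman
spline — and the lowest-CV-error form is used. For gamma-encoded synthetic
data the power law wins and inverts the encoding essentially exactly.
`equalise()` then applies, per channel, the affine map sending the dark and
light standard ROI means to their nominal reflectances; any affine
relighting of an image equalises to identical output, and equalising an
equalised image with its own standards is the identity. ROI extraction
reports the pixel count and excludes pixels that were saturated (>= 99% of
bit depth) in the raw exposure, with the excluded count logged for QC.

## Camera-to-cone mapping

The camera's band sensitivities are shipped as plausible Gaussian bands
(peaks 460/530/600 nm, sd 35 nm) standing in for a converted DSLR's
blue/green/red responses; measured curves can be supplied as CSV. The
mapping regresses each true cone catch (by direct integration) on
polynomial terms — total degree 2 with cross terms by default, degree is a
knob — of the camera band catches over a seeded 200-spectrum synthetic
library (Gaussian peaks, long-pass edges, flat greys and mixtures). The
reported diagnostic is always held-out performance, not in-sample fit:
with the defaults, held-out $R^2$ exceeds 0.99 per channel and pooled RMSE
is below 0.01 catch units. Predicted catches are floored at $10^{-4}$
(with a warning) so log-ratios stay defined. Accuracy is weakest for the
pollack SWS channel, whose 436 nm peak sits at the edge of the camera's
blue band — the same channel that is hardest for physical camera systems.

## The synthetic generator: what it emulates, and what it does not

Reflectance families: green tissue (prawn and sea lettuce) is a Gaussian
reflectance peak near 550 nm on a low baseline; red tissue (prawn and
dulse) is a sigmoid long-pass edge near 590 nm on a *higher* short-wave
baseline (0.11 vs 0.04). The elevated red baseline is deliberate: red algae
reflect a secondary short-wave component, and it is what gives red types a
larger short-wave cone catch than green types, so that during colour change
the two types *cross over* in short-wave reflectance and the main PCA axis
of catch variation is opponent (SWS against MWS+LWS) — the pattern that
motivates the trichromat hue ratio SWS/(MWS+LWS). With an equal baseline
neither feature emerges, because the broad 456 nm pigment template sees the
green 550 nm peak through its long-wavelength tail.

Between-individual variation is parameter jitter (peak/edge position sd
8 nm, amplitude sd 0.05-0.06, baseline sd 0.006-0.008), set once so that
matched prawn-substrate contrasts sit near the 1-JND discrimination
threshold, as reported for the real field data; per-wavelength measurement
noise is 0.005. Matched pairs differ only by this individual variation
(green prawn and sea lettuce share one family, red prawn and dulse the
other) — camouflage *is* the generator's construction, and the field
analysis measures how far individual variation breaks it.

Colour change mixes each individual's start and target spectra with weight
$m(d) = m_{max}(1 - e^{-kd})$, defaults $k = 0.15\,/\mathrm{day}$ and
$m_{max} = 0.8$ (change is strong but incomplete at 30 days). The
exponential approach front-loads the change into the first 10 days, as
observed. An individual of size $s$ (mm, drawn N(8, 1.5)) has rate
$k e^{-\beta(s - 8)}$ with $\beta = 0.1$/mm, so larger individuals change
more slowly. Dropout hazards per 5-day interval (0, 0, 0.05, 0.05, 0.2,
0.2) emulate the experiment's survival profile: everyone alive through day
10, ~90% to day 20, ~58% to day 30; analyses use survivors only.

The choice-trial generator draws a decision with probability 79/180 per
trial and, given a decision, a colour-matching choice with probability 0.8
(90 trials per type).

The generator does **not** emulate: spatial pattern and texture (no
predator acuity modelling), pigment physiology (mixing is in reflectance
space, the simplest model consistent with the observed phenomenology; an
asymmetry between red-to-green and green-to-red change is therefore absent),
UV reflectance (both modelled predators lack UV channels), within-body
colour heterogeneity, or water-column light attenuation. Passing tests
therefore demonstrate the correctness and sensitivity of the measurement
chain under controlled conditions — not that real prawns behave like the
generator.

## Analysis designs

* **Field camouflage** (`run_field_camouflage`): 64 prawns per colour type;
  each prawn is paired with one randomly drawn image from each 64-image
  seaweed pool (without replacement when the pool suffices, seeded), giving
  64 JNDs per comparison group; groups are summarised as mean, SE
  ($sd/\sqrt{n}$), n.
* **Colour change** (`run_colour_change`): 25 individuals per type, days
  0-30 in 5-day steps; per day, each survivor is re-paired at random with
  one of 26 substrate images. Hue uses SWS/LWS for the pollack and
  SWS/(MWS+LWS) for the goby; "standardised cone catch data" for the PCA is
  read as per-channel z-scoring before a covariance PCA, with the sign
  convention that the short-wave loading is non-negative (the source is
  silent on both).
* **Choice trials** (`run_choice_analysis`): per-type matched choices vs
  0.5 by the exact binomial test; the two-sided p sums all outcome
  probabilities not exceeding the observed outcome's probability (the
  small-probability-mass convention, stated explicitly because two-sided
  exact definitions differ between tools). No-choice trials are excluded
  from the denominators and reported as an overall decision rate.

Because the saturating kinetics leave late-day expected JND steps (~0.05
JND) far below the group-mean sampling error under per-day re-pairing and
dropout (~0.3-0.5 JND), trajectory claims are assessed as *trends* — rank
correlation with day, the day-30/day-0 ratio, and front-loading of the
drop into days 0-10 — rather than as strict step-wise orderings, which no
realisation of these study conditions (nor the original experiment, whose
late-day contrasts were non-significant) would satisfy.

## Reproducibility and problem sizes

Every random stage takes an explicit seed and derives per-stage substreams;
re-running a configured analysis is bit-identical, and output tables carry
the package version and a configuration hash. The analysis scripts use the
study-design sizes throughout (64 + 64 per type for the field survey, 25
per type over 7 days with 26-image pools, 180 choice trials); the
acceptance script additionally validates the trichromat formula on 1,000
random record pairs and the mapping on a 200/100 train/hold-out split.
These sizes were chosen to match the emulated study design; a full run of
scripts and test suite completes in well under a minute of compute.

## Known limitations

* The shipped camera sensitivities are plausible stand-ins, not measured
  curves; mapping accuracy against a physical camera is untested.
* Chromatic JNDs only; achromatic (luminance) contrast and pattern metrics
  are out of scope.
* The RNL model's log-linear code is an assumption at high contrasts
  (10+ JND values are best read ordinally).
* Mixed-model inference on trajectories is delegated to lme4/emmeans in an
  optional script and is not part of the tested core.
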