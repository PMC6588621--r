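# prawnvision

Camouflage, to the eye of the predator. `prawnvision` quantifies how well
green and red chameleon prawns (*Hippolyte varians*) match their seaweed
substrates — green sea lettuce and red dulse — as seen by two predatory
fish: the dichromatic pollack and the trichromatic two-spotted goby. It is
aimed at sensory/behavioural ecologists who want the full measurement chain
from calibrated multispectral photographs to receiver-referenced colour
statistics, with a synthetic-data generator that makes every stage testable
against known ground truth.

## What it computes

**Cone catches.** A reflectance spectrum R is converted to the quantum
catch of receptor class *i* under illuminant I (default CIE D65) and ocular
media T, von Kries-normalised to the illuminant:

    q_i = ∫ R I T S_i dλ / ∫ I T S_i dλ

Receptor sensitivities S_i come from the A1 pigment template at the
published peaks (pollack 436/521 nm; goby 456/531/553 nm) with a 410 nm
50%-transmission ocular cutoff. Camera images reach the same space through
standards-based linearisation + equalisation and a fitted degree-2
polynomial mapping from camera bands to cone catches.

**Discrimination (JND).** Pairs of catch records are compared with the
receptor-noise-limited model: receptor contrasts Δf_i = ln(q_i^a / q_i^b),
Weber fractions ω_i = ν/√η_i (ν = 0.05, cone ratios 0.70:1 and
0.72:1:0.60), and

    dichromat:  ΔS = |Δf₁ − Δf₂| / √(ω₁² + ω₂²)
    trichromat: ΔS = √( [ω₁²(Δf₂−Δf₃)² + ω₂²(Δf₁−Δf₃)² + ω₃²(Δf₁−Δf₂)²]
                        / [(ω₁ω₂)² + (ω₁ω₃)² + (ω₂ω₃)²] )

ΔS < 1 JND predicts the pair is indiscriminable to that receiver.

**Colour change and choice.** Hue ratios (SWS/LWS; SWS/(MWS+LWS)) and
survivor-aware JND trajectories summarise a 30-day substrate-swap
experiment; Y-maze substrate choices are tested per colour type with an
exact binomial test (two-sided, small-probability-mass convention).

## Worked example

```r
library(prawnvision)

p <- pollack()
weber_fractions(p)
#>        SWS        LWS
#> 0.05976143 0.05000000

jnd(cone_catch_record("a", c(SWS = 0.50, LWS = 0.50)),
    cone_catch_record("b", c(SWS = 0.55, LWS = 0.45)), p)
#> <jnd a vs b (pollack): dS = 2.575 JND, discriminable>
```

A 10% shift of catch from one channel to the other is ~2.6 JND — well
above threshold for the pollack. Running the synthetic field survey (64
prawns per type, 64-image substrate pools):

```r
fc <- run_field_camouflage(run_config(seed = 11))
fc$summary
#>   system  colour_type substrate    mean    se  n
#>   goby    green       dulse        6.96 0.256 64
#>   goby    green       sea_lettuce  2.33 0.207 64
#>   goby    red         dulse        1.62 0.153 64
#>   goby    red         sea_lettuce  7.11 0.260 64
#>   pollack green       dulse       10.86 0.252 64
#>   pollack green       sea_lettuce  1.90 0.170 64
#>   pollack red         dulse        1.18 0.114 64
#>   pollack red         sea_lettuce 11.11 0.256 64
```

Each colour type sits near the 1-JND discrimination threshold on its own
substrate and far above it on the other — matched camouflage, quantified
through the predator's eye. The choice analysis tells the behavioural half
of the story:

```r
run_choice_analysis(run_config(seed = 3))$per_type
#>   colour_type n_choices matched proportion two_sided_p
#>   green              46      36      0.783    0.000160
#>   red                42      32      0.762    0.000940
```

## Analysis workflow

The `analysis/` scripts run the three studies end to end and write tidy
tables (and figures, if `ggplot2` is present) under `results/`:

1. `01_simulate_data.R` — generate all synthetic inputs with ground truth
2. `02_field_camouflage.R` — field JND comparison (prawn type x seaweed x
   visual system)
3. `03_colour_change.R` — 30-day hue and JND trajectories
4. `04_behavioural_choice.R` — substrate-choice binomial tests
5. `05_mixed_models.R` — optional LMM + Tukey layer (delegates to
   lme4/emmeans)

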