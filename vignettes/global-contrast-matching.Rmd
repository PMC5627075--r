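---
title: "Modelling global contrast perception with Battenberg matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global contrast perception with Battenberg matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(battenberg)
```

## The question

An image has many local contrasts but observers readily judge its overall —
*global* — contrast. Which pooling rule turns a field of local contrasts into
that single judged quantity? Candidate summary statistics range from the
trivial (the maximum local contrast, equivalent here to Michelson contrast)
through the aggregate (sum, average, energy, RMS) to transducer models from
the contrast-discrimination literature. This package implements the whole
candidate set over a common stimulus and task so the candidates can be told
apart behaviourally, with no free parameters.

## Stimuli

Battenberg stimuli disentangle contrast level from spatial spread. The
default geometry is a 20 × 20 grid of 20-px elements at 48 px/deg: each
element holds one cycle of a horizontal sine-wave carrier (2.4 c/deg)
windowed by one positive lobe of a full-wave-rectified vertical sine wave of
half the carrier frequency, so element borders sit exactly at mean luminance.
Alternate elements — or alternate *j* × *j* clusters, *j* ∈ {1, 2, 4, 8} —
form the "A" and "B" components whose Michelson contrasts are set
independently.

Two numerical choices are worth stating:

* **Carrier phase.** The carrier and envelope are sampled on integer pixel
  coordinates 0…19 within each element, placing exact zero crossings on
  element borders and exact ±1 samples inside each element. Consequently the
  spatial mean equals the nominal mean luminance to machine precision, the
  image Michelson contrast equals max(A, B) exactly, and every element's peak
  Weber contrast equals its nominal component contrast exactly — the stimulus
  audits in the test suite assert all three with tolerances of 10⁻⁶ or
  tighter rather than "approximately".
* **j = 8 tiling.** Eight does not divide twenty. `checker_mask()` errors by
  default; the generator builds the mask on the next-larger virtual grid (24
  elements), centre-crops to 20, and truncates the partial border clusters.
  This preserves the overall image size and the 2×-element alternation extent;
  it is a package decision, since no tiling rule for this case is forced by
  the geometry itself.

Presentation timing (100 ms exposures, 400 ms gaps in the original paradigm)
is deliberately absent: nothing in any implemented model depends on time.

## Models and units

Local contrast is the rectified Weber fraction in **percent**; all model
arithmetic happens on percent values, so the gain-control response to an 8%
component involves 8^2.4, not 0.08^2.4. The implemented global statistics
are max, linear sum, average, energy (sum of squares), RMS, the summed
Legge–Foley transducer Σ[C^p/(z + C^q)] (optionally with Minkowski rather
than linear area summation), and the gain-control pool Σ(C^p)/(z + Σ(C^q)).

Defaults p = 2.4, q = 2.0, z = 1. `model_params()` enforces p > q: with
p ≤ q the pooled response saturates and matching levels become
non-identifiable. The package re-runs all predictions at the alternative
suprathreshold pair (p, q) = (2.0, 1.6) as a robustness check; over the
default grid the PSEs move by well under 1 dB. Setting z = 0 moves PSEs by
at most ≈ 0.16 dB (largest for the dual match at A = 0, where z is the
largest share of the suppressive denominator) — negligible against the ≥ 4 dB
differences that separate the models, which is why z can be "safely set to
unity" at suprathreshold contrasts. Rectification precedes exponentiation
throughout; for even q this is immaterial, but it keeps non-integer exponents
real for the q = 1.6 variant.

Three granularities share one interface: *toy* (the model sees only A and B),
*element* (one entry per element), and *pixelwise* (the Weber map of the
rendered image). Element-level pooling is algebraically the toy model with z
rescaled by the element count — the test suite asserts this identity exactly —
so the three levels differ materially only once spatial filtering enters.

## Predicting matches

A matching stimulus carries one component at level m ("single", the other
blank) or both at m ("dual"). The predicted point of subjective equality
(PSE) is the m at which the model's response to the match equals its response
to the test. `predict_pse()` inverts the match response by bisection in log
contrast on [0, 200%]:

* the bracket extends past 100% physical contrast deliberately, so that
  grossly over-predicting models (the summed Legge–Foley transducer predicts
  ≈ 30% for the 4/8 test) still converge; solutions above 100% are flagged;
* convergence is |Δresponse| ≤ 10⁻⁹ of the test response within 60
  iterations;
* monotonicity of the match response in m — guaranteed analytically for
  p > q — is re-checked numerically on a 40-point log grid before each solve,
  and the solver refuses non-monotone families rather than returning an
  arbitrary root;
* match maps are linear in m at every granularity (the Weber map and the
  filter are homogeneous of degree one in contrast), so one unit-level map
  per condition serves the whole bisection; `matching_curve()` additionally
  caches those unit maps across grid points.

Degenerate inputs: a zero-response test (A = B = 0) returns PSE 0 exactly; a
test that no bracketed match can reach returns a non-converged result with
its bracket, never a silent clamp.

The paradox falls out of the algebra: for the 4%/8% single match the
gain-control PSE is 7.19% (< 8%), and for 16%/8% it is 14.20% (< 16%),
whereas max, linear sum, energy and Legge–Foley all stay at or above
max(A, B) for single matching and are monotone in A in both modes. The
default A grid {0, 0.5, 1, 2, 4, 8, 16, 32}% is an octave-spaced
reconstruction of the original eight-level 0–32% design, whose exact levels
are not recorded.

## The spatial-filtering front end

`filter_contrast_map()` implements a single oriented log-Gabor channel:
Gaussian in log frequency (1.6 octaves full width at half height) about the
2.4 c/deg carrier, Gaussian in orientation (±25° half width at half height),
zero DC, transfer peak normalised to 1 so a matched full-field grating of
contrast C returns a peak response of exactly C percent. Cosine, sine and
quadrature phase modes are provided; the three give the same matching
predictions. Those bandwidth and orientation values are conventional
V1-channel figures and are exposed as arguments, since the original filter's
exact parameters are not printed; for that reason the filtering conclusions
below are asserted as orderings at the default parameters, not as point
values tied to a particular kernel.

Convolution is circular in the frequency domain on an image padded to twice
its size with zero contrast — emulating the mid-grey surround of a framed
display and keeping wraparound away from the stimulus. A Parseval check and
a pre-rectification linearity check pin down the FFT conventions in the test
suite.

The scientific point of the filter: its footprint exceeds one element, so at
j = 1 it smears the A/B boundaries and effectively performs A + B before the
gain-control pool — the filtered gain-control predictions swing over to the
(empirically wrong) linear-sum curve. As j grows the boundaries thin out and
the filtered predictions return to the toy gain-control curve; the package
reproduces this reversal as an RMS-dB ordering over the full condition grid.

## The simulated observer

The observer closes the loop between analytic predictions and the
experimental procedure. Each trial, the model response to test and match is
perturbed by independent zero-mean Gaussian noise (a late-noise
signal-detection stage; the original procedure specifies no noise model) and
the noisier-larger stimulus is chosen. Matching levels are driven by two
interleaved 1-up-1-down staircases, each terminating after 12 reversals,
with steps of 3 dB before a staircase's first reversal and 1.5 dB after, and
starting levels ±4 dB around 10%. Step sizes and starting levels are
reconstructions (the originals are unrecorded), chosen so a repetition runs
roughly 42 trials. The default decision noise `noise_sd = 0.15` makes the
fitted psychometric spread σ_log ≈ 0.1, typical of matching data; only the
PSE, never the slope, is compared with theory.

Each repetition's trials are fitted with a two-parameter cumulative
log-Gaussian, Φ((log m − log α)/σ), by maximum likelihood (Nelder–Mead from
three spread starting values; no lapse parameters), and α is averaged over
four repetitions. Degenerate data — fewer than two distinct levels, or only
one response type — are flagged, never silently defaulted. Parameter
recovery at n = 10⁴ trials is verified to 2%, and the simulated experiment
recovers the analytic PSEs over the whole default grid to well within 0.5 dB
at low noise.

What the simulation does *not* emulate: individual observers' differences
(including the slight upward shift of dual matches at j = 4, 8 seen in
practised observers), lapses, learning, or any deliberate non-perceptual
strategy. Passing closed-loop tests therefore shows the machinery is
self-consistent, not that real observers behave this way.

## Scoring models

Model comparison uses the field's RMS error in dB,
sqrt(mean[(20·log₁₀(pred/ref))²]), over aligned condition sets
(`rms_error_db()`, `compare_models()`). The dB convention 20·log₁₀ is the
contrast-literature standard. No human PSEs ship with the package — published
values exist only as figure points, which are unreliable to digitise — so the
reference slot takes either a user-supplied table or a simulated observer's
curve. Self-consistency tests check that whichever model generated the
reference also wins the comparison.

## Problem sizes and limitations

The test suite runs stimulus-level checks at the full 20 × 20-element
geometry and most filter checks at a reduced 10-element grid with identical
element size and carrier (so the filter physics is unchanged while FFTs are
4× smaller); the filtered-versus-toy reversal is asserted at the full
geometry across j = 1 and j = 8. Known limitations: a single filter channel
(no multi-scale bank, no orientation decomposition of natural images);
matching predictions assume the match family's response is monotone, which
excludes p ≤ q regimes by design; and the simulated observer is a convenience
oracle, not a human model.
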