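---
title: "Quantifying transcription-bubble dynamics from ALEX smFRET trajectories"
author: "bubbleFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-bubble dynamics from ALEX smFRET trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement this package models

In bacterial transcription initiation, RNA polymerase bound at a promoter
melts 12-14 bp of duplex DNA to form the open complex; the melted region is
the *transcription bubble*. A donor/acceptor dye pair placed so that bubble
opening changes the inter-dye distance turns this conformational change
into a FRET signal. Surface-immobilized single complexes observed by TIRF
microscopy with alternating-laser excitation (ALEX) yield, per molecule,
three intensity channels per alternation period: DD (donor excitation,
donor emission), DA (donor excitation, acceptor emission, i.e. FRET) and
AA (acceptor excitation, acceptor emission, the acceptor-presence check).

The per-frame apparent FRET efficiency is the proximity ratio

$$E^* = \frac{DA}{DD + DA},$$

and the ALEX stoichiometry is $S = (DD+DA)/(DD+DA+AA)$. $E^*$ is
deliberately *uncorrected*: no detection-factor $\gamma$, spectral leakage
or direct-excitation corrections are applied, because the quantities of
interest (state levels, populations, dwell times) are defined on the
apparent scale throughout. Low $E^*$ (~0.2 with the standard labelling)
reports a closed (duplex) bubble, high $E^*$ (~0.45) an open bubble, with
an occasional intermediate level near 0.35.

The analysis pipeline answers two questions per experimental condition:

1. **Populations** - what fraction of molecules is statically open,
   statically closed, statically intermediate, or dynamically
   interconverting?
2. **Kinetics** - for the dynamic molecules, what are the bubble opening
   and closing rates, obtained from dwell-time distributions of the
   closed and open states?

Because no raw experimental data are distributed with the source study,
the package pairs the analysis chain with a ground-truthed simulator: every
stage can be validated by parameter recovery on data whose truth is known
exactly.

## The simulator

`simulate_dataset()` realizes a `scenario_config()`: a named condition made
of molecular subpopulations (each a `kinetic_scheme()`), shared
photophysics, an alternation rate and a molecule count.

**Kinetics.** Each molecule's conformational trajectory is an exact
continuous-time Markov chain sample (`simulate_state_path()`): sojourns are
exponential in the state exit rate, jumps follow the embedded chain. The
canonical dynamic scheme (`dynamic_bubble_scheme()`) has one closed state
(E* 0.2, exit rate 6.4 s^-1, i.e. a ~156 ms mean closed dwell) and two
open substates sharing E* 0.45 but with exit rates 1/0.22 and 1/1.0 s^-1,
entered from the closed state with probability 0.5 each. The two substates
realize the observed *bi-exponential* open-dwell distribution; since only
the two lifetimes (not their amplitudes) are established, the 50/50
branching is this package's choice. The trajectory is discretized onto
camera frames by occupancy weighting (`discretize_path()`); one frame is
one full alternation period (10 ms at 100 Hz).

**Photophysics and camera.** Per frame, the FRET pair emits on average
`photons_per_frame_dex` photons under donor excitation (default 100),
split DA : DD = E : 1-E, and the acceptor emits `photons_per_frame_aex`
(default 70) under red excitation. Counts are
`gain x photons + background + read noise`, with gain 4.55 counts/photon
(a typical EMCCD real gain at EM setting 300) and the photon variance
inflated by an excess-noise factor of 2 - the standard approximation to
the EM-register cascade, implemented as a scaled Poisson draw
(`F * Poisson(mean/F)`). With these defaults the per-frame E* scatter at
E* = 0.45 is about 0.07, which is what the histograms of such experiments
show. Each dye photobleaches once, after an exponential waiting time
(defaults: acceptor 0.10 s^-1, donor 0.03 s^-1, so most 10-s records
contain one bleach step); after acceptor bleach DA and AA fall to
background while DD rises to the full budget, after donor bleach DD and DA
fall to background. Optional acceptor blinking and contact-mediated
quenching (for intra-bubble labelling schemes where the closed state is
high-FRET and partially quenched) are available.

**What the simulator does not emulate:** image formation (PSFs, pixel
noise, nearest-neighbour crowding), diffusing-molecule confocal bursts,
dye spectral dynamics beyond on/off behaviour, and baseline drift.
Recovery results on simulated data therefore validate the *statistical*
chain - they cannot certify image-extraction artefacts away.

**Bundled conditions.** `scenario_fixture()` exposes the study conditions:
the wild-type double-stranded promoter at 22 C (50% static open, 20%
static closed, 5% static intermediate, 25% dynamic), its 37 C variant
(all E* levels shifted +0.05, intermediate grown to 20%, dynamics 23%;
the unreported static open/closed split keeps the 22 C ratio), the
pre-melted (pmDNA) variants (dynamic molecules with ~240 ms closed dwells;
composition 21/16/13/56 normalized to sum 1, since the reported rounded
percentages add to 106), the sigma3.2-finger deletion (all interconversion
rates x3, the midpoint of the reported 2-4-fold speed-up) and jaw deletion
(x1.3), an intra-bubble labelling condition, and free DNA (single static
state at E* 0.17).

## Trace selection and classification

`apply_selection()` encodes the manual single-molecule curation rules as
an algorithm: at least one fluorophore must show a *single* downward
bleach step ending at background (certifying a single molecule), the
earlier bleach must occur at or after frame 105, dark intervals of >= 3
frames followed by recovery disqualify a trace as blinking (shorter
fluctuations are permitted), and the pre-bleach total intensity must fall
within 0.3-3x the dataset median. Steps are found by recursive binary
segmentation on a two-sample step statistic (mean difference over pooled
within-level sd, standardized by the split sizes); the default acceptance
threshold of 6 sits well above the statistic's null maximum on kilo-frame
traces, while genuine bleach steps at the default photon budget score in
the tens. Image-plane criteria (circular PSF, neighbour exclusion) have no
counterpart on simulated traces and are recorded as auto-pass.

`classify_trace()` then assigns one of four behaviours. A trace is
*dynamic* when its selected HMM (below) has two states separated by at
least 0.1 E*, the decoded path visits a transition between them, and the
DD/DA intensity changes across those transitions are anti-correlated
(Pearson r < -0.5) - the signature that the E* change reflects a genuine
distance change rather than an intensity artefact. The intensity change at
each transition is estimated from dwell means (up to 3 frames each side),
not single-frame differences; at 100 photons/frame the single-frame
estimate is so noisy that its expected correlation is only about -0.6,
which the averaging restores to below -0.8. Non-dynamic traces are
classified static closed / intermediate / open by mean pre-bleach E*
against boundaries 0.275 and 0.40, the midpoints between the canonical
state levels.

Two honest limitations of the classifier follow from the physics rather
than the implementation. First, a truly dynamic molecule that happens not
to transition during its pre-bleach window is unavoidably recorded as
static, so the measured dynamic fraction slightly underestimates the
underlying one (by a few percent of molecules at the default kinetics and
bleach rates). Second, contact-quenched labelling schemes make the donor
budget state-dependent, which the blinking filter can mistake for dark
states; such conditions need the filter relaxed.

## HMM segmentation by variational Bayes

Dynamic-candidate E* series are fitted with Gaussian-emission hidden
Markov models with K = 1, 2, 3 states, and K is chosen by **maximum
evidence**: each fit returns a variational lower bound on the marginal
likelihood, which penalizes superfluous states automatically. This is the
vbFRET-style formulation: conjugate Dirichlet priors (concentration 1) on
the initial distribution and transition rows, Normal-Gamma priors on each
state's emission mean and precision (mean centred on the series mean with
weak scaling beta0 = 0.1; precision shape 1, rate 0.01, i.e. a prior E*
scale of ~0.1). Coordinate ascent alternates forward-backward E-steps
(computed in C++) with conjugate posterior updates until the bound changes
by < 1e-6 (at most 500 iterations). The bound is monotone by construction
and is asserted to be so in the test suite; for K = 1 it equals the exact
conjugate marginal likelihood, which the tests verify against the closed
form.

Ten restarts from quantile-based, seed-jittered initial means guard
against local optima; every restart runs a short burn-in and the best
bound is refined to full convergence (a standard multi-start economy that
does not change which optimum is reported). Invalid frames (non-positive
FRET denominator) are bridged as missing observations when shorter than 3
frames; longer gaps split the series into segments fitted jointly with
shared parameters. Decoding uses dynamic programming under the posterior
point estimates, and states are mapped to closed / intermediate / open by
their emission means against the same 0.275 / 0.40 boundaries (half-open
intervals; a mean of exactly 0.40 is open).

## Dwell-time kinetics

Decoded paths become category dwell records (`extract_dwells()`): maximal
runs of constant category, with the first and last dwell of each segment
flagged censored. Rates are estimated from *uncensored* dwells pooled
across the dynamic molecules of a condition, matching the aggregated
dwell-histogram practice of such studies; the one-frame resolution limit is
handled by left truncation, under which the exponential excess over one
frame is again exponential (memorylessness), giving the shifted MLE
`tau = mean(duration) - t_min`. The opening rate is `k_open = 1/tau_closed`
and the closing rate is reported as `1/tau_open` from the single-exponential
fit (for fold-change comparisons this is far more stable than ratios of
individual mixture components). Open dwells are additionally fitted with a
two-component exponential mixture by seeded multi-restart EM, and the
single- vs bi-exponential choice is made by BIC with guards (fewer than
100 uncensored dwells, or a collapsed component, default to one
component). Confidence intervals come from a seeded bootstrap that
resamples *molecules*, not dwells, respecting within-molecule correlation;
1000 replicates by default.

Known biases, deliberately left uncorrected: events shorter than about one
frame are missed, which merges flanking dwells and inflates dwell means by
several percent at the default frame rate (strongly so for the 3x-faster
mutant fixture, whose recovered fold-change is consequently conservative);
excluding right-censored dwells slightly shortens the mean in finite
windows. Full missed-event corrections are out of scope and the bootstrap
CIs are wide enough to cover the residual bias at the study's scale, which
the acceptance checks verify.

## Reproducibility machinery

A single scenario seed drives everything: per-molecule and per-stage seeds
are derived with a counter-based mixing function (`substream_seed()`), so
a dataset is bit-identical under a fixed seed, stages can be re-run in
isolation, and `run_pipeline()` is deterministic end-to-end (asserted in
the tests). All numbers in stage outputs are written at full precision;
rounding happens only in printed summaries.

Problem sizes used by the validation suite mirror the study design:
100-molecule datasets, 10-s records at 100 Hz, 250 histogram frames per
molecule, 5000-draw dwell-mixture recoveries. On these sizes the
end-to-end checks recover the closed-state exit rate within its bootstrap
CI, the bi-exponential open-dwell components within 10%, the mixture
weights within 3 percentage points, and the class fractions within
binomial error - with the caveat, stated above, that the *observable*
dynamic fraction sits a little below the simulated one because windows
without transitions are unclassifiable as dynamic in principle.
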