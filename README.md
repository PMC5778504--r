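# bubbleFRET

Simulation and kinetic analysis of single-molecule FRET trajectories of
the transcription bubble in RNA polymerase–promoter open complexes.

## What it is for

When RNA polymerase forms an open complex, it melts 12–14 bp of promoter
DNA (the transcription bubble). With a donor/acceptor pair positioned so
that bubble opening changes the inter-dye distance, surface-immobilized
complexes under TIRF/ALEX illumination report the bubble conformation of
one molecule over time through the apparent FRET efficiency

    E* = DA / (DD + DA),        S = (DD + DA) / (DD + DA + AA)

where DD, DA, AA are the donor-excitation donor/acceptor and
acceptor-excitation acceptor intensities per alternation period. Low E*
(≈0.2) reports a closed bubble, high E* (≈0.45) an open bubble. This
package implements, as a tested and reusable pipeline, the analysis by
which such measurements are turned into numbers:

* **Simulator** (`simulate_dataset`) — ground-truthed ALEX trace
  simulation: exact continuous-time Markov conformational kinetics,
  occupancy-weighted frame discretization, photon shot noise with EMCCD
  gain (4.55 counts/photon) and excess noise, background and read noise,
  single-step photobleaching, optional blinking and contact quenching.
  Bundled `scenario_fixture()` conditions encode the study designs
  (wild-type dsDNA at 22/37 °C, pre-melted pmDNA, σ3.2-finger and β' jaw
  deletion variants, intra-bubble labelling, free DNA).
* **FRET core** (`compute_fret_series`, `build_fret_histogram`,
  `fit_fret_mixture`, `distance_to_fret`) — E*/S with background
  subtraction and validity masking, pooled histograms with an equal
  per-molecule frame budget (250 frames by default), Gaussian-mixture
  population summaries.
* **Trace QC** (`detect_bleach_steps`, `apply_selection`, `qc_dataset`) —
  algorithmic single-molecule curation: change-point bleach detection,
  single-step requirement, ≥105 pre-bleach frames, blinking filter,
  intensity band.
* **HMM segmentation** (`fit_vb_hmm`, `select_model`, `decode_path`,
  `categorize_states`) — variational-Bayes Gaussian HMMs (K = 1–3) with
  the number of states chosen by maximum evidence, Viterbi decoding, and
  FRET-level state categorization (closed / intermediate / open).
* **Classification** (`classify_trace`, `population_table`) — the
  four-way behavioural call (static open / closed / intermediate vs
  dynamic), requiring anti-correlated DD/DA changes at decoded
  transitions for a dynamic call.
* **Dwell kinetics** (`extract_dwells`, `fit_exponential`,
  `fit_biexponential`, `compare_exp_models`, `kinetics_report`) —
  left-truncated exponential MLE (k_open = 1/τ_closed), bi-exponential EM
  for the open-state dwells, BIC model choice, molecule-level bootstrap
  CIs.
* **Pipeline** (`run_pipeline`, `compare_conditions`) — deterministic
  end-to-end orchestration with on-disk stage outputs (TSV traces +
  `manifest.json`, CSV/JSON reports) and condition comparisons
  (population deltas, rate fold-changes). A thin CLI lives at
  `inst/scripts/smfret`.

## Worked example

Simulate the wild-type dsDNA 22 °C condition (50% static open, 20% static
closed, 5% static intermediate, 25% dynamic molecules) and run the full
pipeline:

```r
library(bubbleFRET)
cfg <- scenario_fixture("wt_dsDNA_22C", n_molecules = 30, seed = 42)
rep <- run_pipeline(cfg, n_boot = 200)
print(rep)
#> <run_report> scenario 'wt_dsDNA_22C': 18/30 molecules accepted
#>                 class  n   fraction
#> 1         static_open 10 0.55555556
#> 2       static_closed  4 0.22222222
#> 3 static_intermediate  1 0.05555556
#> 4             dynamic  3 0.16666667
#> mixture components (mean / sd / weight):
#>   0.197 / 0.060 / 0.297
#>   0.444 / 0.076 / 0.703
#> kinetics:
#>  category n_dwells     tau_s rate_per_s ci_lo     ci_hi n_components
#>    closed       14 0.1442857   6.930693 0.140 0.1566667            1
#>      open       13 0.4907692   2.037618 0.345 0.5533333            1
```

Reading the output: 18 of 30 simulated traces pass the single-molecule
selection rules (the rest bleach too early, never bleach, or blink). The
accepted traces split into the four behavioural classes; the pooled E*
histogram decomposes into a low-FRET component near 0.2 and a high-FRET
component near 0.45 carrying ~70% of the weight. From the three dynamic
molecules, the pooled closed-state dwells give τ_closed ≈ 0.144 s, i.e. a
bubble opening rate k_open ≈ 6.9 s⁻¹ (the generating truth is 6.4 s⁻¹ —
at n = 30 the bootstrap CI is still wide), and the open-state dwells give
the closing kinetics. At the study scale (100 molecules) the estimates
tighten onto the generating values; see the vignette for the validation
summary.

Every stage is reproducible: the scenario seed drives derived per-molecule
sub-streams, so re-running any stage (or the whole pipeline) with the same
configuration reproduces identical outputs.

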