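# ehtkit

Analysis toolkit for stretch-conditioned engineered heart tissue (EHT)
experiments: force-trace analytics, isometric biomechanics, Ca²⁺/action-
potential morphometrics, and a confocal cell-morphometry pipeline — together
with seeded synthetic-data generators that carry exact ground truth for
every modality.

## The problem

EHTs built from human iPSC-derived cardiomyocytes mature toward an
adult-like phenotype when cultured under progressive diastolic stretch
(groups S0–S3, 0 to 0.32 mm/day of post distension). Assessing that
maturation requires a heterogeneous set of quantitative readouts:

* **Contractile function** — continuous force recordings (2 ms sampling,
  force from spring-post displacement at compliance 71 mm/N) are reduced to
  per-beat features: diastolic force *F*<sub>dia</sub>, peak force
  *F*<sub>peak</sub>, twitch amplitude *F*<sub>tw</sub> =
  *F*<sub>peak</sub> − *F*<sub>dia</sub>, time to peak, relative relaxation
  rate max(−d*F*/d*t*)/*F*<sub>tw</sub>, and contraction duration; on top of
  these sit conditioning time courses, stretch-step responses, hypoxia
  residual force, and the all-or-nothing stimulation threshold.
* **Biomechanics** — Frank–Starling length–force curves with the
  systolic/diastolic ratio at optimum preload, the passive elastic modulus
  *E* = dσ<sub>dia</sub>/dε (σ in kPa from force over the α-actinin⁺
  cross-section; 1 mN/mm² = 1 kPa), specific force
  *F*<sub>tw</sub>/*A*<sub>actinin</sub>, the force–frequency relationship
  normalized to 1 Hz, and inotropic drug-response folds.
* **Excitation–contraction coupling** — Ca²⁺-transient amplitude ΔF/F₀,
  transient durations, and the monoexponential decay constant τ; action
  potential resting potential, amplitude, maximum upstroke velocity
  (d*V*/d*t*)<sub>max</sub>, and APD90.
* **Morphology** — from DAPI/WGA/α-actinin confocal scans (0.1 µm pixels):
  nucleus segmentation, nucleus-seeded watershed on the WGA membrane signal,
  α-actinin thresholding at histogram mode + 1 SD, myocyte filtering
  (actinin area fraction ≥ 0.07 and nucleus ≥ 5 µm²), principal-axis cell
  geometry, the **neighbor dispersion** statistic (axial circular SD of the
  main-axis orientation over each cell and its first- and second-degree
  neighbors), sarcomere length from striation periodicity, and
  actinin⁺ cross-section fractions.

Because such measurements are made on living tissue and raw recordings are
rarely shareable, `ehtkit` ships first-class synthetic generators
(`generate_force_trace`, `generate_ca_transient`,
`generate_action_potential`, `generate_tissue_image`,
`generate_expression_matrix`) that emulate each modality with a single-seed
deterministic ground-truth table, so every analyzer is validated by
round-trip parameter recovery. `eht_preset()` bundles the published S0–S3
group values used as generator calibrations.

## Worked example

```r
library(ehtkit)

## paced force recording with measurement noise
ft <- generate_force_trace(trace_params(duration = 60, twitch_amplitude = 2,
                                        diastolic_force = 1, noise_sd = 0.05,
                                        rng_seed = 1))
beats <- detect_beats(ft$trace)
#> 60 beats; mean twitch 2.02 mN; diastolic 0.984 mN
#> relaxation rate 8.19 1/s; contraction duration 0.332 s

## specific force of an intensely stretched tissue
specific_force(2.82, tissue_geometry(actinin_cross_section_mm2 = 0.25))
#> 11.28 mN/mm^2

## synthetic confocal field -> full morphometry pipeline
img <- generate_tissue_image(image_params(n_cells = 12, myocyte_fraction = 1,
                                          sarcomere_period = 2.19,
                                          orientation_sd = 8, rng_seed = 41))
m <- eht_morphometry(img$channels$dapi, img$channels$wga, img$channels$actinin)
#> cells 12, myocytes 12, sarcomere 2.197 um, dispersion 8.0 deg
```

The 60 detected beats recover the configured 2 mN twitch within 1%; the
morphometry pipeline segments all 12 cells, retains them all as myocytes
(striated, nucleated), measures the rendered 2.19 µm striation period to
within 0.01 µm, and returns a neighborhood orientation dispersion close to
the generator's 8° axial spread.

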