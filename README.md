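# nucleodyn

Quantitative analysis of nucleosome stability and dynamics assays, built
around the question of how a lateral-surface histone modification —
acetylation of histone H3 lysine 64 (H3K64ac), a residue whose main chain
contacts the DNA phosphate backbone of the inner gyre — changes the
physical stability of the nucleosome.

The package implements, as tested and reusable functions:

* **Single-molecule FRET burst analysis** — all-photons burst search
  (≥ 5 photons per 500 µs window, ≥ 30 photons per burst), corrected FRET
  efficiency and PIE stoichiometry
  (`E = F_A / (F_A + γ F_DD)`, `S = (γ F_DD + F_A) / (γ F_DD + F_A + F_AA)`,
  with background, crosstalk α and γ-factor corrections), time-deviation
  filters, and the analysis selection (> 50 photons, 0.1 < S < 0.7,
  TDS < 1, TDS_red-PIE < 0.4).
* **Probability distribution analysis (PDA)** — shot-noise-exact FRET
  efficiency histograms from Gaussian inter-dye distance populations
  (`E(R) = 1/(1+(R/R0)^6)` convolved with binomial photon statistics),
  chi-square fitting, and the intact (high-FRET) nucleosome fraction.
* **Salt-stability titrations** — the sigmoid
  `resp(C) = A2 + (A1 − A2)/(1 + e^((C − C0.5)/dC))`, plateau (1–0) and
  zero-salt normalization, replicate averaging, and midpoint differences
  ΔC0.5 in mM.
* **Gel densitometry** — competitive-assembly efficiency
  `I_nuc/(I_nuc + I_free)` with per-batch reference normalization,
  remodelling kinetics `y = a(1 − e^(−bt))` with initial rate `a·b`, and
  signal/loading band ratios.
* **Tiling-array summaries** — median-0 / common-MAD array normalization,
  probe classification (active/inactive TSS ± 1 kb, enhancer, genic minus
  first 1 kb, intergenic; mutually exclusive by priority), per-class
  five-number summaries, metagene TSS profiles (± 15 kb, 1-kb bins, lowess
  f = 0.05) and raw 2-kb TSS window counts.
* **Contact geometry** — distances from a lysine's main-chain N and
  side-chain NZ to DNA phosphate-backbone oxygens in PDB files, and the
  per-copy-nearest average side-chain distance.

A synthetic-data module (`simulate_photon_stream()`, `simulate_qf_titration()`,
`simulate_gel_tables()`, `simulate_probe_arrays()`,
`write_synthetic_nucleosome_pdb()`) generates every input with the
statistical structure the assays assume, so the whole chain runs without
instruments or downloads. `load_structure()` accepts any real PDB file
(e.g. the 1.9 Å nucleosome structure 1KX5) if you have one locally.

## Worked example

Simulate a two-species salt series with the default preset (two nucleosome
species whose true stability midpoints are 0.55 M and 0.49 M — a 60 mM
shift) and recover the shift end-to-end:

```r
library(nucleodyn)

res <- salt_stability_experiment(
  paper_default_species(),
  salt_grid  = seq(0, 1, by = 0.1),
  replicates = 3,
  config     = sim_config(duration = 60, molecule_rate = 15, seed = 101))

res$delta
#> $delta_mM
#> [1] 63.07904
#>
#> $se_mM
#> [1] 2.928738

head(res$fractions, 3)
#>      species salt  fraction n_bursts fraction_norm
#> 1 unmodified  0.0 0.9981481     1626     1.0000000
#> 2 unmodified  0.1 0.9975644     1713     0.9994152
#> 3 unmodified  0.2 0.9839904     1710     0.9858160
```

`fraction` is the PDA amplitude share of the high-FRET (intact) population
at each salt point, pooled over replicates (`n_bursts` retained bursts);
`fraction_norm` is the same after division by the 0 mM value. The reported
`delta_mM` is the difference of the two species' fitted sigmoid midpoints —
here 63.1 mM against the generating 60 mM — with the propagated standard
error. Runtime is a few minutes on one CPU.

The individual stages are available separately, e.g.:

```r
st  <- simulate_photon_stream(paper_default_species()$unmodified, salt = 0.55,
                              sim_config(duration = 10, seed = 42))
b   <- find_bursts(st)                       # APBS
f   <- burst_features(st, b, correction_set())
ret <- filter_bursts(f)$retained             # analysis selection
fit <- fit_pda(ret$E, ret$n_dd + ret$n_da,
               pda_model(list(distance_population(45, 3, 0.5),
                              distance_population(85, 8, 0.5))))
fit$fraction_high_fret
```

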