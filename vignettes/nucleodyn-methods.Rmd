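---
title: "Methods: nucleosome stability and dynamics analysis in nucleodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome stability and dynamics analysis in nucleodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nucleodyn` implements the quantitative analysis chain used to ask whether a
lateral-surface histone modification — the motivating case is acetylation of
histone H3 lysine 64, a residue whose main chain contacts the DNA phosphate
backbone of the inner gyre — destabilizes the nucleosome. Five assay families
are covered:

1. **Single-molecule FRET burst analysis** of freely diffusing nucleosomes
   under pulsed interleaved excitation (PIE), from raw photon arrival times to
   corrected per-burst FRET efficiency `E` and stoichiometry `S`.
2. **Probability distribution analysis (PDA)**: fitting shot-noise-exact
   efficiency histograms with Gaussian inter-dye distance populations to
   obtain the fraction of intact (high-FRET) nucleosomes.
3. **Salt-stability titrations**: sigmoid fitting of disruption curves and
   extraction of the stability midpoint `C0.5`, for both ensemble
   quenched-fluorescence data and smFRET intact-fraction series.
4. **Gel densitometry**: competitive-assembly efficiencies with per-batch
   normalization, exponential remodelling time courses with initial rates,
   and generic signal/loading band ratios.
5. **Tiling-array summaries**: median/MAD array normalization, genomic
   region-class assignment, per-class boxplot statistics, metagene TSS
   profiles and raw TSS window counts; plus **contact geometry** of a
   lysine's nitrogens against the DNA phosphate backbone in nucleosome
   coordinate files.

Every input can be produced by the package's synthetic-data generators, so
the full chain is testable without instruments or downloads.

# The photon-stream forward model

`simulate_photon_stream()` generates the measurement the burst pipeline
expects. Molecules traverse the confocal volume as a Poisson process
(`molecule_rate`). Each molecule is donor-only with probability
`donor_only_fraction`; otherwise it is *intact* with the logistic probability

$$f(C) = \frac{1}{1 + e^{(C - C_{0.5,\mathrm{true}})/dC_\mathrm{true}}}$$

at NaCl concentration $C$, and *open* (disassembled) otherwise. A
per-molecule inter-dye distance $R$ is drawn from the state's Gaussian and
converted to an efficiency through the Förster relation
$E = 1/(1+(R/R_0)^6)$.

Within a burst, photons are homogeneous Poisson over an exponentially
distributed burst duration — the simplest model consistent with diffusion,
chosen because the instrument's true brightness/duration distributions are
not part of the study conditions. Three design choices make the standard
corrections *exact in expectation* rather than approximate:

* **Crosstalk**: each donor-emitted photon is registered in the acceptor
  channel with probability $\alpha/(1+\alpha)$, so the expected leak equals
  $\alpha$ times the *observed* donor counts and the linear subtraction
  $F_{DA} - \alpha F_{DD}$ is unbiased.
* **Gamma factor**: $\gamma$ is realised as the relative detection
  probability of acceptor- versus donor-emitted photons (thinning), giving
  $P(\mathrm{DA}) = \gamma E / (\gamma E + 1 - E)$ among donor-excitation
  photons, which makes $E = F_A/(F_A + \gamma F_{DD})$ exact.
* **PIE/AA channel**: acceptor-carrying molecules emit acceptor-excitation
  photons at `aa_brightness_ratio` times the donor-excitation rate; donor-only
  molecules emit none, which is what the stoichiometry filter exploits.

Uniform Poisson background is added to all three channels over the full
duration. Defaults mirror the reference instrument constants: 0.2 kHz
background per channel, 4% crosstalk, $\gamma = 0.7$, $R_0 = 60$ Å. A
Förster radius printed as "60 nm" in the source literature is treated as
60 Å: 60 nm would put every nucleosomal inter-dye distance at $E \approx 1$,
which is physically impossible for this dye pair; the unit is taken as a
typo rather than silently recalibrated.

The default two-species preset (`paper_default_species()`) encodes an
unmodified and an H3K64-acetylated nucleosome whose true midpoints are
0.55 M and 0.49 M — a 60 mM destabilization, the reported effect size —
with a shared transition width of 0.08 M. Distances are 45 ± 3 Å (intact;
intermediate-to-high FRET) and 85 ± 8 Å (open; very low FRET), a donor-only
fraction of 0.15 and `aa_brightness_ratio` 0.8. These last values are not
stated by the source study; they are chosen once as realistic for a PIE
confocal measurement of labelled mononucleosomes (dual-label fractions of
80–90% and roughly balanced donor/acceptor excitation are typical) and are
deliberately not tuned afterwards.

What the generator does **not** emulate: diffusion through a Gaussian
excitation profile (brightness varies within real bursts), detector dead
time and afterpulsing, photophysics (blinking, bleaching mid-burst), and
TCSPC micro-times. Passing tests therefore demonstrate the correctness of
the analysis chain under an idealised but statistically faithful model, not
robustness to every instrument artefact.

# Burst search, corrections and filters

`find_bursts()` implements the all-photons burst search: a photon qualifies
when the *centred, closed* window of 500 µs around it contains at least 5
photons (all channels pooled); maximal runs of consecutive qualifying
photons form bursts — split wherever two consecutive photons lie further
apart than the window, since such photons cannot share one (without the
split, molecules arriving during otherwise photon-free stretches would
merge into a single burst) — and bursts with fewer than 30 photons are
discarded. The centring, the closed-interval tie-break and the gap split
are stated choices; the criterion values are the assay's. Unsorted streams are rejected, never
silently sorted. Burst duration is last-minus-first photon time.

`compute_es()` subtracts per-channel background (`rate × duration`), clips
negative corrected counts at zero, removes crosstalk
($F_A = F_{DA} - \alpha F_{DD}$, clipped at 0) and forms

$$E = \frac{F_A}{F_A + \gamma F_{DD}}, \qquad
  S = \frac{\gamma F_{DD} + F_A}{\gamma F_{DD} + F_A + F_{AA}}.$$

Ratios with non-positive denominators are reported as `NA`, a sentinel that
never passes a filter — this keeps background overshoot from producing
out-of-range values that would distort histograms.

The time-deviation signals are a **documented proxy**: the original
instrument paper's exact formula is not restated in the source study, so
`compute_tds()` uses the normalized displacement of a channel subset's mean
arrival time,

$$\mathrm{TDS} = \frac{|\overline{t}_\mathrm{subset} -
\overline{t}_\mathrm{all}|}{\mathrm{duration}/2},$$

with donor-excited photons (DD ∪ DA) for `tds` and acceptor-excited (AA)
photons for `tds_red_pie`. The proxy preserves the filter's purpose —
rejecting temporally asymmetric multi-molecule or bleaching events — and is
isolated so it can be replaced. Empty subsets yield `Inf` (always
rejected).

`filter_bursts()` applies the analysis thresholds: strictly more than 50
photons, $0.1 < S < 0.7$, $\mathrm{TDS} < 1$,
$\mathrm{TDS_{red-PIE}} < 0.4$.

# Probability distribution analysis

`expected_histogram()` computes, for a mixture of Gaussian distance
populations, the distribution of apparent efficiencies $k/N$: the Gaussian
is discretized on a grid of 201 points spanning $\mu \pm 5\sigma$
(configurable), each grid distance maps to $E(R)$, and the photon count $k$
out of $N$ is binomial. Apparent efficiencies are assigned to 40 equal bins
on $[0,1]$ (half-open, last closed) and averaged over the empirical
burst-size list. PDA operates on *corrected* efficiencies — background and
crosstalk are handled upstream — keeping it a pure shot-noise model. Burst
sizes passed to PDA are donor-excitation counts ($n_{DD} + n_{DA}$), the
counts that actually carry the efficiency shot noise; AA photons do not
enter.

`fit_pda()` minimises the Pearson chi-square between observed and expected
histograms (bins pooled to an expected count of at least 5) over the two
means, two widths and the amplitude fraction, with box bounds. Label
switching is damped by evaluating five deterministic jittered
initializations and optimizing from the best (`nlminb`); fitted populations
are re-sorted by mean distance and `fraction_high_fret` is the amplitude
share of the smaller-distance population — the intact fraction. When all
four shape parameters are held fixed, the two population histograms are
precomputed and only the mixture weight is optimized (golden-section), a
fast path the pipeline exploits.

The source study does not state its histogram binning, burst-size handling
or optimizer; the defaults above are this package's declared choices.

# The end-to-end salt-stability experiment

`salt_stability_experiment()` chains everything: simulate (2 species × 11
salts × 3 replicates), burst-search, correct, filter, fit PDA per
(species, salt) on replicate-pooled bursts, normalize the intact fractions
to the 0 mM value, fit the sigmoid per species and report the midpoint
difference in mM.

Two choices deserve justification:

* **Fixed population shapes per salt point.** Whether the published per-salt
  PDA fits shared population parameters is unstated. Here the distance
  populations' means and widths are estimated once per species by a free
  two-population fit on bursts pooled from the salt extremes (where each
  population dominates), then held fixed while only the amplitude fraction
  is fitted per point. This reflects the physics (salt changes *how many*
  nucleosomes are intact, not the geometry of the intact state), stabilises
  the per-point fits at moderate burst counts, and is roughly two orders of
  magnitude faster. The `fixed` argument of `fit_pda()` nevertheless
  defaults to all-free.
* **Burst-size quantization.** Within the pipeline, PDA burst sizes are
  rounded to multiples of 10 and capped at 400, and the distance grid is
  thinned to 61 points. For sizes above ~50 the shot-noise width
  $\sqrt{E(1-E)/N}$ changes by under 10% across a rounding step and the
  populations here are widely separated, so the effect on the fitted
  fraction is negligible; the cost of the binomial convolution, however,
  scales with the number of *distinct* sizes. `fit_pda()` itself applies no
  rounding.

Default problem sizes — 60 s streams at 15 molecules/s, giving roughly
1.5–1.8 thousand retained bursts per salt point — were chosen as the
smallest simulation satisfying the stated study condition of at least 1500
retained bursts per point.

# Salt titrations and the stability midpoint

The sigmoid model is

$$\mathrm{resp}(C) = A_2 + \frac{A_1 - A_2}{1 + e^{(C - C_{0.5})/dC}},$$

which approaches $A_1$ at low salt and $A_2$ at high salt and passes
$(A_1+A_2)/2$ exactly at $C = C_{0.5}$. One consequence is worth stating
explicitly: for curves that *decrease* with salt (smFRET intact fractions)
a fit with $dC > 0$ requires $A_1 > A_2$. The package therefore treats
$A_1$/$A_2$ as the low-/high-salt plateaus rather than the lower/upper
values, initialises them from the curve's endpoints (not its min/max), and
enforces $dC > 0$. Fitting is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm` directly — the `nls`-object wrappers reject
zero-residual noiseless data with spurious singular-gradient errors);
standard errors come from the Jacobian at the optimum. Constant responses
are a flagged failure with `NA` parameters, never fabricated estimates.

Two normalization pathways are kept distinct, as in the assays they mirror:

* **Plateau normalization** (`normalize_curve()`) for ensemble
  quenched-fluorescence titrations: $(\mathrm{resp} - A_1)/(A_2 - A_1)$,
  mapping the fitted plateaus to 0 and 1. Replicates on a common salt grid
  are averaged pointwise (`average_replicates()`, s.e. $= sd/\sqrt{n}$;
  differing grids are refused rather than interpolated) and refitted.
* **Zero-salt normalization** (`normalize_to_zero_salt()`) for smFRET
  intact-fraction series: every fraction divided by the 0 mM value. An
  exact 0 M entry is required by default; `reference = "lowest"` is an
  explicit opt-in, so silent substitution cannot hide design drift.

Midpoint differences are reported in mM
(`delta_c05()`; salts are stored in M throughout), with the s.e. propagated
as the root sum of squares.

# Gel quantification

Assembly efficiency is defined as the nucleosome band's share of total lane
signal, $I_\mathrm{nuc}/(I_\mathrm{nuc}+I_\mathrm{free})$ — the source
assay quantifies bands without writing the ratio, so the definition is
declared here. Per-batch normalization divides every lane by the mean
efficiency of that batch's reference-condition (unmodified) lanes, making
the per-batch reference mean exactly 1.0 and removing gel-to-gel scaling;
the operation is idempotent. Remodelling time courses are fitted as
$y = a(1 - e^{-bt})$ with the $t = 0$ sample included as data (not
constrained), and the initial rate is the derivative at zero time, $ab$,
in min⁻¹. Densitometry starts from intensity tables; image processing and
background handling are upstream of this package.

# Tiling-array summaries

`normalize_arrays()` median-centres each array and rescales it to a common
median absolute deviation; the common target is the mean of the per-array
MADs (the target is otherwise unspecified in the convention this follows).
Medians are exactly zero after normalization and the operation is
idempotent and affine-invariant.

Probe classification uses 0-based half-open coordinates (BED convention)
throughout, with the class definitions: TSS classes are the ±1 kb window
(`[TSS-1000, TSS+1000)`); enhancers are annotated intervals (activity calls
consumed as input — the two-mark significance calling belongs to the
upstream ChIP-seq analysis); genic excludes each gene's first 1000 bp
(strand-aware) to avoid promoters; intergenic is the remainder. Classes
are made mutually exclusive by the priority TSS > enhancer > genic >
intergenic, inferred from the requirement that classes not overlap; the
order is configurable since no tie-break is canonical. Overlap means any
shared base (GenomicRanges). Per-class summaries are five-number tables
with linear-interpolation quartiles (`quantile` type 7).

`metagene_profile()` bins strand-oriented signal in 1-kb windows across
±15 kb around TSSs (30 bins), averages across TSS-signal pairs per bin and
smooths the binned means with `lowess` at `f = 0.05` — mild smoothing: at
30 points this span touches only nearest neighbours. `count_tss_window()`
counts raw positions in the half-open 2-kb window centred on each TSS,
without normalization.

# Contact geometry

`k64_dna_contacts()` reports Euclidean distances from a lysine's main-chain
amide nitrogen and side-chain terminal nitrogen (NZ) to every DNA backbone
phosphate oxygen (OP1/OP2/O5′/O3′; legacy O1P/O2P accepted) within a 10 Å
cutoff, per H3 copy. DNA chains are recognised by residue names DA/DT/DG/DC
with a legacy A/T/G/C fallback; hydrogens are ignored; alternate
conformations resolve to the highest-occupancy atom. The "average
side-chain nitrogen-to-DNA distance" is operationalised as the mean over
H3 copies of each copy's *nearest* NZ-to-phosphate-oxygen distance, since
the exact atom pairs behind the published average are not enumerated — the
acceptance tolerance is widened accordingly.

Because the package ships no third-party coordinates, tests run on
synthetic structures: hand-laid micro-PDB files with known geometry, and
`write_synthetic_nucleosome_pdb()`, a generator for a small synthetic
nucleosome-like fixture (two H3-like chains with full lysines at residue
64 facing short DNA backbone fragments) whose construction places the
per-copy nearest side-chain distances at 5.8 and 6.4 Å and the main-chain
amides at hydrogen-bond range. Tests against this fixture verify that the
measurement machinery recovers constructed geometry; they are not a
measurement of any deposited crystal structure. `load_structure()` accepts
any real PDB file (e.g. the 1.9 Å nucleosome core particle structure
1KX5) for users who have one.

# Numerical choices and degenerate inputs

* Burst E/S undefined (NA) on non-positive denominators; such bursts never
  pass filters. Empty TDS subsets give `Inf`.
* PDA: 201-point distance grid over $\mu \pm 5\sigma$ (61 in the
  pipeline); 40 histogram bins; chi-square pooling threshold 5; box bounds
  $\mu \in [1, 5R_0]$, $\sigma \in [10^{-2}, R_0]$, fraction in $[0,1]$.
* Sigmoid/exponential fits: Levenberg–Marquardt with $dC, b > 0$ bounds;
  degenerate (constant/zero) inputs return flagged failures.
* Zero-MAD arrays, batches without reference lanes, missing 0 M entries,
  plateau-coincident normalizations and zero loading controls all raise
  errors rather than producing numbers.

# Known limitations

* The TDS definition is a declared stand-in for an instrument-specific
  statistic; absolute TDS values are not comparable to other software,
  only the filter's effect is.
* PDA assumes binomial shot noise on corrected efficiencies; the
  correction-induced deviation from strict binomial statistics (gamma
  re-weighting of counts) is absorbed by the fitted widths and does not
  bias the amplitude fraction for well-separated populations, but width
  estimates should not be over-interpreted.
* The generator's idealisations listed above mean instrument-specific
  artefacts (PSF brightness profiles, photobleaching) are untested.
* Enhancer activity and TSS activity calls are consumed, never computed.
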