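#' Define a nucleosome species for the photon-stream forward model
#'
#' A species is characterised by two Gaussian inter-dye distance
#' populations -- the intact nucleosome (short distance, high FRET) and the
#' disassembled/open state (long distance, very low FRET) -- together with
#' the logistic salt dependence of the intact fraction and the fraction of
#' molecules carrying only a donor fluorophore.
#'
#' The intact fraction at NaCl concentration `C` (in M) is
#' `f(C) = 1 / (1 + exp((C - c05_true) / dc_true))`, so `c05_true` is the
#' salt-stability midpoint and `dc_true` the transition width.
#'
#' @param name Species label, e.g. `"unmodified"` or `"H3K64ac"`.
#' @param r_intact_mean,r_intact_sd Mean and s.d. (Angstrom) of the intact
#'   (high-FRET) inter-dye distance population.
#' @param r_open_mean,r_open_sd Mean and s.d. (Angstrom) of the open
#'   (low-FRET) population. Must satisfy `r_intact_mean < r_open_mean`.
#' @param c05_true Salt-stability midpoint (M NaCl).
#' @param dc_true Transition width (M); must be positive.
#' @param donor_only_fraction Fraction of molecules lacking an acceptor,
#'   in `[0, 1]` (1 gives a donor-only control sample).
#' @return An object of class `species_model`.
#' @seealso [paper_default_species()], [simulate_photon_stream()]
#' @export
species_model <- function(name, r_intact_mean, r_intact_sd,
                          r_open_mean, r_open_sd,
                          c05_true, dc_true, donor_only_fraction = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  num <- c(r_intact_mean = r_intact_mean, r_intact_sd = r_intact_sd,
           r_open_mean = r_open_mean, r_open_sd = r_open_sd,
           c05_true = c05_true, dc_true = dc_true,
           donor_only_fraction = donor_only_fraction)
  if (any(!is.finite(num)))
    stop("species_model: all numeric parameters must be finite")
  if (r_intact_mean >= r_open_mean)
    stop("species_model: r_intact_mean must be < r_open_mean (intact = high FRET)")
  if (r_intact_sd <= 0 || r_open_sd <= 0)
    stop("species_model: distance s.d. must be positive")
  if (dc_true <= 0) stop("species_model: dc_true must be positive")
  if (donor_only_fraction < 0 || donor_only_fraction > 1)
    stop("species_model: donor_only_fraction must be in [0, 1]")
  structure(list(name = name,
                 r_intact_mean = r_intact_mean, r_intact_sd = r_intact_sd,
                 r_open_mean = r_open_mean, r_open_sd = r_open_sd,
                 c05_true = c05_true, dc_true = dc_true,
                 donor_only_fraction = donor_only_fraction),
            class = "species_model")
}

#' Default two-species preset for salt-stability experiments
#'
#' Encodes an unmodified and a lateral-surface-acetylated (H3K64ac)
#' nucleosome species whose salt-stability midpoints differ by 60 mM, the
#' destabilisation reported for H3K64 acetylation. Distance populations put
#' the intact state at intermediate-to-high FRET and the open state at very
#' low FRET for a 60 Angstrom Foerster radius.
#'
#' @return Named list of two [species_model()] objects
#'   (`unmodified`, `H3K64ac`).
#' @export
paper_default_species <- function() {
  list(
    unmodified = species_model("unmodified",
                               r_intact_mean = 45, r_intact_sd = 3,
                               r_open_mean = 85, r_open_sd = 8,
                               c05_true = 0.55, dc_true = 0.08,
                               donor_only_fraction = 0.15),
    H3K64ac = species_model("H3K64ac",
                            r_intact_mean = 45, r_intact_sd = 3,
                            r_open_mean = 85, r_open_sd = 8,
                            c05_true = 0.49, dc_true = 0.08,
                            donor_only_fraction = 0.15)
  )
}

#' Configuration of the photon-stream simulator
#'
#' Instrument-level parameters of the forward model. Defaults follow the
#' measurement conditions of a PIE confocal setup: 0.2 kHz background in
#' every detection channel, 4% donor-to-acceptor crosstalk and a
#' gamma-factor of 0.7, with a Foerster radius of 60 Angstrom.
#'
#' @param duration Measurement duration in seconds.
#' @param molecule_rate Mean molecule (burst) arrival rate, per second.
#' @param mean_burst_photons Mean number of donor-excitation photons per
#'   burst of mean duration.
#' @param burst_duration_mean Mean burst duration in milliseconds
#'   (durations are exponential).
#' @param bg_rate_per_channel Background rate per detection channel, kHz.
#' @param crosstalk_alpha Donor-emission crosstalk fraction alpha; each
#'   donor-emitted photon is registered in the acceptor channel with
#'   probability `alpha / (1 + alpha)` so that the expected leak equals
#'   `alpha` times the observed donor counts.
#' @param gamma Detection/quantum-yield correction factor (gamma > 0),
#'   realised as the relative detection probability of acceptor- vs
#'   donor-emitted photons.
#' @param r0 Foerster radius in Angstrom.
#' @param aa_brightness_ratio Acceptor-excitation (AA/PIE) photon rate as a
#'   fraction of the donor-excitation photon rate, for acceptor-carrying
#'   molecules.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 60, molecule_rate = 15,
                       mean_burst_photons = 100, burst_duration_mean = 1,
                       bg_rate_per_channel = 0.2, crosstalk_alpha = 0.04,
                       gamma = 0.7, r0 = 60, aa_brightness_ratio = 0.8,
                       seed = NULL) {
  num <- c(duration, molecule_rate, mean_burst_photons, burst_duration_mean,
           bg_rate_per_channel, crosstalk_alpha, gamma, r0,
           aa_brightness_ratio)
  if (any(!is.finite(num))) stop("sim_config: parameters must be finite")
  if (duration <= 0 || mean_burst_photons <= 0 || burst_duration_mean <= 0)
    stop("sim_config: durations and photon counts must be positive")
  if (molecule_rate < 0 || bg_rate_per_channel < 0 || aa_brightness_ratio < 0)
    stop("sim_config: rates must be non-negative")
  if (crosstalk_alpha < 0 || crosstalk_alpha >= 1)
    stop("sim_config: crosstalk_alpha must be in [0, 1)")
  if (gamma <= 0) stop("sim_config: gamma must be positive")
  if (r0 <= 0) stop("sim_config: r0 must be positive")
  structure(list(duration = duration, molecule_rate = molecule_rate,
                 mean_burst_photons = mean_burst_photons,
                 burst_duration_mean = burst_duration_mean,
                 bg_rate_per_channel = bg_rate_per_channel,
                 crosstalk_alpha = crosstalk_alpha, gamma = gamma, r0 = r0,
                 aa_brightness_ratio = aa_brightness_ratio, seed = seed),
            class = "sim_config")
}

#' Construct a photon stream object
#'
#' A photon stream is a table of arrival times (microseconds, sorted) and
#' detection channels: `DD` (donor excitation, donor emission), `DA` (donor
#' excitation, acceptor emission) and `AA` (acceptor excitation, acceptor
#' emission, i.e. the PIE channel).
#'
#' @param timestamp_us Numeric vector of arrival times in microseconds,
#'   non-decreasing, within `[0, duration * 1e6]`.
#' @param channel Character or factor vector with values in
#'   `c("DD", "DA", "AA")`, same length as `timestamp_us`.
#' @param duration Measurement duration, seconds.
#' @param salt NaCl concentration (M) of the measurement.
#' @param species Species label.
#' @param ... Further metadata stored as attributes (e.g. `seed`).
#' @return A `data.frame` of class `photon_stream` with columns
#'   `timestamp_us` and `channel`, carrying `duration`, `salt` and
#'   `species` attributes.
#' @export
photon_stream <- function(timestamp_us, channel, duration,
                          salt = NA_real_, species = NA_character_, ...) {
  if (length(timestamp_us) != length(channel))
    stop("photon_stream: timestamps and channels must have equal length")
  if (is.unsorted(timestamp_us))
    stop("photon_stream: timestamps must be non-decreasing")
  if (length(timestamp_us) &&
      (min(timestamp_us) < 0 || max(timestamp_us) > duration * 1e6))
    stop("photon_stream: timestamps must lie in [0, duration]")
  channel <- factor(as.character(channel), levels = c("DD", "DA", "AA"))
  if (anyNA(channel)) stop("photon_stream: channels must be DD, DA or AA")
  out <- data.frame(timestamp_us = as.numeric(timestamp_us),
                    channel = channel)
  attr(out, "duration") <- duration
  attr(out, "salt") <- salt
  attr(out, "species") <- species
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("photon_stream", "data.frame")
  out
}

## Logistic intact fraction; internal but reused by tests via ::: is avoided,
## so exported as a small documented helper.

#' Intact fraction of a species at a given salt concentration
#'
#' `1 / (1 + exp((salt - c05_true) / dc_true))`: the generating logistic of
#' the forward model.
#'
#' @param species A [species_model()].
#' @param salt NaCl concentration(s), M.
#' @return Intact fraction(s) in `[0, 1]`.
#' @export
intact_fraction_true <- function(species, salt) {
  stopifnot(inherits(species, "species_model"))
  1 / (1 + exp((salt - species$c05_true) / species$dc_true))
}

#' Simulate a photon stream for one species at one salt concentration
#'
#' Forward model of a diffusing-molecule PIE measurement. Molecules arrive
#' as a Poisson process; each is donor-only with the species'
#' `donor_only_fraction`, otherwise intact with the logistic probability
#' `f(salt)` and open otherwise. A per-molecule inter-dye distance is drawn
#' from the state's Gaussian and converted to a FRET efficiency
#' `E = 1 / (1 + (R/r0)^6)`. Donor-excitation photons are emitted as a
#' homogeneous Poisson process over an exponential burst duration; each is
#' acceptor-emitted with probability `gamma * E / (gamma * E + 1 - E)`
#' (gamma realised as relative detection probability), and donor-emitted
#' photons leak into the DA channel with probability `alpha / (1 + alpha)`.
#' Acceptor-carrying molecules additionally emit AA (PIE) photons at
#' `aa_brightness_ratio` times the donor-excitation rate. Uniform Poisson
#' background is added to all three channels over the full duration.
#'
#' @param species A [species_model()].
#' @param salt NaCl concentration, M (>= 0).
#' @param config A [sim_config()]; its `seed` (if non-`NULL`) makes the
#'   stream fully reproducible.
#' @return A [photon_stream()] with attributes `n_burst_photons` and
#'   `n_bg_photons` (photon-count bookkeeping: their sum is the total
#'   number of photons).
#' @export
simulate_photon_stream <- function(species, salt, config) {
  stopifnot(inherits(species, "species_model"), inherits(config, "sim_config"))
  if (!is.finite(salt) || salt < 0)
    stop("simulate_photon_stream: salt must be finite and >= 0")
  if (!is.null(config$seed)) set.seed(config$seed)

  dur_us <- config$duration * 1e6
  n_mol <- stats::rpois(1, config$molecule_rate * config$duration)

  ts <- numeric(0); ch <- character(0)
  n_burst_photons <- 0L
  if (n_mol > 0) {
    start <- stats::runif(n_mol, 0, dur_us)
    donor_only <- stats::runif(n_mol) < species$donor_only_fraction
    intact <- stats::runif(n_mol) < intact_fraction_true(species, salt)
    mu <- ifelse(intact, species$r_intact_mean, species$r_open_mean)
    sd <- ifelse(intact, species$r_intact_sd, species$r_open_sd)
    r <- pmax(stats::rnorm(n_mol, mu, sd), 1e-3)
    e <- 1 / (1 + (r / config$r0)^6)
    e[donor_only] <- 0

    burst_dur <- stats::rexp(n_mol, rate = 1 / (config$burst_duration_mean * 1e3))
    rate_us <- config$mean_burst_photons / (config$burst_duration_mean * 1e3)
    n_dex <- stats::rpois(n_mol, rate_us * burst_dur)
    n_aa <- ifelse(donor_only, 0L,
                   stats::rpois(n_mol, config$aa_brightness_ratio * rate_us * burst_dur))

    mol_d <- rep.int(seq_len(n_mol), n_dex)
    t_dex <- start[mol_d] + stats::runif(sum(n_dex)) * burst_dur[mol_d]
    q <- config$gamma * e / (config$gamma * e + 1 - e)
    acc_emit <- stats::runif(sum(n_dex)) < q[mol_d]
    leak <- stats::runif(sum(n_dex)) <
      config$crosstalk_alpha / (1 + config$crosstalk_alpha)
    ch_dex <- ifelse(acc_emit | leak, "DA", "DD")

    mol_a <- rep.int(seq_len(n_mol), n_aa)
    t_aa <- start[mol_a] + stats::runif(sum(n_aa)) * burst_dur[mol_a]

    ts <- c(t_dex, t_aa)
    ch <- c(ch_dex, rep.int("AA", sum(n_aa)))
    keep <- ts <= dur_us          # truncate bursts at the measurement end
    ts <- ts[keep]; ch <- ch[keep]
    n_burst_photons <- length(ts)
  }

  bg_per_channel <- config$bg_rate_per_channel * 1e3 * config$duration
  n_bg <- stats::rpois(3, bg_per_channel)
  t_bg <- stats::runif(sum(n_bg), 0, dur_us)
  ch_bg <- rep.int(c("DD", "DA", "AA"), n_bg)

  ts <- c(ts, t_bg); ch <- c(ch, ch_bg)
  o <- order(ts)
  photon_stream(ts[o], ch[o], duration = config$duration,
                salt = salt, species = species$name,
                seed = config$seed,
                n_burst_photons = n_burst_photons,
                n_bg_photons = sum(n_bg))
}

#' Simulate photon streams over a salt series with replicates
#'
#' One stream per (species, salt, replicate) combination, with distinct
#' per-stream seeds derived deterministically from `config$seed`.
#'
#' @param species_list List of [species_model()] objects.
#' @param salt_grid Numeric vector of NaCl concentrations (M), non-empty,
#'   all >= 0.
#' @param replicates Number of replicate measurements per salt point.
#' @param config A [sim_config()]; must carry a non-`NULL` seed.
#' @return A list of [photon_stream()] objects; the `"meta"` attribute is a
#'   `data.frame` (species, salt, replicate, seed) with one row per stream.
#' @export
simulate_salt_series <- function(species_list, salt_grid, replicates = 3,
                                 config = sim_config(seed = 1)) {
  if (inherits(species_list, "species_model"))
    species_list <- list(species_list)
  if (length(salt_grid) == 0) stop("simulate_salt_series: empty salt grid")
  if (any(salt_grid < 0)) stop("simulate_salt_series: salts must be >= 0")
  if (is.null(config$seed)) stop("simulate_salt_series: config$seed required")

  meta <- expand.grid(replicate = seq_len(replicates),
                      salt = salt_grid,
                      species_idx = seq_along(species_list))
  meta$species <- vapply(species_list, `[[`, "", "name")[meta$species_idx]
  meta$seed <- (config$seed + 7919L * seq_len(nrow(meta))) %% .Machine$integer.max
  streams <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    cfg_i <- config
    cfg_i$seed <- meta$seed[i]
    streams[[i]] <- simulate_photon_stream(species_list[[meta$species_idx[i]]],
                                           meta$salt[i], cfg_i)
    attr(streams[[i]], "replicate") <- meta$replicate[i]
  }
  attr(streams, "meta") <-
    meta[, c("species", "salt", "replicate", "seed")]
  streams
}

#' Simulate quenched-fluorescence salt titrations
#'
#' Responses follow the sigmoid
#' `A2 + (A1 - A2) / (1 + exp((C - c05) / dc))` (so the `A1` plateau is
#' approached at low salt and `A2` at high salt) plus i.i.d. Gaussian
#' noise.
#'
#' @param a1,a2 Plateau values (arbitrary fluorescence units): `a1` at low
#'   salt, `a2` at high salt.
#' @param c05 Midpoint (M); `dc` transition width (M, > 0).
#' @param salt_grid NaCl concentrations, M.
#' @param noise_sd Gaussian noise s.d. (>= 0).
#' @param replicates Number of replicate curves.
#' @param seed Integer seed.
#' @param species Species label stored on each curve.
#' @return List of [titration_curve()] objects.
#' @export
simulate_qf_titration <- function(a1, a2, c05, dc, salt_grid,
                                  noise_sd = 0, replicates = 1, seed = 1,
                                  species = "synthetic") {
  if (dc <= 0) stop("simulate_qf_titration: dc must be positive")
  if (noise_sd < 0) stop("simulate_qf_titration: noise_sd must be >= 0")
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    resp <- a2 + (a1 - a2) / (1 + exp((salt_grid - c05) / dc)) +
      stats::rnorm(length(salt_grid), 0, noise_sd)
    titration_curve(salt_grid, resp, species = species, replicate = r)
  })
}

#' Simulate gel densitometry tables
#'
#' Generates the three kinds of densitometry inputs the gel-quantification
#' functions consume:
#' \describe{
#'   \item{`remodelling`}{fraction of nucleosomes repositioned
#'     `y(t) = a * (1 - exp(-b * t))` plus Gaussian noise at the sampling
#'     times (default 0, 5, 10, 15, 20, 30, 45 min). `params`: `a`, `b`,
#'     optionally `timepoints`, `noise_sd`.}
#'   \item{`assembly`}{per-lane nucleosome / free-DNA band intensity pairs
#'     for several conditions over several batches. `params`:
#'     `efficiencies` (named vector of true assembly efficiencies per
#'     condition), `batches`, optionally `lanes_per_condition`,
#'     `noise_sd` (multiplicative, on intensities), `total_intensity`.}
#'   \item{`band_ratio`}{per-lane signal / loading-control intensity
#'     pairs. `params`: `ratios` (named vector of true signal/control
#'     ratios per lane), optionally `control_intensity`, `noise_sd`.}
#' }
#'
#' @param kind One of `"remodelling"`, `"assembly"`, `"band_ratio"`.
#' @param params Named list of kind-specific parameters (see Details).
#' @param seed Integer seed.
#' @return A `data.frame`; long format `(lane, condition, batch, band,
#'   intensity)` for `assembly` and `band_ratio`, `(time_min, fraction)`
#'   for `remodelling`.
#' @export
simulate_gel_tables <- function(kind = c("remodelling", "assembly", "band_ratio"),
                                params = list(), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "remodelling") {
    a <- params$a %||% 0.8
    b <- params$b %||% 0.1
    tp <- params$timepoints %||% c(0, 5, 10, 15, 20, 30, 45)
    noise_sd <- params$noise_sd %||% 0
    y <- a * (1 - exp(-b * tp)) + stats::rnorm(length(tp), 0, noise_sd)
    return(data.frame(time_min = tp, fraction = y))
  }
  if (kind == "assembly") {
    eff <- params$efficiencies
    if (is.null(eff) || is.null(names(eff)))
      stop("assembly: params$efficiencies must be a named vector")
    if (any(eff < 0 | eff > 1)) stop("assembly: efficiencies must be in [0,1]")
    batches <- params$batches %||% 3
    reps <- params$lanes_per_condition %||% 1
    noise_sd <- params$noise_sd %||% 0
    total <- params$total_intensity %||% 1000
    rows <- list()
    lane <- 0L
    for (b_i in seq_len(batches)) {
      batch_scale <- exp(stats::rnorm(1, 0, 0.2))  # batch-to-batch gel scaling
      for (cond in names(eff)) for (r in seq_len(reps)) {
        lane <- lane + 1L
        e <- eff[[cond]]
        tot <- total * batch_scale
        i_nuc <- max(e * tot * exp(stats::rnorm(1, 0, noise_sd)), 0)
        i_free <- max((1 - e) * tot * exp(stats::rnorm(1, 0, noise_sd)), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          lane = lane, condition = cond, batch = b_i,
          band = c("nucleosome", "free_dna"),
          intensity = c(i_nuc, i_free))
      }
    }
    return(do.call(rbind, rows))
  }
  ## band_ratio
  ratios <- params$ratios
  if (is.null(ratios) || is.null(names(ratios)))
    stop("band_ratio: params$ratios must be a named vector")
  ctrl <- params$control_intensity %||% 100
  noise_sd <- params$noise_sd %||% 0
  rows <- lapply(seq_along(ratios), function(i) {
    sig <- max(ratios[[i]] * ctrl * exp(stats::rnorm(1, 0, noise_sd)), 0)
    data.frame(lane = i, condition = names(ratios)[i], batch = 1L,
               band = c("signal", "loading"),
               intensity = c(sig, ctrl))
  })
  do.call(rbind, rows)
}

#' Simulate tiling-array probe sets over a region annotation
#'
#' Probes tile the annotated genome span at fixed spacing; each probe's
#' log2 bound/input ratio is its region class mean plus an array-specific
#' affine distortion (offset and scale) plus Gaussian noise. The class of
#' each probe is determined with [classify_probes()] so that the generator
#' and the classifier share one definition of the class universe.
#'
#' @param annotation A [region_annotation()].
#' @param n_arrays Number of arrays.
#' @param enrichment_by_class Named numeric vector of true class means
#'   (log2 units); classes absent from the vector default to 0. Names from
#'   `c("active_tss", "inactive_tss", "enhancer", "genic", "intergenic")`.
#' @param probe_spacing Probe spacing in bp (> 0); probe length equals the
#'   spacing so probes tile without gaps.
#' @param noise_sd Per-probe Gaussian noise s.d. (log2 units).
#' @param seed Integer seed.
#' @return List of `data.frame`s (chrom, start, end, log2_ratio), one per
#'   array, each with an `"array_id"` attribute and a `"class"` column
#'   recording the generating class.
#' @export
simulate_probe_arrays <- function(annotation, n_arrays = 2,
                                  enrichment_by_class = c(active_tss = 1.5),
                                  probe_spacing = 100, noise_sd = 0.3,
                                  seed = 1) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (probe_spacing <= 0) stop("simulate_probe_arrays: spacing must be > 0")
  spans <- annotation$seqlengths
  if (length(spans) == 0) stop("simulate_probe_arrays: empty annotation")
  set.seed(seed)
  probes <- do.call(rbind, lapply(names(spans), function(chr) {
    starts <- seq(0, spans[[chr]] - probe_spacing, by = probe_spacing)
    data.frame(chrom = chr, start = starts, end = starts + probe_spacing)
  }))
  cls <- classify_probes(probes, annotation)$class
  mu <- rep(0, nrow(probes))
  for (nm in names(enrichment_by_class))
    mu[cls == nm] <- enrichment_by_class[[nm]]
  lapply(seq_len(n_arrays), function(a) {
    offset <- stats::rnorm(1, 0, 0.2)
    scale <- exp(stats::rnorm(1, 0, 0.1))
    out <- probes
    out$log2_ratio <- (mu + stats::rnorm(nrow(probes), 0, noise_sd)) * scale + offset
    out$class <- cls
    attr(out, "array_id") <- a
    out
  })
}

#' Build a small synthetic region annotation
#'
#' One-chromosome annotation with active/inactive TSSs, enhancers and genes
#' laid out without overlap, for exercising the probe classifier and
#' metagene profiling on generated arrays.
#'
#' @param chrom Chromosome name.
#' @param length Chromosome length, bp.
#' @param n_active_tss,n_inactive_tss,n_enhancers,n_genes Feature counts.
#' @param seed Integer seed.
#' @return A [region_annotation()].
#' @export
synthetic_annotation <- function(chrom = "chr19", length = 1e6,
                                 n_active_tss = 5, n_inactive_tss = 5,
                                 n_enhancers = 6, n_genes = 10, seed = 1) {
  set.seed(seed)
  n_slots <- n_active_tss + n_inactive_tss + n_enhancers
  slot_w <- floor(length / (n_slots + n_genes + 1))
  anchors <- seq(slot_w, by = slot_w, length.out = n_slots + n_genes)
  anchors <- sample(anchors)  # interleave feature kinds along the chromosome
  i <- 0
  take <- function(n) { out <- anchors[i + seq_len(n)]; i <<- i + n; out }
  tss_pos <- take(n_active_tss + n_inactive_tss)
  tss <- data.frame(chrom = chrom, position = tss_pos,
                    strand = sample(c("+", "-"), length(tss_pos), TRUE),
                    activity = rep(c("active", "inactive"),
                                   c(n_active_tss, n_inactive_tss)))
  enh_pos <- take(n_enhancers)
  enhancers <- data.frame(chrom = chrom, start = enh_pos,
                          end = enh_pos + 1500,
                          class = rep_len(c("active", "inactive"), n_enhancers))
  gene_pos <- take(n_genes)
  gene_len <- pmax(round(stats::runif(n_genes, 0.4, 0.9) * slot_w), 2000)
  genes <- data.frame(chrom = chrom, start = gene_pos,
                      end = pmin(gene_pos + gene_len, length),
                      strand = sample(c("+", "-"), n_genes, TRUE))
  region_annotation(tss, enhancers, genes,
                    seqlengths = stats::setNames(length, chrom))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
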