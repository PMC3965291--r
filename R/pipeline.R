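#' End-to-end salt-stability experiment on simulated photon streams
#'
#' Runs the complete single-molecule salt-titration analysis on synthetic
#' data: photon streams are simulated for each (species, salt, replicate),
#' bursts are found by the all-photons burst search, corrected E/S/TDS
#' features are computed and filtered, a two-population PDA is fitted per
#' (species, salt) point on the replicate-pooled retained bursts, intact
#' fractions are normalized to the 0 M value, and a sigmoid is fitted per
#' species to extract the stability midpoint `C0.5`. The difference of
#' the two species' midpoints is reported in mM.
#'
#' Population distance shapes (means and widths) are estimated per
#' species by one free two-population PDA fit on bursts pooled from the
#' lowest and highest salt points (where each population dominates), and
#' then held fixed while the amplitude fraction is fitted per salt point.
#'
#' PDA burst sizes are the donor-excitation photon counts
#' (`n_dd + n_da`), the counts that carry the efficiency shot noise.
#'
#' @param species_list List of two [species_model()] objects (first minus
#'   second defines the sign of the reported shift).
#' @param salt_grid NaCl concentrations, M (must include 0).
#' @param replicates Replicates per salt point.
#' @param config A [sim_config()] (seeded).
#' @param corr A [correction_set()].
#' @param thresholds A [filter_thresholds()].
#' @param grid_points Distance-grid resolution for PDA fits (a coarser
#'   grid than the single-fit default keeps the 22-fit pipeline fast
#'   without visible bias for well-separated populations).
#' @param size_round,size_cap Burst sizes used by the PDA shot-noise
#'   model are rounded to multiples of `size_round` and capped at
#'   `size_cap`. Limiting the number of distinct sizes bounds the cost
#'   of the binomial convolution; for sizes above ~50 the shot-noise
#'   width changes negligibly within a rounding step.
#' @param min_retained Warn when a (species, salt) point retains fewer
#'   bursts than this.
#' @return List with `fractions` (per species/salt table of intact
#'   fractions, raw and 0 M-normalized, with retained-burst counts),
#'   `sigmoid_fits` (per-species [fit_sigmoid()] results on the
#'   normalized fractions), `pda_reference` (per-species free PDA fits),
#'   and `delta` (the [delta_c05()] of species 1 minus species 2).
#' @export
salt_stability_experiment <- function(species_list,
                                      salt_grid = seq(0, 1, by = 0.1),
                                      replicates = 3,
                                      config = sim_config(seed = 1),
                                      corr = correction_set(),
                                      thresholds = filter_thresholds(),
                                      grid_points = 61,
                                      size_round = 10, size_cap = 400,
                                      min_retained = 1500) {
  stopifnot(length(species_list) == 2)
  if (!any(salt_grid == 0))
    stop("salt_stability_experiment: salt grid must include 0 M")
  streams <- simulate_salt_series(species_list, salt_grid, replicates, config)
  meta <- attr(streams, "meta")

  ## burst search + features + filters, pooled per (species, salt)
  pooled <- list()
  for (i in seq_along(streams)) {
    b <- find_bursts(streams[[i]])
    f <- burst_features(streams[[i]], b, corr)
    kept <- filter_bursts(f, thresholds)$retained
    key <- paste(meta$species[i], meta$salt[i], sep = "@")
    kept$n_dex <- pmin(pmax(round((kept$n_dd + kept$n_da) / size_round) *
                              size_round, size_round), size_cap)
    pooled[[key]] <- rbind(pooled[[key]],
                           kept[, c("E", "n_dex", "n_total")])
  }

  species_names <- vapply(species_list, `[[`, "", "name")
  r0 <- config$r0
  init_bins <- seq(0, 1, length.out = 41)
  pda_ref <- list(); frac_rows <- list()
  for (sp in species_names) {
    lo_key <- paste(sp, min(salt_grid), sep = "@")
    hi_key <- paste(sp, max(salt_grid), sep = "@")
    ref_dat <- rbind(pooled[[lo_key]], pooled[[hi_key]])
    ## data-driven starting distances: split efficiencies at 0.5
    e_hi <- ref_dat$E[ref_dat$E >= 0.5]; e_lo <- ref_dat$E[ref_dat$E < 0.5]
    inv_e <- function(e) r0 * ((1 - e) / e)^(1 / 6)
    mu_hi <- if (length(e_hi)) inv_e(min(max(mean(e_hi), 0.02), 0.98)) else 0.8 * r0
    mu_lo <- if (length(e_lo)) inv_e(min(max(mean(e_lo), 0.02), 0.98)) else 1.4 * r0
    init <- pda_model(list(distance_population(mu_hi, 0.08 * r0, 0.5),
                           distance_population(mu_lo, 0.15 * r0, 0.5)),
                      r0 = r0, bin_edges = init_bins)
    ref_fit <- fit_pda(ref_dat$E, ref_dat$n_dex, init,
                       grid_points = grid_points)
    pda_ref[[sp]] <- ref_fit

    shape <- ref_fit$model
    for (s in salt_grid) {
      dat <- pooled[[paste(sp, s, sep = "@")]]
      if (is.null(dat) || nrow(dat) == 0)
        stop("no retained bursts for ", sp, " at ", s, " M")
      if (nrow(dat) < min_retained)
        warning(sprintf("only %d retained bursts for %s at %g M",
                        nrow(dat), sp, s))
      fit <- fit_pda(dat$E, dat$n_dex, shape,
                     fixed = c("mu1", "sigma1", "mu2", "sigma2"),
                     grid_points = grid_points)
      frac_rows[[length(frac_rows) + 1L]] <-
        data.frame(species = sp, salt = s,
                   fraction = fit$fraction_high_fret,
                   n_bursts = fit$n_bursts)
    }
  }
  fractions <- do.call(rbind, frac_rows)

  sig_fits <- list()
  norm_rows <- list()
  for (sp in species_names) {
    sub <- fractions[fractions$species == sp, ]
    sub <- normalize_to_zero_salt(sub)
    norm_rows[[sp]] <- sub
    sig_fits[[sp]] <- fit_sigmoid(titration_curve(sub$salt, sub$fraction,
                                                  species = sp))
  }
  fractions$fraction_norm <- do.call(rbind, norm_rows)$fraction[
    match(paste(fractions$species, fractions$salt),
          paste(do.call(rbind, norm_rows)$species,
                do.call(rbind, norm_rows)$salt))]

  list(fractions = fractions,
       sigmoid_fits = sig_fits,
       pda_reference = pda_ref,
       delta = delta_c05(sig_fits[[species_names[1]]],
                         sig_fits[[species_names[2]]]))
}
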