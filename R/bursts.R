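#' Detection-channel correction constants
#'
#' Background rates (kHz, subtracted as `rate * duration` per burst),
#' donor-to-acceptor crosstalk fraction and gamma-factor used to correct
#' raw burst counts. Defaults are the instrument constants of the
#' reference setup: 0.2 kHz in all channels, 4% crosstalk, gamma = 0.7.
#'
#' @param bg_dd,bg_da,bg_aa Background rates per channel, kHz.
#' @param alpha Crosstalk fraction, in `[0, 1)`.
#' @param gamma Gamma-factor (> 0).
#' @return An object of class `correction_set`.
#' @export
correction_set <- function(bg_dd = 0.2, bg_da = 0.2, bg_aa = 0.2,
                           alpha = 0.04, gamma = 0.7) {
  if (any(c(bg_dd, bg_da, bg_aa) < 0)) stop("background rates must be >= 0")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(bg_dd = bg_dd, bg_da = bg_da, bg_aa = bg_aa,
                 alpha = alpha, gamma = gamma),
            class = "correction_set")
}

#' Burst-selection thresholds
#'
#' Analysis filters applied after burst detection: more than
#' `min_photons_analysis` photons in total, stoichiometry strictly between
#' `s_low` and `s_high` (rejects donor-only and acceptor-only molecules),
#' and time-deviation signals below `tds_max` and `tds_red_pie_max`
#' (rejects multi-molecule events).
#'
#' @param min_photons_analysis Burst must have **more than** this many
#'   photons (default 50).
#' @param s_low,s_high Open stoichiometry interval (defaults 0.1, 0.7).
#' @param tds_max,tds_red_pie_max Upper TDS limits (defaults 1.0, 0.4).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_photons_analysis = 50,
                              s_low = 0.1, s_high = 0.7,
                              tds_max = 1.0, tds_red_pie_max = 0.4) {
  if (s_low >= s_high) stop("s_low must be < s_high")
  if (any(!is.finite(c(min_photons_analysis, s_low, s_high,
                       tds_max, tds_red_pie_max))))
    stop("thresholds must be finite")
  structure(list(min_photons_analysis = min_photons_analysis,
                 s_low = s_low, s_high = s_high,
                 tds_max = tds_max, tds_red_pie_max = tds_red_pie_max),
            class = "filter_thresholds")
}

#' All-photons burst search (APBS)
#'
#' A photon qualifies when the window of length `window_us` centred on it
#' (closed interval `[t - w/2, t + w/2]`) contains at least
#' `min_in_window` photons, all channels pooled. Maximal runs of
#' consecutive qualifying photons form candidate bursts, with a run split
#' wherever two consecutive photons lie more than `window_us` apart (such
#' photons cannot share a window, and without the split molecules arriving
#' during otherwise silent stretches would merge into one burst).
#' Candidates with fewer than `min_total` photons are discarded. Defaults are the standard
#' criterion: at least 5 photons in 500 microseconds and at least 30
#' photons in total.
#'
#' @param stream A [photon_stream()] (must be time-sorted; unsorted input
#'   is rejected, not silently sorted).
#' @param window_us Sliding-window length, microseconds.
#' @param min_in_window Minimum photons within the window.
#' @param min_total Minimum photons per burst.
#' @return A `data.frame` of class `burst_table`, one row per burst:
#'   `start_us`, `stop_us`, `n_dd`, `n_da`, `n_aa`, `n_total`,
#'   `first_idx`, `last_idx` (photon index range into `stream`). Bursts
#'   are ordered by start time and non-overlapping.
#' @export
find_bursts <- function(stream, window_us = 500, min_in_window = 5,
                        min_total = 30) {
  stopifnot(inherits(stream, "photon_stream"))
  if (window_us <= 0) stop("window_us must be positive")
  if (min_in_window < 1 || min_total < 1) stop("thresholds must be >= 1")
  ts <- stream$timestamp_us
  if (is.unsorted(ts)) stop("find_bursts: stream is not time-sorted")
  n <- length(ts)
  empty <- data.frame(start_us = numeric(0), stop_us = numeric(0),
                      n_dd = integer(0), n_da = integer(0),
                      n_aa = integer(0), n_total = integer(0),
                      first_idx = integer(0), last_idx = integer(0))
  class(empty) <- c("burst_table", "data.frame")
  if (n == 0) return(empty)

  half <- window_us / 2
  in_win <- findInterval(ts + half, ts) -
    findInterval(ts - half, ts, left.open = TRUE)
  qualified <- in_win >= min_in_window

  ## break qualified runs at photon-index boundaries and at time gaps
  ## longer than the window
  gap_break <- c(FALSE, diff(ts) > window_us)
  run_id <- cumsum(!qualified | gap_break)
  seg <- which(qualified)
  if (length(seg) == 0) return(empty)
  r <- rle(run_id[seg])
  ends_pos <- cumsum(r$lengths)
  starts_pos <- ends_pos - r$lengths + 1L
  keep <- r$lengths >= min_total
  if (!any(keep)) return(empty)
  starts <- seg[starts_pos[keep]]
  ends <- seg[ends_pos[keep]]

  ch <- stream$channel
  count_ch <- function(lv) {
    cum <- cumsum(ch == lv)
    as.integer(cum[ends] - c(0L, cum)[starts])
  }
  out <- data.frame(start_us = ts[starts], stop_us = ts[ends],
                    n_dd = count_ch("DD"), n_da = count_ch("DA"),
                    n_aa = count_ch("AA"),
                    n_total = as.integer(ends - starts + 1L),
                    first_idx = starts, last_idx = ends)
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Corrected FRET efficiency and stoichiometry for bursts
#'
#' Per-channel counts are background-corrected
#' (`F_X = n_X - bg_X * duration`, clipped at 0), the acceptor signal is
#' leak-corrected (`F_A = F_DA - alpha * F_DD`, clipped at 0), and
#' \deqn{E = F_A / (F_A + \gamma F_{DD}), \quad
#'       S = (\gamma F_{DD} + F_A) / (\gamma F_{DD} + F_A + F_{AA}).}
#' Bursts whose denominator is not positive get `NA` (an undefined
#' sentinel that never passes the analysis filters).
#'
#' @param bursts A `burst_table` from [find_bursts()] (or any data.frame
#'   with `start_us`, `stop_us`, `n_dd`, `n_da`, `n_aa`).
#' @param corr A [correction_set()].
#' @return `bursts` with columns `E` and `S` appended.
#' @export
compute_es <- function(bursts, corr = correction_set()) {
  stopifnot(inherits(corr, "correction_set"))
  dur_ms <- (bursts$stop_us - bursts$start_us) / 1e3
  if (any(dur_ms < 0)) stop("compute_es: negative burst duration")
  f_dd <- pmax(bursts$n_dd - corr$bg_dd * dur_ms, 0)
  f_da <- pmax(bursts$n_da - corr$bg_da * dur_ms, 0)
  f_aa <- pmax(bursts$n_aa - corr$bg_aa * dur_ms, 0)
  f_a <- pmax(f_da - corr$alpha * f_dd, 0)
  den_e <- f_a + corr$gamma * f_dd
  den_s <- den_e + f_aa
  bursts$E <- ifelse(den_e > 0, f_a / den_e, NA_real_)
  bursts$S <- ifelse(den_s > 0, den_e / den_s, NA_real_)
  bursts
}

#' Time-deviation signals of bursts
#'
#' Temporal-asymmetry statistics used to reject multi-molecule events.
#' For a photon subset within a burst,
#' `TDS = |mean(t_subset) - mean(t_all)| / (duration / 2)`; `tds` uses the
#' donor-excited photons (DD and DA) as subset and `tds_red_pie` the
#' acceptor-excited (AA) photons. A burst whose photons are
#' time-symmetric across channels has TDS near 0. An empty subset yields
#' `Inf`, a sentinel that fails every upper-limit filter.
#'
#' @param stream The parent [photon_stream()].
#' @param bursts A `burst_table` referencing `stream` (columns
#'   `first_idx`, `last_idx`).
#' @return `bursts` with columns `tds` and `tds_red_pie` appended.
#' @export
compute_tds <- function(stream, bursts) {
  stopifnot(inherits(stream, "photon_stream"))
  n_b <- nrow(bursts)
  if (n_b == 0) {
    bursts$tds <- numeric(0); bursts$tds_red_pie <- numeric(0)
    return(bursts)
  }
  len <- bursts$last_idx - bursts$first_idx + 1L
  idx <- sequence(len) - 1L + rep(bursts$first_idx, len)
  bid <- rep.int(seq_len(n_b), len)
  ts <- stream$timestamp_us[idx]
  ch <- stream$channel[idx]

  mean_all <- rowsum(ts, bid)[, 1] / len
  subset_mean <- function(sel) {
    s <- rowsum(ts * sel, bid)[, 1]
    k <- rowsum(as.numeric(sel), bid)[, 1]
    ifelse(k > 0, s / k, NA_real_)
  }
  mean_dex <- subset_mean(ch %in% c("DD", "DA"))
  mean_aa <- subset_mean(ch == "AA")
  half_dur <- (bursts$stop_us - bursts$start_us) / 2
  dev <- function(m) {
    out <- abs(m - mean_all) / half_dur
    out[is.na(m) | half_dur <= 0] <- Inf
    out
  }
  bursts$tds <- dev(mean_dex)
  bursts$tds_red_pie <- dev(mean_aa)
  bursts
}

#' Compute all burst features
#'
#' Convenience wrapper: [compute_es()] then [compute_tds()].
#'
#' @inheritParams compute_tds
#' @param corr A [correction_set()].
#' @return `bursts` with `E`, `S`, `tds`, `tds_red_pie` columns.
#' @export
burst_features <- function(stream, bursts, corr = correction_set()) {
  compute_tds(stream, compute_es(bursts, corr))
}

#' Apply analysis filters to burst features
#'
#' Retains bursts with `n_total > min_photons_analysis`,
#' `s_low < S < s_high`, `tds < tds_max` and
#' `tds_red_pie < tds_red_pie_max`. Bursts with undefined (NA) features
#' are always rejected. Input order is preserved.
#'
#' @param features Burst table with `E`, `S`, `tds`, `tds_red_pie`
#'   columns (see [burst_features()]).
#' @param thr A [filter_thresholds()].
#' @return List with `retained` (the filtered table) and `mask` (logical
#'   retention vector parallel to the input).
#' @export
filter_bursts <- function(features, thr = filter_thresholds()) {
  stopifnot(inherits(thr, "filter_thresholds"))
  mask <- features$n_total > thr$min_photons_analysis &
    !is.na(features$S) &
    features$S > thr$s_low & features$S < thr$s_high &
    features$tds < thr$tds_max &
    features$tds_red_pie < thr$tds_red_pie_max
  mask[is.na(mask)] <- FALSE
  list(retained = features[mask, , drop = FALSE], mask = mask)
}

#' Write a burst feature table to CSV
#'
#' @param features Burst table (with features and optionally a
#'   `retained` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_burst_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
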