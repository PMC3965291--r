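# Shared fixtures, built in code.

test_species <- function(c05 = 0.55, dc = 0.08, donor_only = 0.15,
                         name = "test") {
  species_model(name, r_intact_mean = 45, r_intact_sd = 3,
                r_open_mean = 85, r_open_sd = 8,
                c05_true = c05, dc_true = dc,
                donor_only_fraction = donor_only)
}

# A hand-laid photon stream: photon times and channels given explicitly.
manual_stream <- function(times_us, channels, duration = NULL) {
  if (is.null(duration)) duration <- max(times_us) / 1e6 + 1
  photon_stream(times_us, channels, duration = duration)
}

# Brute-force O(n^2) APBS oracle: sliding closed window centred on each
# photon, maximal runs of qualified photons split at gaps longer than the
# window, minimum total size.
apbs_oracle <- function(ts, window_us, min_in_window, min_total) {
  n <- length(ts)
  qual <- vapply(seq_len(n), function(i)
    sum(ts >= ts[i] - window_us / 2 & ts <= ts[i] + window_us / 2) >=
      min_in_window, TRUE)
  bursts <- list()
  i <- 1
  while (i <= n) {
    if (qual[i]) {
      j <- i
      while (j < n && qual[j + 1] && ts[j + 1] - ts[j] <= window_us) j <- j + 1
      if (j - i + 1 >= min_total)
        bursts[[length(bursts) + 1]] <- c(first = i, last = j)
      i <- j + 1
    } else i <- i + 1
  }
  bursts
}

# Brute-force interval-overlap check on 0-based half-open intervals.
overlaps_any <- function(p_start, p_end, r_start, r_end) {
  any(p_start < r_end & r_start < p_end)
}
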