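test_that("APBS finds an isolated dense cluster and nothing else", {
  set.seed(1)
  # 100 photons uniformly within 1 ms, then 10 s of silence
  ts <- sort(runif(100, 0, 1000))
  st <- manual_stream(ts, rep("DD", 100), duration = 10)
  b <- find_bursts(st, window_us = 500, min_in_window = 5, min_total = 30)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_total, 100L)
  expect_equal(b$first_idx, 1L)
  expect_equal(b$last_idx, 100L)
})

test_that("APBS yields nothing when the window criterion is unreachable", {
  ts <- seq(0, 999000, by = 1000)  # 1 photon per ms: at most 1 per 500 us
  st <- manual_stream(ts, rep("DD", length(ts)))
  expect_equal(nrow(find_bursts(st)), 0)
})

test_that("a 29-photon cluster fails the minimum total-size criterion", {
  set.seed(2)
  ts <- sort(runif(29, 0, 1000))
  st <- manual_stream(ts, rep("DA", 29), duration = 5)
  expect_equal(nrow(find_bursts(st, min_total = 30)), 0)
  expect_equal(nrow(find_bursts(st, min_total = 29)), 1)
})

test_that("APBS rejects unsorted streams instead of sorting them", {
  st <- manual_stream(c(1, 2, 3), c("DD", "DD", "DD"))
  st$timestamp_us <- c(3, 1, 2)
  expect_error(find_bursts(st), "sorted")
})

test_that("APBS equals the brute-force sliding-window oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    # bursty stream: background plus a few dense clusters
    ts <- sort(c(runif(300, 0, 2e6),
                 unlist(lapply(runif(8, 0, 2e6), function(c0)
                   c0 + runif(rpois(1, 60), 0, 1500)))))
    st <- manual_stream(ts, sample(c("DD", "DA", "AA"), length(ts), TRUE),
                        duration = 3)
    got <- find_bursts(st, window_us = 500, min_in_window = 5, min_total = 20)
    want <- apbs_oracle(ts, 500, 5, 20)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$first_idx, vapply(want, `[[`, 0, "first"))
      expect_equal(got$last_idx, vapply(want, `[[`, 0, "last"))
    }
    # burst intervals are disjoint and ordered
    if (nrow(got) > 1)
      expect_true(all(got$start_us[-1] > got$stop_us[-nrow(got)]))
    expect_true(all(got$n_total >= 20))
  }
})

test_that("E and S match hand-computed corrected values", {
  b <- data.frame(start_us = 0, stop_us = 1000, n_dd = 60L, n_da = 40L,
                  n_aa = 50L, n_total = 150L, first_idx = 1L, last_idx = 150L)
  f <- compute_es(b, correction_set(bg_dd = 0, bg_da = 0, bg_aa = 0,
                                    alpha = 0.04, gamma = 0.7))
  f_a <- 40 - 0.04 * 60           # 37.6
  expect_equal(f$E, f_a / (f_a + 0.7 * 60))
  expect_equal(f$S, (0.7 * 60 + f_a) / (0.7 * 60 + f_a + 50))
  # symmetric no-correction case
  b2 <- transform(b, n_da = 60L, n_aa = 0L)
  f2 <- compute_es(b2, correction_set(0, 0, 0, alpha = 0, gamma = 1))
  expect_equal(f2$E, 0.5)
  expect_equal(f2$S, 1)
  # donor-only-like burst: E ~ 0, S ~ 1
  b3 <- data.frame(start_us = 0, stop_us = 1000, n_dd = 100L,
                   n_da = 4L, n_aa = 0L, n_total = 104L,
                   first_idx = 1L, last_idx = 104L)
  f3 <- compute_es(b3, correction_set(0, 0, 0, alpha = 0.04, gamma = 0.7))
  expect_lt(f3$E, 0.01)
  expect_equal(f3$S, 1)
})

test_that("background correction clips at zero and flags undefined ratios", {
  # 1 ms burst with counts below the expected background
  b <- data.frame(start_us = 0, stop_us = 1e6, n_dd = 0L, n_da = 0L,
                  n_aa = 0L, n_total = 0L, first_idx = 1L, last_idx = 1L)
  f <- compute_es(b, correction_set())
  expect_true(is.na(f$E))
  expect_true(is.na(f$S))
  expect_error(compute_es(transform(b, stop_us = -1)), "duration")
})

test_that("TDS measures temporal asymmetry of channel subsets", {
  # symmetric burst: all channels uniform over [0, 1000]
  ts <- seq(0, 1000, length.out = 90)
  ch <- rep(c("DD", "DA", "AA"), 30)
  st <- manual_stream(ts, ch)
  b <- find_bursts(st, window_us = 200, min_in_window = 2, min_total = 30)
  f <- compute_tds(st, b)
  expect_lt(f$tds, 0.05)
  expect_lt(f$tds_red_pie, 0.05)

  # AA photons all in the first half, others uniform
  n <- 120
  t_other <- seq(0, 1000, length.out = n / 2)
  t_aa <- seq(0, 500, length.out = n / 2)
  ts2 <- sort(c(t_other, t_aa))
  ch2 <- ifelse(ts2 %in% t_aa, "AA", "DD")
  st2 <- manual_stream(ts2, ch2)
  b2 <- find_bursts(st2, window_us = 300, min_in_window = 2, min_total = 30)
  expect_equal(nrow(b2), 1)
  f2 <- compute_tds(st2, b2)
  # mean(AA) = 250, mean(all) = 375, duration 1000 -> |250-375|/500 = 0.25
  expect_equal(f2$tds_red_pie, 0.25, tolerance = 0.02)

  # single AA photon at burst start: verified against hand computation
  ts3 <- c(0, seq(10, 1000, length.out = 59))
  ch3 <- c("AA", rep("DD", 59))
  st3 <- manual_stream(ts3, ch3)
  b3 <- find_bursts(st3, window_us = 500, min_in_window = 2, min_total = 30)
  f3 <- compute_tds(st3, b3)
  expect_equal(f3$tds_red_pie, abs(0 - mean(ts3)) / (max(ts3) / 2))

  # empty AA subset yields the Inf sentinel (never passes a filter)
  st4 <- manual_stream(seq(0, 1000, length.out = 40), rep("DD", 40))
  b4 <- find_bursts(st4, window_us = 500, min_in_window = 2, min_total = 30)
  f4 <- compute_tds(st4, b4)
  expect_identical(f4$tds_red_pie, Inf)
})

test_that("analysis filters apply the exact thresholds", {
  f <- data.frame(n_total = c(50L, 51L, 120L, 120L, 120L, 120L),
                  E = 0.5,
                  S = c(0.5, 0.5, 0.85, 0.5, 0.5, 0.1),
                  tds = c(0.1, 0.1, 0.1, 1.5, 0.1, 0.1),
                  tds_red_pie = c(0.1, 0.1, 0.1, 0.1, 0.6, 0.1))
  out <- filter_bursts(f, filter_thresholds())
  # n_total = 50 excluded (strictly more than 50 required); S = 0.85,
  # S = 0.1, tds >= 1 and tds_red_pie >= 0.4 all excluded
  expect_equal(out$mask, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(nrow(out$retained), 1)
  empty <- filter_bursts(f[0, , drop = FALSE])
  expect_equal(nrow(empty$retained), 0)
})

test_that("corrected mean E of intact bursts matches the Foerster value", {
  sp <- species_model("ideal", 50, 0.5, 85, 8, c05_true = 10, dc_true = 0.1,
                      donor_only_fraction = 0)
  cfg <- sim_config(duration = 30, molecule_rate = 15,
                    bg_rate_per_channel = 0, crosstalk_alpha = 0,
                    gamma = 1, seed = 31)
  st <- simulate_photon_stream(sp, 0, cfg)   # all molecules intact
  b <- find_bursts(st)
  f <- filter_bursts(burst_features(st, b, correction_set(0, 0, 0, 0, 1)))
  e_true <- efficiency_from_distance(50, 60)
  expect_gt(nrow(f$retained), 100)
  se <- sd(f$retained$E) / sqrt(nrow(f$retained))
  expect_lt(abs(mean(f$retained$E) - e_true), 4 * se + 0.01)

  # with background, crosstalk and gamma at their defaults the correction
  # formulas remain unbiased (the forward model matches them exactly)
  cfg2 <- sim_config(duration = 30, molecule_rate = 15, seed = 32)
  st2 <- simulate_photon_stream(sp, 0, cfg2)
  f2 <- filter_bursts(burst_features(st2, find_bursts(st2),
                                     correction_set()))
  expect_gt(nrow(f2$retained), 100)
  se2 <- sd(f2$retained$E) / sqrt(nrow(f2$retained))
  expect_lt(abs(mean(f2$retained$E) - e_true), 4 * se2 + 0.015)
})

test_that("the stoichiometry filter removes donor-only molecules", {
  sp <- test_species(donor_only = 0.3)
  cfg <- sim_config(duration = 30, molecule_rate = 15, seed = 17)
  st <- simulate_photon_stream(sp, 0, cfg)
  b <- find_bursts(st)
  f <- burst_features(st, b, correction_set())
  kept <- filter_bursts(f)$retained
  # donor-only bursts sit at S ~ 1; essentially none survive the S window
  donor_like <- f[f$n_total > 50 & !is.na(f$S) & f$S > 0.9, ]
  expect_gt(nrow(donor_like), 30)   # they are present before filtering
  expect_true(all(kept$S < 0.7))
  expect_lt(mean(kept$E < 0.02 & kept$S > 0.8), 0.05)
})
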