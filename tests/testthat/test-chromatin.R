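simple_annotation <- function() {
  # chr: 100 kb. Active TSS at 10,000 (+), inactive TSS at 30,000 (-).
  # Enhancer [50,000, 52,000). Genes: [9,500, 20,000) on + (overlaps the
  # active TSS window), [70,000, 80,000) on +, [85,000, 95,000) on -.
  region_annotation(
    tss = data.frame(chrom = "chrT", position = c(10000, 30000),
                     strand = c("+", "-"),
                     activity = c("active", "inactive")),
    enhancers = data.frame(chrom = "chrT", start = 50000, end = 52000,
                           class = "active"),
    genes = data.frame(chrom = "chrT",
                       start = c(9500, 70000, 85000),
                       end = c(20000, 80000, 95000),
                       strand = c("+", "+", "-")),
    seqlengths = c(chrT = 100000))
}

probe_at <- function(start, width = 50) {
  data.frame(chrom = "chrT", start = start, end = start + width)
}

test_that("array normalization yields exact median 0 and a common MAD", {
  set.seed(1)
  arrays <- list(data.frame(log2_ratio = rnorm(501, 2, 1)),
                 data.frame(log2_ratio = rnorm(501, -1, 3)),
                 data.frame(log2_ratio = rt(501, 5)))
  out <- normalize_arrays(arrays)
  meds <- vapply(out, function(a) median(a$log2_ratio), 0)
  mads <- vapply(out, function(a) mad(a$log2_ratio), 0)
  expect_equal(meds, rep(0, 3))
  expect_lt(diff(range(mads)), 1e-9)
  # idempotence
  again <- normalize_arrays(out)
  expect_equal(vapply(again, function(a) a$log2_ratio, numeric(501)),
               vapply(out, function(a) a$log2_ratio, numeric(501)))
  # simple median subtraction before scaling
  tri <- normalize_arrays(list(data.frame(log2_ratio = c(1, 2, 3))),
                          target_mad = mad(c(1, 2, 3)))
  expect_equal(tri[[1]]$log2_ratio, c(-1, 0, 1))
  expect_error(normalize_arrays(list(data.frame(log2_ratio = rep(1, 10)))),
               "MAD")
})

test_that("arrays differing by an affine transform normalize identically", {
  set.seed(2)
  base <- rnorm(400)
  out <- normalize_arrays(list(data.frame(log2_ratio = base),
                               data.frame(log2_ratio = 2.5 * base - 3)))
  expect_equal(out[[1]]$log2_ratio, out[[2]]$log2_ratio, tolerance = 1e-12)
})

test_that("probe classes follow the window definitions and priorities", {
  ann <- simple_annotation()
  cls <- function(p) classify_probes(p, ann)$class
  # 500 bp downstream of the active TSS -> inside the +/- 1 kb window
  expect_equal(cls(probe_at(10500)), "active_tss")
  expect_equal(cls(probe_at(30500)), "inactive_tss")
  # half-open window edge: probe starting exactly at TSS+1000 is outside
  # the window (here it falls into the underlying gene body instead)
  expect_equal(cls(probe_at(11000)), "genic")
  expect_equal(cls(probe_at(10999, width = 1)), "active_tss")
  # same edge at the inactive TSS, where no other class lies beneath
  expect_equal(cls(probe_at(31000)), "intergenic")
  expect_equal(cls(probe_at(30999, width = 1)), "inactive_tss")
  # enhancer overlap
  expect_equal(cls(probe_at(50100)), "enhancer")
  # inside a gene but within its first 1000 bp -> not genic
  expect_equal(cls(probe_at(70800)), "intergenic")
  expect_equal(cls(probe_at(71100)), "genic")
  # minus-strand gene: the first 1000 bp are at the high-coordinate end
  expect_equal(cls(probe_at(94500)), "intergenic")
  expect_equal(cls(probe_at(93000)), "genic")
  # TSS window beats the overlapping gene body
  expect_equal(cls(probe_at(10500 + 0)), "active_tss")
  # unknown chromosome -> intergenic with warning
  expect_warning(out <- classify_probes(
    data.frame(chrom = "chrX", start = 1, end = 50), ann), "intergenic")
  expect_equal(out$class, "intergenic")
})

test_that("classification partitions probes and matches a brute-force oracle", {
  ann <- simple_annotation()
  set.seed(3)
  starts <- sort(sample(0:99900, 2000))
  probes <- data.frame(chrom = "chrT", start = starts, end = starts + 50)
  got <- classify_probes(probes, ann)$class
  expect_length(got, nrow(probes))
  expect_true(all(got %in% c("active_tss", "inactive_tss", "enhancer",
                             "genic", "intergenic")))

  # oracle: direct interval checks with the same priority order
  oracle <- vapply(seq_len(nrow(probes)), function(i) {
    s <- probes$start[i]; e <- probes$end[i]
    tss <- ann$tss
    for (act in c("active", "inactive")) {
      tt <- tss[tss$activity == act, ]
      if (overlaps_any(s, e, tt$position - 1000, tt$position + 1000))
        return(paste0(act, "_tss"))
    }
    if (overlaps_any(s, e, ann$enhancers$start, ann$enhancers$end))
      return("enhancer")
    g <- ann$genes
    gs <- ifelse(g$strand == "-", g$start, g$start + 1000)
    ge <- ifelse(g$strand == "-", g$end - 1000, g$end)
    if (overlaps_any(s, e, gs, ge)) return("genic")
    "intergenic"
  }, "")
  expect_equal(got, oracle)
})

test_that("class summaries use linear-interpolation quartiles", {
  probes <- data.frame(log2_ratio = c(1, 2, 3, 4, 5),
                       class = "active_tss")
  s <- class_summary(probes)
  row <- s[s$class == "active_tss", ]
  expect_equal(c(row$min, row$q1, row$median, row$q3, row$max),
               c(1, 2, 3, 4, 5))
  expect_equal(row$n, 5L)
  empty <- s[s$class == "enhancer", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median))
  one <- class_summary(data.frame(log2_ratio = 2.5, class = "genic"))
  row1 <- one[one$class == "genic", ]
  expect_true(all(unlist(row1[, c("min", "q1", "median", "q3", "max")]) == 2.5))
})

test_that("generated enrichment is recovered after normalization", {
  ann <- synthetic_annotation(length = 2e5, seed = 6)
  arrays <- simulate_probe_arrays(ann, n_arrays = 3,
                                  enrichment_by_class = c(active_tss = 1.5),
                                  probe_spacing = 100, noise_sd = 0.3,
                                  seed = 7)
  norm <- normalize_arrays(arrays)
  labelled <- classify_probes(norm[[1]], ann)
  s <- class_summary(labelled)
  med_tss <- s$median[s$class == "active_tss"]
  med_int <- s$median[s$class == "intergenic"]
  expect_gt(med_tss, med_int + 0.5)
})

test_that("metagene profile bins, orients by strand and smooths mildly", {
  tss <- data.frame(chrom = "chrT", position = c(50000, 120000),
                    strand = c("+", "-"))
  # constant signal: profile must be flat at that constant
  pos <- seq(0, 2e5, by = 500)
  vals <- data.frame(chrom = "chrT", pos = pos, value = 3)
  prof <- metagene_profile(vals, tss)
  expect_equal(nrow(prof), 30)
  expect_equal(prof$mean, rep(3, 30))
  expect_equal(prof$smoothed, rep(3, 30), tolerance = 1e-9)
  # a peak at the TSS shows up in the central bins
  peak <- data.frame(chrom = "chrT", pos = pos,
                     value = 1 + 5 * exp(-((pos - 50000) / 800)^2) +
                       5 * exp(-((pos - 120000) / 800)^2))
  prof2 <- metagene_profile(peak, tss)
  expect_true(which.max(prof2$mean) %in% 15:16)
  # strand orientation: signal only upstream of a minus-strand TSS
  up_minus <- data.frame(chrom = "chrT", pos = seq(120500, 125000, 500),
                         value = 10)
  prof3 <- metagene_profile(up_minus, data.frame(chrom = "chrT",
                                                 position = 120000,
                                                 strand = "-"))
  expect_true(all(which(!is.na(prof3$mean) & prof3$mean > 0) <= 15))
  expect_error(metagene_profile(vals, tss, half_window = 15500, bin = 1000),
               "multiple")
})

test_that("TSS window read counts use the half-open 2-kb window", {
  tss <- data.frame(chrom = "chrT", position = 5000, strand = "+")
  reads <- data.frame(chrom = "chrT",
                      pos = c(5000, 4000, 5999, 6000, 3999, 7000))
  out <- count_tss_window(reads, tss)
  # 5000 (at TSS), 4000 (left edge, included) and 5999 count;
  # 6000 (right edge) and 3999 are excluded
  expect_equal(out$count, 3)
  # uniform reads at density d: expectation 2000 * d, Poisson-checked
  set.seed(8)
  n <- 20000
  unif <- data.frame(chrom = "chrT", pos = round(runif(n, 0, 1e5)))
  cnt <- count_tss_window(unif, data.frame(chrom = "chrT", position = 50000,
                                           strand = "+"))$count
  lambda <- 2000 * n / 1e5
  ci <- qpois(c(1e-5, 1 - 1e-5), lambda)
  expect_true(cnt >= ci[1] && cnt <= ci[2])
})
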