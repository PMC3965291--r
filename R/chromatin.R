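#' Genomic region annotation for probe classification
#'
#' Interval universe defining the region classes used to summarise
#' tiling-array enrichment: transcription start sites with an
#' active/inactive call, enhancer intervals with an activity class (from
#' the two-mark rule: active = H3K4me1 + H3K27ac, inactive = H3K4me1
#' only; the calls are consumed as input, never recomputed), and gene
#' intervals with strand. All coordinates are 0-based half-open (BED
#' convention).
#'
#' @param tss `data.frame` (chrom, position, strand, activity) with
#'   activity in `c("active", "inactive")`.
#' @param enhancers `data.frame` (chrom, start, end, class) with class in
#'   `c("active", "inactive")`.
#' @param genes `data.frame` (chrom, start, end, strand).
#' @param seqlengths Named vector of chromosome lengths (bp).
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(tss, enhancers, genes, seqlengths) {
  stopifnot(all(c("chrom", "position", "strand", "activity") %in% names(tss)),
            all(c("chrom", "start", "end", "class") %in% names(enhancers)),
            all(c("chrom", "start", "end", "strand") %in% names(genes)))
  if (!all(tss$activity %in% c("active", "inactive")))
    stop("region_annotation: TSS activity must be 'active' or 'inactive'")
  if (!all(enhancers$class %in% c("active", "inactive")))
    stop("region_annotation: enhancer class must be 'active' or 'inactive'")
  if (any(enhancers$start >= enhancers$end) || any(genes$start >= genes$end))
    stop("region_annotation: intervals must satisfy start < end")
  for (d in list(tss["chrom"], enhancers["chrom"], genes["chrom"]))
    if (!all(d$chrom %in% names(seqlengths)))
      stop("region_annotation: chromosome missing from seqlengths")
  structure(list(tss = tss, enhancers = enhancers, genes = genes,
                 seqlengths = seqlengths),
            class = "region_annotation")
}

## data.frame (chrom, start, end), 0-based half-open -> GRanges
df_to_granges <- function(d) {
  GenomicRanges::GRanges(d$chrom,
                         IRanges::IRanges(start = d$start + 1L, end = d$end))
}

#' Normalize tiling arrays to median 0 and a common MAD
#'
#' Each array's log2 ratios are median-centred and rescaled so that all
#' arrays share one median absolute deviation (the mean of the input
#' per-array MADs by default). After normalization every array has median
#' exactly 0 and the common MAD; the operation is idempotent and removes
#' any per-array affine distortion.
#'
#' @param arrays List of probe `data.frame`s, each with a `log2_ratio`
#'   column and at least 2 probes.
#' @param target_mad Common MAD after scaling; default the mean of the
#'   per-array MADs.
#' @return List of normalized probe tables (same shapes).
#' @export
normalize_arrays <- function(arrays, target_mad = NULL) {
  if (length(arrays) < 1) stop("normalize_arrays: need at least one array")
  stopifnot(all(vapply(arrays, function(a) "log2_ratio" %in% names(a), TRUE)))
  if (any(vapply(arrays, nrow, 0L) < 2))
    stop("normalize_arrays: arrays need >= 2 probes")
  mads <- vapply(arrays, function(a) stats::mad(a$log2_ratio), 0)
  if (any(mads == 0)) stop("normalize_arrays: array with zero MAD")
  if (is.null(target_mad)) target_mad <- mean(mads)
  Map(function(a, m) {
    v <- (a$log2_ratio - stats::median(a$log2_ratio)) / m * target_mad
    ## rescaling can leave a sub-ulp residual median; recentre until the
    ## median is exactly zero
    for (i in 1:3) {
      res <- stats::median(v)
      if (res == 0) break
      v <- v - res
    }
    a$log2_ratio <- v
    a
  }, arrays, mads)
}

#' Classify probes into genomic region classes
#'
#' Assigns every probe exactly one label from `active_tss`,
#' `inactive_tss`, `enhancer`, `genic`, `intergenic`:
#' \itemize{
#'   \item TSS classes: probe overlaps the 2-kb window (+/- 1 kb,
#'     half-open `[TSS-1000, TSS+1000)`) around a TSS of that activity;
#'   \item enhancer: probe overlaps an annotated enhancer interval;
#'   \item genic: probe overlaps a gene body **excluding its first
#'     1000 bp** (strand-aware), to avoid promoter overlap;
#'   \item intergenic: everything else.
#' }
#' Classes are mutually exclusive with priority
#' TSS > enhancer > genic > intergenic (configurable); a probe matching
#' both an active and an inactive TSS window is called `active_tss`.
#' Overlap means any shared base. Probes on chromosomes absent from the
#' annotation become `intergenic` with a warning.
#'
#' @param probes `data.frame` (chrom, start, end, ...), 0-based
#'   half-open.
#' @param ann A [region_annotation()].
#' @param priority Character vector ordering
#'   `c("tss", "enhancer", "genic")` by decreasing precedence.
#' @return `probes` with a `class` column appended.
#' @export
classify_probes <- function(probes, ann,
                            priority = c("tss", "enhancer", "genic")) {
  stopifnot(inherits(ann, "region_annotation"))
  if (any(probes$start >= probes$end))
    stop("classify_probes: probe intervals must satisfy start < end")
  priority <- match.arg(priority, c("tss", "enhancer", "genic"),
                        several.ok = TRUE)
  if (length(priority) != 3) stop("classify_probes: priority must order all 3")
  known <- names(ann$seqlengths)
  if (!all(probes$chrom %in% known))
    warning("classify_probes: probes on chromosomes absent from the ",
            "annotation are classified intergenic")
  gp <- df_to_granges(probes)

  hit <- function(regions) {
    if (nrow(regions) == 0) return(rep(FALSE, nrow(probes)))
    ## disjoint sequence levels (unknown probe chromosomes) are expected
    ## here and handled below; silence the GRanges notice
    suppressWarnings(
      GenomicRanges::countOverlaps(gp, df_to_granges(regions)) > 0)
  }
  tss_win <- function(activity) {
    t <- ann$tss[ann$tss$activity == activity, , drop = FALSE]
    data.frame(chrom = t$chrom, start = t$position - 1000,
               end = t$position + 1000)
  }
  genic_body <- function() {
    g <- ann$genes
    start <- ifelse(g$strand == "-", g$start, g$start + 1000)
    end <- ifelse(g$strand == "-", g$end - 1000, g$end)
    keep <- start < end
    data.frame(chrom = g$chrom[keep], start = start[keep], end = end[keep])
  }

  cls <- rep("intergenic", nrow(probes))
  layers <- list(
    tss = function(free) {
      act <- hit(tss_win("active")); inact <- hit(tss_win("inactive"))
      cls[free & act] <<- "active_tss"
      cls[free & !act & inact] <<- "inactive_tss"
    },
    enhancer = function(free)
      cls[free & hit(ann$enhancers)] <<- "enhancer",
    genic = function(free)
      cls[free & hit(genic_body())] <<- "genic")
  for (layer in priority) {
    layers[[layer]](cls == "intergenic")
  }
  cls[!(probes$chrom %in% known)] <- "intergenic"
  probes$class <- cls
  probes
}

#' Five-number summary of probe values per region class
#'
#' One row per class with min, lower quartile, median, upper quartile,
#' max (linear-interpolation quartiles, `quantile` type 7) and the probe
#' count; classes without probes get an `n = 0` row of `NA`s. This is
#' the table behind per-class enrichment boxplots.
#'
#' @param probes `data.frame` with `log2_ratio` and `class` columns (see
#'   [classify_probes()]).
#' @param classes Class universe to report (default the five standard
#'   classes).
#' @return `data.frame` (class, min, q1, median, q3, max, n).
#' @export
class_summary <- function(probes,
                          classes = c("active_tss", "inactive_tss",
                                      "enhancer", "genic", "intergenic")) {
  stopifnot(all(c("log2_ratio", "class") %in% names(probes)))
  rows <- lapply(classes, function(cl) {
    v <- probes$log2_ratio[probes$class == cl]
    if (length(v) == 0)
      return(data.frame(class = cl, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_,
                        n = 0L))
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    data.frame(class = cl, min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5], n = length(v))
  })
  do.call(rbind, rows)
}

#' Metagene signal profile around TSSs
#'
#' Positioned signal (probe ratios at probe midpoints, or read densities)
#' is assigned to fixed-width bins relative to each TSS
#' (strand-oriented, upstream negative, half-open
#' `[TSS - half_window, TSS + half_window)`), averaged across all
#' TSS-signal pairs per bin, and mildly smoothed with `lowess`
#' (default `f = 0.05`). The default +/- 15 kb window with 1-kb bins
#' yields 30 bins.
#'
#' @param values `data.frame` (chrom, pos, value): signal value at a
#'   genomic position.
#' @param tss TSS table (chrom, position, strand) or a
#'   [region_annotation()] (its `$tss` is used). Must be non-empty.
#' @param half_window Half window, bp; must be a multiple of `bin`.
#' @param bin Bin width, bp.
#' @param smooth_f `lowess` smoother span.
#' @return `data.frame` (offset = bin-centre offset from the TSS, mean,
#'   smoothed, n).
#' @export
metagene_profile <- function(values, tss, half_window = 15000, bin = 1000,
                             smooth_f = 0.05) {
  if (inherits(tss, "region_annotation")) tss <- tss$tss
  if (nrow(tss) == 0) stop("metagene_profile: no TSSs")
  if (half_window %% bin != 0)
    stop("metagene_profile: half_window must be a multiple of bin")
  nb <- 2L * half_window / bin
  acc_sum <- numeric(nb); acc_n <- numeric(nb)
  for (i in seq_len(nrow(tss))) {
    on_chr <- values$chrom == tss$chrom[i]
    rel <- values$pos[on_chr] - tss$position[i]
    if (tss$strand[i] == "-") rel <- -rel
    inside <- rel >= -half_window & rel < half_window
    b <- floor((rel[inside] + half_window) / bin) + 1L
    if (length(b)) {
      agg <- rowsum(values$value[on_chr][inside], b)
      add <- numeric(nb)
      add[as.integer(rownames(agg))] <- agg[, 1]
      acc_sum <- acc_sum + add
      acc_n <- acc_n + tabulate(b, nbins = nb)
    }
  }
  m <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  offset <- seq(-half_window + bin / 2, half_window - bin / 2, by = bin)
  ok <- !is.na(m)
  smoothed <- m
  if (sum(ok) >= 2)
    smoothed[ok] <- stats::lowess(offset[ok], m[ok], f = smooth_f)$y
  data.frame(offset = offset, mean = m, smoothed = smoothed, n = acc_n)
}

#' Count reads in a fixed window centred on each TSS
#'
#' Raw (unnormalized) counts of read positions in the half-open window
#' `[TSS - window/2, TSS + window/2)` per TSS; default a 2-kb window.
#'
#' @param reads `data.frame` (chrom, pos): single positions, e.g. read 5'
#'   ends.
#' @param tss TSS table (chrom, position, ...) or a
#'   [region_annotation()].
#' @param window Window width, bp.
#' @return `tss` with a `count` column appended.
#' @export
count_tss_window <- function(reads, tss, window = 2000) {
  if (inherits(tss, "region_annotation")) tss <- tss$tss
  half <- window / 2
  out <- tss
  out$count <- vapply(seq_len(nrow(tss)), function(i) {
    p <- reads$pos[reads$chrom == tss$chrom[i]]
    sum(p >= tss$position[i] - half & p < tss$position[i] + half)
  }, 0)
  out
}
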