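#' Per-lane nucleosome assembly efficiency
#'
#' Efficiency of competitive nucleosome reconstitution, per lane:
#' the nucleosome band as a fraction of total lane signal,
#' `I_nuc / (I_nuc + I_free)`.
#'
#' @param lanes Long densitometry table with columns `lane`, `condition`,
#'   `batch`, `band`, `intensity`; every lane must carry `nucleosome` and
#'   `free_dna` bands.
#' @return `data.frame` (lane, condition, batch, efficiency), one row per
#'   lane, efficiency in `[0, 1]`.
#' @export
assembly_efficiency <- function(lanes) {
  need <- c("lane", "condition", "batch", "band", "intensity")
  if (!all(need %in% names(lanes)))
    stop("assembly_efficiency: table needs columns ",
         paste(need, collapse = ", "))
  if (any(lanes$intensity < 0)) stop("assembly_efficiency: negative intensity")
  get_band <- function(b) {
    sub <- lanes[lanes$band == b, ]
    stats::setNames(sub$intensity, sub$lane)
  }
  nuc <- get_band("nucleosome"); free <- get_band("free_dna")
  ids <- unique(lanes$lane)
  if (!all(as.character(ids) %in% names(nuc)) ||
      !all(as.character(ids) %in% names(free)))
    stop("assembly_efficiency: every lane needs nucleosome and free_dna bands")
  nuc <- nuc[as.character(ids)]; free <- free[as.character(ids)]
  tot <- nuc + free
  if (any(tot == 0)) stop("assembly_efficiency: lane with both bands zero")
  meta <- unique(lanes[, c("lane", "condition", "batch")])
  meta <- meta[match(ids, meta$lane), ]
  data.frame(lane = ids, condition = meta$condition, batch = meta$batch,
             efficiency = unname(nuc / tot), row.names = NULL)
}

#' Per-batch reference normalization of assembly efficiencies
#'
#' Within each batch, every lane's efficiency is divided by the mean
#' efficiency of the reference-condition lanes of that batch, so the
#' per-batch mean of normalized reference efficiencies is exactly 1.0.
#' This removes batch-to-batch scaling (different gels, exposures).
#'
#' @param efficiencies `data.frame` from [assembly_efficiency()]
#'   (columns `lane`, `condition`, `batch`, `efficiency`).
#' @param reference_condition Condition label defining 1.0 (default
#'   `"unmodified"`). Every batch must contain at least one such lane.
#' @return The input with a `normalized` column appended. Idempotent when
#'   re-applied to the `normalized` values.
#' @export
normalize_batch <- function(efficiencies, reference_condition = "unmodified") {
  stopifnot(all(c("condition", "batch", "efficiency") %in% names(efficiencies)))
  out <- efficiencies
  out$normalized <- NA_real_
  for (b in unique(out$batch)) {
    in_b <- out$batch == b
    ref <- out$efficiency[in_b & out$condition == reference_condition]
    if (length(ref) == 0)
      stop("normalize_batch: batch ", b, " has no '", reference_condition,
           "' lane")
    out$normalized[in_b] <- out$efficiency[in_b] / mean(ref)
  }
  out
}

#' Fit an exponential remodelling time course
#'
#' Least-squares fit of `y(t) = a * (1 - exp(-b * t))` to the fraction of
#' nucleosomes repositioned over time; the initial rate is the derivative
#' at zero time, `a * b` (min^-1).
#'
#' @param times Sampling times, minutes (at least 4, including `t = 0`).
#' @param fractions Parallel normalized repositioned fractions.
#' @param init Optional starting values, named list with `a` and `b`.
#' @return An object of class `exp_fit`: list with `a`, `b`,
#'   `initial_rate` (`= a * b`), `residual_rms`, `converged`. An
#'   essentially flat, zero time course is returned with
#'   `converged = FALSE` and `a = 0`.
#' @export
fit_remodelling <- function(times, fractions, init = NULL) {
  if (length(times) != length(fractions))
    stop("fit_remodelling: times and fractions must be parallel")
  if (length(times) < 4) stop("fit_remodelling: need >= 4 timepoints")
  if (!any(times == 0)) stop("fit_remodelling: t = 0 point required")
  d <- data.frame(t = times, y = fractions)
  if (max(abs(d$y)) < 1e-12)
    return(structure(list(a = 0, b = NA_real_, initial_rate = NA_real_,
                          residual_rms = 0, converged = FALSE),
                     class = "exp_fit"))
  if (is.null(init)) {
    a0 <- max(d$y)
    pos <- d[d$t > 0 & d$y > 0 & d$y < a0, ]
    b0 <- if (nrow(pos)) max(-log(1 - pos$y[1] / a0) / pos$t[1], 1e-3) else 0.1
    init <- list(a = a0, b = b0)
  }
  resid_fn <- function(p) d$y - p[1] * (1 - exp(-p[2] * d$t))
  fit <- lm_least_squares(resid_fn, start = init[c("a", "b")],
                          lower = c(0, 1e-9))
  if (is.null(fit))
    return(structure(list(a = NA_real_, b = NA_real_,
                          initial_rate = NA_real_, residual_rms = NA_real_,
                          converged = FALSE), class = "exp_fit"))
  cf <- fit$par
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 initial_rate = unname(cf["a"] * cf["b"]),
                 residual_rms = fit$rms,
                 converged = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) { cat("exponential fit: FAILED/degenerate\n") }
  else cat(sprintf(
    "exponential fit: a = %.4g, b = %.4g /min, initial rate = %.4g /min\n",
    x$a, x$b, x$initial_rate))
  invisible(x)
}

#' Generic band ratio (signal over loading control)
#'
#' `signal / control` per lane; with a reference lane, ratios are
#' additionally reported relative to the reference lane's ratio.
#'
#' @param lanes Long densitometry table (columns `lane`, `band`,
#'   `intensity`).
#' @param signal,control Band names of the signal and the loading
#'   control; the control intensity must be positive in every lane.
#' @param reference_lane Optional lane id whose ratio defines 1.0 for the
#'   `relative` column.
#' @return `data.frame` (lane, ratio[, relative]).
#' @export
band_ratio <- function(lanes, signal = "signal", control = "loading",
                       reference_lane = NULL) {
  stopifnot(all(c("lane", "band", "intensity") %in% names(lanes)))
  ids <- unique(lanes$lane)
  pick <- function(b) {
    sub <- lanes[lanes$band == b, ]
    if (!all(as.character(ids) %in% as.character(sub$lane)))
      stop("band_ratio: band '", b, "' missing from some lane")
    sub$intensity[match(ids, sub$lane)]
  }
  sig <- pick(signal); ctl <- pick(control)
  if (any(ctl <= 0)) stop("band_ratio: zero control intensity")
  out <- data.frame(lane = ids, ratio = sig / ctl)
  if (!is.null(reference_lane)) {
    ref <- out$ratio[match(reference_lane, out$lane)]
    if (is.na(ref) || ref == 0) stop("band_ratio: invalid reference lane")
    out$relative <- out$ratio / ref
  }
  out
}
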