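#' A salt-titration response curve
#'
#' Response (quenched-fluorescence signal or intact fraction) versus NaCl
#' concentration for one species/replicate. Points are sorted by salt on
#' ingestion.
#'
#' @param salts NaCl concentrations, M.
#' @param responses Parallel response values.
#' @param species Species label.
#' @param replicate Replicate identifier.
#' @param normalized Logical flag; set by [normalize_curve()].
#' @param se Optional per-point standard errors (set by
#'   [average_replicates()]).
#' @return A `data.frame` of class `titration_curve` with columns `salt`,
#'   `response` (and `se` when given), plus `species`, `replicate` and
#'   `normalized` attributes.
#' @export
titration_curve <- function(salts, responses, species = NA_character_,
                            replicate = NA, normalized = FALSE, se = NULL) {
  if (length(salts) != length(responses))
    stop("titration_curve: salts and responses must have equal length")
  o <- order(salts)
  out <- data.frame(salt = salts[o], response = responses[o])
  if (!is.null(se)) out$se <- se[o]
  attr(out, "species") <- species
  attr(out, "replicate") <- replicate
  attr(out, "normalized") <- normalized
  class(out) <- c("titration_curve", "data.frame")
  out
}

sigmoid_response <- function(c, a1, a2, c05, dc) {
  a2 + (a1 - a2) / (1 + exp((c - c05) / dc))
}

## Bounded Levenberg-Marquardt least squares via minpack.lm::nls.lm, with
## standard errors from the Jacobian at the optimum. Robust to
## zero-residual (noiseless) data, which the nls-object wrappers reject.
lm_least_squares <- function(residual_fn, start, lower, upper = NULL) {
  out <- minpack.lm::nls.lm(
    unlist(start), fn = residual_fn,
    lower = lower, upper = upper %||% rep(Inf, length(start)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(out$info %in% 1:4)) return(NULL)
  par <- out$par
  n <- length(out$fvec); p <- length(par)
  sigma2 <- sum(out$fvec^2) / max(n - p, 1)
  se <- tryCatch(sqrt(pmax(diag(sigma2 * solve(out$hessian)), 0)),
                 error = function(e) rep(NA_real_, p))
  list(par = stats::setNames(par, names(start)),
       se = stats::setNames(se, names(start)),
       rms = sqrt(mean(out$fvec^2)))
}

#' Fit the salt-stability sigmoid
#'
#' Least-squares fit of
#' \deqn{resp(C) = A_2 + (A_1 - A_2) / (1 + e^{(C - C_{0.5})/dC}),}
#' where `A1` is the plateau approached at low salt, `A2` the plateau at
#' high salt, `C0.5` the midpoint and `dC` (> 0) the transition width.
#' The curve passes through `(A1 + A2) / 2` at `C = C0.5` by
#' construction. Works for increasing (quenched-fluorescence) and
#' decreasing (intact-fraction) curves alike; for decreasing curves
#' `a1 > a2`.
#'
#' @param curve A [titration_curve()] (or data.frame with `salt`,
#'   `response`). At least 5 points spanning the transition are
#'   recommended (a warning is emitted below 5).
#' @param init Optional named list/vector with starting values `a1`,
#'   `a2`, `c05`, `dc`. Default: endpoints for the plateaus, the salt
#'   whose response is closest to mid-range for `c05`, a tenth of the
#'   salt span for `dc`.
#' @return An object of class `sigmoid_fit`: list with `a1`, `a2`, `c05`,
#'   `dc`, `se_c05`, `residual_rms`, `converged`. Degenerate (constant)
#'   responses give a flagged failure (`converged = FALSE`, `NA`
#'   parameters), never fabricated values.
#' @export
fit_sigmoid <- function(curve, init = NULL) {
  d <- data.frame(salt = curve$salt, response = curve$response)
  d <- d[order(d$salt), ]
  if (nrow(d) < 4) stop("fit_sigmoid: need at least 4 points")
  if (nrow(d) < 5) warning("fit_sigmoid: fewer than 5 points")
  failed <- structure(list(a1 = NA_real_, a2 = NA_real_, c05 = NA_real_,
                           dc = NA_real_, se_c05 = NA_real_,
                           residual_rms = NA_real_, converged = FALSE),
                      class = "sigmoid_fit")
  if (stats::sd(d$response) < 1e-12) return(failed)
  if (is.null(init)) {
    a1 <- d$response[1]
    a2 <- d$response[nrow(d)]
    mid <- (a1 + a2) / 2
    c05 <- d$salt[which.min(abs(d$response - mid))]
    dc <- diff(range(d$salt)) / 10
    init <- list(a1 = a1, a2 = a2, c05 = c05, dc = dc)
  }
  resid_fn <- function(p)
    d$response - sigmoid_response(d$salt, p[1], p[2], p[3], p[4])
  fit <- lm_least_squares(resid_fn,
                          start = init[c("a1", "a2", "c05", "dc")],
                          lower = c(-Inf, -Inf, -Inf, 1e-6))
  if (is.null(fit)) return(failed)
  cf <- fit$par
  structure(list(a1 = unname(cf["a1"]), a2 = unname(cf["a2"]),
                 c05 = unname(cf["c05"]), dc = unname(cf["dc"]),
                 se_c05 = unname(fit$se["c05"]),
                 residual_rms = fit$rms,
                 converged = TRUE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) { cat("sigmoid fit: FAILED\n"); return(invisible(x)) }
  cat(sprintf("sigmoid fit: A1 = %.4g, A2 = %.4g, C0.5 = %.4g M (s.e. %.2g), dC = %.4g M\n",
              x$a1, x$a2, x$c05, x$se_c05, x$dc))
  invisible(x)
}

#' Predict responses from a sigmoid fit
#'
#' @param object A `sigmoid_fit`.
#' @param salts NaCl concentrations at which to evaluate the fitted curve.
#' @param ... Ignored.
#' @return Fitted responses.
#' @export
predict.sigmoid_fit <- function(object, salts, ...) {
  if (!object$converged) stop("predict.sigmoid_fit: failed fit")
  sigmoid_response(salts, object$a1, object$a2, object$c05, object$dc)
}

#' Normalize a titration curve using its fitted plateaus
#'
#' Maps the response scale so the fitted `A1` plateau becomes 0 and `A2`
#' becomes 1: `(response - A1) / (A2 - A1)`. For decreasing
#' (intact-fraction-like) curves where `a1 > a2` this yields the
#' conventional 1-to-0 disruption scale read in the opposite direction;
#' the normalized curve always passes 0.5 at `C0.5`.
#'
#' @param raw The [titration_curve()] the fit came from.
#' @param fit A converged [fit_sigmoid()] result for `raw`.
#' @return A normalized [titration_curve()].
#' @export
normalize_curve <- function(raw, fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) stop("normalize_curve: failed fit")
  span <- fit$a2 - fit$a1
  if (abs(span) < 1e-9 * max(abs(c(fit$a1, fit$a2, 1))))
    stop("normalize_curve: plateaus coincide (A2 ~ A1)")
  titration_curve(raw$salt, (raw$response - fit$a1) / span,
                  species = attr(raw, "species"),
                  replicate = attr(raw, "replicate"),
                  normalized = TRUE)
}

#' Average replicate titration curves pointwise
#'
#' Requires identical salt grids across replicates (no interpolation);
#' returns the pointwise mean and standard error (`sd / sqrt(n)`).
#'
#' @param curves List of [titration_curve()] objects on one salt grid.
#' @return A [titration_curve()] with an `se` column (`NA` for a single
#'   replicate).
#' @export
average_replicates <- function(curves) {
  stopifnot(length(curves) >= 1)
  grids <- lapply(curves, `[[`, "salt")
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])), TRUE)))
    stop("average_replicates: salt grids differ; interpolation is refused")
  resp <- do.call(cbind, lapply(curves, `[[`, "response"))
  n <- ncol(resp)
  se <- if (n >= 2) apply(resp, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, nrow(resp))
  titration_curve(grids[[1]], rowMeans(resp),
                  species = attr(curves[[1]], "species"),
                  replicate = "mean",
                  normalized = isTRUE(attr(curves[[1]], "normalized")),
                  se = se)
}

#' Normalize per-salt intact fractions to the zero-salt value
#'
#' Divides every fraction by the fraction measured at 0 M NaCl (which
#' becomes exactly 1), the convention used to compare smFRET
#' intact-fraction series between species. By default an exact 0 M entry
#' is required; `reference = "lowest"` relaxes this to the lowest salt
#' present.
#'
#' @param series `data.frame` with columns `salt` and `fraction` (e.g.
#'   from [intact_fraction_series()]).
#' @param reference `"zero"` (default) or `"lowest"`.
#' @return The series with `fraction` rescaled.
#' @export
normalize_to_zero_salt <- function(series, reference = c("zero", "lowest")) {
  reference <- match.arg(reference)
  if (nrow(series) == 0) stop("normalize_to_zero_salt: empty series")
  if (reference == "zero") {
    ref_rows <- which(series$salt == 0)
    if (length(ref_rows) == 0)
      stop("normalize_to_zero_salt: no 0 M entry (use reference = 'lowest')")
  } else {
    ref_rows <- which(series$salt == min(series$salt))
  }
  ref <- mean(series$fraction[ref_rows])
  if (!is.finite(ref) || ref <= 0)
    stop("normalize_to_zero_salt: reference fraction is zero or undefined")
  series$fraction <- series$fraction / ref
  series
}

#' Difference between two salt-stability midpoints
#'
#' `(c05_a - c05_b) * 1000`, reported in mM, with the standard error
#' propagated as the root sum of squares of the per-fit midpoint errors.
#'
#' @param fit_a,fit_b Converged [fit_sigmoid()] results.
#' @return List with `delta_mM` and `se_mM`.
#' @export
delta_c05 <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "sigmoid_fit"), inherits(fit_b, "sigmoid_fit"))
  if (!fit_a$converged || !fit_b$converged)
    stop("delta_c05: input fit failed")
  list(delta_mM = (fit_a$c05 - fit_b$c05) * 1000,
       se_mM = sqrt(fit_a$se_c05^2 + fit_b$se_c05^2) * 1000)
}
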