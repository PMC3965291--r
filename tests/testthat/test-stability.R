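make_curve <- function(a1, a2, c05, dc, salts = seq(0, 2, by = 0.1),
                       noise = 0, seed = 1) {
  set.seed(seed)
  titration_curve(salts, a2 + (a1 - a2) / (1 + exp((salts - c05) / dc)) +
                    rnorm(length(salts), 0, noise))
}

test_that("noiseless sigmoid parameters are recovered to high precision", {
  cur <- make_curve(0.1, 0.9, 0.7, 0.08)
  fit <- fit_sigmoid(cur)
  expect_true(fit$converged)
  expect_equal(fit$a1, 0.1, tolerance = 1e-6)
  expect_equal(fit$a2, 0.9, tolerance = 1e-6)
  expect_equal(fit$c05, 0.7, tolerance = 1e-6)
  expect_equal(fit$dc, 0.08, tolerance = 1e-6)
  # decreasing (intact-fraction-like) curve: a1 > a2, same machinery
  dec <- make_curve(1, 0, 0.55, 0.08, salts = seq(0, 1, by = 0.1))
  fd <- fit_sigmoid(dec)
  expect_equal(fd$c05, 0.55, tolerance = 1e-6)
  expect_gt(fd$a1, fd$a2)
  expect_gt(fd$dc, 0)
})

test_that("the fitted curve passes (A1+A2)/2 at C = C0.5", {
  fit <- fit_sigmoid(make_curve(0.15, 0.85, 0.6, 0.1))
  expect_equal(predict(fit, fit$c05), (fit$a1 + fit$a2) / 2)
})

test_that("fit is invariant to the salt order of the input", {
  cur <- make_curve(0.1, 0.9, 0.7, 0.08, noise = 0.02, seed = 3)
  rev_cur <- titration_curve(rev(cur$salt), rev(cur$response))
  f1 <- fit_sigmoid(cur); f2 <- fit_sigmoid(rev_cur)
  expect_equal(f1$c05, f2$c05)
  expect_equal(f1$a1, f2$a1)
})

test_that("degenerate constant data is a flagged failure", {
  flat <- titration_curve(seq(0, 1, by = 0.1), rep(0.5, 11))
  fit <- fit_sigmoid(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$c05))
  expect_error(delta_c05(fit, fit), "failed")
})

test_that("c05 is equivariant under salt shifts, invariant to resp scaling", {
  cur <- make_curve(0.1, 0.9, 0.7, 0.08, noise = 0.01, seed = 5)
  f0 <- fit_sigmoid(cur)
  shifted <- titration_curve(cur$salt + 0.3, cur$response)
  expect_equal(fit_sigmoid(shifted)$c05, f0$c05 + 0.3, tolerance = 1e-6)
  scaled <- titration_curve(cur$salt, cur$response * 7)
  expect_equal(fit_sigmoid(scaled)$c05, f0$c05, tolerance = 1e-6)
})

test_that("plateau normalization maps A1 to 0, A2 to 1 and midpoint to 0.5", {
  cur <- make_curve(0.2, 0.8, 0.7, 0.08)
  fit <- fit_sigmoid(cur)
  norm <- normalize_curve(cur, fit)
  expect_true(attr(norm, "normalized"))
  # plateaus are asymptotic: the lowest/highest sampled salts sit within
  # a few 1e-4 of them for this dc
  expect_lt(abs(min(norm$response)), 1e-3)
  expect_lt(abs(max(norm$response) - 1), 1e-3)
  # round-trip: re-fitting the normalized curve gives plateaus 0 and 1
  refit <- fit_sigmoid(norm)
  expect_equal(refit$a1, 0, tolerance = 1e-5)
  expect_equal(refit$a2, 1, tolerance = 1e-5)
  expect_equal(predict(refit, refit$c05), 0.5, tolerance = 1e-6)
  # coincident plateaus are rejected
  bad <- fit
  bad$a2 <- bad$a1
  expect_error(normalize_curve(cur, bad), "plateau")
})

test_that("replicate averaging computes pointwise mean and s.e.", {
  c1 <- titration_curve(c(0, 1), c(0, 1))
  c2 <- titration_curve(c(0, 1), c(1, 0))
  avg <- average_replicates(list(c1, c2))
  expect_equal(avg$response, c(0.5, 0.5))
  expect_equal(avg$se, c(0.5, 0.5))   # sd/sqrt(2) = (sqrt(0.5)/sqrt(2)) ... = 0.5
  same <- average_replicates(list(c1, c1, c1))
  expect_equal(same$response, c1$response)
  expect_equal(same$se, c(0, 0))
  single <- average_replicates(list(c1))
  expect_equal(single$response, c1$response)
  expect_true(all(is.na(single$se)))
  c3 <- titration_curve(c(0, 2), c(0, 1))
  expect_error(average_replicates(list(c1, c3)), "grids")
})

test_that("zero-salt normalization rescales fractions to the 0 M value", {
  s <- data.frame(salt = c(0, 0.8), fraction = c(0.8, 0.4))
  out <- normalize_to_zero_salt(s)
  expect_equal(out$fraction, c(1, 0.5))
  all_eq <- data.frame(salt = c(0, 0.5, 1), fraction = rep(0.37, 3))
  expect_equal(normalize_to_zero_salt(all_eq)$fraction, rep(1, 3))
  expect_error(normalize_to_zero_salt(
    data.frame(salt = c(0, 1), fraction = c(0, 0.5))), "zero")
  expect_error(normalize_to_zero_salt(
    data.frame(salt = c(0.1, 1), fraction = c(1, 0.5))), "0 M")
  low <- normalize_to_zero_salt(data.frame(salt = c(0.1, 1),
                                           fraction = c(0.8, 0.4)),
                                reference = "lowest")
  expect_equal(low$fraction, c(1, 0.5))
})

test_that("midpoint differences are reported in mM with propagated s.e.", {
  fa <- fit_sigmoid(make_curve(0.1, 0.9, 0.70, 0.08))
  fb <- fit_sigmoid(make_curve(0.1, 0.9, 0.64, 0.08))
  d <- delta_c05(fa, fb)
  expect_equal(d$delta_mM, 60, tolerance = 1e-3)
  expect_equal(delta_c05(fa, fa)$delta_mM, 0)
})

test_that("propagated s.e. of the midpoint difference matches a bootstrap", {
  salts <- seq(0, 1.6, by = 0.1)
  noise <- 0.03
  fit_once <- function(seed_a, seed_b) {
    fa <- fit_sigmoid(make_curve(0.1, 0.9, 0.70, 0.08, salts, noise, seed_a))
    fb <- fit_sigmoid(make_curve(0.1, 0.9, 0.64, 0.08, salts, noise, seed_b))
    c(delta = delta_c05(fa, fb)$delta_mM, se = delta_c05(fa, fb)$se_mM)
  }
  one <- fit_once(1, 2)
  boot <- vapply(1:100, function(i) fit_once(100 + i, 200 + i)["delta"], 0)
  # analytic propagation vs the spread of independent re-simulations
  expect_lt(abs(one[["se"]] - sd(boot)) / sd(boot), 0.2)
})
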