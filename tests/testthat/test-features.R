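test_that("time to peak and recovery match a constructed response", {
  t <- seq(0, 10, by = 0.01)
  # triangular |dJ|: rises to 2 at t = 3, back to 0 at t = 6
  dJ <- -pmax(0, 2 - abs(t - 3) * (2 / 3))
  r <- fake_response(t, dJ)
  expect_equal(time_to_peak(r), 3)
  expect_equal(peak_amplitude(r), 2)
  # 1% of peak = 0.02, crossed at |t-3| = 2.97 (within one grid step)
  expect_equal(recovery_time(r), 5.97, tolerance = 2.5e-3)
})

test_that("recovery handles unrecovered and flat responses", {
  t <- seq(0, 5, by = 0.1)
  lingering <- fake_response(t, -exp(-t / 50))
  out <- recovery_time(lingering)
  expect_true(is.na(out))
  expect_false(attr(out, "recovered"))
  expect_equal(attr(out, "window"), 5)
  flat <- fake_response(t, rep(0, length(t)))
  expect_equal(recovery_time(flat), 0)
  expect_error(time_to_peak(flat), "flat")
})

test_that("recovery requires staying below the tolerance band", {
  t <- seq(0, 10, by = 0.1)
  dJ <- -ifelse(t < 2, t / 2, ifelse(t < 4, (4 - t) / 2,
                ifelse(t < 6, 0.002, ifelse(t < 7, 0.5, 0.001))))
  r <- fake_response(t, dJ)
  # the dip at t in [4,6) does not count: the response rebounds at t = 6
  expect_gte(recovery_time(r), 7)
})

test_that("normalized stimulus-response curves peak at 1 and keep order", {
  t <- seq(0, 5, by = 0.01)
  fam <- lapply(c(1, 10, 100), function(i)
    fake_response(t, -i / (i + 20) * sin(pmin(t, pi)), intensity = i))
  curve <- normalize_family(fam)
  expect_equal(max(curve$amplitude), 1)
  expect_true(all(diff(curve$amplitude) > 0))
  expect_equal(curve$intensity, c(1, 10, 100))
  expect_error(normalize_family(fam[c(1, 1)]), "duplicate")
})

test_that("half-maximal intensity recovers a planted I0", {
  i0 <- 42
  intens <- 10^seq(-1, 4, length.out = 12)
  set.seed(4)
  # small noise: an exact hyperbola defeats nls's relative-offset
  # convergence criterion (zero-residual pathology)
  amp <- intens / (intens + i0) + rnorm(12, sd = 5e-4)
  curve <- structure(data.frame(intensity = intens, amplitude = amp),
                     class = c("stim_response_curve", "data.frame"))
  expect_equal(half_max_intensity(curve), i0, tolerance = 0.03)
  expect_equal(half_max_intensity(curve, method = "fit"), i0,
               tolerance = 0.01)
})

test_that("half-maximal intensity demands a bracketing family", {
  curve <- structure(data.frame(intensity = c(1000, 2000),
                                amplitude = c(0.9, 0.95)),
                     class = c("stim_response_curve", "data.frame"))
  expect_error(half_max_intensity(curve), "bracket")
})

test_that("flash families are spaced as requested", {
  fam <- gen_flash_family(5, 97000, 5)
  intens <- vapply(fam, `[[`, numeric(1), "intensity")
  expect_equal(intens[1], 5)
  expect_equal(intens[5], 97000)
  expect_equal(diff(log10(intens)), rep(log10(97000 / 5) / 4, 4))
  expect_length(gen_flash_family(5, 100, 1), 1)
  lin <- gen_flash_family(0, 10, 11, spacing = "linear")
  expect_equal(vapply(lin, `[[`, numeric(1), "intensity"), 0:10)
})

test_that("the linear toy variant matches its closed-form solution", {
  net <- gen_toy_cascade("linear")
  k1 <- net$parameters[["k1"]]
  k2 <- net$parameters[["k2"]]
  resp <- simulate_flash(net, flash_stimulus(100, duration = 0.01),
                         t_end = 20)
  # closed form from the state at pulse end (t = duration):
  # A(t) = A_d e^{-k2 s} + Rst_d k1/(k2-k1) (e^{-k1 s} - e^{-k2 s})
  i_d <- which.min(abs(resp$time - 0.01))
  s <- resp$time - resp$time[i_d]
  post <- s >= 0
  A_d <- resp$state[i_d, "A"]
  R_d <- resp$state[i_d, "Rst"]
  A_ref <- A_d * exp(-k2 * s[post]) +
    R_d * k1 / (k2 - k1) * (exp(-k1 * s[post]) - exp(-k2 * s[post]))
  expect_equal(unname(resp$dJ[post]), unname(-A_ref), tolerance = 1e-6)
})

test_that("doubling the GAP rate strictly speeds up recovery", {
  net <- toy_precoupled()
  fast <- scale_parameters(net, c(kRGS1 = 0.5))  # fold 0.5 = doubled
  stim <- flash_stimulus(50)
  r0 <- recovery_time(simulate_flash(net, stim, t_end = 40))
  r1 <- recovery_time(simulate_flash(fast, stim, t_end = 40))
  expect_false(is.na(r0))
  expect_false(is.na(r1))
  expect_lt(r1, r0)
})

test_that("response features summarize a family end to end", {
  feats <- response_features(wt_family())
  expect_s3_class(feats, "response_features")
  expect_true(is.finite(feats$I0))
  expect_gt(feats$I0, min(feats$curve$intensity))
  expect_lt(feats$I0, max(feats$curve$intensity))
  expect_equal(feats$time_to_peak,
               time_to_peak(wt_family()[[1]]))
  expect_equal(nrow(feats$per_flash), 7)
})
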