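test_that("sigmoid hits the midpoint and known closed-form values", {
  expect_equal(sigmoid_value(30, d50 = 30, slope = 7.5), 24)
  expect_equal(sigmoid_value(12, d50 = 12, slope = 3), 24)
  # 48 / (1 + e^{ln 3}) = 12
  expect_equal(sigmoid_value(30 + 7.5 * log(3), d50 = 30, slope = 7.5), 12)
  # upper plateau
  expect_equal(sigmoid_value(-1e6, d50 = 30, slope = 7.5), 48)
  expect_error(sigmoid_value(10, d50 = -1, slope = 5), "d50")
  expect_error(sigmoid_value(10, d50 = 30, slope = 0), "slope")
})

test_that("sigmoid is strictly decreasing and F(d50) = 24 across parameters", {
  set.seed(11)
  for (i in 1:25) {
    d50 <- runif(1, 8, 176)
    sl <- runif(1, 2, 40)
    expect_equal(sigmoid_value(d50, d50, sl), 24, tolerance = 1e-12)
    # sample within the numerically representable part of the decline
    t <- d50 + sl * sort(runif(50, -20, 20))
    expect_true(all(diff(sigmoid_value(t, d50, sl)) < 0))
  }
})

test_that("noiseless series recover parameters to relative 1e-4", {
  ctl <- d50_fit_control(anchor_onset = FALSE)
  f <- fit_d50(noiseless_series(30, 7.5, c(6, 12, 18, 24)), ctl)
  expect_true(f$converged)
  expect_equal(f$d50, 30, tolerance = 1e-4)
  expect_equal(f$slope, 7.5, tolerance = 1e-4)
  set.seed(21)
  for (i in 1:20) {
    d50 <- runif(1, 8, 176)
    sl <- runif(1, 2, 40)
    # observation times spanning the decline relative to the time-scale
    times <- pmax(d50 + sl * c(-2, -1, 0, 1, 2), 0.5)
    f <- fit_d50(noiseless_series(d50, sl, times), ctl)
    expect_lt(abs(f$d50 - d50) / d50, 1e-4)
    expect_lt(abs(f$slope - sl) / sl, 1e-4)
  }
})

test_that("a single observation at score 24 pins the midpoint", {
  # grid-search oracle over (d50, slope) for the anchored single-visit fit
  s <- alsfrs_series("p", 36.3, 24)
  oracle <- grid_fit_oracle(s, seq(30, 42, by = 0.05), seq(2, 20, by = 0.5))
  expect_equal(oracle$d50, 36.3, tolerance = 0.1)
  f <- fit_d50(s)
  expect_equal(f$d50, 36.3, tolerance = 0.1)
})

test_that("fitting degenerate plateau series raises, optimizer never silent", {
  s <- alsfrs_series("p", c(1, 4, 8), c(48, 48, 48))
  expect_error(fit_d50(s), "degenerate")
  # a declining series never errors
  f <- fit_d50(alsfrs_series("p", c(5, 20), c(45, 30)))
  expect_true(is.finite(f$rss))
  expect_type(f$converged, "logical")
})

test_that("descriptors at the midpoint and onset match the model identities", {
  f <- fit_d50(noiseless_series(30, 7.5, c(6, 12, 18, 24)),
               d50_fit_control(anchor_onset = FALSE))
  d_mid <- derive_descriptors(f, f$d50)
  expect_equal(d_mid$rd50, 0.5)
  expect_equal(d_mid$cfs, 24, tolerance = 1e-6)
  # cFL at the midpoint is 12/slope points per month
  expect_equal(d_mid$cfl, 12 / f$slope, tolerance = 1e-6)
  d0 <- derive_descriptors(f, 0)
  expect_equal(d0$rd50, 0)
  expect_error(derive_descriptors(f, -1), "t_ref")
})

test_that("cFL equals the negative analytic derivative (finite differences)", {
  set.seed(31)
  for (i in 1:100) {
    d50 <- runif(1, 8, 176)
    sl <- runif(1, 2, 40)
    t0 <- runif(1, 0.1, 2 * d50)
    fit <- structure(list(d50 = d50, slope = sl, max_score = 48),
                     class = "d50_fit")
    cfl <- derive_descriptors(fit, t0)$cfl
    h <- 1e-4
    fd <- -(sigmoid_value(t0 + h, d50, sl) -
              sigmoid_value(t0 - h, d50, sl)) / (2 * h)
    expect_equal(cfl, fd, tolerance = 1e-5)
    expect_gte(cfl, 0)
  }
})

test_that("rd50 is linear in t_ref with slope 1/(2 d50)", {
  fit <- structure(list(d50 = 42, slope = 9, max_score = 48),
                   class = "d50_fit")
  t <- c(0, 10, 42, 84)
  rd <- vapply(t, function(x) derive_descriptors(fit, x)$rd50, 0)
  expect_equal(rd, t / (2 * 42))
  expect_equal(rd[4], 1) # rd50(2 d50) = 1
})

test_that("phase assignment partitions [0, Inf) with half-open boundaries", {
  expect_equal(assign_phase(0.10), "I")
  expect_equal(assign_phase(0.25), "II")
  expect_equal(assign_phase(0.50), "III/IV")
  expect_equal(assign_phase(0), "I")
  expect_equal(assign_phase(0.25 - 1e-12), "I")
  expect_equal(assign_phase(0.5 - 1e-12), "II")
  expect_equal(assign_phase(3), "III/IV")
  expect_error(assign_phase(-0.1), "rd50")
  # exactly one phase for any rd50
  rd <- seq(0, 1.2, by = 0.001)
  ph <- assign_phase(rd)
  expect_true(all(ph %in% c("I", "II", "III/IV")))
  expect_equal(ph, ifelse(rd < 0.25, "I", ifelse(rd < 0.5, "II", "III/IV")))
})

test_that("aggressiveness cut at 30 months, boundary inclusive for low", {
  expect_equal(classify_aggressiveness(29.9), "high")
  expect_equal(classify_aggressiveness(30.0), "low")
  expect_equal(classify_aggressiveness(175.55), "low")
  expect_equal(classify_aggressiveness(8.07), "high")
  expect_error(classify_aggressiveness(0), "d50")
})

test_that("progression rate matches its linear-decline definition", {
  expect_equal(progression_rate(38, 20), 0.5)
  expect_equal(progression_rate(48, 7), 0)
  expect_equal(progression_rate(24, 36.3), 24 / 36.3)
  expect_error(progression_rate(30, 0), "t")
  expect_error(progression_rate(50, 10), "current_score")
})

test_that("series constructor enforces invariants and sorts observations", {
  expect_error(alsfrs_series("p", c(1, 2), c(49, 20)), "scores")
  expect_error(alsfrs_series("p", c(-1, 2), c(40, 20)), "times")
  s <- alsfrs_series("p", c(9, 3, 6), c(30, 44, 38))
  expect_equal(s$observations$t, c(3, 6, 9))
  expect_equal(s$observations$score, c(44, 38, 30))
})
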