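test_that("circuit equations and their analytic inverse are mutually exact", {
  est <- compartmentParams(exactFitObject(100, 400, 10, 10, -10))
  expect_equal(est@c1, 100); expect_equal(est@c2, 400)
  expect_equal(est@r1, 10); expect_equal(est@r2, 10)
  expect_equal(totalCapacitance(est), 500)

  # round trip across a 200-point parameter grid
  grid <- expand.grid(c1 = seq(5, 200, length.out = 5),
                      c2 = seq(100, 1000, length.out = 5),
                      r1 = seq(3, 15, length.out = 4),
                      r2 = seq(2, 20, length.out = 2))
  expect_equal(nrow(grid), 200L)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    est <- compartmentParams(exactFitObject(g$c1, g$c2, g$r1, g$r2, -10))
    expect_equal(c(est@c1, est@c2, est@r1, est@r2),
                 c(g$c1, g$c2, g$r1, g$r2), tolerance = 1e-9)
  }
})

test_that("compartment parameters are scale-invariant and guard degeneracies", {
  f1 <- exactFitObject(60, 300, 8, 12, -10)
  f2 <- new("TwoExponentialFit", a1 = 2 * f1@a1, tau1 = f1@tau1,
            a2 = 2 * f1@a2, tau2 = f1@tau2, iSS = f1@iSS,
            deltaV = 2 * f1@deltaV, rss = 0, converged = TRUE,
            degenerate = FALSE, diagnostics = list())
  e1 <- compartmentParams(f1); e2 <- compartmentParams(f2)
  expect_equal(c(e1@c1, e1@c2, e1@r1, e1@r2),
               c(e2@c1, e2@c2, e2@r1, e2@r2), tolerance = 1e-12)

  fz <- new("TwoExponentialFit", a1 = -500, tau1 = 0.5, a2 = 0, tau2 = 8,
            iSS = -100, deltaV = -10, rss = 0, converged = TRUE,
            degenerate = FALSE, diagnostics = list())
  expect_error(compartmentParams(fz), "A2")
})

test_that("noiseless transient fits recover generator parameters to 0.1%", {
  cases <- list(c(100, 400, 10, 10), c(15, 450, 8, 10), c(50, 800, 5, 18),
                c(200, 150, 12, 4))
  for (p in cases) {
    g <- genTransient(p[1], p[2], p[3], p[4], -10, -100, noiseSd = 0,
                      duration = 0.3)
    est <- compartmentParams(fitTwoExponential(g$trace))
    expect_equal(c(est@c1, est@c2, est@r1, est@r2), p, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("noisy fits recover total capacitance within a few percent", {
  errs <- vapply(1:20, function(s) {
    g <- genTransient(15, 450, 8, 10, -10, -100, noiseSd = 10,
                      duration = 0.12, seed = s)
    est <- compartmentParams(fitTwoExponential(g$trace))
    abs(totalCapacitance(est) - 465) / 465
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("a single-exponential transient is flagged degenerate, not silently split", {
  fs <- 1e5
  time <- seq(0, 0.1, by = 1 / fs)
  sig <- -100 - 900 * exp(-time * 1000 / 5)
  tr <- new("TraceRecording", time = time, signal = sig,
            mode = "voltage_clamp", samplingRate = fs,
            metadata = list(holding_mV = -80, step_mV = -90,
                            step_onset_s = 0))
  fit <- fitTwoExponential(tr)
  expect_true(fit@degenerate)
  expect_error(compartmentParams(fit), "degenerate")
  expect_false(is.null(fit@diagnostics$single_exponential))
  expect_equal(fit@diagnostics$single_exponential$tau, 5, tolerance = 1e-3)
})

test_that("sweep averaging is exact for identical sweeps and cancels noise", {
  g <- genTransient(100, 400, 10, 10, -10, -100, noiseSd = 0,
                    duration = 0.02)
  ten <- rep(list(g$trace), 10)
  avg <- averageSweeps(ten, cutoffHz = 5000)
  one <- averageSweeps(list(g$trace), cutoffHz = 5000)
  expect_equal(avg@signal, one@signal, tolerance = 1e-12)
  expect_equal(avg@metadata$n_sweeps_averaged, 10)

  # white-noise residual SD shrinks ~sqrt(10) before filtering
  set.seed(1)
  sweeps <- lapply(1:10, function(s)
    genTransient(100, 400, 10, 10, -10, -100, noiseSd = 10,
                 duration = 0.02, seed = 100 + s)$trace)
  avgN <- averageSweeps(sweeps, cutoffHz = NA)
  resid1 <- sweeps[[1]]@signal - g$trace@signal
  residAvg <- avgN@signal - g$trace@signal
  ratio <- sd(resid1) / sd(residAvg)
  expect_gt(ratio, sqrt(10) * 0.8)
  expect_lt(ratio, sqrt(10) * 1.2)

  # opposite-sign noise cancels exactly
  up <- g$trace; dn <- g$trace
  up@signal <- up@signal + 7; dn@signal <- dn@signal - 7
  expect_equal(averageSweeps(list(up, dn), cutoffHz = NA)@signal,
               g$trace@signal, tolerance = 1e-12)

  short <- genTransient(100, 400, 10, 10, -10, -100, duration = 0.01)$trace
  expect_error(averageSweeps(list(g$trace, short)), "time base")
})

test_that("area-method capacitance matches the closed-form integral", {
  g <- genTransient(100, 400, 10, 10, -10, -100, noiseSd = 0, duration = 1)
  # (A1 tau1 + A2 tau2) / dV = 425 pF for this circuit
  expect_equal(capacitanceAreaMethod(g$trace), 425, tolerance = 0.01)

  flat <- g$trace
  flat@signal <- rep(-100, length(flat@signal))
  expect_equal(capacitanceAreaMethod(flat), 0, tolerance = 1e-9)

  dbl <- g$trace
  dbl@signal <- -100 + 2 * (g$trace@signal + 100)
  expect_equal(capacitanceAreaMethod(dbl),
               2 * capacitanceAreaMethod(g$trace), tolerance = 1e-9)

  trunc <- genTransient(100, 400, 10, 10, -10, -100, duration = 0.02)
  expect_warning(capacitanceAreaMethod(trunc$trace), "truncation")
})

test_that("recording QC applies the series- and input-resistance rules", {
  expect_true(qcRecording(list(series_r_start_MOhm = 8,
                               series_r_end_MOhm = 9,
                               input_r_MOhm = 150))$pass)
  bad <- qcRecording(list(series_r_start_MOhm = 10, series_r_end_MOhm = 16,
                          input_r_MOhm = 150))
  expect_false(bad$pass)
  expect_match(bad$reasons, "above 15", all = FALSE)

  chg <- qcRecording(list(series_r_start_MOhm = 10,
                          series_r_end_MOhm = 12.5, input_r_MOhm = 150))
  expect_false(chg$pass)
  expect_match(chg$reasons, "changed", all = FALSE)

  lowRi <- qcRecording(list(series_r_start_MOhm = 8, series_r_end_MOhm = 8,
                            input_r_MOhm = 80))
  expect_false(lowRi$pass)
  miss <- qcRecording(list(series_r_start_MOhm = 8, series_r_end_MOhm = 8))
  expect_false(miss$pass)
  expect_match(miss$reasons, "missing", all = FALSE)
})

test_that("junction-potential correction subtracts 10 mV exactly once", {
  expect_equal(correctJunctionPotential(-70), -80)
  expect_equal(correctJunctionPotential(0), -10)

  time <- seq(0, 0.01, by = 1e-4)
  tr <- new("TraceRecording", time = time, signal = rep(-70, length(time)),
            mode = "current_clamp", samplingRate = 1e4,
            metadata = list(junction_corrected = FALSE))
  cor1 <- correctJunctionPotential(tr)
  expect_equal(cor1@signal[1], -80)
  expect_true(cor1@metadata$junction_corrected)
  expect_error(correctJunctionPotential(cor1), "already")
})
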