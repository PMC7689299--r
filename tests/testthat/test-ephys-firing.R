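spikyTrace <- function(spikeTimesS, duration = 2, fs = 2e4, base = -55,
                       peak = 20) {
  time <- seq(0, duration, by = 1 / fs)
  v <- rep(base, length(time))
  for (st in spikeTimesS) {
    ix <- which(time >= st & time < st + 0.001)
    v[ix] <- peak
  }
  new("TraceRecording", time = time, signal = v, mode = "cell_attached",
      samplingRate = fs, metadata = list(junction_corrected = FALSE))
}

test_that("threshold-crossing detection finds stereotyped spikes", {
  truth <- seq(0.1, 2, by = 0.1)[1:20]
  tr <- spikyTrace(truth, duration = 2.2)
  det <- detectSpikes(tr, threshold = -20)
  expect_length(det$times, 20L)
  expect_lt(max(abs(det$times - truth)), 1.5 / tr@samplingRate)

  flat <- spikyTrace(numeric(0))
  expect_length(detectSpikes(flat)$times, 0L)

  # two crossings inside the refractory window collapse to one
  close <- spikyTrace(c(0.5, 0.5015), duration = 1)
  expect_length(detectSpikes(close, refractoryMs = 2)$times, 1L)
  expect_length(detectSpikes(close, refractoryMs = 1)$times, 2L)
})

test_that("spike-train statistics follow the CV definition", {
  # ISIs 8, 10, 12 ms -> mean 10, sample SD 2, CV 0.2
  st <- spikeStats(c(0, 0.008, 0.018, 0.030), duration = 10)
  expect_equal(st@isiMean, 10)
  expect_equal(st@isiSd, 2)
  expect_equal(isiCV(st), 0.2)

  per <- spikeStats(seq(0, 9.9, by = 0.1), duration = 10)
  expect_equal(isiCV(per), 0)
  expect_equal(firingRate(spikeStats(seq(0.05, 9.95, length.out = 100), 10)),
               10)

  two <- spikeStats(c(1, 2), duration = 10)
  expect_false(two@cvDefined)
  expect_true(is.na(isiCV(two)))
})

test_that("CV is invariant to time-unit rescaling", {
  times <- cumsum(rgamma(50, shape = 25, scale = 1 / 25 / 40))
  a <- isiCV(spikeStats(times, duration = max(times) + 0.1))
  b <- isiCV(spikeStats(times * 1000, duration = (max(times) + 0.1) * 1000))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("firing classification applies the strict mean+SD rule and rescue logic", {
  controls <- c(0.05, 0.07, 0.09)  # mean 0.07, SD 0.02 -> threshold 0.09
  mkStats <- function(cv, n = 50) {
    # construct a train with exactly this CV: alternate two ISIs
    m <- 0.02
    s <- cv * m
    isi <- rep(c(m - s, m + s), n)  # sample SD ~ s
    spikeStats(cumsum(isi), duration = sum(isi) + 0.01)
  }
  irr <- classifyFiring(mkStats(0.12), controls)
  expect_equal(irr$label, "irregular")
  expect_equal(irr$threshold, 0.09, tolerance = 1e-9)

  # exactly at threshold: "greater than" is strict, so regular
  atThr <- mkStats(0.09)
  atThr@cv <- 0.09
  atThr@isiSd <- atThr@cv * atThr@isiMean
  expect_equal(classifyFiring(atThr, controls)$label, "regular")

  expect_equal(classifyFiring(mkStats(0.05), controls)$label, "regular")

  silent <- spikeStats(numeric(0), duration = 10)
  expect_equal(classifyFiring(silent, controls, rescueSpikes = 12)$label,
               "non_firing_depol_block")
  expect_equal(classifyFiring(silent, controls, rescueSpikes = 4)$label,
               "discarded")
  # a train of exactly 5 does not qualify (> 5 required)
  expect_equal(classifyFiring(silent, controls, rescueSpikes = 5)$label,
               "discarded")
  expect_error(classifyFiring(silent, controls), "rescue")

  # invariance to control ordering
  sh <- classifyFiring(mkStats(0.12), rev(controls))
  expect_equal(sh$label, irr$label)
  expect_equal(sh$threshold, irr$threshold)
})

test_that("AHP measurement selects the first sweep within the 50 ms delay rule", {
  gen <- genAHPSweeps(delaysMs = c(80, 45, 20))
  res <- measureAHP(gen$sweeps)
  expect_equal(res$sweepIndex, 2L)
  expect_equal(res$delayMs, 45, tolerance = 1)
  expect_equal(res$potentials, gen$truth$potentialsCorrected,
               tolerance = 0.15)

  # an already-corrected sweep is not corrected twice
  corrected <- lapply(gen$sweeps, correctJunctionPotential)
  res2 <- measureAHP(corrected)
  expect_equal(res2$potentials, gen$truth$potentialsCorrected,
               tolerance = 0.15)

  empty <- measureAHP(gen$sweeps, offsetsMs = numeric(0))
  expect_length(empty$potentials, 0L)
  expect_equal(empty$sweepIndex, 2L)

  late <- genAHPSweeps(delaysMs = c(80, 120))
  expect_error(measureAHP(late$sweeps), "50")
  expect_error(measureAHP(gen$sweeps, offsetsMs = c(5, 2.5)), "increasing")
})
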