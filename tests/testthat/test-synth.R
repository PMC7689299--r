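test_that("DE-table generator plants the configured cross-model structure", {
  cfg <- synthConfig(seed = 2)
  universe <- genUniverse(cfg)
  gen <- genDETables(cfg, universe)
  expect_length(gen$truth$atLeast3, 12L)
  expect_length(gen$truth$consistentDown, 11L)

  sets <- lapply(names(gen$tables), function(m)
    filterChannels(gen$tables[[m]], universe, m))
  expect_equal(lengths(lapply(sets, deChannels)),
               unname(cfg$drawSizes))
  s <- computeOverlaps(sets, kStar = 3L)
  expect_setequal(atLeastK(s, 3), gen$truth$atLeast3)
  expect_setequal(consistentDown(s), gen$truth$consistentDown)
})

test_that("a null configuration yields overlaps near chance", {
  cfg <- synthConfig(seed = 3, nShared = 0L, nSharedDown = 0L,
                     drawSizes = c(5L, 5L, 5L, 5L))
  universe <- genUniverse(cfg)
  gen <- genDETables(cfg, universe)
  sets <- lapply(names(gen$tables), function(m)
    filterChannels(gen$tables[[m]], universe, m))
  s <- computeOverlaps(sets, kStar = 3L)
  # with fillers capped at two models the >=3 union is empty by design
  expect_length(atLeastK(s, 3), 0L)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- synthConfig(seed = 8)
  a <- genDETables(cfg); b <- genDETables(cfg)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth$plantedGenes, b$truth$plantedGenes)

  t1 <- genSpikeTrain(60, 0.06, 10, seed = 5)
  t2 <- genSpikeTrain(60, 0.06, 10, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, genSpikeTrain(60, 0.06, 10, seed = 6)))

  g1 <- genTransient(15, 450, 8, 10, noiseSd = 10, duration = 0.01,
                     seed = 2)
  g2 <- genTransient(15, 450, 8, 10, noiseSd = 10, duration = 0.01,
                     seed = 2)
  expect_identical(g1$trace@signal, g2$trace@signal)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(genDETables(synthConfig(seed = 99)))
  invisible(genSpikeTrain(60, 0.06, 10, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("transient truth manifests round-trip through the circuit equations", {
  g <- genTransient(80, 600, 6, 14, -10, -100, noiseSd = 0, duration = 0.3)
  expect_equal(g$truth$a2, 1000 * -10 / 20)
  est <- compartmentParams(fitTwoExponential(g$trace))
  expect_equal(c(est@c1, est@c2, est@r1, est@r2), c(80, 600, 6, 14),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("gamma-ISI trains hit the target rate and CV", {
  cvs <- vapply(1:10, function(s)
    isiCV(spikeStats(genSpikeTrain(60, 0.05, 10, seed = s), 10)),
    numeric(1))
  expect_true(all(cvs > 0.03 & cvs < 0.07))
  rates <- vapply(1:10, function(s)
    firingRate(spikeStats(genSpikeTrain(60, 0.05, 10, seed = s), 10)),
    numeric(1))
  expect_equal(mean(rates), 60, tolerance = 0.05)

  # CV -> 0 approaches periodicity
  tiny <- genSpikeTrain(60, 0.005, 5, seed = 1)
  expect_lt(isiCV(spikeStats(tiny, 5)), 0.01)

  expect_error(genSpikeTrain(0.1, 0.05, 1, seed = 1), "3 spikes")
})

test_that("the firing cohort carries recoverable planted labels", {
  cfg <- synthConfig(seed = 12)
  cohort <- genFiringCohort(cfg)
  controlCVs <- vapply(cohort$controls, function(ts)
    isiCV(spikeStats(ts, cfg$spikes$duration)), numeric(1))
  labels <- vapply(seq_along(cohort$cells), function(i) {
    cell <- cohort$cells[[i]]
    classifyFiring(spikeStats(cell$times, cfg$spikes$duration),
                   controlCVs, rescueSpikes = cell$rescueSpikes)$label
  }, character(1))
  expect_identical(labels, cohort$truth$labels)
})

test_that("ChIP generator output recovers planted percent input", {
  cfg <- synthConfig(seed = 5,
                     chip = list(dilutionsPct = c(2, 0.2, 0.02),
                                 efficiency = 1, interceptCt = 26,
                                 plantedPct = c(0.8, 0.25, 0.05),
                                 ctNoiseSd = 0))
  gen <- genChip(cfg)
  curve <- fitStandardCurve(gen$standards$percent, gen$standards$ct)
  expect_equal(percentInput(gen$samples$ct, curve), gen$truth$plantedPct,
               tolerance = 1e-9)
  expect_equal(efficiency(curve), 1, tolerance = 1e-9)
})
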