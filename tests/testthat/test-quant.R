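test_that("comparative Ct follows dCt averaging and the 2^-ddCt rule", {
  tgt <- ctMeasurement("Kcnma1", "s1", "WT", c(24, 24, 24))
  ref <- ctMeasurement("Actb", "s1", "WT", c(20, 20, 20))
  r <- ddctFold(tgt, ref, calibratorDct = 5)
  expect_equal(r$ddct, -1)
  expect_equal(r$fold, 2)

  same <- ddctFold(tgt, ref, calibratorDct = 4)
  expect_equal(same$fold, 1)

  # replicates are averaged before differencing
  tgt2 <- ctMeasurement("Kcnma1", "s1", "WT", c(20.0, 20.2, 19.8))
  expect_equal(mean(tgt2$cts), 20)
  r2 <- ddctFold(tgt2, ref, calibratorDct = 0)
  expect_equal(r2$dct, 0)

  expect_error(ddctFold(tgt, ctMeasurement("Actb", "s2", "WT", 20), 0),
               "same sample")
  expect_error(ctMeasurement("Actb", "s1", "WT", c(20, 50)), "0, 45")
})

test_that("planted qPCR folds are recovered exactly without noise", {
  cfg <- synthConfig(seed = 4,
                     qpcr = list(baseCt = 22,
                                 foldChanges = c(Kcnma1 = 0.45,
                                                 Cacna1g = 0.55),
                                 ctNoiseSd = 0, nPerGroup = 3L,
                                 nReplicates = 3L))
  gen <- genCtTables(cfg)
  folds <- ddctTable(gen$cts, "Actb", gen$truth$calibrator)
  mut <- folds[folds$group != gen$truth$calibrator, ]
  for (g in names(cfg$qpcr$foldChanges))
    expect_equal(unique(round(mut$fold[mut$gene == g], 9)),
                 unname(cfg$qpcr$foldChanges[g]), tolerance = 1e-9)
})

test_that("standard curves report slope, efficiency and fit quality", {
  # perfect efficiency: one cycle per halving -> slope -1/log10(2)
  pct <- c(2, 0.2, 0.02)
  cts <- 20 + log2(2 / pct)
  curve <- fitStandardCurve(pct, cts)
  expect_equal(curve@slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(efficiency(curve), 1, tolerance = 1e-9)
  expect_equal(curve@rSquared, 1, tolerance = 1e-12)

  expect_error(fitStandardCurve(c(2, 0.2), c(20, 23.3)), "three")
  expect_error(fitStandardCurve(pct, rev(cts)), "slope")
})

test_that("percent input interpolates on the standard curve", {
  pct <- c(2, 0.2, 0.02)
  cts <- 20 + log2(2 / pct)
  curve <- fitStandardCurve(pct, cts)
  expect_equal(percentInput(20, curve), 2, tolerance = 1e-9)
  # one cycle above the 2% standard at 100% efficiency = one halving
  expect_equal(percentInput(21, curve), 1, tolerance = 1e-9)
  # log-midpoint between 0.2 and 2 is their geometric mean
  mid <- (20 + 20 + log2(2 / 0.2)) / 2
  expect_equal(percentInput(mid, curve), sqrt(0.2 * 2), tolerance = 1e-9)
  expect_equal(sqrt(0.2 * 2), 0.632, tolerance = 1e-3)
  expect_warning(percentInput(30, curve), "extrapolating")
})

test_that("profile scores are AUC over line length", {
  pos <- seq(0, 12, by = 0.5)
  const <- profileScore(pos, rep(7, length(pos)))
  expect_equal(const$score, 7)

  # triangle peaking at 10: area = L*10/2, score 5
  tri <- profileScore(seq(0, 10, by = 0.1),
                      10 - abs(seq(0, 10, by = 0.1) - 5) * 2)
  expect_equal(tri$score, 5, tolerance = 1e-9)

  dbl <- profileScore(pos, 2 * rep(7, length(pos)))
  expect_equal(dbl$score, 2 * const$score)

  expect_error(profileScore(c(1, 1), c(2, 3)), "increasing")
  expect_error(profileScore(1, 2), "two samples")
})

test_that("score normalization is anchored to the reference group and scale-free", {
  scores <- data.frame(
    animal = rep(c("w1", "w2", "m1", "m2"), each = 3),
    group = rep(c("WT", "WT", "MUT", "MUT"), each = 3),
    score = c(10, 11, 12, 9, 10, 11, 13, 14, 12, 12, 13, 14))
  norm <- normalizeScores(scores, "WT")
  expect_equal(mean(norm$normalized[norm$group == "WT"]), 1,
               tolerance = 1e-12)

  scaled <- scores; scaled$score <- scores$score * 37.5
  norm2 <- normalizeScores(scaled, "WT")
  expect_equal(norm$normalized, norm2$normalized, tolerance = 1e-12)

  solo <- normalizeScores(scores[scores$animal %in% c("w1", "m1"), ], "WT")
  expect_equal(nrow(solo), 2L)
  expect_error(normalizeScores(scores, "NOPE"), "reference")
})

test_that("percent difference reproduces the ratio convention", {
  expect_equal(percentDifference(1.180, 1.000), 18, tolerance = 1e-9)
  expect_equal(percentDifference(3, 3), 0)
  expect_equal(percentDifference(1.286, 1.026), 25.3, tolerance = 1e-2)
  expect_error(percentDifference(1, 0), "positive")
})

test_that("planted intensity effect is recovered from profile scoring", {
  cfg <- synthConfig(seed = 21)
  gen <- genProfiles(cfg)
  scores <- do.call(rbind, lapply(gen$cells$cell_id, function(cid) {
    p <- gen$profiles[[cid]]
    data.frame(cell_id = cid,
               score = profileScore(p$position_um, p$intensity)$score)
  }))
  scores <- merge(scores, gen$cells, by = "cell_id")
  norm <- normalizeScores(scores, gen$truth$referenceGroup)
  gm <- aggregate(normalized ~ group, data = norm, FUN = mean)
  eff <- percentDifference(
    gm$normalized[gm$group == gen$truth$affectedGroup],
    gm$normalized[gm$group == gen$truth$referenceGroup])
  # planted 18% effect, sampling error a few points
  expect_equal(eff, 18, tolerance = 0.35)
})
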