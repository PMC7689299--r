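test_that("channel filtering keeps DE universe genes and assigns directions", {
  rec <- makeDeTable(c("Kcnma1", "Actb", "Cacna1g"), c(-0.5, -1.0, -0.3))
  u <- smallUniverse(c("Kcnma1", "Cacna1g", "Trpc3"))
  s <- filterChannels(rec, u, "m1")
  expect_setequal(deChannels(s), c("Kcnma1", "Cacna1g"))
  expect_equal(unname(directions(s)[c("Kcnma1", "Cacna1g")]),
               c("down", "down"))

  up <- filterChannels(makeDeTable("Trpc3", 0.4), u, "m2")
  expect_equal(unname(directions(up)["Trpc3"]), "up")

  empty <- filterChannels(makeDeTable("Actb", -1), u, "m3")
  expect_length(deChannels(empty), 0L)

  expect_error(filterChannels(makeDeTable("Kcnma1", 0), u, "m4"),
               "direction")
})

test_that("exclusive intersections and at-least-k unions match hand enumeration", {
  A <- makeSet("A", c("x", "y")); B <- makeSet("B", c("y", "z"))
  C <- makeSet("C", "y")
  s <- computeOverlaps(list(A, B, C), kStar = 2L)
  ex <- exclusiveCounts(s)
  expect_equal(unname(ex[c("A", "B", "C", "A+B", "A+C", "B+C", "A+B+C")]),
               c(1L, 1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(atLeastK(s, 2), "y")
  expect_equal(atLeastK(s, 1), c("x", "y", "z"))

  # four identical sets: all mass on the 4-way cell
  ids <- paste0("M", 1:4)
  genes <- sprintf("g%02d", 1:12)
  same <- lapply(ids, makeSet, genes = genes)
  s4 <- computeOverlaps(same, kStar = 3L)
  expect_length(atLeastK(s4, 3), 12L)
  expect_equal(unname(exclusiveCounts(s4)["M1+M2+M3+M4"]), 12L)
  expect_equal(sum(exclusiveCounts(s4)), 12L)

  # disjoint sets: >=2 union empty
  disj <- list(makeSet("A", c("a", "b")), makeSet("B", c("c", "d")))
  expect_length(atLeastK(computeOverlaps(disj, 2L), 2), 0L)

  expect_error(computeOverlaps(list(A, makeSet("A", "q")), 1L), "duplicate")
})

test_that("exclusive counts partition the union and k-unions are monotone", {
  set.seed(11)
  pool <- sprintf("g%03d", 1:40)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    sets <- lapply(seq_len(n), function(i) {
      g <- sample(pool, sample(3:15, 1))
      makeSet(paste0("M", i), g,
              dirs = sample(c("down", "up"), length(g), replace = TRUE))
    })
    s <- computeOverlaps(sets, kStar = min(2L, n))
    expect_equal(sum(exclusiveCounts(s)),
                 length(unique(unlist(lapply(sets, deChannels)))))
    for (k in seq_len(n - 1))
      expect_true(all(atLeastK(s, k + 1) %in% atLeastK(s, k)))
    # dropping a model never grows an at-least-k union
    if (n > 2) {
      sub <- computeOverlaps(sets[-1], kStar = min(2L, n - 1L))
      for (k in seq_len(n - 1))
        expect_lte(length(atLeastK(sub, k)), length(atLeastK(s, k)))
    }
  }
})

test_that("consistent-down requires downregulation in every member model", {
  A <- makeSet("A", c("x", "y"), c("down", "up"))
  B <- makeSet("B", c("x", "y"), c("down", "down"))
  s <- computeOverlaps(list(A, B), kStar = 2L)
  expect_equal(consistentDown(s), "x")
})

test_that("permutation test honors its contracts", {
  p0 <- permutationOverlapTest(c(2, 2), 4, observed = 0, kStar = 2,
                               nSims = 200, seed = 5)
  expect_equal(pValue(p0), 1, tolerance = 1e-12)

  a <- permutationOverlapTest(c(3, 4, 5), 20, observed = 2, kStar = 2,
                              nSims = 500, seed = 42)
  b <- permutationOverlapTest(c(3, 4, 5), 20, observed = 2, kStar = 2,
                              nSims = 500, seed = 42)
  expect_identical(a@nGe, b@nGe)
  expect_equal(pValue(a), (a@nGe + 1) / (a@nSims + 1))

  expect_error(permutationOverlapTest(c(5), 4, 1, 1, 10, 1), "universe")
})

test_that("permutation estimate agrees with the enumerated two-model case", {
  # P(overlap >= 1) for draws (2,2) from 4 = 1 - C(2,2)/C(4,2) = 5/6
  p <- permutationOverlapTest(c(2, 2), 4, observed = 1, kStar = 2,
                              nSims = 10000, seed = 17)
  exact <- 5 / 6
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(p@pRaw - exact), 3 * se)
})

test_that("exact null distribution matches hand enumeration and normalizes", {
  d1 <- exactOverlapDistribution(3, 3, kStar = 1)
  expect_equal(unname(d1["3"]), 1)

  d2 <- exactOverlapDistribution(c(2, 2), 4, kStar = 2)
  expect_equal(unname(d2[c("0", "1", "2")]), c(1 / 6, 2 / 3, 1 / 6))
  expect_equal(sum(d2), 1, tolerance = 1e-12)

  d3 <- exactOverlapDistribution(c(2, 3, 1), 6, kStar = 2)
  expect_equal(sum(d3), 1, tolerance = 1e-12)

  # the statistic is exchangeable in model order
  d3b <- exactOverlapDistribution(c(1, 2, 3), 6, kStar = 2)
  expect_equal(d3, d3b)

  expect_error(exactOverlapDistribution(c(10, 10), 25, 2, budget = 1e4),
               "budget")
})

test_that("upset export writes the exclusive-count matrix in subset order", {
  A <- makeSet("A", c("x", "y")); B <- makeSet("B", c("y", "z"))
  C <- makeSet("C", "y")
  s <- computeOverlaps(list(A, B, C), kStar = 2L)
  path <- tempfile(fileext = ".tsv")
  tab <- exportUpset(s, path)
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$count, c(1L, 1L, 0L, 0L, 0L, 0L, 1L))
  onDisk <- read.delim(path, check.names = FALSE)
  expect_equal(onDisk$count, tab$count)

  ids <- paste0("M", 1:4)
  s4 <- computeOverlaps(lapply(ids, makeSet, genes = c("a", "b")), 3L)
  expect_equal(nrow(exportUpset(s4, tempfile())), 15L)

  empty <- computeOverlaps(list(makeSet("A", character(0)),
                                makeSet("B", character(0))), 1L)
  expect_error(exportUpset(empty, tempfile()), "empty")
})
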