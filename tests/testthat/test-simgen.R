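test_that("cell layout handles degenerate inputs and is deterministic", {
  spec0 <- fieldSpec(nCells = 0L, seed = 1L)
  g0 <- sampleCellLayout(spec0)
  expect_identical(nrow(g0$cells), 0L)
  expect_identical(nrow(g0$foci), 0L)

  spec1 <- fieldSpec(nCells = 1L, seed = 3L)
  expect_identical(sampleCellLayout(spec1), sampleCellLayout(spec1))
})

test_that("sampled cells are pairwise non-overlapping (brute force)", {
  spec <- fieldSpec(nCells = 9L, imageHeight = 512L, imageWidth = 512L,
                    cellRadiusRange = c(20, 30), seed = 17L)
  g <- sampleCellLayout(spec)
  expect_identical(nrow(g$cells), 9L)
  rb <- pmax(g$cells$a, g$cells$b)
  for (i in 1:8) for (j in (i + 1):9) {
    d <- sqrt((g$cells$cy[i] - g$cells$cy[j])^2 +
              (g$cells$cx[i] - g$cells$cx[j])^2)
    expect_gt(d, rb[i] + rb[j])
  }
})

test_that("placement failure names the achieved count", {
  spec <- fieldSpec(nCells = 40L, imageHeight = 128L, imageWidth = 128L,
                    cellRadiusRange = c(25, 30), seed = 1L)
  expect_error(sampleCellLayout(spec), "placed [0-9]+ of 40")
})

test_that("ground-truth masks are nested: subcompartment in nucleus in cell", {
  for (kind in c("DFC", "heterochromatin")) {
    fx <- fixtureScene("nest", kind = kind, seed = 23L)
    tr <- sceneTruth(fx$scene)
    nuc <- nucleusLabels(tr); cel <- cellLabels(tr)
    expect_false(any(nuc > 0 & cel != nuc))
    sub <- tr@subcompartmentMasks[[kind]]
    expect_false(any(sub & nuc == 0))
    expect_identical(sort(unique(cel[cel > 0])), sort(unique(nuc[nuc > 0])))
  }
})

test_that("noise-free probe values follow the configured compartment levels", {
  fx <- fixtureScene("levels", noise = FALSE, fold = 2.0, seed = 31L)
  sc <- fx$scene; spec <- fx$spec; tr <- sceneTruth(sc)
  probe <- getChannel(sc, "probe")
  dfc <- tr@subcompartmentMasks$DFC
  nucOnly <- nucleusLabels(tr) > 0 & !dfc
  expect_equal(unique(as.vector(probe[dfc])),
               2.0 * spec@baseLevels[["nucleoplasm"]])
  expect_equal(unique(as.vector(probe[nucOnly])),
               spec@baseLevels[["nucleoplasm"]])
  expect_equal(unique(as.vector(probe[pmMask(tr)])), spec@baseLevels[["pm"]])
  # DAPI nonzero only in nuclei; membrane peaks on the band
  dapi <- getChannel(sc, "dapi")
  expect_true(all(dapi[nucleusLabels(tr) == 0] == 0))
  expect_true(all(dapi[nucleusLabels(tr) > 0] > 0))
  mem <- getChannel(sc, "membrane")
  expect_gt(min(mem[pmMask(tr)]), max(mem[!pmMask(tr)]))
})

test_that("untreated scenes carry background only over cells (summation oracle)", {
  fx <- fixtureScene("untr", noise = FALSE, background = 5,
                     condition = "untreated", seed = 37L)
  probe <- getChannel(fx$scene, "probe")
  cells <- cellLabels(sceneTruth(fx$scene)) > 0
  expect_equal(sum(probe[cells]), 5 * sum(cells))
  expect_equal(unique(as.vector(probe)), 5)
})

test_that("unknown condition is rejected", {
  spec <- fieldSpec(nCells = 1L, imageHeight = 128L, imageWidth = 128L)
  g <- sampleCellLayout(spec)
  expect_error(renderScene(g, spec, condition = "irradiated"))
})

test_that("noise model: noiseless limit, determinism, LLN mean", {
  x <- matrix(100, 50, 50)
  expect_identical(applyNoise(x, Inf, 0, 1L), x)
  expect_identical(applyNoise(x, 4, 2, 7L), applyNoise(x, 4, 2, 7L))
  big <- matrix(100, 1000, 1000)
  m <- mean(applyNoise(big, 4, 2, 11L))
  expect_lt(abs(m - 100) / 100, 0.01)
  expect_error(applyNoise(x, -1, 0), "non-negative")
  expect_error(applyNoise(matrix(-1, 2, 2), 4, 2), "non-negative")
})

test_that("time courses scale linearly and are monotone", {
  spec <- fieldSpec(nCells = 3L, imageHeight = 192L, imageWidth = 192L,
                    seed = 41L)
  expect_error(generateTimeCourse(spec, c(-5, 10), 0.01), "non-negative")
  expect_error(generateTimeCourse(spec, c(30, 10), 0.01), "sorted")

  times <- c(0, 10, 30, 60, 120, 360)
  tc <- generateTimeCourse(spec, times, 0.01, noise = FALSE)
  # t = 0: background only
  expect_true(all(getChannel(tc[[1]], "probe") == spec@backgroundLevel))
  # generator-recorded true nuclear means monotone increasing
  mus <- vapply(tc, function(s)
    sceneTruth(s)@trueCompartmentMeans[["nucleoplasm"]], numeric(1))
  expect_true(all(diff(mus) >= 0))
  expect_true(all(diff(mus[-1]) > 0))
  # doubling the rate doubles the noise-free integrated signal at every t
  tc2 <- generateTimeCourse(spec, times, 0.02, noise = FALSE)
  for (i in seq_along(times)) {
    s1 <- sum(getChannel(tc[[i]], "probe"))
    s2 <- sum(getChannel(tc2[[i]], "probe"))
    expect_equal(s2, 2 * s1, tolerance = 1e-12)
  }
})

test_that("synthetic gels honour their configured lane truth", {
  expect_error(gelSpec(laneRoles = character(), trueSignals = numeric()),
               "lane")
  g <- generateGel(gelSpec(noiseSd = 0, seed = 5L))
  # noise-free integration recovers every lane's truth exactly
  q <- quantifyLanes(g$raster, g$lanes)
  expect_equal(q$signal, q$trueSignal, tolerance = 1e-10)
  # 8-lane layout: column-sum profile has 8 well-separated local maxima
  ln <- detectLanes(g$raster, 8)
  expect_false(attr(ln, "fallback"))
  expect_identical(nrow(ln), 8L)
  expect_lt(max(abs(ln$center - g$lanes$center)), 2)
  # determinism
  g2 <- generateGel(gelSpec(noiseSd = 3, seed = 5L))
  g3 <- generateGel(gelSpec(noiseSd = 3, seed = 5L))
  expect_identical(g2$raster, g3$raster)
})

test_that("scene generation is bit-reproducible for a fixed spec", {
  spec <- fieldSpec(nCells = 3L, imageHeight = 160L, imageWidth = 160L,
                    seed = 57L)
  s1 <- renderScene(sampleCellLayout(spec), spec)
  s2 <- renderScene(sampleCellLayout(spec), spec)
  for (ch in channelNames(s1))
    expect_identical(getChannel(s1, ch), getChannel(s2, ch))
})
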