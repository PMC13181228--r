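test_that("uniform marker excludes the nucleus (degenerate threshold)", {
  nl <- matrix(0L, 20, 20); nl[5:15, 5:15] <- 1L
  sm <- segmentSubcompartment(matrix(3, 20, 20), nl, "DFC")
  expect_identical(sm@excluded, 1L)
  expect_identical(max(sm@compartmentLabels), 0L)
})

test_that("marker foci are recovered with IoU >= 0.8 against truth", {
  fx <- fixtureScene("subseg", noise = TRUE, seed = 89L)
  tr <- sceneTruth(fx$scene)
  sm <- segmentSubcompartment(getChannel(fx$scene, "marker"),
                              nucleusLabels(tr), "DFC")
  comp <- sm@compartmentLabels > 0
  expect_gte(sum(comp & tr@subcompartmentMasks$DFC) /
             sum(comp | tr@subcompartmentMasks$DFC), 0.8)
  # compartment + remainder tile every analyzed nucleus exactly
  ids <- setdiff(unique(sm@compartmentLabels[sm@compartmentLabels > 0]),
                 sm@excluded)
  for (k in ids) {
    tiles <- (sm@compartmentLabels == k) | (sm@remainderLabels == k)
    expect_identical(tiles, nucleusLabels(tr) == k)
  }
})

test_that("enrichment folds match hand-computed means", {
  nl <- matrix(0L, 6, 6); nl[2:3, 2:4] <- 1L   # a 6-pixel nucleus
  compL <- matrix(0L, 6, 6); compL[2, 2:3] <- 1L
  remL <- matrix(0L, 6, 6)
  remL[nl == 1L & compL == 0L] <- 1L
  sm <- new("SubcompartmentMasks", kind = "DFC", compartmentLabels = compL,
            remainderLabels = remL, nucleusLabels = nl, excluded = integer(0))
  probe <- matrix(0, 6, 6)
  probe[2, 2] <- 5; probe[2, 3] <- 7                 # compartment {5,7}
  probe[3, 2] <- 2; probe[3, 3] <- 4; probe[3, 4] <- 6; probe[2, 4] <- 4
  rec <- computeEnrichment(probe, sm)
  expect_equal(rec$enrichment_fold, 6 / 4)
  # uniform probe -> fold exactly 1
  rec1 <- computeEnrichment(matrix(9, 6, 6), sm)
  expect_equal(rec1$enrichment_fold, 1)
})

test_that("folds are gain-invariant and shift-invariant after correction", {
  fx <- fixtureScene("subinv", noise = TRUE, seed = 97L)
  tr <- sceneTruth(fx$scene)
  sm <- segmentSubcompartment(getChannel(fx$scene, "marker"),
                              nucleusLabels(tr), "DFC")
  probe <- getChannel(fx$scene, "probe")
  f0 <- computeEnrichment(probe, sm)$enrichment_fold
  fGain <- computeEnrichment(probe * 3, sm)$enrichment_fold
  expect_equal(fGain, f0, tolerance = 1e-12)
  fShiftRaw <- computeEnrichment(probe + 50, sm)$enrichment_fold
  expect_false(isTRUE(all.equal(fShiftRaw, f0)))
  fShiftCorr <- computeEnrichment(probe + 50, sm,
                                  background = 50)$enrichment_fold
  expect_equal(fShiftCorr, f0, tolerance = 1e-10)
})

test_that("non-positive remainder means are dropped with a diagnostic", {
  nl <- matrix(0L, 6, 6); nl[2:3, 2:4] <- 1L
  compL <- matrix(0L, 6, 6); compL[2, 2:3] <- 1L
  remL <- matrix(0L, 6, 6); remL[nl == 1L & compL == 0L] <- 1L
  sm <- new("SubcompartmentMasks", kind = "DFC", compartmentLabels = compL,
            remainderLabels = remL, nucleusLabels = nl, excluded = integer(0))
  expect_message(rec <- computeEnrichment(matrix(1, 6, 6), sm,
                                          background = 2),
                 "non-positive")
  expect_identical(nrow(rec), 0L)
})

test_that("enrichment summaries use SD/sqrt(n)", {
  df <- data.frame(kind = "DFC", probe_id = "p2", uv_condition = "plusUV",
                   enrichment_fold = c(1.2, 1.4))
  s <- summarizeEnrichment(df)
  expect_equal(s$mean_fold, 1.3)
  expect_equal(s$se_fold, 0.1)
  s0 <- summarizeEnrichment(data.frame(kind = "NS", probe_id = "p",
                                       uv_condition = "minusUV",
                                       enrichment_fold = c(1, 1, 1)))
  expect_equal(s0$mean_fold, 1)
  expect_equal(s0$se_fold, 0)
})

test_that("heterochromatin rim null reproduces fold 1 with no rejection", {
  folds <- simulateEnrichmentSample(1.0, 30, seed = 5L,
                                    kind = "heterochromatin")
  expect_lt(abs(mean(folds) - 1), 0.05)
})

test_that("noise-free generator folds are exact (ground-truth consistency)", {
  for (fold in c(1.0, 1.4, 2.0)) {
    fx <- fixtureScene("gt", noise = FALSE, fold = fold,
                       seed = 100L + round(10 * fold))
    tr <- sceneTruth(fx$scene)
    probe <- getChannel(fx$scene, "probe")
    dfc <- tr@subcompartmentMasks$DFC
    rest <- nucleusLabels(tr) > 0 & !dfc
    measured <- mean(probe[dfc]) / mean(probe[rest])
    expect_lt(abs(measured - fold) / fold, 1e-12)
  }
})
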