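test_that("compartment means match hand values and conserve totals", {
  # 4-pixel nucleus valued 1,2,3,4 -> mean 2.5
  cl <- matrix(0L, 8, 8); cl[2:5, 2:5] <- 1L
  nl <- matrix(0L, 8, 8); nl[3:4, 3:4] <- 1L
  probe <- matrix(0, 8, 8)
  probe[3, 3] <- 1; probe[4, 3] <- 2; probe[3, 4] <- 3; probe[4, 4] <- 4
  cm <- deriveCompartments(cl, nl, segmentationParams(
    membraneBandWidth = 1, excludeBorderCells = FALSE))
  rec <- suppressWarnings(measureCompartments(probe, cm))
  expect_equal(rec$mean_intensity[rec$compartment == "nucleus"], 2.5)
  # conservation: sum over compartments of area x mean = whole-cell total
  sub <- rec[rec$compartment != "whole_cell", ]
  whole <- rec[rec$compartment == "whole_cell", ]
  expect_equal(sum(sub$mean_intensity * sub$area),
               whole$mean_intensity * whole$area)
  expect_equal(whole$mean_intensity * whole$area, sum(probe[cl == 1L]))
})

test_that("empty compartments are skipped with a warning, not zeroed", {
  cl <- matrix(0L, 5, 5); cl[2:4, 2:4] <- 1L
  nl <- matrix(0L, 5, 5); nl[3, 3] <- 1L
  pm <- cl == 1L & nl == 0L          # band swallows everything: no cytoplasm
  cy <- matrix(FALSE, 5, 5)
  cm <- new("CompartmentMasks", cellLabels = cl, nucleusLabels = nl,
            pmMask = pm, cytoplasmMask = cy)
  expect_warning(rec <- measureCompartments(matrix(1, 5, 5), cm),
                 "empty cytoplasm")
  expect_false("cytoplasm" %in% rec$compartment)
})

test_that("background estimation pools untreated cell pixels", {
  cl <- matrix(0L, 6, 6); cl[2:5, 2:5] <- 1L
  bm <- estimateBackground(list(matrix(7, 6, 6)), list(cl))
  expect_equal(bm@background, 7)
  # two fields at 4 and 8 AU with equal cell areas pool to 6
  bm2 <- estimateBackground(list(matrix(4, 6, 6), matrix(8, 6, 6)),
                            list(cl, cl))
  expect_equal(bm2@background, 6)
  expect_warning(bm0 <- estimateBackground(list(), list()), "background")
  expect_equal(bm0@background, 0)
})

test_that("background subtraction shifts means without clipping", {
  rec <- data.frame(mean_intensity = c(10, 1), area = c(4, 4),
                    integrated_intensity = c(40, 4))
  out <- subtractBackground(rec, 3)
  expect_equal(out$mean_intensity, c(7, -2))
  expect_equal(subtractBackground(rec, 0), rec)
  # corrected untreated records center near zero (simulation)
  fx <- fixtureScene("bgsim", noise = TRUE, background = 20,
                     condition = "untreated", seed = 79L)
  tr <- sceneTruth(fx$scene)
  probe <- getChannel(fx$scene, "probe")
  bm <- estimateBackground(list(probe), list(cellLabels(tr)))
  # recovered background close to the configured level (noise SE scale)
  expect_lt(abs(bm@background - 20), 0.5)
  recs <- measureSceneTruth(fx$scene)
  corr <- subtractBackground(recs, bm)
  grp <- corr$mean_intensity[corr$compartment == "whole_cell"]
  expect_lt(abs(mean(grp)), 3 * stats::sd(grp) / sqrt(length(grp)) + 0.05)
})

test_that("condition summaries report n, mean, sample SD and SE", {
  df <- data.frame(probe_id = "p", compartment = "nucleus",
                   mean_intensity = c(2, 4, 6))
  s <- summarizeConditions(df, groupBy = c("probe_id", "compartment"))
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$se, 2 / sqrt(3))
  expect_false(s$singleton)
  s1 <- summarizeConditions(df[1, ], groupBy = c("probe_id", "compartment"))
  expect_equal(s1$mean, 2)
  expect_equal(s1$sd, 0)
  expect_true(s1$singleton)
})

test_that("compartment ordering nucleus > cytoplasm > pm is reproduced", {
  fx <- fixtureScene("order", noise = TRUE, nCells = 5L, seed = 83L)
  recs <- measureSceneTruth(fx$scene)
  s <- summarizeConditions(recs, groupBy = "compartment")
  mu <- stats::setNames(s$mean, s$compartment)
  expect_gt(mu[["nucleus"]], mu[["cytoplasm"]])
  expect_gt(mu[["cytoplasm"]], mu[["pm"]])
})

test_that("pooled t-test handles symmetry, separation and degeneracy", {
  r <- compareGroupsTTest(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(r$statistic, 0)
  expect_equal(r$pValue, 0.5)
  r2 <- compareGroupsTTest(c(11, 12, 13), c(1, 2, 3), "greater")
  expect_lt(r2$pValue, 0.001)
  r3 <- compareGroupsTTest(c(5, 5, 5), c(1, 1, 1), "greater")
  expect_true(r3$degenerate)
  expect_equal(r3$pValue, 0)
  expect_error(compareGroupsTTest(1, c(1, 2)), "at least 2")
})

test_that("t-test type-I error is calibrated (null simulation)", {
  set.seed(424242)
  rej <- mean(replicate(2000, {
    compareGroupsTTest(rnorm(20), rnorm(20), "greater")$pValue < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("time-course interpolation is exact at and between knots", {
  cv <- interpolateTimecourse(c(0, 10), c(0, 10))
  expect_equal(cv$fun(5), 5)
  expect_equal(cv$fun(10), 10)
  expect_true(is.na(cv$fun(11)))
  expect_message(cv2 <- interpolateTimecourse(c(0, 0, 10), c(2, 4, 10)),
                 "duplicate")
  expect_equal(cv2$fun(0), 3)
  # monotone means give a monotone curve between knots
  set.seed(7)
  mus <- cumsum(runif(5))
  cv3 <- interpolateTimecourse(c(1, 3, 7, 20, 40), mus)
  q <- cv3$fun(seq(1, 40, length.out = 200))
  expect_true(all(diff(q) >= -1e-12))
})
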