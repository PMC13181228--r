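test_that("blank and invalid DAPI rasters are handled", {
  expect_identical(max(segmentNuclei(matrix(0, 64, 64))), 0L)
  expect_error(segmentNuclei(matrix(NA_real_, 8, 8)), "non-finite")
  expect_error(segmentNuclei(numeric(0)), "matrix")
})

test_that("touching nuclei are split by the distance watershed", {
  H <- 80; W <- 80
  m <- matrix(0, H, W)
  for (ctr in list(c(40, 30), c(40, 50))) {
    idx <- outer((1:H - ctr[1])^2, (1:W - ctr[2])^2, "+") <= 15^2
    m[idx] <- 300
  }
  nl <- segmentNuclei(m)
  expect_identical(max(nl), 2L)
})

test_that("noise-free scene segmentation recovers nuclei with high IoU", {
  fx <- fixtureScene("seg5", noise = FALSE, nCells = 5L, seed = 61L)
  nl <- segmentNuclei(getChannel(fx$scene, "dapi"))
  expect_identical(max(nl), 5L)
  expect_true(all(matchedIoU(nl, nucleusLabels(sceneTruth(fx$scene))) >= 0.9))
})

test_that("cell segmentation yields one cell per nucleus containing it", {
  fx <- fixtureScene("seg1", noise = FALSE, nCells = 1L, seed = 67L)
  nl <- segmentNuclei(getChannel(fx$scene, "dapi"))
  cl <- segmentCells(getChannel(fx$scene, "membrane"), nl)
  expect_identical(sort(unique(cl[cl > 0])), sort(unique(nl[nl > 0])))
  expect_false(any(nl > 0 & cl != nl))
  expect_error(segmentCells(matrix(1, 8, 8), matrix(0L, 8, 8)),
               "segmentNuclei")
})

test_that("segmentation is invariant to a global multiplicative gain", {
  fx <- fixtureScene("seggain", noise = TRUE, nCells = 4L, seed = 71L)
  d <- getChannel(fx$scene, "dapi"); m <- getChannel(fx$scene, "membrane")
  n1 <- segmentNuclei(d); n2 <- segmentNuclei(d * 2)
  expect_identical(n1, n2)
  expect_identical(segmentCells(m, n1), segmentCells(m * 2, n1))
})

test_that("membrane band matches the per-pixel distance oracle", {
  # 1-cell toy field: disk of radius 6 in a 20x20 raster, band width 2
  H <- 20; W <- 20
  cl <- matrix(0L, H, W)
  cl[outer((1:H - 10)^2, (1:W - 10)^2, "+") <= 6^2] <- 1L
  nl <- matrix(0L, H, W)
  nl[outer((1:H - 10)^2, (1:W - 10)^2, "+") <= 2^2] <- 1L
  cm <- deriveCompartments(cl, nl, segmentationParams(
    membraneBandWidth = 2, excludeBorderCells = FALSE))
  # oracle: Euclidean distance to the nearest non-cell pixel, per pixel
  bg <- which(cl == 0, arr.ind = TRUE)
  oracle <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    if (cl[i, j] == 0 || nl[i, j] > 0) next
    dmin <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
    oracle[i, j] <- dmin <= 2
  }
  expect_identical(pmMask(cm), oracle)
})

test_that("compartments tile each cell and border cells are excluded", {
  fx <- fixtureScene("segtile", noise = FALSE, nCells = 5L, seed = 73L)
  tr <- sceneTruth(fx$scene)
  cm <- deriveCompartments(cellLabels(tr), nucleusLabels(tr),
                           segmentationParams(excludeBorderCells = FALSE))
  cl <- cellLabels(cm)
  for (id in sort(unique(cl[cl > 0]))) {
    inCell <- cl == id
    np <- sum(nucleusLabels(cm) == id)
    pp <- sum(pmMask(cm) & inCell)
    cp <- sum(cytoplasmMask(cm) & inCell)
    expect_identical(np + pp + cp, sum(inCell))
  }
  # border-touching cell removed from every raster
  cl2 <- cellLabels(tr); nl2 <- nucleusLabels(tr)
  shifted <- matrix(0L, nrow(cl2), ncol(cl2))
  off <- which(cl2[, 1:40] > 0, arr.ind = TRUE)
  # build a raster where cell 1 touches the left edge by shifting columns
  first <- sort(unique(cl2[cl2 > 0]))[1]
  bb <- which(cl2 == first, arr.ind = TRUE)
  shift <- min(bb[, 2]) - 1L
  cl2s <- cbind(cl2[, (shift + 1):ncol(cl2)],
                matrix(0L, nrow(cl2), shift))
  nl2s <- cbind(nl2[, (shift + 1):ncol(nl2)],
                matrix(0L, nrow(nl2), shift))
  cmB <- suppressWarnings(deriveCompartments(
    cl2s, nl2s, segmentationParams(excludeBorderCells = TRUE)))
  expect_false(first %in% cellLabels(cmB))
  expect_false(first %in% nucleusLabels(cmB))
  expect_false(any(pmMask(cmB) & cl2s == first))
})

test_that("mismatched label sets are rejected", {
  cl <- matrix(0L, 10, 10); cl[3:8, 3:8] <- 1L
  nl <- matrix(0L, 10, 10); nl[4:6, 4:6] <- 2L
  expect_error(deriveCompartments(cl, nl), "label sets differ")
})
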