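test_that("lane detection handles trivial and degenerate inputs", {
  g <- generateGel(gelSpec(seed = 2L))
  one <- detectLanes(g$raster, 1)
  expect_identical(one$colStart, 1L)
  expect_identical(one$colEnd, ncol(g$raster))
  expect_warning(fl <- detectLanes(matrix(5, 40, 60), 4), "fallback")
  expect_true(attr(fl, "fallback"))
  expect_identical(nrow(fl), 4L)
  expect_error(detectLanes(matrix(1, 10, 3), 8), "narrower")
})

test_that("lane integration matches discrete-sum oracles", {
  expect_equal(integrateLane(rep(4, 120)), 0)  # flat profile
  # triangular band, height h, base w, on a zero baseline
  h <- 30; w <- 21
  tri <- c(rep(0, 40), h * (1 - abs(seq(-1, 1, length.out = w))), rep(0, 40))
  oracle <- sum(tri)            # baseline here is exactly 0
  expect_equal(integrateLane(tri), oracle)
  expect_equal(oracle, h * (w - 1) / 2, tolerance = 0.05 * h * w / 2)
  expect_error(integrateLane(numeric(0)), "nonempty")
})

test_that("incorporation ratios follow the stated conversion convention", {
  # S(-UV) = 0.81 x S(+UV) in every replicate -> 81%
  plus <- c(1000, 1200, 900, 1100)
  r <- incorporationRatio(0.81 * plus, plus)
  expect_equal(r$percent, 81)
  expect_equal(incorporationRatio(c(5, 5), c(5, 5))$percent, 100)
  expect_equal(incorporationRatio(c(0, 0), c(10, 10))$percent, 0)
  expect_message(r2 <- incorporationRatio(c(1, 2), c(0, 4)), "dropping")
  expect_identical(r2$n, 1L)
  expect_error(incorporationRatio(1:3, 1:2), "paired")
})

test_that("ratios are invariant to a common gel gain", {
  g <- generateGel(gelSpec(noiseSd = 2, seed = 13L))
  roles <- g$lanes$role
  a <- suppressWarnings(analyzeGel(g$raster, roles))
  b <- suppressWarnings(analyzeGel(g$raster * 7, roles))
  expect_equal(a$incorporation$mean_ratio, b$incorporation$mean_ratio,
               tolerance = 1e-12)
})

test_that("replicate SE of the recovered percent shrinks with n", {
  sds <- vapply(c(2L, 16L), function(n) {
    ps <- vapply(1:20, function(s)
      gelRecoveryStudy(nReplicates = n, seed = 5000L + s)$percent,
      numeric(1))
    stats::sd(ps)
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})
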