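test_that("hand-enumerated example: A={1,2}, B={3,4}", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r@U, 0)
  expect_equal(r@pValue, 2 / 6)
  expect_identical(r@method, "exact")
})

test_that("identical samples give p = 1", {
  r <- mannWhitneyU(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r@pValue, 1)
  r2 <- mannWhitneyU(1:5, 1:5)
  expect_equal(r2@pValue, 1)
})

test_that("empty samples are rejected", {
  expect_error(mannWhitneyU(numeric(0), 1:3), "nonempty")
})

test_that("exact branch matches exhaustive enumeration for n1, n2 <= 6", {
  set.seed(99)
  for (n1 in 1:6) for (n2 in 1:6) {
    vals <- sample(seq_len(200), n1 + n2)  # distinct, no ties
    x <- vals[seq_len(n1)]; y <- vals[n1 + seq_len(n2)]
    oracle <- enumMWU(x, y)
    for (alt in c("two_sided", "greater", "less")) {
      r <- mannWhitneyU(x, y, alt)
      expect_identical(r@method, "exact")
      expect_equal(r@U, oracle$U)
      pref <- switch(alt, two_sided = oracle$pTwoSided,
                     greater = oracle$pGreater, less = oracle$pLess)
      expect_equal(r@pValue, pref, tolerance = 1e-12)
    }
  }
})

test_that("exact branch agrees with the reference implementation", {
  set.seed(5)
  for (i in 1:20) {
    vals <- sample(seq_len(500), 13)
    x <- vals[1:6]; y <- vals[7:13]
    r <- mannWhitneyU(x, y)
    w <- stats::wilcox.test(x, y)
    expect_equal(r@U, unname(w$statistic))
    expect_equal(r@pValue, w$p.value, tolerance = 1e-12)
  }
})

test_that("normal-approximation branch matches the tie-corrected reference", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(30)
    r <- mannWhitneyU(x, y)
    expect_identical(r@method, "normal_approx")
    w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(r@pValue, w$p.value, tolerance = 1e-12)
    # with ties
    xt <- round(rnorm(25), 1); yt <- round(rnorm(30), 1)
    rt <- mannWhitneyU(xt, yt)
    wt <- stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
    expect_equal(rt@pValue, wt$p.value, tolerance = 1e-12)
  }
})

test_that("one-sided alternatives are coherent", {
  set.seed(3)
  x <- rnorm(10, 2); y <- rnorm(12)
  g <- mannWhitneyU(x, y, "greater")
  l <- mannWhitneyU(x, y, "less")
  expect_lt(g@pValue, 0.05)
  expect_gt(l@pValue, 0.95)
  expect_true(g@U >= 0 && g@U <= g@n1 * g@n2)
})
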