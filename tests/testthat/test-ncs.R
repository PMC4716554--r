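test_that("place_knots puts boundary at the range and interior at quantiles", {
  ks <- place_knots(0:100, df = 1)
  expect_equal(ks$boundary, c(0, 100))
  expect_length(ks$interior, 0)

  ks <- place_knots(0:100, df = 4)
  expect_equal(ks$interior, c(25, 50, 75))

  set.seed(7)
  temps <- rnorm(500, 25.7, 4.1)
  ks <- place_knots(temps, df = 5)
  # oracle: direct sort-and-interpolate quantiles at levels 0.2..0.8
  srt <- sort(temps)
  lv <- c(.2, .4, .6, .8)
  h <- (length(srt) - 1) * lv
  manual <- srt[floor(h) + 1] + (h - floor(h)) * (srt[floor(h) + 2] - srt[floor(h) + 1])
  expect_equal(ks$interior, manual, tolerance = 1e-12)
})

test_that("place_knots rejects degenerate inputs", {
  expect_error(place_knots(c(1, 1, 1), df = 2), "insufficient distinct")
  expect_error(place_knots(numeric(0), df = 1), "non-empty")
  expect_error(knot_spec(c(5, 2), c(0, 10)), "strictly increasing")
  expect_error(knot_spec(c(0, 5), c(0, 10)), "strictly inside")
})

test_that("a 1-df NCS basis is affine in x", {
  x <- seq(-3, 12, length.out = 40)
  b <- ncs_basis(x, knot_spec(numeric(0), c(0, 10)))
  expect_equal(ncol(b), 1L)
  slopes <- diff(b[, 1]) / diff(x)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
})

test_that("NCS bases extrapolate linearly beyond the boundary knots", {
  ks <- knot_spec(c(3, 5, 7), c(0, 10))
  x <- c(11, 12.5, 14)   # equally probing above the upper boundary
  b <- ncs_basis(x, ks)
  for (j in seq_len(ncol(b))) {
    s1 <- (b[2, j] - b[1, j]) / (x[2] - x[1])
    s2 <- (b[3, j] - b[2, j]) / (x[3] - x[2])
    expect_equal(s1, s2, tolerance = 1e-10)
  }
})

test_that("NCS basis spans the truncated-power natural-spline space", {
  ks <- knot_spec(c(20, 25, 28), c(14, 34))
  probes <- seq(12, 36, length.out = 10)
  impl <- cbind(1, ncs_basis(probes, ks))
  oracle <- tp_natural_basis(probes, ks$interior, ks$boundary)
  expect_lt(proj_resid(impl, oracle), 1e-8)
  expect_lt(proj_resid(oracle, impl), 1e-8)
})

test_that("basis rows are C2-continuous across interior knots", {
  ks <- knot_spec(c(3, 5, 7), c(0, 10))
  h <- 1e-4
  for (k in ks$interior) {
    x <- k + h * c(-2, -1, 0, 1, 2)
    b <- ncs_basis(x, ks)
    for (j in seq_len(ncol(b))) {
      d2l <- (b[3, j] - 2 * b[2, j] + b[1, j]) / h^2
      d2r <- (b[5, j] - 2 * b[4, j] + b[3, j]) / h^2
      expect_equal(d2l, d2r, tolerance = 1e-3)
    }
  }
})

test_that("shifting x and knots by a constant preserves the column space", {
  set.seed(3)
  x <- runif(60, 0, 10)
  ks <- knot_spec(c(3, 5, 7), c(0, 10))
  ks2 <- knot_spec(ks$interior + 100, ks$boundary + 100)
  b1 <- cbind(1, ncs_basis(x, ks))
  b2 <- cbind(1, ncs_basis(x + 100, ks2))
  expect_lt(proj_resid(b1, b2), 1e-8)
  expect_lt(proj_resid(b2, b1), 1e-8)
})

test_that("basis matrix on enough distinct points has full rank df", {
  for (df in 2:6) {
    ks <- place_knots(seq(0, 1, length.out = 50), df)
    b <- ncs_basis(seq(0, 1, length.out = df + 2), ks)
    expect_equal(qr(b)$rank, df)
  }
})

test_that("non-finite evaluation points are reported with their rows", {
  ks <- knot_spec(numeric(0), c(0, 1))
  expect_error(ncs_basis(c(0.1, NA, 0.5), ks), "rows: 2")
})
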