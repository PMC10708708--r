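test_that("min-max rescaling maps extremes to [-1, 1] and follows the defining formula", {
  expect_equal(minmax_rescale(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(minmax_rescale(c(-1, 1)), c(-1, 1))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1))
    xr <- minmax_rescale(x)
    expect_equal(min(xr), -1)
    expect_equal(max(xr), 1)
    expect_equal(xr, ((x - max(x)) + (x - min(x))) / (max(x) - min(x)))
  }
  expect_error(minmax_rescale(rep(3, 10)), "constant")
})

test_that("PAA frame means are exact, identity at equal length, constant-preserving", {
  expect_equal(paa(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  x <- rnorm(17)
  expect_identical(paa(x, 17L), x)
  expect_equal(paa(rep(2.5, 30), 7), rep(2.5, 7))
  # fractional frames conserve the total mass: mean of output = mean input
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(23)
    ol <- sample(2:23, 1)
    expect_equal(mean(paa(x, ol)), mean(x), tolerance = 1e-12)
  }
  expect_error(paa(1:4, 5), "out_len")
})

test_that("recurrence matrix equals pairwise distances of embedded states", {
  expect_equal(recurrence_matrix(c(0, 1, 2)),
               matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))
  expect_equal(recurrence_matrix(rep(1.3, 6)), matrix(0, 6, 6))
  set.seed(13)
  x <- rnorm(30)
  R <- recurrence_matrix(x)
  expect_identical(R, t(R))
  expect_true(all(diag(R) == 0))
  expect_true(all(R >= 0))
  # m > 1: check against direct enumeration of embedded vectors
  m <- 3L; tau <- 2L
  R2 <- recurrence_matrix(x, m, tau)
  ns <- length(x) - (m - 1L) * tau
  expect_equal(dim(R2), c(ns, ns))
  for (i in c(1L, 5L, ns)) {
    for (j in c(2L, ns - 1L)) {
      vi <- x[i + (0:(m - 1)) * tau]
      vj <- x[j + (0:(m - 1)) * tau]
      expect_equal(R2[i, j], sqrt(sum((vi - vj)^2)))
    }
  }
  expect_error(recurrence_matrix(1:3, m = 5L, tau = 2L), "too short")
})

test_that("GASF/GADF match their angle tables and the algebraic dual formula", {
  expect_equal(gasf(c(-1, 0, 1)),
               matrix(c(1, 0, -1, 0, -1, 0, -1, 0, 1), 3))
  expect_equal(gadf(c(-1, 0, 1)),
               matrix(c(0, -1, 0, 1, 0, -1, 0, 1, 0), 3))
  expect_equal(gasf(rep(1, 5)), matrix(1, 5, 5))
  set.seed(14)
  for (i in 1:100) {
    x <- minmax_rescale(rnorm(16))
    root <- sqrt(1 - x^2)
    gs <- gasf(x); gd <- gadf(x)
    expect_lt(max(abs(gs - (outer(x, x) - outer(root, root)))), 1e-10)
    expect_lt(max(abs(gd - (outer(root, x) - outer(x, root)))), 1e-10)
    expect_true(all(diag(gd) == 0))
    expect_equal(gd, -t(gd))
  }
  expect_error(gasf(c(0, 2)), "within")
  expect_error(gadf(c(-3, 0)), "within")
})

test_that("MTF spreads row-normalized quantile-bin transition probabilities", {
  M <- mtf(c(1, 2, 3, 4), Q = 2)
  expect_equal(M, matrix(c(0.5, 0.5, 0, 0,
                           0.5, 0.5, 0, 0,
                           0.5, 0.5, 1, 1,
                           0.5, 0.5, 1, 1), 4))
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(60)
    Q <- sample(2:8, 1)
    M <- mtf(x, Q)
    expect_true(all(M >= 0 & M <= 1))
    # reconstruct the transition matrix and check row sums
    br <- quantile(x, seq(0, 1, length.out = Q + 1), names = FALSE)
    bins <- as.integer(cut(x, br, include.lowest = TRUE))
    W <- matrix(0, Q, Q)
    for (k in seq_len(59)) W[bins[k], bins[k + 1]] <- W[bins[k], bins[k + 1]] + 1
    occupied <- rowSums(W) > 0
    What <- W / ifelse(rowSums(W) > 0, rowSums(W), 1)
    expect_true(all(abs(rowSums(What)[occupied] - 1) < 1e-12))
    expect_equal(M, What[bins, bins])
  }
  expect_error(mtf(rep(c(1, 2), 20), Q = 4), "distinct")
})

test_that("pixel rendering is an affine 0..255 map with round-half-away and a constant-matrix rule", {
  cfg <- imaging_config("RP")
  img <- to_image(matrix(c(0, 1, 2, 1), 2), cfg)
  expect_identical(img$pixels, matrix(c(0L, 128L, 255L, 128L), 2))
  img0 <- to_image(matrix(pi, 3, 3), cfg)
  expect_identical(img0$pixels, matrix(0L, 3, 3))
  expect_error(to_image(matrix(c(1, NA, 2, 3), 2), cfg), "non-finite")
  # raw matrix is retained untouched
  m <- matrix(rnorm(16), 4)
  expect_identical(to_image(m, cfg)$matrix, m)
})

test_that("a 448-sample beat yields a 448 x 448 image under every method", {
  set.seed(16)
  x <- cumsum(rnorm(448))
  for (method in c("RP", "GASF", "GADF", "MTF")) {
    img <- encode_beat(x, imaging_config(method))
    expect_identical(dim(img$pixels), c(448L, 448L))
    expect_identical(dim(img$matrix), c(448L, 448L))
    expect_true(all(img$pixels >= 0L & img$pixels <= 255L))
  }
  # PAA changes the image side accordingly
  img64 <- encode_beat(x, imaging_config("GADF", paa_output_len = 64))
  expect_identical(dim(img64$pixels), c(64L, 64L))
})

test_that("transforms agree with an independent numpy reference implementation", {
  set.seed(17)
  X <- matrix(rnorm(100 * 64), nrow = 100)
  ref <- reference_transforms(X, Q = 8L)
  expect_false(is.null(ref))  # interpreter is part of the toolchain
  worst <- 0
  for (i in 1:100) {
    x <- X[i, ]
    worst <- max(worst,
                 max(abs(recurrence_matrix(x) - ref$rp[[i]])),
                 max(abs(gasf(minmax_rescale(x)) - ref$gasf[[i]])),
                 max(abs(gadf(minmax_rescale(x)) - ref$gadf[[i]])),
                 max(abs(mtf(x, 8L) - ref$mtf[[i]])))
  }
  expect_lt(worst, 1e-8)
})
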