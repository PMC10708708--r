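test_that("every 2-D model maps a single-channel image to a probability pair", {
  set.seed(51)
  img64 <- array(runif(64 * 64 * 2), dim = c(64, 64, 2))
  for (nm in c("ResNet18", "DenseNet121", "SqueezeNetV1")) {
    m <- build_model(nm, image_side = 64, seed = 1L)
    p <- predict_proba(m, img64)
    expect_identical(dim(p), c(2L, 2L))
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
    expect_true(all(p >= 0))
  }
  img448 <- array(runif(448 * 448), dim = c(448, 448, 1))
  for (nm in c("LeNet-Tanh", "LeNet-ReLU")) {
    m <- build_model(nm, image_side = 448, seed = 1L)
    p <- predict_proba(m, img448)
    expect_identical(dim(p), c(1L, 2L))
    expect_true(abs(sum(p) - 1) < 1e-6)
  }
  expect_error(build_model("nonsense"), "arg")
})

test_that("the 1-D FCN reads back its kernel and filter stack and ignores length", {
  m <- build_fcn1d(seed = 2L)
  convs <- m$layer_graph[m$layer_graph$type == "conv1d+bn", ]
  expect_identical(convs$kernel, c("8", "5", "3"))
  expect_identical(convs$out_channels, c(128, 256, 128))
  p448 <- predict_proba(m, matrix(rnorm(448), 1))
  p300 <- predict_proba(m, matrix(rnorm(300), 1))
  expect_identical(dim(p448), c(1L, 2L))
  expect_identical(dim(p300), c(1L, 2L))
  expect_true(abs(sum(p448) - 1) < 1e-6)
  # zero input still yields a valid probability vector
  p0 <- predict_proba(m, matrix(0, 1, 448))
  expect_true(abs(sum(p0) - 1) < 1e-6)
  # identical seeds give identical parameter counts (and weights)
  expect_identical(n_parameters(build_fcn1d(seed = 3L)),
                   n_parameters(build_fcn1d(seed = 3L)))
})

test_that("the modified LeNet halves the spatial size down to 28 px before its core", {
  m <- build_model("LeNet-Tanh", image_side = 448, seed = 1L)
  lg <- m$layer_graph
  trace <- as.integer(lg$out_size[1:4])
  expect_identical(trace, c(224L, 112L, 56L, 28L))
  # the classic core then shrinks 28 -> 24 -> 12 -> 8 -> 4 -> 1
  expect_identical(as.integer(lg$out_size[5:9]), c(24L, 12L, 8L, 4L, 1L))
  expect_error(build_model("LeNet-Tanh", image_side = 100), "divisible")
  expect_error(build_model("LeNet-Tanh", image_side = 64), "too small")
})

test_that("saving and restoring weights reproduces forward outputs exactly", {
  set.seed(52)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  m <- build_model("SqueezeNetV1", image_side = 64, seed = 5L)
  fit_model(m, x, c(0L, 1L, 0L), epochs = 1, batch_size = 3, lr = 1e-3,
            seed = 6L)
  p1 <- predict_proba(m, x)
  w <- get_weights(m)
  m2 <- build_model("SqueezeNetV1", image_side = 64, seed = 99L)
  set_weights(m2, w)
  expect_identical(predict_proba(m2, x), p1)
})

test_that("two builds under one seed are identical; training moves the weights", {
  m1 <- build_model("ResNet18", image_side = 32, seed = 11L)
  m2 <- build_model("ResNet18", image_side = 32, seed = 11L)
  x <- array(runif(32 * 32 * 2), dim = c(32, 32, 2))
  expect_identical(predict_proba(m1, x), predict_proba(m2, x))
  fit_model(m1, x, c(0L, 1L), epochs = 1, batch_size = 2, lr = 1e-2,
            seed = 1L)
  expect_false(identical(predict_proba(m1, x), predict_proba(m2, x)))
})

test_that("every architecture fits a 200-image separable set to at least 95% within 20 epochs", {
  # all-bright vs all-dark classes; image sides chosen per architecture
  # so the check completes at desk scale (gradient flow, not capacity,
  # is under test)
  cases <- list(
    list(name = "SqueezeNetV1", side = 64L, lr = 1e-3),
    list(name = "ResNet18", side = 64L, lr = 1e-3),
    list(name = "DenseNet121", side = 32L, lr = 1e-3),
    list(name = "LeNet-ReLU", side = 448L, lr = 1e-3),
    list(name = "LeNet-Tanh", side = 448L, lr = 1e-3)
  )
  for (cs in cases) {
    dat <- make_bright_dark_images(200L, cs$side, seed = 404L)
    m <- build_model(cs$name, image_side = cs$side, seed = 7L)
    h <- fit_model(m, dat$x, dat$y, epochs = 20, batch_size = 16,
                   optimizer = "adam", lr = cs$lr, seed = 8L,
                   early_stop_train_acc = 0.995)
    expect_gte(max(h$train_accuracy), 0.95)
  }
  dat1 <- make_bright_dark_series(200L, 64L, seed = 405L)
  mf <- build_fcn1d(seed = 7L)
  hf <- fit_model(mf, dat1$x, dat1$y, epochs = 20, batch_size = 16,
                  optimizer = "adam", lr = 1e-3, seed = 8L,
                  early_stop_train_acc = 0.995)
  expect_gte(max(hf$train_accuracy), 0.95)
})
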