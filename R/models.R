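#' CNN model zoo for beat-image quality classification
#'
#' Builds one of the six classifier architectures used in the pipeline as
#' a ready-to-train network with a two-way softmax head:
#'
#' * `"LeNet-Tanh"` — classic LeNet-5 core (tanh activations, average
#'   pooling) with two extra (5x5, stride-2) convolution + stride-2
#'   average-pooling pairs prepended so the core sees a small feature map
#'   even at high input resolution (448 -> 224 -> 112 -> 56 -> 28).
#' * `"LeNet-ReLU"` — same topology with ReLU activations and max pooling.
#' * `"ResNet18"` — standard 18-layer residual network, first convolution
#'   adapted to a single input channel.
#' * `"DenseNet121"` — four dense blocks of 6/12/24/16 layers, growth
#'   rate 32, bottleneck factor 4, transition compression 0.5.
#' * `"SqueezeNetV1"` — SqueezeNet v1.0 (eight fire modules, no bypass),
#'   convolutional classifier head with global average pooling.
#' * `"FCN1D"` — the 1-D fully convolutional baseline; see [build_fcn1d()].
#'
#' All 2-D models take a single-channel `image_side` x `image_side` input;
#' no pretrained weights are used. Weight initialization draws from the
#' current R RNG stream (or from `seed` when given), so two builds under
#' the same seed are identical.
#'
#' @param name Architecture name (see above).
#' @param image_side Input image side in pixels (default 448). The LeNet
#'   variants require a side divisible by 16 and large enough for their
#'   valid-padding core.
#' @param seed Optional integer; when given, weight initialization is
#'   seeded locally and the caller's RNG state is restored afterwards.
#' @return An object of class `bcg_model` with elements `name`,
#'   `input_shape`, `n_classes`, `layer_graph` (a data.frame describing
#'   every layer: type, kernel, stride, padding, output channels,
#'   activation, output spatial size) and the internal network graph.
#' @export
build_model <- function(name = c("LeNet-Tanh", "LeNet-ReLU", "ResNet18",
                                 "DenseNet121", "SqueezeNetV1", "FCN1D"),
                        image_side = 448L, seed = NULL) {
  name <- match.arg(name)
  image_side <- as.integer(image_side)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (name == "FCN1D") return(build_fcn1d(seed = NULL))
  builder <- switch(name,
    "LeNet-Tanh" = function() build_lenet(image_side, relu = FALSE),
    "LeNet-ReLU" = function() build_lenet(image_side, relu = TRUE),
    "ResNet18" = function() build_resnet18(image_side),
    "DenseNet121" = function() build_densenet121(image_side),
    "SqueezeNetV1" = function() build_squeezenet(image_side))
  out <- builder()
  structure(
    list(name = name, input_shape = c(1L, image_side, image_side),
         n_classes = 2L, image_side = image_side,
         layer_graph = out$layer_graph, graph = out$graph),
    class = "bcg_model")
}

# Layer bookkeeping rows for the human-readable layer_graph table.
lg_row <- function(layer, type, kernel = NA, stride = NA, pad = NA,
                   out_channels = NA, activation = NA, out_size = NA) {
  data.frame(layer = layer, type = type,
             kernel = if (length(kernel) > 1) paste(kernel, collapse = "x") else as.character(kernel),
             stride = as.character(stride), pad = as.character(pad),
             out_channels = out_channels, activation = as.character(activation),
             out_size = as.character(out_size), stringsAsFactors = FALSE)
}

conv_out <- function(s, k, stride, pad) (s + 2L * pad - k) %/% stride + 1L

# Modified LeNet-5. Two (conv 5x5 stride 2, pad 2) + (pool 2 stride 2)
# pairs are prepended to the classic core so that a 448-px image reaches
# the core at 28 px. The third core convolution uses a kernel equal to
# the remaining spatial size (the classic "C5" layer is fully connected
# in effect). Tanh/avg-pool or ReLU/max-pool per variant.
build_lenet <- function(side, relu) {
  if (side %% 16L != 0L) {
    stop("LeNet variants need image_side divisible by 16, got ", side)
  }
  s_core <- side %/% 16L
  if (s_core < 12L || (s_core - 4L) %% 2L != 0L) {
    stop("image_side ", side, " too small for the LeNet valid-padding core")
  }
  act <- if (relu) mod_relu else mod_tanh
  pool <- if (relu) mod_maxpool else mod_avgpool
  scheme <- if (relu) "he" else "glorot"
  g <- nn_graph()
  lg <- list()
  s <- side
  id <- 0L

  add_conv <- function(id, cin, cout, k, stride, pad, label) {
    id <- g_chain(g, id, list(mod_conv(cin, cout, k, stride, pad, init = scheme),
                              act()))
    s <<- conv_out(s, k, stride, pad)
    lg[[length(lg) + 1L]] <<- lg_row(label, "conv", c(k, k), stride, pad, cout,
                                     if (relu) "relu" else "tanh", s)
    id
  }
  add_pool <- function(id, label) {
    id <- g_add(g, pool(2L, 2L), id)
    s <<- conv_out(s, 2L, 2L, 0L)
    lg[[length(lg) + 1L]] <<- lg_row(label, if (relu) "maxpool" else "avgpool",
                                     2, 2, 0, NA, NA, s)
    id
  }

  id <- add_conv(id, 1L, 6L, 5L, 2L, 2L, "pre_conv1")
  id <- add_pool(id, "pre_pool1")
  id <- add_conv(id, 6L, 6L, 5L, 2L, 2L, "pre_conv2")
  id <- add_pool(id, "pre_pool2")
  id <- add_conv(id, 6L, 6L, 5L, 1L, 0L, "C1")
  id <- add_pool(id, "S2")
  id <- add_conv(id, 6L, 16L, 5L, 1L, 0L, "C3")
  id <- add_pool(id, "S4")
  k5 <- s  # full-spatial kernel: C5 acts as a fully connected layer
  id <- add_conv(id, 16L, 120L, k5, 1L, 0L, "C5")
  id <- g_add(g, mod_flatten(), id)
  id <- g_chain(g, id, list(mod_linear(120L, 84L, init = scheme), act()))
  lg[[length(lg) + 1L]] <- lg_row("F6", "linear", NA, NA, NA, 84,
                                  if (relu) "relu" else "tanh", NA)
  id <- g_add(g, mod_linear(84L, 2L, init = scheme), id)
  lg[[length(lg) + 1L]] <- lg_row("output", "linear", NA, NA, NA, 2,
                                  "softmax", NA)
  list(graph = g, layer_graph = do.call(rbind, lg))
}

build_resnet18 <- function(side) {
  g <- nn_graph()
  lg <- list()
  s <- side
  id <- g_chain(g, 0L, list(mod_conv(1L, 64L, 7L, 2L, 3L), mod_bn(64L),
                            mod_relu()))
  s <- conv_out(s, 7L, 2L, 3L)
  lg[[1]] <- lg_row("stem", "conv+bn", c(7, 7), 2, 3, 64, "relu", s)
  id <- g_add(g, mod_maxpool(3L, 2L, 1L), id)
  s <- conv_out(s, 3L, 2L, 1L)
  lg[[2]] <- lg_row("stem_pool", "maxpool", 3, 2, 1, NA, NA, s)

  basic_block <- function(id, cin, cout, stride) {
    main <- g_chain(g, id, list(
      mod_conv(cin, cout, 3L, stride, 1L), mod_bn(cout), mod_relu(),
      mod_conv(cout, cout, 3L, 1L, 1L), mod_bn(cout)))
    short <- if (stride != 1L || cin != cout) {
      g_chain(g, id, list(mod_conv(cin, cout, 1L, stride, 0L), mod_bn(cout)))
    } else id
    g_add(g, mod_relu(), g_add(g, "add", c(main, short)))
  }

  plan <- list(c(64L, 1L), c(64L, 1L), c(128L, 2L), c(128L, 1L),
               c(256L, 2L), c(256L, 1L), c(512L, 2L), c(512L, 1L))
  cin <- 64L
  for (i in seq_along(plan)) {
    cout <- plan[[i]][1]; st <- plan[[i]][2]
    id <- basic_block(id, cin, cout, st)
    s <- conv_out(s, 3L, st, 1L)
    lg[[length(lg) + 1L]] <- lg_row(sprintf("block%d", i), "residual",
                                    c(3, 3), st, 1, cout, "relu", s)
    cin <- cout
  }
  id <- g_add(g, mod_gap(), id)
  id <- g_add(g, mod_linear(512L, 2L), id)
  lg[[length(lg) + 1L]] <- lg_row("head", "gap+linear", NA, NA, NA, 2,
                                  "softmax", 1)
  list(graph = g, layer_graph = do.call(rbind, lg))
}

build_densenet121 <- function(side, growth = 32L, bn_size = 4L) {
  g <- nn_graph()
  lg <- list()
  s <- side
  id <- g_chain(g, 0L, list(mod_conv(1L, 64L, 7L, 2L, 3L), mod_bn(64L),
                            mod_relu()))
  s <- conv_out(s, 7L, 2L, 3L)
  lg[[1]] <- lg_row("stem", "conv+bn", c(7, 7), 2, 3, 64, "relu", s)
  id <- g_add(g, mod_maxpool(3L, 2L, 1L), id)
  s <- conv_out(s, 3L, 2L, 1L)
  lg[[2]] <- lg_row("stem_pool", "maxpool", 3, 2, 1, NA, NA, s)

  dense_layer <- function(id, cin) {
    out <- g_chain(g, id, list(
      mod_bn(cin), mod_relu(), mod_conv(cin, bn_size * growth, 1L, 1L, 0L),
      mod_bn(bn_size * growth), mod_relu(),
      mod_conv(bn_size * growth, growth, 3L, 1L, 1L)))
    g_add(g, "concat", c(id, out))
  }

  ch <- 64L
  blocks <- c(6L, 12L, 24L, 16L)
  for (bi in seq_along(blocks)) {
    for (li in seq_len(blocks[bi])) {
      id <- dense_layer(id, ch)
      ch <- ch + growth
    }
    lg[[length(lg) + 1L]] <- lg_row(sprintf("dense_block%d", bi),
                                    "dense block", "1x1 + 3x3", 1, 1, ch,
                                    "relu", s)
    if (bi < length(blocks)) {
      ch2 <- ch %/% 2L
      id <- g_chain(g, id, list(mod_bn(ch), mod_relu(),
                                mod_conv(ch, ch2, 1L, 1L, 0L),
                                mod_avgpool(2L, 2L)))
      s <- conv_out(s, 2L, 2L, 0L)
      lg[[length(lg) + 1L]] <- lg_row(sprintf("transition%d", bi),
                                      "conv+avgpool", c(1, 1), 2, 0, ch2,
                                      NA, s)
      ch <- ch2
    }
  }
  id <- g_chain(g, id, list(mod_bn(ch), mod_relu(), mod_gap(),
                            mod_linear(ch, 2L)))
  lg[[length(lg) + 1L]] <- lg_row("head", "bn+gap+linear", NA, NA, NA, 2,
                                  "softmax", 1)
  list(graph = g, layer_graph = do.call(rbind, lg))
}

build_squeezenet <- function(side) {
  g <- nn_graph()
  lg <- list()
  s <- side
  id <- g_chain(g, 0L, list(mod_conv(1L, 96L, 7L, 2L, 0L), mod_relu()))
  s <- conv_out(s, 7L, 2L, 0L)
  lg[[1]] <- lg_row("conv1", "conv", c(7, 7), 2, 0, 96, "relu", s)

  fire <- function(id, cin, sq, e1, e3, label) {
    sqz <- g_chain(g, id, list(mod_conv(cin, sq, 1L, 1L, 0L), mod_relu()))
    ex1 <- g_chain(g, sqz, list(mod_conv(sq, e1, 1L, 1L, 0L), mod_relu()))
    ex3 <- g_chain(g, sqz, list(mod_conv(sq, e3, 3L, 1L, 1L), mod_relu()))
    out <- g_add(g, "concat", c(ex1, ex3))
    lg[[length(lg) + 1L]] <<- lg_row(label, "fire",
                                     sprintf("s%d/e%d+e%d", sq, e1, e3),
                                     1, NA, e1 + e3, "relu", s)
    out
  }
  pool <- function(id, label) {
    id <- g_add(g, mod_maxpool(3L, 2L), id)
    s <<- conv_out(s, 3L, 2L, 0L)
    lg[[length(lg) + 1L]] <<- lg_row(label, "maxpool", 3, 2, 0, NA, NA, s)
    id
  }

  id <- pool(id, "pool1")
  id <- fire(id, 96L, 16L, 64L, 64L, "fire2")
  id <- fire(id, 128L, 16L, 64L, 64L, "fire3")
  id <- fire(id, 128L, 32L, 128L, 128L, "fire4")
  id <- pool(id, "pool4")
  id <- fire(id, 256L, 32L, 128L, 128L, "fire5")
  id <- fire(id, 256L, 48L, 192L, 192L, "fire6")
  id <- fire(id, 384L, 48L, 192L, 192L, "fire7")
  id <- fire(id, 384L, 64L, 256L, 256L, "fire8")
  id <- pool(id, "pool8")
  id <- fire(id, 512L, 64L, 256L, 256L, "fire9")
  # positive bias keeps the classifier ReLU in its linear region at the
  # start of training; with only two classes a zero-initialized head can
  # go entirely negative within a few optimizer steps and die
  head_conv <- mod_conv(512L, 2L, 1L, 1L, 0L)
  head_conv$par$b[] <- 0.5
  id <- g_chain(g, id, list(mod_dropout(0.5), head_conv,
                            mod_relu(), mod_gap()))
  lg[[length(lg) + 1L]] <- lg_row("classifier", "dropout+conv+gap",
                                  c(1, 1), 1, 0, 2, "softmax", 1)
  list(graph = g, layer_graph = do.call(rbind, lg))
}

#' 1-D fully convolutional baseline classifier
#'
#' Three 1-D convolution blocks with kernel sizes 8, 5 and 3 and filter
#' counts 128, 256 and 128, each followed by batch normalization and
#' ReLU; a global average pooling layer replaces the fully connected
#' stack, followed by a two-way softmax. Because of the global pooling
#' the network accepts a series of any length, not only the 448-sample
#' default.
#'
#' @param seed Optional integer seed for weight initialization.
#' @return A `bcg_model` whose input is a length-L single-channel series
#'   (internally shaped as a 1 x L image).
#' @export
build_fcn1d <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  g <- nn_graph()
  kernels <- c(8L, 5L, 3L)
  filters <- c(128L, 256L, 128L)
  cin <- 1L
  id <- 0L
  lg <- list()
  for (i in 1:3) {
    k <- kernels[i]; f <- filters[i]
    id <- g_chain(g, id, list(
      mod_conv(cin, f, c(1L, k), c(1L, 1L), c(0L, k %/% 2L)),
      mod_bn(f), mod_relu()))
    lg[[i]] <- lg_row(sprintf("conv%d", i), "conv1d+bn", k, 1, k %/% 2L, f,
                      "relu", NA)
    cin <- f
  }
  id <- g_chain(g, id, list(mod_gap(), mod_linear(128L, 2L)))
  lg[[4]] <- lg_row("head", "gap+linear", NA, NA, NA, 2, "softmax", 1)
  structure(
    list(name = "FCN1D", input_shape = c(1L, NA_integer_), n_classes = 2L,
         image_side = NA_integer_, layer_graph = do.call(rbind, lg),
         graph = g),
    class = "bcg_model")
}

#' @export
print.bcg_model <- function(x, ...) {
  np <- sum(vapply(x$graph$modules,
                   function(m) sum(vapply(m$par, length, integer(1))),
                   numeric(1)))
  cat(sprintf("<bcg_model> %s, %s parameters\n", x$name,
              format(np, big.mark = ",")))
  print(x$layer_graph, row.names = FALSE)
  invisible(x)
}

# Coerce input to the (H, W, C, N) tensor the graph expects.
as_input_tensor <- function(x, model) {
  if (is.matrix(x) && model$name == "FCN1D") {
    # rows = series, columns = time
    array(t(x), dim = c(1L, ncol(x), 1L, nrow(x)))
  } else if (length(dim(x)) == 3L) {
    array(x, dim = c(dim(x)[1], dim(x)[2], 1L, dim(x)[3]))
  } else if (length(dim(x)) == 4L) {
    x
  } else if (is.numeric(x) && is.null(dim(x))) {
    if (model$name == "FCN1D") array(x, dim = c(1L, length(x), 1L, 1L))
    else stop("2-D models need an image array input")
  } else stop("unsupported input shape")
}

#' Forward pass: class probabilities for a batch
#'
#' @param model A `bcg_model`.
#' @param x For 2-D models an (H, W, N) or (H, W, 1, N) array of images
#'   (pixel or raw scale); for `FCN1D` an N x L matrix of series or a
#'   single numeric vector.
#' @param training Logical; use batch statistics and dropout (training
#'   mode) instead of running statistics.
#' @return An N x 2 matrix of class probabilities (columns: low, high),
#'   each row summing to 1.
#' @export
predict_proba <- function(model, x, training = FALSE) {
  xt <- as_input_tensor(x, model)
  logits <- graph_forward(model$graph, xt, training = training)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- t(sweep(ex, 2, colSums(ex), "/"))
  colnames(probs) <- c("low", "high")
  probs
}

#' Train a model by mini-batch gradient descent
#'
#' Runs softmax cross-entropy training with one of the three supported
#' optimizers. Shuffling, weight initialization (at build time) and
#' dropout all draw from the R RNG; call with `seed` for a reproducible
#' run. Training can stop early once the running training accuracy of an
#' epoch reaches `early_stop_train_acc` (useful on easily separable data
#' where further epochs only cost time).
#'
#' @param model A `bcg_model` (modified in place; also returned).
#' @param x Input images/series as in [predict_proba()].
#' @param y Integer or logical labels (0/FALSE = low, 1/TRUE = high), or
#'   a factor/character vector with levels "low"/"high".
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size (default 64).
#' @param optimizer One of `"adam"`, `"sgd"` (momentum 0.9), `"rmsprop"`.
#' @param lr Learning rate.
#' @param seed Optional integer seed for shuffling/dropout.
#' @param early_stop_train_acc Optional accuracy in (0, 1] at which to
#'   stop; `NULL` disables early stopping.
#' @param max_grad_norm Clip gradients to this global L2 norm per step
#'   (default 5); `Inf` disables clipping. Stabilizes the batch-norm-free
#'   architectures against occasional exploding early steps.
#' @param verbose Print per-epoch loss and accuracy.
#' @return Invisibly, a list with per-epoch `loss` and `train_accuracy`.
#' @export
fit_model <- function(model, x, y, epochs = 10L, batch_size = 64L,
                      optimizer = "adam", lr = 1e-3, seed = NULL,
                      early_stop_train_acc = NULL, max_grad_norm = 5,
                      verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  y <- encode_labels(y)
  xt <- as_input_tensor(x, model)
  n <- dim(xt)[4]
  stopifnot(length(y) == n)
  opt <- make_optimizer(optimizer, lr)
  hist_loss <- hist_acc <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    correct <- 0L
    tot_loss <- 0
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      xb <- xt[, , , idx, drop = FALSE]
      yb <- y[idx]
      logits <- graph_forward(model$graph, xb, training = TRUE)
      ls <- softmax_xent(logits, yb)
      graph_backward(model$graph, ls$dlogits)
      clip_gradients(model$graph, max_grad_norm)
      optimizer_step(opt, model$graph)
      graph_clear_cache(model$graph)
      correct <- correct + sum(ls$pred == yb)
      tot_loss <- tot_loss + ls$loss * length(idx)
    }
    hist_loss <- c(hist_loss, tot_loss / n)
    hist_acc <- c(hist_acc, correct / n)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, train acc %.3f", ep,
                      tot_loss / n, correct / n))
    }
    if (!is.null(early_stop_train_acc) &&
        correct / n >= early_stop_train_acc) break
  }
  invisible(list(loss = hist_loss, train_accuracy = hist_acc))
}

# Accept 0/1, logicals, or "low"/"high" labels; return integer 0/1.
encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("low", "high"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.integer(y == "high"))
  }
  yi <- as.integer(y)
  if (!all(yi %in% c(0L, 1L))) stop("labels must be 0/1 or low/high")
  yi
}

#' Extract / restore model weights
#'
#' `get_weights()` returns all trainable parameters (and batch-norm
#' running statistics) as a nested list; `set_weights()` writes such a
#' list back into a model of identical architecture. A save/load
#' round-trip reproduces forward outputs exactly.
#'
#' @param model A `bcg_model`.
#' @return For `get_weights()`, a list with one element per layer.
#' @export
get_weights <- function(model) {
  lapply(model$graph$modules, function(m) {
    w <- m$par
    if (m$type == "bn") {
      w$running_mean <- m$running_mean
      w$running_var <- m$running_var
    }
    w
  })
}

#' @rdname get_weights
#' @param weights A list as returned by `get_weights()`.
#' @export
set_weights <- function(model, weights) {
  mods <- model$graph$modules
  stopifnot(length(weights) == length(mods))
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    w <- weights[[i]]
    if (m$type == "bn") {
      m$running_mean <- w$running_mean
      m$running_var <- w$running_var
      w$running_mean <- NULL
      w$running_var <- NULL
    }
    stopifnot(identical(sort(names(w)), sort(names(m$par))))
    for (nm in names(w)) m$par[[nm]] <- w[[nm]]
  }
  invisible(model)
}

#' Count trainable parameters of a model
#' @param model A `bcg_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$graph$modules,
             function(m) sum(vapply(m$par, length, integer(1))), numeric(1)))
}
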