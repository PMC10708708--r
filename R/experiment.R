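#' Stratified 50/20/30 train/validation/test split
#'
#' Splits `n` labeled samples into training (50%), validation (20%) and
#' test (30%) partitions, stratified by label. Partition sizes follow the
#' rounding scheme `test = ceiling(0.30 n)`, `validation =
#' ceiling(2/7 of the remainder)`, `train = rest`, which for n = 9626
#' yields the canonical 4812 / 1926 / 2888 sizes. Within each partition
#' the per-class counts are proportional (largest-remainder allocation,
#' ties to the earlier class), so class proportions are preserved to
#' within one sample. The assignment is deterministic given `(seed,
#' repeat_index)`.
#'
#' @param labels Vector of class labels (any two or more levels).
#' @param seed Master seed.
#' @param repeat_index Repetition number (1-based); different repetitions
#'   give independent shuffles under the same master seed.
#' @return An object of class `bcg_split`: list of integer index vectors
#'   `train`, `validation`, `test` (disjoint, exhaustive).
#' @export
make_split <- function(labels, seed = 1L, repeat_index = 1L) {
  n <- length(labels)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 3)) {
    stop("make_split(): class '", names(counts)[which.min(counts)],
         "' has fewer than 3 members; cannot stratify into 3 partitions")
  }
  n_test <- as.integer(ceiling(0.30 * n))
  n_val <- as.integer(ceiling(2 / 7 * (n - n_test)))

  # largest-remainder allocation of a partition of size `size` over the
  # remaining per-class counts
  allocate <- function(remaining, size) {
    share <- remaining / sum(remaining) * size
    base <- floor(share)
    left <- size - sum(base)
    if (left > 0) {
      ord <- order(share - base, remaining, decreasing = TRUE)
      base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    as.integer(base)
  }

  mix <- (as.integer(seed) %% 599479L) * 3581L + as.integer(repeat_index)
  pools <- with_seed(mix, {
    lapply(classes, function(cl) sample(which(labels == cl)))
  })
  remaining <- vapply(pools, length, integer(1))

  take <- function(sizes) {
    out <- integer(0)
    for (ci in seq_along(pools)) {
      k <- sizes[ci]
      if (k > 0) {
        out <- c(out, pools[[ci]][seq_len(k)])
        pools[[ci]] <<- pools[[ci]][-seq_len(k)]
      }
    }
    sort(out)
  }
  test <- take(allocate(remaining, n_test))
  remaining <- vapply(pools, length, integer(1))
  validation <- take(allocate(remaining, n_val))
  train <- sort(unlist(pools))

  structure(list(train = train, validation = validation, test = test),
            class = "bcg_split")
}

#' @export
print.bcg_split <- function(x, ...) {
  cat(sprintf("<bcg_split> train %d / validation %d / test %d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Binary confusion matrix
#'
#' @param true,pred Label vectors (0/1, logical or "low"/"high").
#' @return A 2 x 2 integer matrix, rows = true label, columns = predicted
#'   label, in the order (low, high).
#' @export
confusion_matrix <- function(true, pred) {
  t_i <- encode_labels(true)
  p_i <- encode_labels(pred)
  cm <- matrix(0L, 2, 2, dimnames = list(true = c("low", "high"),
                                         predicted = c("low", "high")))
  for (k in seq_along(t_i)) {
    cm[t_i[k] + 1L, p_i[k] + 1L] <- cm[t_i[k] + 1L, p_i[k] + 1L] + 1L
  }
  cm
}

#' Classification accuracy of a confusion matrix
#' @param cm A 2 x 2 confusion matrix of counts.
#' @return Proportion of correctly classified samples in [0, 1].
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("accuracy(): confusion matrix has zero total")
  sum(diag(cm)) / total
}

#' Compare two classifiers by an independent-samples t-test
#'
#' Two-sided, equal-variance (pooled) t-test on the per-repetition
#' accuracies of two models. Two identical zero-variance groups return
#' t = 0, p = 1 by convention.
#'
#' @param acc_a,acc_b Numeric vectors (>= 2 values each) of per-repeat
#'   accuracies.
#' @return List with `t_statistic`, `p_value` and `df`.
#' @export
compare_models <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) >= 2, length(acc_b) >= 2)
  if (stats::sd(acc_a) == 0 && stats::sd(acc_b) == 0) {
    if (isTRUE(all.equal(mean(acc_a), mean(acc_b)))) {
      return(list(t_statistic = 0, p_value = 1,
                  df = length(acc_a) + length(acc_b) - 2))
    }
    return(list(t_statistic = sign(mean(acc_a) - mean(acc_b)) * Inf,
                p_value = 0, df = length(acc_a) + length(acc_b) - 2))
  }
  tt <- stats::t.test(acc_a, acc_b, var.equal = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Training/evaluation protocol configuration
#'
#' Defaults mirror the full protocol: optimizer grid Adam/SGD/RMSprop by
#' learning rates 0.1 to 0.0001 in decades, batch size 64, up to 500
#' epochs, five repetitions. Desk-scale runs override the grid and epoch
#' count.
#'
#' @param optimizers Character subset of `c("adam", "sgd", "rmsprop")`.
#' @param learning_rates Numeric vector of learning rates.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs per grid cell.
#' @param n_repeats Number of independent stratified re-splits.
#' @param seed Master seed fanned out to splits, weight init and data
#'   order.
#' @param early_stop_train_acc Optional early-stopping accuracy passed to
#'   [fit_model()].
#' @param max_grad_norm Gradient-clipping norm passed to [fit_model()].
#' @return A list of class `bcg_experiment_config`.
#' @export
experiment_config <- function(optimizers = c("adam", "sgd", "rmsprop"),
                              learning_rates = c(0.1, 0.01, 0.001, 0.0001),
                              batch_size = 64L, epochs = 500L,
                              n_repeats = 5L, seed = 1L,
                              early_stop_train_acc = NULL,
                              max_grad_norm = 5) {
  stopifnot(all(optimizers %in% c("adam", "sgd", "rmsprop")),
            length(optimizers) >= 1, length(learning_rates) >= 1,
            batch_size >= 1, epochs >= 1, n_repeats >= 1)
  structure(list(optimizers = optimizers,
                 learning_rates = learning_rates,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 early_stop_train_acc = early_stop_train_acc,
                 max_grad_norm = max_grad_norm),
            class = "bcg_experiment_config")
}

#' Run the repeated stratified evaluation protocol for one model
#'
#' For each of `n_repeats` repetitions: draw an independent stratified
#' 50/20/30 split, train one model per (optimizer, learning-rate) grid
#' cell on the training partition, select the cell with the best
#' validation accuracy, and record that cell's test accuracy and test
#' confusion matrix. Confusion matrices are pooled over repetitions, so
#' the pooled total equals `n_repeats` times the test-set size.
#'
#' @param x Input images as an (H, W, N) or (H, W, 1, N) array, or an
#'   N x L series matrix for `"FCN1D"`.
#' @param y Labels (0/1 or "low"/"high"), length N, reasonably balanced.
#' @param model_name One of the six architectures of [build_model()].
#' @param config An [experiment_config()].
#' @param method Optional imaging-method tag stored in the result.
#' @return An object of class `bcg_experiment_result`: per-repeat
#'   accuracies, their mean and SD, the pooled confusion matrix, and the
#'   hyperparameters chosen per repeat.
#' @export
train_and_evaluate <- function(x, y, model_name, config = experiment_config(),
                               method = NA_character_) {
  stopifnot(inherits(config, "bcg_experiment_config"))
  y <- encode_labels(y)
  grid <- expand.grid(optimizer = config$optimizers,
                      lr = config$learning_rates,
                      stringsAsFactors = FALSE)
  if (!nrow(grid)) stop("train_and_evaluate(): empty hyperparameter grid")
  image_side <- if (model_name == "FCN1D") NA_integer_ else dim(x)[1]

  subset_x <- function(idx) {
    if (model_name == "FCN1D") x[idx, , drop = FALSE]
    else if (length(dim(x)) == 3L) x[, , idx, drop = FALSE]
    else x[, , , idx, drop = FALSE]
  }
  eval_on <- function(model, idx) {
    probs <- predict_proba(model, subset_x(idx))
    pred <- as.integer(probs[, "high"] > 0.5)
    confusion_matrix(y[idx], pred)
  }

  per_repeat <- numeric(config$n_repeats)
  chosen <- vector("list", config$n_repeats)
  pooled <- matrix(0L, 2, 2, dimnames = list(true = c("low", "high"),
                                             predicted = c("low", "high")))
  for (r in seq_len(config$n_repeats)) {
    sp <- make_split(y, seed = config$seed, repeat_index = r)
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      cell_seed <- (config$seed * 131L + r * 17L + gi) %% 2147483647L
      model <- build_model(model_name, image_side = max(image_side, 16L,
                                                        na.rm = TRUE),
                           seed = cell_seed)
      fit_model(model, subset_x(sp$train), y[sp$train],
                epochs = config$epochs, batch_size = config$batch_size,
                optimizer = grid$optimizer[gi], lr = grid$lr[gi],
                seed = cell_seed + 1L,
                early_stop_train_acc = config$early_stop_train_acc,
                max_grad_norm = config$max_grad_norm)
      val_acc <- accuracy(eval_on(model, sp$validation))
      if (is.null(best) || val_acc > best$val_acc) {
        best <- list(model = model, val_acc = val_acc,
                     optimizer = grid$optimizer[gi], lr = grid$lr[gi])
      }
    }
    cm <- eval_on(best$model, sp$test)
    per_repeat[r] <- accuracy(cm)
    pooled <- pooled + cm
    chosen[[r]] <- list(optimizer = best$optimizer, lr = best$lr,
                        validation_accuracy = best$val_acc)
  }
  structure(
    list(method = method, model = model_name,
         per_repeat_accuracy = per_repeat,
         mean_accuracy = mean(per_repeat),
         sd_accuracy = stats::sd(per_repeat),
         pooled_confusion = pooled,
         hyperparams = chosen,
         n_test = sum(pooled) / config$n_repeats),
    class = "bcg_experiment_result")
}

#' @export
print.bcg_experiment_result <- function(x, ...) {
  cat(sprintf("<bcg_experiment_result> %s%s\n", x$model,
              if (is.na(x$method)) "" else paste0(" + ", x$method)))
  cat(sprintf("  accuracy: %.3f +/- %.3f over %d repeats\n",
              x$mean_accuracy, x$sd_accuracy,
              length(x$per_repeat_accuracy)))
  cat("  pooled confusion (rows = true, cols = predicted):\n")
  print(x$pooled_confusion)
  invisible(x)
}
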