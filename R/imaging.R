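#' Imaging configuration for beat-to-image encoding
#'
#' Bundles the tunable parameters of the four time-series imaging methods
#' used to turn a one-dimensional BCG beat into a square grayscale image.
#'
#' @param method One of `"RP"` (continuous recurrence plot), `"GASF"`
#'   (Gramian angular summation field), `"GADF"` (Gramian angular
#'   difference field) or `"MTF"` (Markov transition field).
#' @param rp_dimension_m Embedding dimension of the recurrence plot
#'   trajectories. The default 1 uses the raw samples as states.
#' @param rp_delay_tau Embedding time delay in samples (default 1).
#' @param mtf_bins_Q Number of quantile bins of the Markov transition
#'   field (default 8).
#' @param paa_output_len Optional output length of a piecewise aggregate
#'   approximation applied before imaging; `NULL` (the default) disables
#'   PAA so a 448-sample beat yields a 448 x 448 image.
#'
#' @return An object of class `bcg_imaging_config`.
#' @export
imaging_config <- function(method = c("RP", "GASF", "GADF", "MTF"),
                           rp_dimension_m = 1L,
                           rp_delay_tau = 1L,
                           mtf_bins_Q = 8L,
                           paa_output_len = NULL) {
  method <- match.arg(method)
  stopifnot(rp_dimension_m >= 1, rp_delay_tau >= 1, mtf_bins_Q >= 2)
  if (!is.null(paa_output_len)) stopifnot(paa_output_len >= 1)
  structure(
    list(method = method,
         rp_dimension_m = as.integer(rp_dimension_m),
         rp_delay_tau = as.integer(rp_delay_tau),
         mtf_bins_Q = as.integer(mtf_bins_Q),
         paa_output_len = if (is.null(paa_output_len)) NULL else as.integer(paa_output_len),
         pixel_scaling = "per_image_minmax"),
    class = "bcg_imaging_config")
}

#' Min-max rescaling to [-1, 1]
#'
#' Affine map sending the minimum of `x` to -1 and the maximum to +1:
#' \deqn{\tilde x_i = \frac{(x_i - \max X) + (x_i - \min X)}{\max X - \min X}}
#' This is the normalization required before the angular (arccos)
#' projection of the Gramian angular fields.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector of the same length, with range exactly [-1, 1].
#' @export
minmax_rescale <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  lo <- min(x); hi <- max(x)
  if (hi <= lo) {
    stop("minmax_rescale(): input is constant (zero range); cannot rescale")
  }
  ((x - hi) + (x - lo)) / (hi - lo)
}

#' Piecewise aggregate approximation
#'
#' Downsamples a series to `out_len` frame means. Frame boundaries fall at
#' fractional sample positions when `length(x)` is not a multiple of
#' `out_len`; boundary samples are then weighted by the fraction of the
#' sample covered by each frame, so the transform is exact for any pair of
#' lengths and reduces to plain frame means when the lengths divide.
#'
#' @param x Numeric vector.
#' @param out_len Target length, at most `length(x)`. Equal lengths give
#'   the identity.
#' @return Numeric vector of length `out_len`.
#' @export
paa <- function(x, out_len) {
  n <- length(x)
  stopifnot(is.numeric(x), n >= 1)
  out_len <- as.integer(out_len)
  if (out_len < 1 || out_len > n) {
    stop("paa(): out_len must be in [1, length(x)], got ", out_len)
  }
  if (out_len == n) return(as.numeric(x))
  step <- n / out_len
  out <- numeric(out_len)
  for (i in seq_len(out_len)) {
    a <- (i - 1) * step  # frame covers [a, b) in continuous sample units
    b <- i * step
    j0 <- floor(a) + 1
    j1 <- ceiling(b)
    idx <- j0:min(j1, n)
    w <- pmin(idx, b) - pmax(idx - 1, a)
    out[i] <- sum(x[idx] * w) / step
  }
  out
}

#' Continuous recurrence matrix
#'
#' Pairwise Euclidean distances between delay-embedded trajectory points
#' of a series: with embedding dimension `m` and delay `tau`, state i is
#' `(x[i], x[i+tau], ..., x[i+(m-1)tau])` and `R[i, j] = ||state_i -
#' state_j||`. With the defaults `m = 1`, `tau = 1` the states are the raw
#' samples and `R[i, j] = |x_i - x_j|`, giving an n x n matrix for an
#' n-sample beat. No recurrence threshold is applied; the continuous
#' distances themselves form the image.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (positive integer).
#' @param tau Embedding delay in samples (positive integer).
#' @return A square, symmetric, nonnegative matrix with zero diagonal and
#'   side `length(x) - (m - 1) * tau`.
#' @export
recurrence_matrix <- function(x, m = 1L, tau = 1L) {
  stopifnot(is.numeric(x), m >= 1, tau >= 1)
  n <- length(x)
  n_states <- n - (m - 1L) * tau
  if (n_states < 1L) {
    stop("recurrence_matrix(): series of length ", n,
         " too short for embedding (m = ", m, ", tau = ", tau, ")")
  }
  emb <- vapply(seq_len(m), function(k) x[seq_len(n_states) + (k - 1L) * tau],
                numeric(n_states))
  if (n_states == 1L) emb <- matrix(emb, nrow = 1L)
  unname(as.matrix(stats::dist(emb)))
}

.check_unit_range <- function(x, what) {
  if (any(x < -1 - 1e-12 | x > 1 + 1e-12)) {
    stop(what, "(): input must lie within [-1, 1]; rescale with minmax_rescale() first")
  }
  pmin(pmax(x, -1), 1)
}

#' Gramian angular summation field
#'
#' Projects a [-1, 1]-rescaled series to polar angles `phi_i =
#' arccos(x_i)` and returns the matrix `G[i, j] = cos(phi_i + phi_j)`,
#' algebraically `x_i x_j - sqrt(1 - x_i^2) sqrt(1 - x_j^2)`.
#'
#' @param x_rescaled Numeric vector with all values in [-1, 1] (see
#'   [minmax_rescale()]).
#' @return Square symmetric matrix of side `length(x_rescaled)`.
#' @export
gasf <- function(x_rescaled) {
  stopifnot(is.numeric(x_rescaled), all(is.finite(x_rescaled)))
  x <- .check_unit_range(x_rescaled, "gasf")
  phi <- acos(x)
  cos(outer(phi, phi, `+`))
}

#' Gramian angular difference field
#'
#' As [gasf()] but with the trigonometric difference: `G[i, j] =
#' sin(phi_i - phi_j)`, algebraically `sqrt(1 - x_i^2) x_j - x_i sqrt(1 -
#' x_j^2)`. The result is antisymmetric with a zero diagonal, so unlike
#' the summation field it preserves the direction of time.
#'
#' @inheritParams gasf
#' @return Square antisymmetric matrix of side `length(x_rescaled)`.
#' @export
gadf <- function(x_rescaled) {
  stopifnot(is.numeric(x_rescaled), all(is.finite(x_rescaled)))
  x <- .check_unit_range(x_rescaled, "gadf")
  phi <- acos(x)
  sin(outer(phi, phi, `-`))
}

#' Markov transition field
#'
#' Allocates each sample to one of `Q` equal-count quantile bins, counts
#' the first-order transitions `w[i, j] = #\{k : x_k in q_i, x_{k+1} in
#' q_j\}`, row-normalizes the count matrix to transition probabilities,
#' and spreads the probabilities along both time axes: `M[k, l] =
#' w_hat[bin(x_k), bin(x_l)]`. Samples equal to a bin edge go to the
#' lower bin. Rows of the transition matrix whose bin never occurs before
#' another sample stay zero.
#'
#' @param x Numeric vector with at least `Q` distinct quantile edges.
#' @param Q Number of quantile bins (integer >= 2, default 8).
#' @return Square matrix of side `length(x)` with entries in [0, 1].
#' @export
mtf <- function(x, Q = 8L) {
  stopifnot(is.numeric(x), all(is.finite(x)), length(x) >= 2)
  Q <- as.integer(Q)
  if (Q < 2) stop("mtf(): Q must be at least 2")
  breaks <- stats::quantile(x, probs = seq(0, 1, length.out = Q + 1), names = FALSE)
  if (anyDuplicated(breaks)) {
    stop("mtf(): series has too few distinct values to form ", Q,
         " quantile bins")
  }
  bins <- as.integer(cut(x, breaks, include.lowest = TRUE, right = TRUE))
  n <- length(x)
  W <- matrix(0, Q, Q)
  from <- bins[-n]; to <- bins[-1]
  for (k in seq_len(n - 1L)) W[from[k], to[k]] <- W[from[k], to[k]] + 1
  rs <- rowSums(W)
  W_hat <- W / ifelse(rs > 0, rs, 1)  # zero-count rows remain zero
  W_hat[bins, bins]
}

#' Render a transform matrix as an 8-bit grayscale beat image
#'
#' Applies a per-image min-max affine map of the raw transform values to
#' integer pixel intensities in [0, 255] (rounding half away from zero).
#' A constant matrix maps to all-zero pixels. The raw matrix is retained
#' alongside the pixels so downstream analysis is not limited to 8-bit
#' precision.
#'
#' @param matrix Square numeric matrix with finite entries.
#' @param config A [imaging_config()] object recording how the matrix was
#'   produced.
#' @param beat_id Optional integer identifier of the source beat.
#' @return An object of class `bcg_beat_image` with elements `matrix`,
#'   `pixels`, `method`, `config` and `beat_id`.
#' @export
to_image <- function(matrix, config, beat_id = NA_integer_) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!all(is.finite(matrix))) {
    stop("to_image(): transform matrix contains non-finite entries")
  }
  lo <- min(matrix); hi <- max(matrix)
  if (hi > lo) {
    scaled <- (matrix - lo) / (hi - lo) * 255
    pixels <- floor(scaled + 0.5)  # round half away from zero (values >= 0)
  } else {
    pixels <- matrix * 0
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(matrix = matrix, pixels = pixels, method = config$method,
         config = config, beat_id = as.integer(beat_id)),
    class = "bcg_beat_image")
}

#' Encode one BCG beat as a square grayscale image
#'
#' Runs the full imaging chain for a single beat: optional piecewise
#' aggregate approximation, the transform selected in `config` (RP, GASF,
#' GADF or MTF), and 8-bit per-image pixel scaling. The Gramian fields
#' min-max rescale the series to [-1, 1] internally. With PAA disabled a
#' 448-sample beat yields a 448 x 448 pixel image.
#'
#' @param beat A `bcg_beat` (its BCG channel is encoded) or a plain
#'   numeric vector.
#' @param config A [imaging_config()] object.
#' @return A `bcg_beat_image`.
#' @export
encode_beat <- function(beat, config) {
  stopifnot(inherits(config, "bcg_imaging_config"))
  if (inherits(beat, "bcg_beat")) {
    x <- beat$channels$bcg
    beat_id <- beat$beat_id
  } else {
    x <- as.numeric(beat)
    beat_id <- NA_integer_
  }
  if (!is.null(config$paa_output_len)) x <- paa(x, config$paa_output_len)
  mat <- switch(config$method,
    RP = recurrence_matrix(x, config$rp_dimension_m, config$rp_delay_tau),
    GASF = gasf(minmax_rescale(x)),
    GADF = gadf(minmax_rescale(x)),
    MTF = mtf(x, config$mtf_bins_Q))
  to_image(mat, config, beat_id)
}

#' @export
print.bcg_beat_image <- function(x, ...) {
  cat(sprintf("<bcg_beat_image> %s, %d x %d px, beat_id = %s\n",
              x$method, nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$beat_id), "?", x$beat_id)))
  invisible(x)
}

#' @export
print.bcg_imaging_config <- function(x, ...) {
  cat(sprintf("<bcg_imaging_config> method = %s", x$method))
  if (x$method == "RP") cat(sprintf(" (m = %d, tau = %d)", x$rp_dimension_m, x$rp_delay_tau))
  if (x$method == "MTF") cat(sprintf(" (Q = %d)", x$mtf_bins_Q))
  if (!is.null(x$paa_output_len)) cat(sprintf(", PAA -> %d", x$paa_output_len))
  cat("\n")
  invisible(x)
}
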