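# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# A 200-image linearly separable set: class 1 images are bright, class 0
# dark, with uniform texture so gradients flow through every channel.
make_bright_dark_images <- function(n = 200L, side = 64L, seed = 404L) {
  set.seed(seed)
  x <- array(0, dim = c(side, side, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    y[i] <- i %% 2L
    lo <- if (y[i] == 1L) 0.6 else 0
    x[, , i] <- array(stats::runif(side * side, lo, lo + 0.4),
                      dim = c(side, side))
  }
  list(x = x, y = y)
}

make_bright_dark_series <- function(n = 200L, len = 64L, seed = 405L) {
  set.seed(seed)
  y <- seq_len(n) %% 2L
  x <- t(vapply(seq_len(n), function(i) {
    lo <- if (y[i] == 1L) 0.6 else 0
    stats::runif(len, lo, lo + 0.4)
  }, numeric(len)))
  list(x = x, y = y)
}

# Independent numpy implementations of the four imaging transforms,
# written directly from their definitions (delay-embedded distances,
# arccos Gramian fields, quantile-bin Markov transitions). Used as a
# reference oracle only. Takes a matrix of series (rows) and returns,
# per transform, a list of matrices; all series are processed in one
# interpreter call. Returns NULL when no python interpreter is found.
reference_transforms <- function(X, Q = 8L) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) return(NULL)
  dir <- tempfile("refimg")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::write.table(format(X, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(dir, "x.txt"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  script <- file.path(dir, "ref.py")
  writeLines(c(
    "import numpy as np, sys, os",
    "d = sys.argv[1]; Q = int(sys.argv[2])",
    "X = np.atleast_2d(np.loadtxt(os.path.join(d, 'x.txt')))",
    "out = {nm: [] for nm in ('rp', 'gasf', 'gadf', 'mtf')}",
    "for x in X:",
    "    n = x.size",
    "    out['rp'].append(np.abs(x[:, None] - x[None, :]))",
    "    xr = ((x - x.max()) + (x - x.min())) / (x.max() - x.min())",
    "    phi = np.arccos(np.clip(xr, -1.0, 1.0))",
    "    out['gasf'].append(np.cos(phi[:, None] + phi[None, :]))",
    "    out['gadf'].append(np.sin(phi[:, None] - phi[None, :]))",
    "    # quantile bins: R type-7 quantiles, ties to the lower bin",
    "    br = np.quantile(x, np.linspace(0, 1, Q + 1), method='linear')",
    "    bins = np.sum(x[:, None] > br[None, 1:Q], axis=1)",
    "    W = np.zeros((Q, Q))",
    "    for k in range(n - 1):",
    "        W[bins[k], bins[k + 1]] += 1",
    "    rs = W.sum(axis=1, keepdims=True)",
    "    What = np.divide(W, rs, out=np.zeros_like(W), where=rs > 0)",
    "    out['mtf'].append(What[np.ix_(bins, bins)])",
    "for nm, Ms in out.items():",
    "    np.savetxt(os.path.join(d, nm + '.txt'), np.vstack(Ms), fmt='%.17e')"
  ), script)
  status <- system2(py, c(script, dir, Q), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) {
    stop("reference oracle failed: ", paste(status, collapse = "\n"))
  }
  len <- ncol(X)
  read_stack <- function(nm) {
    M <- unname(as.matrix(utils::read.table(file.path(dir,
                                                      paste0(nm, ".txt")))))
    lapply(seq_len(nrow(X)), function(i) M[(i - 1) * len + seq_len(len), ])
  }
  lapply(c(rp = "rp", gasf = "gasf", gadf = "gadf", mtf = "mtf"), read_stack)
}
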