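# Layer-graph engine backing the CNN model zoo. Layers are environments
# holding parameters, gradients and caches; a network is a DAG of nodes
# evaluated in definition order (forward) and reverse order (backward),
# which supports the residual additions of ResNet and the channel
# concatenations of DenseNet/SqueezeNet. Heavy kernels (convolution,
# pooling, batch norm) live in src/nn_ops.cpp.

new_module <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$grad <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

# He-normal (ReLU nets) or Glorot-uniform (tanh nets) weight init; draws
# come from the current R RNG stream so seeding is caller-controlled.
init_weights <- function(dims, fan_in, fan_out, scheme) {
  n <- prod(dims)
  w <- switch(scheme,
    he = stats::rnorm(n, sd = sqrt(2 / fan_in)),
    glorot = stats::runif(n, -sqrt(6 / (fan_in + fan_out)),
                          sqrt(6 / (fan_in + fan_out))),
    stop("unknown init scheme: ", scheme))
  array(w, dim = dims)
}

mod_conv <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                     init = "he") {
  kernel <- rep_len(as.integer(kernel), 2L)
  stride <- rep_len(as.integer(stride), 2L)
  pad <- rep_len(as.integer(pad), 2L)
  m <- new_module("conv", in_ch = in_ch, out_ch = out_ch,
                  kernel = kernel, stride = stride, pad = pad)
  fan_in <- prod(kernel) * in_ch
  fan_out <- prod(kernel) * out_ch
  m$par$W <- init_weights(c(kernel[1], kernel[2], in_ch, out_ch),
                          fan_in, fan_out, init)
  m$par$b <- numeric(out_ch)
  m$fwd <- function(x, training) {
    m$cache_x <- x
    nn_conv2d_fwd(x, m$par$W, m$par$b, m$stride[1], m$stride[2],
                  m$pad[1], m$pad[2])
  }
  m$bwd <- function(dy) {
    g <- nn_conv2d_bwd(m$cache_x, m$par$W, dy, m$stride[1], m$stride[2],
                       m$pad[1], m$pad[2])
    m$grad$W <- g$dw
    m$grad$b <- g$db
    g$dx
  }
  m
}

mod_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  m <- new_module("bn", ch = ch, eps = eps, momentum = momentum)
  m$par$gamma <- rep(1, ch)
  m$par$beta <- numeric(ch)
  m$running_mean <- numeric(ch)
  m$running_var <- rep(1, ch)
  m$fwd <- function(x, training) {
    out <- nn_bn_fwd(x, m$par$gamma, m$par$beta, m$running_mean,
                     m$running_var, m$eps, m$momentum, training)
    m$cache_x <- x
    m$cache_mean <- out$mean
    m$cache_var <- out$var
    out$y
  }
  m$bwd <- function(dy) {
    g <- nn_bn_bwd(m$cache_x, dy, m$par$gamma, m$cache_mean, m$cache_var,
                   m$eps)
    m$grad$gamma <- g$dgamma
    m$grad$beta <- g$dbeta
    g$dx
  }
  m
}

mod_relu <- function() {
  m <- new_module("relu")
  m$fwd <- function(x, training) {
    m$cache_pos <- x > 0
    x * m$cache_pos
  }
  m$bwd <- function(dy) dy * m$cache_pos
  m
}

mod_tanh <- function() {
  m <- new_module("tanh")
  m$fwd <- function(x, training) {
    y <- tanh(x)
    m$cache_y <- y
    y
  }
  m$bwd <- function(dy) dy * (1 - m$cache_y^2)
  m
}

mod_maxpool <- function(k, stride = k, pad = 0L) {
  m <- new_module("maxpool", k = as.integer(k), stride = as.integer(stride),
                  pad = as.integer(pad))
  m$fwd <- function(x, training) {
    out <- nn_maxpool_fwd(x, m$k, m$stride, m$pad)
    m$cache_idx <- out$idx
    m$cache_dim <- dim(x)
    out$y
  }
  m$bwd <- function(dy) nn_maxpool_bwd(dy, m$cache_idx, m$cache_dim)
  m
}

mod_avgpool <- function(k, stride = k, pad = 0L) {
  m <- new_module("avgpool", k = as.integer(k), stride = as.integer(stride),
                  pad = as.integer(pad))
  m$fwd <- function(x, training) {
    m$cache_dim <- dim(x)
    nn_avgpool_fwd(x, m$k, m$stride, m$pad)
  }
  m$bwd <- function(dy) nn_avgpool_bwd(dy, m$cache_dim, m$k, m$stride, m$pad)
  m
}

# Global average pooling: (H, W, C, N) -> (C, N) feature matrix.
mod_gap <- function() {
  m <- new_module("gap")
  m$fwd <- function(x, training) {
    d <- dim(x)
    m$cache_dim <- d
    y <- .colMeans(matrix(x, d[1] * d[2], d[3] * d[4]), d[1] * d[2],
                   d[3] * d[4])
    matrix(y, d[3], d[4])
  }
  m$bwd <- function(dy) {
    d <- m$cache_dim
    hw <- d[1] * d[2]
    array(rep(as.numeric(dy) / hw, each = hw), dim = d)
  }
  m
}

mod_flatten <- function() {
  m <- new_module("flatten")
  m$fwd <- function(x, training) {
    d <- dim(x)
    m$cache_dim <- d
    matrix(x, prod(d[1:3]), d[4])
  }
  m$bwd <- function(dy) array(dy, dim = m$cache_dim)
  m
}

mod_linear <- function(in_f, out_f, init = "he") {
  m <- new_module("linear", in_f = in_f, out_f = out_f)
  m$par$W <- matrix(init_weights(c(out_f, in_f), in_f, out_f, init),
                    out_f, in_f)
  m$par$b <- numeric(out_f)
  m$fwd <- function(x, training) {
    m$cache_x <- x
    m$par$W %*% x + m$par$b
  }
  m$bwd <- function(dy) {
    m$grad$W <- dy %*% t(m$cache_x)
    m$grad$b <- rowSums(dy)
    crossprod(m$par$W, dy)
  }
  m
}

mod_dropout <- function(p = 0.5) {
  m <- new_module("dropout", p = p)
  m$fwd <- function(x, training) {
    if (!training || m$p <= 0) {
      m$cache_mask <- NULL
      return(x)
    }
    mask <- (stats::runif(length(x)) >= m$p) / (1 - m$p)
    dim(mask) <- dim(x)
    m$cache_mask <- mask
    x * mask
  }
  m$bwd <- function(dy) if (is.null(m$cache_mask)) dy else dy * m$cache_mask
  m
}

# --- network graph ---------------------------------------------------------

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()     # each: list(op =, inputs = integer ids; 0 = input)
  g$modules <- list()   # layer environments, in insertion order
  g
}

# Append a node; `op` is a layer module, or the strings "add" / "concat"
# (channel-wise). Returns the node id for wiring later nodes.
g_add <- function(g, op, inputs) {
  inputs <- as.integer(inputs)  # force first: inputs may append nodes
  force(op)
  id <- length(g$nodes) + 1L
  if (is.environment(op)) g$modules[[length(g$modules) + 1L]] <- op
  g$nodes[[id]] <- list(op = op, inputs = as.integer(inputs))
  id
}

# Convenience: chain a list of modules sequentially from node `from`.
g_chain <- function(g, from, mods) {
  for (m in mods) from <- g_add(g, m, from)
  from
}

graph_forward <- function(g, x, training = FALSE) {
  vals <- vector("list", length(g$nodes))
  get_val <- function(i) if (i == 0L) x else vals[[i]]
  for (id in seq_along(g$nodes)) {
    nd <- g$nodes[[id]]
    if (is.environment(nd$op)) {
      vals[[id]] <- nd$op$fwd(get_val(nd$inputs[1]), training)
    } else if (identical(nd$op, "add")) {
      acc <- get_val(nd$inputs[1])
      for (i in nd$inputs[-1]) acc <- acc + get_val(i)
      vals[[id]] <- acc
    } else if (identical(nd$op, "concat")) {
      parts <- lapply(nd$inputs, get_val)
      chs <- vapply(parts, function(p) dim(p)[3], integer(1))
      d <- dim(parts[[1]])
      out <- array(0, dim = c(d[1], d[2], sum(chs), d[4]))
      at <- 0L
      for (p in parts) {
        cp <- dim(p)[3]
        out[, , at + seq_len(cp), ] <- p
        at <- at + cp
      }
      g$nodes[[id]]$split <- chs  # needed to route gradients back
      vals[[id]] <- out
    } else stop("unknown graph op")
  }
  g$vals <- vals
  vals[[length(vals)]]
}

graph_backward <- function(g, dout) {
  n <- length(g$nodes)
  grads <- vector("list", n)
  grads[[n]] <- dout
  add_grad <- function(i, gval) {
    if (i == 0L) return(invisible(NULL))
    grads[[i]] <<- if (is.null(grads[[i]])) gval else grads[[i]] + gval
  }
  for (id in rev(seq_len(n))) {
    gy <- grads[[id]]
    if (is.null(gy)) next
    nd <- g$nodes[[id]]
    if (is.environment(nd$op)) {
      add_grad(nd$inputs[1], nd$op$bwd(gy))
    } else if (identical(nd$op, "add")) {
      for (i in nd$inputs) add_grad(i, gy)
    } else if (identical(nd$op, "concat")) {
      at <- 0L
      for (j in seq_along(nd$inputs)) {
        cp <- nd$split[j]
        add_grad(nd$inputs[j], gy[, , at + seq_len(cp), , drop = FALSE])
        at <- at + cp
      }
    }
    grads[id] <- list(NULL)  # free as we go (keep list length stable)
  }
  invisible(NULL)
}

# Drop forward caches after an optimizer step to keep memory flat.
graph_clear_cache <- function(g) {
  g$vals <- NULL
  for (m in g$modules) {
    for (nm in grep("^cache", ls(m), value = TRUE)) rm(list = nm, envir = m)
  }
  invisible(NULL)
}

# --- optimizers ------------------------------------------------------------

make_optimizer <- function(type = c("adam", "sgd", "rmsprop"), lr) {
  type <- match.arg(type)
  opt <- new.env(parent = emptyenv())
  opt$type <- type
  opt$lr <- lr
  opt$state <- list()
  opt$t <- 0L
  opt
}

# Scale all gradients so their global L2 norm is at most max_norm.
clip_gradients <- function(g, max_norm) {
  if (!is.finite(max_norm)) return(invisible(NULL))
  total <- 0
  for (m in g$modules) {
    for (nm in names(m$grad)) total <- total + sum(m$grad[[nm]]^2)
  }
  total <- sqrt(total)
  if (total > max_norm) {
    sc <- max_norm / total
    for (m in g$modules) {
      for (nm in names(m$grad)) m$grad[[nm]] <- m$grad[[nm]] * sc
    }
  }
  invisible(NULL)
}

optimizer_step <- function(opt, g) {
  opt$t <- opt$t + 1L
  for (mi in seq_along(g$modules)) {
    m <- g$modules[[mi]]
    for (nm in names(m$par)) {
      gr <- m$grad[[nm]]
      if (is.null(gr)) next
      key <- paste0(mi, ".", nm)
      st <- opt$state[[key]]
      p <- m$par[[nm]]
      if (opt$type == "sgd") {           # momentum 0.9
        if (is.null(st)) st <- list(v = 0)
        st$v <- 0.9 * st$v + gr
        p <- p - opt$lr * st$v
      } else if (opt$type == "rmsprop") {  # alpha 0.99
        if (is.null(st)) st <- list(s = 0)
        st$s <- 0.99 * st$s + 0.01 * gr^2
        p <- p - opt$lr * gr / (sqrt(st$s) + 1e-8)
      } else {                           # adam, beta = (0.9, 0.999)
        if (is.null(st)) st <- list(mth = 0, vth = 0)
        st$mth <- 0.9 * st$mth + 0.1 * gr
        st$vth <- 0.999 * st$vth + 0.001 * gr^2
        mhat <- st$mth / (1 - 0.9^opt$t)
        vhat <- st$vth / (1 - 0.999^opt$t)
        p <- p - opt$lr * mhat / (sqrt(vhat) + 1e-8)
      }
      opt$state[[key]] <- st
      m$par[[nm]] <- p
    }
  }
  invisible(NULL)
}

# --- loss ------------------------------------------------------------------

# logits: (n_classes, N); y: integer class in 0..(n_classes-1).
# Returns mean cross-entropy, gradient wrt logits, and argmax predictions.
softmax_xent <- function(logits, y) {
  n <- ncol(logits)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")
  idx <- cbind(y + 1L, seq_len(n))
  loss <- -mean(log(pmax(probs[cbind(y + 1L, seq_len(n))], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n
  list(loss = loss, dlogits = dlogits, probs = probs,
       pred = max.col(t(probs)) - 1L)
}
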