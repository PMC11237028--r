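# Minimal LSTM sequence classifier in base R matrix code: stacked LSTM
# layers, a log-softmax head shared across days, full-batch
# backpropagation-through-time and Adam.  Dimensions here are small (tens of
# patients, days in the single digits to low tens), so full-batch dense
# matrix operations are the fastest simple choice.

sigmoid <- function(x) 1 / (1 + exp(-x))

# parameter initialisation; forget-gate bias starts at 1 (standard trick to
# keep memory open early in training)
lstm_init <- function(p, hidden, layers, n_class = 2L, seed = 1L,
                      bidirectional = FALSE) {
  with_seed(seed, {
    mk_dir <- function() {
      lapply(seq_len(layers), function(l) {
        in_dim <- if (l == 1L) p else hidden
        r <- 1 / sqrt(hidden)
        b <- rep(0, 4L * hidden)
        b[(hidden + 1L):(2L * hidden)] <- 1
        list(W = matrix(stats::runif(in_dim * 4L * hidden, -r, r), in_dim),
             U = matrix(stats::runif(hidden * 4L * hidden, -r, r), hidden),
             b = b)
      })
    }
    dirs <- if (bidirectional) list(fwd = mk_dir(), bwd = mk_dir())
            else list(fwd = mk_dir())
    top <- hidden * length(dirs)
    r <- 1 / sqrt(top)
    list(dirs = dirs,
         V = matrix(stats::runif(top * n_class, -r, r), top),
         bo = rep(0, n_class),
         hidden = hidden, layers = layers, n_class = n_class,
         bidirectional = bidirectional)
  })
}

# forward pass of one direction over X (n x T x p); returns per-layer caches
# and the top hidden states (list over t of n x H)
lstm_forward_dir <- function(dir_params, X, hidden) {
  n <- dim(X)[1]; T_ <- dim(X)[2]
  H <- hidden
  caches <- vector("list", length(dir_params))
  inp <- lapply(seq_len(T_), function(t) X[, t, , drop = FALSE][, 1, , drop = TRUE])
  if (dim(X)[3] == 1L) inp <- lapply(seq_len(T_), function(t) matrix(X[, t, 1], n))
  for (l in seq_along(dir_params)) {
    P <- dir_params[[l]]
    h <- matrix(0, n, H); cc <- matrix(0, n, H)
    steps <- vector("list", T_)
    hs <- vector("list", T_)
    for (t in seq_len(T_)) {
      x_t <- if (is.matrix(inp[[t]])) inp[[t]] else matrix(inp[[t]], n)
      a <- x_t %*% P$W + h %*% P$U + matrix(P$b, n, 4L * H, byrow = TRUE)
      i <- sigmoid(a[, 1:H, drop = FALSE])
      f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cc; h_prev <- h
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h <- o * tc
      steps[[t]] <- list(x = x_t, i = i, f = f, g = g, o = o, c = cc,
                         tc = tc, c_prev = c_prev, h_prev = h_prev)
      hs[[t]] <- h
    }
    caches[[l]] <- steps
    inp <- hs
  }
  list(caches = caches, top = inp)
}

# backward through one direction; dtop is a list over t of gradients w.r.t.
# the top hidden states
lstm_backward_dir <- function(dir_params, cache, dtop, hidden) {
  H <- hidden
  L <- length(dir_params)
  T_ <- length(dtop)
  n <- nrow(dtop[[1]])
  grads <- lapply(dir_params, function(P) {
    list(W = P$W * 0, U = P$U * 0, b = P$b * 0)
  })
  dh_upper <- dtop
  for (l in L:1) {
    P <- dir_params[[l]]
    steps <- cache$caches[[l]]
    dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
    dx_out <- vector("list", T_)
    for (t in T_:1) {
      s <- steps[[t]]
      dh <- dh_upper[[t]] + dh_next
      do <- dh * s$tc
      dc <- dc_next + dh * s$o * (1 - s$tc^2)
      di <- dc * s$g
      dg <- dc * s$i
      df <- dc * s$c_prev
      dc_next <- dc * s$f
      da <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do * s$o * (1 - s$o))
      grads[[l]]$W <- grads[[l]]$W + crossprod(s$x, da)
      grads[[l]]$U <- grads[[l]]$U + crossprod(s$h_prev, da)
      grads[[l]]$b <- grads[[l]]$b + colSums(da)
      dh_next <- da %*% t(P$U)
      dx_out[[t]] <- da %*% t(P$W)
    }
    dh_upper <- dx_out
  }
  grads
}

log_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  logits - m - log(rowSums(exp(logits - m)))
}

# forward over the full network: returns log-probabilities (n x T x C)
lstm_forward <- function(params, X, want_cache = FALSE) {
  T_ <- dim(X)[2]; n <- dim(X)[1]
  fw <- lstm_forward_dir(params$dirs$fwd, X, params$hidden)
  tops <- fw$top
  bw <- NULL
  if (params$bidirectional) {
    Xr <- X[, T_:1, , drop = FALSE]
    bw <- lstm_forward_dir(params$dirs$bwd, Xr, params$hidden)
    tops <- lapply(seq_len(T_), function(t) {
      cbind(fw$top[[t]], bw$top[[T_ - t + 1L]])
    })
  }
  logp <- array(NA_real_, c(n, T_, params$n_class))
  logits_list <- vector("list", T_)
  for (t in seq_len(T_)) {
    logits <- tops[[t]] %*% params$V +
      matrix(params$bo, n, params$n_class, byrow = TRUE)
    logits_list[[t]] <- logits
    logp[, t, ] <- log_softmax(logits)
  }
  if (want_cache) list(logp = logp, fw = fw, bw = bw, tops = tops)
  else logp
}

# negative log-likelihood loss and full gradient; y is n x T in {0, 1}
lstm_loss_grad <- function(params, X, y) {
  n <- dim(X)[1]; T_ <- dim(X)[2]; C <- params$n_class
  fwd <- lstm_forward(params, X, want_cache = TRUE)
  logp <- fwd$logp
  N <- n * T_
  loss <- 0
  dV <- params$V * 0; dbo <- params$bo * 0
  dtop <- vector("list", T_)
  for (t in seq_len(T_)) {
    lp <- matrix(logp[, t, ], n, C)
    onehot <- matrix(0, n, C)
    onehot[cbind(seq_len(n), y[, t] + 1L)] <- 1
    loss <- loss - sum(lp[onehot == 1]) / N
    dlogit <- (exp(lp) - onehot) / N
    dV <- dV + crossprod(fwd$tops[[t]], dlogit)
    dbo <- dbo + colSums(dlogit)
    dtop[[t]] <- dlogit %*% t(params$V)
  }
  H <- params$hidden
  dtop_f <- lapply(dtop, function(d) d[, 1:H, drop = FALSE])
  g_fwd <- lstm_backward_dir(params$dirs$fwd, fwd$fw, dtop_f, H)
  grads <- list(dirs = list(fwd = g_fwd), V = dV, bo = dbo)
  if (params$bidirectional) {
    dtop_b <- lapply(seq_len(T_), function(t) {
      dtop[[T_ - t + 1L]][, (H + 1):(2 * H), drop = FALSE]
    })
    grads$dirs$bwd <- lstm_backward_dir(params$dirs$bwd, fwd$bw, dtop_b, H)
  }
  list(loss = loss, grads = grads)
}

# elementwise map over two parallel parameter trees
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

numeric_leaves <- function(x) !is.list(x)

# Adam on the trainable leaves (dirs, V, bo)
lstm_train <- function(X, y, hidden = 128L, layers = 2L, lr = 0.01,
                       epochs = 100L, seed = 1L, bidirectional = FALSE) {
  params <- lstm_init(dim(X)[3], hidden, layers, 2L, seed, bidirectional)
  train_leaves <- c("dirs", "V", "bo")
  m <- lapply(params[train_leaves], function(x) tree_map2(function(a, b) a * 0, x, x))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  for (e in seq_len(epochs)) {
    lg <- lstm_loss_grad(params, X, y)
    step <- step + 1L
    for (nm in train_leaves) {
      g <- lg$grads[[nm]]
      m[[nm]] <- tree_map2(function(mm, gg) b1 * mm + (1 - b1) * gg, m[[nm]], g)
      v[[nm]] <- tree_map2(function(vv, gg) b2 * vv + (1 - b2) * gg^2, v[[nm]], g)
      upd <- tree_map2(function(mm, vv) {
        mm / (1 - b1^step) / (sqrt(vv / (1 - b2^step)) + eps)
      }, m[[nm]], v[[nm]])
      params[[nm]] <- tree_map2(function(p, u) p - lr * u, params[[nm]], upd)
    }
  }
  params
}
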