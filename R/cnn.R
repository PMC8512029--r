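#' CNN architecture for frequency-domain behavior classification
#'
#' The network consumes a `n_bins x n_channels` absolute-FFT input (256 x 9
#' by default). Three convolutional stages of 32/64/128 kernels of size
#' (3 x 1) slide along the frequency axis only (same zero padding) and over
#' the IMU-channel axis, each followed by ReLU and (2 x 1) max pooling with
#' stride 2, which halves the frequency axis. The resulting
#' `n_bins/8 x n_channels x 128` tensor (32 x 9 x 128 = 36,864 activations
#' at the default size) is flattened into a 500-node fully connected layer
#' with dropout 0.25, then a fully connected softmax layer over the classes.
#'
#' @param n_bins Frequency bins of the input (must be divisible by 8).
#' @param n_channels IMU channels (columns) of the input.
#' @param n_classes Output classes.
#' @param conv_maps Feature maps of the three convolutional layers.
#' @param fc_nodes Width of the fully connected layer.
#' @param dropout Dropout probability after the fully connected layer.
#' @return A `cnn_architecture` object; its `flatten_size` field holds the
#'   number of activations entering the fully connected layer.
#' @export
cnn_architecture <- function(n_bins = 256L, n_channels = 9L, n_classes = 9L,
                             conv_maps = c(32L, 64L, 128L), fc_nodes = 500L,
                             dropout = 0.25) {
  stopifnot(n_bins %% 8L == 0L, length(conv_maps) == 3L)
  structure(list(n_bins = as.integer(n_bins),
                 n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 conv_maps = as.integer(conv_maps),
                 fc_nodes = as.integer(fc_nodes), dropout = dropout,
                 flatten_size = as.integer(n_bins %/% 8L * n_channels *
                                             conv_maps[3])),
            class = "cnn_architecture")
}

# He-normal initialization of all weights
cnn_init <- function(arch, seed = NULL) {
  with_seed(seed, {
    cin <- c(1L, arch$conv_maps[1:2])
    conv <- lapply(1:3, function(l) {
      list(W = array(stats::rnorm(3L * cin[l] * arch$conv_maps[l],
                                  0, sqrt(2 / (3 * cin[l]))),
                     dim = c(3L, cin[l], arch$conv_maps[l])),
           b = rep(0, arch$conv_maps[l]))
    })
    list(conv = conv,
         W4 = matrix(stats::rnorm(arch$flatten_size * arch$fc_nodes,
                                  0, sqrt(2 / arch$flatten_size)),
                     arch$flatten_size, arch$fc_nodes),
         b4 = rep(0, arch$fc_nodes),
         W5 = matrix(stats::rnorm(arch$fc_nodes * arch$n_classes,
                                  0, sqrt(2 / arch$fc_nodes)),
                     arch$fc_nodes, arch$n_classes),
         b5 = rep(0, arch$n_classes))
  })
}

# Activations are stored as a (bins*S) x maps matrix, S = n_channels * n
# streams, rows ordered bin-fastest then stream. Convolution along the bin
# axis is three shifted matrix products with the (3, Cin, Cout) kernel.
# Shift every length-`bins` block of every column by one sample (zero
# fill). Implemented as a flat-vector shift with the block/column boundary
# positions re-zeroed, which costs one copy instead of a row gather.
shift_rows <- function(M, bins, offset) {
  if (offset == 0L) return(M)
  v <- as.vector(M)
  n <- length(v)
  if (offset == 1L) {
    v <- c(v[-1L], 0)
    v[seq(bins, n, by = bins)] <- 0
  } else if (offset == -1L) {
    v <- c(0, v[-n])
    v[seq(1L, n, by = bins)] <- 0
  } else stop("only unit shifts are supported")
  dim(v) <- dim(M)
  v
}

conv_forward <- function(M, bins, W, b) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  Z <- rep(b, each = nrow(M))
  dim(Z) <- c(nrow(M), cout)
  for (d in 1:3)
    Z <- Z + shift_rows(M, bins, d - 2L) %*% matrix(W[d, , ], cin, cout)
  Z
}

conv_backward <- function(dZ, M, bins, W) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  dW <- array(0, dim(W))
  dM <- matrix(0, nrow(M), cin)
  for (d in 1:3) {
    o <- d - 2L
    Md <- shift_rows(M, bins, o)
    dW[d, , ] <- crossprod(Md, dZ)
    dM <- dM + shift_rows(dZ %*% t(matrix(W[d, , ], cin, cout)), bins, -o)
  }
  list(dW = dW, db = colSums(dZ), dM = dM)
}

# (2 x 1) max pooling, stride 2, along the bin axis. Adjacent bin pairs
# are adjacent in memory, so the reduction is a stride-2 pmax on the flat
# vector; ties take the first element of the pair.
pool_forward <- function(A, bins) {
  P <- matrix(as.vector(A), nrow = 2L)
  mask <- P[1L, ] >= P[2L, ]
  list(out = matrix(pmax(P[1L, ], P[2L, ]), nrow(A) %/% 2L, ncol(A)),
       mask = mask)
}

pool_backward <- function(dOut, pool, n_in) {
  v <- as.vector(dOut)
  B <- matrix(0, 2L, length(v))
  B[1L, ] <- v * pool$mask
  B[2L, ] <- v * !pool$mask
  dim(B) <- c(n_in, ncol(dOut))
  B
}

# forward pass; X is an array (bins, channels, n). Returns probabilities
# and, when training, the caches needed for backprop (dropout mask drawn
# from the current RNG stream).
cnn_forward <- function(params, X, arch, training = FALSE) {
  n <- if (length(dim(X)) == 3L) dim(X)[3] else 1L
  S <- arch$n_channels * n
  bins <- arch$n_bins
  M <- matrix(X, bins * S, 1L)
  cache <- list()
  for (l in 1:3) {
    Z <- conv_forward(M, bins, params$conv[[l]]$W, params$conv[[l]]$b)
    A <- pmax(Z, 0)
    pool <- pool_forward(A, bins)
    cache[[l]] <- list(M = M, relu = Z > 0, pool = pool, bins = bins,
                       n_in = nrow(A))
    M <- pool$out
    bins <- bins %/% 2L
  }
  Fm <- t(matrix(aperm(array(M, c(bins, arch$n_channels, n,
                                  arch$conv_maps[3])), c(1, 2, 4, 3)),
                 arch$flatten_size, n))
  H <- pmax(Fm %*% params$W4 + rep(params$b4, each = n), 0)
  drop_mask <- NULL
  if (training && arch$dropout > 0) {
    drop_mask <- matrix(stats::runif(length(H)) >= arch$dropout, nrow(H))
    H <- H * drop_mask / (1 - arch$dropout)
  }
  logits <- H %*% params$W5 + rep(params$b5, each = n)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  list(probs = probs, Fm = Fm, H = H, drop_mask = drop_mask,
       cache = cache, n = n, final_bins = bins)
}

# cross-entropy loss and full gradient for a batch; Y is a 0/1 indicator
# matrix (n x classes)
cnn_loss_grad <- function(params, X, Y, arch) {
  fw <- cnn_forward(params, X, arch, training = TRUE)
  n <- fw$n
  loss <- -mean(log(pmax(rowSums(fw$probs * Y), 1e-12)))
  dlogits <- (fw$probs - Y) / n
  g <- list(W5 = crossprod(fw$H, dlogits), b5 = colSums(dlogits))
  dH <- dlogits %*% t(params$W5)
  if (!is.null(fw$drop_mask)) dH <- dH * fw$drop_mask / (1 - arch$dropout)
  dH <- dH * (fw$H > 0)
  g$W4 <- crossprod(fw$Fm, dH)
  g$b4 <- colSums(dH)
  dF <- dH %*% t(params$W4)
  dM <- matrix(aperm(array(t(dF), c(fw$final_bins, arch$n_channels,
                                    arch$conv_maps[3], n)), c(1, 2, 4, 3)),
               fw$final_bins * arch$n_channels * n, arch$conv_maps[3])
  g$conv <- vector("list", 3L)
  for (l in 3:1) {
    cc <- fw$cache[[l]]
    dA <- pool_backward(dM, cc$pool, cc$n_in)
    dZ <- dA * cc$relu
    cb <- conv_backward(dZ, cc$M, cc$bins, params$conv[[l]]$W)
    g$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dM <- cb$dM
  }
  list(loss = loss, grad = g)
}

adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  grad <- grad[names(params)]  # gradient list is built in backprop order
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grad, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

# minibatch Adam training; returns fitted parameters and the loss trace.
# With val_frac > 0 a stratified tail of the data is held out for early
# stopping (patience epochs without improvement; best weights kept).
cnn_train <- function(X, y, arch, epochs = 20L, batch_size = 64L,
                      lr = 1e-3, val_frac = 0, patience = 10L, seed = 1L,
                      verbose = FALSE) {
  n <- dim(X)[3]
  classes <- levels(y)
  Y <- diag(length(classes))[as.integer(y), , drop = FALSE]
  with_seed(seed, {
    params <- cnn_init(arch)
    st <- adam_init(params)
    idx_val <- integer()
    if (val_frac > 0) {
      idx_val <- unlist(lapply(split(seq_len(n), y), function(ix)
        sample(ix, max(1L, round(val_frac * length(ix))))))
    }
    idx_tr <- setdiff(seq_len(n), idx_val)
    best <- list(loss = Inf, params = params, wait = 0L)
    trace <- numeric()
    for (ep in seq_len(epochs)) {
      ord <- sample(idx_tr)
      ep_loss <- 0
      for (start in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, length(ord))]
        lg <- cnn_loss_grad(params, X[, , bi, drop = FALSE],
                            Y[bi, , drop = FALSE], arch)
        ep_loss <- ep_loss + lg$loss * length(bi)
        res <- adam_step(params, lg$grad, st, lr = lr)
        params <- res$params
        st <- res$state
      }
      trace[ep] <- ep_loss / length(idx_tr)
      if (length(idx_val)) {
        pv <- cnn_forward(params, X[, , idx_val, drop = FALSE], arch)$probs
        vloss <- -mean(log(pmax(rowSums(pv * Y[idx_val, , drop = FALSE]),
                                1e-12)))
        if (vloss < best$loss - 1e-5) {
          best <- list(loss = vloss, params = params, wait = 0L)
        } else {
          best$wait <- best$wait + 1L
          if (best$wait >= patience) break
        }
      }
      if (verbose) message(sprintf("epoch %d loss %.4f", ep, trace[ep]))
    }
    if (length(idx_val) && is.finite(best$loss)) params <- best$params
    list(params = params, trace = trace, classes = classes)
  })
}

# class probabilities for an input array, in prediction mode (no dropout);
# evaluated in chunks to bound memory
cnn_predict_probs <- function(params, X, arch, chunk = 256L) {
  n <- dim(X)[3]
  out <- matrix(0, n, arch$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    out[ix, ] <- cnn_forward(params, X[, , ix, drop = FALSE], arch)$probs
  }
  out
}
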