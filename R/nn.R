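# Minimal reverse-mode training engine for the two neural classifiers: a 1-D
# convolutional network over the ordered feature vector and a stacked LSTM
# over a (channels x band-statistics) folding of it. Dense/conv algebra is
# batched through BLAS matrix products (im2col for convolutions); training
# uses Adam with categorical cross-entropy on one-hot labels. Seeds control
# weight initialisation, shuffling and dropout masks.

.nn_init <- function(nr, nc, scale = sqrt(2 / nr)) {
  matrix(rnorm(nr * nc) * scale, nr, nc)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

.xent <- function(P, Y1hot) {
  -mean(rowSums(Y1hot * log(pmax(P, 1e-12))))
}

.onehot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# Adam: params and grads are flat lists of matrices/vectors.
.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- 1-D convolution helpers ---------------------------------------------
# Batch activations are kept in "vec layout": a (n * L) x C matrix whose row
# index is sample-fastest (row = i + n * (l - 1)). With that layout im2col
# column blocks are contiguous row ranges and no 3-D array reshaping is
# needed anywhere on the hot path.

.im2col_vec <- function(A, n, L, k) {
  L_out <- L - k + 1
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    cols[[j]] <- A[(n * (j - 1) + 1):(n * (j - 1) + n * L_out), , drop = FALSE]
  }
  do.call(cbind, cols)
}

.col2im_vec <- function(dM, n, L, k, C) {
  L_out <- L - k + 1
  dA <- matrix(0, n * L, C)
  for (j in seq_len(k)) {
    r <- (n * (j - 1) + 1):(n * (j - 1) + n * L_out)
    dA[r, ] <- dA[r, , drop = FALSE] +
      dM[, ((j - 1) * C + 1):(j * C), drop = FALSE]
  }
  dA
}

# Max pooling via a reshape: in vec layout, grouping the length axis into
# blocks of p turns each pool-window offset j into a contiguous row block of
# the (n * p) x (L2 * F) view, so the running max touches memory linearly.
.maxpool_fwd <- function(Y, n, L_out, p) {
  Fn <- ncol(Y)
  L2 <- L_out %/% p
  if (L2 < 1) abort("pooling window larger than feature map",
                    class = "painsense_config_error")
  L_use <- p * L2
  V <- matrix(Y[seq_len(n * L_use), , drop = FALSE], n * p)
  amax <- V[seq_len(n), , drop = FALSE]
  arg <- matrix(1L, n, L2 * Fn)
  if (p > 1) {
    for (j in 2:p) {
      sl <- V[((j - 1) * n + 1):(j * n), , drop = FALSE]
      upd <- sl > amax
      amax[upd] <- sl[upd]
      arg[upd] <- j
    }
  }
  list(Y = matrix(as.vector(amax), n * L2, Fn), arg = arg, n = n,
       L_out = L_out, L2 = L2, p = p)
}

.maxpool_bwd <- function(dP, cache) {
  n <- cache$n; L2 <- cache$L2; p <- cache$p
  Fn <- ncol(dP)
  dV <- matrix(0, n * p, L2 * Fn)
  dPm <- matrix(as.vector(dP), n, L2 * Fn)
  for (j in seq_len(p)) {
    sel <- which(cache$arg == j)
    if (length(sel) == 0) next
    gidx <- ((sel - 1L) %/% n) * (n * p) + (j - 1L) * n +
      ((sel - 1L) %% n) + 1L
    dV[gidx] <- dPm[sel]
  }
  dY <- matrix(0, n * cache$L_out, Fn)
  dY[seq_len(n * p * L2), ] <- matrix(as.vector(dV), n * p * L2, Fn)
  dY
}

.dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dims)
}

## ---- CNN -----------------------------------------------------------------

#' Describe the 1-D CNN architecture
#'
#' Two convolution blocks (ReLU), each followed by max-pooling and dropout
#' 0.25; flatten; two hidden fully connected ReLU layers with dropout 0.5 and
#' 0.3; softmax output of width `n_classes`.
#'
#' @param n_classes 2 or 3.
#' @param filters Filters per convolution block (default `c(32, 64)`).
#' @param kernel Kernel length (default 3).
#' @param pool Pooling window (default 2).
#' @param hidden Hidden fully connected widths (default `c(128, 64)`).
#' @param conv_dropout,fc_dropout Dropout rates (defaults 0.25 and
#'   `c(0.5, 0.3)`).
#' @return A `cnn_architecture` list.
#' @export
build_cnn <- function(n_classes, filters = c(32, 64), kernel = 3L, pool = 2L,
                      hidden = c(128, 64), conv_dropout = 0.25,
                      fc_dropout = c(0.5, 0.3)) {
  stopifnot(n_classes %in% c(2L, 3L))
  structure(list(n_classes = as.integer(n_classes), filters = filters,
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 hidden = hidden, conv_dropout = conv_dropout,
                 fc_dropout = fc_dropout,
                 dropout_sequence = c(rep(conv_dropout, length(filters)),
                                      fc_dropout)),
            class = "cnn_architecture")
}

.cnn_params <- function(arch, input_len) {
  L <- input_len
  C <- 1L
  params <- list()
  for (f in arch$filters) {
    params[[length(params) + 1]] <- .nn_init(arch$kernel * C, f,
                                             sqrt(2 / (arch$kernel * C)))
    params[[length(params) + 1]] <- numeric(f)
    L <- (L - arch$kernel + 1) %/% arch$pool
    if (L < 1) abort("input too short for the CNN architecture",
                     class = "painsense_config_error")
    C <- f
  }
  flat <- L * C
  widths <- c(flat, arch$hidden, arch$n_classes)
  for (i in seq_len(length(widths) - 1)) {
    params[[length(params) + 1]] <- .nn_init(widths[i], widths[i + 1])
    params[[length(params) + 1]] <- numeric(widths[i + 1])
  }
  params
}

.cnn_forward <- function(params, arch, X, training = FALSE,
                         dropout_scale = 1) {
  n <- nrow(X)
  L <- ncol(X)
  A <- matrix(as.vector(X), n * L, 1L)   # vec layout
  cache <- list()
  pi <- 1
  for (bi in seq_along(arch$filters)) {
    C_in <- ncol(A)
    M <- .im2col_vec(A, n, L, arch$kernel)
    Y <- M %*% params[[pi]]
    Y <- Y + rep(params[[pi + 1]], each = nrow(Y))
    relu_mask <- Y > 0
    Y <- Y * relu_mask
    L_out <- L - arch$kernel + 1
    pl <- .maxpool_fwd(Y, n, L_out, arch$pool)
    dm <- if (training) .dropout_mask(dim(pl$Y),
                                      arch$conv_dropout * dropout_scale)
    A2 <- if (is.null(dm)) pl$Y else pl$Y * dm
    cache[[bi]] <- list(M = M, relu = relu_mask, pool = pl, drop = dm,
                        n = n, L_in = L, C_in = C_in)
    A <- A2
    L <- pl$L2
    pi <- pi + 2
  }
  H <- matrix(as.vector(A), n)    # flatten: n x (L * C)
  fc_cache <- list(flat_dim = dim(A))
  widths <- length(arch$hidden)
  for (li in seq_len(widths + 1)) {
    Z <- sweep(H %*% params[[pi]], 2, params[[pi + 1]], `+`)
    if (li <= widths) {
      relu_mask <- Z > 0
      Hn <- Z * relu_mask
      dm <- if (training) .dropout_mask(dim(Hn),
                                        arch$fc_dropout[li] * dropout_scale)
      fc_cache[[paste0("l", li)]] <- list(H_in = H, relu = relu_mask,
                                          drop = dm)
      H <- if (is.null(dm)) Hn else Hn * dm
    } else {
      fc_cache[["out"]] <- list(H_in = H)
      H <- Z
    }
    pi <- pi + 2
  }
  list(P = .softmax_rows(H), conv_cache = cache, fc_cache = fc_cache)
}

.cnn_backward <- function(params, arch, fwd, Y1hot) {
  n <- nrow(Y1hot)
  grads <- vector("list", length(params))
  dZ <- (fwd$P - Y1hot) / n
  n_conv <- length(arch$filters)
  pi <- length(params) - 1
  # output layer
  oc <- fwd$fc_cache[["out"]]
  grads[[pi]] <- crossprod(oc$H_in, dZ)
  grads[[pi + 1]] <- colSums(dZ)
  dH <- tcrossprod(dZ, params[[pi]])
  pi <- pi - 2
  for (li in length(arch$hidden):1) {
    lc <- fwd$fc_cache[[paste0("l", li)]]
    if (!is.null(lc$drop)) dH <- dH * lc$drop
    dZ <- dH * lc$relu
    grads[[pi]] <- crossprod(lc$H_in, dZ)
    grads[[pi + 1]] <- colSums(dZ)
    dH <- tcrossprod(dZ, params[[pi]])
    pi <- pi - 2
  }
  dA <- matrix(as.vector(dH), fwd$fc_cache$flat_dim[1],
               fwd$fc_cache$flat_dim[2])
  for (bi in n_conv:1) {
    cc <- fwd$conv_cache[[bi]]
    if (!is.null(cc$drop)) dA <- dA * cc$drop
    dY <- .maxpool_bwd(dA, cc$pool)
    dY <- dY * cc$relu
    grads[[pi]] <- crossprod(cc$M, dY)
    grads[[pi + 1]] <- colSums(dY)
    dM <- tcrossprod(dY, params[[pi]])
    dA <- .col2im_vec(dM, cc$n, cc$L_in, arch$kernel, cc$C_in)
    pi <- pi - 2
  }
  grads
}

## ---- LSTM ----------------------------------------------------------------

#' Describe the stacked-LSTM architecture
#'
#' Stacked LSTM layers (tanh cell activations) with dropout after each
#' layer, a fully connected ReLU layer, and a softmax output of width
#' `n_classes`. A configuration warning is raised when any LSTM width falls
#' outside 32-512 units (performance degrades well outside that range); the
#' defaults sit inside 64-256.
#'
#' @param n_classes 2 or 3.
#' @param lstm_units Units per LSTM layer, descending (default
#'   `c(128, 64)`).
#' @param dropout Dropout rate after each LSTM layer (default 0.2).
#' @param fc_units Width of the fully connected ReLU layer (default 32).
#' @return An `rnn_architecture` list.
#' @export
build_rnn <- function(n_classes, lstm_units = c(128, 64), dropout = 0.2,
                      fc_units = 32L) {
  stopifnot(n_classes %in% c(2L, 3L))
  if (any(lstm_units < 32 | lstm_units > 512)) {
    warn("LSTM unit count outside 32-512; expect degraded performance",
         class = "painsense_config_warning")
  }
  structure(list(n_classes = as.integer(n_classes), lstm_units = lstm_units,
                 dropout = dropout, fc_units = as.integer(fc_units)),
            class = "rnn_architecture")
}

.rnn_params <- function(arch, input_dim) {
  params <- list()
  D <- input_dim
  for (U in arch$lstm_units) {
    params[[length(params) + 1]] <- .nn_init(D, 4 * U, 1 / sqrt(D))
    params[[length(params) + 1]] <- .nn_init(U, 4 * U, 1 / sqrt(U))
    b <- numeric(4 * U)
    b[(U + 1):(2 * U)] <- 1          # forget-gate bias
    params[[length(params) + 1]] <- b
    D <- U
  }
  widths <- c(D, arch$fc_units, arch$n_classes)
  for (i in seq_len(length(widths) - 1)) {
    params[[length(params) + 1]] <- .nn_init(widths[i], widths[i + 1])
    params[[length(params) + 1]] <- numeric(widths[i + 1])
  }
  params
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.lstm_layer_fwd <- function(Xseq, Wx, Wh, b) {
  # Xseq: list of T matrices n x D. Returns hidden sequence + caches.
  U <- ncol(Wh)
  n <- nrow(Xseq[[1]])
  uU <- U / 4
  H <- matrix(0, n, uU); Cs <- matrix(0, n, uU)
  Hs <- vector("list", length(Xseq))
  caches <- vector("list", length(Xseq))
  for (t in seq_along(Xseq)) {
    Z <- sweep(Xseq[[t]] %*% Wx + H %*% Wh, 2, b, `+`)
    i <- .sigmoid(Z[, 1:uU, drop = FALSE])
    f <- .sigmoid(Z[, (uU + 1):(2 * uU), drop = FALSE])
    g <- tanh(Z[, (2 * uU + 1):(3 * uU), drop = FALSE])
    o <- .sigmoid(Z[, (3 * uU + 1):(4 * uU), drop = FALSE])
    C_new <- f * Cs + i * g
    tc <- tanh(C_new)
    H_new <- o * tc
    caches[[t]] <- list(X = Xseq[[t]], H_prev = H, C_prev = Cs, i = i, f = f,
                        g = g, o = o, tc = tc)
    H <- H_new; Cs <- C_new
    Hs[[t]] <- H
  }
  list(Hs = Hs, caches = caches)
}

.lstm_layer_bwd <- function(dHs, caches, Wx, Wh) {
  # dHs: list of T gradients (or zeros) w.r.t. the hidden sequence.
  Tt <- length(caches)
  n <- nrow(dHs[[Tt]])
  uU <- ncol(dHs[[Tt]])
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(ncol(Wx))
  dH_next <- matrix(0, n, uU); dC_next <- matrix(0, n, uU)
  dXs <- vector("list", Tt)
  for (t in Tt:1) {
    ca <- caches[[t]]
    dH <- dHs[[t]] + dH_next
    dC <- dC_next + dH * ca$o * (1 - ca$tc^2)
    d_i <- dC * ca$g * ca$i * (1 - ca$i)
    d_f <- dC * ca$C_prev * ca$f * (1 - ca$f)
    d_g <- dC * ca$i * (1 - ca$g^2)
    d_o <- dH * ca$tc * ca$o * (1 - ca$o)
    dZ <- cbind(d_i, d_f, d_g, d_o)
    dWx <- dWx + crossprod(ca$X, dZ)
    dWh <- dWh + crossprod(ca$H_prev, dZ)
    db <- db + colSums(dZ)
    dXs[[t]] <- tcrossprod(dZ, Wx)
    dH_next <- tcrossprod(dZ, Wh)
    dC_next <- dC * ca$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dXs = dXs)
}

.rnn_forward <- function(params, arch, Xarr, training = FALSE) {
  # Xarr: n x T x D array
  d <- dim(Xarr)
  Xseq <- lapply(seq_len(d[2]), function(t) {
    matrix(Xarr[, t, , drop = FALSE], d[1], d[3])
  })
  pi <- 1
  layer_out <- list()
  for (li in seq_along(arch$lstm_units)) {
    lf <- .lstm_layer_fwd(Xseq, params[[pi]], params[[pi + 1]],
                          params[[pi + 2]])
    dm <- if (training && arch$dropout > 0) {
      lapply(lf$Hs, function(h) .dropout_mask(dim(h), arch$dropout))
    }
    Hs <- if (is.null(dm)) lf$Hs else purrr::map2(lf$Hs, dm, `*`)
    layer_out[[li]] <- list(fwd = lf, drop = dm)
    Xseq <- Hs
    pi <- pi + 3
  }
  H <- Xseq[[length(Xseq)]]         # final hidden state of the top layer
  fc1 <- sweep(H %*% params[[pi]], 2, params[[pi + 1]], `+`)
  relu_mask <- fc1 > 0
  H1 <- fc1 * relu_mask
  Z <- sweep(H1 %*% params[[pi + 2]], 2, params[[pi + 3]], `+`)
  list(P = .softmax_rows(Z), layers = layer_out, H_top = H, relu = relu_mask,
       H1 = H1, n_steps = d[2])
}

.rnn_backward <- function(params, arch, fwd, Y1hot) {
  n <- nrow(Y1hot)
  grads <- vector("list", length(params))
  pi <- length(params) - 3
  dZ <- (fwd$P - Y1hot) / n
  grads[[pi + 2]] <- crossprod(fwd$H1, dZ)
  grads[[pi + 3]] <- colSums(dZ)
  dH1 <- tcrossprod(dZ, params[[pi + 2]])
  dfc1 <- dH1 * fwd$relu
  grads[[pi]] <- crossprod(fwd$H_top, dfc1)
  grads[[pi + 1]] <- colSums(dfc1)
  dH_top <- tcrossprod(dfc1, params[[pi]])
  # only the last time step feeds the head
  Tt <- fwd$n_steps
  n_l <- length(arch$lstm_units)
  dHs <- NULL
  for (li in n_l:1) {
    lo <- fwd$layers[[li]]
    U <- arch$lstm_units[li]
    if (li == n_l) {
      dHs <- lapply(seq_len(Tt), function(t) matrix(0, n, U))
      dHs[[Tt]] <- dH_top
    }
    if (!is.null(lo$drop)) dHs <- purrr::map2(dHs, lo$drop, `*`)
    pi_l <- (li - 1) * 3 + 1
    bw <- .lstm_layer_bwd(dHs, lo$fwd$caches, params[[pi_l]],
                          params[[pi_l + 1]])
    grads[[pi_l]] <- bw$dWx
    grads[[pi_l + 1]] <- bw$dWh
    grads[[pi_l + 2]] <- bw$db
    dHs <- bw$dXs
  }
  grads
}

## ---- shared training loop ------------------------------------------------

.nn_train <- function(arch, X, y, n_classes, lr, epochs, batch_size, seed,
                      kind = c("cnn", "rnn"), rnn_fold = NULL) {
  kind <- match.arg(kind)
  with_local_seed(seed, {
    if (kind == "cnn") {
      params <- .cnn_params(arch, ncol(X))
      fwd_fn <- function(p, Xb, train) .cnn_forward(p, arch, Xb, train)
      bwd_fn <- function(p, fw, Yb) .cnn_backward(p, arch, fw, Yb)
      slice <- function(idx) X[idx, , drop = FALSE]
    } else {
      Xarr <- .fold_sequence(X, rnn_fold)
      params <- .rnn_params(arch, dim(Xarr)[3])
      fwd_fn <- function(p, Xb, train) .rnn_forward(p, arch, Xb, train)
      bwd_fn <- function(p, fw, Yb) .rnn_backward(p, arch, fw, Yb)
      slice <- function(idx) Xarr[idx, , , drop = FALSE]
    }
    Y1 <- .onehot(y, n_classes)
    state <- .adam_new(params)
    n <- length(y)
    history <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        fw <- fwd_fn(params, slice(idx), TRUE)
        Yb <- Y1[idx, , drop = FALSE]
        gr <- bwd_fn(params, fw, Yb)
        st <- .adam_step(params, gr, state, lr)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + .xent(fw$P, Yb) * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(fw$P) == as.integer(y[idx]))
      }
      history[[ep]] <- tibble(epoch = ep, loss = ep_loss / n,
                              accuracy = ep_correct / n)
    }
    list(params = params, history = dplyr::bind_rows(history))
  })
}

# Fold a feature matrix (n x [T * D], columns ordered as T consecutive
# blocks of D) into an n x T x D sequence array for the LSTM.
.fold_sequence <- function(X, fold) {
  n <- nrow(X)
  if (is.null(fold)) fold <- default_sequence_fold(ncol(X))
  Tt <- fold[1]; D <- fold[2]
  if (Tt * D != ncol(X)) {
    abort(sprintf("cannot fold %d features into %d x %d sequence",
                  ncol(X), Tt, D), class = "painsense_config_error")
  }
  aperm(array(X, c(n, D, Tt)), c(1, 3, 2))
}

#' Default sequence folding for the LSTM input
#'
#' The wavelet feature vector is ordered channel-major (each channel
#' contributes a block of `bands x statistics` = 54 values), so when the
#' feature count is a multiple of 54 the sequence axis is channels with a
#' 54-dimensional input per step. Otherwise the largest divisor of the
#' feature count not exceeding 64 is used as the step dimension.
#'
#' @param n_features Length of the feature vector.
#' @return Integer vector `c(steps, dims_per_step)`.
#' @export
default_sequence_fold <- function(n_features) {
  if (n_features %% 54 == 0) {
    return(c(n_features %/% 54L, 54L))
  }
  cand <- which(n_features %% seq_len(min(64L, n_features)) == 0)
  D <- max(cand)
  c(n_features %/% D, D)
}

# Chunked inference keeps the im2col intermediates bounded.
.nn_predict_prob <- function(model, Xs, chunk = 256L) {
  n <- nrow(Xs)
  out <- vector("list", ceiling(n / chunk))
  for (ci in seq_along(out)) {
    idx <- ((ci - 1L) * chunk + 1L):min(ci * chunk, n)
    Xb <- Xs[idx, , drop = FALSE]
    out[[ci]] <- if (model$kind == "cnn") {
      .cnn_forward(model$params, model$arch, Xb, training = FALSE)$P
    } else {
      .rnn_forward(model$params, model$arch,
                   .fold_sequence(Xb, model$rnn_fold), training = FALSE)$P
    }
  }
  do.call(rbind, out)
}
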