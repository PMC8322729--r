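# Convolutional-recurrent window classifier over raw 9-channel windows:
# three blocks of [1-D convolution -> batch normalization -> ReLU -> max
# pooling], two stacked LSTM cells with dropout, and a fully connected
# softmax head over {adl, fall}. The network is implemented natively in R
# (vectorised matrix algebra, manual backpropagation, Adam optimiser) so
# training is single-threaded, deterministic under a seed, and free of
# compiled-backend dependencies. Backpropagation is verified against
# numerical gradients in the test suite.
#
# Array convention: batches are arrays of dim (n, T, C) — sample, frame,
# channel. Flattening an (n, T, C) array with matrix(A, n*T, C) orders rows
# sample-fastest; all reshapes below rely on that column-major layout.

#' Conv+LSTM architecture specification
#'
#' The topology is fixed (three convolutional blocks, two recurrent
#' cells, softmax output); layer sizes are configurable. Defaults:
#' 32/64/128 filters, kernel 5, pool 2, LSTM hidden size 128, dropout 0.5.
#' With 50-frame input the three pools shrink time 50 -> 25 -> 12 -> 6.
#'
#' @param n_filters integer vector of length 3, filters per block.
#' @param kernel odd convolution kernel width (frames).
#' @param pool max-pooling factor per block.
#' @param lstm_hidden hidden units in each of the two LSTM cells.
#' @param dropout dropout fraction applied to recurrent outputs during
#'   training.
#' @param input_width window width in frames (default 50).
#' @param input_channels sensor channels (default 9; configurable so
#'   channel-subset variants, e.g. acceleration-only, fit the same
#'   topology).
#' @param n_classes output classes, default 2 ({adl, fall}).
#' @return An object of class `convlstm_spec`.
#' @export
convlstm_spec <- function(n_filters = c(32L, 64L, 128L), kernel = 5L,
                          pool = 2L, lstm_hidden = 128L, dropout = 0.5,
                          input_width = 50L, input_channels = 9L,
                          n_classes = 2L) {
  if (length(n_filters) != 3L) stop("exactly three convolutional blocks")
  if (kernel %% 2L != 1L) stop("kernel width must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  t_len <- input_width
  for (b in 1:3) {
    t_len <- t_len %/% pool
    if (t_len < 1L)
      stop(sprintf("pooling collapses the temporal axis below 1 at block %d",
                   b))
  }
  structure(list(n_filters = as.integer(n_filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), lstm_hidden = as.integer(lstm_hidden),
                 dropout = dropout, input_width = as.integer(input_width),
                 input_channels = as.integer(input_channels),
                 n_classes = as.integer(n_classes)),
            class = "convlstm_spec")
}

#' Stack `imu_window`s into a raw input array
#'
#' @param windows list of `imu_window` objects of equal width.
#' @param channels which channel groups to include, in order; default all
#'   nine (acc x/y/z, gyro x/y/z, Euler x/y/z).
#' @return Numeric array of dim `(n, width, n_channels)`.
#' @export
windows_to_array <- function(windows, channels = c("acc", "gyro", "euler")) {
  if (length(windows) == 0L) stop("no windows supplied")
  width <- windows[[1L]]$width
  pick <- function(w) {
    m <- NULL
    if ("acc" %in% channels) m <- cbind(m, w$acc_g)
    if ("gyro" %in% channels) m <- cbind(m, w$gyro_dps)
    if ("euler" %in% channels) m <- cbind(m, w$euler_deg)
    m
  }
  nc <- ncol(pick(windows[[1L]]))
  X <- array(0, c(length(windows), width, nc))
  for (i in seq_along(windows)) X[i, , ] <- pick(windows[[i]])
  X
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- layer primitives (forward returns a cache for backward) ----------

conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); n <- d[1L]; Tt <- d[2L]; C <- d[3L]
  P <- (k - 1L) %/% 2L
  Xp <- array(0, c(n, Tt + 2L * P, C))
  Xp[, (P + 1L):(P + Tt), ] <- X
  M <- matrix(0, n * Tt, k * C)
  for (j in seq_len(k))
    M[, ((j - 1L) * C + 1L):(j * C)] <-
      matrix(Xp[, j:(j + Tt - 1L), , drop = FALSE], n * Tt, C)
  Y <- M %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(out = array(Y, c(n, Tt, ncol(W))), M = M, dims = d, k = k, P = P)
}

conv1d_backward <- function(cache, W, dY) {
  d <- cache$dims; n <- d[1L]; Tt <- d[2L]; C <- d[3L]
  k <- cache$k; P <- cache$P
  dYm <- matrix(dY, n * Tt, dim(dY)[3L])
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)
  dXp <- array(0, c(n, Tt + 2L * P, C))
  for (j in seq_len(k))
    dXp[, j:(j + Tt - 1L), ] <- dXp[, j:(j + Tt - 1L), ] +
      array(dM[, ((j - 1L) * C + 1L):(j * C)], c(n, Tt, C))
  list(dX = dXp[, (P + 1L):(P + Tt), , drop = FALSE], dW = dW, db = db)
}

bn_forward <- function(X, gamma, beta, state, training, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(X)
  xm <- matrix(X, prod(d[1:2]), d[3L])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = array(y, d), xhat = xhat, inv = inv, dims = d, state = state)
}

bn_backward <- function(cache, gamma, dY) {
  d <- cache$dims
  m <- prod(d[1:2])
  dym <- matrix(dY, m, d[3L])
  dxhat <- sweep(dym, 2L, gamma, "*")
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  # dx = inv/m * (m*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(m * dxhat, 2L, s1) - sweep(cache$xhat, 2L, s2, "*")
  dx <- sweep(dx, 2L, cache$inv / m, "*")
  list(dX = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(X, p) {
  d <- dim(X); n <- d[1L]; Tt <- d[2L]; C <- d[3L]
  T2 <- Tt %/% p
  Y <- array(-Inf, c(n, T2, C))
  arg <- array(1L, c(n, T2, C))
  for (j in seq_len(p)) {
    slice <- X[, seq.int(j, by = p, length.out = T2), , drop = FALSE]
    upd <- slice > Y
    upd[is.na(upd)] <- TRUE  # propagate non-finite activations
    Y[upd] <- slice[upd]
    arg[upd] <- j
  }
  list(out = Y, arg = arg, dims = d, p = p)
}

maxpool_backward <- function(cache, dY) {
  d <- cache$dims; p <- cache$p
  T2 <- dim(dY)[2L]
  dX <- array(0, d)
  for (j in seq_len(p)) {
    mask <- cache$arg == j
    tmp <- array(0, dim(dY))
    tmp[mask] <- dY[mask]
    idx <- seq.int(j, by = p, length.out = T2)
    dX[, idx, ] <- dX[, idx, ] + tmp
  }
  dX
}

lstm_forward <- function(X, Wx, Wh, b) {
  d <- dim(X); n <- d[1L]; Tt <- d[2L]
  H <- nrow(Wh)
  h <- matrix(0, n, H)
  cc <- matrix(0, n, H)
  Hs <- array(0, c(n, Tt, H))
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- matrix(X[, t, ], n, d[3L])
    z <- xt %*% Wx + h %*% Wh
    z <- sweep(z, 2L, b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = cc, h_prev = h, tc = tc)
    cc <- c_new
    h <- h_new
    Hs[, t, ] <- h
  }
  list(out = Hs, steps = steps, dims = d, H = H)
}

lstm_backward <- function(cache, Wx, Wh, dH) {
  d <- cache$dims; n <- d[1L]; Tt <- d[2L]; H <- cache$H
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, d)
  dh_next <- matrix(0, n, H)
  dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tt))) {
    st <- cache$steps[[t]]
    dh <- matrix(dH[, t, ], n, H) + dh_next
    do_ <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- tcrossprod(dz, Wx)
    dh_next <- tcrossprod(dz, Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

## ---- model construction ------------------------------------------------

#' Build an untrained Conv+LSTM model
#'
#' Weights are initialised with He (convolutions, softmax head) and
#' uniform 1/sqrt(H) (recurrent) schemes; LSTM forget-gate biases start
#' at 1. All draws come from the given seed.
#'
#' @param spec a [convlstm_spec()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `convlstm`.
#' @export
build_convlstm <- function(spec = convlstm_spec(), seed = 1L) {
  stopifnot(inherits(spec, "convlstm_spec"))
  with_seed(seed, {
    k <- spec$kernel
    chans <- c(spec$input_channels, spec$n_filters)
    conv <- lapply(1:3, function(b) {
      fan_in <- k * chans[b]
      list(W = matrix(rnorm(fan_in * chans[b + 1L], 0, sqrt(2 / fan_in)),
                      fan_in, chans[b + 1L]),
           b = numeric(chans[b + 1L]))
    })
    bn <- lapply(1:3, function(b)
      list(gamma = rep(1, chans[b + 1L]), beta = numeric(chans[b + 1L])))
    H <- spec$lstm_hidden
    lstm_in <- c(spec$n_filters[3L], H)
    lstm <- lapply(1:2, function(l) {
      r <- 1 / sqrt(H)
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      list(Wx = matrix(runif(lstm_in[l] * 4L * H, -r, r), lstm_in[l], 4L * H),
           Wh = matrix(runif(H * 4L * H, -r, r), H, 4L * H),
           b = b)
    })
    fc <- list(W = matrix(rnorm(H * spec$n_classes, 0, sqrt(2 / H)),
                          H, spec$n_classes),
               b = numeric(spec$n_classes))
    bn_state <- lapply(1:3, function(b)
      list(mean = numeric(chans[b + 1L]), var = rep(1, chans[b + 1L])))
    structure(list(spec = spec,
                   params = list(conv = conv, bn = bn, lstm = lstm, fc = fc),
                   bn_state = bn_state,
                   input_stats = NULL,
                   classes = c("adl", "fall"),
                   history = numeric(0)),
              class = "convlstm")
  })
}

#' @export
print.convlstm <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<convlstm> 3 conv blocks (%s filters, kernel %d, pool %d) -> 2 LSTM cells (hidden %d) -> softmax(%d)\n",
    paste(s$n_filters, collapse = "/"), s$kernel, s$pool, s$lstm_hidden,
    s$n_classes))
  if (length(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$history), tail(x$history, 1L)))
  invisible(x)
}

# Standardise raw channels with training statistics held by the model.
standardise_input <- function(model, X) {
  if (is.null(model$input_stats)) return(X)
  for (c in seq_len(dim(X)[3L])) {
    X[, , c] <- (X[, , c] - model$input_stats$mean[c]) /
      model$input_stats$sd[c]
  }
  X
}

convlstm_forward <- function(model, X, training = FALSE,
                             dropout_masks = NULL) {
  spec <- model$spec
  p <- model$params
  if (length(dim(X)) != 3L || dim(X)[2L] != spec$input_width ||
      dim(X)[3L] != spec$input_channels)
    stop(sprintf("input must be an (n x %d x %d) array",
                 spec$input_width, spec$input_channels))
  X <- standardise_input(model, X)
  cache <- list()
  out <- X
  for (b in 1:3) {
    cv <- conv1d_forward(out, p$conv[[b]]$W, p$conv[[b]]$b, spec$kernel)
    bn <- bn_forward(cv$out, p$bn[[b]]$gamma, p$bn[[b]]$beta,
                     model$bn_state[[b]], training = training)
    model$bn_state[[b]] <- bn$state
    relu_mask <- bn$out > 0
    act <- bn$out * relu_mask
    mp <- maxpool_forward(act, spec$pool)
    cache[[b]] <- list(conv = cv, bn = bn, relu = relu_mask, pool = mp)
    out <- mp$out
  }
  l1 <- lstm_forward(out, p$lstm[[1L]]$Wx, p$lstm[[1L]]$Wh, p$lstm[[1L]]$b)
  h1 <- l1$out
  m1 <- NULL
  if (training && spec$dropout > 0) {
    m1 <- dropout_masks[[1L]]
    h1 <- h1 * m1
  }
  l2 <- lstm_forward(h1, p$lstm[[2L]]$Wx, p$lstm[[2L]]$Wh, p$lstm[[2L]]$b)
  Tt2 <- dim(l2$out)[2L]
  hT <- matrix(l2$out[, Tt2, ], dim(X)[1L], spec$lstm_hidden)
  m2 <- NULL
  if (training && spec$dropout > 0) {
    m2 <- dropout_masks[[2L]]
    hT <- hT * m2
  }
  logits <- sweep(hT %*% p$fc$W, 2L, p$fc$b, "+")
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, model = model,
       cache = list(blocks = cache, l1 = l1, l2 = l2, h1 = h1, hT = hT,
                    m1 = m1, m2 = m2, n = dim(X)[1L], Tt2 = Tt2))
}

convlstm_backward <- function(model, fw, Y1hot) {
  spec <- model$spec
  p <- model$params
  ch <- fw$cache
  n <- ch$n
  dlogits <- (fw$probs - Y1hot) / n
  g <- list(conv = vector("list", 3L), bn = vector("list", 3L),
            lstm = vector("list", 2L), fc = NULL)
  g$fc <- list(W = crossprod(ch$hT, dlogits), b = colSums(dlogits))
  dhT <- tcrossprod(dlogits, p$fc$W)
  if (!is.null(ch$m2)) dhT <- dhT * ch$m2
  dH2 <- array(0, dim(ch$l2$out))
  dH2[, ch$Tt2, ] <- dhT
  lb2 <- lstm_backward(ch$l2, p$lstm[[2L]]$Wx, p$lstm[[2L]]$Wh, dH2)
  g$lstm[[2L]] <- list(Wx = lb2$dWx, Wh = lb2$dWh, b = lb2$db)
  dH1 <- lb2$dX
  if (!is.null(ch$m1)) dH1 <- dH1 * ch$m1
  lb1 <- lstm_backward(ch$l1, p$lstm[[1L]]$Wx, p$lstm[[1L]]$Wh, dH1)
  g$lstm[[1L]] <- list(Wx = lb1$dWx, Wh = lb1$dWh, b = lb1$db)
  dOut <- lb1$dX
  for (b in 3:1) {
    blk <- ch$blocks[[b]]
    dAct <- maxpool_backward(blk$pool, dOut)
    dAct <- dAct * blk$relu
    bnb <- bn_backward(blk$bn, p$bn[[b]]$gamma, dAct)
    g$bn[[b]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cvb <- conv1d_backward(blk$conv, p$conv[[b]]$W, bnb$dX)
    g$conv[[b]] <- list(W = cvb$dW, b = cvb$db)
    dOut <- cvb$dX
  }
  g
}

convlstm_loss <- function(model, X, Y1hot, training = TRUE,
                          dropout_masks = NULL, want_grads = TRUE) {
  fw <- convlstm_forward(model, X, training = training,
                         dropout_masks = dropout_masks)
  eps <- 1e-12
  loss <- -mean(rowSums(Y1hot * log(fw$probs + eps)))
  grads <- if (want_grads) convlstm_backward(model, fw, Y1hot) else NULL
  list(loss = loss, grads = grads, probs = fw$probs, model = fw$model)
}

# Recursive Adam over the nested parameter list.
adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], mm[[nm]], vv[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      mm <- beta1 * mm + (1 - beta1) * g
      vv <- beta2 * vv + (1 - beta2) * g^2
      mhat <- mm / (1 - beta1^t)
      vhat <- vv / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
    }
  }
  walk(params, grads, m, v)
}

#' Train the Conv+LSTM classifier
#'
#' Minimises mean cross-entropy with Adam over shuffled mini-batches.
#' Input channels are standardised with statistics of the training set
#' (stored in the model). All randomness — shuffling and dropout — is
#' driven by `seed`, so identical calls give identical loss histories.
#'
#' @param X raw window array `(n, width, channels)` (see
#'   [windows_to_array()]).
#' @param y factor of labels with levels `adl`, `fall`.
#' @param spec a [convlstm_spec()]; its `input_width`/`input_channels`
#'   must match `X`.
#' @param epochs training epochs (default 10).
#' @param batch_size mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed master seed for initialisation, shuffling and dropout.
#' @param verbose print per-epoch loss.
#' @return A trained `convlstm` with `$history` holding the per-epoch mean
#'   training loss.
#' @export
train_convlstm <- function(X, y, spec = convlstm_spec(), epochs = 10L,
                           batch_size = 32L, lr = 1e-3, seed = 1L,
                           verbose = FALSE) {
  y <- factor(y, levels = c("adl", "fall"))
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  n <- dim(X)[1L]
  if (n != length(y)) stop("rows of X and labels differ in length")
  model <- build_convlstm(spec, seed = seed)
  ch_mean <- apply(X, 3L, mean)
  ch_sd <- apply(X, 3L, sd)
  ch_sd[ch_sd == 0] <- 1
  model$input_stats <- list(mean = ch_mean, sd = ch_sd)
  Y1 <- cbind(as.numeric(y == "adl"), as.numeric(y == "fall"))
  m_state <- adam_init(model$params)
  v_state <- adam_init(model$params)
  t_len <- spec$input_width %/% spec$pool %/% spec$pool %/% spec$pool
  step <- 0L
  history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq.int(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        nb <- length(idx)
        Xb <- X[idx, , , drop = FALSE]
        Yb <- Y1[idx, , drop = FALSE]
        masks <- NULL
        if (spec$dropout > 0) {
          keep <- 1 - spec$dropout
          masks <- list(
            array(rbinom(nb * t_len * spec$lstm_hidden, 1L, keep) / keep,
                  c(nb, t_len, spec$lstm_hidden)),
            matrix(rbinom(nb * spec$lstm_hidden, 1L, keep) / keep,
                   nb, spec$lstm_hidden))
        }
        res <- convlstm_loss(model, Xb, Yb, training = TRUE,
                             dropout_masks = masks)
        if (!is.finite(res$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        model <- res$model  # carries updated batch-norm running stats
        step <- step + 1L
        upd <- adam_step(model$params, res$grads, m_state, v_state, lr, step)
        model$params <- upd$p
        m_state <- upd$m
        v_state <- upd$v
        losses <- c(losses, res$loss)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
    }
  })
  model$history <- history
  model
}

#' Class probabilities for raw windows
#'
#' @param object a trained `convlstm`.
#' @param x array `(n, width, channels)` matching the model's spec.
#' @param ... unused.
#' @return Matrix `n x 2` of class probabilities (columns `adl`, `fall`),
#'   each row summing to 1.
#' @export
predict.convlstm <- function(object, x, ...) {
  fw <- convlstm_forward(object, x, training = FALSE)
  colnames(fw$probs) <- object$classes
  fw$probs
}

#' @export
predict_windows.convlstm <- function(model, x) {
  if (is.list(x)) x <- windows_to_array(x)
  if (length(dim(x)) == 2L)
    stop("convlstm expects a raw (n x width x channels) window array")
  if (dim(x)[1L] == 0L) return(factor(character(0), levels = model$classes))
  probs <- predict(model, x)
  factor(model$classes[max.col(probs, ties.method = "first")],
         levels = model$classes)
}
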