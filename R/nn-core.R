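# Recurrent network core shared by the generative CLM, the ELECTRA
# discriminator and the ordinal classifier.
#
# Architecture (one-hot input of width V):
#   feature normalization (4V parameters: gain, bias, moving mean/variance)
#   -> LSTM block 1 (h1 cells; 4*h1*(V+h1+1) parameters)
#   -> LSTM block 2 (h2 cells; 4*h2*(h1+h2+1) parameters)
#   -> feature normalization (4*h2 parameters)
#   -> task head: per-step V-way softmax (generative), per-step sigmoid
#      (ELECTRA), or final-state 3-unit sigmoid with dropout (ordinal).
#
# Everything is plain batched matrix algebra; the backward pass is exact
# backpropagation through time and is verified by finite differences in the
# test suite. Batch statistics are computed over non-padding positions only.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_init_block <- function(nrow, ncol, seed_offset, scale) {
  matrix(runif(nrow * ncol, -scale, scale), nrow, ncol)
}

# Initialize a model. `head` decides the output layer:
#   "softmax"   : per-step projection to V (generative CLM)
#   "binary"    : per-step single sigmoid (ELECTRA discriminator)
#   "ordinal"   : final-state dense with `out_dim` sigmoids (classifier)
nn_init <- function(vocab, units = c(1024L, 256L),
                    head = c("softmax", "binary", "ordinal"),
                    out_dim = NULL, seed = 1L) {
  head <- match.arg(head)
  V <- vocab_size(vocab)
  h1 <- as.integer(units[1]); h2 <- as.integer(units[2])
  out_dim <- as.integer(out_dim %||% switch(head, softmax = V, binary = 1L, ordinal = 3L))
  withr::with_seed(seed, {
    s1 <- sqrt(6 / (V + h1)); s2 <- sqrt(6 / (h1 + h2)); s3 <- sqrt(6 / (h2 + out_dim))
    params <- list(
      bn0  = list(gamma = rep(1, V), beta = rep(0, V),
                  mean = rep(0, V), var = rep(1, V)),
      lstm1 = list(W = nn_init_block(V + h1, 4L * h1, 1L, s1), b = rep(0, 4L * h1)),
      lstm2 = list(W = nn_init_block(h1 + h2, 4L * h2, 2L, s2), b = rep(0, 4L * h2)),
      bn1  = list(gamma = rep(1, h2), beta = rep(0, h2),
                  mean = rep(0, h2), var = rep(1, h2)),
      head = list(W = nn_init_block(h2, out_dim, 3L, s3), b = rep(0, out_dim))
    )
    # forget-gate bias starts at 1 (standard LSTM initialization)
    params$lstm1$b[(h1 + 1L):(2L * h1)] <- 1
    params$lstm2$b[(h2 + 1L):(2L * h2)] <- 1
    structure(
      list(head = head, vocab = vocab, units = c(h1, h2), out_dim = out_dim,
           params = params, opt = NULL, step = 0L,
           history = tibble(epoch = integer(0), loss = numeric(0))),
      class = c(paste0("declm_", head, "_model"), "declm_model"))
  })
}

#' Total parameter count of a fitted or initialized model
#'
#' Sums the sizes of every parameter array in the network, including the
#' moving mean and variance of the normalization layers (the convention used
#' when deep-learning frameworks report "total parameters").
#'
#' @param model A `declm_model`.
#' @return Integer parameter count.
#' @export
model_parameter_count <- function(model) {
  stopifnot(inherits(model, "declm_model"))
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

#' @export
print.declm_model <- function(x, ...) {
  cat(sprintf("<declm %s model> V=%d units=%d/%d out=%d params=%s epochs=%d\n",
              x$head, vocab_size(x$vocab), x$units[1], x$units[2], x$out_dim,
              format(model_parameter_count(x), big.mark = ","),
              nrow(x$history)))
  invisible(x)
}

# ---- batching -------------------------------------------------------------

# pad a list of integer token vectors into a B x T matrix (pad index 1)
pad_batch <- function(tokens, pad = 1L) {
  Tm <- max(lengths(tokens))
  out <- matrix(pad, length(tokens), Tm)
  for (i in seq_along(tokens)) out[i, seq_along(tokens[[i]])] <- tokens[[i]]
  out
}

onehot_step <- function(idx, V) {
  B <- length(idx)
  m <- matrix(0, B, V)
  m[cbind(seq_len(B), idx)] <- 1
  m
}

# ---- batchnorm ------------------------------------------------------------

# x: rows = observations, columns = features; msk: logical rows to use for
# statistics. Returns normalized x plus the cache needed for backprop.
bn_forward <- function(x, bn, training, msk = NULL) {
  if (training) {
    rows <- if (is.null(msk)) seq_len(nrow(x)) else which(msk)
    m <- colMeans(x[rows, , drop = FALSE])
    v <- colMeans(sweep(x[rows, , drop = FALSE], 2, m)^2)
    bn$mean <- BN_MOMENTUM * bn$mean + (1 - BN_MOMENTUM) * m
    bn$var  <- BN_MOMENTUM * bn$var  + (1 - BN_MOMENTUM) * v
  } else {
    m <- bn$mean; v <- bn$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2, m), 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, m = sum(if (is.null(msk)) rep(TRUE, nrow(x)) else msk),
                           msk = msk, training = training),
       bn = bn)
}

# dy -> list(dx, dgamma, dbeta). In inference mode the transform is affine
# per feature so the backward pass is elementwise.
bn_backward <- function(dy, bn, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  if (!is.null(cache$msk)) {
    dy <- dy * cache$msk  # masked rows carry no gradient
    xh <- xhat * cache$msk
  } else xh <- xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  if (!cache$training) {
    dx <- sweep(dy, 2, bn$gamma * inv, `*`)
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  m <- cache$m
  dxhat <- sweep(dy, 2, bn$gamma, `*`)
  # derivative through the batch statistics (standard batchnorm backward)
  t1 <- sweep(dxhat, 2, colSums(dxhat * (if (is.null(cache$msk)) 1 else cache$msk)) / m)
  t2 <- sweep(xhat, 2, colSums(dxhat * xh) / m, `*`)
  dx <- sweep(t1 - t2, 2, inv, `*`)
  if (!is.null(cache$msk)) dx <- dx * cache$msk
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- lstm -----------------------------------------------------------------

lstm_step <- function(x, h_prev, c_prev, W, b) {
  H <- length(b) / 4L
  z <- cbind(x, h_prev) %*% W
  z <- sweep(z, 2, b, `+`)
  i <- sigmoid(z[, 1:H, drop = FALSE])
  f <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
  g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
  o <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
  cc <- f * c_prev + i * g
  tc <- tanh(cc)
  h <- o * tc
  list(h = h, c = cc,
       cache = list(x = x, h_prev = h_prev, c_prev = c_prev,
                    i = i, f = f, g = g, o = o, c = cc, tc = tc))
}

lstm_step_backward <- function(dh, dc_next, cache, W) {
  H <- ncol(cache$i)
  o <- cache$o; tc <- cache$tc
  do <- dh * tc
  dc <- dh * o * (1 - tc^2) + dc_next
  di <- dc * cache$g
  dg <- dc * cache$i
  df <- dc * cache$c_prev
  dc_prev <- dc * cache$f
  dzi <- di * cache$i * (1 - cache$i)
  dzf <- df * cache$f * (1 - cache$f)
  dzg <- dg * (1 - cache$g^2)
  dzo <- do * o * (1 - o)
  dz <- cbind(dzi, dzf, dzg, dzo)
  xin <- cbind(cache$x, cache$h_prev)
  dW <- crossprod(xin, dz)
  db <- colSums(dz)
  dxin <- dz %*% t(W)
  nx <- ncol(cache$x)
  list(dx = dxin[, 1:nx, drop = FALSE],
       dh_prev = dxin[, (nx + 1L):ncol(dxin), drop = FALSE],
       dc_prev = dc_prev, dW = dW, db = db)
}

# ---- forward / backward over a batch -------------------------------------

# X: B x T matrix of token indices. task: list describing targets:
#   head "softmax": targets are X shifted (predict token t+1 from steps 1..t)
#   head "binary":  task$labels B x T in {0,1}, masked by non-pad
#   head "ordinal": task$y B x out_dim in {0,1}; task$dropout rate;
#                   prediction uses the state at each sequence's stop token.
nn_forward <- function(model, X, task = list(), training = TRUE) {
  p <- model$params
  V <- vocab_size(model$vocab)
  h1 <- model$units[1]; h2 <- model$units[2]
  B <- nrow(X); Tm <- ncol(X)
  pad <- model$vocab$pad
  mask <- X != pad

  steps <- if (model$head == "softmax") Tm - 1L else Tm
  # frozen normalization blocks run in inference mode (stats untouched)
  frozen <- model$frozen %||% character(0)
  tr_bn0 <- training && !("bn0" %in% frozen)
  tr_bn1 <- training && !("bn1" %in% frozen)
  # input normalization: statistics over all non-pad positions of the batch
  oh <- lapply(seq_len(steps), function(t) onehot_step(X[, t], V))
  flat <- do.call(rbind, oh)
  fmask <- as.vector(mask[, seq_len(steps)])
  bn0 <- bn_forward(flat, p$bn0, tr_bn0, msk = fmask)
  model$params$bn0 <- bn0$bn
  xn <- lapply(seq_len(steps), function(t) bn0$y[((t - 1L) * B + 1L):(t * B), , drop = FALSE])

  h1s <- matrix(0, B, h1); c1s <- matrix(0, B, h1)
  h2s <- matrix(0, B, h2); c2s <- matrix(0, B, h2)
  cache1 <- vector("list", steps); cache2 <- vector("list", steps)
  H2 <- vector("list", steps)
  for (t in seq_len(steps)) {
    s1 <- lstm_step(xn[[t]], h1s, c1s, p$lstm1$W, p$lstm1$b)
    h1s <- s1$h; c1s <- s1$c; cache1[[t]] <- s1$cache
    s2 <- lstm_step(h1s, h2s, c2s, p$lstm2$W, p$lstm2$b)
    h2s <- s2$h; c2s <- s2$c; cache2[[t]] <- s2$cache
    H2[[t]] <- h2s
  }

  out <- list(X = X, mask = mask, steps = steps,
              bn0_cache = bn0$cache, cache1 = cache1, cache2 = cache2, H2 = H2)

  if (model$head == "ordinal") {
    lens <- rowSums(mask)
    hlast <- do.call(rbind, lapply(seq_len(B), function(b) H2[[lens[b]]][b, , drop = FALSE]))
    bn1 <- bn_forward(hlast, p$bn1, tr_bn1)
    model$params$bn1 <- bn1$bn
    drop_rate <- task$dropout %||% 0
    dmask <- if (training && drop_rate > 0) {
      (matrix(runif(B * h2), B, h2) >= drop_rate) / (1 - drop_rate)
    } else matrix(1, B, h2)
    hd <- bn1$y * dmask
    logits <- sweep(hd %*% p$head$W, 2, p$head$b, `+`)
    probs <- sigmoid(logits)
    loss <- if (!is.null(task$y)) {
      eps <- 1e-12
      -mean(task$y * log(probs + eps) + (1 - task$y) * log(1 - probs + eps))
    } else NA_real_
    out <- c(out, list(lens = lens, hlast = hlast, bn1_cache = bn1$cache,
                       dmask = dmask, hd = hd, probs = probs, loss = loss))
    out$model <- model
    return(out)
  }

  flatH2 <- do.call(rbind, H2)
  bn1 <- bn_forward(flatH2, p$bn1, tr_bn1, msk = fmask)
  model$params$bn1 <- bn1$bn
  Y <- sweep(bn1$y %*% p$head$W, 2, p$head$b, `+`)  # (B*steps) x out

  if (model$head == "softmax") {
    targets <- X[, 2:Tm, drop = FALSE]
    tmask <- mask[, 2:Tm, drop = FALSE]
    mx <- apply(Y, 1, max)
    eY <- exp(Y - mx)
    probs <- eY / rowSums(eY)
    tgt_flat <- as.vector(targets)           # column t stacked as block t
    pm <- as.vector(tmask)
    rows <- which(pm)
    picked <- probs[cbind(rows, tgt_flat[rows])]
    loss <- -mean(log(picked + 1e-12))
    out <- c(out, list(bn1_cache = bn1$cache, probs = probs,
                       tgt_flat = tgt_flat, loss_mask = pm, loss = loss))
  } else { # binary, per position
    probs <- sigmoid(Y)
    labels <- as.vector(task$labels[, seq_len(steps), drop = FALSE])
    pm <- fmask
    eps <- 1e-12
    ll <- labels * log(probs + eps) + (1 - labels) * log(1 - probs + eps)
    loss <- -sum(ll[pm]) / sum(pm)
    out <- c(out, list(bn1_cache = bn1$cache, probs = probs,
                       labels = labels, loss_mask = pm, loss = loss))
  }
  out$model <- model
  out
}

nn_backward <- function(fwd, task = list()) {
  model <- fwd$model
  p <- model$params
  B <- nrow(fwd$X); steps <- fwd$steps
  h1 <- model$units[1]; h2 <- model$units[2]
  g <- list(bn0 = list(gamma = 0, beta = 0),
            lstm1 = list(W = 0 * p$lstm1$W, b = 0 * p$lstm1$b),
            lstm2 = list(W = 0 * p$lstm2$W, b = 0 * p$lstm2$b),
            bn1 = list(gamma = 0, beta = 0),
            head = list(W = 0 * p$head$W, b = 0 * p$head$b))

  if (model$head == "ordinal") {
    n <- length(fwd$probs)
    dlogits <- (fwd$probs - task$y) / n
    g$head$W <- crossprod(fwd$hd, dlogits)
    g$head$b <- colSums(dlogits)
    dhd <- dlogits %*% t(p$head$W)
    dbn1y <- dhd * fwd$dmask
    bb <- bn_backward(dbn1y, p$bn1, fwd$bn1_cache)
    g$bn1$gamma <- bb$dgamma; g$bn1$beta <- bb$dbeta
    dH2 <- lapply(seq_len(steps), function(t) matrix(0, B, h2))
    for (b in seq_len(B)) dH2[[fwd$lens[b]]][b, ] <- bb$dx[b, ]
  } else {
    if (model$head == "softmax") {
      n <- sum(fwd$loss_mask)
      dY <- fwd$probs
      rows <- which(fwd$loss_mask)
      dY[cbind(rows, fwd$tgt_flat[rows])] <- dY[cbind(rows, fwd$tgt_flat[rows])] - 1
      dY <- dY * fwd$loss_mask / n
    } else {
      n <- sum(fwd$loss_mask)
      dY <- (fwd$probs - fwd$labels) * fwd$loss_mask / n
    }
    flatH2bn <- sweep(sweep(fwd$bn1_cache$xhat, 2, p$bn1$gamma, `*`), 2, p$bn1$beta, `+`)
    g$head$W <- crossprod(flatH2bn, dY)
    g$head$b <- colSums(dY)
    dbn1y <- dY %*% t(p$head$W)
    bb <- bn_backward(dbn1y, p$bn1, fwd$bn1_cache)
    g$bn1$gamma <- bb$dgamma; g$bn1$beta <- bb$dbeta
    dH2 <- lapply(seq_len(steps), function(t) bb$dx[((t - 1L) * B + 1L):(t * B), , drop = FALSE])
  }

  dh1_carry <- matrix(0, B, h1); dc1_carry <- matrix(0, B, h1)
  dh2_carry <- matrix(0, B, h2); dc2_carry <- matrix(0, B, h2)
  dXn <- vector("list", steps)
  for (t in rev(seq_len(steps))) {
    b2 <- lstm_step_backward(dH2[[t]] + dh2_carry, dc2_carry, fwd$cache2[[t]], p$lstm2$W)
    g$lstm2$W <- g$lstm2$W + b2$dW; g$lstm2$b <- g$lstm2$b + b2$db
    dh2_carry <- b2$dh_prev; dc2_carry <- b2$dc_prev
    b1 <- lstm_step_backward(b2$dx + dh1_carry, dc1_carry, fwd$cache1[[t]], p$lstm1$W)
    g$lstm1$W <- g$lstm1$W + b1$dW; g$lstm1$b <- g$lstm1$b + b1$db
    dh1_carry <- b1$dh_prev; dc1_carry <- b1$dc_prev
    dXn[[t]] <- b1$dx
  }
  b0 <- bn_backward(do.call(rbind, dXn), p$bn0, fwd$bn0_cache)
  g$bn0$gamma <- b0$dgamma; g$bn0$beta <- b0$dbeta
  g
}

# ---- optimizer ------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = 0 * x, v = 0 * x), how = "list",
         classes = c("numeric", "matrix", "array"))
}

# one Adam step over trainable leaves; `freeze` names parameter blocks
# (bn0, lstm1, lstm2, bn1, head) whose values stay untouched. Moving
# statistics (mean/var) are never updated by the optimizer.
adam_step <- function(model, grads, lr, freeze = character(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(model$opt)) model$opt <- adam_init(model$params)
  model$step <- model$step + 1L
  t <- model$step
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  for (blk in names(grads)) {
    if (blk %in% freeze) next
    for (leaf in names(grads[[blk]])) {
      gl <- grads[[blk]][[leaf]]
      st <- model$opt[[blk]][[leaf]]
      st$m <- beta1 * st$m + (1 - beta1) * gl
      st$v <- beta2 * st$v + (1 - beta2) * gl^2
      model$opt[[blk]][[leaf]] <- st
      upd <- lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
      model$params[[blk]][[leaf]] <- model$params[[blk]][[leaf]] - upd
    }
  }
  model
}

# ---- generic training loop ------------------------------------------------

# task_fn(batch_index_list, epoch) -> list(X = matrix, task = list)
nn_train_loop <- function(model, n_obs, task_fn, epochs, lr, batch_size,
                          seed, freeze = character(0), norm_training = TRUE,
                          epoch_hook = NULL) {
  if (epochs == 0L) return(model)
  model$frozen <- freeze
  for (ep in seq_len(epochs)) {
    ord <- withr::with_seed(derive_seed(seed, ep), sample.int(n_obs))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    losses <- numeric(0)
    for (bi in seq_along(batches)) {
      built <- task_fn(batches[[bi]], ep)
      withr::with_seed(derive_seed(seed, ep * 100003L + bi), {
        fwd <- nn_forward(model, built$X, built$task, training = norm_training)
      })
      model <- fwd$model
      grads <- nn_backward(fwd, built$task)
      model <- adam_step(model, grads, lr, freeze = freeze)
      losses <- c(losses, fwd$loss)
    }
    model$history <- dplyr::bind_rows(model$history,
                                      tibble(epoch = nrow(model$history) + 1L,
                                             loss = mean(losses)))
    if (!is.null(epoch_hook)) model <- epoch_hook(model, ep) %||% model
  }
  model
}

# evaluate mean loss without updating anything
nn_eval_loss <- function(model, tokens, task_builder, batch_size = 64L) {
  X <- pad_batch(tokens, model$vocab$pad)
  built <- task_builder(X)
  fwd <- nn_forward(model, built$X, built$task, training = FALSE)
  fwd$loss
}

# single-step state advance used during generation (inference mode)
nn_state_init <- function(model, B) {
  list(h1 = matrix(0, B, model$units[1]), c1 = matrix(0, B, model$units[1]),
       h2 = matrix(0, B, model$units[2]), c2 = matrix(0, B, model$units[2]))
}

nn_state_step <- function(model, idx, state) {
  p <- model$params
  V <- vocab_size(model$vocab)
  x <- onehot_step(idx, V)
  xn <- bn_forward(x, p$bn0, training = FALSE)$y
  s1 <- lstm_step(xn, state$h1, state$c1, p$lstm1$W, p$lstm1$b)
  s2 <- lstm_step(s1$h, state$h2, state$c2, p$lstm2$W, p$lstm2$b)
  yn <- bn_forward(s2$h, p$bn1, training = FALSE)$y
  logits <- sweep(yn %*% p$head$W, 2, p$head$b, `+`)
  list(state = list(h1 = s1$h, c1 = s1$c, h2 = s2$h, c2 = s2$c),
       logits = logits)
}

#' Save / load a model checkpoint
#'
#' Checkpoints round-trip bit-identically: reloading reproduces identical
#' predictions.
#'
#' @param model A `declm_model`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
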