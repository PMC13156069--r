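## Minimal deterministic feed-forward network engine.
##
## Architecture: per-block affine encoders -> concatenation -> dense trunk
## -> scalar output, trained with Adam on mean squared error. Written as
## plain matrix code so that a fixed seed gives a bit-stable training log on
## one CPU; no external deep-learning runtime is involved.

.act <- function(x, name) switch(name, relu = pmax(x, 0), identity = x,
                                 stop("unknown activation: ", name))
.act_grad <- function(x, name) switch(name, relu = (x > 0) * 1, identity = x * 0 + 1)

.init_mat <- function(p, q) {
  # Glorot-uniform initialisation; draws come from the caller's seeded RNG
  r <- sqrt(6 / (p + q))
  matrix(stats::runif(p * q, -r, r), p, q)
}

# initialise parameters for block dims `dims` (named int vector)
nn_init <- function(dims, encoder_width, trunk_widths) {
  enc <- lapply(dims, function(p) {
    if (encoder_width <= 0) return(NULL)
    list(W = .init_mat(p, encoder_width), b = numeric(encoder_width))
  })
  d <- sum(vapply(dims, function(p)
    if (encoder_width <= 0) as.integer(p) else as.integer(encoder_width),
    integer(1)))
  trunk <- list()
  for (w in trunk_widths) {
    trunk[[length(trunk) + 1L]] <- list(W = .init_mat(d, w), b = numeric(w))
    d <- w
  }
  out <- list(W = .init_mat(d, 1L), b = 0)
  list(encoders = enc, trunk = trunk, out = out, dims = dims,
       encoder_width = encoder_width)
}

nn_n_params <- function(params) {
  n <- length(params$out$W) + 1L
  for (e in params$encoders) if (!is.null(e)) n <- n + length(e$W) + length(e$b)
  for (l in params$trunk) n <- n + length(l$W) + length(l$b)
  n
}

# forward pass; X is a named list of matrices in params$dims order.
# Returns prediction and (if grad=TRUE) the caches needed for backprop.
nn_forward <- function(params, X, activation, dropout = 0, training = FALSE,
                       grad = FALSE) {
  H <- vector("list", length(params$dims))
  preact <- vector("list", length(params$dims))
  for (i in seq_along(params$dims)) {
    xb <- X[[i]]
    e <- params$encoders[[i]]
    if (is.null(e)) {
      H[[i]] <- xb
      preact[i] <- list(NULL)
    } else {
      z <- sweep(xb %*% e$W, 2, e$b, "+")
      preact[[i]] <- z
      H[[i]] <- .act(z, activation)
    }
  }
  C <- do.call(cbind, H)
  t_in <- list(C)
  t_pre <- list()
  t_mask <- list()
  A <- C
  for (l in seq_along(params$trunk)) {
    z <- sweep(A %*% params$trunk[[l]]$W, 2, params$trunk[[l]]$b, "+")
    A <- .act(z, activation)
    mask <- NULL
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A)) /
        (1 - dropout)
      A <- A * mask
    }
    t_pre[[l]] <- z
    t_mask[l] <- list(mask)
    t_in[[l + 1L]] <- A
  }
  yhat <- drop(A %*% params$out$W + params$out$b)
  if (!grad) return(yhat)
  list(yhat = yhat, enc_pre = preact, enc_H = H, trunk_in = t_in,
       trunk_pre = t_pre, trunk_mask = t_mask)
}

# backward pass for MSE loss 1/n sum (yhat - y)^2; returns gradients with
# the same shape as params.
nn_backward <- function(params, X, y, fw, activation) {
  n <- length(y)
  dy <- matrix(2 * (fw$yhat - y) / n, ncol = 1)
  g <- list(encoders = vector("list", length(params$encoders)),
            trunk = vector("list", length(params$trunk)),
            out = NULL)
  A_last <- fw$trunk_in[[length(params$trunk) + 1L]]
  g$out <- list(W = t(A_last) %*% dy, b = sum(dy))
  dA <- dy %*% t(params$out$W)
  for (l in rev(seq_along(params$trunk))) {
    if (!is.null(fw$trunk_mask[[l]])) dA <- dA * fw$trunk_mask[[l]]
    dz <- dA * .act_grad(fw$trunk_pre[[l]], activation)
    g$trunk[[l]] <- list(W = t(fw$trunk_in[[l]]) %*% dz, b = colSums(dz))
    dA <- dz %*% t(params$trunk[[l]]$W)
  }
  # split concatenated gradient back into per-block encoder gradients
  offs <- 0L
  for (i in seq_along(params$dims)) {
    width <- if (is.null(params$encoders[[i]])) params$dims[[i]] else ncol(params$encoders[[i]]$W)
    dH <- dA[, offs + seq_len(width), drop = FALSE]
    offs <- offs + width
    if (!is.null(params$encoders[[i]])) {
      dz <- dH * .act_grad(fw$enc_pre[[i]], activation)
      g$encoders[[i]] <- list(W = t(X[[i]]) %*% dz, b = colSums(dz))
    }
  }
  g
}

# one Adam update over the flattened parameter list (in place on copies)
.adam_new_state <- function(params) {
  zero_like <- function(p) if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0)
  list(m = list(encoders = lapply(params$encoders, zero_like),
                trunk = lapply(params$trunk, zero_like),
                out = zero_like(params$out)),
       v = list(encoders = lapply(params$encoders, zero_like),
                trunk = lapply(params$trunk, zero_like),
                out = zero_like(params$out)),
       t = 0L)
}

.adam_step_one <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m$W <- b1 * m$W + (1 - b1) * g$W
  m$b <- b1 * m$b + (1 - b1) * g$b
  v$W <- b2 * v$W + (1 - b2) * g$W^2
  v$b <- b2 * v$b + (1 - b2) * g$b^2
  mh_W <- m$W / (1 - b1^t); mh_b <- m$b / (1 - b1^t)
  vh_W <- v$W / (1 - b2^t); vh_b <- v$b / (1 - b2^t)
  p$W <- p$W - lr * mh_W / (sqrt(vh_W) + eps)
  p$b <- p$b - lr * mh_b / (sqrt(vh_b) + eps)
  list(p = p, m = m, v = v)
}

nn_adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  for (i in seq_along(params$encoders)) {
    if (is.null(params$encoders[[i]]) || is.null(grads$encoders[[i]])) next
    u <- .adam_step_one(params$encoders[[i]], grads$encoders[[i]],
                        state$m$encoders[[i]], state$v$encoders[[i]], lr, state$t)
    params$encoders[[i]] <- u$p
    state$m$encoders[[i]] <- u$m; state$v$encoders[[i]] <- u$v
  }
  for (l in seq_along(params$trunk)) {
    u <- .adam_step_one(params$trunk[[l]], grads$trunk[[l]],
                        state$m$trunk[[l]], state$v$trunk[[l]], lr, state$t)
    params$trunk[[l]] <- u$p
    state$m$trunk[[l]] <- u$m; state$v$trunk[[l]] <- u$v
  }
  u <- .adam_step_one(params$out, grads$out, state$m$out, state$v$out, lr, state$t)
  params$out <- u$p
  state$m$out <- u$m; state$v$out <- u$v
  list(params = params, state = state)
}

.mse <- function(a, b) mean((a - b)^2)

# core training loop: Adam + MSE, optional held-out early stopping with
# best-weight restoration. Caller is responsible for seeding the RNG.
nn_train <- function(params, X, y, config, lr, Xval = NULL, yval = NULL,
                     state = NULL, max_epochs = config$max_epochs,
                     patience = config$patience) {
  n <- length(y)
  if (is.null(state)) state <- .adam_new_state(params)
  bs <- config$batch_size
  if (is.null(bs) || bs <= 0 || bs > n) bs <- n
  best <- list(val = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_mse = numeric(),
                    val_mse = numeric())
  wait <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- lapply(X, function(m) m[idx, , drop = FALSE])
      fw <- nn_forward(params, Xb, config$activation, config$dropout,
                       training = TRUE, grad = TRUE)
      if (any(!is.finite(fw$yhat)))
        stop("non-finite predictions during training (diverged); ",
             "reduce the learning rate", call. = FALSE)
      gr <- nn_backward(params, Xb, y[idx], fw, config$activation)
      up <- nn_adam_step(params, gr, state, lr)
      params <- up$params; state <- up$state
    }
    tr_mse <- .mse(nn_forward(params, X, config$activation), y)
    if (!is.finite(tr_mse))
      stop("non-finite training loss (diverged); reduce the learning rate",
           call. = FALSE)
    va_mse <- if (!is.null(Xval))
      .mse(nn_forward(params, Xval, config$activation), yval) else NA_real_
    log <- rbind(log, data.frame(epoch = ep, train_mse = tr_mse,
                                 val_mse = va_mse))
    if (!is.null(Xval)) {
      if (va_mse < best$val - 1e-12) {
        best <- list(val = va_mse, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (!is.null(Xval)) params <- best$params
  list(params = params, state = state, log = log,
       best_epoch = if (!is.null(Xval)) best$epoch else nrow(log))
}
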