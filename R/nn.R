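# Neural-network primitives for the Siamese multi-task retention-time model.
#
# Everything is plain vectorised R on base matrices: an embedding lookup, a
# recurrent encoder (GRU or LSTM) unrolled over the padded sequence with
# masking, per-task dense subnetworks with batch normalisation and inverted
# dropout, and Adam. Gradients are hand-derived backprop-through-time and are
# verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(z, b) sweep(z, 2L, b, "+")

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---- parameter initialisation -----------------------------------------------

nn_init_params <- function(config, vocab_size) {
  E <- config$embedding_dim
  U <- config$recurrent_units
  params <- list()
  # row 1 = padding code 0, fixed at zero
  params$emb <- rbind(matrix(0, 1, E),
                      matrix(stats::rnorm(vocab_size * E, sd = 0.1),
                             vocab_size, E))
  if (config$recurrent_type == "GRU") {
    params$rnn <- list(
      Wz = glorot(E, U), Wr = glorot(E, U), Wh = glorot(E, U),
      Uz = glorot(U, U), Ur = glorot(U, U), Uh = glorot(U, U),
      bz = numeric(U), br = numeric(U), bh = numeric(U)
    )
  } else if (config$recurrent_type == "LSTM") {
    params$rnn <- list(
      Wi = glorot(E, U), Wf = glorot(E, U), Wo = glorot(E, U), Wc = glorot(E, U),
      Ui = glorot(U, U), Uf = glorot(U, U), Uo = glorot(U, U), Uc = glorot(U, U),
      bi = numeric(U), bf = rep(1, U), bo = numeric(U), bc = numeric(U)
    )
  } else {
    stop("recurrent_type must be 'GRU' or 'LSTM'")
  }
  comb_dim <- if (config$combination == "concatenate") 2L * U else U
  params$heads <- list()
  for (task in config$task_set) {
    sizes <- config$subnet_layer_sizes
    out_dim <- if (task == "RP") 1L else config$n_fractions[[task]]
    layers <- list()
    nin <- comb_dim
    for (s in sizes) {
      layers[[length(layers) + 1L]] <- list(
        W = glorot(nin, s), b = numeric(s),
        gamma = rep(1, s), beta = numeric(s)
      )
      nin <- s
    }
    params$heads[[task]] <- list(
      layers = layers,
      out = list(W = glorot(nin, out_dim), b = numeric(out_dim))
    )
  }
  params
}

nn_init_bn_stats <- function(params, config) {
  stats <- list()
  for (task in names(params$heads)) {
    stats[[task]] <- lapply(params$heads[[task]]$layers, function(l) {
      list(mean = numeric(length(l$b)), var = rep(1, length(l$b)))
    })
  }
  stats
}

# ---- recurrent encoder ------------------------------------------------------

# X: B x T integer matrix, 0 = padding. Returns final hidden state (B x U)
# and, if keep_cache, the per-timestep quantities needed for BPTT.
rnn_forward <- function(params, X, config, keep_cache = FALSE) {
  B <- nrow(X); T_ <- ncol(X); U <- config$recurrent_units
  p <- params$rnn
  h <- matrix(0, B, U)
  cst <- matrix(0, B, U)  # LSTM cell state
  cache <- if (keep_cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    Et <- params$emb[X[, t] + 1L, , drop = FALSE]
    m <- as.numeric(X[, t] > 0L)
    if (config$recurrent_type == "GRU") {
      z <- sigmoid(add_bias(Et %*% p$Wz + h %*% p$Uz, p$bz))
      r <- sigmoid(add_bias(Et %*% p$Wr + h %*% p$Ur, p$br))
      rh <- r * h
      cnd <- tanh(add_bias(Et %*% p$Wh + rh %*% p$Uh, p$bh))
      h_new <- (1 - z) * h + z * cnd
      if (keep_cache) {
        cache[[t]] <- list(Et = Et, m = m, h_prev = h, z = z, r = r,
                           cnd = cnd, tok = X[, t])
      }
      h <- m * h_new + (1 - m) * h
    } else {
      i <- sigmoid(add_bias(Et %*% p$Wi + h %*% p$Ui, p$bi))
      f <- sigmoid(add_bias(Et %*% p$Wf + h %*% p$Uf, p$bf))
      o <- sigmoid(add_bias(Et %*% p$Wo + h %*% p$Uo, p$bo))
      g <- tanh(add_bias(Et %*% p$Wc + h %*% p$Uc, p$bc))
      cst_new <- f * cst + i * g
      h_new <- o * tanh(cst_new)
      if (keep_cache) {
        cache[[t]] <- list(Et = Et, m = m, h_prev = h, cst_prev = cst,
                           i = i, f = f, o = o, g = g, cst_new = cst_new,
                           tok = X[, t])
      }
      h <- m * h_new + (1 - m) * h
      cst <- m * cst_new + (1 - m) * cst
    }
  }
  list(h = h, cache = cache)
}

# dh: gradient wrt the final hidden state (B x U). Returns gradients for the
# rnn parameters and the embedding matrix.
rnn_backward <- function(params, cache, dh, config, vocab_rows) {
  p <- params$rnn
  g <- lapply(p, function(x) x * 0)
  d_emb <- matrix(0, vocab_rows, ncol(params$emb))
  dcs <- dh * 0
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    m <- cc$m
    if (config$recurrent_type == "GRU") {
      dh_new <- m * dh
      dh_prev <- (1 - m) * dh
      dz <- dh_new * (cc$cnd - cc$h_prev)
      dcnd <- dh_new * cc$z
      dh_prev <- dh_prev + dh_new * (1 - cc$z)
      dc_pre <- dcnd * (1 - cc$cnd^2)
      rh <- cc$r * cc$h_prev
      g$Wh <- g$Wh + crossprod(cc$Et, dc_pre)
      g$Uh <- g$Uh + crossprod(rh, dc_pre)
      g$bh <- g$bh + colSums(dc_pre)
      drh <- dc_pre %*% t(p$Uh)
      dr <- drh * cc$h_prev
      dh_prev <- dh_prev + drh * cc$r
      dz_pre <- dz * cc$z * (1 - cc$z)
      dr_pre <- dr * cc$r * (1 - cc$r)
      g$Wz <- g$Wz + crossprod(cc$Et, dz_pre)
      g$Uz <- g$Uz + crossprod(cc$h_prev, dz_pre)
      g$bz <- g$bz + colSums(dz_pre)
      g$Wr <- g$Wr + crossprod(cc$Et, dr_pre)
      g$Ur <- g$Ur + crossprod(cc$h_prev, dr_pre)
      g$br <- g$br + colSums(dr_pre)
      dh_prev <- dh_prev + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
      dEt <- dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr) + dc_pre %*% t(p$Wh)
      dh <- dh_prev
    } else {
      dh_new <- m * dh
      dh_prev <- (1 - m) * dh
      dcs_new <- m * dcs
      dcs_prev <- (1 - m) * dcs
      tc <- tanh(cc$cst_new)
      do_ <- dh_new * tc
      dcs_new <- dcs_new + dh_new * cc$o * (1 - tc^2)
      df <- dcs_new * cc$cst_prev
      di <- dcs_new * cc$g
      dg <- dcs_new * cc$i
      dcs_prev <- dcs_prev + dcs_new * cc$f
      di_pre <- di * cc$i * (1 - cc$i)
      df_pre <- df * cc$f * (1 - cc$f)
      do_pre <- do_ * cc$o * (1 - cc$o)
      dg_pre <- dg * (1 - cc$g^2)
      g$Wi <- g$Wi + crossprod(cc$Et, di_pre)
      g$Wf <- g$Wf + crossprod(cc$Et, df_pre)
      g$Wo <- g$Wo + crossprod(cc$Et, do_pre)
      g$Wc <- g$Wc + crossprod(cc$Et, dg_pre)
      g$Ui <- g$Ui + crossprod(cc$h_prev, di_pre)
      g$Uf <- g$Uf + crossprod(cc$h_prev, df_pre)
      g$Uo <- g$Uo + crossprod(cc$h_prev, do_pre)
      g$Uc <- g$Uc + crossprod(cc$h_prev, dg_pre)
      g$bi <- g$bi + colSums(di_pre)
      g$bf <- g$bf + colSums(df_pre)
      g$bo <- g$bo + colSums(do_pre)
      g$bc <- g$bc + colSums(dg_pre)
      dh_prev <- dh_prev + di_pre %*% t(p$Ui) + df_pre %*% t(p$Uf) +
        do_pre %*% t(p$Uo) + dg_pre %*% t(p$Uc)
      dEt <- di_pre %*% t(p$Wi) + df_pre %*% t(p$Wf) +
        do_pre %*% t(p$Wo) + dg_pre %*% t(p$Wc)
      dh <- dh_prev
      dcs <- dcs_prev
    }
    agg <- rowsum(dEt, group = cc$tok + 1L)
    rows <- as.integer(rownames(agg))
    d_emb[rows, ] <- d_emb[rows, , drop = FALSE] + agg
  }
  d_emb[1L, ] <- 0  # padding row stays zero
  list(rnn = g, emb = d_emb)
}

# ---- dense heads ------------------------------------------------------------

head_forward <- function(head, a, config, training, bn_stats, task) {
  cache <- list(layers = list())
  bn_updates <- list()
  for (li in seq_along(head$layers)) {
    l <- head$layers[[li]]
    z <- add_bias(a %*% l$W, l$b)
    if (isTRUE(config$use_batch_norm)) {
      if (training && nrow(z) > 1L) {
        mu <- colMeans(z)
        va <- colMeans(sweep(z, 2L, mu)^2)
        bn_updates[[li]] <- list(mean = mu, var = va)
      } else {
        mu <- bn_stats[[task]][[li]]$mean
        va <- bn_stats[[task]][[li]]$var
      }
      zhat <- sweep(sweep(z, 2L, mu), 2L, sqrt(va + 1e-5), "/")
      zt <- add_bias(sweep(zhat, 2L, l$gamma, "*"), l$beta)
    } else {
      zhat <- NULL
      zt <- z
    }
    act <- pmax(zt, 0)
    if (training && config$dropout_rate > 0) {
      keep <- 1 - config$dropout_rate
      mask <- matrix(stats::rbinom(length(act), 1L, keep) / keep,
                     nrow(act), ncol(act))
      act_out <- act * mask
    } else {
      mask <- NULL
      act_out <- act
    }
    cache$layers[[li]] <- list(a_in = a, z = z, zhat = zhat, zt = zt,
                               act = act, mask = mask,
                               mu = if (isTRUE(config$use_batch_norm)) mu,
                               va = if (isTRUE(config$use_batch_norm)) va)
    a <- act_out
  }
  zo <- add_bias(a %*% head$out$W, head$out$b)
  pred <- if (task == "RP") zo else sigmoid(zo)
  cache$a_out <- a
  cache$pred <- pred
  list(pred = pred, cache = cache, bn_updates = bn_updates)
}

# d_pre: gradient wrt the output pre-activation (already includes the
# sigmoid/linear loss shortcut). Returns head parameter gradients and the
# gradient wrt the head input.
head_backward <- function(head, cache, d_pre, config) {
  g <- list(layers = vector("list", length(head$layers)), out = list())
  g$out$W <- crossprod(cache$a_out, d_pre)
  g$out$b <- colSums(d_pre)
  da <- d_pre %*% t(head$out$W)
  for (li in rev(seq_along(head$layers))) {
    l <- head$layers[[li]]
    cc <- cache$layers[[li]]
    if (!is.null(cc$mask)) da <- da * cc$mask
    dzt <- da * (cc$zt > 0)
    if (isTRUE(config$use_batch_norm)) {
      dgamma <- colSums(dzt * cc$zhat)
      dbeta <- colSums(dzt)
      dzhat <- sweep(dzt, 2L, l$gamma, "*")
      B <- nrow(dzhat)
      inv_sd <- 1 / sqrt(cc$va + 1e-5)
      # batch-stats backprop (biased variance, denominator B)
      dz <- sweep(dzhat -
                    matrix(colMeans(dzhat), B, ncol(dzhat), byrow = TRUE) -
                    cc$zhat * matrix(colMeans(dzhat * cc$zhat), B,
                                     ncol(dzhat), byrow = TRUE),
                  2L, inv_sd, "*")
    } else {
      dgamma <- l$gamma * 0
      dbeta <- l$beta * 0
      dz <- dzt
    }
    g$layers[[li]] <- list(
      W = crossprod(cc$a_in, dz), b = colSums(dz),
      gamma = dgamma, beta = dbeta
    )
    da <- dz %*% t(l$W)
  }
  list(grads = g, d_input = da)
}

# ---- full forward/backward --------------------------------------------------

# batch: list(Xa, Xb) of B x T integer matrices; Xb NULL in linear mode.
nn_forward <- function(params, batch, config, training = FALSE,
                       bn_stats = NULL, keep_cache = FALSE) {
  fa <- rnn_forward(params, batch$Xa, config, keep_cache)
  if (!is.null(batch$Xb)) {
    fb <- rnn_forward(params, batch$Xb, config, keep_cache)
    comb <- switch(config$combination,
      add = fa$h + fb$h,
      multiply = fa$h * fb$h,
      concatenate = cbind(fa$h, fb$h),
      stop("unknown combination: ", config$combination)
    )
  } else {
    fb <- NULL
    comb <- if (config$combination == "concatenate") {
      cbind(fa$h, fa$h * 0)  # single branch paired with an empty peptide
    } else if (config$combination == "multiply") {
      fa$h  # empty branch acts as the multiplicative identity
    } else {
      fa$h
    }
  }
  preds <- list()
  caches <- list()
  bn_updates <- list()
  for (task in config$task_set) {
    hf <- head_forward(params$heads[[task]], comb, config, training,
                       bn_stats, task)
    preds[[task]] <- hf$pred
    caches[[task]] <- hf$cache
    bn_updates[[task]] <- hf$bn_updates
  }
  list(preds = preds, comb = comb, fa = fa, fb = fb,
       head_caches = caches, bn_updates = bn_updates)
}

# d_pre_by_task: list of gradients wrt each head's output pre-activation.
nn_backward <- function(params, fwd, batch, d_pre_by_task, config) {
  comb_grad <- fwd$comb * 0
  head_grads <- list()
  for (task in names(d_pre_by_task)) {
    hb <- head_backward(params$heads[[task]], fwd$head_caches[[task]],
                        d_pre_by_task[[task]], config)
    head_grads[[task]] <- hb$grads
    comb_grad <- comb_grad + hb$d_input
  }
  U <- config$recurrent_units
  if (!is.null(batch$Xb)) {
    d_ha <- switch(config$combination,
      add = comb_grad,
      multiply = comb_grad * fwd$fb$h,
      concatenate = comb_grad[, seq_len(U), drop = FALSE]
    )
    d_hb <- switch(config$combination,
      add = comb_grad,
      multiply = comb_grad * fwd$fa$h,
      concatenate = comb_grad[, U + seq_len(U), drop = FALSE]
    )
  } else {
    d_ha <- if (config$combination == "concatenate") {
      comb_grad[, seq_len(U), drop = FALSE]
    } else {
      comb_grad
    }
    d_hb <- NULL
  }
  vocab_rows <- nrow(params$emb)
  ra <- rnn_backward(params, fwd$fa$cache, d_ha, config, vocab_rows)
  g_rnn <- ra$rnn
  g_emb <- ra$emb
  if (!is.null(d_hb)) {
    rb <- rnn_backward(params, fwd$fb$cache, d_hb, config, vocab_rows)
    g_rnn <- Map("+", g_rnn, rb$rnn)
    g_emb <- g_emb + rb$emb
  }
  list(emb = g_emb, rnn = g_rnn, heads = head_grads)
}

# ---- losses -----------------------------------------------------------------

# truths: list(RP = numeric (standardised), SCX = B x n matrix, hSAX = ...).
# Returns per-task losses and gradients wrt each head's output pre-activation.
nn_loss <- function(preds, truths, task_weights) {
  losses <- list()
  d_pre <- list()
  for (task in names(preds)) {
    p <- preds[[task]]
    y <- truths[[task]]
    w <- task_weights[[task]]
    if (task == "RP") {
      B <- length(y)
      losses[[task]] <- mean((p[, 1L] - y)^2)
      d_pre[[task]] <- matrix(w * 2 * (p[, 1L] - y) / B, ncol = 1L)
    } else {
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      losses[[task]] <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
      d_pre[[task]] <- w * (p - y) / length(y)
    }
  }
  list(losses = losses, d_pre = d_pre)
}

#' Weighted multi-task loss
#'
#' The total training objective: a weighted sum of the mean squared error on
#' the (standardised) RP retention time and the mean binary cross-entropy of
#' the ordinal SCX/hSAX encodings. Tasks absent from \code{predictions}
#' contribute zero.
#'
#' @param predictions List with elements among \code{RP} (numeric vector),
#'   \code{SCX}, \code{hSAX} (probability matrices, rows = CSMs).
#' @param truths List with matching elements; ordinal truths as 0/1 matrices
#'   from \code{encodeOrdinal()}.
#' @param task_weights Named list/vector of non-negative weights.
#' @return Total loss (single number).
#' @export
totalLoss <- function(predictions, truths, task_weights) {
  if (any(unlist(task_weights) < 0)) stop("task weights must be non-negative")
  total <- 0
  for (task in names(predictions)) {
    p <- predictions[[task]]
    y <- truths[[task]]
    if (is.null(y)) stop("truths missing task ", task)
    w <- task_weights[[task]]
    if (is.null(w)) w <- 1
    if (task == "RP") {
      total <- total + w * mean((as.numeric(p) - as.numeric(y))^2)
    } else {
      p <- pmin(pmax(as.matrix(p), 1e-7), 1 - 1e-7)
      y <- as.matrix(y)
      total <- total + w * -mean(y * log(p) + (1 - y) * log(1 - p))
    }
  }
  total
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(upd, p, g, m, v)
      return(list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  res <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(res, `[[`, "p"),
       state = list(m = lapply(res, `[[`, "m"),
                    v = lapply(res, `[[`, "v"), t = t))
}
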