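# The hand-derived backprop is the foundation of the model module; verify it
# against central finite differences on small networks.

nn_test_setup <- function(rtype, combination, use_bn) {
  cfg <- rtModelConfig(max_len = 6L, embedding_dim = 4L,
                       recurrent_type = rtype, recurrent_units = 5L,
                       use_batch_norm = use_bn, combination = combination,
                       task_set = c("RP", "SCX"),
                       subnet_layer_sizes = c(5L, 4L), dropout_rate = 0,
                       n_fractions = list(SCX = 3L), seed = 7L)
  set.seed(42)
  V <- 6L
  params <- nn_init_params(cfg, V)
  bns <- nn_init_bn_stats(params, cfg)
  B <- 4L
  Xa <- matrix(sample(0:V, B * 6L, TRUE), B)
  Xa[, 1] <- sample(1:V, B, TRUE)
  Xb <- matrix(sample(0:V, B * 6L, TRUE), B)
  Xb[, 1] <- sample(1:V, B, TRUE)
  truths <- list(RP = stats::rnorm(B),
                 SCX = t(sapply(sample(1:3, B, TRUE), encodeOrdinal, n = 3L)))
  list(cfg = cfg, params = params, bns = bns,
       batch = list(Xa = Xa, Xb = Xb), truths = truths)
}

weighted_total <- function(losses, cfg) {
  sum(unlist(Map(function(l, task) cfg$task_weights[[task]] * l,
                 losses, names(losses))))
}

check_gradients <- function(rtype, combination, use_bn, n_probe = 3L) {
  s <- nn_test_setup(rtype, combination, use_bn)
  fwd <- nn_forward(s$params, s$batch, s$cfg, training = TRUE,
                    bn_stats = s$bns, keep_cache = TRUE)
  nl <- nn_loss(fwd$preds, s$truths, s$cfg$task_weights)
  grads <- nn_backward(s$params, fwd, s$batch, nl$d_pre, s$cfg)
  loss_at <- function(params) {
    f <- nn_forward(params, s$batch, s$cfg, training = TRUE, bn_stats = s$bns)
    weighted_total(nn_loss(f$preds, s$truths, s$cfg$task_weights)$losses,
                   s$cfg)
  }
  leaf_paths <- local({
    walk <- function(x, prefix) {
      if (is.list(x)) {
        unlist(lapply(names(x), function(nm) walk(x[[nm]], c(prefix, nm))),
               recursive = FALSE)
      } else list(prefix)
    }
    walk(s$params, character())
  })
  set.seed(1)
  max_rel <- 0
  for (pth in leaf_paths) {
    leaf <- Reduce(`[[`, pth, s$params)
    gleaf <- Reduce(`[[`, pth, grads)
    for (i in sample(length(leaf), min(n_probe, length(leaf)))) {
      eps <- 1e-5
      bump <- function(delta) {
        p <- s$params
        sel <- paste0("p[[\"", paste(pth, collapse = "\"]][[\""), "\"]]")
        lf <- leaf
        lf[i] <- lf[i] + delta
        eval(parse(text = paste0(sel, " <- lf")))
        p
      }
      num <- (loss_at(bump(eps)) - loss_at(bump(-eps))) / (2 * eps)
      rel <- abs(num - gleaf[i]) / max(1e-6, abs(num) + abs(gleaf[i]))
      max_rel <- max(max_rel, rel)
    }
  }
  max_rel
}

test_that("backprop matches finite differences for GRU and LSTM encoders", {
  expect_lt(check_gradients("GRU", "add", TRUE), 1e-4)
  expect_lt(check_gradients("LSTM", "add", TRUE), 1e-4)
  expect_lt(check_gradients("GRU", "concatenate", FALSE), 1e-4)
  expect_lt(check_gradients("GRU", "multiply", TRUE), 1e-4)
})

test_that("total loss decomposes into weighted per-task losses", {
  set.seed(9)
  B <- 20L
  preds <- list(RP = matrix(stats::rnorm(B)),
                SCX = matrix(stats::runif(B * 4L), B),
                hSAX = matrix(stats::runif(B * 5L), B))
  truths <- list(RP = stats::rnorm(B),
                 SCX = t(sapply(sample(1:4, B, TRUE), encodeOrdinal, n = 4L)),
                 hSAX = t(sapply(sample(1:5, B, TRUE), encodeOrdinal, n = 5L)))
  w <- list(RP = 1.5, SCX = 0.5, hSAX = 2)
  per_task <- vapply(names(preds), function(task) {
    totalLoss(preds[task], truths[task], stats::setNames(list(1), task))
  }, numeric(1))
  expect_equal(totalLoss(preds, truths, w),
               sum(unlist(w)[names(per_task)] * per_task), tolerance = 1e-6)
  # weights (1,0,0) reduce to the plain RP error
  expect_equal(totalLoss(preds, truths, list(RP = 1, SCX = 0, hSAX = 0)),
               mean((preds$RP - truths$RP)^2), tolerance = 1e-10)
  # doubling all weights doubles the loss
  w2 <- lapply(w, `*`, 2)
  expect_equal(totalLoss(preds, truths, w2), 2 * totalLoss(preds, truths, w))
  expect_error(totalLoss(preds, truths, list(RP = -1, SCX = 1, hSAX = 1)),
               "non-negative")
})

test_that("perfect predictions give zero loss", {
  truths <- list(RP = c(1, 2, 3),
                 SCX = rbind(encodeOrdinal(2, 3), encodeOrdinal(1, 3),
                             encodeOrdinal(3, 3)))
  preds <- list(RP = matrix(truths$RP), SCX = truths$SCX)
  expect_lt(totalLoss(preds, truths, list(RP = 1, SCX = 1)), 1e-5)
})
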