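#' Model configuration for the Siamese retention-time network
#'
#' Assembles and validates the hyper-parameters of the multi-task model.
#' The encoder is an embedding layer followed by a recurrent layer (GRU or
#' LSTM) whose weights are shared between the two peptides of a crosslink
#' (Siamese). The two encoder outputs are combined (additive by default,
#' which makes predictions independent of peptide order) and feed one
#' pyramid-shaped dense subnetwork per prediction task: RP (linear output,
#' squared-error loss, minutes) and SCX/hSAX (per-position sigmoid outputs
#' over the ordinal fraction encoding, binary cross-entropy).
#'
#' @param max_len Maximum peptide length in tokens (longer peptides are
#'   rejected at encoding time).
#' @param embedding_dim Embedding dimension.
#' @param recurrent_type "GRU" or "LSTM".
#' @param recurrent_units Hidden units of the recurrent layer.
#' @param use_batch_norm Batch-normalise the dense subnet layers.
#' @param combination How the two encoder outputs are merged:
#'   "add" (default), "concatenate" or "multiply".
#' @param task_set Subset of c("RP", "SCX", "hSAX").
#' @param subnet_layer_sizes Non-increasing integer vector of dense layer
#'   sizes shared by all task subnets.
#' @param dropout_rate Dropout rate between dense layers.
#' @param task_weights Named list of positive loss weights per task.
#' @param n_fractions Named list with the ordinal output lengths, e.g.
#'   \code{list(SCX = 9, hSAX = 10)}.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (the best epoch by validation loss is kept).
#' @param batch_size Minibatch size.
#' @param seed Master seed: fans out to weight initialisation, shuffling and
#'   dropout so training is exactly reproducible.
#' @param mod_vocabulary Modification suffixes understood by the tokenizer.
#' @param ordinal_threshold Decode threshold for fraction predictions.
#' @return A validated configuration list of class \code{"rt_model_config"}.
#' @export
rtModelConfig <- function(max_len = 40L, embedding_dim = 50L,
                          recurrent_type = c("GRU", "LSTM"),
                          recurrent_units = 50L, use_batch_norm = TRUE,
                          combination = c("add", "concatenate", "multiply"),
                          task_set = c("RP", "SCX", "hSAX"),
                          subnet_layer_sizes = c(50L, 20L, 10L),
                          dropout_rate = 0.1,
                          task_weights = list(RP = 1, SCX = 1, hSAX = 1),
                          n_fractions = list(SCX = 9L, hSAX = 10L),
                          learning_rate = 3e-3, epochs = 50L,
                          batch_size = 128L, seed = 42L,
                          mod_vocabulary = c("ox", "cm"),
                          ordinal_threshold = 0.5) {
  recurrent_type <- match.arg(recurrent_type)
  combination <- match.arg(combination)
  task_set <- match.arg(task_set, several.ok = TRUE)
  if (any(diff(subnet_layer_sizes) > 0)) {
    stop("subnet_layer_sizes must be non-increasing (pyramid-shaped)")
  }
  if (any(unlist(task_weights[task_set]) <= 0)) {
    stop("task weights must be positive")
  }
  for (task in setdiff(task_set, "RP")) {
    if (is.null(n_fractions[[task]]) || n_fractions[[task]] < 2L) {
      stop("n_fractions must give >= 2 fractions for task ", task)
    }
  }
  cfg <- list(
    max_len = as.integer(max_len), embedding_dim = as.integer(embedding_dim),
    recurrent_type = recurrent_type,
    recurrent_units = as.integer(recurrent_units),
    use_batch_norm = isTRUE(use_batch_norm), combination = combination,
    task_set = task_set,
    subnet_layer_sizes = as.integer(subnet_layer_sizes),
    dropout_rate = dropout_rate, task_weights = task_weights,
    n_fractions = lapply(n_fractions, as.integer),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), seed = as.integer(seed),
    mod_vocabulary = mod_vocabulary, ordinal_threshold = ordinal_threshold
  )
  class(cfg) <- "rt_model_config"
  cfg
}

#' Build an untrained retention-time model
#'
#' Initialises the network parameters (seeded by \code{config$seed}) for a
#' given token alphabet. In \code{"crosslink"} mode two encoded sequences
#' pass through one shared embedding + recurrent stack; \code{"linear"} mode
#' uses a single branch with the same stack, so a model can score both pairs
#' and single peptides with identical weights.
#'
#' @param config From \code{rtModelConfig()}.
#' @param alphabet Named integer token map from \code{buildAlphabet()}.
#' @param mode "crosslink" or "linear".
#' @return An \code{RTModel}.
#' @export
buildModel <- function(config, alphabet, mode = c("crosslink", "linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "rt_model_config"))
  set.seed(config$seed)
  params <- nn_init_params(config, vocab_size = length(alphabet))
  new("RTModel", config = unclass(config), alphabet = alphabet,
      params = params, bnStats = nn_init_bn_stats(params, config),
      rpScale = c(0, 1), history = data.frame(), mode = mode)
}

.model_cfg <- function(model) {
  cfg <- model@config
  class(cfg) <- "rt_model_config"
  cfg
}

# Encode the peptides of a CSM data.frame into padded integer matrices.
.encode_pair <- function(df, alphabet, cfg, mode) {
  Xa <- encodePeptideMatrix(df$peptide_a, df$link_pos_a, alphabet,
                            cfg$max_len, cfg$mod_vocabulary)
  if (mode == "linear") return(list(Xa = Xa, Xb = NULL))
  if (any(!nzchar(df$peptide_b))) {
    stop("crosslink mode requires a non-empty second peptide; ",
         "use linear mode for single peptides")
  }
  Xb <- encodePeptideMatrix(df$peptide_b, df$link_pos_b, alphabet,
                            cfg$max_len, cfg$mod_vocabulary)
  list(Xa = Xa, Xb = Xb)
}

.encode_truths <- function(df, cfg, rp_scale) {
  truths <- list()
  for (task in cfg$task_set) {
    if (task == "RP") {
      if (anyNA(df$rp_rt)) stop("missing rp_rt in training data")
      truths$RP <- (df$rp_rt - rp_scale[1]) / rp_scale[2]
    } else {
      col <- if (task == "SCX") "scx_fraction" else "hsax_fraction"
      n <- cfg$n_fractions[[task]]
      if (anyNA(df[[col]])) stop("missing ", col, " in training data")
      if (any(df[[col]] > n)) {
        stop("observed ", col, " exceeds configured n_fractions (", n, ")")
      }
      truths[[task]] <- t(vapply(df[[col]], encodeOrdinal, numeric(n), n = n))
    }
  }
  truths
}

.eval_losses <- function(params, bn_stats, batch, truths, cfg) {
  fwd <- nn_forward(params, batch, cfg, training = FALSE, bn_stats = bn_stats)
  nl <- nn_loss(fwd$preds, truths, cfg$task_weights)
  losses <- nl$losses
  total <- sum(unlist(Map(function(l, task) cfg$task_weights[[task]] * l,
                          losses, names(losses))))
  list(losses = losses, total = total)
}

#' Train a retention-time model
#'
#' Minibatch Adam training of the multi-task loss with best-checkpoint
#' selection: the parameters from the epoch with the lowest total
#' (weighted) validation loss are returned. All randomness (shuffling,
#' dropout) derives from \code{config$seed}, so two runs with the same seed
#' produce identical histories. RP targets are standardised internally
#' (centre/scale stored in the model); history losses for RP are therefore
#' in standardised units.
#'
#' @param model An \code{RTModel} from \code{buildModel()}.
#' @param train A \code{CSMSet} (or CSM data.frame) of training CSMs.
#' @param validation A non-empty \code{CSMSet}/data.frame used for
#'   checkpoint selection across epochs.
#' @param verbose Print per-epoch losses.
#' @return The trained \code{RTModel} with \code{trainingHistory()} filled.
#' @export
fitModel <- function(model, train, validation, verbose = FALSE) {
  stopifnot(is(model, "RTModel"))
  cfg <- .model_cfg(model)
  tr <- if (is(train, "CSMSet")) csmData(train) else train
  va <- if (is(validation, "CSMSet")) csmData(validation) else validation
  if (is.null(va) || nrow(va) == 0L) {
    stop("empty validation set: best-checkpoint selection undefined")
  }
  if (nrow(tr) < 2L) stop("need at least 2 training CSMs")
  set.seed(cfg$seed)
  rp_scale <- c(0, 1)
  if ("RP" %in% cfg$task_set) {
    rp_scale <- c(mean(tr$rp_rt), max(stats::sd(tr$rp_rt), 1e-8))
  }
  tr_batch <- .encode_pair(tr, model@alphabet, cfg, model@mode)
  tr_truths <- .encode_truths(tr, cfg, rp_scale)
  va_batch <- .encode_pair(va, model@alphabet, cfg, model@mode)
  va_truths <- .encode_truths(va, cfg, rp_scale)

  params <- model@params
  bn_stats <- model@bnStats
  opt <- adam_init(params)
  n <- nrow(tr)
  best <- list(total = Inf, params = params, bn = bn_stats, epoch = 0L)
  hist_rows <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_losses <- NULL
    for (s in starts) {
      take <- idx[s:min(s + cfg$batch_size - 1L, n)]
      batch <- list(Xa = tr_batch$Xa[take, , drop = FALSE],
                    Xb = if (!is.null(tr_batch$Xb))
                      tr_batch$Xb[take, , drop = FALSE])
      truths <- lapply(tr_truths, function(y) {
        if (is.matrix(y)) y[take, , drop = FALSE] else y[take]
      })
      fwd <- nn_forward(params, batch, cfg, training = TRUE,
                        bn_stats = bn_stats, keep_cache = TRUE)
      nl <- nn_loss(fwd$preds, truths, cfg$task_weights)
      grads <- nn_backward(params, fwd, batch, nl$d_pre, cfg)
      st <- adam_step(params, grads, opt, lr = cfg$learning_rate)
      params <- st$params
      opt <- st$state
      # exponential running statistics for inference-time batch norm
      if (cfg$use_batch_norm) {
        for (task in names(fwd$bn_updates)) {
          for (li in seq_along(fwd$bn_updates[[task]])) {
            u <- fwd$bn_updates[[task]][[li]]
            if (is.null(u)) next
            bn_stats[[task]][[li]]$mean <-
              0.9 * bn_stats[[task]][[li]]$mean + 0.1 * u$mean
            bn_stats[[task]][[li]]$var <-
              0.9 * bn_stats[[task]][[li]]$var + 0.1 * u$var
          }
        }
      }
      w <- length(take)
      lvec <- unlist(nl$losses)
      ep_losses <- if (is.null(ep_losses)) lvec * w else ep_losses + lvec * w
    }
    ep_losses <- ep_losses / n
    ev <- .eval_losses(params, bn_stats, va_batch, va_truths, cfg)
    row <- data.frame(epoch = epoch, val_total = ev$total)
    for (task in cfg$task_set) {
      row[[paste0("train_", task)]] <- ep_losses[[task]]
      row[[paste0("val_", task)]] <- ev$losses[[task]]
    }
    hist_rows[[epoch]] <- row
    if (ev$total < best$total) {
      best <- list(total = ev$total, params = params, bn = bn_stats,
                   epoch = epoch)
    }
    if (verbose) {
      message(sprintf("epoch %3d | val total %.4f%s", epoch, ev$total,
                      if (best$epoch == epoch) " *" else ""))
    }
  }
  history <- do.call(rbind, hist_rows)
  initialize(model, params = best$params, bnStats = best$bn,
             rpScale = rp_scale, history = history)
}

#' Predict retention behaviour for CSMs
#'
#' One prediction per CSM: the RP retention time (back-transformed to the
#' training units), per-position ordinal probabilities for the fraction
#' tasks and the decoded fraction numbers (\code{decodeOrdinal()}). With the
#' additive combination the output is invariant to swapping the two
#' peptides.
#'
#' @param model A trained \code{RTModel}.
#' @param csms A \code{CSMSet} or CSM data.frame.
#' @param chunk_size Internal batch size for inference.
#' @return data.frame with columns \code{csm_id}, and per task \code{rp},
#'   \code{scx_fraction}, \code{hsax_fraction}; ordinal probability matrices
#'   attached as attributes \code{scx_probs} / \code{hsax_probs}.
#' @export
predictRt <- function(model, csms, chunk_size = 256L) {
  stopifnot(is(model, "RTModel"))
  cfg <- .model_cfg(model)
  df <- if (is(csms, "CSMSet")) csmData(csms) else csms
  enc <- .encode_pair(df, model@alphabet, cfg, model@mode)
  .predict_encoded(model, enc, df$csm_id, chunk_size)
}

#' Predict retention behaviour for single peptides
#'
#' Runs the shared encoder on one peptide only (the linear path): the branch
#' output is passed to the task heads as if paired with an empty peptide.
#' Used for the alpha/beta single-peptide features during rescoring.
#'
#' @param model A trained \code{RTModel}.
#' @param peptides Character vector of modified peptide strings.
#' @param link_pos Integer vector of crosslink sites (NA for none).
#' @param chunk_size Internal batch size.
#' @return data.frame as for \code{predictRt()}.
#' @export
predictSingle <- function(model, peptides, link_pos = rep(NA_integer_,
                          length(peptides)), chunk_size = 256L) {
  cfg <- .model_cfg(model)
  Xa <- encodePeptideMatrix(peptides, link_pos, model@alphabet,
                            cfg$max_len, cfg$mod_vocabulary)
  .predict_encoded(model, list(Xa = Xa, Xb = NULL),
                   as.character(seq_along(peptides)), chunk_size)
}

.predict_encoded <- function(model, enc, ids, chunk_size) {
  cfg <- .model_cfg(model)
  n <- nrow(enc$Xa)
  out <- data.frame(csm_id = ids, stringsAsFactors = FALSE)
  preds_all <- list()
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    take <- s:min(s + chunk_size - 1L, n)
    batch <- list(Xa = enc$Xa[take, , drop = FALSE],
                  Xb = if (!is.null(enc$Xb)) enc$Xb[take, , drop = FALSE])
    fwd <- nn_forward(model@params, batch, cfg, training = FALSE,
                      bn_stats = model@bnStats)
    for (task in cfg$task_set) {
      preds_all[[task]] <- rbind(preds_all[[task]], fwd$preds[[task]])
    }
  }
  if ("RP" %in% cfg$task_set) {
    out$rp <- preds_all$RP[, 1L] * model@rpScale[2] + model@rpScale[1]
  }
  if ("SCX" %in% cfg$task_set) {
    out$scx_fraction <- apply(preds_all$SCX, 1L, decodeOrdinal,
                              threshold = cfg$ordinal_threshold)
    attr(out, "scx_probs") <- preds_all$SCX
  }
  if ("hSAX" %in% cfg$task_set) {
    out$hsax_fraction <- apply(preds_all$hSAX, 1L, decodeOrdinal,
                               threshold = cfg$ordinal_threshold)
    attr(out, "hsax_probs") <- preds_all$hSAX
  }
  out
}

#' Transfer a trained model to a new task configuration
#'
#' Copies the shared embedding and recurrent weights into a model built for
#' \code{new_config}. Task heads whose output shape is unchanged are copied;
#' heads whose output shape changed (e.g. a different number of fractions)
#' or that are new are freshly initialised. Used when the number of
#' collected fractions differs between the pre-training data and the new
#' prediction task, or when pre-training on a large dataset before
#' fine-tuning on a small one.
#'
#' @param model A trained source \code{RTModel}.
#' @param new_config An \code{rtModelConfig()}; must agree with the source
#'   on \code{embedding_dim}, \code{recurrent_type}, \code{recurrent_units}
#'   and \code{combination}.
#' @param mode Mode of the new model.
#' @return A new \code{RTModel} carrying the transferred weights (and the
#'   source RP scale, so an un-fine-tuned transfer predicts sensibly).
#' @export
transferModel <- function(model, new_config, mode = model@mode) {
  stopifnot(is(model, "RTModel"), inherits(new_config, "rt_model_config"))
  old <- .model_cfg(model)
  for (f in c("embedding_dim", "recurrent_type", "recurrent_units",
              "combination", "max_len")) {
    if (!identical(old[[f]], new_config[[f]])) {
      stop("transfer requires identical ", f, " (shared encoder)")
    }
  }
  target <- buildModel(new_config, model@alphabet, mode = mode)
  params <- target@params
  params$emb <- model@params$emb
  params$rnn <- model@params$rnn
  bn <- target@bnStats
  for (task in new_config$task_set) {
    if (!task %in% old$task_set) next
    same_shape <- if (task == "RP") TRUE else
      identical(old$n_fractions[[task]], new_config$n_fractions[[task]])
    if (same_shape) {
      params$heads[[task]] <- model@params$heads[[task]]
      bn[[task]] <- model@bnStats[[task]]
    }
  }
  initialize(target, params = params, bnStats = bn,
             rpScale = model@rpScale, history = model@history)
}

#' Number of trainable parameters
#' @param model An \code{RTModel}.
#' @return Integer count of scalar parameters (the shared encoder counted
#'   once: both Siamese branches use the same weights).
#' @export
countParameters <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  as.integer(cnt(model@params))
}
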