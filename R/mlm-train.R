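# ---- parameter-tree utilities ----------------------------------------------

.tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, .tree_map, f = f) else f(x)
}

# Leaves are paired by name where names exist (gradient trees are built in
# backward order), positionally otherwise.
.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    out <- lapply(keys, function(k) .tree_map2(a[[k]], b[[k]], f))
    names(out) <- names(a)
    out
  } else f(a, b)
}

.tree_sumsq <- function(x) {
  if (is.list(x)) sum(vapply(x, .tree_sumsq, numeric(1))) else sum(x * x)
}

# One Adam step (in place on a state list); returns list(params, m, v).
.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, clip = 1) {
  gnorm <- sqrt(.tree_sumsq(grads))
  if (is.finite(clip) && gnorm > clip)
    grads <- .tree_map(grads, function(g) g * (clip / gnorm))
  state$m <- .tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  upd <- .tree_map2(state$m, state$v,
                    function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  state$params <- .tree_map2(params, upd, function(p, u) p - lr * u)
  state
}

# Masked-position cross-entropy (equals KL against the one-hot truth) and its
# logit gradient, averaged over masked positions.
.masked_loss_grad <- function(logits, labels) {
  rows <- which(!is.na(labels))
  if (!length(rows)) return(list(loss = 0, dlogits = .zeros_like(logits)))
  P <- .softmax_rows(logits[rows, , drop = FALSE])
  tgt <- labels[rows]
  picked <- P[cbind(seq_along(rows), tgt)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dP <- P
  dP[cbind(seq_along(rows), tgt)] <- dP[cbind(seq_along(rows), tgt)] - 1
  dlogits <- .zeros_like(logits)
  dlogits[rows, ] <- dP / length(rows)
  list(loss = loss, dlogits = dlogits)
}

.mask_batch <- function(ids_list, vocab, rate) {
  masked <- lapply(ids_list, dynamic_mask, vocab = vocab, rate = rate)
  list(pack = .pack(lapply(masked, `[[`, "input_ids")),
       labels = unlist(lapply(masked, `[[`, "labels"), use.names = FALSE))
}

.eval_kl <- function(model, ids_list, vocab, rate, batch_size = 64L) {
  total <- 0; n <- 0
  for (batch in split(ids_list, ceiling(seq_along(ids_list) / batch_size))) {
    mb <- .mask_batch(batch, vocab, rate)
    fwd <- .mlm_forward_pack(model, mb$pack, train = FALSE)
    lg <- .masked_loss_grad(fwd$logits, mb$labels)
    k <- sum(!is.na(mb$labels))
    total <- total + lg$loss * k
    n <- n + k
  }
  if (n == 0) 0 else total / n
}

#' Train the masked language model
#'
#' Trains the encoder on complete reaction SMILES with dynamic masking: a
#' fresh random 15% of usable tokens is masked every epoch, the model
#' predicts the originals, and the KL divergence between the one-hot truth
#' and the predicted distribution at masked positions is minimized with the
#' Adam optimizer (gradient-norm clipping at 1). The corpus is split
#' 9 : 0.5 : 0.5 into training, validation and test partitions; training and
#' validation losses are logged per epoch and the test partition is reserved
#' for hidden-molecule evaluation. Fully seeded: the same seed reproduces
#' the loss curve exactly.
#'
#' @param corpus character vector of reaction SMILES, or a pre-encoded list
#'   of integer id sequences.
#' @param vocab a trained [bpe_train()] vocabulary.
#' @param config an [mlm_config()]; default is the desk preset sized to the
#'   vocabulary.
#' @param epochs,batch_size,lr optimizer schedule (defaults 30, 32, 3e-3).
#' @param mask_rate dynamic masking rate (default 0.15).
#' @param seed seed for the split, masking, batching and initialization.
#' @param quiet suppress per-epoch progress messages.
#' @return an `mlm_fit` list: `model`, `history` (data.frame of epoch,
#'   train_kl, valid_kl), `split` (index lists), `vocab`.
#' @export
mlm_train <- function(corpus, vocab, config = NULL, epochs = 30L,
                      batch_size = 32L, lr = 3e-3, mask_rate = 0.15,
                      seed = 1L, quiet = FALSE) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  ids_all <- if (is.character(corpus)) bpe_encode_corpus(corpus, vocab) else corpus
  if (is.null(config))
    config <- mlm_config("desk", vocab_size = length(vocab$tokens), seed = seed)
  model <- mlm_build(config, quiet = TRUE)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(ids_all)
  perm <- sample.int(n)
  n_train <- floor(n * 0.9)
  n_valid <- floor(n * 0.05)
  split <- list(train = perm[seq_len(n_train)],
                valid = perm[seq2(n_train + 1L, n_train + n_valid)],
                test = perm[seq2(n_train + n_valid + 1L, n)])
  train_ids <- ids_all[split$train]
  valid_ids <- ids_all[split$valid]

  state <- list(params = model$params,
                m = .tree_map(model$params, .zeros_like),
                v = .tree_map(model$params, .zeros_like))
  history <- data.frame(epoch = integer(0), train_kl = numeric(0),
                        valid_kl = numeric(0))
  t_step <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(length(train_ids))
    ep_loss <- 0; ep_n <- 0
    for (batch_idx in split(ord, ceiling(seq_along(ord) / batch_size))) {
      mb <- .mask_batch(train_ids[batch_idx], vocab, mask_rate)
      model$params <- state$params
      fwd <- .mlm_forward_pack(model, mb$pack, train = TRUE)
      lg <- .masked_loss_grad(fwd$logits, mb$labels)
      if (!is.finite(lg$loss))
        stop("training diverged at epoch ", epoch, " (non-finite loss); ",
             "reduce the learning rate")
      grads <- .mlm_backward_pack(model, fwd, lg$dlogits)
      t_step <- t_step + 1L
      state <- .adam_step(state$params, grads, state, lr, t_step)
      k <- sum(!is.na(mb$labels))
      ep_loss <- ep_loss + lg$loss * k
      ep_n <- ep_n + k
    }
    model$params <- state$params
    valid_kl <- .eval_kl(model, valid_ids, vocab, mask_rate)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_kl = ep_loss / max(ep_n, 1),
                                valid_kl = valid_kl))
    if (!quiet)
      message(sprintf("epoch %3d  train KL %.4f  valid KL %.4f",
                      epoch, ep_loss / max(ep_n, 1), valid_kl))
  }
  model$params <- state$params
  structure(list(model = model, history = history, split = split, vocab = vocab),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<mlm_fit> ", nrow(x$history), " epochs; final train KL ",
      sprintf("%.4f", last$train_kl), ", valid KL ",
      sprintf("%.4f", last$valid_kl), "\n", sep = "")
  invisible(x)
}

#' Save or load a model checkpoint directory
#'
#' Writes `config.json`, `params.json` (full-precision weights), the
#' training history CSV and, when present on the fit, the tokenizer
#' vocabulary, into a directory; `mlm_checkpoint_load()` restores the fit.
#'
#' @param fit an `mlm_fit` (or bare `mlm_model`).
#' @param dir checkpoint directory (created if needed).
#' @return the directory (`mlm_checkpoint_save`), or the restored object.
#' @export
mlm_checkpoint_save <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (inherits(fit, "mlm_fit")) fit$model else fit
  cfg <- model$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.tree_map(model$params, function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x)) else as.numeric(x)
  }), file.path(dir, "params.json"), digits = NA, auto_unbox = FALSE)
  if (inherits(fit, "mlm_fit")) {
    utils::write.csv(fit$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
    bpe_save(fit$vocab, file.path(dir, "vocab.json"))
  }
  invisible(dir)
}

#' @rdname mlm_checkpoint_save
#' @export
mlm_checkpoint_load <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- mlm_config(cfg_raw$preset, vocab_size = cfg_raw$vocab_size,
                    hidden_size = cfg_raw$hidden_size,
                    num_layers = cfg_raw$num_layers,
                    num_heads = cfg_raw$num_heads, max_len = cfg_raw$max_len,
                    dropout = cfg_raw$dropout,
                    attention_dropout = cfg_raw$attention_dropout,
                    layer_norm_eps = cfg_raw$layer_norm_eps,
                    activation = cfg_raw$activation, seed = cfg_raw$seed)
  raw <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  restore <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim")))
      matrix(x$data, x$dim[1], x$dim[2])
    else if (is.list(x)) lapply(x, restore)
    else as.numeric(x)
  }
  model <- structure(list(params = restore(raw), config = cfg),
                     class = "mlm_model")
  out <- list(model = model)
  hist_path <- file.path(dir, "history.csv")
  vocab_path <- file.path(dir, "vocab.json")
  if (file.exists(hist_path)) out$history <- utils::read.csv(hist_path)
  if (file.exists(vocab_path)) out$vocab <- bpe_load(vocab_path)
  if (!is.null(out$vocab)) structure(out, class = "mlm_fit") else model
}
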