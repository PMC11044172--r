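#' Masked-language-model configuration
#'
#' Architecture hyperparameters for the bidirectional-transformer masked
#' language model. Two named presets ship with the package: `"desk"`
#' (hidden 64, 2 layers, 4 heads, maximum length 128), sized so a full
#' train/evaluate cycle runs on one CPU core in minutes, and `"production"`
#' (hidden 768, 6 layers, 12 heads, maximum length 512), the scale the
#' method targets on real reaction corpora. Both use GELU activations, dropout 0.1 on fully
#' connected layers and attention probabilities, and layer-norm epsilon
#' 1e-12.
#'
#' @param preset `"desk"` or `"production"`.
#' @param vocab_size vocabulary size (required; determines the output width:
#'   every position's output vector has one logit per vocabulary token).
#' @param hidden_size,num_layers,num_heads,max_len,dropout,attention_dropout,
#'   layer_norm_eps,activation overrides of the preset values.
#' @param seed integer seed for weight initialization.
#' @return an `mlm_config` list.
#' @export
mlm_config <- function(preset = c("desk", "production"), vocab_size,
                       hidden_size = NULL, num_layers = NULL, num_heads = NULL,
                       max_len = NULL, dropout = 0.1, attention_dropout = 0.1,
                       layer_norm_eps = 1e-12, activation = "gelu", seed = 1L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk = list(hidden_size = 64L, num_layers = 2L, num_heads = 4L, max_len = 128L),
    production = list(hidden_size = 768L, num_layers = 6L,
                      num_heads = 12L, max_len = 512L))
  cfg <- list(
    preset = preset,
    vocab_size = as.integer(vocab_size),
    hidden_size = as.integer(hidden_size %||% base$hidden_size),
    num_layers = as.integer(num_layers %||% base$num_layers),
    num_heads = as.integer(num_heads %||% base$num_heads),
    max_len = as.integer(max_len %||% base$max_len),
    dropout = dropout, attention_dropout = attention_dropout,
    layer_norm_eps = layer_norm_eps, activation = activation,
    seed = as.integer(seed))
  if (cfg$hidden_size %% cfg$num_heads != 0L)
    stop("hidden_size must be divisible by num_heads")
  if (!identical(cfg$activation, "gelu"))
    stop("only the GELU activation is supported")
  class(cfg) <- "mlm_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of trainable parameters for a configuration
#'
#' A pure function of the configuration: embeddings (token, position, and
#' their layer norm), the encoder layers, and the tied output head (its
#' decoder shares the token-embedding matrix, adding only a bias).
#'
#' @param config an [mlm_config()].
#' @return integer parameter count.
#' @export
mlm_n_params <- function(config) {
  H <- config$hidden_size; V <- config$vocab_size; L <- config$max_len
  per_layer <- 4L * (H * H + H) +      # q, k, v, o projections
    2L * H +                           # ln1
    H * 4L * H + 4L * H +              # ffn in
    4L * H * H + H +                   # ffn out
    2L * H                             # ln2
  V * H + L * H + 2L * H +             # embeddings + embedding ln
    config$num_layers * per_layer +
    (H * H + H) + 2L * H +             # head transform + head ln
    V                                  # tied decoder bias
}

.rnorm_mat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

#' Build an untrained masked language model
#'
#' Initializes all weights (normal, sd 0.02; layer-norm gains 1, biases 0)
#' under the configuration seed and reports the parameter count.
#'
#' @param config an [mlm_config()].
#' @param quiet suppress the parameter-count message.
#' @return an object of class `mlm_model`.
#' @export
mlm_build <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "mlm_config"))
  H <- config$hidden_size; V <- config$vocab_size
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  layer <- function() list(
    Wq = .rnorm_mat(H, H), bq = numeric(H),
    Wk = .rnorm_mat(H, H), bk = numeric(H),
    Wv = .rnorm_mat(H, H), bv = numeric(H),
    Wo = .rnorm_mat(H, H), bo = numeric(H),
    ln1_g = rep(1, H), ln1_b = numeric(H),
    W1 = .rnorm_mat(H, 4L * H), b1 = numeric(4L * H),
    W2 = .rnorm_mat(4L * H, H), b2 = numeric(H),
    ln2_g = rep(1, H), ln2_b = numeric(H))
  params <- list(
    E = .rnorm_mat(V, H), P = .rnorm_mat(config$max_len, H),
    ln0_g = rep(1, H), ln0_b = numeric(H),
    layers = lapply(seq_len(config$num_layers), function(i) layer()),
    Wh = .rnorm_mat(H, H), bh = numeric(H),
    lnh_g = rep(1, H), lnh_b = numeric(H),
    out_b = numeric(V))
  model <- structure(list(params = params, config = config), class = "mlm_model")
  if (!quiet)
    message("mlm model built: ", format(mlm_n_params(config), big.mark = ","),
            " parameters")
  model
}

#' @export
print.mlm_model <- function(x, ...) {
  cfg <- x$config
  cat("<mlm_model> ", cfg$preset, " preset: hidden ", cfg$hidden_size,
      ", layers ", cfg$num_layers, ", heads ", cfg$num_heads,
      ", vocab ", cfg$vocab_size, ", ",
      format(mlm_n_params(cfg), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# ---- numerical primitives ---------------------------------------------------

.add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

.ln_fwd <- function(x, g, b, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xh <- xc * inv
  list(y = .add_bias(xh * matrix(g, nrow(x), length(g), byrow = TRUE), b),
       xh = xh, inv = inv)
}

.ln_bwd <- function(dy, cache, g) {
  xh <- cache$xh
  dxh <- dy * matrix(g, nrow(dy), length(g), byrow = TRUE)
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dx <- cache$inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
  list(dx = dx, dg = dg, db = db)
}

.gelu_fwd <- function(x) x * stats::pnorm(x)
.gelu_bwd <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

.dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

# ---- forward / backward -----------------------------------------------------

# Pack a list of id sequences: rows concatenated, with per-sequence ranges.
.pack <- function(ids_list) {
  lens <- lengths(ids_list)
  ends <- cumsum(lens)
  list(ids = unlist(ids_list, use.names = FALSE), lens = lens,
       starts = ends - lens + 1L, ends = ends,
       pos = unlist(lapply(lens, seq_len), use.names = FALSE))
}

.mlm_forward_pack <- function(model, pack, train = FALSE) {
  p <- model$params; cfg <- model$config
  H <- cfg$hidden_size; nh <- cfg$num_heads; dk <- H %/% nh
  eps <- cfg$layer_norm_eps
  if (any(pack$lens > cfg$max_len))
    stop("sequence length ", max(pack$lens), " exceeds max_len ", cfg$max_len)
  if (any(pack$ids > cfg$vocab_size))
    stop("token id outside vocabulary")
  N <- length(pack$ids)
  drop_p <- if (train) cfg$dropout else 0
  attn_p <- if (train) cfg$attention_dropout else 0

  X0 <- p$E[pack$ids, , drop = FALSE] + p$P[pack$pos, , drop = FALSE]
  ln0 <- .ln_fwd(X0, p$ln0_g, p$ln0_b, eps)
  d0 <- .dropout_mask(N, H, drop_p)
  X <- if (is.null(d0)) ln0$y else ln0$y * d0

  caches <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    lp <- p$layers[[l]]
    Xin <- X
    Q <- .add_bias(Xin %*% lp$Wq, lp$bq)
    K <- .add_bias(Xin %*% lp$Wk, lp$bk)
    V <- .add_bias(Xin %*% lp$Wv, lp$bv)
    Ctx <- matrix(0, N, H)
    A_list <- vector("list", length(pack$lens))
    Ad_list <- vector("list", length(pack$lens))
    for (s in seq_along(pack$lens)) {
      rows <- seq2(pack$starts[s], pack$ends[s])
      A_heads <- vector("list", nh); Ad_heads <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- seq2((h - 1L) * dk + 1L, h * dk)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dk)
        A <- .softmax_rows(S)
        Ad <- .dropout_mask(nrow(A), ncol(A), attn_p)
        Au <- if (is.null(Ad)) A else A * Ad
        Ctx[rows, cols] <- Au %*% V[rows, cols, drop = FALSE]
        A_heads[[h]] <- A; Ad_heads[h] <- list(Ad)  # list() keeps NULL slots
      }
      A_list[[s]] <- A_heads; Ad_list[[s]] <- Ad_heads
    }
    O_pre <- .add_bias(Ctx %*% lp$Wo, lp$bo)
    do_m <- .dropout_mask(N, H, drop_p)
    O <- if (is.null(do_m)) O_pre else O_pre * do_m
    ln1 <- .ln_fwd(Xin + O, lp$ln1_g, lp$ln1_b, eps)
    X2 <- ln1$y
    U_pre <- .add_bias(X2 %*% lp$W1, lp$b1)
    U <- .gelu_fwd(U_pre)
    F_pre <- .add_bias(U %*% lp$W2, lp$b2)
    df_m <- .dropout_mask(N, H, drop_p)
    Fo <- if (is.null(df_m)) F_pre else F_pre * df_m
    ln2 <- .ln_fwd(X2 + Fo, lp$ln2_g, lp$ln2_b, eps)
    caches[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, A = A_list, Ad = Ad_list,
                        Ctx = Ctx, do_m = do_m, ln1 = ln1, X2 = X2,
                        U_pre = U_pre, U = U, df_m = df_m, ln2 = ln2)
    X <- ln2$y
  }
  Hd_pre <- .add_bias(X %*% p$Wh, p$bh)
  Hd <- .gelu_fwd(Hd_pre)
  lnh <- .ln_fwd(Hd, p$lnh_g, p$lnh_b, eps)
  logits <- .add_bias(tcrossprod(lnh$y, p$E), p$out_b)
  list(logits = logits,
       cache = list(X0 = X0, ln0 = ln0, d0 = d0, layers = caches,
                    Xtop = X, Hd_pre = Hd_pre, lnh = lnh, pack = pack))
}

.zeros_like <- function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

.mlm_backward_pack <- function(model, fwd, dlogits) {
  p <- model$params; cfg <- model$config
  H <- cfg$hidden_size; nh <- cfg$num_heads; dk <- H %/% nh
  pack <- fwd$cache$pack
  g <- list(E = .zeros_like(p$E), P = .zeros_like(p$P),
            ln0_g = numeric(H), ln0_b = numeric(H),
            layers = vector("list", cfg$num_layers),
            Wh = .zeros_like(p$Wh), bh = numeric(H),
            lnh_g = numeric(H), lnh_b = numeric(H),
            out_b = numeric(cfg$vocab_size))

  # tied output head
  Hn <- fwd$cache$lnh$y
  g$out_b <- colSums(dlogits)
  dHn <- dlogits %*% p$E
  g$E <- g$E + crossprod(dlogits, Hn)
  bl <- .ln_bwd(dHn, fwd$cache$lnh, p$lnh_g)
  g$lnh_g <- bl$dg; g$lnh_b <- bl$db
  dHd <- bl$dx * .gelu_bwd(fwd$cache$Hd_pre)
  g$Wh <- crossprod(fwd$cache$Xtop, dHd)
  g$bh <- colSums(dHd)
  dX <- dHd %*% t(p$Wh)

  for (l in rev(seq_len(cfg$num_layers))) {
    lp <- p$layers[[l]]; cc <- fwd$cache$layers[[l]]
    gl <- list()
    b2l <- .ln_bwd(dX, cc$ln2, lp$ln2_g)
    gl$ln2_g <- b2l$dg; gl$ln2_b <- b2l$db
    dsum2 <- b2l$dx                       # gradient into X2 + Fo
    dFo <- if (is.null(cc$df_m)) dsum2 else dsum2 * cc$df_m
    gl$W2 <- crossprod(cc$U, dFo)
    gl$b2 <- colSums(dFo)
    dU <- dFo %*% t(lp$W2)
    dU_pre <- dU * .gelu_bwd(cc$U_pre)
    gl$W1 <- crossprod(cc$X2, dU_pre)
    gl$b1 <- colSums(dU_pre)
    dX2 <- dsum2 + dU_pre %*% t(lp$W1)
    b1l <- .ln_bwd(dX2, cc$ln1, lp$ln1_g)
    gl$ln1_g <- b1l$dg; gl$ln1_b <- b1l$db
    dsum1 <- b1l$dx                       # gradient into Xin + O
    dO <- if (is.null(cc$do_m)) dsum1 else dsum1 * cc$do_m
    gl$Wo <- crossprod(cc$Ctx, dO)
    gl$bo <- colSums(dO)
    dCtx <- dO %*% t(lp$Wo)
    dQ <- matrix(0, nrow(dCtx), H); dK <- dQ; dV <- dQ
    for (s in seq_along(pack$lens)) {
      rows <- seq2(pack$starts[s], pack$ends[s])
      for (h in seq_len(nh)) {
        cols <- seq2((h - 1L) * dk + 1L, h * dk)
        A <- cc$A[[s]][[h]]; Ad <- cc$Ad[[s]][[h]]
        Au <- if (is.null(Ad)) A else A * Ad
        dCtx_sh <- dCtx[rows, cols, drop = FALSE]
        Vsh <- cc$V[rows, cols, drop = FALSE]
        dAu <- tcrossprod(dCtx_sh, Vsh)
        dV[rows, cols] <- crossprod(Au, dCtx_sh)
        dA <- if (is.null(Ad)) dAu else dAu * Ad
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] / sqrt(dk)
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) / sqrt(dk)
      }
    }
    gl$Wq <- crossprod(cc$Xin, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(cc$Xin, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(cc$Xin, dV); gl$bv <- colSums(dV)
    dXin <- dsum1 + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    g$layers[[l]] <- gl
    dX <- dXin
  }

  dEmb <- if (is.null(fwd$cache$d0)) dX else dX * fwd$cache$d0
  b0 <- .ln_bwd(dEmb, fwd$cache$ln0, p$ln0_g)
  g$ln0_g <- b0$dg; g$ln0_b <- b0$db
  dX0 <- b0$dx
  gE_in <- rowsum(dX0, group = pack$ids)
  idx <- as.integer(rownames(gE_in))
  g$E[idx, ] <- g$E[idx, , drop = FALSE] + gE_in
  gP <- rowsum(dX0, group = pack$pos)
  idxp <- as.integer(rownames(gP))
  g$P[idxp, ] <- g$P[idxp, , drop = FALSE] + gP
  g
}

#' Forward pass: logits for a token-id sequence
#'
#' Runs the encoder over one sequence (inference mode: dropout disabled) and
#' returns the position-by-vocabulary logit matrix. Over-length sequences
#' raise an error; there is no silent truncation.
#'
#' @param model an `mlm_model`.
#' @param ids integer token ids (including `<bos>`/`<eos>`).
#' @return numeric matrix, `length(ids)` rows by `vocab_size` columns.
#' @export
mlm_forward <- function(model, ids) {
  stopifnot(inherits(model, "mlm_model"))
  .mlm_forward_pack(model, .pack(list(as.integer(ids))), train = FALSE)$logits
}

#' Decode logits to token ids
#'
#' Softmax over each position followed by argmax; ties resolve to the lowest
#' token id. Softmax is monotone, so the argmax is taken on the logits; the
#' probability view enters the loss via [kl_loss()].
#'
#' @param logits numeric matrix, positions by vocabulary.
#' @return integer token ids, one per row.
#' @export
decode_tokens <- function(logits) {
  apply(logits, 1L, which.max)
}

#' Kullback-Leibler divergence between token distributions
#'
#' Mean over positions of `sum(y_true * log(y_true / y_pred))`, the training
#' and validation loss of the masked language model; computed at masked
#' positions only during training. `y_pred` is floored at 1e-12.
#'
#' @param y_true,y_pred numeric matrices of row-wise distributions with equal
#'   dimensions.
#' @return non-negative scalar.
#' @export
kl_loss <- function(y_true, y_pred) {
  if (!all(dim(y_true) == dim(y_pred)))
    stop("y_true and y_pred must have identical dimensions")
  y_pred <- pmax(y_pred, 1e-12)
  terms <- ifelse(y_true > 0, y_true * log(y_true / y_pred), 0)
  mean(rowSums(terms))
}

#' Dynamically mask a token sequence
#'
#' Replaces `round(rate * usable)` uniformly chosen non-special positions
#' with the `<mask>` token, where usable positions exclude `<bos>`, `<eos>`
#' and `<pad>`. A fresh RNG state per epoch yields different masks, so every
#' token is eventually exposed as a prediction target.
#'
#' @param ids integer token ids including specials.
#' @param vocab a `bpe_vocab` (supplies the special-token ids).
#' @param rate masking rate in `[0, 1]`, default 0.15.
#' @return list with `input_ids` (masked sequence), `labels` (original ids at
#'   masked positions, `NA` elsewhere) and `mask_pos` (indices).
#' @export
dynamic_mask <- function(ids, vocab, rate = 0.15) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  ids <- as.integer(ids)
  usable <- which(!(ids %in% vocab$special))
  n_mask <- round(rate * length(usable))
  mask_pos <- if (n_mask > 0) sort(sample(usable, n_mask)) else integer(0)
  labels <- rep(NA_integer_, length(ids))
  labels[mask_pos] <- ids[mask_pos]
  input_ids <- ids
  input_ids[mask_pos] <- vocab$special[["mask"]]
  list(input_ids = input_ids, labels = labels, mask_pos = mask_pos)
}
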