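tiny_setup <- function(hidden = 8L, layers = 2L, heads = 2L) {
  vocab <- bpe_train(c("CCO>>CCO", "CC(=O)O.CO>>COC(C)=O.O"), vocab_size = 40L)
  cfg <- mlm_config("desk", vocab_size = length(vocab$tokens),
                    hidden_size = hidden, num_layers = layers,
                    num_heads = heads, max_len = 32L,
                    dropout = 0, attention_dropout = 0, seed = 3L)
  list(vocab = vocab, cfg = cfg, model = mlm_build(cfg, quiet = TRUE))
}

test_that("analytic gradients match finite differences", {
  st <- tiny_setup()
  ids <- bpe_encode("CC(=O)O.CO>>COC(C)=O.O", st$vocab)
  set.seed(9)
  mk <- dynamic_mask(ids, st$vocab, 0.3)
  pack <- rxncomplete:::.pack(list(mk$input_ids))
  loss_of <- function(model) {
    fwd <- rxncomplete:::.mlm_forward_pack(model, pack, train = FALSE)
    rxncomplete:::.masked_loss_grad(fwd$logits, mk$labels)$loss
  }
  fwd <- rxncomplete:::.mlm_forward_pack(st$model, pack, train = FALSE)
  lg <- rxncomplete:::.masked_loss_grad(fwd$logits, mk$labels)
  gr <- rxncomplete:::.mlm_backward_pack(st$model, fwd, lg$dlogits)

  probes <- list(
    list(get = function(m) m$params$E[5, 3],
         set = function(m, v) { m$params$E[5, 3] <- v; m },
         grad = gr$E[5, 3]),
    list(get = function(m) m$params$layers[[1]]$Wq[3, 6],
         set = function(m, v) { m$params$layers[[1]]$Wq[3, 6] <- v; m },
         grad = gr$layers[[1]]$Wq[3, 6]),
    list(get = function(m) m$params$layers[[2]]$W2[10, 2],
         set = function(m, v) { m$params$layers[[2]]$W2[10, 2] <- v; m },
         grad = gr$layers[[2]]$W2[10, 2]),
    list(get = function(m) m$params$layers[[1]]$ln1_g[5],
         set = function(m, v) { m$params$layers[[1]]$ln1_g[5] <- v; m },
         grad = gr$layers[[1]]$ln1_g[5]),
    list(get = function(m) m$params$Wh[2, 2],
         set = function(m, v) { m$params$Wh[2, 2] <- v; m },
         grad = gr$Wh[2, 2]),
    list(get = function(m) m$params$ln0_b[1],
         set = function(m, v) { m$params$ln0_b[1] <- v; m },
         grad = gr$ln0_b[1]))
  eps <- 1e-5
  for (p in probes) {
    up <- loss_of(p$set(st$model, p$get(st$model) + eps))
    dn <- loss_of(p$set(st$model, p$get(st$model) - eps))
    fd <- (up - dn) / (2 * eps)
    expect_equal(p$grad, fd, tolerance = 1e-4)
  }
})

test_that("unmasked positions contribute zero gradient", {
  st <- tiny_setup()
  ids <- bpe_encode("CC(=O)O.CO>>COC(C)=O.O", st$vocab)
  set.seed(5)
  mk <- dynamic_mask(ids, st$vocab, 0.2)
  pack <- rxncomplete:::.pack(list(mk$input_ids))
  fwd <- rxncomplete:::.mlm_forward_pack(st$model, pack, train = FALSE)
  lg <- rxncomplete:::.masked_loss_grad(fwd$logits, mk$labels)
  unmasked <- which(is.na(mk$labels))
  expect_true(all(lg$dlogits[unmasked, ] == 0))
  expect_true(any(lg$dlogits[mk$mask_pos, ] != 0))
})

test_that("dynamic masking rounds 15% of usable tokens and never touches specials", {
  st <- tiny_setup()
  ids <- c(st$vocab$special[["bos"]], rep(10L, 20L), st$vocab$special[["eos"]])
  set.seed(1)
  mk <- dynamic_mask(ids, st$vocab, 0.15)
  expect_length(mk$mask_pos, 3L)  # round(0.15 * 20)
  expect_false(1L %in% mk$mask_pos)
  expect_false(length(ids) %in% mk$mask_pos)
  expect_true(all(mk$input_ids[mk$mask_pos] == st$vocab$special[["mask"]]))
  expect_identical(mk$labels[mk$mask_pos], ids[mk$mask_pos])
  expect_true(all(is.na(mk$labels[-mk$mask_pos])))

  mk0 <- dynamic_mask(ids, st$vocab, 0)
  expect_length(mk0$mask_pos, 0L)
  expect_true(all(is.na(mk0$labels)))
  expect_error(dynamic_mask(ids, st$vocab, 1.5), "rate")
})

test_that("fresh masks differ across epochs and eventually cover the sequence", {
  st <- tiny_setup()
  ids <- c(st$vocab$special[["bos"]], rep(10L, 100L), st$vocab$special[["eos"]])
  set.seed(100)
  m1 <- dynamic_mask(ids, st$vocab, 0.15)
  set.seed(101)
  m2 <- dynamic_mask(ids, st$vocab, 0.15)
  expect_false(identical(m1$mask_pos, m2$mask_pos))
  covered <- integer(0)
  for (ep in 1:50) {
    set.seed(200 + ep)
    covered <- union(covered, dynamic_mask(ids, st$vocab, 0.15)$mask_pos)
  }
  expect_gt(length(covered) / 100, 0.95)
})

test_that("softmax rows normalize and decoding breaks ties toward low ids", {
  st <- tiny_setup()
  ids <- bpe_encode("CCO>>CCO", st$vocab)
  logits <- mlm_forward(st$model, ids)
  probs <- rxncomplete:::.softmax_rows(logits)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)

  onehot <- matrix(0, 2, 6); onehot[1, 4] <- 50
  expect_identical(decode_tokens(onehot), c(4L, 1L))  # uniform row 2 -> id 1

  long <- rep(5L, st$cfg$max_len + 3L)
  expect_error(mlm_forward(st$model, long), "max_len")
})

test_that("kl loss is zero at equality, matches the closed form, and is asymmetric", {
  p <- matrix(c(1, 0, 0, 0), 1, 4)
  q <- matrix(0.25, 1, 4)
  expect_equal(kl_loss(q, q), 0)
  expect_equal(kl_loss(p, q), log(4))
  expect_false(isTRUE(all.equal(kl_loss(p, q), kl_loss(q, p))))
  expect_error(kl_loss(p, matrix(0.5, 1, 2)), "identical dimensions")
})

test_that("parameter count follows the configuration closed form", {
  st <- tiny_setup()
  n_leaf <- function(x) if (is.list(x)) sum(vapply(x, n_leaf, numeric(1))) else length(x)
  expect_identical(n_leaf(st$model$params), as.numeric(mlm_n_params(st$cfg)))
  expect_error(mlm_config("desk", vocab_size = 10, hidden_size = 10,
                          num_heads = 4), "divisible")
})

test_that("training is seeded and loss decreases", {
  corpus <- vapply(generate_reactions(160, seed = 55), serialize_reaction, "",
                   "plain2")
  vocab <- bpe_train(corpus, vocab_size = 120L)
  cfg <- mlm_config("desk", vocab_size = length(vocab$tokens),
                    hidden_size = 32L, num_layers = 1L, num_heads = 2L,
                    max_len = 64L, dropout = 0, attention_dropout = 0, seed = 2L)
  fit1 <- mlm_train(corpus, vocab, config = cfg, epochs = 8L, seed = 13L,
                    quiet = TRUE)
  fit2 <- mlm_train(corpus, vocab, config = cfg, epochs = 8L, seed = 13L,
                    quiet = TRUE)
  expect_identical(fit1$history, fit2$history)  # bitwise-identical loss curve
  expect_lt(fit1$history$train_kl[8], fit1$history$train_kl[1])
  expect_true(all(is.finite(fit1$history$valid_kl)))
})

test_that("masked learning converges on a degenerate corpus", {
  # a handful of fixed reaction strings, heavily repeated: every masked token
  # is deterministically recoverable from its context, so held-out
  # masked-token accuracy should approach 1 within a few dozen epochs
  base <- vapply(generate_reactions(20, seed = 55), serialize_reaction, "",
                 "plain2")
  corpus <- rep(base, 30)
  vocab <- bpe_train(base, vocab_size = 120L)
  cfg <- mlm_config("desk", vocab_size = length(vocab$tokens),
                    hidden_size = 32L, num_layers = 1L, num_heads = 2L,
                    max_len = 64L, dropout = 0, attention_dropout = 0, seed = 2L)
  fit <- mlm_train(corpus, vocab, config = cfg, epochs = 40L, seed = 13L,
                   quiet = TRUE)
  test_ids <- bpe_encode_corpus(corpus[fit$split$test], vocab)
  n_ok <- 0; n <- 0
  for (ids in test_ids) {
    set.seed(n + 1)
    mk <- dynamic_mask(ids, vocab, 0.15)
    if (!length(mk$mask_pos)) next
    pred <- decode_tokens(mlm_forward(fit$model, mk$input_ids))
    n_ok <- n_ok + sum(pred[mk$mask_pos] == ids[mk$mask_pos])
    n <- n + length(mk$mask_pos)
  }
  expect_gt(n_ok / n, 0.9)
})

test_that("checkpoints round-trip through the directory format", {
  st <- tiny_setup()
  corpus <- c("CCO>>CCO", "CC(=O)O.CO>>COC(C)=O.O", "CC>>CC", "CCO>>CCO",
              "CC(=O)O.CO>>COC(C)=O.O", "CC>>CC")
  fit <- mlm_train(corpus, st$vocab, config = st$cfg, epochs = 2L, seed = 4L,
                   quiet = TRUE)
  dir <- withr::local_tempdir()
  mlm_checkpoint_save(fit, dir)
  back <- mlm_checkpoint_load(dir)
  expect_s3_class(back, "mlm_fit")
  ids <- bpe_encode("CCO>>CCO", st$vocab)
  expect_equal(mlm_forward(back$model, ids), mlm_forward(fit$model, ids),
               tolerance = 1e-12)
  expect_equal(back$history$train_kl, fit$history$train_kl, tolerance = 1e-6)
})
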