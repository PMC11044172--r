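# Independent pair-frequency oracle: recount every adjacent pair over plain
# character/token string lists, pick the most frequent (lexicographic ties)
# and merge it, without the package's flat-vector machinery.
naive_bpe_merges <- function(corpus, n_merges) {
  seqs <- lapply(strsplit(corpus, "", fixed = TRUE), identity)
  merges <- character(0)
  for (step in seq_len(n_merges)) {
    pairs <- list()
    for (s in seqs) {
      if (length(s) < 2) next
      for (i in seq_len(length(s) - 1)) {
        key <- paste0(s[i], "\r", s[i + 1])
        pairs[[key]] <- (pairs[[key]] %||% 0) + 1
      }
    }
    if (!length(pairs)) break
    freq <- unlist(pairs)
    top <- max(freq)
    if (top < 2) break
    best <- sort(names(freq)[freq == top], method = "radix")[1]
    ab <- strsplit(best, "\r", fixed = TRUE)[[1]]
    merges <- c(merges, paste0(ab[1], ab[2]))
    seqs <- lapply(seqs, function(s) {
      out <- character(0)
      i <- 1
      while (i <= length(s)) {
        if (i < length(s) && s[i] == ab[1] && s[i + 1] == ab[2]) {
          out <- c(out, paste0(ab[1], ab[2])); i <- i + 2
        } else {
          out <- c(out, s[i]); i <- i + 1
        }
      }
      out
    })
  }
  merges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merged_tokens <- function(vocab) {
  n_base <- length(vocab$tokens) - length(vocab$merges)
  vocab$tokens[seq2(n_base + 1L, length(vocab$tokens))]
}
seq2 <- function(from, to) if (from > to) integer(0) else from:to

test_that("merge learning matches the brute-force pair-frequency oracle", {
  corpora <- list(
    "CCO>>CCO",
    c("CC(=O)O.CCO>>CCOC(C)=O.O", "CC(=O)O.CO>>COC(C)=O.O"),
    vapply(generate_reactions(40, seed = 17), serialize_reaction, "", "plain2")
  )
  for (corpus in corpora) {
    vocab <- bpe_train(corpus, vocab_size = 300L)
    oracle <- naive_bpe_merges(corpus, n_merges = length(vocab$merges) + 5L)
    expect_identical(unname(merged_tokens(vocab)), oracle)
  }
})

test_that("vocabulary carries exactly four reserved special tokens", {
  vocab <- bpe_train(c("CCO>>CCO", "CC>>CC"), vocab_size = 64L)
  expect_identical(names(vocab$special), c("bos", "eos", "mask", "pad"))
  expect_identical(unname(vocab$special), 1:4)
  expect_identical(sum(vocab$tokens %in% c("<bos>", "<eos>", "<mask>", "<pad>")), 4L)
  expect_error(bpe_train("CCO>>CCO", vocab_size = 5L), "below base alphabet")
  expect_error(bpe_train(character(0)), "empty corpus")
})

test_that("encode/decode round-trips losslessly and bounds token count", {
  corpus <- vapply(generate_reactions(60, seed = 23), serialize_reaction, "",
                   "plain2")
  vocab <- bpe_train(corpus, vocab_size = 200L)
  for (s in corpus[1:20]) {
    ids <- bpe_encode(s, vocab)
    expect_identical(ids[1], vocab$special[["bos"]])
    expect_identical(ids[length(ids)], vocab$special[["eos"]])
    expect_identical(bpe_decode(ids, vocab), s)
    expect_lte(length(ids), nchar(s) + 2L)
  }
  expect_identical(bpe_encode("", vocab),
                   c(vocab$special[["bos"]], vocab$special[["eos"]]))
  expect_error(bpe_encode("CC%CC", vocab), "not in tokenizer alphabet")
})

test_that("corpus encoding equals per-string encoding", {
  corpus <- vapply(generate_reactions(30, seed = 29), serialize_reaction, "",
                   "plain2")
  vocab <- bpe_train(corpus, vocab_size = 150L)
  batch <- bpe_encode_corpus(corpus, vocab)
  single <- lapply(corpus, bpe_encode, vocab = vocab)
  expect_identical(batch, single)
})

test_that("training is deterministic and merges may span the molecule separator", {
  corpus <- vapply(generate_reactions(40, seed = 31), serialize_reaction, "",
                   "plain2")
  v1 <- bpe_train(corpus, vocab_size = 200L)
  v2 <- bpe_train(corpus, vocab_size = 200L)
  expect_identical(v1, v2)
  # nothing in the learner forbids tokens containing '.': on this corpus the
  # separator-adjacent pairs are frequent enough to merge
  expect_true(any(grepl(".", merged_tokens(v1), fixed = TRUE)))
})

test_that("vocabulary save/load round-trips through JSON", {
  corpus <- c("CC(=O)O.CCO>>CCOC(C)=O.O", "CC(=O)O.CO>>COC(C)=O.O")
  vocab <- bpe_train(corpus, vocab_size = 64L)
  path <- withr::local_tempfile(fileext = ".json")
  bpe_save(vocab, path)
  back <- bpe_load(path)
  expect_identical(back$tokens, vocab$tokens)
  expect_identical(back$special, vocab$special)
  expect_identical(back$merges, vocab$merges)
  expect_identical(bpe_encode("CC(=O)O.CO>>COC(C)=O.O", back),
                   bpe_encode("CC(=O)O.CO>>COC(C)=O.O", vocab))
})
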