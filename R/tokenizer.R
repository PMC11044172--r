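#' Byte-pair-encoding tokenizer for reaction SMILES
#'
#' @description
#' Subword tokenization for reaction SMILES strings. Starting from the
#' corpus character alphabet, training iteratively merges the most frequent
#' adjacent token pair into a new token until the vocabulary budget is
#' reached; frequency ties are broken lexicographically. Merges are free to
#' span the `'.'` molecule separator, so tokens such as `".["` can arise -
#' the tokenizer sees a reaction string as one sequence, which lets a model
#' learn cross-molecule context. Four special tokens - `<bos>`, `<eos>`,
#' `<mask>`, `<pad>` - occupy the first four reserved ids.
#'
#' `bpe_encode()` applies the learned merges greedily in training order and
#' wraps the sequence in `<bos>`/`<eos>`; `bpe_decode()` inverts it exactly
#' (round trips are lossless for any in-alphabet string).
#'
#' @param corpus character vector of reaction SMILES.
#' @param vocab_size total vocabulary budget including base characters and
#'   the four special tokens (toy default 256; production-scale vocabularies
#'   are a configuration value).
#' @return `bpe_train()`: an object of class `bpe_vocab` with `tokens`
#'   (token strings indexed by id), `special` (named ids of the four special
#'   tokens) and `merges` (ordered integer pairs of merged token ids).
#' @name smiles_tokenizer
NULL

.SPECIAL_TOKENS <- c(bos = "<bos>", eos = "<eos>", mask = "<mask>", pad = "<pad>")

# Flatten a list of integer token sequences into one vector with 0 separators.
.flatten_ids <- function(seqs) {
  if (!length(seqs)) return(integer(0))
  n <- lengths(seqs)
  out <- integer(sum(n) + length(seqs))
  pos <- 1L
  for (i in seq_along(seqs)) {
    if (n[i] > 0L) out[pos:(pos + n[i] - 1L)] <- seqs[[i]]
    pos <- pos + n[i] + 1L  # leaves a 0 separator
  }
  out
}

# Inverse of .flatten_ids: every sequence ends with one 0 separator.
.unflatten_ids <- function(v) {
  sep <- which(v == 0L)
  starts <- c(1L, utils::head(sep, -1L) + 1L)
  out <- vector("list", length(sep))
  for (i in seq_along(sep)) out[[i]] <- v[seq2(starts[i], sep[i] - 1L)]
  out
}

seq2 <- function(from, to) if (from > to) integer(0) else from:to

# Merge all non-overlapping (left-to-right) occurrences of pair (a, b) in a
# flat id vector (0 = sequence separator); occurrences become new_id.
.apply_merge_flat <- function(v, a, b, new_id) {
  n <- length(v)
  if (n < 2L) return(v)
  hit <- which(v[-n] == a & v[-1L] == b)
  if (!length(hit)) return(v)
  if (a == b) {  # overlapping runs: keep leftmost of each run
    keep <- logical(length(hit))
    last <- -2L
    for (k in seq_along(hit)) {
      if (hit[k] != last + 1L) { keep[k] <- TRUE; last <- hit[k] }
    }
    hit <- hit[keep]
  }
  v[hit] <- new_id
  v[-(hit + 1L)]
}

#' @rdname smiles_tokenizer
#' @export
bpe_train <- function(corpus, vocab_size = 256L) {
  corpus <- as.character(corpus)
  if (!length(corpus) || all(!nzchar(corpus))) stop("empty corpus")
  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))),
                method = "radix")
  n_special <- length(.SPECIAL_TOKENS)
  if (vocab_size < length(chars) + n_special)
    stop("vocab_size ", vocab_size, " is below base alphabet (",
         length(chars), ") + ", n_special, " special tokens")
  tokens <- c(unname(.SPECIAL_TOKENS), chars)
  special <- stats::setNames(seq_len(n_special), names(.SPECIAL_TOKENS))
  char_id <- stats::setNames(seq_along(chars) + n_special, chars)

  seqs <- lapply(strsplit(corpus, "", fixed = TRUE),
                 function(cs) unname(char_id[cs]))
  v <- .flatten_ids(seqs)
  merges <- list()
  while (length(tokens) < vocab_size) {
    n <- length(v)
    if (n < 2L) break
    a <- v[-n]; b <- v[-1L]
    ok <- a != 0L & b != 0L
    if (!any(ok)) break
    key <- (a[ok] - 1L) * length(tokens) + b[ok]
    tab <- tabulate(key)
    top <- max(tab)
    if (top < 2L) break  # merging a singleton pair cannot compress anything
    cand_keys <- which(tab == top)
    ca <- (cand_keys - 1L) %/% length(tokens) + 1L
    cb <- (cand_keys - 1L) %% length(tokens) + 1L
    ord <- order(tokens[ca], tokens[cb], method = "radix")  # lexicographic tie-break
    best_a <- ca[ord[1]]; best_b <- cb[ord[1]]
    new_id <- length(tokens) + 1L
    tokens <- c(tokens, paste0(tokens[best_a], tokens[best_b]))
    merges[[length(merges) + 1L]] <- c(best_a, best_b)
    v <- .apply_merge_flat(v, best_a, best_b, new_id)
  }
  structure(list(tokens = tokens, special = special, merges = merges),
            class = "bpe_vocab")
}

#' @export
print.bpe_vocab <- function(x, ...) {
  cat("<bpe_vocab> ", length(x$tokens), " tokens (",
      length(x$special), " special, ", length(x$merges), " merges)\n", sep = "")
  invisible(x)
}

.base_char_ids <- function(vocab) {
  n_base <- length(vocab$tokens) - length(vocab$merges)
  ids <- seq(length(vocab$special) + 1L, n_base)
  stats::setNames(ids, vocab$tokens[ids])
}

# Character ids for a string; errors on characters outside the alphabet.
.chars_to_ids <- function(s, vocab) {
  if (!nzchar(s)) return(integer(0))
  char_id <- .base_char_ids(vocab)
  cs <- strsplit(s, "", fixed = TRUE)[[1]]
  unknown <- setdiff(cs, names(char_id))
  if (length(unknown))
    stop("character not in tokenizer alphabet: '", unknown[1], "'")
  unname(char_id[cs])
}

# Encode without specials: greedy merge application in training order.
.bpe_encode_raw <- function(s, vocab) {
  v <- .chars_to_ids(s, vocab)
  n_base <- length(vocab$tokens) - length(vocab$merges)
  for (k in seq_along(vocab$merges)) {
    m <- vocab$merges[[k]]
    v <- .apply_merge_flat(v, m[1], m[2], n_base + k)
  }
  v
}

#' @rdname smiles_tokenizer
#' @param smiles a reaction SMILES string to encode.
#' @param vocab a trained `bpe_vocab`.
#' @param add_special wrap the encoding in `<bos>`/`<eos>` (default).
#' @export
bpe_encode <- function(smiles, vocab, add_special = TRUE) {
  stopifnot(inherits(vocab, "bpe_vocab"), is.character(smiles), length(smiles) == 1L)
  v <- .bpe_encode_raw(smiles, vocab)
  if (add_special) c(vocab$special[["bos"]], v, vocab$special[["eos"]]) else v
}

#' @rdname smiles_tokenizer
#' @details `bpe_encode_corpus()` encodes many strings in one pass over a
#'   flattened id vector, which is considerably faster than encoding strings
#'   one at a time; the result is identical.
#' @export
bpe_encode_corpus <- function(corpus, vocab, add_special = TRUE) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  if (!length(corpus)) return(list())
  seqs <- lapply(corpus, .chars_to_ids, vocab = vocab)
  v <- .flatten_ids(seqs)
  n_base <- length(vocab$tokens) - length(vocab$merges)
  for (k in seq_along(vocab$merges)) {
    m <- vocab$merges[[k]]
    v <- .apply_merge_flat(v, m[1], m[2], n_base + k)
  }
  out <- .unflatten_ids(v)
  if (add_special)
    out <- lapply(out, function(x)
      c(vocab$special[["bos"]], x, vocab$special[["eos"]]))
  out
}

#' @rdname smiles_tokenizer
#' @param ids integer token ids.
#' @export
bpe_decode <- function(ids, vocab) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  if (any(ids < 1L | ids > length(vocab$tokens)))
    stop("token id out of vocabulary range")
  ids <- ids[!(ids %in% vocab$special)]
  paste(vocab$tokens[ids], collapse = "")
}

#' Save or load a tokenizer vocabulary as JSON
#'
#' @param vocab a `bpe_vocab`.
#' @param path JSON file path.
#' @return `bpe_load()` returns the `bpe_vocab`; `bpe_save()` its path,
#'   invisibly.
#' @export
bpe_save <- function(vocab, path) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  jsonlite::write_json(
    list(tokens = vocab$tokens, special = as.list(vocab$special),
         merges = lapply(vocab$merges, as.integer)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname bpe_save
#' @export
bpe_load <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(tokens = raw$tokens,
                 special = stats::setNames(as.integer(unlist(raw$special)),
                                           names(raw$special)),
                 merges = lapply(seq_len(NROW(raw$merges)), function(i)
                   as.integer(raw$merges[i, ]))),
            class = "bpe_vocab")
}
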