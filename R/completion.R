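#' Insert the missing-molecule placeholder
#'
#' Appends exactly one `"@@@"` placeholder - the single-missing-molecule
#' marker - to the side of the reaction the balancer classified as
#' insufficient, separated by the `'.'` molecule symbol.
#'
#' @param rec a [reaction_record()].
#' @param side `"LHS"` (a reactant is missing) or `"RHS"` (a product is).
#' @return the annotated reaction SMILES string (two-field dialect).
#' @examples
#' \donttest{
#' p <- parse_reaction("Nc1ccc(O)cc1.CC(=O)OC(C)=O>>CC(=O)Nc1ccc(O)cc1", "plain2")
#' insert_placeholder(p, "RHS")
#' }
#' @export
insert_placeholder <- function(rec, side) {
  if (!side %in% c("LHS", "RHS")) stop("side must be 'LHS' or 'RHS'")
  s <- serialize_reaction(rec, "plain2")
  if (grepl("@@@", s, fixed = TRUE))
    stop("record '", rec$id, "' already carries a placeholder ",
         "(one missing molecule per reaction)")
  if (side == "RHS") paste0(s, ".@@@")
  else sub(">>", ".@@@>>", s, fixed = TRUE)
}

# The separator '.' and the reactant-product arrow are reaction syntax, not
# molecule content. Byte-pair merges may pull a separator into the same token
# as the molecule next to it, so a decoded span can carry leading or trailing
# syntax characters; stripping them (and empty fragments) recovers the
# molecule(s) the span denotes.
.normalize_candidate <- function(s) {
  s <- gsub("^[.>]+|[.>]+$", "", s)
  frags <- strsplit(s, ".", fixed = TRUE)[[1]]
  paste(frags[nzchar(frags)], collapse = ".")
}

# Token-id sequence for an annotated reaction with the placeholder replaced
# by n_mask mask tokens. The pieces around "@@@" are encoded independently;
# the separator adjoining the placeholder is dropped so that the masked span
# covers it, matching the training-time tokenization where separators merge
# into the tokens of the molecule they precede.
.splice_masks <- function(annotated, vocab, n_mask) {
  pieces <- strsplit(annotated, "@@@", fixed = TRUE)[[1]]
  if (length(pieces) == 1L && !endsWith(annotated, "@@@"))
    stop("annotated reaction carries no '@@@' placeholder")
  left_str <- sub("\\.$", "", pieces[1])
  right_str <- if (length(pieces) > 1L) sub("^\\.", "", pieces[2]) else ""
  left <- .bpe_encode_raw(left_str, vocab)
  right <- if (nzchar(right_str)) .bpe_encode_raw(right_str, vocab) else integer(0)
  mask_id <- vocab$special[["mask"]]
  ids <- c(vocab$special[["bos"]], left, rep(mask_id, n_mask), right,
           vocab$special[["eos"]])
  list(ids = ids, mask_pos = length(left) + 1L + seq_len(n_mask))
}

# Predict the masked span: single forward pass, greedy argmax at every
# masked position simultaneously.
.predict_span <- function(model, vocab, annotated, n_mask) {
  sp <- .splice_masks(annotated, vocab, n_mask)
  logits <- mlm_forward(model, sp$ids)
  pred <- decode_tokens(logits[sp$mask_pos, , drop = FALSE])
  bpe_decode(pred, vocab)
}

#' Enumerate mask-length completions for a missing molecule
#'
#' The token length of a missing molecule is unknown, so every length from 1
#' to `max_len_enum` is enumerated: the placeholder is replaced by that many
#' mask tokens, the model predicts all of them in one pass, and the decoded
#' string becomes a candidate molecule (possibly several molecules when the
#' decode contains `'.'`). Candidates are tested for SMILES validity;
#' duplicates keep the smallest token length. At production scale the
#' enumeration bound is the longest molecule token length in the training
#' corpus; the desk default is 30.
#'
#' @param annotated output of [insert_placeholder()].
#' @param model a trained `mlm_model` (or `mlm_fit`).
#' @param vocab the tokenizer vocabulary (taken from an `mlm_fit` when
#'   omitted).
#' @param max_len_enum largest mask count to enumerate.
#' @return data.frame with columns `smiles`, `token_length`, `syntax_valid`.
#' @export
enumerate_predictions <- function(annotated, model, vocab = NULL,
                                  max_len_enum = 30L) {
  if (inherits(model, "mlm_fit")) {
    vocab <- vocab %||% model$vocab
    model <- model$model
  }
  stopifnot(inherits(model, "mlm_model"), inherits(vocab, "bpe_vocab"),
            max_len_enum >= 1L)
  if (length(vocab$tokens) != model$config$vocab_size)
    stop("vocabulary size does not match the model configuration")
  out <- data.frame(smiles = character(0), token_length = integer(0),
                    syntax_valid = logical(0))
  seen <- character(0)
  for (L in seq_len(max_len_enum)) {
    cand <- .normalize_candidate(.predict_span(model, vocab, annotated, L))
    if (!nzchar(cand) || cand %in% seen) next
    seen <- c(seen, cand)
    frags <- strsplit(cand, ".", fixed = TRUE)[[1]]
    valid <- all(smiles_valid(frags))
    out <- rbind(out, data.frame(smiles = cand, token_length = L,
                                 syntax_valid = valid))
  }
  out
}

#' Verify proposed molecules with the balancer and rank the solutions
#'
#' Every syntactically valid candidate is inserted into the reaction on the
#' insufficient side and the updated reaction is passed to
#' [classify_and_balance()]. Candidates whose updated reaction is complete
#' as-is (originally or by stoichiometry alone) rank as `COMPLETED_MLM`;
#' candidates that need further balancer additions rank as
#' `COMPLETED_MLM_PLUS_BALANCER`, below them (fewer added species is the
#' more parsimonious completion). Within a tier the scorer confidence
#' decides, then smaller token length, then lexicographic SMILES.
#'
#' @param rec the incomplete [reaction_record()].
#' @param side `"LHS"` or `"RHS"`, from the balancer classification.
#' @param candidates data.frame from [enumerate_predictions()].
#' @param library,scorer,max_coeff,max_loops balancer configuration.
#' @return a `completion_result` list: `original`, `side`, `status`
#'   (`COMPLETED_MLM`, `COMPLETED_MLM_PLUS_BALANCER` or `INCOMPLETE`),
#'   `chosen` (list with `smiles`, `token_length`, `confidence`,
#'   `balance_outcome`) and `all_candidates`.
#' @export
verify_and_rank <- function(rec, side, candidates,
                            library = default_help_species(),
                            scorer = fallback_score, max_coeff = 6L,
                            max_loops = 3L) {
  stopifnot(side %in% c("LHS", "RHS"))
  solutions <- list()
  if (NROW(candidates)) {
    for (i in seq_len(nrow(candidates))) {
      if (!candidates$syntax_valid[i]) next
      frags <- strsplit(candidates$smiles[i], ".", fixed = TRUE)[[1]]
      rec2 <- if (side == "RHS") .with_additions(rec, rhs_add = frags)
              else .with_additions(rec, lhs_add = frags)
      outcome <- classify_and_balance(rec2, library = library, scorer = scorer,
                                      max_coeff = max_coeff,
                                      max_loops = max_loops)
      if (!startsWith(outcome$status, "COMPLETE")) next
      tier <- if (outcome$status %in% c("COMPLETE_ORIGINAL", "COMPLETE_STOICH"))
        "COMPLETED_MLM" else "COMPLETED_MLM_PLUS_BALANCER"
      solutions[[length(solutions) + 1L]] <- list(
        smiles = candidates$smiles[i],
        token_length = candidates$token_length[i],
        confidence = scorer(outcome$completed),
        balance_outcome = outcome, tier = tier)
    }
  }
  if (!length(solutions))
    return(structure(list(original = rec, side = side, status = "INCOMPLETE",
                          chosen = NULL, all_candidates = candidates),
                     class = "completion_result"))
  key <- vapply(solutions, function(s) {
    tier_rank <- if (s$tier == "COMPLETED_MLM") 0 else 1
    sprintf("%d|%012.9f|%06d|%s", tier_rank, 1 - s$confidence,
            s$token_length, s$smiles)
  }, character(1))
  chosen <- solutions[[order(key, method = "radix")[1]]]
  structure(list(original = rec, side = side, status = chosen$tier,
                 chosen = chosen, all_candidates = candidates),
            class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat("<completion_result> ", x$status, " (side ", x$side, ")\n", sep = "")
  if (!is.null(x$chosen))
    cat("  chosen: ", x$chosen$smiles, " (", x$chosen$token_length,
        " token(s))\n", sep = "")
  invisible(x)
}

#' Complete one incomplete reaction end to end
#'
#' The full per-record workflow: the balancer classifies the record; if it
#' completes it, that outcome is returned. Otherwise the placeholder goes on
#' the insufficient side, the model enumerates missing-molecule proposals,
#' and every proposal is re-verified by the balancer.
#'
#' @param rec a [reaction_record()].
#' @param fit an `mlm_fit` (trained model plus vocabulary).
#' @param max_len_enum enumeration bound for [enumerate_predictions()].
#' @inheritParams verify_and_rank
#' @return a `completion_result`; when the balancer already completed the
#'   record, `status` is the balancer status and `chosen` is `NULL` with the
#'   outcome in `balance_outcome`.
#' @export
complete_reaction <- function(rec, fit, max_len_enum = 30L,
                              library = default_help_species(),
                              scorer = fallback_score, max_coeff = 6L,
                              max_loops = 3L) {
  outcome <- classify_and_balance(rec, library = library, scorer = scorer,
                                  max_coeff = max_coeff, max_loops = max_loops)
  if (startsWith(outcome$status, "COMPLETE"))
    return(structure(list(original = rec, side = NA_character_,
                          status = outcome$status, chosen = NULL,
                          balance_outcome = outcome, all_candidates = NULL),
                     class = "completion_result"))
  side <- if (outcome$status == "LHS_INSUFFICIENT") "LHS" else "RHS"
  annotated <- insert_placeholder(rec, side)
  cands <- enumerate_predictions(annotated, fit, max_len_enum = max_len_enum)
  verify_and_rank(rec, side, cands, library = library, scorer = scorer,
                  max_coeff = max_coeff, max_loops = max_loops)
}

#' Hidden-molecule evaluation of a trained model
#'
#' The test protocol for whole-molecule inference: in every complete test
#' reaction, each molecule on the evaluated side is hidden once in turn
#' (a reaction `A.B.C>>D.E` yields three LHS items and two RHS items). The
#' hidden molecule's token count is given to the model: the tokens of the
#' full-reaction encoding that cover the molecule's characters - including
#' any adjoining separator a byte-pair merge pulled in - are replaced by
#' that many mask tokens, the model predicts them in one pass, and the
#' decoded span (syntax characters stripped) must match the ground-truth
#' SMILES exactly. Results are stratified by token length: short (= 1),
#' middle (2-10) and long (> 10).
#'
#' @param records list of balanced [reaction_record()]s.
#' @param fit an `mlm_fit`.
#' @param side `"RHS"` (hide products) or `"LHS"` (hide reactants).
#' @return list with `items` (one row per hidden molecule: id, truth,
#'   prediction, token_length, stratum, correct) and `rates` (per-stratum
#'   and overall exact-match rates with counts).
#' @export
hidden_molecule_eval <- function(records, fit, side = c("RHS", "LHS")) {
  side <- match.arg(side)
  stopifnot(inherits(fit, "mlm_fit"))
  vocab <- fit$vocab
  mask_id <- vocab$special[["mask"]]
  items <- list()
  for (rec in records) {
    s <- serialize_reaction(rec, "plain2")
    ids_raw <- .bpe_encode_raw(s, vocab)
    tok_chr <- vocab$tokens[ids_raw]
    tok_end <- cumsum(nchar(tok_chr))
    tok_start <- tok_end - nchar(tok_chr) + 1L
    lhs_str <- paste(rec$reactants, collapse = ".")
    mols <- if (side == "RHS") rec$products else rec$reactants
    for (i in seq_along(mols)) {
      truth <- mols[[i]]
      # character interval of molecule i on the evaluated side
      before <- if (i > 1L) sum(nchar(mols[seq_len(i - 1L)])) + (i - 1L) else 0L
      offset <- if (side == "RHS") nchar(lhs_str) + 2L else 0L
      a <- offset + before + 1L
      b <- a + nchar(truth) - 1L
      span <- which(tok_end >= a & tok_start <= b)
      input <- c(vocab$special[["bos"]], ids_raw, vocab$special[["eos"]])
      mask_pos <- span + 1L
      input[mask_pos] <- mask_id
      logits <- mlm_forward(fit$model, input)
      pred_ids <- decode_tokens(logits[mask_pos, , drop = FALSE])
      pred_span <- bpe_decode(pred_ids, vocab)
      # the span may cover characters of neighboring molecules that a merge
      # pulled in; the prediction must reproduce them, and the hidden
      # molecule is read off by position
      pre_len <- a - tok_start[span[1]]
      post_len <- tok_end[span[length(span)]] - b
      pred <- if (nchar(pred_span) > pre_len + post_len)
        .normalize_candidate(substr(pred_span, pre_len + 1L,
                                    nchar(pred_span) - post_len))
      else .normalize_candidate(pred_span)
      n_tok <- length(span)
      items[[length(items) + 1L]] <- data.frame(
        id = rec$id, truth = truth, prediction = pred,
        token_length = n_tok,
        stratum = if (n_tok == 1L) "short" else if (n_tok <= 10L) "middle"
                  else "long",
        correct = identical(pred, truth))
    }
  }
  items <- do.call(rbind, items)
  strata <- c("short", "middle", "long")
  rates <- data.frame(
    stratum = c(strata, "overall"),
    n = c(vapply(strata, function(s) sum(items$stratum == s), integer(1)),
          nrow(items)),
    correct_rate = c(
      vapply(strata, function(s) {
        sel <- items$stratum == s
        if (any(sel)) mean(items$correct[sel]) else NA_real_
      }, numeric(1)),
      mean(items$correct)))
  list(items = items, rates = rates)
}
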