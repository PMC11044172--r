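# Shared toy model fixture: a small encoder memorizes a degenerate corpus of
# 40 template reactions, giving near-exact masked-span predictions so the
# completion machinery can be exercised quickly. Built lazily, once per run.
.fit_cache <- new.env(parent = emptyenv())

toy_fit <- function() {
  if (!is.null(.fit_cache$fit)) return(.fit_cache$fit)
  base_recs <- generate_reactions(40, seed = 77)
  base <- vapply(base_recs, serialize_reaction, "", "plain2")
  vocab <- bpe_train(base, vocab_size = 80L)
  cfg <- mlm_config("desk", vocab_size = length(vocab$tokens),
                    hidden_size = 32L, num_layers = 1L, num_heads = 2L,
                    max_len = 80L, dropout = 0, attention_dropout = 0,
                    seed = 5L)
  fit <- mlm_train(rep(base, 15), vocab, config = cfg, epochs = 60L,
                   seed = 19L, quiet = TRUE)
  .fit_cache$fit <- fit
  .fit_cache$records <- base_recs
  fit
}

toy_records <- function() {
  toy_fit()
  .fit_cache$records
}
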