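# Shared desk-scale fixtures: a small synthetic corpus, activity set and
# lightly trained models reused across test files. Everything is seeded.

fx_spec <- fixture_spec(seed = 42L)  # study-shaped defaults: 2000 / 198
fx_corpus <- make_pretrain_corpus(fx_spec)
fx_act <- make_activity_set(fx_spec)
fx_vocab <- build_vocabulary(c(fx_corpus$canonical_smiles, fx_act$canonical_smiles))
fx_tokens <- tokenize_smiles(fx_corpus$canonical_smiles, fx_vocab)

fx_clm <- clm_pretrain(fx_tokens, fx_vocab, units = c(32L, 8L), epochs = 5L,
                       batch_size = 64L, seed = 7L)
fx_eclm <- electra_pretrain(fx_tokens, fx_vocab, units = c(32L, 8L),
                            rate = 0.15, epochs = 10L, batch_size = 64L, seed = 9L)

# rank-based AUC for separating two score groups
rank_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
}

# constant-output ordinal classifier: head weights zeroed, bias set so every
# molecule receives the given sigmoid outputs (fixture for vote machinery)
constant_classifier <- function(outputs, vocab = fx_vocab) {
  m <- nn_init(vocab, units = c(8L, 4L), head = "ordinal", seed = 1L)
  m$params$head$W[] <- 0
  m$params$head$b <- stats::qlogis(outputs)
  m$threshold <- 0.4
  m
}
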