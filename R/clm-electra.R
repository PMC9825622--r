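# ELECTRA-style pretraining: corrupt token sequences by random substitution
# and train a discriminator to flag the substituted positions.

#' Corrupt a tokenized SMILES string
#'
#' Each non-special position is independently substituted with probability
#' `rate`; a substitution draws uniformly from the chemical tokens excluding
#' the original token, so every substituted position genuinely differs from
#' the original. Labels mark exactly the substituted positions. Start, stop
#' and pad tokens are never touched.
#'
#' @param tokens Integer token vector (with start/stop), or a list of them.
#' @param rate Per-position substitution probability in `[0, 1]`.
#' @param vocab The `declm_vocab`.
#' @param seed Seed for the corruption draw.
#' @return A list with `corrupted` and binary `labels` aligned to positions
#'   (lists of vectors when the input is a list).
#' @export
corrupt_tokens <- function(tokens, rate, vocab, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  chem <- chemical_indices(vocab)
  if (length(chem) < 2L) {
    declm_abort("Vocabulary has no alternative chemical token to substitute.",
                "declm_singleton_vocabulary")
  }
  single <- is.numeric(tokens)
  if (single) tokens <- list(as.integer(tokens))
  res <- withr::with_seed(seed, lapply(tokens, function(ts) {
    labels <- integer(length(ts))
    editable <- which(ts > 3L)
    hit <- editable[runif(length(editable)) < rate]
    corrupted <- ts
    for (i in hit) {
      alt <- chem[chem != ts[i]]
      corrupted[i] <- if (length(alt) == 1L) alt else alt[sample.int(length(alt), 1L)]
    }
    labels[hit] <- 1L
    list(corrupted = corrupted, labels = labels)
  }))
  if (single) res[[1]] else {
    list(corrupted = lapply(res, `[[`, "corrupted"),
         labels = lapply(res, `[[`, "labels"))
  }
}

#' Pretrain an ELECTRA discriminator on SMILES
#'
#' Trains the recurrent backbone with a per-position sigmoid head to
#' distinguish original from substituted tokens (binary cross-entropy, Adam,
#' default learning rate 1e-3, 50 epochs at production scale). A fresh
#' corruption is drawn every epoch from a per-epoch derived seed.
#'
#' @param tokens Tokenized corpus.
#' @param vocab The vocabulary.
#' @param units Recurrent block sizes.
#' @param rate Corruption rate (default 0.15 per position).
#' @param epochs,lr,batch_size,seed Training controls.
#' @return A trained `declm_binary_model` (the E-CLM).
#' @export
electra_pretrain <- function(tokens, vocab, units = c(1024L, 256L), rate = 0.15,
                             epochs = 50L, lr = 1e-3, batch_size = 64L, seed = 1L) {
  stopifnot(length(tokens) > 0L)
  if (rate <= 0) {
    declm_abort("Corruption rate 0 yields degenerate all-negative labels.",
                "declm_invalid_training_data")
  }
  model <- nn_init(vocab, units = units, head = "binary", seed = seed)
  pad <- vocab$pad
  task_fn <- function(idx, epoch) {
    cr <- corrupt_tokens(tokens[idx], rate, vocab, seed = derive_seed(seed, 31L * epoch))
    X <- pad_batch(cr$corrupted, pad)
    L <- pad_batch(lapply(cr$labels, as.integer), 0L)
    list(X = X, task = list(labels = L))
  }
  nn_train_loop(model, length(tokens), task_fn, epochs = epochs, lr = lr,
                batch_size = batch_size, seed = seed)
}

#' Per-position corruption scores
#'
#' @param model A trained `declm_binary_model`.
#' @param tokens List of token vectors to score.
#' @return List of numeric vectors in `[0, 1]`, one score per position.
#' @export
electra_scores <- function(model, tokens) {
  stopifnot(inherits(model, "declm_binary_model"))
  X <- pad_batch(tokens, model$vocab$pad)
  fwd <- nn_forward(model, X, task = list(labels = matrix(0, nrow(X), ncol(X))),
                    training = FALSE)
  B <- nrow(X)
  lapply(seq_len(B), function(b) {
    len <- length(tokens[[b]])
    fwd$probs[(seq_len(len) - 1L) * B + b]
  })
}
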