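# Generative chemical language model: architecture accounting, pretraining,
# transfer learning with layer freezing, sampling policies and generation
# quality metrics.

#' Generative CLM architecture description
#'
#' The network is: input feature normalization -> LSTM block of `units[1]`
#' memory cells -> LSTM block of `units[2]` cells -> feature normalization ->
#' per-step dense projection to the vocabulary with softmax. The published
#' architecture uses 1024/256 cells and a 71-symbol vocabulary.
#'
#' @param vocab_size One-hot input width V (number of vocabulary symbols).
#' @param units Sizes of the two recurrent blocks.
#' @param lr_pretrain,lr_transfer Adam learning rates for pretraining and
#'   transfer learning.
#' @param epochs Default pretraining epochs.
#' @return A `declm_arch` list.
#' @export
clm_architecture <- function(vocab_size, units = c(1024L, 256L),
                             lr_pretrain = 1e-3, lr_transfer = 1e-4,
                             epochs = 40L) {
  stopifnot(is_count(vocab_size), vocab_size >= 1)
  structure(list(vocab_size = as.integer(vocab_size),
                 units = as.integer(units),
                 lr_pretrain = lr_pretrain, lr_transfer = lr_transfer,
                 epochs = as.integer(epochs)),
            class = "declm_arch")
}

#' Closed-form parameter count of the generative architecture
#'
#' Counts trainable weights plus normalization moving statistics:
#' `4V + 4*h1*(V+h1+1) + 4*h2*(h1+h2+1) + 4*h2 + (h2+1)*V`.
#' At V = 71 with 1024/256 cells this equals 5,820,515, and it must agree
#' with [model_parameter_count()] of the instantiated network.
#'
#' @param spec A `declm_arch` from [clm_architecture()], or an integer
#'   vocabulary size.
#' @param units Recurrent block sizes (used when `spec` is an integer).
#' @return The total parameter count (double to avoid integer overflow).
#' @export
count_parameters <- function(spec, units = c(1024L, 256L)) {
  if (inherits(spec, "declm_arch")) {
    V <- spec$vocab_size; units <- spec$units
  } else {
    stopifnot(is_count(spec)); V <- spec
  }
  h1 <- as.double(units[1]); h2 <- as.double(units[2]); V <- as.double(V)
  4 * V + 4 * h1 * (V + h1 + 1) + 4 * h2 * (h1 + h2 + 1) + 4 * h2 + (h2 + 1) * V
}

#' Instantiate an untrained generative CLM
#'
#' @param vocab A `declm_vocab`.
#' @param units Recurrent block sizes.
#' @param seed Seed for weight initialization.
#' @return A `declm_softmax_model`.
#' @export
clm_build <- function(vocab, units = c(1024L, 256L), seed = 1L) {
  nn_init(vocab, units = units, head = "softmax", seed = seed)
}

softmax_task_fn <- function(tokens, pad) {
  function(idx, epoch) list(X = pad_batch(tokens[idx], pad), task = list())
}

#' Pretrain the generative CLM
#'
#' Autoregressive next-token training with categorical cross-entropy and the
#' Adam optimizer (default learning rate 1e-3).
#'
#' @param tokens List of tokenized sequences ([tokenize_smiles()]).
#' @param vocab The `declm_vocab` used to tokenize.
#' @param units Recurrent block sizes.
#' @param epochs Training epochs (the production default is 40).
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling initialization and shuffling.
#' @param model Optionally continue training an existing model.
#' @return A trained `declm_softmax_model` with a `history` of per-epoch loss.
#' @export
clm_pretrain <- function(tokens, vocab, units = c(1024L, 256L), epochs = 40L,
                         lr = 1e-3, batch_size = 64L, seed = 1L, model = NULL) {
  stopifnot(length(tokens) > 0L)
  V <- vocab_size(vocab)
  if (any(unlist(tokens) > V)) {
    declm_abort("Token index exceeds the vocabulary width.", "declm_shape_mismatch")
  }
  if (is.null(model)) model <- clm_build(vocab, units, seed = seed)
  if (vocab_size(model$vocab) != V) {
    declm_abort("Model and corpus vocabulary sizes differ.", "declm_shape_mismatch")
  }
  nn_train_loop(model, length(tokens), softmax_task_fn(tokens, vocab$pad),
                epochs = epochs, lr = lr, batch_size = batch_size, seed = seed)
}

#' Transfer-learn (fine-tune) a pretrained CLM
#'
#' Continues training on a small target-focused corpus at a reduced learning
#' rate, keeping the first recurrent block frozen by default (its parameters
#' stay bit-identical). Normalization layers run in inference mode during
#' fine-tuning. Optionally samples molecules on a fixed cadence so the
#' novelty trajectory across epochs can be monitored.
#'
#' @param model A pretrained `declm_softmax_model`.
#' @param tokens Tokenized fine-tuning corpus (same vocabulary).
#' @param epochs Number of transfer epochs.
#' @param lr Learning rate (default 1e-4).
#' @param freeze Character vector of frozen blocks among
#'   `"bn0", "lstm1", "lstm2", "bn1", "head"`.
#' @param batch_size Minibatch size.
#' @param seed Seed.
#' @param sample_every,sample_n If `sample_every > 0`, sample `sample_n`
#'   strings with `sample_policy` after every `sample_every` epochs.
#' @param sample_policy A [sampling_policy()] used for the cadence sampling.
#' @return The fine-tuned model; cadence samples (if any) are in
#'   `model$transfer_samples` (tibble with an `epoch` column).
#' @export
clm_transfer <- function(model, tokens, epochs = 10L, lr = 1e-4,
                         freeze = "lstm1", batch_size = 32L, seed = 1L,
                         sample_every = 0L, sample_n = 0L,
                         sample_policy = sampling_policy("nucleus", p = 0.85)) {
  stopifnot(inherits(model, "declm_softmax_model"))
  if (any(unlist(tokens) > vocab_size(model$vocab))) {
    declm_abort("Fine-tuning corpus uses tokens outside the model vocabulary.",
                "declm_vocab_mismatch")
  }
  if (epochs == 0L) return(model)
  samples <- list()
  hook <- NULL
  if (sample_every > 0L && sample_n > 0L) {
    hook <- function(m, ep) {
      if (ep %% sample_every == 0L) {
        pol <- sample_policy; pol$seed <- derive_seed(seed, 7000L + ep)
        sm <- generate_smiles(m, pol, n = sample_n)
        sm$epoch <- ep
        samples[[length(samples) + 1L]] <<- sm
      }
      m
    }
  }
  model <- nn_train_loop(model, length(tokens), softmax_task_fn(tokens, model$vocab$pad),
                         epochs = epochs, lr = lr, batch_size = batch_size,
                         seed = seed, freeze = freeze, norm_training = FALSE,
                         epoch_hook = hook)
  if (length(samples)) model$transfer_samples <- dplyr::bind_rows(samples)
  model
}

# ---- sampling policies ----------------------------------------------------

#' Sampling policy for SMILES generation
#'
#' Either temperature sampling (softmax with logits divided by `T`) or
#' nucleus (top-p) sampling, which restricts each step to the minimal set of
#' highest-probability tokens whose cumulative probability strictly exceeds
#' `p` and samples within it at temperature 1.
#'
#' @param mode `"temperature"` or `"nucleus"`.
#' @param temperature Positive temperature (temperature mode).
#' @param p Nucleus parameter in `[0, 1)` (nucleus mode).
#' @param max_len Maximum generated length in tokens (excluding start/stop).
#' @param seed Sampling seed.
#' @return A `declm_policy`.
#' @export
sampling_policy <- function(mode = c("nucleus", "temperature"), temperature = 1,
                            p = 0.85, max_len = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "temperature" && (!is.numeric(temperature) || temperature <= 0)) {
    declm_abort("Temperature must be > 0.", "declm_invalid_temperature")
  }
  if (mode == "nucleus" && (p < 0 || p >= 1)) {
    declm_abort("Nucleus parameter must satisfy 0 <= p < 1.", "declm_invalid_nucleus")
  }
  structure(list(mode = mode, temperature = temperature, p = p,
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "declm_policy")
}

#' Temperature-scaled softmax probabilities
#'
#' `q_i = exp(z_i / T) / sum_j exp(z_j / T)`; at `T = 1` this is the plain
#' softmax. Smaller temperatures sharpen the distribution.
#'
#' @param logits Finite numeric vector of unnormalized scores.
#' @param temperature Positive scalar `T`.
#' @return A probability vector summing to 1.
#' @export
temperature_probs <- function(logits, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    declm_abort("Temperature must be a single value > 0.", "declm_invalid_temperature")
  }
  stopifnot(is.numeric(logits), all(is.finite(logits)))
  z <- logits / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Nucleus (top-p) vocabulary
#'
#' Returns the minimal prefix of tokens, in descending probability order,
#' whose cumulative probability strictly exceeds `p`; dropping its least
#' probable member would bring the cumulative mass to `<= p`. Probability
#' ties are broken by ascending token index so the prefix is deterministic.
#'
#' @param probs Probability vector (sums to 1).
#' @param p Nucleus parameter in `[0, 1)`.
#' @return Integer vector of token indices forming the top vocabulary.
#' @export
nucleus_top_vocab <- function(probs, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1) {
    declm_abort("Nucleus parameter must satisfy 0 <= p < 1.", "declm_invalid_nucleus")
  }
  stopifnot(is.numeric(probs), all(probs >= -1e-12))
  ord <- order(probs, seq_along(probs), decreasing = c(TRUE, FALSE), method = "radix")
  cum <- cumsum(probs[ord])
  k <- which(cum > p)[1]
  if (is.na(k)) k <- length(probs)  # numerical guard: mass sums just below p
  ord[seq_len(k)]
}

sample_index <- function(probs) {
  # inverse-CDF draw; deterministic under the caller's RNG state
  sample.int(length(probs), 1L, prob = probs)
}

#' Generate SMILES strings from a trained CLM
#'
#' Strings are extended from the start token until the stop token is sampled
#' or `max_len` is reached (such strings are flagged as truncated). Under
#' nucleus mode each step samples only within that step's top vocabulary at
#' temperature 1; with `trace = TRUE` the per-step top vocabulary and chosen
#' token are recorded for auditing.
#'
#' @param model A trained `declm_softmax_model`.
#' @param policy A [sampling_policy()].
#' @param n Number of strings to sample.
#' @param trace Record a per-step audit trail (attribute `"trace"`).
#' @return A tibble with columns `smiles` and `truncated`.
#' @export
generate_smiles <- function(model, policy = sampling_policy(), n = 100L,
                            trace = FALSE) {
  stopifnot(inherits(model, "declm_softmax_model"), n >= 1)
  vocab <- model$vocab
  V <- vocab_size(vocab)
  withr::with_seed(policy$seed, {
    state <- nn_state_init(model, n)
    cur <- rep(vocab$start, n)
    alive <- rep(TRUE, n)
    seqs <- vector("list", n)
    audit <- if (trace) list() else NULL
    for (step in seq_len(policy$max_len + 1L)) {
      out <- nn_state_step(model, cur, state)
      state <- out$state
      nxt <- cur
      for (b in which(alive)) {
        lz <- out$logits[b, ]
        if (policy$mode == "temperature") {
          pr <- temperature_probs(lz, policy$temperature)
          allowed <- seq_len(V)
        } else {
          pr_full <- temperature_probs(lz, 1)
          allowed <- nucleus_top_vocab(pr_full, policy$p)
          pr <- pr_full[allowed] / sum(pr_full[allowed])
        }
        tok <- if (policy$mode == "temperature") sample_index(pr) else {
          if (length(allowed) == 1L) allowed else allowed[sample_index(pr)]
        }
        if (trace) audit[[length(audit) + 1L]] <-
            list(seq = b, step = step, allowed = allowed, chosen = tok)
        seqs[[b]] <- c(seqs[[b]], tok)
        nxt[b] <- tok
        if (tok == vocab$stop) alive[b] <- FALSE
      }
      cur <- nxt
      if (!any(alive)) break
    }
    truncated <- alive
    smiles <- vapply(seq_len(n), function(b) {
      idx <- seqs[[b]]
      idx <- idx[idx > 3L]  # drop any sampled special tokens
      paste(vocab$tokens[idx], collapse = "")
    }, character(1))
    res <- tibble(smiles = smiles, truncated = truncated)
    if (trace) attr(res, "trace") <- audit
    res
  })
}

#' Evaluate a generated batch: validity, uniqueness, novelty
#'
#' Validity is the fraction of sampled strings the chemistry backend parses;
#' uniqueness the fraction that are distinct canonical molecules among the
#' valid ones; novelty the fraction that are distinct canonical molecules
#' absent from the union of the pretraining and fine-tuning canonical sets.
#' All three percentages use the number of sampled strings as denominator by
#' default (`denominator = "sampled"`), so novelty <= uniqueness <= validity;
#' `denominator = "valid"` rescales uniqueness and novelty to the valid count.
#'
#' @param samples Character vector of sampled SMILES, or the tibble returned
#'   by [generate_smiles()].
#' @param train_ref,fine_ref Character vectors of canonical reference SMILES.
#' @param denominator `"sampled"` (default) or `"valid"`.
#' @return A `declm_generation_report`.
#' @export
evaluate_generation <- function(samples, train_ref = character(0),
                                fine_ref = character(0),
                                denominator = c("sampled", "valid")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(samples)) samples <- samples$smiles
  n <- length(samples)
  can <- canonicalize_smiles(samples)
  valid <- !is.na(can)
  unique_flag <- valid & !duplicated(can) & !is.na(can)
  refs <- unique(c(train_ref, fine_ref))
  novel <- unique_flag & !(can %in% refs)
  denom <- if (denominator == "sampled") n else sum(valid)
  pct <- function(x) if (denom == 0) 0 else 100 * sum(x) / denom
  report <- structure(list(
    n_sampled = n,
    pct_valid = if (n == 0) 0 else 100 * sum(valid) / n,
    pct_unique = pct(unique_flag),
    pct_novel = pct(novel),
    denominator = denominator,
    molecules = tibble(smiles = samples, canonical_smiles = can,
                       valid = valid, unique = unique_flag, novel = novel)
  ), class = "declm_generation_report")
  report
}

#' @export
print.declm_generation_report <- function(x, ...) {
  cat(sprintf("<generation report> n=%d valid=%.1f%% unique=%.1f%% novel=%.1f%% (of %s)\n",
              x$n_sampled, x$pct_valid, x$pct_unique, x$pct_novel, x$denominator))
  invisible(x)
}
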