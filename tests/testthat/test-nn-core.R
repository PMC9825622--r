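# The network core is verified directly: exact backprop via finite
# differences, optimizer determinism, and checkpoint identity.

fd_check <- function(head, n_entries = 4L, tol = 1e-4) {
  vocab <- build_vocabulary(c("CCO", "CCN", "c1ccccc1", "CC(=O)O"))
  toks <- tokenize_smiles(c("CCO", "c1ccccc1", "CC(=O)O"), vocab)
  model <- nn_init(vocab, units = c(6L, 5L), head = head, seed = 3L)
  X <- pad_batch(toks, vocab$pad)
  task <- list()
  withr::with_seed(11, {
    if (head == "binary") task$labels <- matrix(rbinom(length(X), 1, 0.3), nrow(X))
    if (head == "ordinal") {
      task$y <- encode_ordinal(c("inactive", "highly_active", "moderately_active"))
      task$dropout <- 0.5
    }
  })
  set.seed(99); fwd <- nn_forward(model, X, task, training = TRUE)
  grads <- nn_backward(fwd, task)
  eps <- 1e-5
  for (blk in names(grads)) {
    for (leaf in names(grads[[blk]])) {
      g <- grads[[blk]][[leaf]]
      idx <- withr::with_seed(5, sample(length(g), min(n_entries, length(g))))
      for (i in idx) {
        m1 <- model; m1$params[[blk]][[leaf]][i] <- m1$params[[blk]][[leaf]][i] + eps
        m2 <- model; m2$params[[blk]][[leaf]][i] <- m2$params[[blk]][[leaf]][i] - eps
        set.seed(99); l1 <- nn_forward(m1, X, task, training = TRUE)$loss
        set.seed(99); l2 <- nn_forward(m2, X, task, training = TRUE)$loss
        num <- (l1 - l2) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), tol)
      }
    }
  }
}

test_that("backpropagation matches finite differences for every head", {
  fd_check("softmax")
  fd_check("binary")
  fd_check("ordinal")
})

test_that("training is deterministic and checkpoints round-trip", {
  toks <- head(fx_tokens, 40)
  m1 <- clm_pretrain(toks, fx_vocab, units = c(12L, 6L), epochs = 2L,
                     batch_size = 16L, seed = 5L)
  m2 <- clm_pretrain(toks, fx_vocab, units = c(12L, 6L), epochs = 2L,
                     batch_size = 16L, seed = 5L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, path)
  m3 <- load_model(path)
  X <- pad_batch(head(toks, 5), fx_vocab$pad)
  p1 <- nn_forward(m1, X, training = FALSE)$probs
  p3 <- nn_forward(m3, X, training = FALSE)$probs
  expect_identical(p1, p3)
})

test_that("instantiated networks report the closed-form parameter count", {
  for (V in c(4L, 32L, 71L)) {
    vocab <- build_vocabulary("C")  # 4 tokens; padded out to width V below
    if (V > 4L) vocab$tokens <- c(vocab$tokens, paste0("T", seq_len(V - 4L)))
    expect_equal(length(vocab$tokens), V)
    m <- nn_init(vocab, units = c(1024L, 256L), head = "softmax", seed = 1L)
    expect_equal(model_parameter_count(m), count_parameters(V))
  }
})
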