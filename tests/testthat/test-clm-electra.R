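test_that("corruption marks exactly the substituted positions", {
  ts <- fx_tokens[[1]]
  # rate 0: identity, all labels 0
  r0 <- corrupt_tokens(ts, 0, fx_vocab, seed = 1)
  expect_identical(r0$corrupted, ts)
  expect_true(all(r0$labels == 0))
  # rate 1: every chemical position substituted and different
  r1 <- corrupt_tokens(ts, 1, fx_vocab, seed = 1)
  chem <- ts > 3L
  expect_true(all(r1$labels[chem] == 1))
  expect_true(all(r1$corrupted[chem] != ts[chem]))
  expect_identical(r1$corrupted[!chem], ts[!chem])  # specials untouched

  # label/difference consistency and vocabulary closure across seeds
  for (seed in 1:20) {
    r <- corrupt_tokens(ts, 0.3, fx_vocab, seed = seed)
    expect_identical(which(r$corrupted != ts), which(r$labels == 1L))
    expect_true(all(r$corrupted >= 1 & r$corrupted <= length(fx_vocab$tokens)))
    expect_true(all(r$corrupted[!chem] == ts[!chem]))
  }
  # reproducibility: same seed, same draw
  expect_identical(corrupt_tokens(ts, 0.3, fx_vocab, seed = 7),
                   corrupt_tokens(ts, 0.3, fx_vocab, seed = 7))

  # singleton chemistry has no alternative token
  v1 <- build_vocabulary("C")
  expect_error(corrupt_tokens(tokenize_smiles("CC", v1)[[1]], 0.5, v1, seed = 1),
               class = "declm_singleton_vocabulary")
})

test_that("corruption rate concentrates at its nominal value", {
  # 10,000 seeded draws over a length-20 payload: empirical rate in 0.15 +- 0.01
  payload <- rep(4L, 22L); payload[1] <- 2L; payload[22] <- 3L  # start/stop
  many <- corrupt_tokens(rep(list(payload), 10000L), 0.15, fx_vocab, seed = 99)
  rate <- sum(unlist(many$labels)) / (20 * 10000)
  expect_gt(rate, 0.14)
  expect_lt(rate, 0.16)
})

test_that("the discriminator learns to spot corrupted tokens", {
  # held-out molecules, fresh corruptions
  heldout <- tokenize_smiles(fx_act$canonical_smiles[1:60], fx_vocab)
  cr <- corrupt_tokens(heldout, 0.15, fx_vocab, seed = 123)
  scores <- unlist(electra_scores(fx_eclm, cr$corrupted))
  labels <- unlist(cr$labels)
  auc <- rank_auc(scores[labels == 1], scores[labels == 0])
  expect_gt(auc, 0.8)

  # an untrained discriminator sits at chance
  m0 <- nn_init(fx_vocab, units = c(32L, 8L), head = "binary", seed = 77L)
  s0 <- unlist(electra_scores(m0, cr$corrupted))
  auc0 <- rank_auc(s0[labels == 1], s0[labels == 0])
  expect_gt(auc0, 0.45)
  expect_lt(auc0, 0.55)

  # degenerate all-negative training data is rejected
  expect_error(electra_pretrain(fx_tokens, fx_vocab, rate = 0),
               class = "declm_invalid_training_data")
})

test_that("E-CLM backbone weights load into the classifier without reshaping", {
  clf <- classifier_from_backbone(fx_eclm, seed = 1L)
  for (blk in c("bn0", "lstm1", "lstm2", "bn1")) {
    expect_identical(clf$params[[blk]], fx_eclm$params[[blk]])
  }
  expect_equal(dim(clf$params$head$W), c(fx_eclm$units[2], 3L))
})
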