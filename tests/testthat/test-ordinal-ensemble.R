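test_that("activity binning uses <= boundaries into the lower class", {
  expect_equal(as.character(assign_activity_class(4.0)), "inactive")
  expect_equal(as.character(assign_activity_class(6.5)), "moderately_active")
  expect_equal(as.character(assign_activity_class(7.2)), "highly_active")
  expect_equal(as.character(assign_activity_class(c(3.9, 4.0001, 6.6))),
               c("inactive", "moderately_active", "highly_active"))
  expect_true(is.ordered(assign_activity_class(5)))
})

test_that("cumulative ordinal encoding round-trips all classes", {
  expect_equal(encode_ordinal("inactive")[1, ], c(1, 0, 0))
  expect_equal(encode_ordinal("moderately_active")[1, ], c(1, 1, 0))
  expect_equal(encode_ordinal("highly_active")[1, ], c(1, 1, 1))
  cls <- factor(c("inactive", "moderately_active", "highly_active"),
                levels = levels(assign_activity_class(1)), ordered = TRUE)
  expect_equal(decode_ordinal(encode_ordinal(cls)), cls)
})

test_that("the thresholded decision scans leading outputs and is monotone", {
  expect_equal(as.character(decide_class(c(0.9, 0.8, 0.7))), "highly_active")
  expect_equal(as.character(decide_class(c(0.9, 0.5, 0.3))), "moderately_active")
  # the scan stops at the first sub-threshold output: (0.9, 0.3, 0.9) has a
  # single leading pass -> inactive (the documented tie case)
  expect_equal(as.character(decide_class(c(0.9, 0.3, 0.9))), "inactive")
  expect_equal(as.character(decide_class(c(0, 0, 0))), "inactive")

  # monotonicity: elementwise-larger outputs never lower the class
  withr::with_seed(5, for (i in 1:200) {
    a <- runif(3); b <- pmin(a + runif(3, 0, 0.5), 1)
    expect_gte(as.integer(decide_class(b)), as.integer(decide_class(a)))
  })

  # one-hot mode: highly active iff the third neuron clears the threshold
  expect_equal(as.character(decide_class(c(0.9, 0.1, 0.45), encoding = "one_hot")),
               "highly_active")
  expect_equal(as.character(decide_class(c(0.9, 0.1, 0.2), encoding = "one_hot")),
               "inactive")
})

test_that("oversampling adds +add to the two smallest classes", {
  mk <- function(n1, n2, n3) tibble::tibble(
    canonical_smiles = paste0("C", seq_len(n1 + n2 + n3)),
    activity_class = rep(c("inactive", "moderately_active", "highly_active"),
                         c(n1, n2, n3)))
  # the published class sizes: (34, 121, 43) -> (74, 121, 83)
  out <- oversample_classes(mk(34, 121, 43), add = 40, seed = 1)
  expect_equal(unname(c(table(factor(out$activity_class,
                                     levels = c("inactive", "moderately_active",
                                                "highly_active"))))),
               c(74, 121, 83))
  expect_equal(nrow(out), 34 + 121 + 43 + 80)

  # ties broken toward the lower ordinal classes
  tie <- oversample_classes(mk(5, 5, 5), add = 40, seed = 1)
  expect_equal(unname(c(table(factor(tie$activity_class,
                                     levels = c("inactive", "moderately_active",
                                                "highly_active"))))),
               c(45, 45, 5))
  # add = 0 is the identity
  expect_identical(oversample_classes(mk(3, 4, 5), add = 0), mk(3, 4, 5))
  # oversampled rows are drawn from the class itself
  expect_true(all(out$canonical_smiles %in% mk(34, 121, 43)$canonical_smiles))
  empty_class <- tibble::tibble(
    canonical_smiles = paste0("C", 1:10),
    activity_class = rep(c("moderately_active", "highly_active"), 5))
  expect_error(oversample_classes(empty_class, add = 5),
               class = "declm_degenerate_class")
})

test_that("clustered folds recover planted fingerprint blobs", {
  # five well-separated binary blobs: exact recovery expected
  withr::with_seed(8, {
    centers <- diag(5)[rep(1:5, each = 12), ] %x% t(rep(1, 40))  # 60 x 200
    fp <- (centers + matrix(runif(60 * 200) < 0.02, 60, 200)) > 0
  })
  df <- tibble::tibble(smiles = paste0("m", 1:60),
                       blob = rep(1:5, each = 12))
  folds <- clustered_folds(df, k = 5, seed = 3, fingerprints = fp * 1)
  # each planted blob maps to exactly one cluster
  tab <- table(folds$blob, folds$cluster)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(sum(folds$role == "test"), 12)
  # determinism
  expect_identical(folds, clustered_folds(df, k = 5, seed = 3, fingerprints = fp * 1))
  expect_error(clustered_folds(df, k = 1), class = "declm_too_few_records")
  expect_error(clustered_folds(df[1:3, ], k = 5, fingerprints = fp[1:3, ]),
               class = "declm_too_few_records")
})

test_that("classifier training beats the majority baseline on planted signal", {
  clf <- train_ordinal_classifier(fx_eclm, fx_act, epochs = 50L, lr = 1e-3,
                                  batch_size = 32L, dropout = 0.2,
                                  oversample_add = 10L, seed = 11L)
  out <- classifier_outputs(clf, fx_act$canonical_smiles)
  acc <- mean(as.character(decide_class(out, 0.4)) ==
                as.character(fx_act$activity_class))
  expect_gt(acc, max(table(fx_act$activity_class)) / nrow(fx_act))

  # freezing both recurrent blocks keeps the backbone bit-identical
  frozen <- train_ordinal_classifier(fx_eclm, fx_act, epochs = 2L,
                                     freeze = c("bn0", "lstm1", "lstm2", "bn1"),
                                     seed = 5L)
  for (blk in c("bn0", "lstm1", "lstm2", "bn1")) {
    expect_identical(frozen$params[[blk]], fx_eclm$params[[blk]])
  }

  # epochs = 0: untrained head at its initialization
  init <- train_ordinal_classifier(fx_eclm, fx_act, epochs = 0L, seed = 5L)
  expect_identical(init$params$head,
                   classifier_from_backbone(fx_eclm, seed = 5L)$params$head)
})

test_that("ensemble votes count highly-active decisions and rank stably", {
  mols <- fx_act$canonical_smiles[1:6]
  high <- constant_classifier(c(0.9, 0.9, 0.9))
  low <- constant_classifier(c(0.9, 0.3, 0.1))
  models <- c(rep(list(high), 7), rep(list(low), 3))
  v <- ensemble_votes(models, mols)
  expect_equal(v$votes, rep(7L, 6))

  # permutation invariance in model order
  v2 <- ensemble_votes(models[c(4:10, 1:3)], mols)
  expect_equal(v2$votes, v$votes)

  # all pass / none pass
  expect_equal(ensemble_votes(rep(list(high), 4), mols)$votes, rep(4L, 6))
  expect_equal(ensemble_votes(rep(list(low), 4), mols)$votes, rep(0L, 6))

  # rank_library: counts non-increasing in the confidence level
  votes <- tibble::tibble(smiles = paste0("m", 1:20),
                          votes = withr::with_seed(2, sample(0:10, 20, TRUE)))
  counts <- vapply(0:11, function(cf) nrow(rank_library(votes, cf)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(nrow(rank_library(votes, 0)), 20)
  expect_equal(nrow(rank_library(votes, 11)), 0)
  rk <- rank_library(votes, 9)
  expect_true(all(diff(rk$votes) <= 0))
})

test_that("matched-TPR operating points agree with an independent ROC", {
  withr::with_seed(10, {
    truth <- rep(c("highly_active", "inactive"), c(30, 40))
    scores <- c(rnorm(30, 1), rnorm(40))
  })
  op <- fpr_at_tpr(scores, truth, 70)
  r <- pROC::roc(response = factor(truth, levels = c("inactive", "highly_active")),
                 predictor = scores, quiet = TRUE)
  sens <- rev(r$sensitivities)
  fpr <- rev(1 - r$specificities)
  idx <- which(sens * 100 >= 70)[1]
  expect_equal(op$fpr, fpr[idx] * 100, tolerance = 1e-9)
  expect_equal(op$tpr, sens[idx] * 100, tolerance = 1e-9)
})

test_that("the ROC operating point follows confusion-matrix arithmetic", {
  # perfect classifier
  p <- roc_operating_point(rep(c("highly_active", "inactive"), c(4, 4)),
                           rep(c("highly_active", "inactive"), c(4, 4)))
  expect_equal(c(p$tpr, p$fpr), c(100, 0))
  # constant-high classifier
  p2 <- roc_operating_point(rep("highly_active", 8),
                            rep(c("highly_active", "inactive"), c(4, 4)))
  expect_equal(c(p2$tpr, p2$fpr), c(100, 100))
  # 10-molecule fixture: 4 TP / 1 FN / 2 FP / 3 TN -> (80, 40)
  truth <- rep(c("highly_active", "inactive"), c(5, 5))
  pred <- c(rep("highly_active", 4), "inactive",
            rep("highly_active", 2), rep("inactive", 3))
  p3 <- roc_operating_point(pred, truth)
  expect_equal(c(p3$tpr, p3$fpr), c(80, 40))
  expect_error(roc_operating_point(pred, rep("inactive", 10)),
               class = "declm_degenerate_test_set")
})
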