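# Ordinal three-class bioactivity classification on a pretrained backbone,
# with activity binning, oversampling, clustered cross-validation folds,
# thresholded ordinal decisions and a deep voting ensemble.

ACTIVITY_LEVELS <- c("inactive", "moderately_active", "highly_active")

#' Bin pIC50 values into ordered activity classes
#'
#' `inactive` for pIC50 <= `low_cut`, `moderately_active` for
#' `low_cut` < pIC50 <= `high_cut`, `highly_active` above. Boundary values
#' fall in the lower class.
#'
#' @param pIC50 Numeric vector of -log10 molar IC50 values.
#' @param low_cut,high_cut Class boundaries (defaults 4.0 and 6.5).
#' @return Ordered factor with levels inactive < moderately_active <
#'   highly_active.
#' @export
assign_activity_class <- function(pIC50, low_cut = 4.0, high_cut = 6.5) {
  stopifnot(is.numeric(pIC50), all(is.finite(pIC50)))
  cls <- ifelse(pIC50 <= low_cut, 1L, ifelse(pIC50 <= high_cut, 2L, 3L))
  factor(ACTIVITY_LEVELS[cls], levels = ACTIVITY_LEVELS, ordered = TRUE)
}

#' Cumulative (ordinal) target encoding
#'
#' Frank-Hall style coding that preserves the class order:
#' inactive -> (1,0,0), moderately_active -> (1,1,0),
#' highly_active -> (1,1,1). Output k is the indicator of "class at least
#' level k".
#'
#' @param cls Ordered activity factor (or character vector of levels).
#' @return A binary matrix with one row per observation and 3 columns.
#' @export
encode_ordinal <- function(cls) {
  if (!is.factor(cls)) cls <- factor(cls, levels = ACTIVITY_LEVELS, ordered = TRUE)
  k <- as.integer(cls)
  stopifnot(!anyNA(k))
  t(vapply(k, function(ki) as.numeric(seq_len(3L) <= ki), numeric(3)))
}

#' Decode an ordinal encoding back to a class
#'
#' @param mat Binary matrix as produced by [encode_ordinal()].
#' @return Ordered activity factor.
#' @export
decode_ordinal <- function(mat) {
  k <- rowSums(mat >= 0.5)
  factor(ACTIVITY_LEVELS[pmax(k, 1)], levels = ACTIVITY_LEVELS, ordered = TRUE)
}

#' Thresholded ordinal decision
#'
#' Scans the sigmoid outputs left to right and counts the leading outputs
#' strictly above `threshold`; the predicted class is that count minus one
#' (floored at inactive). Monotone: raising any output never lowers the
#' class.
#'
#' @param outputs Numeric vector of 3 sigmoid outputs, or a matrix with one
#'   row per molecule.
#' @param threshold Decision threshold (default 0.4).
#' @param encoding `"cumulative"` (default) applies the scan rule;
#'   `"one_hot"` predicts `highly_active` iff the third output exceeds the
#'   threshold, otherwise the larger of the first two outputs.
#' @return Ordered activity factor.
#' @export
decide_class <- function(outputs, threshold = 0.4,
                         encoding = c("cumulative", "one_hot")) {
  encoding <- match.arg(encoding)
  if (is.vector(outputs)) outputs <- matrix(outputs, nrow = 1L)
  stopifnot(ncol(outputs) == 3L)
  if (encoding == "cumulative") {
    pass <- outputs > threshold
    lead <- apply(pass, 1, function(r) {
      w <- which(!r)
      if (!length(w)) 3L else w[1] - 1L
    })
    k <- pmax(lead, 1L)
  } else {
    k <- ifelse(outputs[, 3] > threshold, 3L,
                ifelse(outputs[, 2] >= outputs[, 1], 2L, 1L))
  }
  factor(ACTIVITY_LEVELS[k], levels = ACTIVITY_LEVELS, ordered = TRUE)
}

#' Oversample the minority classes
#'
#' Adds `add` records, drawn uniformly with replacement from themselves, to
#' each of the two smallest classes; the largest class is untouched, so the
#' output has `nrow(data) + 2 * add` rows. Size ties are broken by class
#' order (lower ordinal classes count as less represented first).
#'
#' @param data Data frame with an `activity_class` column.
#' @param add Records added per minority class (default 40).
#' @param seed Seed for the resampling draw.
#' @return The augmented tibble.
#' @export
oversample_classes <- function(data, add = 40L, seed = 1L) {
  stopifnot(is.data.frame(data), "activity_class" %in% names(data))
  cls <- factor(data$activity_class, levels = ACTIVITY_LEVELS, ordered = TRUE)
  counts <- table(cls)
  if (any(counts == 0)) {
    declm_abort("Every activity class must be represented.", "declm_degenerate_class")
  }
  if (add == 0L) return(as_tibble(data))
  # two smallest classes; ties resolved toward the lower ordinal class
  ord <- order(as.integer(counts), seq_along(counts))
  minority <- names(counts)[ord[1:2]]
  extra <- withr::with_seed(seed, lapply(minority, function(lv) {
    pool <- which(cls == lv)
    data[sample(pool, add, replace = TRUE), , drop = FALSE]
  }))
  dplyr::bind_rows(as_tibble(data), dplyr::bind_rows(extra))
}

#' Cluster molecules into similarity folds
#'
#' k-means (`stats::kmeans`) on Morgan fingerprint vectors (Euclidean
#' distance on 0/1 coordinates) groups molecules by structural similarity;
#' one cluster is designated the held-out test group and the remainder serve
#' as cross-validation folds.
#'
#' @param data Data frame with a `canonical_smiles` (or `smiles`) column.
#' @param k Number of clusters (default 5); must leave at least one
#'   cross-validation fold, so `k >= 2`.
#' @param seed Seed for center initialization.
#' @param test_cluster Index (1..k) of the cluster held out for testing.
#' @param radius,n_bits Fingerprint parameters.
#' @param fingerprints Optional precomputed fingerprint matrix (one row per
#'   record) used instead of computing Morgan fingerprints.
#' @return The tibble with added `cluster` and `role`
#'   (`"cv"`/`"test"`) columns.
#' @export
clustered_folds <- function(data, k = 5L, seed = 1L, test_cluster = k,
                            radius = 2L, n_bits = 2048L, fingerprints = NULL) {
  stopifnot(is.data.frame(data))
  if (k < 2L) {
    declm_abort("k must be at least 2: one test cluster plus >= 1 CV fold.",
                "declm_too_few_records")
  }
  if (nrow(data) < k) {
    declm_abort("Fewer records than clusters.", "declm_too_few_records")
  }
  fp <- fingerprints %||%
    morgan_fingerprints(pull_smiles(data), radius = radius, n_bits = n_bits)
  km <- withr::with_seed(seed, kmeans(fp, centers = k, nstart = 5L, iter.max = 50L))
  out <- as_tibble(data)
  out$cluster <- as.integer(km$cluster)
  out$role <- ifelse(out$cluster == test_cluster, "test", "cv")
  out
}

# ---- classifier training --------------------------------------------------

#' Build an ordinal classifier from a pretrained backbone
#'
#' Copies the normalization and recurrent weights of a pretrained CLM or
#' E-CLM into a classifier with a fresh dropout + 3-unit sigmoid head.
#'
#' @param backbone A trained `declm_model` (generative or ELECTRA) sharing
#'   the target vocabulary, or a `declm_vocab` for a from-scratch classifier.
#' @param seed Head initialization seed.
#' @return An untrained `declm_ordinal_model`.
#' @export
classifier_from_backbone <- function(backbone, seed = 1L) {
  if (inherits(backbone, "declm_vocab")) {
    return(nn_init(backbone, units = c(1024L, 256L), head = "ordinal", seed = seed))
  }
  stopifnot(inherits(backbone, "declm_model"))
  model <- nn_init(backbone$vocab, units = backbone$units, head = "ordinal",
                   seed = seed)
  for (blk in c("bn0", "lstm1", "lstm2", "bn1")) {
    model$params[[blk]] <- backbone$params[[blk]]
  }
  model
}

#' Train the ordinal bioactivity classifier
#'
#' Fine-tunes the backbone plus head with binary cross-entropy on the
#' cumulative class encoding (Adam, default learning rate 1e-4, 200 epochs
#' at production scale; sigmoid decision threshold 0.4).
#'
#' @param backbone Pretrained `declm_model` (E-CLM or generative CLM).
#' @param data Data frame with `canonical_smiles`/`smiles` and either
#'   `activity_class` or `pIC50`.
#' @param epochs,lr,batch_size Training controls.
#' @param dropout Dropout rate before the head.
#' @param freeze Blocks kept constant: `character(0)` (full fine-tune,
#'   default), `"lstm1"`, `"lstm2"`, or both.
#' @param oversample_add If positive, minority-class oversampling applied
#'   before training.
#' @param seed Seed (initialization, shuffling, dropout, oversampling).
#' @return A trained `declm_ordinal_model` carrying its `threshold`.
#' @export
train_ordinal_classifier <- function(backbone, data, epochs = 200L, lr = 1e-4,
                                     batch_size = 32L, dropout = 0.2,
                                     freeze = character(0), threshold = 0.4,
                                     oversample_add = 0L, seed = 1L) {
  stopifnot(is.data.frame(data))
  if (!"activity_class" %in% names(data)) {
    data$activity_class <- assign_activity_class(data$pIC50)
  }
  if (oversample_add > 0L) {
    data <- oversample_classes(data, add = oversample_add, seed = seed)
  }
  model <- classifier_from_backbone(backbone, seed = seed)
  vocab <- model$vocab
  tokens <- tokenize_smiles(pull_smiles(data), vocab)
  Y <- encode_ordinal(data$activity_class)
  model$threshold <- threshold
  if (epochs == 0L) return(model)
  task_fn <- function(idx, epoch) {
    list(X = pad_batch(tokens[idx], vocab$pad),
         task = list(y = Y[idx, , drop = FALSE], dropout = dropout))
  }
  nn_train_loop(model, length(tokens), task_fn, epochs = epochs, lr = lr,
                batch_size = batch_size, seed = seed, freeze = freeze)
}

#' Classifier sigmoid outputs for molecules
#'
#' @param model A `declm_ordinal_model`.
#' @param smiles Character vector (or data frame) of molecules.
#' @return Matrix of three sigmoid outputs per molecule.
#' @export
classifier_outputs <- function(model, smiles) {
  stopifnot(inherits(model, "declm_ordinal_model"))
  smiles <- pull_smiles(smiles)
  tokens <- tokenize_smiles(smiles, model$vocab)
  X <- pad_batch(tokens, model$vocab$pad)
  fwd <- nn_forward(model, X, task = list(dropout = 0), training = FALSE)
  unname(fwd$probs)
}

#' Train a deep voting ensemble of ordinal classifiers
#'
#' Trains `members` independent classifiers that differ only in their seed
#' (initialization, shuffling, dropout and oversampling draws), mirroring
#' the nondeterministic-optimization source of ensemble diversity.
#'
#' @inheritParams train_ordinal_classifier
#' @param members Ensemble size M (production default 100).
#' @return A `declm_ensemble` (list of models).
#' @export
train_ensemble <- function(backbone, data, members = 100L, epochs = 200L,
                           lr = 1e-4, batch_size = 32L, dropout = 0.2,
                           freeze = character(0), threshold = 0.4,
                           oversample_add = 40L, seed = 1L) {
  models <- purrr::map(seq_len(members), function(m) {
    train_ordinal_classifier(backbone, data, epochs = epochs, lr = lr,
                             batch_size = batch_size, dropout = dropout,
                             freeze = freeze, threshold = threshold,
                             oversample_add = oversample_add,
                             seed = derive_seed(seed, m))
  })
  structure(list(models = models, threshold = threshold, members = members),
            class = "declm_ensemble")
}

#' @export
print.declm_ensemble <- function(x, ...) {
  cat(sprintf("<declm ensemble> %d members, threshold %.2f\n",
              x$members, x$threshold))
  invisible(x)
}

#' Count "highly active" votes for each molecule
#'
#' A molecule's vote count is the number of ensemble members whose
#' thresholded ordinal decision is `highly_active`; it quantifies prediction
#' confidence. The reported `predicted_class` is the modal class across
#' members.
#'
#' @param ensemble A `declm_ensemble` (or plain list of classifier models).
#' @param smiles Character vector or data frame of molecules.
#' @param threshold Decision threshold (defaults to the ensemble's).
#' @return A tibble `smiles, votes, predicted_class` with one row per input
#'   molecule, in input order.
#' @export
ensemble_votes <- function(ensemble, smiles, threshold = NULL) {
  models <- if (inherits(ensemble, "declm_ensemble")) ensemble$models else ensemble
  threshold <- threshold %||%
    (if (inherits(ensemble, "declm_ensemble")) ensemble$threshold else 0.4)
  smiles <- pull_smiles(smiles)
  decisions <- vapply(models, function(m) {
    as.integer(decide_class(classifier_outputs(m, smiles), threshold))
  }, integer(length(smiles)))
  if (is.vector(decisions)) decisions <- matrix(decisions, nrow = length(smiles))
  votes <- rowSums(decisions == 3L)
  modal <- apply(decisions, 1, function(d) {
    tb <- tabulate(d, nbins = 3L)
    which.max(tb)
  })
  tibble(smiles = smiles, votes = as.integer(votes),
         predicted_class = factor(ACTIVITY_LEVELS[modal],
                                  levels = ACTIVITY_LEVELS, ordered = TRUE))
}

#' Rank a library by vote confidence
#'
#' Returns the molecules with at least `confidence` votes, sorted by votes
#' (descending) with input order breaking ties. The retained count is
#' non-increasing in the confidence level.
#'
#' @param votes A tibble from [ensemble_votes()] (columns `smiles`, `votes`).
#' @param confidence Minimum number of votes (0..M).
#' @return The filtered, sorted tibble.
#' @export
rank_library <- function(votes, confidence = 0L) {
  stopifnot(is.data.frame(votes), "votes" %in% names(votes), confidence >= 0)
  out <- votes[votes$votes >= confidence, , drop = FALSE]
  out[order(-out$votes, seq_len(nrow(out))), , drop = FALSE]
}

#' Operating point for the highly-active-versus-inactive task
#'
#' True positive rate among truly highly active molecules and false positive
#' rate among truly inactive molecules, for "predicted highly active"
#' decisions at the given threshold.
#'
#' @param predictions Ordered factor (or character) of predicted classes, or
#'   a matrix of sigmoid outputs (then decided at `threshold`).
#' @param truth Ordered factor / character of true classes.
#' @param threshold Threshold used when `predictions` is an output matrix.
#' @return A one-row tibble with `tpr` and `fpr` in percent.
#' @export
roc_operating_point <- function(predictions, truth, threshold = 0.4) {
  if (is.matrix(predictions)) predictions <- decide_class(predictions, threshold)
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  pos <- truth == "highly_active"
  neg <- truth == "inactive"
  if (!any(pos) || !any(neg)) {
    declm_abort("Test set must contain both highly active and inactive records.",
                "declm_degenerate_test_set")
  }
  pred_high <- predictions == "highly_active"
  tibble(tpr = 100 * sum(pred_high & pos) / sum(pos),
         fpr = 100 * sum(pred_high & neg) / sum(neg))
}

#' False positive rate at a matched true positive rate
#'
#' Sweeps a score threshold to the smallest value whose true positive rate
#' (highly active vs inactive) reaches `target_tpr`, and reports the false
#' positive rate there. Used to compare pretraining strategies at a common
#' operating point.
#'
#' @param scores Numeric score per molecule (larger = more active).
#' @param truth True classes.
#' @param target_tpr Required true positive rate in percent.
#' @return A one-row tibble with `threshold`, `tpr`, `fpr` (percent).
#' @export
fpr_at_tpr <- function(scores, truth, target_tpr = 71.3) {
  truth <- as.character(truth)
  pos <- scores[truth == "highly_active"]
  neg <- scores[truth == "inactive"]
  if (!length(pos) || !length(neg)) {
    declm_abort("Need both highly active and inactive records.",
                "declm_degenerate_test_set")
  }
  cuts <- sort(unique(c(pos, neg)), decreasing = TRUE)
  for (ct in cuts) {
    tpr <- 100 * mean(pos >= ct)
    if (tpr >= target_tpr) {
      return(tibble(threshold = ct, tpr = tpr, fpr = 100 * mean(neg >= ct)))
    }
  }
  tibble(threshold = min(cuts), tpr = 100, fpr = 100)
}
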