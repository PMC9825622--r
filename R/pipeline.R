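# End-to-end orchestration: pretrain -> fine-tune -> sample -> ELECTRA
# pretrain -> classifier ensemble -> vote-rank -> analyze / screen.

#' Pipeline run configuration
#'
#' Collects every stage's settings. `preset = "production"` mirrors the
#' published workflow shape (1024/256 cells, nucleus p = 0.85, 100 ensemble
#' members, sigmoid threshold 0.4, +40 oversampling, 200 classifier
#' epochs); `preset = "small"` shrinks widths to 64/16 cells (keeping the
#' 4:1 ratio of the two recurrent blocks), members and epochs for desk-scale
#' runs.
#'
#' @param pretrain_smi Path to the pretraining `.smi` file.
#' @param activity_csv Path to the activity CSV (`smiles,pIC50`).
#' @param queries_smi Optional query-set `.smi` for virtual screening.
#' @param preset `"small"` or `"production"`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param ... Overrides of individual fields.
#' @return A `declm_config` list.
#' @export
pipeline_config <- function(pretrain_smi, activity_csv, queries_smi = NULL,
                            preset = c("small", "production"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- list(
    pretrain_smi = pretrain_smi, activity_csv = activity_csv,
    queries_smi = queries_smi, preset = preset, seed = as.integer(seed),
    max_len = 90L, scheme = "token",
    units = c(1024L, 256L), pretrain_epochs = 40L, batch_size = 64L,
    transfer_epochs = 50L, transfer_freeze = "lstm1",
    sample_every = 1L, sample_n = 5000L,
    policy_mode = "nucleus", policy_p = 0.85, policy_temperature = 0.7,
    gen_max_len = 100L,
    electra_epochs = 50L, electra_rate = 0.15,
    members = 100L, classifier_epochs = 200L, dropout = 0.2,
    threshold = 0.4, oversample_add = 40L, confidence = 99L,
    fp_radius = 2L, fp_bits = 2048L)
  if (preset == "small") {
    base <- modifyList(base, list(
      units = c(64L, 16L), pretrain_epochs = 4L, batch_size = 32L,
      transfer_epochs = 4L, sample_every = 2L, sample_n = 100L,
      electra_epochs = 4L, members = 5L, classifier_epochs = 12L,
      oversample_add = 10L, confidence = 3L))
  }
  cfg <- modifyList(base, list(...))
  structure(cfg, class = "declm_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    declm_abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                        conditionMessage(e)),
                "declm_stage_error", stage = stage)
  })
}

#' Run the full design pipeline
#'
#' Executes, in order: corpus standardization and filtering, vocabulary
#' construction, generative pretraining, transfer learning with cadence
#' sampling, generation-quality evaluation, ELECTRA pretraining, ensemble
#' classifier training, vote ranking of the sampled library, structural
#' analysis (scaffold novelty, nearest-neighbor similarity versus votes)
#' and, when a query set is supplied, similarity screening. All artifacts,
#' plus a manifest (configuration, seeds, file hashes), are written to
#' `out_dir`. Deterministic per seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results; artifacts on
#'   disk in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "declm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  corpus <- run_stage("corpus", {
    raw <- read_smi(config$pretrain_smi)
    filter_corpus(standardize_molecules(raw, strict = FALSE), config$max_len)
  })
  activities <- run_stage("activities", {
    act <- read_activity(config$activity_csv)
    act <- filter_corpus(standardize_molecules(act, strict = FALSE), config$max_len)
    act$activity_class <- assign_activity_class(act$pIC50)
    act
  })

  vocab <- run_stage("vocabulary", {
    v <- build_vocabulary(c(corpus$canonical_smiles, activities$canonical_smiles),
                          scheme = config$scheme)
    write_vocabulary(v, file.path(out_dir, "vocabulary.json"))
    v
  })

  tokens <- tokenize_smiles(corpus$canonical_smiles, vocab)
  ft_tokens <- tokenize_smiles(activities$canonical_smiles, vocab)

  clm <- run_stage("pretrain", {
    m <- clm_pretrain(tokens, vocab, units = config$units,
                      epochs = config$pretrain_epochs,
                      batch_size = config$batch_size,
                      seed = derive_seed(seed, 11L))
    save_model(m, file.path(out_dir, "clm_pretrained.rds"))
    m
  })

  policy <- sampling_policy(config$policy_mode,
                            temperature = config$policy_temperature,
                            p = config$policy_p, max_len = config$gen_max_len,
                            seed = derive_seed(seed, 13L))

  clm_ft <- run_stage("transfer", {
    m <- clm_transfer(clm, ft_tokens, epochs = config$transfer_epochs,
                      freeze = config$transfer_freeze,
                      batch_size = min(config$batch_size, 32L),
                      seed = derive_seed(seed, 17L),
                      sample_every = config$sample_every,
                      sample_n = config$sample_n, sample_policy = policy)
    save_model(m, file.path(out_dir, "clm_finetuned.rds"))
    m
  })

  report <- run_stage("generation_report", {
    samples <- clm_ft$transfer_samples %||%
      generate_smiles(clm_ft, policy, n = config$sample_n)
    rep <- evaluate_generation(samples$smiles, corpus$canonical_smiles,
                               activities$canonical_smiles)
    mol <- rep$molecules
    mol$epoch <- samples$epoch %||% NA_integer_
    readr::write_csv(mol, file.path(out_dir, "samples.csv"))
    jsonlite::write_json(glance(rep), file.path(out_dir, "generation_report.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  eclm <- run_stage("electra", {
    m <- electra_pretrain(tokens, vocab, units = config$units,
                          rate = config$electra_rate,
                          epochs = config$electra_epochs,
                          batch_size = config$batch_size,
                          seed = derive_seed(seed, 19L))
    save_model(m, file.path(out_dir, "eclm_pretrained.rds"))
    m
  })

  ensemble <- run_stage("ensemble", {
    if (!nrow(activities)) declm_abort("Empty activity table.", "declm_invalid_argument")
    en <- train_ensemble(eclm, activities, members = config$members,
                         epochs = config$classifier_epochs,
                         dropout = config$dropout, threshold = config$threshold,
                         oversample_add = config$oversample_add,
                         seed = derive_seed(seed, 23L))
    save_model(en, file.path(out_dir, "ensemble.rds"))
    en
  })

  library_tbl <- run_stage("library", {
    mol <- report$molecules
    lib <- unique(mol$canonical_smiles[mol$valid & mol$novel])
    if (!length(lib)) lib <- unique(stats::na.omit(mol$canonical_smiles))
    # the classifier can only score designs representable in its vocabulary
    lib <- lib[tokenizable(lib, vocab)]
    tibble(smiles = lib)
  })

  votes <- run_stage("votes", {
    v <- ensemble_votes(ensemble, library_tbl)
    readr::write_csv(v, file.path(out_dir, "votes.csv"))
    v
  })

  analysis <- run_stage("analysis", {
    ranked <- rank_library(votes, config$confidence)
    top <- if (nrow(ranked)) ranked$smiles else votes$smiles
    nov <- scaffold_novelty(top, activities$canonical_smiles)
    nnp <- nn_similarity(votes$smiles, activities$canonical_smiles,
                         radius = config$fp_radius, n_bits = config$fp_bits)
    nnp$votes <- votes$votes
    sim_by_votes <- nnp |>
      dplyr::group_by(.data$votes) |>
      dplyr::summarise(mean_similarity = mean(.data$similarity), n = dplyr::n(),
                       .groups = "drop")
    out <- list(confidence = config$confidence,
                n_top_ranked = nrow(ranked),
                scaffold_novelty = as.list(nov),
                similarity_vs_votes = sim_by_votes)
    jsonlite::write_json(out, file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  scores <- NULL
  if (!is.null(config$queries_smi)) {
    scores <- run_stage("screen", {
      queries <- standardize_molecules(read_smi(config$queries_smi), strict = FALSE)
      sc <- screen_library(library_tbl, queries$canonical_smiles,
                           radius = config$fp_radius, n_bits = config$fp_bits)
      readr::write_csv(sc, file.path(out_dir, "screen_scores.csv"))
      sc
    })
  }

  run_stage("manifest", {
    arts <- list.files(out_dir, full.names = TRUE)
    arts <- arts[!grepl("manifest[.]json$", arts)]
    manifest <- list(
      config = unclass(config),
      seed = seed,
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("declm")),
      artifacts = lapply(setNames(arts, basename(arts)),
                         function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(corpus = corpus, activities = activities, vocab = vocab,
                 clm = clm, clm_finetuned = clm_ft, report = report,
                 eclm = eclm, ensemble = ensemble, votes = votes,
                 analysis = analysis, screen = scores, out_dir = out_dir))
}
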