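# Similarity-based virtual screening with reciprocal-rank fusion.

#' Rank a library against one query
#'
#' Rank 1 is the library molecule most similar to the query (Tanimoto on
#' Morgan fingerprints); ties are broken by library order, so every member
#' receives a distinct integer rank.
#'
#' @param similarities Numeric vector of similarities of each library
#'   molecule to the query.
#' @return Integer rank vector (1 = most similar).
#' @export
rank_per_query <- function(similarities) {
  stopifnot(is.numeric(similarities), length(similarities) > 0L)
  ord <- order(-similarities, seq_along(similarities))
  rk <- integer(length(similarities))
  rk[ord] <- seq_along(similarities)
  rk
}

#' Reciprocal-rank fusion of per-query rankings
#'
#' Fuses the per-query ranks of each library molecule into the score
#' `S = sum_i 1 / rank_i` over the N query molecules; greater S corresponds
#' to better rank positions. Invariant under permutation of the queries.
#'
#' @param ranks Integer matrix: one row per library molecule, one column per
#'   query (as produced by stacking [rank_per_query()] outputs).
#' @return A tibble `index, S, best_rank`, sorted by decreasing S with input
#'   order breaking ties.
#' @export
fuse_ranks <- function(ranks) {
  if (is.vector(ranks)) ranks <- matrix(ranks, ncol = 1L)
  if (any(ranks < 1L)) {
    declm_abort("Ranks must be positive integers.", "declm_rank_vector_mismatch")
  }
  S <- rowSums(1 / ranks)
  out <- tibble(index = seq_len(nrow(ranks)), S = S,
                best_rank = apply(ranks, 1, min))
  out[order(-out$S, out$index), , drop = FALSE]
}

#' Screen a compound library against a query set
#'
#' Ranks every library molecule by Tanimoto similarity (Morgan fingerprints)
#' to each query molecule, then fuses the per-query rankings by reciprocal
#' rank summation.
#'
#' @param library Data frame with `smiles` (and optionally `id`) columns, or
#'   a character vector.
#' @param queries Character vector or data frame of query SMILES (e.g. the
#'   fine-tuning set).
#' @param radius,n_bits Fingerprint parameters.
#' @return A tibble `id, smiles, S, best_rank` sorted by decreasing S.
#' @export
screen_library <- function(library, queries, radius = 2L, n_bits = 2048L) {
  if (!is.data.frame(library)) library <- tibble(smiles = as.character(library))
  if (!"id" %in% names(library)) library$id <- as.character(seq_len(nrow(library)))
  lib_smiles <- pull_smiles(library)
  q_smiles <- pull_smiles(queries)
  stopifnot(length(lib_smiles) > 0L, length(q_smiles) > 0L)
  lfp <- morgan_fingerprints(lib_smiles, radius, n_bits)
  qfp <- morgan_fingerprints(q_smiles, radius, n_bits)
  sims <- tanimoto(lfp, qfp)                      # n_lib x n_query
  if (is.null(dim(sims))) sims <- matrix(sims, nrow(lfp), nrow(qfp))
  ranks <- apply(sims, 2, rank_per_query)
  if (is.vector(ranks)) ranks <- matrix(ranks, ncol = ncol(sims))
  fused <- fuse_ranks(ranks)
  tibble(id = library$id[fused$index],
         smiles = lib_smiles[fused$index],
         S = fused$S,
         best_rank = as.integer(fused$best_rank))
}
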