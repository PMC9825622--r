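# Structural analytics for generated libraries: circular fingerprints,
# Tanimoto similarity, nearest-neighbor profiles, Bemis-Murcko scaffold
# novelty and the Frechet distance between molecule-set embeddings.

#' Morgan-style circular fingerprints
#'
#' Computes extended-connectivity (circular) fingerprints of the given
#' radius through the OpenBabel backend (ECFP of diameter `2 * radius`,
#' 4096 bits) and folds them to `n_bits` by modular OR, the standard folding
#' scheme. Deterministic in the canonical SMILES and the parameters.
#'
#' @param smiles Character vector (or data frame) of valid SMILES.
#' @param radius Circular neighborhood radius (default 2).
#' @param n_bits Folded fingerprint length (default 2048).
#' @return A binary matrix with one row per molecule (rownames = input).
#' @export
morgan_fingerprints <- function(smiles, radius = 2L, n_bits = 2048L) {
  smiles <- pull_smiles(smiles)
  stopifnot(length(smiles) > 0L, radius >= 0L, n_bits >= 1L)
  sdf <- smiles_to_sdfset(smiles)
  fpname <- paste0("ECFP", 2L * radius)
  raw <- suppressWarnings(ChemmineR::fingerprintOB(sdf, fpname))@fpma
  if (n_bits < ncol(raw)) {
    folded <- matrix(0L, nrow(raw), n_bits)
    for (blk in seq_len(ceiling(ncol(raw) / n_bits))) {
      cols <- ((blk - 1L) * n_bits + 1L):min(blk * n_bits, ncol(raw))
      folded[, seq_along(cols)] <- folded[, seq_along(cols), drop = FALSE] |
        (raw[, cols, drop = FALSE] > 0)
    }
    raw <- folded * 1L
  }
  rownames(raw) <- smiles
  raw
}

#' Tanimoto similarity between fingerprints
#'
#' `|a AND b| / |a OR b|`. By convention the similarity of two all-zero
#' fingerprints is 1 (indistinguishable objects).
#'
#' @param a,b Binary vectors of equal length, or matrices with one
#'   fingerprint per row (then the full similarity matrix is returned).
#' @return A scalar, or an `nrow(a) x nrow(b)` matrix.
#' @export
tanimoto <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, nrow = 1L)
  if (is.vector(b)) b <- matrix(b, nrow = 1L)
  if (ncol(a) != ncol(b)) {
    declm_abort("Fingerprint lengths differ.", "declm_length_mismatch")
  }
  a <- (a > 0) * 1; b <- (b > 0) * 1
  inter <- a %*% t(b)
  na <- rowSums(a); nb <- rowSums(b)
  uni <- outer(na, nb, `+`) - inter
  sim <- ifelse(uni == 0, 1, inter / ifelse(uni == 0, 1, uni))
  if (nrow(sim) == 1L && ncol(sim) == 1L) sim[1, 1] else sim
}

#' Nearest-neighbor similarity profile
#'
#' For each design, the maximum Tanimoto similarity over a reference set and
#' the index of the nearest reference (ties broken by reference order).
#'
#' @param designs,reference Character vectors of valid SMILES, or
#'   fingerprint matrices from [morgan_fingerprints()].
#' @param radius,n_bits Fingerprint parameters (when SMILES are given).
#' @return A tibble `design, nn_index, nn_smiles, similarity`.
#' @export
nn_similarity <- function(designs, reference, radius = 2L, n_bits = 2048L) {
  dfp <- if (is.matrix(designs)) designs else morgan_fingerprints(designs, radius, n_bits)
  rfp <- if (is.matrix(reference)) reference else morgan_fingerprints(reference, radius, n_bits)
  stopifnot(nrow(rfp) > 0L)
  sim <- tanimoto(dfp, rfp)
  if (is.null(dim(sim))) sim <- matrix(sim, nrow(dfp), nrow(rfp))
  nn <- apply(sim, 1, which.max)
  tibble(design = rownames(dfp) %||% as.character(seq_len(nrow(dfp))),
         nn_index = as.integer(nn),
         nn_smiles = if (!is.null(rownames(rfp))) rownames(rfp)[nn] else NA_character_,
         similarity = sim[cbind(seq_len(nrow(sim)), nn)])
}

# ---- Bemis-Murcko scaffolds ----------------------------------------------

# Extract the ring-and-linker framework of one parsed molecule.
# Phase 1 prunes terminal atoms iteratively (pure topology), leaving rings
# plus linkers; phase 2 re-attaches atoms joined to the framework by a
# double or triple bond (exocyclic =O and the like). `graph = TRUE`
# additionally turns every atom into carbon and every bond into a single
# bond, erasing atom and bond types.
murcko_one <- function(sdf, graph = FALSE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0L || n < 3L) return(NA_character_)
  bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  keep <- rep(TRUE, n)
  eb <- bonds
  repeat {
    deg <- tabulate(c(eb[, 1], eb[, 2]), nbins = n)
    drop <- which(keep & deg == 1L)
    if (!length(drop)) break
    keep[drop] <- FALSE
    eb <- eb[!(eb[, 1] %in% drop | eb[, 2] %in% drop), , drop = FALSE]
  }
  if (!sum(keep) || nrow(eb) < sum(keep)) return(NA_character_)  # acyclic
  extra <- unique(unlist(lapply(seq_len(nrow(bonds)), function(i) {
    b <- bonds[i, ]
    if (b[3] >= 2L) {
      if (keep[b[1]] && !keep[b[2]]) return(b[2])
      if (keep[b[2]] && !keep[b[1]]) return(b[1])
    }
    NULL
  })))
  keep[extra] <- TRUE
  fb <- bonds[keep[bonds[, 1]] & keep[bonds[, 2]], , drop = FALSE]
  idx <- which(keep)
  remap <- match(seq_len(n), idx)
  ab2 <- ab[idx, , drop = FALSE]
  if (graph) {
    rownames(ab2) <- paste0("C_", seq_along(idx))
    ab2[, 5:ncol(ab2)] <- 0
    fb[, 3] <- 1L
  }
  bb2 <- matrix(0, nrow(fb), ncol(bb), dimnames = list(seq_len(nrow(fb)), colnames(bb)))
  bb2[, 1] <- remap[fb[, 1]]; bb2[, 2] <- remap[fb[, 2]]; bb2[, 3] <- fb[, 3]
  out <- sdf
  out@atomblock <- ab2
  out@bondblock <- bb2
  h <- ChemmineR::header(out)
  h["Counts_Line"] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              nrow(ab2), nrow(bb2))
  out@header <- h
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  ChemmineR::write.SDF(out, tmp)
  res <- ChemmineOB::convertFormat("SDF", "CAN", paste(readLines(tmp), collapse = "\n"),
                                   options = ob_empty_options())
  smi <- sub("\t.*", "", strsplit(res, "\n")[[1]][1])
  if (is.na(smi) || !nzchar(smi)) NA_character_ else smi
}

#' Bemis-Murcko atom and graph scaffolds
#'
#' The atom scaffold is the ring systems plus linkers with substituents
#' pruned (atom and bond types retained, exocyclic multiple-bonded atoms
#' kept); the graph scaffold additionally replaces every atom by carbon and
#' every bond by a single bond. Acyclic molecules have no scaffold: both
#' columns are `NA` (or, with `strict = TRUE`, a classed error
#' `declm_acyclic_molecule` is raised).
#'
#' @param smiles Character vector (or data frame) of valid SMILES.
#' @param strict Error on acyclic molecules instead of returning `NA`.
#' @return A tibble `smiles, atom_scaffold, graph_scaffold` (canonical
#'   SMILES of the frameworks).
#' @export
murcko_scaffolds <- function(smiles, strict = FALSE) {
  smiles <- pull_smiles(smiles)
  sdf <- smiles_to_sdfset(smiles)
  atom <- vapply(seq_along(smiles), function(i) murcko_one(sdf[[i]], FALSE), character(1))
  graph <- vapply(seq_along(smiles), function(i) murcko_one(sdf[[i]], TRUE), character(1))
  if (strict && anyNA(atom)) {
    declm_abort(sprintf("Acyclic molecule(s) have no scaffold: %s",
                        paste(smiles[is.na(atom)], collapse = ", ")),
                "declm_acyclic_molecule")
  }
  tibble(smiles = smiles, atom_scaffold = atom, graph_scaffold = graph)
}

#' Scaffold novelty of a design set
#'
#' Percentage of designs whose atom (or graph) scaffold does not occur among
#' the reference scaffolds. Acyclic designs, which have no scaffold, are
#' excluded from the denominator.
#'
#' @param designs,reference Character vectors of valid SMILES.
#' @return A one-row tibble: `pct_new_atom`, `pct_new_graph`,
#'   `n_scored` (designs with a scaffold).
#' @export
scaffold_novelty <- function(designs, reference) {
  ds <- murcko_scaffolds(designs)
  rs <- murcko_scaffolds(reference)
  scored <- !is.na(ds$atom_scaffold)
  n <- sum(scored)
  if (n == 0L) return(tibble(pct_new_atom = NA_real_, pct_new_graph = NA_real_, n_scored = 0L))
  new_atom <- !(ds$atom_scaffold[scored] %in% stats::na.omit(rs$atom_scaffold))
  new_graph <- !(ds$graph_scaffold[scored] %in% stats::na.omit(rs$graph_scaffold))
  tibble(pct_new_atom = 100 * sum(new_atom) / n,
         pct_new_graph = 100 * sum(new_graph) / n,
         n_scored = n)
}

# ---- Frechet distance -----------------------------------------------------

#' Physicochemical descriptor features
#'
#' A fixed descriptor vector per molecule (atom, bond, ring, heteroatom and
#' aromaticity counts plus molecular weight), used as the default pluggable
#' featurizer for molecule-set embeddings. Values are internally comparable
#' across runs of this package but are not the ChemNet embedding, so
#' Frechet distances computed from them are not numerically comparable to
#' published Frechet ChemNet Distance values.
#'
#' @param smiles Character vector (or data frame) of valid SMILES.
#' @return A numeric matrix, one row per molecule.
#' @export
descriptor_features <- function(smiles) {
  smiles <- pull_smiles(smiles)
  sdf <- smiles_to_sdfset(smiles)
  feats <- t(vapply(seq_along(smiles), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    el <- gsub("_.*", "", rownames(ab))
    nb <- if (is.null(bb)) 0L else nrow(bb)
    arom <- sum(grepl("[cnosp]", strsplit(smiles[i], "")[[1]]))
    c(n_atoms = nrow(ab),
      n_bonds = nb,
      n_rings = nb - nrow(ab) + 1L,
      n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
      n_S = sum(el == "S"), n_hal = sum(el %in% c("F", "Cl", "Br", "I")),
      n_aromatic = arom,
      smiles_len = nchar(smiles[i]))
  }, numeric(10)))
  rownames(feats) <- smiles
  feats
}

#' Gaussian embedding summary of a molecule set
#'
#' Mean vector and covariance matrix of per-molecule feature vectors.
#'
#' @param x Feature matrix (rows = molecules), or SMILES to be featurized
#'   with [descriptor_features()].
#' @param featurizer Identifier recorded with the summary.
#' @return A `declm_embedding_summary`.
#' @export
embedding_summary <- function(x, featurizer = "descriptor") {
  if (!is.matrix(x)) x <- descriptor_features(x)
  if (nrow(x) < 2L) {
    declm_abort("Need at least two molecules to summarize.", "declm_invalid_argument")
  }
  structure(list(mean = colMeans(x), cov = stats::cov(x), n = nrow(x),
                 featurizer = featurizer),
            class = "declm_embedding_summary")
}

# symmetric PSD square root; tiny negative eigenvalues are clipped at 0
sqrtm_psd <- function(S, tol = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (any(e$values < -max(tol, tol * max(abs(e$values))))) {
    declm_abort("Covariance matrix is not positive semidefinite.",
                "declm_non_psd_covariance")
  }
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Frechet distance between two molecule-set embeddings
#'
#' Squared Frechet (Wasserstein-2) distance between the Gaussian summaries:
#' `d2 = |mu1 - mu2|^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})`. Symmetric, zero for
#' identical summaries; for 1-D Gaussians it reduces to
#' `(mu1 - mu2)^2 + (sd1 - sd2)^2`.
#'
#' @param s1,s2 `declm_embedding_summary` objects over the same featurizer.
#' @return The squared distance (nonnegative scalar).
#' @export
frechet_distance <- function(s1, s2) {
  stopifnot(inherits(s1, "declm_embedding_summary"),
            inherits(s2, "declm_embedding_summary"))
  if (length(s1$mean) != length(s2$mean) || !identical(s1$featurizer, s2$featurizer)) {
    declm_abort("Summaries use different featurizers or dimensions.",
                "declm_dimension_mismatch")
  }
  dmu <- s1$mean - s2$mean
  r1 <- sqrtm_psd(s1$cov)
  cross <- sqrtm_psd(r1 %*% s2$cov %*% r1)
  d2 <- sum(dmu^2) + sum(diag(s1$cov)) + sum(diag(s2$cov)) - 2 * sum(diag(cross))
  max(d2, 0)
}
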