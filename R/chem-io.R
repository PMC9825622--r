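# Reading, standardizing and filtering SMILES corpora.

#' Read a .smi file
#'
#' One SMILES per line with an optional tab-separated identifier; lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path Path to a `.smi` file (UTF-8).
#' @return A tibble with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    smiles = vapply(parts, `[[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                character(1))
  )
}

#' Write a .smi file
#'
#' @param data Data frame with a `smiles` (or `canonical_smiles`) column and
#'   optionally an `id` column.
#' @param path Output path.
#' @export
write_smi <- function(data, path) {
  smiles <- pull_smiles(data)
  id <- if (is.data.frame(data) && "id" %in% names(data)) data$id else NULL
  lines <- if (is.null(id)) smiles else {
    ifelse(is.na(id), smiles, paste0(smiles, "\t", id))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an activity table
#'
#' CSV with header `smiles,pIC50` (additional columns are kept).
#'
#' @param path CSV path.
#' @return A tibble with at least `smiles` and `pIC50` (numeric).
#' @export
read_activity <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("smiles", "pIC50") %in% names(x))) {
    declm_abort("Activity CSV must have columns `smiles` and `pIC50`.",
                "declm_invalid_argument")
  }
  x$pIC50 <- as.numeric(x$pIC50)
  as_tibble(x)
}

#' Standardize molecules
#'
#' Canonicalizes each SMILES with the chemistry backend, strips salts by
#' retaining the largest organic (carbon-containing) fragment, and
#' re-canonicalizes. Standardization is idempotent on its own output.
#'
#' @param data Data frame with a `smiles` column, or a character vector.
#' @param strict If `TRUE` (default), unparseable SMILES or inputs with no
#'   organic fragment raise a classed error (`declm_unparseable_smiles`,
#'   `declm_empty_after_stripping`). If `FALSE`, offending rows are dropped
#'   with a message.
#' @return A tibble with columns `raw_smiles`, `canonical_smiles`, plus any
#'   other input columns.
#' @export
standardize_molecules <- function(data, strict = TRUE) {
  if (!is.data.frame(data)) data <- tibble(smiles = as.character(data))
  raw <- pull_smiles(data)
  if (!length(raw)) {
    return(tibble(raw_smiles = character(0), canonical_smiles = character(0)))
  }
  if (any(is.na(raw) | !nzchar(raw))) {
    declm_abort("SMILES input must be non-empty text.", "declm_invalid_argument")
  }
  can <- canonicalize_smiles(raw)
  if (strict && anyNA(can)) {
    declm_abort(sprintf("Unparseable SMILES: %s",
                        paste(unique(raw[is.na(can)]), collapse = ", ")),
                "declm_unparseable_smiles")
  }
  frag <- largest_organic_fragment(can)
  stripped_away <- !is.na(can) & is.na(frag)
  if (strict && any(stripped_away)) {
    declm_abort(sprintf("No organic fragment remains after salt stripping: %s",
                        paste(unique(raw[stripped_away]), collapse = ", ")),
                "declm_empty_after_stripping")
  }
  # fragments of multi-component inputs are re-canonicalized
  multi <- !is.na(frag) & frag != can
  if (any(multi)) frag[multi] <- canonicalize_smiles(frag[multi])
  out <- data
  out$smiles <- NULL
  out <- tibble(raw_smiles = raw, canonical_smiles = frag, !!!out)
  dropped <- is.na(out$canonical_smiles)
  if (any(dropped)) {
    message(sprintf("Dropped %d unstandardizable molecule(s).", sum(dropped)))
    out <- out[!dropped, , drop = FALSE]
  }
  out
}

#' Filter a standardized corpus
#'
#' Retains molecules whose canonical SMILES has at most `max_len` characters
#' and removes exact-string duplicates (first occurrence kept, input order
#' preserved). Idempotent.
#'
#' @param data Data frame with a `canonical_smiles` column (as produced by
#'   [standardize_molecules()]).
#' @param max_len Maximum canonical SMILES length in characters (default 90).
#' @return The filtered tibble.
#' @export
filter_corpus <- function(data, max_len = 90) {
  stopifnot(is.data.frame(data), "canonical_smiles" %in% names(data))
  out <- data[nchar(data$canonical_smiles) <= max_len, , drop = FALSE]
  out <- out[!duplicated(out$canonical_smiles), , drop = FALSE]
  as_tibble(out)
}
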