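# OpenBabel-backed chemistry primitives.
#
# Canonicalization and validity go through the `obabel` command-line tool in
# batch mode: one process call per vector of SMILES, with `-e` so invalid
# entries are dropped (not fatal) and a per-line integer title so output lines
# can be realigned with the input. In-process conversions (ChemmineOB) are
# used where a parsed molecule object is needed (SDF, fingerprints).

ob_empty_options <- function() data.frame(names = character(0), args = character(0))

#' Canonicalize SMILES strings with OpenBabel
#'
#' Returns the toolkit-canonical SMILES for each input, or `NA` where the
#' input is not parseable. Vectorized; a single OpenBabel process is used per
#' call.
#'
#' @param x Character vector of SMILES strings.
#' @return Character vector of the same length; `NA` marks unparseable input.
#' @export
canonicalize_smiles <- function(x) {
  if (length(x) == 0L) return(character(0))
  stopifnot(is.character(x))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(trimws(x))
  if (!any(ok)) return(out)
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".smi")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste0(x[ok], "\t", which(ok)), infile)
  system2("obabel",
          c("-ismi", infile, "-ocan", "-O", outfile, "-e"),
          stdout = FALSE, stderr = FALSE)
  if (!file.exists(outfile)) return(out)
  lines <- readLines(outfile, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1L)
  idx <- suppressWarnings(as.integer(vapply(parts, function(p) {
    if (length(p) >= 2L) p[[2L]] else NA_character_
  }, character(1))))
  keep <- !is.na(idx) & nzchar(smi)
  out[idx[keep]] <- smi[keep]
  out
}

#' Test whether SMILES strings are parseable
#'
#' @param x Character vector of SMILES strings.
#' @return Logical vector: `TRUE` where the backend parses the string.
#' @export
is_valid_smiles <- function(x) {
  !is.na(canonicalize_smiles(x))
}

# Parse valid SMILES into a ChemmineR SDFset (2D coordinates generated).
# Inputs must already be known-valid; invalid entries error.
smiles_to_sdfset <- function(x) {
  stopifnot(is.character(x), length(x) > 0L)
  names(x) <- paste0("m", seq_along(x))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(x))
  if (length(sdf) != length(x)) {
    declm_abort("Some SMILES could not be parsed into molecules.",
                "declm_unparseable_smiles")
  }
  sdf
}

# Fragment bookkeeping for salt stripping: split a SMILES at top-level dots
# (dots never occur inside brackets) and count heavy atoms per fragment.
split_fragments <- function(smiles) {
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

fragment_atom_count <- function(frag) {
  toks <- gregexpr("\\[[^]]+\\]|Br|Cl|Si|Se|[BCNOPSFIbcnops]", frag, perl = TRUE)[[1]]
  if (identical(as.integer(toks[1]), -1L)) 0L else length(toks)
}

fragment_has_carbon <- function(frag) {
  grepl("C(?![ael-u])|c(?![dlnou])|\\[[0-9]*[Cc][Hh@+\\-0-9]*\\]", frag, perl = TRUE)
}

# Keep the largest organic (carbon-containing) fragment of each SMILES.
# Returns NA where no organic fragment remains.
largest_organic_fragment <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    frags <- split_fragments(s)
    if (length(frags) == 1L) {
      return(if (fragment_has_carbon(frags)) frags else NA_character_)
    }
    organic <- frags[vapply(frags, fragment_has_carbon, logical(1))]
    if (!length(organic)) return(NA_character_)
    sizes <- vapply(organic, fragment_atom_count, integer(1))
    organic[[which.max(sizes)]]
  }, character(1), USE.NAMES = FALSE)
}
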