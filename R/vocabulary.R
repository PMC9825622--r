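# Vocabulary and tokenization shared by the generative and ELECTRA models.
#
# Two tokenization schemes are supported:
#  * "token" (default): two-character element symbols (Cl, Br, Si, Se),
#    bracket atoms ([nH], [O-], ...) and ring-bond escapes (%NN) are single
#    tokens, so every sampled sequence detokenizes to a coherent atom stream;
#  * "char": strict character-level splitting.

token_pattern <- function(scheme = c("token", "char")) {
  scheme <- match.arg(scheme)
  if (scheme == "token") "\\[[^]]+\\]|Br|Cl|Si|Se|%[0-9]{2}|." else "."
}

split_tokens <- function(smiles, scheme = "token") {
  regmatches(smiles, gregexpr(token_pattern(scheme), smiles, perl = TRUE))
}

#' Build a SMILES vocabulary from a corpus
#'
#' Collects every symbol occurring in the corpus under the chosen
#' tokenization scheme and prepends the three special tokens. Special token
#' indices are fixed: pad = 1, start = 2, stop = 3; chemical tokens are
#' sorted and occupy indices 4 onward.
#'
#' @param smiles Character vector of (standardized) SMILES strings, or a data
#'   frame with a `canonical_smiles` or `smiles` column.
#' @param scheme Tokenization scheme, `"token"` or `"char"`.
#' @return An object of class `declm_vocab`.
#' @export
build_vocabulary <- function(smiles, scheme = c("token", "char")) {
  scheme <- match.arg(scheme)
  smiles <- pull_smiles(smiles)
  if (!length(smiles)) declm_abort("Cannot build a vocabulary from an empty corpus.",
                                   "declm_empty_corpus")
  toks <- unique(unlist(split_tokens(smiles, scheme)))
  toks <- sort(toks, method = "radix")
  vocab <- list(
    tokens = c("<pad>", "^", "$", toks),
    pad = 1L, start = 2L, stop = 3L,
    scheme = scheme
  )
  class(vocab) <- "declm_vocab"
  vocab
}

#' @export
print.declm_vocab <- function(x, ...) {
  cat(sprintf("<declm_vocab> %d tokens (%s scheme): pad=1 start=2 stop=3\n",
              length(x$tokens), x$scheme))
  cat("  chemical tokens:", paste(x$tokens[-(1:3)], collapse = " "), "\n")
  invisible(x)
}

#' @export
length.declm_vocab <- function(x) length(x$tokens)

vocab_size <- function(vocab) length(vocab$tokens)

chemical_indices <- function(vocab) seq.int(4L, length(vocab$tokens))

# grab a smiles column from tabular or vector input
pull_smiles <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("canonical_smiles", "smiles"), names(x))[1]
    if (is.na(col)) declm_abort("No `canonical_smiles` or `smiles` column found.",
                                "declm_invalid_argument")
    x[[col]]
  } else {
    as.character(x)
  }
}

#' Tokenize SMILES strings
#'
#' Maps each string to an integer index sequence framed by the start and stop
#' tokens. The inverse of [detokenize_smiles()].
#'
#' @param smiles Character vector.
#' @param vocab A `declm_vocab`.
#' @return A list of integer vectors.
#' @export
tokenize_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "declm_vocab"))
  pieces <- split_tokens(smiles, vocab$scheme)
  lapply(seq_along(pieces), function(i) {
    idx <- match(pieces[[i]], vocab$tokens)
    if (anyNA(idx)) {
      bad <- unique(pieces[[i]][is.na(idx)])
      declm_abort(sprintf("Unknown token(s) in \"%s\": %s", smiles[[i]],
                          paste(bad, collapse = " ")),
                  "declm_unknown_token")
    }
    c(vocab$start, idx, vocab$stop)
  })
}

#' Test whether SMILES are representable in a vocabulary
#'
#' @param smiles Character vector.
#' @param vocab A `declm_vocab`.
#' @return Logical vector: `TRUE` where every token of the string is in the
#'   vocabulary.
#' @export
tokenizable <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "declm_vocab"))
  pieces <- split_tokens(smiles, vocab$scheme)
  vapply(pieces, function(p) !anyNA(match(p, vocab$tokens)), logical(1))
}

#' Detokenize index sequences back to SMILES
#'
#' @param tokens A list of integer vectors (or a single integer vector).
#' @param vocab A `declm_vocab`.
#' @return Character vector of SMILES payloads (specials removed).
#' @export
detokenize_smiles <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "declm_vocab"))
  if (is.numeric(tokens)) tokens <- list(as.integer(tokens))
  vapply(tokens, function(idx) {
    if (any(idx < 1L | idx > length(vocab$tokens))) {
      declm_abort("Token index outside the vocabulary.", "declm_unknown_token")
    }
    idx <- idx[!(idx %in% c(vocab$pad, vocab$start, vocab$stop))]
    paste(vocab$tokens[idx], collapse = "")
  }, character(1))
}

#' Write a vocabulary to JSON
#'
#' Serializes the token list in index order plus the special-token indices.
#'
#' @param vocab A `declm_vocab`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "declm_vocab"))
  jsonlite::write_json(
    list(tokens = vocab$tokens,
         special = list(pad = vocab$pad, start = vocab$start, stop = vocab$stop),
         scheme = vocab$scheme),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#'
#' @param path File path written by [write_vocabulary()].
#' @return A `declm_vocab`.
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- list(tokens = x$tokens, pad = as.integer(x$special$pad),
                start = as.integer(x$special$start), stop = as.integer(x$special$stop),
                scheme = x$scheme %||% "token")
  class(vocab) <- "declm_vocab"
  vocab
}
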