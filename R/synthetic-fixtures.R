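# Synthetic corpora with known structure: every other module is testable
# without downloads. Molecules are built by decorating curated ring-system
# templates with substituent fragments, so validity is guaranteed by
# construction and scaffold membership is known ground truth.

# each template is a character vector; "R" elements are substitution slots
# filled with "" or "(<fragment>)"
fixture_templates <- function() {
  list(
    benzene      = c("c1cc", "R", "cc", "R", "c1"),
    pyridine     = c("c1cc", "R", "cnc1"),
    pyrimidine   = c("c1cc", "R", "ncn1"),
    thiophene    = c("c1cc", "R", "cs1"),
    cyclohexane  = c("C1CC", "R", "CCC1"),
    piperidine   = c("C1CC", "R", "CNC1"),
    indole       = c("c1ccc2[nH]cc", "R", "c2c1"),
    quinoline    = c("c1ccc2ncc", "R", "cc2c1")
  )
}

fixture_substituents <- function() {
  # composed as (optional linker)(terminal group) plus ring substituents,
  # all valid as parenthesized branches attached to a ring atom; ring
  # closures inside substituents use digit 3 to avoid template collisions
  linkers <- c("", "C", "CC", "CCC", "O", "OC")
  terminals <- c("C", "CC", "C(C)C", "CO", "CCO", "N", "N(C)C", "NC",
                 "F", "Cl", "Br", "C#N", "C(=O)N", "C(=O)OC", "CC(=O)N",
                 "C(F)(F)F", "OC(C)C")
  rings <- c("c3ccccc3", "Cc3ccccc3", "C3CCCCC3", "c3ccncc3", "CC3CCNCC3")
  unique(c(as.vector(outer(linkers, terminals, paste0)), rings))
}

#' Specification of a synthetic study fixture
#'
#' Defines the generator for a pretraining corpus (valid, standardized,
#' deduplicated SMILES of bounded length built from a scaffold pool) and a
#' labeled activity set in which a planted pharmacophore substructure
#' drives activity: `pIC50 = base + effect * carrier + N(0, sigma)`. The
#' defaults emulate the shape of the study data: a 198-molecule activity
#' set whose carrier fraction and class cuts (4.0 / 6.5) reproduce
#' approximately the 34 : 121 : 43 inactive / moderately active / highly
#' active split.
#'
#' @param n_pretrain Pretraining corpus size (default 2000).
#' @param n_finetune Activity set size (default 198).
#' @param base Baseline pIC50 of non-carriers (default 4.2).
#' @param effect Activity shift of pharmacophore carriers in log units
#'   (default 3.0).
#' @param sigma Gaussian noise on pIC50, log units (default 0.3).
#' @param carrier_frac Fraction of activity-set molecules carrying the
#'   pharmacophore (default 43/198).
#' @param pharmacophore Substituent fragment planted in carriers (default a
#'   sulfonamide).
#' @param max_len Maximum SMILES length (characters; default 90).
#' @param seed Generator seed.
#' @return A `declm_fixture_spec` list.
#' @export
fixture_spec <- function(n_pretrain = 2000L, n_finetune = 198L, base = 4.2,
                         effect = 3.0, sigma = 0.3, carrier_frac = 43 / 198,
                         pharmacophore = "S(=O)(=O)N", max_len = 90L,
                         seed = 42L) {
  structure(list(n_pretrain = as.integer(n_pretrain),
                 n_finetune = as.integer(n_finetune),
                 base = base, effect = effect, sigma = sigma,
                 carrier_frac = carrier_frac, pharmacophore = pharmacophore,
                 max_len = as.integer(max_len), seed = as.integer(seed),
                 templates = fixture_templates(),
                 substituents = fixture_substituents()),
            class = "declm_fixture_spec")
}

# decorate one template: slots filled independently with probability p_fill
decorate <- function(template, substituents, p_fill = 0.7, force = NULL) {
  slots <- which(template == "R")
  out <- template
  out[slots] <- ""
  fill <- slots[runif(length(slots)) < p_fill]
  for (s in fill) out[s] <- paste0("(", substituents[sample.int(length(substituents), 1L)], ")")
  if (!is.null(force)) {
    s <- slots[sample.int(length(slots), 1L)]
    out[s] <- paste0("(", force, ")")
  }
  paste(out, collapse = "")
}

#' Generate the synthetic pretraining corpus
#'
#' Emits `n_pretrain` valid, standardized, deduplicated SMILES built by
#' decorating the scaffold pool; deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return A tibble with a `canonical_smiles` column.
#' @export
make_pretrain_corpus <- function(spec) {
  stopifnot(inherits(spec, "declm_fixture_spec"))
  withr::with_seed(spec$seed, {
    seen <- character(0)
    rounds <- 0L
    while (length(seen) < spec$n_pretrain && rounds < 60L) {
      rounds <- rounds + 1L
      raw <- vapply(seq_len(max(2L * (spec$n_pretrain - length(seen)), 64L)),
                    function(i) {
                      tpl <- spec$templates[[sample.int(length(spec$templates), 1L)]]
                      # the pharmacophore occurs at low frequency in the
                      # pretraining chemistry so its tokens are in-vocabulary
                      force <- if (runif(1) < 0.05) spec$pharmacophore else NULL
                      decorate(tpl, spec$substituents, force = force)
                    }, character(1))
      can <- canonicalize_smiles(raw)
      can <- can[!is.na(can) & nchar(can) <= spec$max_len]
      seen <- unique(c(seen, can))
    }
    if (length(seen) < spec$n_pretrain) {
      warn(sprintf("Template space exhausted: %d of %d requested molecules.",
                   length(seen), spec$n_pretrain))
    }
    tibble(canonical_smiles = seen[seq_len(min(spec$n_pretrain, length(seen)))])
  })
}

#' Generate the synthetic labeled activity set
#'
#' A `carrier_frac` fraction of molecules carry the planted pharmacophore;
#' `pIC50 = base + effect * carrier + N(0, sigma)`. With the default
#' settings all three activity classes are represented, in proportions
#' approximating 34 : 121 : 43.
#'
#' @param spec A [fixture_spec()].
#' @return A tibble `canonical_smiles, carrier, pIC50, activity_class`.
#' @export
make_activity_set <- function(spec) {
  stopifnot(inherits(spec, "declm_fixture_spec"))
  withr::with_seed(derive_seed(spec$seed, 2L), {
    n <- spec$n_finetune
    n_car <- round(spec$carrier_frac * n)
    draw_set <- function(target, force) {
      seen <- character(0)
      rounds <- 0L
      while (length(seen) < target && rounds < 60L) {
        rounds <- rounds + 1L
        raw <- vapply(seq_len(max(2L * (target - length(seen)), 32L)), function(i) {
          tpl <- spec$templates[[sample.int(length(spec$templates), 1L)]]
          decorate(tpl, spec$substituents, force = force)
        }, character(1))
        can <- canonicalize_smiles(raw)
        can <- can[!is.na(can) & nchar(can) <= spec$max_len]
        seen <- unique(c(seen, can))
      }
      seen[seq_len(min(target, length(seen)))]
    }
    carriers <- draw_set(n_car, spec$pharmacophore)
    plain <- setdiff(draw_set(n - n_car + n_car, NULL), carriers)[seq_len(n - n_car)]
    out <- tibble(
      canonical_smiles = c(carriers, plain),
      carrier = rep(c(TRUE, FALSE), c(length(carriers), length(plain))))
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    out$pIC50 <- spec$base + spec$effect * out$carrier + rnorm(nrow(out), 0, spec$sigma)
    out$activity_class <- assign_activity_class(out$pIC50)
    out
  })
}
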