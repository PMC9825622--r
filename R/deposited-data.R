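# Checks against the deposited study data (when available locally).

#' Summarize a deposited pretraining corpus and activity set
#'
#' For a locally available copy of the study's deposited data (a pretraining
#' corpus as `.smi` and a PI3K-gamma activity table as CSV), reports the
#' number of unique canonical SMILES in the corpus and the activity-class
#' counts at the 4.0 / 6.5 pIC50 cuts. The deposited corpus is expected to
#' contain 839,674 unique molecules and the 198-compound activity set to
#' split 34 / 121 / 43.
#'
#' @param corpus_smi Path to the deposited pretraining `.smi` file.
#' @param activity_csv Path to the deposited activity CSV (`smiles,pIC50`).
#' @return A list with `n_unique_corpus` and `class_counts` (named integer
#'   vector over the three activity classes).
#' @export
verify_deposited_data <- function(corpus_smi, activity_csv) {
  if (!file.exists(corpus_smi) || !file.exists(activity_csv)) {
    declm_abort("Deposited data files not found locally.",
                "declm_missing_deposited_data")
  }
  corpus <- read_smi(corpus_smi)
  act <- read_activity(activity_csv)
  cls <- assign_activity_class(act$pIC50)
  list(n_unique_corpus = length(unique(corpus$smiles)),
       n_activity = nrow(act),
       class_counts = table(cls))
}
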