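---
title: "Methods: hybrid chemical language models for activity-focused design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid chemical language models for activity-focused design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, the numerical
choices, what the synthetic data generator does and does not emulate, and
the known limitations.

## The design problem

De novo design with chemical language models treats a molecule as a SMILES
string and a design campaign as three steps: (i) pretrain a generative
sequence model on a large, general corpus so it learns SMILES grammar and
broad chemistry; (ii) fine-tune it on a small set of ligands of one target
so sampling concentrates on that chemical space; (iii) sample new strings.
Because bioactivity labels exist for the fine-tuning ligands, a second
model can score the generated library: `declm` implements that scorer as an
ordinal classifier on the same recurrent backbone, pretrained with a
replaced-token (ELECTRA) objective and deployed as a deep voting ensemble.

## Generative model

The network consumes one-hot token vectors of width `V`:

* input feature normalization (`4V` parameters: gain, bias, moving
  mean/variance),
* LSTM block of `h1` cells (`4·h1·(V+h1+1)`),
* LSTM block of `h2` cells (`4·h2·(h1+h2+1)`),
* feature normalization (`4·h2`),
* per-step dense projection to `V` with softmax (`(h2+1)·V`).

The production widths are `h1 = 1024`, `h2 = 256`; the dense projection is
required for the model to emit a distribution over the vocabulary, and with
it the closed-form total reconciles the published count exactly at
`V = 71` (5,820,515) — `count_parameters()` and `model_parameter_count()`
assert this against the instantiated network, counting normalization
moving statistics the way deep-learning frameworks report totals.

Training is autoregressive next-token prediction with categorical
cross-entropy and Adam (learning rate 1e-3, 40 epochs at production scale).
Transfer learning continues at 1e-4 with the **first recurrent block
frozen**. The source text describes freezing "the first network layer"; we
read that as the first LSTM block because freezing the parameter-poor
input-normalization layer would make the statement vacuous. Normalization
layers run in inference mode during fine-tuning (and whenever a
normalization block is listed as frozen, its moving statistics are left
untouched — the freeze contract is bit-identity, and the tests assert it).

## Sampling policies

*Temperature sampling* rescales logits: `q_i = exp(z_i/T) / Σ_j exp(z_j/T)`;
`T = 1` is the plain softmax, smaller `T` sharpens. *Nucleus sampling*
(`p ∈ [0,1)`) keeps the minimal set of highest-probability tokens whose
cumulative probability **strictly exceeds** `p` and samples inside it at
`T = 1` after renormalization. Ties in probability are broken by ascending
token index so the top vocabulary is deterministic; `p = 0` reduces to
greedy argmax decoding. Generation extends from the start token until the
stop token or `max_len` (default 100 tokens: the training corpus is capped
at 90 characters, with headroom for the specials); truncated strings are
flagged. With `trace = TRUE` the per-step top vocabulary and the chosen
token are recorded so a seeded audit can verify no token was ever sampled
outside its step's nucleus.

## Tokenization

The default scheme is token-level: two-character element symbols (`Cl`,
`Br`, `Si`, `Se`), bracket atoms (`[nH]`, `[O-]`, …) and ring-bond escapes
(`%NN`) are single tokens, which guarantees every sampled sequence
detokenizes to a coherent atom stream. A strict character-level scheme is
available (`scheme = "char"`). Specials have fixed indices: pad 1, start 2,
stop 3. Both readings are consistent with a 71-symbol vocabulary on the
original corpus; token-level is the default because it can never emit half
a chlorine.

## Standardization and corpus filtering

SMILES are canonicalized with the OpenBabel backend; salt stripping keeps
the largest carbon-containing fragment and re-canonicalizes, so
standardization is idempotent. The length filter (≤ 90 characters) is
applied to the canonical string — the model only ever sees canonical
strings — and duplicate removal is exact string equality on canonical
SMILES, which deliberately keeps stereoisomers as distinct records.
Validity of generated strings likewise means "the backend parses it".

## ELECTRA pretraining

Each non-special position of a tokenized string is independently
substituted with probability `rate` (default 0.15); a substitution draws
uniformly from the chemical tokens excluding the original, so labels
(1 = substituted) coincide exactly with positions that differ. There is no
generator network — substitutions are uniform random, matching the random
character replacement described for the original pipeline. A fresh
corruption is drawn every epoch from a per-epoch derived seed, preventing
the discriminator from memorizing one mask. The per-position sigmoid head
is trained with binary cross-entropy (Adam, 1e-3, 50 epochs at production
scale). Bernoulli corruption (rather than a fixed count) handles short
strings without special cases; the original corruption rate is not stated,
and 0.15 follows the replaced-token-detection literature.

## Ordinal classification and the voting ensemble

Activity classes partition pIC50 with boundary values in the lower class:
inactive (≤ 4.0), moderately active (4.0, 6.5], highly active (> 6.5).
Targets use cumulative (Frank–Hall) coding — (1,0,0), (1,1,0), (1,1,1) —
because the class order is the point of the ordinal framing; a literal
one-neuron-per-class mode is available behind `encoding = "one_hot"`, with
"highly active iff the third sigmoid clears the threshold". The decision
rule scans the outputs left to right and counts leading outputs strictly
above the threshold (default 0.4), flooring at inactive; it is monotone by
construction.

Class imbalance is handled by oversampling: the two smallest classes each
gain `add` (default 40) records drawn uniformly with replacement from
themselves; size ties resolve toward the lower ordinal class. Similarity
folds come from k-means (k = 5) on Morgan fingerprints (Euclidean on 0/1
coordinates, equivalent to Hamming up to a monotone transform), with a
configurable held-out test cluster — the original choice of held-out group
is not documented, so the index is a parameter (default: the last
cluster).

Ensemble members differ only in their seed (initialization, shuffling,
dropout, oversampling draws), the "nondeterministic optimization" source
of diversity; votes count members deciding highly active, and the number
of molecules retained is non-increasing in the confidence level by
construction.

For the directional comparison of pretraining schemes the package uses a
stratified 75/25 split (both extreme classes must appear in the test set)
and compares false positive rates at a matched true positive rate via a
score-threshold sweep on the ensemble's mean highly-active output. The
cluster-based split exists for hyperparameter selection; the stratified
split is the right tool for a matched-TPR operating-point comparison on
a 198-record set.

## Library analytics

*Fingerprints.* Morgan-style circular fingerprints are computed as
OpenBabel ECFP of diameter `2·radius` (radius 2 by default) and folded
from 4096 to `n_bits` (default 2048) by modular OR — the parameters the
field treats as default; they are configurable. Tanimoto similarity of two
all-zero fingerprints is defined as 1.

*Scaffolds.* Bemis–Murcko decomposition prunes terminal atoms iteratively
(pure topology) to rings plus linkers, then re-attaches atoms joined to
the framework by a double or triple bond (exocyclic carbonyls and the
like); the graph scaffold additionally sets every atom to carbon and every
bond to single before re-canonicalization. Acyclic molecules have no
scaffold and are excluded from scaffold-novelty denominators — counting
"no scaffold" as "new scaffold" would inflate novelty.

*Fréchet distance.* `d² = |μ1−μ2|² + Tr(Σ1 + Σ2 − 2(Σ1Σ2)^{1/2})` over
Gaussian summaries of per-molecule feature vectors. The matrix square root
uses a symmetric eigendecomposition with negative eigenvalues clipped at
zero (tolerance 1e-10), the standard stabilization. The default featurizer
is a fixed physicochemical descriptor vector (atom/bond/ring/heteroatom/
aromaticity counts, string length): values are internally comparable
across runs of this package but are **not** comparable to published
Fréchet ChemNet Distance numbers, which depend on a specific pretrained
ChemNet embedding this package does not ship.

## Virtual screening

Per query, library molecules are ranked by Tanimoto similarity (rank 1 =
most similar; dense, deterministic, library-order tie-break — the fused
score is sensitive to rank integers, so ties must be resolved
reproducibly). Scores fuse by reciprocal rank summation `S = Σ_i
1/rank(x_i)`; `S` is invariant under query permutation, strictly improved
by improving any single rank, and maximal (`S = N`) for a molecule ranked
first by every query.

## Dose–response fitting

The binding model is `Response = Background + (Signal − Background)/(1 +
Dose/Kd)` with the Hill slope fixed at −1 (so `Kd^s/Dose^s = Dose/Kd`).
Fitting is unweighted nonlinear least squares with the
Levenberg–Marquardt algorithm (`minpack.lm::nlsLM`), doses in molar units
internally (the CLI accepts nM). Starting values are the standard robust
choice: background = min(response), signal = max(response), Kd = the dose
nearest the half-range crossing. Constant responses are rejected as
unidentifiable. The simulator mirrors an 11-point three-fold serial
dilution; its noise model is multiplicative — each response is scaled by
`1 + N(0, noise)` — the usual heteroscedastic behavior of assay signals,
under which 5% noise leaves the median relative Kd error below 10% on the
11-point design.

## Synthetic data generator

Fixtures are built by decorating a curated pool of eight ring-system
templates (benzene, pyridine, pyrimidine, thiophene, cyclohexane,
piperidine, indole, quinoline) with composed substituent fragments, so
every emitted string is valid by construction, already canonical,
deduplicated, and ≤ 90 characters; scaffold membership is known ground
truth. The activity set plants a pharmacophore (a sulfonamide) in a
fraction of molecules and sets `pIC50 = base + effect·carrier + N(0, σ)`
with defaults base 4.2, effect 3.0, σ 0.3, carrier fraction 43/198: with
the 4.0/6.5 cuts this reproduces approximately the 34:121:43 class shape
of the original 198-ligand set (the realized split at the default seed is
35/120/43). σ = 0.3 log units keeps class boundaries crisp but
non-trivial.

What the generator does **not** emulate: the property distributions of a
patent-derived corpus, activity cliffs, assay noise structure, or any
target-specific pharmacology. Tests passing on these fixtures demonstrate
that the algorithms are implemented correctly and that the training
machinery can extract a planted substructure signal — not that the models
reach publication-scale performance on real chemistry.

## Numerical choices

* Weight initialization: uniform Glorot-style ranges per block; LSTM
  forget-gate bias starts at 1.
* Optimizer: Adam (β1 0.9, β2 0.999, ε 1e-8); gradients are exact
  backpropagation through time, verified against finite differences in the
  test suite.
* Feature normalization: batch statistics over non-padding positions;
  moving statistics with momentum 0.9 (rather than the common 0.99) so
  that inference-mode statistics are usable after the short training runs
  the package targets; ε 1e-5.
* Padding: sequences are padded to the batch maximum; losses are masked to
  real positions, and the ordinal head reads the state at each sequence's
  stop token.
* Seeds: every entry point takes a seed; internal per-epoch/per-member
  seeds are derived deterministically and kept below 2^31.

## Desk-scale problem sizes

The test suite and the small pipeline preset run with 2,000-molecule
corpora, 64/16- or 32/8-cell networks (keeping the 4:1 width ratio of the
1024/256 production architecture), single-digit pretraining epochs,
ensembles of 3–5 members, and libraries of a few hundred molecules. These
sizes were chosen so the full suite completes comfortably on one CPU while
still exercising every code path end to end; production-shaped settings
remain available through `pipeline_config(preset = "production")`.

## Known limitations

* Canonical SMILES, validity and scaffold strings come from OpenBabel;
  other toolkits' canonical dialects differ, so cross-toolkit comparisons
  must go through a common canonicalizer (the tests do).
* OpenBabel is permissive about valence, so "validity" is a grammar check
  more than a chemistry check.
* Fingerprints ignore stereochemistry; two stereoisomers share a
  fingerprint (and a similarity of 1).
* The Fréchet distance is embedding-relative (see above).
* The from-scratch LSTM engine favors clarity and exactness over speed; it
  is sized for desk-scale experiments, not for the 839,674-molecule
  production corpus, although nothing but time prevents that run.
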