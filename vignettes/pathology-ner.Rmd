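---
title: "Extracting diagnostic entities from breast pathology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting diagnostic entities from breast pathology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task

A breast pathology report is free text, but most of its diagnostic value is
carried by a handful of short phrases: the *cancer subtype* ("invasive
ductal carcinoma", "ductal carcinoma in situ"), the *cancer grade* ("high
nuclear grade", "poorly differentiated") and the *lesion position* ("upper
outer quadrant", "10 o'clock 2 cm from the nipple"). pathner frames the
extraction as named entity recognition: given a word sequence
$x = x_1,\dots,x_m$, predict a list of tuples $(I_s, I_e, c)$ — start
index, end index and category $c \in \{$subtype, grade, position$\}$.

Span annotations are translated to per-word labels in the IO scheme: words
inside an entity get `I-<category>`, everything else gets `O`. The scheme
cannot represent a boundary between two adjacent same-category entities, so
such spans are merged (with a warning) at encoding time; decoding returns
maximal same-label runs. This lossiness is inherent to IO tagging and shows
up in the codec round-trip property the tests check.

Report classification is a derived task: a report is *cancer-positive* iff
it contains a non-negated cancer-positive finding (the bundled list covers
the primary breast cancers, DCIS, and lymphoma; lobular carcinoma in situ
is a high-risk benign finding and deliberately absent). How NER output
becomes a report label is not uniquely determined; pathner uses a
normalized token-subset match between predicted subtype spans and the
positive-findings lexicon, and exposes the lexicon as configuration.

## The tagger

The model is a token classifier over the 4-label IO alphabet. Words are
split into subwords; an encoder produces a hidden vector $h_i \in
\mathbb{R}^H$ per subword; a linear head $W \in \mathbb{R}^{|C| \times H}$
produces scores $z_i = W h_i$, turned into probabilities by a softmax. Only
the *first* subword of each word is supervised: continuation subwords and
padding carry an ignore marker and contribute nothing to the token-level
cross-entropy loss (mean over supervised positions). Prediction takes the
argmax of each word's first-subtoken probability row; entities are the
maximal runs of the predicted labels.

Two encoder backends ship with the package, both written in base R with
hand-derived backprop (verified against finite differences in the test
suite) and trained with Adam:

* a **small transformer** (default): learned token + position embeddings,
  pre-norm single-head self-attention and a feed-forward block, H = 48 and
  one layer by default;
* a **bidirectional LSTM**, which doubles as the classical recurrent
  baseline; word embeddings are learned from scratch.

There is no dependency on a pre-trained language model: the subword
vocabulary is built from the training corpus (one id per known word) with a
deterministic character-bigram hash fallback for unseen words, so
misspellings and dialect short forms still receive a stable encoding.
A clinically pre-trained encoder would raise absolute numbers, but every
contract here — supervision masking, windowing, decoding, augmentation —
is encoder-agnostic.

Sequences longer than the 128-subword window are split into word-aligned
windows overlapping by 16 words; at prediction time each word is scored by
the window in which it sits most centrally. This avoids silently truncating
long reports.

Early stopping keeps the checkpoint with the lowest validation loss
(patience 5 epochs by default, 50 epochs maximum). Training is
bit-reproducible given the config seed: initialisation, batch order and
augmentation all draw from one seeded stream.

### Learning rates

The configuration selected on the original corpora — batch size 8,
learning rate 6e-5, all four augmentation operators at p = 0.1 — is a
*fine-tuning* setting for a pre-trained encoder. Under that learning rate a
randomly initialised small encoder needs a few thousand Adam steps to
converge, so experiments that pin lr = 6e-5 should let early stopping, not
the epoch cap, end training (the learnability experiment below uses
`max_epochs = 200`, `patience = 8`, and typically stops near epoch 90–140).
When the configuration is free, from-scratch training uses the package
default lr = 1e-3, which converges in roughly ten epochs on the benchmark
corpora.

## Data augmentation

Four operators generate label-consistent variants of a training sequence,
applied in the fixed order MR, SR, LwTR, SiS:

* **Mention replacement (MR)**: each entity segment may be replaced by
  another same-category mention drawn (with multiplicity, so frequent
  mentions are favoured) from the training corpus;
* **Synonym replacement (SR)**: each word may be replaced by a synonym; a
  bundled pathology-domain lexicon is the default so no external lexical
  database is needed;
* **Label-wise token replacement (LwTR)**: each token may be replaced by a
  training-corpus token carrying the same IO label;
* **Shuffle within segments (SiS)**: tokens are permuted inside maximal
  same-label runs, including `O` runs (an entity-only mode is available).

Randomness is two-level: an instance-level Bernoulli gate with the policy's
p decides whether an operator applies to a given training instance at all;
once gated on, MR and SiS act per segment and SR and LwTR per token with an
internal rate that defaults to the same p. The instance gate is stated
behaviour of the method being reproduced; the within-instance rate is not
uniquely pinned down by its description, so it is a separate, configurable
knob. Both levels and the operator internals consume one shared seeded
stream, making augmented corpora bit-reproducible.

With a policy configured, `train_tagger()` re-augments every training
instance with fresh draws each epoch, maximising the diversity the method
aims for; validation and test corpora are never augmented. The augmented
text is often ungrammatical — that is the point: entity surface forms
become unreliable during training, pushing the model towards contextual
cues, which is what transfers across report dialects.

## The synthetic corpus generator

The corpora the method was developed on are private, so pathner ships a
seeded generator of annotated synthetic reports and treats it as a
first-class, tested module. Reports are assembled from data-file grammars
(subtype/grade/position lexicons, finding templates, negation templates,
filler lines, per-dialect headers), so every entity span is known exactly
at emission. The generator emulates the phenomena that make real reports
hard:

* **Negation**: a subtype mention may be embedded in a negation template
  ("fall short of the criteria for <subtype>", "no evidence of
  <subtype>"); its tokens are labelled `O`, which matches how negated
  mentions are annotated in the emulated corpora and makes negation a
  learnable context signal.
* **Misspellings**: per-word 1-edit corruptions ("caricinoma") at a
  configurable rate.
* **Dialect shift**: the external dialect prefers abbreviations ("uoq",
  "dcis", "10/2 cm" for "10 o'clock 2 cm"), different headers and more
  frequent negation.
* **Grade-inside-subtype collisions** ("invasive poorly differentiated
  carcinoma, high nuclear grade") at a low rate, labelled per the outer
  span.

Default rates mirror the emulated corpora where those are documented:
entity frequencies of roughly 1.08 subtype / 0.71 grade / 0.74 position
mentions per report, and benchmark split sizes of 968 / 276 / 194 / 55
reports (train / validation / internal test / external test). Where no
value is documented the defaults are one-time choices of plausible report
statistics: negation 0.12, misspelling 0.02, abbreviation 0.05 internally;
the external test set raises negation to 0.25, misspelling to 0.05 and
abbreviation to 0.55; cancer prevalence 0.6; clock-face notation for 30%
of positions. Grades attach only to cancer findings — benign lesions are
not graded — so the realized grade-span rate also depends on prevalence
and negation.

What the generator does *not* emulate: real layout and section structure,
institution-specific boilerplate, PHI-like headers, the long tail of rare
diagnoses, and genuinely free prose. Passing tests on this corpus
therefore demonstrate that the pipeline's contracts hold and that relative
comparisons (augmented vs not, internal vs shifted) behave as the method
predicts — not that any absolute score would transfer to real reports.

## Evaluation

Three protocols, mirroring increasing difficulty:

* **Report classification**: binary precision/recall/F1 on the derived
  cancer-positive flag.
* **Word classification**: pooled per-token precision/recall/F1 per entity
  class; `other` is excluded from averages.
* **Entity recognition**: exact match — a predicted span counts only if
  its start, end and category all equal a gold span's. Precision is over
  predicted spans, recall over gold spans.

"Weighted" metrics are support-weighted averages (true token counts at word
level, true entity counts at entity level) — the only reading of a
weighted sum of per-class scores that stays in [0, 1]. Zero denominators
yield 0 by convention; classes absent from both truth and prediction are
reported with support 0 and excluded from weighting. Word-level F1 is *not*
asserted to dominate entity-level F1 — it is not a theorem — both are
simply reported.

## Numerical and design notes

* Word spans are 0-based half-open, as are character offsets; converters at
  the file boundary handle 1-based dialects if needed.
* Tokenization lowercases and splits punctuation into single-character
  tokens; offsets always index the original text. The exact pre-subword
  tokenization rule of the emulated system is unrecoverable, so this rule
  is the package's own and is used consistently everywhere.
* Overlapping or nested spans are rejected as invalid annotation; the NER
  formulation being reproduced implies non-overlap.
* MR may draw a mention equal to the one it replaces — it is a draw from
  the inventory with multiplicity.
* Probability rows are validated to sum to 1 within 1e-6; layer norm uses
  eps 1e-5; Adam uses the standard (0.9, 0.999, 1e-8) defaults, as the
  optimiser's description leaves them unstated.
* Class imbalance is left alone (no loss re-weighting), matching the
  training description being reproduced.
* The acceptance experiments scale problem sizes to desk hardware: the
  learnability check trains on 400 synthetic reports, and the
  augmentation-robustness comparison uses the full 968/276/194/55 benchmark
  with 5 seeds per arm and a 20-epoch budget at lr 1e-3. These sizes are
  the package's own experimental design choices.

## Known limitations

* The bundled encoders are small and randomly initialised; absolute scores
  on real clinical text would require plugging in a pre-trained clinical
  encoder behind the same contracts.
* The WordNet-backed synonym source is replaced by a bundled domain
  lexicon; SR's diversity is correspondingly narrower.
* The rule-based baseline is negation-blind by design, reproducing the
  documented behaviour of such systems.
* IO tagging cannot separate adjacent same-category entities; a BIO codec
  would, but is out of scope because the emulated annotation scheme is IO.
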