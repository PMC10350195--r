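# pathner

Named entity recognition for breast pathology reports, with data
augmentation for robustness.

Pathology reports carry the diagnostic ground truth of cancer research,
but the information sits in free text. Framing extraction as report
classification loses the fine structure — which finding has which grade,
at which position — so pathner frames it as NER: given the word sequence
`x = x1 … xm` of a report, predict tuples `(Is, Ie, c)` with
`c ∈ {cancer_subtype, cancer_grade, lesion_position}`. Annotations use the
IO scheme (`I-<category>` inside entities, `O` elsewhere); a trainable
sequence tagger (subword encoder + linear softmax head, first-subtoken
supervision, masked cross-entropy) predicts per-word labels that decode
into entities. Report-level cancer status falls out of the entities via a
positive-findings lexicon.

Because real training corpora of this kind are rarely shareable, small
training sets are the norm, and taggers overfit surface forms. The package
implements the four sequence-labelling augmentation operators — mention
replacement (MR), synonym replacement (SR), label-wise token replacement
(LwTR), shuffle within segments (SiS) — composed in that fixed order under
a Bernoulli-gated policy, plus rule-based (wildcard string matching) and
TF-IDF + XGBoost baselines, three-tier evaluation (report / word / entity
level, exact-match entities, support-weighted averages), and a seeded
generator of annotated synthetic reports with a controllable
internal/external dialect shift for benchmarking all of it end to end.

For whom: anyone building or studying clinical information extraction who
needs a fully inspectable, dependency-light NER pipeline — the encoders
(small transformer, BiLSTM) are implemented in base R with hand-derived
gradients, so there is nothing to download and every contract is testable.

## Worked example

```r
library(pathner)

# a synthetic annotated corpus with dialect shift
bm <- make_shift_benchmark(n = c(train = 300, val = 60,
                                 test_internal = 60, test_external = 60),
                           seed = 1)

# train with the four-operator augmentation policy at p = 0.1
cfg <- train_config(batch_size = 8, learning_rate = 1e-3,
                    max_epochs = 15, policy = augmentation_policy(0.1),
                    seed = 7)
m <- train_tagger(bm$train, bm$val, cfg)

r <- bm$test_internal[[1]]
predict_entities(m, r)
evaluate_system(m, bm$test_internal)
```

The prediction call returns the entity spans of one report —

```
  start end       category
1     6   7 cancer_subtype
```

word indices (0-based, half-open) into the tokenized report (here the
single token "fibroadenoma") — and `evaluate_system()` prints per-class
and support-weighted precision/recall/F1 at word and entity level plus
report-level binary metrics:

```
<ner_eval> on 60 reports

Word classification:
        category precision recall    f1 support
  cancer_subtype     1.000  0.942 0.970     137
    cancer_grade     0.891  0.980 0.933      50
 lesion_position     0.967  0.979 0.973     236
    weighted_avg     0.968  0.967 0.967     423

Entity recognition (exact match):
        category precision recall    f1 support
  cancer_subtype     0.871  0.900 0.885      60
    cancer_grade     0.760  0.950 0.844      20
 lesion_position     0.755  0.851 0.800      47
    weighted_avg     0.810  0.890 0.847     127

Report classification:
precision    recall        f1  accuracy 
    1.000     0.967     0.983     0.983
```

Entity-level scores trail word-level ones because an entity counts as
correct only if start, end and category all match a gold span exactly. On the external (dialect-shifted) test set the same model
scores lower — and the gap between an augmented and an unaugmented model
is the package's headline experiment.

A thin CLI over the same functions lives in `inst/cli/pathner`
(`generate`, `augment`, `train`, `predict`, `evaluate`, `baseline`
subcommands).

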