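---
title: "Extracting structured attributes from GEO sample metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting structured attributes from GEO sample metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomex)
```

## The problem

Gene Expression Omnibus (GEO) sample metadata is free text: submitters
describe a sample's biosample, assay and donor in whatever fields and
phrasing they like. Downstream integration pipelines instead need a fixed
table. `geomex` extracts a 15-attribute table — cell line, cell type, tissue,
technique, technique type, target, species, life stage, age, age units, sex,
ethnicity, disease, classification and feature — from each sample's metadata,
harmonizing the vocabularies of curated resources (Cistrome-style and
ENCODE-style annotation tables) into one output schema.

The extraction model is a task-conditioned autoregressive language model. A
sample record is linearized into bracketed key/value text,

```
[gsm]: gsm1565792 [title]: DC_MTB_H3K9me3_rep1 (ChIP-Seq) [source name]: ...
```

and the model is asked for one attribute at a time by conditioning the
generation on a task keyword: the model sees
`<BOS> input-text <SEP> cell line:` and generates the value followed by
`<EOS>`. Formally the model represents `P(output | input, task)`; every
attribute is a task, so a single model learns the union of the attributes
annotated by heterogeneous sources, and each attribute is extracted
independently of the others. Because the value is *generated*, not
classified, the model is not limited to values seen at training time, can
resolve synonyms and abbreviations, and can infer attributes that are only
implicit in the text (a prostate biosample implies a male donor; the K562
cell line implies a haematopoietic and lymphoid tissue of origin and a
leukemia disease state).

## Preprocessing

Linearized text is lowercased; the characters `*` and `_` are replaced by a
single space (replacement rather than deletion, so compound tokens like
`dc_mtb` become separable words); words longer than 30 characters are
removed (they are almost always URLs, hashes or serialized arrays); and the
token sequence is truncated to the first 400 tokens, which keeps the head of
the document — GEO records front-load their identifying fields. The
operation is idempotent, so preprocessed corpora can safely be preprocessed
again.

## Confidence and the traffic-light classes

Each generated token carries the conditional probability the model assigned
to it. Three strategies turn a multi-token generation into one confidence:
the product of all token probabilities, the minimum, or the probability of
the first token. Products and minima systematically produce low values even
for correct predictions (later tokens of a multi-token value are nearly
deterministic); the first-token probability is the best calibrated with
correctness, and is the default. `product <= min <= first` holds for every
trace.

Confidence maps to traffic lights with two thresholds: strictly above 0.8 is
green (accurate), strictly below 0.6 is red (probably wrong), everything
between — including the boundary values themselves — is yellow (to be
verified). When the model immediately emits `<EOS>` the value is reported as
`"unknown"` with the `<EOS>` probability as confidence: that probability is
the model's commitment to "nothing to extract".

## Saliency

To let an annotator judge *why* a value was predicted, `input_x_grad()`
computes input-times-gradient attributions: for each generated token, the
gradient of that token's probability with respect to each input-token
embedding is multiplied elementwise by the embedding and reduced to a
per-input-token L2 norm. Norms are summed across the generated tokens (the
display aggregates a whole value, not single tokens) and normalized to sum
to one; an all-zero map falls back to uniform. Equal-width binning of
`[0, max score]` yields display intensities. The analytic gradients are
validated in the test suite against a central finite-difference oracle that
perturbs embeddings through the forward pass only.

## The active/online-learning loop

Annotation proceeds in four repeated phases: (1) the user supplies GSM/GSE
identifiers and the model extracts the table for each resolved sample;
(2) the queue is sorted by descending count of low-confidence fields — a
"low-confidence field" is any non-green field, since yellow and red both
require attention — so the sample needing the most editing is first; (3) the
user confirms, blanks (`unknown`) or corrects each field; (4) once every
field is approved the sample is finalized: its approved values become
training examples appended to an augmentation store, the model is retrained
on the base dataset plus the store, the sample moves to the annotated store,
and the remaining queue is re-extracted and re-sorted. The loop stops when
the queue is empty or everything is green.

Three design points deserve note. Retraining uses the *union* of the base
dataset and the augmentation store (training only on corrections would make
the model forget its base behavior). Online updates are deliberately small —
one epoch at a low learning rate per finalize — while the augmentation store
is replayed with a higher weight (`augmentation_weight`, default 8): a
handful of corrections is tiny next to the base dataset, and replaying them
lets the model absorb a correction within a couple of finalizes without
reshuffling the confidence landscape of the untouched samples. Fields
approved as `unknown` are
excluded from the augmentation examples by default — training a generative
model to emit the literal token `unknown` changes its behavior on every
sample — with a session flag to include them. Re-extraction after retraining
regenerates queued samples only; pending (unfinalized) edits on other queued
samples are superseded by the regenerated table.

## The model backend

The backend contract is a small adapter interface — `generate()`,
`fine_tune()`, `adapter_capabilities()`, `saliency_grads()` — so any
autoregressive model can sit behind the pipeline. Two implementations ship:

* `fixture_lm()`, an exact table-driven adapter for tests and examples;
* `tiny_lm()`, a from-scratch decoder-only transformer (2 layers, 2
  attention heads, embedding size 64, feed-forward width 128, word-level
  tokenizer with `<BOS>`/`<SEP>`/`<EOS>` reserved) with forward, analytic
  backward and Adam implemented in compiled code. The same configuration
  object can express much larger decoder stacks (12 layers, 12 heads,
  embedding 768 — the GPT2-small configuration), but only the
  small setting is exercised on CPU here.

Training minimizes the cross-entropy of the formatted training strings.
By default the loss is masked to the target-and-`<EOS>` span (tokens after
the task keyword), aligning optimization with the extraction objective;
full-sequence loss is available via `train_config(loss_mask = "full")`.
A seeded 10% validation split drives early stopping: training halts once the
validation loss has failed to improve by `min_delta` for more than
`patience` consecutive epochs (defaults: patience 2, min-delta 0). Greedy
(argmax) decoding is used everywhere: the annotation loop and the tests
need determinism, and extraction targets are short.

`train_config()` defaults to a setup for fine-tuning a pretrained
GPT2-class backbone (Adam,
learning rate `1e-4`, batch size 12, with `replicas` multiplying the
effective batch as data-parallel copies would). That rate suits fine-tuning
a large pretrained model; for the small from-scratch backend the package's
own tests and acceptance script use `2e-3`, a conventional rate for small
transformers trained from random initialization.

## The synthetic corpus

`generate_corpus()` emulates GEO sample records with known ground truth so
the whole pipeline is testable without downloads. Each sample draws a
biosample profile — a cell line (60%) with its documented cell type, tissue,
disease, donor sex, age and ethnicity, or a tissue (40%) with independently
drawn donor attributes — plus an assay (ChIP-seq 40%, RNA-seq 30%, ATAC-seq
20%, WGBS 10%; ChIP targets imply a feature class). The record template
mirrors the usual GEO field inventory (gsm, title, sample type, source name,
organism, characteristics, description).

Three mechanisms make the learning problem realistic:

* **Dropout** (`field_dropout_rate`, default 0.2): an attribute's explicit
  mention is omitted. If a cue present in the text implies it (the cell-line
  name, `prostate` for sex, the assay for its type), the truth keeps the
  value labeled *implicit*; otherwise the truth becomes null. The record
  always names its biosample anchor, as real records do.
* **Synonyms** (`synonym_rate`, default 0.2): mentions are swapped for a
  listed synonym (`homo sapiens`/`human`, `chip-seq`/`chip sequencing`, ...)
  while the truth keeps the canonical value.
* **Deterministic cues**: every implication in the default cue table is
  consistent corpus-wide, so implicit attributes are learnable in principle;
  accuracy on them measures pattern inference, not memorization.

What the generator does *not* emulate: the long free-form prose of real
descriptions, misspellings, contradictory submitter annotations, multi-value
attributes, and the heavy-tailed vocabulary of real GEO. Passing the
synthetic recovery checks therefore demonstrates that the engine — the
task conditioning, training loop, decoding and confidence machinery — works
end to end; it does not certify real-GEO accuracy, which depends on a large
pretrained backbone and the real Cistrome/ENCODE training tables.

## Problem sizes and numerical choices

The acceptance checks train the default tiny backend on a 2000-sample
corpus (dropout 0.2, synonym rate 0.2, 80/20 split, seeded), a size at which
held-out exact-match accuracy reliably exceeds 90% on explicit and 70% on
cue-implied attributes after a handful of epochs; the bundled
`scripts/acceptance.R` uses 1200 samples for its reported numbers, with the
annotation-loop demonstration on a 120-sample base corpus and a 50-sample
queue. Layer normalization uses eps `1e-5`; weights initialize from
N(0, 0.02²); softmax rows are max-shifted; generation caches per-layer
keys/values and is bit-identical to step-by-step full recomputation (a
tested invariant). Argmax ties break toward the lowest token index, fixed
by the vocabulary ordering. Token-probability scores in saliency use the
softmax probability of the chosen token, so attributions and finite
differences measure the same scalar.

## Known limitations

* A corrected value whose words are absent from the word-level vocabulary
  encodes to `<UNK>` and cannot be generated afterwards; a subword
  tokenizer (as used by large pretrained backbones) removes this limit.
* Re-extraction after each finalize discards unapproved edits on still-
  queued samples by design ("the table is generated again").
* The saliency aggregation sums attribution norms across generated tokens;
  per-token maps are available from `saliency_grads()` if a display wants
  them separately.
* Attribute values are single strings; multi-valued attributes and ontology
  normalization are out of scope.
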