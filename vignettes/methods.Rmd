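---
title: "Extracting drug-drug interactions with hierarchical recurrent networks over sentence sequence and shortest dependency paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting drug-drug interactions with hierarchical recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddisdp)
```

## The task and the model

A drug-drug interaction (DDI) is one drug modulating the level or
activity of a co-administered drug. Sentence-level DDI extraction, as
standardised by the DDIExtraction-2013 shared task, classifies every
ordered pair of drug mentions in a sentence into one of five classes:
`Negative` (no interaction asserted), `Advice`, `Effect`, `Mechanism`
and `Int`. Biomedical sentences are long and multi-clausal, which makes
plain sequence encoders struggle; the *shortest dependency path* (SDP)
between the two mentions in the sentence's dependency tree retains the
content words that link them while dropping adjuncts, and is a
well-established source of signal for relation extraction.

`ddisdp` implements a hierarchical bidirectional recurrent architecture
that integrates both views of the sentence:

1. **Preprocessing.** The corpus (DDIExtraction-2013 XML dialect) is
   joined with per-sentence dependency parses (CoNLL-U). The two target
   mentions are anonymized to the placeholders `drug0`/`drug1` (other
   drug mentions become `drugn`), multi-token mentions are collapsed
   onto their internal syntactic head so the parse remains a tree, and
   the SDP between the two placeholder tokens is extracted by
   breadth-first search on the undirected tree (on a tree this path is
   unique).
2. **Four-channel token embedding.** Each token is represented as
   $z_{w_i} = [w_i^{word}; w_i^{POS}; w_i^{dis_0}; w_i^{dis_1}]$ — a word
   vector (200 dimensions by default, optionally initialised from
   word2vec-format pretrained vectors), a POS-tag vector (10), and two
   position vectors (10 each) indexed by the signed token distance to
   each target mention, clipped to ±30. A drug mention's word channel is
   the arithmetic mean of its original (pre-anonymization) word vectors,
   its POS channel the noun tag's vector.
3. **Embedding-level entity attention.** Token relevance to entity
   $e_k$ is $\theta_i^k = \mathrm{softmax}_i(\langle w_i^{word},
   e_k^{word}\rangle)$, and each token's full vector is scaled by the
   joint weight $(\theta_i^0 + \theta_i^1)/2$. Only the word channel
   enters the dot products; the scalar multiplies all four channels.
4. **Hierarchical encoders.** The sentence is split at the two entity
   positions into `sub0 | e0 | sub1 | e1 | sub2`. Bottom bidirectional
   recurrent encoders (LSTM cells by default; GRU and gate-free simple
   cells are config options) encode the three subsequences and the SDP
   token sequence into fixed vectors (concatenated final forward and
   backward states, 2 × 100). A top bidirectional encoder then reads the
   six-slot sequence `[v(sub0), p(e0), v(sub1), p(e1), v(sub2), v(sdp)]`
   and its concatenated final states form the representation $s$.
5. **Classifier and training.** $p(i \mid s) = \mathrm{softmax}(W_o s +
   b_o)$ over the five classes, trained by mean cross-entropy with
   RMSProp (learning rate 0.001, mini-batches of 64), dropout 0.7 on the
   embedding outputs and 0.5 on $s$.

All recurrent cells, backpropagation through time and RMSProp are
implemented directly in R on BLAS matrix operations; variable-length
segments are processed as length-sorted packed batches so no computation
is spent on padding. The backward pass differentiates through every
stage, including the attention softmax and the entity word-vector means,
so embedding tables are trained jointly with the encoders. Correctness
of the analytic gradients is asserted against central finite differences
in the test suite for all three cell types.

## Tunable parameters

| Section | Key | Default | Meaning |
|---|---|---|---|
| embedding | `d_word`, `d_pos`, `d_dis` | 200, 10, 10 | channel widths |
| embedding | `clip` | 30 | max absolute signed token distance |
| embedding | `min_count` | 1 | rarer surfaces map to `<unk>` |
| embedding | `noun_pos` | `"NN"` | POS tag assigned to entity slots |
| embedding | `attention_rescale` | `"none"` | optionally multiply attended rows by the sequence length |
| embedding | `sdp_include_relations` | `FALSE` | interleave dependency labels as pseudo-tokens on the SDP |
| model | `bottom_hidden`, `top_hidden` | 100, 100 | hidden units per direction |
| model | `cell` | `"lstm"` | `lstm`, `gru` or `simple` |
| model | `dropout_embed`, `dropout_output` | 0.7, 0.5 | drop probabilities |
| model | `share_bottom_across_subsequences` | `TRUE` | one encoder for the three subsequences |
| model | `entity_projection` | `TRUE` | learned linear map of entity vectors to the slot width |
| model | `bottom_pooling` | `"final"` | `final` states or elementwise `max` over steps |
| train | `learning_rate`, `batch_size`, `epochs` | 0.001, 64, 30 | RMSProp settings |

The defaults marked with concrete numbers are the reference
configuration of the architecture; `train` with no overrides runs exactly that setup.

## Design choices where the architecture was open

Several wiring details are not fully determined by the reference
description; the package fixes them as follows and exposes each as a
configuration flag so the alternatives remain testable.

* **Attention normalisation domain.** The attention softmax for the
  sentence runs over the $m$ sentence tokens; for the SDP it runs
  independently over the $n$ path tokens. The path tokens therefore
  receive their own unit-sum weights rather than re-using sentence
  weights gathered along the path.
* **Attended entity slots.** Entity tokens take part in the sentence
  softmax through their placeholder vectors, while the `e0`/`e1` slots
  fed to the top encoder use the mean-of-original-words entity vectors,
  scaled by the entity token's own joint weight.
* **Attention shrinkage.** The literal attended vector
  $\frac{\theta^0_i+\theta^1_i}{2} z_{w_i}$ scales like $1/m$ on long
  sentences. The faithful form is the default;
  `attention_rescale = "times_m"` undoes the shrinkage for
  experimentation.
* **SDP input content.** The SDP sequence consists of the on-path
  *tokens* only: the token representation has word/POS/position
  channels, none of which exist for dependency-relation labels.
  `sdp_include_relations = TRUE` interleaves relation labels as pseudo
  tokens with their own learned full-width embeddings.
* **Segment-to-vector reduction.** Bottom encoders are reduced by their
  concatenated final forward/backward states (`bottom_pooling = "final"`);
  the top encoder, not pooling, integrates the parts. Elementwise max
  pooling is available for comparison.
* **Weight sharing.** One bottom encoder is shared by the three
  subsequences (they share a linguistic distribution) and a separate one
  encodes the SDP (distributionally different token sequences); a flag
  un-shares the subsequence encoders.
* **Entity slot dimension matching.** The 230-dimensional entity
  vectors are linearly projected (learned) to the 200-dimensional slot
  width so the top encoder sees a homogeneous six-step sequence.
* **Blinding of non-target mentions.** Other drug mentions in the
  sentence are replaced by the shared placeholder `drugn` by default
  (flag `anonymize_others`): the placeholders prevent the model from
  memorising drug names, standard practice for this corpus.
* **Empty segments.** A subsequence can be empty (entity-initial or
  adjacent entities); its encoder output is the zero vector of the
  contracted length.
* **Discontinuous mention offsets** (`"a-b;c-d"`) keep their first span,
  with a warning; spans stay contiguous as the data model requires.
* **RMSProp internals.** Only the learning rate is prescribed;
  decay 0.9 and epsilon 1e-8 follow common framework defaults. Epoch
  count and early stopping are likewise unprescribed: the default is 30
  epochs, retaining the parameters of the best dev micro-F when a dev
  set is supplied and the final parameters otherwise.
* **Parameter initialisation.** Glorot-uniform input weights,
  orthogonal recurrent weights, zero biases with the LSTM forget gate
  at 1; word/POS tables are drawn from 0.1-scaled standard normals
  (unless loaded from a vector file) and position tables from a standard
  normal, all reproducible from `embedding$seed`.

## The synthetic corpus generator

Real DDI corpora cannot be bundled, so the generator builds desk-scale
corpora with a *planted, SDP-localised* class signal, exercising every
stage of the pipeline: XML with character-offset entities and labelled
pairs, CoNLL-U trees, anonymization, SDP extraction, training and
evaluation.

Each sentence is built around a chain `e0 – (filler) – centre –
(filler) – e1` that by construction *is* the dependency path between
the two drug mentions; every other token attaches as a dependent of an
already-placed node, which can never alter that path. For a positive
label the centre region carries the class's trigger lemma (on the path
with probability `p_trigger_on_sdp`, default 1; off the path as a leaf
otherwise); Negative sentences never carry a trigger on the path.
Token order is a random permutation of the nodes, so linear position
carries no information about the tree. About 15% of mentions are
two-token drug names to exercise span collapsing.

Defaults, chosen once as realistic desk-scale study conditions:
2000 sentences; class priors 0.8/0.05/0.05/0.05/0.05 mirroring the
Negative-dominant imbalance of real DDI corpora; sentence lengths
uniform on 8–16 tokens (desk-scale — real corpus sentences are longer,
but length only adds computation, not signal structure, here);
120 filler word types; path lengths 3–5 nodes. `make_toy_vectors()`
writes word2vec-format vectors in which the four trigger lemmas get
mutually orthogonal directions (exactly zero pairwise dot products), so
the class signal is linearly separable at the embedding level.

With `trigger_only_on_sdp = TRUE` every sentence contains exactly one
token of each of the four trigger lemmas — positives with their own
class's trigger on the path and the other three as off-path leaves,
negatives with all four off-path. The bag of words is then identical in
distribution across classes and only the *structural position* of the
trigger separates them: a model whose SDP slot is zeroed at inference
must lose essentially all signal. This contrast demonstrates that the
SDP pathway, not the linear context, carries the planted signal.

What passing these tests does **not** show: linguistic realism.
Generated sentences have no grammar, no shared substructure between the
linear order and the tree beyond the construction above, and triggers
are single unambiguous lemmas. Results on the synthetic conditions
certify the machinery (parsing, alignment, attention arithmetic,
gradient flow, signal recovery through the intended pathway), not
corpus-level performance on real text.

## Numerical and procedural details

* Softmaxes (attention, classifier) subtract the row maximum before
  exponentiation.
* The evaluation follows the shared-task convention: per-class tp/fp/fn
  for the four positive classes, pooled into micro precision/recall/F
  with `Negative` excluded; a positive prediction is a true positive
  only when the type matches. Zero-denominator precision or recall is
  reported as 0 so F is always defined.
* Character offsets are 0-based half-open internally; the XML dialect's
  inclusive offsets are converted on read and restored on write.
  Heads are 1-based with `NA` for the root.
* Training is bitwise deterministic on CPU given the data and the two
  seeds (`embedding$seed` for tables, `train$seed` for initialisation,
  shuffling and dropout).
* A non-finite training loss aborts with the offending epoch and batch.
* Problem sizes used by the bundled checks: the signal-recovery suite
  trains on 1600 of 2000 generated sentences for the default 30 epochs
  (a few minutes of CPU time per condition); unit suites use corpora of
  10–80 sentences and reduced dimensions.

## Known limitations

* No GPU path and no minibatch-level parallelism; the implementation
  targets desk-scale corpora and method study, not production-scale
  training runs.
* Tokenization and parsing are out of scope: the package consumes
  CoNLL-U produced by any parser and fails loudly when a sentence lacks
  a parse or offsets cannot be aligned.
* Nested or discontinuous entity mentions are simplified (first span,
  contiguous token range).
* The relaxed/partial-match evaluation modes of the shared task are not
  implemented.

## A worked run

```{r, eval = FALSE}
d <- tempfile(); dir.create(d)
spec <- synthetic_spec(n_sentences = 400, seed = 7)
generate_corpus(spec, out_dir = d)
inst <- prepare_instances(file.path(d, "corpus.xml"),
                          file.path(d, "parses.conllu"))
sp <- split_instances(inst, 0.8, seed = 1)
cfg <- ddi_config(train = list(epochs = 10))
model <- ddi_fit(sp$train, sp$test, cfg, quiet = TRUE)
report <- ddi_score(predict(model, sp$test), sp$test[, c("pair_id", "label")])
report
tidy(report)
autoplot(model)
```

The README shows the same pipeline with the numbers it prints.
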