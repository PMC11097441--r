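---
title: "Denoised diagnosis-sequence modelling: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoised diagnosis-sequence modelling: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxbert)
```

## The problem

Claims-style EMRs record, per visit, a date and a handful of ICD-9
diagnosis codes. Influenza-like illnesses (the shipped noise list of 29
codes: acute upper-respiratory infections, viral pneumonias, influenza and
related symptom codes) are seasonal, short-lived, and close to independent
of a patient's chronic state; they typically revisit within about ten days
and then vanish. Chronic conditions — hypertension (401.9) and its
comorbid circle of heart disease, diabetes and hyperlipidemia — recur on
much longer, multi-modal schedules (monthly to annual follow-ups).
`dxbert` predicts whether one of the configured target diseases appears
within a horizon `T` after a trigger disease has occurred `k` times,
after filtering the noise codes out of the sequence.

## Sequence derivation

`derive_sequences()` flattens a record into the aligned triple
`(D, VS, TIS)`: codes in visit order, the visit index per code, and the day
gap to the previous visit placed on each visit's first code (0 elsewhere,
with the first visit's gap defined as 0). These are exact, deterministic
transforms; the test suite pins them to a worked four-visit record.
Conventions worth knowing:

* **Truncation keeps the most recent suffix** (`pad_sequences()`): the
  model predicts the future, and recency carries most of the signal.
* **Within-visit code order is preserved as given**; no intra-visit
  ordering is imposed.
* Dates are ISO-8601 by default (`emr_dialect(date_format=)` overrides);
  intervals are calendar days, ignoring time of day.
* `ε`/empty diagnosis slots and the reserved token `EPS` are dropped at
  parse time and are never vocabulary items.
* ICD-9 codes are normalized to the `XXX.X` level, except codes listed in
  the configured noise/trigger/target sets, which are kept verbatim — the
  shipped noise list itself contains two-decimal codes (e.g. 466.11), so
  normalizing them away would break the very sets that define the task.

## Comorbidity graph

A target counts for a patient when some occurrence sits strictly after the
k-th trigger occurrence in the flattened sequence ("after" on positions,
not visits; same-visit co-listings after the k-th occurrence count).
Support is per patient (prevalence, not incidence). Trigger selection
applies four rules: more than two occurrences within at least one record, a
non-empty comorbidity set, exclusion of noise codes, and patient prevalence
of at least 1%.

Edge weights follow the mean entropy-weighted rank difference over shared
comorbidities. Two choices the formula leaves open:

* **Rank ties** are broken lexicographically by code after sorting by
  support, making ranks deterministic.
* **Entropy reference distribution**: `F_k` defaults to the binary entropy
  of patient prevalence, `-p log2 p - (1-p) log2 (1-p)`; `entropy_fun` is
  pluggable because the quantity is only pinned down up to its reference
  distribution.
* **Pairs with no shared comorbidity** keep their edge (adjacency is
  defined by the trigger/target relation alone) and receive the maximum
  observed finite weight + 1, flagged in the output. The weight is a
  distance, so this penalizes unrelated pairs in the walk-based embedding
  without deleting the relation.

`embed_graph()` runs weighted random walks (transition probability
proportional to `1/(1+wt)`, converting the rank distance into an affinity)
and fits skip-gram vectors with negative sampling. Defaults: 10 walks per
vertex of length 20, window 5, `d_emb = 64` (the pipeline uses 32 for the
desk-scale experiments below). Codes outside the graph — noise codes above
all — receive seeded random rows, which is not a bug but a feature: their
vectors are unstructured relative to the comorbidity-coherent chronic
codes, which is exactly the signal the denoiser learns to exploit.

## The denoiser

The first layer runs two recurrences over the embedded sequence with
sigmoid activations: the full block reads both directions with shared
weights, concatenates the two states and projects back to the hidden size
through a tanh output layer; the noise block reads backwards only. Shape
conventions: `W_t: q×q`, `W_x: q×p`, `b: q` — the unique assignment under
which the recurrence typechecks. The states mix as
`v_t = α h_t + β ĥ_t`; α and β are **estimated, not trained**:
α = P(trigger | noise history), β = P(noise history | trigger), computed on
the corpus by `estimate_mix_weights()` (on the reference registry these
were 1 and 0.2107).

The second layer is scaled dot-product attention over the mixed states with
learned Q/K projections (`dim_k = q`). The per-position attention mass
`a_i` is the column mean of the masked row-softmax matrix — the natural
reduction of the n×n attention to the per-position vector the scoring head
needs. The value projection `W_v` produces the attended context output but
receives no gradient from the denoising loss, which scores only `a`.

**Scoring and extraction.** The dense head is
`f_s(a_i) = sigmoid(w'·(n·a_i) + b')`. The attention mass is
length-normalized (`n·a_i = 1` under uniform attention) before the affine:
raw softmax mass scales as `1/n`, so without normalization a single
threshold θ cannot be compared across sequences of different lengths — in
practice the θ = 0.5 cut then keeps everything in one cohort and drops half
the chronic positions in another. Extraction keeps position i iff
`f_s(a_i) > θ` strictly ("exceeds" read as strict), preserves order, and
zero-pads back to the original length. θ defaults to 0.5 and is
configurable.

**Semi-supervision.** Labels exist only where the noise set (label 1) or
the trigger/target sets (label 0) apply; every other position is unlabeled
and contributes no loss. The loss is binary cross-entropy of the keep score
against the keep/noise label at labeled positions. Optimization uses Adam
(learning rate 0.02, 10 epochs, minibatch 64 by default) — the training
recipe is an implementation choice, logged in the fit object via the loss
trace. Gradients are hand-derived (batched BPTT through both recurrences
and the attention layer) and verified against central finite differences in
the test suite.

## The encoder

A compact post-LayerNorm transformer (default 2 layers, 2 heads, hidden 64,
feed-forward 4×hidden, ReLU; the pipeline experiments below use hidden 32
to keep runtimes desk-scale). Input channels:

* token embedding of the (denoised) disease sequence, with reserved ids for
  `[PAD]`, `[CLS]`, `[SEP]`, `[MASK]`;
* segment embedding of the visit index, capped at 50;
* time embedding of the interval sequence bucketized on
  {0, 1–7, 8–30, 31–90, 91–365, >365} days;
* a two-valued separator-side embedding (sentence A/B in the original BERT
  sense: 1 up to and including `[SEP]`, 2 after). This channel is a design
  deviation worth explaining: visit-index and time-bucket embeddings cannot
  express "this code occurs *after* the separator", and without any such
  signal the next-sentence objective is unlearnable in principle at this
  scale — empirically the encoder then memorizes its training set (training
  accuracy 1.0, validation AUC ≈ 0.55 on a 600-patient synthetic cohort)
  instead of learning the rule; with the channel the same setup reaches
  validation AUC ≈ 0.94. BERT's own NSP design includes exactly this
  channel, so we consider it part of faithfully "borrowing BERT".

**Masked-code objective.** Positions enter the objective independently
with `p_select` (default 0.15, the BERT convention; conditional on
selection the mask/random/keep split is 70/15/15, and the random
replacement never reproduces the original code). The corruption consumes the RNG
stream with a documented contract (one uniform for selection, one for the
branch, one `sample.int` for the replacement), so a fixed seed reproduces
the exact pattern — the tests replay it independently.

**Next-sentence objective.** `[SEP]` is inserted after the visit holding
the k-th trigger occurrence; the label is 1 iff any configured target
occurs in a *strictly later* visit dated within `T` of the separator visit
(a target co-listed in the separator visit itself does not count). Patients
with trigger or target codes but fewer than k trigger occurrences get
`[SEP]` appended and label 0; patients with neither are excluded.
Pretraining data is rebalanced to 20% positive by stratified sampling
without replacement, taking the largest total consistent with both class
counts. Defaults: `k = 2`, `T = 365` days, `L = 75` (`L = 285` supported).

**Fine-tuning** re-initializes the prediction head and updates it together
with the body by default (`freeze_body = TRUE` restricts gradients to the
head); whether to fine-tune the denoiser jointly is exposed the same way —
the pipeline trains the denoiser first and freezes it, which keeps the two
stages separately testable. Over-long encodings give priority to the
post-separator segment (which carries the outcome window) and keep the most
recent pre-separator history in the remaining room.

All forward/backward passes are hand-written batched matrix algebra in base
R; finite-difference tests cover every parameter group of both networks.

## Synthetic cohorts

`generate_cohort()` emulates the statistical structure the method assumes,
not any real registry:

* **Noise revisit gaps**: log-normal with median 10 days (`sdlog = 0.3`),
  giving the single short peak characteristic of influenza-like codes;
  noise arrives in short episodes of 2–4 visits of one code.
* **Chronic revisit gaps**: a four-component Gaussian mixture (peaks at 30,
  90, 180, 365 days; weights 0.35/0.30/0.20/0.15) — four distinct peaks,
  emulating prescription-refill and follow-up rhythms. The peak locations
  are configuration, not fitted values.
* **Noise share**: the expected fraction of noise positions is
  `noise_prevalence = 0.205`, the marginal probability of influenza-like
  diagnosis in the reference registry.
* **Event budget**: negative-binomial with mean 27.34 and SD 20.93 chronic
  events per patient, split across the patient's condition streams.
* **Planted rule**: patients whose trigger occurs k times develop a target
  within `T` with probability `rule_strength` (default 0.5, a realistic
  one-year comorbidity onset rate that leaves both classes well populated);
  the construction plants or suppresses in-window target events so the
  ground-truth labels are controlled exactly, and the truth sidecar is
  cross-checked against the example builder.
* Background chronic codes co-occur with the trigger/target streams, so
  they join the comorbidity graph and receive structured embeddings — this
  is what lets the semi-supervised denoiser generalize from the labeled
  trigger/target positions to unlabeled chronic codes.

What the generator does **not** emulate: demographics (age/gender play no
role in the model), code-frequency long tails, coding-system drift,
multi-site heterogeneity, and visit-level billing structure. Passing tests
on these cohorts therefore demonstrate that the machinery recovers planted
structure under the stated assumptions, not that it reaches any particular
performance on real registries.

## Problem sizes and numerical notes

The shipped experiments are sized for a single CPU: the noise-recovery
check trains the denoiser on 2,000-sequence cohorts (three seeds) and the
denoise-on/off comparison runs 400-patient cohorts (three seeds) with the
2-layer, 2-head, hidden-32 encoder, 2 pretraining epochs and 25 fine-tuning
epochs. Numerical details: softmax rows are max-shifted; probabilities are
clamped at 1e-12 before logs; LayerNorm uses eps 1e-5; all stochastic steps
flow from explicit integer seeds through a seed-restoring wrapper, so every
result in the tests and the acceptance script is reproducible bit-for-bit
in a single-threaded run.

## Known limitations

* The denoiser scores positions by received attention mass; two occurrences
  of the same code in similar contexts get similar scores, so it filters
  code *types* more than individual events.
* With long sequences the extraction step can also remove genuine target
  codes (the score head has no access to the label definition); the
  pipeline therefore always computes NSP labels from the raw record and
  only filters the *encoding*.
* ICD-10, procedure/drug codes, and external ontologies are out of scope.
* AUC above 0.8 in the noise-recovery property reflects the synthetic
  separation between comorbidity-embedded chronic codes and
  randomly-embedded noise codes; real registries will be harder.
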