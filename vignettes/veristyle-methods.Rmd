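---
title: "Theory-based stylometry for verbal lie detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theory-based stylometry for verbal lie detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

veristyle analyses short labelled statements — truthful or deceptive — the
way deception researchers do: extract a theory-grounded style vector per
statement, test which features separate the two classes, evaluate how well a
classifier detects deception within and across content domains, and explain
the classifier's mistakes through the same stylometry. This vignette records
the models, the tunable parameters, the numerical choices, and the design
decisions behind each stage, together with what the synthetic test bed does
and does not demonstrate.

## The 26-feature style vector

Four psychological frameworks motivate the features:

* **Cognitive Load** — fabrication consumes cognitive resources, so lies
  tend to be shorter and simpler. Features: `num_sentences`, `num_words`,
  `num_syllables`, `avg_syllabes_per_word`, and the Flesch–Kincaid grade
  `0.39·(w/s) + 11.8·(y/w) − 15.59` and Flesch reading ease
  `206.835 − 1.015·(w/s) − 84.6·(y/w)`, with `w` words, `s` sentences, `y`
  syllables.
* **Distancing** — liars avoid self-involvement. `Self_reference` is the
  summed percentage of the `i` and `we` lexicon categories;
  `Other_reference` sums `shehe`, `they` and `you`.
* **Reality Monitoring** — experienced events carry perceptual and
  contextual traces, imagined ones carry cognitive operations.
  `Perceptual_details = attention + visual + auditory + feeling`,
  `Contextual_Embedding = space + motion + time`, and
  `Reality_Monitoring = Perceptual + Contextual + Affect − Cognition`
  (which may be negative). `Concreteness_score` is the mean 1–5
  concreteness rating of the statement's content words.
* **Verifiability** — truthful statements name checkable details. The four
  entity features (`People`, `Temporal_details`, `Spatial_details`,
  `Quantity_details`) count *unique* normalized entity surfaces per
  category, as returned by a pluggable recognizer.

Category percentages are `100 × matching word tokens / word tokens`;
matching is case-insensitive and a trailing-asterisk entry matches by
prefix. One token may feed several categories.

### Choices where published tools are proprietary or unspecified

* **Lexicon**: the package is dictionary-agnostic and reads any LIWC-style
  `.dic` file. A small open fixture lexicon (28 categories) ships for tests
  and examples. Feature values are comparable across studies **only** when
  the same dictionary is used; the fixture is a test instrument, not a
  replacement for a validated dictionary.
* **`Analytic`** uses the published categorical–dynamic index,
  `30 + article + prep − ppron − ipron − auxverb − conj − adverb − negate`,
  clamped to [0, 100]. **`Authentic`** uses an open composite following the
  deception-language factor structure — self-references and cognitive
  ("insight-like") terms load positively, negative-tone and motion words
  negatively: `30 + Self_reference + Cognition − tone_neg − motion`,
  clamped to [0, 100]. Both are documented approximations of proprietary
  summary scores and should be read as such.
* **`Tone`** is specified only as a standardized 0–100 difference of
  positive and negative tone; we use the bounded ratio
  `50·(1 + (pos − neg)/(pos + neg))`, which is symmetric, maps
  `pos = neg` (and the empty case) to 50, and respects the printed range.
* **Tokenizer**: deterministic — whitespace split, leading/trailing
  punctuation peeled into separate tokens, clitic apostrophes kept
  (`"it's"` is one word), numerals are words. All word counts in the
  package use it, so counts are reproducible without a heavyweight NLP
  dependency; an external recognizer or lemmatizer may tokenize its own
  way internally without affecting them.
* **Syllables**: vowel-group runs (`aeiouy`), silent terminal `e` dropped
  unless it is the only group, minimum one per word. Deterministic;
  exactness against any specific readability tool is not claimed.
* **Sentences**: split at `. ! ?` followed by whitespace and an
  uppercase/digit, with a small abbreviation stop-list (configurable).
* **Concreteness**: lowercase → tokenize → drop stopwords → lemmatize
  (rule-based suffix stripper by default, pluggable) → look up. Unmatched
  words are *excluded* from the mean rather than scored zero; a statement
  with no match carries a missing value through the statistics stage.
* **Entity recognition** is a plug-in contract (`text → surface, category`).
  The shipped recognizer is a deterministic gazetteer/pattern stub so that
  the pipeline runs and is testable offline; swap in a trained NER model
  for real analyses. Model-style labels (PERSON, GPE, DATE, CARDINAL, …)
  map onto the four verifiability categories; unknown labels are ignored.

## Group comparison

For each feature we test the truthful-minus-deceptive mean difference with
a Monte-Carlo permutation test: group labels are reshuffled (independent
design) or within-pair signs flipped (paired design), `n_permutations`
times (default 10,000). Tests are two-sided, because effects in both
directions are substantively meaningful and reported. The p-value uses the
add-one convention `(1 + #{|T*| ≥ |T_obs|})/(1 + B)`, standard Monte-Carlo
practice that avoids zero p-values; note its smallest attainable value is
`1/(B + 1)`, so `B` must be large enough for the correction in use (with 26
features under Holm, `B ≥ 999`).

The opinion-style design averages each subject's truthful and deceptive
style vectors first, giving one pair per subject; this removes topic and
stance effects and motivates the sign-flip test. Subjects missing a
veracity side are dropped with a warning; feature values missing within a
side are excluded from that mean.

Holm–Bonferroni correction is applied across the 26 features of one
contrast — the family the analysis reports on. Effect sizes are the common
language effect size (probability a random truthful statement exceeds a
random deceptive one; ties weighted ½ so identical groups score exactly the
0.5 null) with a seeded percentile bootstrap CI (2,000 resamples by
default; the construction is a package choice, as is the normal
approximation `se = sqrt((n1+n2)/(n1·n2) + d²/(2(n1+n2)))` for the Cohen's
d CI — both are swappable). A constant feature reports `p = 1`, CLES 0.5,
`d = 0`, direction `none`. Per-feature random streams are derived from the
master seed and the feature *name*, so adding a feature never perturbs the
others' results.

## Evaluation scenarios and the adapter contract

Three designs probe within-domain learning, cross-domain transfer, and
multi-domain learning:

* **S1** — 10-fold cross-validation within one corpus.
* **S2** — train on the union of two full corpora, test on the held-out
  third; no folds.
* **S3** — reuse the S1 folds and aggregate: unit *i* joins the corpora's
  fold-*i* train sets and fold-*i* test sets.

Folds are seeded and cacheable, so different classifiers can be compared on
identical splits. Opinion-style corpora are always split by subject —
otherwise a model can score by recognizing an author's style rather than
deception. Other corpora split by statement unless repeated subject ids are
present, in which case grouping turns on by default (a conservative choice;
the original datasets' practice is not documented). The fold-size remainder
rule gives the first `n mod k` folds one extra unit.

Classifiers enter through a two-function adapter (`fit(train)`,
`predict(model, texts)`) whose outputs are *strings*, parsed
case-insensitively to the two labels after stripping surrounding
punctuation — the natural interface for text-to-text models that answer
with the training label words. Unparseable outputs are logged, tallied, and
scored as incorrect (never re-prompted: scoring stays deterministic). The
built-in baseline is a unigram bag-of-words counter with vocabulary built
from the training split only (cap 5,000 most frequent tokens) and an
L2-regularized logistic regression (ridge, fixed `lambda = 0.01`);
out-of-vocabulary tokens at predict time are ignored. The vocabulary size
and penalty are package defaults, configurable, since the reference
experiments do not state theirs. A fine-tuned sequence-to-sequence model
plugs in through the same adapter; no training loop ships with the package.

Accuracy is reported per fold with mean and sample sd; the 2×2 confusion
matrix (positive class = truthful) is averaged elementwise across folds.

## Explainability by confusion quadrant

Each fold's test set is partitioned into TP/TN/FN/FP (truthful positive).
Four contrasts are tested per fold — FN vs FP, TN vs FN, TP vs FP, TP vs TN
— each a 26-feature independent permutation analysis with Holm applied
within the fold-contrast family. The direction convention is first-listed
minus second-listed, so CLES > 0.5 means higher in the first group. A
quadrant smaller than two statements skips its contrasts (logged); the
threshold is a package choice for degenerate folds. Aggregation counts the
folds in which each feature survived correction and averages CLES, d *and
their CI bounds* across folds; averaged bounds summarize the per-fold
intervals but have no strict coverage interpretation — a documented caveat.
A feature tested in no fold is reported absent, never as zero.

## The synthetic test bed

The generator emulates the *structure* of short-statement deception
corpora: three nominal domains; the opinion-like domain with five
statements per subject (3/2 or 2/3 truthful/deceptive, the extra
alternating across subjects, so every subject supports the paired design by
construction); one balanced statement per subject elsewhere. Texts are
template-assembled word sequences — eight-word sentences drawn from fixed,
published pools: function words, inert pseudo-words, a low-rate sprinkle
from every lexicon category (so every percentage feature has sampling
variance), content words with known concreteness norms, and background
entity mentions (class-independent). Default sizes (50 opinion subjects,
150 statements per other domain) and lengths (mean 50, sd 12 words, floor
6) mirror the order of magnitude of published deception corpora at desk
scale; calibration simulations use shorter texts (mean 24) to keep
thousands of replicates fast, which is a statement about simulation sizing,
not about the defaults.

Planted effects are declarative: a feature, a target truthful-minus-
deceptive shift, and a carrier. Lexicon carriers replace base draws with
category words at per-slot rate `δ/100`; the length carrier shifts the
truthful length mean; entity carriers append `δ` unique reserve-gazetteer
mentions (a reserve disjoint from the background-noise gazetteer, so
uniqueness is exact); the concreteness carrier mixes low-concreteness
content words into the deceptive class at the rate that produces the target
score gap. The returned ground truth records the *expected* shift of every
feature, computed analytically — including the arithmetic couplings the
carriers create (appended entity words lengthen truthful texts; content
overwrites dilute lexicon carriers; the ratio expectation is evaluated over
the discrete length distribution). Carrier maps and pools are published in
the ground-truth attributes so tests validate against the recorded truth
rather than reverse-engineering the generator. Features with no natural
carrier under this scheme (`Tone`, `Analytic`, `Authentic`, `fk_*`,
`avg_syllabes_per_word`) refuse to be planted with a configuration error.

With `domain_specific = TRUE`, the class signal is carried by per-domain
marker tokens absent from every other domain's vocabulary. A bag-of-words
learner then succeeds within domain (S1, S3) and falls to chance on an
unseen domain (S2) — reproducing, by construction, the qualitative
cross-domain transfer failure that motivates the three-scenario design.

**What passing tests show, and what they do not.** The synthetic corpora
validate the *machinery*: extraction arithmetic, test calibration, power
against known effects, split integrity, and the end-to-end scenario
pattern. They are not fluent prose; they say nothing about how large or in
which direction stylometric effects are in real deception data, and a
sequence-to-sequence model fine-tuned on them would learn token lookup, not
language.

## Numerical and calibration notes

* All randomness flows from explicit seeds; generation, folds, permutation
  and bootstrap streams save and restore the global RNG state.
* Type-I calibration (rejection rate at α = 0.05 within [0.03, 0.07] over
  2,000 null replicates) is asserted on the continuously distributed
  features (length, readability, concreteness). Sparse count features
  (entity counts, rare lexicon categories at short lengths) are heavily
  tied, and a permutation test on tied data is *conservative* — its size
  falls below the nominal level; for those the suite asserts the one-sided
  bound (never anticonservative) plus Holm familywise control across all
  26 features.
* Monte-Carlo permutation p-values are checked against full enumeration
  (all group assignments; all 2^n sign patterns) for every design with at
  most ten observations, within three Monte-Carlo standard errors.
* Simulation sizes in the shipped suite (e.g. 2,000 calibration
  replicates of 30-statement corpora; 20 power replicates at 200 per
  class; 25 null explainability runs of 160 statements) were chosen as the
  smallest designs whose pass/fail bands are statistically meaningful.

## Known limitations

* The fixture lexicon is tiny; real analyses need a validated dictionary,
  and `Analytic`/`Authentic`/`Tone` are open approximations of proprietary
  summary scores.
* The gazetteer recognizer stub has no recall outside its lists; entity
  features on real text require a plugged-in NER model.
* The syllable and sentence heuristics are deterministic approximations;
  readability values can differ slightly from other tools.
* Averaged CI bounds in the explainability aggregation are descriptive.
* The paired-design CLES treats the subject-averaged vectors as two
  groups; its bootstrap resamples subjects independently per side.
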