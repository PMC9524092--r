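---
title: "Mining self-reported headache narratives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining self-reported headache narratives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headachetext)
```

## The problem

Primary headache disorders — here migraine and cluster headache — are
diagnosed almost entirely from what patients say about their attacks; there
is no biomarker. When patients write freely about their disorder, their
lexical choices carry diagnostic signal: cluster headache narratives dwell
on strictly unilateral periorbital *pain*, migraine narratives on
*headache*, nausea and sensory sensitivity. `headachetext` implements a
complete token-based analysis of such narrative corpora:

1. **Corpus statistics** — per-group medians and quartiles of tokens, types
   and sentences per text, plus age/sex summaries.
2. **Keyness** — per word type, a 2×2 chi-square comparing its frequency in
   one diagnostic group against the other.
3. **Thematic proportions** — given sentence-level stand-off annotations in
   seven themes (attack description, burden of disease, comorbidities,
   technical investigations, triggers, treatment, medical history), the
   share of each text's tokens devoted to each theme.
4. **Cascade sentiment** — a token-sum valence score over an ordered
   sequence of lexicons with first-match-wins lookup.
5. **Classification** — migraine vs cluster headache from word/character
   n-gram and metadata features, with naive Bayes, linear SVM and logistic
   regression, evaluated by nested stratified 5-fold cross-validation and
   leave-one-out.

Because real patient texts cannot be redistributed, the package ships a
synthetic-narrative generator whose outputs carry exact, recountable ground
truth; every stage is validated against it.

## Pre-processing model

Cleaning normalises to Unicode NFC, deletes control/format characters,
collapses horizontal whitespace and preserves single newlines: patient-typed
text often uses a line break as its only sentence boundary, so the splitter
treats newlines as terminators alongside `.`, `!`, `?` (with decimal-number
and abbreviation guards). The tokenizer is rule-based — maximal runs of
letters/digits with internal hyphens/apostrophes, lowercased, punctuation
discarded — and deliberately pluggable; nothing downstream depends on more
than the sentence-structured token lists.

Two token filters follow for the analysis corpus, in this order: a
*label blocklist* (diagnosis mentions, medication names — anything that
would leak the class label into features) and a *stop-word list*. Both are
plain-text files; defaults for Dutch are bundled. The sentiment stage keeps
stop words, because valence lexicons may score intensifiers ("heel") and
negators ("niet"); it still applies the blocklist. Tokens are lowercased for
all stages and punctuation never counts toward token totals — choices the
package fixes so that counts are reproducible.

## Keyness

For word type $w$ with count $a$ in the target group and $b$ in the
reference group, and $c, d$ the remaining token masses, the statistic is the
classical 2×2 chi-square with Yates continuity correction

$$\chi^2 = \frac{N\,(|ad-bc| - N/2)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with direction `target` when $a/(a+c) > b/(b+d)$, a p-value from
$\chi^2_1$, and significance tiers `*`, `**`, `***` at $p <
10^{-2}, 10^{-5}, 10^{-8}$. The correction is the conservative default for
sparse word counts and can be disabled (`correct = FALSE`), which is also
the variant under which proportionally identical distributions give an
exact zero. Words with combined count below `min_count` (default 5) are not
ranked: single-occurrence keys are unstable. Ties in $\chi^2$ break
alphabetically so rankings are deterministic.

## Thematic proportions

A theme's proportion in a text is the token count of sentences carrying the
theme divided by the text's total tokens; unannotated sentences count only
in the denominator. Sentences may carry several themes; each theme's
proportion is computed independently, so proportions need not sum to one
even under full annotation. Annotations are stand-off JSON keyed by sentence
index (0-based on disk, 1-based in R) and therefore presuppose the package's
own sentence splitter — a constraint `extract_theme_subcorpus()` shares,
since it re-splits the stored text to pull out, e.g., the attack-description
sub-corpus on which classification runs.

## Cascade sentiment

Lexicons are TSV word–valence tables on arbitrary native scales; at load
each is rescaled by its maximum absolute valence, the sign-preserving linear
map onto $[-1, 1]$. A cascade consults its lexicons in order and the first
lexicon containing a token fixes the valence (mirroring a
Pattern → in-house → Duoman → NRC arrangement for Dutch; the package bundles
synthetic fixture lexicons, not the licensed originals). The document score
is the plain sum over all matched token occurrences — no negation or
intensifier arithmetic — and polarity is `positive` iff the score exceeds
zero. A zero score (including the no-match case) maps to `negative` by
default: the reported distributions are a strict two-way split without a
neutral class, and the boundary is assigned to the majority clinical
polarity; the choice is a flag (`zero_polarity`).

## Classification

Feature families:

* **word n-grams** (orders 1–3, within sentences, e.g. `w:pijn_oog`),
* **character n-grams** (orders 1–3 inside `#`-padded tokens, so they never
  span the gaps left by removed stop words),
* **metadata** — age and a female indicator.

The vectorizer's vocabulary, document-frequency table and age
standardization statistics are functions of the training portion only;
held-out documents project onto that vocabulary with unseen n-grams
ignored. Weighting is raw counts by default (binary and tf-idf by flag):
counts are the multinomial-naive-Bayes-native choice, and the comparison
across classifiers is cleanest when all see the same matrix.

Classifiers, each with balanced class weighting as one concrete
interpretation per algorithm:

* **Multinomial naive Bayes** (implemented in-package; additive smoothing
  $\alpha$ is the gridded hyperparameter, uniform class priors realise the
  balancing). Its metadata columns stay unstandardized — the multinomial
  model needs non-negative features.
* **Linear SVM** via libsvm (`e1071`), cost $C$ gridded,
  inverse-class-frequency weights, `scale = FALSE`, sparse input.
* **Logistic regression** via `glmnet` ridge with $\lambda = 1/(Cn)$, so the
  familiar $C \in \{0.1, 1, 10, 100\}$ grid applies to all three
  algorithms; instance weights balance the classes. One warm-started
  $\lambda$-path per training set serves the whole grid (convergence
  threshold $10^{-6}$; at that tolerance path predictions coincide with
  cold single-$\lambda$ fits at glmnet's default tolerance).

The grid $\{0.1, 1, 10, 100\}$ is the log grid over the 0.1–100 range; the
first-listed value wins ties in the grid search, making reports
reproducible bit for bit given `(corpus, specs, seed)`.

**Nested stratified cross-validation.** Outer stratified 5-fold; inside
every outer training portion, an inner stratified 5-fold grid search
maximises macro-averaged F1 (equal class weight, so the minority
cluster-headache class is not drowned out by accuracy), the winner is refit
on the whole outer-training portion and scored on the held-out fold.
Reported metrics are across-fold means. Stratification assigns each class's
fold counts within one instance of proportionality, distributing remainders
to the smallest folds — a 74/38 corpus yields fold sizes
{23, 23, 22, 22, 22} with 7–8 minority instances each. `audit = TRUE`
retains fold memberships, vocabularies and standardization statistics so
leakage can be checked mechanically.

**Leave-one-out.** N singleton test rounds (no stratification is possible),
each with its own inner stratified 5-fold grid search; metrics pool the N
single predictions.

## The synthetic generator

The generator emulates the corpus the analysis was designed for, at the
level every consumer actually touches — token streams, not fluent Dutch:

* 81 migraine and 40 cluster-headache records; log-normal tokens-per-text
  targeting medians (Q1–Q3) of 474 (227–745) and 508 (198–794); ~20 tokens
  per sentence.
* Age $\mathcal{N}(43.1, 12^2)$ / $\mathcal{N}(48.9, 14.2^2)$ years,
  80% / 20% female.
* One theme per sentence from a mixture concentrated on attack description
  (0.30), treatment (0.18), medical history and burden (0.12 each);
  comorbidities and technical investigations are rare (0.01), so their
  per-text median proportion is 0. Exactly 7 migraine and 2
  cluster-headache records carry no attack-description sentence, making the
  attack-description extraction a fixed 121 → 112 reduction with a 74/38
  split.
* Class-exclusive keywords at a per-token emission rate (default 0.04),
  using the field-reported key words (*oog*, *pijn*, *terug*, *linker*,
  *tanden* vs *hoofdpijn*, *stress*, *misselijkheid*, *geluid*, *vaak*) so
  keyness output is human-checkable; label mentions (*migraine*,
  *clusterhoofdpijn*, *medicatie*) at rate 0.01, which is exactly what the
  blocklist later removes.
* Valence words at rate 0.05 from pools wired into four fixture lexicons
  (different native scales, controlled overlaps including sign conflicts
  between the first and third lexicon). All valence words in a document
  share its drawn polarity sign (negative with probability 0.9, and at
  least one is always present), so the corpus-level negative share is
  exactly Binomial($n$, 0.9) and per-document polarity is part of the
  ground truth.
* Background text mixes bundled Dutch stop words (35% of background draws)
  with a Zipf-weighted inventory of pronounceable CVC pseudo-words that is
  disjoint, by construction, from keywords, label mentions, lexicon entries
  and stop words.

`verify_ground_truth()` re-derives every stated quantity from the emitted
text with the package's own pipeline — sentence counts via the splitter,
keyword counts via the tokenizer, net valence via the cascade — and flags
any mismatch, so generator and pipeline cross-validate each other.

What the generator does *not* emulate: realistic n-gram dependence between
words, spelling variation, negation scope, multi-theme sentences (covered
instead by hand-written fixtures in the tests), or the unknown overlap
structure of real patients' vocabularies. Passing tests on synthetic data
therefore demonstrate correctness of the machinery and qualitative
behaviour (signal recovery, null calibration), not clinical performance;
the study's own accuracy figures depend on the non-deposited patient corpus
and are deliberately not targets.

## Numerical and design choices

* Quartiles: `stats::quantile` type 7 everywhere, fixed for testability.
* Chi-square continuity correction on by default; the Yates term clamps at
  zero as in `chisq.test`.
* Zero-valence documents are `negative` (documented above, flag-controlled).
* Grid-search ties: first-listed hyperparameter wins.
* Naive-Bayes prediction ties: first class level wins.
* All randomness (generation, fold draws) flows from explicit integer
  seeds; per-fold inner seeds are derived as `seed + 7919 * fold` modulo a
  Mersenne prime below 2^31.
* Degenerate inputs error loudly (empty corpora, zero-token documents,
  out-of-range annotation indices, single-class training folds) rather than
  being repaired.

## Problem sizes used in the test-suite

Validation runs the full study-shaped corpus (121 records) for generation,
keyness, sentiment and theme accounting, and for one nested-CV signal
recovery check per discriminative classifier. The null-calibration study
uses twenty 74/38 corpora with shorter texts (median ≈ 80 tokens) and
identical per-class length/metadata models, the construction that makes
labels independent of text; under the balanced class weighting used
throughout, zero-signal accuracy concentrates near 0.5 rather than at the
majority rate, and the calibration check is applied to the across-seed mean
together with a per-seed no-optimism bound. Quick classifier unit tests use
24–60-record corpora.

## Known limitations

* The sentence splitter's abbreviation list is small and Dutch-oriented;
  texts dense in unlisted abbreviations will over-split (annotations are
  tied to the splitter's segmentation).
* Valence normalization by maximum absolute value makes a lexicon's scale
  sensitive to its single most extreme entry.
* The linear SVM on raw counts is sensitive to document-length outliers;
  tf-idf or binary weighting (available by flag) is advisable for corpora
  with very heavy-tailed lengths.
* Only the binary migraine / cluster-headache task is supported; no neural
  models, probability calibration, lemmatization or POS tagging.
```
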