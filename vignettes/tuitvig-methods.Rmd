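---
title: "Methods: measuring depression signals in Spanish tweet corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring depression signals in Spanish tweet corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuitvig)
options(tuitvig.verbose = FALSE)
```

## The study design

`tuitvig` implements an observational design for detecting behavioral and
linguistic signals of depression in Spanish-language Twitter data. Three
datasets are compared:

* **control** — timelines of randomly sampled users whose profile does not
  mention depression, minus retweets;
* **depressive users** — timelines of users who state depression in their
  profile description, minus retweets and minus the flagged tweets below;
* **depressive tweets** — a hand-flagged subset of those users' tweets that
  explicitly express depressive content.

Candidate users are found by streaming tweets that contain at least one of
twenty clinician-curated Spanish depression keywords (`depression_keywords()`;
entries such as `agobiado/a` expand to both gendered forms). A candidate is
admitted when their profile description contains, at token level and case-
insensitively, one of the derivations of *depr* (`depre`, `depresión`,
`depresivo/a`, `deprimido/a`), and retained only if at least `min_flagged`
(default 10) of their timeline tweets were flagged as depressive. Keyword
matching is accent-sensitive with a single documented relaxation: the
unaccented spelling *depresion* also matches *depresión*, because that accent
is the one users most often drop. Both behaviors are switchable. The manual
clinical judgment that vets profile statements and flags tweets is outside
the package's scope; in synthetic data it is replaced by ground-truth labels.

The three corpora are pairwise disjoint by tweet id; `assemble_datasets()`
enforces this and errors on flagged ids that do not resolve.

## Tokenization and surface features

The tokenizer is Twitter-aware and total: whitespace is discarded and every
other character belongs to exactly one token of kind word, mention, hashtag,
URL, emoji, number or punctuation, so concatenating surfaces reconstructs the
text. Emoji are recognized by explicit Unicode codepoint ranges (Miscellaneous
Symbols through Supplemental Symbols & Pictographs, flags) with variation
selectors and skin-tone modifiers attached and zero-width-joiner sequences
merged, so a composed family or profession emoji is one token. Character
counts are raw code-point counts of the unmodified text, URLs and mentions
included (a flag excludes them), since no exclusion rule is part of the
design. Ranked word lists (`top_words()`) lower-case, remove a bundled
100-word Spanish stopword list, and break count ties lexicographically for
reproducibility.

## Grammatical profiling

POS tagging is a *contract*: any component mapping word tokens to the eight
categories (noun, verb, pronoun, adjective, determiner, adverb, adposition,
conjunction) can be plugged in, because statistical tagging is not a
contribution of this pipeline. The bundled implementation is a deterministic
dictionary lookup over a tagged vocabulary (`dict_tagger()`), which keeps
tests hermetic; unknown words and non-word tokens tag as `other`, which is
excluded from the eight-way totals used for percentages.

Personal pronouns are classified into six person/number classes. Clitic and
object forms are mapped by a fixed table: *se*, *lo*, *la*, *le* to 3S;
*los*, *las*, *les* to 3P; *nos* to 1P; *os* and *ustedes* to 2P. Spanish
grammar is genuinely ambiguous here (*se* can be impersonal; *ustedes* takes
third-person agreement); a fixed mapping was chosen over context resolution
because the downstream statistic is a six-class frequency profile and any
consistent mapping preserves between-group contrasts. Share percentages are
computed over the six-class personal total, not over all pronouns.

## Lexicon scoring

* **Negations** are counted, not scope-resolved: the analysis reports how
  often negation cues occur, and no polarity flipping under negation is
  attempted. The bundled cue list is *no, nada, nadie, nunca, jamás, ni,
  ningún, ninguno, ninguna, tampoco, sin*.
* **Emotions**: each word token matching an entry of a six-emotion lexicon
  (happiness, sadness, anger, fear, disgust, surprise) increments that
  emotion; terms listed under several emotions increment each.
* **Binary polarity**: a tweet is labeled by hit majority over a ±1 lexicon;
  no hits mean `none` (the tweet shows no polarity) and a non-zero tie
  defaults to `none` (configurable), since only the category sets, not the
  aggregation rule, are fixed by the design.
* **Graded polarity**: the mean value `s` of matched entries of a
  real-valued lexicon in [−1, 1] is thresholded at `t_mod` (default 0.5):
  `s ≥ t_mod` positive, `0 < s < t_mod` moderate positive, symmetrically for
  negatives, `s = 0` or no match `none`. The default 0.5 splits the graded
  scale at its midpoint; it is a tuning parameter, not an estimate.

The published Spanish sentiment and emotion lexicons are not
redistributable, so the package ships small synthetic stand-in lexicons
(~16–24 terms each, filenames marked `_synthetic`) aligned with the
synthetic vocabulary; the loaders accept the real resources in the same
`term<TAB>annotation` TSV layout.

## Temporal profiles

Local time is `created_at_utc + utc_offset_seconds`; tweets with no stored
offset are dropped from temporal analyses by default (or treated as UTC).
Each user contributes a 24-bin hourly (or 7-bin Monday-first weekday) vector
of tweets per bin divided by the user's number of distinct observed local
days; the group profile is the mean ± SEM of those per-user vectors. The
per-user normalization is deliberate: averaging raw counts would let heavy
posters dominate the group curve. Retweets are excluded by default and
includable by flag.

## Statistical layer

* `chi_square()` is the uncorrected Pearson statistic (no continuity
  correction) with margin-based expected counts — the variant that
  reproduces the published POS table comparison.
* `welch_t()` accepts raw vectors or mean/SD/n summaries, so printed
  summary tables can be tested directly; both paths agree to numerical
  precision.
* `mann_whitney_u()` reports U for the first sample from midrank rank sums;
  p is exact (Wilcoxon distribution) when `n_x n_y ≤ 400` with no ties,
  otherwise a tie-corrected normal approximation without continuity
  correction.
* `mixed_anova_gg()` is a split-plot ANOVA (one between-subject group
  factor, one within-subject factor such as the 24 hour bins). The
  Greenhouse-Geisser epsilon is computed from the eigenvalue form
  ε̂ = (Σλ)²/((L−1)Σλ²) on the double-centered pooled within-group
  covariance, and shrinks the degrees of freedom of the within and
  interaction F tests. With two within-levels ε̂ = 1 exactly. Because the
  design leaves ambiguous which effect the published F refers to, all three
  effects are reported and the group×level interaction — "do the two
  populations have different activity *shapes*?" — is treated as the
  headline.
* `run_comparisons()` emits the full battery: χ² on POS, pronoun persons,
  emotions, binary polarity (positive/negative among polar tweets) and
  graded polarity (four labels) for all three dataset pairs; Welch t on
  characters for control vs depressive users and depressive users vs
  depressive tweets; Mann-Whitney on per-tweet negation counts for the
  three pairs; and the two GG-ANOVAs — 22 tests. Categories absent from
  both datasets in a pair are dropped before χ² (they carry no information
  and would make the statistic undefined). Mirroring the original design,
  no multiple-testing adjustment is applied to the reported p-values; a
  Bonferroni column is emitted alongside for transparency.

## The synthetic-data generator

Synthetic tweets are token sequences drawn from a curated vocabulary bank,
not grammatical Spanish. This is a deliberate design: every analysis in the
pipeline operates on token and lexicon statistics, so grammaticality is
irrelevant, while hermetic end-to-end testing requires *exact bookkeeping* —
the generator records, per tweet, the grammatical category of every drawn
token, the person of every personal pronoun, and every injected negation,
emotion, keyword and polarity word. The base token stream is drawn from
lexicon-free inventories, so every lexicon hit in a synthetic corpus is an
explicit recorded injection, and pipeline-recovered POS shares, pronoun
shares and negation counts equal the truth sidecar exactly (the test suite
asserts this to 1e-12).

A consequence worth noting: the *reported* POS shares of a synthetic corpus
include the categories of injected lexicon words (negation cues are
adverbs, most emotion terms nouns, polarity terms adjectives), so output
shares deviate by a few points from the base `pos_mixture`. The mixtures
parameterize the base stream; the truth sidecar, not the nominal mixture,
is the reference for exact recovery.

### Preset provenance

The presets encode the reported contrasts between the populations:

* `pos_mixture` — the three published POS share columns
  (e.g. nouns 28.48% control, 17.77% depressive users, 15.07% flagged).
* `pronoun_mixture` — first-person-singular shares 38.37%, 57.59% and
  80.00%; the remaining five classes are not published and are filled with
  realistic Spanish usage shares that respect the reported 0.4% 1P/2P
  floor in flagged tweets.
* `personal_pronoun_share` — 51.38%, 55.16%, 53.16% of pronoun tokens are
  personal.
* `negation_rate` — Poisson means 0.28, 0.49, 0.67 per tweet.
* `emotion_rates` — per-tweet Bernoulli rates back-derived from the
  published per-dataset hit totals and emotion shares (happiness 53.3% of
  control hits, sadness 25.5% of depressive-user hits, and so on).
* `polarity_mixture` and `graded_negative_share` — back-derived from the
  published prevalence (33.5% / 41.3% / 58.9% binary; 21.0% / 29.3% /
  33.3% graded) and positive-share figures.
* `hourly_weights` — a day-peaked curve for controls and a night-elevated
  curve (maximum near 23:00–0:00) for the depressive population;
  `weekday_weights` — a ×0.6 weekend dip for controls only.
* `entity_rates` and `length_tokens` — the published link/hashtag/mention/
  emoji prevalences and mean tweet lengths (≈14 vs ≈11 word tokens,
  matching the 83.5 vs 65.8 character means at ~6 characters per token).
* `flagged_fraction` — 0.08 of a depressive user's non-retweet tweets,
  ≈11 flagged tweets per user at the default timeline length, matching the
  1000-flagged / 90-user ratio of the original cohort.
* `retweet_fraction` — 0.376 control and 0.257 depressive, the reduction
  from collected to retained tweet counts.

Cohort sizes are scaled: the defaults generate tens of users and one to two
hundred tweets per user, and the recovery and power analyses in the test
suite run at 10,000 tweets per population (recovery, three seeds) and
20,000 per group (directional reproduction). These sizes give the acceptance
properties ample resolution while keeping the full suite fast; the original
cohort scale (hundreds of users, ~10⁵–10⁶ tweets) adds nothing to the
correctness argument.

Randomness is fully reproducible: one master seed, with per-user substreams
derived from `(seed, user_index)` by a fixed integer recurrence, so
regeneration is byte-identical and insensitive to evaluation order.

### What the generator does and does not emulate

It emulates the measured quantities — activity levels and their temporal
shape, POS and pronoun mixtures, lexicon hit rates, tweet length, entity
prevalence, profile statements, retweets, flagged subsets. It does not
emulate Spanish syntax or discourse, word co-occurrence structure,
user-to-user interaction, topic drift, irony, or misspellings. Passing
recovery tests therefore shows the pipeline measures token-level rates
without bias; it does not validate lexicon coverage or tagger accuracy on
real Spanish, which depend on the external resources supplied.

## Numerical and testing choices

* Degenerate inputs fail loudly: empty corpora in temporal profiling,
  zero-margin contingency tables, zero pooled variance in Welch t,
  incomplete repeated-measures vectors and unsorted timelines are errors,
  not silent results.
* The recovery acceptance test asserts exact bookkeeping equality per seed,
  and compares drawn rates to nominal generating rates within 3 standard
  errors on estimates pooled over the three seeds. Pooling is the
  calibration-correct form of the check: ~90 simultaneous per-seed 3-SE
  comparisons would reject a correct generator in a sizeable fraction of
  runs on noise alone, while any real mis-wiring of a rate displaces its
  pooled estimate by tens of standard errors.
* Type-I calibration of χ², Welch t and Mann-Whitney is checked by 500-run
  null simulations (rejection rate within [0.03, 0.07] at α = 0.05), and
  the χ² and U implementations are cross-checked against independent
  brute-force oracles (margin formula; O(n²) pairwise comparison count) to
  1e-9 on random instances. The GG-ANOVA is cross-checked against an
  independent multivariate implementation (`car::Anova`).

## Known limitations

* The dictionary tagger has no morphological generalization: real-corpus
  use should plug in a full Spanish tagger via the tagging contract.
* Negation is counted, never scope-resolved; intensifiers and word-sense
  ambiguity are out of scope.
* Polarity denominators are tweet counts; published per-lexicon
  denominators that exceed the tweet counts of their datasets could not be
  reconstructed from the available description and were not imitated.
* Language identification is taken from the stored `lang` field; no
  independent language detection is performed.
* Seasonality and longitudinal change are not modeled.
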