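---
title: "Emotional co-occurrence networks: entropy, triadic complexity and null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotional co-occurrence networks: entropy, triadic complexity and null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emonet)
```

## What this package models

Short emotionally loaded texts — farewell notes, emotional-recall word
lists — carry structure beyond their bag of words: which concepts co-occur,
how prominent each concept is in the discourse, and how the narrative moves
between positive, negative and neutral affective states. `emonet` implements
a cognitive-network pipeline for such corpora in four layers:

1. **Affective annotation.** A valence lexicon (word → continuous
   pleasantness score) is discretized into three sentiment labels by the
   quartiles of the score distribution over the *whole* lexicon: scores at
   or below Q1 are negative, at or above Q3 positive, the middle half
   neutral. An emotion lexicon adds, per word, a subset of the eight basic
   emotions (joy, trust, fear, surprise, sadness, disgust, anger,
   anticipation). Negated phrases are re-anchored: "not good" is counted as
   an antonym ("bad"), and when no antonym is known the token keeps its
   form but its polarity is inverted, so negation always flips affect
   rather than silently dropping tokens.

2. **Word co-occurrence networks.** Two words are linked when one
   immediately follows the other in at least one sentence. Stopwords and
   pronouns stay in the graph — they carry real connectivity — but are
   excluded from word *sets* such as the last-words inventory. Conceptual
   prominence is closeness centrality, `C_i = (N - 1) / sum_j d_ij`,
   computed with unweighted shortest paths within each connected component
   (a singleton has no distances and gets 0 by convention). Valence
   homophily across links is the Kendall tau-b correlation between the
   polarity codes (-1/0/+1) of edge endpoints, with each undirected edge
   contributing both orientations so storage order cannot matter.

3. **Emotional word lists and fluency-style networks.** Each text is
   stemmed, filtered against an emotional dictionary of stems, and kept as
   an *ordered* list (duplicates preserved — repetition is transition
   structure). Lists shorter than 5 emotional words are dropped, mirroring
   the inclusion threshold of recall-task data. A windowed co-occurrence
   network is built over these lists: stem pairs within 2 positions of one
   another are counted, pairs seen fewer than 2 times are discarded, and a
   one-sided binomial filter removes pairs explicable by word frequency
   alone. The null used by the filter treats each of the `T` within-window
   positional pairs in the data as a trial with success probability
   `p_uv = f_u * f_v` (relative stem frequencies); an edge is kept when
   `P(X >= k) < 0.05`. The trial definition is deliberately explicit and
   configurable, because fluency-network constructions in the literature
   differ in what they count as a trial.

4. **Entropy, triads, and null models** — the package's analytical core,
   described next.

## Emotional entropy of a valence sequence

Walk an ordered list's valence labels and write `0` when the next label
repeats the current one, `1` when it switches. The emotional entropy `h` is
the two-event Shannon entropy of that indicator string, in bits
(`0 log 0 = 0`). The two canonical five-word lists make the measure
concrete:

```{r entropy}
n1 <- c("negative", "negative", "positive", "positive", "neutral")
emotional_entropy(n1)          # indicators 0101 -> h = 1 bit

n2 <- c("positive", "negative", "positive", "negative", "neutral")
emotional_entropy(n2)$h        # indicators 1111 -> h = 0
```

Both lists contain the same words; only the *placement* of switches
differs. `h = 1` means switching and staying are equally frequent and
maximally scattered; `h = 0` means the list never varies its transition
behavior (always stays, or always switches). Neutral is an ordinary third
state: a move to or from neutral is a switch like any other, which the
worked examples above fix unambiguously.

## Triadic emotional complexity

At the network level the elementary unit of emotional structure is the
closed triangle. A triangle is **incoherent** when its three words mix the
two polarities — at least one positive and one negative member — and
**coherent** otherwise; neutral creates no contrast, so all-neutral and
neutral-plus-one-polarity triangles are coherent. This is a node-attribute
analog of structural balance theory, which classifies triangles by *edge*
signs. The degree of emotional complexity of a labeled network is

  c = n_incoherent / (n_coherent + n_incoherent),

the complement of the coherent fraction. The full ten-signature taxonomy:

```{r taxonomy}
census <- triad_census(
  # one planted triangle per signature would do; here a random fixture
  local({
    g <- igraph::sample_gnp(12, 0.5)
    igraph::V(g)$name <- paste0("w", 1:12)
    igraph::V(g)$valence <- sample(c("positive", "negative", "neutral"),
                                   12, replace = TRUE)
    g
  })
)
tidy(census)
glance(census)
```

Sliding (ordered) triads complement the census at the list level:
`ordered_triad_counts()` counts consecutive label triples such as `+-+`,
the signature of a positive-negative-positive flicker inside a single
narrative, which unordered triangles cannot see.

## Null models and what each one tests

Both randomizations hold everything fixed except the valence labels:

* **Shuffled** permutes the observed labels (across a list's positions, or
  across the network's nodes). Every iteration conserves the empirical
  label histogram exactly; it asks whether the observed statistic could
  arise from the observed *composition* placed without structure.
* **Uniform** redraws each label independently and uniformly over the
  three classes. It additionally destroys composition; for any topology
  the expected complexity under this model is
  `1 - 2 (2/3)^3 + (1/3)^3 = 4/9` by inclusion-exclusion per triangle,
  a closed form the test suite checks to Monte-Carlo precision.

Departures are summarized as `z = (observed - null mean) / null sd`, with
`|z| > 1.96` flagged. A degenerate null (zero spread — e.g. an all-neutral
network under shuffling) yields an explicit `undefined` flag rather than an
infinite z. Default iteration counts are 500 at both levels; both are
arguments. Because the Shuffled model conserves composition, its
per-signature counts are mutually dependent — the package follows the
convention of reporting the ensemble-level complexity `c` alongside
per-signature z-scores rather than attempting a covariance correction.

Emotion profiling uses the same z-score logic against a resampling null:
the richness `r_i = m_i / N` (fraction of a text's `N` words eliciting
emotion `i`; unknown words count in `N` and elicit nothing) is compared
against 1,000 samples of equal size drawn without replacement from a pool —
by default the largest connected component of the full co-occurrence
network minus stopwords, so that the baseline respects connectivity rather
than raw text frequency. Both one-sided and two-sided readings of the 1.96
threshold appear in the literature; the package reports signed z-scores and
flags `|z| > 1.96`, letting the analyst apply either convention. No
multiple-testing correction is applied across the eight emotions, matching
common practice for these displays; the raw z-scores are returned so any
correction can be layered on.

## The synthetic-data generator

Corpora of genuine farewell notes are ethically sensitive and cannot be
redistributed, so the package ships a generator that emulates the
*statistical shape* of such data end to end; every pipeline stage is
exercised against it. `generator_spec()` holds the conditions:

* 139 notes averaging 120 tokens, final sentences of 16 +/- 2 tokens
  (truncated at 3), body sentences of Poisson(12) length;
* valence usage mixes of 52/31/17 (positive/negative/neutral) for
  note-like material versus 48/22/30 for healthy recall-like material;
* 200 recall lists of exactly 10 distinct stems each, each respondent
  tagged with a screening score whose zero value defines the healthy
  subgroup;
* a 5,000 pseudo-word lexicon (1,600 positive / 1,300 negative / 2,100
  neutral) with a 475-stem emotional dictionary;
* first-order Markov valence dynamics: `P(next = j | current = i) =
  (1 - s) pi_j + s [i == j]` with stickiness `s = 0.15`, the minimal
  mechanism spanning coherent runs and frequent switching;
* Zipf-like word use within each valence class (exponent 1.5).

The last two defaults were calibrated against the reported shape of real
data of this kind: stickiness 0.15 reproduces weak positive edge-valence
homophily in the corpus network (Kendall tau around 0.04, significant at
n ~ 9,000 edges), and the Zipf exponent 1.5 reproduces the heavy clustering
of fluency networks, whose triangle counts are of the same order as their
link counts. Pseudo-words are class-tagged strings, so no real lexicon is
shipped; a real valence/emotion lexicon drops in through the same TSV
readers.

What the generator deliberately does *not* model: syntax or topical
semantics (tokens are exchangeable within a valence class), word sense,
higher-order valence dynamics, item-level screening responses, and
documents mixing languages. Tests passing on generated data therefore
certify the *pipeline mechanics and statistical behavior* — conservation
laws, calibration of z-scores, closed-form limits, directional parameter
recovery — not linguistic validity on real corpora.

A note on problem sizes: the package's own test suite runs the null models
at a few hundred iterations and the parameter-recovery experiment at 50
generated population pairs, sizes chosen so the full statistical battery
stays comfortably fast on a laptop while keeping Monte-Carlo error well
below the effects being tested.

## Numerical and design choices

* **Quantile convention.** `stats::quantile()` type 7 (inclusive linear
  interpolation). Boundary ties: `<= Q1` negative, `>= Q3` positive; when
  Q1 equals Q3 (massive central ties) strict inequalities apply, so the
  fully degenerate all-equal distribution is all neutral. The source data
  for such labelings rarely document their convention; this one is fixed,
  documented, and tested.
* **Tokenization.** Lowercase; sentences split at `.`, `!`, `?`; tokens
  split on anything but letters, digits and intra-word apostrophes.
  Notes with fewer than two sentences are dropped at load.
* **Stemming.** A small deterministic suffix-stripper (`-ness`, `-ing`,
  `-ed`, `-ies`, plural `-s`, ...; never below three characters) written
  for reproducibility rather than linguistic coverage; `stem_words()`
  documents its rule list, and `extract_emotional_lists()` accepts any
  deterministic stemmer in its place.
* **Negation.** Markers {not, no, never, n't, cannot, without}; scope is
  the single following token, matching the adjacent-bigram network model.
  Multiple antonyms resolve to the lexicographically first one present in
  the lexicon — deterministic and auditable.
* **Edge weights.** Bigram multiplicities are stored on edges but all
  Study-1 statistics use unweighted topology, consistent with the
  unweighted shortest paths in closeness.
* **Seeds.** Every random stage takes a `seed`; pipeline functions derive
  per-stage substreams from one top-level seed, so reports are
  bit-reproducible. RNG state of the caller is never disturbed.
* **Degenerate inputs.** Sequences shorter than 2 have no transitions
  (error); triangle-free networks have undefined `c` (flagged, and the
  network-level nulls refuse them with a clear message); zero-variance
  nulls flag z as undefined; a zero marginal invalidates the contingency
  test.

## Known limitations

Valence and emotion annotations are population-level norms: subjective or
contextual readings of a word are invisible, a limitation inherited from
the lexicon approach. Complexity considers only closed triads, not longer
cycles. The binomial link filter implements one explicit reading of
"co-occurring more often than frequency predicts"; alternative trial
definitions from the fluency-network literature can be expressed by
adjusting the filter's inputs but are not built in. And all group-level
statistics here are exactly that — group-level; nothing in this package
supports individual-level inference.
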