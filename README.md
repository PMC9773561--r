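# emonet

Cognitive-network analysis of emotional narratives: valence-annotated word
co-occurrence networks, emotion profiling against resampled baselines, and
two measures of how narratives organize affect — the **emotional entropy**
of valence transition sequences and the **triadic emotional complexity** of
emotional co-occurrence networks — tested against Shuffled and Uniform
label-randomization null models.

The package is aimed at researchers in cognitive network science and
mental-health text analytics who work with short, affect-dense documents
(farewell notes, emotional-recall fluency lists) and need group-level,
statistically controlled descriptions of their emotional structure. Because
such corpora are sensitive, a seeded synthetic-data generator reproduces
their statistical shape so the entire pipeline can be developed, tested and
demonstrated without any real data.

## The measures

**Emotional entropy.** An ordered list of emotional words maps to a valence
label sequence (positive/negative/neutral). Writing 0 when the next label
repeats the current one and 1 when it switches gives a binary indicator
string; the entropy (in bits)

    h = - p0 log2 p0 - p1 log2 p1,   0 log 0 := 0

measures whether affective switches are scattered uniformly through the
list (h near 1) or absent/clustered (h near 0). The canonical five-word
examples: labels (−, −, +, +, n) give indicators 0101 and h = 1; labels
(+, −, +, −, n) give 1111 and h = 0.

**Emotional complexity.** In a network whose nodes carry valence labels, a
closed triangle is *incoherent* iff it contains at least one positive and
one negative word (neutral contrasts with nothing). The complexity

    c = n_incoherent / (n_coherent + n_incoherent)

is the node-attribute analog of the degree of (im)balance in structural
balance theory. Both measures are compared against a **Shuffled** null
(labels permuted; composition conserved exactly) and a **Uniform** null
(labels iid uniform over three classes; E[c] = 4/9 for any topology), with
z-scores flagged at |z| > 1.96.

## Worked example

Everything below runs from scratch off the synthetic generator; the printed
numbers are what the code produces.

```r
library(emonet)

spec   <- generator_spec()                      # the study conditions
gl     <- gen_lexicon(spec, seed = 11)          # pseudo-word lexicon + dictionary
corpus <- as_note_corpus(gen_corpus(spec, gl$lexicon, seed = 12))

rep1 <- run_study1(corpus, gl$lexicon, seed = 13)
rep1
#> <study1_report>
#>   corpus: 139 notes (0 dropped at load)
#>   network (all sentences): 956 nodes, 7962 edges
#>   network (last sentences): 392 nodes, 1570 edges
#>   last words: 198 unique (pool 581)
#>   closeness rank test: H = 23.862, p = 1.03e-06
#>   sentiment contingency: chi2 = 51.612, p = 6.2e-12
#>   edge-valence homophily: tau = 0.0626, p = 1.01e-17
```

The closeness rank test compares the prominence (inverse average network
distance) of the words in each note's final sentence against every other
word; the homophily line is the Kendall correlation between the valence
polarities of linked words — weakly positive here, i.e. words tend to
co-occur with words of like valence.

```r
note_lists <- extract_emotional_lists(corpus, gl$dictionary,
                                      stem_fun = identity)
recalls    <- filter_screened(gen_recall_lists(spec, gl$dictionary, seed = 14))

rep2 <- run_study2(note_lists, recalls, n_iter = 500, seed = 15)
rep2
#> <study2_report>
#>   lists: 94 note-derived, 99 recall-derived
#>   entropy rank test: K = 1.317, p = 0.251
#>   complexity c: notes 0.7857, recalls 0.3506
```

The two populations switch affective state at statistically
indistinguishable rates (entropy test), yet the note-like network mixes
positive and negative words in its triangles far more than the healthy
recall-like network — the same dissociation the measures were designed to
expose. Null-model detail is one `tidy()` away:

```r
tidy(rep2$network_nulls$notes_uniform)
#> # A tibble: 11 × 7
#>    statistic observed null_mean null_sd       z significant defined
#>    <chr>        <dbl>     <dbl>   <dbl>   <dbl> <lgl>       <lgl>
#>  1 +++          0         0.508   1.08  -0.468  FALSE       TRUE
#>  4 +--          7         1.65    2.04   2.63   TRUE        TRUE
#> 11 c            0.786     0.454   0.258  1.29   FALSE       TRUE
#>  # ... (one row per triad signature plus one for c)
```

`glance()` methods summarize every report and fitted object in one row;
`autoplot()` draws the emotion z-score "flower", null-ensemble histograms
and triad censuses.

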