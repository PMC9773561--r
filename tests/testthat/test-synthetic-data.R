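test_that("generator specs validate their probability inputs", {
  expect_s3_class(generator_spec(), "generator_spec")
  expect_error(generator_spec(note_valence_mix = c(positive = 0.9,
                                                   negative = 0.2,
                                                   neutral = 0.1)),
               "sum to 1")
  expect_error(generator_spec(stickiness = 1), "stickiness")
  expect_error(generator_spec(lexicon_sizes = c(positive = 1,
                                                negative = 10,
                                                neutral = 10)),
               "at least 2")
})

test_that("the transition matrix is row-stochastic with the mix stationary", {
  mix <- c(positive = 0.5, negative = 0.3, neutral = 0.2)
  P <- valence_transition_matrix(mix, 0.4)
  expect_equal(unname(rowSums(P)), rep(1, 3))
  # stationarity: mix %*% P = mix
  expect_equal(as.numeric(mix[rownames(P)] %*% P), unname(mix[colnames(P)]),
               tolerance = 1e-12)
})

test_that("quartile labeling recovers the requested class sizes exactly", {
  spec <- generator_spec(lexicon_sizes = c(positive = 100, negative = 100,
                                           neutral = 200),
                         dictionary_size = 50)
  gl <- gen_lexicon(spec, seed = 2)
  relabeled <- assign_sentiment_labels(gl$lexicon[, c("word", "valence")])
  counts <- table(relabeled$sentiment_label)
  expect_equal(unname(counts["positive"]), 100)
  expect_equal(unname(counts["negative"]), 100)
  expect_equal(unname(counts["neutral"]), 200)
  # and with the package defaults
  gl2 <- gen_lexicon(generator_spec(), seed = 3)
  counts2 <- table(gl2$lexicon$sentiment_label)
  expect_equal(unname(counts2["positive"]), 1600)
  expect_equal(unname(counts2["negative"]), 1300)
})

test_that("lexicon generation is seed-deterministic with tunable emotions", {
  spec <- generator_spec(lexicon_sizes = c(positive = 30, negative = 30,
                                           neutral = 40),
                         dictionary_size = 20)
  a <- gen_lexicon(spec, seed = 10)
  b <- gen_lexicon(spec, seed = 10)
  expect_identical(a$lexicon, b$lexicon)
  expect_identical(a$dictionary, b$dictionary)

  none <- gen_lexicon(generator_spec(
    lexicon_sizes = c(positive = 30, negative = 30, neutral = 40),
    dictionary_size = 20, emotion_prob = 0
  ), seed = 10)
  emo_cols <- c("joy", "trust", "fear", "surprise", "sadness", "disgust",
                "anger", "anticipation")
  expect_false(any(as.matrix(none$lexicon[, emo_cols])))
})

test_that("a degenerate single-class mix yields zero-entropy lists", {
  spec <- generator_spec(
    n_notes = 6, note_length_mean = 60, note_length_sd = 5,
    note_valence_mix = c(positive = 1, negative = 0, neutral = 0),
    lexicon_sizes = c(positive = 300, negative = 200, neutral = 200),
    dictionary_size = 400, stopword_rate = 0.2
  )
  gl <- gen_lexicon(spec, seed = 21)
  corpus <- as_note_corpus(gen_corpus(spec, gl$lexicon, seed = 22))
  lists <- extract_emotional_lists(corpus, gl$dictionary, min_length = 2,
                                   stem_fun = identity)
  expect_true(all(lists$valence == "positive"))
  h <- list_entropies(lists)
  expect_true(all(h$h[!is.na(h$h)] == 0))
})

test_that("generated token mixes recover the spec within sampling error", {
  spec <- generator_spec(n_notes = 60, note_length_mean = 200,
                         note_length_sd = 10, stopword_rate = 0,
                         name_rate = 0, stickiness = 0)
  gl <- gen_lexicon(spec, seed = 31)
  corpus <- as_note_corpus(gen_corpus(spec, gl$lexicon, seed = 32))
  labs <- gl$lexicon$sentiment_label[match(corpus$token, gl$lexicon$word)]
  labs <- labs[!is.na(labs)]
  n <- length(labs)
  expect_gt(n, 5000)
  for (cls in c("positive", "negative", "neutral")) {
    p_hat <- mean(labs == cls)
    p <- spec$note_valence_mix[[cls]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(p_hat - p), 3 * se + 0.01)
  }
})

test_that("stickiness controls the same-label transition rate", {
  spec <- generator_spec(stickiness = 0.5,
                         recall_valence_mix = c(positive = 1 / 3,
                                                negative = 1 / 3,
                                                neutral = 1 / 3),
                         n_lists = 150, list_length = 10)
  gl <- gen_lexicon(spec, seed = 41)
  lists <- gen_recall_lists(spec, gl$dictionary, seed = 42)
  stay <- lists |>
    dplyr::group_by(source_id) |>
    dplyr::summarise(
      same = sum(valence[-1] == valence[-dplyr::n()]),
      trans = dplyr::n() - 1
    )
  p_hat <- sum(stay$same) / sum(stay$trans)
  # P(stay) = s + (1-s) * sum(pi^2) = 0.5 + 0.5/3
  p_theory <- 0.5 + 0.5 * (1 / 3)
  se <- sqrt(p_theory * (1 - p_theory) / sum(stay$trans))
  expect_lt(abs(p_hat - p_theory), 3 * se + 0.01)
})

test_that("recall lists have exact lengths, unique stems and screen filters", {
  spec <- generator_spec(n_lists = 40, list_length = 10)
  gl <- gen_lexicon(spec, seed = 51)
  lists <- gen_recall_lists(spec, gl$dictionary, seed = 52)
  sizes <- dplyr::count(lists, source_id)
  expect_true(all(sizes$n == 10))
  dup <- lists |>
    dplyr::group_by(source_id) |>
    dplyr::summarise(d = anyDuplicated(stem))
  expect_true(all(dup$d == 0))

  healthy <- filter_screened(lists)
  expect_true(all(healthy$screening_score == 0))
  expect_error(filter_screened(dplyr::select(lists, -screening_score)),
               "screening_score")

  a <- gen_recall_lists(spec, gl$dictionary, seed = 52)
  expect_identical(as.data.frame(a), as.data.frame(lists))

  tiny_dict <- emotional_dictionary(c("one", "two"), c("positive", "negative"))
  expect_error(gen_recall_lists(spec, tiny_dict, seed = 1),
               "dictionary size")
})

test_that("screen filtering keeps exactly the zero-score respondents", {
  lists <- emotional_word_lists(tibble::tibble(
    source_id = rep(c("r1", "r2", "r3", "r4"), each = 2),
    position = rep(1:2, 4),
    stem = paste0("s", 1:8),
    valence = rep(c("positive", "negative"), 4),
    screening_score = rep(c(0L, 0L, 3L, 1L), each = 2)
  ))
  kept <- filter_screened(lists)
  expect_setequal(unique(kept$source_id), c("r1", "r2"))
})

test_that("corpus shape tracks the spec: lengths and final sentences", {
  spec <- generator_spec(n_notes = 50)
  gl <- gen_lexicon(spec, seed = 61)
  raw <- gen_corpus(spec, gl$lexicon, seed = 62)
  expect_equal(nrow(raw), 50)
  corpus <- as_note_corpus(raw)
  tok_per_note <- dplyr::count(corpus, note_id)
  expect_lt(abs(mean(tok_per_note$n) - spec$note_length_mean), 15)

  last_lens <- corpus |>
    dplyr::group_by(note_id) |>
    dplyr::filter(sentence == max(sentence)) |>
    dplyr::count(note_id)
  expect_lt(abs(mean(last_lens$n) - 16), 2.5)
  expect_gt(min(last_lens$n), 2)
})
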