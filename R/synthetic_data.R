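#' Specification for the synthetic data generator
#'
#' Collects every tunable of the generator in one validated list. The
#' defaults describe the study conditions this package is built around: a
#' corpus of 139 short notes averaging 120 tokens with final sentences of
#' 16 +/- 2 tokens, 200 recall lists of exactly 10 emotional words, a
#' note-like valence mixture of 52/31/17 (positive/negative/neutral
#' emotional-state usage) versus 48/22/30 for healthy recalls, a 475-stem
#' emotional dictionary drawn from a 5,000-pseudo-word lexicon, Zipf-like
#' word frequencies within each valence class, and a first-order Markov
#' chain over valence classes whose stickiness induces weak positive
#' edge-valence homophily.
#'
#' @param n_notes Number of notes in a generated corpus.
#' @param note_length_mean,note_length_sd Total tokens per note
#'   (normal, truncated at 25).
#' @param last_sentence_length_mean,last_sentence_length_sd Tokens in the
#'   final sentence (normal, truncated at 3).
#' @param body_sentence_length_mean Mean tokens per body sentence (Poisson).
#' @param note_valence_mix Named probabilities (`positive`, `negative`,
#'   `neutral`) of emotional-state classes in notes; must sum to 1.
#' @param recall_valence_mix Same, for recall lists.
#' @param stickiness Probability mass moved onto self-transitions of the
#'   valence Markov chain, in \[0, 1); 0 gives independent draws from the
#'   mix, values near 1 give long single-valence runs.
#' @param n_lists,list_length Recall lists: how many, and exactly how many
#'   stems each.
#' @param lexicon_sizes Named counts of lexicon pseudo-words per sentiment
#'   class (`positive`, `negative`, `neutral`). Each extreme class must hold
#'   at least a quartile of the lexicon for exact label recovery (see
#'   [gen_lexicon()]).
#' @param dictionary_size Number of lexicon words flagged as emotional
#'   stems.
#' @param emotion_prob Per-emotion Bernoulli probability that a lexicon
#'   word elicits each of the 8 emotions.
#' @param zipf_exponent Within-class word-frequency decay (rank^-s).
#' @param stopword_rate Fraction of note tokens that are stopwords.
#' @param name_rate Rate of anonymized-name placeholder tokens in notes.
#' @param p_screen_zero Probability that a respondent's screening score is
#'   0 (the "healthy" filter value); nonzero scores are 1 + Poisson(8).
#' @return A validated list of class `generator_spec`.
#' @export
generator_spec <- function(n_notes = 139,
                           note_length_mean = 120,
                           note_length_sd = 25,
                           last_sentence_length_mean = 16,
                           last_sentence_length_sd = 2,
                           body_sentence_length_mean = 12,
                           note_valence_mix = c(positive = 0.52,
                                                negative = 0.31,
                                                neutral = 0.17),
                           recall_valence_mix = c(positive = 0.48,
                                                  negative = 0.22,
                                                  neutral = 0.30),
                           stickiness = 0.15,
                           n_lists = 200,
                           list_length = 10,
                           lexicon_sizes = c(positive = 1600,
                                             negative = 1300,
                                             neutral = 2100),
                           dictionary_size = 475,
                           emotion_prob = 0.12,
                           zipf_exponent = 1.5,
                           stopword_rate = 0.40,
                           name_rate = 0.01,
                           p_screen_zero = 0.5) {
  spec <- list(
    n_notes = n_notes,
    note_length_mean = note_length_mean,
    note_length_sd = note_length_sd,
    last_sentence_length_mean = last_sentence_length_mean,
    last_sentence_length_sd = last_sentence_length_sd,
    body_sentence_length_mean = body_sentence_length_mean,
    note_valence_mix = note_valence_mix[VALENCE_LEVELS],
    recall_valence_mix = recall_valence_mix[VALENCE_LEVELS],
    stickiness = stickiness,
    n_lists = n_lists,
    list_length = list_length,
    lexicon_sizes = lexicon_sizes[VALENCE_LEVELS],
    dictionary_size = dictionary_size,
    emotion_prob = emotion_prob,
    zipf_exponent = zipf_exponent,
    stopword_rate = stopword_rate,
    name_rate = name_rate,
    p_screen_zero = p_screen_zero
  )
  for (mx in c("note_valence_mix", "recall_valence_mix")) {
    v <- spec[[mx]]
    if (anyNA(v) || abs(sum(v) - 1) > 1e-8 || any(v < 0)) {
      abort(sprintf("`%s` must be nonnegative and sum to 1 over %s",
                    mx, paste(VALENCE_LEVELS, collapse = "/")))
    }
  }
  if (anyNA(spec$lexicon_sizes) || any(spec$lexicon_sizes < 2)) {
    abort("each lexicon valence class needs at least 2 words")
  }
  if (spec$stickiness < 0 || spec$stickiness >= 1) {
    abort("`stickiness` must lie in [0, 1)")
  }
  counts <- c(spec$n_notes, spec$n_lists, spec$list_length,
              spec$dictionary_size)
  if (any(counts < 1)) abort("all counts must be positive")
  class(spec) <- "generator_spec"
  spec
}

#' Valence transition matrix implied by a spec
#'
#' The first-order Markov chain over valence classes used by the
#' generator: `P(next = j | current = i) = (1 - s) * mix_j + s * [i == j]`,
#' a stationary chain with the target mixture as its stationary
#' distribution and stickiness `s` controlling run lengths.
#'
#' @param mix Named stationary probabilities over the valence classes.
#' @param stickiness Self-transition boost `s` in \[0, 1).
#' @return 3x3 row-stochastic matrix with valence-class dimnames.
#' @export
valence_transition_matrix <- function(mix, stickiness) {
  mix <- mix[VALENCE_LEVELS]
  P <- matrix(rep(mix, each = 3) * (1 - stickiness), nrow = 3,
              dimnames = list(VALENCE_LEVELS, VALENCE_LEVELS))
  diag(P) <- diag(P) + stickiness
  if (any(rowSums(P) - 1 > 1e-8) || any(!is.finite(P))) {
    abort("degenerate transition matrix row")
  }
  P
}

# sample a length-n label chain from the stationary mixture
sample_valence_chain <- function(n, mix, stickiness) {
  P <- valence_transition_matrix(mix, stickiness)
  out <- character(n)
  out[1] <- sample(VALENCE_LEVELS, 1, prob = mix[VALENCE_LEVELS])
  if (n > 1) {
    for (i in 2:n) {
      out[i] <- sample(VALENCE_LEVELS, 1, prob = P[out[i - 1], ])
    }
  }
  out
}

# Zipf-like sampling weights for a class of m words
zipf_weights <- function(m, s) {
  w <- seq_len(m)^(-s)
  w / sum(w)
}

#' Generate a pseudo-word affective lexicon and emotional dictionary
#'
#' Produces `sum(lexicon_sizes)` pseudo-words (class-tagged random strings,
#' so no real lexicon is shipped or needed). All words of one valence class
#' share one valence score (2 / 5 / 8 for negative / neutral / positive), so
#' quartile labeling by [assign_sentiment_labels()] recovers the requested
#' class sizes exactly whenever each extreme class holds at least a quartile
#' of the lexicon. Each of the 8 emotions is assigned to each word by an
#' independent Bernoulli(`emotion_prob`) flip. A `dictionary_size` subset is
#' flagged as emotional stems (sampled uniformly across classes) and
#' returned as the emotional dictionary.
#'
#' @param spec A [generator_spec()].
#' @param seed Optional integer seed.
#' @return List with elements `lexicon` (an [affect_lexicon()]) and
#'   `dictionary` (an [emotional_dictionary()]).
#' @export
gen_lexicon <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  sizes <- spec$lexicon_sizes
  with_seed_or_not(seed, {
    words <- unlist(purrr::imap(as.list(sizes), function(k, cls) {
      sprintf("%s%04d", substr(cls, 1, 3), seq_len(k))
    }), use.names = FALSE)
    cls <- rep(names(sizes), sizes)
    score <- c(positive = 8, negative = 2, neutral = 5)[cls]
    lex <- affect_lexicon(tibble(word = words, valence = unname(score)))
    for (e in EMOTIONS) {
      lex[[e]] <- runif(nrow(lex)) < spec$emotion_prob
    }
    if (spec$dictionary_size > nrow(lex)) {
      abort("`dictionary_size` exceeds the lexicon size")
    }
    dict_words <- sort(sample(lex$word, spec$dictionary_size))
    dict <- emotional_dictionary(
      stems = dict_words,
      valence_label = lex$sentiment_label[match(dict_words, lex$word)]
    )
    list(lexicon = lex, dictionary = dict)
  })
}

# draw n content words: valence chain + Zipf pick within class
sample_content_words <- function(n, mix, spec, lexicon) {
  chain <- sample_valence_chain(n, mix, spec$stickiness)
  by_class <- split(lexicon$word, lexicon$sentiment_label)
  weights <- lapply(by_class, function(w) zipf_weights(length(w),
                                                       spec$zipf_exponent))
  vapply(chain, function(cl) {
    sample(by_class[[cl]], 1, prob = weights[[cl]])
  }, character(1))
}

#' Generate a synthetic note corpus
#'
#' Each note's content words follow a first-order Markov chain over valence
#' classes (then a Zipf-weighted word draw within the class), interleaved
#' with stopwords at `stopword_rate` and occasional anonymized-name
#' placeholders (`personN`). Tokens are segmented into sentences: body
#' sentences of Poisson length and a final sentence of normal length
#' (mean 16, sd 2, truncated at 3).
#'
#' @param spec A [generator_spec()].
#' @param lexicon An [affect_lexicon()] from [gen_lexicon()].
#' @param seed Optional integer seed.
#' @return Tibble with columns `note_id`, `text`; pipe into
#'   [as_note_corpus()] to tokenize.
#' @export
gen_corpus <- function(spec, lexicon, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  stopwords <- default_stopwords()
  with_seed_or_not(seed, {
    texts <- vapply(seq_len(spec$n_notes), function(i) {
      total <- max(25, round(rnorm(1, spec$note_length_mean,
                                   spec$note_length_sd)))
      last_len <- max(3, round(rnorm(1, spec$last_sentence_length_mean,
                                     spec$last_sentence_length_sd)))
      body_len <- max(5, total - last_len)

      n_content <- stats::rbinom(1, total, 1 - spec$stopword_rate)
      n_content <- max(n_content, 3)
      content <- sample_content_words(n_content, spec$note_valence_mix,
                                      spec, lexicon)
      # interleave stopwords / placeholders to reach the target length
      tokens <- character(total)
      content_slots <- sort(sample.int(total, n_content))
      tokens[content_slots] <- content
      fill <- which(tokens == "")
      tokens[fill] <- sample(stopwords, length(fill), replace = TRUE)
      is_name <- runif(total) < spec$name_rate
      tokens[is_name] <- sprintf("person%d", sample.int(50, sum(is_name),
                                                        replace = TRUE))

      # sentence segmentation: body then the final farewell sentence
      body <- tokens[seq_len(body_len)]
      last <- tokens[(body_len + 1):min(total, body_len + last_len)]
      sent_lens <- integer(0)
      remaining <- length(body)
      while (remaining > 0) {
        l <- min(remaining, max(2, rpois(1, spec$body_sentence_length_mean)))
        # never leave a trailing 1-token fragment
        if (remaining - l == 1) l <- l + 1
        sent_lens <- c(sent_lens, l)
        remaining <- remaining - l
      }
      sentences <- split(body, rep(seq_along(sent_lens), sent_lens))
      paste(
        c(vapply(sentences, paste, character(1), collapse = " "),
          paste(last, collapse = " ")),
        collapse = ". "
      )
    }, character(1))
    tibble(note_id = sprintf("note%03d", seq_len(spec$n_notes)),
           text = paste0(texts, "."))
  })
}

#' Generate ERT-like emotional recall lists
#'
#' Each of `n_lists` respondents contributes exactly `list_length` distinct
#' dictionary stems: a valence chain is drawn from the recall mixture and
#' each state is realized as a Zipf-weighted draw (without replacement
#' within the list) from the dictionary stems of that class. Every list is
#' tagged with a screening score (0 with probability `p_screen_zero`, else
#' positive), emulating a symptom-scale total used to select the healthy
#' comparison group.
#'
#' @param spec A [generator_spec()].
#' @param dictionary An [emotional_dictionary()].
#' @param mix Valence mixture to use (defaults to `spec$recall_valence_mix`;
#'   pass `spec$note_valence_mix` to generate note-like lists).
#' @param seed Optional integer seed.
#' @return An [`emotional_word_lists`][emotional_word_lists] tibble with an
#'   extra `screening_score` column.
#' @export
gen_recall_lists <- function(spec, dictionary, mix = NULL, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  mix <- mix %||% spec$recall_valence_mix
  by_class <- split(dictionary$stem, dictionary$valence_label)
  if (spec$list_length > nrow(dictionary)) {
    abort("`list_length` exceeds the dictionary size")
  }
  with_seed_or_not(seed, {
    rows <- purrr::map(seq_len(spec$n_lists), function(i) {
      chain <- sample_valence_chain(spec$list_length, mix, spec$stickiness)
      used <- character(0)
      stems <- vapply(chain, function(cl) {
        avail <- setdiff(by_class[[cl]], used)
        if (length(avail) > 0) {
          w <- zipf_weights(length(by_class[[cl]]), spec$zipf_exponent)
          w <- w[match(avail, by_class[[cl]])]
        } else {  # class exhausted within this list: fall back to any stem
          avail <- setdiff(dictionary$stem, used)
          if (length(avail) == 0) {
            abort("`list_length` exceeds the dictionary size")
          }
          w <- rep(1, length(avail))
        }
        pick <- if (length(avail) == 1) avail else sample(avail, 1, prob = w)
        used <<- c(used, pick)
        pick
      }, character(1))
      tibble(
        source_id = sprintf("resp%03d", i),
        position = seq_len(spec$list_length),
        stem = stems,
        valence = dictionary$valence_label[match(stems, dictionary$stem)]
      )
    })
    score <- ifelse(runif(spec$n_lists) < spec$p_screen_zero, 0L,
                    1L + rpois(spec$n_lists, 8))
    df <- bind_rows(rows)
    df$screening_score <- score[as.integer(sub("resp", "", df$source_id))]
    emotional_word_lists(df)
  })
}

#' Keep only lists from screened (score-0) respondents
#'
#' @param lists Lists carrying a `screening_score` column.
#' @param max_score Highest score retained (default 0, the healthy filter).
#' @return Filtered [`emotional_word_lists`][emotional_word_lists].
#' @export
filter_screened <- function(lists, max_score = 0) {
  if (!"screening_score" %in% names(lists)) {
    abort("`lists` carries no screening_score column")
  }
  out <- filter(as_tibble(lists), .data$screening_score <= max_score)
  emotional_word_lists(out)
}
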