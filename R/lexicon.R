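#' Derive three-way sentiment labels from valence scores
#'
#' Discretizes continuous valence scores into `negative` / `neutral` /
#' `positive` labels using the quartiles of the score distribution over the
#' whole lexicon: scores at or below the first quartile are negative, scores
#' at or above the third quartile are positive, everything between is
#' neutral. Quartiles use the inclusive linear-interpolation rule
#' (`stats::quantile()` type 7). When the two quartiles coincide (heavy ties,
#' or all scores equal) strict inequalities are applied, so a fully
#' degenerate distribution is labeled entirely neutral.
#'
#' @param valence_scores A data frame with columns `word` and `valence`, or a
#'   named numeric vector of scores.
#' @return A tibble with columns `word`, `valence`, `sentiment_label`.
#' @examples
#' assign_sentiment_labels(tibble::tibble(word = letters[1:8], valence = 1:8))
#' @export
assign_sentiment_labels <- function(valence_scores) {
  if (is.numeric(valence_scores)) {
    if (is.null(names(valence_scores))) {
      abort("`valence_scores` given as a vector must be named by word")
    }
    valence_scores <- tibble(
      word = names(valence_scores),
      valence = unname(valence_scores)
    )
  }
  df <- as_tibble(valence_scores)
  if (!all(c("word", "valence") %in% names(df))) {
    abort("`valence_scores` needs columns `word` and `valence`")
  }
  if (nrow(df) == 0) abort("empty lexicon")
  bad <- df$word[!is.finite(df$valence)]
  if (length(bad) > 0) {
    abort(sprintf("non-finite valence score for word(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (nrow(df) < 4) abort("need at least 4 scored words to form quartiles")

  q <- quantile(df$valence, c(0.25, 0.75), type = 7, names = FALSE)
  lab <- if (q[1] == q[2]) {
    dplyr::case_when(
      df$valence < q[1] ~ "negative",
      df$valence > q[2] ~ "positive",
      TRUE ~ "neutral"
    )
  } else {
    dplyr::case_when(
      df$valence <= q[1] ~ "negative",
      df$valence >= q[2] ~ "positive",
      TRUE ~ "neutral"
    )
  }
  df$sentiment_label <- lab
  df
}

#' Build an affective lexicon
#'
#' Combines a valence table and (optionally) an emotion table into a single
#' annotated lexicon: every word carries a valence score, a quartile-derived
#' sentiment label (see [assign_sentiment_labels()]), a membership flag for
#' each of the eight basic emotions (joy, trust, fear, surprise, sadness,
#' disgust, anger, anticipation), and a lowercase stem.
#'
#' @param valence A data frame with columns `word`, `valence` (or a named
#'   numeric vector).
#' @param emotions Optional data frame in long form (`word`, `emotion`,
#'   `flag` in 0/1) or wide form (`word` plus one 0/1 or logical column per
#'   emotion). Missing words elicit no emotion.
#' @return A tibble of class `affect_lexicon` with columns `word`, `valence`,
#'   `sentiment_label`, `stem`, and one logical column per emotion.
#' @export
affect_lexicon <- function(valence, emotions = NULL) {
  lex <- assign_sentiment_labels(valence)
  lex$word <- tolower(lex$word)
  if (anyDuplicated(lex$word)) {
    lex <- dplyr::distinct(lex, .data$word, .keep_all = TRUE)
  }
  lex$stem <- stem_words(lex$word)

  for (e in EMOTIONS) lex[[e]] <- FALSE
  if (!is.null(emotions)) {
    emo <- as_tibble(emotions)
    if (all(c("word", "emotion") %in% names(emo))) {
      if (!"flag" %in% names(emo)) emo$flag <- 1L
      emo <- filter(emo, .data$flag > 0, .data$emotion %in% EMOTIONS)
      emo$word <- tolower(emo$word)
      idx <- match(emo$word, lex$word)
      ok <- !is.na(idx)
      for (e in unique(emo$emotion[ok])) {
        lex[[e]][idx[ok & emo$emotion == e]] <- TRUE
      }
    } else if ("word" %in% names(emo)) {
      emo$word <- tolower(emo$word)
      idx <- match(emo$word, lex$word)
      ok <- !is.na(idx)
      for (e in intersect(EMOTIONS, names(emo))) {
        lex[[e]][idx[ok]] <- as.logical(emo[[e]][ok]) %in% TRUE
      }
    } else {
      abort("`emotions` needs a `word` column")
    }
  }
  class(lex) <- c("affect_lexicon", class(lex))
  lex
}

#' @export
print.affect_lexicon <- function(x, ...) {
  cat(sprintf(
    "<affect_lexicon> %d words (%d negative / %d neutral / %d positive)\n",
    nrow(x),
    sum(x$sentiment_label == "negative"),
    sum(x$sentiment_label == "neutral"),
    sum(x$sentiment_label == "positive")
  ))
  NextMethod()
}

#' Look up the emotions elicited by a word
#'
#' Case-insensitive lookup of a word's emotion set in an affective lexicon.
#' Unknown words elicit no emotion and return an empty character vector.
#'
#' @param word A single word.
#' @param lexicon An [affect_lexicon()].
#' @return Character vector of emotion names (possibly empty).
#' @export
emotions_of <- function(word, lexicon) {
  stopifnot(length(word) == 1)
  i <- match(tolower(word), lexicon$word)
  if (is.na(i)) return(character(0))
  EMOTIONS[vapply(EMOTIONS, function(e) isTRUE(lexicon[[e]][i]), logical(1))]
}

#' Look up a word's sentiment label (internal helper)
#'
#' @return One of "positive"/"negative"/"neutral"; unknown words are neutral.
#' @noRd
sentiment_of <- function(words, lexicon) {
  i <- match(tolower(words), lexicon$word)
  out <- lexicon$sentiment_label[i]
  out[is.na(out)] <- "neutral"
  out
}

#' Resolve a negated token to its affective replacement
#'
#' Implements the negation rule used throughout the pipeline: when a negation
#' marker (`not`, `no`, `never`, `n't`, `cannot`, `without`) immediately
#' precedes a content word, that word is replaced by an antonym so the
#' negated phrase contributes the opposite affect (e.g. "not good" is counted
#' as "bad"). When several antonyms exist, the lexicographically first among
#' those present in the lexicon (falling back to the table at large) is
#' chosen. When no antonym is available the original token is kept but its
#' sentiment label is inverted (positive and negative swap, neutral stays).
#'
#' @param negator The negation marker token.
#' @param word The token immediately following the negator.
#' @param lexicon An [affect_lexicon()].
#' @param antonyms A data frame with columns `word`, `antonym` (see
#'   [read_antonym_table()]).
#' @return A list with elements `token` (the replacement token),
#'   `sentiment_label` (its effective label), and `how` (one of
#'   `"antonym"`, `"inverted"`).
#' @examples
#' lex <- affect_lexicon(tibble::tibble(
#'   word = c("good", "bad", "fine", "awful", "table", "chair"),
#'   valence = c(8, 2, 6, 1, 5, 5)
#' ))
#' ant <- tibble::tibble(word = "good", antonym = "bad")
#' resolve_negation("not", "good", lex, ant)
#' @export
resolve_negation <- function(negator, word, lexicon, antonyms = NULL) {
  if (!tolower(negator) %in% NEGATION_MARKERS) {
    abort(sprintf("'%s' is not a recognized negation marker", negator))
  }
  w <- tolower(word)
  cands <- character(0)
  if (!is.null(antonyms) && nrow(antonyms) > 0) {
    cands <- sort(tolower(antonyms$antonym[tolower(antonyms$word) == w]))
  }
  if (length(cands) > 0) {
    in_lex <- cands[cands %in% lexicon$word]
    pick <- if (length(in_lex) > 0) in_lex[1] else cands[1]
    return(list(
      token = pick,
      sentiment_label = sentiment_of(pick, lexicon),
      how = "antonym"
    ))
  }
  lab <- sentiment_of(w, lexicon)
  inv <- c(positive = "negative", negative = "positive", neutral = "neutral")
  list(token = w, sentiment_label = unname(inv[lab]), how = "inverted")
}

#' Apply the negation rule along a token sequence
#'
#' Scans a token sequence for negation markers and replaces each marker plus
#' its immediately following token by the resolution of
#' [resolve_negation()]; the marker itself is dropped from the affective
#' count. Tokens outside negation scope pass through with their lexicon
#' label.
#'
#' @param tokens Character vector of tokens in text order.
#' @inheritParams resolve_negation
#' @return A tibble with columns `token` (effective token),
#'   `sentiment_label` (effective label) and `negated` (logical).
#' @export
resolve_negations <- function(tokens, lexicon, antonyms = NULL) {
  n <- length(tokens)
  keep_token <- character(0)
  keep_label <- character(0)
  keep_neg <- logical(0)
  i <- 1L
  while (i <= n) {
    tok <- tolower(tokens[i])
    if (tok %in% NEGATION_MARKERS && i < n) {
      res <- resolve_negation(tok, tokens[i + 1L], lexicon, antonyms)
      keep_token <- c(keep_token, res$token)
      keep_label <- c(keep_label, res$sentiment_label)
      keep_neg <- c(keep_neg, TRUE)
      i <- i + 2L
    } else {
      keep_token <- c(keep_token, tok)
      keep_label <- c(keep_label, sentiment_of(tok, lexicon))
      keep_neg <- c(keep_neg, FALSE)
      i <- i + 1L
    }
  }
  tibble(token = keep_token, sentiment_label = keep_label, negated = keep_neg)
}

# ---- file readers (plain TSV dialects) --------------------------------------

#' Read a two-column valence lexicon (word TAB score)
#'
#' @param path Path to a TSV file with columns word, score (no header or
#'   header `word`/`valence` accepted).
#' @return Tibble with columns `word`, `valence`.
#' @export
read_valence_lexicon <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2) abort("valence lexicon must have two columns")
  df <- df[, 1:2]
  names(df) <- c("word", "valence")
  if (is.character(df$valence)) {  # header row present
    df <- df[-1, ]
    df$valence <- as.numeric(df$valence)
  }
  df$word <- tolower(as.character(df$word))
  df
}

#' Read a three-column emotion lexicon (word TAB emotion TAB 0/1)
#'
#' @param path Path to a TSV file with columns word, emotion, flag.
#' @return Tibble with columns `word`, `emotion`, `flag`.
#' @export
read_emotion_lexicon <- function(path) {
  df <- readr::read_tsv(path, col_names = c("word", "emotion", "flag"),
                        show_col_types = FALSE, progress = FALSE)
  if (is.character(df$flag)) {
    df <- df[df$flag %in% c("0", "1"), ]
    df$flag <- as.integer(df$flag)
  }
  df$word <- tolower(df$word)
  df$emotion <- tolower(df$emotion)
  df
}

#' Read an emotional dictionary of stems
#'
#' One stem per line, with an optional second (tab-separated) column carrying
#' a valence label. Stems without a label are labeled from `lexicon` when
#' given, else neutral.
#'
#' @param path Path to the stem list.
#' @param lexicon Optional [affect_lexicon()] used to label unlabeled stems.
#' @return A tibble of class `emotional_dictionary` with columns `stem`,
#'   `valence_label`.
#' @export
read_emotional_dictionary <- function(path, lexicon = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stems <- tolower(vapply(parts, `[[`, character(1), 1))
  labels <- vapply(parts, function(p) if (length(p) >= 2) tolower(p[[2]]) else NA_character_,
                   character(1))
  if (anyNA(labels) && !is.null(lexicon)) {
    labels[is.na(labels)] <- sentiment_of(stems[is.na(labels)], lexicon)
  }
  labels[is.na(labels)] <- "neutral"
  emotional_dictionary(stems, labels)
}

#' Construct an emotional dictionary from stems and valence labels
#'
#' @param stems Character vector of stems (lowercased, deduplicated).
#' @param valence_label Valence label per stem.
#' @return Tibble of class `emotional_dictionary`.
#' @export
emotional_dictionary <- function(stems, valence_label) {
  stems <- tolower(stems)
  assert_valence_labels(valence_label, "valence_label")
  d <- distinct(tibble(stem = stems, valence_label = valence_label),
                .data$stem, .keep_all = TRUE)
  class(d) <- c("emotional_dictionary", class(d))
  d
}

#' Read an antonym table (word TAB antonym)
#'
#' @param path Path to a two-column TSV.
#' @return Tibble with columns `word`, `antonym`.
#' @export
read_antonym_table <- function(path) {
  df <- readr::read_tsv(path, col_names = c("word", "antonym"),
                        show_col_types = FALSE, progress = FALSE)
  df$word <- tolower(df$word)
  df$antonym <- tolower(df$antonym)
  df
}
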