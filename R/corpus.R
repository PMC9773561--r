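#' Default English stopword list
#'
#' A fixed, versioned stopword list shipped with the package (function
#' words, pronouns, auxiliaries). Used when flagging tokens at corpus load;
#' note that stopwords are *flagged*, not removed — the co-occurrence
#' network deliberately keeps them as nodes.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "emonet")
  readr::read_lines(path, progress = FALSE)
}

#' Split raw text into sentences of lowercase tokens
#'
#' Sentence boundaries are `.`, `!`, `?`; tokens are lowercased and split on
#' anything that is not a letter, digit or intra-word apostrophe.
#'
#' @param text A single character string.
#' @return List of character vectors, one per non-empty sentence.
#' @export
tokenize_text <- function(text) {
  stopifnot(length(text) == 1)
  sentences <- strsplit(text, "[.!?]+")[[1]]
  toks <- lapply(sentences, function(s) {
    s <- tolower(s)
    t <- strsplit(s, "[^a-z0-9']+")[[1]]
    t <- gsub("^'+|'+$", "", t)  # trim quote apostrophes, keep don't
    t[nzchar(t)]
  })
  toks[vapply(toks, length, integer(1)) > 0]
}

#' Assemble a tokenized note corpus from a table of raw texts
#'
#' Tokenizes each note into sentences (see [tokenize_text()]), flags
#' stopwords and anonymized-name placeholders, and drops notes with fewer
#' than `min_sentences` sentences. The result is a long tibble: one row per
#' token, with its note, sentence index and position.
#'
#' @param df Data frame with columns `note_id`, `text`.
#' @param stopwords Character vector of stopwords to flag.
#' @param name_pattern Regex matching name-placeholder tokens (the corpora
#'   this package targets are pre-anonymized with placeholder names).
#' @param min_sentences Minimum sentences for a note to be retained.
#' @return A tibble of class `note_corpus` with columns `note_id`,
#'   `sentence`, `position`, `token`, `is_stopword`, `is_name`. The number
#'   of dropped notes is stored in `attr(, "n_dropped")`.
#' @export
as_note_corpus <- function(df, stopwords = default_stopwords(),
                           name_pattern = "^person[0-9]+$",
                           min_sentences = 2) {
  df <- as_tibble(df)
  if (!all(c("note_id", "text") %in% names(df))) {
    abort("`df` needs columns `note_id` and `text`")
  }
  rows <- purrr::map2(df$note_id, df$text, function(id, txt) {
    sent <- tokenize_text(txt)
    if (length(sent) < min_sentences) return(NULL)
    tibble(
      note_id = as.character(id),
      sentence = rep(seq_along(sent), lengths(sent)),
      token = unlist(sent, use.names = FALSE)
    )
  })
  n_dropped <- sum(vapply(rows, is.null, logical(1)))
  corpus <- bind_rows(rows)
  if (nrow(corpus) == 0) abort("empty corpus after filtering short notes")
  corpus <- corpus %>%
    group_by(.data$note_id, .data$sentence) %>%
    mutate(position = row_number()) %>%
    ungroup() %>%
    mutate(
      is_stopword = .data$token %in% stopwords,
      is_name = grepl(name_pattern, .data$token)
    ) %>%
    select("note_id", "sentence", "position", "token",
           "is_stopword", "is_name")
  attr(corpus, "n_dropped") <- n_dropped
  class(corpus) <- c("note_corpus", class(corpus))
  corpus
}

#' Load a note corpus from disk
#'
#' Accepts either a CSV file with columns `note_id,text` or a directory of
#' `.txt` files (one note per file; the file name becomes the note id).
#' Notes with fewer than `min_sentences` sentences are excluded, matching
#' the usual preprocessing of short-text corpora.
#'
#' @param path CSV file or directory of .txt files.
#' @inheritParams as_note_corpus
#' @return A [`note_corpus`][as_note_corpus] tibble.
#' @export
load_corpus <- function(path, stopwords = default_stopwords(),
                        name_pattern = "^person[0-9]+$",
                        min_sentences = 2) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0) abort(sprintf("no .txt files found in '%s'", path))
    df <- tibble(
      note_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readr::read_lines(f, progress = FALSE), collapse = " "),
        character(1))
    )
  } else if (file.exists(path)) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    abort(sprintf("cannot read corpus at '%s'", path))
  }
  as_note_corpus(df, stopwords = stopwords, name_pattern = name_pattern,
                 min_sentences = min_sentences)
}

#' @export
print.note_corpus <- function(x, ...) {
  cat(sprintf("<note_corpus> %d notes, %d tokens (%d notes dropped at load)\n",
              dplyr::n_distinct(x$note_id), nrow(x),
              attr(x, "n_dropped") %||% 0L))
  NextMethod()
}
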