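#' Construct a set of ordered emotional word lists
#'
#' The container for the dictionary-filtered, stemmed emotional tokens of a
#' note or a recall: one row per stem occurrence, ordered within source.
#'
#' @param df Data frame with columns `source_id`, `position`, `stem`,
#'   `valence` (extra columns such as `screening_score` are kept).
#' @return Tibble of class `emotional_word_lists`.
#' @export
emotional_word_lists <- function(df) {
  df <- as_tibble(df)
  need <- c("source_id", "position", "stem", "valence")
  if (!all(need %in% names(df))) {
    abort(sprintf("`df` needs columns %s", paste(need, collapse = ", ")))
  }
  assert_valence_labels(df$valence, "valence")
  df <- arrange(df, .data$source_id, .data$position)
  class(df) <- c("emotional_word_lists", setdiff(class(df), "emotional_word_lists"))
  df
}

#' @export
print.emotional_word_lists <- function(x, ...) {
  cat(sprintf("<emotional_word_lists> %d lists, %d stem occurrences\n",
              dplyr::n_distinct(x$source_id), nrow(x)))
  NextMethod()
}

#' Extract ordered emotional word lists from a corpus
#'
#' Transforms each note into the ordered list of its emotional words: all
#' tokens are stemmed (see [stem_words()]), stems outside the emotional
#' dictionary are removed, ordering is preserved and repeated stems are
#' kept (a stem recurring in a note carries real transition structure).
#' Punctuation never reaches this stage (it is discarded at tokenization).
#' Lists with fewer than `min_length` stems are dropped; the drop count is
#' recorded in `attr(, "n_dropped")`.
#'
#' @param corpus A [`note_corpus`][as_note_corpus].
#' @param dictionary An [emotional_dictionary()].
#' @param min_length Minimum emotional words for a list to be retained
#'   (default 5).
#' @param stem_fun Deterministic token-to-stem function (default
#'   [stem_words()]; use `identity` when tokens are already stems).
#' @return An [`emotional_word_lists`][emotional_word_lists] tibble.
#' @export
extract_emotional_lists <- function(corpus, dictionary, min_length = 5,
                                    stem_fun = stem_words) {
  if (nrow(dictionary) == 0) abort("empty emotional dictionary")
  df <- as_tibble(corpus) %>%
    arrange(.data$note_id, .data$sentence, .data$position) %>%
    mutate(stem = stem_fun(.data$token)) %>%
    filter(.data$stem %in% dictionary$stem) %>%
    group_by(.data$note_id) %>%
    mutate(list_position = row_number()) %>%
    ungroup()
  sizes <- df %>% count(.data$note_id)
  keep_ids <- sizes$note_id[sizes$n >= min_length]
  n_dropped <- dplyr::n_distinct(as_tibble(corpus)$note_id) - length(keep_ids)
  df <- df %>%
    filter(.data$note_id %in% keep_ids) %>%
    mutate(valence = dictionary$valence_label[
      match(.data$stem, dictionary$stem)]) %>%
    select(source_id = "note_id", position = "list_position",
           "stem", "valence")
  out <- emotional_word_lists(df)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build an emotional co-occurrence network from word lists
#'
#' Fluency-style network construction: for every unordered pair of stems,
#' `k` counts the positions (across all lists) at which the two stems lie
#' within `window` entries of one another; windows never cross list
#' boundaries and a stem never pairs with itself. Candidate edges need
#' `k >= min_count` and must pass a one-sided binomial filter: with
#' `T` the total number of within-window positional pairs in the data and
#' `p_uv = f_u * f_v` the independent-placement rate given relative stem
#' frequencies `f`, the edge is retained when `P(X >= k) < alpha` for
#' `X ~ Binomial(T, p_uv)` — i.e. the pair co-occurs more often than word
#' frequency alone explains. Nodes carry the dictionary valence of their
#' stem.
#'
#' @param lists An [`emotional_word_lists`][emotional_word_lists].
#' @param window Co-occurrence window `a` (entries before/after; default 2).
#' @param min_count Minimum raw co-occurrence count (default 2).
#' @param alpha Binomial filter significance level (default 0.05).
#' @return An object of class `recall_network` (also usable wherever a
#'   `cooccurrence_network` is): list with `nodes` (`word`,
#'   `sentiment_label`, `component`), `edges` (`from`, `to`, `k`,
#'   `p_value`, `retained` — retained edges only are in the graph), the
#'   igraph in `$graph`, and bookkeeping in `$stats`.
#' @export
build_recall_network <- function(lists, window = 2, min_count = 2,
                                 alpha = 0.05) {
  if (window < 1) abort("`window` must be >= 1")
  if (min_count < 1) abort("`min_count` must be >= 1")
  df <- as_tibble(lists)
  lens <- df %>% count(.data$source_id)
  if (nrow(df) == 0 || max(lens$n) < 2) {
    abort("need at least one list with >= 2 stems")
  }

  # within-window positional pairs, per list
  pair_rows <- df %>%
    group_by(.data$source_id) %>%
    dplyr::group_map(function(g, key) {
      g <- arrange(g, .data$position)
      l <- nrow(g)
      out <- vector("list", window)
      for (d in seq_len(window)) {
        if (l > d) {
          i <- seq_len(l - d)
          out[[d]] <- tibble(u = g$stem[i], v = g$stem[i + d])
        }
      }
      bind_rows(out)
    }) %>%
    bind_rows()

  T_pairs <- nrow(pair_rows)
  pair_counts <- pair_rows %>%
    filter(.data$u != .data$v) %>%
    mutate(from = pmin(.data$u, .data$v), to = pmax(.data$u, .data$v)) %>%
    count(.data$from, .data$to, name = "k")

  freq <- df %>% count(.data$stem, name = "n_tok")
  f <- setNames(freq$n_tok / sum(freq$n_tok), freq$stem)

  edges <- pair_counts %>%
    filter(.data$k >= min_count) %>%
    mutate(
      p_uv = unname(f[.data$from] * f[.data$to]),
      p_value = pbinom(.data$k - 1, T_pairs, .data$p_uv, lower.tail = FALSE),
      retained = .data$p_value < alpha
    ) %>%
    select(-"p_uv")

  kept <- filter(edges, .data$retained)
  words <- sort(unique(c(kept$from, kept$to)))
  dict_val <- df %>% distinct(.data$stem, .data$valence)
  nodes <- tibble(
    word = words,
    sentiment_label = dict_val$valence[match(words, dict_val$stem)]
  )
  g <- igraph::graph_from_data_frame(
    select(kept, "from", "to", "k", "p_value"),
    directed = FALSE, vertices = nodes
  )
  if (nrow(nodes) > 0) {
    comp <- igraph::components(g)
    nodes$component <- comp$membership[nodes$word]
  } else {
    nodes$component <- integer(0)
  }

  structure(
    list(
      nodes = nodes,
      edges = kept,
      candidates = edges,
      graph = g,
      stats = list(
        window = window, min_count = min_count, alpha = alpha,
        T_pairs = T_pairs,
        n_candidates = nrow(edges),
        n_retained = nrow(kept)
      )
    ),
    class = c("recall_network", "cooccurrence_network")
  )
}

#' @export
print.recall_network <- function(x, ...) {
  cat(sprintf(
    "<recall_network> %d nodes, %d edges (%d candidates, window %d, binomial alpha %.3g)\n",
    nrow(x$nodes), nrow(x$edges), x$stats$n_candidates,
    x$stats$window, x$stats$alpha
  ))
  invisible(x)
}
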