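#' Build a word-word co-occurrence network from a note corpus
#'
#' Two words are connected when one occurs immediately after the other in at
#' least one sentence of the scoped corpus. Every token becomes a node —
#' including pronouns and stopwords, which carry structural information in
#' short-text networks. The graph is simple and undirected: repeated bigrams
#' accumulate into an edge weight but never multiply edges, and an
#' immediately repeated token yields no self-loop.
#'
#' @param corpus A [`note_corpus`][as_note_corpus].
#' @param scope `"all_sentences"` uses the whole corpus;
#'   `"last_sentences"` restricts to each note's final sentence.
#' @param lexicon Optional [affect_lexicon()]; when given, nodes carry their
#'   sentiment labels (unknown words are neutral) and emotion sets become
#'   available to [semantic_frame()].
#' @return An object of class `cooccurrence_network`: a list with tibbles
#'   `nodes` (`word`, `sentiment_label`, `component`) and `edges` (`from`,
#'   `to`, `weight`), plus the underlying igraph in `$graph`.
#' @export
build_cooccurrence_network <- function(corpus,
                                       scope = c("all_sentences",
                                                 "last_sentences"),
                                       lexicon = NULL) {
  scope <- match.arg(scope)
  df <- as_tibble(corpus)
  if (nrow(df) == 0) abort("corpus is empty")
  if (scope == "last_sentences") {
    df <- df %>%
      group_by(.data$note_id) %>%
      filter(.data$sentence == max(.data$sentence)) %>%
      ungroup()
  }
  if (nrow(df) == 0) abort("scope selects zero sentences")

  edges <- df %>%
    arrange(.data$note_id, .data$sentence, .data$position) %>%
    group_by(.data$note_id, .data$sentence) %>%
    mutate(next_token = dplyr::lead(.data$token)) %>%
    ungroup() %>%
    filter(!is.na(.data$next_token), .data$token != .data$next_token) %>%
    mutate(
      from = pmin(.data$token, .data$next_token),
      to = pmax(.data$token, .data$next_token)
    ) %>%
    count(.data$from, .data$to, name = "weight")

  words <- sort(unique(df$token))
  nodes <- tibble(word = words)
  nodes$sentiment_label <- if (is.null(lexicon)) {
    NA_character_
  } else {
    sentiment_of(words, lexicon)
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  nodes$component <- comp$membership[nodes$word]

  structure(
    list(nodes = nodes, edges = edges, graph = g,
         scope = scope, lexicon = lexicon),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence_network> %d nodes, %d edges, %d component(s) [scope: %s]\n",
    nrow(x$nodes), nrow(x$edges),
    length(unique(x$nodes$component)), x$scope
  ))
  invisible(x)
}

#' Closeness prominence of every word in the network
#'
#' Within each connected component of `N` nodes, a node's closeness is
#' `(N - 1) / sum_j d_ij` with `d_ij` the unweighted shortest-path length —
#' the inverse average distance to all words reachable from it. Distances
#' never cross components; singleton components get closeness 0 by
#' convention.
#'
#' @param network A [`cooccurrence_network`][build_cooccurrence_network] or
#'   [`recall_network`][build_recall_network].
#' @return Tibble with columns `word`, `component`, `closeness`.
#' @export
closeness_centrality <- function(network) {
  g <- network$graph
  nodes <- network$nodes
  out <- numeric(nrow(nodes))
  for (cid in unique(nodes$component)) {
    members <- which(nodes$component == cid)
    if (length(members) == 1) {
      out[members] <- 0
      next
    }
    sub <- igraph::induced_subgraph(g, nodes$word[members])
    d <- igraph::distances(sub)
    cl <- (nrow(d) - 1) / rowSums(d)
    out[members] <- cl[nodes$word[members]]
  }
  tibble(word = nodes$word, component = nodes$component, closeness = out)
}

#' Valence homophily across network links
#'
#' Kendall tau-b correlation between the sentiment polarities (coded
#' -1/0/+1) of words joined by an edge. Each undirected edge contributes
#' both orientations so the statistic does not depend on edge storage
#' order. Positive tau indicates homophily: words tend to link to words of
#' the same polarity.
#'
#' @param network A labeled [`cooccurrence_network`][build_cooccurrence_network].
#' @return Tibble with columns `kendall_tau`, `p_value`, `n_edges`,
#'   `defined`. When every endpoint label is identical the correlation is
#'   undefined and `defined` is `FALSE`.
#' @export
edge_valence_homophily <- function(network) {
  edges <- network$edges
  if (nrow(edges) < 2) abort("need at least 2 edges")
  labels <- network$nodes$sentiment_label
  if (all(is.na(labels))) abort("network has no sentiment labels")
  code <- c(negative = -1, neutral = 0, positive = 1)
  lu <- setNames(code[labels], network$nodes$word)
  x <- c(lu[edges$from], lu[edges$to])
  y <- c(lu[edges$to], lu[edges$from])
  if (length(unique(x)) == 1) {
    return(tibble(kendall_tau = NA_real_, p_value = NA_real_,
                  n_edges = nrow(edges), defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  tibble(kendall_tau = unname(ct$estimate), p_value = ct$p.value,
         n_edges = nrow(edges), defined = TRUE)
}

#' Unique words of the final sentences, minus stopwords and names
#'
#' The union across notes of the tokens in each note's final sentence,
#' excluding stopwords and anonymized-name placeholders; each word appears
#' once (set semantics).
#'
#' @param corpus A [`note_corpus`][as_note_corpus].
#' @return Character vector of unique last words.
#' @export
last_words <- function(corpus) {
  df <- as_tibble(corpus) %>%
    group_by(.data$note_id) %>%
    filter(.data$sentence == max(.data$sentence)) %>%
    ungroup() %>%
    filter(!.data$is_stopword, !.data$is_name)
  sort(unique(df$token))
}

#' Semantic frame of a word
#'
#' The network neighborhood of a concept — the words that directly co-occur
#' with it — annotated with each neighbor's sentiment label and, when the
#' network carries a lexicon, its emotion set.
#'
#' @param network A [`cooccurrence_network`][build_cooccurrence_network].
#' @param word The focal word (must be a node).
#' @return Tibble with columns `word`, `sentiment_label`, `emotions`
#'   (list-column of character vectors; empty when no lexicon is attached).
#' @export
semantic_frame <- function(network, word) {
  word <- tolower(word)
  if (!word %in% network$nodes$word) {
    abort(sprintf("word '%s' is not a node in the network", word))
  }
  nb <- sort(unique(c(
    network$edges$to[network$edges$from == word],
    network$edges$from[network$edges$to == word]
  )))
  nb <- setdiff(nb, word)
  out <- tibble(word = nb)
  out$sentiment_label <-
    network$nodes$sentiment_label[match(nb, network$nodes$word)]
  out$emotions <- if (is.null(network$lexicon)) {
    rep(list(character(0)), length(nb))
  } else {
    lapply(nb, emotions_of, lexicon = network$lexicon)
  }
  out
}
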