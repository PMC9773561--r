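# Fixtures built in code: a small hand-made affective lexicon, an antonym
# table, and constructors for random labeled graphs and word lists.

fixture_lexicon <- function() {
  valence <- tibble::tibble(
    word = c("good", "great", "fine", "freedom", "love", "peace", "hope",
             "bad", "awful", "sad", "sick", "pain", "hurt", "pandemic",
             "normal", "table", "chair", "paper", "time", "day"),
    valence = c(8, 9, 7, 8.5, 9.5, 8.2, 7.5,
                2, 1, 1.5, 2.2, 1.2, 1.8, 2.5,
                5, 5.2, 4.8, 5.1, 4.9, 5.3)
  )
  emotions <- tibble::tibble(
    word = c("pandemic", "love", "love", "sad", "sick", "pain", "hurt",
             "hope", "great"),
    emotion = c("fear", "joy", "trust", "sadness", "sadness", "sadness",
                "fear", "anticipation", "joy"),
    flag = 1L
  )
  affect_lexicon(valence, emotions)
}

fixture_antonyms <- function() {
  tibble::tibble(
    word =    c("good", "good", "love", "hope", "peace"),
    antonym = c("bad",  "poor", "hate", "despair", "war")
  )
}

# random simple undirected graph with valence labels, as an igraph with a
# `valence` vertex attribute (accepted by triad_census / network_null)
random_labeled_graph <- function(n_nodes, p_edge = 0.4) {
  g <- igraph::sample_gnp(n_nodes, p_edge)
  igraph::V(g)$name <- paste0("w", seq_len(n_nodes))
  igraph::V(g)$valence <- sample(c("positive", "negative", "neutral"),
                                 n_nodes, replace = TRUE)
  g
}

igraph_edges_df <- function(g) {
  el <- igraph::as_edgelist(g)
  tibble::tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]))
}

igraph_labels <- function(g) {
  setNames(igraph::V(g)$valence, igraph::V(g)$name)
}

# wrap an edge tibble into the minimal network object the package accepts
network_from_edges <- function(edges, labels) {
  nodes <- tibble::tibble(word = names(labels),
                          sentiment_label = unname(labels))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  nodes$component <- comp$membership[nodes$word]
  structure(list(nodes = nodes, edges = edges, graph = g, scope = "fixture",
                 lexicon = NULL),
            class = "cooccurrence_network")
}

# random emotional word lists (already stemmed)
random_lists <- function(n_lists, min_len = 2, max_len = 12, n_stems = 8) {
  stems <- paste0("s", seq_len(n_stems))
  val <- sample(c("positive", "negative", "neutral"), n_stems, replace = TRUE)
  rows <- lapply(seq_len(n_lists), function(i) {
    l <- sample(min_len:max_len, 1)
    idx <- sample.int(n_stems, l, replace = TRUE)
    tibble::tibble(
      source_id = sprintf("L%02d", i),
      position = seq_len(l),
      stem = stems[idx],
      valence = val[idx]
    )
  })
  emotional_word_lists(dplyr::bind_rows(rows))
}

# a planted-triangles fixture graph: k disjoint triangles plus random labels,
# guaranteeing a large triangle count for null-model checks
triangle_rich_graph <- function(k_triangles, labels = NULL) {
  edges <- dplyr::bind_rows(lapply(seq_len(k_triangles), function(i) {
    v <- paste0("t", i, "_", 1:3)
    tibble::tibble(from = v[c(1, 2, 1)], to = v[c(2, 3, 3)])
  }))
  words <- sort(unique(c(edges$from, edges$to)))
  if (is.null(labels)) {
    labels <- setNames(sample(c("positive", "negative", "neutral"),
                              length(words), replace = TRUE), words)
  }
  network_from_edges(edges, labels[words])
}
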