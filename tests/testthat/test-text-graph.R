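make_corpus <- function(texts) {
  as_note_corpus(tibble::tibble(
    note_id = sprintf("n%02d", seq_along(texts)),
    text = texts
  ))
}

test_that("tokenization lowercases and splits sentences at . ! ?", {
  s <- tokenize_text("I am tired. Goodbye all.")
  expect_length(s, 2)
  expect_equal(s[[1]], c("i", "am", "tired"))
  expect_equal(s[[2]], c("goodbye", "all"))
  # intra-word apostrophes survive
  expect_equal(tokenize_text("don't go!")[[1]], c("don't", "go"))
})

test_that("notes with fewer than two sentences are dropped at load", {
  corpus <- make_corpus(c("One sentence only",
                          "Two sentences. Here they are.",
                          "Also two. Indeed!"))
  expect_equal(dplyr::n_distinct(corpus$note_id), 2)
  expect_equal(attr(corpus, "n_dropped"), 1)
  expect_error(make_corpus("just one sentence"), "empty corpus")
})

test_that("a 143-note corpus with 4 single-sentence notes keeps 139", {
  texts <- c(
    sprintf("Note %d first sentence. Note %d second sentence.", 1:139, 1:139),
    sprintf("Short note %d only", 1:4)
  )
  corpus <- make_corpus(texts)
  expect_equal(dplyr::n_distinct(corpus$note_id), 139)
  expect_equal(attr(corpus, "n_dropped"), 4)
})

test_that("adjacent words in a sentence become single undirected edges", {
  corpus <- make_corpus(c("i love you. very very sad."))
  net <- build_cooccurrence_network(corpus)
  e <- dplyr::arrange(net$edges, from, to)
  expect_setequal(paste(e$from, e$to),
                  c("i love", "love you", "sad very"))
  # no self-loop from the repeated token
  expect_false(any(e$from == e$to))
})

test_that("repeated bigrams accumulate weight on a single edge", {
  texts <- rep("the pain hurt badly. it did.", 5)
  corpus <- make_corpus(texts)
  net <- build_cooccurrence_network(corpus)
  w <- net$edges$weight[net$edges$from == "hurt" & net$edges$to == "pain"]
  expect_equal(w, 5)
  expect_equal(sum(net$edges$from == "hurt" & net$edges$to == "pain"), 1)
})

test_that("closeness matches hand values on path and complete graphs", {
  path <- network_from_edges(
    tibble::tibble(from = c("a", "b"), to = c("b", "c")),
    setNames(rep("neutral", 3), c("a", "b", "c"))
  )
  cl <- closeness_centrality(path)
  expect_equal(cl$closeness[cl$word == "b"], 1)
  expect_equal(cl$closeness[cl$word == "a"], 2 / 3)
  expect_equal(cl$closeness[cl$word == "c"], 2 / 3)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  full <- network_from_edges(igraph_edges_df(k5),
                             setNames(rep("neutral", 5), letters[1:5]))
  expect_true(all(closeness_centrality(full)$closeness == 1))
})

test_that("closeness agrees with a BFS oracle on random graphs, singletons 0", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_labeled_graph(sample(4:12, 1), p_edge = 0.3)
    net <- network_from_edges(igraph_edges_df(g), igraph_labels(g))
    got <- closeness_centrality(net)
    want <- oracle_closeness(net$edges, net$nodes$word)
    expect_equal(setNames(got$closeness, got$word), want[got$word],
                 tolerance = 1e-12)
  }
})

test_that("edge-valence homophily is +1/-1 in the perfect cases", {
  same <- network_from_edges(
    tibble::tibble(from = c("a", "c"), to = c("b", "d")),
    c(a = "positive", b = "positive", c = "negative", d = "negative")
  )
  expect_equal(edge_valence_homophily(same)$kendall_tau, 1)

  cross <- network_from_edges(
    tibble::tibble(from = c("a", "c"), to = c("b", "d")),
    c(a = "positive", b = "negative", c = "positive", d = "negative")
  )
  expect_equal(edge_valence_homophily(cross)$kendall_tau, -1)
})

test_that("homophily matches the O(E^2) tau oracle and flags degeneracy", {
  set.seed(11)
  for (rep in 1:10) {
    g <- random_labeled_graph(10, p_edge = 0.5)
    net <- network_from_edges(igraph_edges_df(g), igraph_labels(g))
    if (nrow(net$edges) < 2) next
    got <- edge_valence_homophily(net)
    code <- c(negative = -1, neutral = 0, positive = 1)
    lab <- setNames(code[net$nodes$sentiment_label], net$nodes$word)
    x <- c(lab[net$edges$from], lab[net$edges$to])
    y <- c(lab[net$edges$to], lab[net$edges$from])
    if (!got$defined) {
      expect_true(length(unique(x)) == 1)
      next
    }
    expect_equal(got$kendall_tau, oracle_kendall_tau(x, y),
                 tolerance = 1e-10)
  }

  allsame <- network_from_edges(
    tibble::tibble(from = c("a", "b"), to = c("b", "c")),
    setNames(rep("positive", 3), c("a", "b", "c"))
  )
  expect_false(edge_valence_homophily(allsame)$defined)
})

test_that("last words drop stopwords and name placeholders, set semantics", {
  corpus <- make_corpus(c(
    "The body sentence here. Goodbye to my dear person07.",
    "Another body line. We found peace.",
    "Third note body. There is peace."
  ))
  lw <- last_words(corpus)
  expect_true(all(c("goodbye", "dear", "peace") %in% lw))
  expect_false("person07" %in% lw)
  expect_false("my" %in% lw)
  expect_equal(sum(lw == "peace"), 1)
})

test_that("an all-stopword final sentence contributes nothing", {
  corpus <- make_corpus(c("Real words live here. It was the.",
                          "Body text. Goodbye friend."))
  expect_setequal(last_words(corpus), c("goodbye", "friend"))
})

test_that("semantic frames are the labeled adjacency set", {
  star <- network_from_edges(
    tibble::tibble(from = rep("hub", 3), to = c("a", "b", "c")),
    c(hub = "neutral", a = "positive", b = "negative", c = "neutral")
  )
  fr <- semantic_frame(star, "hub")
  expect_setequal(fr$word, c("a", "b", "c"))
  expect_equal(fr$sentiment_label[fr$word == "a"], "positive")
  expect_equal(nrow(semantic_frame(star, "a")), 1)
  expect_error(semantic_frame(star, "ghost"), "ghost")
})

test_that("every edge is witnessed by an adjacent sentence pair", {
  set.seed(3)
  texts <- replicate(6, paste(
    replicate(3, paste(sample(letters[1:9], 5, replace = TRUE),
                       collapse = " ")),
    collapse = ". "
  ))
  corpus <- make_corpus(texts)
  net <- build_cooccurrence_network(corpus)
  pairs <- corpus |>
    dplyr::group_by(note_id, sentence) |>
    dplyr::mutate(nxt = dplyr::lead(token)) |>
    dplyr::filter(!is.na(nxt))
  witnessed <- unique(paste(pmin(pairs$token, pairs$nxt),
                            pmax(pairs$token, pairs$nxt)))
  expect_true(all(paste(net$edges$from, net$edges$to) %in% witnessed))
})

test_that("the last-sentence network vocabulary nests in the full one", {
  set.seed(5)
  texts <- replicate(8, paste(
    replicate(4, paste(sample(letters, 6, replace = TRUE), collapse = " ")),
    collapse = ". "
  ))
  corpus <- make_corpus(texts)
  all_net <- build_cooccurrence_network(corpus, "all_sentences")
  last_net <- build_cooccurrence_network(corpus, "last_sentences")
  expect_true(all(last_net$nodes$word %in% all_net$nodes$word))
})

test_that("load_corpus reads both CSV files and directories of txt", {
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "corpus.csv")
  readr::write_csv(tibble::tibble(
    note_id = c("a", "b"),
    text = c("First part. Second part.", "Hello there. Bye now.")
  ), csv)
  expect_equal(dplyr::n_distinct(load_corpus(csv)$note_id), 2)

  dir.create(file.path(tmp, "notes"))
  writeLines("One line here. Another line.", file.path(tmp, "notes", "x.txt"))
  writeLines("Second file. More text!", file.path(tmp, "notes", "y.txt"))
  corpus <- load_corpus(file.path(tmp, "notes"))
  expect_setequal(unique(corpus$note_id), c("x", "y"))
  expect_error(load_corpus(file.path(tmp, "missing.csv")), "cannot read")
})
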