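test_that("entropy of the two worked five-word lists is 1 and 0 bits", {
  # {sad, sick, fine, great, normal} -> neg neg pos pos neu -> 0101
  r1 <- emotional_entropy(c("negative", "negative", "positive",
                            "positive", "neutral"))
  expect_equal(r1$indicators, c(0L, 1L, 0L, 1L))
  expect_equal(r1$h, 1)

  # {great, sad, fine, sick, normal} -> pos neg pos neg neu -> 1111
  r2 <- emotional_entropy(c("positive", "negative", "positive",
                            "negative", "neutral"))
  expect_equal(r2$indicators, c(1L, 1L, 1L, 1L))
  expect_equal(r2$h, 0)
})

test_that("constant sequences have zero entropy and short ones error", {
  expect_equal(emotional_entropy(rep("positive", 7))$h, 0)
  expect_error(emotional_entropy("positive"), "no transitions")
  expect_error(emotional_entropy(c("positive", "wrong")), "invalid valence")
})

test_that("entropy stays in [0,1] and survives polarity flips", {
  set.seed(17)
  flip <- c(positive = "negative", negative = "positive",
            neutral = "neutral")
  for (rep in 1:40) {
    seq_len_n <- sample(2:12, 1)
    s <- sample(c("positive", "negative", "neutral"), seq_len_n,
                replace = TRUE)
    h <- emotional_entropy(s)$h
    expect_gte(h, 0)
    expect_lte(h, 1)
    expect_equal(emotional_entropy(unname(flip[s]))$h, h)
    expect_equal(h, oracle_entropy(s))
  }
})

test_that("triad taxonomy: mixing the two polarities is the only incoherence", {
  expect_equal(classify_triad(rep("positive", 3)), "coherent")
  expect_equal(classify_triad(c("positive", "negative", "neutral")),
               "incoherent")
  expect_equal(classify_triad(rep("neutral", 3)), "coherent")
  expect_error(classify_triad(c("positive", "negative")), "exactly 3")
  expect_error(classify_triad(c("positive", "negative", "meh")),
               "invalid valence")
})

test_that("single-triangle censuses give c = 0 and c = 1", {
  tri_edges <- tibble::tibble(from = c("a", "b", "a"), to = c("b", "c", "c"))
  all_pos <- network_from_edges(tri_edges,
                                setNames(rep("positive", 3), c("a", "b", "c")))
  cen <- triad_census(all_pos)
  expect_equal(cen$n_triangles, 1)
  expect_equal(cen$c, 0)
  expect_equal(cen$counts$n[cen$counts$signature == "+++"], 1)

  mixed <- network_from_edges(tri_edges,
                              c(a = "positive", b = "negative", c = "neutral"))
  cen2 <- triad_census(mixed)
  expect_equal(cen2$c, 1)
  expect_equal(cen2$counts$n[cen2$counts$signature == "+-n"], 1)
})

test_that("census matches the brute-force triple loop on random graphs", {
  set.seed(23)
  for (rep in 1:20) {
    g <- random_labeled_graph(sample(5:12, 1), p_edge = 0.45)
    got <- triad_census(g)
    want <- oracle_triad_census(igraph_edges_df(g), igraph_labels(g))
    expect_equal(got$n_triangles, want$n_triangles)
    expect_equal(got$n_incoherent, want$n_incoherent)
    if (want$n_triangles > 0) {
      expect_equal(got$c, want$c)
      for (sig in names(want$counts)) {
        expect_equal(got$counts$n[got$counts$signature == sig],
                     unname(want$counts[sig]))
      }
    } else {
      expect_false(got$defined)
      expect_true(is.na(got$c))
    }
    # conservation: signatures sum to the triangle count
    expect_equal(sum(got$counts$n), got$n_triangles)
  }
})

test_that("census is equivariant under polarity swap and neutral collapse", {
  set.seed(29)
  g <- random_labeled_graph(10, p_edge = 0.5)
  cen <- triad_census(g)
  flip <- c(positive = "negative", negative = "positive",
            neutral = "neutral")
  g2 <- igraph::set_vertex_attr(g, "valence",
                                value = unname(flip[igraph::V(g)$valence]))
  cen2 <- triad_census(g2)
  expect_equal(cen2$c, cen$c)
  expect_equal(cen2$n_incoherent, cen$n_incoherent)

  g3 <- igraph::set_vertex_attr(g, "valence",
                                value = rep("neutral", igraph::vcount(g)))
  cen3 <- triad_census(g3)
  if (cen3$defined) expect_equal(cen3$c, 0)
})

test_that("unlabeled nodes inside a triangle are reported by name", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("x", "y", "z")
  igraph::V(g)$valence <- c("positive", NA, "neutral")
  expect_error(triad_census(g), "y")
})

test_that("ordered triads slide one position at a time", {
  got <- ordered_triad_counts(c("positive", "negative", "positive",
                                "negative"))
  expect_equal(got$n[got$triple == "+-+"], 1)
  expect_equal(got$n[got$triple == "-+-"], 1)
  expect_equal(sum(got$n), 2)

  too_short <- ordered_triad_counts(c("positive", "positive"))
  expect_equal(sum(too_short$n), 0)

  const <- ordered_triad_counts(rep("neutral", 9))
  expect_equal(const$n[const$triple == "nnn"], 7)
  expect_equal(sum(const$n), 7)
})

test_that("ordered triads match the scan oracle on random sequences", {
  set.seed(31)
  sym_of <- c(positive = "+", negative = "-", neutral = "n")
  for (rep in 1:20) {
    s <- sample(c("positive", "negative", "neutral"), sample(3:12, 1),
                replace = TRUE)
    got <- ordered_triad_counts(s)
    want <- oracle_ordered_triads(unname(sym_of[s]))
    for (key in names(want)) {
      expect_equal(got$n[got$triple == key], unname(want[key]))
    }
    expect_equal(sum(got$n), max(0, length(s) - 2))
  }
})

test_that("per-list entropies flag too-short lists as NA", {
  lists <- emotional_word_lists(tibble::tibble(
    source_id = c("a", "a", "a", "b"),
    position = c(1, 2, 3, 1),
    stem = c("s1", "s2", "s3", "s4"),
    valence = c("positive", "negative", "positive", "neutral")
  ))
  h <- list_entropies(lists)
  expect_equal(h$h[h$source_id == "a"],
               oracle_entropy(c("positive", "negative", "positive")))
  expect_true(is.na(h$h[h$source_id == "b"]))
})
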