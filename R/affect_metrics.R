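#' Emotional entropy of a valence-label sequence
#'
#' Walks an ordered sequence of valence labels and writes a `0` whenever the
#' next label equals the current one and a `1` otherwise; the entropy `h` is
#' the two-event Shannon entropy (binary logarithm, with `0 log 0 = 0`) of
#' this indicator string. `h` is 1 bit when same- and different-label
#' transitions are equally frequent and 0 when the sequence never (or
#' always) switches, so it captures how scattered emotional transitions are
#' along a list. Neutral is an ordinary third label: a switch to or from
#' neutral counts as a transition.
#'
#' @param valence_seq Character vector of labels in
#'   `positive`/`negative`/`neutral`, in text order; length at least 2.
#' @return An object of class `transition_record`: a list with
#'   `indicators` (0/1 integer vector), `p` (named probabilities of the
#'   `same`/`different` events) and `h` (bits).
#' @examples
#' emotional_entropy(c("negative", "negative", "positive", "positive",
#'                     "neutral"))$h  # 1 bit
#' @export
emotional_entropy <- function(valence_seq) {
  assert_valence_labels(valence_seq, "valence_seq")
  n <- length(valence_seq)
  if (n < 2) abort("no transitions: need a sequence of length >= 2")
  ind <- as.integer(valence_seq[-1] != valence_seq[-n])
  p_diff <- mean(ind)
  p <- c(same = 1 - p_diff, different = p_diff)
  h <- -sum(ifelse(p > 0, p * log2(p), 0)) + 0  # + 0 normalizes IEEE -0
  structure(list(indicators = ind, p = p, h = h),
            class = "transition_record")
}

#' @export
print.transition_record <- function(x, ...) {
  cat(sprintf("<transition_record> %s  h = %.4f bits\n",
              paste(x$indicators, collapse = ""), x$h))
  invisible(x)
}

#' Per-list emotional entropies
#'
#' Applies [emotional_entropy()] to every list in a set of emotional word
#' lists. Lists with fewer than two entries have no transitions and get
#' `NA`.
#'
#' @param lists An [`emotional_word_lists`][emotional_word_lists] object (or
#'   any tibble with `source_id`, `position`, `valence`).
#' @return Tibble with columns `source_id`, `n` (list length), `h` (bits).
#' @export
list_entropies <- function(lists) {
  as_tibble(lists) %>%
    arrange(.data$source_id, .data$position) %>%
    group_by(.data$source_id) %>%
    summarise(
      n = dplyr::n(),
      h = if (dplyr::n() >= 2) emotional_entropy(.data$valence)$h else NA_real_,
      .groups = "drop"
    )
}

#' Classify a valence triad as coherent or incoherent
#'
#' A triangle of words is emotionally incoherent when its labels mix the two
#' polarities — at least one positive and one negative word — and coherent
#' otherwise. Neutral words create no contrast: all-neutral triads and
#' triads mixing neutral with a single polarity are coherent.
#'
#' @param labels Character vector of exactly 3 valence labels.
#' @return `"coherent"` or `"incoherent"`.
#' @examples
#' classify_triad(c("positive", "negative", "neutral"))  # incoherent
#' classify_triad(c("positive", "positive", "neutral"))  # coherent
#' @export
classify_triad <- function(labels) {
  if (length(labels) != 3) abort("a triad has exactly 3 labels")
  assert_valence_labels(labels, "labels")
  if (any(labels == "positive") && any(labels == "negative")) {
    "incoherent"
  } else {
    "coherent"
  }
}

#' Triangle census by valence signature, and emotional complexity
#'
#' Enumerates every closed triangle of the network once, tallies the 10
#' possible label signatures (multisets over +/-/n), splits them into
#' coherent and incoherent (see [classify_triad()]), and reports the degree
#' of emotional complexity `c = n_incoherent / (n_coherent + n_incoherent)`
#' — the complement of the coherent fraction, the affective analog of the
#' degree of balance in structural balance theory.
#'
#' @param network A labeled network
#'   ([`cooccurrence_network`][build_cooccurrence_network] or
#'   [`recall_network`][build_recall_network]), or an igraph with a
#'   `valence` vertex attribute.
#' @return An object of class `triad_census_affect`: list with `counts`
#'   (tibble `signature`, `n`, `coherent`), `n_coherent`, `n_incoherent`,
#'   `c` (NA with `defined = FALSE` when the graph has no triangle) and
#'   `n_triangles`.
#' @export
triad_census <- function(network) {
  tri <- triangle_matrix(network)
  labels <- node_labels(network)
  names <- if (inherits(network, "igraph")) {
    igraph::V(network)$name
  } else {
    network$nodes$word
  }
  census_from_triangles(tri, labels, node_names = names)
}

# 3-column matrix of node indices, one row per triangle (enumerated once)
triangle_matrix <- function(network) {
  g <- if (inherits(network, "igraph")) network else network$graph
  tri <- igraph::triangles(g)
  if (length(tri) == 0) {
    return(matrix(integer(0), ncol = 3))
  }
  matrix(as.integer(tri), ncol = 3, byrow = TRUE)
}

node_labels <- function(network) {
  labels <- if (inherits(network, "igraph")) {
    igraph::vertex_attr(network, "valence")
  } else {
    network$nodes$sentiment_label
  }
  if (is.null(labels)) abort("network nodes carry no valence labels")
  labels
}

# census given precomputed triangles + a label vector (fast path reused by
# the network-level null models, where topology is fixed and labels vary)
census_from_triangles <- function(tri, labels, node_names = NULL) {
  if (nrow(tri) > 0) {
    lab_tri <- matrix(labels[tri], ncol = 3)
    if (anyNA(lab_tri)) {
      bad <- unique(as.vector(tri)[is.na(labels[as.vector(tri)])])
      nm <- if (is.null(node_names)) bad else node_names[bad]
      abort(sprintf("unlabeled node(s) in a triangle: %s",
                    paste(head(nm, 5), collapse = ", ")))
    }
    sigs <- triad_signatures_fast(lab_tri)
    tab <- table(factor(sigs, levels = all_triad_signatures()))
  } else {
    tab <- table(factor(character(0), levels = all_triad_signatures()))
  }
  counts <- tibble(
    signature = names(tab),
    n = as.integer(tab)
  )
  counts$coherent <- !(grepl("\\+", counts$signature) &
                         grepl("-", counts$signature, fixed = TRUE))
  n_inc <- sum(counts$n[!counts$coherent])
  n_coh <- sum(counts$n[counts$coherent])
  total <- n_inc + n_coh
  structure(
    list(
      counts = counts,
      n_coherent = n_coh,
      n_incoherent = n_inc,
      n_triangles = total,
      c = if (total > 0) n_inc / total else NA_real_,
      defined = total > 0
    ),
    class = "triad_census_affect"
  )
}

# vectorized signature computation for a matrix of label triples
triad_signatures_fast <- function(lab_tri) {
  np <- rowSums(lab_tri == "positive")
  nn <- rowSums(lab_tri == "negative")
  nu <- 3L - np - nn
  paste0(strrep("+", np), strrep("-", nn), strrep("n", nu))
}

#' @export
print.triad_census_affect <- function(x, ...) {
  cat(sprintf(
    "<triad census> %d triangles: %d coherent, %d incoherent, c = %s\n",
    x$n_triangles, x$n_coherent, x$n_incoherent,
    if (x$defined) sprintf("%.4f", x$c) else "undefined (no triangles)"
  ))
  invisible(x)
}

#' Ordered (sliding-window) triad counts along a valence sequence
#'
#' Counts every window of three consecutive labels in an ordered list, keyed
#' by the ordered triple — e.g. the key `+-+` counts positions where a
#' positive word is followed by a negative then a positive one. Sequences
#' shorter than 3 yield all-zero counts.
#'
#' @param valence_seq Character vector of valence labels in order.
#' @return Tibble with columns `triple` (e.g. `"+-+"`) and `n`, covering all
#'   27 ordered triples.
#' @export
ordered_triad_counts <- function(valence_seq) {
  assert_valence_labels(valence_seq, "valence_seq")
  sym <- unname(VALENCE_SYMBOLS[valence_seq])
  keys <- expand.grid(a = c("+", "-", "n"), b = c("+", "-", "n"),
                      c = c("+", "-", "n"), stringsAsFactors = FALSE)
  all_triples <- paste0(keys$a, keys$b, keys$c)
  L <- length(sym)
  observed <- if (L >= 3) {
    paste0(sym[1:(L - 2)], sym[2:(L - 1)], sym[3:L])
  } else {
    character(0)
  }
  tab <- table(factor(observed, levels = all_triples))
  tibble(triple = names(tab), n = as.integer(tab))
}
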