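#' Run the Study-1 analysis: prominence and emotions of last words
#'
#' End-to-end orchestration over a note corpus and an affective lexicon:
#' builds the all-sentences and last-sentences co-occurrence networks,
#' computes closeness prominence, extracts the unique last words, compares
#' the closeness of last words against all other words (Kruskal-Wallis),
#' tests whether last and non-last words differ in sentiment composition
#' (chi-square on the 2x3 label table), and profiles the 8 emotions of last
#' words against resampled non-last words drawn from the largest connected
#' component of the full network excluding stopwords.
#'
#' @param corpus A [`note_corpus`][as_note_corpus].
#' @param lexicon An [affect_lexicon()].
#' @param n_samples Random profiles for the z-score baseline (default 1000).
#' @param seed Optional top-level seed; stage substreams are derived from it.
#' @return A list of class `study1_report` with elements `network_all`,
#'   `network_last`, `closeness`, `last_words`, `closeness_test`,
#'   `sentiment_test`, `sentiment_counts`, `zscore_profile`, `homophily`,
#'   and `log` (stage bookkeeping counts).
#' @export
run_study1 <- function(corpus, lexicon, n_samples = 1000, seed = NULL) {
  net_all <- build_cooccurrence_network(corpus, "all_sentences", lexicon)
  net_last <- build_cooccurrence_network(corpus, "last_sentences", lexicon)
  cl <- closeness_centrality(net_all)
  lw <- last_words(corpus)

  cl$is_last <- cl$word %in% lw
  closeness_test <- compare_groups_rank(cl, values = closeness,
                                        groups = is_last)

  labels <- net_all$nodes$sentiment_label
  is_last_node <- net_all$nodes$word %in% lw
  counts <- rbind(
    last = table(factor(labels[is_last_node], levels = VALENCE_LEVELS)),
    other = table(factor(labels[!is_last_node], levels = VALENCE_LEVELS))
  )
  sentiment_test <- sentiment_contingency_test(counts)

  # null pool: largest connected component of the full network, minus
  # stopwords and the last words themselves
  stop_set <- default_stopwords()
  comp_sizes <- table(net_all$nodes$component)
  big <- names(comp_sizes)[which.max(comp_sizes)]
  pool <- net_all$nodes$word[
    net_all$nodes$component == as.integer(big) &
      !net_all$nodes$word %in% stop_set &
      !net_all$nodes$word %in% lw
  ]
  zp <- profile_zscores(lw, pool, lexicon, n_samples = n_samples,
                        seed = derive_seed(seed, 1))

  structure(
    list(
      network_all = net_all,
      network_last = net_last,
      closeness = cl,
      last_words = lw,
      closeness_test = closeness_test,
      sentiment_test = sentiment_test,
      sentiment_counts = counts,
      zscore_profile = zp,
      homophily = edge_valence_homophily(net_all),
      log = list(
        n_notes = dplyr::n_distinct(as_tibble(corpus)$note_id),
        n_notes_dropped = attr(corpus, "n_dropped") %||% 0L,
        n_nodes_all = nrow(net_all$nodes),
        n_edges_all = nrow(net_all$edges),
        n_nodes_last = nrow(net_last$nodes),
        n_edges_last = nrow(net_last$edges),
        n_last_words = length(lw),
        pool_size = length(pool)
      )
    ),
    class = "study1_report"
  )
}

#' Run the Study-2 analysis: entropy and emotional complexity
#'
#' Orchestrates the sequence-and-network analysis over two populations of
#' emotional word lists (note-derived and recall-derived): per-list
#' entropies and their rank comparison, ordered triad counts, the windowed
#' co-occurrence networks with binomial filtering, triad censuses with
#' complexity `c`, the list-level entropy null models (Shuffled and
#' Uniform, on the note lists), and the network-level null models (both
#' models, both networks).
#'
#' @param note_lists,recall_lists [`emotional_word_lists`][emotional_word_lists]
#'   for the two populations.
#' @param window,min_count,alpha Network construction parameters (see
#'   [build_recall_network()]).
#' @param n_iter Null-model iterations (default 500).
#' @param seed Optional top-level seed; stage substreams are derived.
#' @return A list of class `study2_report` with entropies, the entropy rank
#'   test, ordered triad count totals, both networks and censuses, and the
#'   null ensembles (`list_nulls`, `network_nulls`, each split by model).
#' @export
run_study2 <- function(note_lists, recall_lists, window = 2, min_count = 2,
                       alpha = 0.05, n_iter = 500, seed = NULL) {
  h_notes <- list_entropies(note_lists)
  h_recalls <- list_entropies(recall_lists)
  entropy_test <- compare_ensembles(h_notes$h[!is.na(h_notes$h)],
                                    h_recalls$h[!is.na(h_recalls$h)])

  ordered_counts <- function(lists) {
    as_tibble(lists) %>%
      group_by(.data$source_id) %>%
      summarise(counts = list(ordered_triad_counts(.data$valence)),
                .groups = "drop") %>%
      tidyr::unnest("counts") %>%
      group_by(.data$triple) %>%
      summarise(n = sum(.data$n), .groups = "drop")
  }
  triads_notes <- ordered_counts(note_lists)
  triads_recalls <- ordered_counts(recall_lists)

  net_notes <- build_recall_network(note_lists, window, min_count, alpha)
  net_recalls <- build_recall_network(recall_lists, window, min_count, alpha)
  census_notes <- triad_census(net_notes)
  census_recalls <- triad_census(net_recalls)

  list_nulls <- list(
    shuffled = list_null(note_lists, "shuffled", n_iter,
                         derive_seed(seed, 11)),
    uniform = list_null(note_lists, "uniform", n_iter,
                        derive_seed(seed, 12))
  )
  safe_network_null <- function(net, model, off) {
    if (nrow(triangle_matrix(net)) == 0) return(NULL)
    network_null(net, model, n_iter, derive_seed(seed, off))
  }
  network_nulls <- list(
    notes_shuffled = safe_network_null(net_notes, "shuffled", 21),
    notes_uniform = safe_network_null(net_notes, "uniform", 22),
    recalls_shuffled = safe_network_null(net_recalls, "shuffled", 23),
    recalls_uniform = safe_network_null(net_recalls, "uniform", 24)
  )

  structure(
    list(
      entropies = list(notes = h_notes, recalls = h_recalls),
      entropy_test = entropy_test,
      ordered_triads = list(notes = triads_notes, recalls = triads_recalls),
      networks = list(notes = net_notes, recalls = net_recalls),
      censuses = list(notes = census_notes, recalls = census_recalls),
      list_nulls = list_nulls,
      network_nulls = network_nulls,
      log = list(
        n_note_lists = dplyr::n_distinct(as_tibble(note_lists)$source_id),
        n_recall_lists = dplyr::n_distinct(as_tibble(recall_lists)$source_id),
        c_notes = census_notes$c,
        c_recalls = census_recalls$c,
        c_notes_defined = census_notes$defined,
        c_recalls_defined = census_recalls$defined
      )
    ),
    class = "study2_report"
  )
}

#' Write a machine-readable report to a directory
#'
#' Serializes the scalar results of a study report as `report.json` and the
#' main tables as TSV/CSV files (`edges.tsv`, `nodes.csv`, and for Study 2
#' `lists_entropy.csv` and `ensembles.csv`).
#'
#' @param report A `study1_report` or `study2_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(as.list(glance(report)), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  if (inherits(report, "study1_report")) {
    readr::write_tsv(report$network_all$edges, file.path(dir, "edges.tsv"))
    readr::write_csv(
      left_join(report$network_all$nodes, report$closeness,
                by = c("word", "component")),
      file.path(dir, "nodes.csv")
    )
    readr::write_csv(as_tibble(report$zscore_profile),
                     file.path(dir, "zscore_profile.csv"))
    paths <- c(paths, file.path(dir, c("edges.tsv", "nodes.csv",
                                       "zscore_profile.csv")))
  } else if (inherits(report, "study2_report")) {
    readr::write_tsv(report$networks$notes$edges, file.path(dir, "edges.tsv"))
    readr::write_csv(report$networks$notes$nodes, file.path(dir, "nodes.csv"))
    readr::write_csv(
      bind_rows(
        mutate(report$entropies$notes, population = "notes"),
        mutate(report$entropies$recalls, population = "recalls")
      ),
      file.path(dir, "lists_entropy.csv")
    )
    ens <- purrr::imap(report$network_nulls, function(e, nm) {
      if (is.null(e)) return(NULL)
      mutate(e$z, ensemble = nm, .before = 1)
    })
    readr::write_csv(bind_rows(ens), file.path(dir, "ensembles.csv"))
    paths <- c(paths, file.path(dir, c("edges.tsv", "nodes.csv",
                                       "lists_entropy.csv", "ensembles.csv")))
  }
  invisible(paths)
}

#' @export
print.study1_report <- function(x, ...) {
  cat("<study1_report>\n")
  cat(sprintf("  corpus: %d notes (%d dropped at load)\n",
              x$log$n_notes, x$log$n_notes_dropped))
  cat(sprintf("  network (all sentences): %d nodes, %d edges\n",
              x$log$n_nodes_all, x$log$n_edges_all))
  cat(sprintf("  network (last sentences): %d nodes, %d edges\n",
              x$log$n_nodes_last, x$log$n_edges_last))
  cat(sprintf("  last words: %d unique (pool %d)\n",
              x$log$n_last_words, x$log$pool_size))
  cat(sprintf("  closeness rank test: H = %.3f, p = %.3g\n",
              x$closeness_test$statistic, x$closeness_test$p_value))
  cat(sprintf("  sentiment contingency: chi2 = %.3f, p = %.3g\n",
              x$sentiment_test$statistic, x$sentiment_test$p_value))
  if (isTRUE(x$homophily$defined)) {
    cat(sprintf("  edge-valence homophily: tau = %.4f, p = %.3g\n",
                x$homophily$kendall_tau, x$homophily$p_value))
  }
  invisible(x)
}

#' @export
print.study2_report <- function(x, ...) {
  cat("<study2_report>\n")
  cat(sprintf("  lists: %d note-derived, %d recall-derived\n",
              x$log$n_note_lists, x$log$n_recall_lists))
  cat(sprintf("  entropy rank test: K = %.3f, p = %.3g\n",
              x$entropy_test$statistic, x$entropy_test$p_value))
  fmt_c <- function(v, ok) if (isTRUE(ok)) sprintf("%.4f", v) else "undefined"
  cat(sprintf("  complexity c: notes %s, recalls %s\n",
              fmt_c(x$log$c_notes, x$log$c_notes_defined),
              fmt_c(x$log$c_recalls, x$log$c_recalls_defined)))
  invisible(x)
}
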