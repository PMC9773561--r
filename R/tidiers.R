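# broom-style tidiers for the package's result objects

#' @exportS3Method generics::tidy
tidy.cooccurrence_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' @exportS3Method generics::glance
glance.cooccurrence_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = length(unique(x$nodes$component)),
    n_positive = sum(x$nodes$sentiment_label == "positive", na.rm = TRUE),
    n_negative = sum(x$nodes$sentiment_label == "negative", na.rm = TRUE),
    n_neutral = sum(x$nodes$sentiment_label == "neutral", na.rm = TRUE)
  )
}

#' @exportS3Method generics::glance
glance.recall_network <- function(x, ...) {
  out <- glance.cooccurrence_network(x)
  out$n_candidates <- x$stats$n_candidates
  out$window <- x$stats$window
  out$alpha <- x$stats$alpha
  out
}

#' @exportS3Method generics::tidy
tidy.triad_census_affect <- function(x, ...) {
  as_tibble(x$counts)
}

#' @exportS3Method generics::glance
glance.triad_census_affect <- function(x, ...) {
  tibble(
    n_triangles = x$n_triangles,
    n_coherent = x$n_coherent,
    n_incoherent = x$n_incoherent,
    c = x$c,
    defined = x$defined
  )
}

#' @exportS3Method generics::tidy
tidy.null_ensemble <- function(x, ...) {
  as_tibble(x$z)
}

#' @exportS3Method generics::glance
glance.null_ensemble <- function(x, ...) {
  tibble(
    model = x$model,
    level = x$level,
    n_iter = x$n_iter,
    n_significant = sum(x$z$significant & !is.na(x$z$z)),
    n_statistics = nrow(x$z)
  )
}

#' @exportS3Method generics::tidy
tidy.transition_record <- function(x, ...) {
  tibble(event = names(x$p), p = unname(x$p))
}

#' @exportS3Method generics::glance
glance.transition_record <- function(x, ...) {
  tibble(n_transitions = length(x$indicators),
         n_switches = sum(x$indicators), h = x$h)
}

#' @exportS3Method generics::glance
glance.study1_report <- function(x, ...) {
  tibble(
    n_notes = x$log$n_notes,
    n_notes_dropped = x$log$n_notes_dropped,
    n_nodes_all = x$log$n_nodes_all,
    n_edges_all = x$log$n_edges_all,
    n_nodes_last = x$log$n_nodes_last,
    n_edges_last = x$log$n_edges_last,
    n_last_words = x$log$n_last_words,
    closeness_H = x$closeness_test$statistic,
    closeness_p = x$closeness_test$p_value,
    sentiment_chisq = x$sentiment_test$statistic,
    sentiment_p = x$sentiment_test$p_value,
    kendall_tau = x$homophily$kendall_tau,
    n_significant_emotions = sum(x$zscore_profile$significant)
  )
}

#' @exportS3Method generics::glance
glance.study2_report <- function(x, ...) {
  tibble(
    n_note_lists = x$log$n_note_lists,
    n_recall_lists = x$log$n_recall_lists,
    median_h_notes = median(x$entropies$notes$h, na.rm = TRUE),
    median_h_recalls = median(x$entropies$recalls$h, na.rm = TRUE),
    entropy_K = x$entropy_test$statistic,
    entropy_p = x$entropy_test$p_value,
    c_notes = x$log$c_notes,
    c_recalls = x$log$c_recalls,
    n_triangles_notes = x$censuses$notes$n_triangles,
    n_triangles_recalls = x$censuses$recalls$n_triangles
  )
}
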