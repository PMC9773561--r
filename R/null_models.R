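#' z-score of an observed value against null samples
#'
#' `(observed - mean(samples)) / sd(samples)`; when the null distribution is
#' degenerate (zero spread) the z-score is undefined and returned as `NA`
#' with `defined = FALSE` rather than an infinity.
#'
#' @param observed A single observed value.
#' @param samples Numeric vector of at least 2 null-model samples.
#' @return Tibble with columns `observed`, `null_mean`, `null_sd`, `z`,
#'   `significant` (|z| > 1.96), `defined`.
#' @export
zscore <- function(observed, samples) {
  if (length(samples) < 2) abort("need at least 2 null samples")
  mu <- mean(samples)
  sig <- sd(samples)
  z <- if (sig > 0) (observed - mu) / sig else NA_real_
  tibble(
    observed = observed, null_mean = mu, null_sd = sig, z = z,
    significant = !is.na(z) && abs(z) > 1.96,
    defined = sig > 0
  )
}

#' List-level null models for emotional entropy
#'
#' Randomizes every list `n_iter` times and recomputes the per-list
#' entropy. The `shuffled` model permutes the order of each list's labels,
#' preserving its exact label multiset; the `uniform` model replaces each
#' label independently and uniformly at random over
#' positive/negative/neutral, preserving only list length. Per-iteration
#' mean and median entropies summarize each draw; the observed values are
#' compared by z-score.
#'
#' @param lists An [`emotional_word_lists`][emotional_word_lists].
#' @param model `"shuffled"` or `"uniform"`.
#' @param n_iter Number of iterations (default 500).
#' @param seed Optional integer seed.
#' @param keep_labels Store every iteration's randomized label draws in
#'   `$label_draws` (for conservation audits; default `FALSE`).
#' @return An object of class `null_ensemble` (level `"list"`): list with
#'   `samples` (tibble `iteration`, `source_id`, `h`), `iteration_summary`
#'   (tibble `iteration`, `mean_h`, `median_h`), `observed` (tibble from
#'   [list_entropies()]), and `z` (tibble with z-scores of the observed
#'   mean and median entropy).
#' @export
list_null <- function(lists, model = c("shuffled", "uniform"),
                      n_iter = 500, seed = NULL, keep_labels = FALSE) {
  model <- match.arg(model)
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  df <- as_tibble(lists) %>% arrange(.data$source_id, .data$position)
  split_labels <- split(df$valence, df$source_id)
  split_labels <- split_labels[lengths(split_labels) >= 2]
  if (length(split_labels) == 0) abort("no list has >= 2 entries")
  ids <- names(split_labels)

  observed <- list_entropies(lists) %>% filter(!is.na(.data$h))

  entropy_of <- function(labs) {
    ind <- labs[-1] != labs[-length(labs)]
    p1 <- mean(ind)
    p0 <- 1 - p1
    -sum(ifelse(c(p0, p1) > 0, c(p0, p1) * log2(c(p0, p1)), 0)) + 0
  }

  label_draws <- if (keep_labels) vector("list", n_iter) else NULL
  samples <- with_seed_or_not(seed, {
    purrr::map(seq_len(n_iter), function(it) {
      draws <- lapply(split_labels, function(labs) {
        switch(model,
          shuffled = sample(labs),
          uniform = sample(VALENCE_LEVELS, length(labs), replace = TRUE)
        )
      })
      if (keep_labels) label_draws[[it]] <<- draws
      h <- vapply(draws, entropy_of, numeric(1))
      tibble(iteration = it, source_id = ids, h = unname(h))
    }) %>% bind_rows()
  })

  iteration_summary <- samples %>%
    group_by(.data$iteration) %>%
    summarise(mean_h = mean(.data$h), median_h = median(.data$h),
              .groups = "drop")

  z <- bind_rows(
    mutate(zscore(mean(observed$h), iteration_summary$mean_h),
           statistic = "mean_h", .before = 1),
    mutate(zscore(median(observed$h), iteration_summary$median_h),
           statistic = "median_h", .before = 1)
  )

  structure(
    list(model = model, level = "list", n_iter = n_iter, seed = seed,
         samples = samples, iteration_summary = iteration_summary,
         observed = observed, z = z, label_draws = label_draws),
    class = "null_ensemble"
  )
}

#' Network-level null models for the triad census
#'
#' Holds the network topology fixed (degree sequence, triangle count and
#' placement never change) and randomizes only the node valence labels:
#' `shuffled` permutes the observed labels across nodes, conserving the
#' empirical label histogram exactly in every iteration; `uniform` redraws
#' every label independently and uniformly over the three classes. Each
#' iteration records the full signature census and the complexity `c_r`;
#' z-scores compare the observed census against the ensemble, flagged
#' significant outside |z| <= 1.96.
#'
#' @param network A labeled network with at least one triangle.
#' @param model `"shuffled"` or `"uniform"`.
#' @param n_iter Number of iterations (default 500).
#' @param seed Optional integer seed.
#' @param keep_labels Store every iteration's randomized node-label vector
#'   in `$label_draws` (for conservation audits; default `FALSE`).
#' @return An object of class `null_ensemble` (level `"network"`): list
#'   with `samples` (tibble `iteration`, one column per signature, `c_r`),
#'   `observed` (the observed [triad_census()]), and `z` (tibble
#'   `statistic`, `observed`, `null_mean`, `null_sd`, `z`, `significant`,
#'   `defined`, one row per signature plus one for `c`).
#' @export
network_null <- function(network, model = c("shuffled", "uniform"),
                         n_iter = 500, seed = NULL, keep_labels = FALSE) {
  model <- match.arg(model)
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  tri <- triangle_matrix(network)
  if (nrow(tri) == 0) abort("no triads: the network has no triangle")
  labels <- node_labels(network)
  n_nodes <- length(labels)
  observed <- census_from_triangles(tri, labels)

  sigs <- all_triad_signatures()
  incoherent_sig <- grepl("\\+", sigs) & grepl("-", sigs, fixed = TRUE)
  n_tri <- nrow(tri)
  res <- with_seed_or_not(seed, {
    out <- matrix(0L, nrow = n_iter, ncol = length(sigs),
                  dimnames = list(NULL, sigs))
    c_r <- numeric(n_iter)
    draws <- if (keep_labels) vector("list", n_iter) else NULL
    for (it in seq_len(n_iter)) {
      rl <- switch(model,
        shuffled = sample(labels),
        uniform = sample(VALENCE_LEVELS, n_nodes, replace = TRUE)
      )
      if (keep_labels) draws[[it]] <- rl
      lab_tri <- matrix(rl[tri], ncol = 3)
      cnt <- tabulate(factor(triad_signatures_fast(lab_tri), levels = sigs),
                      nbins = length(sigs))
      out[it, ] <- cnt
      c_r[it] <- sum(cnt[incoherent_sig]) / n_tri
    }
    list(counts = out, c_r = c_r, draws = draws)
  })

  samples <- as_tibble(res$counts)
  samples$c_r <- res$c_r
  samples <- mutate(samples, iteration = row_number(), .before = 1)

  z <- bind_rows(purrr::map(sigs, function(s) {
    obs_n <- observed$counts$n[observed$counts$signature == s]
    mutate(zscore(obs_n, res$counts[, s]), statistic = s, .before = 1)
  }))
  z <- bind_rows(z, mutate(zscore(observed$c, res$c_r),
                           statistic = "c", .before = 1))

  structure(
    list(model = model, level = "network", n_iter = n_iter, seed = seed,
         samples = samples, observed = observed, z = z,
         label_draws = res$draws),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s model, %s level, %d iterations\n",
              x$model, x$level, x$n_iter))
  sig <- x$z[!is.na(x$z$z) & x$z$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("significant departures (|z| > 1.96):",
        paste(sprintf("%s (z = %.2f)", sig$statistic, sig$z),
              collapse = ", "), "\n")
  } else {
    cat("no significant departures at |z| > 1.96\n")
  }
  invisible(x)
}

#' Rank test between two ensembles of statistics
#'
#' Kruskal-Wallis comparison of two samples — e.g. the observed per-list
#' entropies against a null model's pooled entropy samples.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @return Tibble with columns `statistic` (K), `df`, `p_value`, `n`.
#' @export
compare_ensembles <- function(sample_a, sample_b) {
  compare_groups_rank(list(sample_a, sample_b))
}
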