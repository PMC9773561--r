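#' Emotional richness profile of a word multiset
#'
#' For each of the eight basic emotions, the richness `r_i = m_i / N` is the
#' fraction of the text's `N` words that elicit emotion `i` under the
#' emotion lexicon. Words absent from the lexicon count toward `N` but
#' elicit nothing, so `r_i` is defined over the text, not over lexicon hits.
#' A single word may elicit several emotions, so the `m_i` can sum past `N`
#' while every `r_i` stays in \[0, 1\].
#'
#' @param words Character vector (a multiset: duplicates count).
#' @param lexicon An [affect_lexicon()].
#' @return A tibble of class `emotion_profile` with columns `emotion`, `m`,
#'   `r`; the word count is stored in `attr(, "N")`.
#' @export
emotional_richness <- function(words, lexicon) {
  words <- tolower(words)
  N <- length(words)
  if (N == 0) abort("no scorable words")
  idx <- match(words, lexicon$word)
  m <- vapply(EMOTIONS, function(e) {
    flags <- lexicon[[e]][idx]
    sum(flags, na.rm = TRUE)
  }, numeric(1))
  out <- tibble(emotion = EMOTIONS, m = unname(m), r = unname(m) / N)
  attr(out, "N") <- N
  class(out) <- c("emotion_profile", class(out))
  out
}

#' Emotion z-score profile against a resampled baseline
#'
#' Compares the emotional richness of a target word set against the
#' distribution of richness over `n_samples` random samples (without
#' replacement, each of the target's size) drawn from a pool of words. For
#' each emotion, `z = (r_target - mean(r_null)) / sd(r_null)`; `|z| > 1.96`
#' flags significance at the 0.05 level. These z values are the data behind
#' "emotional flower" displays.
#'
#' @param target_words Character vector, the profile under test.
#' @param pool_words Character vector to resample from; must be at least as
#'   large as `target_words`.
#' @param lexicon An [affect_lexicon()].
#' @param n_samples Number of random profiles (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `zscore_profile` with columns `emotion`,
#'   `r_target`, `null_mean`, `null_sd`, `z`, `significant`, `defined`.
#'   Emotions with zero null variance get `defined = FALSE` and `z = NA`.
#' @export
profile_zscores <- function(target_words, pool_words, lexicon,
                            n_samples = 1000, seed = NULL) {
  target_words <- tolower(target_words)
  pool_words <- tolower(pool_words)
  k <- length(target_words)
  if (k == 0) abort("no scorable words")
  if (length(pool_words) < k) {
    abort("pool must be at least as large as the target")
  }
  obs <- emotional_richness(target_words, lexicon)

  # emotion membership matrix for the pool: one row per word, col per emotion
  idx <- match(pool_words, lexicon$word)
  M <- vapply(EMOTIONS, function(e) {
    f <- lexicon[[e]][idx]
    f[is.na(f)] <- FALSE
    as.numeric(f)
  }, numeric(length(pool_words)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)

  null_r <- with_seed_or_not(seed, {
    t(vapply(seq_len(n_samples), function(i) {
      rows <- sample.int(length(pool_words), k)
      colMeans(M[rows, , drop = FALSE])
    }, numeric(length(EMOTIONS))))
  })

  mu <- colMeans(null_r)
  sig <- apply(null_r, 2, sd)
  z <- ifelse(sig > 0, (obs$r - mu) / sig, NA_real_)
  out <- tibble(
    emotion = EMOTIONS,
    r_target = obs$r,
    null_mean = unname(mu),
    null_sd = unname(sig),
    z = unname(z),
    significant = !is.na(z) & abs(z) > 1.96,
    defined = sig > 0
  )
  attr(out, "n_samples") <- n_samples
  attr(out, "sample_size") <- k
  attr(out, "seed") <- seed
  class(out) <- c("zscore_profile", class(out))
  out
}

#' Rank-based comparison of two or more groups
#'
#' Kruskal-Wallis rank-sum test (with the standard tie correction) on a
#' value column split by group; the workhorse comparison for closeness and
#' entropy distributions.
#'
#' @param df Data frame with the value and group columns, or a list of
#'   numeric vectors (one per group).
#' @param values,groups Column names (tidy-eval) when `df` is a data frame.
#' @return Tibble with columns `statistic` (H), `df`, `p_value`, `n`.
#' @export
compare_groups_rank <- function(df, values = value, groups = group) {
  if (is.list(df) && !is.data.frame(df)) {
    sizes <- lengths(df)
    if (any(sizes == 0)) abort("all groups must be non-empty")
    x <- unlist(df, use.names = FALSE)
    g <- factor(rep(seq_along(df), sizes))
  } else {
    df <- as_tibble(df)
    x <- dplyr::pull(df, {{ values }})
    g <- factor(dplyr::pull(df, {{ groups }}))
    if (any(table(g) == 0) || nlevels(g) < 2) {
      abort("need at least two non-empty groups")
    }
  }
  kt <- kruskal.test(x, g)
  tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n = length(x)
  )
}

#' Chi-square test of sentiment-label composition across groups
#'
#' Pearson chi-square (no continuity correction) on a groups-by-labels
#' contingency table of positive/negative/neutral counts.
#'
#' @param counts A matrix or data frame of nonnegative counts, groups in
#'   rows, sentiment labels in columns.
#' @return Tibble with columns `statistic` (chi-square), `df`, `p_value`.
#' @export
sentiment_contingency_test <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || any(m < 0)) abort("counts must be nonnegative numbers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}
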