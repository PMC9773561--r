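# Independent brute-force oracles. Each one is deliberately naive (double
# and triple loops, BFS by hand) and shares no code with the package paths
# it cross-checks.

# all-pairs shortest paths by breadth-first search on an edge list;
# closeness (N-1)/sum(d) within each connected component, singletons 0
oracle_closeness <- function(edges, words) {
  adj <- lapply(setNames(vector("list", length(words)), words), identity)
  for (w in words) adj[[w]] <- character(0)
  for (i in seq_len(nrow(edges))) {
    u <- edges$from[i]; v <- edges$to[i]
    adj[[u]] <- union(adj[[u]], v)
    adj[[v]] <- union(adj[[v]], u)
  }
  bfs_dist <- function(src) {
    d <- setNames(rep(Inf, length(words)), words)
    d[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.infinite(d[nb])) {
          d[nb] <- d[cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
    d
  }
  vapply(words, function(w) {
    d <- bfs_dist(w)
    reach <- d[is.finite(d) & names(d) != w]
    if (length(reach) == 0) return(0)
    length(reach) / sum(reach)
  }, numeric(1))
}

# exhaustive triple loop over node triples; counts closed triangles by
# label signature and the incoherent fraction
oracle_triad_census <- function(edges, labels) {
  words <- names(labels)
  has_edge <- function(a, b) {
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  }
  sig_count <- integer(0)
  n_inc <- 0L; n_tot <- 0L
  n <- length(words)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- words[i]; b <- words[j]; d <- words[k]
      if (has_edge(a, b) && has_edge(b, d) && has_edge(a, d)) {
        lab <- labels[c(a, b, d)]
        np <- sum(lab == "positive"); nn <- sum(lab == "negative")
        sig <- paste0(strrep("+", np), strrep("-", nn),
                      strrep("n", 3 - np - nn))
        sig_count[sig] <- (if (is.na(sig_count[sig])) 0L else sig_count[sig]) + 1L
        n_tot <- n_tot + 1L
        if (np >= 1 && nn >= 1) n_inc <- n_inc + 1L
      }
    }
  }
  list(counts = sig_count, n_triangles = n_tot, n_incoherent = n_inc,
       c = if (n_tot > 0) n_inc / n_tot else NA_real_)
}

# scan of consecutive label triples
oracle_ordered_triads <- function(symbols) {
  out <- integer(0)
  if (length(symbols) >= 3) {
    for (t in 1:(length(symbols) - 2)) {
      key <- paste0(symbols[t], symbols[t + 1], symbols[t + 2])
      out[key] <- (if (is.na(out[key])) 0L else out[key]) + 1L
    }
  }
  out
}

# O(n^2) Kendall tau-b from concordant/discordant pair counts
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; Tx <- 0; Ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) next
    if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (dx * dy > 0) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

# exhaustive double loop over positions of every list: counts, for each
# unordered stem pair, positional pairs within distance <= a
oracle_window_counts <- function(lists_df, a) {
  out <- new.env()
  for (id in unique(lists_df$source_id)) {
    g <- lists_df[lists_df$source_id == id, ]
    g <- g[order(g$position), ]
    l <- nrow(g)
    if (l < 2) next
    for (i in 1:(l - 1)) for (j in (i + 1):l) {
      if (j - i <= a && g$stem[i] != g$stem[j]) {
        key <- paste(sort(c(g$stem[i], g$stem[j])), collapse = "|")
        cur <- if (is.null(out[[key]])) 0L else out[[key]]
        out[[key]] <- cur + 1L
      }
    }
  }
  as.list(out)
}

# two-event Shannon entropy computed directly from a label sequence
oracle_entropy <- function(labels) {
  ind <- as.integer(labels[-1] != labels[-length(labels)])
  p1 <- sum(ind) / length(ind)
  p0 <- 1 - p1
  h <- 0
  if (p0 > 0) h <- h - p0 * log2(p0)
  if (p1 > 0) h <- h - p1 * log2(p1)
  h
}
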