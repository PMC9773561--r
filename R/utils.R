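# internal helpers shared across modules

# Derive a reproducible substream seed from a top-level seed and a stage
# offset; keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

# Run `code` under `seed` without disturbing the caller's RNG state;
# a NULL seed leaves the RNG stream untouched.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

assert_valence_labels <- function(labels, arg = "labels") {
  bad <- setdiff(unique(labels), VALENCE_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid valence label(s) in `%s`: %s (expected %s)",
      arg, paste(bad, collapse = ", "), paste(VALENCE_LEVELS, collapse = "/")
    ))
  }
  invisible(labels)
}

# multiset of three valence labels -> canonical signature string, e.g. "++n"
triad_signature <- function(labels) {
  np <- sum(labels == "positive")
  nn <- sum(labels == "negative")
  nu <- sum(labels == "neutral")
  paste0(strrep("+", np), strrep("-", nn), strrep("n", nu))
}

# the 10 unordered signatures of a labeled triangle, in display order
all_triad_signatures <- function() {
  sigs <- character(0)
  for (np in 3:0) for (nn in (3 - np):0) {
    nu <- 3 - np - nn
    sigs <- c(sigs, paste0(strrep("+", np), strrep("-", nn), strrep("n", nu)))
  }
  sigs
}
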