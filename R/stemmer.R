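#' Reduce words to crude dictionary stems
#'
#' A small, deterministic suffix-stripping stemmer used to map inflected
#' tokens onto the stems of an [emotional dictionary][read_emotional_dictionary].
#' It strips a fixed set of common English suffixes (`-iness`/`-ness`,
#' `-fully`/`-ful`, `-ingly`, `-ing`, `-ied`/`-ed`, `-ies`/`-es`/`-s`, `-ly`),
#' never shortens a word below three characters, and lowercases its input.
#' It is intentionally much lighter than a full Porter stemmer: the goal is a
#' reproducible token-to-stem map, not linguistically complete stemming.
#'
#' @param words Character vector of tokens.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' stem_words(c("sadness", "sad", "worried", "happiness", "loves"))
#' @export
stem_words <- function(words) {
  w <- tolower(words)
  w <- sub("'s$", "", w)
  # ordered rules: (pattern, replacement); first match wins per word
  rules <- list(
    c("iness$", "y"),   # happiness -> happy
    c("fulness$", "ful"),
    c("ness$", ""),     # sadness -> sad
    c("ingly$", ""),
    c("fully$", "ful"),
    c("ied$", "y"),     # worried -> worry
    c("ies$", "y"),     # worries -> worry
    c("ing$", ""),
    c("ed$", ""),
    c("ly$", ""),
    c("(s|x|z|ch|sh)es$", "\\1"),  # wishes -> wish, loves falls through to s$
    c("s$", "")
  )
  out <- w
  done <- rep(FALSE, length(w))
  for (rule in rules) {
    hit <- !done & grepl(rule[[1]], out)
    if (any(hit)) {
      cand <- sub(rule[[1]], rule[[2]], out[hit])
      keep <- nchar(cand) >= 3
      out[hit][keep] <- cand[keep]
      done[hit][keep] <- TRUE
    }
  }
  out
}
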