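# Shared text normalization.
#
# Both catalog descriptions and impression phrases are reduced to lowercase
# alphanumeric tokens the same way (characters outside [A-Za-z0-9] and
# whitespace are *deleted*, so "1.2 cm" becomes tokens "12" "cm"); phrases
# additionally pass through inflection reduction and the clinical synonym
# table, descriptions drop single-character tokens.

tokenize1 <- function(x, drop_short = TRUE) {
  y <- tolower(x)
  y <- gsub("[^a-z0-9[:space:]]", "", y)
  toks <- strsplit(trimws(y), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (drop_short) toks <- toks[nchar(toks) >= 2L]
  toks
}

# Light singular/inflection reduction: "masses" -> "mass",
# "hemorrhages" -> "hemorrhage", "opacities" -> "opacity".
reduce_token <- function(tok) {
  n <- nchar(tok)
  if (n < 4L) return(tok)
  if (grepl("ies$", tok)) return(sub("ies$", "y", tok))
  if (grepl("(ss|x|z|ch|sh)es$", tok)) return(sub("es$", "", tok))
  # Latin/Greek singulars ("stenosis", "calculus") are not plurals
  if (grepl("(is|us|ss)$", tok)) return(tok)
  if (grepl("s$", tok)) return(sub("s$", "", tok))
  tok
}

#' Normalize a phrase to matcher tokens
#'
#' Case-folds, deletes characters outside `[A-Za-z0-9]` and whitespace,
#' splits on whitespace, applies singular/inflection reduction, and then
#' replaces tokens via the clinical synonym table (e.g. `bleed` ->
#' `hemorrhage`). Token order is preserved. Punctuation-only input yields
#' an empty token vector.
#'
#' @param x A single phrase string.
#' @param synonyms Named character vector mapping surface tokens to
#'   canonical tokens; defaults to the bundled table ([radcoder_synonyms()]).
#' @return Character vector of normalized tokens (possibly empty).
#' @examples
#' normalize_phrase("No acute intracranial hemorrhage.")
#' @export
normalize_phrase <- function(x, synonyms = radcoder_synonyms()) {
  stopifnot(length(x) == 1L)
  toks <- tokenize1(x, drop_short = FALSE)
  if (length(toks) == 0L) return(character(0))
  toks <- vapply(toks, reduce_token, character(1), USE.NAMES = FALSE)
  hit <- toks %in% names(synonyms)
  toks[hit] <- unname(synonyms[toks[hit]])
  toks
}

# Stopwords for the non-codable test: function words plus generic
# study/exam nouns that carry no finding information.
radcoder_stopwords <- function() {
  c(
    "the", "a", "an", "of", "for", "is", "are", "was", "were", "and", "or",
    "in", "on", "at", "to", "this", "that", "there",
    "study", "exam", "examination", "scan", "image", "series", "overall",
    "otherwise", "grossly", "again", "noted", "seen", "identified",
    "appearance", "appearing", "interval"
  )
}
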