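# Phrase polarity: positive finding, pertinent negative finding (PNF), or
# non-codable normality statement.

#' Classify the polarity of a normalized phrase
#'
#' A phrase is a *pertinent negative* when a negation trigger (e.g. "no",
#' "without", "free", "resolved") precedes a finding-bearing token; the
#' negation scope is the whole phrase, since phrases are already atomic
#' findings after segmentation. A phrase is *non-codable* when it consists
#' solely of normality terms ("normal", "unremarkable", "stable",
#' "negative") and stopwords, with no finding-bearing token -- the
#' engine-side analog of a reviewer's "no applicable code" verdict.
#' Everything else (including hedged findings such as "possible infarct")
#' is a *positive* finding. An empty token vector is non-codable.
#'
#' The classification is a pure function of the tokens and the trigger
#' table. Negative phrases still receive ranked code candidates downstream
#' (the negated finding's code, flagged negative); non-codable phrases
#' receive none.
#'
#' @param tokens Normalized token vector (see [normalize_phrase()]).
#' @param triggers Trigger table with columns `token`, `role` in
#'   `{negation, normality}` (see [radcoder_triggers()]).
#' @param lexicon Word-class lexicon; its pathology tokens are the
#'   finding-bearing nouns.
#' @return One of `"positive"`, `"negative"`, `"noncodable"`.
#' @examples
#' classify_polarity(c("no", "acute", "intracranial", "hemorrhage"))
#' classify_polarity("unremarkable")
#' @export
classify_polarity <- function(tokens, triggers = radcoder_triggers(),
                              lexicon = radcoder_lexicon()) {
  if (length(tokens) == 0L) return("noncodable")
  negation <- triggers$token[triggers$role == "negation"]
  normality <- triggers$token[triggers$role == "normality"]
  pathology <- lexicon$token[lexicon$class == "pathology"]
  neg_pos <- which(tokens %in% negation)
  finding_pos <- which(tokens %in% pathology)
  if (length(neg_pos) > 0L && any(finding_pos > min(neg_pos))) {
    return("negative")
  }
  if (all(tokens %in% c(normality, radcoder_stopwords()))) {
    return("noncodable")
  }
  "positive"
}
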