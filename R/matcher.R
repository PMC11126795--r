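# The contextual bag-of-words matcher: a nonnegative, odds-ratio-like
# match score per (phrase, catalog entry) pair, and ranked candidates.
#
# score = [ sum over shared tokens t of idf(t)^idf_exponent * class_weight(t) ]
#         * coverage^coverage_exponent * align * region
#
#   idf(t)   = ln((1 + n_entries) / (1 + df(t))) + 1   (rare terms count more)
#   coverage = |shared| / |description tokens|          (longer matches score higher)
#   align    = order_bonus when the shared tokens appear in the same
#              relative order in phrase and description, else 1
#   region   = region_match_multiplier / region_mismatch_multiplier / 1
#              according to exam-vs-entry body-region compatibility
#
# The score is 0 exactly when no token is shared; it is unbounded above.

#' Matcher weight configuration
#'
#' All tunable weights of the match score. Multipliers must be strictly
#' positive; `order_bonus` and `region_match_multiplier` are at least 1 and
#' `region_mismatch_multiplier` lies in (0, 1].
#'
#' @param idf_exponent Exponent on the inverse-document-frequency factor.
#' @param class_weight_anatomy,class_weight_pathology Weights for shared
#'   tokens that the catalog entry tags as anatomic or pathologic terms;
#'   untagged tokens weigh 1.
#' @param order_bonus Multiplier applied when shared tokens occur in the
#'   same relative order in phrase and description.
#' @param region_match_multiplier,region_mismatch_multiplier Multipliers
#'   applied when the exam's body region is, respectively, among or absent
#'   from the entry's tagged regions (entries tagging no region are
#'   region-neutral).
#' @param coverage_exponent Exponent on the fraction of the description's
#'   tokens that are matched.
#' @return A `matcher_weights` list.
#' @export
matcher_weights <- function(idf_exponent = 1,
                            class_weight_anatomy = 1.25,
                            class_weight_pathology = 2,
                            order_bonus = 1.2,
                            region_match_multiplier = 1.5,
                            region_mismatch_multiplier = 0.6,
                            coverage_exponent = 0.5) {
  w <- list(idf_exponent = idf_exponent,
            class_weight_anatomy = class_weight_anatomy,
            class_weight_pathology = class_weight_pathology,
            order_bonus = order_bonus,
            region_match_multiplier = region_match_multiplier,
            region_mismatch_multiplier = region_mismatch_multiplier,
            coverage_exponent = coverage_exponent)
  if (any(vapply(w, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1)))) {
    stop("all matcher weights must be single positive numbers")
  }
  if (w$order_bonus < 1) stop("order_bonus must be >= 1")
  if (w$region_match_multiplier < 1) stop("region_match_multiplier must be >= 1")
  if (w$region_mismatch_multiplier > 1) {
    stop("region_mismatch_multiplier must be in (0, 1]")
  }
  structure(w, class = "matcher_weights")
}

#' Read matcher weights from a YAML config file
#'
#' Any subset of the [matcher_weights()] fields may be given; the rest keep
#' their defaults.
#'
#' @param path Path to a YAML key-value file.
#' @return A `matcher_weights` list.
#' @export
read_matcher_weights <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(matcher_weights))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown matcher weight(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")))
  }
  do.call(matcher_weights, vals)
}

score_entry_idx <- function(tokens, idx, catalog, weights, body_region) {
  e <- catalog$entries
  dtoks <- e$tokens[[idx]]
  shared <- intersect(unique(tokens), dtoks)
  if (length(shared) == 0L) return(0)
  n <- catalog$entry_count
  df <- catalog$term_document_frequency[shared]
  idf <- log((1 + n) / (1 + df)) + 1
  cls <- rep(1, length(shared))
  cls[shared %in% e$anatomy_terms[[idx]]] <- weights$class_weight_anatomy
  cls[shared %in% e$pathology_terms[[idx]]] <- weights$class_weight_pathology
  base <- sum(idf^weights$idf_exponent * cls)
  coverage <- length(shared) / length(dtoks)
  in_phrase <- shared[order(match(shared, tokens))]
  in_desc <- shared[order(match(shared, dtoks))]
  align <- if (identical(in_phrase, in_desc)) weights$order_bonus else 1
  regions <- e$body_regions[[idx]]
  region <- if (length(regions) == 0L || is.na(body_region)) {
    1
  } else if (body_region %in% regions) {
    weights$region_match_multiplier
  } else {
    weights$region_mismatch_multiplier
  }
  base * coverage^weights$coverage_exponent * align * region
}

#' Score one phrase against one catalog entry
#'
#' @param tokens Normalized phrase tokens.
#' @param code The entry's code (display or normalized form).
#' @param catalog An `icd10_catalog`.
#' @param weights A [matcher_weights()] configuration.
#' @param body_region The exam's body region (`NA` for region-neutral
#'   scoring).
#' @return A single nonnegative score; 0 iff no token is shared.
#' @export
score_phrase <- function(tokens, code, catalog, weights = matcher_weights(),
                         body_region = NA_character_) {
  idx <- match(icd10_normalize(code), catalog$entries$code)
  if (is.na(idx)) stop(sprintf("code %s not in catalog", code))
  score_entry_idx(tokens, idx, catalog, weights, body_region)
}

#' Rank catalog candidates for a phrase
#'
#' Scores every catalog entry and returns the `k` highest-scoring
#' candidates with positive score, ties broken by lexicographic code
#' order; ranks are dense from 1. Non-codable phrases receive no
#' candidates.
#'
#' @inheritParams score_phrase
#' @param k Maximum number of candidates (default 100, covering the
#'   largest evaluated rank cutoff).
#' @param polarity Phrase polarity, copied onto each candidate row.
#' @param phrase_id Optional identifier, copied onto each candidate row.
#' @return Data frame with columns `phrase_id`, `rank`, `code`, `score`,
#'   `polarity` (zero rows possible).
#' @export
rank_candidates <- function(tokens, catalog, weights = matcher_weights(),
                            k = 100, body_region = NA_character_,
                            polarity = "positive",
                            phrase_id = NA_character_) {
  stopifnot(k >= 1)
  empty <- data.frame(phrase_id = character(0), rank = integer(0),
                      code = character(0), score = numeric(0),
                      polarity = character(0), stringsAsFactors = FALSE)
  if (identical(polarity, "noncodable") || catalog$entry_count == 0L) {
    return(empty)
  }
  scores <- vapply(seq_len(catalog$entry_count), function(i) {
    score_entry_idx(tokens, i, catalog, weights, body_region)
  }, numeric(1))
  keep <- which(scores > 0)
  if (length(keep) == 0L) return(empty)
  ord <- keep[order(-scores[keep], catalog$entries$code[keep])]
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(phrase_id = phrase_id, rank = seq_along(ord),
             code = catalog$entries$code[ord], score = scores[ord],
             polarity = polarity, stringsAsFactors = FALSE)
}

#' Auto-code a corpus of reports
#'
#' Runs the full pipeline (ingest, polarity, candidate ranking) over every
#' report and returns the match table: one row per (phrase, candidate).
#' The ingested phrase table is attached as attribute `"phrases"`, so
#' phrases that received no candidates (non-codable phrases, or phrases
#' sharing no token with any entry) remain observable. Output is
#' deterministic given identical inputs.
#'
#' @param corpus Corpus data frame (see [ingest_corpus()]).
#' @param catalog An `icd10_catalog`.
#' @param weights A [matcher_weights()] configuration.
#' @param k Rank cutoff for emitted candidates.
#' @param quiet Suppress the per-run phrase-count message.
#' @inheritParams ingest_corpus
#' @return Match table data frame with columns `report_id`, `phrase_id`,
#'   `line_index`, `phrase_index`, `rank`, `code`, `score`, `polarity`,
#'   `raw_text`, with the phrase table as attribute `"phrases"`.
#' @export
code_corpus <- function(corpus, catalog = radcoder_catalog(),
                        weights = matcher_weights(), k = 100,
                        lexicon = radcoder_lexicon(),
                        synonyms = radcoder_synonyms(),
                        triggers = radcoder_triggers(),
                        quiet = FALSE) {
  phrases <- ingest_corpus(corpus, lexicon = lexicon, synonyms = synonyms,
                           triggers = triggers)
  out <- lapply(seq_len(nrow(phrases)), function(i) {
    cand <- rank_candidates(phrases$tokens[[i]], catalog, weights = weights,
                            k = k, body_region = phrases$body_region[i],
                            polarity = phrases$polarity[i],
                            phrase_id = phrases$phrase_id[i])
    if (nrow(cand) == 0L) return(NULL)
    cbind(
      data.frame(report_id = phrases$report_id[i],
                 line_index = phrases$line_index[i],
                 phrase_index = phrases$phrase_index[i],
                 raw_text = phrases$raw_text[i],
                 stringsAsFactors = FALSE),
      cand
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  matches <- if (length(out) > 0L) {
    do.call(rbind, out)[, c("report_id", "phrase_id", "line_index",
                            "phrase_index", "rank", "code", "score",
                            "polarity", "raw_text")]
  } else {
    data.frame(report_id = character(0), phrase_id = character(0),
               line_index = integer(0), phrase_index = integer(0),
               rank = integer(0), code = character(0), score = numeric(0),
               polarity = character(0), raw_text = character(0),
               stringsAsFactors = FALSE)
  }
  if (!quiet) {
    message(sprintf(
      "coded %d phrases from %d reports (%d with candidates; score range %s)",
      nrow(phrases), length(unique(phrases$report_id)),
      length(unique(matches$phrase_id)),
      if (nrow(matches) > 0L) {
        sprintf("%.2f-%.2f", min(matches$score), max(matches$score))
      } else "empty"
    ))
  }
  attr(matches, "phrases") <- phrases
  matches
}
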