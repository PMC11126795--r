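# Validation framework: unanimity ground truth, TP-score thresholds,
# confusion classification, and sensitivity/specificity/F2 grids over code
# lengths {3,4,7} x rank cutoffs {1,5,20,100}.
#
# Classification rules, per comparison length L and rank cutoff k:
#   * phrase with a unanimous code: TP if the truncated unanimous code is
#     among the truncated top-k candidates, else FN (membership only; the
#     threshold plays no role here);
#   * any other evaluated phrase: FP if at least one top-k candidate score
#     is >= the threshold, else TN, where the threshold is the mean score
#     of the TP matches in that (L, k) cell. ">= / <" makes FP and TN
#     exhaustive and exclusive.
#   * phrases that are unanimously "no applicable code" are, by default,
#     routed through the same FP/TN rule (they have no agreed code, so the
#     TP/FN track does not apply); `nocode_mode = "exclude"` drops them.

#' Derive the unanimity ground truth from annotations
#'
#' A phrase's reference code exists only when every reviewer independently
#' selected the identical code once truncated to length `L`. Phrases where
#' every reviewer chose [NO_CODE] are `unanimous_no_code`; everything else
#' is `not_unanimous`.
#'
#' @inheritParams krippendorff_alpha
#' @return Data frame with columns `phrase_id`, `status` (one of
#'   `unanimous`, `unanimous_no_code`, `not_unanimous`), `code` (truncated
#'   unanimous code, or `NA`).
#' @export
derive_ground_truth <- function(annotations, L) {
  check_annotations(annotations)
  v <- truncate_verdict(annotations$code, L)
  units <- split(v, annotations$phrase_id)
  status <- vapply(units, function(u) {
    if (length(unique(u)) > 1L) "not_unanimous"
    else if (u[1L] == NO_CODE) "unanimous_no_code"
    else "unanimous"
  }, character(1))
  code <- vapply(units, function(u) {
    if (length(unique(u)) == 1L && u[1L] != NO_CODE) u[1L] else NA_character_
  }, character(1))
  data.frame(phrase_id = names(units), status = unname(status),
             code = unname(code), stringsAsFactors = FALSE)
}

# For each unanimous-code phrase, the score of its matched candidate in
# the top-k at length L (NA when the code is absent from the top-k).
tp_match_scores <- function(matches, truth, L, k) {
  mm <- matches[matches$rank <= k, , drop = FALSE]
  mm$code_l <- icd10_truncate(mm$code, L)
  una <- truth[truth$status == "unanimous", , drop = FALSE]
  vapply(seq_len(nrow(una)), function(i) {
    rows <- mm[mm$phrase_id == una$phrase_id[i] & mm$code_l == una$code[i], ,
               drop = FALSE]
    if (nrow(rows) == 0L) NA_real_ else max(rows$score)
  }, numeric(1))
}

#' Threshold match score for a grid cell
#'
#' The mean match score of the true-positive matches (phrases whose
#' unanimous code is found among the top-`k` candidates at length `L`);
#' used to split the remaining phrases into FP and TN.
#'
#' @param matches Match table (see [code_corpus()]).
#' @param truth Ground truth from [derive_ground_truth()] at the same `L`.
#' @param L,k Comparison length and rank cutoff.
#' @return The threshold (mean TP score).
#' @section Errors: Signals a condition of class
#'   `radcoder_threshold_undefined` when the cell has no true positives;
#'   [evaluate_grid()] marks such cells unavailable and continues.
#' @export
compute_threshold <- function(matches, truth, L, k) {
  s <- tp_match_scores(matches, truth, L, k)
  s <- s[!is.na(s)]
  if (length(s) == 0L) {
    stop(structure(
      class = c("radcoder_threshold_undefined", "error", "condition"),
      list(message = sprintf(
        "threshold undefined: no true positives at L=%d, k=%d", L, k),
        call = sys.call())
    ))
  }
  mean(s)
}

#' Classify phrases into confusion counts
#'
#' @inheritParams compute_threshold
#' @param threshold Threshold match score for this cell (see
#'   [compute_threshold()]).
#' @param nocode_mode How to treat unanimous no-code phrases:
#'   `"negative-pool"` (default) evaluates them under the FP/TN rule,
#'   `"exclude"` drops them from the cell.
#' @param include_negatives Keep pertinent-negative phrases in the
#'   evaluation (default). Exclusion requires the phrase table (attribute
#'   `"phrases"` of [code_corpus()] output, or a `phrases` argument).
#' @param phrases Optional phrase table used to look up phrase polarity
#'   when `include_negatives = FALSE`.
#' @return A `confusion_counts` list: `TP`, `FP`, `TN`, `FN`, `L`, `k`,
#'   `threshold`.
#' @export
classify_confusion <- function(matches, truth, L, k, threshold,
                               nocode_mode = c("negative-pool", "exclude"),
                               include_negatives = TRUE, phrases = NULL) {
  nocode_mode <- match.arg(nocode_mode)
  if (!include_negatives) {
    if (is.null(phrases)) phrases <- attr(matches, "phrases")
    if (is.null(phrases)) {
      stop("excluding negatives requires the ingested phrase table")
    }
    neg <- phrases$phrase_id[phrases$polarity == "negative"]
    truth <- truth[!truth$phrase_id %in% neg, , drop = FALSE]
  }
  if (nocode_mode == "exclude") {
    truth <- truth[truth$status != "unanimous_no_code", , drop = FALSE]
  }
  mm <- matches[matches$rank <= k, , drop = FALSE]
  mm$code_l <- icd10_truncate(mm$code, L)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(truth))) {
    rows <- mm[mm$phrase_id == truth$phrase_id[i], , drop = FALSE]
    if (truth$status[i] == "unanimous") {
      if (any(rows$code_l == truth$code[i])) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (nrow(rows) > 0L && any(rows$score >= threshold)) {
        fp <- fp + 1L
      } else {
        tn <- tn + 1L
      }
    }
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, L = L, k = k,
                 threshold = threshold),
            class = "confusion_counts")
}

#' Sensitivity, specificity, precision, and F2 from confusion counts
#'
#' `F2 = 5 * precision * recall / (4 * precision + recall)`: the F-beta
#' score with beta = 2, weighting recall (sensitivity) over precision.
#' Undefined 0/0 ratios are reported as 0 with a warning.
#'
#' @param counts A `confusion_counts` object (or list with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return Named list with `sensitivity`, `specificity`, `precision`,
#'   `f2`.
#' @export
confusion_metrics <- function(counts) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (0/0); reporting 0", what))
      return(0)
    }
    num / den
  }
  sens <- ratio(counts$TP, counts$TP + counts$FN, "sensitivity")
  spec <- ratio(counts$TN, counts$TN + counts$FP, "specificity")
  prec <- ratio(counts$TP, counts$TP + counts$FP, "precision")
  f2 <- if (4 * prec + sens == 0) 0 else 5 * prec * sens / (4 * prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec, f2 = f2)
}

#' Evaluate the full metrics grid
#'
#' Computes, for every combination of comparison length and rank cutoff,
#' the TP-score threshold, the confusion counts, and
#' sensitivity/specificity/precision/F2. Cells whose threshold is
#' undefined (no true positives) are marked unavailable and the run
#' continues.
#'
#' @inheritParams classify_confusion
#' @param annotations Reviewer annotation data frame.
#' @param lengths Code comparison lengths.
#' @param ranks Rank cutoffs.
#' @return A `metrics_grid` data frame with columns `length`, `rank`,
#'   `available`, `threshold`, `TP`, `FP`, `TN`, `FN`, `sensitivity`,
#'   `specificity`, `precision`, `f2`.
#' @export
evaluate_grid <- function(matches, annotations, lengths = c(3, 4, 7),
                          ranks = c(1, 5, 20, 100),
                          nocode_mode = c("negative-pool", "exclude"),
                          include_negatives = TRUE, phrases = NULL) {
  nocode_mode <- match.arg(nocode_mode)
  rows <- list()
  for (L in lengths) {
    truth <- derive_ground_truth(annotations, L)
    for (k in ranks) {
      row <- data.frame(length = L, rank = k, available = TRUE,
                        threshold = NA_real_, TP = NA_integer_,
                        FP = NA_integer_, TN = NA_integer_, FN = NA_integer_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        precision = NA_real_, f2 = NA_real_)
      res <- tryCatch({
        th <- compute_threshold(matches, truth, L, k)
        cc <- classify_confusion(matches, truth, L, k, th,
                                 nocode_mode = nocode_mode,
                                 include_negatives = include_negatives,
                                 phrases = phrases)
        met <- suppressWarnings(confusion_metrics(cc))
        row$threshold <- th
        row$TP <- cc$TP; row$FP <- cc$FP; row$TN <- cc$TN; row$FN <- cc$FN
        row$sensitivity <- met$sensitivity
        row$specificity <- met$specificity
        row$precision <- met$precision
        row$f2 <- met$f2
        row
      }, radcoder_threshold_undefined = function(e) {
        row$available <- FALSE
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_grid", class(out))
  out
}

#' Compare the accuracy of two grid cells
#'
#' Two-proportion chi-square test (with continuity correction) on the
#' pooled correct (`TP + TN`) versus incorrect (`FP + FN`) classifications
#' of two cells -- e.g. the length-3 and length-7 cells at the same rank
#' cutoff.
#'
#' @param counts_a,counts_b `confusion_counts` objects (or one-row slices
#'   of a `metrics_grid`).
#' @return The p-value.
#' @export
compare_proportions <- function(counts_a, counts_b) {
  correct <- c(counts_a$TP + counts_a$TN, counts_b$TP + counts_b$TN)
  total <- c(counts_a$TP + counts_a$FP + counts_a$TN + counts_a$FN,
             counts_b$TP + counts_b$FP + counts_b$TN + counts_b$FN)
  if (any(total == 0)) stop("cannot compare cells with zero evaluated phrases")
  suppressWarnings(stats::prop.test(correct, total)$p.value)
}
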