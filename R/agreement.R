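# Inter-reviewer reliability: Cohen's kappa, Fleiss' kappa, Krippendorff's
# alpha (nominal), and percent exact agreement, all evaluated on verdicts
# truncated to a comparison length with NO_CODE as its own category.

truncate_verdict <- function(v, L) {
  out <- v
  idx <- v != NO_CODE
  out[idx] <- icd10_truncate(v[idx], L)
  out
}

#' Read reviewer annotations
#'
#' Annotation CSVs have columns `phrase_id`, `reviewer_id`, `code`; an
#' empty code means the reviewer found no applicable ICD-10 code and is
#' mapped to the [NO_CODE] verdict.
#'
#' @param path CSV file path.
#' @return Annotation data frame with validated, normalized codes.
#' @export
read_annotations <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(code = "character"))
  stopifnot(all(c("phrase_id", "reviewer_id", "code") %in% names(tab)))
  blank <- is.na(tab$code) | !nzchar(trimws(tab$code))
  tab$code[blank] <- NO_CODE
  tab$code[!blank] <- icd10_normalize(tab$code[!blank])
  check_annotations(tab)
  tab
}

check_annotations <- function(annotations) {
  stopifnot(all(c("phrase_id", "reviewer_id", "code") %in% names(annotations)))
  tab <- table(annotations$phrase_id, annotations$reviewer_id)
  if (any(tab != 1L)) {
    stop("annotations must contain exactly one verdict per (phrase, reviewer)")
  }
  invisible(annotations)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement for two label sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with expected agreement `p_e` from
#' the product of the raters' marginal category proportions. Perfect
#' agreement with degenerate marginals (`p_e = 1`, `p_o = 1`) returns 1.
#'
#' @param a,b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label sequences must have equal length")
  if (length(a) == 0L) stop("label sequences must be non-empty")
  lev <- union(a, b)
  n <- length(a)
  p_o <- mean(a == b)
  pa <- table(factor(a, levels = lev)) / n
  pb <- table(factor(b, levels = lev)) / n
  p_e <- sum(pa * pb)
  if (1 - p_e == 0) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa for three or more raters
#'
#' Standard multi-rater formulation: mean per-item agreement compared with
#' chance agreement from the pooled category proportions.
#'
#' @param counts Item-by-category matrix of rater counts; every row must
#'   sum to `raters_per_item`.
#' @param raters_per_item Number of raters per item (>= 2); inferred from
#'   the first row when `NULL`.
#' @return Kappa; `NaN` with a warning when only a single category is ever
#'   used (the chance-agreement denominator vanishes).
#' @export
fleiss_kappa <- function(counts, raters_per_item = NULL) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  if (is.null(raters_per_item)) raters_per_item <- rs[1L]
  if (raters_per_item < 2L) stop("raters_per_item must be >= 2")
  if (any(rs != raters_per_item)) {
    stop("every row of the count matrix must sum to raters_per_item")
  }
  n <- raters_per_item
  p_j <- colSums(counts) / (nrow(counts) * n)
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (1 - p_e == 0) {
    warning("Fleiss kappa undefined: a single category was used throughout")
    return(NaN)
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Krippendorff's alpha (nominal) on an annotation set
#'
#' Verdicts are truncated to comparison length `L` before comparison;
#' [NO_CODE] participates as its own nominal category. Alpha is
#' `1 - D_o / D_e` from the coincidence matrix over all within-phrase value
#' pairs. Complete agreement returns 1 even when only one value occurs;
#' any other vanishing expected disagreement yields `NaN` with a warning.
#'
#' @param annotations Annotation data frame (`phrase_id`, `reviewer_id`,
#'   `code`).
#' @param L Comparison length (3, 4, or 7).
#' @param bootstrap Number of phrase-level bootstrap resamples for an
#'   uncertainty estimate (0 = none).
#' @param conf_level Confidence level for the bootstrap interval.
#' @return Alpha in `[-1, 1]`. With `bootstrap > 0`, attributes `"ci"`
#'   (percentile interval) and `"p_value"` (one-sided bootstrap probability
#'   that alpha <= 0) are attached; resampling uses the current RNG state,
#'   so seed the session for reproducibility.
#' @export
krippendorff_alpha <- function(annotations, L, bootstrap = 0,
                               conf_level = 0.95) {
  check_annotations(annotations)
  if (length(unique(annotations$reviewer_id)) < 2L) {
    stop("Krippendorff alpha needs at least two reviewers")
  }
  v <- truncate_verdict(annotations$code, L)
  units <- split(v, annotations$phrase_id)
  alpha <- alpha_from_units(units)
  if (bootstrap > 0) {
    reps <- vapply(seq_len(bootstrap), function(i) {
      alpha_from_units(units[sample.int(length(units), replace = TRUE)])
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    a <- (1 - conf_level) / 2
    attr(alpha, "ci") <- unname(stats::quantile(reps, c(a, 1 - a)))
    attr(alpha, "p_value") <- mean(reps <= 0)
  }
  alpha
}

alpha_from_units <- function(units) {
  units <- units[lengths(units) >= 2L]
  if (length(units) == 0L) stop("no phrase has two or more verdicts")
  vals <- sort(unique(unlist(units)))
  n_uc <- t(vapply(units, function(u) {
    tabulate(match(u, vals), nbins = length(vals))
  }, integer(length(vals))))
  if (length(vals) == 1L) n_uc <- matrix(n_uc, ncol = 1L)
  m_u <- rowSums(n_uc)
  n <- sum(m_u)
  # observed disagreement: within-unit pairs with differing values
  d_o <- sum(n_uc * (m_u - n_uc) / (m_u - 1)) / n
  n_c <- colSums(n_uc)
  d_e <- sum(n_c * (n - n_c)) / (n * (n - 1))
  if (d_e == 0) {
    if (d_o == 0) return(1)
    warning("Krippendorff alpha undefined: zero expected disagreement")
    return(NaN)
  }
  1 - d_o / d_e
}

#' Percent exact agreement for a reviewer pair
#'
#' Percentage of phrases on which two reviewers' verdicts, truncated to
#' length `L`, are identical ([NO_CODE] agreeing only with itself).
#' Optionally restricted to the phrases where *all* reviewers in the set
#' assigned a code (no [NO_CODE] verdicts).
#'
#' @inheritParams krippendorff_alpha
#' @param pair Character vector of two reviewer ids.
#' @param restrict_to_all_coded Restrict to fully-coded phrases.
#' @return Percentage in `[0, 100]`.
#' @export
percent_exact_agreement <- function(annotations, L, pair,
                                    restrict_to_all_coded = FALSE) {
  check_annotations(annotations)
  stopifnot(length(pair) == 2L, all(pair %in% annotations$reviewer_id))
  wide <- split(annotations, annotations$phrase_id)
  if (restrict_to_all_coded) {
    wide <- wide[vapply(wide, function(d) all(d$code != NO_CODE), logical(1))]
    if (length(wide) == 0L) stop("no phrase was coded by all reviewers")
  }
  same <- vapply(wide, function(d) {
    va <- d$code[d$reviewer_id == pair[1L]]
    vb <- d$code[d$reviewer_id == pair[2L]]
    identical(truncate_verdict(va, L), truncate_verdict(vb, L))
  }, logical(1))
  100 * mean(same)
}

#' Reliability report over reviewer subsets
#'
#' For every reviewer pair, triple, and the full panel: the
#' binary-applicability kappa (did the reviewer assign *any* code? Cohen
#' for pairs, Fleiss for larger subsets) and Krippendorff's alpha on the
#' specific code (or no-code) verdict at each comparison length.
#'
#' @inheritParams krippendorff_alpha
#' @param lengths Comparison lengths for alpha.
#' @return Data frame with one row per reviewer subset: `reviewers`,
#'   `kappa_applicability`, and one `alpha_<L>` column per length.
#' @export
agreement_report <- function(annotations, lengths = c(3, 4, 7)) {
  check_annotations(annotations)
  revs <- sort(unique(annotations$reviewer_id))
  if (length(revs) < 2L) stop("need at least two reviewers")
  subsets <- list()
  for (size in seq(2L, length(revs))) {
    cmb <- utils::combn(revs, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  rows <- lapply(subsets, function(sub) {
    ann <- annotations[annotations$reviewer_id %in% sub, , drop = FALSE]
    applicable <- ifelse(ann$code == NO_CODE, "no_code", "coded")
    kap <- if (length(sub) == 2L) {
      a <- applicable[ann$reviewer_id == sub[1L]][order(ann$phrase_id[ann$reviewer_id == sub[1L]])]
      b <- applicable[ann$reviewer_id == sub[2L]][order(ann$phrase_id[ann$reviewer_id == sub[2L]])]
      cohen_kappa(a, b)
    } else {
      counts <- table(ann$phrase_id, factor(applicable,
                                            levels = c("coded", "no_code")))
      suppressWarnings(fleiss_kappa(unclass(counts), length(sub)))
    }
    out <- data.frame(reviewers = paste(sub, collapse = "+"),
                      kappa_applicability = kap, stringsAsFactors = FALSE)
    for (L in lengths) {
      out[[sprintf("alpha_%d", L)]] <- as.numeric(krippendorff_alpha(ann, L))
    }
    out
  })
  do.call(rbind, rows)
}
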