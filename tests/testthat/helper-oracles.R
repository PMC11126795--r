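# Independent brute-force oracles for the agreement statistics and the
# matcher, written as plain loops/pair enumerations so they share no code
# path with the package implementations.

oracle_cohen <- function(a, b) {
  n <- length(a)
  p_o <- sum(a == b) / n
  cats <- unique(c(a, b))
  p_e <- 0
  for (cc in cats) {
    p_e <- p_e + (sum(a == cc) / n) * (sum(b == cc) / n)
  }
  if (p_e == 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

oracle_fleiss <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts[1L, ])
  N <- nrow(counts)
  # per-item agreement: fraction of agreeing ordered rater pairs
  p_i <- numeric(N)
  for (i in seq_len(N)) {
    agree <- 0
    for (j in seq_len(ncol(counts))) {
      agree <- agree + counts[i, j] * (counts[i, j] - 1)
    }
    p_i[i] <- agree / (n * (n - 1))
  }
  p_j <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) p_j[j] <- sum(counts[, j]) / (N * n)
  p_e <- sum(p_j^2)
  if (p_e == 1) return(NaN)
  (mean(p_i) - p_e) / (1 - p_e)
}

# Nominal Krippendorff alpha by explicit enumeration of ordered value
# pairs: within-unit pairs for observed disagreement, all-value pairs for
# expected disagreement.
oracle_alpha <- function(units) {
  units <- units[lengths(units) >= 2L]
  num <- 0
  n <- 0
  for (u in units) {
    m <- length(u)
    n <- n + m
    dis <- 0
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j && u[i] != u[j]) dis <- dis + 1
      }
    }
    num <- num + dis / (m - 1)
  }
  d_o <- num / n
  all_v <- unlist(units)
  dis <- 0
  for (i in seq_along(all_v)) {
    for (j in seq_along(all_v)) {
      if (i != j && all_v[i] != all_v[j]) dis <- dis + 1
    }
  }
  d_e <- dis / (length(all_v) * (length(all_v) - 1))
  if (d_e == 0) return(if (d_o == 0) 1 else NaN)
  1 - d_o / d_e
}

# alpha oracle from a long annotation data frame at comparison length L
oracle_alpha_annotations <- function(ann, L) {
  v <- ifelse(ann$code == NO_CODE, NO_CODE,
              substr(gsub(".", "", ann$code, fixed = TRUE), 1, L))
  oracle_alpha(split(v, ann$phrase_id))
}

# random annotation panel: n_phrases x n_reviewers nominal verdicts drawn
# from a small code pool (plus NO_CODE)
random_panel <- function(n_phrases, n_reviewers,
                         pool = c("I639", "I609", "G935", "R220", "S0620",
                                  NO_CODE)) {
  data.frame(
    phrase_id = rep(sprintf("p%02d", seq_len(n_phrases)), n_reviewers),
    reviewer_id = rep(sprintf("R%d", seq_len(n_reviewers)),
                      each = n_phrases),
    code = sample(pool, n_phrases * n_reviewers, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Independent re-derivation of the match score for the oracle-equivalence
# tests: straightforward loops over the formula's definition.
oracle_score <- function(tokens, entry, tdf, n_entries, w, body_region) {
  shared <- character(0)
  for (t in unique(tokens)) {
    if (t %in% entry$tokens) shared <- c(shared, t)
  }
  if (length(shared) == 0L) return(0)
  base <- 0
  for (t in shared) {
    idf <- log((1 + n_entries) / (1 + tdf[[t]])) + 1
    cw <- 1
    if (t %in% entry$pathology) cw <- w$class_weight_pathology
    else if (t %in% entry$anatomy) cw <- w$class_weight_anatomy
    base <- base + idf^w$idf_exponent * cw
  }
  cov <- length(shared) / length(entry$tokens)
  ord_phrase <- shared[order(match(shared, tokens))]
  ord_desc <- shared[order(match(shared, entry$tokens))]
  align <- if (all(ord_phrase == ord_desc)) w$order_bonus else 1
  region <- 1
  if (length(entry$regions) > 0L && !is.na(body_region)) {
    region <- if (body_region %in% entry$regions) w$region_match_multiplier
              else w$region_mismatch_multiplier
  }
  base * cov^w$coverage_exponent * align * region
}
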