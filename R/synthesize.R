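# Synthetic study-shaped data: report corpora with planted ground truth,
# and reviewer panels with tunable agreement. Everything is deterministic
# given the config seed.

#' Synthetic corpus configuration
#'
#' Defaults reproduce the shape of the reference 200-report craniospinal
#' corpus: exam types and patient settings sampled with the bundled mix
#' weights, a phrase-count distribution with mean about 3.2 phrases per
#' report, a 4.8 % non-codable phrase rate, and a 20 % pertinent-negative
#' rate.
#'
#' @param n_reports Number of reports to generate.
#' @param exam_mix Exam mix table (see [radcoder_exam_mix()]); `n_reports`
#'   column used as sampling weights.
#' @param setting_mix Setting mix table.
#' @param phrase_count_probs Named probability vector over phrases per
#'   report.
#' @param noncodable_rate Probability a planted phrase is a bare normality
#'   statement with no applicable code.
#' @param negative_rate Probability a codable planted phrase is a
#'   pertinent negative ("No ...").
#' @param two_phrase_line_prob Probability an Impression line carries two
#'   phrases (joined by "; ") rather than one.
#' @param seed Integer seed; the generator is fully determined by it.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_reports = 200,
                          exam_mix = radcoder_exam_mix(),
                          setting_mix = radcoder_setting_mix(),
                          phrase_count_probs = c(`1` = 0.10, `2` = 0.22,
                                                 `3` = 0.28, `4` = 0.22,
                                                 `5` = 0.12, `6` = 0.06),
                          noncodable_rate = 0.048,
                          negative_rate = 0.20,
                          two_phrase_line_prob = 0.7,
                          seed = 1L) {
  stopifnot(n_reports >= 1)
  if (abs(sum(phrase_count_probs) - 1) > 1e-9) {
    stop("phrase_count_probs must sum to 1")
  }
  for (p in c(noncodable_rate, negative_rate, two_phrase_line_prob)) {
    stopifnot(p >= 0, p <= 1)
  }
  structure(list(n_reports = n_reports, exam_mix = exam_mix,
                 setting_mix = setting_mix,
                 phrase_count_probs = phrase_count_probs,
                 noncodable_rate = noncodable_rate,
                 negative_rate = negative_rate,
                 two_phrase_line_prob = two_phrase_line_prob,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Reviewer panel configuration
#'
#' @param n_reviewers Panel size.
#' @param p_correct Probability a reviewer selects the planted code (or,
#'   for planted non-codable phrases, the no-code verdict).
#' @param p_nocode_error Probability of a spurious [NO_CODE] verdict on a
#'   codable phrase.
#' @param confusion_pool Optional named list mapping each code to its
#'   plausible distractor codes; defaults to same-category catalog
#'   neighbours, falling back to the rest of the catalog.
#' @param seed Integer seed.
#' @return A `reviewer_panel_config` list.
#' @export
reviewer_panel_config <- function(n_reviewers = 4, p_correct = 0.9,
                                  p_nocode_error = 0.02,
                                  confusion_pool = NULL, seed = 1L) {
  stopifnot(n_reviewers >= 2, p_correct >= 0, p_correct <= 1,
            p_nocode_error >= 0, p_nocode_error <= 1)
  structure(list(n_reviewers = as.integer(n_reviewers),
                 p_correct = p_correct, p_nocode_error = p_nocode_error,
                 confusion_pool = confusion_pool, seed = as.integer(seed)),
            class = "reviewer_panel_config")
}

# Phrase surface templates are derived from the catalog descriptions:
# conjunctions and filler words are dropped, an optional severity modifier
# is prepended, an optional measurement appended, and occasionally one
# canonical token is swapped for a clinical synonym (which normalization
# maps back).
template_drop_words <- c("and", "with", "of", "other", "specified",
                         "unspecified", "initial", "encounter", "due", "to",
                         "on", "site")
template_modifiers <- c("Mild", "Small", "Moderate", "Chronic", "Acute",
                        "Subtle")
template_surface_swaps <- c(hemorrhage = "bleed", infarction = "stroke",
                            neoplasm = "tumor", stenosis = "narrowing",
                            displacement = "bulge", calculus = "stone")
noncodable_templates <- c("Normal study", "Unremarkable examination",
                          "Stable exam", "Negative study")

make_phrase_text <- function(entry_desc, polarity) {
  toks <- tokenize1(entry_desc, drop_short = TRUE)
  toks <- toks[!toks %in% template_drop_words]
  swap <- intersect(names(template_surface_swaps), toks)
  if (length(swap) > 0L && runif(1) < 0.3) {
    pick <- sample(swap, 1L)
    toks[toks == pick] <- template_surface_swaps[[pick]]
  }
  txt <- paste(toks, collapse = " ")
  if (polarity == "negative") {
    txt <- paste("No", txt)
  } else {
    if (runif(1) < 0.5) txt <- paste(sample(template_modifiers, 1L), txt)
    if (runif(1) < 0.15) txt <- paste(txt, "measuring 1.2 cm")
  }
  paste0(toupper(substr(txt, 1L, 1L)), substr(txt, 2L, nchar(txt)))
}

#' Generate a synthetic report corpus with planted truth
#'
#' Samples exam types and settings from the configured mixes, draws a
#' phrase count per report, instantiates positive / pertinent-negative /
#' non-codable phrase templates keyed to catalog entries compatible with
#' the exam's body region, and assembles an enumerated Impression under a
#' randomly chosen recognized heading. The planted code, polarity, and
#' phrase position of every phrase are recorded as ground truth.
#'
#' @param config A [corpus_config()].
#' @param catalog Catalog whose entries seed the phrase templates.
#' @return A list of class `synthetic_corpus`: `corpus` (data frame of
#'   reports with exam context), `truth` (data frame with `phrase_id`,
#'   `report_id`, `line_index`, `phrase_index`, `code`, `polarity`,
#'   `planted_text`, and context columns), and `config`.
#' @export
generate_reports <- function(config = corpus_config(),
                             catalog = radcoder_catalog()) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  mix <- config$exam_mix
  if (any(mix$n_reports < 0) || sum(mix$n_reports) <= 0) {
    stop("invalid exam mix: nonpositive weights")
  }
  smix <- config$setting_mix
  entries <- catalog$entries
  by_region <- function(region) {
    hit <- vapply(entries$body_regions,
                  function(r) length(r) == 0L || region %in% r, logical(1))
    if (!any(hit)) hit <- rep(TRUE, nrow(entries))
    which(hit)
  }
  region_pool <- lapply(unique(mix$body_region), by_region)
  names(region_pool) <- unique(mix$body_region)
  counts <- as.integer(names(config$phrase_count_probs))
  corpus <- list()
  truth <- list()
  for (r in seq_len(config$n_reports)) {
    rid <- sprintf("R%04d", r)
    exam <- mix[sample.int(nrow(mix), 1L, prob = mix$n_reports), ]
    setting <- smix$setting[sample.int(nrow(smix), 1L, prob = smix$n_reports)]
    n_phr <- sample(counts, 1L, prob = config$phrase_count_probs)
    pool <- region_pool[[exam$body_region]]
    phr <- lapply(seq_len(n_phr), function(i) {
      u <- runif(1)
      if (u < config$noncodable_rate) {
        list(code = NA_character_, polarity = "noncodable",
             text = sample(noncodable_templates, 1L))
      } else {
        pol <- if (runif(1) < config$negative_rate) "negative" else "positive"
        idx <- pool[sample.int(length(pool), 1L)]
        # a pertinent negative needs a negatable finding noun; entries whose
        # description carries no pathology term (e.g. device-presence codes)
        # are always planted as positives
        if (length(entries$pathology_terms[[idx]]) == 0L) pol <- "positive"
        list(code = entries$code[idx], polarity = pol,
             text = make_phrase_text(entries$long_desc[idx], pol))
      }
    })
    # pack phrases into impression lines (1 or 2 phrases per line)
    line_of <- integer(n_phr)
    pos_of <- integer(n_phr)
    li <- 0L
    i <- 1L
    while (i <= n_phr) {
      li <- li + 1L
      take <- if (i < n_phr && runif(1) < config$two_phrase_line_prob) 2L else 1L
      for (j in seq_len(take)) {
        line_of[i] <- li
        pos_of[i] <- j
        i <- i + 1L
      }
    }
    line_texts <- vapply(seq_len(li), function(l) {
      paste0(paste(vapply(phr[line_of == l], `[[`, character(1), "text"),
                   collapse = "; "), ".")
    }, character(1))
    heading <- sample(c("IMPRESSION:", "IMPRESSIONS:", "Conclusions:"),
                      1L, prob = c(0.7, 0.1, 0.2))
    body <- paste(sprintf("%d. %s", seq_len(li), line_texts), collapse = "\n")
    text <- paste0(
      "EXAM: ", exam$exam_type, "\n",
      "INDICATION: ", setting, " patient.\n",
      "FINDINGS: Described below.\n\n",
      heading, "\n", body, "\n"
    )
    corpus[[r]] <- data.frame(
      report_id = rid, text = text, exam_type = exam$exam_type,
      modality = exam$modality, body_region = exam$body_region,
      contrast = exam$contrast, setting = setting, stringsAsFactors = FALSE
    )
    truth[[r]] <- data.frame(
      report_id = rid,
      phrase_id = sprintf("%s-L%d-P%d", rid, line_of, pos_of),
      line_index = line_of, phrase_index = pos_of,
      code = vapply(phr, `[[`, character(1), "code"),
      polarity = vapply(phr, `[[`, character(1), "polarity"),
      planted_text = vapply(phr, `[[`, character(1), "text"),
      modality = exam$modality, body_region = exam$body_region,
      contrast = exam$contrast, setting = setting,
      stringsAsFactors = FALSE
    )
  }
  structure(list(corpus = do.call(rbind, corpus),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "synthetic_corpus")
}

#' Simulate a reviewer panel over planted truth
#'
#' Each reviewer, independently per phrase: on a codable phrase, errs to a
#' spurious no-code verdict with probability `p_nocode_error`; otherwise
#' selects the planted code with probability `p_correct` and a
#' confusion-pool distractor otherwise. On a planted non-codable phrase
#' the reviewer gives [NO_CODE] with probability `p_correct` and a random
#' catalog code otherwise. With `p_nocode_error = 0`, the probability that
#' a panel of `m` reviewers is unanimous is `p_correct^m` for every phrase
#' (distractor collisions aside).
#'
#' @param truth Planted truth table (see [generate_reports()]), or any data
#'   frame with `phrase_id`, `code` (`NA` = non-codable), `polarity`.
#' @param panel A [reviewer_panel_config()].
#' @param catalog Catalog supplying the default confusion pools.
#' @return Annotation data frame (`phrase_id`, `reviewer_id`, `code`).
#' @export
simulate_reviewers <- function(truth, panel = reviewer_panel_config(),
                               catalog = radcoder_catalog()) {
  stopifnot(inherits(panel, "reviewer_panel_config"))
  set.seed(panel$seed)
  codes <- catalog$entries$code
  pool_of <- function(code) {
    if (!is.null(panel$confusion_pool)) {
      p <- panel$confusion_pool[[code]]
      if (is.null(p)) stop(sprintf("no confusion pool for code %s", code))
      return(p)
    }
    p <- setdiff(codes[icd10_category(codes) == icd10_category(code)], code)
    if (length(p) == 0L) p <- setdiff(codes, code)
    p
  }
  reviewers <- sprintf("R%s", LETTERS[seq_len(panel$n_reviewers)])
  n <- nrow(truth)
  rows <- vector("list", panel$n_reviewers)
  for (rv in seq_along(reviewers)) {
    verdict <- character(n)
    for (i in seq_len(n)) {
      if (is.na(truth$code[i])) {
        verdict[i] <- if (runif(1) < panel$p_correct) NO_CODE
                      else codes[sample.int(length(codes), 1L)]
      } else if (runif(1) < panel$p_nocode_error) {
        verdict[i] <- NO_CODE
      } else if (runif(1) < panel$p_correct) {
        verdict[i] <- truth$code[i]
      } else {
        p <- pool_of(truth$code[i])
        verdict[i] <- p[sample.int(length(p), 1L)]
      }
    }
    rows[[rv]] <- data.frame(phrase_id = truth$phrase_id,
                             reviewer_id = reviewers[rv], code = verdict,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write the bundled catalog fixture
#'
#' Copies the shipped 74-code catalog flat file to `path`; the output is
#' byte-stable across runs.
#'
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
build_catalog_fixture <- function(path) {
  writeLines(readLines(extdata("icd10_catalog_unanimous.tsv"),
                       encoding = "UTF-8"), path, useBytes = TRUE)
  invisible(path)
}

#' Generate a complete fixture bundle
#'
#' Writes, into `dir`: the catalog flat file (`catalog.tsv`), a JSON-lines
#' corpus (`corpus.jsonl`), the planted truth (`truth.csv`), and simulated
#' reviewer annotations (`annotations.csv`).
#'
#' @param dir Output directory (created if needed).
#' @param config A [corpus_config()].
#' @param panel A [reviewer_panel_config()].
#' @param catalog Catalog used for templates and confusion pools.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, config = corpus_config(),
                                 panel = reviewer_panel_config(),
                                 catalog = radcoder_catalog()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(catalog = file.path(dir, "catalog.tsv"),
             corpus = file.path(dir, "corpus.jsonl"),
             truth = file.path(dir, "truth.csv"),
             annotations = file.path(dir, "annotations.csv"))
  build_catalog_fixture(paths[["catalog"]])
  syn <- generate_reports(config, catalog = catalog)
  write_corpus_jsonl(syn$corpus, paths[["corpus"]])
  write.csv(syn$truth, paths[["truth"]], row.names = FALSE)
  ann <- simulate_reviewers(syn$truth, panel, catalog = catalog)
  ann_out <- ann
  ann_out$code[ann_out$code == NO_CODE] <- ""
  write.csv(ann_out, paths[["annotations"]], row.names = FALSE)
  invisible(paths)
}
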