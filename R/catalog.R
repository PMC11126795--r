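# ICD-10 catalog: flat-file parsing, description tokenization, word-class
# tagging, body-region tagging, and per-term document frequencies for the
# matcher.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "radcoder")
  if (!nzchar(path)) stop(sprintf("bundled data file '%s' not found", file))
  path
}

#' Bundled lexicons and study tables
#'
#' Accessors for the editable data files shipped with the package: the
#' anatomy/pathology word-class lexicon, the clinical synonym table, the
#' polarity trigger table, the keyword-to-body-region map, the exam-type
#' and patient-setting mixes of the reference 200-report corpus, the
#' reviewer-arm summary counts, and the three unanimity code lists (60
#' codes at length 3, 74 at length 4, 74 at length 7).
#'
#' @return `radcoder_lexicon()`, `radcoder_triggers()` and
#'   `radcoder_region_terms()` return data frames; `radcoder_synonyms()` a
#'   named character vector (from -> to); `radcoder_exam_mix()` and
#'   `radcoder_setting_mix()` data frames of mix weights;
#'   `radcoder_study_counts()` a named numeric vector;
#'   `radcoder_unanimity_codes(L)` a character vector of normalized codes.
#' @name bundled-data
NULL

#' @rdname bundled-data
#' @export
radcoder_lexicon <- function() {
  read.csv(extdata("lexicon.csv"), comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname bundled-data
#' @export
radcoder_synonyms <- function() {
  tab <- read.csv(extdata("synonyms.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
  setNames(tab$to, tab$from)
}

#' @rdname bundled-data
#' @export
radcoder_triggers <- function() {
  read.csv(extdata("triggers.csv"), comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname bundled-data
#' @export
radcoder_region_terms <- function() {
  read.csv(extdata("region_terms.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

#' @rdname bundled-data
#' @export
radcoder_exam_mix <- function() {
  read.delim(extdata("exam_mix.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

#' @rdname bundled-data
#' @export
radcoder_setting_mix <- function() {
  read.delim(extdata("setting_mix.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

#' @rdname bundled-data
#' @export
radcoder_study_counts <- function() {
  tab <- read.delim(extdata("study_counts.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  setNames(tab$value, tab$name)
}

#' @rdname bundled-data
#' @param L Comparison length of the unanimity list, one of 3, 4, 7.
#' @export
radcoder_unanimity_codes <- function(L) {
  L <- check_length_l(L)
  tab <- read.delim(extdata("unanimity_codes.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  icd10_normalize(tab$code[tab$length == L])
}

#' Load an ICD-10 catalog flat file
#'
#' Reads a UTF-8 tab-delimited catalog modeled on the CMS ICD-10-CM order
#' file: columns `code`, `billable`, `short_desc`, `long_desc`, one row per
#' code, `#` comment lines allowed. Codes are validated and normalized
#' (dot removed); long descriptions are tokenized (case-folded, characters
#' outside `[A-Za-z0-9]` deleted, single-character tokens dropped); each
#' entry is tagged with its anatomy and pathology terms from the word-class
#' lexicon and with body regions from the keyword map; and the per-term
#' document frequency over all entries is computed for the matcher's
#' inverse-document-frequency weighting.
#'
#' @param path Path to the catalog file.
#' @param lexicon Word-class lexicon data frame (`token`, `class`).
#' @param region_terms Keyword-to-region map data frame (`token`, `region`).
#' @return An object of class `icd10_catalog`: a list with `entries` (data
#'   frame with list columns `tokens`, `anatomy_terms`, `pathology_terms`,
#'   `body_regions`), `term_document_frequency` (named integer vector), and
#'   `entry_count`.
#' @export
load_catalog <- function(path, lexicon = radcoder_lexicon(),
                         region_terms = radcoder_region_terms()) {
  raw <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", raw))
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0L) {
    stop(sprintf("catalog line %d: expected 4 tab-delimited fields, found %d",
                 keep[bad[1L]], length(fields[[bad[1L]]])))
  }
  if (length(fields) == 0L) {
    return(structure(
      list(entries = empty_catalog_entries(),
           term_document_frequency = setNames(integer(0), character(0)),
           entry_count = 0L),
      class = "icd10_catalog"
    ))
  }
  mat <- do.call(rbind, fields)
  codes <- vapply(seq_len(nrow(mat)), function(i) {
    tryCatch(icd10_normalize(mat[i, 1L]),
             error = function(e) stop(sprintf("catalog line %d: %s",
                                              keep[i], conditionMessage(e))))
  }, character(1))
  dup <- codes[duplicated(codes)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate code in catalog: %s", icd10_display(dup[1L])))
  }
  anatomy <- lexicon$token[lexicon$class == "anatomy"]
  pathology <- lexicon$token[lexicon$class == "pathology"]
  tokens <- lapply(mat[, 4L], tokenize1, drop_short = TRUE)
  empty <- which(lengths(tokens) == 0L)
  if (length(empty) > 0L) {
    stop(sprintf("catalog line %d: description has no tokens", keep[empty[1L]]))
  }
  entries <- data.frame(
    code = codes,
    billable = as.integer(mat[, 2L]),
    short_desc = mat[, 3L],
    long_desc = mat[, 4L],
    stringsAsFactors = FALSE
  )
  entries$tokens <- I(lapply(tokens, unique))
  entries$anatomy_terms <- I(lapply(tokens, function(t) intersect(t, anatomy)))
  entries$pathology_terms <- I(lapply(tokens, function(t) intersect(t, pathology)))
  entries$body_regions <- I(lapply(tokens, function(t) {
    sort(unique(region_terms$region[region_terms$token %in% t]))
  }))
  tdf <- table(unlist(lapply(entries$tokens, unique)))
  structure(
    list(entries = entries,
         term_document_frequency = setNames(as.integer(tdf), names(tdf)),
         entry_count = nrow(entries)),
    class = "icd10_catalog"
  )
}

empty_catalog_entries <- function() {
  out <- data.frame(code = character(0), billable = integer(0),
                    short_desc = character(0), long_desc = character(0),
                    stringsAsFactors = FALSE)
  out$tokens <- I(list())
  out$anatomy_terms <- I(list())
  out$pathology_terms <- I(list())
  out$body_regions <- I(list())
  out
}

#' The bundled unanimity-code catalog
#'
#' Loads the catalog fixture shipped with the package: the 74 full-length
#' codes of the reference unanimity list with synthetic plain-English
#' descriptions (see the file header in
#' `system.file("extdata", "icd10_catalog_unanimous.tsv", package = "radcoder")`).
#'
#' @inheritParams load_catalog
#' @return An `icd10_catalog` object with 74 entries.
#' @export
radcoder_catalog <- function(lexicon = radcoder_lexicon(),
                             region_terms = radcoder_region_terms()) {
  load_catalog(extdata("icd10_catalog_unanimous.tsv"),
               lexicon = lexicon, region_terms = region_terms)
}

#' @export
print.icd10_catalog <- function(x, ...) {
  cat(sprintf("<icd10_catalog> %d entries, %d distinct description terms\n",
              x$entry_count, length(x$term_document_frequency)))
  invisible(x)
}
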