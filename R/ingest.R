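# Report ingestion: Impression extraction, line segmentation, phrase
# segmentation, and corpus-level ingestion with exam context.

impression_headings <- c("IMPRESSION", "IMPRESSIONS", "CONCLUSION",
                         "CONCLUSIONS", "OPINION")

#' Extract the Impression section from report text
#'
#' Finds the first Impression-style heading (`IMPRESSION`, `IMPRESSIONS`,
#' `CONCLUSION`, `CONCLUSIONS`, or `OPINION`, case-insensitively, followed
#' by a colon or a line break) and returns the text from there to the next
#' all-caps section heading or the end of the document.
#'
#' @param text Full report text (single string, newline separated).
#' @return The Impression section text (heading removed).
#' @section Errors: Signals a condition of class `radcoder_no_impression`
#'   when no recognized heading is present; batch ingestion catches this,
#'   logs a warning, and skips the report.
#' @export
extract_impression <- function(text) {
  stopifnot(length(text) == 1L, nzchar(text))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pat <- sprintf("^\\s*(%s)\\s*(:|$)", paste(impression_headings, collapse = "|"))
  hit <- which(grepl(pat, lines, ignore.case = TRUE))
  if (length(hit) == 0L) {
    stop(structure(
      class = c("radcoder_no_impression", "error", "condition"),
      list(message = "no impression section: no recognized heading found",
           call = sys.call())
    ))
  }
  i <- hit[1L]
  first <- sub(pat, "", lines[i], ignore.case = TRUE)
  rest <- if (i < length(lines)) lines[(i + 1L):length(lines)] else character(0)
  # stop at the next all-caps heading line (e.g. "ATTESTATION:"),
  # ignoring enumerated impression items that happen to be upper case
  is_heading <- grepl("^[A-Z][A-Z0-9 /&-]{2,}:?$", trimws(rest)) &
    !grepl("^\\s*(\\d+[.)]|[-*•])", rest)
  if (any(is_heading)) rest <- rest[seq_len(which(is_heading)[1L] - 1L)]
  out <- paste(c(first, rest), collapse = "\n")
  trimws(out)
}

#' Segment an Impression into lines
#'
#' Splits the Impression text into the bulleted or numbered elements of the
#' report ("Impression lines"): a new line starts at an enumerator pattern
#' (`1.`, `2)`, `-`, `*`, or a bullet glyph) at the start of a physical
#' line, or after a blank line. Enumerator glyphs are stripped;
#' continuation (wrapped) physical lines are joined to the current element.
#' Unenumerated text yields a single line.
#'
#' @param text Impression section text.
#' @return Data frame with columns `line_index` (1-based, contiguous) and
#'   `text`.
#' @export
segment_lines <- function(text) {
  stopifnot(length(text) == 1L)
  phys <- strsplit(text, "\n", fixed = TRUE)[[1]]
  enum <- "^\\s*(\\d+[.)]|[-*•])\\s+"
  out <- character(0)
  open <- FALSE
  for (ln in phys) {
    if (!nzchar(trimws(ln))) {
      open <- FALSE
      next
    }
    if (grepl(enum, ln)) {
      out <- c(out, trimws(sub(enum, "", ln)))
      open <- TRUE
    } else if (open) {
      out[length(out)] <- paste(out[length(out)], trimws(ln))
    } else {
      out <- c(out, trimws(ln))
      open <- TRUE
    }
  }
  out <- out[nzchar(out)]
  if (length(out) == 0L && nzchar(trimws(text))) out <- trimws(text)
  data.frame(line_index = seq_along(out), text = out, stringsAsFactors = FALSE)
}

# Does a text fragment contain at least one finding-bearing (pathology)
# noun after normalization?
has_finding <- function(text, pathology, synonyms) {
  any(normalize_phrase(text, synonyms) %in% pathology)
}

#' Segment an Impression line into atomic phrases
#'
#' Splits a line into phrases of distinct imaging findings: always at
#' semicolons and sentence boundaries; at commas and the conjunctions
#' "and" / "with" / "as well as" only when both sides contain at least one
#' finding-bearing noun (a pathology token of the word-class lexicon), so
#' that constructions like "mass with surrounding soft tissue" stay whole.
#' Leading conjunctions and trailing sentence punctuation are stripped from
#' each phrase. At least one phrase is always returned.
#'
#' @param text The line text.
#' @param lexicon Word-class lexicon (see [radcoder_lexicon()]).
#' @param synonyms Synonym table used during normalization.
#' @return Character vector of phrase texts, in order.
#' @export
segment_phrases <- function(text, lexicon = radcoder_lexicon(),
                            synonyms = radcoder_synonyms()) {
  stopifnot(length(text) == 1L, nzchar(trimws(text)))
  pathology <- lexicon$token[lexicon$class == "pathology"]
  # unconditional splits: semicolons and sentence boundaries
  pieces <- strsplit(text, "(;|(?<=[.!?])[[:space:]]+)", perl = TRUE)[[1]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  # gated splits: commas and conjunctions with findings on both sides
  out <- character(0)
  for (piece in pieces) {
    m <- gregexpr(",|\\b(and|with|as well as)\\b", piece, ignore.case = TRUE)[[1]]
    if (m[1L] == -1L) {
      out <- c(out, piece)
      next
    }
    starts <- as.integer(m)
    ends <- starts + attr(m, "match.length") - 1L
    seg_start <- 1L
    for (j in seq_along(starts)) {
      if (starts[j] < seg_start) next
      left <- substr(piece, seg_start, starts[j] - 1L)
      right <- substr(piece, ends[j] + 1L, nchar(piece))
      if (has_finding(left, pathology, synonyms) &&
          has_finding(right, pathology, synonyms)) {
        out <- c(out, left)
        seg_start <- ends[j] + 1L
      }
    }
    out <- c(out, substr(piece, seg_start, nchar(piece)))
  }
  out <- trimws(out)
  # strip leading conjunction residue ("and uncal herniation") and
  # trailing sentence punctuation
  out <- sub("^(and|with|as well as)\\b\\s*", "", out, ignore.case = TRUE)
  out <- sub("[.!?]+$", "", out)
  out <- trimws(out)
  out <- out[nzchar(out)]
  # degenerate input (e.g. punctuation only): the whole line is one phrase
  if (length(out) == 0L) out <- trimws(text)
  out
}

#' Ingest a single report into an Impression phrase table
#'
#' Runs Impression extraction, line segmentation, phrase segmentation,
#' normalization, and polarity classification for one report.
#'
#' @param report_id Report identifier.
#' @param text Full report text.
#' @param context Named list or one-row data frame with exam context
#'   (`modality`, `body_region`, `contrast`, `setting`); missing fields are
#'   stored as `NA`.
#' @param lexicon,synonyms,triggers Bundled-data overrides.
#' @return Data frame with one row per phrase: `report_id`, `phrase_id`,
#'   `line_index`, `phrase_index`, `raw_text`, `polarity`, exam context
#'   columns, and a list column `tokens`.
#' @export
ingest_report <- function(report_id, text, context = list(),
                          lexicon = radcoder_lexicon(),
                          synonyms = radcoder_synonyms(),
                          triggers = radcoder_triggers()) {
  imp <- extract_impression(text)
  lines <- segment_lines(imp)
  rows <- list()
  ctx <- function(f) if (!is.null(context[[f]]) && !is.na(context[[f]])) context[[f]] else NA_character_
  for (i in seq_len(nrow(lines))) {
    phr <- segment_phrases(lines$text[i], lexicon = lexicon, synonyms = synonyms)
    for (j in seq_along(phr)) {
      toks <- normalize_phrase(phr[j], synonyms = synonyms)
      rows[[length(rows) + 1L]] <- data.frame(
        report_id = report_id,
        phrase_id = sprintf("%s-L%d-P%d", report_id, lines$line_index[i], j),
        line_index = lines$line_index[i],
        phrase_index = j,
        raw_text = phr[j],
        polarity = classify_polarity(toks, triggers = triggers, lexicon = lexicon),
        modality = ctx("modality"),
        body_region = ctx("body_region"),
        contrast = ctx("contrast"),
        setting = ctx("setting"),
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$tokens <- I(list(toks))
    }
  }
  do.call(rbind, rows)
}

#' Ingest a corpus of reports
#'
#' Applies [ingest_report()] to every row of a corpus data frame. Reports
#' without a recognizable Impression section are skipped with a warning
#' naming the report.
#'
#' @param corpus Data frame with columns `report_id`, `text`, and
#'   optionally `modality`, `body_region`, `contrast`, `setting`.
#' @inheritParams ingest_report
#' @return Combined phrase table (see [ingest_report()]).
#' @export
ingest_corpus <- function(corpus, lexicon = radcoder_lexicon(),
                          synonyms = radcoder_synonyms(),
                          triggers = radcoder_triggers()) {
  stopifnot(is.data.frame(corpus), all(c("report_id", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$report_id)) stop("duplicate report_id in corpus")
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    tryCatch(
      ingest_report(corpus$report_id[i], corpus$text[i],
                    context = as.list(corpus[i, , drop = FALSE]),
                    lexicon = lexicon, synonyms = synonyms, triggers = triggers),
      radcoder_no_impression = function(e) {
        warning(sprintf("report %s skipped: %s", corpus$report_id[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) stop("no report in the corpus had an impression section")
  do.call(rbind, out)
}

#' Read and write JSON-lines corpora
#'
#' A corpus file holds one JSON object per line with fields `report_id`,
#' `text`, `modality`, `body_region`, `contrast`, `setting`.
#'
#' @param path File path.
#' @return `read_corpus_jsonl()` returns the corpus data frame.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname read_corpus_jsonl
#' @param corpus Corpus data frame to write.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(as.list(corpus[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
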