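# Small in-code fixtures shared across test files. The bundled 74-entry
# catalog is loaded once per test run; a tiny hand-checkable catalog is
# built from literal rows.

shared_catalog <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- radcoder_catalog()
    cached
  }
})

write_catalog_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# test catalog", rows), path)
  path
}

tiny_catalog <- function() {
  load_catalog(write_catalog_file(c(
    "I60.9\t1\tSAH\tNontraumatic subarachnoid hemorrhage",
    "I67.1\t1\tCerebral aneurysm\tCerebral aneurysm nonruptured",
    "I72.6\t1\tVertebral aneurysm\tAneurysm of vertebral artery",
    "R22.0\t1\tMass head\tLocalized swelling mass and lump of head",
    "G93.6\t1\tCerebral edema\tCerebral edema",
    "N20.0\t1\tKidney stone\tCalculus of kidney"
  )))
}

# minimal one-report corpus
tiny_corpus <- function(text, report_id = "T1", body_region = "head") {
  data.frame(report_id = report_id, text = text, modality = "CT",
             body_region = body_region, contrast = "without",
             setting = "emergency", stringsAsFactors = FALSE)
}

# annotations where every reviewer gives the verdicts in `codes` (a list
# of per-reviewer vectors, or one vector recycled for all reviewers)
make_annotations <- function(codes, n_reviewers = NULL) {
  if (!is.list(codes)) {
    stopifnot(!is.null(n_reviewers))
    codes <- rep(list(codes), n_reviewers)
  }
  n <- length(codes[[1L]])
  do.call(rbind, lapply(seq_along(codes), function(r) {
    data.frame(phrase_id = sprintf("p%03d", seq_len(n)),
               reviewer_id = sprintf("R%d", r), code = codes[[r]],
               stringsAsFactors = FALSE)
  }))
}

# synthetic match table: one phrase per row of `truth`, with candidate
# codes/scores planted directly (bypasses the text pipeline; used to test
# evaluation logic in isolation)
make_matches <- function(phrase_id, candidates) {
  do.call(rbind, lapply(seq_along(phrase_id), function(i) {
    cand <- candidates[[i]]
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    data.frame(report_id = "S", phrase_id = phrase_id[i],
               line_index = 1L, phrase_index = 1L,
               rank = seq_len(nrow(cand)), code = cand$code,
               score = cand$score, polarity = "positive", raw_text = "",
               stringsAsFactors = FALSE)
  }))
}
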