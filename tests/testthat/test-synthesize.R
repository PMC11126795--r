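test_that("the catalog fixture is byte-stable with 74 rows", {
  p1 <- tempfile(); p2 <- tempfile()
  build_catalog_fixture(p1)
  build_catalog_fixture(p2)
  expect_identical(readLines(p1), readLines(p2))
  rows <- readLines(p1)
  rows <- rows[!grepl("^#", rows)]
  expect_length(rows, 74)
  expect_equal(load_catalog(p1)$entry_count, 74)
})

test_that("generation is fully determined by the seed", {
  a <- generate_reports(corpus_config(n_reports = 15, seed = 20))
  b <- generate_reports(corpus_config(n_reports = 15, seed = 20))
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth, b$truth)
  c_ <- generate_reports(corpus_config(n_reports = 15, seed = 21))
  expect_false(identical(a$corpus$text, c_$corpus$text))
})

test_that("the default corpus reproduces the study's shape", {
  syn <- generate_reports(corpus_config(seed = 29))
  n_phr <- nrow(syn$truth)
  expect_equal(nrow(syn$corpus), 200)
  expect_gte(n_phr, 580); expect_lte(n_phr, 710)
  mean_ppr <- n_phr / 200
  expect_gte(mean_ppr, 2.9); expect_lte(mean_ppr, 3.5)
  # noncodable phrases occur at roughly the configured 4.8 % rate
  frac_nc <- mean(syn$truth$polarity == "noncodable")
  expect_gt(frac_nc, 0.02); expect_lt(frac_nc, 0.09)
  # exam contexts come from the closed vocabularies
  expect_true(all(syn$corpus$modality %in% c("CT", "CTA", "MR", "MRA")))
  expect_true(all(syn$corpus$setting %in%
                    c("emergency", "inpatient", "outpatient")))
})

test_that("mix proportions are respected at scale", {
  syn <- generate_reports(corpus_config(n_reports = 400, seed = 17))
  # CT Head w/o Contrast carries 73/200 of the weight
  frac <- mean(syn$corpus$exam_type == "CT Head w/o Contrast")
  expect_gt(frac, 0.28); expect_lt(frac, 0.45)
  frac_head <- mean(syn$corpus$body_region == "head")
  expect_gt(frac_head, 0.5)  # 124/200 of the weight is head imaging
})

test_that("zero rates switch the corresponding phrase classes off", {
  syn <- generate_reports(corpus_config(n_reports = 40, seed = 9,
                                        noncodable_rate = 0))
  expect_equal(sum(syn$truth$polarity == "noncodable"), 0)
  syn2 <- generate_reports(corpus_config(n_reports = 40, seed = 9,
                                         noncodable_rate = 0,
                                         negative_rate = 0))
  expect_setequal(unique(syn2$truth$polarity), "positive")
})

test_that("planted truth is conserved through ingestion", {
  syn <- generate_reports(corpus_config(n_reports = 50, seed = 41))
  phrases <- ingest_corpus(syn$corpus)
  expect_setequal(phrases$phrase_id, syn$truth$phrase_id)
  merged <- merge(phrases[, c("phrase_id", "raw_text")],
                  syn$truth[, c("phrase_id", "planted_text")],
                  by = "phrase_id")
  expect_equal(merged$raw_text, merged$planted_text)
})

test_that("a perfect panel reproduces the planted codes exactly", {
  syn <- generate_reports(corpus_config(n_reports = 40, seed = 13))
  ann <- simulate_reviewers(syn$truth,
                            reviewer_panel_config(p_correct = 1,
                                                  p_nocode_error = 0,
                                                  seed = 1))
  gt <- derive_ground_truth(ann, 7)
  planted <- syn$truth[match(gt$phrase_id, syn$truth$phrase_id), ]
  is_code <- !is.na(planted$code)
  expect_true(all(gt$status[is_code] == "unanimous"))
  expect_equal(gt$code[is_code], planted$code[is_code])
  expect_true(all(gt$status[!is_code] == "unanimous_no_code"))
})

test_that("unanimity occurs at the closed-form rate p_correct^4", {
  truth <- data.frame(
    phrase_id = sprintf("p%04d", 1:600),
    code = sample(shared_catalog()$entries$code, 600, replace = TRUE),
    polarity = "positive", stringsAsFactors = FALSE
  )
  ann <- simulate_reviewers(truth,
                            reviewer_panel_config(p_correct = 0.8,
                                                  p_nocode_error = 0,
                                                  seed = 51))
  gt <- derive_ground_truth(ann, 7)
  rate <- mean(gt$status != "not_unanimous")
  expected <- 0.8^4
  ci <- 1.96 * sqrt(expected * (1 - expected) / 600)
  expect_lt(abs(rate - expected), ci)
})

test_that("pure-distractor panels drive alpha to chance level", {
  codes <- shared_catalog()$entries$code
  set.seed(19)
  truth <- data.frame(phrase_id = sprintf("p%03d", 1:120),
                      code = sample(codes, 120, replace = TRUE),
                      polarity = "positive", stringsAsFactors = FALSE)
  # wide (near-disjoint) confusion pools: every other catalog code
  pools <- setNames(lapply(codes, function(cd) setdiff(codes, cd)), codes)
  ann <- simulate_reviewers(truth,
                            reviewer_panel_config(p_correct = 0,
                                                  p_nocode_error = 0,
                                                  confusion_pool = pools,
                                                  seed = 3))
  a <- krippendorff_alpha(ann, 7)
  expect_lt(a, 0.1)
  # the default same-category pools keep structure: alpha is higher at
  # the category level than full length under partial agreement
  ann2 <- simulate_reviewers(truth,
                             reviewer_panel_config(p_correct = 0.6,
                                                   p_nocode_error = 0,
                                                   seed = 5))
  expect_gt(krippendorff_alpha(ann2, 3), krippendorff_alpha(ann2, 7))
})

test_that("missing confusion pools are reported", {
  truth <- data.frame(phrase_id = "p1", code = "I639",
                      polarity = "positive", stringsAsFactors = FALSE)
  panel <- reviewer_panel_config(p_correct = 0, confusion_pool = list(),
                                 seed = 2)
  expect_error(simulate_reviewers(truth, panel), "confusion pool")
})

test_that("the fixture bundle round-trips through the file formats", {
  dir <- file.path(tempdir(), "bundle-test")
  paths <- write_fixture_bundle(dir,
                                config = corpus_config(n_reports = 10, seed = 6),
                                panel = reviewer_panel_config(seed = 7))
  expect_true(all(file.exists(paths)))
  corpus <- read_corpus_jsonl(paths[["corpus"]])
  expect_equal(nrow(corpus), 10)
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(length(unique(ann$reviewer_id)), 4)
  truth <- read.csv(paths[["truth"]])
  expect_setequal(unique(ann$phrase_id), truth$phrase_id)
})
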