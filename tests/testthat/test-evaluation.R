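test_that("unanimity ground truth distinguishes its three statuses", {
  ann <- make_annotations(list(
    c("I639", "I639", NO_CODE, "I6351"),
    c("I639", "I638", NO_CODE, "I6352"),
    c("I639", "I639", NO_CODE, "I6351"),
    c("I639", "I639", NO_CODE, "G935")
  ))
  gt7 <- derive_ground_truth(ann, 7)
  expect_equal(gt7$status[gt7$phrase_id == "p001"], "unanimous")
  expect_equal(gt7$code[gt7$phrase_id == "p001"], "I639")
  expect_equal(gt7$status[gt7$phrase_id == "p002"], "not_unanimous")
  expect_equal(gt7$status[gt7$phrase_id == "p003"], "unanimous_no_code")
  expect_equal(gt7$status[gt7$phrase_id == "p004"], "not_unanimous")
  # truncation can create unanimity: all verdicts of p002 share category
  gt3 <- derive_ground_truth(ann, 3)
  expect_equal(gt3$status[gt3$phrase_id == "p002"], "unanimous")
  expect_equal(gt3$code[gt3$phrase_id == "p002"], "I63")
})

test_that("the threshold is the mean of the matched TP scores", {
  ann <- make_annotations(c("I639", "G935", "R220"), n_reviewers = 4)
  truth <- derive_ground_truth(ann, 7)
  matches <- make_matches(
    c("p001", "p002", "p003"),
    list(data.frame(code = c("I639", "I609"), score = c(6, 2)),
         data.frame(code = c("G935", "G936"), score = c(8, 1)),
         data.frame(code = "R220", score = 10))
  )
  expect_equal(compute_threshold(matches, truth, 7, 5), 8)
  # single TP: the threshold is that score
  expect_equal(compute_threshold(matches[matches$phrase_id == "p003", ],
                                 truth[truth$phrase_id == "p003", ], 7, 1),
               10)
  # no TPs anywhere -> dedicated condition
  empty <- make_matches("p001", list(data.frame(code = "Z982", score = 1)))
  expect_error(compute_threshold(empty, truth, 7, 5),
               class = "radcoder_threshold_undefined")
})

test_that("confusion classification follows the rank/threshold rules", {
  ann <- make_annotations(list(
    c("I639", "G935", "I609", NO_CODE),
    c("I639", "G936", "I609", NO_CODE),
    c("I639", "G935", "I609", NO_CODE),
    c("I639", "G935", "I609", NO_CODE)
  ))
  truth <- derive_ground_truth(ann, 3)
  matches <- make_matches(
    c("p001", "p002", "p003", "p004"),
    list(
      # unanimous I63 sits at rank 4: TP at k=5, FN at k=1
      data.frame(code = c("R220", "G935", "I609", "I639"),
                 score = c(9, 8, 7, 6)),
      # not unanimous at 7L (G935 vs G936) but unanimous at 3L
      data.frame(code = "G935", score = 5),
      # unanimous I60 at rank 1
      data.frame(code = "I609", score = 12),
      # unanimous no-code, with a high-scoring candidate
      data.frame(code = "R220", score = 11)
    )
  )
  th <- compute_threshold(matches, truth, 3, 5)
  expect_equal(th, mean(c(6, 5, 12)))
  cc <- classify_confusion(matches, truth, 3, 5, th)
  # p001, p002, p003 are unanimous-code TPs; p004 scores above threshold
  expect_equal(cc$TP, 3)
  expect_equal(cc$FP, 1)
  expect_equal(cc$TN, 0)
  expect_equal(cc$FN, 0)
  cc1 <- classify_confusion(matches, truth, 3, 1, compute_threshold(matches, truth, 3, 1))
  expect_equal(cc1$FN, 1)  # I63 outside top-1 of p001
  # excluding unanimous no-code phrases removes p004 entirely
  cc_ex <- classify_confusion(matches, truth, 3, 5, th,
                              nocode_mode = "exclude")
  expect_equal(cc_ex$FP + cc_ex$TN, 0)
  expect_equal(cc_ex$TP + cc_ex$FP + cc_ex$TN + cc_ex$FN, 3)
})

test_that("TN requires every top-k score below the threshold", {
  ann <- make_annotations(list(c("I639", "G935"), c("I639", "G936"),
                               c("I639", "G935"), c("I639", "G938")))
  truth <- derive_ground_truth(ann, 7)
  matches <- make_matches(
    c("p001", "p002"),
    list(data.frame(code = "I639", score = 10),
         data.frame(code = c("G935", "G936"), score = c(9, 2)))
  )
  th <- compute_threshold(matches, truth, 7, 5)  # 10
  cc <- classify_confusion(matches, truth, 7, 5, th)
  expect_equal(cc$TN, 1)  # 9 and 2 both below 10
  cc2 <- classify_confusion(matches, truth, 7, 5, 9)
  expect_equal(cc2$FP, 1)  # at/above threshold counts as FP
})

test_that("metrics implement sensitivity, specificity, and F2", {
  cc <- list(TP = 8, FP = 8, TN = 2, FN = 2)
  m <- confusion_metrics(cc)
  # precision = recall = 0.8 -> F2 = 0.8 (harmonic-mean identity)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 0.5)
  expect_equal(m$f2, 5 * 0.5 * 0.8 / (4 * 0.5 + 0.8))
  m2 <- confusion_metrics(list(TP = 5, FP = 5, TN = 0, FN = 0))
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$f2, 5 * 0.5 / (4 * 0.5 + 1))  # 0.8333...
  m3 <- suppressWarnings(confusion_metrics(list(TP = 0, FP = 0, TN = 3, FN = 4)))
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$f2, 0)
  # equal precision and recall collapse F2 to their common value
  for (r in c(0.25, 0.5, 0.75)) {
    p <- r
    expect_equal(5 * p * r / (4 * p + r), r)
  }
})

test_that("F2 equals its brute-force evaluation on random count triples", {
  set.seed(1234)
  for (trial in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    m <- suppressWarnings(confusion_metrics(list(TP = tp, FP = fp,
                                                 TN = 0, FN = fn)))
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    f2 <- if (p + r == 0) 0 else (1 + 4) * p * r / (4 * p + r)
    expect_equal(m$f2, f2)
  }
})

test_that("a perfect engine scores sensitivity 1 everywhere, a blind one 0", {
  ann <- make_annotations(c("I639", "G935", "R220", "I609"),
                          n_reviewers = 4)
  ids <- sprintf("p%03d", 1:4)
  perfect <- make_matches(ids, lapply(c("I639", "G935", "R220", "I609"),
                                      function(cd) data.frame(code = cd, score = 5)))
  grid <- evaluate_grid(perfect, ann)
  expect_true(all(grid$sensitivity[grid$available] == 1))
  blind <- make_matches(ids, rep(list(data.frame(code = "Z982", score = 5)), 4))
  grid0 <- evaluate_grid(blind, ann)
  # no TPs at all: thresholds undefined, all cells unavailable
  expect_true(all(!grid0$available))
})

test_that("grid invariants hold on simulated evaluations", {
  set.seed(555)
  codes <- shared_catalog()$entries$code
  for (trial in 1:100) {
    n <- 40
    planted <- sample(codes, n, replace = TRUE)
    ids <- sprintf("p%03d", seq_len(n))
    ann <- make_annotations(lapply(1:4, function(r) {
      ifelse(runif(n) < 0.8, planted, sample(codes, n, replace = TRUE))
    }))
    cand <- lapply(seq_len(n), function(i) {
      k <- sample(3:8, 1)
      pool <- unique(c(if (runif(1) < 0.7) planted[i], sample(codes, k)))
      data.frame(code = pool, score = round(sort(runif(length(pool), 0, 10),
                                                 decreasing = TRUE), 3))
    })
    matches <- make_matches(ids, cand)
    grid <- evaluate_grid(matches, ann, lengths = c(3, 7), ranks = c(1, 5, 20))
    for (L in c(3, 7)) {
      sub <- grid[grid$length == L & grid$available, ]
      if (nrow(sub) < 2) next
      # sensitivity monotone non-decreasing in k (nested candidate sets)
      expect_true(all(diff(sub$sensitivity) >= -1e-12))
      # TP+FN invariant across k; counts partition the evaluated phrases
      expect_equal(length(unique(sub$TP + sub$FN)), 1)
      expect_equal(unique(sub$TP + sub$FP + sub$TN + sub$FN), n)
      # for a fixed threshold, TN shrinks and FP grows with k
      truth <- derive_ground_truth(ann, L)
      th <- sub$threshold[1]
      cs <- lapply(c(1, 5, 20), function(k) {
        classify_confusion(matches, truth, L, k, th)
      })
      expect_true(all(diff(vapply(cs, `[[`, numeric(1), "TN")) <= 0))
      expect_true(all(diff(vapply(cs, `[[`, numeric(1), "FP")) >= 0))
    }
  }
})

test_that("proportion comparison matches a longhand chi-square", {
  a <- list(TP = 44, FP = 6, TN = 44, FN = 6)   # 88/100 correct
  b <- list(TP = 41, FP = 9, TN = 41, FN = 9)   # 82/100 correct
  p_pkg <- compare_proportions(a, b)
  # independent longhand: 2x2 chi-square with Yates continuity correction
  x <- c(88, 82); n <- c(100, 100)
  tab <- rbind(x, n - x)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((abs(tab - E) - 0.5)^2 / E)
  p_hand <- 1 - pchisq(chi, df = 1)
  expect_equal(p_pkg, p_hand, tolerance = 1e-12)
  # identical counts agree perfectly
  expect_equal(compare_proportions(a, a), 1)
  # degenerate separation: p shrinks with n
  sep <- function(n) {
    compare_proportions(list(TP = n, FP = 0, TN = 0, FN = 0),
                        list(TP = 0, FP = n, TN = 0, FN = 0))
  }
  expect_true(sep(40) < sep(20) && sep(20) < sep(10))
  expect_error(compare_proportions(a, list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "zero")
})

test_that("planted top-k inclusion probability is recovered as sensitivity", {
  set.seed(777)
  n <- 500
  p_inc <- 0.85
  ids <- sprintf("p%03d", seq_len(n))
  ann <- make_annotations(rep("I639", n), n_reviewers = 4)
  ann$phrase_id <- rep(ids, 4)
  included <- runif(n) < p_inc
  cand <- lapply(seq_len(n), function(i) {
    if (included[i]) data.frame(code = c("I639", "G935"), score = c(7, 3))
    else data.frame(code = "G935", score = 7)
  })
  matches <- make_matches(ids, cand)
  truth <- derive_ground_truth(ann, 3)
  th <- compute_threshold(matches, truth, 3, 5)
  cc <- classify_confusion(matches, truth, 3, 5, th)
  # all phrases are unanimous positives here, so specificity is 0/0
  sens <- suppressWarnings(confusion_metrics(cc))$sensitivity
  se <- sqrt(p_inc * (1 - p_inc) / n)
  expect_lt(abs(sens - p_inc), 3 * se)
})
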