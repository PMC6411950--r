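# Performance measures: confusion counts, Ac/Sn/Sp/MCC, ROC/AUC, AUC01,
# thresholds and the CV harnesses.

test_that("confusion counts follow the strict-greater call rule", {
  cnt <- confusion_at_threshold(c(0.9, 0.6, 0.4, 0.1),
                                c("positive", "negative", "positive",
                                  "negative"), 0.5)
  expect_equal(cnt, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  # a score exactly at the threshold is a negative call
  cnt2 <- confusion_at_threshold(c(0.5, 0.5), c("positive", "negative"), 0.5)
  expect_equal(cnt2$FN, 1L)
  expect_equal(cnt2$TN, 1L)
  cnt3 <- confusion_at_threshold(c(0.8, 0.9), c("positive", "positive"), 0.5)
  expect_equal(cnt3$FN + cnt3$FP, 0L)
  expect_error(confusion_at_threshold(numeric(0), character(0), 0.5))
})

test_that("Ac/Sn/Sp/MCC match the closed-form definitions", {
  m <- suppressMessages(metrics(list(TP = 25L, FP = 25L, TN = 25L, FN = 25L)))
  expect_equal(unname(m), c(0.5, 0.5, 0.5, 0))
  perfect <- metrics(list(TP = 10L, FP = 0L, TN = 10L, FN = 0L))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  hand <- metrics(list(TP = 3L, FP = 1L, TN = 5L, FN = 1L))
  expect_equal(unname(hand["MCC"]), 14 / 24)
  expect_equal(unname(hand["Ac"]), 8 / 10)
  expect_equal(unname(hand["Sn"]), 3 / 4)
  expect_equal(unname(hand["Sp"]), 5 / 6)
  # zero-denominator convention
  expect_message(z <- metrics(list(TP = 0L, FP = 0L, TN = 5L, FN = 5L)),
                 "undefined")
  expect_equal(unname(z["MCC"]), 0)
})

test_that("MCC flips sign when predictions are inverted", {
  cnt <- list(TP = 7L, FP = 2L, TN = 8L, FN = 3L)
  inv <- list(TP = cnt$FN, FP = cnt$TN, TN = cnt$FP, FN = cnt$TP)
  expect_equal(metrics(cnt)["MCC"], -metrics(inv)["MCC"],
               ignore_attr = TRUE)
})

test_that("sweep AUC equals the exhaustive pairwise rank statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("positive", "positive", "negative", "negative"))$auc,
               1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("positive", "negative"), 5))$auc,
               0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6),
                       c("positive", "negative", "positive",
                         "negative"))$auc, 0.75)
  set.seed(77)
  for (i in 1:25) {
    n <- sample(10:120, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc,
                 pairwise_auc_oracle(scores, labels))
  }
  expect_error(roc_auc(1:4 / 4, rep("positive", 4)), "both classes")
})

test_that("sweep AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- runif(200)
  labels <- runif(200) < 0.3
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("ROC invariants hold", {
  set.seed(8)
  ra <- roc_auc(runif(50), runif(50) < 0.5)
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[1], 0)
  expect_equal(utils::tail(ra$roc$fpr, 1), 1)
  expect_equal(utils::tail(ra$roc$tpr, 1), 1)
  expect_true(all(diff(ra$roc$fpr) >= 0))
})

test_that("AUC01 integrates the low-FPR region by trapezoids", {
  perfect <- data.frame(threshold = c(Inf, 1, 0),
                        fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  expect_equal(auc01(perfect), 0.1)
  diagonal <- data.frame(threshold = c(Inf, 0), fpr = c(0, 1), tpr = c(0, 1))
  expect_equal(auc01(diagonal), 0.005)
  piecewise <- data.frame(threshold = c(Inf, 0.8, 0.5, 0),
                          fpr = c(0, 0.05, 0.1, 1),
                          tpr = c(0, 0.6, 0.8, 1))
  expect_equal(auc01(piecewise), 0.05)   # 0.05*0.3 + 0.05*0.7, by hand
  expect_equal(auc01(piecewise, normalized = TRUE), 0.5)
})

test_that("AUC01 never exceeds AUC nor 0.1", {
  set.seed(19)
  for (i in 1:10) {
    scores <- runif(80)
    labels <- runif(80) < 0.5
    if (!any(labels) || all(labels)) next
    ra <- roc_auc(scores, labels)
    a01 <- auc01(ra$roc)
    expect_lte(a01, ra$auc)
    expect_lte(a01, 0.1)
    expect_gte(a01, 0)
  }
})

test_that("threshold_at_specificity returns the smallest adequate threshold", {
  scores <- c(seq(0.1, 1.0, by = 0.1), 0.95, 0.99)
  labels <- c(rep("negative", 10), "positive", "positive")
  thr <- threshold_at_specificity(scores, labels, target_sp = 0.9)
  expect_equal(thr, 0.9)                 # exactly one negative above
  cnt <- confusion_at_threshold(scores, labels, thr)
  expect_gte(cnt$TN / (cnt$TN + cnt$FP), 0.9)
  expect_equal(threshold_at_specificity(scores, labels, 1.0), 1.0)
  # the largest negative score always reaches specificity 1 under the
  # strict-greater call rule
  thr2 <- threshold_at_specificity(c(0.5, 0.5, 0.6), c(FALSE, FALSE, TRUE),
                                   target_sp = 0.999)
  expect_equal(thr2, 0.5)
})

test_that("metrics are invariant under reordering of the windows", {
  set.seed(31)
  scores <- runif(60); labels <- runif(60) < 0.4
  perm <- sample(60)
  r1 <- evaluate_predictions(scores, labels, threshold = 0.5)
  r2 <- evaluate_predictions(scores[perm], labels[perm], threshold = 0.5)
  expect_equal(r1$metrics, r2$metrics)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$auc01, r2$auc01)
})

test_that("evaluation reports round-trip to disk", {
  set.seed(2)
  rep <- evaluate_predictions(runif(50), runif(50) < 0.5, threshold = 0.5)
  prefix <- file.path(withr::local_tempdir(), "eval")
  write_eval_report(rep, prefix)
  summ <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(summ$auc, rep$auc)
  roc <- utils::read.table(paste0(prefix, "_roc.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(roc), nrow(rep$roc))
})

test_that("learning curve is protein-grouped, seeded and fraction-sized", {
  set.seed(6)
  win <- toy_window_df(n_proteins = 16L, windows_per_protein = 6L)
  method <- list(
    train = function(tr) train_forest(encode_aac(tr$window), tr$label,
                                      n_trees = 30L, seed = 1L),
    predict = function(m, te) predict_scores(m, encode_aac(te$window)))
  lc <- learning_curve(win, list(rf = method), fractions = c(0.5, 1),
                       k = 3L, seed = 9L)
  expect_equal(nrow(lc), 2L)
  expect_equal(lc$n_windows[lc$fraction == 1], nrow(win))
  expect_equal(lc$n_windows[lc$fraction == 0.5], 8L * 6L)
  lc2 <- learning_curve(win, list(rf = method), fractions = c(0.5, 1),
                        k = 3L, seed = 9L)
  expect_identical(lc, lc2)              # fixed seed -> identical table
  expect_error(learning_curve(win, list(rf = method), fractions = 0.1,
                              k = 3L, seed = 1L), "fewer proteins")
})

test_that("window-size comparison rebuilds windows per size", {
  set.seed(41)
  proteins <- stats::setNames(vapply(1:12, function(i) random_protein(70),
                                     character(1)), sprintf("P%02d", 1:12))
  sites <- do.call(rbind, lapply(names(proteins), function(id) {
    kpos <- which(strsplit(proteins[[id]], "")[[1]] == "K")
    if (length(kpos) == 0) return(NULL)
    data.frame(protein_id = id, position = kpos,
               label = sample(c("positive", "negative"), length(kpos), TRUE),
               andromeda_score = NA_real_, localization_prob = NA_real_)
  }))
  method <- list(
    train = function(tr) train_forest(encode_aac(tr$window), tr$label,
                                      n_trees = 20L, seed = 1L),
    predict = function(m, te) predict_scores(m, encode_aac(te$window)))
  res <- compare_window_sizes(proteins, sites, method, sizes = c(15L, 19L),
                              k = 3L, seed = 4L)
  expect_equal(res$size, c(15L, 19L))
  expect_true(all(is.finite(res$auc)))
  res2 <- compare_window_sizes(proteins, sites, method, sizes = c(15L, 19L),
                               k = 3L, seed = 4L)
  expect_identical(res, res2)
  expect_error(compare_window_sizes(proteins, sites, method, sizes = 16L),
               "odd")
})
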