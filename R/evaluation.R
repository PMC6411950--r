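## Performance assessment: confusion counts, Ac/Sn/Sp/MCC, ROC, AUC and the
## partial AUC restricted to false-positive rate < 0.1 (AUC01), plus the
## cross-validation / learning-curve harnesses.

#' Coerce labels to logical (TRUE = positive)
#'
#' Accepts logical, 0/1 numeric, or character/factor "positive"/"negative".
#' @param labels Label vector.
#' @return Logical vector.
#' @export
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  l <- tolower(as.character(labels))
  if (!all(l %in% c("positive", "negative")))
    stop("labels must be logical, 0/1, or 'positive'/'negative'")
  l == "positive"
}

#' Confusion counts at a score threshold (strict-greater call rule)
#'
#' A window is called positive iff its score is strictly greater than the
#' threshold; a score exactly equal to the threshold is a negative call.
#'
#' @param scores Numeric prediction scores.
#' @param labels True labels (see [as_binary_labels()]).
#' @param threshold Decision threshold.
#' @return Named list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (length(scores) == 0L) stop("no scores to threshold")
  stopifnot(length(scores) == length(labels))
  y <- as_binary_labels(labels)
  call_pos <- scores > threshold
  list(TP = sum(call_pos & y), FP = sum(call_pos & !y),
       TN = sum(!call_pos & !y), FN = sum(!call_pos & y))
}

#' Accuracy, sensitivity, specificity and Matthews correlation coefficient
#'
#' Ac = (TP+TN)/(TP+FN+TN+FP), Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FN)(TN+FP)).
#' When any MCC denominator factor is zero the MCC is reported as 0 (the
#' undefined case), with a message.
#'
#' @param counts List with TP, FP, TN, FN as from [confusion_at_threshold()].
#' @return Named numeric vector `Ac`, `Sn`, `Sp`, `MCC`.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  ac <- (TP + TN) / (TP + FN + TN + FP)
  sn <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FN) * (TN + FP)
  if (denom == 0) {
    message("MCC undefined (zero denominator factor); reporting 0")
    mcc <- 0
  } else {
    mcc <- (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  }
  c(Ac = ac, Sn = sn, Sp = sp, MCC = mcc)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct scores (tied scores grouped
#' into single steps) and integrates the curve by trapezoids, which equals the
#' rank statistic P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @inheritParams confusion_at_threshold
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (!any(y) || all(y))
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  ## group ties: step only after the last instance of each distinct score
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(yy)[last]
  fp <- cumsum(!yy)[last]
  P <- sum(y); N <- sum(!y)
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Partial AUC at false-positive rate below 0.1
#'
#' Unnormalised trapezoid area of the ROC over FPR in [0, 0.1], with linear
#' interpolation of the curve at FPR = 0.1; the maximum attainable value is
#' 0.1.  Set `normalized = TRUE` to divide by 0.1.
#'
#' @param roc ROC data.frame from [roc_auc()].
#' @param max_fpr Upper FPR bound (default 0.1).
#' @param normalized Report area / max_fpr instead (default FALSE).
#' @return Partial area (in [0, max_fpr] when unnormalised).
#' @export
auc01 <- function(roc, max_fpr = 0.1, normalized = FALSE) {
  stopifnot(is.data.frame(roc), all(diff(roc$fpr) >= 0))
  x <- roc$fpr; yv <- roc$tpr
  if (max(x) < max_fpr) stop("ROC does not reach FPR = ", max_fpr)
  ## interpolate the curve at max_fpr, then clip
  keep <- x <= max_fpr
  xs <- x[keep]; ys <- yv[keep]
  if (max(xs) < max_fpr) {
    i <- which(x > max_fpr)[1]
    x0 <- x[i - 1L]; x1 <- x[i]
    yi <- if (x1 == x0) yv[i] else
      yv[i - 1L] + (yv[i] - yv[i - 1L]) * (max_fpr - x0) / (x1 - x0)
    xs <- c(xs, max_fpr); ys <- c(ys, yi)
  }
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  if (normalized) area / max_fpr else area
}

#' Smallest threshold reaching a target specificity
#'
#' Returns the smallest threshold t such that Sp >= target_sp under the
#' strict-greater call rule (negatives with score exactly t are correct
#' rejections).  If the target is unattainable the maximum observed score is
#' returned with a warning.
#'
#' @inheritParams confusion_at_threshold
#' @param target_sp Target specificity (default 0.90).
#' @return Threshold value.
#' @export
threshold_at_specificity <- function(scores, labels, target_sp = 0.90) {
  y <- as_binary_labels(labels)
  if (!any(!y)) stop("negatives required to compute specificity")
  neg <- sort(scores[!y])
  n <- length(neg)
  ## at threshold neg[i], negatives <= neg[i] are correct rejections
  sp <- vapply(seq_len(n), function(i) sum(neg <= neg[i]) / n, numeric(1))
  ok <- which(sp >= target_sp)
  if (length(ok) == 0L) {
    warning("target specificity ", target_sp, " unattainable; returning max score")
    return(max(scores))
  }
  neg[min(ok)]
}

#' Full evaluation report for a set of scored windows
#'
#' @inheritParams confusion_at_threshold
#' @param threshold Decision threshold; default picks the operating point with
#'   specificity >= 0.9 on these data via [threshold_at_specificity()].
#' @return Object of class `lemp_eval`: confusion counts, Ac/Sn/Sp/MCC, ROC
#'   points, AUC, AUC01 and the threshold used.
#' @export
evaluate_predictions <- function(scores, labels, threshold = NULL) {
  y <- as_binary_labels(labels)
  if (is.null(threshold)) threshold <- threshold_at_specificity(scores, y, 0.90)
  cnt <- confusion_at_threshold(scores, y, threshold)
  ra <- roc_auc(scores, y)
  out <- list(counts = cnt, metrics = metrics(cnt), roc = ra$roc,
              auc = ra$auc, auc01 = auc01(ra$roc), threshold = threshold,
              n = length(y), n_positive = sum(y))
  class(out) <- "lemp_eval"
  out
}

#' @export
print.lemp_eval <- function(x, ...) {
  cat(sprintf("Evaluation of %d windows (%d positive)\n", x$n, x$n_positive))
  cat(sprintf("  AUC = %.4f   AUC01 = %.4f (max 0.1)\n", x$auc, x$auc01))
  m <- x$metrics
  cat(sprintf("  at threshold %.4f: Ac = %.4f  Sn = %.4f  Sp = %.4f  MCC = %.4f\n",
              x$threshold, m["Ac"], m["Sn"], m["Sp"], m["MCC"]))
  invisible(x)
}

#' Write an evaluation report (summary JSON + ROC points TSV)
#' @param report `lemp_eval` object.
#' @param prefix Output path prefix; writes `<prefix>.json`, `<prefix>_roc.tsv`.
#' @export
write_eval_report <- function(report, prefix) {
  summ <- list(n = report$n, n_positive = report$n_positive,
               counts = report$counts, metrics = as.list(report$metrics),
               auc = report$auc, auc01 = report$auc01,
               threshold = report$threshold)
  jsonlite::write_json(summ, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(report$roc, paste0(prefix, "_roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

## ---- cross-validation plumbing --------------------------------------------

## window-level folds (used when no grouping applies)
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2L, n >= k)
  r <- with_local_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[r] <- rep_len(seq_len(k), n)
  folds
}

## run a function with a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Out-of-fold scores from protein-grouped cross-validation
#'
#' Generic harness: trains `train_fn` on each training fold and scores the
#' held-out fold with `predict_fn`.  Folds come from [group_kfold()] so no
#' protein straddles a fold boundary.
#'
#' @param windows Window data.frame (`protein_id`, `position`, `label`,
#'   `window`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param train_fn `function(train_windows)` returning a fitted model.
#' @param predict_fn `function(model, windows)` returning scores.
#' @return Numeric vector of out-of-fold scores aligned with `windows` rows,
#'   with the fold assignment as attribute `"fold"`.
#' @export
cv_scores <- function(windows, k, seed, train_fn, predict_fn) {
  folds <- group_kfold(windows, k = k, seed = seed)
  scores <- rep(NA_real_, nrow(windows))
  fold_id <- integer(nrow(windows))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train_idx
    va <- folds[[f]]$validation_idx
    model <- train_fn(windows[tr, , drop = FALSE])
    scores[va] <- predict_fn(model, windows[va, , drop = FALSE])
    fold_id[va] <- f
  }
  attr(scores, "fold") <- fold_id
  scores
}

#' Learning curve over nested fractions of the training proteins
#'
#' Subsamples proteins (never splitting a protein's windows) to each fraction,
#' runs protein-grouped k-fold cross-validation for every method, and reports
#' AUC and AUC01 per (method, fraction).
#'
#' @param windows Window data.frame.
#' @param methods Named list; each element a list with `train` and `predict`
#'   functions as in [cv_scores()].
#' @param fractions Training-set fractions (default 1/8, 1/4, 1/2, 1).
#' @param k Folds per evaluation (default 10).
#' @param seed Integer seed.
#' @return Data.frame `method`, `fraction`, `n_windows`, `auc`, `auc01`.
#' @export
learning_curve <- function(windows, methods,
                           fractions = c(1 / 8, 1 / 4, 1 / 2, 1),
                           k = 10L, seed = 1L) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  prot <- unique(windows$protein_id)
  prot <- with_local_seed(seed, sample(prot))    # nested subsets
  res <- list()
  for (fr in sort(fractions)) {
    n_p <- max(1L, floor(length(prot) * fr))
    sub <- windows[windows$protein_id %in% prot[seq_len(n_p)], , drop = FALSE]
    if (length(unique(sub$protein_id)) < k)
      stop("fraction ", fr, " leaves fewer proteins than folds")
    for (m in names(methods)) {
      sc <- cv_scores(sub, k = k, seed = seed,
                      train_fn = methods[[m]]$train,
                      predict_fn = methods[[m]]$predict)
      ra <- roc_auc(sc, sub$label)
      res[[length(res) + 1L]] <- data.frame(
        method = m, fraction = fr, n_windows = nrow(sub),
        auc = ra$auc, auc01 = auc01(ra$roc))
    }
  }
  do.call(rbind, res)
}

#' Cross-validated AUC as a function of window size
#'
#' Rebuilds peptide windows at each size from the source proteins and sites,
#' then reports the protein-grouped CV AUC of a method per size.
#'
#' @param proteins Named character vector of protein sequences.
#' @param sites Site table (see [read_sites()]).
#' @param method List with `train` and `predict` functions ([cv_scores()]).
#' @param sizes Odd window sizes (default 15, 19, 23, 27, 31, 35).
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @return Data.frame `size`, `n_windows`, `auc`.
#' @export
compare_window_sizes <- function(proteins, sites, method,
                                 sizes = c(15L, 19L, 23L, 27L, 31L, 35L),
                                 k = 10L, seed = 1L) {
  if (any(sizes %% 2L == 0L)) stop("window sizes must be odd")
  res <- lapply(sizes, function(w) {
    win <- extract_windows(proteins, sites, window = w)
    win <- remove_conflicting_7mers(win)
    sc <- cv_scores(win, k = k, seed = seed,
                    train_fn = method$train, predict_fn = method$predict)
    data.frame(size = w, n_windows = nrow(win),
               auc = roc_auc(sc, win$label)$auc)
  })
  do.call(rbind, res)
}
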