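## Random-forest classifier on peptide feature encodings (RF_EAAC and
## friends), backed by ranger with single-thread deterministic training.

#' Train a random-forest classifier on a feature matrix
#'
#' Defaults follow the published setup: 1000 trees.  Candidate features per
#' split default to sqrt(d); pass `mtry = ncol(features)` for bagged
#' unrandomised trees.  Scores are the averaged per-tree class probabilities
#' (`score_type = "prob"`) or the fraction of trees voting positive
#' (`score_type = "vote"`).
#'
#' @param features Numeric matrix with column names (one row per window).
#' @param labels Binary labels (see [as_binary_labels()]).
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate features per split (default `floor(sqrt(d))`).
#' @param seed Integer seed; training is reproducible.
#' @param score_type `"prob"` (default) or `"vote"`.
#' @return Object of class `lemp_forest_model`.
#' @export
train_forest <- function(features, labels, n_trees = 1000L, mtry = NULL,
                         seed = 1L, score_type = c("prob", "vote")) {
  score_type <- match.arg(score_type)
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  df <- as.data.frame(features, check.names = FALSE)
  df$.label <- factor(ifelse(y, "positive", "negative"),
                      levels = c("negative", "positive"))
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        num.trees = n_trees, mtry = mtry,
                        probability = score_type == "prob",
                        seed = seed, num.threads = 1L,
                        verbose = FALSE)
  structure(list(fit = fit, feature_names = colnames(features),
                 score_type = score_type,
                 metadata = list(n_trees = n_trees, mtry = mtry, seed = seed,
                                 package_version =
                                   as.character(utils::packageVersion("lemp")))),
            class = "lemp_forest_model")
}

#' @rdname predict_scores
#' @export
predict_scores.lemp_forest_model <- function(model, inputs, ...) {
  stopifnot(is.matrix(inputs))
  if (!identical(colnames(inputs), model$feature_names))
    stop("feature names of the input do not match the training encoding")
  df <- as.data.frame(inputs, check.names = FALSE)
  if (model$score_type == "prob") {
    pr <- stats::predict(model$fit, data = df, num.threads = 1L)$predictions
    unname(pr[, "positive"])
  } else {
    pr <- stats::predict(model$fit, data = df, num.threads = 1L,
                         predict.all = TRUE)$predictions
    ## per-tree class indices into levels(negative, positive)
    rowMeans(pr == 2L)
  }
}

#' @export
print.lemp_forest_model <- function(x, ...) {
  cat(sprintf("<lemp_forest_model: %d trees, %d features, score = %s>\n",
              x$metadata$n_trees, length(x$feature_names), x$score_type))
  invisible(x)
}
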