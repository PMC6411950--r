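## Integration of the deep and forest classifiers: the final score S solves
## log(S / (1 - S)) = w1 * C1 + w2 * C2 + b, with C1 the deep-model score,
## C2 the forest score, and (w1, w2, b) fitted by maximum-likelihood logistic
## regression on out-of-fold component scores.

#' Fit the two-component logistic ensemble
#'
#' Plain maximum-likelihood logistic regression (no regularisation) of the
#' label on the component scores.  Scores must be out-of-fold (each window
#' scored by models not trained on it) to avoid optimistic weights.
#'
#' @param scores Data.frame with columns `c1` (deep score), `c2` (forest
#'   score) and `label`; an optional `fold` column is carried through.
#' @return Object of class `lemp_ensemble` with `w1`, `w2`, `b` and the
#'   underlying `glm` fit.
#' @export
fit_ensemble <- function(scores) {
  stopifnot(all(c("c1", "c2", "label") %in% names(scores)))
  for (comp in c("c1", "c2"))
    if (stats::var(scores[[comp]]) == 0)
      stop("component '", comp, "' is constant; cannot fit ensemble weights")
  y <- as_binary_labels(scores$label)
  fit <- stats::glm(y ~ c1 + c2, family = stats::binomial(), data = scores)
  co <- stats::coef(fit)
  if (any(!is.finite(co)))
    stop("logistic fit produced non-finite coefficients (separation?)")
  structure(list(w1 = unname(co["c1"]), w2 = unname(co["c2"]),
                 b = unname(co["(Intercept)"]), fit = fit,
                 components = c("deep", "forest")),
            class = "lemp_ensemble")
}

#' Ensemble score from component scores
#'
#' S = 1 / (1 + exp(-(w1 C1 + w2 C2 + b))).
#'
#' @param model `lemp_ensemble` (or any list with `w1`, `w2`, `b`).
#' @param c1,c2 Component scores (vectors of equal length).
#' @return Scores in (0, 1).
#' @export
predict_ensemble <- function(model, c1, c2) {
  stopifnot(length(c1) == length(c2), all(is.finite(c1)), all(is.finite(c2)))
  stats::plogis(model$w1 * c1 + model$w2 * c2 + model$b)
}

#' @rdname predict_scores
#' @export
predict_scores.lemp_ensemble <- function(model, inputs, ...) {
  stopifnot(all(c("c1", "c2") %in% names(inputs)))
  predict_ensemble(model, inputs$c1, inputs$c2)
}

#' Out-of-fold component scores for ensemble fitting
#'
#' Runs protein-grouped k-fold cross-validation: in each fold a deep model and
#' a forest are trained on the fold's training windows and score the held-out
#' windows.  The pooled out-of-fold scores feed [fit_ensemble()].
#'
#' @param windows Window data.frame (`protein_id`, `label`, `window`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (folds, forest and deep training).
#' @param slide EAAC slide length for the forest component (default 8).
#' @param n_trees Forest size (default 1000).
#' @param deep_spec Architecture for the deep component
#'   ([deep_model_spec()]).
#' @param deep_cfg Training configuration for the deep component
#'   ([train_config()]).
#' @return Data.frame `c1` (deep), `c2` (forest), `label`, `fold`, aligned to
#'   `windows` rows.
#' @export
component_scores_cv <- function(windows, k = 10L, seed = 1L, slide = 8L,
                                n_trees = 1000L,
                                deep_spec = deep_model_spec(),
                                deep_cfg = train_config()) {
  folds <- group_kfold(windows, k = k, seed = seed)
  tokens <- encode_tokens(windows$window, unknown_as_gap = TRUE)
  eaac <- encode_eaac(windows$window, slide = slide)
  c1 <- rep(NA_real_, nrow(windows)); c2 <- c1
  fold_id <- integer(nrow(windows))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train_idx; va <- folds[[f]]$validation_idx
    dm <- build_deep_model(deep_spec, "embedding", seed = seed + f)
    dcfg <- deep_cfg; dcfg$seed <- seed + f
    dm <- train_deep(dm, tokens[tr, , drop = FALSE], windows$label[tr], dcfg)
    c1[va] <- predict_scores(dm, tokens[va, , drop = FALSE])
    fm <- train_forest(eaac[tr, , drop = FALSE], windows$label[tr],
                       n_trees = n_trees, seed = seed + f)
    c2[va] <- predict_scores(fm, eaac[va, , drop = FALSE])
    fold_id[va] <- f
  }
  data.frame(c1 = c1, c2 = c2, label = windows$label, fold = fold_id)
}

#' @export
print.lemp_ensemble <- function(x, ...) {
  cat(sprintf("<lemp_ensemble: logit(S) = %.3f*C_deep + %.3f*C_forest + %.3f>\n",
              x$w1, x$w2, x$b))
  invisible(x)
}
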