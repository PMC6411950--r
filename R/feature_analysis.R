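## Interpretation analyses: position-specific residue enrichment between
## modified and unmodified peptide sets (two-sample-logo statistics),
## information-gain ranking of EAAC features, and hierarchical clustering of
## the learned residue embeddings.

#' Position-specific residue enrichment (two-sample-logo statistics)
#'
#' For every (position, residue) pair excluding the constant center, compares
#' the per-window occurrence fractions between positive and negative windows
#' with an unpooled two-proportion z-test (the large-sample equivalent of a
#' two-sample t-test on 0/1 indicators), falling back to Fisher's exact test
#' when any expected count is below 5.  P-values are Bonferroni-corrected over
#' the full family of (window - 1) x 20 tests (600 for 31-residue windows).
#'
#' @param pos_windows,neg_windows Character vectors of windows (equal length).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param return_all Return every cell rather than only significant ones.
#' @return Data.frame `position`, `residue`, `freq_pos`, `freq_neg`, `p_raw`,
#'   `p_adj`, `direction` ("enriched"/"depleted" in positives), ordered by
#'   adjusted p-value.
#' @export
two_sample_logo <- function(pos_windows, neg_windows, alpha = 0.05,
                            return_all = FALSE) {
  stopifnot(length(pos_windows) > 0L, length(neg_windows) > 0L)
  cmp <- window_char_matrix(pos_windows)
  cmn <- window_char_matrix(neg_windows)
  stopifnot(ncol(cmp) == ncol(cmn))
  W <- ncol(cmp)
  pos <- window_positions(W)
  center <- which(pos == 0L)
  n1 <- nrow(cmp); n2 <- nrow(cmn)
  n_tests <- (W - 1L) * 20L
  rows <- vector("list", n_tests)
  r <- 0L
  for (j in seq_len(W)) {
    if (j == center) next
    for (a in AA_ALPHABET) {
      x1 <- sum(cmp[, j] == a); x2 <- sum(cmn[, j] == a)
      p1 <- x1 / n1; p2 <- x2 / n2
      pp <- (x1 + x2) / (n1 + n2)
      expmin <- min(n1 * pp, n2 * pp, n1 * (1 - pp), n2 * (1 - pp))
      if (expmin < 5) {
        p_raw <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2L))$p.value
      } else {
        se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
        p_raw <- if (se == 0) 1 else 2 * stats::pnorm(-abs(p1 - p2) / se)
      }
      r <- r + 1L
      rows[[r]] <- data.frame(position = pos[j], residue = a,
                              freq_pos = p1, freq_neg = p2, p_raw = p_raw,
                              p_adj = min(1, p_raw * n_tests),
                              direction = if (p1 >= p2) "enriched" else
                                "depleted",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_adj, out$p_raw), ]
  rownames(out) <- NULL
  if (return_all) out else out[out$p_adj < alpha, , drop = FALSE]
}

## entropy in bits of a class-count vector
.entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

## Fayyad-Irani recursive MDL partitioning of one numeric feature.
## Works on (sorted unique value, class-count) aggregates; returns cut points.
.mdl_cuts <- function(vals, pos_counts, tot_counts) {
  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    if (hi <= lo) return()
    pos <- pos_counts[lo:hi]; tot <- tot_counts[lo:hi]
    N <- sum(tot)
    if (N < 2L) return()
    cp <- cumsum(pos); ct <- cumsum(tot)
    P <- cp[length(cp)]; Tt <- ct[length(ct)]
    ent_all <- .entropy_bits(c(P, Tt - P))
    ## candidate boundaries between distinct adjacent values
    best_gain <- -Inf; best_i <- 0L
    for (i in seq_len(length(tot) - 1L)) {
      e1 <- .entropy_bits(c(cp[i], ct[i] - cp[i]))
      e2 <- .entropy_bits(c(P - cp[i], (Tt - ct[i]) - (P - cp[i])))
      gain <- ent_all - (ct[i] / Tt) * e1 - ((Tt - ct[i]) / Tt) * e2
      if (gain > best_gain) {
        best_gain <- gain; best_i <- i; best_e1 <- e1; best_e2 <- e2
      }
    }
    if (best_i == 0L) return()
    k <- as.integer(P > 0) + as.integer(P < Tt)
    k1 <- as.integer(cp[best_i] > 0) + as.integer(cp[best_i] < ct[best_i])
    n2p <- P - cp[best_i]; n2t <- Tt - ct[best_i]
    k2 <- as.integer(n2p > 0) + as.integer(n2p < n2t)
    delta <- log2(3^k - 2) - (k * ent_all - k1 * best_e1 - k2 * best_e2)
    if (best_gain <= (log2(Tt - 1) + delta) / Tt) return()
    cuts <<- c(cuts, (vals[lo + best_i - 1L] + vals[lo + best_i]) / 2)
    recurse(lo, lo + best_i - 1L)
    recurse(lo + best_i, hi)
  }
  recurse(1L, length(vals))
  sort(cuts)
}

#' Information gain of a numeric feature for a binary label
#'
#' IG(f) = H(label) - H(label | discretised f), in bits.  Discretisation is
#' supervised minimum-description-length binning (Fayyad-Irani) by default,
#' with an equal-frequency 10-bin alternative; MDL features in which no cut
#' passes the MDL criterion get IG = 0.
#'
#' @param feature Numeric vector.
#' @param labels Binary labels.
#' @param method `"mdl"` (default) or `"equalfreq"`.
#' @param bins Bin count for `"equalfreq"` (default 10).
#' @return Information gain in bits (non-negative).
#' @export
information_gain <- function(feature, labels, method = c("mdl", "equalfreq"),
                             bins = 10L) {
  method <- match.arg(method)
  y <- as_binary_labels(labels)
  ord <- order(feature)
  f <- feature[ord]; yy <- y[ord]
  vals <- unique(f)
  if (length(vals) < 2L) return(0)
  pos_counts <- as.vector(rowsum(as.numeric(yy), group = match(f, vals),
                                 reorder = TRUE))
  tot_counts <- as.vector(rowsum(rep(1, length(f)), group = match(f, vals),
                                 reorder = TRUE))
  cuts <- if (method == "mdl") {
    .mdl_cuts(vals, pos_counts, tot_counts)
  } else {
    qs <- unique(stats::quantile(feature, probs = seq_len(bins - 1L) / bins,
                                 type = 1))
    qs[qs < max(vals)]
  }
  if (length(cuts) == 0L) return(0)
  bin <- findInterval(vals, cuts, left.open = FALSE) # values <= cut -> left
  bp <- rowsum(pos_counts, bin); bt <- rowsum(tot_counts, bin)
  h_y <- .entropy_bits(c(sum(pos_counts), sum(tot_counts) - sum(pos_counts)))
  h_cond <- sum(vapply(seq_len(nrow(bt)), function(i)
    (bt[i] / sum(bt)) * .entropy_bits(c(bp[i], bt[i] - bp[i])), numeric(1)))
  max(0, h_y - h_cond)
}

#' Rank features by information gain
#'
#' @param features Numeric matrix with column names (e.g. [encode_eaac()]).
#' @param labels Binary labels.
#' @param top_n Number of features to return (default 30).
#' @param method Discretisation method (see [information_gain()]).
#' @return Data.frame `name`, `information_gain`, `rank` (descending gain;
#'   ties broken by feature name).
#' @export
information_gain_ranking <- function(features, labels, top_n = 30L,
                                     method = c("mdl", "equalfreq")) {
  method <- match.arg(method)
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  ig <- vapply(seq_len(ncol(features)), function(j)
    information_gain(features[, j], labels, method = method), numeric(1))
  ord <- order(-ig, colnames(features))
  out <- data.frame(name = colnames(features)[ord], information_gain = ig[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  utils::head(out, top_n)
}

#' Hierarchically cluster the learned residue embeddings
#'
#' Average-linkage agglomerative clustering of the 20 amino-acid embedding
#' rows (the gap row is excluded) on Euclidean distances; deterministic given
#' the matrix.
#'
#' @param embedding Embedding matrix from [extract_embedding()] (or any
#'   numeric matrix whose rownames contain the 20 amino acids).
#' @return An `hclust` object with the 20 residues as leaves.
#' @export
cluster_embeddings <- function(embedding) {
  stopifnot(is.matrix(embedding), !is.null(rownames(embedding)))
  if (!all(AA_ALPHABET %in% rownames(embedding)))
    stop("embedding must contain rows for all 20 amino acids")
  m <- embedding[AA_ALPHABET, , drop = FALSE]
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Export a dendrogram in Newick format
#'
#' @param hc `hclust` object (e.g. from [cluster_embeddings()]).
#' @param path Optional output file; when NULL the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write a residue-enrichment table as TSV
#' @param cells Data.frame from [two_sample_logo()].
#' @param path Output path.
#' @export
write_enrichment_table <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
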