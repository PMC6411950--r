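## Feature encodings for 31-residue peptide windows.
##
## All encoders accept a character vector of windows (equal length, odd) and
## return a dense numeric matrix with one row per window and named columns.
## Terminal gap ('-') handling follows the conventions recorded in each
## encoder; the unknown residue 'X' never contributes to composition counts.

#' EAAC: enhanced amino-acid composition
#'
#' Counts the frequency of the 20 amino acids inside a short window slid one
#' position at a time from the N- to the C-terminus of the peptide.  A
#' 31-residue peptide with the default slide of 8 yields 31 - 8 + 1 = 24
#' sliding windows and 24 x 20 = 480 features.  Frequencies are counts divided
#' by the fixed slide length, so gaps (and 'X') dilute the composition near
#' the termini rather than shrinking the denominator.
#'
#' Feature names use center-relative coordinates, e.g. `G[-5,2]` is the
#' frequency of glycine in the sliding window covering positions -5..+2.
#'
#' @param windows Character vector of peptide windows (equal odd length).
#' @param slide Sliding-window length (default 8).
#' @return Numeric matrix, rows = windows, 20 x (W - slide + 1) named columns.
#' @export
encode_eaac <- function(windows, slide = 8L) {
  cm <- window_char_matrix(windows)
  W <- ncol(cm)
  if (slide <= 0L || slide > W)
    stop("slide must be in 1..window length (", W, "); got ", slide)
  n_sw <- W - slide + 1L
  pos <- window_positions(W)
  ## W x n_sw 0/1 matrix summing columns s..s+slide-1
  sw <- matrix(0, W, n_sw)
  for (j in seq_len(n_sw)) sw[j:(j + slide - 1L), j] <- 1
  out <- matrix(0, nrow(cm), n_sw * 20L)
  cn <- character(n_sw * 20L)
  for (j in seq_len(n_sw))
    cn[(j - 1L) * 20L + seq_len(20L)] <-
      sprintf("%s[%d,%d]", AA_ALPHABET, pos[j], pos[j] + slide - 1L)
  for (a in seq_along(AA_ALPHABET)) {
    ind <- (cm == AA_ALPHABET[a]) + 0
    out[, (seq_len(n_sw) - 1L) * 20L + a] <- (ind %*% sw) / slide
  }
  colnames(out) <- cn
  rownames(out) <- names(windows)
  out
}

#' AAC: whole-window amino-acid composition
#'
#' Frequency of each of the 20 amino acids over the full window; gaps and 'X'
#' count in the denominator (window length) only.
#'
#' @inheritParams encode_eaac
#' @return Numeric matrix with 20 named columns.
#' @export
encode_aac <- function(windows) {
  cm <- window_char_matrix(windows)
  out <- vapply(AA_ALPHABET, function(a) rowSums(cm == a) / ncol(cm),
                numeric(nrow(cm)))
  out <- matrix(out, nrow = nrow(cm), ncol = 20L,
                dimnames = list(names(windows), AA_ALPHABET))
  out
}

#' One-hot encoding of a single peptide window
#'
#' Each residue becomes a 20-dimensional indicator row; terminal gap rows (and
#' unknown 'X') are filled with a uniform 0.05 across all 20 columns so that
#' every row sums to one.
#'
#' @param window A single peptide window (character scalar).
#' @return W x 20 numeric matrix; rows named by position, columns by residue.
#' @export
encode_onehot <- function(window) {
  stopifnot(is.character(window), length(window) == 1L)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- matrix(0, length(chars), 20L,
              dimnames = list(window_positions(length(chars)), AA_ALPHABET))
  idx <- match(chars, AA_ALPHABET)
  for (i in seq_along(chars)) {
    if (is.na(idx[i])) m[i, ] <- 0.05 else m[i, idx[i]] <- 1
  }
  m
}

#' One-hot encoding of many windows as a 3-d array
#'
#' @inheritParams encode_eaac
#' @return Array of dimension n x W x 20.
#' @export
encode_onehot_batch <- function(windows) {
  cm <- window_char_matrix(windows)
  n <- nrow(cm); W <- ncol(cm)
  arr <- array(0, dim = c(n, W, 20L),
               dimnames = list(NULL, NULL, AA_ALPHABET))
  idx <- match(cm, AA_ALPHABET)          # n*W vector, NA for gap/'X'
  na <- is.na(idx)
  arr[cbind(rep(seq_len(n), W)[!na], rep(seq_len(W), each = n)[!na],
            idx[!na])] <- 1
  if (any(na)) {
    who <- which(matrix(na, n, W), arr.ind = TRUE)
    for (a in seq_len(20L)) arr[cbind(who, a)] <- 0.05
  }
  arr
}

#' Integer token encoding for the embedding-input deep models
#'
#' Maps each of the 21 window symbols to a stable integer id: the 20 amino
#' acids (alphabetical) to 0..19 and the gap '-' to 20.  The map is a package
#' constant and is persisted in saved model metadata.
#'
#' @inheritParams encode_eaac
#' @param unknown_as_gap Map characters outside the 21-symbol alphabet (e.g.
#'   the sanitised unknown residue 'X') to the gap id instead of erroring.
#' @return Integer matrix n x W of token ids in 0..20.
#' @export
encode_tokens <- function(windows, unknown_as_gap = FALSE) {
  cm <- window_char_matrix(windows)
  id <- .token_id[cm]
  if (anyNA(id)) {
    if (unknown_as_gap) {
      id[is.na(id)] <- .token_id[[GAP_SYMBOL]]
    } else {
      bad <- unique(cm[is.na(id)])
      stop("unmappable character(s) in window: ", paste(bad, collapse = " "))
    }
  }
  matrix(as.integer(id), nrow(cm), ncol(cm), dimnames = list(names(windows), NULL))
}

#' Decode token ids back to a peptide window
#' @param tokens Integer vector or matrix of ids in 0..20.
#' @return Character vector of windows.
#' @export
decode_tokens <- function(tokens) {
  if (is.null(dim(tokens))) tokens <- matrix(tokens, nrow = 1L)
  stopifnot(all(tokens >= 0L & tokens <= 20L))
  apply(tokens, 1L, function(r) paste(WINDOW_ALPHABET[r + 1L], collapse = ""))
}

## ---- AAindex ---------------------------------------------------------------

## value order of the two 'I' lines in the AAindex flat-file format
.aaindex_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an AAindex1 flat file
#'
#' Parses records of the AAindex format (fields `H` accession, `D` description
#' and `I` followed by two lines of 10 values in the standard
#' A/R/N/D/C/Q/E/G/H/I then L/K/M/F/P/S/T/W/Y/V order).
#'
#' @param path Path to the flat file.
#' @param drop_na Drop properties with any missing ("NA" or "-") value
#'   (default TRUE, matching the usual pre-filtering of the index).
#' @return A data.frame with columns `property_id`, `description` and one
#'   numeric column per amino acid (canonical alphabetical order).
#' @export
read_aaindex <- function(path, drop_na = TRUE) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(TRUE, lines[-length(lines)] == "//")))
  rows <- lapply(recs, function(r) {
    h <- grep("^H ", r, value = TRUE)
    if (length(h) == 0L) return(NULL)
    id <- sub("^H\\s+", "", h[1])
    d <- grep("^D ", r, value = TRUE)
    desc <- if (length(d)) sub("^D\\s+", "", d[1]) else ""
    i <- grep("^I ", r)
    if (length(i) == 0L || i[1] + 2L > length(r)) return(NULL)
    toks <- unlist(strsplit(trimws(r[c(i[1] + 1L, i[1] + 2L)]), "\\s+"))
    vals <- suppressWarnings(as.numeric(toks))   # "NA"/"-" -> NA
    if (length(vals) != 20L) return(NULL)
    names(vals) <- .aaindex_order
    c(list(property_id = id, description = desc),
      as.list(vals[AA_ALPHABET]))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no AAindex records found in ", path)
  tbl <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  rownames(tbl) <- NULL
  if (drop_na) tbl <- tbl[stats::complete.cases(tbl[, AA_ALPHABET]), , drop = FALSE]
  tbl
}

#' Write a property table in AAindex flat-file format
#'
#' Used to materialise synthetic property tables in the same dialect the
#' reader consumes.
#'
#' @param tbl Data.frame as returned by [read_aaindex()].
#' @param path Output path.
#' @export
write_aaindex <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) paste(formatC(v, format = "g", digits = 6), collapse = "  ")
  for (i in seq_len(nrow(tbl))) {
    v <- as.numeric(tbl[i, AA_ALPHABET])
    names(v) <- AA_ALPHABET
    v <- v[.aaindex_order]
    writeLines(c(paste("H", tbl$property_id[i]),
                 paste("D", tbl$description[i]),
                 "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
                 paste0("   ", fmt(v[1:10])),
                 paste0("   ", fmt(v[11:20])),
                 "//"), con)
  }
  invisible(path)
}

#' AAindex physicochemical-property encoding
#'
#' Each window position contributes one value per property (the property value
#' of the residue at that position); gap and unknown positions contribute 0.
#' With 11 properties a 31-residue window becomes a 31 x 11 = 341-dimensional
#' vector.
#'
#' @inheritParams encode_eaac
#' @param properties Property table ([read_aaindex()] format), one row per
#'   retained property.
#' @return Numeric matrix n x (W * nrow(properties)), columns named
#'   `<property_id>[pos]`.
#' @export
encode_aaindex <- function(windows, properties) {
  stopifnot(nrow(properties) >= 1L)
  cm <- window_char_matrix(windows)
  W <- ncol(cm)
  pos <- window_positions(W)
  idx <- match(cm, AA_ALPHABET)                 # NA -> gap rule
  out <- matrix(0, nrow(cm), W * nrow(properties))
  cn <- character(ncol(out))
  for (p in seq_len(nrow(properties))) {
    vals <- c(as.numeric(properties[p, AA_ALPHABET]), 0)
    v <- vals[ifelse(is.na(idx), 21L, idx)]
    out[, (p - 1L) * W + seq_len(W)] <- matrix(v, nrow(cm), W)
    cn[(p - 1L) * W + seq_len(W)] <-
      sprintf("%s[%d]", properties$property_id[p], pos)
  }
  colnames(out) <- cn
  rownames(out) <- names(windows)
  out
}

#' Rank AAindex properties by single-property classifier performance
#'
#' Encodes each property alone (one value per window position), scores it by
#' the cross-validated AUC of a random forest, ranks properties by AUC, and
#' returns the top `top_n` among those exceeding `auc_cutoff` (fewer if the
#' cutoff removes more).
#'
#' @inheritParams encode_aaindex
#' @param labels Binary labels ("positive"/"negative", logical or 0/1).
#' @param auc_cutoff Minimum out-of-fold AUC for a property to qualify.
#' @param top_n Number of properties to return (default 11).
#' @param k Cross-validation folds (default 5).
#' @param n_trees Trees per forest (default 100; a screening forest).
#' @param seed Integer seed for folds and forests.
#' @return Character vector of selected property ids (best first), with the
#'   full ranking as attribute `"ranking"`.
#' @export
rank_aaindex_properties <- function(properties, windows, labels,
                                    auc_cutoff = 0.7, top_n = 11L,
                                    k = 5L, n_trees = 100L, seed = 1L) {
  if (length(windows) == 0L) stop("empty dataset")
  y <- as_binary_labels(labels)
  folds <- make_folds(length(windows), k, seed)
  aucs <- vapply(seq_len(nrow(properties)), function(p) {
    X <- encode_aaindex(windows, properties[p, , drop = FALSE])
    oof <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- train_forest(X[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                        seed = seed + f)
      oof[!tr] <- predict_scores(m, X[!tr, , drop = FALSE])
    }
    roc_auc(oof, y)$auc
  }, numeric(1))
  ord <- order(aucs, decreasing = TRUE)
  ranking <- data.frame(property_id = properties$property_id[ord],
                        auc = aucs[ord], stringsAsFactors = FALSE)
  sel <- ranking$property_id[ranking$auc > auc_cutoff]
  sel <- utils::head(sel, top_n)
  attr(sel, "ranking") <- ranking
  sel
}

## ---- comparator encodings --------------------------------------------------

## Z-scales (Sandberg et al. 1998): five principal-property scores per residue
.zscales <- matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,   # A
   0.84, -1.67,  3.71,  0.18, -2.65,   # C
   3.98,  0.93,  1.93, -2.46,  0.75,   # D
   3.11,  0.26, -0.11, -3.04, -0.25,   # E
  -4.22,  1.94,  1.06,  0.54, -0.62,   # F
   2.05, -4.06,  0.36, -0.82, -0.38,   # G
   2.47,  1.95,  0.26,  3.90,  0.09,   # H
  -3.89, -1.73, -1.71, -0.84,  0.26,   # I
   2.29,  0.89, -2.49,  1.49,  0.31,   # K
  -4.28, -1.30, -1.49, -0.72,  0.84,   # L
  -2.85, -0.22,  0.47,  1.94, -0.98,   # M
   3.05,  1.62,  1.04, -1.15,  1.61,   # N
  -1.66,  0.27,  1.84,  0.70,  2.00,   # P
   1.75,  0.50, -1.44, -1.34,  0.66,   # Q
   3.52,  2.50, -3.50,  1.99, -0.17,   # R
   2.39, -1.07,  1.15, -1.39,  0.67,   # S
   0.75, -2.18, -1.12, -1.46, -0.40,   # T
  -2.59, -2.64, -1.54, -0.85, -0.02,   # V
  -4.36,  3.94,  0.59,  3.44, -1.59,   # W
  -2.54,  2.44,  0.43,  0.04, -1.47),  # Y
  nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET, paste0("z", 1:5)))

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
}

#' Comparator feature encodings (BLOSUM62, binary, CKSAAP, Z-scales)
#'
#' Standard published encodings provided for benchmarking against EAAC:
#' \describe{
#'   \item{blosum62}{per-position substitution-matrix row (W x 20; gap/'X'
#'     rows are zero).}
#'   \item{binary}{flattened one-hot (W x 20 = 620 for W = 31; gap rows 0.05).}
#'   \item{cksaap}{k-spaced amino-acid-pair counts for k = 0..4, each
#'     normalised by the number of k-spaced pairs in the window; pairs
#'     involving gaps or 'X' are skipped.}
#'   \item{zscales}{per-position five-dimensional Z-scale values (W x 5; gap
#'     positions zero).}
#' }
#'
#' @inheritParams encode_eaac
#' @param scheme One of `"blosum62"`, `"binary"`, `"cksaap"`, `"zscales"`.
#' @return Numeric matrix with named columns.
#' @export
encode_comparators <- function(windows,
                               scheme = c("blosum62", "binary", "cksaap",
                                          "zscales")) {
  scheme <- match.arg(scheme)
  cm <- window_char_matrix(windows)
  n <- nrow(cm); W <- ncol(cm)
  pos <- window_positions(W)
  idx <- matrix(match(cm, AA_ALPHABET), n, W)
  if (scheme == "binary") {
    arr <- encode_onehot_batch(windows)
    ## position-major layout: 20 residue columns for pos 1, then pos 2, ...
    out <- matrix(aperm(arr, c(1L, 3L, 2L)), n, W * 20L)
    colnames(out) <- sprintf("bin[%d].%s", rep(pos, each = 20L),
                             rep(AA_ALPHABET, W))
    return(out)
  }
  if (scheme %in% c("blosum62", "zscales")) {
    tab <- if (scheme == "blosum62") blosum62_matrix() else .zscales
    d <- ncol(tab)
    tab0 <- rbind(tab, 0)                      # row 21 = gap/'X'
    out <- matrix(0, n, W * d)
    for (p in seq_len(W)) {
      rows <- ifelse(is.na(idx[, p]), 21L, idx[, p])
      out[, (p - 1L) * d + seq_len(d)] <- tab0[rows, , drop = FALSE]
    }
    colnames(out) <- sprintf("%s[%d].%s",
                             ifelse(scheme == "blosum62", "b62", "zs"),
                             rep(pos, each = d), rep(colnames(tab), W))
    return(out)
  }
  ## cksaap, k = 0..4
  ks <- 0:4
  pair_names <- as.vector(outer(AA_ALPHABET, AA_ALPHABET,
                                function(a, b) paste0(a, b)))
  out <- matrix(0, n, length(ks) * 400L)
  cn <- character(ncol(out))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    n_pairs <- W - k - 1L
    block <- matrix(0, n, 400L)
    for (p in seq_len(n_pairs)) {
      a <- idx[, p]; b <- idx[, p + k + 1L]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        j <- (b[ok] - 1L) * 20L + a[ok]
        ij <- cbind(which(ok), j)
        block[ij] <- block[ij] + 1
      }
    }
    out[, (ki - 1L) * 400L + seq_len(400L)] <- block / n_pairs
    cn[(ki - 1L) * 400L + seq_len(400L)] <-
      sprintf("cksaap.k%d.%s", k, pair_names)
  }
  colnames(out) <- cn
  out
}

#' Write a dense feature matrix as TSV (feature names in the header)
#' @param x Feature matrix with column names.
#' @param path Output path.
#' @export
write_feature_matrix <- function(x, path) {
  utils::write.table(as.data.frame(x, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
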