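## Dataset construction: from protein sequences + site tables to labeled,
## redundancy-reduced peptide windows with protein-grouped splits.
##
## The pipeline follows five steps: (1) high-confidence filtering of positive
## sites, (2) clustering of proteins above 30% identity with selection of the
## most-modified member as representative and exclusion of representative
## negatives whose aligned counterparts are modified elsewhere in the cluster,
## (3) removal of center 7-mers shared between positive and negative windows,
## (4) extraction of gap-padded odd-length windows, and (5) a protein-grouped
## train/test split (with protein-grouped k-fold CV for model selection).

#' Read protein sequences from a FASTA file
#'
#' The identifier is the first whitespace-delimited token of the header.  Rare
#' one-letter codes (B, Z, U, O, J, *) are mapped to the unknown residue 'X'.
#'
#' @param path FASTA path (any line wrapping).
#' @param sanitize Map unusual residue codes to 'X' (default TRUE).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, sanitize = TRUE) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein ids in ", path)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  if (sanitize) seqs <- vapply(seqs, sanitize_sequence, character(1))
  seqs
}

#' Write protein sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a site-label table
#'
#' Tab-separated with header `protein_id  position  label  andromeda_score
#' localization_prob`; empty strings are allowed for the optional score
#' fields.  Positions are 1-based.
#'
#' @param path TSV path.
#' @return Data.frame with typed columns.
#' @export
read_sites <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "character",
                                          "numeric", "numeric"),
                           na.strings = c("", "NA"), stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label", "andromeda_score",
            "localization_prob")
  if (!identical(names(tbl), need))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (!all(tbl$label %in% c("positive", "negative")))
    stop("site labels must be 'positive' or 'negative'")
  tbl
}

#' Write a site-label table (round-trips through [read_sites()])
#' @param sites Site data.frame.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  out <- sites[, c("protein_id", "position", "label", "andromeda_score",
                   "localization_prob")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Check that every site's residue is a lysine
#' @param proteins Named character vector of sequences.
#' @param sites Site data.frame.
#' @return Invisibly TRUE; errors on the first violation.
#' @export
validate_sites <- function(proteins, sites) {
  miss <- setdiff(sites$protein_id, names(proteins))
  if (length(miss))
    stop("site table references unknown protein(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  res <- substr(proteins[sites$protein_id], sites$position, sites$position)
  bad <- which(res != "K")
  if (length(bad))
    stop("site table corrupt: residue at ", sites$protein_id[bad[1]], ":",
         sites$position[bad[1]], " is '", res[bad[1]], "', not 'K'")
  invisible(TRUE)
}

#' Retain high-confidence positive sites
#'
#' Positives are kept iff their identification score is strictly greater than
#' `min_score` AND their localization probability is strictly greater than
#' `min_locprob`.  Negatives pass through unchanged.  Positives with missing
#' scores are rejected with a warning, not an error.
#'
#' @param sites Site data.frame.
#' @param min_score Andromeda-score cutoff (default 50, strict).
#' @param min_locprob Localization-probability cutoff (default 0.75, strict).
#' @return Filtered site data.frame.
#' @export
filter_high_confidence <- function(sites, min_score = 50, min_locprob = 0.75) {
  pos <- sites$label == "positive"
  miss <- pos & (is.na(sites$andromeda_score) | is.na(sites$localization_prob))
  if (any(miss))
    warning(sum(miss), " positive site(s) with missing scores rejected")
  keep <- !pos | (!miss &
                    sites$andromeda_score > min_score &
                    sites$localization_prob > min_locprob)
  sites[keep, , drop = FALSE]
}

## global-alignment identity = exact matches / length of the shorter sequence
alignment_identity <- function(a, b, submat = NULL) {
  if (is.null(submat)) submat <- .blosum62_full()
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62_full <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Greedy identity-based protein clustering
#'
#' Redundancy reduction in the spirit of greedy incremental clustering tools:
#' proteins are processed longest-first; each joins the earliest-created
#' cluster whose seed shares global-alignment identity strictly greater than
#' `identity_threshold` (identity = matched positions / shorter-sequence
#' length), else founds a new cluster.  A shared-k-mer prefilter avoids
#' aligning unrelated pairs.  Precomputed assignments from an external
#' clustering tool can be supplied instead.
#'
#' @param proteins Named character vector of sequences.
#' @param identity_threshold Identity fraction above which proteins cluster
#'   (default 0.30).
#' @param sites Optional site table; when given, each cluster's representative
#'   is chosen by [select_representative()], otherwise the seed (longest
#'   member) is used.
#' @param kmer Prefilter k-mer length (default 5).
#' @param precomputed Optional data.frame `protein_id`, `cluster` from an
#'   external tool; skips the internal clustering.
#' @return List of clusters, each a list with `members` (ids, seed first) and
#'   `representative` (id).
#' @export
cluster_proteins <- function(proteins, identity_threshold = 0.30, sites = NULL,
                             kmer = 5L, precomputed = NULL) {
  stopifnot(length(proteins) >= 1L, !is.null(names(proteins)))
  if (!is.null(precomputed)) {
    stopifnot(all(names(proteins) %in% precomputed$protein_id))
    grp <- split(precomputed$protein_id, precomputed$cluster)
    clusters <- lapply(grp, function(ids) list(members = ids,
                                               representative = ids[[1]]))
  } else {
    ord <- order(-nchar(proteins), names(proteins))
    ids <- names(proteins)[ord]
    seqs <- proteins[ord]
    clusters <- list()
    seed_seq <- character(0)
    kmer_index <- new.env(parent = emptyenv())   # kmer -> cluster indices
    submat <- .blosum62_full()
    for (i in seq_along(ids)) {
      km <- kmer_set(seqs[[i]], kmer)
      cand <- sort(unique(unlist(lapply(km, function(x)
        kmer_index[[x]]), use.names = FALSE)))
      if (nchar(seqs[[i]]) <= 2L * kmer)   # too short for the prefilter
        cand <- seq_along(clusters)
      joined <- FALSE
      for (ci in cand) {
        if (alignment_identity(seqs[[i]], seed_seq[[ci]], submat) >
            identity_threshold) {
          clusters[[ci]]$members <- c(clusters[[ci]]$members, ids[[i]])
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        clusters[[length(clusters) + 1L]] <-
          list(members = ids[[i]], representative = ids[[i]])
        seed_seq <- c(seed_seq, seqs[[i]])
        ci <- length(clusters)
        for (x in km) kmer_index[[x]] <- c(kmer_index[[x]], ci)
      }
    }
  }
  if (!is.null(sites)) {
    for (ci in seq_along(clusters))
      clusters[[ci]]$representative <-
        select_representative(clusters[[ci]]$members, proteins, sites)
  }
  clusters
}

#' Choose a cluster representative: the member with the most positive sites
#'
#' Ties are broken deterministically: longer sequence first, then the
#' lexicographically smaller id.
#'
#' @param members Character vector of member protein ids.
#' @param proteins Named character vector of sequences.
#' @param sites Site data.frame.
#' @return The representative protein id.
#' @export
select_representative <- function(members, proteins, sites) {
  stopifnot(length(members) >= 1L)
  pos <- sites[sites$label == "positive" & sites$protein_id %in% members, ]
  npos <- vapply(members, function(m) sum(pos$protein_id == m), integer(1))
  len <- nchar(proteins[members])
  members[order(-npos, -len, members)][1L]
}

## 7-mer (-3..+3) around a site, '-'-padded at the termini
site_7mer <- function(seq, position) {
  padded <- paste0("---", seq, "---")
  substr(padded, position, position + 6L)
}

#' Drop representative negatives whose aligned counterparts are modified
#'
#' A negative lysine of the representative is removed (not relabeled) when a
#' positive site in another member of the same cluster carries an identical
#' center 7-mer (positions -3..+3) — a conservative surrogate for the aligned
#' counterpart being malonylated.
#'
#' @param representative Representative protein id.
#' @param members All member ids of the cluster.
#' @param proteins Named character vector of sequences.
#' @param sites Site data.frame (any proteins; only this cluster is touched).
#' @return Site data.frame with the offending negatives removed.
#' @export
exclude_aligned_positives <- function(representative, members, proteins, sites) {
  others <- setdiff(members, representative)
  if (length(others) == 0L) return(sites)
  op <- sites[sites$protein_id %in% others & sites$label == "positive", ]
  if (nrow(op) == 0L) return(sites)
  pos7 <- unique(mapply(function(p, i) site_7mer(proteins[[p]], i),
                        op$protein_id, op$position))
  drop <- sites$protein_id == representative & sites$label == "negative" &
    mapply(function(p, i) site_7mer(proteins[[p]], i),
           sites$protein_id, sites$position) %in% pos7
  sites[!drop, , drop = FALSE]
}

#' Extract a gap-padded peptide window around a lysine
#'
#' @param protein Protein sequence (character scalar).
#' @param position 1-based position of the central lysine.
#' @param window Odd window length (default 31).
#' @return The window string; gaps ('-') fill positions beyond the termini.
#' @export
extract_window <- function(protein, position, window = 31L) {
  stopifnot(window %% 2L == 1L, position >= 1L, position <= nchar(protein))
  if (substr(protein, position, position) != "K")
    stop("residue at position ", position, " is not 'K': corrupt site table?")
  half <- (window - 1L) %/% 2L
  pad <- strrep(GAP_SYMBOL, half)
  substr(paste0(pad, protein, pad), position, position + 2L * half)
}

#' Extract windows for every site in a table
#'
#' @param proteins Named character vector of sequences.
#' @param sites Site data.frame.
#' @param window Odd window length (default 31).
#' @return Data.frame `protein_id`, `position`, `label`, `window`.
#' @export
extract_windows <- function(proteins, sites, window = 31L) {
  validate_sites(proteins, sites)
  half <- (window - 1L) %/% 2L
  pad <- strrep(GAP_SYMBOL, half)
  padded <- stats::setNames(paste0(pad, proteins, pad), names(proteins))
  win <- substr(padded[sites$protein_id], sites$position,
                sites$position + 2L * half)
  data.frame(protein_id = sites$protein_id, position = sites$position,
             label = sites$label, window = unname(win),
             stringsAsFactors = FALSE)
}

#' Remove windows whose center 7-mer occurs with both labels
#'
#' Any 7-mer (center -3..+3) present in at least one positive AND one negative
#' window causes removal of every window (either label) that carries it.  The
#' operation is idempotent.
#'
#' @param windows Window data.frame (`label`, `window` columns), or a
#'   character vector of positive windows if `windows_neg` is given.
#' @param windows_neg Optional character vector of negative windows.
#' @return Same shape as the input: a filtered data.frame, or a list with
#'   `positive` and `negative` character vectors.
#' @export
remove_conflicting_7mers <- function(windows, windows_neg = NULL) {
  center7 <- function(w) {
    c0 <- (nchar(w) + 1L) %/% 2L
    substr(w, c0 - 3L, c0 + 3L)
  }
  if (is.null(windows_neg)) {
    stopifnot(is.data.frame(windows))
    m7 <- center7(windows$window)
    conflict <- intersect(m7[windows$label == "positive"],
                          m7[windows$label == "negative"])
    windows[!(m7 %in% conflict), , drop = FALSE]
  } else {
    p7 <- center7(windows); n7 <- center7(windows_neg)
    conflict <- intersect(p7, n7)
    list(positive = windows[!(p7 %in% conflict)],
         negative = windows_neg[!(n7 %in% conflict)])
  }
}

#' Protein-grouped train/test split
#'
#' Proteins (not windows) are randomly partitioned so that all windows of a
#' protein fall on one side; reproducible from the seed.
#'
#' @param windows Window data.frame.
#' @param train_fraction Fraction of proteins assigned to training
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` window data.frames; the seed and
#'   protein assignment are attached as attributes.
#' @export
split_by_protein <- function(windows, train_fraction = 0.8, seed = 1L) {
  prot <- unique(windows$protein_id)
  n_train <- round(train_fraction * length(prot))
  train_prot <- with_local_seed(seed, sample(prot, n_train))
  out <- list(train = windows[windows$protein_id %in% train_prot, , drop = FALSE],
              test = windows[!(windows$protein_id %in% train_prot), , drop = FALSE])
  attr(out, "seed") <- seed
  attr(out, "train_proteins") <- train_prot
  out
}

#' Protein-grouped k-fold cross-validation folds
#'
#' Shuffled proteins are dealt round-robin into k folds, so folds are balanced
#' by protein count and every protein's windows land in exactly one validation
#' fold.
#'
#' @param windows Window data.frame.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of k folds, each with `train`, `validation` data.frames and
#'   `train_idx`, `validation_idx` row indices into `windows`.
#' @export
group_kfold <- function(windows, k = 10L, seed = 1L) {
  prot <- unique(windows$protein_id)
  if (length(prot) < k)
    stop("need at least k = ", k, " proteins; have ", length(prot))
  prot <- with_local_seed(seed, sample(prot))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(prot)), prot)
  lapply(seq_len(k), function(f) {
    va <- which(fold_of[windows$protein_id] == f)
    tr <- setdiff(seq_len(nrow(windows)), va)
    list(train = windows[tr, , drop = FALSE],
         validation = windows[va, , drop = FALSE],
         train_idx = tr, validation_idx = va)
  })
}

#' Run the full dataset-construction pipeline
#'
#' Filters positives by identification confidence, clusters proteins above the
#' identity threshold, keeps each cluster's representative (most positive
#' sites) with negatives excluded where a cluster mate's aligned counterpart
#' is modified, extracts gap-padded windows, and removes label-conflicting
#' center 7-mers.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Site data.frame.
#' @param window Odd window length (default 31).
#' @param min_score,min_locprob Confidence cutoffs (strict; defaults 50, 0.75).
#' @param identity_threshold Clustering identity (default 0.30).
#' @param cluster_assignments Optional precomputed clustering
#'   (see [cluster_proteins()]).
#' @return Window data.frame; clusters and parameters attached as attributes.
#' @export
build_dataset <- function(proteins, sites, window = 31L,
                          min_score = 50, min_locprob = 0.75,
                          identity_threshold = 0.30,
                          cluster_assignments = NULL) {
  validate_sites(proteins, sites)
  sites <- filter_high_confidence(sites, min_score, min_locprob)
  clusters <- cluster_proteins(proteins, identity_threshold, sites = sites,
                               precomputed = cluster_assignments)
  kept <- list()
  for (cl in clusters) {
    s <- sites[sites$protein_id %in% cl$members, , drop = FALSE]
    s <- exclude_aligned_positives(cl$representative, cl$members, proteins, s)
    kept[[length(kept) + 1L]] <-
      s[s$protein_id == cl$representative, , drop = FALSE]
  }
  rep_sites <- do.call(rbind, kept)
  win <- extract_windows(proteins, rep_sites, window = window)
  win <- remove_conflicting_7mers(win)
  rownames(win) <- NULL
  attr(win, "clusters") <- clusters
  attr(win, "params") <- list(window = window, min_score = min_score,
                              min_locprob = min_locprob,
                              identity_threshold = identity_threshold)
  win
}

#' Write a window dataset as TSV (`protein_id  position  label  window`)
#' @param windows Window data.frame.
#' @param path Output path.
#' @export
write_dataset <- function(windows, path) {
  utils::write.table(windows[, c("protein_id", "position", "label", "window")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window dataset written by [write_dataset()] (bit-exact round trip)
#' @param path TSV path.
#' @return Window data.frame.
#' @export
read_dataset <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "character"),
                    stringsAsFactors = FALSE)
}
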