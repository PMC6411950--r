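# Shared fixture builders: everything is generated in code at test time.

# random peptide window with a central K
random_window <- function(width = 31L) {
  half <- (width - 1L) %/% 2L
  paste(c(sample(AA_ALPHABET, half, TRUE), "K",
          sample(AA_ALPHABET, half, TRUE)), collapse = "")
}

random_windows <- function(n, width = 31L) {
  vapply(seq_len(n), function(i) random_window(width), character(1))
}

# windows whose flank composition differs by class: positives draw flanks
# from `pos_probs`, negatives from `neg_probs` (named over AA_ALPHABET)
biased_windows <- function(n, probs, width = 31L) {
  half <- (width - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    paste(c(sample(AA_ALPHABET, half, TRUE, prob = probs), "K",
            sample(AA_ALPHABET, half, TRUE, prob = probs)), collapse = ""),
    character(1))
}

# small window data.frame with per-protein grouping
toy_window_df <- function(n_proteins = 12L, windows_per_protein = 4L,
                          width = 31L) {
  do.call(rbind, lapply(seq_len(n_proteins), function(p) {
    data.frame(protein_id = sprintf("P%02d", p),
               position = 16L + seq_len(windows_per_protein),
               label = rep(c("positive", "negative"),
                           length.out = windows_per_protein),
               window = random_windows(windows_per_protein, width),
               stringsAsFactors = FALSE)
  }))
}

# random protein with guaranteed lysines
random_protein <- function(len = 60L) {
  paste(sample(AA_ALPHABET, len, TRUE), collapse = "")
}

# mutate a sequence at the given per-residue rate
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  ch[hit] <- sample(AA_ALPHABET, length(hit), TRUE)
  paste(ch, collapse = "")
}

# exhaustive pairwise AUC oracle: P(pos > neg) + 0.5 P(tie)
pairwise_auc_oracle <- function(scores, labels) {
  y <- as_binary_labels(labels)
  sp <- scores[y]; sn <- scores[!y]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# synthetic AAindex-style property table
synthetic_property_table <- function(n = 3L, seed = 1L) {
  set.seed(seed)
  tbl <- data.frame(property_id = sprintf("SYNP%03d", seq_len(n)),
                    description = sprintf("synthetic property %d", seq_len(n)),
                    stringsAsFactors = FALSE)
  vals <- matrix(round(stats::rnorm(20L * n), 3), n, 20L)
  colnames(vals) <- AA_ALPHABET
  cbind(tbl, vals)
}
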