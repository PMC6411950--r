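# Dataset construction: filtering, clustering, window extraction, conflict
# removal, grouped splits, and the text-format round trips.

site_row <- function(id, pos, label, score = NA, prob = NA) {
  data.frame(protein_id = id, position = pos, label = label,
             andromeda_score = score, localization_prob = prob,
             stringsAsFactors = FALSE)
}

test_that("high-confidence filter applies strict cutoffs to positives only", {
  sites <- rbind(site_row("P1", 5L, "positive", 51, 0.76),
                 site_row("P1", 9L, "positive", 50, 0.90),
                 site_row("P1", 12L, "negative"))
  out <- filter_high_confidence(sites)
  expect_equal(out$position, c(5L, 12L))          # score 50 fails "> 50"
  # 10 positives with scores 45..54: exactly those strictly above 50 remain
  many <- do.call(rbind, lapply(45:54, function(s)
    site_row("P2", s, "positive", s, 0.8)))
  expect_equal(nrow(filter_high_confidence(many)), 4L)
  # missing scores reject the record with a warning, not an error
  expect_warning(out2 <- filter_high_confidence(
    rbind(site_row("P3", 1L, "positive"), site_row("P3", 2L, "negative"))),
    "missing")
  expect_equal(out2$label, "negative")
})

test_that("window extraction pads termini with gaps and round-trips", {
  prot <- paste(c("K", sample(setdiff(AA_ALPHABET, "K"), 20, TRUE),
                  sample(AA_ALPHABET, 19, TRUE)), collapse = "")
  w1 <- extract_window(prot, 1L)
  expect_equal(nchar(w1), 31L)
  expect_equal(substr(w1, 1, 15), strrep("-", 15))
  expect_equal(substr(w1, 16, 16), "K")
  prot2 <- random_protein(40)
  substr(prot2, 20, 20) <- "K"
  w2 <- extract_window(prot2, 20L)
  expect_false(grepl("-", w2, fixed = TRUE))
  expect_equal(w2, substr(prot2, 5, 35))
  prot3 <- paste0(paste(rep("A", 19), collapse = ""), "K")
  w3 <- extract_window(prot3, 20L)
  expect_equal(substr(w3, 17, 31), strrep("-", 15))
  expect_equal(substr(w3, 1, 16), paste0(strrep("A", 15), "K"))
  expect_error(extract_window("AAAA", 2L), "not 'K'")
})

test_that("stripping gaps from any window yields a substring of the source", {
  set.seed(13)
  for (i in 1:20) {
    prot <- random_protein(sample(16:80, 1))
    kpos <- which(strsplit(prot, "")[[1]] == "K")
    if (length(kpos) == 0) next
    p <- kpos[sample(length(kpos), 1)]
    w <- extract_window(prot, p)
    expect_true(grepl(gsub("-", "", w, fixed = TRUE), prot, fixed = TRUE))
  }
})

test_that("greedy clustering groups similar sequences and splits unrelated", {
  set.seed(23)
  a <- random_protein(60)
  b <- mutate_seq(a, 0.1)                          # ~90% identical to a
  c_ <- random_protein(55)
  prots <- c(A = a, B = b, C = c_)
  cl <- cluster_proteins(prots, identity_threshold = 0.30)
  sets <- lapply(cl, function(x) sort(x$members))
  expect_true(any(vapply(sets, identical, logical(1), y = c("A", "B"))))
  expect_equal(length(cl), 2L)
  # oracle: exhaustive pairwise identity agrees with the grouping
  ns <- asNamespace("lemp")
  expect_gt(ns$alignment_identity(a, b), 0.30)
  expect_lt(ns$alignment_identity(a, c_), 0.30)
  # identical sequences cluster together; unrelated stay apart
  cl2 <- cluster_proteins(c(X = a, Y = a))
  expect_equal(length(cl2), 1L)
  expect_equal(length(cl2[[1]]$members), 2L)
  cl3 <- cluster_proteins(c(X = a, Z = c_))
  expect_equal(length(cl3), 2L)
})

test_that("raising the identity threshold never reduces the cluster count", {
  set.seed(37)
  fam1 <- random_protein(50)
  fam2 <- random_protein(50)
  prots <- c(A1 = fam1, A2 = mutate_seq(fam1, 0.2), A3 = mutate_seq(fam1, 0.4),
             B1 = fam2, B2 = mutate_seq(fam2, 0.3))
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th)
    length(cluster_proteins(prots, identity_threshold = th)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("precomputed cluster assignments are honoured", {
  prots <- c(A = random_protein(40), B = random_protein(40),
             C = random_protein(40))
  pre <- data.frame(protein_id = c("A", "B", "C"), cluster = c(1L, 1L, 2L))
  cl <- cluster_proteins(prots, precomputed = pre)
  expect_equal(length(cl), 2L)
  expect_setequal(cl[[1]]$members, c("A", "B"))
})

test_that("representative selection maximises positives with documented ties", {
  prots <- c(A = strrep("AK", 20), B = strrep("CK", 25), C = strrep("DK", 25))
  sites <- rbind(site_row("A", 2L, "positive", 60, .9),
                 site_row("A", 4L, "positive", 60, .9),
                 site_row("A", 6L, "positive", 60, .9),
                 site_row("B", 2L, "positive", 60, .9))
  expect_equal(select_representative(c("A", "B"), prots, sites), "A")
  expect_equal(select_representative("B", prots, sites), "B")
  # tie on positives (0 vs 0): longer sequence wins, then smaller id
  expect_equal(select_representative(c("A", "B"), prots,
                                     sites[0, , drop = FALSE]), "B")
  expect_equal(select_representative(c("C", "B"), prots,
                                     sites[0, , drop = FALSE]), "B")
})

test_that("negatives aligned to a cluster mate's positive are excluded", {
  rep_seq <- paste0("MMM", "ACD", "K", "FGH", "WWWWW")
  mem_seq <- paste0("TT", "ACD", "K", "FGH", "YYYY")
  prots <- c(R = rep_seq, M = mem_seq)
  sites <- rbind(site_row("R", 7L, "negative"),
                 site_row("M", 6L, "positive", 60, .9))
  out <- exclude_aligned_positives("R", c("R", "M"), prots, sites)
  expect_false(any(out$protein_id == "R"))          # matching 7-mer dropped
  # no other members: nothing changes
  out2 <- exclude_aligned_positives("R", "R", prots, sites)
  expect_equal(out2, sites)
  # member positive with a different 7-mer: representative negatives kept
  prots2 <- c(R = rep_seq, M = paste0("TT", "WCD", "K", "FGW", "YYYY"))
  out3 <- exclude_aligned_positives("R", c("R", "M"), prots2, sites)
  expect_true(any(out3$protein_id == "R" & out3$label == "negative"))
})

test_that("conflicting center 7-mers remove windows of both labels", {
  mk <- function(core7, label) {
    data.frame(protein_id = "P", position = 16L, label = label,
               window = paste0(strrep("A", 12), core7, strrep("A", 12)),
               stringsAsFactors = FALSE)
  }
  win <- rbind(mk("CCCKDDD", "positive"), mk("CCCKDDD", "negative"),
               mk("CCCKDDD", "negative"), mk("EEEKFFF", "positive"),
               mk("GGGKHHH", "negative"))
  out <- remove_conflicting_7mers(win)
  expect_equal(nrow(out), 2L)                       # 1 pos + 2 neg removed
  expect_setequal(substr(out$window, 13, 19), c("EEEKFFF", "GGGKHHH"))
  # idempotence
  expect_equal(remove_conflicting_7mers(out), out)
  # disjoint sets unchanged
  win2 <- rbind(mk("EEEKFFF", "positive"), mk("GGGKHHH", "negative"))
  expect_equal(remove_conflicting_7mers(win2), win2)
  # everything shares one 7-mer: both sides empty
  win3 <- rbind(mk("CCCKDDD", "positive"), mk("CCCKDDD", "negative"))
  expect_equal(nrow(remove_conflicting_7mers(win3)), 0L)
  # vector interface
  lst <- remove_conflicting_7mers(win3$window[1], win3$window[2])
  expect_equal(length(lst$positive), 0L)
  expect_equal(length(lst$negative), 0L)
})

test_that("protein-grouped splits never split a protein and are seeded", {
  set.seed(3)
  win <- toy_window_df(n_proteins = 10L, windows_per_protein = 5L)
  sp <- split_by_protein(win, train_fraction = 0.8, seed = 42L)
  expect_equal(length(unique(sp$train$protein_id)), 8L)
  expect_length(intersect(sp$train$protein_id, sp$test$protein_id), 0L)
  sp2 <- split_by_protein(win, train_fraction = 0.8, seed = 42L)
  expect_identical(sp$train, sp2$train)
  # uneven window counts: the split is by protein, never by window
  win2 <- do.call(rbind, lapply(1:5, function(p)
    data.frame(protein_id = sprintf("Q%d", p), position = 16L,
               label = "negative",
               window = random_windows(c(10, 10, 10, 10, 60)[p]),
               stringsAsFactors = FALSE)))
  sp3 <- split_by_protein(win2, train_fraction = 0.8, seed = 7L)
  expect_equal(length(unique(sp3$train$protein_id)), 4L)
  expect_length(intersect(sp3$train$protein_id, sp3$test$protein_id), 0L)
  expect_equal(nrow(sp3$train) + nrow(sp3$test), 100L)
})

test_that("grouped k-fold partitions windows by protein into balanced folds", {
  win <- toy_window_df(n_proteins = 4L, windows_per_protein = 3L)
  folds <- group_kfold(win, k = 2L, seed = 1L)
  expect_length(folds, 2L)
  for (f in folds) {
    expect_equal(length(unique(f$validation$protein_id)), 2L)
    expect_length(intersect(f$train$protein_id, f$validation$protein_id), 0L)
  }
  # validation folds partition all windows
  va <- unlist(lapply(folds, `[[`, "validation_idx"))
  expect_setequal(va, seq_len(nrow(win)))
  expect_equal(anyDuplicated(va), 0L)
  win20 <- toy_window_df(n_proteins = 20L, windows_per_protein = 2L)
  folds10 <- group_kfold(win20, k = 10L, seed = 2L)
  expect_true(all(vapply(folds10, function(f)
    length(unique(f$validation$protein_id)), integer(1)) == 2L))
  expect_error(group_kfold(win, k = 10L, seed = 1L), "at least k")
})

test_that("FASTA, site-table and dataset TSVs round-trip bit-exactly", {
  set.seed(17)
  dir <- withr::local_tempdir()
  seqs <- stats::setNames(vapply(1:5, function(i) random_protein(45),
                                 character(1)), sprintf("SEQ%d", 1:5))
  fa <- file.path(dir, "p.fasta")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
  sites <- rbind(site_row("SEQ1", 3L, "positive", 62.5, 0.91),
                 site_row("SEQ1", 7L, "negative"))
  ts <- file.path(dir, "s.tsv")
  write_sites(sites, ts)
  expect_identical(read_sites(ts), sites)
  win <- toy_window_df(n_proteins = 3L)
  ds <- file.path(dir, "d.tsv")
  write_dataset(win, ds)
  back <- read_dataset(ds)
  rownames(win) <- NULL
  expect_identical(back, win)
})

test_that("the full pipeline keeps one representative per cluster", {
  set.seed(29)
  base <- random_protein(60)
  prots <- c(P1 = base, P2 = mutate_seq(base, 0.05), P3 = random_protein(50),
             P4 = random_protein(55))
  sites <- do.call(rbind, lapply(names(prots), function(id) {
    kpos <- which(strsplit(prots[[id]], "")[[1]] == "K")
    if (!length(kpos)) return(NULL)
    lab <- ifelse(seq_along(kpos) == 1L, "positive", "negative")
    data.frame(protein_id = id, position = kpos, label = lab,
               andromeda_score = ifelse(lab == "positive", 80, NA),
               localization_prob = ifelse(lab == "positive", 0.95, NA),
               stringsAsFactors = FALSE)
  }))
  win <- build_dataset(prots, sites)
  cl <- attr(win, "clusters")
  reps <- vapply(cl, `[[`, character(1), "representative")
  expect_true(all(win$protein_id %in% reps))
  expect_lte(length(unique(win$protein_id)), length(cl))
  # fasta/site validation catches corrupt tables
  bad <- sites
  bad$position[1] <- bad$position[1] + 1L
  expect_error(suppressWarnings(build_dataset(prots, bad)), "not 'K'")
})
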