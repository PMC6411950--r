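## Synthetic proteomes with plantable malonylation motifs.
##
## Sequences are drawn i.i.d. from configurable background frequencies; a
## configured fraction of lysines is labeled positive, and the flanks of every
## labeled site are resampled under position-specific log-odds shifts.  The
## default motif mirrors the sequence pattern around real Kmal sites: glycine
## enriched at positions -4..+2 and lysine depleted at -1..+2 in positives,
## and glutamic acid enriched at -4..+4 (except -1 and +3) around negatives.

#' Default planted motif effects
#'
#' One row per (class, residue, offset): the background odds of `residue` at
#' center-relative `position` are multiplied by `exp(log_odds)` when the
#' site's flanks are resampled.  Position 0 (the central K) is never touched.
#'
#' @param g_lor Log-odds shift for G at -4..+2 in positives (default 3.5).
#' @param k_lor Log-odds shift for K at -1..+2 in positives (default -3.5).
#' @param e_lor Log-odds shift for E at -4..+4 except -1, +3 in negatives
#'   (default 1.75).
#' @return Data.frame `class`, `residue`, `position`, `log_odds`.
#' @export
default_motif_effects <- function(g_lor = 3.5, k_lor = -3.5, e_lor = 1.75) {
  g_pos <- setdiff(-4:2, 0L)
  k_pos <- setdiff(-1:2, 0L)
  e_pos <- setdiff(-4:4, c(-1L, 0L, 3L))
  rbind(
    data.frame(class = "positive", residue = "G", position = g_pos,
               log_odds = g_lor),
    data.frame(class = "positive", residue = "K", position = k_pos,
               log_odds = k_lor),
    data.frame(class = "negative", residue = "E", position = e_pos,
               log_odds = e_lor))
}

#' Configuration for the synthetic proteome generator
#'
#' Defaults define the package's standard strong-effect study conditions:
#' 2000 proteins of mean length 80, uniform residue background, a quarter of
#' lysines positive, the [default_motif_effects()] motif, and 5% of proteins
#' duplicated with point mutations to exercise the clustering step.
#' Identification-score stand-ins for positives are drawn from Normal(110, 40)
#' (Andromeda-like score) and Beta(8, 1.5) (localization probability), so a
#' realistic minority of positives fails the high-confidence filter.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param mean_length Mean protein length, Poisson-distributed (default 80).
#' @param background_frequencies Named numeric vector over the 20 amino acids
#'   (default uniform); normalised internally.
#' @param positive_fraction_of_K Probability that a lysine is a positive site
#'   (default 0.25).
#' @param motif_effects Data.frame as from [default_motif_effects()]; use
#'   `motif_effects = NULL` for the null (motif-free) generator.
#' @param duplication_rate Fraction of proteins duplicated with mutation
#'   (default 0.05).
#' @param mutation_rate Per-residue mutation probability in duplicates
#'   (default 0.05).
#' @param score_mean,score_sd Positive-site score distribution (110, 40).
#' @param locprob_shape1,locprob_shape2 Beta parameters for localization
#'   probability (8, 1.5).
#' @param seed Integer seed.
#' @return Object of class `lemp_synth_config`.
#' @export
synthetic_config <- function(n_proteins = 2000L, mean_length = 80L,
                             background_frequencies = NULL,
                             positive_fraction_of_K = 0.25,
                             motif_effects = default_motif_effects(),
                             duplication_rate = 0.05,
                             mutation_rate = 0.05,
                             score_mean = 110, score_sd = 40,
                             locprob_shape1 = 8, locprob_shape2 = 1.5,
                             seed = 1L) {
  if (is.null(background_frequencies))
    background_frequencies <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(identical(sort(names(background_frequencies)), AA_ALPHABET),
            all(background_frequencies > 0))
  background_frequencies <-
    background_frequencies[AA_ALPHABET] / sum(background_frequencies)
  if (!is.null(motif_effects) && nrow(motif_effects) > 0) {
    stopifnot(all(motif_effects$class %in% c("positive", "negative")),
              all(motif_effects$residue %in% AA_ALPHABET),
              all(motif_effects$position %in% setdiff(-15:15, 0L)))
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 mean_length = as.integer(mean_length),
                 background_frequencies = background_frequencies,
                 positive_fraction_of_K = positive_fraction_of_K,
                 motif_effects = motif_effects,
                 duplication_rate = duplication_rate,
                 mutation_rate = mutation_rate,
                 score_mean = score_mean, score_sd = score_sd,
                 locprob_shape1 = locprob_shape1,
                 locprob_shape2 = locprob_shape2,
                 seed = as.integer(seed)),
            class = "lemp_synth_config")
}

## per-offset shifted residue distributions for one class
shifted_distributions <- function(config, class) {
  me <- config$motif_effects
  bg <- config$background_frequencies
  if (is.null(me)) return(list())
  me <- me[me$class == class, , drop = FALSE]
  out <- list()
  for (p in unique(me$position)) {
    q <- bg
    rows <- me[me$position == p, , drop = FALSE]
    q[rows$residue] <- q[rows$residue] * exp(rows$log_odds)
    out[[as.character(p)]] <- q / sum(q)
  }
  out
}

#' Expected flank residue frequency under the generator
#'
#' Closed-form per-position frequencies the generator targets; used by the
#' calibration checks.
#'
#' @param config Generator configuration.
#' @param class `"positive"` or `"negative"`.
#' @param position Center-relative offset.
#' @return Named numeric vector of 20 expected frequencies.
#' @export
expected_flank_frequencies <- function(config, class, position) {
  sd <- shifted_distributions(config, class)
  q <- sd[[as.character(position)]]
  if (is.null(q)) config$background_frequencies else q
}

#' Generate a synthetic proteome with labeled malonylation sites
#'
#' @param config Configuration from [synthetic_config()].
#' @return Object of class `lemp_synth_truth`: `proteins` (named character
#'   vector), `sites` (data.frame `protein_id`, `position`, `label`,
#'   `andromeda_score`, `localization_prob`, `motif`), and `config`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "lemp_synth_config"))
  for (attempt in 1:10) {
    truth <- with_local_seed(config$seed + (attempt - 1L) * 1000003L,
                             .generate_once(config))
    if (nrow(truth$sites) > 0L) {
      if (attempt > 1L)
        warning("regenerated proteome ", attempt - 1L,
                " time(s) before lysines appeared")
      return(truth)
    }
  }
  stop("configuration produced no lysine sites after 10 attempts")
}

.generate_once <- function(config) {
  bg <- config$background_frequencies
  n <- config$n_proteins
  lens <- pmax(15L, stats::rpois(n, config$mean_length))
  chars <- sample(AA_ALPHABET, sum(lens), replace = TRUE, prob = bg)
  stop_at <- cumsum(lens)
  start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
  ids <- sprintf("SYN%05d", seq_len(n))
  seq_chars <- lapply(seq_len(n), function(i) chars[start_at[i]:stop_at[i]])
  names(seq_chars) <- ids

  dist_pos <- shifted_distributions(config, "positive")
  dist_neg <- shifted_distributions(config, "negative")

  ## offsets whose motif explicitly depletes lysine: there, resampling may
  ## overwrite a neighbouring site's central K (the site is then dropped),
  ## so the depletion is observable in window statistics the way it is in
  ## real modified-site neighbourhoods.  All other offsets protect centers.
  k_dep <- function(me_class) {
    me <- config$motif_effects
    if (is.null(me)) return(integer(0))
    me[me$class == me_class & me$residue == "K" & me$log_odds < 0,
       "position"]
  }
  kdep_pos <- k_dep("positive"); kdep_neg <- k_dep("negative")

  sites <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seq_chars[[i]]
    kpos <- which(s == "K")
    if (length(kpos) == 0L) next
    lab <- ifelse(stats::runif(length(kpos)) < config$positive_fraction_of_K,
                  "positive", "negative")
    centers <- kpos
    for (j in seq_along(kpos)) {
      positive <- lab[j] == "positive"
      dists <- if (positive) dist_pos else dist_neg
      kdep <- if (positive) kdep_pos else kdep_neg
      for (off_chr in names(dists)) {
        off <- as.integer(off_chr)
        p <- kpos[j] + off
        if (p < 1L || p > length(s)) next
        if (p %in% centers && !(off %in% kdep)) next
        s[p] <- sample(AA_ALPHABET, 1L, prob = dists[[off_chr]])
      }
    }
    seq_chars[[i]] <- s
    still_k <- s[kpos] == "K"              # centers overwritten by depletion
    if (!any(still_k)) next
    sites[[i]] <- data.frame(protein_id = ids[i], position = kpos[still_k],
                             label = lab[still_k],
                             motif = (lab[still_k] == "positive" &
                                        length(dist_pos) > 0L) |
                               (lab[still_k] == "negative" &
                                  length(dist_neg) > 0L),
                             stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  if (is.null(sites))
    return(list(proteins = character(0),
                sites = data.frame(protein_id = character(0)),
                config = config))

  ## duplicate-with-mutation to exercise the clustering step
  dup <- which(stats::runif(n) < config$duplication_rate)
  for (i in dup) {
    s <- seq_chars[[i]]
    mut <- which(stats::runif(length(s)) < config$mutation_rate)
    if (length(mut))
      s[mut] <- sample(AA_ALPHABET, length(mut), replace = TRUE, prob = bg)
    did <- paste0(ids[i], "_dup")
    seq_chars[[did]] <- s
    orig <- sites[sites$protein_id == ids[i], , drop = FALSE]
    if (nrow(orig)) {
      still_k <- s[orig$position] == "K"
      if (any(still_k)) {
        ds <- orig[still_k, , drop = FALSE]
        ds$protein_id <- did
        sites <- rbind(sites, ds)
      }
    }
  }

  npos <- sum(sites$label == "positive")
  sites$andromeda_score <- NA_real_
  sites$localization_prob <- NA_real_
  if (npos) {
    sites$andromeda_score[sites$label == "positive"] <-
      pmax(1, stats::rnorm(npos, config$score_mean, config$score_sd))
    sites$localization_prob[sites$label == "positive"] <-
      stats::rbeta(npos, config$locprob_shape1, config$locprob_shape2)
  }
  proteins <- vapply(seq_chars, paste, character(1), collapse = "")
  sites <- sites[order(sites$protein_id, sites$position), ]
  rownames(sites) <- NULL
  structure(list(proteins = proteins,
                 sites = sites[, c("protein_id", "position", "label",
                                   "andromeda_score", "localization_prob",
                                   "motif")],
                 config = config),
            class = "lemp_synth_truth")
}

#' Write a synthetic proteome as FASTA + site TSV (+ config JSON)
#'
#' Files round-trip losslessly through [read_fasta()] and [read_sites()].
#'
#' @param truth Object from [generate_proteome()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "lemp_synth_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "proteins.fasta")
  tsv <- file.path(dir, "sites.tsv")
  cfg <- file.path(dir, "config.json")
  write_fasta(truth$proteins, fa)
  write_sites(truth$sites, tsv)
  cj <- truth$config
  cj$motif_effects <- if (is.null(cj$motif_effects)) NULL else
    as.list(cj$motif_effects)
  jsonlite::write_json(unclass(cj), cfg, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(fasta = fa, sites = tsv, config = cfg)
}

#' EAAC features expected to carry the planted motif signal
#'
#' For each motif (class, residue) the EAAC features `R[s,e]` whose sliding
#' window covers more than half of the motif's offsets.  Used to score the
#' recall of information-gain rankings against the generator's ground truth.
#'
#' By default only enrichment motifs (positive log-odds) contribute:
#' depletion features carry much weaker univariate composition signal (a
#' residue dropping from ~5% to ~1% moves counts far less than one rising to
#' ~50%), so they sit at the margin of a top-30 ranking; the depletion pairs
#' are asserted instead through the two-sample-logo statistics (direction
#' "depleted"), where they are recovered decisively.
#'
#' @param config Generator configuration.
#' @param slide EAAC slide length (default 8).
#' @param window Peptide window length (default 31).
#' @param include_depletion Also include negatively-shifted motifs
#'   (default FALSE).
#' @return Character vector of EAAC feature names.
#' @export
planted_eaac_features <- function(config, slide = 8L, window = 31L,
                                  include_depletion = FALSE) {
  me <- config$motif_effects
  if (!include_depletion && !is.null(me))
    me <- me[me$log_odds > 0, , drop = FALSE]
  if (is.null(me) || nrow(me) == 0L) return(character(0))
  half <- (window - 1L) %/% 2L
  starts <- seq.int(-half, half - slide + 1L)
  out <- character(0)
  for (key in unique(paste(me$class, me$residue))) {
    rows <- me[paste(me$class, me$residue) == key, , drop = FALSE]
    need <- floor(length(rows$position) / 2) + 1L
    for (s in starts) {
      covered <- sum(rows$position >= s & rows$position <= s + slide - 1L)
      if (covered >= need)
        out <- c(out, sprintf("%s[%d,%d]", rows$residue[1], s,
                              s + slide - 1L))
    }
  }
  unique(out)
}
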