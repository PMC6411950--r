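#' @keywords internal
"_PACKAGE"

## Fixed residue ordering used by every encoding and persisted in model
## metadata.  Changing it silently invalidates saved models, so it is a
## package constant, not an option.

#' The 20 standard amino acids in the package's canonical (alphabetical) order
#'
#' All feature columns, one-hot columns and token ids follow this ordering.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Gap symbol used to pad peptide windows at protein termini
#' @format Character scalar.
#' @export
GAP_SYMBOL <- "-"

#' The 21-symbol window alphabet (20 amino acids plus the terminal gap)
#' @format Character vector of length 21.
#' @export
WINDOW_ALPHABET <- c(AA_ALPHABET, GAP_SYMBOL)

## token ids are 0-based: amino acids 0..19 (alphabetical), gap 20
.token_id <- stats::setNames(seq_along(WINDOW_ALPHABET) - 1L, WINDOW_ALPHABET)

#' Relative positions of a peptide window
#'
#' @param window Odd window length (default 31).
#' @return Integer vector `-(window-1)/2 .. +(window-1)/2` (0 = central K).
#' @export
window_positions <- function(window = 31L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  half <- (window - 1L) %/% 2L
  seq.int(-half, half)
}

## split windows (character vector) into an n x W character matrix
window_char_matrix <- function(windows) {
  stopifnot(is.character(windows), length(windows) >= 1L)
  w <- unique(nchar(windows))
  if (length(w) != 1L)
    stop("all windows must have the same length; got lengths ",
         paste(w, collapse = ", "))
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = w, byrow = TRUE)
}

## map rare one-letter codes to the unknown residue 'X'
sanitize_sequence <- function(seq) {
  seq <- toupper(seq)
  gsub("[BZUOJ*]", "X", seq)
}
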