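#' One-hot encode a sequence record
#'
#' Produces the `L x 4` one-hot matrix over channels (A, C, G, U), or
#' `L x 6` when `use_tracks = TRUE`, appending the first-codon-frame and
#' 5'-splice-junction tracks as channels 5 and 6. Channel order is fixed
#' as documented here and relied on throughout the package.
#'
#' @param sequence sequence string over ACGU (or a single-record subset of
#'   a [labeled_seqs()] set).
#' @param frame_track,splice_track optional 0/1 integer vectors of length
#'   `nchar(sequence)`; required when `use_tracks = TRUE`.
#' @param use_tracks append the two annotation channels.
#' @return numeric matrix, `L x 4` or `L x 6`.
#' @export
encode_sequence <- function(sequence, frame_track = NULL, splice_track = NULL,
                            use_tracks = FALSE) {
  if (inherits(sequence, "labeled_seqs")) {
    stopifnot(length(sequence) == 1L)
    frame_track <- sequence$frame_track[[1L]]
    splice_track <- sequence$splice_track[[1L]]
    sequence <- sequence$sequence[1L]
  }
  s <- seq_chars(normalize_rna(sequence))[[1L]]
  L <- length(s)
  n_ch <- if (use_tracks) 6L else 4L
  m <- matrix(0, L, n_ch)
  colnames(m) <- c(RNA_ALPHABET, if (use_tracks) c("frame", "splice"))
  m[cbind(seq_len(L), match(s, RNA_ALPHABET))] <- 1
  if (use_tracks) {
    if (is.null(frame_track) || is.null(splice_track))
      stop("use_tracks = TRUE requires frame_track and splice_track",
           call. = FALSE)
    stopifnot(length(frame_track) == L, length(splice_track) == L)
    m[, 5L] <- frame_track
    m[, 6L] <- splice_track
  }
  m
}

#' One-hot encode a whole set into a batch array
#'
#' Sequences shorter than the longest are right-padded with all-zero
#' channel vectors; the true lengths are kept in the `"lengths"` attribute
#' and padded positions are masked out of the convolutional blocks.
#'
#' @param x a [labeled_seqs()] set.
#' @param use_tracks append annotation channels (requires tracks on `x`).
#' @return numeric array `(n, L_max, C)` with attribute `lengths`.
#' @export
encode_set <- function(x, use_tracks = FALSE) {
  stopifnot(inherits(x, "labeled_seqs"))
  lens <- nchar(x$sequence)
  Lm <- max(lens)
  n <- length(x)
  n_ch <- if (use_tracks) 6L else 4L
  if (use_tracks && (is.null(x$frame_track) || is.null(x$splice_track)))
    stop("use_tracks = TRUE requires frame and splice tracks", call. = FALSE)
  X <- array(0, c(n, Lm, n_ch))
  chars <- seq_chars(x$sequence)
  for (i in seq_len(n)) {
    idx <- match(chars[[i]], RNA_ALPHABET)
    X[cbind(i, seq_len(lens[i]), idx)] <- 1
    if (use_tracks) {
      X[i, seq_len(lens[i]), 5L] <- x$frame_track[[i]]
      X[i, seq_len(lens[i]), 6L] <- x$splice_track[[i]]
    }
  }
  attr(X, "lengths") <- lens
  X
}

#' Decode one-hot nucleotide channels back to a string
#' @param m encoded matrix from [encode_sequence()].
#' @export
decode_sequence <- function(m) {
  keep <- rowSums(m[, 1:4, drop = FALSE]) > 0
  paste(RNA_ALPHABET[max.col(m[keep, 1:4, drop = FALSE], ties.method = "first")],
        collapse = "")
}
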