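#' Construct a motif (position probability matrix)
#'
#' A motif is an `L x 4` column-stochastic matrix over the RNA alphabet
#' (columns A, C, G, U; one row per position), together with a name, the
#' number of sites it was built from (`n_sites`, used as the pseudo-count
#' base by downstream consumers), and a provenance tag.
#'
#' @param name motif name (character scalar).
#' @param matrix numeric `L x 4` matrix; each row must sum to 1 within 1e-9.
#'   Rows deviating by less than `renorm_tol` are renormalized with a
#'   warning; larger deviations are an error.
#' @param n_sites positive integer; number of sequences behind the PPM.
#' @param source one of `"discovered"`, `"library"`, `"annotation"`.
#' @param renorm_tol renormalization tolerance for slightly off rows.
#' @return an object of class `"motif"`.
#' @examples
#' m <- consensus_motif("m6A", "GGACU")
#' motif_ic(m)
#' @export
motif <- function(name, matrix, n_sites = 20L,
                  source = c("library", "discovered", "annotation"),
                  renorm_tol = 1e-3) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L)
    stop("motif matrix must have 4 columns (A,C,G,U)", call. = FALSE)
  L <- nrow(matrix)
  if (L < 4L || L > 64L)
    stop("motif length must be in [4, 64], got ", L, call. = FALSE)
  if (any(matrix < 0))
    stop("motif matrix entries must be non-negative", call. = FALSE)
  rs <- rowSums(matrix)
  dev <- max(abs(rs - 1))
  if (dev > 1e-9) {
    if (dev < renorm_tol) {
      warning("motif '", name, "': rows renormalized (max deviation ",
              signif(dev, 3), ")", call. = FALSE)
      matrix <- matrix / rs
    } else {
      stop("motif '", name, "': rows do not sum to 1 (max deviation ",
           signif(dev, 3), ")", call. = FALSE)
    }
  }
  colnames(matrix) <- RNA_ALPHABET
  rownames(matrix) <- NULL
  structure(list(name = as.character(name), matrix = matrix,
                 n_sites = as.integer(n_sites), source = source),
            class = "motif")
}

#' Build an exact-consensus motif from a string
#'
#' Each position gets probability 1 on the stated base; useful for defined
#' motif libraries (e.g. the m6A consensus `GGACU`).
#'
#' @param name motif name.
#' @param consensus string over A/C/G/U/T.
#' @param n_sites see [motif()].
#' @export
consensus_motif <- function(name, consensus, n_sites = 20L) {
  s <- seq_chars(normalize_rna(consensus, paste0("consensus of ", name)))[[1L]]
  m <- matrix(0, length(s), 4L, dimnames = list(NULL, RNA_ALPHABET))
  m[cbind(seq_along(s), match(s, RNA_ALPHABET))] <- 1
  motif(name, m, n_sites = n_sites, source = "library")
}

#' Per-column information content of a motif
#'
#' Computed against a uniform background (0.25 per base):
#' `IC_j = 2 + sum_b p_jb log2 p_jb` bits.
#'
#' @param m a [motif()].
#' @return numeric vector, one value per motif column (position).
#' @export
motif_ic <- function(m) {
  p <- m$matrix
  plogp <- ifelse(p > 0, p * log2(p), 0)
  2 + rowSums(plogp)
}

#' @export
length.motif <- function(x) nrow(x$matrix)

#' Consensus string of a motif (majority base per position)
#' @param m a [motif()].
#' @export
motif_consensus <- function(m) {
  paste(RNA_ALPHABET[max.col(m$matrix, ties.method = "first")], collapse = "")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s  length %d  source %s  n_sites %d\n",
              x$name, length(x), x$source, x$n_sites))
  cat("  consensus:", motif_consensus(x),
      sprintf(" (total IC %.2f bits)\n", sum(motif_ic(x))))
  invisible(x)
}

#' @export
print.motif_list <- function(x, ...) {
  cat("<motif_list> of", length(x), "motifs:\n")
  for (m in x)
    cat(sprintf("  %-16s L=%-3d %s\n", m$name, length(m), motif_consensus(m)))
  invisible(x)
}

as_motif_list <- function(x) {
  if (inherits(x, "motif")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "motif")))
  structure(x, class = "motif_list")
}

#' Sample a sequence string from a motif PPM
#' @noRd
sample_motif_instance <- function(m) {
  p <- m$matrix
  idx <- apply(p, 1L, function(row) sample.int(4L, 1L, prob = row))
  paste(RNA_ALPHABET[idx], collapse = "")
}
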