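## Column-normalized PPM: each column of t(matrix) centred and scaled so
## that the dot product of two normalized columns is their Pearson
## correlation; zero-variance columns become zero vectors (correlation 0
## by convention).
norm_cols <- function(m) {
  M <- t(m$matrix)            # 4 x L
  M <- sweep(M, 2L, colMeans(M))
  ss <- sqrt(colSums(M * M))
  ss[ss == 0] <- Inf
  sweep(M, 2L, ss, "/")
}

## mean column-Pearson score at every ungapped offset with overlap >= 4;
## offset = position of target column 1 relative to query column 1.
## Ties between equally-correlated offsets are broken toward the longer
## overlap (an infinitesimal bonus used for selection and for the
## permutation-null comparison, never reported): consensus-like motifs
## have duplicate columns, and without the tie-break a column shuffle
## that recreates any 4-column run would count as matching a perfect
## full-length alignment.
offset_scores <- function(Qn, Tn) {
  Lq <- ncol(Qn); Lt <- ncol(Tn)
  D <- crossprod(Qn, Tn)      # Lq x Lt matrix of column correlations
  offsets <- (-(Lt - 4L)):(Lq - 4L)
  scores <- vapply(offsets, function(o) {
    qi <- max(1L, 1L + o):min(Lq, Lt + o)
    mean(D[cbind(qi, qi - o)]) + length(qi) * 1e-9
  }, numeric(1L))
  list(offsets = offsets, scores = scores, D = D,
       overlaps = vapply(offsets, function(o)
         length(max(1L, 1L + o):min(Lq, Lt + o)), integer(1L)))
}

#' Ungapped similarity between two motifs
#'
#' Slides the target over the query (no gaps, no reverse complement —
#' single-stranded RNA) and scores each offset by the mean column-wise
#' Pearson correlation over the overlap; overlaps shorter than 4 columns
#' are not considered. Zero-variance columns (e.g. uniform positions)
#' contribute correlation 0.
#'
#' @param query,target [motif()] objects of length >= 4.
#' @return list with `offset` (position of target column 1 relative to
#'   query column 1, 0-based) and `score` (in `[-1, 1]`) of the best
#'   offset.
#' @export
similarity_score <- function(query, target) {
  stopifnot(length(query) >= 4L, length(target) >= 4L)
  os <- offset_scores(norm_cols(query), norm_cols(target))
  j <- which.max(os$scores)
  list(offset = os$offsets[j],
       score = os$scores[j] - os$overlaps[j] * 1e-9)
}

#' Annotate query motifs against a motif library
#'
#' For each (query, target) pair the observed best-offset similarity is
#' compared with a null in which the query's column order is shuffled
#' (preserving per-column information content); the add-one smoothed
#' permutation p-value is `(c + 1)/(n + 1)` where `c` counts null scores
#' at or above the observed one. q-values are Benjamini-Hochberg across
#' all pairs; hits with `q <= alpha_q` are flagged significant.
#'
#' @param queries motif or list of motifs to annotate.
#' @param library annotation library (list of motifs).
#' @param n_permutations number of column shuffles per pair (>= 1000,
#'   required for resolution at the 0.001 threshold).
#' @param alpha_q significance threshold on the q-value.
#' @param seed permutation seed.
#' @return data frame of class `"similarity_hits"` with columns `query`,
#'   `target`, `offset`, `score`, `p`, `q`, `significant`, ordered by q.
#' @export
annotate_motifs <- function(queries, library, n_permutations = 2000L,
                            alpha_q = 0.001, seed = 1L) {
  queries <- as_motif_list(queries)
  library <- as_motif_list(library)
  if (!length(library)) stop("annotation library is empty", call. = FALSE)
  if (n_permutations < 1000L)
    stop("n_permutations must be >= 1000 for q-value resolution at 0.001",
         call. = FALSE)
  set.seed(seed)
  rows <- vector("list", length(queries) * length(library))
  ri <- 0L
  for (q in queries) {
    Qn <- norm_cols(q)
    Lq <- ncol(Qn)
    ## permutations of the query's columns, shared across targets of this
    ## query so the expensive correlation matrix is reused
    perms <- replicate(n_permutations, sample.int(Lq), simplify = FALSE)
    for (t in library) {
      Tm <- norm_cols(t)
      os <- offset_scores(Qn, Tm)
      j <- which.max(os$scores)
      obs <- os$scores[j]
      ## a column shuffle of the query permutes the rows of D; rescore all
      ## offsets on the permuted correlation matrix
      D <- os$D
      Lt <- ncol(Tm)
      offs <- os$offsets
      idx <- lapply(offs, function(o) {
        qi <- max(1L, 1L + o):min(Lq, Lt + o)
        cbind(qi, qi - o)
      })
      null_scores <- vapply(perms, function(pm) {
        Dp <- D[pm, , drop = FALSE]
        max(vapply(idx, function(ij) mean(Dp[ij]) + nrow(ij) * 1e-9,
                   numeric(1L)))
      }, numeric(1L))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(query = q$name, target = t$name,
                               offset = os$offsets[j],
                               score = obs - os$overlaps[j] * 1e-9,
                               p = (sum(null_scores >= obs) + 1) /
                                 (n_permutations + 1),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha_q
  out <- out[order(out$q, out$p, -out$score), ]
  rownames(out) <- NULL
  class(out) <- c("similarity_hits", "data.frame")
  out
}

#' @export
print.similarity_hits <- function(x, ...) {
  cat(sprintf("<similarity_hits> %d pair(s), %d significant (q <= threshold)\n",
              nrow(x), sum(x$significant)))
  print.data.frame(head(x, 10L), digits = 4)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
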