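#' Extract maximal-activation seqlets for one neuron
#'
#' For every sequence, the receptive-field window with the highest
#' activation of the given neuron is a candidate; the `top_fraction`
#' highest-activation candidates across the dataset (at least `min_n`
#' where available) are returned with their subsequences. Only windows
#' whose full receptive field lies inside the sequence are considered, so
#' every seqlet subsequence has the exact receptive-field width. Ties in
#' activation are broken by (sequence id, start) lexicographic order.
#'
#' @param model trained `"seqfun_model"`.
#' @param layer_index convolutional block index.
#' @param neuron neuron (filter) index within the layer.
#' @param dataset [labeled_seqs()] set.
#' @param top_fraction fraction of per-sequence candidates kept
#'   (default 0.005).
#' @param min_n floor on the number of seqlets kept when enough positive
#'   candidates exist.
#' @param activations optional precomputed [layer_activations()] array for
#'   this layer, to amortize forward passes across neurons.
#' @return data frame with columns `sequence_id`, `start`, `end` (0-based,
#'   half-open, input coordinates), `activation`, `subsequence`; zero rows
#'   if the neuron never activates.
#' @export
extract_seqlets <- function(model, layer_index, neuron, dataset,
                            top_fraction = 0.005, min_n = 200L,
                            activations = NULL) {
  stopifnot(inherits(dataset, "labeled_seqs"), length(dataset) > 0L)
  rf <- receptive_field(model, layer_index)
  if (is.null(activations))
    activations <- layer_activations(model, layer_index, dataset)
  acts <- activations[, , neuron, drop = FALSE]
  dim(acts) <- dim(activations)[1:2]
  Lp <- ncol(acts)
  lens <- nchar(dataset$sequence)
  ## layer positions (0-based) whose receptive field is fully interior
  pos0 <- 0:(Lp - 1L)
  starts <- pos0 * rf$stride + rf$offset
  keep_pos <- starts >= 0L
  if (!any(keep_pos)) stop("no interior window at layer ", layer_index,
                           call. = FALSE)
  acts <- acts[, keep_pos, drop = FALSE]
  starts <- starts[keep_pos]
  ## per sequence: maximal interior window within its own length
  n <- nrow(acts)
  ends_all <- starts + rf$width
  best_val <- numeric(n); best_start <- integer(n)
  for (i in seq_len(n)) {
    ok <- ends_all <= lens[i]
    if (!any(ok)) { best_val[i] <- -Inf; next }
    v <- acts[i, ok]
    j <- which.max(v)  # first maximum: lowest start wins ties
    best_val[i] <- v[j]
    best_start[i] <- starts[ok][j]
  }
  cand <- data.frame(sequence_id = dataset$id, start = best_start,
                     activation = best_val, stringsAsFactors = FALSE)
  cand <- cand[is.finite(cand$activation) & cand$activation > 0, ]
  if (!nrow(cand))
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), activation = numeric(),
                      subsequence = character(), stringsAsFactors = FALSE))
  n_keep <- min(nrow(cand),
                max(ceiling(top_fraction * nrow(cand)), min_n))
  ord <- order(-cand$activation, cand$sequence_id, cand$start)
  cand <- cand[ord[seq_len(n_keep)], ]
  cand$end <- cand$start + rf$width
  cand$subsequence <- substr(dataset$sequence[match(cand$sequence_id,
                                                    dataset$id)],
                             cand$start + 1L, cand$end)
  rownames(cand) <- NULL
  cand[, c("sequence_id", "start", "end", "activation", "subsequence")]
}

one_hot_seqlets <- function(subseqs) {
  W <- nchar(subseqs[1L])
  chars <- seq_chars(subseqs)
  X <- matrix(0, length(subseqs), 4L * W)
  for (i in seq_along(chars))
    X[i, (seq_len(W) - 1L) * 4L + match(chars[[i]], RNA_ALPHABET)] <- 1
  X
}

ppm_from_seqlets <- function(subseqs, name, n_sites_total = length(subseqs)) {
  W <- nchar(subseqs[1L])
  n <- length(subseqs)
  counts <- matrix(0, W, 4L)
  chars <- seq_chars(subseqs)
  for (s in chars)
    counts[cbind(seq_len(W), match(s, RNA_ALPHABET))] <-
      counts[cbind(seq_len(W), match(s, RNA_ALPHABET))] + 1
  pc <- 1 / sqrt(n)  # pseudo-count, split evenly over the 4 bases
  p <- (counts + pc / 4) / (n + pc)
  motif(name, p, n_sites = n, source = "discovered")
}

#' Decouple a neuron's seqlets into one or more motifs
#'
#' A convolutional neuron can be multifaceted: it responds to several
#' distinct sequence patterns, and averaging all its seqlets into one PPM
#' blurs them. Seqlets are one-hot encoded and k-means clustered for
#' k = 1..`max_clusters`; k is chosen by mean silhouette width (k = 1 when
#' the best silhouette is below 0.1), and each cluster becomes a PPM by
#' position-wise frequency with pseudo-count `1/sqrt(n)`.
#'
#' @param seqlets data frame from [extract_seqlets()] (>= 20 rows).
#' @param max_clusters maximum number of facets to consider.
#' @param name_prefix motif name prefix (`<prefix>C<k>` per cluster).
#' @param seed k-means seed.
#' @return object of class `"neuron_interpretation"`: list with
#'   `clusters` (each: `motif`, `weight`, `mean_activation`), `silhouette`
#'   and `k`.
#' @export
decouple_and_build_motifs <- function(seqlets, max_clusters = 4L,
                                      name_prefix = "N", seed = 1L) {
  if (nrow(seqlets) < 20L)
    stop("need at least 20 seqlets to interpret a neuron (got ",
         nrow(seqlets), "): insufficient activation support", call. = FALSE)
  X <- one_hot_seqlets(seqlets$subsequence)
  n <- nrow(X)
  kmax <- min(max_clusters, n - 1L)
  set.seed(seed)
  best <- list(k = 1L, sil = -Inf, cl = rep(1L, n))
  if (kmax >= 2L) {
    dx <- dist(X)
    for (k in 2:kmax) {
      km <- suppressWarnings(
        tryCatch(kmeans(X, centers = k, nstart = 5L, iter.max = 50L),
                 error = function(e) NULL))
      if (is.null(km) || length(unique(km$cluster)) < k) next
      sil <- mean(cluster::silhouette(km$cluster, dx)[, "sil_width"])
      if (sil > best$sil) best <- list(k = k, sil = sil, cl = km$cluster)
    }
  }
  if (best$sil < 0.1) best <- list(k = 1L, sil = best$sil, cl = rep(1L, n))
  clusters <- lapply(seq_len(best$k), function(ci) {
    idx <- best$cl == ci
    list(motif = ppm_from_seqlets(seqlets$subsequence[idx],
                                  paste0(name_prefix, "C", ci)),
         weight = mean(idx),
         mean_activation = mean(seqlets$activation[idx]),
         member_subsequences = seqlets$subsequence[idx])
  })
  ## heaviest facet first
  clusters <- clusters[order(-vapply(clusters, `[[`, 0, "weight"))]
  structure(list(clusters = clusters, k = best$k,
                 silhouette = if (is.finite(best$sil)) best$sil else NA_real_,
                 n_seqlets = n),
            class = "neuron_interpretation")
}

#' @export
print.neuron_interpretation <- function(x, ...) {
  cat(sprintf("<neuron_interpretation> %d facet(s) from %d seqlets (silhouette %.3f)\n",
              x$k, x$n_seqlets,
              if (is.na(x$silhouette)) NA else x$silhouette))
  for (cl in x$clusters)
    cat(sprintf("  %-14s weight %.2f  consensus %s\n", cl$motif$name,
                cl$weight, motif_consensus(cl$motif)))
  invisible(x)
}

#' Interpret every neuron of a convolutional layer
#'
#' Runs [extract_seqlets()] + [decouple_and_build_motifs()] over all
#' filters of one layer; neurons with insufficient activation support are
#' skipped.
#'
#' @inheritParams extract_seqlets
#' @inheritParams decouple_and_build_motifs
#' @param neurons neuron indices (default all).
#' @return named list of `"neuron_interpretation"` objects (names
#'   `L<layer>N<neuron>`); skipped neurons are absent.
#' @export
interpret_layer <- function(model, layer_index, dataset, neurons = NULL,
                            top_fraction = 0.005, min_n = 200L,
                            max_clusters = 4L, seed = 1L) {
  acts <- layer_activations(model, layer_index, dataset)
  if (is.null(neurons)) neurons <- seq_len(dim(acts)[3L])
  out <- list()
  for (nr in neurons) {
    sq <- extract_seqlets(model, layer_index, nr, dataset,
                          top_fraction = top_fraction, min_n = min_n,
                          activations = acts)
    if (nrow(sq) < 20L) next
    nm <- sprintf("L%dN%d", layer_index, nr)
    out[[nm]] <- decouple_and_build_motifs(sq, max_clusters = max_clusters,
                                           name_prefix = nm, seed = seed)
  }
  out
}

## disjoint high-information subregions: maximal runs of columns with
## IC >= gap_ic, at least min_width long, whose mean IC reaches min_ic.
## The per-column floor keeps two nearby motifs from being bridged into
## one region by a low-information gap.
high_ic_regions <- function(ic, min_ic = 0.5, min_width = 4L, gap_ic = 0.3) {
  L <- length(ic)
  if (L < min_width) return(list())
  r <- rle(ic >= gap_ic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_width)
  regs <- lapply(keep, function(i) c(starts[i], ends[i]))
  Filter(function(rg) mean(ic[rg[1L]:rg[2L]]) >= min_ic, regs)
}

empty_pairs <- function() {
  data.frame(motif_a = character(), motif_b = character(),
             neuron = character(), cluster = integer(),
             evidence = character(), score_a = numeric(),
             score_b = numeric(), stringsAsFactors = FALSE)
}

## per-seqlet presence of a log-odds instance of each library motif
seqlet_presence <- function(subseqs, library, threshold_fraction = 0.8) {
  ds <- labeled_seqs(sprintf("q%06d", seq_along(subseqs)), subseqs,
                     rep(0, length(subseqs)))
  vapply(library, function(m) {
    inst <- scan_motif_instances(ds, m, threshold_fraction)
    ds$id %in% inst$sequence_id
  }, logical(length(subseqs)))
}

#' Propose motif pairs from deep-layer neuron interpretations
#'
#' A deep convolutional neuron whose receptive field spans two motifs can
#' encode their combination. Two kinds of evidence emit a pair (A, B)
#' from a cluster of a deep-layer interpretation:
#'
#' * *PPM subregions*: the cluster PPM contains two disjoint
#'   high-information subregions (mean column IC >= `min_ic` bits over a
#'   run of at least `min_width` columns), each matching a distinct
#'   library motif (best ungapped column-Pearson score >= `min_score`).
#'   This resolves combinations whose two parts sit at fixed relative
#'   positions.
#' * *Seqlet co-occurrence*: the positions of the partner motif often
#'   vary across the seqlets (spacing is free in most training data), in
#'   which case the pooled PPM shows only the anchoring motif. The
#'   cluster's member seqlets are therefore scanned directly: a pair is
#'   emitted when instances of two distinct library motifs occur
#'   *jointly in the same seqlet* in at least `min_frac` of the members
#'   (the default, 0.15, is about five-fold the chance rate of a partner
#'   motif landing in a receptive-field-sized window of random
#'   sequence).
#'   Joint presence is required so that a multifaceted neuron whose
#'   facets are two single motifs — some seqlets carrying one, some the
#'   other — does not masquerade as a combination detector.
#'
#' @param interpretations list from [interpret_layer()] on a deep layer.
#' @param library list of annotated [motif()]s to match against.
#' @param min_ic,min_width high-information subregion definition (bits,
#'   columns).
#' @param min_score minimal similarity score for a subregion-library match.
#' @param min_frac minimal seqlet fraction for co-occurrence evidence.
#' @return data frame with columns `motif_a`, `motif_b` (library names,
#'   `motif_a < motif_b`), `neuron`, `cluster`, `evidence`, `score_a`,
#'   `score_b` (similarity scores or seqlet fractions, per evidence
#'   route); deduplicated per pair, keeping the best-supported proposal.
#' @export
candidate_pairs_from_deep_neurons <- function(interpretations, library,
                                              min_ic = 0.5, min_width = 4L,
                                              min_score = 0.6,
                                              min_frac = 0.15) {
  library <- as_motif_list(library)
  lib_names <- vapply(library, `[[`, "", "name")
  rows <- list()
  add_row <- function(ta, tb, sa, sb, nm, ci, ev) {
    o <- order(c(ta, tb))
    rows[[length(rows) + 1L]] <<-
      data.frame(motif_a = c(ta, tb)[o[1L]], motif_b = c(ta, tb)[o[2L]],
                 neuron = nm, cluster = ci, evidence = ev,
                 score_a = c(sa, sb)[o[1L]], score_b = c(sa, sb)[o[2L]],
                 stringsAsFactors = FALSE)
  }
  for (nm in names(interpretations)) {
    interp <- interpretations[[nm]]
    for (ci in seq_along(interp$clusters)) {
      cl <- interp$clusters[[ci]]
      m <- cl$motif
      ## route 1: two aligned high-IC subregions
      regions <- high_ic_regions(motif_ic(m), min_ic, min_width)
      hits <- list()
      if (length(regions) >= 2L) {
        hits <- lapply(regions, function(rg) {
          sub <- m$matrix[rg[1L]:rg[2L], , drop = FALSE]
          if (nrow(sub) < 4L) return(NULL)
          subm <- motif(paste0(m$name, "r"), sub, source = "discovered")
          sc <- vapply(library, function(t)
            similarity_score(subm, t)$score, numeric(1L))
          j <- which.max(sc)
          if (sc[j] < min_score) NULL
          else list(target = lib_names[j], score = sc[j])
        })
        hits <- Filter(Negate(is.null), hits)
      }
      if (length(hits) >= 2L) {
        targets <- vapply(hits, `[[`, "", "target")
        scores <- vapply(hits, `[[`, 0, "score")
        for (a in seq_along(hits)) for (b in seq_along(hits)) {
          if (a >= b || targets[a] == targets[b]) next
          add_row(targets[a], targets[b], scores[a], scores[b], nm, ci,
                  "ppm_subregions")
        }
      }
      ## route 2: joint co-occurrence of two motifs within member seqlets
      if (length(cl$member_subsequences) >= 20L) {
        pres <- seqlet_presence(cl$member_subsequences, library)
        for (a in seq_along(lib_names)) for (b in seq_along(lib_names)) {
          if (a >= b) next
          joint <- mean(pres[, a] & pres[, b])
          if (joint >= min_frac)
            add_row(lib_names[a], lib_names[b], joint, joint, nm, ci,
                    "cooccurrence")
        }
      }
    }
  }
  if (!length(rows)) return(empty_pairs())
  out <- do.call(rbind, rows)
  ## keep the best-supported proposal per unordered pair
  out <- out[order(paste(out$motif_a, out$motif_b),
                   -(out$score_a + out$score_b)), ]
  out <- out[!duplicated(paste(out$motif_a, out$motif_b)), ]
  rownames(out) <- NULL
  out
}

#' Collect all motifs from a set of neuron interpretations
#' @param interpretations list from [interpret_layer()].
#' @return a `motif_list`.
#' @export
interpretation_motifs <- function(interpretations) {
  as_motif_list(unlist(lapply(interpretations, function(it)
    lapply(it$clusters, `[[`, "motif")), recursive = FALSE))
}
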