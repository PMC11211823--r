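#' Scan a dataset for instances of a motif
#'
#' Log-odds scan of the motif PPM against a uniform background (0.25 per
#' base) with pseudo-count 0.01 added to each probability. Positions
#' scoring at least `threshold_fraction` of the maximum attainable score
#' are instances; overlapping instances of the same motif are merged
#' keeping the best scorer. Degenerate motifs (total information content
#' below `min_ic` bits) are rejected: every position of a near-uniform
#' PPM would attain the maximum score.
#'
#' @param dataset [labeled_seqs()] set.
#' @param motif a [motif()].
#' @param threshold_fraction fraction of the maximum attainable log-odds.
#' @param min_ic minimum total information content (bits).
#' @return data frame with `sequence_id`, `motif_name`, `start`, `end`
#'   (0-based half-open) and `match_score` (log2 odds).
#' @export
scan_motif_instances <- function(dataset, motif, threshold_fraction = 0.8,
                                 min_ic = 2) {
  stopifnot(inherits(dataset, "labeled_seqs"))
  if (sum(motif_ic(motif)) < min_ic)
    stop("motif '", motif$name, "' is too degenerate to scan (total IC ",
         signif(sum(motif_ic(motif)), 3), " < ", min_ic, " bits)",
         call. = FALSE)
  lw <- log2((motif$matrix + 0.01) / (1 + 0.04) / 0.25)  # W x 4
  W <- nrow(lw)
  lens <- nchar(dataset$sequence)
  if (W > min(lens))
    stop("motif longer than the shortest sequence", call. = FALSE)
  max_score <- sum(apply(lw, 1L, max))
  thr <- threshold_fraction * max_score
  chars <- seq_chars(dataset$sequence)
  rows <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    b <- match(chars[[i]], RNA_ALPHABET)
    np <- lens[i] - W + 1L
    sc <- numeric(np)
    for (w in seq_len(W))
      sc <- sc + lw[w, b[w:(w + np - 1L)]]
    hit <- which(sc >= thr)
    if (!length(hit)) next
    ## merge overlapping hits, best score wins
    keep <- integer()
    last_end <- -1L
    for (h in hit) {
      if (h > last_end) {
        keep <- c(keep, h)
        last_end <- h + W - 1L
      } else if (sc[h] > sc[keep[length(keep)]]) {
        keep[length(keep)] <- h
        last_end <- h + W - 1L
      }
    }
    rows[[i]] <- data.frame(sequence_id = dataset$id[i],
                            motif_name = motif$name,
                            start = keep - 1L, end = keep - 1L + W,
                            match_score = sc[keep],
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(sequence_id = character(), motif_name = character(),
                      start = integer(), end = integer(),
                      match_score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scramble a motif instance within a sequence
#'
#' Replaces the bases in `[start, end)` by an i.i.d. uniform random ACGU
#' string of the same length, leaving the rest of the sequence untouched.
#'
#' @param sequence sequence string.
#' @param instance list or one-row data frame with `start`, `end`
#'   (0-based half-open).
#' @param n_replicates number of independent scrambles.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return character vector of `n_replicates` scrambled sequences.
#' @export
scramble_instance <- function(sequence, instance, n_replicates = 8L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- instance$start; e <- instance$end
  L <- nchar(sequence)
  stopifnot(s >= 0, e <= L, e > s)
  w <- e - s
  vapply(seq_len(n_replicates), function(i) {
    repl <- paste(sample(RNA_ALPHABET, w, replace = TRUE), collapse = "")
    paste0(substr(sequence, 1L, s), repl, substr(sequence, e + 1L, L))
  }, character(1L))
}

scramble_two <- function(sequence, inst_a, inst_b, n_replicates) {
  ## both windows scrambled within one replicate (no reseeding)
  va <- scramble_instance(sequence, inst_a, n_replicates)
  vapply(va, function(x) scramble_instance(x, inst_b, 1L), character(1L),
         USE.NAMES = FALSE)
}

#' Combinatorial mutagenesis quadruple for one sequence
#'
#' Model predictions for the intact sequence (`o`), with motif B
#' scrambled (`a`), with motif A scrambled (`b`), and with both scrambled
#' (`n`, the null sequence); the three scrambled values are means over
#' `n_replicates` independent scrambles, which damps the variance the
#' random replacement injects into the paired test.
#'
#' @param model trained `"seqfun_model"`.
#' @param sequence sequence string.
#' @param instance_a,instance_b instance rows (`start`, `end`); windows
#'   must not overlap.
#' @param n_replicates scrambles per condition.
#' @param seed RNG seed.
#' @return one-row data frame with `o`, `a`, `b`, `n`.
#' @export
mutagenesis_quadruple <- function(model, sequence, instance_a, instance_b,
                                  n_replicates = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (instance_a$start < instance_b$end && instance_b$start < instance_a$end)
    stop("instances overlap; pair skipped on this sequence", call. = FALSE)
  variants <- c(sequence,
                scramble_instance(sequence, instance_b, n_replicates),
                scramble_instance(sequence, instance_a, n_replicates),
                scramble_two(sequence, instance_a, instance_b, n_replicates))
  pred <- predict(model, variants)
  r <- n_replicates
  data.frame(o = pred[1L],
             a = mean(pred[2L:(1L + r)]),
             b = mean(pred[(2L + r):(1L + 2L * r)]),
             n = mean(pred[(2L + 2L * r):(1L + 3L * r)]))
}

#' Paired Wilcoxon test for epistasis over mutagenesis quadruples
#'
#' Compares the joint effect `x_i = (o - n)_i` with the sum of marginal
#' effects `y_i = (a - n)_i + (b - n)_i` by a two-sided Wilcoxon
#' signed-rank test on the paired differences. Direction is
#' `joint_greater` when the median difference is positive and p <= alpha,
#' `joint_smaller` when negative, otherwise `none`.
#'
#' @param quadruples data frame with columns `o`, `a`, `b`, `n` (>= 10
#'   rows).
#' @param alpha significance level.
#' @return list with `p_value`, `direction`, `median_difference`.
#' @export
epistasis_test <- function(quadruples, alpha = 0.05) {
  if (nrow(quadruples) < 10L)
    stop("need >= 10 quadruples for the paired test (got ",
         nrow(quadruples), ")", call. = FALSE)
  d <- (quadruples$o - quadruples$n) -
    ((quadruples$a - quadruples$n) + (quadruples$b - quadruples$n))
  if (all(d == 0))
    return(list(p_value = 1, direction = "none", median_difference = 0))
  p <- suppressWarnings(wilcox.test(d)$p.value)
  md <- median(d)
  dir <- if (p <= alpha && md > 0) "joint_greater"
  else if (p <= alpha && md < 0) "joint_smaller" else "none"
  list(p_value = p, direction = dir, median_difference = md)
}

#' Classify a motif-pair interaction
#'
#' Implements the judgment rules relating the signs of the two motifs'
#' individual contributions and the outcome of the joint-versus-marginal
#' comparison: same-sign pairs are synergistic when the joint effect
#' significantly overshoots the additive expectation in the direction of
#' the shared effect (positive/positive and joint_greater, or
#' negative/negative and joint_smaller) and antagonistic when it
#' undershoots; no significant deviation is additive. For opposite-sign
#' pairs, with A the positive-effect motif, a joint effect significantly
#' above A's marginal effect, or significantly below B's, is sign
#' epistasis; when neither comparison triggers the pair is additive, and
#' when both trigger the pair is reported as sign epistasis with
#' `both_triggered = TRUE`.
#'
#' @param sign_a,sign_b `"positive"` or `"negative"` motif effect signs.
#' @param direction `"joint_greater"`, `"joint_smaller"` or `"none"` from
#'   [epistasis_test()] (same-sign pairs).
#' @param mixed_vs_a,mixed_vs_b for mixed signs: outcome of testing
#'   (o - n) against (a - n) and against (b - n) respectively, each
#'   `"greater"`, `"smaller"` or `"none"` (a and b here refer to the
#'   positive-sign motif A and negative-sign motif B after normalization).
#' @return list with `interaction_class` in
#'   {synergistic, antagonistic, additive, sign} and `both_triggered`.
#' @export
classify_interaction <- function(sign_a, sign_b, direction = "none",
                                 mixed_vs_a = "none", mixed_vs_b = "none") {
  stopifnot(sign_a %in% c("positive", "negative"),
            sign_b %in% c("positive", "negative"))
  if (sign_a == sign_b) {
    cls <- if (direction == "none") "additive"
    else if (sign_a == "positive") {
      if (direction == "joint_greater") "synergistic" else "antagonistic"
    } else {
      if (direction == "joint_greater") "antagonistic" else "synergistic"
    }
    return(list(interaction_class = cls, both_triggered = FALSE))
  }
  ## mixed signs; comparisons are stated for A = positive-effect motif
  trig_a <- mixed_vs_a == "greater"   # (o-n) significantly > (a-n)
  trig_b <- mixed_vs_b == "smaller"   # (o-n) significantly < (b-n)
  if (trig_a || trig_b)
    list(interaction_class = "sign", both_triggered = trig_a && trig_b)
  else list(interaction_class = "additive", both_triggered = FALSE)
}

## best instance per sequence for a scan result
best_instance_per_sequence <- function(inst) {
  inst <- inst[order(inst$sequence_id, -inst$match_score, inst$start), ]
  inst[!duplicated(inst$sequence_id), ]
}

#' Mutagenesis epistasis test for one motif pair over a dataset
#'
#' Finds all sequences carrying non-overlapping instances of both motifs
#' (best-scoring instance of each per sequence; sequences where the two
#' windows overlap are skipped and counted), computes the mutagenesis
#' quadruple for each (batched through the model), runs the paired
#' Wilcoxon test, and classifies the interaction. For mixed-sign pairs
#' the two sign-rule comparisons (o vs a and o vs b, the shared n
#' cancelling) are each tested the same way.
#'
#' @param model trained `"seqfun_model"`.
#' @param dataset [labeled_seqs()] set.
#' @param motif_a,motif_b [motif()] objects.
#' @param sign_a,sign_b effect signs from contribution analysis.
#' @param threshold_fraction scan threshold (see [scan_motif_instances()]).
#' @param n_replicates scrambles per condition.
#' @param max_sequences cap on co-occurrence instances used (subsampled
#'   deterministically from `seed`).
#' @param alpha significance level.
#' @param seed RNG seed for scrambles and subsampling.
#' @return one-row data frame (class `epistasis_result`) with identifying
#'   columns, `n_instances`, `n_overlap_skipped`, o/a/b/n medians,
#'   `p_value`, `direction`, `interaction_class`, `both_triggered`.
#' @export
test_motif_pair <- function(model, dataset, motif_a, motif_b,
                            sign_a = "positive", sign_b = "positive",
                            threshold_fraction = 0.8, n_replicates = 8L,
                            max_sequences = 200L, alpha = 0.05, seed = 1L,
                            instances_a = NULL, instances_b = NULL) {
  set.seed(seed)
  ia <- if (is.null(instances_a)) best_instance_per_sequence(
    scan_motif_instances(dataset, motif_a, threshold_fraction))
  else instances_a
  ib <- if (is.null(instances_b)) best_instance_per_sequence(
    scan_motif_instances(dataset, motif_b, threshold_fraction))
  else instances_b
  shared <- intersect(ia$sequence_id, ib$sequence_id)
  ia <- ia[match(shared, ia$sequence_id), ]
  ib <- ib[match(shared, ib$sequence_id), ]
  overlap <- ia$start < ib$end & ib$start < ia$end
  n_skip <- sum(overlap)
  shared <- shared[!overlap]
  ia <- ia[!overlap, ]; ib <- ib[!overlap, ]
  empty <- data.frame(motif_a = motif_a$name, motif_b = motif_b$name,
                      sign_a = sign_a, sign_b = sign_b,
                      n_instances = length(shared),
                      n_overlap_skipped = n_skip,
                      o = NA_real_, a = NA_real_, b = NA_real_, n = NA_real_,
                      p_value = NA_real_, direction = "none",
                      interaction_class = "untested",
                      both_triggered = FALSE, stringsAsFactors = FALSE)
  if (length(shared) < 10L) return(empty)
  if (length(shared) > max_sequences) {
    pick <- sort(sample.int(length(shared), max_sequences))
    shared <- shared[pick]; ia <- ia[pick, ]; ib <- ib[pick, ]
  }
  seqs <- dataset$sequence[match(shared, dataset$id)]
  ## build all variants, predict in one batch
  r <- n_replicates
  variants <- character(length(shared) * (1L + 3L * r))
  k <- 0L
  for (i in seq_along(shared)) {
    variants[k + 1L] <- seqs[i]
    variants[k + 1L + seq_len(r)] <-
      scramble_instance(seqs[i], ib[i, ], r)
    variants[k + 1L + r + seq_len(r)] <-
      scramble_instance(seqs[i], ia[i, ], r)
    variants[k + 1L + 2L * r + seq_len(r)] <-
      scramble_two(seqs[i], ia[i, ], ib[i, ], r)
    k <- k + 1L + 3L * r
  }
  pred <- predict(model, variants)
  per <- 1L + 3L * r
  quads <- data.frame(
    sequence_id = shared,
    o = pred[seq_along(shared) * per - per + 1L],
    a = vapply(seq_along(shared), function(i)
      mean(pred[(i - 1L) * per + 1L + seq_len(r)]), numeric(1L)),
    b = vapply(seq_along(shared), function(i)
      mean(pred[(i - 1L) * per + 1L + r + seq_len(r)]), numeric(1L)),
    n = vapply(seq_along(shared), function(i)
      mean(pred[(i - 1L) * per + 1L + 2L * r + seq_len(r)]), numeric(1L)),
    stringsAsFactors = FALSE)
  et <- epistasis_test(quads, alpha = alpha)
  if (sign_a == sign_b) {
    cls <- classify_interaction(sign_a, sign_b, et$direction)
  } else {
    ## normalize so A is the positive-effect motif
    if (sign_a == "negative") {
      tmp <- quads$a; quads$a <- quads$b; quads$b <- tmp
    }
    test_side <- function(d) {
      if (all(d == 0)) return("none")
      p <- suppressWarnings(wilcox.test(d)$p.value)
      if (p <= alpha && median(d) > 0) "greater"
      else if (p <= alpha && median(d) < 0) "smaller" else "none"
    }
    cls <- classify_interaction("positive", "negative",
                                mixed_vs_a = test_side(quads$o - quads$a),
                                mixed_vs_b = test_side(quads$o - quads$b))
    if (sign_a == "negative") {  # restore reporting order
      tmp <- quads$a; quads$a <- quads$b; quads$b <- tmp
    }
  }
  out <- empty
  out$n_instances <- nrow(quads)
  out$o <- median(quads$o); out$a <- median(quads$a)
  out$b <- median(quads$b); out$n <- median(quads$n)
  out$p_value <- et$p_value
  out$direction <- et$direction
  out$interaction_class <- cls$interaction_class
  out$both_triggered <- cls$both_triggered
  attr(out, "quadruples") <- quads
  out
}

#' Epistasis analysis over a set of candidate motif pairs
#'
#' @param model trained `"seqfun_model"`.
#' @param dataset [labeled_seqs()] set.
#' @param motifs named list of [motif()]s (the candidates).
#' @param pairs data frame with columns `motif_a`, `motif_b` (names into
#'   `motifs`), e.g. from [candidate_pairs_from_deep_neurons()], or
#'   `"all"` for every unordered pair.
#' @param signs named character vector of effect signs per motif name
#'   (from contribution analysis).
#' @param threshold_fraction scan threshold; instances are scanned once
#'   per motif and shared across pairs.
#' @param adjust apply Benjamini-Hochberg across pairs (off by default;
#'   raw paired-Wilcoxon p-values are reported either way).
#' @param ... passed to [test_motif_pair()].
#' @return data frame of class `"epistasis_results"`, one row per pair.
#' @export
epistasis_analysis <- function(model, dataset, motifs, pairs = "all",
                               signs, adjust = FALSE,
                               threshold_fraction = 0.8, ...) {
  motifs <- as_motif_list(motifs)
  mn <- vapply(motifs, `[[`, "", "name")
  names(motifs) <- mn
  if (identical(pairs, "all")) {
    cmb <- t(utils::combn(mn, 2L))
    pairs <- data.frame(motif_a = cmb[, 1L], motif_b = cmb[, 2L],
                        stringsAsFactors = FALSE)
  }
  used <- unique(c(pairs$motif_a, pairs$motif_b))
  inst <- lapply(stats::setNames(used, used), function(m)
    best_instance_per_sequence(
      scan_motif_instances(dataset, motifs[[m]], threshold_fraction)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$motif_a[i]; b <- pairs$motif_b[i]
    test_motif_pair(model, dataset, motifs[[a]], motifs[[b]],
                    sign_a = unname(signs[a]), sign_b = unname(signs[b]),
                    threshold_fraction = threshold_fraction,
                    instances_a = inst[[a]], instances_b = inst[[b]], ...)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    tested <- !is.na(out$p_value)
    out$p_adjusted <- NA_real_
    out$p_adjusted[tested] <- p.adjust(out$p_value[tested], method = "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("epistasis_results", "data.frame")
  out
}

#' Motif interaction map
#'
#' Symmetric matrix over motifs summarizing pairwise interaction classes.
#' Pairs never proposed/tested are distinguished (`absent`) from pairs
#' tested without a significant interaction (`additive`).
#'
#' @param results an `"epistasis_results"` data frame.
#' @param motif_names motif universe for the axes (default: all motifs in
#'   `results`).
#' @return object of class `"interaction_map"`: character matrix plus
#'   tallies; has a `plot()` method.
#' @export
interaction_map <- function(results, motif_names = NULL) {
  if (is.null(motif_names))
    motif_names <- sort(unique(c(results$motif_a, results$motif_b)))
  M <- matrix("absent", length(motif_names), length(motif_names),
              dimnames = list(motif_names, motif_names))
  diag(M) <- ""
  if (nrow(results)) for (i in seq_len(nrow(results))) {
    cls <- results$interaction_class[i]
    if (cls == "untested") next
    M[results$motif_a[i], results$motif_b[i]] <- cls
    M[results$motif_b[i], results$motif_a[i]] <- cls
  }
  counts <- table(factor(results$interaction_class,
                         levels = c("synergistic", "antagonistic",
                                    "additive", "sign", "untested")))
  structure(list(matrix = M, counts = counts, n_pairs = nrow(results)),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("<interaction_map>", nrow(x$matrix), "motifs;",
      x$n_pairs, "pair(s) proposed\n")
  print(x$counts)
  invisible(x)
}

#' @export
plot.interaction_map <- function(x, ...) {
  M <- x$matrix
  n <- nrow(M)
  lv <- c("absent", "additive", "synergistic", "antagonistic", "sign")
  cols <- c(absent = "white", additive = "steelblue",
            synergistic = "firebrick", antagonistic = "goldenrod2",
            sign = "darkorchid")
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0.5, n + 0.5),
                 xaxt = "n", yaxt = "n", xlab = "", ylab = "", asp = 1, ...)
  graphics::axis(1L, seq_len(n), colnames(M), las = 2, cex.axis = 0.8)
  graphics::axis(2L, seq_len(n), rev(rownames(M)), las = 2, cex.axis = 0.8)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- M[i, j]
    if (i == j || v == "absent") next
    graphics::points(j, n + 1L - i, pch = 21, cex = 2.2,
                     bg = cols[[v]])
  }
  graphics::legend("topright", legend = lv[-1], pt.bg = cols[lv[-1]],
                   pch = 21, bty = "n", cex = 0.8)
  invisible(x)
}
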