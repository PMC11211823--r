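#' Split a dataset by whether sequences activate a neuron
#'
#' A sequence activates the neuron iff its maximum positional activation
#' exceeds `gamma` times the dataset-wide maximum activation of that
#' neuron. The post-ReLU ">0" criterion is too permissive for deep
#' layers, hence the relative threshold (default 0.5).
#'
#' @param model trained `"seqfun_model"`.
#' @param layer_index,neuron neuron address.
#' @param dataset [labeled_seqs()] set.
#' @param gamma relative activation threshold in (0, 1).
#' @param activations optional precomputed [layer_activations()] array.
#' @return list with `activating` and `non_activating` id vectors; the two
#'   partition the dataset.
#' @export
activation_split <- function(model, layer_index, neuron, dataset,
                             gamma = 0.5, activations = NULL) {
  stopifnot(gamma > 0, gamma < 1)
  if (is.null(activations))
    activations <- layer_activations(model, layer_index, dataset)
  a <- activations[, , neuron, drop = FALSE]
  dim(a) <- dim(activations)[1:2]
  mx <- apply(a, 1L, max)
  top <- max(mx)
  if (top <= 0)
    stop("neuron ", neuron, " at layer ", layer_index,
         " is dead (never activates) on this dataset", call. = FALSE)
  act <- mx > gamma * top
  list(activating = dataset$id[act], non_activating = dataset$id[!act])
}

#' Test a neuron's contribution to the predicted property
#'
#' Compares the labels of activating and non-activating sequences with a
#' two-sided Mann-Whitney U test (labels are often non-Gaussian, e.g.
#' bimodal ribosome-load distributions). Direction is positive when the
#' activating group's median label is significantly higher, negative when
#' lower, and none otherwise. Groups smaller than 10 yield direction
#' `"none"` with an `underpowered` flag instead of an error.
#'
#' @param split list from [activation_split()].
#' @param dataset the same [labeled_seqs()] set (provides labels).
#' @param alpha significance level applied to the (adjusted) p-value.
#' @return one-row data frame: `n_activating`, `n_nonactivating`,
#'   `median_difference` (label units), `p_value`, `q_value` (equal to p
#'   for a single test; adjusted by [neuron_contributions()]),
#'   `effect_direction`, `underpowered`.
#' @export
contribution_test <- function(split, dataset, alpha = 0.05) {
  la <- dataset$label[dataset$id %in% split$activating]
  ln <- dataset$label[dataset$id %in% split$non_activating]
  md <- median(la) - median(ln)
  if (length(la) < 10L || length(ln) < 10L)
    return(data.frame(n_activating = length(la), n_nonactivating = length(ln),
                      median_difference = md, p_value = NA_real_,
                      q_value = NA_real_, effect_direction = "none",
                      underpowered = TRUE, stringsAsFactors = FALSE))
  p <- suppressWarnings(wilcox.test(la, ln)$p.value)
  dir <- if (p <= alpha && md > 0) "positive"
  else if (p <= alpha && md < 0) "negative" else "none"
  data.frame(n_activating = length(la), n_nonactivating = length(ln),
             median_difference = md, p_value = p, q_value = p,
             effect_direction = dir, underpowered = FALSE,
             stringsAsFactors = FALSE)
}

#' Contribution analysis for many neurons of one layer
#'
#' Runs [activation_split()] + [contribution_test()] per neuron and
#' applies Benjamini-Hochberg correction across all neurons tested in the
#' run; directions are then re-derived from the adjusted q-values at
#' `alpha`.
#'
#' @inheritParams activation_split
#' @param neurons neuron indices (default all).
#' @param alpha significance level on q.
#' @return data frame, one row per testable neuron, with `layer_index` and
#'   `neuron_index` columns prepended; dead neurons are skipped.
#' @export
neuron_contributions <- function(model, layer_index, dataset, neurons = NULL,
                                 gamma = 0.5, alpha = 0.05) {
  acts <- layer_activations(model, layer_index, dataset)
  if (is.null(neurons)) neurons <- seq_len(dim(acts)[3L])
  rows <- list()
  for (nr in neurons) {
    sp <- tryCatch(activation_split(model, layer_index, nr, dataset,
                                    gamma = gamma, activations = acts),
                   error = function(e) NULL)
    if (is.null(sp)) next
    r <- contribution_test(sp, dataset, alpha = alpha)
    r <- cbind(data.frame(layer_index = layer_index, neuron_index = nr), r)
    rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out$effect_direction <- ifelse(
    tested & out$q_value <= alpha & out$median_difference > 0, "positive",
    ifelse(tested & out$q_value <= alpha & out$median_difference < 0,
           "negative", "none"))
  rownames(out) <- NULL
  out
}
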