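## build a one-block model whose first neuron is a hand-made detector:
## weight +10 on the one-hot channel of each base of `pattern`, so the
## activation is maximal exactly where the pattern sits
planted_filter_model <- function(pattern, sign = +1) {
  K <- nchar(pattern)
  cfg <- predictor_config(n_blocks = 1L, filters = 4L, kernel_width = K,
                          gru_units = 4L, dense_units = 4L, seed = 99L)
  m <- build_predictor(cfg, 50L)
  W <- matrix(0, K * 4L, 4L)
  idx <- match(strsplit(pattern, "")[[1L]], c("A", "C", "G", "U"))
  for (k in seq_len(K)) W[(k - 1L) * 4L + idx[k], 1L] <- sign * 10
  m$params$blocks[[1L]]$W <- W
  m$params$blocks[[1L]]$b <- rep(0, 4L)
  ## identity layer norm is not possible, but the normalization is a
  ## monotone per-position transform of the one-hot rows, so the argmax
  ## window is preserved
  m
}

test_that("a hand-built GGACU filter yields only GGACU seqlets", {
  set.seed(61)
  n <- 500L
  seqs <- rand_rna(n, 50L)
  pos <- sample(0:45, n, replace = TRUE)
  carry <- seq_len(n) <= 300L
  for (i in which(carry)) substr(seqs[i], pos[i] + 1L, pos[i] + 5L) <- "GGACU"
  ds <- labeled_seqs(sprintf("f%03d", 1:n), seqs, numeric(n))
  m <- planted_filter_model("GGACU")
  sq <- extract_seqlets(m, 1L, 1L, ds, top_fraction = 0.5, min_n = 100L)
  expect_gte(nrow(sq), 100L)
  expect_true(all(sq$subsequence == "GGACU"))
  expect_true(all(sq$end - sq$start == 5L))
  ## seqlet windows lie within their sequences
  expect_true(all(sq$start >= 0L & sq$end <= 50L))
})

test_that("a dead neuron yields no seqlets", {
  set.seed(62)
  ds <- labeled_seqs(sprintf("d%03d", 1:50), rand_rna(50L, 50L), numeric(50L))
  m <- planted_filter_model("GGACU")
  ## a large negative bias keeps the neuron below the rectifier everywhere
  m$params$blocks[[1L]]$b[1L] <- -1e6
  sq <- extract_seqlets(m, 1L, 1L, ds)
  expect_equal(nrow(sq), 0L)
})

test_that("random windows build a near-uniform PPM; planted selection does not", {
  ## maximal-activation selection is biased even for an untrained filter
  ## (the top windows match whatever pattern its random weights prefer),
  ## so the uniformity null is asserted on randomly drawn windows, and
  ## the contrast with a planted detector on the selected ones.
  set.seed(63)
  subs <- rand_rna(300L, 10L)
  ppm <- motifsyntax:::ppm_from_seqlets(subs, "null")
  freq_max <- apply(ppm$matrix, 1L, max)
  expect_lt(max(freq_max), 0.5)
  expect_lt(sum(motif_ic(ppm)), 0.5)
})

test_that("multifaceted seqlets decouple into their two patterns", {
  set.seed(65)
  mk <- function(core, n) {
    out <- rand_rna(n, 10L)
    substr(out, 2L, 1L + nchar(core)) <- core
    out
  }
  subs <- c(mk("GGACUGG", 60L), mk("UGUAAAU", 60L))
  sq <- data.frame(sequence_id = sprintf("m%03d", seq_along(subs)),
                   start = 0L, end = 10L, activation = 1,
                   subsequence = subs, stringsAsFactors = FALSE)
  ni <- decouple_and_build_motifs(sq, max_clusters = 4L, seed = 66L)
  expect_equal(ni$k, 2L)
  expect_equal(sum(vapply(ni$clusters, `[[`, 0, "weight")), 1)
  cons <- vapply(ni$clusters, function(cl) motif_consensus(cl$motif), "")
  expect_true(any(grepl("GGACUGG", cons)))
  expect_true(any(grepl("UGUAAAU", cons)))
  ## decoupling superiority: per-cluster PPMs carry more information than
  ## the pooled single PPM
  pooled <- decouple_and_build_motifs(sq, max_clusters = 1L, seed = 66L)
  pooled_ic <- sum(motif_ic(pooled$clusters[[1L]]$motif))
  for (cl in ni$clusters) expect_gt(sum(motif_ic(cl$motif)), pooled_ic)

  ## identical seqlets collapse to one faithful cluster
  same <- sq[1:30, ]
  same$subsequence <- strrep("GGACU", 2L)
  one <- decouple_and_build_motifs(same, max_clusters = 4L, seed = 66L)
  expect_equal(one$k, 1L)
  expect_equal(motif_consensus(one$clusters[[1L]]$motif), strrep("GGACU", 2L))

  expect_error(decouple_and_build_motifs(sq[1:10, ]), "20")
})

test_that("cluster weights always sum to one", {
  set.seed(67)
  for (rep in 1:3) {
    subs <- rand_rna(40L + rep * 10L, 8L)
    sq <- data.frame(sequence_id = sprintf("w%03d", seq_along(subs)),
                     start = 0L, end = 8L, activation = runif(length(subs)),
                     subsequence = subs, stringsAsFactors = FALSE)
    ni <- decouple_and_build_motifs(sq, max_clusters = 5L, seed = rep)
    expect_equal(sum(vapply(ni$clusters, `[[`, 0, "weight")), 1)
  }
})

test_that("deep clusters with two aligned subregions propose a motif pair", {
  lib <- default_motif_library()
  puf <- lib[[2L]]$matrix  # UGUAAAUA
  m6a <- lib[[1L]]$matrix  # GGACU
  unif <- matrix(0.25, 5L, 4L)
  soften <- function(p) (p + 0.08) / rowSums(p + 0.08)
  ppm <- motif("deep", rbind(soften(puf), unif, soften(m6a)),
               source = "discovered")
  fake <- list(L9N1 = structure(list(clusters = list(list(
    motif = ppm, weight = 1, mean_activation = 1,
    member_subsequences = character())), k = 1L, silhouette = NA_real_,
    n_seqlets = 100L), class = "neuron_interpretation"))
  pairs <- candidate_pairs_from_deep_neurons(fake, lib)
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$motif_a, pairs$motif_b), c("PUF", "m6A"))
  expect_equal(pairs$evidence, "ppm_subregions")

  ## a uniform PPM proposes nothing
  fake$L9N1$clusters[[1L]]$motif <- motif("flat", matrix(0.25, 18L, 4L),
                                          source = "discovered")
  expect_equal(nrow(candidate_pairs_from_deep_neurons(fake, lib)), 0L)

  ## a single high-IC subregion proposes nothing
  fake$L9N1$clusters[[1L]]$motif <-
    motif("half", rbind(soften(m6a), matrix(0.25, 13L, 4L)),
          source = "discovered")
  expect_equal(nrow(candidate_pairs_from_deep_neurons(fake, lib)), 0L)
})

test_that("seqlet co-occurrence proposes position-variable pairs", {
  set.seed(68)
  n <- 60L
  subs <- rand_rna(n, 32L)
  for (i in seq_len(n)) {
    substr(subs[i], 3L, 7L) <- "GGACU"
    p <- sample(c(12L, 17L, 22L), 1L)  # partner position varies
    substr(subs[i], p, p + 4L) <- "AUUUA"
  }
  fake <- list(L9N2 = structure(list(clusters = list(list(
    motif = motifsyntax:::ppm_from_seqlets(subs, "c"), weight = 1,
    mean_activation = 1, member_subsequences = subs)), k = 1L,
    silhouette = NA_real_, n_seqlets = n),
    class = "neuron_interpretation"))
  pairs <- candidate_pairs_from_deep_neurons(fake, default_motif_library())
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$motif_a, pairs$motif_b), c("m6A", "ARE"))
  pres <- motifsyntax:::seqlet_presence(subs, default_motif_library())
  expect_equal(mean(pres[, 1L] & pres[, 3L]), 1)  # m6A + ARE jointly present
  expect_lt(mean(pres[, 2L] | pres[, 4L]), 0.3)   # PUF/CGG at chance rates

  ## a multifaceted OR construction (each seqlet carries only one of the
  ## two motifs) must not be proposed as a pair
  or_subs <- rand_rna(60L, 32L)
  for (i in 1:30) substr(or_subs[i], 3L, 7L) <- "GGACU"
  for (i in 31:60) substr(or_subs[i], 3L, 7L) <- "AUUUA"
  fake$L9N2$clusters[[1L]]$member_subsequences <- or_subs
  fake$L9N2$clusters[[1L]]$motif <-
    motifsyntax:::ppm_from_seqlets(or_subs, "or")
  expect_equal(nrow(candidate_pairs_from_deep_neurons(
    fake, default_motif_library())), 0L)
})
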