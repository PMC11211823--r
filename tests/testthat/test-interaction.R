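m6a <- function() default_motif_library()[[1L]]

test_that("log-odds scanning finds planted and tandem instances", {
  set.seed(91)
  s <- rand_rna(1L, 50L)
  ## avoid chance hits, then plant at 17
  s <- gsub("GGACU", "GGAAU", s, fixed = TRUE)
  substr(s, 18L, 22L) <- "GGACU"
  ds <- labeled_seqs("one", s, 0)
  inst <- scan_motif_instances(ds, m6a())
  expect_equal(inst$start, 17L)
  expect_equal(inst$end, 22L)

  tandem <- labeled_seqs("two", "GGACUAAGGACU", 0)
  inst2 <- scan_motif_instances(tandem, m6a())
  expect_equal(inst2$start, c(0L, 7L))

  unif <- motif("flat", matrix(0.25, 5L, 4L))
  expect_error(scan_motif_instances(ds, unif), "degenerate")
})

test_that("scrambling only touches the window and erases the instance", {
  set.seed(92)
  s <- paste0(strrep("A", 10L), "GGACU", strrep("C", 10L))
  inst <- list(start = 10L, end = 15L)
  reps <- scramble_instance(s, inst, n_replicates = 10000L, seed = 93L)
  expect_true(all(nchar(reps) == nchar(s)))
  expect_true(all(substr(reps, 1L, 10L) == strrep("A", 10L)))
  expect_true(all(substr(reps, 16L, 25L) == strrep("C", 10L)))
  ## uniform composition inside the window: 0.25 each +- 3 SE
  chars <- unlist(strsplit(substr(reps, 11L, 15L), ""))
  freq <- table(factor(chars, levels = c("A", "C", "G", "U"))) / length(chars)
  se <- sqrt(0.25 * 0.75 / length(chars))
  expect_true(all(abs(freq - 0.25) < 3 * se))
  ## the motif survives a scramble only rarely
  ds <- labeled_seqs(sprintf("r%05d", 1:2000), reps[1:2000], numeric(2000L))
  still <- unique(scan_motif_instances(ds, m6a())$sequence_id)
  expect_lt(length(still) / 2000, 0.05)
})

test_that("mutagenesis quadruples recover oracle effect structure", {
  set.seed(94)
  s <- rand_rna(1L, 50L)
  s <- gsub("GGACU", "GGAAU", s, fixed = TRUE)
  s <- gsub("AUUUA", "AUGUA", s, fixed = TRUE)
  substr(s, 6L, 10L) <- "GGACU"
  substr(s, 31L, 35L) <- "AUUUA"
  ia <- list(start = 5L, end = 10L)
  ib <- list(start = 30L, end = 35L)

  const <- oracle_model(function(x) rep(7, length(x)))
  q <- mutagenesis_quadruple(const, s, ia, ib, seed = 95L)
  expect_equal(unlist(q), c(o = 7, a = 7, b = 7, n = 7))

  addi <- presence_oracle(c("GGACU", "AUUUA"), c(2, 1))
  qa <- mutagenesis_quadruple(addi, s, ia, ib, n_replicates = 64L, seed = 95L)
  d <- (qa$o - qa$n) - ((qa$a - qa$n) + (qa$b - qa$n))
  expect_lt(abs(d), 0.15)  # additive: epistasis ~ 0 within scramble noise
  expect_equal(qa$o, 3)

  epi <- presence_oracle(c("GGACU", "AUUUA"), c(2, 1), e_ab = 1.5)
  qe <- mutagenesis_quadruple(epi, s, ia, ib, n_replicates = 64L, seed = 95L)
  de <- (qe$o - qe$n) - ((qe$a - qe$n) + (qe$b - qe$n))
  expect_equal(de, 1.5, tolerance = 0.15)

  expect_error(mutagenesis_quadruple(const, s, list(start = 5L, end = 10L),
                                     list(start = 8L, end = 13L)),
               "overlap")
})

test_that("the paired signed-rank test matches exact enumeration", {
  quads <- data.frame(o = rep(0, 12L), a = 0, b = 0, n = 0)
  expect_equal(epistasis_test(quads)$direction, "none")
  expect_error(epistasis_test(quads[1:5, ]), "10")

  ## 10 all-positive differences: enumerate all 2^10 sign assignments of
  ## the rank-sum statistic for the exact two-sided p
  set.seed(96)
  d <- sort(runif(10L, 0.5, 1))
  quads2 <- data.frame(o = 2 * d, a = d, b = d, n = d)  # (o-n)-(a+b-2n) = d
  et <- epistasis_test(quads2)
  ranks <- rank(abs(d))
  V <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 10L))
  Vnull <- as.matrix(signs) %*% ranks
  p_exact <- 2 * min(mean(Vnull >= V), mean(Vnull <= V))
  expect_equal(p_exact, 2 / 1024)
  expect_equal(et$p_value, p_exact)
  expect_equal(et$direction, "joint_greater")
})

test_that("the epistasis null rejection rate stays near alpha", {
  set.seed(97)
  rejected <- vapply(1:1000, function(i) {
    d <- rnorm(30L)
    quads <- data.frame(o = d, a = numeric(30L), b = numeric(30L),
                        n = numeric(30L))
    epistasis_test(quads)$direction != "none"
  }, logical(1L))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(rejected), 0.05 + 2 * se)
})

test_that("interaction classification reproduces the judgment rules exactly", {
  ## hand-coded truth table: sign_a, sign_b, joint-vs-sum direction -> class
  same_sign <- expand.grid(a = c("positive", "negative"),
                           b = c("positive", "negative"),
                           dir = c("joint_greater", "joint_smaller", "none"),
                           stringsAsFactors = FALSE)
  expected <- function(a, b, dir) {
    if (dir == "none") return("additive")
    if (a == b) {
      up <- dir == "joint_greater"
      pos <- a == "positive"
      if (up == pos) "synergistic" else "antagonistic"
    } else NA_character_
  }
  for (i in seq_len(nrow(same_sign))) {
    a <- same_sign$a[i]; b <- same_sign$b[i]; dir <- same_sign$dir[i]
    if (a != b) next
    expect_equal(classify_interaction(a, b, dir)$interaction_class,
                 expected(a, b, dir), label = paste(a, b, dir))
  }
  ## mixed signs: (o-n) > (a-n) or (o-n) < (b-n) significant -> sign
  combos <- expand.grid(va = c("greater", "none"), vb = c("smaller", "none"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    got <- classify_interaction("positive", "negative",
                                mixed_vs_a = combos$va[i],
                                mixed_vs_b = combos$vb[i])
    trig <- combos$va[i] == "greater" || combos$vb[i] == "smaller"
    expect_equal(got$interaction_class, if (trig) "sign" else "additive")
    expect_equal(got$both_triggered,
                 combos$va[i] == "greater" && combos$vb[i] == "smaller")
  }
  expect_error(classify_interaction("up", "down"), "positive")
})

test_that("pair testing is symmetric in the motif labels", {
  set.seed(98)
  n <- 80L
  seqs <- rand_rna(n, 50L)
  for (i in seq_len(n)) {
    substr(seqs[i], 3L, 7L) <- "GGACU"
    substr(seqs[i], 30L, 34L) <- "AUUUA"
  }
  ds <- labeled_seqs(sprintf("y%03d", 1:n), seqs, numeric(n))
  lib <- default_motif_library()
  orac <- presence_oracle(c("GGACU", "AUUUA"), c(1, 1), e_ab = 1)
  r1 <- test_motif_pair(orac, ds, lib[[1L]], lib[[3L]], "positive",
                        "positive", seed = 7L)
  r2 <- test_motif_pair(orac, ds, lib[[3L]], lib[[1L]], "positive",
                        "positive", seed = 7L)
  expect_equal(r1$interaction_class, "synergistic")
  expect_equal(r2$interaction_class, r1$interaction_class)
  expect_equal(r1$direction, r2$direction)
})

test_that("the interaction map distinguishes absent from additive pairs", {
  empty <- interaction_map(
    structure(data.frame(motif_a = character(), motif_b = character(),
                         interaction_class = character(),
                         stringsAsFactors = FALSE),
              class = c("epistasis_results", "data.frame")))
  expect_equal(nrow(empty$matrix), 0L)

  res <- structure(data.frame(
    motif_a = c("m6A", "ARE"), motif_b = c("PUF", "CGG"),
    interaction_class = c("synergistic", "additive"),
    stringsAsFactors = FALSE), class = c("epistasis_results", "data.frame"))
  mp <- interaction_map(res, motif_names = c("ARE", "CGG", "PUF", "m6A"))
  expect_equal(mp$matrix["m6A", "PUF"], "synergistic")
  expect_equal(mp$matrix["PUF", "m6A"], "synergistic")
  expect_equal(mp$matrix["ARE", "CGG"], "additive")
  expect_equal(mp$matrix["m6A", "ARE"], "absent")
  ## legend tallies equal result-list tallies
  expect_equal(unname(mp$counts["synergistic"]), 1L)
  expect_equal(unname(mp$counts["additive"]), 1L)
  expect_equal(mp$n_pairs, 2L)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(mp); grDevices::dev.off()
  expect_true(file.exists(f))
})
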