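#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases, maps T to U, and validates that only A/C/G/U remain.
#' All sequences held by the package are RNA-sense (`ACGU`); DNA-sense
#' input (`ACGT`) is accepted and silently converted.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages (e.g. a record id).
#' @return character vector over `ACGU`.
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1L], regexpr("[^ACGU]", x[bad][1L]))
    stop("invalid character '", ch, "' in ", what,
         if (sum(bad) > 1L) paste0(" (and ", sum(bad) - 1L, " more records)"),
         call. = FALSE)
  }
  if (any(!nzchar(x))) stop("empty ", what, " not allowed", call. = FALSE)
  x
}

#' Split sequences into one-character vectors
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

## FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
## result-table headers and for deterministic data splits.
fnv1a32 <- function(s) {
  xor32 <- function(a, b) {
    # xor on doubles holding 32-bit values (bitwXor needs < 2^31)
    hi <- bitwXor(a %/% 65536, b %/% 65536)
    lo <- bitwXor(a %% 65536, b %% 65536)
    hi * 65536 + lo
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- xor32(h, b)
    ## 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  h
}

config_hash <- function(config) {
  sprintf("%08x", fnv1a32(paste(deparse(config), collapse = "")))
}

#' Write a result table as TSV with a provenance header
#'
#' Adds a single comment line recording the package version and a hash of
#' the run configuration, then the tab-separated table with column names.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param config optional configuration object folded into the header hash.
#' @export
write_result_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# motifsyntax %s; config_hash=%s",
                     as.character(packageVersion("motifsyntax")),
                     config_hash(config)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
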