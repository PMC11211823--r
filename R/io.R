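#' Construct a labeled sequence set
#'
#' The universal dataset object: RNA sequences with one scalar label each
#' (mean ribosome load, half-life z-score, or a synthetic label) and
#' optional per-position binary annotation tracks (first-codon-frame and
#' 5' splice-junction, as used by half-life predictors).
#'
#' @param id character vector of unique record ids.
#' @param sequence character vector over A/C/G/U (T accepted, mapped to U).
#' @param label numeric vector of labels, in dataset units.
#' @param frame_track,splice_track optional lists of 0/1 integer vectors,
#'   each the same length as its sequence.
#' @return object of class `"labeled_seqs"`.
#' @export
labeled_seqs <- function(id, sequence, label,
                         frame_track = NULL, splice_track = NULL) {
  id <- unname(as.character(id))
  if (anyDuplicated(id))
    stop("duplicate sequence id: '", id[duplicated(id)][1L], "'", call. = FALSE)
  sequence <- unname(normalize_rna(sequence))
  label <- unname(as.numeric(label))
  if (length(id) != length(sequence) || length(id) != length(label))
    stop("id, sequence and label must have equal length", call. = FALSE)
  if (any(!is.finite(label))) stop("labels must be finite", call. = FALSE)
  check_track <- function(tr, nm) {
    if (is.null(tr)) return(NULL)
    stopifnot(length(tr) == length(sequence))
    tr <- lapply(tr, as.integer)
    ok <- mapply(function(t, s) length(t) == nchar(s) && all(t %in% 0:1),
                 tr, sequence)
    if (!all(ok))
      stop(nm, " must be 0/1 vectors matching sequence lengths (record ",
           which(!ok)[1L], ")", call. = FALSE)
    tr
  }
  structure(list(id = id, sequence = sequence, label = label,
                 frame_track = check_track(frame_track, "frame_track"),
                 splice_track = check_track(splice_track, "splice_track")),
            class = "labeled_seqs")
}

#' @export
length.labeled_seqs <- function(x) length(x$id)

#' @export
`[.labeled_seqs` <- function(x, i) {
  labeled_seqs(x$id[i], x$sequence[i], x$label[i],
               if (!is.null(x$frame_track)) x$frame_track[i],
               if (!is.null(x$splice_track)) x$splice_track[i])
}

#' @export
print.labeled_seqs <- function(x, ...) {
  L <- nchar(x$sequence)
  cat(sprintf("<labeled_seqs> %d records; length %s; label range [%.3g, %.3g]%s\n",
              length(x),
              if (length(unique(L)) == 1L) as.character(L[1L])
              else sprintf("%d-%d", min(L), max(L)),
              min(x$label), max(x$label),
              if (!is.null(x$frame_track)) "; with tracks" else ""))
  invisible(x)
}

#' @export
as.data.frame.labeled_seqs <- function(x, ...) {
  data.frame(id = x$id, sequence = x$sequence, label = x$label,
             stringsAsFactors = FALSE)
}

track_to_string <- function(tr) vapply(tr, paste, "", collapse = "")
string_to_track <- function(s) lapply(strsplit(s, "", fixed = TRUE), as.integer)

#' Read a labeled sequence set from FASTA or TSV
#'
#' FASTA headers carry the label as a `label=<float>` token
#' (`>id label=3.0`). TSV files need columns `id`, `sequence`, `label`,
#' and may carry optional `frame_track`/`splice_track` columns as 0/1
#' strings of the same length as the sequence. T is mapped to U and case
#' is folded on read.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return a [labeled_seqs()] set.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (!length(ss)) stop("no FASTA records in ", path, call. = FALSE)
    toks <- strsplit(trimws(names(ss)), "\\s+")
    ids <- vapply(toks, `[[`, "", 1L)
    labels <- vapply(seq_along(toks), function(i) {
      lab <- grep("^label=", toks[[i]], value = TRUE)
      if (!length(lab))
        stop("FASTA record ", i, " ('", ids[i],
             "'): missing 'label=' token", call. = FALSE)
      v <- suppressWarnings(as.numeric(sub("^label=", "", lab[1L])))
      if (is.na(v))
        stop("FASTA record ", i, ": malformed label '", lab[1L], "'",
             call. = FALSE)
      v
    }, numeric(1L))
    labeled_seqs(ids, as.character(ss), labels)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                     colClasses = "character")
    need <- c("id", "sequence", "label")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("TSV ", path, " lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    labeled_seqs(df$id, df$sequence, df$label,
                 if ("frame_track" %in% names(df))
                   string_to_track(df$frame_track),
                 if ("splice_track" %in% names(df))
                   string_to_track(df$splice_track))
  }
}

#' Write a labeled sequence set to FASTA or TSV
#'
#' @param x a [labeled_seqs()] set.
#' @inheritParams read_sequences
#' @export
write_sequences <- function(x, path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  if (format == "fasta") {
    out <- character(2L * length(x))
    out[c(TRUE, FALSE)] <- sprintf(">%s label=%.17g", x$id, x$label)
    out[c(FALSE, TRUE)] <- x$sequence
    writeLines(out, path)
  } else {
    df <- as.data.frame(x)
    if (!is.null(x$frame_track)) df$frame_track <- track_to_string(x$frame_track)
    if (!is.null(x$splice_track)) df$splice_track <- track_to_string(x$splice_track)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## ---- MEME minimal motif format -------------------------------------------
## No installed package reads MEME minimal motif text, so the dialect
## (version 4/5 header, optional ALPHABET/strands/background lines, MOTIF +
## letter-probability matrix blocks) is parsed here directly.

#' Read motifs from a MEME minimal-format file
#'
#' Supports MEME version 4/5 minimal motif files. An `ALPHABET= ACGT` file
#' is accepted; columns are reported over ACGU (T and U occupy the same
#' column slot, so matrices are unchanged). Rows deviating from sum 1 by
#' less than 1e-3 are renormalized with a warning; larger deviations error.
#'
#' @param path MEME motif file.
#' @param source provenance tag for the imported motifs.
#' @return a list of [motif()] objects (class `motif_list`).
#' @export
read_meme_motifs <- function(path, source = "annotation") {
  lines <- trimws(readLines(path))
  if (!length(grep("^MEME version [45]", lines)))
    stop(path, ": missing 'MEME version 4|5' header", call. = FALSE)
  alpha_ln <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alpha_ln)) {
    alpha <- gsub("\\s", "", sub("^ALPHABET=", "", alpha_ln[1L]))
    if (!alpha %in% c("ACGU", "ACGT"))
      stop(path, ": unsupported alphabet '", alpha, "'", call. = FALSE)
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop(path, ": no MOTIF blocks", call. = FALSE)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    name <- strsplit(lines[starts[i]], "\\s+")[[1L]][2L]
    j <- starts[i] + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j]))
      j <- j + 1L
    if (j > length(lines))
      stop(path, ": motif '", name, "' has no letter-probability matrix",
           call. = FALSE)
    hdr <- lines[j]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    ns <- if (grepl("nsites=", hdr))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)) else 20L
    if (is.na(w)) stop(path, ": motif '", name, "': malformed matrix header",
                       call. = FALSE)
    rows <- lines[seq.int(j + 1L, j + w)]
    mat <- t(vapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(strsplit(r, "\\s+")[[1L]]))
      if (length(v) != 4L || anyNA(v))
        stop(path, ": motif '", name, "': malformed matrix row '", r, "'",
             call. = FALSE)
      v
    }, numeric(4L), USE.NAMES = FALSE))
    out[[i]] <- motif(name, mat, n_sites = ns, source = source)
  }
  as_motif_list(out)
}

#' Write motifs to a MEME minimal-format file
#'
#' @param motifs a [motif()] or list of motifs.
#' @param path output path.
#' @param background background frequencies written to the header.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4L)) {
  motifs <- as_motif_list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               sprintf("Background letter frequencies"),
               paste(sprintf("%s %.5f", RNA_ALPHABET, background),
                     collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      length(m), m$n_sites), con)
    writeLines(apply(m$matrix, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' YAML when the `yaml` package is available, otherwise a minimal
#' `key: value` parser. Configurations drive the command-line interface;
#' every stochastic operation's seed is a required key there.
#'
#' @param path config file.
#' @export
read_config <- function(path) {
  if (requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1L], collapse = ":"))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- trimws(vapply(kv, `[[`, "", 1L))
  out
}
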