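# Reading and writing motif matrices (TRANSFAC flat file, JASPAR PFM)
# and FASTA / tabular outputs.

#' Parse motif matrices from TRANSFAC or JASPAR text
#'
#' TRANSFAC flat-file blocks look like
#' \preformatted{ID  V.EXAMPLE_01
#' P0   A   C   G   T
#' 01  10   0   0   0  A
#' ...
#' XX
#' //}
#' JASPAR PFM records are a `>id name` header followed by four base rows,
#' either `A [ 4 19 0 ]` or four bare numeric rows in A, C, G, T order.
#'
#' Rows are interpreted as counts unless every row already sums to 1, in
#' which case they are taken as frequencies.  The default pseudocount is 1
#' for count matrices and 0 for frequency matrices; pass `pseudocount`
#' to override.  A `CC cutoff=...` comment line inside a TRANSFAC block
#' (as written by [write_motifs()]) restores the matrix cutoff.
#'
#' @param text either a file path or a character vector of lines.
#' @param format `"auto"` (default), `"transfac"` or `"jaspar"`.
#' @param pseudocount optional pseudocount overriding the defaults above.
#' @return A list of [pwm()] objects (empty input gives an empty list).
#' @export
parse_motifs <- function(text, format = c("auto", "transfac", "jaspar"),
                         pseudocount = NULL) {
  format <- match.arg(format)
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("\r$", "", lines)
  nonblank <- lines[trimws(lines) != ""]
  if (length(nonblank) == 0L) return(list())
  if (format == "auto") {
    format <- if (any(grepl("^>", nonblank))) "jaspar" else "transfac"
  }
  if (format == "transfac") parse_transfac(lines, pseudocount)
  else parse_jaspar(lines, pseudocount)
}

finish_pwm <- function(id, rows, cutoff, pseudocount, line_no) {
  mat <- do.call(rbind, rows)
  if (is.null(mat) || nrow(mat) == 0L)
    stop(sprintf("motif block '%s' near line %d has no matrix rows", id, line_no))
  is_freq <- all(abs(rowSums(mat) - 1) < 1e-6)
  pc <- pseudocount %||% (if (is_freq) 0 else 1)
  pwm(id, mat, cutoff = cutoff, pseudocount = pc)
}

parse_transfac <- function(lines, pseudocount) {
  out <- list()
  id <- NULL; rows <- list(); cutoff <- NA_real_; start_line <- 1L
  flush <- function(i) {
    if (!is.null(id)) {
      out[[length(out) + 1L]] <<- finish_pwm(id, rows, cutoff, pseudocount, i)
    } else if (length(rows) > 0L) {
      stop(sprintf("matrix rows before any ID line (line %d)", start_line))
    }
    id <<- NULL; rows <<- list(); cutoff <<- NA_real_
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || ln == "XX") next
    if (ln == "//") { flush(i); next }
    tag <- sub("\\s.*$", "", ln)
    if (tag == "ID" || tag == "NA") {
      if (tag == "ID") {
        flush(i)
        id <- trimws(sub("^ID\\s+", "", ln))
        start_line <- i
      }
      next
    }
    if (tag == "P0" || tag == "PO") next
    if (tag == "CC") {
      m <- regmatches(ln, regexec("cutoff\\s*=\\s*([0-9.eE+-]+)", ln))[[1L]]
      if (length(m) == 2L) cutoff <- as.numeric(m[[2L]])
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      fields <- strsplit(ln, "\\s+")[[1L]]
      if (length(fields) < 5L)
        stop(sprintf("line %d: matrix row has %d fields, need position + 4 base counts",
                     i, length(fields)))
      vals <- suppressWarnings(as.numeric(fields[2:5]))
      if (any(is.na(vals)))
        stop(sprintf("line %d: non-numeric base count in '%s'", i, ln))
      rows[[length(rows) + 1L]] <- vals
      next
    }
    # other TRANSFAC tags (BF, DE, ...) are ignored
  }
  flush(length(lines))
  out
}

parse_jaspar <- function(lines, pseudocount) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (ln == "") { i <- i + 1L; next }
    if (!startsWith(ln, ">"))
      stop(sprintf("line %d: expected a '>' header, got '%s'", i, ln))
    id <- strsplit(sub("^>\\s*", "", ln), "\\s+")[[1L]][1L]
    rows <- list()
    bases <- character()
    i <- i + 1L
    while (i <= n && length(rows) < 4L) {
      rl <- trimws(lines[[i]])
      if (rl == "") { i <- i + 1L; next }
      if (startsWith(rl, ">")) break
      base <- NA_character_
      if (grepl("^[ACGTacgt]\\b", rl)) {
        base <- toupper(substr(rl, 1L, 1L))
        rl <- sub("^[ACGTacgt]", "", rl)
      }
      rl <- gsub("\\[|\\]", " ", rl)
      fields <- strsplit(trimws(rl), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) == 0L || any(is.na(vals)))
        stop(sprintf("line %d: non-numeric value in JASPAR row", i))
      rows[[length(rows) + 1L]] <- vals
      bases[length(rows)] <- base
      i <- i + 1L
    }
    if (length(rows) != 4L)
      stop(sprintf("JASPAR record '%s' has %d base rows, need 4", id, length(rows)))
    if (length(unique(vapply(rows, length, integer(1L)))) != 1L)
      stop(sprintf("JASPAR record '%s': base rows differ in length", id))
    mat <- do.call(cbind, rows)  # positions x 4, rows in file order
    if (!any(is.na(bases))) {
      if (!setequal(bases, DNA_BASES))
        stop(sprintf("JASPAR record '%s': base labels %s", id,
                     paste(bases, collapse = ",")))
      mat <- mat[, match(DNA_BASES, bases), drop = FALSE]
    }
    is_freq <- all(abs(rowSums(mat) - 1) < 1e-6)
    pc <- pseudocount %||% (if (is_freq) 0 else 1)
    out[[length(out) + 1L]] <- pwm(id, mat, pseudocount = pc)
  }
  out
}

#' Write motifs as a TRANSFAC flat file
#'
#' Frequencies are written with full precision so that
#' `parse_motifs(write_motifs(x))` round-trips exactly; a set cutoff is
#' preserved in a `CC cutoff=` comment line.
#'
#' @param pwms list of [pwm()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pw in pwms) {
    writeLines(c(paste("ID", pw$id), "P0\tA\tC\tG\tT"), con)
    for (i in seq_len(pw$length)) {
      writeLines(paste(c(sprintf("%02d", i),
                         format(pw$freqs[i, ], digits = 17)),
                       collapse = "\t"), con)
    }
    if (!is.na(pw$cutoff))
      writeLines(sprintf("CC cutoff=%s", format(pw$cutoff, digits = 17)), con)
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Wraps [Biostrings::readDNAStringSet()]; multi-line records and
#' lower-case bases are handled, and only the first whitespace-delimited
#' token of each header is kept as the name.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write motif hits as BED-like TSV
#'
#' Columns: `sequence_id`, `start`, `end`, `matrix_id`, `score`, `strand`
#' (0-based, half-open coordinates).
#' @param hits data frame from [scan_hits()] (possibly row-bound).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write_tsv(hits[, c("sequence_id", "start", "end", "matrix_id",
                     "score", "strand")], path)
}

#' Write an enrichment matrix as TSV
#'
#' First column `sequence_id`, then one column per matrix id.
#' @param E matrix from [enrichment_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(E, path) {
  df <- data.frame(sequence_id = rownames(E), E, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an enrichment matrix written by [write_enrichment()]
#' @param path TSV path.
#' @return Numeric matrix with sequence ids as row names.
#' @export
read_enrichment <- function(path) {
  df <- read_tsv(path)
  E <- as.matrix(df[, -1L, drop = FALSE])
  rownames(E) <- df[[1L]]
  storage.mode(E) <- "double"
  E
}
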