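# Tab-delimited score-matrix and site-file input/output.
#
# Matrix format:
#   # motif=HELPER cutoff=5.51
#   pos  A  C  G  T
#   1    w  w  w  w
#   ...
# Values round-trip bit-exactly (written with 17 significant digits).

#' Load an additive score matrix from a tab-delimited file
#'
#' The file carries the motif kind and score cutoff in a leading `#` header
#' line, a `pos A C G T` column header, and one row of four real scores per
#' position. Values are reproduced bit-exactly, so matrices distributed as
#' plain text apply exactly as printed.
#'
#' @param path Path to the matrix file.
#' @param cutoff Optional cutoff override (e.g. from a sidecar config); by
#'   default the value in the file header is used.
#' @return A `wre_pwm` (see [build_pwm()]); its `pseudocount` is `NA` since
#'   the matrix was loaded, not built.
#' @seealso [write_matrix()]
#' @export
load_matrix <- function(path, cutoff = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("matrix file %s: too few lines", path)
  header_i <- grep("^#.*motif=", lines)
  if (length(header_i) == 0L) stopf("matrix file %s: missing '# motif=... cutoff=...' header", path)
  header <- lines[header_i[1]]
  motif <- sub(".*motif=([A-Za-z]+).*", "\\1", header)
  if (!motif %in% c("HMG", "HELPER")) {
    stopf("matrix file %s: unknown motif kind '%s'", path, motif)
  }
  file_cutoff <- if (grepl("cutoff=", header)) {
    as.numeric(sub(".*cutoff=([-0-9.eE+]+).*", "\\1", header))
  } else NA_real_
  body <- lines[!grepl("^#", lines)]
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(cols, c("pos", "A", "C", "G", "T"))) {
    stopf("matrix file %s: expected column header 'pos A C G T', got '%s'",
          path, body[1])
  }
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0L) stopf("matrix file %s: width 0 (no position rows)", path)
  weights <- matrix(NA_real_, nrow = length(rows), ncol = 4L,
                    dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(rows)) {
    fields <- strsplit(rows[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5L) {
      stopf("matrix file %s: row %d has %d columns, expected 5 (pos + A C G T)",
            path, i, length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stopf("matrix file %s: non-numeric cell at row %d, column %s",
            path, i, DNA_BASES[bad])
    }
    weights[i, ] <- vals
  }
  new_pwm(motif, weights,
          cutoff = if (is.null(cutoff)) file_cutoff else cutoff,
          background = rep(0.25, 4), pseudocount = NA_real_)
}

#' Write a score matrix to a tab-delimited file
#'
#' Inverse of [load_matrix()]; a written matrix reloads cell-for-cell.
#'
#' @param pwm A `wre_pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(pwm, path) {
  header <- if (is.na(pwm$cutoff)) {
    sprintf("# motif=%s", pwm$motif)
  } else {
    sprintf("# motif=%s cutoff=%s", pwm$motif, sprintf("%.17g", pwm$cutoff))
  }
  rows <- vapply(seq_len(pwm$width), function(i) {
    paste(c(i, sprintf("%.17g", pwm$weights[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, paste(c("pos", DNA_BASES), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read aligned sites from a FASTA or plain-text site file
#'
#' Plain-text files carry one site per line with `#` comment lines; files
#' whose first non-comment line starts with `>` are parsed as FASTA.
#'
#' @param path Path to the site file.
#' @param motif Motif kind for the resulting [site_set()].
#' @return A [site_set()].
#' @export
read_sites <- function(path, motif = c("HELPER", "HMG")) {
  motif <- match.arg(motif)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("site file %s is empty", path)
  if (startsWith(lines[1], ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    site_set(as.character(seqs), motif = motif, labels = names(seqs))
  } else {
    fields <- strsplit(trimws(lines), "\\s+")
    sites <- vapply(fields, `[`, character(1), 1L)
    labels <- vapply(fields, function(f) {
      if (length(f) > 1L) paste(f[-1], collapse = " ") else NA_character_
    }, character(1))
    if (all(is.na(labels))) labels <- NULL
    site_set(sites, motif = motif, labels = labels)
  }
}
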