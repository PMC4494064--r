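# Readers and writers for the standard interchange formats: FASTA and
# relaxed PHYLIP alignments (via phangorn), Newick trees, and the TSV
# tables used by the filtering and survey stages.

#' Read an alignment (FASTA or relaxed PHYLIP)
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"` (interleaved/sequential detected
#'   by phangorn).
#' @return Named character vector of sequence strings.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  pd <- tryCatch(phangorn::read.phyDat(path, format = format, type = "AA"),
                 error = function(e) NULL)
  if (!is.null(pd)) return(aln_strings(toupper(as.character(pd))))
  if (format != "phylip") stop("could not read alignment from ", path)
  # relaxed sequential PHYLIP fallback (phangorn's reader assumes longer
  # sequences than tiny test files provide)
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  out <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  if (length(out) != hdr[1] || any(nchar(out) != hdr[2]))
    stop("malformed PHYLIP file ", path)
  toupper(out)
}

#' Write an alignment to FASTA
#' @param aln Alignment (named character vector or matrix).
#' @param path Output path.
#' @export
write_fasta <- function(aln, path) {
  aln <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln))
    writeLines(c(paste0(">", names(aln)[i]), unname(aln[i])), con)
  invisible(path)
}

#' Write an alignment to relaxed PHYLIP
#' @param aln Alignment (named character vector or matrix).
#' @param path Output path.
#' @export
write_phylip <- function(aln, path) {
  aln <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln), nchar(aln[1])), con)
  writeLines(sprintf("%s  %s", names(aln), unname(aln)), con)
  invisible(path)
}

#' Write a partition table (gene, start, end; 0-based half-open)
#' @param supermatrix A `supermatrix` object.
#' @param path Output path.
#' @export
write_partitions <- function(supermatrix, path) {
  utils::write.table(supermatrix$partitions, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic TSV table
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic TSV table
#' @param path File path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a calibration table (TSV or JSON)
#'
#' TSV columns: `tips` (comma-separated taxa), `kind`, `age`. JSON: an
#' array of objects with the same fields.
#'
#' @param path File path.
#' @return List of [calibration()] objects.
#' @export
read_calibrations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(raw, function(x)
      calibration(unlist(x$tips), x$kind, x$age)))
  }
  df <- read_tsv(path)
  lapply(seq_len(nrow(df)), function(i)
    calibration(strsplit(df$tips[i], ",", fixed = TRUE)[[1]],
                df$kind[i], df$age[i]))
}
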