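# Copy-number survey of carbohydrate-active enzyme (CAZy) families from
# homology hit tables: e-value screening, functional-domain filtering and
# per-genome, per-family tabulation, with a pectin-specific summary.

#' The surveyed 20-family pectinase catalog
#'
#' Glycoside hydrolase (GH), polysaccharide lyase (PL) and carbohydrate
#' esterase (CE) families involved in pectin degradation; nine are
#' pectin-specific.
#'
#' @return Data frame with columns `family`, `class`, `pectin_specific`.
#' @export
cazy_catalog <- function() {
  specific <- c("GH28", "GH53", "GH93", "PL1", "PL3", "PL4", "PL11",
                "CE8", "CE13")
  nonspecific <- c("GH2", "GH35", "GH43", "GH51", "GH54", "GH78", "GH88",
                   "GH105", "PL9", "CE12", "CE1")
  fam <- c(specific, nonspecific)
  data.frame(family = fam,
             class = sub("[0-9]+$", "", fam),
             pectin_specific = fam %in% specific,
             stringsAsFactors = FALSE)
}

#' Filter homology hits by e-value and functional domain
#'
#' Keeps rows with `evalue <= e_max` (inclusive) and, when
#' `require_domain`, a TRUE domain flag; duplicate (family, genome,
#' protein) rows collapse to one.
#'
#' @param hits Data frame (`family`, `genome`, `protein`, `evalue`,
#'   `domain_ok`).
#' @param e_max E-value threshold (> 0), default `1e-5`.
#' @param require_domain Drop hits lacking the predicted functional domain.
#' @return Filtered hit table.
#' @export
filter_hits <- function(hits, e_max = 1e-5, require_domain = TRUE) {
  stopifnot(e_max > 0)
  keep <- hits$evalue <= e_max
  if (require_domain) keep <- keep & hits$domain_ok
  out <- hits[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("family", "genome", "protein")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genomes x families copy-number matrix
#'
#' Counts distinct proteins per (genome, family). A protein hitting two
#' families counts once in each and is flagged in the `multi_family`
#' attribute.
#'
#' @param hits Filtered hit table.
#' @param catalog Family catalog (see [cazy_catalog()]).
#' @param genomes Character vector of all genomes (absent genomes get zero
#'   rows).
#' @return Integer matrix `genomes x families` with attribute
#'   `multi_family` (data frame of multiply assigned proteins).
#' @export
copy_number_matrix <- function(hits, catalog = cazy_catalog(), genomes) {
  bad <- setdiff(hits$family, catalog$family)
  if (length(bad))
    stop("unknown family: ", paste(unique(bad), collapse = ", "))
  badg <- setdiff(hits$genome, genomes)
  if (length(badg))
    stop("unknown genome: ", paste(unique(badg), collapse = ", "))
  m <- matrix(0L, length(genomes), nrow(catalog),
              dimnames = list(genomes, catalog$family))
  if (nrow(hits)) {
    tab <- table(hits$genome, hits$family)
    m[rownames(tab), colnames(tab)] <- m[rownames(tab), colnames(tab)] +
      as.integer(tab)
    pf <- unique(hits[, c("protein", "family")])
    dup <- pf$protein[duplicated(pf$protein)]
    attr(m, "multi_family") <- pf[pf$protein %in% dup, , drop = FALSE]
  } else {
    attr(m, "multi_family") <- data.frame(protein = character(),
                                          family = character())
  }
  m
}

#' Per-genome summary of pectin-specific families
#'
#' @param matrix Copy-number matrix from [copy_number_matrix()].
#' @param catalog Family catalog.
#' @return Data frame with one row per genome: `genome`,
#'   `pectin_specific_total` (copy total over flagged families),
#'   `families_present` (count of flagged families with >= 1 copy), and a
#'   presence/absence column `pres_<family>` for every family.
#' @export
summarize_families <- function(matrix, catalog = cazy_catalog()) {
  stopifnot(all(colnames(matrix) %in% catalog$family))
  spec <- catalog$family[catalog$pectin_specific]
  spec <- intersect(spec, colnames(matrix))
  out <- data.frame(
    genome = rownames(matrix),
    pectin_specific_total = as.integer(rowSums(matrix[, spec, drop = FALSE])),
    families_present = as.integer(rowSums(matrix[, spec, drop = FALSE] > 0)),
    stringsAsFactors = FALSE
  )
  pres <- matrix > 0
  colnames(pres) <- paste0("pres_", colnames(matrix))
  cbind(out, as.data.frame(pres, stringsAsFactors = FALSE))
}
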