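# Single-copy ortholog filtering, reciprocal-best-hit vetting, supermatrix
# concatenation and Dayhoff 6-state recoding.

#' Retain single-copy, well-occupied, non-redundant clusters
#'
#' A cluster is kept when no genome contributes more than one protein and
#' the fraction of genomes represented is at least `min_occupancy`
#' (inclusive). Redundant clusters -- identical protein membership -- are
#' collapsed to the first by cluster id.
#'
#' @param clusters Data frame with columns `cluster`, `genome`, `protein`.
#' @param n_genomes Total number of genomes in the study.
#' @param min_occupancy Minimum fraction of genomes present, in `(0, 1]`.
#' @return The filtered cluster table; attribute `kept` holds the kept
#'   cluster ids.
#' @export
filter_single_copy <- function(clusters, n_genomes, min_occupancy = 0.5) {
  stopifnot(n_genomes >= 1, min_occupancy > 0, min_occupancy <= 1)
  if (nrow(clusters) == 0L) {
    attr(clusters, "kept") <- character(0)
    return(clusters)
  }
  sp <- split(clusters, clusters$cluster)
  keep <- vapply(sp, function(df) {
    max(table(df$genome)) <= 1L &&
      length(unique(df$genome)) / n_genomes >= min_occupancy
  }, logical(1))
  kept_ids <- names(sp)[keep]
  # redundancy: identical membership (same protein set)
  sig <- vapply(sp[kept_ids],
                function(df) paste(sort(df$protein), collapse = ";"),
                character(1))
  kept_ids <- kept_ids[!duplicated(sig)]
  out <- clusters[clusters$cluster %in% kept_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- sort(kept_ids)
  out
}

#' Genome of a protein id
#'
#' Default convention: the substring before the first separator.
#' @param protein Character vector of protein ids.
#' @param sep Separator (default `"|"`).
#' @export
protein_genome <- function(protein, sep = "|") {
  vapply(strsplit(protein, sep, fixed = TRUE), `[[`, character(1), 1L)
}

#' Keep clusters whose members are mutual best hits
#'
#' A cluster passes when, for every member `p` and every other genome `g`
#' represented in the cluster, `p`'s single best-scoring hit among scored
#' proteins of `g` is the cluster's member from `g` (ties with an
#' out-of-cluster hit fail, conservatively). Clusters with a member lacking
#' any scored hit into some co-member genome are reported as unevaluable
#' and removed.
#'
#' @param clusters Data frame (`cluster`, `genome`, `protein`).
#' @param scores Data frame (`query`, `subject`, `score`).
#' @param genome_of Function mapping protein ids to genome ids.
#' @return Filtered cluster table with attributes `kept`, `removed`,
#'   `unevaluable`.
#' @export
rbh_filter <- function(clusters, scores, genome_of = protein_genome) {
  if (nrow(clusters) == 0L) {
    attr(clusters, "kept") <- character(0)
    attr(clusters, "removed") <- character(0)
    attr(clusters, "unevaluable") <- character(0)
    return(clusters)
  }
  scores$subject_genome <- genome_of(scores$subject)
  by_query <- split(scores, scores$query)
  sp <- split(clusters, clusters$cluster)
  status <- vapply(sp, function(df) {
    gs <- unique(df$genome)
    if (length(gs) < 2L) return("kept")
    for (i in seq_len(nrow(df))) {
      p <- df$protein[i]
      hits <- by_query[[p]]
      if (is.null(hits)) return("unevaluable")
      for (g in setdiff(gs, df$genome[i])) {
        hg <- hits[hits$subject_genome == g, , drop = FALSE]
        if (nrow(hg) == 0L) return("unevaluable")
        best <- unique(hg$subject[hg$score == max(hg$score)])
        expected <- df$protein[df$genome == g]
        if (length(best) != 1L || !(best %in% expected)) return("removed")
      }
    }
    "kept"
  }, character(1))
  kept_ids <- names(sp)[status == "kept"]
  out <- clusters[clusters$cluster %in% kept_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- sort(kept_ids)
  attr(out, "removed") <- sort(names(sp)[status == "removed"])
  attr(out, "unevaluable") <- sort(names(sp)[status == "unevaluable"])
  out
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in lexicographic order of their names, so the
#' result is invariant to input order. Taxa absent from a gene are filled
#' with the missing symbol `?` over that gene's columns (`-` is reserved
#' for alignment gaps). The partition table uses 0-based half-open column
#' intervals.
#'
#' @param alignments Named list of alignments (named character vectors of
#'   equal-length strings).
#' @param taxon_universe Character vector of all taxa for the matrix rows.
#' @return Object of class `supermatrix`: list with `seqs` (named character
#'   vector over `taxon_universe`), `partitions` (data frame `gene`,
#'   `start`, `end`), `occupancy` (named fraction of genes present per
#'   taxon).
#' @export
concat_supermatrix <- function(alignments, taxon_universe) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  ord <- order(names(alignments))
  alignments <- alignments[ord]
  taxon_universe <- sort(unique(taxon_universe))
  widths <- integer(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (anyDuplicated(names(a)))
      stop("duplicate taxon within gene ", names(alignments)[i], ": ",
           names(a)[duplicated(names(a))][1])
    w <- unique(nchar(a))
    if (length(w) != 1L)
      stop("unequal aligned lengths within gene ", names(alignments)[i])
    widths[i] <- w
    extra <- setdiff(names(a), taxon_universe)
    if (length(extra))
      stop("taxon not in universe: ", paste(extra, collapse = ", "))
  }
  ends <- cumsum(widths)
  starts <- c(0L, ends[-length(ends)])
  parts <- data.frame(gene = names(alignments), start = starts, end = ends,
                      stringsAsFactors = FALSE)
  present <- matrix(FALSE, length(taxon_universe), length(alignments),
                    dimnames = list(taxon_universe, names(alignments)))
  pieces <- matrix("", length(taxon_universe), length(alignments))
  rownames(pieces) <- taxon_universe
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    fill <- strrep("?", widths[i])
    col <- rep(fill, length(taxon_universe))
    names(col) <- taxon_universe
    col[names(a)] <- unname(a)
    pieces[, i] <- col
    present[names(a), i] <- TRUE
  }
  seqs <- apply(pieces, 1, paste, collapse = "")
  occ <- rowMeans(present)
  structure(list(seqs = seqs, partitions = parts, occupancy = occ),
            class = "supermatrix")
}

DAYHOFF6 <- local({
  groups <- list(`0` = c("A", "G", "P", "S", "T"),
                 `1` = c("D", "E", "N", "Q"),
                 `2` = c("H", "K", "R"),
                 `3` = c("I", "L", "M", "V"),
                 `4` = c("F", "W", "Y"),
                 `5` = "C")
  map <- character(0)
  for (g in names(groups)) map[groups[[g]]] <- g
  map
})

#' Dayhoff 6-state recoding of an amino-acid alignment
#'
#' Collapses the 20 amino acids into the six Dayhoff exchange groups
#' `{AGPST}=0, {DENQ}=1, {HKR}=2, {ILMV}=3, {FWY}=4, {C}=5`. Gaps (`-`) and
#' missing (`?`) are preserved; ambiguity codes (`X`, `B`, `Z`, `J`, `U`,
#' `O`) become missing. Any other symbol is an error.
#'
#' @param aln Alignment (named character vector or matrix).
#' @return Recoded alignment in the same representation.
#' @export
dayhoff_recode <- function(aln) {
  was_matrix <- is.matrix(aln)
  m <- aln_matrix(aln)
  up <- toupper(m)
  out <- DAYHOFF6[up]
  out[up %in% c("X", "B", "Z", "J", "U", "O")] <- "?"
  out[up == "?"] <- "?"
  out[up == "-"] <- "-"
  bad <- is.na(out)
  if (any(bad))
    stop("unknown residue symbol: ", paste(unique(m[bad]), collapse = ", "))
  dim(out) <- dim(m)
  rownames(out) <- rownames(m)
  if (was_matrix) out else aln_strings(out)
}
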