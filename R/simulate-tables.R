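# Synthetic ortholog-cluster and homology-hit tables with planted truth
# labels, used to exercise the filter chain and the copy-number survey.

#' Simulate an ortholog cluster table with planted filter violations
#'
#' Each cluster is independently assigned up to three planted defects:
#' a paralog (two proteins from one genome, fails the single-copy rule), a
#' dropout (fewer than half the genomes represented, fails 50% occupancy),
#' and a reciprocal-best-hit violation (one member's best-scoring hit in a
#' co-member's genome lies outside the cluster). The accompanying score
#' table makes planted violations detectable; the truth label `keep` is
#' TRUE iff the cluster has no defect.
#'
#' Protein ids are `genome|cluster|index`; the genome of a protein is the
#' substring before the first `|`.
#'
#' @param n_genomes,n_clusters Counts.
#' @param paralog_fraction,dropout_fraction,rbh_violation_fraction
#'   Independent defect probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `clusters` (data frame: cluster, genome, protein),
#'   `scores` (data frame: query, subject, score), and `truth` (data frame:
#'   cluster, paralog, dropout, rbh_violation, keep).
#' @export
sim_cluster_table <- function(n_genomes, n_clusters, paralog_fraction = 0,
                              dropout_fraction = 0,
                              rbh_violation_fraction = 0, seed = 1L) {
  stopifnot(n_genomes >= 4, n_clusters >= 1)
  fr <- c(paralog_fraction, dropout_fraction, rbh_violation_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1))
  genomes <- sprintf("g%02d", seq_len(n_genomes))
  pick1 <- function(v) v[sample.int(length(v), 1L)]
  with_seed(seed, {
    rows <- list(); score_rows <- list(); truth <- list()
    min_keep <- ceiling(n_genomes / 2)
    for (j in seq_len(n_clusters)) {
      cid <- sprintf("c%04d", j)
      paralog <- stats::runif(1) < paralog_fraction
      dropout <- stats::runif(1) < dropout_fraction
      viol <- stats::runif(1) < rbh_violation_fraction
      m <- if (dropout) pick1(seq_len(min_keep - 1))
           else pick1(min_keep:n_genomes)
      gs <- sample(genomes, m)
      prot <- paste(gs, cid, "p1", sep = "|")
      df <- data.frame(cluster = cid, genome = gs, protein = prot,
                       stringsAsFactors = FALSE)
      if (paralog) {
        gdup <- pick1(gs)
        df <- rbind(df, data.frame(cluster = cid, genome = gdup,
                                   protein = paste(gdup, cid, "p2", sep = "|"),
                                   stringsAsFactors = FALSE))
      }
      rows[[j]] <- df
      # scores: every member scores every co-member highest, decoys lower
      members <- df$protein
      mg <- df$genome
      sc <- list()
      for (a in seq_along(members)) {
        for (b in seq_along(members)) {
          if (mg[a] == mg[b]) next
          sc[[length(sc) + 1L]] <- data.frame(
            query = members[a], subject = members[b],
            score = stats::runif(1, 80, 100), stringsAsFactors = FALSE)
        }
        # one decoy hit per foreign genome, normally scoring below members
        for (g in setdiff(unique(mg), mg[a])) {
          sc[[length(sc) + 1L]] <- data.frame(
            query = members[a], subject = paste(g, "decoy", a, sep = "|"),
            score = stats::runif(1, 10, 50), stringsAsFactors = FALSE)
        }
      }
      sc <- do.call(rbind, sc)
      if (viol && length(unique(mg)) > 1L) {
        a <- pick1(seq_along(members))
        foreign <- setdiff(unique(mg), mg[a])
        g <- pick1(foreign)
        sc <- rbind(sc, data.frame(
          query = members[a], subject = paste(g, "decoyX", sep = "|"),
          score = 150, stringsAsFactors = FALSE))
      }
      score_rows[[j]] <- sc
      truth[[j]] <- data.frame(cluster = cid, paralog = paralog,
                               dropout = dropout, rbh_violation = viol,
                               keep = !(paralog || dropout || viol),
                               stringsAsFactors = FALSE)
    }
    list(clusters = do.call(rbind, rows),
         scores = do.call(rbind, score_rows),
         truth = do.call(rbind, truth))
  })
}

#' Simulate a homology hit table with decoys
#'
#' True hits receive e-values at or below `1e-5` and a TRUE domain flag;
#' decoy hits fail one (or both) of the two filters: e-value above the
#' threshold, or a FALSE domain flag.
#'
#' @param families Character vector of family ids (must be in the catalog
#'   used downstream).
#' @param genomes Character vector of genome ids.
#' @param true_counts Integer matrix `genomes x families` of planted copy
#'   numbers.
#' @param decoy_rate Expected number of decoy rows per genome (Poisson).
#' @param seed Integer seed.
#' @return Data frame (family, genome, protein, evalue, domain_ok) with
#'   attribute `truth` = `true_counts`.
#' @export
sim_hit_table <- function(families, genomes, true_counts, decoy_rate = 0,
                          seed = 1L) {
  true_counts <- as.matrix(true_counts)
  stopifnot(nrow(true_counts) == length(genomes),
            ncol(true_counts) == length(families),
            all(true_counts >= 0), decoy_rate >= 0)
  dimnames(true_counts) <- list(genomes, families)
  with_seed(seed, {
    rows <- list()
    for (g in genomes) for (f in families) {
      n <- true_counts[g, f]
      if (n > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, genome = g,
          protein = sprintf("%s|%s|t%03d", g, f, seq_len(n)),
          evalue = 10^-stats::runif(n, 6, 50), domain_ok = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    for (g in genomes) {
      nd <- stats::rpois(1, decoy_rate)
      if (nd > 0) {
        f <- sample(families, nd, replace = TRUE)
        mode <- sample(c("evalue", "domain", "both"), nd, replace = TRUE)
        ev <- ifelse(mode %in% c("evalue", "both"),
                     10^-stats::runif(nd, 0, 4.9),
                     10^-stats::runif(nd, 6, 50))
        dom <- !(mode %in% c("domain", "both"))
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, genome = g,
          protein = sprintf("%s|%s|d%03d", g, f, seq_len(nd)),
          evalue = ev, domain_ok = dom, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(family = character(), genome = character(),
                        protein = character(), evalue = numeric(),
                        domain_ok = logical(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "truth") <- true_counts
    out
  })
}
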