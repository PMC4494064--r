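# Random-addition concatenation (RADICAL) curves and clade fixation points.
#
# Genes are shuffled, concatenated in growing prefixes, and a tree is
# estimated at each concatenation size; a clade's fixation point is the
# smallest size from which it is recovered in every tree at every larger
# size in every replicate, reported as a fraction of the total gene count.

#' Default tree estimator: neighbor joining on ML distances
#'
#' @param model A [subst_model()] used for the distance correction.
#' @return A function mapping an alignment to an unrooted `phylo`.
#' @export
nj_estimator <- function(model = subst_model()) {
  function(aln) {
    D <- ml_distance(aln, model)
    ape::nj(stats::as.dist(D))
  }
}

#' Random-addition concatenation curves
#'
#' @param genes Named list of per-gene alignments (named character vectors;
#'   taxa may differ per gene, missing taxa are `?`-filled on
#'   concatenation).
#' @param estimator Function alignment -> `phylo` (see [nj_estimator()]).
#'   Estimator failure aborts the replicate, which is reported in
#'   `$aborted`.
#' @param n_replicates Number of random gene orders.
#' @param step Concatenation step size (prefixes of `step, 2*step, ..., G`).
#' @param seed Integer seed.
#' @return Object of class `radical_curves`: list with `G`, `taxa`,
#'   `replicates` (each: `order`, `steps`, `clades` -- a list of canonical
#'   split-key vectors per step), and `aborted`.
#' @export
radical <- function(genes, estimator = nj_estimator(), n_replicates = 10L,
                    step = 1L, seed = 1L) {
  G <- length(genes)
  stopifnot(G >= 2L, step >= 1L, !is.null(names(genes)))
  taxa <- sort(unique(unlist(lapply(genes, names))))
  sizes <- unique(c(seq(step, G, by = step), G))
  orders <- with_seed(seed, replicate(n_replicates, sample.int(G),
                                      simplify = FALSE))
  reps <- vector("list", n_replicates)
  aborted <- integer(0)
  for (r in seq_len(n_replicates)) {
    ord <- orders[[r]]
    clades <- vector("list", length(sizes))
    ok <- TRUE
    for (si in seq_along(sizes)) {
      sel <- genes[ord[seq_len(sizes[si])]]
      sm <- concat_supermatrix(sel, taxa)
      tr <- tryCatch(estimator(sm$seqs), error = function(e) NULL)
      if (is.null(tr)) { ok <- FALSE; break }
      clades[[si]] <- clade_set(tr)
    }
    if (!ok) { aborted <- c(aborted, r); next }
    reps[[r]] <- list(order = ord, steps = sizes, clades = clades)
  }
  structure(list(G = G, taxa = taxa, replicates = reps[!vapply(reps, is.null, logical(1))],
                 aborted = aborted),
            class = "radical_curves")
}

#' Fixation points of clades in RADICAL curves
#'
#' For clade X, the raw fixation point m is the smallest step size s such
#' that X appears in every estimated tree at every step >= s in every
#' replicate; the reported value is `m / G`. A clade absent from any
#' final-step tree (or never stabilizing) is `"unfixed"` (NA fraction).
#'
#' @param curves A `radical_curves` object.
#' @param clades Character vector of canonical split keys (see
#'   [clade_key()]), or a list of taxon sets to be keyed against the
#'   curves' taxon universe.
#' @return Data frame with columns `clade`, `fixation` (fraction in (0,1],
#'   NA when unfixed), `fixed`.
#' @export
fixation_points <- function(curves, clades) {
  stopifnot(inherits(curves, "radical_curves"))
  if (is.list(clades))
    clades <- vapply(clades, clade_key, character(1), universe = curves$taxa)
  G <- curves$G
  out <- data.frame(clade = clades, fixation = NA_real_, fixed = FALSE,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(clades)) {
    x <- clades[ci]
    m <- 0L  # smallest feasible step size so far (0 = first step works)
    feasible <- TRUE
    for (rep in curves$replicates) {
      last <- rep$clades[[length(rep$clades)]]
      if (!(x %in% last)) { feasible <- FALSE; break }
      present <- vapply(rep$clades, function(cl) x %in% cl, logical(1))
      # smallest step index from which presence is uninterrupted
      bad <- which(!present)
      first_ok <- if (length(bad)) max(bad) + 1L else 1L
      if (first_ok > length(rep$steps)) { feasible <- FALSE; break }
      m <- max(m, rep$steps[first_ok])
    }
    if (feasible && length(curves$replicates) > 0L) {
      if (m == 0L) m <- curves$replicates[[1]]$steps[1]
      out$fixation[ci] <- m / G
      out$fixed[ci] <- TRUE
    }
  }
  out
}
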