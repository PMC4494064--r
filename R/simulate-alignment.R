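# Alignment simulation under a reversible model with discrete-gamma rates.

#' Simulate an alignment along a tree
#'
#' Sites evolve independently root-to-tips under the model's rate matrix;
#' each site is assigned one of the model's discrete-gamma rate categories
#' (recorded in the `"categories"` attribute of the result).
#'
#' @param tree `phylo` with branch lengths in expected substitutions/site.
#' @param n_sites Number of sites.
#' @param model A [subst_model()].
#' @param seed Integer seed (fixed seed gives bit-identical output).
#' @return Named character vector of sequence strings (one per tip), with
#'   attribute `categories` (integer per site).
#' @export
sim_alignment <- function(tree, n_sites, model, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  k <- model$states
  with_seed(seed, {
    cat_idx <- sample.int(length(model$cat_rates), n_sites, replace = TRUE)
    site_rate <- model$cat_rates[cat_idx]
    states <- matrix(0L, nn, n_sites)
    states[root, ] <- sample.int(k, n_sites, replace = TRUE, prob = model$freqs)
    # preorder: cladewise edge order guarantees parents before children
    ord <- ape::reorder.phylo(tree, "cladewise")
    rates_u <- sort(unique(site_rate))
    for (ei in seq_len(nrow(ord$edge))) {
      p <- ord$edge[ei, 1]; ch <- ord$edge[ei, 2]
      t0 <- ord$edge.length[ei]
      for (r in rates_u) {
        cols <- which(site_rate == r)
        if (!length(cols)) next
        P <- pmat(model, t0 * r)
        ps <- states[p, cols]
        for (s in unique(ps)) {
          sel <- cols[ps == s]
          states[ch, sel] <- sample.int(k, length(sel), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1,
                  function(row) paste(model$labels[row], collapse = ""))
    names(seqs) <- tree$tip.label
    attr(seqs, "categories") <- cat_idx
    seqs
  })
}
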