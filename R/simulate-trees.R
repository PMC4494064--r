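# Simulators for species trees and relaxed-clock phylograms.
# All generators are pure functions of (parameters, seed): they set the RNG
# from `seed` and restore the caller's RNG state on exit.

#' Evaluate code under a fixed seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate an ultrametric species tree
#'
#' A pure-birth (Yule) tree on `n_taxa` genomes, rescaled so the root age is
#' exactly `root_age`. Node ages are stored in the `$age` element; tips are
#' labeled `g01`, `g02`, ...
#'
#' @param n_taxa Number of genomes (>= 2).
#' @param root_age Root age in Ma.
#' @param birth_rate Speciation rate per lineage per Ma (shape parameter of
#'   the Yule process before rescaling; the default 0.01 gives realistic
#'   node-age spread for ancient clades).
#' @param seed Integer seed.
#' @return An ultrametric binary `phylo` with `$age` set (leaf ages 0).
#' @export
sim_species_tree <- function(n_taxa, root_age, birth_rate = 0.01, seed = 1L) {
  stopifnot(n_taxa >= 2, root_age > 0, birth_rate > 0)
  with_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  })
  tree$tip.label <- sprintf("g%02d", seq_len(n_taxa))
  age <- node_ages_from_lengths(tree)
  sc <- root_age / age[length(tree$tip.label) + 1L]
  tree$edge.length <- tree$edge.length * sc
  age <- age * sc
  age[seq_len(n_taxa)] <- 0  # exact leaf ages
  tree$age <- age
  tree$support <- rep(NA_real_, tree$Nnode)
  tree
}

#' @keywords internal
node_ages_from_lengths <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Simulate a relaxed-clock phylogram from a dated species tree
#'
#' Branch rates are i.i.d. lognormal with expectation `mean_rate`
#' (substitutions/site/Ma) and standard deviation `sigma` on the log scale
#' (uncorrelated lognormal clock). Each branch length is rate x duration,
#' with no further noise.
#'
#' @param species_tree Ultrametric `phylo` with `$age` (or branch lengths in
#'   Ma).
#' @param mean_rate Expected rate, substitutions/site/Ma.
#' @param sigma Standard deviation of log rate (>= 0; 0 gives a strict clock).
#' @param seed Integer seed.
#' @return A list of class `relaxed_phylogram` with elements `tree` (the
#'   phylogram: `phylo` with branch lengths in substitutions/site), `rates`
#'   (per edge, in `tree$edge` order), `ages` (true node ages), `sigma`.
#' @export
sim_relaxed_phylogram <- function(species_tree, mean_rate, sigma, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"))
  if (sigma < 0) stop("sigma must be >= 0")
  age <- node_ages(species_tree)
  dur <- age[species_tree$edge[, 1]] - age[species_tree$edge[, 2]]
  stopifnot(all(dur >= 0))
  ne <- nrow(species_tree$edge)
  rates <- with_seed(seed, {
    if (sigma == 0) rep(mean_rate, ne)
    else stats::rlnorm(ne, meanlog = log(mean_rate) - sigma^2 / 2, sdlog = sigma)
  })
  phy <- species_tree
  phy$age <- NULL
  phy$edge.length <- rates * dur
  structure(list(tree = phy, rates = rates, ages = age, sigma = sigma),
            class = "relaxed_phylogram")
}
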