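# Independent oracles used across the suite. These deliberately avoid the
# package's own reconciliation / pruning code paths: the DL oracle
# enumerates ancestor-consistent maps directly, and the likelihood oracle
# sums over all internal-state assignments.

# --- rooted-binary-topology enumeration ------------------------------------

# all rooted binary topologies (nested lists) on the given leaf labels
all_topologies <- function(labels) {
  if (length(labels) == 1L) return(list(list(label = labels[1])))
  prev <- all_topologies(labels[-length(labels)])
  leaf <- list(label = labels[length(labels)])
  insert_everywhere <- function(t, b) {
    res <- list(list(children = list(t, b)))
    if (is.null(t$label)) {
      for (i in seq_along(t$children)) {
        for (sub in insert_everywhere(t$children[[i]], b)) {
          t2 <- t
          t2$children[[i]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  out <- list()
  for (t in prev) out <- c(out, insert_everywhere(t, leaf))
  out
}

nested_newick <- function(t) {
  if (!is.null(t$label)) return(t$label)
  paste0("(", paste(vapply(t$children, nested_newick, character(1)),
                    collapse = ","), ")")
}

topology_phylo <- function(t) ape::read.tree(text = paste0(nested_newick(t), ";"))

# --- species-tree bookkeeping (independent of the package's index) --------

oracle_species <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  nn <- ntip + species_tree$Nnode
  parent <- rep(NA_integer_, nn)
  for (i in seq_len(nrow(species_tree$edge)))
    parent[species_tree$edge[i, 2]] <- species_tree$edge[i, 1]
  anc <- vector("list", nn)  # self first, then ancestors to root
  for (v in seq_len(nn)) {
    path <- v
    while (!is.na(parent[path[length(path)]]))
      path <- c(path, parent[path[length(path)]])
    anc[[v]] <- path
  }
  depth <- vapply(anc, length, integer(1))  # root depth 1
  list(ntip = ntip, nn = nn, parent = parent, anc = anc, depth = depth,
       tips = species_tree$tip.label)
}

oracle_lca <- function(os, a, b) {
  ia <- os$anc[[a]]
  for (v in os$anc[[b]]) if (v %in% ia) return(v)
  stop("no common ancestor")
}

oracle_dist <- function(os, anc_node, desc_node) {
  os$depth[desc_node] - os$depth[anc_node]
}

is_anc_or_eq <- function(os, a, d) a %in% os$anc[[d]]

# Minimum duplication+loss cost over all ancestor-consistent maps of the
# gene tree into the species tree. `gene` is a nested-list topology whose
# leaf labels map to species tips via `leaf_species` (named vector).
oracle_min_dl <- function(gene, species_tree, leaf_species) {
  os <- oracle_species(species_tree)
  cost_of <- function(t) {
    # returns list of (species node, cost) alternatives for the subtree
    if (!is.null(t$label)) {
      sp <- match(leaf_species[[t$label]], os$tips)
      return(list(list(m = sp, cost = 0)))
    }
    left <- cost_of(t$children[[1]])
    right <- cost_of(t$children[[2]])
    out <- list()
    for (L in left) for (R in right) {
      low <- oracle_lca(os, L$m, R$m)
      for (m in os$anc[[low]]) {  # every ancestor-or-equal placement
        d1 <- oracle_dist(os, m, L$m)
        d2 <- oracle_dist(os, m, R$m)
        # speciation iff children descend through different children of m
        sameL <- L$m == m
        sameR <- R$m == m
        speciation <- !sameL && !sameR && {
          # first step from m toward each child must differ
          step <- function(dn) {
            p <- dn
            while (!identical(os$parent[p], m) &&
                   !is.na(os$parent[p])) p <- os$parent[p]
            p
          }
          step(L$m) != step(R$m)
        }
        cost <- L$cost + R$cost +
          if (speciation) (d1 - 1) + (d2 - 1) else 1 + d1 + d2
        out <- c(out, list(list(m = m, cost = cost)))
      }
    }
    # prune dominated alternatives (same placement, higher cost)
    best <- list()
    for (o in out) {
      k <- as.character(o$m)
      if (is.null(best[[k]]) || o$cost < best[[k]]$cost) best[[k]] <- o
    }
    unname(best)
  }
  alts <- cost_of(gene)
  min(vapply(alts, function(o) o$cost, numeric(1)))
}

# --- explicit-summation likelihood oracle ----------------------------------

brute_loglik <- function(tree, aln, model) {
  m <- aln_matrix(aln)
  ntip <- nrow(m)
  nn <- ntip + tree$Nnode
  states <- lapply(rownames(m), function(tx) match(m[tx, ], model$labels))
  names(states) <- rownames(m)
  tot <- 0
  ints <- (ntip + 1):nn
  for (site in seq_len(ncol(m))) {
    tip_states <- vapply(tree$tip.label, function(tx) states[[tx]][site],
                         integer(1))
    unknown <- which(is.na(tip_states))  # gaps marginalize like internals
    freevars <- c(ints, unknown)
    grid <- as.matrix(expand.grid(rep(list(seq_len(model$states)),
                                      length(freevars))))
    lik_site <- 0
    for (ci in seq_along(model$cat_rates)) {
      r <- model$cat_rates[ci]
      Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
        pmat(model, tree$edge.length[i] * r))
      s_mix <- 0
      for (g in seq_len(nrow(grid))) {
        asg <- integer(nn)
        asg[seq_len(ntip)] <- tip_states
        asg[freevars] <- grid[g, ]
        pr <- model$freqs[asg[ntip + 1]]
        for (i in seq_len(nrow(tree$edge)))
          pr <- pr * Ps[[i]][asg[tree$edge[i, 1]], asg[tree$edge[i, 2]]]
        s_mix <- s_mix + pr
      }
      lik_site <- lik_site + s_mix / length(model$cat_rates)
    }
    tot <- tot + log(lik_site)
  }
  tot
}

# --- exhaustive reconciliation case set ------------------------------------

# species trees and gene-leaf multisets for the oracle-equivalence sweep
oracle_case_set <- function() {
  list(
    list(species = "(A,B);",
         leafsets = list(c("a1", "a2", "b1"),
                         c("a1", "a2", "b1", "b2"),
                         c("a1", "a2", "a3", "b1"),
                         c("a1", "a2", "a3", "b1", "b2", "b3"))),
    list(species = "((A,B),C);",
         leafsets = list(c("a1", "b1", "c1"),
                         c("a1", "a2", "b1", "c1"),
                         c("a1", "b1", "b2", "c1", "c2"),
                         c("a1", "a2", "b1", "c1", "c2"))),
    list(species = "((A,B),(C,D));",
         leafsets = list(c("a1", "b1", "c1", "d1"),
                         c("a1", "a2", "b1", "c1", "d1"))),
    list(species = "(((A,B),C),D);",
         leafsets = list(c("a1", "b1", "c1", "d1"),
                         c("a1", "b1", "c1", "c2", "d1")))
  )
}

oracle_leafmap <- function(labels) {
  out <- toupper(substr(labels, 1, 1))
  names(out) <- labels
  out
}
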