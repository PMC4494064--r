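# Birth-death gene-family simulator along a dated species tree.
#
# One ancestral copy enters the species root; along every species branch
# each gene lineage duplicates at rate `dup_rate` and dies at rate
# `loss_rate` (Gillespie simulation in continuous time). The ground truth --
# per-branch duplication and loss counts plus entering/exiting copy
# numbers -- is recorded so reconciliation output can be scored against it.

#' Simulate a gene family with recorded duplication/loss truth
#'
#' @param species_tree Ultrametric `phylo` with `$age` set (see
#'   [sim_species_tree()]).
#' @param dup_rate,loss_rate Per-lineage event rates, per Ma (>= 0).
#' @param seed Integer seed.
#' @param family Family label used in gene leaf names (`genome:family:copy`).
#' @param max_resample Maximum number of attempts when the family goes
#'   globally extinct before reaching any tip (then an error).
#' @return An object of class `gene_family`: list with elements
#'   \describe{
#'   \item{tree}{the gene tree (`phylo`, branch lengths in Ma; a 1-copy
#'     family is returned as a `single_tip` stub with a `tip.label`)}
#'   \item{branches}{data frame, one row per species branch (keyed by the
#'     child node id and its descendant tip set) plus a virtual `root`
#'     branch, with columns `entering`, `dups`, `losses`, `exiting`}
#'   \item{leaf_counts}{named integer vector, gene copies per genome}
#'   \item{rates}{`c(dup, loss)`}
#'   \item{n_resampled}{extinct histories discarded before this one}
#'   }
#' @export
sim_gene_family <- function(species_tree, dup_rate, loss_rate, seed = 1L,
                            family = "fam1", max_resample = 10000L) {
  stopifnot(inherits(species_tree, "phylo"), dup_rate >= 0, loss_rate >= 0)
  age <- node_ages(species_tree)
  ntip <- length(species_tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + species_tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(species_tree$edge))) {
    e <- species_tree$edge[i, ]
    kids[[e[1]]] <- c(kids[[e[1]]], e[2])
  }
  with_seed(seed, {
    for (attempt in seq_len(max_resample)) {
      env <- new.env(parent = emptyenv())
      env$entering <- integer(nn); env$dups <- integer(nn)
      env$losses <- integer(nn); env$exiting <- integer(nn)
      env$copy_idx <- integer(ntip)
      rate_tot <- dup_rate + loss_rate

      at_node <- function(sp) {
        env$exiting[sp] <- env$exiting[sp] + 1L
        if (sp <= ntip) {
          env$copy_idx[sp] <- env$copy_idx[sp] + 1L
          return(list(age = 0,
                      label = paste(species_tree$tip.label[sp], family,
                                    env$copy_idx[sp], sep = ":")))
        }
        subs <- list()
        for (ch in kids[[sp]]) {
          env$entering[ch] <- env$entering[ch] + 1L
          s <- evolve_branch(age[sp], ch)
          if (!is.null(s)) subs[[length(subs) + 1L]] <- s
        }
        if (length(subs) == 0L) return(NULL)
        if (length(subs) == 1L) return(subs[[1L]])
        list(age = age[sp], children = subs)
      }
      # One lineage alive on the branch above species node `sp`, at time
      # `t_top`. Entering counts are tallied by the caller: duplicated
      # sub-lineages continue on the same branch without re-entering it.
      evolve_branch <- function(t_top, sp) {
        t_bot <- age[sp]
        t_ev <- if (rate_tot > 0) t_top - stats::rexp(1, rate_tot) else -Inf
        if (t_ev <= t_bot) return(at_node(sp))
        if (stats::runif(1) < loss_rate / rate_tot) {
          env$losses[sp] <- env$losses[sp] + 1L
          return(NULL)
        }
        env$dups[sp] <- env$dups[sp] + 1L
        left <- evolve_branch(t_ev, sp)
        right <- evolve_branch(t_ev, sp)
        if (is.null(left) && is.null(right)) return(NULL)
        if (is.null(left)) return(right)
        if (is.null(right)) return(left)
        list(age = t_ev, children = list(left, right))
      }

      env$entering[root] <- 1L
      gt <- at_node(root)
      if (!is.null(gt)) {
        n_resampled <- attempt - 1L
        break
      }
      gt <- NULL
    }
    if (is.null(gt))
      stop("family went extinct in all ", max_resample, " attempts")

    tu <- tips_under(species_tree)
    nodes <- c(root, setdiff(seq_len(nn), root))
    br <- data.frame(
      node = nodes,
      key = c("root", vapply(tu[setdiff(seq_len(nn), root)],
                             paste, character(1), collapse = "|")),
      entering = env$entering[nodes],
      dups = env$dups[nodes],
      losses = env$losses[nodes],
      exiting = env$exiting[nodes],
      stringsAsFactors = FALSE
    )
    lc <- env$copy_idx
    names(lc) <- species_tree$tip.label
    tree <- nested_to_phylo(gt)
    structure(list(tree = tree, branches = br, leaf_counts = lc,
                   rates = c(dup = dup_rate, loss = loss_rate),
                   family = family, n_resampled = n_resampled),
              class = "gene_family")
  })
}

#' @keywords internal
count_nested_leaves <- function(node) {
  if (!is.null(node$label)) return(1L)
  sum(vapply(node$children, count_nested_leaves, integer(1)))
}

# Convert a nested (age, children|label) structure into a phylo object with
# branch lengths equal to age differences. A single leaf becomes a
# `single_tip` stub because ape cannot represent 1-tip trees.
#' @keywords internal
nested_to_phylo <- function(node) {
  nleaf <- count_nested_leaves(node)
  if (nleaf == 1L) {
    lab <- local({
      n <- node
      while (is.null(n$label)) n <- n$children[[1L]]
      n$label
    })
    return(structure(list(tip.label = lab), class = "single_tip"))
  }
  env <- new.env(parent = emptyenv())
  env$tip <- 0L; env$int <- nleaf; env$edges <- NULL; env$lens <- NULL
  env$labels <- character(nleaf)
  walk <- function(n) {
    if (!is.null(n$label)) {
      env$tip <- env$tip + 1L
      env$labels[env$tip] <- n$label
      return(c(env$tip, n$age))
    }
    env$int <- env$int + 1L
    my_id <- env$int
    for (ch in n$children) {
      res <- walk(ch)
      env$edges <- rbind(env$edges, c(my_id, res[1]))
      env$lens <- c(env$lens, n$age - res[2])
    }
    c(my_id, n$age)
  }
  walk(node)
  phy <- structure(list(edge = env$edges, tip.label = env$labels,
                        edge.length = env$lens,
                        Nnode = env$int - nleaf),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Check the copy-number conservation law of a simulated family
#'
#' Verifies, for every species branch, that
#' `exiting == entering + dups - losses`, that each child branch's entering
#' count equals its parent branch's exiting count, and that terminal-branch
#' exiting counts equal the gene-tree leaf counts per genome.
#'
#' @param fam A `gene_family` object.
#' @param species_tree The species tree it was simulated on.
#' @return TRUE (invisibly) or an error describing the violated branch.
#' @export
check_conservation <- function(fam, species_tree) {
  br <- fam$branches
  bad <- which(br$exiting != br$entering + br$dups - br$losses)
  if (length(bad))
    stop("conservation violated on branch ", br$key[bad[1]])
  ntip <- length(species_tree$tip.label)
  for (i in seq_len(nrow(species_tree$edge))) {
    p <- species_tree$edge[i, 1]; ch <- species_tree$edge[i, 2]
    ex_p <- br$exiting[br$node == p]
    en_c <- br$entering[br$node == ch]
    if (ex_p != en_c)
      stop("entering(child) != exiting(parent) at node ", ch)
  }
  lc <- br$exiting[match(seq_len(ntip), br$node)]
  obs <- fam$leaf_counts[species_tree$tip.label]
  if (any(lc != obs))
    stop("leaf exiting counts do not match gene-tree leaf counts")
  invisible(TRUE)
}
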