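# Weak-branch rearrangement: collapse poorly supported gene-tree edges
# into polytomies and re-resolve them to the duplication-loss-minimal
# configuration, exhaustively when the resolution space is small and by
# NNI hill-climbing (flagged heuristic) otherwise.

# --- nested-list topology helpers -----------------------------------------
# A nested node is list(label=) for a leaf or list(children=list(...)).

#' @keywords internal
phylo_to_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  sup <- tree$support
  rec <- function(node) {
    if (node <= ntip) return(list(label = tree$tip.label[node]))
    s <- if (!is.null(sup)) sup[node - ntip] else NA_real_
    list(children = lapply(kids[[node]], rec), support = s)
  }
  rec(ntip + 1L)
}

#' @keywords internal
nested_to_phylo_topo <- function(node) {
  env <- new.env(parent = emptyenv())
  env$labels <- character(0); env$edges <- NULL
  count <- function(n) if (!is.null(n$label)) 1L else
    sum(vapply(n$children, count, integer(1)))
  nleaf <- count(node)
  env$tip <- 0L; env$int <- nleaf
  walk <- function(n) {
    if (!is.null(n$label)) {
      env$tip <- env$tip + 1L
      env$labels[env$tip] <- n$label
      return(env$tip)
    }
    env$int <- env$int + 1L
    my_id <- env$int
    for (ch in n$children) {
      cid <- walk(ch)
      env$edges <- rbind(env$edges, c(my_id, cid))
    }
    my_id
  }
  walk(node)
  phy <- structure(list(edge = env$edges, tip.label = env$labels,
                        Nnode = env$int - nleaf),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# collapse internal edges whose child support is below the threshold
#' @keywords internal
collapse_weak <- function(nested, threshold) {
  rec <- function(n) {
    if (!is.null(n$label)) return(n)
    new_children <- list()
    for (ch in n$children) {
      ch <- rec(ch)
      weak <- is.null(ch$label) && !is.na(ch$support %||% NA_real_) &&
        (ch$support %||% Inf) < threshold
      if (weak) new_children <- c(new_children, ch$children)
      else new_children <- c(new_children, list(ch))
    }
    list(children = new_children, support = n$support %||% NA_real_)
  }
  rec(nested)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of rooted binary topologies on m labeled blocks: (2m-3)!!
#' @keywords internal
n_rooted_topologies <- function(m) {
  if (m <= 2) return(1)
  prod(seq(3, 2 * m - 3, by = 2))
}

#' @keywords internal
count_resolutions <- function(n) {
  if (!is.null(n$label)) return(1)
  child_counts <- vapply(n$children, count_resolutions, numeric(1))
  prod(child_counts) * n_rooted_topologies(length(n$children))
}

# all rooted binary topologies joining the given blocks (nested nodes)
#' @keywords internal
binary_joins <- function(blocks) {
  m <- length(blocks)
  if (m == 1L) return(list(blocks[[1]]))
  if (m == 2L) return(list(list(children = blocks)))
  prev <- binary_joins(blocks[-m])
  out <- list()
  insert_all <- function(t, b) {
    res <- list(list(children = list(t, b)))
    if (is.null(t$label)) {
      for (i in seq_along(t$children)) {
        for (sub in insert_all(t$children[[i]], b)) {
          t2 <- t
          t2$children[[i]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  for (t in prev) out <- c(out, insert_all(t, blocks[[m]]))
  out
}

# all binary resolutions of a (possibly multifurcating) nested tree
#' @keywords internal
enumerate_resolutions <- function(n) {
  if (!is.null(n$label)) return(list(n))
  child_res <- lapply(n$children, enumerate_resolutions)
  combos <- list(list())
  for (cr in child_res) {
    combos <- unlist(lapply(combos, function(acc)
      lapply(cr, function(x) c(acc, list(x)))), recursive = FALSE)
  }
  out <- list()
  for (blocks in combos) out <- c(out, binary_joins(blocks))
  out
}

# the two NNI neighbours across the edge above internal node `path`
#' @keywords internal
nni_neighbours <- function(nested, path) {
  get_node <- function(n, p) { for (i in p) n <- n$children[[i]]; n }
  set_node <- function(n, p, v) {
    if (!length(p)) return(v)
    n$children[[p[1]]] <- set_node(n$children[[p[1]]], p[-1], v)
    n
  }
  parent_path <- path[-length(path)]
  child_idx <- path[length(path)]
  parent <- get_node(nested, parent_path)
  node <- parent$children[[child_idx]]
  if (!is.null(node$label) || length(node$children) != 2L) return(list())
  sib_idx <- setdiff(seq_along(parent$children), child_idx)
  out <- list()
  for (s in sib_idx) {
    for (k in 1:2) {
      p2 <- parent
      sib <- p2$children[[s]]
      node2 <- node
      moved <- node2$children[[k]]
      node2$children[[k]] <- sib
      p2$children[[s]] <- moved
      p2$children[[child_idx]] <- node2
      out <- c(out, list(set_node(nested, parent_path, p2)))
    }
  }
  out
}

#' @keywords internal
weak_paths <- function(nested, threshold) {
  out <- list()
  rec <- function(n, path) {
    if (!is.null(n$label)) return()
    for (i in seq_along(n$children)) {
      ch <- n$children[[i]]
      if (is.null(ch$label)) {
        s <- ch$support %||% NA_real_
        if (!is.na(s) && s < threshold)
          out[[length(out) + 1L]] <<- c(path, i)
        rec(ch, c(path, i))
      }
    }
  }
  rec(nested, integer(0))
  out
}

#' Rearrange weakly supported gene-tree branches to minimize DL cost
#'
#' Internal edges with support strictly below `support_threshold` are
#' collapsed into polytomies, which are re-resolved to minimize the total
#' duplication + loss cost against the species tree. The search is
#' exhaustive over all joint resolutions when their number is at most
#' `max_exhaustive`; otherwise NNI hill-climbing across the weak edges is
#' used and the result is flagged heuristic. The returned cost never
#' exceeds the input tree's cost.
#'
#' @param gene_tree Rooted binary `phylo` with `$support`.
#' @param species_tree Rooted binary `phylo`.
#' @param leafmap Named character vector gene leaf -> genome.
#' @param support_threshold Percent in `[0, 100]`; edges with support
#'   strictly below it are rearrangeable (0 therefore changes nothing).
#' @param max_exhaustive Cap on the exhaustive resolution count.
#' @return List with `tree` (rearranged `phylo`), `result` (its
#'   `reconciliation`), `cost`, `input_cost`, `heuristic`.
#' @export
rearrange_weak <- function(gene_tree, species_tree,
                           leafmap = leafmap_from_labels(gene_tree$tip.label),
                           support_threshold = 70,
                           max_exhaustive = 20000) {
  if (support_threshold < 0 || support_threshold > 100)
    stop("support_threshold must be in [0, 100]")
  res0 <- reconcile_dl(gene_tree, species_tree, leafmap)
  nested0 <- phylo_to_nested(gene_tree)
  collapsed <- collapse_weak(nested0, support_threshold)
  n_res <- count_resolutions(collapsed)
  if (n_res == 1) {
    return(list(tree = gene_tree, result = res0, cost = res0$cost,
                input_cost = res0$cost, heuristic = FALSE))
  }
  best_tree <- gene_tree; best_res <- res0
  if (n_res <= max_exhaustive) {
    for (cand in enumerate_resolutions(collapsed)) {
      tr <- nested_to_phylo_topo(cand)
      r <- reconcile_dl(tr, species_tree, leafmap)
      if (r$cost < best_res$cost) { best_res <- r; best_tree <- tr }
    }
    heuristic <- FALSE
  } else {
    cur <- nested0
    repeat {
      improved <- FALSE
      for (p in weak_paths(cur, support_threshold)) {
        for (nb in nni_neighbours(cur, p)) {
          tr <- nested_to_phylo_topo(nb)
          r <- reconcile_dl(tr, species_tree, leafmap)
          if (r$cost < best_res$cost) {
            best_res <- r; best_tree <- tr; cur <- nb; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    heuristic <- TRUE
  }
  list(tree = best_tree, result = best_res, cost = best_res$cost,
       input_cost = res0$cost, heuristic = heuristic)
}
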