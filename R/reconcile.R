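# Duplication-loss parsimony reconciliation of gene trees against a rooted
# binary species tree: LCA mapping, event inference with unit costs,
# per-branch duplication/loss tallies, ancestral copy numbers via the
# conservation law, minimum-cost rooting, weak-branch rearrangement and
# bootstrap averaging.

#' Leaf map from gene leaf labels
#'
#' Gene copies are labeled `genome:family:copy`; the genome is the prefix
#' before the first separator.
#'
#' @param labels Gene-tree tip labels.
#' @param sep Separator (default `":"`).
#' @return Named character vector: gene leaf -> genome.
#' @export
leafmap_from_labels <- function(labels, sep = ":") {
  out <- vapply(strsplit(labels, sep, fixed = TRUE), `[[`, character(1), 1L)
  names(out) <- labels
  out
}

# Precomputed species-tree index: parents, depths, children, clade keys.
#' @keywords internal
species_index <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  nn <- ntip + species_tree$Nnode
  parent <- rep(NA_integer_, nn)
  kids <- vector("list", nn)
  for (i in seq_len(nrow(species_tree$edge))) {
    e <- species_tree$edge[i, ]
    parent[e[2]] <- e[1]
    kids[[e[1]]] <- c(kids[[e[1]]], e[2])
  }
  root <- ntip + 1L
  depth <- rep(NA_integer_, nn)
  depth[root] <- 0L
  ord <- ape::reorder.phylo(species_tree, "cladewise")
  for (i in seq_len(nrow(ord$edge)))
    depth[ord$edge[i, 2]] <- depth[ord$edge[i, 1]] + 1L
  tu <- tips_under(species_tree)
  keys <- vapply(tu, paste, character(1), collapse = "|")
  list(ntip = ntip, nn = nn, root = root, parent = parent, kids = kids,
       depth = depth, keys = keys, tips = species_tree$tip.label)
}

#' @keywords internal
species_lca <- function(si, a, b) {
  while (a != b) {
    if (si$depth[a] < si$depth[b]) b <- si$parent[b]
    else if (si$depth[b] < si$depth[a]) a <- si$parent[a]
    else { a <- si$parent[a]; b <- si$parent[b] }
  }
  a
}

#' LCA mapping of gene-tree nodes onto the species tree
#'
#' Maps each gene leaf to its genome's species leaf and each internal gene
#' node to the most recent common ancestor of its children's images.
#'
#' @param gene_tree Rooted `phylo` (or `single_tip` stub).
#' @param species_tree Rooted binary `phylo`.
#' @param leafmap Named character vector gene leaf -> genome; default
#'   derived from `genome:...` leaf labels.
#' @return Integer vector: species node id per gene node (gene-tree node
#'   numbering).
#' @export
lca_map <- function(gene_tree, species_tree,
                    leafmap = leafmap_from_labels(gene_tree$tip.label)) {
  si <- species_index(species_tree)
  if (inherits(gene_tree, "single_tip")) {
    g <- leafmap[[gene_tree$tip.label]]
    m <- match(g, species_tree$tip.label)
    if (is.na(m)) stop("gene leaf maps to unknown genome: ", g)
    return(m)
  }
  gt <- gene_tree
  ntip <- length(gt$tip.label)
  M <- rep(NA_integer_, ntip + gt$Nnode)
  gm <- leafmap[gt$tip.label]
  bad <- which(is.na(gm) | !(gm %in% species_tree$tip.label))
  if (length(bad))
    stop("gene leaf maps to unknown genome: ",
         paste(gt$tip.label[bad], collapse = ", "))
  M[seq_len(ntip)] <- match(gm, species_tree$tip.label)
  po <- ape::reorder.phylo(gt, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    M[p] <- if (is.na(M[p])) M[ch] else species_lca(si, M[p], M[ch])
  }
  M
}

#' Duplication-loss reconciliation with ancestral copy numbers
#'
#' LCA reconciliation under unit duplication and loss costs. An internal
#' gene node is a duplication iff its species image equals a child's image.
#' Losses on a gene edge (u, v) follow the path-length rule (`d - 1` below
#' a speciation, `d` below a duplication, `d` = species edges between the
#' images) and are attributed to the sibling species branches pruned along
#' the path; duplications are attributed to the species branch entering
#' their image (a virtual `root` branch for the species root). Copy
#' numbers follow from `exiting = entering + dups - losses` starting from a
#' single copy entering the branch above the gene root's image.
#'
#' Duplications whose image is a species leaf happen within that species;
#' they are included in the cost and the branch tally but also reported in
#' `within_dups` so presentation layers can exclude them.
#'
#' @inheritParams lca_map
#' @return Object of class `reconciliation`: list with `M` (LCA map),
#'   `events` (per gene internal node: `"speciation"`/`"duplication"`),
#'   `branches` (data frame: `node`, `key`, `entering`, `dups`,
#'   `within_dups`, `losses`, `exiting`; first row the virtual `root`
#'   branch), `duplications`, `losses`, `cost`, `origin` (species node of
#'   the gene root's image).
#' @export
reconcile_dl <- function(gene_tree, species_tree, leafmap = NULL) {
  if (is.null(leafmap)) leafmap <- leafmap_from_labels(gene_tree$tip.label)
  si <- species_index(species_tree)
  dups <- integer(si$nn); losses <- integer(si$nn); wdups <- integer(si$nn)
  root_dups <- 0L
  M <- lca_map(gene_tree, species_tree, leafmap)

  if (inherits(gene_tree, "single_tip")) {
    origin <- M[1]
    events <- character(0)
    obs <- table(factor(species_tree$tip.label[origin],
                        levels = species_tree$tip.label))
  } else {
    gt <- gene_tree
    gntip <- length(gt$tip.label)
    if (any(tabulate(gt$edge[, 1]) > 2))
      stop("gene tree must be binary for reconciliation")
    origin <- M[gntip + 1L]
    events <- rep("speciation", gt$Nnode)
    kids_g <- vector("list", gntip + gt$Nnode)
    for (i in seq_len(nrow(gt$edge)))
      kids_g[[gt$edge[i, 1]]] <- c(kids_g[[gt$edge[i, 1]]], gt$edge[i, 2])
    for (u in (gntip + 1L):(gntip + gt$Nnode)) {
      if (any(M[kids_g[[u]]] == M[u])) {
        events[u - gntip] <- "duplication"
        if (M[u] == si$root) root_dups <- root_dups + 1L
        else dups[M[u]] <- dups[M[u]] + 1L
        if (M[u] <= si$ntip) wdups[M[u]] <- wdups[M[u]] + 1L
      }
    }
    # losses along each gene edge
    for (i in seq_len(nrow(gt$edge))) {
      u <- gt$edge[i, 1]; v <- gt$edge[i, 2]
      is_dup <- events[u - gntip] == "duplication"
      # path M(u) = s0, s1, ..., sk = M(v)
      path <- M[v]
      while (path[1] != M[u]) path <- c(si$parent[path[1]], path)
      k <- length(path) - 1L
      if (k == 0L) next
      from <- if (is_dup) 1L else 2L
      if (from <= k) for (j in from:k) {
        s <- path[j]          # node where the pruned sibling hangs
        nxt <- path[j + 1L]
        sib <- setdiff(si$kids[[s]], nxt)
        losses[sib] <- losses[sib] + 1L
      }
    }
    obs <- table(factor(leafmap[gt$tip.label],
                        levels = species_tree$tip.label))
  }

  # copy numbers by conservation, from one copy entering the origin branch;
  # branches outside the origin's subtree stay at zero
  entering <- integer(si$nn); exiting <- integer(si$nn)
  in_scope <- rep(FALSE, si$nn)
  in_scope[origin] <- TRUE
  root_entering <- 0L; root_exiting <- 0L
  if (origin == si$root) {
    root_entering <- 1L
    root_exiting <- 1L + root_dups
  }
  ord <- order(si$depth)  # preorder by depth
  for (nd in ord) {
    if (nd == si$root) next
    if (!in_scope[nd] && !in_scope[si$parent[nd]]) next
    in_scope[nd] <- TRUE
    entering[nd] <- if (nd == origin && origin != si$root) 1L
                    else if (si$parent[nd] == si$root) root_exiting
                    else exiting[si$parent[nd]]
    exiting[nd] <- entering[nd] + dups[nd] - losses[nd]
  }
  # observed leaf counts must be reproduced by the conservation law
  leaf_ex <- exiting[seq_len(si$ntip)]
  if (!all(leaf_ex == as.integer(obs)))
    stop("internal error: conservation law does not reproduce leaf counts")

  nodes <- setdiff(seq_len(si$nn), si$root)
  branches <- data.frame(
    node = c(NA_integer_, nodes),
    key = c("root", si$keys[nodes]),
    entering = c(root_entering, entering[nodes]),
    dups = c(root_dups, dups[nodes]),
    within_dups = c(0L, wdups[nodes]),
    losses = c(0L, losses[nodes]),
    exiting = c(root_exiting, exiting[nodes]),
    stringsAsFactors = FALSE
  )
  total_d <- root_dups + sum(dups)
  total_l <- sum(losses)
  structure(list(M = M, events = events,
                 branches = branches, duplications = total_d,
                 losses = total_l, cost = total_d + total_l,
                 origin = origin, species_tree = species_tree),
            class = "reconciliation")
}

#' Root an unrooted gene tree by minimizing duplication-loss cost
#'
#' Tries every edge of the unrooted tree as root position, reconciles, and
#' returns the rooting with minimal total cost; ties break by smallest
#' duplication count, then by lexicographically smallest induced root
#' bipartition, so the result is deterministic.
#'
#' @param gene_tree `phylo` (rooted input is unrooted first; >= 3 leaves).
#' @param species_tree Rooted binary `phylo`.
#' @param leafmap Named character vector gene leaf -> genome.
#' @return The rooted `phylo`; attributes `cost` and `result` hold the
#'   reconciliation at the chosen rooting.
#' @export
root_min_dl <- function(gene_tree, species_tree,
                        leafmap = leafmap_from_labels(gene_tree$tip.label)) {
  stopifnot(length(gene_tree$tip.label) >= 3L)
  ut <- if (ape::is.rooted(gene_tree)) ape::unroot(gene_tree) else gene_tree
  if (is.null(ut$edge.length)) ut$edge.length <- rep(1, nrow(ut$edge))
  tu <- tips_under(ut)
  universe <- sort(ut$tip.label)
  best <- NULL
  for (i in seq_len(nrow(ut$edge))) {
    side <- tu[[ut$edge[i, 2]]]
    if (length(side) == length(universe)) next
    rt <- tryCatch(ape::root(ut, outgroup = side, resolve.root = TRUE),
                   error = function(e) NULL)
    if (is.null(rt) || !ape::is.rooted(rt)) next
    res <- reconcile_dl(rt, species_tree, leafmap)
    cand <- list(tree = rt, res = res,
                 cost = res$cost, d = res$duplications,
                 bip = clade_key(side, universe))
    if (is.null(best) ||
        cand$cost < best$cost ||
        (cand$cost == best$cost && cand$d < best$d) ||
        (cand$cost == best$cost && cand$d == best$d && cand$bip < best$bip)) {
      best <- cand
    }
  }
  out <- best$tree
  attr(out, "cost") <- best$cost
  attr(out, "result") <- best$res
  out
}

#' Ancestral copy numbers at requested species nodes
#'
#' @param result A `reconciliation` (or averaged) object.
#' @param nodes Character vector of branch keys: `"root"` or the
#'   `|`-joined sorted descendant tip sets of species nodes; or a list of
#'   tip vectors.
#' @return Named numeric vector of exiting copy counts.
#' @export
ancestral_copy_numbers <- function(result, nodes) {
  br <- result$branches
  if (is.list(nodes))
    nodes <- vapply(nodes, function(x) paste(sort(x), collapse = "|"),
                    character(1))
  # the species root is the virtual "root" branch; accept its full tip set
  leaves <- br$key[!grepl("|", br$key, fixed = TRUE) & br$key != "root"]
  full <- paste(sort(leaves), collapse = "|")
  nodes_eff <- ifelse(nodes == full, "root", nodes)
  idx <- match(nodes_eff, br$key)
  if (anyNA(idx))
    stop("unknown species node: ", paste(nodes[is.na(idx)], collapse = ", "))
  col <- if ("exiting" %in% names(br)) "exiting" else "mean_exiting"
  stats::setNames(br[[col]][idx], nodes)
}

#' Average reconciliations across bootstrap replicate gene trees
#'
#' Each replicate tree is reconciled independently (optionally after
#' weak-branch rearrangement) and per-branch duplication counts and exiting
#' copy numbers are averaged arithmetically.
#'
#' @param replicate_trees List of rooted `phylo` objects over the same leaf
#'   set.
#' @param species_tree Rooted binary `phylo`.
#' @param leafmap Named character vector gene leaf -> genome (shared).
#' @param support_threshold Percent threshold for [rearrange_weak()], or
#'   NULL for plain reconciliation.
#' @return Object of class `averaged_reconciliation`: list with `branches`
#'   (data frame `key`, `mean_dups`, `mean_within_dups`, `mean_losses`,
#'   `mean_exiting`, `min_dups`, `max_dups`), `n_replicates`.
#' @export
bootstrap_average <- function(replicate_trees, species_tree, leafmap = NULL,
                              support_threshold = NULL) {
  stopifnot(length(replicate_trees) >= 1L)
  ref <- sort(replicate_trees[[1]]$tip.label)
  for (i in seq_along(replicate_trees)) {
    if (!identical(sort(replicate_trees[[i]]$tip.label), ref))
      stop("replicate ", i, " has a mismatched leaf set")
  }
  if (is.null(leafmap)) leafmap <- leafmap_from_labels(ref)
  acc <- NULL
  for (i in seq_along(replicate_trees)) {
    tr <- replicate_trees[[i]]
    res <- if (!is.null(support_threshold))
      rearrange_weak(tr, species_tree, leafmap, support_threshold)$result
    else reconcile_dl(tr, species_tree, leafmap)
    br <- res$branches
    if (is.null(acc)) {
      acc <- br[, c("node", "key")]
      acc$sum_dups <- 0; acc$sum_wdups <- 0; acc$sum_losses <- 0
      acc$sum_ex <- 0; acc$min_dups <- Inf; acc$max_dups <- -Inf
    }
    stopifnot(identical(acc$key, br$key))
    acc$sum_dups <- acc$sum_dups + br$dups
    acc$sum_wdups <- acc$sum_wdups + br$within_dups
    acc$sum_losses <- acc$sum_losses + br$losses
    acc$sum_ex <- acc$sum_ex + br$exiting
    acc$min_dups <- pmin(acc$min_dups, br$dups)
    acc$max_dups <- pmax(acc$max_dups, br$dups)
  }
  n <- length(replicate_trees)
  branches <- data.frame(
    node = acc$node, key = acc$key,
    mean_dups = acc$sum_dups / n,
    mean_within_dups = acc$sum_wdups / n,
    mean_losses = acc$sum_losses / n,
    mean_exiting = acc$sum_ex / n,
    min_dups = acc$min_dups, max_dups = acc$max_dups,
    stringsAsFactors = FALSE
  )
  structure(list(branches = branches, n_replicates = n),
            class = "averaged_reconciliation")
}
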