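# Tree data model and Newick I/O.
#
# Trees are ape "phylo" objects throughout, optionally carrying two extra
# elements maintained by this package:
#   $support : numeric, length Nnode, support per internal node (0-100 scale,
#              NA where absent), stored on the child node of the edge it
#              annotates;
#   $age     : numeric, length Ntip + Nnode, node ages in Ma (tips 0 for
#              ultrametric trees).

#' Parse a Newick string into a tree
#'
#' Internal node labels are interpreted as support values when numeric.
#' Supports on a 0-1 scale (posterior probabilities) are auto-detected and
#' normalized to 0-100.
#'
#' @param text A Newick string (single tree, terminated by `;`).
#' @return A `phylo` object with `$support` populated (NA where absent).
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string", depth))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick: could not parse tree")
  # unwrap single-quoted labels (ape keeps the quote characters)
  quoted <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[quoted] <-
    gsub("''", "'", sub("^'(.*)'$", "\\1", tree$tip.label[quoted]))
  sup <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
  }
  tree$support <- normalize_support(sup)
  tree$node.label <- NULL
  tree
}

#' @keywords internal
normalize_support <- function(s) {
  if (all(is.na(s))) return(s)
  if (max(s, na.rm = TRUE) <= 1) s * 100 else s
}

#' Serialize a tree to Newick with canonical child ordering
#'
#' Children of every node are ordered by their smallest descendant leaf
#' label, so two isomorphic trees serialize identically.
#'
#' @param tree A `phylo` object.
#' @param include Character vector choosing optional fields: any of
#'   `"lengths"` and `"supports"`. Requesting a field the tree lacks is an
#'   error. The default serializes whichever of the two the tree carries.
#' @param digits Significant digits for numeric fields.
#' @return A single Newick string.
#' @export
write_newick <- function(tree, include = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(include)) {
    include <- character(0)
    if (!is.null(tree$edge.length)) include <- c(include, "lengths")
    if (!is.null(tree$support) && any(!is.na(tree$support)))
      include <- c(include, "supports")
  }
  want_len <- "lengths" %in% include
  want_sup <- "supports" %in% include
  if (want_len && is.null(tree$edge.length))
    stop("tree has no branch lengths to serialize")
  if (want_sup && is.null(tree$support))
    stop("tree has no support values to serialize")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  elen <- numeric(nn)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  # smallest descendant leaf label per node (postorder fill)
  minlab <- character(nn)
  minlab[seq_len(ntip)] <- tree$tip.label
  fill <- function(node) {
    if (node <= ntip) return(minlab[node])
    labs <- vapply(kids[[node]], fill, character(1))
    minlab[node] <<- min(labs)
    minlab[node]
  }
  fill(root)
  fmt <- function(x) sprintf("%.*g", digits, x)
  quote_label <- function(s) {
    # labels holding Newick metacharacters are single-quoted
    if (grepl("[][():,; \t']", s))
      paste0("'", gsub("'", "''", s), "'")
    else s
  }
  rec <- function(node) {
    if (node <= ntip) {
      s <- quote_label(tree$tip.label[node])
    } else {
      ch <- kids[[node]]
      ch <- ch[order(minlab[ch])]
      s <- paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")")
      if (want_sup && node != root) {
        sv <- tree$support[node - ntip]
        if (!is.na(sv)) s <- paste0(s, fmt(sv))
      }
    }
    if (want_len && node != root) s <- paste0(s, ":", fmt(elen[node]))
    s
  }
  paste0(rec(root), ";")
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of taxon names (subset of the tree's tips).
#' @return The node id of the lowest node whose descendant leaf set contains
#'   all given leaves (a tip id when a single leaf is given).
#' @export
mrca_node <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), length(leaves) >= 1L)
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    stop("unknown taxon: ", paste(unknown, collapse = ", "))
  leaves <- unique(leaves)
  if (length(leaves) == 1L) return(match(leaves, tree$tip.label))
  ape::getMRCA(tree, leaves)
}

#' Node ages from branch lengths
#'
#' For an ultrametric tree, returns the age of every node (distance to the
#' tips). If the tree carries an `$age` element it is returned as-is.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  if (!is.null(tree$age)) return(tree$age)
  stopifnot(!is.null(tree$edge.length))
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Descendant tip labels of every node
#' @keywords internal
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  lapply(out, sort)
}

#' Canonical key for a bipartition of a taxon set
#'
#' The key is the sorted side of the split that does not contain the
#' alphabetically first taxon of the universe, so a bipartition and its
#' complement map to the same key.
#'
#' @param taxa Taxa on one side of the split.
#' @param universe All taxa.
#' @return A single string key.
#' @export
clade_key <- function(taxa, universe) {
  taxa <- sort(unique(taxa))
  universe <- sort(unique(universe))
  stopifnot(all(taxa %in% universe))
  ref <- universe[1]
  side <- if (ref %in% taxa) setdiff(universe, taxa) else taxa
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions induced by a tree
#'
#' One bipartition per internal edge, in the unrooted view: splits with at
#' least two taxa on each side. The root edge is excluded (the two edges at
#' a bifurcating root induce the same split and are counted once). A star
#' tree yields an empty set.
#'
#' @param tree A `phylo` object (rooted or unrooted, polytomies allowed).
#' @return Character vector of canonical split keys (see [clade_key()]).
#' @export
clade_set <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character(0))
  universe <- sort(tree$tip.label)
  tu <- tips_under(tree)
  root <- ntip + 1L
  internal <- setdiff(seq_len(ntip + tree$Nnode), c(seq_len(ntip), root))
  keys <- character(0)
  for (nd in internal) {
    side <- tu[[nd]]
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      keys <- c(keys, clade_key(side, universe))
  }
  sort(unique(keys))
}

#' Rooted clades of a tree (descendant tip sets of internal nodes)
#'
#' Unlike [clade_set()], this keeps the rooted view: every internal
#' non-root node contributes its descendant tip set.
#'
#' @param tree A `phylo` object.
#' @return List of sorted character vectors, named by their `|`-joined tips.
#' @export
rooted_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  tu <- tips_under(tree)
  root <- ntip + 1L
  internal <- setdiff(seq_len(ntip + tree$Nnode), c(seq_len(ntip), root))
  out <- tu[internal]
  names(out) <- vapply(out, paste, character(1), collapse = "|")
  out
}

#' @keywords internal
node_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

#' @keywords internal
node_parent <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (!length(p)) NA_integer_ else p
}
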