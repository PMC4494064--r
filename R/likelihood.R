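# Substitution models and a Felsenstein pruning likelihood engine for
# amino-acid (or recoded 6-state) alignments with discrete-gamma rate
# heterogeneity. The engine powers four-cluster likelihood mapping and the
# distance estimator used in random-addition concatenation.

AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Construct a reversible substitution model
#'
#' The rate matrix is `Q[i,j] = R[i,j] * pi[j]`, rescaled so the expected
#' number of substitutions per unit branch length is 1. Rate heterogeneity
#' uses `n_cat` equiprobable discrete-gamma categories with shape
#' `gamma_shape` (mean rate 1).
#'
#' @param states Number of states (20 for amino acids, 6 for Dayhoff
#'   recoding).
#' @param exch `"poisson"` for equal exchangeabilities, or a symmetric
#'   `states x states` matrix (e.g. read with [read_paml_matrix()]).
#' @param freqs Stationary frequencies (default uniform); must sum to 1.
#' @param gamma_shape Gamma shape alpha (> 0).
#' @param n_cat Number of discrete gamma categories (1 = no heterogeneity).
#' @param labels State symbols; defaults to the standard one-letter amino
#'   acid order for 20 states and `0:5` for 6 states.
#' @return An object of class `subst_model`.
#' @export
subst_model <- function(states = 20L, exch = "poisson", freqs = NULL,
                        gamma_shape = 1, n_cat = 4L, labels = NULL) {
  states <- as.integer(states)
  if (gamma_shape <= 0) stop("gamma_shape must be > 0")
  if (is.null(labels))
    labels <- if (states == 20L) AA_ORDER else as.character(seq_len(states) - 1L)
  stopifnot(length(labels) == states)
  if (is.null(freqs)) freqs <- rep(1 / states, states)
  stopifnot(length(freqs) == states, abs(sum(freqs) - 1) < 1e-8, all(freqs > 0))
  if (identical(exch, "poisson")) {
    R <- matrix(1, states, states)
  } else {
    R <- as.matrix(exch)
    stopifnot(nrow(R) == states, ncol(R) == states,
              isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
  }
  diag(R) <- 0
  Q <- R * rep(freqs, each = states)
  diag(Q) <- -rowSums(Q)
  beta <- -1 / sum(freqs * diag(Q))
  Q <- Q * beta
  # symmetric eigendecomposition of D^1/2 Q D^-1/2 (reversibility)
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- diag(1 / d) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(d)
  structure(list(states = states, labels = labels, freqs = freqs, Q = Q,
                 eigenval = eig$values, V = V, Vinv = Vinv,
                 gamma_shape = gamma_shape, n_cat = as.integer(n_cat),
                 cat_rates = discrete_gamma_rates(gamma_shape, n_cat)),
            class = "subst_model")
}

#' Mean rates of equiprobable discrete gamma categories
#' @keywords internal
discrete_gamma_rates <- function(alpha, k) {
  k <- as.integer(k)
  if (k == 1L) return(1)
  b <- c(0, stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha), Inf)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

#' Transition probability matrix P(t)
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions/site).
#' @return `states x states` matrix.
#' @export
pmat <- function(model, t) {
  P <- model$V %*% (exp(model$eigenval * t) * model$Vinv)
  P[P < 0] <- 0
  P
}

#' Read a PAML-format exchangeability matrix (e.g. LG)
#'
#' Expects the standard lower-triangular 19-row layout followed by 20
#' stationary frequencies, in PAML amino-acid order.
#'
#' @param path File path.
#' @return List with `exch` (symmetric 20x20 matrix) and `freqs`.
#' @export
read_paml_matrix <- function(path) {
  nums <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  need <- 19 * 20 / 2 + 20
  if (length(nums) < need)
    stop("expected at least ", need, " numbers in PAML matrix file")
  R <- matrix(0, 20, 20)
  k <- 1
  for (i in 2:20) for (j in 1:(i - 1)) {
    R[i, j] <- R[j, i] <- nums[k]
    k <- k + 1
  }
  freqs <- nums[k:(k + 19)]
  freqs <- freqs / sum(freqs)
  list(exch = R, freqs = freqs)
}

# --- alignment helpers -----------------------------------------------------

#' Convert an alignment to a character matrix (taxa x sites)
#' @param aln Named character vector of equal-length sequence strings, or a
#'   character matrix with taxon rownames.
#' @return Character matrix.
#' @export
aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  stopifnot(is.character(aln), !is.null(names(aln)))
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("sequences differ in length")
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Convert a character matrix back to an alignment vector
#' @param m Character matrix with taxon rownames.
#' @return Named character vector of sequence strings.
#' @export
aln_strings <- function(m) {
  if (!is.matrix(m)) return(m)
  out <- apply(m, 1, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

# Encode an alignment into state indices (0 = gap/missing), pattern-compress.
#' @keywords internal
encode_patterns <- function(aln, model) {
  m <- aln_matrix(aln)
  idx <- matrix(match(m, model$labels), nrow = nrow(m))
  idx[is.na(idx) & !(m %in% c("-", "?", "X", "x", "*"))] <-
    NA  # keep NA for unknowns; gaps handled below
  unknown <- !(m %in% c(model$labels, "-", "?", "X", "x", "*"))
  if (any(unknown))
    stop("unknown state symbol in alignment: ",
         paste(unique(m[unknown]), collapse = ", "))
  idx[is.na(idx)] <- 0L
  rownames(idx) <- rownames(m)
  key <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(patterns = idx[, first, drop = FALSE], weights = w)
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Computes the summed per-site log-likelihood under the given reversible
#' model with discrete-gamma rate heterogeneity, with per-node rescaling for
#' numerical stability. Alignment taxa must be a subset of the tree's tips;
#' extra tips are pruned (keeping path lengths).
#'
#' @param tree `phylo` with branch lengths (expected substitutions/site).
#' @param aln Alignment (named character vector or matrix).
#' @param model A `subst_model`.
#' @return Total log-likelihood (scalar).
#' @export
tree_loglik <- function(tree, aln, model) {
  m <- aln_matrix(aln)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  missing_tax <- setdiff(rownames(m), tree$tip.label)
  if (length(missing_tax))
    stop("alignment taxa absent from tree: ", paste(missing_tax, collapse = ", "))
  extra <- setdiff(tree$tip.label, rownames(m))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  enc <- encode_patterns(m, model)
  pat <- enc$patterns[tree$tip.label, , drop = FALSE]
  npat <- ncol(pat)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  k <- model$states
  # leaf partials shared across categories
  leaf_part <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    L <- matrix(0, k, npat)
    st <- pat[i, ]
    L[cbind(st[st > 0L], which(st > 0L))] <- 1
    L[, st == 0L] <- 1
    leaf_part[[i]] <- L
  }
  site_ll_cat <- matrix(0, length(model$cat_rates), npat)
  for (ci in seq_along(model$cat_rates)) {
    r <- model$cat_rates[ci]
    partial <- vector("list", ntip + tree$Nnode)
    logscale <- matrix(0, ntip + tree$Nnode, npat)
    for (i in seq_len(ntip)) partial[[i]] <- leaf_part[[i]]
    for (ei in seq_len(nrow(po$edge))) {
      p <- po$edge[ei, 1]; ch <- po$edge[ei, 2]
      P <- pmat(model, po$edge.length[ei] * r)
      contrib <- P %*% partial[[ch]]
      if (is.null(partial[[p]])) {
        partial[[p]] <- contrib
        logscale[p, ] <- logscale[ch, ]
      } else {
        partial[[p]] <- partial[[p]] * contrib
        logscale[p, ] <- logscale[p, ] + logscale[ch, ]
      }
      if (ei %% 4L == 0L || p == root) {
        mx <- apply(partial[[p]], 2, max)
        mx[mx <= 0] <- 1
        partial[[p]] <- sweep(partial[[p]], 2, mx, "/")
        logscale[p, ] <- logscale[p, ] + log(mx)
      }
    }
    lik <- as.vector(model$freqs %*% partial[[root]])
    site_ll_cat[ci, ] <- log(lik) + logscale[root, ]
  }
  # average over categories in log space
  mx <- apply(site_ll_cat, 2, max)
  site_ll <- mx + log(colMeans(exp(sweep(site_ll_cat, 2, mx, "-"))))
  sum(site_ll * enc$weights)
}

#' Maximum-likelihood pairwise distance under an equal-frequency model
#'
#' Closed-form ML distance for a k-state model with equal exchangeabilities
#' and uniform frequencies: `d = -((k-1)/k) log(1 - (k/(k-1)) p)` with `p`
#' the proportion of differing (comparable) sites. Saturated pairs are
#' capped at `max_dist`.
#'
#' @param aln Alignment (named character vector or matrix).
#' @param model A `subst_model` (used for the state count and symbols).
#' @param max_dist Cap for saturated distances.
#' @return A `dist`-like symmetric matrix of distances.
#' @export
ml_distance <- function(aln, model, max_dist = 10) {
  m <- aln_matrix(aln)
  idx <- matrix(match(m, model$labels), nrow = nrow(m))
  n <- nrow(m); k <- model$states
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    nc <- sum(ok)
    p <- if (nc == 0) NA_real_ else sum(idx[i, ok] != idx[j, ok]) / nc
    d <- if (is.na(p)) max_dist
         else if (p >= (k - 1) / k) max_dist
         else -((k - 1) / k) * log(1 - (k / (k - 1)) * p)
    D[i, j] <- D[j, i] <- d
  }
  D
}
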