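# Four-cluster likelihood mapping: per-quartet maximum-likelihood weights
# of the three resolved topologies, mapped into the 2-simplex and binned
# into seven support regions.

#' Optimize branch lengths of one quartet topology
#'
#' Cyclic one-dimensional (Brent) optimization over the five branch lengths
#' of an unrooted quartet, to a log-likelihood tolerance of `tol` per full
#' cycle, starting from 0.1 on every branch.
#'
#' @param aln Alignment of exactly four taxa.
#' @param topology Integer 1-3 or a list of two character pairs. With taxa
#'   `t1..t4` in the order of `rownames`/`names` of the alignment, topology
#'   1 is `(t1,t2)|(t3,t4)`, 2 is `(t1,t3)|(t2,t4)`, 3 is `(t1,t4)|(t2,t3)`.
#' @param model A [subst_model()].
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_cycles Maximum optimization cycles (non-convergence is
#'   flagged, not silent).
#' @return List with `loglik`, `lengths` (5 branch lengths: four terminal,
#'   internal last), `converged`, `cycles`.
#' @export
optimize_quartet <- function(aln, topology, model, tol = 1e-6,
                             max_cycles = 100L) {
  m <- aln_matrix(aln)
  if (nrow(m) != 4L) stop("quartet alignment must have exactly 4 sequences")
  taxa <- rownames(m)
  if (is.numeric(topology)) {
    pairs <- switch(topology,
                    list(taxa[c(1, 2)], taxa[c(3, 4)]),
                    list(taxa[c(1, 3)], taxa[c(2, 4)]),
                    list(taxa[c(1, 4)], taxa[c(2, 3)]))
  } else pairs <- topology
  ordtaxa <- c(pairs[[1]], pairs[[2]])
  enc <- encode_patterns(m[ordtaxa, , drop = FALSE], model)
  pat <- enc$patterns
  w <- enc$weights
  k <- model$states
  ncat <- length(model$cat_rates)
  colsel <- function(P, s) {
    # columns of P selected by leaf states; all-ones where state missing
    M <- matrix(1, k, length(s))
    nz <- s > 0L
    M[, nz] <- P[, s[nz], drop = FALSE]
    M
  }
  # quartet likelihood rooted at the inner node joining the first pair:
  # L = sum_x pi_x (P1 L1)_x (P2 L2)_x [P5 (P3 L3 * P4 L4)]_x
  ll_fun <- function(b) {
    site_l <- numeric(ncol(pat))
    for (ci in seq_len(ncat)) {
      r <- model$cat_rates[ci]
      U <- colsel(pmat(model, b[1] * r), pat[1, ]) *
           colsel(pmat(model, b[2] * r), pat[2, ])
      W <- colsel(pmat(model, b[3] * r), pat[3, ]) *
           colsel(pmat(model, b[4] * r), pat[4, ])
      A <- pmat(model, b[5] * r) %*% W
      site_l <- site_l + colSums(model$freqs * U * A)
    }
    sum(w * log(site_l / ncat))
  }
  # per-branch profile evaluation: with the other four branches fixed, the
  # site likelihood is linear in the changing branch's leaf-partial column,
  # so the fixed factor is precomputed per rate category
  leafP <- function(bi, r) pmat(model, b[bi] * r)
  profile_opt <- function(i) {
    fixed <- vector("list", ncat)
    for (ci in seq_len(ncat)) {
      r <- model$cat_rates[ci]
      P5 <- pmat(model, b[5] * r)
      L1 <- colsel(leafP(1, r), pat[1, ]); L2 <- colsel(leafP(2, r), pat[2, ])
      L3 <- colsel(leafP(3, r), pat[3, ]); L4 <- colsel(leafP(4, r), pat[4, ])
      fixed[[ci]] <- switch(i,
        model$freqs * L2 * (P5 %*% (L3 * L4)),
        model$freqs * L1 * (P5 %*% (L3 * L4)),
        L4 * crossprod(P5, model$freqs * L1 * L2),
        L3 * crossprod(P5, model$freqs * L1 * L2),
        list(U = model$freqs * L1 * L2, W = L3 * L4))
    }
    npat <- ncol(pat)
    if (i < 5) {
      # colSums(colsel(P, s) * F)[j] == crossprod(P, F)[s_j, j]; missing
      # states contribute colSums(F)
      s <- pat[i, ]
      obs <- s > 0L
      selidx <- cbind(s[obs], which(obs))
      cs_fixed <- lapply(fixed, .colSums, m = k, n = npat)
    }
    f <- function(x) {
      site_l <- numeric(npat)
      for (ci in seq_len(ncat)) {
        r <- model$cat_rates[ci]
        if (i == 5) {
          site_l <- site_l +
            .colSums(fixed[[ci]]$U * (pmat(model, x * r) %*% fixed[[ci]]$W),
                     k, npat)
        } else {
          G <- crossprod(pmat(model, x * r), fixed[[ci]])
          contrib <- cs_fixed[[ci]]
          contrib[obs] <- G[selidx]
          site_l <- site_l + contrib
        }
      }
      sum(w * log(site_l / ncat))
    }
    stats::optimize(f, interval = c(1e-9, 10), maximum = TRUE, tol = 1e-5)
  }
  b <- rep(0.1, 5)
  ll <- ll_fun(b)
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    cycles <- cyc
    ll_prev <- ll
    for (i in seq_len(5)) {
      opt <- profile_opt(i)
      if (opt$objective >= ll) { b[i] <- opt$maximum; ll <- opt$objective }
    }
    if (ll - ll_prev < tol) { converged <- TRUE; break }
  }
  list(loglik = ll, lengths = b, converged = converged, cycles = cycles)
}

#' Classify a simplex point into one of seven support regions
#'
#' Vertex regions are `p_i > 1/2`; edge regions require both adjacent
#' weights at most 1/2 and the opposite weight strictly below 1/4; the
#' remainder is the center. Boundary ties resolve toward the less-resolved
#' region.
#'
#' @param p Numeric vector of three non-negative weights summing to 1.
#' @return One of `"v1" "v2" "v3" "e12" "e13" "e23" "center"`.
#' @export
simplex_region <- function(p) {
  stopifnot(length(p) == 3, all(p >= 0), abs(sum(p) - 1) < 1e-9)
  i <- which(p > 0.5)
  if (length(i) == 1L) return(paste0("v", i))
  k <- which(p < 0.25)
  if (length(k) == 1L) {
    ij <- setdiff(1:3, k)
    return(paste0("e", ij[1], ij[2]))
  }
  "center"
}

#' Four-cluster likelihood mapping
#'
#' Samples quartets (one taxon per cluster, without replacement over the
#' full combination space; all combinations when `n_quartets` covers them),
#' computes the three topologies' maximum log-likelihoods per quartet,
#' normalizes to simplex weights `p_i = exp(l_i - max l) / sum`, and bins
#' the weights into the seven regions. Topology 1 pairs clusters (1,2) vs
#' (3,4); topology 2 pairs (1,3); topology 3 pairs (1,4).
#'
#' @param aln Alignment containing all cluster members.
#' @param clusters List of four disjoint, nonempty character vectors of
#'   taxa.
#' @param n_quartets Number of quartets to sample.
#' @param model A [subst_model()].
#' @param seed Integer seed for quartet sampling.
#' @return Object of class `fclm_report`: list with `n` (quartets used),
#'   `fractions` (named length-7, sums to 1), `points` (n x 3 matrix of
#'   simplex weights), `regions`, `quartets` (n x 4 taxa).
#' @export
fclm <- function(aln, clusters, n_quartets = 100L, model = subst_model(),
                 seed = 1L) {
  stopifnot(length(clusters) == 4L)
  if (any(vapply(clusters, length, integer(1)) == 0L))
    stop("every cluster must be nonempty")
  if (length(unique(unlist(clusters))) != length(unlist(clusters)))
    stop("clusters must be disjoint")
  m <- aln_matrix(aln)
  absent <- setdiff(unlist(clusters), rownames(m))
  if (length(absent))
    stop("cluster members absent from alignment: ",
         paste(absent, collapse = ", "))
  sizes <- vapply(clusters, length, integer(1))
  total <- prod(sizes)
  idx <- if (n_quartets >= total) seq_len(total)
         else with_seed(seed, sample.int(total, n_quartets))
  combo <- function(r) {
    r <- r - 1L
    out <- integer(4)
    for (c in 1:4) { out[c] <- r %% sizes[c] + 1L; r <- r %/% sizes[c] }
    out
  }
  n <- length(idx)
  points <- matrix(NA_real_, n, 3)
  regions <- character(n)
  quartets <- matrix(NA_character_, n, 4)
  for (q in seq_len(n)) {
    sel <- combo(idx[q])
    taxa <- vapply(1:4, function(c) clusters[[c]][sel[c]], character(1))
    quartets[q, ] <- taxa
    sub <- m[taxa, , drop = FALSE]
    ll <- vapply(1:3, function(topo)
      optimize_quartet(sub, topo, model)$loglik, numeric(1))
    w <- exp(ll - max(ll))
    p <- w / sum(w)
    points[q, ] <- p
    regions[q] <- simplex_region(p)
  }
  lev <- c("v1", "v2", "v3", "e12", "e13", "e23", "center")
  fr <- as.vector(table(factor(regions, levels = lev))) / n
  names(fr) <- lev
  structure(list(n = n, fractions = fr, points = points,
                 regions = regions, quartets = quartets),
            class = "fclm_report")
}
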