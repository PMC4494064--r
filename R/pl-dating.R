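# Penalized-likelihood divergence-time estimation: a Poisson branch-length
# likelihood penalized by the roughness of rate changes between neighboring
# branches, with fixed/min/max age calibrations and leave-one-terminal-out
# cross-validation of the smoothing parameter.

#' A node-age calibration
#'
#' @param tips Character vector of tips whose MRCA is calibrated.
#' @param kind `"fixed"`, `"min"` or `"max"`.
#' @param age Age in Ma (> 0).
#' @export
calibration <- function(tips, kind = c("fixed", "min", "max"), age) {
  kind <- match.arg(kind)
  stopifnot(age > 0, length(tips) >= 1L)
  structure(list(tips = tips, kind = kind, age = age), class = "calibration")
}

#' Penalized log-likelihood of a dated tree with branch rates
#'
#' The likelihood treats each branch's observed substitutions
#' `x_e = length_e * sites` as continuous Poisson data with intensity
#' `mu_e = rate_e * duration_e`:
#' `sum_e [ x_e log mu_e - mu_e - log Gamma(x_e + 1) ]`. The roughness
#' penalty is `sum_e (rate_e - rate_parent(e))^2` over branches with a
#' parent branch, plus the variance of the root-children rates, weighted
#' by `lambda`.
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param ages Numeric vector of node ages (length `Ntip + Nnode`).
#' @param rates Positive rates per edge (in `tree$edge` order).
#' @param lambda Smoothing weight (>= 0).
#' @param sites Number of sites behind the branch lengths (default 1;
#'   `x_e` is treated as continuous).
#' @param log_rates If TRUE, penalize differences of log rates instead of
#'   raw rates.
#' @return Scalar penalized log-likelihood (`-Inf` when a branch has zero
#'   duration but nonzero observed length).
#' @export
pl_objective <- function(tree, ages, rates, lambda, sites = 1,
                         log_rates = FALSE) {
  e <- tree$edge
  dur <- ages[e[, 1]] - ages[e[, 2]]
  if (any(dur < 0)) return(-Inf)
  if (any(rates <= 0)) return(-Inf)
  x <- tree$edge.length * sites
  mu <- rates * dur
  zero <- mu <= 0
  if (any(zero & x > 0)) return(-Inf)
  ll <- sum(ifelse(zero, 0, x * log(mu) - mu - lgamma(x + 1)))
  r <- if (log_rates) log(rates) else rates
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- match(e[, 1], e[, 2])  # NA for root children
  has_parent <- !is.na(parent_edge)
  pen <- sum((r[has_parent] - r[parent_edge[has_parent]])^2)
  root_kids <- which(e[, 1] == root)
  if (length(root_kids) > 1L) pen <- pen + stats::var(r[root_kids])
  ll - lambda * pen
}

# Build the calibration bookkeeping: fixed ages and static lower/upper info.
#' @keywords internal
resolve_calibrations <- function(tree, calibrations) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  fixed <- rep(NA_real_, nn); amin <- rep(NA_real_, nn); amax <- rep(NA_real_, nn)
  for (cal in calibrations) {
    nd <- mrca_node(tree, cal$tips)
    if (cal$kind == "fixed") {
      if (!is.na(amin[nd]) || !is.na(amax[nd]))
        stop("node has both fixed and min/max calibrations")
      if (!is.na(fixed[nd]) && fixed[nd] != cal$age)
        stop("conflicting fixed calibrations on one node")
      fixed[nd] <- cal$age
    } else if (cal$kind == "min") {
      if (!is.na(fixed[nd])) stop("node has both fixed and min calibrations")
      amin[nd] <- max(amin[nd], cal$age, na.rm = TRUE)
    } else {
      if (!is.na(fixed[nd])) stop("node has both fixed and max calibrations")
      amax[nd] <- min(amax[nd], cal$age, na.rm = TRUE)
    }
  }
  list(fixed = fixed, amin = amin, amax = amax)
}

#' Fit a chronogram by penalized likelihood
#'
#' Node ages are parameterized as relative positions inside the interval
#' allowed by their parent's age and the static lower bound of their
#' subtree (the largest fixed/min calibration below them), which enforces
#' the age order and all calibrations by construction. Rates are optimized
#' on the log scale. The optimizer is bounded quasi-Newton (L-BFGS-B) with
#' seeded random restarts; the best objective is kept.
#'
#' @param phylogram `phylo` with branch lengths in substitutions/site.
#' @param calibrations List of [calibration()] objects; at least one
#'   `fixed` calibration (or a `max` at the root) is required for
#'   identifiability.
#' @param lambda Smoothing weight.
#' @param opts List of optimizer settings: `sites` (default 10000, the
#'   alignment width the branch lengths are treated as coming from; it
#'   sets the weight of the Poisson likelihood against the penalty),
#'   `n_restarts` (default 5), `seed` (default 1), `maxit` (default 500),
#'   `log_rates` (default FALSE), `init` (optional warm start:
#'   list(p, logr)).
#' @return Object of class `chronogram`: list with `tree` (branch lengths
#'   in Ma), `ages` (named by node id), `rates` (per edge of the input
#'   topology), `lambda`, `objective`, `convergence` (TRUE when the
#'   gradient norm < 1e-6), `gradient_norm`.
#' @export
fit_chronogram <- function(phylogram, calibrations, lambda = 1,
                           opts = list()) {
  sites <- opts$sites %||% 10000
  n_restarts <- opts$n_restarts %||% 5L
  seed <- opts$seed %||% 1L
  maxit <- opts$maxit %||% 500L
  log_rates <- opts$log_rates %||% FALSE
  tree <- phylogram
  stopifnot(!is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  cal <- resolve_calibrations(tree, calibrations)
  if (!any(!is.na(cal$fixed)) && is.na(cal$amax[root]))
    stop("need at least one fixed calibration or a max calibration at the root")
  parent <- rep(NA_integer_, nn)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  # static lower bound: largest fixed/min age in the subtree (tips at 0)
  lb <- rep(0, nn)
  po <- ape::reorder.phylo(tree, "postorder")
  self_lb <- pmax(ifelse(is.na(cal$fixed), 0, cal$fixed),
                  ifelse(is.na(cal$amin), 0, cal$amin))
  lb <- self_lb
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    lb[p] <- max(lb[p], lb[ch])
  }
  # feasibility: every node's upper bound must exceed its lower bound
  ub_static <- rep(Inf, nn)
  ord_pre <- c(root, po$edge[rev(seq_len(nrow(po$edge))), 2])
  ord_pre <- ord_pre[!duplicated(ord_pre)]
  for (nd in ord_pre) {
    u <- if (!is.na(cal$fixed[nd])) cal$fixed[nd]
         else min(ifelse(is.na(cal$amax[nd]), Inf, cal$amax[nd]),
                  if (nd == root) Inf else ub_static[parent[nd]])
    ub_static[nd] <- u
    low <- if (!is.na(cal$fixed[nd])) cal$fixed[nd] else lb[nd]
    if (low > u + 1e-12)
      stop("infeasible calibration set at node ", nd,
           " (lower bound ", low, " > upper bound ", u, ")")
  }
  internal <- (ntip + 1L):nn
  free <- internal[is.na(cal$fixed[internal])]
  root_free <- root %in% free  # root free only when bounded by a max
  if (root_free && is.infinite(ub_static[root]))
    stop("root age unbounded: add a fixed or max calibration on the root")
  ne <- nrow(tree$edge)
  eps <- 1e-6

  # precomputed index structures for a fast objective
  pidx <- rep(NA_integer_, nn)
  pidx[free] <- seq_along(free)
  ord_int <- ord_pre[ord_pre > ntip]           # internal nodes, preorder
  is_fixed <- !is.na(cal$fixed)
  fixed_ages <- ifelse(is_fixed, cal$fixed, 0)
  amax_eff <- ifelse(is.na(cal$amax), Inf, cal$amax)
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]
  x <- tree$edge.length * sites
  parent_edge <- match(e1, e2)
  has_parent <- !is.na(parent_edge)
  pe <- parent_edge[has_parent]
  root_kids <- which(e1 == root)
  lgx <- sum(lgamma(x + 1))

  ages_from_p <- function(p) {
    ages <- numeric(nn)
    his <- numeric(nn)
    par_active <- logical(nn)  # parent age (not a max cal) is the ceiling
    ages[is_fixed] <- fixed_ages[is_fixed]
    for (nd in ord_int) {
      if (is_fixed[nd]) next
      if (nd == root) {
        hi <- ub_static[root]
      } else {
        hi <- ages[parent[nd]]
        if (amax_eff[nd] < hi) hi <- amax_eff[nd]
        else par_active[nd] <- TRUE
      }
      his[nd] <- hi
      ages[nd] <- lb[nd] + p[pidx[nd]] * (hi - lb[nd])
    }
    list(ages = ages, his = his, par_active = par_active)
  }
  nfree <- length(free)
  rev_int <- rev(ord_int)
  rk2 <- length(root_kids) == 2L
  objfun <- function(par) {
    p <- par[seq_len(nfree)]
    r <- exp(par[(nfree + 1L):length(par)])
    ages <- ages_from_p(p)$ages
    dur <- ages[e1] - ages[e2]
    mu <- r * dur
    bad <- mu <= 0
    if (any(bad & x > 0)) return(1e10)
    ll <- sum((x * log(mu) - mu)[!bad]) - sum(mu[bad]) - lgx
    rr <- if (log_rates) log(r) else r
    pen <- sum((rr[has_parent] - rr[pe])^2)
    if (rk2) pen <- pen + (rr[root_kids[1]] - rr[root_kids[2]])^2 / 2
    else if (length(root_kids) > 1L) pen <- pen + stats::var(rr[root_kids])
    -(ll - lambda * pen)
  }
  gradfun <- function(par) {
    p <- par[seq_len(nfree)]
    r <- exp(par[(nfree + 1L):length(par)])
    ap <- ages_from_p(p)
    ages <- ap$ages
    dur <- pmax(ages[e1] - ages[e2], 1e-12)
    # d ll / d logr_e = x_e - mu_e ; d pen / d rr_e via neighbor terms
    mu <- r * dur
    dll_dlogr <- x - mu
    rr <- if (log_rates) log(r) else r
    dpen_drr <- numeric(length(r))
    diffs <- rr[has_parent] - rr[pe]
    idx_hp <- which(has_parent)
    dpen_drr[idx_hp] <- dpen_drr[idx_hp] + 2 * diffs
    for (j in seq_along(idx_hp))
      dpen_drr[pe[j]] <- dpen_drr[pe[j]] - 2 * diffs[j]
    if (rk2) {
      d12 <- rr[root_kids[1]] - rr[root_kids[2]]
      dpen_drr[root_kids[1]] <- dpen_drr[root_kids[1]] + d12
      dpen_drr[root_kids[2]] <- dpen_drr[root_kids[2]] - d12
    }
    dpen_dlogr <- if (log_rates) dpen_drr else dpen_drr * r
    g_logr <- -(dll_dlogr - lambda * dpen_dlogr)
    # d ll / d age[node] accumulated from incident branches
    dll_ddur <- x / dur - r
    g_age <- numeric(nn)
    for (j in seq_along(dll_ddur)) {
      g_age[e1[j]] <- g_age[e1[j]] + dll_ddur[j]
      g_age[e2[j]] <- g_age[e2[j]] - dll_ddur[j]
    }
    # reverse sweep through the recursive parameterization
    g_p <- numeric(nfree)
    for (nd in rev_int) {
      if (is_fixed[nd]) { g_age[nd] <- 0; next }
      span <- ap$his[nd] - lb[nd]
      g_p[pidx[nd]] <- g_age[nd] * span
      if (nd != root && ap$par_active[nd])
        g_age[parent[nd]] <- g_age[parent[nd]] + g_age[nd] * p[pidx[nd]]
    }
    c(-g_p, g_logr)
  }
  lower <- c(rep(eps, length(free)), rep(log(1e-10), ne))
  upper <- c(rep(1 - eps, length(free)), rep(log(1e4), ne))
  # initial rates from observed lengths over a mid-interval age guess
  init_one <- function(jitter) {
    p0 <- rep(0.5, length(free))
    if (jitter) p0 <- stats::runif(length(free), 0.15, 0.85)
    ages0 <- ages_from_p(p0)$ages
    dur0 <- ages0[tree$edge[, 1]] - ages0[tree$edge[, 2]]
    r0 <- (tree$edge.length * sites) / pmax(dur0, 1e-8)
    r0 <- pmax(r0, 1e-9)
    if (jitter) r0 <- r0 * exp(stats::rnorm(ne, 0, 0.3))
    c(p0, log(r0))
  }
  best <- NULL
  with_seed(seed, {
    if (!is.null(opts$init)) {
      st <- c(opts$init$p, opts$init$logr)
      st <- pmin(pmax(st, lower), upper)
      fit <- stats::optim(st, objfun, gr = gradfun, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = maxit))
      best <- fit
    }
    for (k in seq_len(n_restarts)) {
      st <- init_one(jitter = (k > 1))
      st <- pmin(pmax(st, lower), upper)
      fit <- tryCatch(
        stats::optim(st, objfun, gr = gradfun, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
  })
  if (is.null(best)) stop("optimization failed from every start")
  par <- best$par
  p <- par[seq_along(free)]
  rates <- exp(par[-seq_along(free)])
  ages <- ages_from_p(p)$ages
  # gradient norm at the optimum for the convergence flag, ignoring
  # components pinned at the box bounds
  g <- gradfun(par)
  at_bound <- (par <= lower + 1e-9 & g > 0) | (par >= upper - 1e-9 & g < 0)
  gnorm <- sqrt(sum(g[!at_bound]^2))
  chrono <- tree
  chrono$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  chrono$age <- ages
  structure(list(tree = chrono, ages = ages,
                 rates = rates / sites,  # substitutions/site/Ma
                 lambda = lambda, sites = sites,
                 objective = -best$value, convergence = gnorm < 1e-6,
                 gradient_norm = gnorm,
                 par = list(p = p, logr = log(rates), free = free)),
            class = "chronogram")
}

#' Cross-validate the smoothing parameter
#'
#' Leave-one-terminal-out: for each tip, the tip's branch is pruned, the
#' remaining phylogram is fitted, and the pruned branch's expected
#' substitutions are predicted as `x_hat = r_adj * t_attach`, where
#' `r_adj` is the fitted rate of the branch the tip attached to and
#' `t_attach` the fitted age of its nearest surviving ancestor. The score
#' per tip is `(x - x_hat)^2 / max(x_hat, eps)`; `CV(lambda)` sums over
#' tips, and the selected lambda is the argmin (ties to the smaller
#' lambda).
#'
#' @param phylogram `phylo` with branch lengths (>= 4 tips).
#' @param calibrations List of [calibration()] objects (clades must
#'   survive every single-tip pruning).
#' @param lambda_grid Numeric vector of candidate smoothing weights.
#' @param opts Optimizer options passed to [fit_chronogram()]; CV fits
#'   default to a single restart.
#' @param eps Denominator guard.
#' @return List with `table` (data frame `lambda`, `cv`), `selected`.
#' @export
cross_validate <- function(phylogram, calibrations, lambda_grid,
                           opts = list(), eps = 1e-6) {
  if (!length(lambda_grid)) stop("lambda_grid is empty")
  stopifnot(length(phylogram$tip.label) >= 4L)
  opts$n_restarts <- opts$n_restarts %||% 1L
  sites <- opts$sites %||% 10000
  tree <- phylogram
  ntip <- length(tree$tip.label)
  tu <- tips_under(tree)
  cv <- numeric(length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    total <- 0
    for (tip in seq_len(ntip)) {
      lab <- tree$tip.label[tip]
      x <- tree$edge.length[tree$edge[, 2] == tip] * sites
      pruned <- ape::drop.tip(tree, lab)
      # nearest surviving ancestor: MRCA (in the pruned tree) of the tips
      # that flanked the removed leaf
      par_full <- tree$edge[tree$edge[, 2] == tip, 1]
      gp <- tree$edge[tree$edge[, 2] == par_full, 1]
      anc_tips <- if (length(gp)) setdiff(tu[[gp]], lab)
                  else setdiff(tree$tip.label, lab)
      cal_pruned <- lapply(calibrations, function(cl) {
        keep <- setdiff(cl$tips, lab)
        if (!length(keep)) stop("calibration clade lost by pruning ", lab)
        calibration(keep, cl$kind, cl$age)
      })
      fit <- fit_chronogram(pruned, cal_pruned, lam, opts)
      anc <- mrca_node(pruned, anc_tips)
      t_attach <- fit$ages[anc]
      # rate of the branch immediately below that ancestor on the side
      # where the tip attached
      sib_tips <- setdiff(tu[[par_full]], lab)
      below <- mrca_node(pruned, sib_tips)
      edge_i <- which(pruned$edge[, 2] == below)
      r_adj <- if (length(edge_i)) fit$rates[edge_i]
               else mean(fit$rates[pruned$edge[, 1] == below])
      x_hat <- r_adj * t_attach * sites
      total <- total + (x - x_hat)^2 / max(x_hat, eps)
    }
    cv[li] <- total
  }
  sel <- lambda_grid[which.min(cv)]
  list(table = data.frame(lambda = lambda_grid, cv = cv),
       selected = sel)
}
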