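test_that("pruning likelihood matches closed forms on two taxa", {
  mod <- subst_model(20, n_cat = 1)
  tr0 <- parse_newick("(A:0,B:0);")
  expect_equal(tree_loglik(tr0, c(A = "A", B = "A"), mod), log(1 / 20))

  t_tot <- 0.41
  tr <- parse_newick(sprintf("(A:%g,B:%g);", t_tot / 2, t_tot / 2))
  P <- pmat(mod, t_tot)
  expect_equal(tree_loglik(tr, c(A = "A", B = "R"), mod),
               log(P[1, 2] / 20), tolerance = 1e-10)
  expect_equal(tree_loglik(tr, c(A = "A", B = "A"), mod),
               log(P[1, 1] / 20), tolerance = 1e-10)
})

test_that("pruning equals explicit summation over internal states", {
  mod20 <- subst_model(20, gamma_shape = 0.8, n_cat = 2)
  tr4 <- parse_newick("((A:0.2,B:0.5):0.3,(C:0.1,D:0.9):0.15);")
  aln4 <- c(A = "AR", B = "AA", C = "RV", D = "A-")
  expect_equal(tree_loglik(tr4, aln4, mod20), brute_loglik(tr4, aln4, mod20),
               tolerance = 1e-8)

  mod6 <- subst_model(6, gamma_shape = 1.2, n_cat = 3)
  tr5 <- parse_newick("(((A:0.1,B:0.2):0.1,C:0.4):0.2,(D:0.3,E:0.1):0.25);")
  aln5 <- c(A = "012", B = "015", C = "330", D = "51?", E = "024")
  expect_equal(tree_loglik(tr5, aln5, mod6), brute_loglik(tr5, aln5, mod6),
               tolerance = 1e-8)
})

test_that("likelihood is invariant under consistent relabeling", {
  mod <- subst_model(6, n_cat = 2)
  tr <- parse_newick("((A:0.1,B:0.3):0.2,(C:0.15,D:0.05):0.1);")
  aln <- c(A = "0123", B = "1123", C = "5013", D = "0120")
  ll1 <- tree_loglik(tr, aln, mod)
  swap <- c(A = "W", B = "X", C = "Y", D = "Z")
  tr2 <- tr; tr2$tip.label <- unname(swap[tr$tip.label])
  aln2 <- aln; names(aln2) <- unname(swap[names(aln)])
  expect_equal(tree_loglik(tr2, aln2, mod), ll1)
})

test_that("errors on empty alignments and unknown symbols", {
  mod <- subst_model(20)
  tr <- parse_newick("(A:0.1,B:0.1);")
  expect_error(tree_loglik(tr, character(0), mod))
  expect_error(tree_loglik(tr, c(A = "J", B = "A"), mod), "unknown state")
})

test_that("quartet optimization: indistinguishable data, ascent, consistency", {
  mod <- subst_model(20, n_cat = 1)
  same <- c(A = "ARNDCQ", B = "ARNDCQ", C = "ARNDCQ", D = "ARNDCQ")
  lls <- vapply(1:3, function(i)
    optimize_quartet(same, i, mod)$loglik, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-4)

  tr <- parse_newick("((A:0.15,B:0.15):0.3,C:0.15,D:0.15);")
  aln <- sim_alignment(tr, 5000, mod, seed = 13)
  m <- aln_matrix(aln)[c("A", "B", "C", "D"), ]
  o <- lapply(1:3, function(i) optimize_quartet(m, i, mod))
  expect_true(o[[1]]$loglik > o[[2]]$loglik)
  expect_true(o[[1]]$loglik > o[[3]]$loglik)
  expect_true(o[[1]]$converged)

  # ascent property: optimum at least the starting-point likelihood
  ll_start <- tree_loglik(
    parse_newick("((A:0.1,B:0.1):0.1,C:0.1,D:0.1);"), m, mod)
  expect_gte(o[[1]]$loglik, ll_start)
})

test_that("ml distances grow with divergence and respect saturation cap", {
  mod <- subst_model(20, n_cat = 1)
  tr <- parse_newick("(A:0.05,B:0.05);")
  aln <- sim_alignment(tr, 20000, mod, seed = 5)
  D <- ml_distance(aln, mod)
  expect_equal(D["A", "B"], 0.1, tolerance = 0.05)
  sat <- ml_distance(c(A = "AR", B = "RA"), mod)
  expect_equal(sat["A", "B"], 10)
})

test_that("PAML matrix reader produces a usable reversible model", {
  # a tiny synthetic exchangeability file in PAML layout
  path <- tempfile(fileext = ".dat")
  set.seed(42)
  vals <- round(stats::runif(190, 0.1, 5), 4)
  lines <- character(19)
  k <- 1
  for (i in 1:19) {
    lines[i] <- paste(vals[k:(k + i - 1)], collapse = " ")
    k <- k + i
  }
  freqs <- round(stats::runif(20, 0.5, 2), 4)
  writeLines(c(lines, "", paste(freqs, collapse = " ")), path)
  pm <- read_paml_matrix(path)
  expect_true(isSymmetric(pm$exch))
  expect_equal(sum(pm$freqs), 1)
  mod <- subst_model(20, exch = pm$exch, freqs = pm$freqs)
  P <- pmat(mod, 0.3)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9)
  # detailed balance of the stationary distribution
  expect_equal(pm$freqs %*% P, matrix(pm$freqs, 1), tolerance = 1e-9)
})
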