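S3 <- parse_newick("((A,B),C);")
S2 <- parse_newick("(A,B);")

test_that("lca_map follows the by-hand mapping and the ancestry property", {
  G <- parse_newick("((a1,b1),(a2,c1));")
  lm <- c(a1 = "A", b1 = "B", a2 = "A", c1 = "C")
  M <- lca_map(G, S3, lm)
  root_s <- 4L  # species root of the 3-taxon tree
  expect_equal(M[5], root_s)               # gene root -> abc
  ab_node <- mrca_node(S3, c("A", "B"))
  g_ab <- mrca_node(G, c("a1", "b1"))
  expect_equal(M[g_ab], ab_node)
  g_ac <- mrca_node(G, c("a2", "c1"))
  expect_equal(M[g_ac], root_s)

  # congruent single-copy tree: natural isomorphism
  Gc <- parse_newick("((a1,b1),c1);")
  Mc <- lca_map(Gc, S3, c(a1 = "A", b1 = "B", c1 = "C"))
  expect_equal(Mc[1:3], match(c("A", "B", "C"), S3$tip.label))

  # M(parent) ancestral-or-equal to M(child) on every edge
  si_anc <- function(tree, a, d) {
    while (!is.na(d) && d != a) d <- tree$edge[tree$edge[, 2] == d, 1][1]
    identical(d, a)
  }
  for (i in seq_len(nrow(G$edge)))
    expect_true(si_anc(S3, M[G$edge[i, 1]], M[G$edge[i, 2]]))

  expect_error(lca_map(parse_newick("(a1,z9);"), S3,
                       c(a1 = "A", z9 = "Z")), "unknown genome")
})

test_that("reconcile_dl reproduces the worked duplication-loss examples", {
  # congruent single-copy family: no events, all copies 1
  Gc <- parse_newick("((a1,b1),c1);")
  rc <- reconcile_dl(Gc, S3, c(a1 = "A", b1 = "B", c1 = "C"))
  expect_equal(rc$cost, 0)
  expect_true(all(rc$branches$exiting == 1))

  # one within-lineage duplication
  G2 <- parse_newick("((a1,a2),b1);")
  r2 <- reconcile_dl(G2, S2, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(r2$duplications, 1)
  expect_equal(r2$losses, 0)

  # the D=1, L=2 example with its copy-number profile
  G <- parse_newick("((a1,b1),(a2,c1));")
  r <- reconcile_dl(G, S3, c(a1 = "A", b1 = "B", a2 = "A", c1 = "C"))
  expect_equal(r$duplications, 1)
  expect_equal(r$losses, 2)
  cn <- ancestral_copy_numbers(r, list(c("A", "B", "C"), c("A", "B")))
  expect_equal(unname(cn), c(2, 2))
  leaf <- ancestral_copy_numbers(r, list("A", "B", "C"))
  expect_equal(unname(leaf), c(2, 1, 1))
  expect_error(ancestral_copy_numbers(r, "Q"), "unknown species node")
})

test_that("reconciliation cost equals the map-enumeration oracle (sample)", {
  # a quick slice of the exhaustive sweep; the full sweep runs in the
  # acceptance suite
  cs <- oracle_case_set()[[2]]
  S <- parse_newick(cs$species)
  ls <- cs$leafsets[[2]]
  lm <- oracle_leafmap(ls)
  for (tp in all_topologies(ls)) {
    gt <- topology_phylo(tp)
    expect_equal(reconcile_dl(gt, S, lm)$cost, oracle_min_dl(tp, S, lm))
  }
})

test_that("conservation law and leaf counts hold on random families", {
  sp <- sim_species_tree(9, 700, seed = 4)
  for (seed in 1:60) {
    fam <- sim_gene_family(sp, 0.003, 0.002, seed = seed)
    r <- reconcile_dl(fam$tree, sp)
    br <- r$branches
    expect_true(all(br$exiting == br$entering + br$dups - br$losses))
    lm <- leafmap_from_labels(
      if (inherits(fam$tree, "single_tip")) fam$tree$tip.label
      else fam$tree$tip.label)
    obs <- table(factor(lm, levels = sp$tip.label))
    leaf_rows <- match(sp$tip.label, br$key)
    expect_equal(br$exiting[leaf_rows], as.integer(obs),
                 ignore_attr = TRUE)
  }
})

test_that("root_min_dl recovers zero-cost rootings and the rooting minimum", {
  # unrooted congruent tree -> cost 0
  Gu <- ape::unroot(parse_newick("((a1:1,b1:1):1,c1:1);"))
  rt <- root_min_dl(Gu, S3, c(a1 = "A", b1 = "B", c1 = "C"))
  expect_equal(attr(rt, "cost"), 0)

  # equals the minimum over every explicit rooting, deterministic reruns
  sp <- sim_species_tree(6, 500, seed = 8)
  for (seed in 1:12) {
    fam <- sim_gene_family(sp, 0.004, 0.003, seed = 200 + seed)
    if (inherits(fam$tree, "single_tip") ||
        length(fam$tree$tip.label) < 3 ||
        length(fam$tree$tip.label) > 8) next
    ut <- ape::unroot(fam$tree)
    costs <- c()
    for (i in seq_len(nrow(ut$edge))) {
      side <- ape::prop.part(ut)  # placeholder to keep ape loaded
      tu <- lapply(seq_len(max(ut$edge)), function(n)
        if (n <= length(ut$tip.label)) ut$tip.label[n] else
          ape::extract.clade(ut, n)$tip.label)
      out <- tu[[ut$edge[i, 2]]]
      if (length(out) == length(ut$tip.label)) next
      cand <- tryCatch(ape::root(ut, outgroup = out, resolve.root = TRUE),
                       error = function(e) NULL)
      if (is.null(cand)) next
      costs <- c(costs, reconcile_dl(cand, sp)$cost)
    }
    r1 <- root_min_dl(ut, sp)
    r2 <- root_min_dl(ut, sp)
    expect_equal(attr(r1, "cost"), min(costs))
    expect_identical(write_newick(r1, include = character(0)),
                     write_newick(r2, include = character(0)))
  }
})

test_that("weak-branch rearrangement lowers cost and respects thresholds", {
  G <- parse_newick("((a1:1,c1:1)50:1,b1:1);")
  lm <- c(a1 = "A", c1 = "C", b1 = "B")
  r0 <- reconcile_dl(G, S3, lm)
  expect_equal(c(r0$duplications, r0$losses), c(1, 3))
  rw <- rearrange_weak(G, S3, lm, 70)
  expect_equal(rw$cost, 0)
  expect_false(rw$heuristic)
  expect_identical(write_newick(rw$tree, include = character(0)),
                   "((a1,b1),c1);")

  # all supports at or above the threshold -> unchanged
  Gs <- parse_newick("((a1:1,c1:1)90:1,b1:1);")
  rw2 <- rearrange_weak(Gs, S3, lm, 70)
  expect_equal(rw2$cost, rw2$input_cost)
  # threshold 0: nothing strictly below zero support
  rw3 <- rearrange_weak(G, S3, lm, 0)
  expect_equal(rw3$cost, rw3$input_cost)
  expect_error(rearrange_weak(G, S3, lm, 150), "support_threshold")

  # never increases cost on random noisy trees with random supports
  sp <- sim_species_tree(7, 400, seed = 3)
  for (seed in 1:10) {
    fam <- sim_gene_family(sp, 0.004, 0.002, seed = 400 + seed)
    if (inherits(fam$tree, "single_tip") ||
        length(fam$tree$tip.label) < 4) next
    gt <- fam$tree
    set.seed(seed)
    gt$support <- c(NA, sample(30:100, gt$Nnode - 1, replace = TRUE))
    rw <- rearrange_weak(gt, sp, support_threshold = 70)
    expect_lte(rw$cost, rw$input_cost)
  }
})

test_that("bootstrap averaging is arithmetic and brackets the replicates", {
  G1 <- parse_newick("((a1,a2),b1);")   # one duplication
  G2 <- parse_newick("((a1,b1),a2);")   # different resolution
  lm <- c(a1 = "A", a2 = "A", b1 = "B")
  same <- bootstrap_average(rep(list(G1), 100), S2, lm)
  single <- reconcile_dl(G1, S2, lm)
  expect_equal(same$branches$mean_dups,
               as.numeric(single$branches$dups))
  expect_equal(same$n_replicates, 100L)

  mix <- bootstrap_average(list(G1, G2), S2, lm)
  expect_true(all(mix$branches$mean_dups >= mix$branches$min_dups - 1e-12))
  expect_true(all(mix$branches$mean_dups <= mix$branches$max_dups + 1e-12))

  G3 <- parse_newick("((a1,b1),c1);")
  expect_error(bootstrap_average(list(G1, G3), S2, lm), "replicate 2")
})

test_that("reconciled duplications track simulated truth across branches", {
  sp <- sim_species_tree(10, 800, seed = 77)
  nfam <- 200
  truth <- NULL; recon <- NULL
  for (i in seq_len(nfam)) {
    fam <- sim_gene_family(sp, 0.002, 0.002, seed = 5000 + i)
    r <- reconcile_dl(fam$tree, sp)
    if (is.null(truth)) {
      truth <- matrix(0, nfam, nrow(fam$branches))
      colnames(truth) <- fam$branches$key
      recon <- truth
    }
    truth[i, ] <- fam$branches$dups
    recon[i, ] <- r$branches$dups[match(fam$branches$key, r$branches$key)]
  }
  internal <- grepl("|", colnames(truth), fixed = TRUE) |
    colnames(truth) == "root"
  mt <- colMeans(truth[, internal]); mr <- colMeans(recon[, internal])
  se <- apply(truth[, internal], 2, stats::sd) / sqrt(nfam)
  # parsimony under losses can only undercount duplications
  expect_true(all(mr <= mt + 3 * se))
  expect_gte(stats::cor(mt, mr), 0.8)
})
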