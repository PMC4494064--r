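test_that("sim_species_tree builds dated ultrametric trees", {
  tr <- sim_species_tree(2, 500, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(tr$age[3], 500)

  for (seed in 1:20) {
    tr <- sim_species_tree(8, 800, seed = seed)
    expect_equal(tr$Nnode, 7L)  # binary: n - 1 internal nodes
    expect_equal(tr$age[9], 800)
    expect_true(all(tr$age[tr$edge[, 1]] > tr$age[tr$edge[, 2]]))
    expect_true(all(tr$age[1:8] == 0))
  }
  # pure function of seed
  expect_identical(write_newick(sim_species_tree(6, 100, seed = 3)),
                   write_newick(sim_species_tree(6, 100, seed = 3)))
})

test_that("gene families honor the conservation law and degenerate rates", {
  sp <- sim_species_tree(8, 800, seed = 2)
  # no events: congruent single-copy family
  fam0 <- sim_gene_family(sp, 0, 0, seed = 1)
  expect_true(all(fam0$branches$dups == 0))
  expect_true(all(fam0$branches$losses == 0))
  expect_true(all(fam0$branches$exiting == 1))
  expect_equal(sort(leafmap_from_labels(fam0$tree$tip.label)),
               sort(stats::setNames(sp$tip.label, fam0$tree$tip.label)),
               ignore_attr = TRUE)

  for (seed in 1:200) {
    fam <- sim_gene_family(sp, 0.002, 0.003, seed = seed)
    expect_true(check_conservation(fam, sp))
  }
})

test_that("pure-birth expectation matches e^(rate*t) on a single branch", {
  # two-taxon tree: each terminal branch has duration t, entering 1 copy
  t_len <- 300
  rate <- 0.003
  sp <- sim_species_tree(2, t_len, seed = 5)
  n <- 4000
  exiting <- vapply(seq_len(n), function(s) {
    fam <- sim_gene_family(sp, rate, 0, seed = s)
    fam$branches$exiting[fam$branches$key == "g01"]
  }, numeric(1))
  expected <- exp(rate * t_len)
  se <- stats::sd(exiting) / sqrt(n)
  expect_lt(abs(mean(exiting) - expected), 3 * se)
})

test_that("alignment simulation matches the two-state collapse probability", {
  mod <- subst_model(20, n_cat = 1)
  t_tot <- 0.5
  tr <- parse_newick(sprintf("(A:%g,B:%g);", t_tot / 2, t_tot / 2))
  n <- 100000
  aln <- sim_alignment(tr, n, mod, seed = 9)
  m <- aln_matrix(aln)
  p_obs <- mean(m["A", ] != m["B", ])
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * t_tot))
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("alignment simulation is deterministic and degenerate-safe", {
  mod <- subst_model(6, gamma_shape = 0.5, n_cat = 4)
  tr <- parse_newick("(A:0.1,B:0.2,C:0.05);")
  a1 <- sim_alignment(tr, 200, mod, seed = 4)
  a2 <- sim_alignment(tr, 200, mod, seed = 4)
  expect_identical(a1, a2)
  expect_length(attr(a1, "categories"), 200L)

  star0 <- parse_newick("(A:0,B:0,C:0);")
  a0 <- sim_alignment(star0, 50, mod, seed = 1)
  expect_true(all(a0 == a0[1]))
  expect_error(subst_model(20, gamma_shape = 0), "gamma_shape")
})

test_that("relaxed phylogram: lengths = rate x duration, mean rate unbiased", {
  sp <- sim_species_tree(6, 600, seed = 11)
  ph0 <- sim_relaxed_phylogram(sp, 2e-4, 0, seed = 1)
  expect_true(all(abs(ph0$rates - 2e-4) < 1e-18))

  ph <- sim_relaxed_phylogram(sp, 2e-4, 0.4, seed = 2)
  dur <- ph$ages[sp$edge[, 1]] - ph$ages[sp$edge[, 2]]
  expect_equal(ph$tree$edge.length, ph$rates * dur)
  expect_error(sim_relaxed_phylogram(sp, 2e-4, -0.1), "sigma")

  # mean over many branches approaches the nominal mean rate
  big <- sim_species_tree(60, 600, seed = 3)
  rates <- unlist(lapply(1:90, function(s)
    sim_relaxed_phylogram(big, 2e-4, 0.5, seed = s)$rates))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 2e-4), 3 * se)
})

test_that("cluster and hit simulators plant detectable, labeled defects", {
  clean <- sim_cluster_table(8, 30, 0, 0, 0, seed = 1)
  expect_true(all(clean$truth$keep))
  allbad <- sim_cluster_table(8, 30, 1, 0, 0, seed = 2)
  expect_true(all(!allbad$truth$keep))
  expect_true(all(allbad$truth$paralog))

  ht0 <- sim_hit_table(c("GH28", "PL1"), c("g01", "g02"),
                       matrix(c(2, 0, 1, 3), 2, 2), decoy_rate = 0, seed = 1)
  expect_true(all(ht0$evalue <= 1e-5))
  expect_true(all(ht0$domain_ok))
  hts <- sim_hit_table(c("GH28"), c("g01"), matrix(0, 1, 1),
                       decoy_rate = 8, seed = 2)
  expect_true(all(hts$evalue > 1e-5 | !hts$domain_ok))
})
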