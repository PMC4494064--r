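test_that("radical records the expected bookkeeping deterministically", {
  mod <- subst_model(6, n_cat = 1)
  tr <- parse_newick("((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2);")
  genes <- lapply(1:3, function(i) sim_alignment(tr, 100, mod, seed = i))
  names(genes) <- paste0("gene", 1:3)
  rc <- radical(genes, nj_estimator(mod), n_replicates = 2, step = 1, seed = 5)
  expect_equal(rc$G, 3L)
  expect_length(rc$replicates, 2L)
  # G=3, step=1, 2 replicates -> 6 estimated trees recorded
  expect_equal(sum(vapply(rc$replicates, function(r) length(r$clades),
                          integer(1))), 6L)
  expect_equal(rc$replicates[[1]]$steps, 1:3)

  rc2 <- radical(genes, nj_estimator(mod), n_replicates = 2, step = 1, seed = 5)
  expect_identical(lapply(rc$replicates, `[[`, "order"),
                   lapply(rc2$replicates, `[[`, "order"))
})

test_that("congruent genes give final-step trees with the true clades", {
  mod <- subst_model(6, n_cat = 1)
  tr <- parse_newick(
    "(((A:0.1,B:0.1):0.15,(C:0.1,D:0.1):0.15):0.1,(E:0.1,F:0.1):0.25);")
  genes <- lapply(1:5, function(i) sim_alignment(tr, 400, mod, seed = 40 + i))
  names(genes) <- paste0("gene", 1:5)
  rc <- radical(genes, nj_estimator(mod), n_replicates = 3, step = 1, seed = 2)
  truth <- clade_set(tr)
  for (r in rc$replicates)
    expect_true(all(truth %in% r$clades[[length(r$clades)]]))
})

test_that("fixation points follow the definitional rules", {
  mk_curves <- function(presence, steps, taxa, clade) {
    # presence: list per replicate of logical vectors per step
    reps <- lapply(presence, function(pr)
      list(order = seq_along(steps), steps = steps,
           clades = lapply(pr, function(has)
             if (has) clade else character(0))))
    structure(list(G = max(steps), taxa = taxa, replicates = reps,
                   aborted = integer(0)),
              class = "radical_curves")
  }
  taxa <- LETTERS[1:6]
  key <- clade_key(c("A", "B"), taxa)

  # present everywhere -> fixation at the first step
  c1 <- mk_curves(list(c(TRUE, TRUE, TRUE)), c(2, 4, 6), taxa, key)
  f1 <- fixation_points(c1, key)
  expect_equal(f1$fixation, 2 / 6)

  # absent from one replicate's final tree -> unfixed
  c2 <- mk_curves(list(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE)),
                  c(2, 4, 6), taxa, key)
  f2 <- fixation_points(c2, key)
  expect_false(f2$fixed)
  expect_true(is.na(f2$fixation))

  # absent at step 6, stable from step 8 of G=10 -> fraction 0.8
  steps10 <- c(2, 4, 6, 8, 10)
  c3 <- mk_curves(list(c(TRUE, TRUE, FALSE, TRUE, TRUE)), steps10, taxa, key)
  f3 <- fixation_points(c3, key)
  expect_equal(f3$fixation, 0.8)
})

test_that("a more accurate estimator never raises the fixation point", {
  mod <- subst_model(6, n_cat = 1)
  tr <- parse_newick(
    "(((A:0.1,B:0.1):0.12,(C:0.1,D:0.1):0.12):0.1,(E:0.1,F:0.1):0.2);")
  genes <- lapply(1:6, function(i) sim_alignment(tr, 250, mod, seed = 70 + i))
  names(genes) <- paste0("gene", 1:6)
  perfect <- function(aln) tr  # oracle estimator always returns the truth
  noisy <- nj_estimator(mod)
  rc_p <- radical(genes, perfect, n_replicates = 2, step = 2, seed = 3)
  rc_n <- radical(genes, noisy, n_replicates = 2, step = 2, seed = 3)
  truth <- clade_set(tr)
  fp <- fixation_points(rc_p, truth)
  fn <- fixation_points(rc_n, truth)
  for (i in seq_along(truth)) {
    if (fn$fixed[i]) {
      expect_true(fp$fixed[i])
      expect_lte(fp$fixation[i], fn$fixation[i])
    }
  }
})

test_that("estimator failures abort and report the replicate", {
  mod <- subst_model(6, n_cat = 1)
  tr <- parse_newick("((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2);")
  genes <- lapply(1:3, function(i) sim_alignment(tr, 50, mod, seed = i))
  names(genes) <- paste0("gene", 1:3)
  n_calls <- 0
  flaky <- function(aln) {
    n_calls <<- n_calls + 1
    if (n_calls == 2) stop("estimator blew up")
    tr
  }
  rc <- radical(genes, flaky, n_replicates = 2, step = 1, seed = 9)
  expect_equal(rc$aborted, 1L)
  expect_length(rc$replicates, 1L)
})
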