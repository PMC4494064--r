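test_that("pl_objective has the documented structure", {
  sp <- sim_species_tree(6, 400, seed = 2)
  ph <- sim_relaxed_phylogram(sp, 3e-4, 0, seed = 1)
  ages <- ph$ages
  r <- rep(3e-4, nrow(sp$edge))
  # strict-clock data at the true rates: penalty exactly zero, so the
  # lambda term vanishes
  o1 <- pl_objective(ph$tree, ages, r, lambda = 0)
  o2 <- pl_objective(ph$tree, ages, r, lambda = 1e6)
  expect_equal(o1, o2)

  # lambda = 0 reduces to the unpenalized Poisson (Langley-Fitch) form
  x <- ph$tree$edge.length
  dur <- ages[sp$edge[, 1]] - ages[sp$edge[, 2]]
  mu <- r * dur
  expect_equal(o1, sum(x * log(mu) - mu - lgamma(x + 1)))

  # per-branch maximum at mu = x: perturbing any rate cannot improve
  r_opt <- x / dur
  base <- pl_objective(ph$tree, ages, r_opt, lambda = 0)
  for (j in c(1, 4, 7)) {
    rp <- r_opt; rp[j] <- rp[j] * 1.3
    expect_lt(pl_objective(ph$tree, ages, rp, lambda = 0), base)
  }

  # zero duration with observed substitutions is rejected
  ages0 <- ages
  ages0[sp$edge[1, 2]] <- ages0[sp$edge[1, 1]]
  expect_identical(pl_objective(ph$tree, ages0, r, 1), -Inf)
})

test_that("fixed calibrations are honored exactly and infeasibility caught", {
  sp <- sim_species_tree(8, 750, seed = 5)
  ph <- sim_relaxed_phylogram(sp, 4e-4, 0.1, seed = 2)
  # fix an internal (non-root) node: the returned age must equal it exactly
  inner <- setdiff((9):(15), 9)[1]
  tips_in <- ape::extract.clade(sp, inner)$tip.label
  true_age <- sp$age[inner]
  cals <- list(calibration(sp$tip.label, "fixed", 750),
               calibration(tips_in, "fixed", true_age))
  fit <- fit_chronogram(ph$tree, cals, lambda = 1,
                        opts = list(seed = 1, n_restarts = 2))
  expect_identical(fit$ages[inner], true_age)
  expect_identical(fit$ages[9], 750)
  # order constraints always hold
  expect_true(all(fit$ages[sp$edge[, 1]] > fit$ages[sp$edge[, 2]]))

  bad <- list(calibration(sp$tip.label, "fixed", 100),
              calibration(tips_in, "min", 500))
  expect_error(fit_chronogram(ph$tree, bad, 1), "infeasible")
  expect_error(fit_chronogram(ph$tree, list(calibration(tips_in, "min", 10)), 1),
               "fixed calibration or a max")
})

test_that("strict-clock data is recovered to high precision", {
  sp <- sim_species_tree(12, 887, seed = 42)
  ph <- sim_relaxed_phylogram(sp, 5e-4, 0, seed = 7)
  cal <- list(calibration(sp$tip.label, "fixed", 887))
  fit <- fit_chronogram(ph$tree, cal, lambda = 1, opts = list(seed = 3))
  ints <- 13:23
  rel <- abs(fit$ages[ints] - ph$ages[ints]) / ph$ages[ints]
  expect_lt(max(rel), 0.01)
  expect_lt(max(abs(fit$rates - 5e-4) / 5e-4), 0.01)
})

test_that("the smoothing penalty drives rates to a single clock as lambda grows", {
  sp <- sim_species_tree(10, 600, seed = 21)
  ph <- sim_relaxed_phylogram(sp, 5e-4, 0.25, seed = 22)
  cal <- list(calibration(sp$tip.label, "fixed", 600))
  fit <- fit_chronogram(ph$tree, cal, lambda = 1e6, opts = list(seed = 2))
  expect_lt(stats::sd(fit$rates) / mean(fit$rates), 1e-3)
})

test_that("cross-validation scores are finite, tie-break to smaller lambda", {
  sp <- sim_species_tree(8, 500, seed = 31)
  ph <- sim_relaxed_phylogram(sp, 5e-4, 0.2, seed = 32)
  cal <- list(calibration(sp$tip.label, "fixed", 500))
  expect_error(cross_validate(ph$tree, cal, numeric(0)), "empty")
  one <- cross_validate(ph$tree, cal, 3.2, opts = list(seed = 1))
  expect_equal(one$selected, 3.2)
  expect_true(all(is.finite(one$table$cv)))

  # clock data: large smoothing never hurts; the chosen lambda sits in the
  # heavily smoothed (upper) part of the grid
  ph0 <- sim_relaxed_phylogram(sp, 5e-4, 0, seed = 33)
  grid <- 10^seq(-2, 2)
  cv0 <- cross_validate(ph0$tree, cal, grid, opts = list(seed = 1))
  expect_lte(cv0$table$cv[length(grid)],
             cv0$table$cv[1] * (1 + 1e-6))
  expect_gte(cv0$selected, grid[3])
})
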