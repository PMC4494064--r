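mk_cluster <- function(id, genomes, proteins = NULL) {
  if (is.null(proteins))
    proteins <- if (length(genomes)) paste(genomes, id, "p1", sep = "|")
                else character(0)
  data.frame(cluster = rep(id, length(genomes)), genome = genomes,
             protein = proteins, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single-copy filter enforces one protein per genome and occupancy", {
  # two proteins from one genome -> removed
  bad <- mk_cluster("c1", c("g01", "g01", "g02"),
                    c("g01|c1|p1", "g01|c1|p2", "g02|c1|p1"))
  good <- mk_cluster("c2", sprintf("g%02d", 1:25))
  # 19 of 40 genomes at 0.5 -> removed; 20 of 40 -> kept (inclusive bound)
  nineteen <- mk_cluster("c3", sprintf("g%02d", 1:19))
  twenty <- mk_cluster("c4", sprintf("g%02d", 1:20))
  out <- filter_single_copy(rbind(bad, good, nineteen, twenty), 40, 0.5)
  expect_setequal(attr(out, "kept"), c("c2", "c4"))

  # identical membership -> one retained
  dup1 <- mk_cluster("c5", sprintf("g%02d", 1:20))
  dup2 <- dup1; dup2$cluster <- "c6"
  out2 <- filter_single_copy(rbind(dup1, dup2), 40, 0.5)
  expect_identical(attr(out2, "kept"), "c5")

  empty <- filter_single_copy(mk_cluster("x", character(0)), 40, 0.5)
  expect_equal(nrow(empty), 0L)
})

test_that("rbh filter removes planted violations and ties, reports unevaluable", {
  cl <- mk_cluster("c1", c("g01", "g02"))
  sc <- data.frame(
    query = c("g01|c1|p1", "g02|c1|p1"),
    subject = c("g02|c1|p1", "g01|c1|p1"),
    score = c(90, 91), stringsAsFactors = FALSE)
  expect_identical(attr(rbh_filter(cl, sc), "kept"), "c1")

  # best hit outside the cluster -> removed
  sc_bad <- rbind(sc, data.frame(query = "g01|c1|p1", subject = "g02|zz|p9",
                                 score = 99))
  expect_identical(attr(rbh_filter(cl, sc_bad), "removed"), "c1")

  # tie between in- and out-of-cluster hits -> removed (conservative)
  sc_tie <- rbind(sc, data.frame(query = "g01|c1|p1", subject = "g02|zz|p9",
                                 score = 90))
  expect_identical(attr(rbh_filter(cl, sc_tie), "removed"), "c1")

  # missing scores -> unevaluable, not silently kept
  out <- rbh_filter(cl, sc[1, , drop = FALSE])
  expect_identical(attr(out, "unevaluable"), "c1")
  expect_equal(nrow(out), 0L)
})

test_that("filter chain recovers planted truth labels exactly", {
  sim <- sim_cluster_table(12, 120, 0.25, 0.2, 0.25, seed = 31)
  f1 <- filter_single_copy(sim$clusters, 12, 0.5)
  f2 <- rbh_filter(f1, sim$scores)
  expect_setequal(attr(f2, "kept"), sim$truth$cluster[sim$truth$keep])
})

test_that("supermatrix concatenation is canonical and gap-fills", {
  g1 <- c(A = "MKLV", B = "MKIV", C = "MKLV")
  g2 <- c(A = "PQRSTWYVHH", B = "PQRSTWYVHH")
  sm <- concat_supermatrix(list(gene2 = g2, gene1 = g1), c("A", "B", "C"))
  expect_equal(nchar(sm$seqs[["A"]]), 14L)
  expect_equal(sm$partitions$gene, c("gene1", "gene2"))
  expect_equal(sm$partitions$start, c(0L, 4L))
  expect_equal(sm$partitions$end, c(4L, 14L))
  expect_equal(unname(sm$occupancy[c("A", "B", "C")]), c(1, 1, 0.5))
  expect_equal(substr(sm$seqs[["C"]], 5, 14), strrep("?", 10))

  # invariant to gene input order
  sm2 <- concat_supermatrix(list(gene1 = g1, gene2 = g2), c("A", "B", "C"))
  expect_identical(sm, sm2)

  dup <- c(A = "MK", A = "ML")
  expect_error(concat_supermatrix(list(g = dup), c("A")), "duplicate taxon")
})

test_that("Dayhoff recoding collapses exactly the six declared groups", {
  expect_equal(unname(dayhoff_recode(c(x = "ASTG"))), "0000")
  expect_equal(unname(dayhoff_recode(c(x = "CHED"))), "5211")
  expect_equal(unname(dayhoff_recode(c(x = "-X?"))), "-??")
  expect_error(dayhoff_recode(c(x = "A$T")), "\\$")

  # surjective onto <= 6 states; groups collapse together
  all20 <- paste(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], collapse = "")
  rec <- dayhoff_recode(stats::setNames(all20, "t"))
  states <- sort(unique(strsplit(unname(rec), "")[[1]]))
  expect_identical(states, as.character(0:5))
  expect_equal(sum(strsplit(unname(rec), "")[[1]] == "0"), 5L)  # AGPST
})
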