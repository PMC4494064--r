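# Small shared fixtures built in code.

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sort(tr$tip.label)
  tr
}

# leaf labels genome:fam:idx for a given genome multiset
gene_labels <- function(genomes, fam = "f") {
  idx <- stats::ave(seq_along(genomes), genomes, FUN = seq_along)
  paste(genomes, fam, idx, sep = ":")
}
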