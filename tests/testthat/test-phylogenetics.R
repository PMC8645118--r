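# Progressive alignment, NJ on additive matrices, bootstrap, newick I/O.

test_that("progressive alignment handles identical and gapped pairs", {
  aln <- progressive_align(c(a = "MKVL", b = "MKVL"))
  expect_equal(unname(unclass(aln)), c("MKVL", "MKVL"))

  aln2 <- progressive_align(c(a = "MKVL", b = "MKL"))
  expect_equal(nchar(aln2[[1]]), nchar(aln2[[2]]))
  expect_equal(sum(strsplit(paste(aln2, collapse = ""), "")[[1]] == "-"), 1L)
  # ungap invariant
  expect_equal(unname(unclass(gsub("-", "", aln2))), c("MKVL", "MKL"))
})

test_that("planted family alignment keeps conserved columns intact", {
  base <- fix_gene(len = 100L, seed = 13L)
  seqs <- sapply(1:5, function(i) tr1(mutate_to_identity(base$cds, 0.9,
                                                         seed = i)))
  names(seqs) <- paste0("m", 1:5)
  aln <- progressive_align(seqs)
  expect_true(all(gsub("-", "", aln) == seqs[names(aln)]))
  m <- do.call(rbind, strsplit(unname(aln), ""))
  base_chars <- strsplit(base$protein, "")[[1]]
  # positions mutated in no member must align as fully conserved columns
  conserved_input <- colSums(do.call(rbind, lapply(seqs, function(s) {
    strsplit(s, "")[[1]] == base_chars
  }))) == 5
  ident_cols <- apply(m, 2, function(col) length(unique(col)) == 1 &&
                        col[1] != "-")
  expect_gte(sum(ident_cols), sum(conserved_input))
})

test_that("NJ recovers hand-built additive trees exactly", {
  # three leaves: unique topology, additive lengths from the 3-point formula
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_from_dist(D3)
  expect_equal(sort(t3$tip.label), c("a", "b", "c"))
  expect_equal(sum(t3$edge.length), 6)   # (1 + 2 + 3)

  # four leaves from tree ((a:1,b:2):3,c:4,d:5)
  D4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D4["a", "b"] <- 3; D4["a", "c"] <- 8; D4["a", "d"] <- 9
  D4["b", "c"] <- 9; D4["b", "d"] <- 10; D4["c", "d"] <- 9
  D4 <- D4 + t(D4)
  t4 <- nj_from_dist(D4)
  # recovered tree must reproduce the generating distances exactly
  back <- ape::cophenetic.phylo(t4)[letters[1:4], letters[1:4]]
  expect_equal(back, D4, tolerance = 1e-12)
  # and agree with ape's independent NJ implementation
  expect_equal(ape::dist.topo(ape::unroot(t4),
                              ape::unroot(ape::nj(as.dist(D4)))), 0,
               ignore_attr = TRUE)
})

test_that("distance matrices are symmetric with zero diagonal; Poisson domain", {
  msa <- progressive_align(c(a = "MKVLWAAL", b = "MKVLWAAL", c = "MPVLWAGL"))
  D <- msa_distances(msa)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  bad <- structure(c(x = "AAAA", y = "CCCC"), class = "dup_msa")
  expect_error(msa_distances(bad), "p-distance")
})

test_that("faster-evolving duplicate clades get longer branches", {
  base <- fix_gene(len = 150L, seed = 33L)
  parents <- sapply(1:3, function(i) tr1(mutate_to_identity(base$cds, 0.97,
                                                            seed = i)))
  dups <- sapply(4:6, function(i) tr1(mutate_to_identity(base$cds, 0.80,
                                                         seed = i)))
  seqs <- c(parents, dups)
  names(seqs) <- c(paste0("par", 1:3), paste0("dup", 1:3))
  tree <- nj_tree(progressive_align(seqs))
  tip_len <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                             tree$edge[, 2])],
                      tree$tip.label)
  expect_gt(mean(tip_len[paste0("dup", 1:3)]),
            mean(tip_len[paste0("par", 1:3)]))
})

test_that("bootstrap is seeded, reproducible, and strong signal scores high", {
  base1 <- fix_gene(len = 120L, seed = 41L)
  base2 <- fix_gene(id = "gB", len = 120L, seed = 99L)
  cladeA <- sapply(1:3, function(i) tr1(mutate_to_identity(base1$cds, 0.95,
                                                           seed = i)))
  cladeB <- sapply(1:3, function(i) tr1(mutate_to_identity(base2$cds, 0.95,
                                                           seed = i)))
  seqs <- c(cladeA, cladeB)
  names(seqs) <- c(paste0("a", 1:3), paste0("b", 1:3))
  msa <- progressive_align(seqs)
  t1 <- nj_bootstrap(msa, n_replicates = 100L, seed = 7L)
  t2 <- nj_bootstrap(msa, n_replicates = 100L, seed = 7L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("newick output round-trips and parse errors name the position", {
  base <- fix_gene(len = 80L, seed = 3L)
  seqs <- sapply(1:4, function(i) tr1(mutate_to_identity(base$cds, 0.9,
                                                         seed = i)))
  names(seqs) <- paste0("t", 1:4)
  tree <- nj_bootstrap(progressive_align(seqs), 25L, seed = 5L)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tmp)
  back <- read_newick(tmp)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(ape::dist.topo(back, tree), 0, ignore_attr = TRUE)

  t3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a:1,b:1,c:1);", t3)
  expect_equal(length(read_newick(t3)$tip.label), 3L)

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a,b;", bad)
  expect_error(read_newick(bad), "unclosed")
  bad2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("a,b));", bad2)
  expect_error(read_newick(bad2), "position")
})
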