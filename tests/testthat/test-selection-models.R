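# NG86 counting vs a pathway-enumeration oracle; Goldman-Yang model fits,
# nesting, rerooting invariance; simulator limits; LRT arithmetic.

sim_tree <- function() {
  ape::read.tree(text = "((t1:0.2,t2:0.2):0.1,(t3:0.2,t4:0.2):0.1,(t5:0.2,t6:0.2):0.1);")
}

test_that("back_translate maps columns to source codons", {
  msa <- structure(c(a = "MK", b = "MK"), class = "dup_msa")
  cds <- c(a = "ATGAAA", b = "ATGAAG")
  caln <- back_translate(msa, cds)
  expect_equal(unname(unclass(caln)), c("ATGAAA", "ATGAAG"))

  msa2 <- structure(c(a = "MKV", b = "M-V"), class = "dup_msa")
  cds2 <- c(a = "ATGAAAGTT", b = "ATGGTA")
  caln2 <- back_translate(msa2, cds2)
  expect_equal(unname(caln2["b"]), "ATG---GTA")

  # terminal stop codons are tolerated, mismatches are not
  expect_silent(back_translate(msa, c(a = "ATGAAATAA", b = "ATGAAG")))
  expect_error(back_translate(msa, c(a = "ATGCCC", b = "ATGAAG")),
               "mismatch at residue 2")
})

test_that("ng86 handles identical pairs and single synonymous changes", {
  s <- paste(rep("ATGAAAGTTCTGTGGGCTGCA", 5), collapse = "")  # 30 codons
  o <- ng86(s, s)
  expect_equal(o$dN, 0)
  expect_equal(o$dS, 0)

  # one synonymous third-position change (AAA -> AAG)
  s2 <- sub("ATGAAA", "ATGAAG", s)
  o2 <- ng86(s, s2)
  expect_equal(o2$dN, 0)
  expect_gt(o2$dS, 0)
  expect_equal(o2$Nd, 0)
  expect_equal(o2$Sd, 1)
})

test_that("ng86 pathway averaging equals exhaustive enumeration", {
  # 9-codon pair with one 2-step codon difference (TTT -> GTA: F -> V)
  a <- "ATGAAAGTTTTTCTGTGGGCTGCAGAA"
  b <- sub("TTT(CTG)", "GTA\\1", a)
  got <- ng86(a, b)
  want <- oracle_ng86_pair("TTT", "GTA")
  expect_equal(got$Sd, unname(want["sd"]))
  expect_equal(got$Nd, unname(want["nd"]))

  # sweep random multi-hit codon pairs against the oracle
  sc <- Biostrings::GENETIC_CODE
  sense <- names(sc)[sc != "*"]
  set.seed(17)
  for (i in 1:30) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    got_i <- dupscan:::ng86_pair_counts(c1, c2)
    want_i <- oracle_ng86_pair(c1, c2)
    expect_equal(unname(got_i["sd"]), unname(want_i["sd"]),
                 label = paste(c1, c2))
    expect_equal(unname(got_i["nd"]), unname(want_i["nd"]),
                 label = paste(c1, c2))
  }
})

test_that("simulator limits: omega 0 forbids amino-acid change, t = 0 copies", {
  tree <- sim_tree()
  aln <- simulate_codons(tree, omega = 1e-9, kappa = 2, n_codons = 150L,
                         seed = 3L)
  prots <- vapply(unclass(aln), function(s) tr1(s), "")
  expect_equal(length(unique(prots)), 1L)

  tree0 <- ape::read.tree(text = "(x:0,(y:0,z:0):0);")
  aln0 <- simulate_codons(tree0, omega = 0.5, n_codons = 100L, seed = 4L)
  expect_equal(unname(unclass(aln0)["x"]), unname(unclass(aln0)["y"]))
})

test_that("fitted omega recovers the simulated value", {
  tree <- sim_tree()
  aln <- simulate_codons(tree, omega = 0.2, kappa = 2, n_codons = 500L,
                         seed = 42L)
  fit <- fit_codon_model(aln, tree, "one_ratio")
  expect_true(fit$converged)
  expect_gte(unname(fit$omega), 0.1)
  expect_lte(unname(fit$omega), 0.3)
  expect_gte(fit$kappa, 1.3)
  expect_lte(fit$kappa, 3)
})

test_that("lnL is nested across models and invariant to rerooting", {
  tree <- sim_tree()
  aln <- simulate_codons(tree, omega = 0.3, kappa = 2, n_codons = 300L,
                         seed = 11L)
  fit_free <- fit_codon_model(aln, tree, "one_ratio",
                              control = list(omega_start = 0.4))
  fit_fix <- fit_codon_model(aln, tree, "one_ratio_fixed1")
  fit_two <- fit_codon_model(aln, tree, "two_ratio",
                             foreground_edges = c("t1", "t2"),
                             start = fit_free,
                             control = list(omega_start = 0.4))
  expect_lte(fit_fix$lnL, fit_free$lnL + 1e-3)
  expect_lte(fit_free$lnL, fit_two$lnL + 1e-3)

  rerooted <- ape::root(tree, outgroup = "t5", resolve.root = TRUE)
  fit_re <- fit_codon_model(aln, rerooted, "one_ratio",
                            control = list(omega_start = 0.4))
  expect_equal(fit_re$lnL, fit_free$lnL, tolerance = 1e-4)
  expect_equal(unname(fit_re$omega), unname(fit_free$omega), tolerance = 0.02)
})

test_that("fit_codon_model and ng86 agree in omega rank order", {
  tree <- sim_tree()
  cherry_omega <- function(w) {
    aln <- simulate_codons(tree, omega = w, kappa = 2, n_codons = 400L,
                           seed = 7L + round(100 * w))
    fit <- fit_codon_model(aln, tree, "one_ratio",
                           control = list(omega_start = 0.4))
    ng <- ng86(unclass(aln)[["t1"]], unclass(aln)[["t2"]])
    c(fit = unname(fit$omega), ng = ng$omega)
  }
  res <- vapply(c(0.05, 0.2, 0.5, 1.0), cherry_omega, c(fit = 0, ng = 0))
  expect_equal(order(res["fit", ]), 1:4)
  expect_equal(order(res["ng", ]), 1:4)
})

test_that("LRT arithmetic: identical fits give p = 1; 3.84 on 1 df ~ 0.05", {
  f <- structure(list(model_tag = "one_ratio", lnL = -100, np = 10L,
                      converged = TRUE), class = "codon_fit")
  g <- structure(list(model_tag = "two_ratio", lnL = -100, np = 11L,
                      converged = TRUE), class = "codon_fit")
  r <- lrt(f, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  g2 <- structure(list(model_tag = "two_ratio", lnL = -100 + 3.84 / 2,
                       np = 11L, converged = TRUE), class = "codon_fit")
  r2 <- lrt(f, g2)
  expect_equal(r2$p_value, 0.05, tolerance = 0.002)

  bad <- structure(list(model_tag = "two_ratio", lnL = -101, np = 11L,
                        converged = TRUE), class = "codon_fit")
  expect_error(lrt(f, bad), "optimization failure")
})

test_that("empirical dN/dS on a long cherry approaches the simulated omega", {
  tree <- ape::read.tree(text = "(x:0.4,y:0.4);")
  # a cherry is two taxa; simulate via a 3-taxon tree with a zero third branch
  tree3 <- ape::read.tree(text = "(x:0.2,y:0.2,z:0);")
  aln <- simulate_codons(tree3, omega = 0.3, kappa = 2, n_codons = 5000L,
                         seed = 19L)
  o <- ng86(unclass(aln)[["x"]], unclass(aln)[["y"]])
  expect_gte(o$omega, 0.24)
  expect_lte(o$omega, 0.37)
})
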