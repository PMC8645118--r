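# Mechanism classification, pseudogene calling, identity/age classes, and
# synteny-based event collapsing.

test_that("mechanism follows the retained-intron rule on planted copies", {
  gene <- fix_gene(n_exons = 3L, len = 150L)   # 2 introns
  cases <- list(
    list(dup = fix_dup(mechanism = "retro", identity = 0.95),
         mech = "retro", retained = 0L),
    list(dup = fix_dup(mechanism = "dna", identity = 0.95),
         mech = "dna", retained = 2L),
    list(dup = fix_dup(mechanism = "partial_retro", identity = 0.95,
                       retained_introns = 1L),
         mech = "partial_retro", retained = 1L)
  )
  for (cs in cases) {
    gen <- fix_genome(list(cs$dup), gene)
    loci <- nonself(fix_loci(gen, gene))
    expect_length(loci, 1L)
    got <- classify_mechanism(loci[[1]], gene)
    expect_equal(got$mechanism, cs$mech)
    expect_equal(got$retained_introns, cs$retained)
    expect_equal(got$parental_introns, 2L)
  }
})

test_that("a single-exon parent copy retaining its intron is DNA-mediated", {
  gene <- fix_gene(n_exons = 2L, len = 120L)   # 1 intron, like Ran/aKap3
  gen <- fix_genome(list(fix_dup(mechanism = "dna", identity = 0.9)), gene)
  loci <- nonself(fix_loci(gen, gene))
  got <- classify_mechanism(loci[[1]], gene)
  expect_equal(got$mechanism, "dna")
  expect_equal(got$retained_introns, 1L)
})

test_that("low-coverage loci are classified as fragments", {
  locus <- structure(list(coverage = 0.3, strand = "+",
                          hits = data.frame(qstart = 0L, qend = 30L,
                                            gstart = 0L, gend = 90L)),
                     class = "candidate_locus")
  got <- classify_mechanism(locus, fix_gene(n_exons = 2L))
  expect_equal(got$mechanism, "fragment")
})

test_that("pseudogene rule is a step function with its jump at 10 aa", {
  gene <- fix_gene(n_exons = 1L, len = 120L, seed = 9L)
  for (trunc in c(1L, 5L, 8L, 9L, 10L, 11L, 15L, 20L)) {
    gen <- fix_genome(list(fix_dup(identity = 0.95, pseudogenize = TRUE,
                                   truncation_aa = trunc)), gene)
    loci <- nonself(fix_loci(gen, gene))
    expect_length(loci, 1L)
    st <- call_status(loci[[1]], gene$protein, gen$genome)
    want <- if (trunc >= 10L) "pseudogene" else "functional"
    expect_equal(st$status, want, label = sprintf("truncation %d", trunc))
    if (trunc >= 10L) expect_equal(st$reason, "premature_stop")
  }
})

test_that("full-length high-identity copies are functional", {
  gene <- fix_gene(len = 120L)
  gen <- fix_genome(list(fix_dup(identity = 0.95)), gene)
  loci <- nonself(fix_loci(gen, gene))
  st <- call_status(loci[[1]], gene$protein, gen$genome)
  expect_equal(st$status, "functional")
  expect_lt(st$removed_aa, 10L)
})

test_that("identity and age classes use strict thresholds", {
  expect_equal(dupscan:::age_class(1.0), "young")
  expect_equal(dupscan:::age_class(0.95), "young")
  expect_equal(dupscan:::age_class(0.90), "mid")   # > 90% is strict
  expect_equal(dupscan:::age_class(0.81), "mid")
  expect_equal(dupscan:::age_class(0.80), "old")   # > 80% is strict

  gene <- fix_gene(len = 150L)
  gen <- fix_genome(list(fix_dup(identity = 0.95)), gene)
  loci <- nonself(fix_loci(gen, gene))
  idn <- identity_to_parent(loci[[1]], gene$protein, gen$genome)
  expect_gte(idn$identity, 0.93)
  expect_lte(idn$identity, 0.97)
  expect_equal(idn$age_class, "young")
})

test_that("events merge on shared flanks and split on disjoint flanks", {
  ctx <- function(id, up, down) list(copy_id = id, upstream = up,
                                     downstream = down)
  copies <- data.frame(
    copy_id = c("c1", "c2", "c3"),
    species_id = c("s1", "s2", "s3"),
    parent_gene_id = "g",
    mechanism = "retro", status = "functional", identity = 0.9,
    stringsAsFactors = FALSE)
  contexts <- list(
    c1 = ctx("c1", c("f1", "f2", "f3"), c("f4", "f5", "f6")),
    c2 = ctx("c2", c("f1", "f2", "f3"), c("f4", "f5", "f6")),
    c3 = ctx("c3", c("x1", "x2", "x3"), c("x4", "x5", "x6")))
  ev <- call_events(copies, contexts, min_shared_flank = 2L)
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(ev$n_copies), c(1L, 2L))
})

test_that("event partition equals the brute-force transitive closure", {
  set.seed(55)
  ids <- paste0("c", 1:6)
  species <- paste0("s", 1:6)   # all distinct so closure is unconstrained
  flanks <- list(
    c1 = c("a1", "a2", "a3"), c2 = c("a2", "a3", "z9"),
    c3 = c("a3", "z9", "z8"), c4 = c("b1", "b2", "b3"),
    c5 = c("b2", "b3", "q1"), c6 = c("m1", "m2", "m3"))
  contexts <- lapply(ids, function(id) {
    list(copy_id = id, upstream = flanks[[id]], downstream = character())
  })
  names(contexts) <- ids
  copies <- data.frame(copy_id = ids, species_id = species,
                       parent_gene_id = "g", mechanism = "retro",
                       status = "functional", identity = 0.9,
                       stringsAsFactors = FALSE)
  rel <- matrix(FALSE, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (i != j) {
      shared <- dupscan:::lcs_len(flanks[[ids[i]]], flanks[[ids[j]]])
      rel[i, j] <- shared >= 2
    }
  }
  want <- oracle_transitive_partition(ids, rel)
  ev <- call_events(copies, contexts, min_shared_flank = 2L)
  got <- lapply(strsplit(ev$copy_ids, ","), sort)
  canon <- function(p) unname(p[order(vapply(p, `[`, "", 1))])
  expect_equal(canon(got), canon(lapply(want, sort)))
})

test_that("event calling is invariant to copy input order", {
  copies <- data.frame(
    copy_id = c("c1", "c2", "c3", "c4"),
    species_id = c("s1", "s2", "s1", "s3"),
    parent_gene_id = "g", mechanism = "retro", status = "functional",
    identity = 0.9, stringsAsFactors = FALSE)
  contexts <- list(
    c1 = list(copy_id = "c1", upstream = c("f1", "f2"), downstream = "f3"),
    c2 = list(copy_id = "c2", upstream = c("f1", "f2"), downstream = "f3"),
    c3 = list(copy_id = "c3", upstream = c("y1", "y2"), downstream = "y3"),
    c4 = list(copy_id = "c4", upstream = c("y1", "y2"), downstream = "y3"))
  ev1 <- call_events(copies, contexts)
  perm <- c(4, 2, 1, 3)
  ev2 <- call_events(copies[perm, ], contexts)
  expect_equal(ev1$copy_ids, ev2$copy_ids)
  # one copy per species per event is preserved
  expect_true(all(ev1$n_copies == ev1$n_species))
})

test_that("mechanism tallies mirror the event table", {
  ev <- data.frame(
    event_id = sprintf("e%d", 1:6),
    parent_gene_id = c(rep("ntf2", 6)),
    mechanism = c(rep("retro", 5), "dna"),
    stringsAsFactors = FALSE)
  t1 <- tally_mechanisms(ev)
  expect_equal(t1$rna_fraction[t1$parent_gene_id == "ntf2"], 5 / 6)

  ev13 <- data.frame(event_id = sprintf("e%d", 1:13), parent_gene_id = "ran",
                     mechanism = c(rep("retro", 12), "dna"),
                     stringsAsFactors = FALSE)
  t2 <- tally_mechanisms(ev13)
  expect_equal(t2$rna_fraction[t2$parent_gene_id == "ran"], 12 / 13)

  alldna <- data.frame(event_id = "e1", parent_gene_id = "g",
                       mechanism = "dna", stringsAsFactors = FALSE)
  expect_equal(tally_mechanisms(alldna)$rna_fraction, c(0, 0))
})
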