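# Generator invariants: determinism, ORF validity, planted structure,
# divergence targeting, flank sharing.

test_that("identical seeds give byte-identical FASTA and GFF3 output", {
  gene <- fix_gene()
  dup <- fix_dup()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome(fix_genome(list(dup), gene), d1)
  write_genome(fix_genome(list(dup), gene), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted genes are valid ORFs whose translation equals the protein", {
  for (ne in c(1L, 2L, 4L)) {
    g <- fix_gene(id = paste0("g", ne), n_exons = ne, len = 80L)
    expect_true(startsWith(g$cds, "ATG"))
    prot <- sub("\\*$", "", unname(six_frame_translate(paste0(g$cds, "TAA"))["+1"]))
    expect_identical(prot, g$protein)
    expect_length(g$intron_lengths, ne - 1L)
    expect_equal(sum(g$exon_lengths), 3L * (nchar(g$protein) + 1L))
  }
})

test_that("a retro copy of a multi-exon parent is one contiguous CDS", {
  gene <- fix_gene(n_exons = 4L, len = 110L)
  gen <- fix_genome(list(fix_dup(mechanism = "retro", identity = 0.95)), gene)
  truth <- gen$truth
  expect_equal(nrow(truth), 1L)
  expect_equal(truth$mechanism, "retro")
  # contiguous: span length == CDS length (no introns inserted)
  expect_equal(truth$end - truth$start, 3L * (nchar(gene$protein) + 1L))
  # dna copy spans CDS plus all introns
  gen2 <- fix_genome(list(fix_dup(mechanism = "dna", identity = 0.95)), gene)
  expect_equal(gen2$truth$end - gen2$truth$start,
               3L * (nchar(gene$protein) + 1L) + sum(gene$intron_lengths))
})

test_that("pseudogenized copies stop at least truncation_aa early", {
  gene <- fix_gene(len = 100L)
  gen <- fix_genome(list(fix_dup(identity = 0.9, pseudogenize = TRUE,
                                 truncation_aa = 15L)), gene)
  tr <- gen$truth
  seq <- substr(gen$genome$contigs[[tr$contig]], tr$start + 1L, tr$end)
  prot <- unname(six_frame_translate(seq)["+1"])
  stop_at <- regexpr("*", prot, fixed = TRUE)
  removed <- nchar(gene$protein) - (stop_at - 1L)
  expect_gte(removed, 15L)
  expect_equal(tr$status, "pseudogene")
})

test_that("mutate_to_identity hits its target and is deterministic", {
  g <- fix_gene(len = 200L)
  expect_identical(mutate_to_identity(g$cds, 1.0), g$cds)

  out <- mutate_to_identity(g$cds, 0.85, seed = 9L)
  ident <- mean(strsplit(tr1(out), "")[[1]] ==
                  strsplit(g$protein, "")[[1]])
  expect_gte(ident, 0.83)
  expect_lte(ident, 0.87)
  expect_equal(nchar(out), nchar(g$cds))
  expect_false(grepl("\\*", tr1(out)))
  expect_identical(out, mutate_to_identity(g$cds, 0.85, seed = 9L))

  expect_error(mutate_to_identity(g$cds, 0), "in \\(0, 1\\]")
  expect_error(mutate_to_identity(g$cds, 1.2), "in \\(0, 1\\]")
  short <- "ATGAAAGTTCTGTGG"   # MKVLW
  expect_error(mutate_to_identity(short, 0.99), "unreachable")
})

test_that("generated annotations survive a write/read round trip", {
  gene <- fix_gene(n_exons = 3L)
  gen <- fix_genome(list(fix_dup()), gene)
  dir <- withr::local_tempdir()
  paths <- write_genome(gen, dir)
  contigs <- read_fasta(paths["fasta"])
  expect_identical(contigs, gen$genome$contigs)
  models <- read_gff3(paths["gff3"], genome = gen$genome)
  expect_equal(length(models), length(gen$genome$genes))
  for (id in names(models)) {
    expect_equal(models[[id]]$exons, gen$genome$genes[[id]]$exons, label = id)
    expect_equal(models[[id]]$strand, gen$genome$genes[[id]]$strand)
  }
})

test_that("copies of one event share flanks; different events share none", {
  gene <- fix_gene()
  d1 <- fix_dup(event = "evA", species = c("s1", "s2"))
  d2 <- fix_dup(event = "evB", species = c("s1", "s2"), identity = 0.8)
  gens <- lapply(c("s1", "s2"), function(sp) {
    spec <- species_spec(sp, 3L, 30000L, 0L, seed = 3L)
    generate_genome(spec, list(gene), list(d1, d2))
  })
  ctx <- function(gen, ev) {
    tr <- gen$truth[gen$truth$event_id == ev, ]
    synteny_context(list(copy_id = tr$copy_id, contig_id = tr$contig,
                         gstart = tr$start, gend = tr$end), gen$genome, 3L)
  }
  a1 <- ctx(gens[[1]], "evA"); a2 <- ctx(gens[[2]], "evA")
  b1 <- ctx(gens[[1]], "evB")
  expect_gte(length(intersect(a1$upstream, a2$upstream)), 3L)
  expect_gte(length(intersect(a1$downstream, a2$downstream)), 3L)
  expect_length(intersect(c(a1$upstream, a1$downstream),
                          c(b1$upstream, b1$downstream)), 0L)
})

test_that("contig overflow raises a sizing error naming the contig", {
  gene <- fix_gene(len = 300L)
  expect_error(fix_genome(gene = gene, contig_length = 1500L),
               "ctg.*overflows")
})
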