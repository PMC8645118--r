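# FASTA / GFF3 round trips, coordinate conventions, translation utilities.

test_that("FASTA reading and writing round-trip, validate ids and characters", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc ignored", "ACGT", ">b", "ttagga"), tmp)
  seqs <- read_fasta(tmp)
  expect_identical(seqs, c(a = "ACGT", b = "TTAGGA"))

  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, out)
  expect_identical(read_fasta(out), seqs)

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_fasta(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC!T"), bad)
  expect_error(read_fasta(bad), "position")
})

test_that("GFF3 writes 1-based inclusive and reads back identical models", {
  g <- gene_model("g1", "c1", "+",
                  exons = cbind(c(100L, 300L), c(200L, 420L)),
                  attributes = c(biotype = "parent"))
  m <- gene_model("g2", "c1", "-", exons = cbind(500L, 650L))
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(g, m), tmp)

  lines <- readLines(tmp)
  gene_row <- strsplit(grep("\tgene\t.*ID=g1", lines, value = TRUE), "\t")[[1]]
  # internal (100, 420) half-open -> file 101..420 inclusive
  expect_equal(as.integer(gene_row[4]), 101L)
  expect_equal(as.integer(gene_row[5]), 420L)

  back <- read_gff3(tmp)
  expect_equal(back$g1$exons, g$exons)
  expect_equal(back$g1$cds, g$cds)
  expect_equal(back$g1$strand, "+")
  expect_equal(back$g2$strand, "-")
  expect_equal(unname(back$g1$attributes["biotype"]), "parent")

  # round trip again: byte-stable
  tmp2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("GFF3 referential and bounds errors are reported", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tmRNA\t1\t50\t.\t+\t.\tID=m1;Parent=missing",
               "c1\tx\tCDS\t1\t50\t.\t+\t0\tID=m1.c;Parent=m1"), tmp)
  expect_error(read_gff3(tmp), "missing gene")

  tmp2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tgene\t10\t50\t.\t+\t.\tID=g1",
               "c1\tx\tmRNA\t10\t50\t.\t+\t.\tID=m1;Parent=g1",
               "c1\tx\tCDS\t10\t80\t.\t+\t0\tID=m1.c;Parent=m1"), tmp2)
  expect_error(read_gff3(tmp2), "CDS outside gene span")

  g <- gene_model("g1", "cZ", "+", exons = cbind(0L, 30L))
  tmp3 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(g), tmp3)
  expect_error(read_gff3(tmp3, genome = c(c1 = 1000L)), "unknown contig")
})

test_that("six-frame translation follows the standard code on all frames", {
  fr <- six_frame_translate("ATGAAATGA")
  expect_equal(unname(fr["+1"]), "MK*")
  # frame +2 of TTTTTT: one codon TTT after the offset, remainder dropped
  expect_equal(unname(six_frame_translate("TTTTTT")["+2"]), "F")
  # reverse-complement symmetry
  s <- "ATGGCCATTGTAATGGGCCGCTGAAAGGGTGCCCGATAG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(unname(six_frame_translate(s)["-1"]),
               unname(six_frame_translate(rc)["+1"]))
  # ambiguity codes translate to X
  expect_equal(unname(six_frame_translate("ATGNNNAAA")["+1"]), "MXK")
})

test_that("translation matches a hard-coded standard genetic code table", {
  # independent table: hard-coded here, not taken from the package
  bases <- c("T", "C", "A", "G")
  aa64 <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  expect_length(codons, 64L)
  for (i in seq_along(codons)) {
    got <- unname(six_frame_translate(codons[i])["+1"])
    expect_identical(got, aa64[i])
  }
})

test_that("annotated genomes validate gene bounds and extract CDS/protein", {
  gene <- fix_gene(n_exons = 3L, len = 60L)
  gen <- fix_genome(gene = gene, contig_length = 20000L)
  model <- gen$genome$genes[[gene$gene_id]]
  # translating the annotated CDS reproduces the planted protein (the parent
  # in its own genome is diverged from the reference by ~4%)
  prot <- gene_protein(gen$genome, model)
  expect_equal(nchar(prot), nchar(gene$protein))
  expect_false(grepl("\\*", prot))

  expect_error(
    annotated_genome("x", c(c1 = "ACGT"),
                     list(gene_model("g", "c1", "+", cbind(0L, 30L)))),
    "exceeds bounds")
})
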