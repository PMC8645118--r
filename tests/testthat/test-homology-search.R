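# Local alignment against a brute-force DP oracle; translated search and
# chaining on planted fixtures.

test_that("align_local matches self-alignment and simple identities", {
  mat <- blosum62_test()
  a <- align_local("MKV", "MKV")
  expect_equal(a$identity, 1.0)
  expect_equal(a$score, mat["M", "M"] + mat["K", "K"] + mat["V", "V"])
  expect_equal(align_local("MKV", "MAV")$identity, 2 / 3)
  expect_error(align_local("", "MKV"), "empty")
})

test_that("align_local equals the brute-force affine DP oracle on 20-aa pairs", {
  mat <- blosum62_test()
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(101)
  for (rep in 1:25) {
    a <- paste(sample(aas, 20, replace = TRUE), collapse = "")
    b <- if (rep %% 3 == 0) {
      # related pair: mutate a few residues so alignments are non-trivial
      bb <- strsplit(a, "")[[1]]
      idx <- sample(20, 6)
      bb[idx] <- sample(aas, 6, replace = TRUE)
      paste(bb, collapse = "")
    } else {
      paste(sample(aas, sample(10:25, 1), replace = TRUE), collapse = "")
    }
    got <- align_local(a, b)$score
    want <- oracle_sw_score(a, b, mat)
    expect_equal(got, want, label = sprintf("pair %d", rep))
  }
})

test_that("alignment score is symmetric", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    a <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 25, replace = TRUE), collapse = "")
    expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  }
})

test_that("a planted retrocopy yields exactly one non-self covering hit", {
  gene <- fix_gene(n_exons = 3L, len = 120L)
  gen <- fix_genome(list(fix_dup(mechanism = "retro", identity = 0.95)), gene)
  hits <- search_translated(gene$protein, gen$genome,
                            parent_locus = gen$genome$genes[[gene$gene_id]])
  ns <- hits[!hits$self, , drop = FALSE]
  expect_equal(nrow(ns), 1L)
  expect_gte((ns$qend - ns$qstart) / nchar(gene$protein), 0.9)
  expect_gte(ns$identity, 0.9)
})

test_that("a planted 3-exon DNA copy appears as >= 3 colinear hits", {
  gene <- fix_gene(n_exons = 3L, len = 150L)
  gen <- fix_genome(list(fix_dup(mechanism = "dna", identity = 0.92)), gene)
  hits <- search_translated(gene$protein, gen$genome,
                            parent_locus = gen$genome$genes[[gene$gene_id]])
  ns <- hits[!hits$self, , drop = FALSE]
  expect_gte(nrow(ns), 3L)
  expect_equal(length(unique(ns$contig_id)), 1L)
  expect_equal(length(unique(ns$strand)), 1L)
  ns <- ns[order(ns$qstart), ]
  gaps <- ns$gstart[-1] - ns$gend[-nrow(ns)]
  # inter-hit gaps match the planted intron lengths (within junction slop)
  expect_equal(length(gaps), length(gene$intron_lengths))
  expect_true(all(abs(sort(gaps) - sort(gene$intron_lengths)) <= 30))
})

test_that("a genome without homologs returns only the self-hit", {
  gene <- fix_gene(len = 100L)
  gen <- fix_genome(gene = gene, contig_length = 20000L)
  hits <- search_translated(gene$protein, gen$genome,
                            parent_locus = gen$genome$genes[[gene$gene_id]])
  expect_true(all(hits$self))
})

test_that("lowering min_identity never removes hits", {
  gene <- fix_gene(len = 120L)
  gen <- fix_genome(list(fix_dup(identity = 0.7)), gene)
  strict <- search_translated(gene$protein, gen$genome, min_identity = 0.6)
  loose <- search_translated(gene$protein, gen$genome, min_identity = 0.4)
  key <- function(h) paste(h$contig_id, h$strand, h$gstart, h$gend)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("chaining joins colinear hits and splits strands", {
  hit <- function(qs, qe, gs, ge, strand = "+", contig = "c1", score = 100) {
    data.frame(query_id = "q", contig_id = contig, strand = strand,
               frame = 1L, qstart = qs, qend = qe, gstart = gs, gend = ge,
               identity = 0.9, score = score, naln = qe - qs,
               q_aligned = "", s_aligned = "", self = FALSE,
               stringsAsFactors = FALSE)
  }
  two <- rbind(hit(0, 50, 1000, 1150), hit(50, 100, 1650, 1800))
  loci <- chain_hits(two, query_len = 100L)
  expect_length(loci, 1L)
  expect_equal(nrow(loci[[1]]$hits), 2L)
  jn <- dupscan:::locus_junctions(loci[[1]])
  expect_equal(jn$gap_bp, 500)

  opp <- rbind(hit(0, 50, 1000, 1150), hit(50, 100, 1650, 1800, strand = "-"))
  expect_length(chain_hits(opp, query_len = 100L), 2L)
})

test_that("chain extraction matches exhaustive best-chain enumeration", {
  hit <- function(qs, qe, gs, ge, strand = "+", contig = "c1", score) {
    data.frame(query_id = "q", contig_id = contig, strand = strand,
               frame = 1L, qstart = qs, qend = qe, gstart = gs, gend = ge,
               identity = 0.9, score = score, naln = qe - qs,
               q_aligned = "", s_aligned = "", self = FALSE,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(
    hit(0, 30, 1000, 1090, score = 80),
    hit(30, 60, 1200, 1290, score = 70),
    hit(60, 90, 1500, 1590, score = 60),
    hit(0, 40, 5000, 5120, score = 95),       # competing start
    hit(25, 60, 30000, 30105, score = 50),    # too far for any chain
    hit(0, 30, 800, 890, contig = "c2", score = 40))
  want <- oracle_best_chain(hits, max_intron_bp = 20000L)
  loci <- chain_hits(hits, max_intron_bp = 20000L, query_len = 90L)
  best <- loci[[which.max(vapply(loci, function(l) sum(l$hits$score), 0))]]
  expect_equal(sum(best$hits$score), want$score)
  got_idx <- sort(match(paste(best$hits$gstart, best$hits$gend),
                        paste(hits$gstart, hits$gend)))
  expect_equal(got_idx, want$idx)
  # every hit assigned to exactly one locus
  expect_equal(sum(vapply(loci, function(l) nrow(l$hits), 0L)), nrow(hits))
})
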