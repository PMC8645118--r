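# Synthetic annotated genomes with planted parental genes, duplicates of
# known mechanism and status, and conserved flanking-gene neighborhoods, so
# every downstream stage is testable against ground truth.
#
# Determinism: all randomness is routed through with_seed()/child_seed(), so
# identical specs give byte-identical FASTA/GFF3/TSV output.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character())
  paste0("M", paste(sample(aas, n - 1L, replace = TRUE), collapse = ""))
}

# Reverse-translate a protein into a CDS by sampling synonymous codons
protein_to_cds <- function(protein) {
  by_aa <- codons_for_aa()
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(codons, collapse = "")
}

# Intron with canonical GT..AG ends and guaranteed stop codons in all three
# frames near the 5' end (so translated search cannot read through it)
random_intron <- function(n) {
  stopifnot(n >= 20)
  body <- random_dna(n - 4L)
  substr(body, 5L, 13L) <- "TAATAATAA"
  paste0("GT", body, "AG")
}

#' Specification of one synthetic species genome
#'
#' @param species_id species label.
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param intergenic_gene_count extra unrelated filler genes per genome.
#' @param seed RNG seed; identical seeds give byte-identical genomes.
#' @return A `species_spec` list.
#' @export
species_spec <- function(species_id, n_contigs = 3L, contig_length = 60000L,
                         intergenic_gene_count = 4L, seed = 1L) {
  stopifnot(n_contigs >= 1, contig_length > 0, intergenic_gene_count >= 0)
  structure(list(species_id = species_id, n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 intergenic_gene_count = as.integer(intergenic_gene_count),
                 seed = as.integer(seed)),
            class = "species_spec")
}

#' A parental gene to plant
#'
#' The concatenated exons form an ORF (ATG start, single terminal stop); the
#' translation equals `protein`.
#'
#' @param gene_id gene identifier (shared across species for orthologs).
#' @param protein amino-acid string (must start with `M`); if `NULL`, a random
#'   protein of `protein_length` residues is generated from `seed`.
#' @param n_exons number of exons.
#' @param exon_lengths optional bp lengths (must sum to `3 * (naa + 1)`).
#' @param intron_lengths optional bp lengths (length `n_exons - 1`).
#' @param strand `"+"` or `"-"`.
#' @param protein_length used when `protein` is `NULL`.
#' @param seed RNG seed for sequence generation.
#' @return A `planted_gene` list (includes the reference `cds`, stop codon
#'   excluded).
#' @export
planted_gene <- function(gene_id, protein = NULL, n_exons = 1L,
                         exon_lengths = NULL, intron_lengths = NULL,
                         strand = "+", protein_length = 150L, seed = 1L) {
  with_seed(child_seed(seed, gene_id), {
    if (is.null(protein)) protein <- random_protein(protein_length)
    stopifnot(startsWith(protein, "M"))
    naa <- nchar(protein)
    cds_len <- 3L * (naa + 1L)  # including stop codon
    if (is.null(exon_lengths)) {
      base <- cds_len %/% n_exons
      exon_lengths <- rep(base, n_exons)
      exon_lengths[n_exons] <- cds_len - base * (n_exons - 1L)
    }
    if (sum(exon_lengths) != cds_len) {
      stopf("gene %s: exon lengths sum to %d, expected %d",
            gene_id, sum(exon_lengths), cds_len)
    }
    if (is.null(intron_lengths)) {
      intron_lengths <- if (n_exons > 1L) sample(61:180, n_exons - 1L,
                                                 replace = TRUE) else integer()
    }
    stopifnot(length(intron_lengths) == n_exons - 1L)
    cds <- protein_to_cds(protein)
    introns <- vapply(intron_lengths, random_intron, "")
    structure(list(gene_id = gene_id, protein = protein, cds = cds,
                   n_exons = as.integer(n_exons),
                   exon_lengths = as.integer(exon_lengths),
                   intron_lengths = as.integer(intron_lengths),
                   introns = introns, strand = strand, seed = seed),
              class = "planted_gene")
  })
}

#' A duplicate copy to plant
#'
#' @param parent_gene_id id of the [planted_gene()] it derives from.
#' @param mechanism `"retro"` (no introns), `"dna"` (all parental introns) or
#'   `"partial_retro"` (a proper non-empty subset).
#' @param retained_intron_indices introns kept (1-based, in transcription
#'   order); required for `partial_retro`, implied otherwise.
#' @param target_protein_identity protein identity to the parent in (0, 1].
#' @param pseudogenize if `TRUE`, a premature stop is introduced.
#' @param truncation_aa residues removed by the premature stop (>= 1 when
#'   pseudogenizing).
#' @param placement `"unlinked"` (different contig, own flanks) or `"tandem"`
#'   (within 10 kb downstream of the parent).
#' @param species_set species carrying this (orthologous) copy; they share
#'   flanking filler genes so synteny collapses them into one event.
#' @param event_id label shared by orthologous copies.
#' @param strand strand the copy is inserted on.
#' @param seed RNG seed for the divergence mutations.
#' @return A `planted_duplicate` list.
#' @export
planted_duplicate <- function(parent_gene_id, mechanism = c("retro", "dna",
                                                            "partial_retro"),
                              retained_intron_indices = NULL,
                              target_protein_identity = 0.9,
                              pseudogenize = FALSE, truncation_aa = 0L,
                              placement = c("unlinked", "tandem"),
                              species_set, event_id, strand = "+",
                              seed = 1L) {
  mechanism <- match.arg(mechanism)
  placement <- match.arg(placement)
  if (target_protein_identity <= 0 || target_protein_identity > 1) {
    stopf("target_protein_identity must be in (0, 1]")
  }
  if (pseudogenize && truncation_aa < 1L) {
    stopf("pseudogenized copies need truncation_aa >= 1")
  }
  if (mechanism == "partial_retro" &&
      (is.null(retained_intron_indices) || !length(retained_intron_indices))) {
    stopf("partial_retro requires retained_intron_indices")
  }
  structure(list(parent_gene_id = parent_gene_id, mechanism = mechanism,
                 retained_intron_indices = as.integer(retained_intron_indices %||% integer()),
                 target_protein_identity = target_protein_identity,
                 pseudogenize = isTRUE(pseudogenize),
                 truncation_aa = as.integer(truncation_aa),
                 placement = placement, species_set = as.character(species_set),
                 event_id = as.character(event_id), strand = strand,
                 seed = as.integer(seed)),
            class = "planted_duplicate")
}

#' Diverge a coding sequence to a target protein identity
#'
#' Introduces amino-acid-changing codon substitutions at
#' `round((1 - target) * naa)` positions (the initiator ATG is preserved),
#' plus synonymous codon swaps at rate `syn_rate`. The realized protein
#' identity is within 2 percentage points of `target_identity` (exact up to
#' rounding of the substitution count).
#'
#' @param cds coding nucleotide string (no terminal stop, valid ORF).
#' @param target_identity fraction in (0, 1]; 1 returns the input unchanged.
#' @param seed RNG seed.
#' @param syn_rate per-codon synonymous substitution rate.
#' @return Diverged CDS of the same length.
#' @export
mutate_to_identity <- function(cds, target_identity, seed = 1L,
                               syn_rate = 0.08) {
  if (target_identity <= 0 || target_identity > 1) {
    stopf("target_identity must be in (0, 1]")
  }
  if (nchar(cds) %% 3L != 0L) stopf("CDS length is not a multiple of 3")
  prot <- translate_cds(cds)
  if (grepl("\\*", prot)) stopf("input CDS contains an internal stop codon")
  if (target_identity == 1) return(cds)
  naa <- nchar(prot)
  k <- round((1 - target_identity) * naa)
  if (k == 0L) {
    stopf("identity target %.3f unreachable: protein of %d aa is too short",
          target_identity, naa)
  }
  if (k > naa - 1L) {
    stopf("identity target %.3f unreachable for a %d-aa protein",
          target_identity, naa)
  }
  with_seed(seed, {
    codons <- as_codons(cds)
    by_aa <- codons_for_aa()
    aas <- translate_codon(codons)
    pos <- sample(2:naa, k)  # keep the initiator methionine
    for (p in pos) {
      alt_aa <- sample(setdiff(names(by_aa), c(aas[p], "*")), 1L)
      opts <- by_aa[[alt_aa]]
      codons[p] <- opts[sample.int(length(opts), 1L)]
    }
    rest <- setdiff(seq_len(naa)[-1], pos)
    nsyn <- rbinom(1L, length(rest), syn_rate)
    if (nsyn > 0) {
      for (p in rest[sample.int(length(rest), nsyn)]) {
        opts <- setdiff(by_aa[[aas[p]]], codons[p])
        if (length(opts)) codons[p] <- opts[sample.int(length(opts), 1L)]
      }
    }
    paste(codons, collapse = "")
  })
}

# Replace the codon at (naa - truncation_aa + 1) with TAA: the premature stop
# removes exactly `truncation_aa` residues relative to the parent's stop.
insert_premature_stop <- function(cds, truncation_aa) {
  codons <- as_codons(cds)
  naa <- length(codons)
  q <- naa - truncation_aa + 1L
  if (q < 2L) stopf("truncation_aa %d leaves no ORF", truncation_aa)
  codons[q] <- "TAA"
  paste(codons, collapse = "")
}

# Filler gene: 300-bp single-exon ORF (99 aa + stop) whose sequence is a
# deterministic function of its id, so shared flank genes are identical
# orthologs across species.
filler_gene_cds <- function(filler_id) {
  with_seed(child_seed(823L, filler_id), {
    paste0(protein_to_cds(random_protein(99L)), "TAA")
  })
}

# Assemble the transcript-order genomic sequence of a gene (exons+introns)
# and the transcript-relative exon intervals.
gene_genomic_seq <- function(cds_with_stop, exon_lengths, introns) {
  n <- length(exon_lengths)
  pieces <- character(0)
  exon_tx <- matrix(0L, n, 2)
  at <- 0L
  cur <- 0L  # position within CDS
  for (i in seq_len(n)) {
    ex <- substr(cds_with_stop, cur + 1L, cur + exon_lengths[i])
    pieces <- c(pieces, ex)
    exon_tx[i, ] <- c(at, at + exon_lengths[i])
    at <- at + exon_lengths[i]
    cur <- cur + exon_lengths[i]
    if (i < n) {
      pieces <- c(pieces, introns[i])
      at <- at + nchar(introns[i])
    }
  }
  list(seq = paste(pieces, collapse = ""), exon_tx = exon_tx)
}

# Transcript-relative intervals -> genomic intervals given insertion start,
# total length and strand (kept in transcription order).
tx_to_genome <- function(tx, start, total_len, strand) {
  if (strand == "+") {
    cbind(start + tx[, 1], start + tx[, 2])
  } else {
    cbind(start + total_len - tx[, 2], start + total_len - tx[, 1])
  }
}

#' Generate one annotated genome with planted genes and duplicates
#'
#' Lays out, per contig, alternating intergenic spacers and gene blocks:
#' parent genes with their conserved flanking filler genes on the first
#' contig, unlinked duplicates (with event-specific conserved flanks) on the
#' remaining contigs, tandem duplicates within 10 kb downstream of their
#' parent. Duplicate copies are inserted as raw sequence (not annotated) and
#' recorded in the ground truth.
#'
#' @param spec a [species_spec()].
#' @param genes list of [planted_gene()] reference genes (planted as this
#'   species' orthologs, diverged to `parent_identity`).
#' @param dups list of [planted_duplicate()]; only those whose `species_set`
#'   contains this species are planted.
#' @param parent_identity protein identity of this species' parent genes to
#'   the reference (1 keeps them identical).
#' @param flank_n conserved filler genes on each side of parents and
#'   unlinked duplicates.
#' @return List with `genome` (an [annotated_genome()]) and `truth`
#'   (data.frame: copy_id, species_id, contig, start, end, strand, mechanism,
#'   status, identity, event_id, parent_gene_id).
#' @export
generate_genome <- function(spec, genes, dups = list(),
                            parent_identity = 0.96, flank_n = 3L) {
  stopifnot(inherits(spec, "species_spec"))
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  sp <- spec$species_id
  contig_ids <- sprintf("%s_ctg%d", sp, seq_len(spec$n_contigs))
  cursors <- setNames(rep(0L, spec$n_contigs), contig_ids)
  parts <- setNames(vector("list", spec$n_contigs), contig_ids)
  models <- list()
  truth <- list()

  emit <- function(contig, seq) {
    if (cursors[[contig]] + nchar(seq) > spec$contig_length) {
      stopf("contig %s of %s overflows its %d bp budget",
            contig, sp, spec$contig_length)
    }
    parts[[contig]][[length(parts[[contig]]) + 1L]] <<- seq
    start <- cursors[[contig]]
    cursors[[contig]] <<- cursors[[contig]] + nchar(seq)
    start
  }
  spacer <- function(contig, n) emit(contig, with_seed(
    child_seed(spec$seed, paste0("spacer", contig, cursors[[contig]])),
    random_dna(n)))

  plant_filler <- function(contig, filler_id) {
    cds <- filler_gene_cds(filler_id)
    start <- emit(contig, cds)
    models[[filler_id]] <<- gene_model(
      filler_id, contig, "+",
      exons = cbind(start, start + nchar(cds)),
      attributes = c(biotype = "filler"))
    spacer(contig, 120L)
  }

  plant_gene_copy <- function(contig, gene_id, cds_nostop, exon_lengths,
                              introns, strand, annotate = TRUE,
                              attributes = character()) {
    gs <- gene_genomic_seq(paste0(cds_nostop, "TAA"), exon_lengths, introns)
    seq <- if (strand == "+") gs$seq else revcomp(gs$seq)
    start <- emit(contig, seq)
    exons <- tx_to_genome(gs$exon_tx, start, nchar(gs$seq), strand)
    if (annotate) {
      models[[gene_id]] <<- gene_model(gene_id, contig, strand,
                                       exons = exons, attributes = attributes)
    }
    list(start = start, end = start + nchar(gs$seq), exons = exons)
  }

  # --- parent genes (+ conserved flanks) on contig 1
  main <- contig_ids[1]
  parent_loc <- list()
  spacer(main, 400L)
  for (g in genes) {
    for (i in seq_len(flank_n)) plant_filler(main, sprintf("%s_flu%d", g$gene_id, i))
    cds <- if (parent_identity < 1) {
      mutate_to_identity(g$cds, parent_identity,
                         seed = child_seed(spec$seed, paste0("par", g$gene_id)))
    } else {
      g$cds
    }
    loc <- plant_gene_copy(main, g$gene_id, cds, g$exon_lengths, g$introns,
                           g$strand, attributes = c(biotype = "parent"))
    parent_loc[[g$gene_id]] <- loc
    spacer(main, 150L)
    # tandem duplicates sit inside the parent's downstream neighborhood
    for (d in dups) {
      if (d$placement == "tandem" && d$parent_gene_id == g$gene_id &&
          sp %in% d$species_set) {
        truth[[length(truth) + 1L]] <-
          plant_duplicate_seq(d, genes[[d$parent_gene_id]], main, sp,
                              emit, plant_gene_copy)
        spacer(main, 150L)
      }
    }
    for (i in seq_len(flank_n)) plant_filler(main, sprintf("%s_fld%d", g$gene_id, i))
    spacer(main, 300L)
  }

  # --- unlinked duplicates with event-specific conserved flanks
  other <- if (spec$n_contigs > 1) contig_ids[-1] else contig_ids
  oi <- 0L
  for (d in dups) {
    if (!(sp %in% d$species_set) || d$placement != "unlinked") next
    oi <- oi + 1L
    contig <- other[(oi - 1L) %% length(other) + 1L]
    spacer(contig, 350L)
    for (i in seq_len(flank_n)) plant_filler(contig, sprintf("%s_flu%d", d$event_id, i))
    truth[[length(truth) + 1L]] <-
      plant_duplicate_seq(d, genes[[d$parent_gene_id]], contig, sp,
                          emit, plant_gene_copy)
    spacer(contig, 150L)
    for (i in seq_len(flank_n)) plant_filler(contig, sprintf("%s_fld%d", d$event_id, i))
  }

  # --- unrelated intergenic filler genes
  for (i in seq_len(spec$intergenic_gene_count)) {
    contig <- contig_ids[(i - 1L) %% spec$n_contigs + 1L]
    spacer(contig, 250L)
    plant_filler(contig, sprintf("%s_rnd%d", sp, i))
  }

  # pad contigs to their declared length
  contigs <- vapply(contig_ids, function(cid) {
    pad <- spec$contig_length - cursors[[cid]]
    if (pad > 0) {
      emit(cid, with_seed(child_seed(spec$seed, paste0("pad", cid)),
                          random_dna(pad)))
    }
    paste(unlist(parts[[cid]]), collapse = "")
  }, "")

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(copy_id = character(), species_id = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), mechanism = character(),
               status = character(), identity = double(),
               event_id = character(), parent_gene_id = character(),
               stringsAsFactors = FALSE)
  list(genome = annotated_genome(sp, contigs, models), truth = truth_df)
}

# Build and insert the sequence of one duplicate copy; returns its truth row.
plant_duplicate_seq <- function(d, parent, contig, sp, emit, plant_gene_copy) {
  seed <- child_seed(d$seed, paste0(d$event_id, sp))
  cds <- mutate_to_identity(parent$cds, d$target_protein_identity, seed = seed)
  status <- "functional"
  if (d$pseudogenize) {
    cds <- insert_premature_stop(cds, d$truncation_aa)
    status <- "pseudogene"
  }
  n_parent_introns <- parent$n_exons - 1L
  retained <- switch(d$mechanism,
    retro = integer(),
    dna = seq_len(n_parent_introns),
    partial_retro = sort(d$retained_intron_indices))
  if (d$mechanism == "partial_retro" &&
      (length(retained) == 0 || length(retained) >= n_parent_introns)) {
    stopf("event %s: partial_retro must retain a proper non-empty intron subset",
          d$event_id)
  }
  if (length(retained)) {
    # merge exons across spliced-out introns
    exon_lengths <- integer()
    introns <- character()
    acc <- parent$exon_lengths[1]
    for (i in seq_len(n_parent_introns)) {
      if (i %in% retained) {
        exon_lengths <- c(exon_lengths, acc)
        introns <- c(introns, parent$introns[i])
        acc <- parent$exon_lengths[i + 1L]
      } else {
        acc <- acc + parent$exon_lengths[i + 1L]
      }
    }
    exon_lengths <- c(exon_lengths, acc)
  } else {
    exon_lengths <- sum(parent$exon_lengths)
    introns <- character()
  }
  loc <- plant_gene_copy(contig, paste0(d$event_id, "_", sp), cds,
                         exon_lengths, introns, d$strand, annotate = FALSE)
  realized <- {
    pa <- strsplit(parent$protein, "")[[1]]
    ca <- strsplit(translate_cds(cds), "")[[1]]
    sum(pa == ca) / length(pa)
  }
  data.frame(copy_id = paste0(d$event_id, "_", sp), species_id = sp,
             contig = contig, start = loc$start, end = loc$end,
             strand = d$strand, mechanism = d$mechanism, status = status,
             identity = realized, event_id = d$event_id,
             parent_gene_id = d$parent_gene_id, stringsAsFactors = FALSE)
}

#' Write a generated genome to FASTA + GFF3 (+ ground-truth TSV)
#'
#' @param gen result of [generate_genome()].
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_genome <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- gen$genome$species_id
  fa <- file.path(dir, paste0(sp, ".fa"))
  gff <- file.path(dir, paste0(sp, ".gff3"))
  write_fasta(gen$genome$contigs, fa)
  write_gff3(gen$genome$genes, gff)
  invisible(c(fasta = fa, gff3 = gff))
}
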