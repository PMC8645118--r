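# FASTA / GFF3 readers and writers plus translation utilities.
#
# Internal coordinates are 0-based half-open throughout the package; GFF3
# emission converts to 1-based inclusive (and back on read). Exon and CDS
# blocks of a gene model are stored in transcription order (5' to 3'), so on
# the minus strand the first block is the one with the largest genomic start.

#' Construct a gene model
#'
#' @param gene_id unique gene identifier.
#' @param contig_id contig the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (0-based half-open),
#'   one row per exon, in transcription order.
#' @param cds like `exons`, for the coding part; defaults to `exons`.
#' @param attributes named character vector of extra GFF3 attributes,
#'   preserved verbatim on write.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig_id, strand, exons, cds = exons,
                       attributes = character()) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) >= 2)
  exons <- matrix(as.integer(exons[, 1:2]), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.integer(cds[, 1:2]), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2] <= exons[, 1])) stopf("gene %s: empty exon interval", gene_id)
  ord <- if (strand == "+") order(exons[, 1]) else order(-exons[, 1])
  exons <- exons[ord, , drop = FALSE]
  cds <- cds[if (strand == "+") order(cds[, 1]) else order(-cds[, 1]), , drop = FALSE]
  gs <- sort(exons[, 1])
  ge <- sort(exons[, 2])
  if (nrow(exons) > 1 && any(gs[-1] < ge[-length(ge)])) {
    stopf("gene %s: overlapping exons", gene_id)
  }
  structure(list(gene_id = as.character(gene_id),
                 contig_id = as.character(contig_id),
                 strand = strand, exons = exons, cds = cds,
                 phase = cds_phases(cds),
                 attributes = attributes),
            class = "gene_model")
}

# GFF3 phase of each CDS block from cumulative coding length
cds_phases <- function(cds) {
  len <- cds[, 2] - cds[, 1]
  before <- c(0L, cumsum(len)[-length(len)])
  as.integer((3L - before %% 3L) %% 3L)
}

gene_span <- function(model) {
  c(min(model$exons[, 1]), max(model$exons[, 2]))
}

#' Construct an annotated genome
#'
#' @param species_id species label.
#' @param contigs named character vector of contig sequences.
#' @param genes list of [gene_model()] objects.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(species_id, contigs, genes = list()) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  for (g in genes) {
    if (!g$contig_id %in% names(contigs)) {
      stopf("gene %s references unknown contig %s", g$gene_id, g$contig_id)
    }
    sp <- gene_span(g)
    if (sp[1] < 0 || sp[2] > nchar(contigs[[g$contig_id]])) {
      stopf("gene %s exceeds bounds of contig %s", g$gene_id, g$contig_id)
    }
  }
  ord <- order(vapply(genes, `[[`, "", "contig_id"),
               vapply(genes, function(g) gene_span(g)[1], 0))
  structure(list(species_id = species_id, contigs = toupper(contigs),
                 genes = genes[ord]),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d contig(s), %.0f bp, %d gene model(s)\n",
              x$species_id, length(x$contigs), sum(nchar(x$contigs)),
              length(x$genes)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and ids are taken up to the first whitespace.
#' Duplicate ids and non-IUPAC characters are format errors.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- regexpr("[^ACGTUNRYSWKMBDHV*\\-]", gsub("\\*$", "", seqs),
                 perl = TRUE)
  aa <- regexpr("[^A-Z*\\-]", seqs, perl = TRUE)
  if (any(aa > 0)) {
    i <- which(aa > 0)[1]
    stopf("non-IUPAC character in sequence '%s' at position %d", ids[i], aa[i])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

gff3_attr <- function(attrs) {
  paste(sprintf("%s=%s", names(attrs), attrs), collapse = ";")
}

#' Write gene models to GFF3
#'
#' Deterministic emitter: genes sorted by contig and start; each gene gets a
#' gene row, a single mRNA row (`<gene>.t1`), exon rows and CDS rows with
#' phase. Internal 0-based half-open coordinates are converted to 1-based
#' inclusive.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  ord <- order(vapply(models, `[[`, "", "contig_id"),
               vapply(models, function(g) gene_span(g)[1], 0))
  for (g in models[ord]) {
    sp <- gene_span(g)
    row <- function(type, s, e, phase, attrs) {
      sprintf("%s\tdupscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$contig_id, type, s + 1L, e, g$strand, phase, attrs)
    }
    mrna <- paste0(g$gene_id, ".t1")
    extra <- if (length(g$attributes)) paste0(";", gff3_attr(g$attributes)) else ""
    lines <- c(lines,
               row("gene", sp[1], sp[2], ".", paste0("ID=", g$gene_id, extra)),
               row("mRNA", sp[1], sp[2], ".",
                   sprintf("ID=%s;Parent=%s", mrna, g$gene_id)))
    exo <- g$exons[order(g$exons[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(exo))) {
      lines <- c(lines, row("exon", exo[i, 1], exo[i, 2], ".",
                            sprintf("ID=%s.e%d;Parent=%s", mrna, i, mrna)))
    }
    gord <- order(g$cds[, 1])
    cds <- g$cds[gord, , drop = FALSE]
    ph <- g$phase[gord]
    for (i in seq_len(nrow(cds))) {
      lines <- c(lines, row("CDS", cds[i, 1], cds[i, 2], ph[i],
                            sprintf("ID=%s.c;Parent=%s", mrna, mrna)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/CDS rows linked by `Parent` attributes (exon rows are
#' used when present). File coordinates (1-based inclusive) are converted to
#' internal 0-based half-open; minus-strand blocks are returned in
#' transcription order.
#'
#' @param path GFF3 file.
#' @param genome optional [annotated_genome()] or named contig-length vector
#'   used to validate contig references and bounds.
#' @return List of [gene_model()] objects.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(gr$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, "")
  contig_len <- NULL
  if (inherits(genome, "annotated_genome")) {
    contig_len <- setNames(nchar(genome$contigs), names(genome$contigs))
  } else if (!is.null(genome)) {
    contig_len <- genome
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (any(!mrnas$Parent %in% genes$ID)) {
    bad <- mrnas$ID[!mrnas$Parent %in% genes$ID][1]
    stopf("mRNA %s has Parent pointing to a missing gene", bad)
  }
  if (any(!parts$Parent %in% mrnas$ID)) {
    bad <- parts$Parent[!parts$Parent %in% mrnas$ID][1]
    stopf("exon/CDS rows reference missing mRNA %s", bad)
  }
  models <- vector("list", nrow(genes))
  reserved <- c("ID", "Parent", "Name")
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    if (!is.null(contig_len)) {
      if (!g$seqnames %in% names(contig_len)) {
        stopf("gene %s references unknown contig %s", g$ID, g$seqnames)
      }
      if (g$end > contig_len[[as.character(g$seqnames)]]) {
        stopf("gene %s exceeds bounds of contig %s", g$ID, g$seqnames)
      }
    }
    mid <- mrnas$ID[mrnas$Parent == g$ID][1]
    sub <- parts[parts$Parent == mid, , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    exo <- sub[sub$type == "exon", , drop = FALSE]
    if (!nrow(exo)) exo <- cds
    if (!nrow(cds)) stopf("gene %s has no CDS rows", g$ID)
    if (min(cds$start) < g$start || max(cds$end) > g$end) {
      stopf("gene %s: CDS outside gene span", g$ID)
    }
    extra_cols <- setdiff(colnames(df), c("seqnames", "start", "end", "width",
                                          "strand", "source", "type", "score",
                                          "phase", reserved, "Parent"))
    attrs <- character()
    for (cc in extra_cols) {
      v <- genes[k, cc]
      if (!is.na(v) && !is.null(v)) attrs[cc] <- as.character(v)
    }
    models[[k]] <- gene_model(
      gene_id = g$ID, contig_id = as.character(g$seqnames),
      strand = as.character(g$strand),
      exons = cbind(exo$start - 1L, exo$end),
      cds = cbind(cds$start - 1L, cds$end),
      attributes = attrs
    )
  }
  names(models) <- genes$ID
  models
}

#' Six-frame translation
#'
#' @param seq nucleotide string.
#' @return Named character vector of translations for frames `+1..+3` (forward)
#'   and `-1..-3` (reverse complement); stops are rendered `*`, codons
#'   containing ambiguity codes give `X`, trailing partial codons are dropped.
#' @export
six_frame_translate <- function(seq) {
  seq <- toupper(seq)
  one <- function(s, off) {
    n <- nchar(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    sub <- Biostrings::DNAString(substr(s, off + 1L, off + n))
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  rc <- revcomp(seq)
  out <- c(one(seq, 0L), one(seq, 1L), one(seq, 2L),
           one(rc, 0L), one(rc, 1L), one(rc, 2L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Spliced CDS sequence of a gene model (transcription order, minus-strand
#' blocks reverse-complemented)
#' @param genome an [annotated_genome()].
#' @param model a [gene_model()] from that genome.
#' @return Nucleotide string.
#' @export
extract_cds <- function(genome, model) {
  contig <- genome$contigs[[model$contig_id]]
  pieces <- apply(model$cds, 1, function(r) substr(contig, r[1] + 1L, r[2]))
  if (model$strand == "-") {
    pieces <- vapply(pieces, revcomp, "")
  }
  paste(pieces, collapse = "")
}

#' Protein encoded by a gene model (terminal stop stripped)
#' @inheritParams extract_cds
#' @return Amino-acid string.
#' @export
gene_protein <- function(genome, model) {
  sub("\\*$", "", translate_cds(extract_cds(genome, model)))
}
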