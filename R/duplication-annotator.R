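# Turning candidate loci into classified gene copies and cross-species
# duplication events.
#
# Mechanism rule: a retrocopy appears as one solid hit with no introns; a
# DNA-mediated copy retains the parental exon/intron structure, so its exons
# appear as individual hits separated by intron-scale gaps. A copy retaining
# a proper subset of parental introns is a partially processed retrocopy.
# Status rule: a premature stop codon removing at least 10 amino acids, or a
# truncation of at least 10 amino acids, makes the copy a pseudogene.

#' Parental intron junction positions in protein coordinates
#'
#' @param parent a [gene_model()] or [planted_gene()].
#' @return Numeric vector of junction positions (aa, cumulative coding length
#'   before each intron / 3); length = number of introns.
#' @export
parent_junctions_aa <- function(parent) {
  if (inherits(parent, "planted_gene")) {
    lens <- parent$exon_lengths
  } else {
    lens <- parent$cds[, 2] - parent$cds[, 1]
  }
  if (length(lens) < 2) return(numeric())
  cumsum(lens[-length(lens)]) / 3
}

# Genome gap (bp) between consecutive hits of a locus, in query order, plus
# the query-coordinate of each junction.
locus_junctions <- function(locus) {
  h <- locus$hits
  h <- h[order(h$qstart), , drop = FALSE]
  n <- nrow(h)
  if (n < 2) {
    return(data.frame(q_aa = numeric(), gap_bp = numeric()))
  }
  i <- seq_len(n - 1)
  gap <- if (locus$strand == "+") h$gstart[i + 1] - h$gend[i]
  else h$gstart[i] - h$gend[i + 1]
  # the junction lies between the end of one hit and the start of the next;
  # overlapping hits (shared junction codons) bracket it from either side
  data.frame(q_lo = pmin(h$qend[i], h$qstart[i + 1]),
             q_hi = pmax(h$qend[i], h$qstart[i + 1]),
             gap_bp = gap)
}

#' Classify the duplication mechanism of a candidate locus
#'
#' Maps intron-scale gaps between the locus's chained hits (>=
#' `min_intron_bp`) onto the parent's intron positions in query coordinates
#' (+/- `junction_tol_aa`).
#'
#' @param locus a `candidate_locus` from [chain_hits()].
#' @param parent the parental [gene_model()] or [planted_gene()].
#' @param min_intron_bp smallest genome gap treated as an intron.
#' @param junction_tol_aa tolerance when matching junction positions.
#' @return List with `mechanism` (`"retro"`, `"partial_retro"`, `"dna"`,
#'   `"fragment"` for loci covering < 50% of the query, or `"undetermined"`
#'   for intronless parents), `retained_introns`, `parental_introns`.
#' @export
classify_mechanism <- function(locus, parent, min_intron_bp = 40L,
                               junction_tol_aa = 2) {
  pj <- parent_junctions_aa(parent)
  if (locus$coverage < 0.5) {
    return(list(mechanism = "fragment", retained_introns = NA_integer_,
                parental_introns = length(pj)))
  }
  if (!length(pj)) {
    return(list(mechanism = "undetermined", retained_introns = 0L,
                parental_introns = 0L))
  }
  jn <- locus_junctions(locus)
  jn <- jn[jn$gap_bp >= min_intron_bp, , drop = FALSE]
  retained <- 0L
  used <- rep(FALSE, length(pj))
  for (r in seq_len(nrow(jn))) {
    # distance from each parental junction to the observed junction interval
    d <- pmax(0, jn$q_lo[r] - pj, pj - jn$q_hi[r])
    k <- which(!used & d <= junction_tol_aa)
    if (length(k)) {
      used[k[which.min(d[k])]] <- TRUE
      retained <- retained + 1L
    }
  }
  mech <- if (retained == 0L) "retro"
  else if (retained == length(pj)) "dna"
  else "partial_retro"
  list(mechanism = mech, retained_introns = retained,
       parental_introns = length(pj))
}

#' Reconstruct the protein encoded by a candidate locus
#'
#' Assembles the copy protein hit by hit: each hit contributes its in-frame
#' subject translation (exons sit in different reading frames, so per-hit
#' frames are the only safe ones), sub-intron gaps between hits (<
#' `min_intron_bp`) are translated in the preceding hit's frame (a premature
#' stop codon lives in such a gap), intron-scale gaps contribute nothing,
#' and the terminal hits are extended genomically to the query's ends plus
#' the stop codon so truncations are measured on the genome rather than on
#' local-alignment endpoints.
#'
#' @param locus a `candidate_locus`.
#' @param genome the [annotated_genome()] searched.
#' @param query_len parent protein length (aa).
#' @param min_intron_bp smallest genome gap spliced out as an intron.
#' @return List with `protein` (may contain `*`), `cds` (its coding
#'   sequence), and `qpos` (0-based query coordinate of every residue).
#' @export
reconstruct_copy <- function(locus, genome, query_len,
                             min_intron_bp = 40L) {
  contig <- genome$contigs[[locus$contig_id]]
  clen <- nchar(contig)
  plus <- locus$strand == "+"
  h <- locus$hits[order(locus$hits$qstart), , drop = FALSE]
  n <- nrow(h)

  # genomic piece of k codons continuing 3'-ward (transcript sense) from a
  # forward-coordinate anchor, or preceding it 5'-ward
  downstream <- function(anchor, k) {
    if (k <= 0) return("")
    if (plus) substr(contig, anchor + 1L, min(clen, anchor + 3L * k))
    else revcomp(substr(contig, max(0L, anchor - 3L * k) + 1L, anchor))
  }
  upstream <- function(anchor, k) {
    if (k <= 0) return("")
    if (plus) substr(contig, max(0L, anchor - 3L * k) + 1L, anchor)
    else revcomp(substr(contig, anchor + 1L, min(clen, anchor + 3L * k)))
  }
  add <- function(state, cds_piece, q_from) {
    cds_piece <- substr(cds_piece, 1L, nchar(cds_piece) - nchar(cds_piece) %% 3L)
    k <- nchar(cds_piece) %/% 3L
    if (k > 0) {
      state$cds <- c(state$cds, cds_piece)
      state$aa <- c(state$aa, translate_codon(as_codons(cds_piece)))
      state$qpos <- c(state$qpos, q_from + seq_len(k) - 1L)
    }
    state
  }

  state <- list(cds = character(), aa = character(), qpos = integer())
  # 5' extension back to the query start
  state <- add(state,
               upstream(if (plus) h$gstart[1] else h$gend[1], h$qstart[1]),
               0L)
  for (i in seq_len(n)) {
    qa <- strsplit(h$q_aligned[i], "")[[1]]
    sa <- strsplit(h$s_aligned[i], "")[[1]]
    qcoord <- h$qstart[i] + cumsum(qa != "-") - (qa != "-")
    # aligned columns only: subject insertions are alignment noise relative
    # to the query (typically intron fragments bridged by the aligner)
    keep <- sa != "-" & qa != "-"
    # trim columns already covered by the previous hit
    if (i > 1) keep <- keep & qcoord >= h$qend[i - 1]
    # subject residues: their codons, read off the hit's own frame
    span_seq <- if (plus) substr(contig, h$gstart[i] + 1L, h$gend[i])
    else revcomp(substr(contig, h$gstart[i] + 1L, h$gend[i]))
    cod <- as_codons(span_seq)
    scons <- cumsum(sa != "-")
    sel <- scons[keep]
    state$cds <- c(state$cds, cod[sel])
    state$aa <- c(state$aa, sa[keep])
    state$qpos <- c(state$qpos, qcoord[keep])
    # gap to the next hit: coding only when sub-intron sized AND consistent
    # with the query-side gap (genome gap of ~3 bp per missing residue); a
    # larger genome gap is intron remnant around ragged hit ends, spliced out
    if (i < n) {
      gap <- if (plus) h$gstart[i + 1] - h$gend[i]
      else h$gstart[i] - h$gend[i + 1]
      qgap <- h$qstart[i + 1] - h$qend[i]
      if (gap > 0 && gap < min_intron_bp && qgap >= 0 &&
          abs(gap - 3L * qgap) <= 6L) {
        anchor <- if (plus) h$gend[i] else h$gstart[i]
        state <- add(state, downstream(anchor, gap %/% 3L), h$qend[i])
      }
    }
  }
  # 3' extension to the query end plus the stop codon
  ext3 <- query_len + 1L - h$qend[n]
  state <- add(state,
               downstream(if (plus) h$gend[n] else h$gstart[n], ext3),
               h$qend[n])
  list(protein = paste(state$aa, collapse = ""),
       cds = paste(state$cds, collapse = ""),
       qpos = state$qpos)
}

#' Call the functional status of a candidate locus
#'
#' Pseudogene iff a premature stop removes at least `truncation_aa` residues
#' relative to the parent's stop, or the reconstructed protein is at least
#' `truncation_aa` residues shorter than the parent ("at least" makes the
#' boundary inclusive). An unreadable locus (reconstructed protein with < 20%
#' identity to the parent) is a pseudogene with reason `"unreadable"`.
#'
#' @param locus a `candidate_locus`.
#' @param parent_protein the parent's amino-acid sequence.
#' @param genome the searched [annotated_genome()].
#' @param truncation_aa pseudogene threshold (default 10).
#' @param min_intron_bp passed to [reconstruct_copy()].
#' @return List with `status`, `reason`, `protein` (reconstructed, up to the
#'   full extension), `effective_len`, `removed_aa`.
#' @export
call_status <- function(locus, parent_protein, genome, truncation_aa = 10L,
                        min_intron_bp = 40L) {
  plen <- nchar(parent_protein)
  rec <- reconstruct_copy(locus, genome, plen, min_intron_bp)
  prot <- rec$protein
  stops <- which(strsplit(prot, "")[[1]] == "*")
  stop_q <- if (length(stops)) rec$qpos[stops[1]] else NA_integer_
  eff <- if (!is.na(stop_q)) min(stop_q, plen)
  else min(max(rec$qpos) + 1L, plen)
  removed <- plen - eff
  if (!is.na(stop_q) && removed >= truncation_aa) {
    return(list(status = "pseudogene", reason = "premature_stop",
                protein = prot, effective_len = eff, removed_aa = removed))
  }
  upto <- if (length(stops)) stops[1] - 1L else nchar(prot)
  ident <- align_global_identity(substr(prot, 1, max(upto, 1L)),
                                 parent_protein)
  if (ident < 0.2) {
    return(list(status = "pseudogene", reason = "unreadable",
                protein = prot, effective_len = eff, removed_aa = removed))
  }
  if (removed >= truncation_aa) {
    return(list(status = "pseudogene", reason = "truncated",
                protein = prot, effective_len = eff, removed_aa = removed))
  }
  list(status = "functional", reason = NA_character_, protein = prot,
       effective_len = eff, removed_aa = max(removed, 0L))
}

age_class <- function(identity) {
  ifelse(identity > 0.90, "young", ifelse(identity > 0.80, "mid", "old"))
}

#' Protein identity of a copy to its parent, with age class
#'
#' Global alignment identity of the reconstructed copy protein against the
#' parent. Age classes follow the strict thresholds: young > 0.90,
#' mid > 0.80, old otherwise.
#'
#' @inheritParams call_status
#' @return List with `identity` and `age_class`.
#' @export
identity_to_parent <- function(locus, parent_protein, genome,
                               min_intron_bp = 40L) {
  rec <- reconstruct_copy(locus, genome, nchar(parent_protein), min_intron_bp)
  prot <- gsub("\\*+$", "", rec$protein)
  if (!nzchar(prot)) return(list(identity = 0, age_class = "old"))
  ident <- align_global_identity(prot, parent_protein)
  list(identity = ident, age_class = age_class(ident))
}

#' Flanking-gene context of a locus
#'
#' @param locus a `candidate_locus` (or any list with `contig_id`, `gstart`,
#'   `gend`).
#' @param genome the [annotated_genome()].
#' @param w flank width (genes per side).
#' @return List with `copy_id`, `upstream` and `downstream` gene-id vectors
#'   (genomic order, at most `w` each, excluding genes overlapping the locus).
#' @export
synteny_context <- function(locus, genome, w = 3L) {
  on_ctg <- Filter(function(g) g$contig_id == locus$contig_id, genome$genes)
  sp <- t(vapply(on_ctg, gene_span, c(0, 0)))
  ids <- vapply(on_ctg, `[[`, "", "gene_id")
  if (!length(ids)) {
    return(list(copy_id = locus$copy_id, upstream = character(),
                downstream = character()))
  }
  ord <- order(sp[, 1])
  ids <- ids[ord]; sp <- sp[ord, , drop = FALSE]
  up <- ids[sp[, 2] <= locus$gstart]
  down <- ids[sp[, 1] >= locus$gend]
  list(copy_id = locus$copy_id,
       upstream = utils::tail(up, w),
       downstream = utils::head(down, w))
}

# length of the longest common ordered subsequence of two id vectors
lcs_len <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  d <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1L, j + 1L] <- if (a[i] == b[j]) d[i, j] + 1L
      else max(d[i, j + 1L], d[i + 1L, j])
    }
  }
  d[na + 1L, nb + 1L]
}

# max ordered flank sharing between two synteny contexts (either side,
# either orientation)
shared_flank <- function(ca, cb) {
  max(lcs_len(ca$upstream, cb$upstream),
      lcs_len(ca$downstream, cb$downstream),
      lcs_len(ca$upstream, rev(cb$downstream)),
      lcs_len(ca$downstream, rev(cb$upstream)))
}

#' Collapse copies across species into independent duplication events
#'
#' Copies of the same parent gene in different species merge into one event
#' when they share at least `min_shared_flank` flanking gene families on one
#' side in conserved order; merging is transitive, but never puts two copies
#' from the same species into one event. Remaining copies are singleton
#' events.
#'
#' @param copies data.frame with at least `copy_id`, `species_id`,
#'   `parent_gene_id`, `mechanism`, `status`, `identity`.
#' @param contexts list of [synteny_context()] results keyed by copy id.
#' @param min_shared_flank sharing threshold (default 2).
#' @return data.frame of events: `event_id`, `parent_gene_id`, `mechanism`
#'   (majority), `n_copies`, `n_species`, `n_functional`, `n_pseudogene`,
#'   `mean_identity`, `copy_ids` (comma-joined).
#' @export
call_events <- function(copies, contexts, min_shared_flank = 2L) {
  if (!nrow(copies)) {
    return(data.frame(event_id = character(), parent_gene_id = character(),
                      mechanism = character(), n_copies = integer(),
                      n_species = integer(), n_functional = integer(),
                      n_pseudogene = integer(), mean_identity = double(),
                      copy_ids = character(), stringsAsFactors = FALSE))
  }
  copies <- copies[order(copies$copy_id), , drop = FALSE]
  n <- nrow(copies)
  parent_uf <- seq_len(n)
  find <- function(i) {
    while (parent_uf[i] != i) i <- parent_uf[i]
    i
  }
  members <- function(r) which(vapply(seq_len(n), find, 0L) == r)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (copies$parent_gene_id[i] != copies$parent_gene_id[j]) next
      if (copies$species_id[i] == copies$species_id[j]) next
      ca <- contexts[[copies$copy_id[i]]]
      cb <- contexts[[copies$copy_id[j]]]
      if (is.null(ca) || is.null(cb)) next
      if (shared_flank(ca, cb) >= min_shared_flank) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  for (p in pairs) {
    ri <- find(p[1]); rj <- find(p[2])
    if (ri == rj) next
    # refuse merges that would duplicate a species within one event
    si <- copies$species_id[members(ri)]
    sj <- copies$species_id[members(rj)]
    if (length(intersect(si, sj))) next
    parent_uf[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  groups <- groups[order(vapply(groups, function(g) copies$copy_id[min(g)], ""))]
  rows <- lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    mech_tab <- sort(table(copies$mechanism[g]), decreasing = TRUE)
    data.frame(event_id = sprintf("event%03d", k),
               parent_gene_id = copies$parent_gene_id[g[1]],
               mechanism = names(mech_tab)[1],
               n_copies = length(g),
               n_species = length(unique(copies$species_id[g])),
               n_functional = sum(copies$status[g] == "functional"),
               n_pseudogene = sum(copies$status[g] == "pseudogene"),
               mean_identity = mean(copies$identity[g]),
               copy_ids = paste(sort(copies$copy_id[g]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' RNA- vs DNA-mediated fractions per gene
#'
#' RNA-mediated events are retrocopies plus partially processed retrocopies.
#'
#' @param events event table from [call_events()].
#' @return data.frame per parent gene (plus a `total` row): `n_events`,
#'   `n_rna`, `n_dna`, `rna_fraction`, `dna_fraction`.
#' @export
tally_mechanisms <- function(events) {
  stopifnot(nrow(events) >= 1)
  tally_one <- function(ev, label) {
    rna <- sum(ev$mechanism %in% c("retro", "partial_retro"))
    dna <- sum(ev$mechanism == "dna")
    data.frame(parent_gene_id = label, n_events = nrow(ev),
               n_rna = rna, n_dna = dna,
               rna_fraction = rna / nrow(ev), dna_fraction = dna / nrow(ev),
               stringsAsFactors = FALSE)
  }
  per <- lapply(split(events, events$parent_gene_id), function(ev) {
    tally_one(ev, ev$parent_gene_id[1])
  })
  out <- do.call(rbind, c(per, list(tally_one(events, "total"))))
  rownames(out) <- NULL
  out
}

#' Classify all non-self loci of one query against one genome
#'
#' Convenience wrapper combining [classify_mechanism()], [call_status()],
#' [identity_to_parent()] and [synteny_context()] over the loci of a search.
#'
#' @param loci list from [chain_hits()].
#' @param parent parental [gene_model()] (from this genome) or
#'   [planted_gene()].
#' @param parent_protein query protein.
#' @param genome the searched [annotated_genome()].
#' @param w flank width for the synteny context.
#' @param min_intron_bp intron-size threshold.
#' @return List with `copies` (data.frame, one row per non-self, non-fragment
#'   locus), `fragments` (fragment rows), `contexts` (synteny contexts keyed
#'   by copy id).
#' @export
classify_copies <- function(loci, parent, parent_protein, genome, w = 3L,
                            min_intron_bp = 40L) {
  rows <- list()
  frags <- list()
  contexts <- list()
  parent_span <- if (inherits(parent, "gene_model")) gene_span(parent) else NULL
  for (locus in loci) {
    if (isTRUE(locus$self)) next
    mech <- classify_mechanism(locus, parent, min_intron_bp)
    if (mech$mechanism == "fragment") {
      frags[[length(frags) + 1L]] <- data.frame(
        copy_id = locus$copy_id, species_id = genome$species_id,
        contig = locus$contig_id, start = locus$gstart, end = locus$gend,
        coverage = locus$coverage, reason = "low_query_coverage",
        stringsAsFactors = FALSE)
      next
    }
    st <- call_status(locus, parent_protein, genome,
                      min_intron_bp = min_intron_bp)
    idn <- identity_to_parent(locus, parent_protein, genome, min_intron_bp)
    tandem <- !is.null(parent_span) &&
      inherits(parent, "gene_model") &&
      locus$contig_id == parent$contig_id &&
      min(abs(c(locus$gstart - parent_span[2], parent_span[1] - locus$gend))) <=
        10000
    rows[[length(rows) + 1L]] <- data.frame(
      copy_id = locus$copy_id, species_id = genome$species_id,
      parent_gene_id = if (inherits(parent, "planted_gene")) parent$gene_id
      else parent$gene_id,
      contig = locus$contig_id, start = locus$gstart, end = locus$gend,
      strand = locus$strand,
      mechanism = mech$mechanism,
      retained_introns = mech$retained_introns,
      parental_introns = mech$parental_introns,
      status = st$status, status_reason = st$reason,
      identity = idn$identity, age_class = idn$age_class,
      tandem = tandem, coverage = locus$coverage,
      stringsAsFactors = FALSE)
    contexts[[locus$copy_id]] <- synteny_context(locus, genome, w)
  }
  empty_cp <- data.frame(copy_id = character(), species_id = character(),
                         parent_gene_id = character(), contig = character(),
                         start = integer(), end = integer(),
                         strand = character(), mechanism = character(),
                         retained_introns = integer(),
                         parental_introns = integer(), status = character(),
                         status_reason = character(), identity = double(),
                         age_class = character(), tandem = logical(),
                         coverage = double(), stringsAsFactors = FALSE)
  list(copies = if (length(rows)) do.call(rbind, rows) else empty_cp,
       fragments = if (length(frags)) do.call(rbind, frags) else NULL,
       contexts = contexts)
}
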