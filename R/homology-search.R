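# Protein-vs-protein and protein-vs-translated-genome local search,
# emulating the BlastP / tBLASTn stages of a duplicate scan: six-frame
# translation, exact k-mer seeding, Smith-Waterman extension, splitting of
# alignments at intron-scale gaps, and colinear chaining of hits into
# candidate loci.

subst_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  if (!is.null(.code_cache[[name]])) return(.code_cache[[name]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  .code_cache[[name]] <- get(name, envir = e)
  .code_cache[[name]]
}

blosum62 <- function() subst_matrix("BLOSUM62")

aln_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- !(ca == "-" & cb == "-")
  sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`, the BLAST convention).
#'
#' @param query,subject amino-acid strings.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return List with `score`, `identity` (matches / alignment columns),
#'   `query_aligned`, `subject_aligned`, and 0-based half-open `query_span`
#'   and `subject_span`.
#' @export
align_local <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject)) {
    stopf("align_local: empty sequence")
  }
  mat <- subst_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  qa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  qr <- aln@pattern@range
  sr <- aln@subject@range
  list(score = Biostrings::score(aln),
       identity = aln_identity(qa, sa),
       query_aligned = qa, subject_aligned = sa,
       query_span = c(BiocGenerics::start(qr) - 1L, BiocGenerics::end(qr)),
       subject_span = c(BiocGenerics::start(sr) - 1L, BiocGenerics::end(sr)))
}

#' Optimal global alignment identity of two proteins
#' @inheritParams align_local
#' @return Fraction of identical columns (double-gap columns excluded).
#' @export
align_global_identity <- function(query, subject, matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1) {
  mat <- subst_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aln_identity(as.character(Biostrings::alignedPattern(aln)),
               as.character(Biostrings::alignedSubject(aln)))
}

# Score one alignment column pair under BLOSUM62 / affine gaps; used when
# re-scoring split segments.
score_segment <- function(qa, sa, mat, gap_open, gap_extend) {
  n <- length(qa)
  sc <- 0
  in_gap <- FALSE
  for (k in seq_len(n)) {
    if (qa[k] == "-" || sa[k] == "-") {
      sc <- sc - gap_extend - (if (in_gap) 0 else gap_open)
      in_gap <- TRUE
    } else {
      sc <- sc + mat[qa[k], sa[k]]
      in_gap <- FALSE
    }
  }
  sc
}

# Split an alignment at long subject-side insertions or strongly negative
# internal stretches (X-dropoff-like). A plain optimal local alignment will
# happily bridge an in-frame intron with one long gap; BLAST, whose behaviour
# the mechanism rule relies on ("exons appear as individual hits"), does not.
# Returns a list of (qcols, scols) index vectors into the alignment columns.
split_alignment_segments <- function(qa, sa, mat, gap_open, gap_extend,
                                     min_split_aa = 12L, drop_score = 20) {
  n <- length(qa)
  colsc <- numeric(n)
  for (k in seq_len(n)) {
    colsc[k] <- if (qa[k] == "-" || sa[k] == "-") -gap_extend - gap_open / 4
    else mat[qa[k], sa[k]]
  }
  # candidate split regions: runs of query-gap (subject insertion) of
  # >= min_split_aa, or internal windows with cumulative score <= -drop_score
  bad <- logical(n)
  r <- rle(qa == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= min_split_aa) {
      bad[starts[i]:ends[i]] <- TRUE
    }
  }
  # negative-stretch scan
  run <- 0; run_start <- 1L
  for (k in seq_len(n)) {
    run <- run + colsc[k]
    if (run > 0) { run <- 0; run_start <- k + 1L }
    if (run <= -drop_score && (k - run_start + 1L) >= min_split_aa) {
      bad[run_start:k] <- TRUE
      run <- 0; run_start <- k + 1L
    }
  }
  if (!any(bad)) return(list(seq_len(n)))
  keep <- rle(!bad)
  ke <- cumsum(keep$lengths)
  ks <- ke - keep$lengths + 1L
  segs <- list()
  for (i in seq_along(keep$lengths)) {
    if (keep$values[i]) segs[[length(segs) + 1L]] <- ks[i]:ke[i]
  }
  segs
}

frame_to_genome <- function(strand, frame_off, contig_len, aa_start, aa_end) {
  # aa coords 0-based half-open within the frame translation
  if (strand == "+") {
    c(frame_off + 3L * aa_start, frame_off + 3L * aa_end)
  } else {
    c(contig_len - (frame_off + 3L * aa_end),
      contig_len - (frame_off + 3L * aa_start))
  }
}

empty_hits <- function() {
  data.frame(query_id = character(), contig_id = character(),
             strand = character(), frame = integer(),
             qstart = integer(), qend = integer(),
             gstart = integer(), gend = integer(),
             identity = double(), score = double(), naln = integer(),
             q_aligned = character(), s_aligned = character(),
             self = logical(), stringsAsFactors = FALSE)
}

#' Translated homology search of a protein against a genome
#'
#' Seeds exact protein k-mer matches in all six reading frames of every
#' contig, extends seed clusters by Smith-Waterman local alignment, splits
#' alignments at intron-scale internal gaps, and retains hits passing the
#' identity and length thresholds. Hits overlapping `parent_locus` (the
#' query's own annotated gene) are flagged `self`.
#'
#' @param query_protein amino-acid string.
#' @param genome an [annotated_genome()].
#' @param min_identity minimum hit identity (default 0.40).
#' @param min_hit_aa minimum aligned query residues per hit.
#' @param k seed word size (amino acids).
#' @param query_id label written into the hit table.
#' @param parent_locus optional list/vector `(contig_id, start, end)` of the
#'   query's own locus, or a [gene_model()].
#' @param frame_cache optional environment reused across searches of the same
#'   genome to avoid recomputing six-frame translations.
#' @return data.frame of hits, one row per local alignment segment, with
#'   0-based half-open `qstart/qend` (aa) and `gstart/gend` (bp, forward
#'   strand coordinates).
#' @export
search_translated <- function(query_protein, genome, min_identity = 0.40,
                              min_hit_aa = 20L, k = 4L,
                              query_id = "query", parent_locus = NULL,
                              frame_cache = NULL) {
  stopifnot(min_identity > 0, min_identity <= 1)
  mat <- blosum62()
  qlen <- nchar(query_protein)
  qk <- substring(query_protein, seq_len(max(qlen - k + 1L, 0L)),
                  seq_len(max(qlen - k + 1L, 0L)) + k - 1L)
  if (!length(qk)) return(empty_hits())
  qpos <- split(seq_along(qk) - 1L, qk)

  if (inherits(parent_locus, "gene_model")) {
    sp <- gene_span(parent_locus)
    parent_locus <- list(contig_id = parent_locus$contig_id,
                         start = sp[1], end = sp[2])
  }

  rows <- list()
  for (contig_id in names(genome$contigs)) {
    contig <- genome$contigs[[contig_id]]
    clen <- nchar(contig)
    ckey <- paste0(genome$species_id, "|", contig_id, "|", clen)
    cached <- if (!is.null(frame_cache)) frame_cache[[ckey]] else NULL
    if (is.null(cached)) {
      frames <- six_frame_translate(contig)
      fkmers <- lapply(frames, function(ftrans) {
        flen <- nchar(ftrans)
        if (flen < k) return(character())
        substring(ftrans, seq_len(flen - k + 1L),
                  seq_len(flen - k + 1L) + k - 1L)
      })
      cached <- list(frames = frames, fkmers = fkmers, k = k)
      if (!is.null(frame_cache)) frame_cache[[ckey]] <- cached
    }
    if (cached$k != k) stopf("frame_cache built with k = %d", cached$k)
    frames <- cached$frames
    for (fr in names(frames)) {
      ftrans <- frames[[fr]]
      flen <- nchar(ftrans)
      if (flen < k) next
      strand <- if (startsWith(fr, "+")) "+" else "-"
      frame_off <- abs(as.integer(fr)) - 1L
      fk <- cached$fkmers[[fr]]
      hitskmer <- which(fk %in% names(qpos))
      if (!length(hitskmer)) next
      seeds <- do.call(rbind, lapply(hitskmer, function(fp) {
        cbind(q = qpos[[fk[fp]]], f = fp - 1L)
      }))
      diag <- seeds[, "f"] - seeds[, "q"]
      ord <- order(diag, seeds[, "f"])
      seeds <- seeds[ord, , drop = FALSE]
      diag <- diag[ord]
      # cluster seeds: same or nearby diagonal, nearby frame position
      grp <- cumsum(c(1L, (abs(diff(diag)) > 10) |
                        (diff(seeds[, "f"]) > 60)))
      grps <- split(seq_along(grp), grp)
      # two-hit seeding: isolated single k-mer matches are almost always
      # noise (real homologs produce runs of seeds on one diagonal); very
      # short queries are exempt
      if (qlen >= 8L * k) grps <- Filter(function(idx) length(idx) >= 2L, grps)
      # window = seed-cluster extent plus a bounded margin; unbounded
      # full-query slack would swallow the windows of neighboring copies
      # (e.g. a tandem duplicate next to its parent) and shadow their
      # alignments. Exons missed at window edges are recovered by chaining.
      windows <- lapply(grps, function(idx) {
        fs <- seeds[idx, "f"]
        qs <- seeds[idx, "q"]
        c(max(0L, min(fs) - min(30L, min(qs)) - 10L),
          min(flen, max(fs) + k + min(30L, qlen - max(qs) - k) + 10L))
      })
      # merge overlapping windows
      windows <- windows[order(vapply(windows, `[`, 0L, 1))]
      merged <- list()
      for (w in windows) {
        last <- if (length(merged)) merged[[length(merged)]] else NULL
        if (!is.null(last) && w[1] <= last[2]) {
          merged[[length(merged)]] <- c(last[1], max(last[2], w[2]))
        } else {
          merged[[length(merged) + 1L]] <- w
        }
      }
      for (w in merged) {
        # multi-HSP behaviour: after each accepted local alignment, recurse
        # into the window remainder on both sides (two exons of one copy can
        # share a frame and a seed window; a single optimal local alignment
        # would silently drop one of them)
        stack <- list(w)
        alns <- list()
        while (length(stack)) {
          piece <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          if (piece[2] - piece[1] < min_hit_aa) next
          win <- substr(ftrans, piece[1] + 1L, piece[2])
          aln <- tryCatch(align_local(query_protein, win, matrix = mat),
                          error = function(e) NULL)
          if (is.null(aln) || aln$score < 25) next
          aln$offset <- piece[1]
          alns[[length(alns) + 1L]] <- aln
          if (length(alns) > 24L) break
          s0 <- piece[1] + aln$subject_span[1]
          s1 <- piece[1] + aln$subject_span[2]
          stack[[length(stack) + 1L]] <- c(piece[1], s0)
          stack[[length(stack) + 1L]] <- c(s1, piece[2])
        }
        for (aln in alns) {
        qa <- strsplit(aln$query_aligned, "")[[1]]
        sa <- strsplit(aln$subject_aligned, "")[[1]]
        segs <- split_alignment_segments(qa, sa, mat, 11, 1)
        # column -> query/frame coordinates
        qcoord <- aln$query_span[1] + cumsum(qa != "-") - (qa != "-")
        scoord <- aln$offset + aln$subject_span[1] +
          cumsum(sa != "-") - (sa != "-")
        for (seg in segs) {
          segq <- qa[seg]
          segs_ <- sa[seg]
          naln_q <- sum(segq != "-")
          if (naln_q < min_hit_aa) next
          ident <- sum(segq == segs_ & segq != "-") / length(seg)
          if (ident < min_identity) next
          q0 <- qcoord[seg[1]]
          q1 <- qcoord[seg[length(seg)]] + as.integer(segq[length(seg)] != "-")
          s0 <- scoord[seg[1]]
          s1 <- scoord[seg[length(seg)]] + as.integer(segs_[length(seg)] != "-")
          gsp <- frame_to_genome(strand, frame_off, clen, s0, s1)
          sc <- score_segment(segq, segs_, mat, 11, 1)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = query_id, contig_id = contig_id, strand = strand,
            frame = as.integer(fr), qstart = q0, qend = q1,
            gstart = gsp[1], gend = gsp[2],
            identity = ident, score = sc, naln = as.integer(naln_q),
            q_aligned = paste(segq, collapse = ""),
            s_aligned = paste(segs_, collapse = ""),
            self = FALSE, stringsAsFactors = FALSE)
        }
        }
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  # collapse duplicate/overlapping hits from merged seed windows: same
  # contig/strand and overlapping genome span -> keep best score
  hits <- hits[order(hits$contig_id, hits$strand, -hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) {
      for (j in (i + 1L):nrow(hits)) {
        if (!keep[j]) next
        if (hits$contig_id[j] == hits$contig_id[i] &&
            hits$strand[j] == hits$strand[i]) {
          ov <- min(hits$gend[i], hits$gend[j]) -
            max(hits$gstart[i], hits$gstart[j])
          minw <- min(hits$gend[i] - hits$gstart[i],
                      hits$gend[j] - hits$gstart[j])
          if (ov > 0.5 * minw) keep[j] <- FALSE
        }
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- trim_overlapping_hits(hits, mat, min_hit_aa, min_identity)
  if (!is.null(parent_locus)) {
    hits$self <- hits$contig_id == parent_locus$contig_id &
      hits$gstart < parent_locus$end & hits$gend > parent_locus$start
  }
  hits <- hits[order(hits$contig_id, hits$gstart), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Rebuild a hit row from a subset of its alignment columns (used when a
# low-identity extension is trimmed back).
rebuild_hit <- function(row, keep_cols, mat, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(row$q_aligned, "")[[1]]
  sa <- strsplit(row$s_aligned, "")[[1]]
  qcons <- cumsum(qa != "-")
  scons <- cumsum(sa != "-")
  k0 <- keep_cols[1]
  k1 <- keep_cols[length(keep_cols)]
  q_lead <- if (k0 > 1) qcons[k0 - 1] else 0L
  s_lead <- if (k0 > 1) scons[k0 - 1] else 0L
  q_trail <- qcons[length(qa)] - qcons[k1]
  s_trail <- scons[length(sa)] - scons[k1]
  row$qstart <- row$qstart + q_lead
  row$qend <- row$qend - q_trail
  if (row$strand == "+") {
    row$gstart <- row$gstart + 3L * s_lead
    row$gend <- row$gend - 3L * s_trail
  } else {
    # query-order leading columns sit at the high-coordinate end
    row$gend <- row$gend - 3L * s_lead
    row$gstart <- row$gstart + 3L * s_trail
  }
  segq <- qa[keep_cols]
  segs <- sa[keep_cols]
  row$naln <- as.integer(sum(segq != "-"))
  row$identity <- sum(segq == segs & segq != "-") / length(keep_cols)
  row$score <- score_segment(segq, segs, mat, gap_open, gap_extend)
  row$q_aligned <- paste(segq, collapse = "")
  row$s_aligned <- paste(segs, collapse = "")
  row
}

# A local alignment can extend through an intron as weakly positive-scoring
# noise and then re-enter the next exon, producing a low-identity hit that
# overlaps a better hit in query coordinates and blocks colinear chaining.
# Where two hits on one contig/strand are close enough genomically to be
# consecutive exons of one copy and overlap in the query by more than the
# chaining tolerance, the lower-identity hit is trimmed back to the boundary
# of the better one.
trim_overlapping_hits <- function(hits, mat, min_hit_aa, min_identity,
                                  max_intron_bp = 20000L, tol = 10L) {
  n <- nrow(hits)
  if (n < 2) return(hits)
  drop <- rep(FALSE, n)
  ord <- order(-hits$identity)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    if (drop[i]) next
    for (b in (a + 1):n) {
      j <- ord[b]
      if (drop[j]) next
      if (hits$contig_id[i] != hits$contig_id[j] ||
          hits$strand[i] != hits$strand[j]) next
      gdist <- max(hits$gstart[i], hits$gstart[j]) -
        min(hits$gend[i], hits$gend[j])
      if (gdist > max_intron_bp) next
      qa <- strsplit(hits$q_aligned[j], "")[[1]]
      qcoord <- hits$qstart[j] + cumsum(qa != "-") - (qa != "-")
      keep <- rep(TRUE, length(qa))
      span_j <- hits$qend[j] - hits$qstart[j]
      # only partial overlaps are junction noise; two hits covering mostly
      # the same query region are separate gene copies, not one copy's exons
      ov_left <- hits$qend[i] - hits$qstart[j]
      if (ov_left > tol && hits$qend[j] > hits$qend[i] &&
          ov_left <= 0.5 * span_j) {
        keep <- keep & qcoord >= hits$qend[i]
      }
      ov_right <- hits$qend[j] - hits$qstart[i]
      if (ov_right > tol && hits$qstart[j] < hits$qstart[i] &&
          ov_right <= 0.5 * span_j) {
        keep <- keep & qcoord < hits$qstart[i]
      }
      if (all(keep)) next
      kc <- which(keep)
      # only contiguous trims are meaningful; a hit split in two by a better
      # hit is dominated noise
      if (!length(kc) || any(diff(kc) != 1L)) {
        drop[j] <- TRUE
        next
      }
      hits[j, ] <- rebuild_hit(hits[j, , drop = FALSE], kc, mat)
      if (hits$naln[j] < min_hit_aa || hits$identity[j] < min_identity) {
        drop[j] <- TRUE
      }
    }
  }
  hits <- hits[!drop, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Chain colinear hits into candidate loci
#'
#' Optimal score-weighted colinear chaining per contig and strand: consecutive
#' hits in a chain must advance in both query and genome (transcription
#' direction) with genomic gaps at most `max_intron_bp`. Chains are extracted
#' best-first; every hit belongs to exactly one locus.
#'
#' @param hits hit table from [search_translated()].
#' @param max_intron_bp maximum inferred intron size (default 20000).
#' @param query_len query length in aa (for coverage); defaults to max qend.
#' @param id_prefix prefix for generated copy ids (defaults to the query id);
#'   pass e.g. `"sp1_ran"` to keep ids unique across genomes.
#' @return List of `candidate_locus` objects: `copy_id`, `hits` (rows of the
#'   hit table in query order), `coverage`, `single_hit`, `contig_id`,
#'   `strand`, `gstart`, `gend`, `self`.
#' @export
chain_hits <- function(hits, max_intron_bp = 20000L, query_len = NULL,
                       id_prefix = NULL) {
  if (!nrow(hits)) return(list())
  if (is.null(query_len)) query_len <- max(hits$qend)
  if (is.null(id_prefix)) id_prefix <- hits$query_id[1]
  loci <- list()
  for (key in unique(paste(hits$contig_id, hits$strand, hits$self))) {
    sub <- hits[paste(hits$contig_id, hits$strand, hits$self) == key, ,
                drop = FALSE]
    sub <- sub[order(sub$qstart, sub$gstart), , drop = FALSE]
    repeat {
      n <- nrow(sub)
      if (!n) break
      # DP over chains ordered by qstart
      best <- sub$score
      prev <- rep(0L, n)
      for (j in seq_len(n)) {
        for (i in seq_len(n)) {
          if (i == j) next
          # small query overlap allowed: exon-junction codons plus alignment
          # slop at diverged copies can appear in both flanking hits
          if (sub$qstart[j] < sub$qstart[i] ||
              sub$qend[i] - 10L > sub$qstart[j] ||
              sub$qend[j] <= sub$qend[i]) next
          gap <- if (sub$strand[j] == "+") sub$gstart[j] - sub$gend[i]
          else sub$gstart[i] - sub$gend[j]
          if (gap < -15 || gap > max_intron_bp) next
          cand <- best[i] + sub$score[j]
          if (cand > best[j]) {
            best[j] <- cand
            prev[j] <- i
          }
        }
      }
      end <- which.max(best)
      chain <- integer()
      at <- end
      while (at != 0L) {
        chain <- c(at, chain)
        at <- prev[at]
      }
      ch <- sub[chain, , drop = FALSE]
      cov <- min(1, sum(ch$naln) / query_len)
      loci[[length(loci) + 1L]] <- structure(list(
        copy_id = NA_character_,
        query_id = ch$query_id[1],
        hits = ch,
        coverage = cov,
        single_hit = nrow(ch) == 1L && cov >= 0.9,
        contig_id = ch$contig_id[1],
        strand = ch$strand[1],
        gstart = min(ch$gstart), gend = max(ch$gend),
        self = ch$self[1]
      ), class = "candidate_locus")
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  # deterministic ids in genome order
  ord <- order(vapply(loci, `[[`, "", "contig_id"),
               vapply(loci, function(l) as.numeric(l$gstart), 0))
  loci <- loci[ord]
  for (i in seq_along(loci)) {
    loci[[i]]$copy_id <- sprintf("%s_locus%02d", id_prefix, i)
  }
  loci
}

#' @export
print.candidate_locus <- function(x, ...) {
  cat(sprintf("candidate_locus %s: %s:%d-%d (%s), %d hit(s), coverage %.2f%s\n",
              x$copy_id %||% "?", x$contig_id, x$gstart, x$gend, x$strand,
              nrow(x$hits), x$coverage, if (isTRUE(x$self)) " [self]" else ""))
  invisible(x)
}
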