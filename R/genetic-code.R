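# Standard nuclear genetic code helpers shared by the simulator, the
# translated search and the codon models. All tables derive from
# Biostrings::GENETIC_CODE; ordering is fixed (alphabetical codons) so that
# codon indices are stable across sessions.

.code_cache <- new.env(parent = emptyenv())

#' The 64 codons in fixed alphabetical order with their amino acids
#' @noRd
codon_table <- function() {
  if (is.null(.code_cache$tab)) {
    gc <- Biostrings::GENETIC_CODE
    ord <- order(names(gc))
    .code_cache$tab <- setNames(unname(gc[ord]), names(gc)[ord])
  }
  .code_cache$tab
}

#' The 61 sense codons (alphabetical); index order used throughout
#' @noRd
sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

#' Amino acid of each sense codon, aligned with sense_codons()
#' @noRd
sense_aa <- function() {
  tab <- codon_table()
  unname(tab[tab != "*"])
}

translate_codon <- function(codon) {
  tab <- codon_table()
  aa <- tab[codon]
  ifelse(is.na(aa), "X", aa)
}

#' All ordered sense-codon pairs differing at exactly one position.
#'
#' Returns an integer matrix with 0-based columns i, j plus indicator columns
#' ts (transition) and syn (synonymous) — the structural input of the
#' Goldman-Yang rate matrix.
#' @noRd
codon_pairs <- function() {
  if (is.null(.code_cache$pairs)) {
    cod <- sense_codons()
    aa <- sense_aa()
    n <- length(cod)
    mat <- do.call(rbind, strsplit(cod, ""))
    out <- matrix(0L, 0L, 4L)
    rows <- vector("list", 2048L)
    k <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        diff <- which(mat[i, ] != mat[j, ])
        if (length(diff) == 1L) {
          pair <- sort(c(mat[i, diff], mat[j, diff]))
          ts <- identical(pair, c("A", "G")) || identical(pair, c("C", "T"))
          k <- k + 1L
          rows[[k]] <- c(i - 1L, j - 1L, as.integer(ts), as.integer(aa[i] == aa[j]))
        }
      }
    }
    out <- do.call(rbind, rows[seq_len(k)])
    colnames(out) <- c("i", "j", "ts", "syn")
    .code_cache$pairs <- out
  }
  .code_cache$pairs
}

#' Split a coding sequence into codons
#' @noRd
as_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding nucleotide string (codons with N or gaps give X)
#' @noRd
translate_cds <- function(cds) {
  paste(translate_codon(as_codons(toupper(cds))), collapse = "")
}

#' Codons encoding each amino acid (list keyed by single-letter code)
#' @noRd
codons_for_aa <- function() {
  if (is.null(.code_cache$by_aa)) {
    tab <- codon_table()
    .code_cache$by_aa <- split(names(tab), unname(tab))
  }
  .code_cache$by_aa
}
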