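# Results-level arithmetic and hypothesis tests: pseudogene rates per gene
# per genome, two-proportion Z-tests comparing duplicate proportions between
# taxon groups (pooled variance, no continuity correction), and a
# one-proportion Z-test against a genome-average pseudogene rate.

#' Two-proportion Z-test (pooled variance)
#'
#' `z = (k1/n1 - k2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled estimate
#' `p = (k1+k2)/(n1+n2)`; no continuity correction. Two-sided normal p-value.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return A `proportion_test`: `k1`, `n1`, `k2`, `n2`, `p1`, `p2`, `z`,
#'   `p_two_sided`, `pooled = TRUE`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    stopf("two_proportion_z: degenerate pooled proportion %.3f", pool)
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
                 z = z, p_two_sided = 2 * pnorm(-abs(z)), pooled = TRUE),
            class = "proportion_test")
}

#' One-proportion Z-test against a fixed baseline
#'
#' `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`; the reported p-value is
#' one-sided for the "higher than baseline" alternative.
#'
#' @param k,n observed count and trials.
#' @param p0 baseline proportion in (0, 1).
#' @return A `proportion_test` with `z` and `p_greater`.
#' @export
one_proportion_z <- function(k, n, p0) {
  stopifnot(n > 0, k >= 0)
  if (p0 <= 0 || p0 >= 1) stopf("one_proportion_z: p0 must be in (0, 1)")
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  structure(list(k = k, n = n, p0 = p0, z = z, p_greater = pnorm(z, lower.tail = FALSE)),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  if (!is.null(x$p_two_sided)) {
    cat(sprintf("two-proportion Z: %d/%d vs %d/%d, Z = %.4f, two-sided p = %.4g\n",
                x$k1, x$n1, x$k2, x$n2, x$z, x$p_two_sided))
  } else {
    cat(sprintf("one-proportion Z: %d/%d vs p0 = %.4g, Z = %.4f, one-sided p = %.4g\n",
                x$k, x$n, x$p0, x$z, x$p_greater))
  }
  invisible(x)
}

#' Pseudogene rate per gene and per genome
#'
#' @param copies copy table (from [classify_copies()] or a pipeline run) with
#'   `parent_gene_id` and `status`; alternatively pass the pseudogene count
#'   directly as `copies`.
#' @param gene_id parent gene to summarize (ignored when `copies` is a count).
#' @param n_genomes genomes searched.
#' @return A `rate_summary`: `gene_id`, `pseudogene_count`, `genome_count`,
#'   `rate` (count / genomes), `rate_display` (2 decimals).
#' @export
pseudogene_rate <- function(copies, gene_id = NULL, n_genomes) {
  stopifnot(n_genomes > 0)
  count <- if (is.numeric(copies) && length(copies) == 1) {
    as.integer(copies)
  } else {
    sum(copies$status == "pseudogene" &
          (is.null(gene_id) | copies$parent_gene_id == gene_id))
  }
  rate <- count / n_genomes
  structure(list(gene_id = gene_id %||% NA_character_,
                 pseudogene_count = count, genome_count = n_genomes,
                 rate = rate, rate_display = round(rate, 2)),
            class = "rate_summary")
}

#' Per-gene turnover summary
#'
#' Aggregates the copy and event tables into one row per parent gene:
#' duplication events, DNA-mediated events, RNA fraction, pseudogene copies,
#' and duplicates per species.
#'
#' @param copies copy table.
#' @param events event table from [call_events()].
#' @return data.frame sorted by `parent_gene_id`; the `n_events` column sums
#'   to `nrow(events)`.
#' @export
summarize_turnover <- function(copies, events) {
  genes <- sort(unique(c(copies$parent_gene_id, events$parent_gene_id)))
  if (!length(genes)) {
    return(data.frame(parent_gene_id = character(), n_copies = integer(),
                      n_events = integer(), n_dna_events = integer(),
                      n_rna_events = integer(), rna_fraction = double(),
                      n_pseudogenes = integer(), n_species = integer(),
                      copies_per_species = double(), stringsAsFactors = FALSE))
  }
  rows <- lapply(genes, function(g) {
    cp <- copies[copies$parent_gene_id == g, , drop = FALSE]
    ev <- events[events$parent_gene_id == g, , drop = FALSE]
    nsp <- length(unique(cp$species_id))
    rna <- sum(ev$mechanism %in% c("retro", "partial_retro"))
    data.frame(parent_gene_id = g, n_copies = nrow(cp), n_events = nrow(ev),
               n_dna_events = sum(ev$mechanism == "dna"),
               n_rna_events = rna,
               rna_fraction = if (nrow(ev)) rna / nrow(ev) else NA_real_,
               n_pseudogenes = sum(cp$status == "pseudogene"),
               n_species = nsp,
               copies_per_species = if (nsp) nrow(cp) / nsp else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(sum(out$n_events) == nrow(events))
  out
}
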