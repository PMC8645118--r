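# Shared fixtures: small planted genes / genomes built in code at test time.

fix_gene <- function(id = "gA", n_exons = 2L, len = 120L, seed = 5L) {
  planted_gene(id, n_exons = n_exons, protein_length = len, seed = seed)
}

# one-species genome with a configurable set of duplicates of a single parent
fix_genome <- function(dups = list(), gene = fix_gene(), species = "spX",
                       contig_length = 30000L, seed = 3L,
                       n_contigs = 3L) {
  spec <- species_spec(species, n_contigs = n_contigs,
                       contig_length = contig_length,
                       intergenic_gene_count = 2L, seed = seed)
  generate_genome(spec, list(gene), dups)
}

fix_dup <- function(gene = "gA", mechanism = "retro", identity = 0.9,
                    species = "spX", event = "evT", retained_introns = NULL,
                    ...) {
  planted_duplicate(gene, mechanism,
                    retained_intron_indices = retained_introns,
                    target_protein_identity = identity,
                    species_set = species, event_id = event, seed = 17L, ...)
}

# search + chain the single planted gene's copies in a fixture genome
fix_loci <- function(gen, gene, min_identity = 0.4) {
  hits <- search_translated(gene$protein, gen$genome,
                            min_identity = min_identity,
                            query_id = gene$gene_id,
                            parent_locus = gen$genome$genes[[gene$gene_id]])
  chain_hits(hits, query_len = nchar(gene$protein),
             id_prefix = paste0(gen$genome$species_id, "_", gene$gene_id))
}

# non-self loci with enough query coverage to be a copy (not a fragment)
nonself <- function(loci) {
  Filter(function(l) !isTRUE(l$self) && l$coverage >= 0.5, loci)
}

# frame +1 translation (standard code) for test assertions
tr1 <- function(s) unname(six_frame_translate(s)["+1"])
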