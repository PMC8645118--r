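# End-to-end orchestration: simulate -> search -> families -> annotate ->
# phylo -> selection -> stats, with per-stage outputs, logging and a
# machine-readable run report. Rerunning with the same config and seed
# reproduces byte-identical data outputs (the report additionally carries
# wall-clock timings).

#' Default analysis thresholds
#'
#' All thresholds surfaced in one place: 0.50 protein-vs-protein identity for
#' the family scan, 0.40 for the translated cross-genome search, 10-aa
#' pseudogene truncation rule, strict > 0.90 "young" identity class, 3-gene
#' synteny flank window with 2 shared genes required, 100 bootstrap
#' replicates, MCL inflation 2.0.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_identity_protein = 0.50,
       min_identity_translated = 0.40,
       min_hit_aa = 20L,
       pseudogene_truncation_aa = 10L,
       young_identity = 0.90,
       flank_window = 3L,
       min_shared_flank = 2L,
       bootstrap_n = 100L,
       mcl_inflation = 2.0,
       max_intron_bp = 20000L,
       min_intron_bp = 40L)
}

#' Demo simulation + analysis configuration
#'
#' Five species, three multi-exon parent genes (2, 4 and 5 exons) and twelve
#' planted duplicate copies: four functional retrocopies, three partially
#' processed retrocopies, three DNA-mediated copies (one tandem), and two
#' pseudogenized retrocopies, spanning protein identities 0.65-0.98 and nine
#' independent duplication events.
#'
#' @param seed master seed.
#' @return Config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  sp <- paste0("sp", 1:5)
  dup <- function(parent, mech, id, species, event, ...) {
    c(list(parent = parent, mechanism = mech, identity = id,
           species = species, event = event), list(...))
  }
  list(
    seed = as.integer(seed),
    species = sp,
    n_contigs = 3L,
    contig_length = 42000L,
    intergenic_genes = 3L,
    parent_identity = 0.96,
    genes = list(
      list(gene_id = "ranA", n_exons = 2L, protein_length = 215L),
      list(gene_id = "ntfB", n_exons = 4L, protein_length = 130L),
      list(gene_id = "kapC", n_exons = 5L, protein_length = 200L)
    ),
    duplicates = list(
      dup("ranA", "retro", 0.95, c("sp1", "sp2"), "ev01"),
      dup("ranA", "retro", 0.65, "sp3", "ev02", strand = "-"),
      dup("ranA", "retro", 0.70, "sp4", "ev03",
          pseudogenize = TRUE, truncation_aa = 12L),
      dup("ranA", "dna", 0.92, "sp5", "ev04", strand = "-"),
      dup("ntfB", "retro", 0.88, "sp1", "ev05"),
      dup("ntfB", "partial_retro", 0.85, c("sp2", "sp3"), "ev06",
          retained_introns = 2L),
      dup("ntfB", "dna", 0.75, "sp4", "ev07"),
      dup("kapC", "partial_retro", 0.98, "sp5", "ev08",
          retained_introns = 3L),
      dup("kapC", "dna", 0.92, "sp2", "ev09", placement = "tandem"),
      dup("kapC", "retro", 0.82, "sp3", "ev10",
          pseudogenize = TRUE, truncation_aa = 15L)
    ),
    thresholds = default_thresholds()
  )
}

config_genes <- function(config) {
  lapply(config$genes, function(g) {
    planted_gene(g$gene_id, n_exons = g$n_exons,
                 protein_length = g$protein_length,
                 seed = child_seed(config$seed, "genes"))
  })
}

config_duplicates <- function(config) {
  lapply(config$duplicates, function(d) {
    planted_duplicate(
      parent_gene_id = d$parent, mechanism = d$mechanism,
      retained_intron_indices = d$retained_introns,
      target_protein_identity = d$identity,
      pseudogenize = isTRUE(d$pseudogenize),
      truncation_aa = d$truncation_aa %||% 0L,
      placement = d$placement %||% "unlinked",
      species_set = d$species, event_id = d$event,
      strand = d$strand %||% "+",
      seed = child_seed(config$seed, "dups"))
  })
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [demo_config()].
#' @return Config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  cfg$thresholds <- modifyList(default_thresholds(), cfg$thresholds %||% list())
  cfg
}

#' Run the full duplicate-scan pipeline
#'
#' Stages run in dependency order (`simulate`, `search`, `families`,
#' `annotate`, `phylo`, `selection`, `stats`); each stage writes its outputs
#' under `outdir` before the next starts. A failing stage is recorded in the
#' report, downstream stages are skipped, and the returned report carries
#' `success = FALSE`.
#'
#' @param config config list (see [demo_config()]) or path to a YAML file.
#' @param outdir output directory.
#' @param stages optional character vector restricting which stages run
#'   (upstream in-memory state is rebuilt as needed, so normally run all).
#' @return The run report (list, also written to `run_report.json`):
#'   per-stage record counts, warnings, timings, output paths, config echo.
#' @export
run_pipeline <- function(config, outdir, stages = NULL) {
  if (is.character(config)) config <- read_config(config)
  config$thresholds <- modifyList(default_thresholds(),
                                  config$thresholds %||% list())
  th <- config$thresholds
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "search", "families", "annotate", "phylo",
                  "selection", "stats")
  if (is.null(stages)) stages <- all_stages
  st <- new.env(parent = emptyenv())   # shared pipeline state
  report <- list(package = "dupscan",
                 version = as.character(utils::packageVersion("dupscan")),
                 seed = config$seed, outdir = outdir, stages = list())
  ok <- TRUE

  stage_fns <- list(
    simulate = function() {
      st$genes <- config_genes(config)
      names(st$genes) <- vapply(st$genes, `[[`, "", "gene_id")
      dups <- config_duplicates(config)
      gdir <- file.path(outdir, "genomes")
      st$genomes <- list(); truths <- list()
      for (sp in config$species) {
        spec <- species_spec(sp, config$n_contigs, config$contig_length,
                             config$intergenic_genes,
                             seed = child_seed(config$seed, sp))
        gen <- generate_genome(spec, st$genes, dups,
                               parent_identity = config$parent_identity %||% 0.96,
                               flank_n = th$flank_window)
        write_genome(gen, gdir)
        st$genomes[[sp]] <- gen$genome
        truths[[sp]] <- gen$truth
      }
      st$truth <- do.call(rbind, truths)
      write_tsv(st$truth, file.path(outdir, "truth.tsv"))
      write_fasta(setNames(vapply(st$genes, `[[`, "", "protein"),
                           names(st$genes)),
                  file.path(outdir, "queries.fa"))
      c(genomes = length(st$genomes), planted_copies = nrow(st$truth))
    },

    search = function() {
      if (is.null(st$genomes)) stopf("search stage needs simulate outputs")
      st$loci <- list()
      hit_rows <- list()
      for (sp in config$species) {
        genome <- st$genomes[[sp]]
        fcache <- new.env(parent = emptyenv())
        for (g in st$genes) {
          hits <- search_translated(
            g$protein, genome, min_identity = th$min_identity_translated,
            min_hit_aa = th$min_hit_aa, query_id = g$gene_id,
            parent_locus = genome$genes[[g$gene_id]],
            frame_cache = fcache)
          if (nrow(hits)) {
            hit_rows[[length(hit_rows) + 1L]] <-
              cbind(species_id = sp,
                    hits[, setdiff(colnames(hits),
                                   c("q_aligned", "s_aligned"))])
          }
          st$loci[[sp]][[g$gene_id]] <- chain_hits(
            hits, max_intron_bp = th$max_intron_bp,
            query_len = nchar(g$protein),
            id_prefix = paste0(sp, "_", g$gene_id))
        }
      }
      ht <- do.call(rbind, hit_rows)
      write_tsv(ht, file.path(outdir, "hits.tsv"))
      c(hits = nrow(ht),
        loci = sum(vapply(unlist(st$loci, recursive = FALSE), length, 0L)))
    },

    families = function() {
      if (is.null(st$genomes)) stopf("families stage needs simulate outputs")
      # orthologous parent proteins across species (one family per gene)
      # plus a few unrelated filler proteins that must stay singletons
      prots <- character()
      for (sp in config$species) {
        genome <- st$genomes[[sp]]
        for (g in st$genes) {
          prots[paste0(sp, "_", g$gene_id)] <-
            gene_protein(genome, genome$genes[[g$gene_id]])
        }
      }
      ref <- st$genomes[[config$species[1]]]
      fillers <- Filter(function(g) identical(unname(g$attributes["biotype"]),
                                              "filler"), ref$genes)
      for (f in utils::head(fillers, 5)) {
        prots[f$gene_id] <- gene_protein(ref, f)
      }
      fam <- gene_families(prots, min_identity = th$min_identity_protein,
                           inflation = th$mcl_inflation)
      st$families <- fam
      write_tsv(data.frame(protein_id = names(fam$membership),
                           cluster_id = unname(fam$membership),
                           stringsAsFactors = FALSE),
                file.path(outdir, "families.tsv"))
      c(proteins = length(fam$membership), families = length(fam$clusters))
    },

    annotate = function() {
      if (is.null(st$loci)) stopf("annotate stage needs search outputs")
      copies <- list(); ctx <- list(); frags <- list()
      for (sp in config$species) {
        genome <- st$genomes[[sp]]
        for (g in st$genes) {
          cl <- classify_copies(st$loci[[sp]][[g$gene_id]],
                                genome$genes[[g$gene_id]], g$protein, genome,
                                w = th$flank_window,
                                min_intron_bp = th$min_intron_bp)
          copies[[length(copies) + 1L]] <- cl$copies
          ctx <- c(ctx, cl$contexts)
          if (!is.null(cl$fragments)) frags[[length(frags) + 1L]] <- cl$fragments
        }
      }
      st$copies <- do.call(rbind, copies)
      st$contexts <- ctx
      st$events <- call_events(st$copies, ctx,
                               min_shared_flank = th$min_shared_flank)
      write_tsv(st$copies, file.path(outdir, "copies.tsv"))
      write_tsv(st$events, file.path(outdir, "events.tsv"))
      if (length(frags)) {
        write_tsv(do.call(rbind, frags), file.path(outdir, "fragments.tsv"))
      }
      c(copies = nrow(st$copies), events = nrow(st$events),
        fragments = if (length(frags)) nrow(do.call(rbind, frags)) else 0L)
    },

    phylo = function() {
      if (is.null(st$copies)) stopf("phylo stage needs annotate outputs")
      tdir <- file.path(outdir, "trees")
      dir.create(tdir, showWarnings = FALSE)
      st$gene_seqs <- list(); st$trees <- list()
      n_trees <- 0L
      for (g in st$genes) {
        seqs <- list(); cds <- list()
        for (sp in config$species) {
          genome <- st$genomes[[sp]]
          model <- genome$genes[[g$gene_id]]
          tip <- paste0(sp, "_", g$gene_id)
          seqs[[tip]] <- gene_protein(genome, model)
          cds[[tip]] <- sub("(TAA|TAG|TGA)$", "", extract_cds(genome, model))
        }
        cp <- st$copies[st$copies$parent_gene_id == g$gene_id &
                          st$copies$status == "functional", , drop = FALSE]
        for (k in seq_len(nrow(cp))) {
          rec <- reconstruct_copy(
            locus_by_id(st$loci, cp$copy_id[k]),
            st$genomes[[cp$species_id[k]]], nchar(g$protein),
            th$min_intron_bp)
          trimmed <- trim_cds_at_stop(rec$cds, nchar(g$protein))
          seqs[[cp$copy_id[k]]] <- translate_cds(trimmed)
          cds[[cp$copy_id[k]]] <- trimmed
        }
        if (length(seqs) < 3) next
        msa <- progressive_align(unlist(seqs))
        tree <- nj_bootstrap(msa, n_replicates = th$bootstrap_n,
                             seed = child_seed(config$seed, g$gene_id))
        write_fasta(unclass(msa), file.path(tdir, paste0(g$gene_id, ".aln.fa")))
        write_newick(tree, file.path(tdir, paste0(g$gene_id, ".nwk")))
        st$gene_seqs[[g$gene_id]] <- list(msa = msa, cds = unlist(cds),
                                          copies = cp$copy_id)
        st$trees[[g$gene_id]] <- tree
        n_trees <- n_trees + 1L
      }
      c(trees = n_trees)
    },

    selection = function() {
      if (is.null(st$trees)) stopf("selection stage needs phylo outputs")
      rows <- list()
      for (gid in names(st$trees)) {
        gs <- st$gene_seqs[[gid]]
        if (!length(gs$copies)) next
        caln <- back_translate(gs$msa, gs$cds)
        tree <- st$trees[[gid]]
        fit <- fit_codon_model(caln, tree, "one_ratio")
        fit1 <- fit_codon_model(caln, tree, "one_ratio_fixed1")
        fit2 <- fit_codon_model(caln, tree, "two_ratio",
                                foreground_edges = gs$copies, start = fit)
        l_fixed <- lrt(fit1, fit)
        l_two <- lrt(fit, fit2)
        rows[[length(rows) + 1L]] <- data.frame(
          parent_gene_id = gid, n_seqs = length(gs$msa),
          lnL_one_ratio = fit$lnL, omega = unname(fit$omega[1]),
          kappa = fit$kappa,
          lnL_fixed1 = fit1$lnL, p_omega_ne_1 = l_fixed$p_value,
          lnL_two_ratio = fit2$lnL,
          omega_background = unname(fit2$omega["background"]),
          omega_foreground = unname(fit2$omega["foreground"]),
          p_two_ratio = l_two$p_value, stringsAsFactors = FALSE)
      }
      st$selection <- do.call(rbind, rows)
      write_tsv(st$selection, file.path(outdir, "selection.tsv"))
      c(genes_tested = nrow(st$selection))
    },

    stats = function() {
      if (is.null(st$copies)) stopf("stats stage needs annotate outputs")
      turn <- summarize_turnover(st$copies, st$events)
      write_tsv(turn, file.path(outdir, "stats.tsv"))
      rates <- lapply(turn$parent_gene_id, function(g) {
        r <- pseudogene_rate(st$copies, g, length(config$species))
        data.frame(gene_id = g, pseudogene_count = r$pseudogene_count,
                   genome_count = r$genome_count, rate = r$rate,
                   stringsAsFactors = FALSE)
      })
      write_tsv(do.call(rbind, rates), file.path(outdir, "pseudogene_rates.tsv"))
      c(genes = nrow(turn))
    }
  )

  for (name in all_stages) {
    if (!name %in% stages) next
    t0 <- Sys.time()
    if (!ok) {
      report$stages[[name]] <- list(status = "skipped")
      next
    }
    res <- tryCatch({
      counts <- stage_fns[[name]]()
      list(status = "ok", counts = as.list(counts),
           seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    }, error = function(e) {
      ok <<- FALSE
      list(status = "failed", error = conditionMessage(e),
           seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    })
    report$stages[[name]] <- res
    if (res$status == "failed") {
      warnf("stage '%s' failed: %s", name, res$error)
    }
  }
  report$success <- ok
  report$config <- config[setdiff(names(config), "outdir")]
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

locus_by_id <- function(loci, copy_id) {
  for (sp in names(loci)) {
    for (g in names(loci[[sp]])) {
      for (l in loci[[sp]][[g]]) {
        if (identical(l$copy_id, copy_id)) return(l)
      }
    }
  }
  stopf("locus %s not found", copy_id)
}

# trim a reconstructed CDS to the parent's length (or the first stop codon),
# yielding a clean coding sequence for alignment-based analyses
trim_cds_at_stop <- function(cds, parent_len) {
  cod <- as_codons(cds)
  aa <- translate_codon(cod)
  stop_at <- which(aa == "*")
  last <- if (length(stop_at)) min(stop_at[1] - 1L, parent_len)
  else min(length(cod), parent_len)
  paste(cod[seq_len(last)], collapse = "")
}
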