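## Pipeline orchestration: simulate -> census -> snv -> synteny ->
## expression as one reproducible run with a single root seed and
## stage-namespaced configuration.

.STAGES <- c("simulate", "census", "snv", "synteny", "expression")

#' Default pipeline configuration
#'
#' Stage-namespaced parameter blocks.  Thresholds default to the values the
#' reference analyses print: identity 0.80 and coverage 0.70 (inclusive),
#' max_copies 20, mapping quality 20 (strict), min_contigs 2, FPKM threshold
#' 1.0 (strict), 10,000 fragments and 1,000 rounds for the fragmentation
#' null.
#'
#' @param seed root seed; all stage seeds are derived from it
#' @return nested named list of class `run_config`
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = .STAGES,
    simulate = list(
      n_genes = 200L,
      n_chromosomes = 2L,
      config = polyploid_config(seed = as.integer(seed))
    ),
    census = list(
      min_identity = 0.80,
      min_cov = 0.70,
      max_copies = 20L,
      len_tolerance = 0.20,
      regions = c("CDS", "up100", "up500", "up1000")
    ),
    snv = list(
      min_mapq = 20L,
      min_contigs = 2L
    ),
    synteny = list(
      min_identity = 0.80,
      min_cov = 0.70,
      max_evalue = 1e-5,
      n_fragments = 10000L,
      rounds = 1000L,
      mode = "strict"
    ),
    expression = list(
      threshold = 1.0
    )
  ), class = "run_config")
}

#' Read a pipeline configuration file
#'
#' Flat YAML with stage-namespaced keys (`census.min_identity: 0.8`,
#' `simulate.config.sub_rate_cds: 0.005`, ...).  Unknown keys are rejected.
#'
#' @param path YAML file
#' @param seed optional root seed overriding the file
#' @return a `run_config`
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed %||% raw$seed %||% 1L)
  for (key in names(raw)) {
    if (key == "seed") next
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    ## validate the path against the defaults
    for (i in seq_along(parts)) {
      if (is.null(node[[parts[i]]]) && !(length(parts) >= 3 && parts[1] == "simulate" && parts[2] == "config")) {
        stop("unknown configuration key: ", key)
      }
      node <- node[[parts[i]]]
    }
    cfg[[parts]] <- raw[[key]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_polyploid_config(cfg$simulate$config)
  cfg
}

#' Run the full pipeline
#'
#' Stages run in dependency order (census and expression need simulate; snv
#' and synteny need census).  All randomness derives from the root seed via
#' fixed per-stage offsets, so reruns with an identical configuration are
#' identical.
#'
#' @param config a `run_config` (see [default_run_config()])
#' @param outdir output directory; stage tables, FASTA/GFF3/VCF outputs and
#'   a JSON run manifest are written beneath it
#' @param stages stages to run (default: from the config)
#' @return invisibly, a list of in-memory stage results plus the manifest
#' @export
run_pipeline <- function(config = default_run_config(), outdir,
                         stages = config$stages) {
  bad <- setdiff(stages, .STAGES)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs <- list(census = "simulate", expression = c("simulate", "census"),
                snv = c("simulate", "census"),
                synteny = c("simulate", "census"))
  for (st in stages) {
    missing <- setdiff(needs[[st]], stages)
    if (length(missing) > 0L) {
      stop(sprintf("stage '%s' requires stage(s): %s", st,
                   paste(missing, collapse = ", ")))
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  seed <- as.integer(config$seed)

  ## ---- simulate ---------------------------------------------------------
  if ("simulate" %in% stages) {
    sc <- config$simulate
    pcfg <- sc$config
    pcfg$seed <- seed
    ancestor <- generate_ancestor(sc$n_genes, sc$n_chromosomes, seed = seed)
    sim <- polyploidize(ancestor, pcfg)
    sim <- plant_rearrangements(sim, seed = seed + 1L)
    contigs <- fragment_genome(sim, seed = seed + 2L)
    expr <- simulate_expression(sim, seed = seed + 3L)
    write_simulation(sim, contigs, expr, file.path(outdir, "simulate"))
    res$simulate <- list(sim = sim, contigs = contigs, expression = expr)
  }

  ## ---- census -----------------------------------------------------------
  if ("census" %in% stages) {
    cc <- config$census
    sim <- res$simulate$sim
    aln_tab <- align_anchor_copies(sim$ancestor$cds, sim$copy_cds)
    clusters <- assign_homoeologs(aln_tab, cc$min_identity, cc$min_cov)
    clusters <- filter_clusters(clusters, cc$max_copies)
    dist_k <- copy_count_distribution(clusters,
                                      anchors = sim$ancestor$genes$gene_id)
    kept <- clusters$clusters[clusters$clusters$kept, , drop = FALSE]
    rec_list <- list(); cds_alns <- list()
    for (i in seq_len(nrow(kept))) {
      mem <- kept$members[[i]]
      if (length(mem) < 2L) next
      for (region in cc$regions) {
        seqs <- if (region == "CDS") sim$copy_cds else sim$copy_upstream
        rec <- pairwise_dissimilarity(kept$anchor_id[i], mem, seqs, region,
                                      cc$len_tolerance,
                                      keep_alignments = (region == "CDS"))
        rec_list[[length(rec_list) + 1L]] <- rec
        if (region == "CDS") {
          cds_alns <- c(cds_alns, attr(rec, "alignments"))
        }
      }
    }
    records <- .rbind_or_empty(rec_list,
      c("anchor_id", "member1", "member2", "region", "value"))
    medians <- vapply(cc$regions, function(rg) {
      if (any(records$region == rg)) median_dissimilarity(records, rg)
      else NA_real_
    }, 0)
    spectrum <- indel_spectrum(cds_alns)
    cdir <- file.path(outdir, "census")
    dir.create(cdir, showWarnings = FALSE)
    cl_tab <- clusters$clusters
    cl_tab$members <- vapply(cl_tab$members, paste, "", collapse = ",")
    .write_tsv(cl_tab, file.path(cdir, "clusters.tsv"))
    .write_tsv(records, file.path(cdir, "dissimilarity.tsv"))
    .write_tsv(data.frame(length = as.integer(names(spectrum$counts)),
                          count = spectrum$counts),
               file.path(cdir, "indel_spectrum.tsv"))
    .write_tsv(data.frame(count = names(dist_k), frequency = as.numeric(dist_k)),
               file.path(cdir, "copy_count_distribution.tsv"))
    res$census <- list(alignments = aln_tab, clusters = clusters,
                       copy_count_distribution = dist_k,
                       dissimilarity = records, medians = medians,
                       spectrum = spectrum)
  }

  ## ---- snv --------------------------------------------------------------
  if ("snv" %in% stages) {
    sc <- config$snv
    sim <- res$simulate$sim
    kept <- res$census$clusters$clusters
    kept <- kept[kept$kept, , drop = FALSE]
    alns <- list()
    for (i in seq_len(nrow(kept))) {
      an <- kept$anchor_id[i]
      for (mem in kept$members[[i]]) {
        alns[[length(alns) + 1L]] <- align_global(
          as.character(sim$ancestor$cds[[an]]),
          as.character(sim$copy_cds[[mem]]),
          query_id = an, subject_id = mem)
      }
    }
    sites <- call_sites(alns, sim$ancestor$cds, sc$min_mapq, sc$min_contigs)
    per_gene <- if (nrow(sites) > 0L) count_snvs_per_gene(sites) else
      data.frame()
    sdir <- file.path(outdir, "snv")
    dir.create(sdir, showWarnings = FALSE)
    write_sites_vcf(sites, file.path(sdir, "sites.vcf"))
    .write_tsv(sites, file.path(sdir, "sites.tsv"))
    if (nrow(sites) > 0L) .write_tsv(per_gene, file.path(sdir, "per_gene.tsv"))
    res$snv <- list(sites = sites, per_gene = per_gene)
  }

  ## ---- synteny ----------------------------------------------------------
  if ("synteny" %in% stages) {
    sy <- config$synteny
    sim <- res$simulate$sim
    contigs <- res$simulate$contigs
    aln_tab <- res$census$alignments
    genes <- rbind(
      data.frame(genome_id = "reference",
                 gene_id = sim$ancestor$genes$gene_id,
                 stringsAsFactors = FALSE),
      data.frame(genome_id = "polyploid", gene_id = sim$copies$copy_id,
                 stringsAsFactors = FALSE))
    groups <- build_ortho_groups(aln_tab, genes, sy$min_cov, sy$min_identity,
                                 sy$max_evalue)
    coords <- rbind(
      data.frame(genome_id = "reference",
                 gene_id = sim$ancestor$genes$gene_id,
                 seq_id = sim$ancestor$genes$chromosome,
                 position = sim$ancestor$genes$order_index,
                 strand = sim$ancestor$genes$strand,
                 stringsAsFactors = FALSE),
      data.frame(genome_id = "polyploid",
                 gene_id = contigs$contig_map$copy_id,
                 seq_id = contigs$contig_map$contig_id,
                 position = contigs$contig_map$order,
                 strand = contigs$contig_map$strand,
                 stringsAsFactors = FALSE))
    anchors <- select_anchors(groups, coords, "reference",
                              c("reference", "polyploid"))
    rank_map <- reference_rank_map(anchors, "reference")
    poly <- anchors[anchors$genome_id == "polyploid", , drop = FALSE]
    block_counts <- integer(0)
    fully <- logical(0)
    for (ctg in unique(poly$seq_id)) {
      ca <- poly[poly$seq_id == ctg, , drop = FALSE]
      ca <- ca[order(ca$position), , drop = FALSE]
      b <- detect_blocks(ca, rank_map, sy$mode)
      block_counts[ctg] <- nrow(b)
      fully[ctg] <- nrow(ca) >= 2L && nrow(b) == 1L
    }
    ## null model fragments the (pre-fragmentation) chromosome layout
    lay <- sim$layout
    lay$group <- groups$group_id[match(lay$copy_id, groups$gene_id)]
    lay <- lay[lay$group %in% rank_map$group_id, , drop = FALSE]
    target <- data.frame(seq_id = lay$chromosome, group_id = lay$group,
                         strand = lay$strand, stringsAsFactors = FALSE)
    null <- monte_carlo_fragmentation(target, rank_map,
                                      sim$config$genes_per_contig_dist,
                                      sy$n_fragments, sy$rounds,
                                      seed = seed + 4L, mode = sy$mode)
    multi <- names(block_counts)[vapply(unique(poly$seq_id), function(ctg)
      sum(poly$seq_id == ctg) >= 2L, TRUE)]
    comparison <- compare_block_distributions(unname(block_counts), null)
    ydir <- file.path(outdir, "synteny")
    dir.create(ydir, showWarnings = FALSE)
    .write_tsv(groups, file.path(ydir, "groups.tsv"))
    .write_tsv(anchors, file.path(ydir, "anchors.tsv"))
    .write_tsv(data.frame(contig_id = names(block_counts),
                          blocks = unname(block_counts),
                          fully_syntenic = unname(fully)),
               file.path(ydir, "blocks.tsv"))
    .write_tsv(comparison, file.path(ydir, "null_comparison.tsv"))
    res$synteny <- list(groups = groups, anchors = anchors,
                        rank_map = rank_map,
                        block_counts = block_counts,
                        fully_syntenic = fully,
                        multi_anchor_contigs = multi,
                        null = null, comparison = comparison)
  }

  ## ---- expression -------------------------------------------------------
  if ("expression" %in% stages) {
    ec <- config$expression
    clusters <- res$census$clusters
    ab <- res$simulate$expression$abundance
    mat_sense <- copies_expressed_matrix(clusters, ab, "sense", ec$threshold)
    mat_anti <- copies_expressed_matrix(clusters, ab, "antisense",
                                        ec$threshold)
    level <- copies_vs_level(clusters, ab, ec$threshold)
    edir <- file.path(outdir, "expression")
    dir.create(edir, showWarnings = FALSE)
    utils::write.table(mat_sense, file.path(edir, "matrix_sense.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(mat_anti, file.path(edir, "matrix_antisense.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    .write_tsv(level, file.path(edir, "copies_vs_level.tsv"))
    res$expression <- list(sense = mat_sense, antisense = mat_anti,
                           level = level)
  }

  ## ---- manifest ---------------------------------------------------------
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "polycensus",
    version = as.character(utils::packageVersion("polycensus")),
    seed = seed,
    stages = stages,
    outputs = lapply(stats::setNames(files, sub(paste0("^", outdir, "/?"), "",
                                                files)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
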