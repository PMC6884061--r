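# Shared simulation fixtures, built once per test run.

# A one-row alignment table with chosen identity/coverage.
aln_row <- function(query = "A1", subject = "c1", identity = 0.9,
                    cov_q = 1, cov_s = 1, len = 100L) {
  n_col <- len
  n_match <- round(identity * n_col)
  data.frame(query_id = query, subject_id = subject,
             q_start = 0, q_end = cov_q * len,
             s_start = 0, s_end = cov_s * len,
             strand = "+", n_columns = n_col, n_matches = n_match,
             n_mismatches = n_col - n_match, n_gap_columns = 0L,
             gap_opens = 0L, evalue = 1e-20, score = 100,
             q_len = len, s_len = len, stringsAsFactors = FALSE)
}

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small polyploid simulation with all mutation channels active.
small_sim <- function() {
  fixture("small_sim", function() {
    anc <- generate_ancestor(30, 2, seed = 42)
    polyploidize(anc, polyploid_config(seed = 42))
  })
}

# Substitution-only simulation used for divergence checks.
subs_only_sim <- function(n_genes = 40, seed = 7) {
  fixture(paste0("subs_only_", n_genes, "_", seed), function() {
    anc <- generate_ancestor(n_genes, 2, seed = seed)
    cfg <- polyploid_config(seed = seed, snv_sites_per_gene = 0,
                            large_effect_rate = 0, indel_rate = 0)
    polyploidize(anc, cfg)
  })
}

# Constant-copy-number simulation for synteny checks (uniform ploidy makes
# planted rearrangements the only source of collinearity breaks).
uniform_k_config <- function(k = 2L, seed = 1L, ...) {
  d <- stats::setNames(1, as.character(k))
  polyploid_config(copy_count_dist = d, seed = seed,
                   snv_sites_per_gene = 0, large_effect_rate = 0,
                   indel_rate = 0, ...)
}

# Build ortholog groups + anchors + rank map for a simulation via the
# pipeline route (k-mer candidates, global alignment, union-find).
synteny_setup <- function(sim, contigs) {
  tab <- align_anchor_copies(sim$ancestor$cds, sim$copy_cds)
  genes <- rbind(
    data.frame(genome_id = "reference", gene_id = sim$ancestor$genes$gene_id,
               stringsAsFactors = FALSE),
    data.frame(genome_id = "polyploid", gene_id = sim$copies$copy_id,
               stringsAsFactors = FALSE))
  groups <- build_ortho_groups(tab, genes)
  coords <- rbind(
    data.frame(genome_id = "reference", gene_id = sim$ancestor$genes$gene_id,
               seq_id = sim$ancestor$genes$chromosome,
               position = sim$ancestor$genes$order_index,
               strand = sim$ancestor$genes$strand, stringsAsFactors = FALSE),
    data.frame(genome_id = "polyploid", gene_id = contigs$contig_map$copy_id,
               seq_id = contigs$contig_map$contig_id,
               position = contigs$contig_map$order,
               strand = contigs$contig_map$strand, stringsAsFactors = FALSE))
  anchors <- select_anchors(groups, coords, "reference",
                            c("reference", "polyploid"))
  list(groups = groups, anchors = anchors,
       rank_map = reference_rank_map(anchors, "reference"))
}

# Per-contig planted breakpoint count from the ground truth: breakpoints are
# recorded as (left_copy, right_copy) adjacencies.
contig_truth_breakpoints <- function(contig_map, breakpoints, contig_id) {
  mem <- contig_map[contig_map$contig_id == contig_id, , drop = FALSE]
  mem <- mem[order(mem$order), , drop = FALSE]
  ids <- mem$copy_id
  if (length(ids) < 2) return(0L)
  adj <- paste(ids[-length(ids)], ids[-1], sep = "|")
  bp <- paste(breakpoints$left_copy, breakpoints$right_copy, sep = "|")
  sum(adj %in% bp)
}
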