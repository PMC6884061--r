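## Writers for the simulator's external formats: FASTA, GFF3 (1-based,
## closed intervals, gene/mRNA/CDS with Parent attributes), and truth TSVs.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a contig set as FASTA and GFF3
#'
#' @param contigs a `contig_set` from [fragment_genome()]
#' @param fasta_path,gff_path output paths
#' @return invisibly, the paths
#' @export
write_contigs <- function(contigs, fasta_path, gff_path) {
  Biostrings::writeXStringSet(contigs$sequences, fasta_path, width = 80L)
  m <- contigs$contig_map
  gr <- GenomicRanges::GRanges(
    seqnames = rep(m$contig_id, each = 3L),
    ranges = IRanges::IRanges(
      start = rep(m$cds_start, each = 3L),
      end = rep(m$cds_end, each = 3L)),
    strand = rep(m$strand, each = 3L))
  type <- rep(c("gene", "mRNA", "CDS"), nrow(m))
  ids <- as.vector(rbind(m$copy_id,
                         paste0(m$copy_id, ".t1"),
                         paste0(m$copy_id, ".t1.cds")))
  parents <- as.vector(rbind(NA_character_,
                             m$copy_id,
                             paste0(m$copy_id, ".t1")))
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- ids
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(parents), "", parents)
  S4Vectors::mcols(gr)$gene_id <- rep(m$gene_id, each = 3L)
  S4Vectors::mcols(gr)$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

#' Write a full simulation to disk
#'
#' Emits the ancestor CDS/upstream FASTA and gene table, the polyploid copy
#' CDS/upstream FASTA, contig FASTA + GFF3, per-category ground-truth TSVs,
#' and the abundance TSV.
#'
#' @param sim a `polyploid_sim`
#' @param contigs a `contig_set` (optional)
#' @param expression result of [simulate_expression()] (optional)
#' @param outdir output directory (created if missing)
#' @return invisibly, a character vector of the files written
#' @export
write_simulation <- function(sim, contigs = NULL, expression = NULL,
                             outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  written <- character(0)
  w <- function(f) { written <<- c(written, f); f }

  Biostrings::writeXStringSet(sim$ancestor$cds, w(p("ancestor_cds.fasta")),
                              width = 80L)
  Biostrings::writeXStringSet(sim$ancestor$upstream,
                              w(p("ancestor_upstream.fasta")), width = 80L)
  .write_tsv(sim$ancestor$genes, w(p("ancestor_genes.tsv")))
  Biostrings::writeXStringSet(sim$copy_cds, w(p("copies_cds.fasta")),
                              width = 80L)
  Biostrings::writeXStringSet(sim$copy_upstream,
                              w(p("copies_upstream.fasta")), width = 80L)
  .write_tsv(sim$copies, w(p("copies.tsv")))
  .write_tsv(sim$layout, w(p("layout.tsv")))
  .write_tsv(sim$truth$copy_counts, w(p("truth_copy_counts.tsv")))
  .write_tsv(sim$truth$mutations, w(p("truth_mutations.tsv")))
  .write_tsv(sim$truth$indels, w(p("truth_indels.tsv")))
  .write_tsv(sim$truth$sites, w(p("truth_sites.tsv")))
  .write_tsv(sim$truth$large_effects, w(p("truth_large_effects.tsv")))
  .write_tsv(sim$truth$breakpoints, w(p("truth_breakpoints.tsv")))
  if (!is.null(contigs)) {
    write_contigs(contigs, w(p("contigs.fasta")), w(p("contigs.gff3")))
    .write_tsv(contigs$contig_map, w(p("contig_map.tsv")))
  }
  if (!is.null(expression)) {
    write_abundance(expression$abundance, w(p("abundance.tsv")))
    .write_tsv(expression$truth, w(p("truth_expression.tsv")))
  }
  invisible(written)
}

#' Extract upstream windows from contigs via their gene models
#'
#' For every gene on a contig, returns the `window` nt immediately upstream
#' of the coding start (strand-aware: reverse-complemented for minus-strand
#' genes), clipped at the contig edge.
#'
#' @param sequences contig [Biostrings::DNAStringSet]
#' @param gff data.frame or GRanges of gene models with `type == "gene"`,
#'   seqnames, start, end, strand, and an ID
#' @param window window length (nt)
#' @return named [Biostrings::DNAStringSet] (names = gene IDs); genes whose
#'   upstream window is fully outside the contig are dropped
#' @export
extract_upstream_window <- function(sequences, gff, window = 1000L) {
  if (methods::is(gff, "GRanges")) {
    df <- data.frame(seqnames = as.character(GenomicRanges::seqnames(gff)),
                     start = GenomicRanges::start(gff),
                     end = GenomicRanges::end(gff),
                     strand = as.character(GenomicRanges::strand(gff)),
                     type = S4Vectors::mcols(gff)$type,
                     ID = S4Vectors::mcols(gff)$ID,
                     stringsAsFactors = FALSE)
  } else {
    df <- gff
  }
  df <- df[df$type == "gene", , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(df))) {
    ctg <- as.character(sequences[[df$seqnames[i]]])
    if (df$strand[i] == "-") {
      from <- df$end[i] + 1L
      to <- min(nchar(ctg), df$end[i] + window)
      if (from > nchar(ctg)) next
      s <- substr(ctg, from, to)
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    } else {
      to <- df$start[i] - 1L
      from <- max(1L, df$start[i] - window)
      if (to < 1L) next
      s <- substr(ctg, from, to)
    }
    out[df$ID[i]] <- s
  }
  Biostrings::DNAStringSet(out)
}
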