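## Synthetic allopolyploid genome generator with fully recorded ground truth.
##
## The generator emulates the statistical structure the downstream analyses
## assume: an ancestral diploid gene set on chromosomes; per-gene copy counts
## 1-15 (mode 2-6); region-dependent divergence increasing from the CDS to
## the 1,000-nt upstream window; CDS indels enriched for multiples of 3;
## planted variant sites with controlled allele multiplicity; inversions and
## translocations; fragmentation into contigs; per-copy expression states.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

.sense_codons <- function() {
  all <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  setdiff(all, .STOP_CODONS)
}

.check_dist <- function(d, what, integer_support = TRUE) {
  if (length(d) == 0L) stop(sprintf("%s: empty distribution", what))
  if (is.null(names(d))) stop(sprintf("%s: distribution must be named", what))
  if (any(d < 0)) stop(sprintf("%s: negative probability", what))
  if (abs(sum(d) - 1) > 1e-9) {
    stop(sprintf("%s: probabilities sum to %.12f, not 1", what, sum(d)))
  }
  if (integer_support && anyNA(suppressWarnings(as.integer(names(d))))) {
    stop(sprintf("%s: support must be integer", what))
  }
  invisible(d)
}

.sample_dist <- function(d, n) {
  as.integer(sample(names(d), n, replace = TRUE, prob = d))
}

#' Convert a target pairwise dissimilarity to a per-copy substitution rate
#'
#' Two copies independently substituted from a common ancestor at per-site
#' rate `r` (uniform over the three alternative bases) differ at a site with
#' probability `d = 2 r - (4/3) r^2`.  This inverts that relation, so that a
#' desired median pairwise divergence between copies can be specified
#' directly.
#'
#' @param d target pairwise dissimilarity (fraction)
#' @return per-copy per-site substitution rate
#' @export
pairwise_to_copy_rate <- function(d) {
  stopifnot(d >= 0, d < 0.75)
  0.375 * (2 - sqrt(4 - (16 / 3) * d))
}

#' Expected pairwise dissimilarity implied by a per-copy substitution rate
#'
#' Inverse of [pairwise_to_copy_rate()].
#'
#' @param r per-copy per-site substitution rate
#' @return expected fraction of differing sites between two copies
#' @export
copy_rate_to_pairwise <- function(r) 2 * r - (4 / 3) * r^2

#' Parameter set for the synthetic polyploid generator
#'
#' Defaults reproduce the study conditions of the package's reference
#' analyses: copy counts supported on 1..15 with mode 2-6; per-copy
#' substitution rates chosen so the expected pairwise divergence between
#' copies is 0.90% in the CDS and 1.03% / 4.47% / 7.50% in the 100 / 500 /
#' 1,000-nt upstream windows; CDS indels mostly frame-preserving; planted
#' variant-site multiplicities 12.03% mono-, 80.8% bi-, 6.2% tri- and 0.97%
#' tetra-allelic.
#'
#' @param copy_count_dist named probability vector over copy counts (1..15)
#' @param sub_rate_cds,sub_rate_up100,sub_rate_up500,sub_rate_up1000 per-copy
#'   per-site substitution rates; the upstream rates are window-level rates
#'   for the 100 / 500 / 1,000-nt windows ending at the start codon (zone
#'   rates for 0-100, 100-500 and 500-1,000 nt are derived internally)
#' @param indel_rate indel events per kb per copy
#' @param indel_len_dist named probability vector over indel lengths
#' @param frame_preserving_frac_cds probability that a CDS indel length is a
#'   multiple of 3
#' @param multiplicity_dist named probability vector over allele
#'   multiplicities 1..4 for planted variant sites
#' @param snv_sites_per_gene expected number of planted variant sites per gene
#' @param large_effect_rate probability a gene carries one planted
#'   large-effect substitution
#' @param inversion_rate,translocation_rate rearrangement events per 100 gene
#'   copies
#' @param genes_per_contig_dist named probability vector over genes per contig
#' @param expressed_frac probability a copy is expressed
#' @param antisense_frac probability an expressed copy is antisense-only
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM parameters for expressed
#'   copies (truncated above 1)
#' @param seed integer seed
#' @return an object of class `polyploid_config`
#' @export
polyploid_config <- function(
    copy_count_dist = c(`1` = 0.06, `2` = 0.17, `3` = 0.18, `4` = 0.16,
                        `5` = 0.13, `6` = 0.10, `7` = 0.06, `8` = 0.045,
                        `9` = 0.03, `10` = 0.02, `11` = 0.015, `12` = 0.012,
                        `13` = 0.008, `14` = 0.006, `15` = 0.004),
    sub_rate_cds = pairwise_to_copy_rate(0.0090),
    sub_rate_up100 = pairwise_to_copy_rate(0.0103),
    sub_rate_up500 = pairwise_to_copy_rate(0.0447),
    sub_rate_up1000 = pairwise_to_copy_rate(0.0750),
    indel_rate = 0.3,
    indel_len_dist = {p <- 0.55^(1:30); p <- p / sum(p); names(p) <- 1:30; p},
    frame_preserving_frac_cds = 0.65,
    multiplicity_dist = c(`1` = 0.1203, `2` = 0.808, `3` = 0.062,
                          `4` = 0.0097),
    snv_sites_per_gene = 3,
    large_effect_rate = 0.05,
    inversion_rate = 0,
    translocation_rate = 0,
    genes_per_contig_dist = c(`1` = 0.80, `2` = 0.12, `3` = 0.045, `4` = 0.02,
                              `5` = 0.01, `6` = 0.005),
    expressed_frac = 0.7,
    antisense_frac = 0.05,
    fpkm_meanlog = 1.5,
    fpkm_sdlog = 1,
    seed = 1L) {
  cfg <- list(copy_count_dist = copy_count_dist,
              sub_rate_cds = sub_rate_cds,
              sub_rate_up100 = sub_rate_up100,
              sub_rate_up500 = sub_rate_up500,
              sub_rate_up1000 = sub_rate_up1000,
              indel_rate = indel_rate,
              indel_len_dist = indel_len_dist,
              frame_preserving_frac_cds = frame_preserving_frac_cds,
              multiplicity_dist = multiplicity_dist,
              snv_sites_per_gene = snv_sites_per_gene,
              large_effect_rate = large_effect_rate,
              inversion_rate = inversion_rate,
              translocation_rate = translocation_rate,
              genes_per_contig_dist = genes_per_contig_dist,
              expressed_frac = expressed_frac,
              antisense_frac = antisense_frac,
              fpkm_meanlog = fpkm_meanlog,
              fpkm_sdlog = fpkm_sdlog,
              seed = as.integer(seed))
  validate_polyploid_config(cfg)
  structure(cfg, class = "polyploid_config")
}

#' Validate a polyploid generator configuration
#'
#' @param cfg a list of configuration fields
#' @return the config, invisibly; errors on invalid input
#' @export
validate_polyploid_config <- function(cfg) {
  .check_dist(cfg$copy_count_dist, "copy_count_dist")
  if (any(!as.integer(names(cfg$copy_count_dist)) %in% 1:15)) {
    stop("copy_count_dist support must lie in 1..15")
  }
  .check_dist(cfg$indel_len_dist, "indel_len_dist")
  .check_dist(cfg$multiplicity_dist, "multiplicity_dist")
  if (any(!as.integer(names(cfg$multiplicity_dist)) %in% 1:4)) {
    stop("multiplicity_dist support must lie in 1..4")
  }
  .check_dist(cfg$genes_per_contig_dist, "genes_per_contig_dist")
  probs <- c(cfg$sub_rate_cds, cfg$sub_rate_up100, cfg$sub_rate_up500,
             cfg$sub_rate_up1000, cfg$frame_preserving_frac_cds,
             cfg$expressed_frac, cfg$antisense_frac)
  if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]")
  if (cfg$indel_rate < 0 || cfg$large_effect_rate < 0 ||
      cfg$inversion_rate < 0 || cfg$translocation_rate < 0 ||
      cfg$snv_sites_per_gene < 0) {
    stop("rates must be non-negative")
  }
  zr <- .zone_rates(cfg)
  if (any(unlist(zr) < 0)) {
    stop("upstream window rates imply a negative zone rate; ",
         "window rates must be non-decreasing fast enough ",
         "(100*r100 <= 500*r500 <= 1000*r1000)")
  }
  invisible(cfg)
}

## Upstream zone rates (0-100, 100-500, 500-1000 nt from the start codon)
## derived from window-level rates so that window averages hit the targets.
.zone_rates <- function(cfg) {
  z100 <- cfg$sub_rate_up100
  z500 <- (500 * cfg$sub_rate_up500 - 100 * z100) / 400
  z1000 <- (1000 * cfg$sub_rate_up1000 - 500 * cfg$sub_rate_up500) / 500
  list(z100 = z100, z500 = z500, z1000 = z1000)
}

#' Generate an ancestral diploid gene set
#'
#' Genes are distributed evenly across chromosomes with consecutive order
#' indices.  Each CDS starts with ATG, ends with a stop codon, contains no
#' internal in-frame stop, and has length a multiple of 3; each gene carries
#' exactly 1,000 nt of upstream sequence whose 3' end abuts the start codon.
#'
#' @param n_genes number of genes (>= 1)
#' @param n_chromosomes number of chromosomes
#' @param cds_len_dist named probability vector over CDS lengths (multiples
#'   of 3, >= 300)
#' @param seed integer seed
#' @return an object of class `ancestor_genome` with elements `genes`
#'   (data.frame: gene_id, chromosome, order_index, strand, cds_len), `cds`
#'   and `upstream` (named [Biostrings::DNAStringSet] objects)
#' @export
generate_ancestor <- function(n_genes, n_chromosomes = 1,
                              cds_len_dist = c(`300` = 0.25, `450` = 0.5,
                                               `600` = 0.25),
                              seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  .check_dist(cds_len_dist, "cds_len_dist")
  lens <- as.integer(names(cds_len_dist))
  if (any(lens %% 3 != 0) || any(lens < 300)) {
    stop("cds_len_dist support must be multiples of 3, >= 300")
  }
  withr::with_seed(as.integer(seed), {
    sense <- .sense_codons()
    ## even split: chromosome sizes differ by at most one, consecutive order
    sizes <- rep(n_genes %/% n_chromosomes, n_chromosomes)
    extra <- n_genes %% n_chromosomes
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    chrom <- rep(paste0("chr", seq_len(n_chromosomes)), sizes)
    order_index <- unlist(lapply(sizes, function(s) seq_len(s) - 1L),
                          use.names = FALSE)
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    cds_len <- .sample_dist(cds_len_dist, n_genes)
    cds <- vapply(cds_len, function(L) {
      n_cod <- L / 3
      paste0("ATG",
             paste(sample(sense, n_cod - 2, replace = TRUE), collapse = ""),
             sample(.STOP_CODONS, 1))
    }, "")
    upstream <- vapply(seq_len(n_genes), function(i) {
      paste(sample(.BASES, 1000, replace = TRUE), collapse = "")
    }, "")
    genes <- data.frame(gene_id = gene_id, chromosome = chrom,
                        order_index = order_index, strand = strand,
                        cds_len = cds_len, stringsAsFactors = FALSE)
    cds_set <- Biostrings::DNAStringSet(cds)
    names(cds_set) <- gene_id
    up_set <- Biostrings::DNAStringSet(upstream)
    names(up_set) <- gene_id
    structure(list(genes = genes, cds = cds_set, upstream = up_set,
                   n_chromosomes = n_chromosomes, seed = as.integer(seed)),
              class = "ancestor_genome")
  })
}

## --------------------------------------------------------------------------
## helpers working on character vectors of single bases

.str_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
.chars_to_str <- function(v) paste(v, collapse = "")

## alternatives to `base` that keep the codon containing position `pos` free
## of stop codons (codon context taken from the current char vector).
.sense_alts <- function(chars, pos, avoid_stop = TRUE) {
  alts <- setdiff(.BASES, chars[pos])
  if (!avoid_stop) return(alts)
  cod_start <- pos - ((pos - 1) %% 3)
  keep <- vapply(alts, function(a) {
    cod <- chars[cod_start:(cod_start + 2)]
    cod[pos - cod_start + 1] <- a
    !(paste(cod, collapse = "") %in% .STOP_CODONS)
  }, TRUE)
  alts[keep]
}

## apply recorded indels (ancestor coordinates) to a char vector;
## insertions insert after `position`, deletions remove
## position..position+length-1.  Applied in descending coordinate order.
.apply_indels <- function(chars, indels) {
  if (nrow(indels) == 0L) return(chars)
  idx <- order(indels$position, decreasing = TRUE)
  for (i in idx) {
    p <- indels$position[i]
    if (indels$type[i] == "ins") {
      ins <- .str_to_chars(indels$inserted_seq[i])
      chars <- append(chars, ins, after = p)
    } else {
      chars <- chars[-(p:(p + indels$length[i] - 1))]
    }
  }
  chars
}

#' Derive a polyploid gene set from an ancestor
#'
#' Each gene receives `k` copies (`k ~ copy_count_dist`) laid out on
#' homoeologous chromosome sets (`<chrom>_h1`, `<chrom>_h2`, ...; set `i`
#' carries copy `i` of every gene with at least `i` copies, preserving
#' ancestral gene order).  Copies accumulate region-specific substitutions,
#' indels, planted variant sites realising `multiplicity_dist`, and planted
#' large-effect substitutions.  Every event is recorded in the ground truth.
#'
#' @param ancestor an `ancestor_genome`
#' @param cfg a [polyploid_config()]
#' @return an object of class `polyploid_sim`: the ancestor, config, copy
#'   table and layout, copy sequences (`copy_cds`, `copy_upstream`), and a
#'   `truth` list (copy_counts, mutations, indels, sites, large_effects,
#'   breakpoints)
#' @export
polyploidize <- function(ancestor, cfg = polyploid_config()) {
  validate_polyploid_config(cfg)
  genes <- ancestor$genes
  zr <- .zone_rates(cfg)

  withr::with_seed(cfg$seed, {
    k <- .sample_dist(cfg$copy_count_dist, nrow(genes))
    copy_counts <- data.frame(gene_id = genes$gene_id, k = k,
                              stringsAsFactors = FALSE)

    mut_list <- list(); indel_list <- list(); site_list <- list()
    le_list <- list()
    n_total <- sum(k)
    copy_cds <- character(n_total); copy_up <- character(n_total)
    copy_names <- character(n_total); n_copy <- 0L
    copy_rows <- list()

    anc_cds_chr <- as.character(ancestor$cds)
    anc_up_chr <- as.character(ancestor$upstream)
    for (gi in seq_len(nrow(genes))) {
      g <- genes$gene_id[gi]
      L <- genes$cds_len[gi]
      anc_cds <- .str_to_chars(anc_cds_chr[[g]])
      anc_up <- .str_to_chars(anc_up_chr[[g]])
      kg <- k[gi]
      copy_ids <- sprintf("%s_c%02d", g, seq_len(kg))

      ## planted multiplicity sites (shared positions across copies)
      n_sites <- stats::rpois(1, cfg$snv_sites_per_gene)
      interior <- if (L > 6) 4:(L - 3) else integer(0)
      site_pos <- integer(0)
      site_alleles <- list()  # per site: character vector length kg
      if (n_sites > 0 && length(interior) > 0) {
        cand <- sample(interior, min(n_sites, length(interior)))
        for (p in cand) {
          m_max <- min(kg, 4L)
          md <- cfg$multiplicity_dist[as.integer(names(cfg$multiplicity_dist)) <= m_max]
          if (length(md) == 0L || sum(md) == 0) next
          md <- md / sum(md)
          m <- .sample_dist(md, 1)
          ref <- anc_cds[p]
          valid_alts <- .sense_alts(anc_cds, p)
          if (m == 1L) {
            if (length(valid_alts) == 0L) next
            alleles <- sample(valid_alts, 1)
          } else {
            if (length(valid_alts) < m - 1L) next
            alleles <- c(ref, sample(valid_alts, m - 1L))
          }
          ## surjective assignment: each allele appears on >= 1 copy
          assign <- c(alleles,
                      sample(alleles, kg - length(alleles), replace = TRUE))
          assign <- assign[sample.int(kg)]
          site_pos <- c(site_pos, p)
          site_alleles[[length(site_alleles) + 1L]] <- assign
          site_list[[length(site_list) + 1L]] <- data.frame(
            gene_id = g, cds_pos = p, ref = ref,
            multiplicity = length(unique(assign)),
            alleles = paste(sort(unique(assign)), collapse = ","),
            stringsAsFactors = FALSE)
        }
      }

      ## planted large-effect substitution (at most one per gene)
      le_plan <- NULL
      if (stats::runif(1) < cfg$large_effect_rate && L >= 9) {
        le_copy <- sample.int(kg, 1)
        le_type <- sample(c("premature_stop", "start_loss", "stop_loss"), 1)
        le_plan <- .plan_large_effect(anc_cds, L, le_type, site_pos)
        if (!is.null(le_plan)) le_plan$copy <- le_copy
      }

      for (ci in seq_len(kg)) {
        cid <- copy_ids[ci]
        cds <- anc_cds
        up <- anc_up
        blocked <- site_pos
        ## per-copy mutation accumulators (vectors; one data.frame per copy)
        m_region <- character(0); m_pos <- integer(0)
        m_ref <- character(0); m_alt <- character(0); m_origin <- character(0)
        rec <- function(region, pos, ref, alt, origin) {
          m_region <<- c(m_region, region); m_pos <<- c(m_pos, pos)
          m_ref <<- c(m_ref, ref); m_alt <<- c(m_alt, alt)
          m_origin <<- c(m_origin, origin)
        }

        ## planted multiplicity alleles
        if (length(site_pos) > 0) {
          for (si in seq_along(site_pos)) {
            allele <- site_alleles[[si]][ci]
            p <- site_pos[si]
            if (allele != cds[p]) {
              rec("cds", p, cds[p], allele, "site")
              cds[p] <- allele
            }
          }
        }

        ## planted large-effect substitution
        if (!is.null(le_plan) && le_plan$copy == ci) {
          p <- le_plan$pos
          rec("cds", p, cds[p], le_plan$alt, "large_effect")
          le_list[[length(le_list) + 1L]] <- data.frame(
            copy_id = cid, gene_id = g, cds_pos = p, ref = cds[p],
            alt = le_plan$alt, effect = le_plan$effect,
            stringsAsFactors = FALSE)
          cds[p] <- le_plan$alt
          blocked <- c(blocked, p)
        }

        ## background CDS substitutions (interior codons, sense-preserving)
        if (cfg$sub_rate_cds > 0 && L > 6) {
          hits <- which(stats::runif(L) < cfg$sub_rate_cds)
          hits <- setdiff(hits, c(1:3, (L - 2):L, blocked))
          for (p in hits) {
            alts <- .sense_alts(cds, p)
            if (length(alts) == 0L) next
            alt <- if (length(alts) == 1L) alts else sample(alts, 1)
            rec("cds", p, cds[p], alt, "background")
            cds[p] <- alt
          }
        }

        ## upstream substitutions by zone (coordinates 1..1000, 1000 abuts ATG)
        zones <- list(up100 = list(idx = 901:1000, rate = zr$z100),
                      up500 = list(idx = 501:900, rate = zr$z500),
                      up1000 = list(idx = 1:500, rate = zr$z1000))
        for (zn in names(zones)) {
          z <- zones[[zn]]
          if (z$rate <= 0) next
          hits <- z$idx[stats::runif(length(z$idx)) < z$rate]
          if (length(hits) == 0L) next
          refs <- up[hits]
          ## uniform choice among the 3 alternative bases, vectorised
          altmat <- vapply(refs, function(b) setdiff(.BASES, b),
                           character(3))
          alts <- altmat[cbind(sample.int(3, length(hits), replace = TRUE),
                               seq_along(hits))]
          rec(rep(zn, length(hits)), hits, refs, alts,
              rep("background", length(hits)))
          up[hits] <- alts
        }
        if (length(m_pos) > 0L) {
          mut_list[[length(mut_list) + 1L]] <- data.frame(
            copy_id = cid, gene_id = g, region = m_region, position = m_pos,
            ref = unname(m_ref), alt = unname(m_alt), origin = m_origin,
            stringsAsFactors = FALSE)
        }

        ## indels: CDS (frame-mix model) and upstream
        cds_indels <- .draw_indels(cfg, region = "cds", seq_len = L,
                                   blocked = blocked)
        up_indels <- .draw_indels(cfg, region = "upstream", seq_len = 1000,
                                  blocked = integer(0))
        for (d in list(cds_indels, up_indels)) {
          if (nrow(d) > 0L) {
            d$copy_id <- cid; d$gene_id <- g
            indel_list[[length(indel_list) + 1L]] <- d
          }
        }
        cds <- .apply_indels(cds, cds_indels)
        up <- .apply_indels(up, up_indels)

        n_copy <- n_copy + 1L
        copy_names[n_copy] <- cid
        copy_cds[n_copy] <- .chars_to_str(cds)
        copy_up[n_copy] <- .chars_to_str(up)
        copy_rows[[length(copy_rows) + 1L]] <- data.frame(
          copy_id = cid, gene_id = g, copy_index = ci,
          chromosome = paste0(genes$chromosome[gi], "_h", ci),
          order_index = genes$order_index[gi],
          strand = genes$strand[gi], stringsAsFactors = FALSE)
      }
    }

    copies <- do.call(rbind, copy_rows)
    layout <- copies[order(copies$chromosome, copies$order_index), ]
    layout$position <- stats::ave(seq_len(nrow(layout)), layout$chromosome,
                                  FUN = seq_along)
    rownames(layout) <- NULL

    truth <- list(
      copy_counts = copy_counts,
      mutations = .rbind_or_empty(mut_list,
        c("copy_id", "gene_id", "region", "position", "ref", "alt", "origin")),
      indels = .rbind_or_empty(indel_list,
        c("region", "position", "type", "length", "inserted_seq", "copy_id",
          "gene_id")),
      sites = .rbind_or_empty(site_list,
        c("gene_id", "cds_pos", "ref", "multiplicity", "alleles")),
      large_effects = .rbind_or_empty(le_list,
        c("copy_id", "gene_id", "cds_pos", "ref", "alt", "effect")),
      breakpoints = data.frame(type = character(0), chromosome = character(0),
                               left_copy = character(0),
                               right_copy = character(0),
                               stringsAsFactors = FALSE)
    )

    cds_set <- Biostrings::DNAStringSet(stats::setNames(copy_cds, copy_names))
    up_set <- Biostrings::DNAStringSet(stats::setNames(copy_up, copy_names))
    structure(list(ancestor = ancestor, config = cfg, copies = copies,
                   layout = layout, copy_cds = cds_set,
                   copy_upstream = up_set, truth = truth),
              class = "polyploid_sim")
  })
}

.rbind_or_empty <- function(lst, cols) {
  if (length(lst) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  out <- as.data.frame(data.table::rbindlist(lst))
  rownames(out) <- NULL
  out
}

## plan a single large-effect substitution of the requested type; returns
## list(pos, alt, effect) in CDS coordinates, or NULL if impossible.
.plan_large_effect <- function(anc_cds, L, type, blocked) {
  if (type == "start_loss") {
    p <- sample(1:3, 1)
    alt <- sample(setdiff(.BASES, anc_cds[p]), 1)
    return(list(pos = p, alt = alt, effect = "start_loss"))
  }
  if (type == "stop_loss") {
    stop_start <- L - 2
    for (off in sample(0:2)) {
      p <- stop_start + off
      cod <- anc_cds[stop_start:L]
      for (alt in sample(setdiff(.BASES, anc_cds[p]))) {
        cod2 <- cod; cod2[off + 1] <- alt
        if (!(paste(cod2, collapse = "") %in% .STOP_CODONS)) {
          return(list(pos = p, alt = alt, effect = "stop_loss"))
        }
      }
    }
    return(NULL)
  }
  ## premature stop: find an interior codon admitting a single-base change
  ## to a stop codon
  n_cod <- L / 3
  for (ci in sample(2:(n_cod - 1), min(20L, n_cod - 2L))) {
    s <- (ci - 1) * 3 + 1
    cod <- anc_cds[s:(s + 2)]
    hits <- list()
    for (off in 0:2) {
      p <- s + off
      if (p %in% blocked) next
      for (alt in setdiff(.BASES, cod[off + 1])) {
        cod2 <- cod; cod2[off + 1] <- alt
        if (paste(cod2, collapse = "") %in% .STOP_CODONS) {
          hits[[length(hits) + 1L]] <- list(pos = p, alt = alt)
        }
      }
    }
    if (length(hits) > 0) {
      h <- hits[[sample.int(length(hits), 1)]]
      return(list(pos = h$pos, alt = h$alt, effect = "premature_stop"))
    }
  }
  NULL
}

## draw indel events for one copy/region; positions in ancestor coordinates.
.draw_indels <- function(cfg, region, seq_len, blocked) {
  empty <- data.frame(region = character(0), position = integer(0),
                      type = character(0), length = integer(0),
                      inserted_seq = character(0), stringsAsFactors = FALSE)
  if (cfg$indel_rate <= 0) return(empty)
  n <- stats::rpois(1, cfg$indel_rate * seq_len / 1000)
  if (n == 0L) return(empty)
  lens <- as.integer(names(cfg$indel_len_dist))
  v_pos <- integer(0); v_type <- character(0); v_len <- integer(0)
  v_ins <- character(0)
  for (i in seq_len(n)) {
    if (region == "cds") {
      fp <- stats::runif(1) < cfg$frame_preserving_frac_cds
      ok <- if (fp) lens %% 3 == 0 else lens %% 3 != 0
      if (!any(ok)) next
      d <- cfg$indel_len_dist[ok] / sum(cfg$indel_len_dist[ok])
      len <- .sample_dist(d, 1)
      lo <- 4L; hi <- seq_len - 3L
    } else {
      len <- .sample_dist(cfg$indel_len_dist, 1)
      lo <- 1L; hi <- seq_len
    }
    type <- sample(c("ins", "del"), 1)
    placed <- FALSE
    for (try in 1:20) {
      if (type == "ins") {
        if (hi - 1L < lo) break
        p <- sample(lo:(hi - 1L), 1)
        win <- integer(0)
      } else {
        if (hi - len < lo) break
        p <- sample(lo:(hi - len), 1)
        win <- p:(p + len - 1L)
      }
      if (length(intersect(win, blocked)) == 0L) { placed <- TRUE; break }
    }
    if (!placed) next
    v_pos <- c(v_pos, p); v_type <- c(v_type, type); v_len <- c(v_len, len)
    v_ins <- c(v_ins, if (type == "ins")
      paste(sample(.BASES, len, replace = TRUE), collapse = "") else "")
  }
  if (length(v_pos) == 0L) return(empty)
  data.frame(region = region, position = v_pos, type = v_type,
             length = v_len, inserted_seq = v_ins, stringsAsFactors = FALSE)
}

#' Reconstruct a copy sequence from the ground truth
#'
#' Applies the recorded substitutions and indels for one copy to the
#' ancestral sequences; used to verify that every emitted sequence difference
#' is traceable to the truth records.
#'
#' @param sim a `polyploid_sim`
#' @param copy_id copy identifier
#' @return list with `cds` and `upstream` character strings
#' @export
reconstruct_copy <- function(sim, copy_id) {
  gene <- sim$copies$gene_id[match(copy_id, sim$copies$copy_id)]
  if (is.na(gene)) stop("unknown copy_id: ", copy_id)
  cds <- .str_to_chars(as.character(sim$ancestor$cds[[gene]]))
  up <- .str_to_chars(as.character(sim$ancestor$upstream[[gene]]))
  mut <- sim$truth$mutations
  mut <- mut[mut$copy_id == copy_id, , drop = FALSE]
  for (i in seq_len(nrow(mut))) {
    if (mut$region[i] == "cds") cds[mut$position[i]] <- mut$alt[i]
    else up[mut$position[i]] <- mut$alt[i]
  }
  ind <- sim$truth$indels
  ind <- ind[ind$copy_id == copy_id, , drop = FALSE]
  cds <- .apply_indels(cds, ind[ind$region == "cds", , drop = FALSE])
  up <- .apply_indels(up, ind[ind$region == "upstream", , drop = FALSE])
  list(cds = .chars_to_str(cds), upstream = .chars_to_str(up))
}

#' Plant chromosomal rearrangements
#'
#' Inversions reverse a contiguous run of >= 2 gene copies and flip their
#' strands; translocations move a run into a different chromosome context.
#' Event runs are sampled disjoint and non-adjacent so that each junction
#' created is attributable to exactly one event; every created junction is
#' recorded as a breakpoint (adjacent pair of copy ids).
#'
#' @param sim a `polyploid_sim`
#' @param inversion_rate,translocation_rate events per 100 gene copies;
#'   default to the simulation's config
#' @param seed integer seed (default derived from config seed)
#' @return the modified `polyploid_sim` with updated `layout` and
#'   `truth$breakpoints`
#' @export
plant_rearrangements <- function(sim,
                                 inversion_rate = sim$config$inversion_rate,
                                 translocation_rate = sim$config$translocation_rate,
                                 seed = sim$config$seed + 1L) {
  if (inversion_rate < 0 || translocation_rate < 0) {
    stop("rearrangement rates must be >= 0")
  }
  if (inversion_rate == 0 && translocation_rate == 0) return(sim)
  layout <- sim$layout
  n <- nrow(layout)
  withr::with_seed(as.integer(seed), {
    n_inv <- stats::rpois(1, inversion_rate * n / 100)
    n_tra <- stats::rpois(1, translocation_rate * n / 100)
    chroms <- split(layout$copy_id, layout$chromosome)
    strands <- stats::setNames(layout$strand, layout$copy_id)
    used <- character(0)   # copies inside an event run or adjacent to one
    bp <- list()

    pick_run <- function(min_len = 2L, max_len = 5L) {
      for (try in 1:50) {
        cn <- sample(names(chroms), 1)
        v <- chroms[[cn]]
        if (length(v) < min_len + 2L) next
        len <- sample(min_len:min(max_len, length(v) - 2L), 1)
        s <- sample(2:(length(v) - len), 1)  # keep run off the ends
        run <- s:(s + len - 1L)
        zone <- v[max(1, s - 1L):min(length(v), s + len)]
        if (length(intersect(zone, used)) > 0L) next
        return(list(chrom = cn, s = s, len = len))
      }
      NULL
    }

    for (e in seq_len(n_inv)) {
      r <- pick_run()
      if (is.null(r)) { warning("inversion skipped: no eligible run"); next }
      v <- chroms[[r$chrom]]
      run <- r$s:(r$s + r$len - 1L)
      run_ids <- v[run]
      v[run] <- rev(run_ids)
      strands[run_ids] <- ifelse(strands[run_ids] == "+", "-", "+")
      chroms[[r$chrom]] <- v
      used <- c(used, v[max(1, r$s - 1L):min(length(v), r$s + r$len)])
      bp[[length(bp) + 1L]] <- data.frame(
        type = "inversion", chromosome = r$chrom,
        left_copy = v[r$s - 1L], right_copy = v[r$s],
        stringsAsFactors = FALSE)
      bp[[length(bp) + 1L]] <- data.frame(
        type = "inversion", chromosome = r$chrom,
        left_copy = v[r$s + r$len - 1L], right_copy = v[r$s + r$len],
        stringsAsFactors = FALSE)
    }

    for (e in seq_len(n_tra)) {
      if (length(chroms) < 2L) { warning("translocation skipped: single chromosome"); next }
      r <- pick_run()
      if (is.null(r)) { warning("translocation skipped: no eligible run"); next }
      dest <- setdiff(names(chroms), r$chrom)
      placed <- FALSE
      for (try in 1:50) {
        dn <- sample(dest, 1)
        w <- chroms[[dn]]
        if (length(w) < 4L) next
        ip <- sample(2:(length(w) - 2L), 1)  # insert after position ip
        zone <- w[ip:(ip + 1L)]
        if (length(intersect(zone, used)) > 0L) next
        placed <- TRUE
        break
      }
      if (!placed) { warning("translocation skipped: no insertion point"); next }
      v <- chroms[[r$chrom]]
      run <- r$s:(r$s + r$len - 1L)
      run_ids <- v[run]
      left_src <- v[r$s - 1L]; right_src <- v[r$s + r$len]
      chroms[[r$chrom]] <- v[-run]
      w <- chroms[[dn]]
      chroms[[dn]] <- append(w, run_ids, after = ip)
      used <- c(used, run_ids, left_src, right_src, w[ip], w[ip + 1L])
      bp[[length(bp) + 1L]] <- data.frame(
        type = "translocation", chromosome = r$chrom,
        left_copy = left_src, right_copy = right_src,
        stringsAsFactors = FALSE)
      bp[[length(bp) + 1L]] <- data.frame(
        type = "translocation", chromosome = dn,
        left_copy = w[ip], right_copy = run_ids[1],
        stringsAsFactors = FALSE)
      bp[[length(bp) + 1L]] <- data.frame(
        type = "translocation", chromosome = dn,
        left_copy = run_ids[r$len], right_copy = w[ip + 1L],
        stringsAsFactors = FALSE)
    }

    ## rebuild layout from the chromosome lists
    new_layout <- do.call(rbind, lapply(names(chroms), function(cn) {
      ids <- chroms[[cn]]
      idx <- match(ids, sim$layout$copy_id)
      data.frame(copy_id = ids,
                 gene_id = sim$layout$gene_id[idx],
                 copy_index = sim$layout$copy_index[idx],
                 chromosome = cn,
                 order_index = sim$layout$order_index[idx],
                 strand = unname(strands[ids]),
                 position = seq_along(ids),
                 stringsAsFactors = FALSE)
    }))
    rownames(new_layout) <- NULL
    sim$layout <- new_layout
    sim$truth$breakpoints <- rbind(sim$truth$breakpoints,
                                   .rbind_or_empty(bp, names(sim$truth$breakpoints)))
    sim
  })
}

#' Fragment the polyploid genome into contigs
#'
#' Cuts each chromosome of the layout into contigs whose gene counts follow
#' `genes_per_contig_dist` (the final contig of a chromosome may be
#' truncated).  Contig sequences carry, per gene, the 1,000-nt upstream
#' region followed by the CDS (reverse-complemented for minus-strand genes),
#' separated by neutral spacer sequence.
#'
#' @param sim a `polyploid_sim`
#' @param genes_per_contig_dist named probability vector; defaults to the
#'   simulation's config
#' @param seed integer seed
#' @param spacer_len length of neutral spacer between genes (nt)
#' @return an object of class `contig_set`: `contig_map` (data.frame:
#'   contig_id, copy_id, order, strand, cds_start, cds_end, up_start,
#'   up_end), `sequences` (DNAStringSet), and `contigs` (per-contig summary)
#' @export
fragment_genome <- function(sim,
                            genes_per_contig_dist = sim$config$genes_per_contig_dist,
                            seed = sim$config$seed + 2L,
                            spacer_len = 200L) {
  .check_dist(genes_per_contig_dist, "genes_per_contig_dist")
  layout <- sim$layout
  withr::with_seed(as.integer(seed), {
    map_rows <- list(); seqs <- character(0); contig_rows <- list()
    cnum <- 0L
    for (cn in unique(layout$chromosome)) {
      block <- layout[layout$chromosome == cn, , drop = FALSE]
      i <- 1L
      while (i <= nrow(block)) {
        g <- .sample_dist(genes_per_contig_dist, 1)
        g <- min(g, nrow(block) - i + 1L)
        cnum <- cnum + 1L
        cid <- sprintf("ctg%05d", cnum)
        members <- block[i:(i + g - 1L), , drop = FALSE]
        pos <- 0L
        seq_parts <- character(0)
        for (j in seq_len(nrow(members))) {
          sp <- paste(sample(.BASES, spacer_len, replace = TRUE),
                      collapse = "")
          up <- as.character(sim$copy_upstream[[members$copy_id[j]]])
          cds <- as.character(sim$copy_cds[[members$copy_id[j]]])
          cassette <- paste0(up, cds)
          if (members$strand[j] == "-") {
            cassette <- as.character(
              Biostrings::reverseComplement(Biostrings::DNAString(cassette)))
            cds_start <- pos + spacer_len + 1L
            cds_end <- cds_start + nchar(cds) - 1L
            up_start <- cds_end + 1L
            up_end <- up_start + nchar(up) - 1L
          } else {
            up_start <- pos + spacer_len + 1L
            up_end <- up_start + nchar(up) - 1L
            cds_start <- up_end + 1L
            cds_end <- cds_start + nchar(cds) - 1L
          }
          seq_parts <- c(seq_parts, sp, cassette)
          map_rows[[length(map_rows) + 1L]] <- data.frame(
            contig_id = cid, copy_id = members$copy_id[j],
            gene_id = members$gene_id[j], order = j,
            strand = members$strand[j],
            cds_start = cds_start, cds_end = cds_end,
            up_start = up_start, up_end = up_end,
            chromosome = cn, chrom_position = members$position[j],
            stringsAsFactors = FALSE)
          pos <- pos + spacer_len + nchar(cassette)
        }
        seqs[cid] <- paste(seq_parts, collapse = "")
        contig_rows[[length(contig_rows) + 1L]] <- data.frame(
          contig_id = cid, chromosome = cn, n_genes = g,
          first_position = members$position[1],
          last_position = members$position[nrow(members)],
          stringsAsFactors = FALSE)
        i <- i + g
      }
    }
    structure(list(
      contig_map = do.call(rbind, map_rows),
      contigs = do.call(rbind, contig_rows),
      sequences = Biostrings::DNAStringSet(seqs)),
      class = "contig_set")
  })
}

#' Simulate per-copy expression states and abundances
#'
#' Each copy is expressed with probability `expressed_frac`; an expressed
#' copy is antisense-only with probability `antisense_frac`.  Expressed
#' orientations receive FPKM drawn from a log-normal truncated above 1 in
#' every sample; silent sense orientations receive FPKM in `[0, 1]`.
#' Antisense records are emitted only for antisense-active copies.
#'
#' @param sim a `polyploid_sim`
#' @param expressed_frac,antisense_frac fractions in `[0, 1]`
#' @param samples sample labels
#' @param fpkm_meanlog,fpkm_sdlog log-normal parameters
#' @param seed integer seed
#' @return list with `abundance` (data.frame: copy_id, sample, orientation,
#'   fpkm) and `truth` (data.frame: copy_id, state in
#'   none/sense/antisense_only)
#' @export
simulate_expression <- function(sim,
                                expressed_frac = sim$config$expressed_frac,
                                antisense_frac = sim$config$antisense_frac,
                                samples = c("L", "I1", "I5"),
                                fpkm_meanlog = sim$config$fpkm_meanlog,
                                fpkm_sdlog = sim$config$fpkm_sdlog,
                                seed = sim$config$seed + 3L) {
  if (expressed_frac < 0 || expressed_frac > 1 ||
      antisense_frac < 0 || antisense_frac > 1) {
    stop("fractions must lie in [0, 1]")
  }
  ids <- sim$copies$copy_id
  withr::with_seed(as.integer(seed), {
    expressed <- stats::runif(length(ids)) < expressed_frac
    anti <- expressed & (stats::runif(length(ids)) < antisense_frac)
    state <- ifelse(!expressed, "none",
                    ifelse(anti, "antisense_only", "sense"))

    rtrunc_fpkm <- function(n) {
      lo <- stats::plnorm(1, fpkm_meanlog, fpkm_sdlog)
      stats::qlnorm(stats::runif(n, lo, 1), fpkm_meanlog, fpkm_sdlog)
    }

    rows <- list()
    for (smp in samples) {
      fpkm_sense <- ifelse(state == "sense", rtrunc_fpkm(length(ids)),
                           stats::runif(length(ids)))
      rows[[length(rows) + 1L]] <- data.frame(
        copy_id = ids, sample = smp, orientation = "sense",
        fpkm = fpkm_sense, stringsAsFactors = FALSE)
      if (any(state == "antisense_only")) {
        w <- which(state == "antisense_only")
        rows[[length(rows) + 1L]] <- data.frame(
          copy_id = ids[w], sample = smp, orientation = "antisense",
          fpkm = rtrunc_fpkm(length(w)), stringsAsFactors = FALSE)
      }
    }
    abundance <- do.call(rbind, rows)
    rownames(abundance) <- NULL
    list(abundance = abundance,
         truth = data.frame(copy_id = ids, state = state,
                            stringsAsFactors = FALSE))
  })
}
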