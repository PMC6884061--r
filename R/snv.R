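## Variant sites across homo(eo)logous copies against the diploid reference:
## allelic multiplicity (mono- to tetra-allelic), large-effect consequences,
## per-gene tallies, and binomial functional enrichment.

.EFFECT_PRIORITY <- c("frameshift", "premature_stop", "stop_loss",
                      "start_loss", "splice_disruption", "none")

#' Single-exon gene model from a CDS
#'
#' Wraps a plain CDS (no introns) as a `gene_model` so that the effect
#' classifier applies.
#'
#' @param cds CDS string (ATG ... stop)
#' @return a `gene_model`
#' @export
gene_model_from_cds <- function(cds) {
  cds <- as.character(cds)
  structure(list(genomic = cds,
                 exons = data.frame(start = 1L, end = nchar(cds)),
                 introns = data.frame(start = integer(0), end = integer(0)),
                 cds = cds),
            class = "gene_model")
}

## walk one global alignment (query = reference CDS, subject = copy) and
## return the copy's allele at every reference position (NA under deletions)
## plus its indel events in reference coordinates.
.walk_alignment <- function(aln, ref_len) {
  if (aln$n_gap_columns == 0L && aln$q_start == 0L &&
      aln$q_end == ref_len) {
    ## gapless full-length alignment: columns map 1:1 to reference positions
    return(list(allele = .str_to_chars(aln$b_aln),
                indels = .rbind_or_empty(list(), c("type", "pos", "length"))))
  }
  a <- .str_to_chars(aln$a_aln)
  b <- .str_to_chars(aln$b_aln)
  allele <- rep(NA_character_, ref_len)
  indels <- list()
  rpos <- aln$q_start  # 0-based count of reference bases consumed
  i <- 1L
  n <- length(a)
  while (i <= n) {
    if (a[i] != "-" && b[i] != "-") {
      rpos <- rpos + 1L
      allele[rpos] <- b[i]
      i <- i + 1L
    } else if (b[i] == "-") {
      ## deletion in the copy
      j <- i
      while (j <= n && b[j] == "-" && a[j] != "-") j <- j + 1L
      len <- j - i
      indels[[length(indels) + 1L]] <- data.frame(
        type = "del", pos = rpos + 1L, length = len,
        stringsAsFactors = FALSE)
      rpos <- rpos + len
      i <- j
    } else {
      ## insertion in the copy
      j <- i
      while (j <= n && a[j] == "-" && b[j] != "-") j <- j + 1L
      indels[[length(indels) + 1L]] <- data.frame(
        type = "ins", pos = rpos, length = j - i,
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  list(allele = allele,
       indels = .rbind_or_empty(indels, c("type", "pos", "length")))
}

#' Call variant sites across homo(eo)log copies
#'
#' Compares each copy to its anchor (reference) CDS along the supplied
#' global alignments.  Copies with mapping quality present and `<= min_mapq`
#' are excluded (strict `>` filter); anchors retaining fewer than
#' `min_contigs` copies yield no sites.  A substitution site is emitted at
#' every reference position where at least one copy carries a different
#' base; copy indels are emitted as separate sites.  Substitution sites are
#' classified for large-effect consequences against the reference gene
#' model.
#'
#' @param alignments list of `pairwise_alignment` objects with the anchor
#'   CDS as query and a copy as subject
#' @param ref_seqs named [Biostrings::DNAStringSet] (or character) of anchor
#'   CDSs
#' @param min_mapq mapping-quality threshold; copies kept only when
#'   `map_quality > min_mapq` (records without a mapq are kept)
#' @param min_contigs minimum aligned copies per anchor (default 2)
#' @return data.frame of sites: `gene_id`, `pos` (1-based CDS), `type`
#'   (sub/ins/del), `ref`, `alts` (comma-separated non-reference alleles),
#'   `observed` (comma-separated `copy=allele` pairs), `multiplicity`,
#'   `n_observed`, `length` (indels), `effect`
#' @export
call_sites <- function(alignments, ref_seqs, min_mapq = 20L,
                       min_contigs = 2L) {
  keep <- vapply(alignments, function(a) {
    mq <- a$map_quality
    is.null(mq) || is.na(mq) || mq > min_mapq
  }, TRUE)
  alignments <- alignments[keep]
  anchors <- vapply(alignments, `[[`, "", "query_id")
  out <- list()
  for (an in unique(anchors)) {
    alns <- alignments[anchors == an]
    if (length(alns) < min_contigs) next
    ref <- as.character(ref_seqs[[an]])
    L <- nchar(ref)
    ref_chars <- .str_to_chars(ref)
    model <- gene_model_from_cds(ref)
    walks <- lapply(alns, .walk_alignment, ref_len = L)
    copy_ids <- vapply(alns, `[[`, "", "subject_id")
    names(walks) <- copy_ids

    allele_mat <- do.call(cbind, lapply(walks, `[[`, "allele"))
    diff_any <- rowSums(allele_mat != ref_chars, na.rm = TRUE) > 0
    for (p in which(diff_any)) {
      obs <- allele_mat[p, ]
      obs <- obs[!is.na(obs)]
      alts <- sort(unique(obs[obs != ref_chars[p]]))
      effects <- vapply(alts, function(alt) {
        classify_effect(list(pos = p, type = "sub", alt = alt), model)
      }, "")
      eff <- .EFFECT_PRIORITY[min(match(effects, .EFFECT_PRIORITY))]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = an, pos = p, type = "sub", ref = ref_chars[p],
        alts = paste(alts, collapse = ","),
        observed = paste(sprintf("%s=%s", names(obs), obs), collapse = ","),
        multiplicity = length(unique(obs)),
        n_observed = length(obs),
        length = NA_integer_,
        effect = eff, stringsAsFactors = FALSE)
    }

    for (ci in seq_along(walks)) {
      ind <- walks[[ci]]$indels
      for (r in seq_len(nrow(ind))) {
        eff <- if (ind$length[r] %% 3L != 0L) "frameshift" else "none"
        out[[length(out) + 1L]] <- data.frame(
          gene_id = an, pos = ind$pos[r], type = ind$type[r],
          ref = NA_character_,
          alts = sprintf("%s%d", toupper(substr(ind$type[r], 1, 1)),
                         ind$length[r]),
          observed = copy_ids[ci],
          multiplicity = NA_integer_, n_observed = 1L,
          length = ind$length[r], effect = eff,
          stringsAsFactors = FALSE)
      }
    }
  }
  .rbind_or_empty(out, c("gene_id", "pos", "type", "ref", "alts", "observed",
                         "multiplicity", "n_observed", "length", "effect"))
}

#' Allelic multiplicity of a site
#'
#' The number of distinct alleles among the observed copy alleles; the
#' reference allele counts when some copy carries it.
#'
#' @param observed character vector of copy alleles at the site
#' @return integer multiplicity
#' @export
site_multiplicity <- function(observed) {
  observed <- observed[!is.na(observed)]
  if (length(observed) == 0L) stop("site has no observed alleles")
  length(unique(observed))
}

#' Per-gene variant tallies
#'
#' One row per gene: total sites, counts per multiplicity class (1-4), and
#' counts per base change (12-cell `ref>alt` table over substitution sites;
#' each distinct alternative allele of a site contributes one tally).
#'
#' @param sites data.frame from [call_sites()]
#' @param collapse_ref_base collapse the 12 `ref>alt` cells to 4 reference
#'   -base classes
#' @return data.frame with one row per gene plus class columns; row totals
#'   over genes sum to the number of sites
#' @export
count_snvs_per_gene <- function(sites, collapse_ref_base = FALSE) {
  genes <- sort(unique(sites$gene_id))
  changes <- as.vector(outer(.BASES, .BASES, function(r, a)
    paste0(r, ">", a)))
  changes <- changes[substr(changes, 1, 1) != substr(changes, 3, 3)]
  rows <- lapply(genes, function(g) {
    s <- sites[sites$gene_id == g, , drop = FALSE]
    sub <- s[s$type == "sub", , drop = FALSE]
    mult <- table(factor(sub$multiplicity, levels = 1:4))
    cc <- stats::setNames(rep(0L, length(changes)), changes)
    for (i in seq_len(nrow(sub))) {
      for (alt in strsplit(sub$alts[i], ",", fixed = TRUE)[[1]]) {
        key <- paste0(sub$ref[i], ">", alt)
        cc[key] <- cc[key] + 1L
      }
    }
    out <- data.frame(gene_id = g, n_total = nrow(s), n_sub = nrow(sub),
                      n_indel = nrow(s) - nrow(sub),
                      stringsAsFactors = FALSE)
    for (m in 1:4) out[[paste0("mult", m)]] <- as.integer(mult[as.character(m)])
    if (collapse_ref_base) {
      for (b in .BASES) {
        out[[paste0("ref", b)]] <-
          sum(cc[substr(names(cc), 1, 1) == b])
      }
    } else {
      for (k in changes) out[[k]] <- cc[[k]]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binomial functional enrichment test
#'
#' For each annotation term among the gene set, tests whether the term's
#' frequency in the set exceeds its background proportion using the upper
#' binomial tail: `p_value = P(X >= k)`, `X ~ Binomial(n, p)` with `n` the
#' gene-set size and `p` the background proportion of the term.
#'
#' @param geneset character vector of gene ids
#' @param annotation data.frame with columns `gene_id`, `term` covering the
#'   gene set
#' @param background data.frame with columns `gene_id`, `term` covering all
#'   annotated genes; every gene-set gene must appear in it
#' @param alpha significance threshold (results flagged at `p_value < alpha`)
#' @param correct `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values in an extra column
#' @return data.frame sorted by p-value: `term`, `k`, `n`, `p`, `p_value`,
#'   `significant` (and `p_adjust` when corrected)
#' @export
binomial_enrichment <- function(geneset, annotation, background,
                                alpha = 0.05, correct = c("none", "BH")) {
  correct <- match.arg(correct)
  if (!all(geneset %in% background$gene_id)) {
    missing <- setdiff(geneset, background$gene_id)
    stop("gene(s) absent from the background: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  n <- length(unique(geneset))
  bg_genes <- unique(background$gene_id)
  ann <- annotation[annotation$gene_id %in% geneset, , drop = FALSE]
  terms <- sort(unique(ann$term))
  rows <- list()
  for (tm in terms) {
    bg_hit <- unique(background$gene_id[background$term == tm])
    if (length(bg_hit) == 0L) {
      warning("term absent from the background, skipped: ", tm)
      next
    }
    p <- length(bg_hit) / length(bg_genes)
    k <- length(unique(ann$gene_id[ann$term == tm]))
    p_value <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term = tm, k = k, n = n, p = p, p_value = p_value,
      stringsAsFactors = FALSE)
  }
  out <- .rbind_or_empty(rows, c("term", "k", "n", "p", "p_value"))
  if (nrow(out) > 0L) {
    out <- out[order(out$p_value, out$term), , drop = FALSE]
    rownames(out) <- NULL
    if (correct == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
    out$significant <- out$p_value < alpha
  }
  out
}

#' Write variant sites as VCF v4.2
#'
#' One record per site; CHROM is the anchor gene id and POS the 1-based CDS
#' coordinate.  INFO carries MULT (allelic multiplicity), EFFECT and NCOPIES
#' (observed copies).
#'
#' @param sites data.frame from [call_sites()]
#' @param path output path
#' @export
write_sites_vcf <- function(sites, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MULT,Number=1,Type=Integer,Description=\"Allelic multiplicity across polyploid copies\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Predicted large-effect class\">",
    "##INFO=<ID=NCOPIES,Number=1,Type=Integer,Description=\"Copies observed at the site\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    ref <- if (is.na(s$ref)) "N" else s$ref
    alt <- gsub(",", ",", s$alts, fixed = TRUE)
    info <- sprintf("MULT=%s;EFFECT=%s;NCOPIES=%d",
                    ifelse(is.na(s$multiplicity), ".",
                           as.character(s$multiplicity)),
                    s$effect, s$n_observed)
    body[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       s$gene_id, s$pos, ref, alt, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
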