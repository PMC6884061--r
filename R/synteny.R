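## Ortholog grouping by union-find over filtered cross-genome alignments,
## single-reference-copy anchor selection, collinear block detection, and a
## Monte Carlo chromosome-fragmentation null for block counts.

#' Disjoint-set union (union-find) over labelled items
#'
#' Path-halving find with union by index; exposed for reuse and testing.
#'
#' @param items character vector of item labels
#' @param edges two-column matrix or data.frame of item label pairs
#' @return integer vector of component ids (1-based, dense), named by item
#' @export
union_find <- function(items, edges) {
  n <- length(items)
  parent <- seq_len(n)
  idx <- stats::setNames(seq_len(n), items)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]  # path halving
      x <- parent[x]
    }
    x
  }
  if (length(edges) > 0L && nrow(edges) > 0L) {
    a <- idx[as.character(edges[[1]])]
    b <- idx[as.character(edges[[2]])]
    if (anyNA(a) || anyNA(b)) stop("edge references unknown item")
    for (i in seq_along(a)) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- match(roots, unique(roots))
  stats::setNames(comp, items)
}

#' Build putative ortholog groups from cross-genome alignments
#'
#' Alignments passing all filters (identity >= `min_identity`, coverage >=
#' `min_cov` of both sequences, e-value <= `max_evalue` when present) become
#' edges; groups are the connected components under union-find.  Genes with
#' no passing edge remain singleton groups.
#'
#' @param alignments alignment table with `q_len`/`s_len` (or supply
#'   lengths via `seq_lengths`)
#' @param genes data.frame with columns `genome_id`, `gene_id` listing the
#'   full gene universe (singletons are retained from it)
#' @param min_cov inclusive coverage threshold (default 0.70)
#' @param min_identity inclusive identity threshold (default 0.80)
#' @param max_evalue e-value ceiling applied when the table has an `evalue`
#'   column (default 1e-5)
#' @param seq_lengths optional named vector of full sequence lengths
#' @return data.frame: `group_id`, `genome_id`, `gene_id`
#' @export
build_ortho_groups <- function(alignments, genes, min_cov = 0.70,
                               min_identity = 0.80, max_evalue = 1e-5,
                               seq_lengths = NULL) {
  a <- alignments
  if (!is.null(seq_lengths)) {
    a$q_len <- unname(seq_lengths[a$query_id])
    a$s_len <- unname(seq_lengths[a$subject_id])
  }
  if (nrow(a) > 0L) {
    if (is.null(a$q_len) || is.null(a$s_len)) {
      stop("build_ortho_groups needs full sequence lengths")
    }
    identity <- ifelse(a$n_columns > 0, a$n_matches / a$n_columns, 0)
    cov_q <- (a$q_end - a$q_start) / a$q_len
    cov_s <- (a$s_end - a$s_start) / a$s_len
    pass <- identity >= min_identity & cov_q >= min_cov & cov_s >= min_cov
    if (!is.null(a$evalue)) pass <- pass & (is.na(a$evalue) | a$evalue <= max_evalue)
    edges <- a[pass & a$query_id != a$subject_id,
               c("query_id", "subject_id"), drop = FALSE]
  } else {
    edges <- data.frame(query_id = character(0), subject_id = character(0))
  }
  comp <- union_find(genes$gene_id, edges)
  data.frame(group_id = sprintf("og%05d", unname(comp[genes$gene_id])),
             genome_id = genes$genome_id,
             gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Select synteny anchors from ortholog groups
#'
#' Keeps groups containing exactly one reference-genome gene and at least
#' one gene from every required genome, then ranks the anchors on every
#' sequence by coordinate order (ranks are dense, 0-based, computed among
#' anchors only).
#'
#' @param groups data.frame from [build_ortho_groups()]
#' @param gene_coords data.frame: `genome_id`, `gene_id`, `seq_id`,
#'   `position` (sortable coordinate), `strand`
#' @param reference_genome reference genome id (single-copy side)
#' @param required_genomes genomes that must all be represented (defaults to
#'   all genomes in `groups`)
#' @return data.frame of anchors: `group_id`, `genome_id`, `gene_id`,
#'   `seq_id`, `position`, `strand`, `rank`
#' @export
select_anchors <- function(groups, gene_coords, reference_genome,
                           required_genomes = unique(groups$genome_id)) {
  gs <- split(groups, groups$group_id)
  keep <- vapply(gs, function(g) {
    sum(g$genome_id == reference_genome) == 1L &&
      all(required_genomes %in% g$genome_id)
  }, TRUE)
  kept <- do.call(rbind, gs[keep])
  if (is.null(kept) || nrow(kept) == 0L) {
    return(data.frame(group_id = character(0), genome_id = character(0),
                      gene_id = character(0), seq_id = character(0),
                      position = numeric(0), strand = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  out <- merge(kept, gene_coords, by = c("genome_id", "gene_id"))
  out <- out[order(out$genome_id, out$seq_id, out$position), , drop = FALSE]
  out$rank <- stats::ave(out$position,
                         paste(out$genome_id, out$seq_id, sep = "\r"),
                         FUN = function(x) seq_along(x) - 1L)
  rownames(out) <- NULL
  out[, c("group_id", "genome_id", "gene_id", "seq_id", "position",
          "strand", "rank")]
}

#' Reference rank map for block detection
#'
#' @param anchors data.frame from [select_anchors()]
#' @param reference_genome reference genome id
#' @return data.frame keyed by `group_id`: `ref_seq`, `ref_rank`,
#'   `ref_strand`
#' @export
reference_rank_map <- function(anchors, reference_genome) {
  r <- anchors[anchors$genome_id == reference_genome, , drop = FALSE]
  data.frame(group_id = r$group_id, ref_seq = r$seq_id,
             ref_rank = r$rank, ref_strand = r$strand,
             stringsAsFactors = FALSE)
}

## per-junction "collinearity break" predicate for a sequence of anchors
## ordered along one contig/fragment.  Relative orientation o = target
## strand agrees with reference strand.  A junction is collinear when both
## anchors share the reference sequence and either (o, o, rank +1) or
## (-o, -o, rank -1) holds.  mode = "monotone" relaxes the +-1 step to any
## step preserving direction.
.junction_breaks <- function(ref_seq, ref_rank, rel, mode = "strict") {
  n <- length(ref_rank)
  if (n <= 1L) return(logical(0))
  same_seq <- ref_seq[-1] == ref_seq[-n]
  d <- diff(ref_rank)
  fwd <- rel[-1] == "+" & rel[-n] == "+"
  rev <- rel[-1] == "-" & rel[-n] == "-"
  if (mode == "strict") {
    ok <- same_seq & ((fwd & d == 1) | (rev & d == -1))
  } else {
    ok <- same_seq & ((fwd & d > 0) | (rev & d < 0))
  }
  !ok
}

#' Detect collinear syntenic blocks on a contig
#'
#' A block is a maximal run of anchors whose reference ranks step by exactly
#' +1 (forward, strand-concordant) or -1 (inverted) per junction, on a
#' single reference sequence.  `mode = "monotone"` relaxes the step to any
#' direction-preserving increment.
#'
#' @param contig_anchors data.frame of the contig's anchors in contig order:
#'   `group_id`, `strand` (strand of the gene on the contig)
#' @param rank_map data.frame from [reference_rank_map()]
#' @param mode `"strict"` (default) or `"monotone"`
#' @return data.frame of blocks: `block`, `start`, `end` (anchor indices on
#'   the contig), `ref_seq`, `orientation`
#' @export
detect_blocks <- function(contig_anchors, rank_map, mode = c("strict",
                                                             "monotone")) {
  mode <- match.arg(mode)
  m <- match(contig_anchors$group_id, rank_map$group_id)
  if (anyNA(m)) stop("anchor without a reference rank")
  ref_seq <- rank_map$ref_seq[m]
  ref_rank <- rank_map$ref_rank[m]
  rel <- ifelse(contig_anchors$strand == rank_map$ref_strand[m], "+", "-")
  n <- nrow(contig_anchors)
  if (n == 0L) {
    return(data.frame(block = integer(0), start = integer(0),
                      end = integer(0), ref_seq = character(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  breaks <- .junction_breaks(ref_seq, ref_rank, rel, mode)
  block_id <- cumsum(c(1L, as.integer(breaks)))
  starts <- which(!duplicated(block_id))
  ends <- c(starts[-1] - 1L, n)
  data.frame(block = seq_along(starts), start = starts, end = ends,
             ref_seq = ref_seq[starts],
             orientation = ifelse(ends == starts, "single",
                                  ifelse(rel[starts] == "+", "forward",
                                         "inverted")),
             stringsAsFactors = FALSE)
}

#' Is a contig fully syntenic?
#'
#' True iff the contig carries at least 2 anchors and exactly one block
#' covers them all (all anchors in the same order and orientation as the
#' reference).
#'
#' @inheritParams detect_blocks
#' @return logical scalar
#' @export
fully_syntenic <- function(contig_anchors, rank_map,
                           mode = c("strict", "monotone")) {
  mode <- match.arg(mode)
  if (nrow(contig_anchors) < 2L) return(FALSE)
  b <- detect_blocks(contig_anchors, rank_map, mode)
  nrow(b) == 1L
}

#' Monte Carlo fragmentation null for block counts
#'
#' Repeatedly fragments the target genome in gene space: per fragment a gene
#' count `g` is drawn from `genes_per_contig_dist`, a uniformly random start
#' admitting `g` consecutive genes on one sequence is picked, and the number
#' of syntenic blocks on the fragment is counted.  Per round, the relative
#' frequency of fragments per block count is recorded.
#'
#' @param target_anchors data.frame of the target genome's anchors in
#'   genome order: `seq_id`, `group_id`, `strand` (one row per anchor,
#'   ordered by position within `seq_id`)
#' @param rank_map data.frame from [reference_rank_map()]
#' @param genes_per_contig_dist named probability vector
#' @param n_fragments fragments per round (default 10000)
#' @param rounds number of rounds (default 1000)
#' @param seed integer seed
#' @param mode block mode passed to the junction predicate
#' @param max_retry redraws allowed when `g` exceeds every sequence
#' @return object of class `fragmentation_null`: `freq` (named mean relative
#'   frequency per block count), `per_round` (rounds x block-count matrix of
#'   relative frequencies), `dispersion` (per block count, sd across
#'   rounds), `rounds`, `n_fragments`
#' @export
monte_carlo_fragmentation <- function(target_anchors, rank_map,
                                      genes_per_contig_dist,
                                      n_fragments = 10000L, rounds = 1000L,
                                      seed = 1L,
                                      mode = c("strict", "monotone"),
                                      max_retry = 100L) {
  mode <- match.arg(mode)
  .check_dist(genes_per_contig_dist, "genes_per_contig_dist")
  m <- match(target_anchors$group_id, rank_map$group_id)
  if (anyNA(m)) stop("anchor without a reference rank")
  ref_seq <- rank_map$ref_seq[m]
  ref_rank <- rank_map$ref_rank[m]
  rel <- ifelse(target_anchors$strand == rank_map$ref_strand[m], "+", "-")

  ## per-sequence cumulative break counts: blocks on [a, b] =
  ## 1 + breaks in junctions a..b-1
  seqs <- unique(target_anchors$seq_id)
  seq_of <- target_anchors$seq_id
  cum_breaks <- list(); seq_len_genes <- integer(0)
  offset <- list()
  for (sq in seqs) {
    w <- which(seq_of == sq)
    br <- .junction_breaks(ref_seq[w], ref_rank[w], rel[w], mode)
    cum_breaks[[sq]] <- c(0L, cumsum(as.integer(br)))
    seq_len_genes[sq] <- length(w)
  }
  glens <- as.integer(names(genes_per_contig_dist))

  withr::with_seed(as.integer(seed), {
    per_round <- list()
    max_blocks <- 1L
    for (r in seq_len(rounds)) {
      g <- .sample_dist(genes_per_contig_dist, n_fragments)
      blocks <- integer(n_fragments)
      for (i in seq_len(n_fragments)) {
        gi <- g[i]
        ok <- names(seq_len_genes)[seq_len_genes >= gi]
        tries <- 0L
        while (length(ok) == 0L) {
          tries <- tries + 1L
          if (tries > max_retry) {
            stop("fragment size exceeds every sequence after ", max_retry,
                 " redraws")
          }
          gi <- .sample_dist(genes_per_contig_dist, 1)
          ok <- names(seq_len_genes)[seq_len_genes >= gi]
        }
        ## choose a sequence weighted by the number of admissible starts
        n_starts <- seq_len_genes[ok] - gi + 1L
        sq <- if (length(ok) == 1L) ok else
          sample(ok, 1, prob = n_starts)
        s <- sample.int(seq_len_genes[sq] - gi + 1L, 1)
        cb <- cum_breaks[[sq]]
        blocks[i] <- 1L + (cb[s + gi - 1L] - cb[s])
      }
      tb <- table(blocks)
      max_blocks <- max(max_blocks, max(blocks))
      per_round[[r]] <- tb / n_fragments
    }
    mat <- matrix(0, nrow = rounds, ncol = max_blocks,
                  dimnames = list(NULL, as.character(seq_len(max_blocks))))
    for (r in seq_len(rounds)) {
      tb <- per_round[[r]]
      mat[r, names(tb)] <- as.numeric(tb)
    }
    structure(list(freq = colMeans(mat),
                   per_round = mat,
                   dispersion = apply(mat, 2, stats::sd),
                   rounds = rounds, n_fragments = n_fragments),
              class = "fragmentation_null")
  })
}

#' @export
print.fragmentation_null <- function(x, ...) {
  cat(sprintf("fragmentation_null: %d rounds x %d fragments\n",
              x$rounds, x$n_fragments))
  print(round(x$freq, 4))
  invisible(x)
}

#' Compare observed block-count frequencies with the null
#'
#' @param observed_blocks integer vector of block counts, one per observed
#'   contig
#' @param null a `fragmentation_null`
#' @return long-format data.frame: `source` (observed/null), `blocks`,
#'   `frequency`, `dispersion` (sd across rounds; NA for observed)
#' @export
compare_block_distributions <- function(observed_blocks, null) {
  if (length(observed_blocks) == 0L) stop("no observed contigs")
  maxb <- max(max(observed_blocks), length(null$freq))
  lv <- seq_len(maxb)
  obs <- table(factor(observed_blocks, levels = lv)) / length(observed_blocks)
  nullf <- stats::setNames(rep(0, maxb), as.character(lv))
  nullf[names(null$freq)] <- null$freq
  disp <- stats::setNames(rep(NA_real_, maxb), as.character(lv))
  disp[names(null$dispersion)] <- null$dispersion
  rbind(
    data.frame(source = "observed", blocks = lv,
               frequency = as.numeric(obs), dispersion = NA_real_),
    data.frame(source = "null", blocks = lv,
               frequency = as.numeric(nullf),
               dispersion = as.numeric(disp))
  )
}
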