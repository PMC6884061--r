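## Homo(eo)log census: assign polyploid gene copies to single-copy anchor
## genes, count copies, and profile divergence across the CDS and upstream
## windows, including the indel frame spectrum.

#' Align candidate anchor-copy pairs
#'
#' Shortlists candidate anchors for each copy by exact shared k-mers (a
#' seed-and-verify step, so the all-vs-all dynamic program is avoided), then
#' computes affine-gap global alignments for the shortlisted pairs.
#'
#' @param anchors named [Biostrings::DNAStringSet] of anchor CDSs
#' @param copies named [Biostrings::DNAStringSet] of polyploid copy CDSs
#' @param scheme a [scoring_scheme()]
#' @param k k-mer length for candidate shortlisting
#' @param stride sample every `stride`-th k-mer of each copy
#' @param min_shared minimum shared k-mers to shortlist a pair
#' @return alignment table (see [alignment_table()]) with anchors as queries
#'   and copies as subjects
#' @export
align_anchor_copies <- function(anchors, copies, scheme = scoring_scheme(),
                                k = 15L, stride = 7L, min_shared = 2L) {
  pairs <- kmer_candidate_pairs(anchors, copies, k = k, stride = stride,
                                min_shared = min_shared)
  alns <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a_id <- pairs$anchor_id[i]; c_id <- pairs$copy_id[i]
    alns[[i]] <- align_global(as.character(anchors[[a_id]]),
                              as.character(copies[[c_id]]),
                              scheme, query_id = a_id, subject_id = c_id)
  }
  alignment_table(alns)
}

#' Candidate anchor-copy pairs by shared k-mers
#'
#' @inheritParams align_anchor_copies
#' @return data.frame with columns `anchor_id`, `copy_id`, `shared`
#' @export
kmer_candidate_pairs <- function(anchors, copies, k = 15L, stride = 7L,
                                 min_shared = 2L) {
  kmers_of <- function(s, step) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq(1L, n - k + 1L, by = step)
    substring(s, starts, starts + k - 1L)
  }
  anchor_tab <- data.table::rbindlist(lapply(names(anchors), function(id) {
    data.table::data.table(kmer = kmers_of(as.character(anchors[[id]]), 1L),
                           anchor_id = id)
  }))
  copy_tab <- data.table::rbindlist(lapply(names(copies), function(id) {
    data.table::data.table(kmer = kmers_of(as.character(copies[[id]]), stride),
                           copy_id = id)
  }))
  if (nrow(anchor_tab) == 0L || nrow(copy_tab) == 0L) {
    return(data.frame(anchor_id = character(0), copy_id = character(0),
                      shared = integer(0), stringsAsFactors = FALSE))
  }
  hits <- merge(copy_tab, anchor_tab, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(anchor_id = character(0), copy_id = character(0),
                      shared = integer(0), stringsAsFactors = FALSE))
  }
  shared <- NULL  # appease R CMD check
  counts <- hits[, list(shared = .N), by = c("anchor_id", "copy_id")]
  counts <- counts[counts$shared >= min_shared, ]
  out <- as.data.frame(counts)
  out[order(out$anchor_id, out$copy_id), , drop = FALSE]
}

#' Assign polyploid copies to single-copy anchors
#'
#' A copy joins the cluster of every anchor whose alignment passes the
#' inclusive identity and coverage filters (identity >= `min_identity`,
#' coverage >= `min_cov` on both sequences).  Copies passing for more than
#' one anchor are flagged ambiguous and excluded from all clusters.
#'
#' @param alignments alignment table (anchor = query, copy = subject) with
#'   `q_len`/`s_len` columns, or pass `anchor_lengths`/`copy_lengths`
#' @param min_identity inclusive identity threshold (default 0.80)
#' @param min_cov inclusive coverage threshold on both sequences (0.70)
#' @param anchor_lengths,copy_lengths named numeric vectors of full sequence
#'   lengths; used when the table has no `q_len`/`s_len` columns
#' @return object of class `homoeolog_clusters`: data.frame `clusters`
#'   (anchor_id, n_members, members list-column, kept, discard_reason) and
#'   character vector `ambiguous` of excluded copy ids
#' @export
assign_homoeologs <- function(alignments, min_identity = 0.80,
                              min_cov = 0.70, anchor_lengths = NULL,
                              copy_lengths = NULL) {
  a <- alignments
  if (!is.null(anchor_lengths)) a$q_len <- unname(anchor_lengths[a$query_id])
  if (!is.null(copy_lengths)) a$s_len <- unname(copy_lengths[a$subject_id])
  if (is.null(a$q_len) || is.null(a$s_len) || anyNA(a$q_len) || anyNA(a$s_len)) {
    stop("assign_homoeologs needs full sequence lengths ",
         "(q_len/s_len columns or anchor_lengths/copy_lengths)")
  }
  identity <- ifelse(a$n_columns > 0, a$n_matches / a$n_columns, 0)
  cov_q <- (a$q_end - a$q_start) / a$q_len
  cov_s <- (a$s_end - a$s_start) / a$s_len
  pass <- identity >= min_identity & cov_q >= min_cov & cov_s >= min_cov
  hits <- a[pass, c("query_id", "subject_id"), drop = FALSE]
  hits <- unique(hits)

  ## copies passing for more than one anchor are ambiguous
  n_anchors <- table(hits$subject_id)
  ambiguous <- names(n_anchors)[n_anchors > 1L]
  hits <- hits[!(hits$subject_id %in% ambiguous), , drop = FALSE]

  anchors <- sort(unique(hits$query_id))
  members <- lapply(anchors, function(an) {
    sort(hits$subject_id[hits$query_id == an])
  })
  clusters <- data.frame(anchor_id = anchors,
                         n_members = lengths(members),
                         kept = TRUE,
                         discard_reason = NA_character_,
                         stringsAsFactors = FALSE)
  clusters$members <- members
  structure(list(clusters = clusters, ambiguous = sort(ambiguous)),
            class = "homoeolog_clusters")
}

#' Discard clusters with implausibly many members
#'
#' Clusters with more than `max_copies` members are flagged `kept = FALSE`
#' with the reason recorded; they remain in the table for reporting.
#'
#' @param clusters a `homoeolog_clusters` object
#' @param max_copies maximum credible copy number (default 20)
#' @return the object with updated `kept`/`discard_reason`
#' @export
filter_clusters <- function(clusters, max_copies = 20L) {
  if (max_copies < 1L) stop("max_copies must be >= 1")
  cl <- clusters$clusters
  too_big <- cl$n_members > max_copies
  cl$kept[too_big] <- FALSE
  cl$discard_reason[too_big] <-
    sprintf("%d members exceed max_copies=%d", cl$n_members[too_big],
            max_copies)
  clusters$clusters <- cl
  clusters
}

#' Copy-count distribution over kept clusters
#'
#' @param clusters a `homoeolog_clusters` object
#' @param anchors optional character vector of all anchor ids; anchors with
#'   no passing copies are reported in the `unmatched` attribute
#' @return named numeric vector mapping copy count to relative frequency
#'   (sums to 1), with attribute `unmatched`
#' @export
copy_count_distribution <- function(clusters, anchors = NULL) {
  cl <- clusters$clusters
  kept <- cl[cl$kept, , drop = FALSE]
  counts <- table(kept$n_members)
  freq <- as.numeric(counts) / sum(counts)
  names(freq) <- names(counts)
  unmatched <- character(0)
  if (!is.null(anchors)) unmatched <- setdiff(anchors, cl$anchor_id)
  attr(freq, "unmatched") <- unmatched
  freq
}

#' Pairwise dissimilarity records for a cluster
#'
#' Aligns the region sequences of every unordered member pair globally and
#' records `(mismatches + gap columns) / columns`.  For upstream windows,
#' records whose aligned spans deviate from the window length by more than
#' `len_tolerance` are discarded (partial-alignment guard); the CDS region
#' is exempt.
#'
#' @param anchor_id cluster anchor id (carried into the records)
#' @param member_ids cluster member ids
#' @param sequences named [Biostrings::DNAStringSet]; for upstream regions
#'   these must be full upstream sequences whose 3' end abuts the start
#'   codon (the window is taken from the 3' end)
#' @param region one of `"CDS"`, `"up100"`, `"up500"`, `"up1000"`
#' @param len_tolerance allowed relative deviation of alignment length from
#'   the window length (upstream regions only)
#' @param scheme a [scoring_scheme()]
#' @return data.frame: anchor_id, member1, member2, region, value, plus a
#'   list-column `aln` of the underlying alignments when `keep_alignments`
#' @param keep_alignments keep the `pairwise_alignment` objects
#' @export
pairwise_dissimilarity <- function(anchor_id, member_ids, sequences,
                                   region = c("CDS", "up100", "up500",
                                              "up1000"),
                                   len_tolerance = 0.20,
                                   scheme = scoring_scheme(),
                                   keep_alignments = FALSE) {
  region <- match.arg(region)
  window_len <- switch(region, CDS = NA_integer_, up100 = 100L,
                       up500 = 500L, up1000 = 1000L)
  if (length(member_ids) < 2L) {
    return(data.frame(anchor_id = character(0), member1 = character(0),
                      member2 = character(0), region = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  }
  get_seq <- function(id) {
    if (!(id %in% names(sequences))) return(NULL)
    s <- as.character(sequences[[id]])
    if (!is.na(window_len)) {
      ## clip at the available length; the tolerance filter below discards
      ## alignments that end up too short
      s <- substr(s, max(1L, nchar(s) - window_len + 1L), nchar(s))
    }
    if (nchar(s) == 0L) return(NULL)
    s
  }
  rows <- list(); alns <- list()
  pairs <- utils::combn(sort(member_ids), 2L)
  for (j in seq_len(ncol(pairs))) {
    id1 <- pairs[1, j]; id2 <- pairs[2, j]
    s1 <- get_seq(id1); s2 <- get_seq(id2)
    if (is.null(s1) || is.null(s2)) {
      warning(sprintf("missing sequence for pair (%s, %s); record skipped",
                      id1, id2))
      next
    }
    aln <- align_global(s1, s2, scheme, query_id = id1, subject_id = id2)
    if (!is.na(window_len)) {
      ## partial-alignment guard: both aligned spans must sit within
      ## len_tolerance of the window length
      lo <- (1 - len_tolerance) * window_len
      hi <- (1 + len_tolerance) * window_len
      span_q <- aln$q_end - aln$q_start
      span_s <- aln$s_end - aln$s_start
      if (span_q < lo || span_q > hi || span_s < lo || span_s > hi) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      anchor_id = anchor_id, member1 = id1, member2 = id2, region = region,
      value = aln_dissimilarity(aln), stringsAsFactors = FALSE)
    if (keep_alignments) alns[[length(alns) + 1L]] <- aln
  }
  out <- .rbind_or_empty(rows, c("anchor_id", "member1", "member2", "region",
                                 "value"))
  if (keep_alignments) attr(out, "alignments") <- alns
  out
}

#' Median dissimilarity pooled across clusters
#'
#' @param records data.frame of dissimilarity records (long format)
#' @param region region label to pool
#' @return median value
#' @export
median_dissimilarity <- function(records, region) {
  v <- records$value[records$region == region]
  if (length(v) == 0L) stop("no dissimilarity records for region ", region)
  stats::median(v)
}

#' Frame classification of an indel length
#'
#' @param length indel length(s) in nt (>= 1)
#' @return `"frame_preserving"` when the length is a multiple of 3, else
#'   `"frameshift"` (vectorised)
#' @export
classify_frame <- function(length) {
  if (any(length < 1L)) stop("indel length must be >= 1")
  ifelse(length %% 3L == 0L, "frame_preserving", "frameshift")
}

#' Indel length spectrum from CDS alignments
#'
#' Pools the gap runs of the supplied pairwise alignments (all member-pair
#' combinations of all kept clusters) into a length histogram and tallies
#' frame-preserving versus frameshift events.
#'
#' @param alignments list of `pairwise_alignment` objects
#' @return object of class `indel_spectrum`: `counts` (named integer vector,
#'   length -> occurrences), `frame_preserving_count`, `frameshift_count`
#' @export
indel_spectrum <- function(alignments) {
  lens <- unlist(lapply(alignments, function(a) a$gap_runs$length),
                 use.names = FALSE)
  if (is.null(lens)) lens <- integer(0)
  counts <- table(factor(lens, levels = sort(unique(lens))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  fp <- sum(counts[as.integer(names(counts)) %% 3L == 0L])
  structure(list(counts = counts,
                 frame_preserving_count = fp,
                 frameshift_count = sum(counts) - fp),
            class = "indel_spectrum")
}

#' @export
print.indel_spectrum <- function(x, ...) {
  cat(sprintf("indel_spectrum: %d events (%d frame-preserving, %d frameshift)\n",
              sum(x$counts), x$frame_preserving_count, x$frameshift_count))
  invisible(x)
}
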