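#' Scoring scheme for pairwise alignment
#'
#' A gap run of length `L` costs `gap_open + L * gap_extend`; both penalties
#' are non-positive, as is the mismatch score.
#'
#' @param match per-column score for identical bases (>= 0)
#' @param mismatch per-column score for differing bases (<= 0)
#' @param gap_open cost charged once when a gap run opens (<= 0)
#' @param gap_extend cost charged per gap column (<= 0)
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -1) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend))
  if (!(mismatch <= 0 && 0 <= match)) {
    stop("scoring scheme requires mismatch <= 0 <= match")
  }
  if (gap_open > 0 || gap_extend > 0) {
    stop("gap penalties must be <= 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

## Build a pairwise_alignment record from aligned strings returned by the DP.
.aln_from_strings <- function(res, query_id, subject_id, q_len, s_len,
                              mode, map_quality = NA_integer_) {
  a <- strsplit(res$a_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(res$b_aln, "", fixed = TRUE)[[1]]
  n_columns <- length(a)
  gap_a <- a == "-"
  gap_b <- b == "-"
  n_gap_columns <- sum(gap_a) + sum(gap_b)
  matches <- !gap_a & !gap_b & a == b
  n_matches <- sum(matches)
  n_mismatches <- n_columns - n_matches - n_gap_columns

  runs <- .gap_runs_from_masks(gap_a, gap_b)

  structure(list(
    query_id = query_id, subject_id = subject_id,
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end,
    q_len = q_len, s_len = s_len,
    strand = "+",
    n_columns = n_columns,
    n_matches = n_matches,
    n_mismatches = n_mismatches,
    n_gap_columns = n_gap_columns,
    gap_runs = runs,
    score = res$score,
    map_quality = map_quality,
    mode = mode,
    a_aln = res$a_aln, b_aln = res$b_aln
  ), class = "pairwise_alignment")
}

## Run-length encode gap columns; side = "query" means the gap characters sit
## in the query row (i.e. the subject has extra sequence there).
.gap_runs_from_masks <- function(gap_a, gap_b) {
  side <- character(0)
  len <- integer(0)
  if (any(gap_a)) {
    r <- rle(gap_a)
    ends <- cumsum(r$lengths)
    w <- which(r$values)
    side <- c(side, rep("query", length(w)))
    len <- c(len, r$lengths[w])
  }
  if (any(gap_b)) {
    r <- rle(gap_b)
    w <- which(r$values)
    side <- c(side, rep("subject", length(w)))
    len <- c(len, r$lengths[w])
  }
  data.frame(side = side, length = len, stringsAsFactors = FALSE)
}

#' Global (Needleman-Wunsch-Gotoh) pairwise alignment
#'
#' Optimal affine-gap global alignment with a deterministic traceback
#' (tie order: diagonal, then gap-in-subject, then gap-in-query).
#'
#' @param a,b DNA strings (character scalars), or objects coercible via
#'   `as.character()`
#' @param scheme a [scoring_scheme()]
#' @param query_id,subject_id identifiers stored in the record
#' @return a `pairwise_alignment` record
#' @export
align_global <- function(a, b, scheme = scoring_scheme(),
                         query_id = "query", subject_id = "subject") {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("align_global requires non-empty sequences")
  }
  res <- .cpp_align_global(a, b, scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend)
  .aln_from_strings(res, query_id, subject_id, nchar(a), nchar(b), "global")
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Affine-gap local alignment; the empty alignment (score 0) is returned when
#' no positive-scoring alignment exists.
#'
#' @inheritParams align_global
#' @return a `pairwise_alignment` record
#' @export
align_local <- function(a, b, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject") {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("align_local requires non-empty sequences")
  }
  res <- .cpp_align_local(a, b, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend)
  .aln_from_strings(res, query_id, subject_id, nchar(a), nchar(b), "local")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment (%s): %s vs %s\n", x$mode,
              x$query_id, x$subject_id))
  cat(sprintf("  score %g, %d columns: %d match / %d mismatch / %d gap\n",
              x$score, x$n_columns, x$n_matches, x$n_mismatches,
              x$n_gap_columns))
  invisible(x)
}

#' Fraction of identical alignment columns
#'
#' `n_matches / n_columns`; gap columns count against identity.
#'
#' @param aln a `pairwise_alignment`
#' @return fraction in `[0, 1]`
#' @export
aln_identity <- function(aln) {
  if (aln$n_columns == 0L) stop("identity undefined for an empty alignment")
  aln$n_matches / aln$n_columns
}

#' Fraction of a sequence covered by the aligned span
#'
#' @param aln a `pairwise_alignment`
#' @param side `"query"` or `"subject"`
#' @param seq_length full sequence length; defaults to the length stored in
#'   the record (available for internally computed alignments)
#' @return fraction in `[0, 1]`
#' @export
aln_coverage <- function(aln, side = c("query", "subject"),
                         seq_length = NULL) {
  side <- match.arg(side)
  span <- if (side == "query") aln$q_end - aln$q_start else
    aln$s_end - aln$s_start
  if (is.null(seq_length)) {
    seq_length <- if (side == "query") aln$q_len else aln$s_len
  }
  if (is.null(seq_length) || is.na(seq_length)) {
    stop("sequence length unknown; pass seq_length")
  }
  span / seq_length
}

#' Dissimilarity of an alignment
#'
#' `(n_mismatches + n_gap_columns) / n_columns`, the complement of
#' [aln_identity()]: mismatches and gaps both count as differences.
#'
#' @param aln a `pairwise_alignment`
#' @return fraction in `[0, 1]`
#' @export
aln_dissimilarity <- function(aln) {
  if (aln$n_columns == 0L) {
    stop("dissimilarity undefined for an empty alignment")
  }
  (aln$n_mismatches + aln$n_gap_columns) / aln$n_columns
}

#' Gap runs of an alignment
#'
#' One row per maximal run of gap characters; `side` names the sequence
#' carrying the gap characters, `length` the run length in columns.
#'
#' @param aln a `pairwise_alignment`
#' @return data.frame with columns `side`, `length`
#' @export
gap_runs <- function(aln) aln$gap_runs

## ---------------------------------------------------------------------------
## 12-column tabular alignment (BLAST outfmt-6 dialect) I/O.
## Input coordinates are 1-based inclusive; sstart > send encodes - strand.
## Internal coordinates are 0-based half-open on the forward strand.

.TAB_COLS <- c("query_id", "subject_id", "pident", "length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore")

#' Read 12-column tabular alignments
#'
#' Parses the common 12-column tab-separated alignment format (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bitscore).  1-based inclusive input
#' coordinates are converted to 0-based half-open; `sstart > send` encodes a
#' minus-strand hit.  `n_matches` and `n_gap_columns` are reconstructed from
#' the integer fields (`gapcols = 2*length - qspan - sspan`,
#' `matches = length - mismatch - gapcols`).
#'
#' @param path file path
#' @return data.frame with one row per alignment: ids, 0-based half-open
#'   coordinates, strand, `n_columns`, `n_matches`, `n_mismatches`,
#'   `n_gap_columns`, `gap_opens`, `evalue`, `score`
#' @export
read_tabular_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(.empty_alignment_table())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed tabular alignment row at line %d: %d columns (12 expected)",
                 bad[1], nf[bad[1]]))
  }
  m <- do.call(rbind, parts)
  num <- function(k) suppressWarnings(as.numeric(m[, k]))
  qstart <- num(7); qend <- num(8); sstart <- num(9); send <- num(10)
  if (anyNA(qstart) || anyNA(qend) || anyNA(sstart) || anyNA(send)) {
    bad <- which(is.na(qstart) | is.na(qend) | is.na(sstart) | is.na(send))[1]
    stop(sprintf("malformed tabular alignment row at line %d: non-numeric coordinate",
                 bad))
  }
  strand <- ifelse(sstart > send, "-", "+")
  s_lo <- pmin(sstart, send); s_hi <- pmax(sstart, send)
  len <- num(4); mism <- num(5)
  q_start <- qstart - 1; q_end <- qend
  s_start <- s_lo - 1; s_end <- s_hi
  gapcols <- 2 * len - (q_end - q_start) - (s_end - s_start)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    q_start = q_start, q_end = q_end,
    s_start = s_start, s_end = s_end,
    strand = strand,
    n_columns = len,
    n_matches = len - mism - gapcols,
    n_mismatches = mism,
    n_gap_columns = gapcols,
    gap_opens = num(6),
    evalue = num(11),
    score = num(12),
    stringsAsFactors = FALSE
  )
  out$pident <- num(3)
  out
}

.empty_alignment_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = numeric(0), q_end = numeric(0),
             s_start = numeric(0), s_end = numeric(0),
             strand = character(0), n_columns = numeric(0),
             n_matches = numeric(0), n_mismatches = numeric(0),
             n_gap_columns = numeric(0), gap_opens = numeric(0),
             evalue = numeric(0), score = numeric(0), pident = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write alignments in 12-column tabular format
#'
#' Inverse of [read_tabular_alignments()]: internal 0-based half-open
#' coordinates are emitted 1-based inclusive, minus-strand hits with
#' `sstart > send`.
#'
#' @param alignments data.frame as returned by [read_tabular_alignments()]
#'   or [alignment_table()]
#' @param path output file path
#' @export
write_tabular_alignments <- function(alignments, path) {
  a <- alignments
  pident <- ifelse(a$n_columns > 0, 100 * a$n_matches / a$n_columns, 0)
  qstart <- a$q_start + 1; qend <- a$q_end
  sstart <- ifelse(a$strand == "-", a$s_end, a$s_start + 1)
  send <- ifelse(a$strand == "-", a$s_start + 1, a$s_end)
  gapopen <- if ("gap_opens" %in% names(a)) a$gap_opens else 0
  evalue <- if ("evalue" %in% names(a)) a$evalue else 0
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%g",
                   a$query_id, a$subject_id, pident,
                   as.integer(a$n_columns), as.integer(a$n_mismatches),
                   as.integer(gapopen), as.integer(qstart), as.integer(qend),
                   as.integer(sstart), as.integer(send), evalue, a$score)
  writeLines(lines, path)
  invisible(path)
}

#' Collect pairwise_alignment records into an alignment table
#'
#' @param alns list of `pairwise_alignment` records
#' @return data.frame in the layout of [read_tabular_alignments()], plus
#'   `map_quality`
#' @export
alignment_table <- function(alns) {
  if (length(alns) == 0L) {
    out <- .empty_alignment_table()
    out$map_quality <- integer(0)
    return(out)
  }
  out <- data.frame(
    query_id = vapply(alns, `[[`, "", "query_id"),
    subject_id = vapply(alns, `[[`, "", "subject_id"),
    q_start = vapply(alns, `[[`, 0, "q_start"),
    q_end = vapply(alns, `[[`, 0, "q_end"),
    s_start = vapply(alns, `[[`, 0, "s_start"),
    s_end = vapply(alns, `[[`, 0, "s_end"),
    strand = vapply(alns, `[[`, "", "strand"),
    n_columns = vapply(alns, `[[`, 0L, "n_columns"),
    n_matches = vapply(alns, `[[`, 0L, "n_matches"),
    n_mismatches = vapply(alns, `[[`, 0L, "n_mismatches"),
    n_gap_columns = vapply(alns, `[[`, 0L, "n_gap_columns"),
    gap_opens = vapply(alns, function(x) nrow(x$gap_runs), 0L),
    evalue = 0,
    score = vapply(alns, `[[`, 0, "score"),
    stringsAsFactors = FALSE
  )
  out$pident <- ifelse(out$n_columns > 0, 100 * out$n_matches / out$n_columns, 0)
  out$q_len <- vapply(alns, function(x) x$q_len %||% NA_real_, 0)
  out$s_len <- vapply(alns, function(x) x$s_len %||% NA_real_, 0)
  out$map_quality <- vapply(alns, function(x) {
    mq <- x$map_quality
    if (is.null(mq)) NA_integer_ else as.integer(mq)
  }, 0L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brute-force best alignment score (validation reference)
#'
#' Enumerates every gapped alignment of two short sequences (all monotone
#' paths of diagonal / gap ops, with affine gap-run state) and returns the
#' best total score.  Exponential-time; intended only for validating the
#' dynamic programs on sequences of length <= ~10.
#'
#' @inheritParams align_global
#' @param mode `"global"` or `"local"`
#' @return best score (numeric scalar)
#' @export
enumerate_alignment_score <- function(a, b, scheme = scoring_scheme(),
                                      mode = c("global", "local")) {
  mode <- match.arg(mode)
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) > 10 || nchar(b) > 10) {
    stop("enumeration reference is limited to sequences of length <= 10")
  }
  if (mode == "global") {
    .cpp_enum_global_score(a, b, scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend)
  } else {
    .cpp_enum_local_score(a, b, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend)
  }
}
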