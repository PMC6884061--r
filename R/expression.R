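## Per-cluster expression tallies: how many copies exist versus how many are
## expressed, by orientation.

#' Expression call for an abundance value
#'
#' Strict threshold: a record counts as expressed iff `fpkm > threshold`.
#'
#' @param fpkm abundance value(s), non-negative
#' @param threshold expression threshold (default 1.0)
#' @return logical vector
#' @export
is_expressed <- function(fpkm, threshold = 1.0) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("fpkm must be non-negative")
  fpkm > threshold
}

## expressed copies per cluster member set, for one orientation
.expressed_members <- function(members, abundance, orientation, threshold,
                               per_sample = NULL) {
  ab <- abundance[abundance$orientation == orientation &
                    abundance$copy_id %in% members, , drop = FALSE]
  if (!is.null(per_sample)) {
    ab <- ab[ab$sample == per_sample, , drop = FALSE]
  }
  ab <- ab[is_expressed(ab$fpkm, threshold), , drop = FALSE]
  unique(ab$copy_id)
}

#' Percentage-frequency matrix of copies versus expressed copies
#'
#' Cell `(k, m)` holds the percentage of kept clusters with `k` members of
#' which `m` are expressed in the requested orientation (a copy counts as
#' expressed when it passes the threshold in at least one sample, or in the
#' single sample given by `per_sample`).  Entries sum to 100.
#'
#' @param clusters a `homoeolog_clusters` object
#' @param abundance data.frame: `copy_id`, `sample`, `orientation`, `fpkm`
#' @param orientation `"sense"` or `"antisense"`
#' @param threshold expression threshold (strict `>`)
#' @param per_sample restrict to one sample label (default: any sample)
#' @return matrix with rownames `k` and colnames `m` (percentages), with
#'   attribute `summary`: per-cluster data.frame (anchor_id, k, m)
#' @export
copies_expressed_matrix <- function(clusters, abundance,
                                    orientation = c("sense", "antisense"),
                                    threshold = 1.0, per_sample = NULL) {
  orientation <- match.arg(orientation)
  cl <- clusters$clusters
  cl <- cl[cl$kept, , drop = FALSE]
  if (nrow(cl) == 0L) stop("no kept clusters")
  k <- cl$n_members
  m <- vapply(cl$members, function(mem) {
    length(.expressed_members(mem, abundance, orientation, threshold,
                              per_sample))
  }, 0L)
  summary <- data.frame(anchor_id = cl$anchor_id, k = k, m = m,
                        stringsAsFactors = FALSE)
  kmax <- max(k)
  mat <- matrix(0, nrow = kmax, ncol = kmax + 1L,
                dimnames = list(k = seq_len(kmax), m = 0:kmax))
  tb <- table(factor(k, levels = seq_len(kmax)), factor(m, levels = 0:kmax))
  mat[] <- 100 * as.numeric(tb) / nrow(cl)
  attr(mat, "summary") <- summary
  mat
}

#' Expressed-copy count versus summed abundance per cluster
#'
#' Descriptive table pairing, per kept cluster, the number of expressed
#' copies with the cluster's total sense abundance (summed over members and
#' samples); no statistical test is attached.
#'
#' @inheritParams copies_expressed_matrix
#' @return data.frame: `anchor_id`, `n_expressed`, `sum_fpkm`
#' @export
copies_vs_level <- function(clusters, abundance, threshold = 1.0) {
  cl <- clusters$clusters
  cl <- cl[cl$kept, , drop = FALSE]
  sense <- abundance[abundance$orientation == "sense", , drop = FALSE]
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    mem <- cl$members[[i]]
    expressed <- .expressed_members(mem, abundance, "sense", threshold)
    data.frame(anchor_id = cl$anchor_id[i],
               n_expressed = length(expressed),
               sum_fpkm = sum(sense$fpkm[sense$copy_id %in% mem]),
               stringsAsFactors = FALSE)
  })
  out <- .rbind_or_empty(rows, c("anchor_id", "n_expressed", "sum_fpkm"))
  out
}

#' Read / write abundance tables
#'
#' Plain TSV with header `copy_id, sample, orientation, fpkm`.
#'
#' @param path file path
#' @return data.frame
#' @export
read_abundance <- function(path) {
  ab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("copy_id", "sample", "orientation", "fpkm")
  if (!all(need %in% names(ab))) {
    stop("abundance table must have columns: ", paste(need, collapse = ", "))
  }
  ab
}

#' @rdname read_abundance
#' @param abundance data.frame to write
#' @export
write_abundance <- function(abundance, path) {
  utils::write.table(abundance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
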