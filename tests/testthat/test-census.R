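test_that("identity and coverage filters are inclusive at the printed thresholds", {
  tab <- rbind(aln_row("A1", "keep", identity = 0.80, cov_q = 0.70,
                       cov_s = 0.70),
               aln_row("A1", "drop", identity = 0.79))
  cl <- assign_homoeologs(tab)
  expect_equal(cl$clusters$members[[1]], "keep")
  expect_false("drop" %in% unlist(cl$clusters$members))
})

test_that("copies passing for several anchors are ambiguous and excluded", {
  tab <- rbind(aln_row("A1", "c1"), aln_row("A2", "c1"),
               aln_row("A1", "c2"), aln_row("A1", "c3"),
               aln_row("A1", "c4"), aln_row("A1", "c5"))
  cl <- assign_homoeologs(tab)
  expect_equal(cl$ambiguous, "c1")
  expect_equal(cl$clusters$members[[which(cl$clusters$anchor_id == "A1")]],
               c("c2", "c3", "c4", "c5"))
  expect_equal(cl$clusters$n_members[cl$clusters$anchor_id == "A1"], 4L)
})

test_that("cluster size filter discards a 21-member cluster at max 20", {
  tab <- do.call(rbind, lapply(sprintf("c%02d", 1:21), function(s)
    aln_row("A1", s)))
  tab <- rbind(tab, do.call(rbind, lapply(sprintf("d%02d", 1:15), function(s)
    aln_row("A2", s))))
  cl <- filter_clusters(assign_homoeologs(tab), max_copies = 20)
  expect_false(cl$clusters$kept[cl$clusters$anchor_id == "A1"])
  expect_match(cl$clusters$discard_reason[cl$clusters$anchor_id == "A1"],
               "21 members")
  expect_true(cl$clusters$kept[cl$clusters$anchor_id == "A2"])
  ## max_copies = 1 discards any 2-member cluster
  tab2 <- rbind(aln_row("A1", "x1"), aln_row("A1", "x2"))
  cl2 <- filter_clusters(assign_homoeologs(tab2), max_copies = 1)
  expect_false(any(cl2$clusters$kept))
})

test_that("copy-count distribution sums to 1 and reports unmatched anchors", {
  tab <- rbind(aln_row("A1", "a"), aln_row("A1", "b"),
               aln_row("A2", "c"), aln_row("A2", "d"),
               do.call(rbind, lapply(sprintf("e%d", 1:6), function(s)
                 aln_row("A3", s))))
  cl <- filter_clusters(assign_homoeologs(tab))
  freq <- copy_count_distribution(cl, anchors = c("A1", "A2", "A3", "A4"))
  expect_equal(sum(freq), 1)
  expect_equal(unname(freq["2"]), 2 / 3)
  expect_equal(unname(freq["6"]), 1 / 3)
  expect_equal(attr(freq, "unmatched"), "A4")
})

test_that("a fixed simulated copy number is recovered as a point mass", {
  anc <- generate_ancestor(25, 1, seed = 31)
  sim <- polyploidize(anc, uniform_k_config(k = 4, seed = 31,
                                            sub_rate_cds = 0.005,
                                            sub_rate_up100 = 0.005,
                                            sub_rate_up500 = 0.01,
                                            sub_rate_up1000 = 0.02))
  tab <- align_anchor_copies(sim$ancestor$cds, sim$copy_cds)
  cl <- filter_clusters(assign_homoeologs(tab))
  freq <- copy_count_distribution(cl)
  expect_equal(names(freq), "4")
  expect_equal(as.numeric(freq), 1)
})

test_that("identical copies give all-zero dissimilarity records", {
  seqs <- Biostrings::DNAStringSet(c(m1 = strrep("ACGT", 30),
                                     m2 = strrep("ACGT", 30),
                                     m3 = strrep("ACGT", 30)))
  rec <- pairwise_dissimilarity("A1", c("m1", "m2", "m3"), seqs, "CDS")
  expect_equal(nrow(rec), 3L)
  expect_true(all(rec$value == 0))
})

test_that("upstream window tolerance discards out-of-band alignment spans", {
  ## 79-nt sequences for the 100-nt window: alignment spans 79 columns,
  ## below the [80, 120] band, so the record is discarded
  seqs <- Biostrings::DNAStringSet(c(m1 = random_dna(79), m2 = random_dna(79)))
  rec <- pairwise_dissimilarity("A1", c("m1", "m2"), seqs, "up100",
                                len_tolerance = 0.20)
  expect_equal(nrow(rec), 0L)
  ## 100-nt sequences are retained
  s <- random_dna(100)
  seqs2 <- Biostrings::DNAStringSet(c(m1 = s, m2 = s))
  rec2 <- pairwise_dissimilarity("A1", c("m1", "m2"), seqs2, "up100")
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$value, 0)
})

test_that("median dissimilarity pools across clusters", {
  rec <- data.frame(anchor_id = "A", member1 = "x", member2 = "y",
                    region = "CDS", value = c(0.01, 0.02, 0.03))
  expect_equal(median_dissimilarity(rec, "CDS"), 0.02)
  expect_error(median_dissimilarity(rec, "up100"), "no dissimilarity")
})

test_that("region medians recover the planted divergence gradient", {
  sim <- subs_only_sim(40, 7)
  tab <- align_anchor_copies(sim$ancestor$cds, sim$copy_cds)
  cl <- filter_clusters(assign_homoeologs(tab))
  kept <- cl$clusters[cl$clusters$kept & cl$clusters$n_members >= 2, ]
  recs <- list()
  for (i in seq_len(nrow(kept))) {
    for (rg in c("CDS", "up100", "up500", "up1000")) {
      seqs <- if (rg == "CDS") sim$copy_cds else sim$copy_upstream
      recs[[length(recs) + 1]] <- pairwise_dissimilarity(
        kept$anchor_id[i], kept$members[[i]], seqs, rg)
    }
  }
  records <- do.call(rbind, recs)
  med <- vapply(c("CDS", "up100", "up500", "up1000"), function(rg)
    median_dissimilarity(records, rg), 0)
  expect_true(all(diff(med) >= 0))  # monotone with the planted ordering
  targets <- expected_pairwise(c(sim$config$sub_rate_cds,
                                 sim$config$sub_rate_up100,
                                 sim$config$sub_rate_up500,
                                 sim$config$sub_rate_up1000))
  ## small simulation: generous band; the acceptance suite tightens this
  expect_true(all(abs(med - targets) / targets < 0.5))
})

test_that("frame classification matches the mod-3 rule", {
  expect_equal(classify_frame(3), "frame_preserving")
  expect_equal(classify_frame(7), "frameshift")
  lens <- 1:1000
  expect_equal(classify_frame(lens),
               ifelse(lens %% 3 == 0, "frame_preserving", "frameshift"))
  expect_error(classify_frame(0), ">= 1")
})

test_that("indel spectrum pools gap runs and conserves totals", {
  s <- scoring_scheme()
  a1 <- align_global("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGT", s)
  a2 <- align_global("ACGTTTTACGT", "ACGTACGT", s)
  sp <- indel_spectrum(list(a1, a2))
  expect_equal(sum(sp$counts),
               sp$frame_preserving_count + sp$frameshift_count)
  expect_equal(sum(sp$counts * as.integer(names(sp$counts))),
               a1$n_gap_columns + a2$n_gap_columns)
})
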