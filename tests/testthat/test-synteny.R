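test_that("union-find groups transitive chains and keeps singletons", {
  comp <- union_find(c("A", "B", "C", "D"),
                     data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(unname(comp["A"]), unname(comp["B"]))
  expect_equal(unname(comp["B"]), unname(comp["C"]))
  expect_false(comp[["D"]] == comp[["A"]])
  ## no edges: everyone their own group
  comp0 <- union_find(c("x", "y", "z"), data.frame(a = character(0),
                                                   b = character(0)))
  expect_equal(length(unique(comp0)), 3L)
})

test_that("union-find components equal graph components on random instances", {
  skip_if_not_installed("igraph")
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(2:20, 1)
    items <- sprintf("n%02d", seq_len(n))
    n_edges <- sample(0:(2 * n), 1)
    edges <- data.frame(from = sample(items, n_edges, replace = TRUE),
                        to = sample(items, n_edges, replace = TRUE))
    comp <- union_find(items, edges)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = items)
    ref <- igraph::components(g)$membership[items]
    ## same partition: equal label co-membership
    expect_equal(outer(comp, comp, "=="), outer(ref, ref, "=="),
                 ignore_attr = TRUE)
  }
})

test_that("ortholog group filters honour identity, coverage and e-value", {
  base <- function(q, s, identity = 0.9, cov = 0.9, evalue = 1e-20) {
    data.frame(query_id = q, subject_id = s, q_start = 0, q_end = cov * 100,
               s_start = 0, s_end = cov * 100, strand = "+",
               n_columns = 100, n_matches = identity * 100,
               n_mismatches = 100 - identity * 100, n_gap_columns = 0,
               gap_opens = 0, evalue = evalue, score = 50,
               q_len = 100, s_len = 100)
  }
  genes <- data.frame(genome_id = c("r", "p", "p"),
                      gene_id = c("A", "B", "C"))
  ## B passes, C fails the e-value ceiling
  tab <- rbind(base("A", "B"), base("A", "C", evalue = 1e-3))
  gr <- build_ortho_groups(tab, genes)
  expect_equal(gr$group_id[gr$gene_id == "A"], gr$group_id[gr$gene_id == "B"])
  expect_false(gr$group_id[gr$gene_id == "C"] == gr$group_id[gr$gene_id == "A"])
})

test_that("anchor selection keeps single-reference groups present in all genomes", {
  groups <- data.frame(
    group_id = c("og1", "og1", "og2", "og2", "og2", "og3"),
    genome_id = c("ref", "poly", "ref", "ref", "poly", "ref"),
    gene_id = c("r1", "p1", "r2", "r3", "p2", "r4"))
  coords <- data.frame(
    genome_id = c("ref", "ref", "ref", "ref", "poly", "poly"),
    gene_id = c("r1", "r2", "r3", "r4", "p1", "p2"),
    seq_id = c("chr1", "chr1", "chr1", "chr1", "ctg1", "ctg1"),
    position = c(1, 2, 3, 4, 1, 2),
    strand = "+")
  anchors <- select_anchors(groups, coords, "ref", c("ref", "poly"))
  ## og2 has two reference genes, og3 lacks the polyploid genome
  expect_equal(sort(unique(anchors$group_id)), "og1")
  ## ranks are dense per sequence
  five <- data.frame(
    group_id = sprintf("og%d", 1:5), genome_id = "ref",
    gene_id = sprintf("r%d", 1:5))
  five <- rbind(five, transform(five, genome_id = "poly",
                                gene_id = sprintf("p%d", 1:5)))
  coords5 <- data.frame(
    genome_id = rep(c("ref", "poly"), each = 5),
    gene_id = c(sprintf("r%d", 1:5), sprintf("p%d", 1:5)),
    seq_id = rep(c("chr9", "ctg9"), each = 5),
    position = c(10, 20, 30, 40, 50, 1:5), strand = "+")
  a5 <- select_anchors(five, coords5, "ref", c("ref", "poly"))
  expect_equal(sort(a5$rank[a5$genome_id == "ref"]), 0:4)
})

test_that("block detection follows strict rank adjacency and orientation", {
  rank_map <- data.frame(group_id = sprintf("og%d", 1:12), ref_seq = "chr1",
                         ref_rank = 0:11, ref_strand = "+")
  ca <- function(ranks, strands = rep("+", length(ranks))) {
    data.frame(group_id = sprintf("og%d", ranks + 1), strand = strands)
  }
  ## consecutive ranks (5,6,7): one forward block, fully syntenic
  b1 <- detect_blocks(ca(c(5, 6, 7)), rank_map)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$orientation, "forward")
  expect_true(fully_syntenic(ca(c(5, 6, 7)), rank_map))
  ## rank gap (5,6,9,10): two blocks, not fully syntenic
  b2 <- detect_blocks(ca(c(5, 6, 9, 10)), rank_map)
  expect_equal(nrow(b2), 2L)
  expect_false(fully_syntenic(ca(c(5, 6, 9, 10)), rank_map))
  ## descending ranks with flipped strands: one inverted block
  b3 <- detect_blocks(ca(c(7, 6, 5), strands = rep("-", 3)), rank_map)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$orientation, "inverted")
  ## descending ranks without strand flip break at every junction
  b4 <- detect_blocks(ca(c(7, 6, 5)), rank_map)
  expect_equal(nrow(b4), 3L)
  ## monotone mode accepts rank jumps in one direction
  b5 <- detect_blocks(ca(c(5, 6, 9, 10)), rank_map, mode = "monotone")
  expect_equal(nrow(b5), 1L)
  ## single-anchor contigs are never fully syntenic
  expect_false(fully_syntenic(ca(5), rank_map))
  expect_error(detect_blocks(data.frame(group_id = "missing", strand = "+"),
                             rank_map), "rank")
})

test_that("blocks agree with a brute-force longest-run scan", {
  set.seed(33)
  rank_map <- data.frame(group_id = sprintf("og%d", 1:30), ref_seq = "chr1",
                         ref_rank = 0:29, ref_strand = "+")
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    ranks <- sample(0:29, n)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ca <- data.frame(group_id = sprintf("og%d", ranks + 1), strand = strands)
    got <- nrow(detect_blocks(ca, rank_map))
    ## reference: count junctions violating the adjacency rule directly
    breaks <- 0
    for (i in seq_len(n - 1)) {
      fwd <- strands[i] == "+" && strands[i + 1] == "+" &&
        ranks[i + 1] == ranks[i] + 1
      rev <- strands[i] == "-" && strands[i + 1] == "-" &&
        ranks[i + 1] == ranks[i] - 1
      if (!fwd && !rev) breaks <- breaks + 1
    }
    expect_equal(got, breaks + 1)
  }
})

test_that("an unrearranged uniform-ploidy genome is fully syntenic", {
  anc <- generate_ancestor(60, 2, seed = 61)
  sim <- polyploidize(anc, uniform_k_config(k = 2, seed = 61,
                                            sub_rate_cds = 0.005))
  contigs <- fragment_genome(sim, c(`1` = 0.3, `2` = 0.3, `3` = 0.2,
                                    `4` = 0.2), seed = 61)
  st <- synteny_setup(sim, contigs)
  poly <- st$anchors[st$anchors$genome_id == "polyploid", ]
  n_multi <- 0
  for (ctg in unique(poly$seq_id)) {
    ca <- poly[poly$seq_id == ctg, ]
    ca <- ca[order(ca$position), ]
    if (nrow(ca) >= 2) {
      n_multi <- n_multi + 1
      expect_true(fully_syntenic(ca, st$rank_map), info = ctg)
    }
  }
  expect_gt(n_multi, 5)
})

test_that("block counts equal planted breakpoints + 1 per contig", {
  anc <- generate_ancestor(80, 2, seed = 62)
  sim <- polyploidize(anc, uniform_k_config(k = 2, seed = 62,
                                            sub_rate_cds = 0.005))
  sim <- plant_rearrangements(sim, inversion_rate = 3, translocation_rate = 2,
                              seed = 62)
  expect_gt(nrow(sim$truth$breakpoints), 0)
  contigs <- fragment_genome(sim, c(`2` = 0.4, `4` = 0.3, `6` = 0.3),
                             seed = 62)
  st <- synteny_setup(sim, contigs)
  poly <- st$anchors[st$anchors$genome_id == "polyploid", ]
  checked <- 0
  for (ctg in unique(poly$seq_id)) {
    ca <- poly[poly$seq_id == ctg, ]
    ca <- ca[order(ca$position), ]
    b <- detect_blocks(ca, st$rank_map)
    bp <- contig_truth_breakpoints(contigs$contig_map,
                                   sim$truth$breakpoints, ctg)
    expect_equal(nrow(b), bp + 1, info = ctg)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("fragmentation null is deterministic and degenerate cases hold", {
  anc <- generate_ancestor(50, 1, seed = 63)
  sim <- polyploidize(anc, uniform_k_config(k = 2, seed = 63,
                                            sub_rate_cds = 0.005))
  contigs <- fragment_genome(sim, seed = 63)
  st <- synteny_setup(sim, contigs)
  lay <- sim$layout
  lay$group <- st$groups$group_id[match(lay$copy_id, st$groups$gene_id)]
  target <- data.frame(seq_id = lay$chromosome, group_id = lay$group,
                       strand = lay$strand)
  dist <- c(`1` = 0.4, `2` = 0.4, `3` = 0.2)
  n1 <- monte_carlo_fragmentation(target, st$rank_map, dist,
                                  n_fragments = 200, rounds = 4, seed = 9)
  n2 <- monte_carlo_fragmentation(target, st$rank_map, dist,
                                  n_fragments = 200, rounds = 4, seed = 9)
  expect_identical(n1, n2)
  ## unrearranged genome: every fragment is a single block
  expect_equal(unname(n1$freq["1"]), 1)
  ## g fixed at 1: single block by construction even with rearrangements
  simr <- plant_rearrangements(sim, inversion_rate = 5, translocation_rate = 0,
                               seed = 64)
  # rebuild target on the rearranged layout
  layr <- simr$layout
  layr$group <- st$groups$group_id[match(layr$copy_id, st$groups$gene_id)]
  targetr <- data.frame(seq_id = layr$chromosome, group_id = layr$group,
                        strand = layr$strand)
  ng1 <- monte_carlo_fragmentation(targetr, st$rank_map, c(`1` = 1),
                                   n_fragments = 100, rounds = 2, seed = 10)
  expect_equal(unname(ng1$freq["1"]), 1)
  ## per-round frequencies sum to 1
  expect_equal(unname(rowSums(n1$per_round)), rep(1, 4))
})

test_that("observed-versus-null comparison is a proper frequency table", {
  anc <- generate_ancestor(40, 1, seed = 65)
  sim <- polyploidize(anc, uniform_k_config(k = 2, seed = 65,
                                            sub_rate_cds = 0.005))
  contigs <- fragment_genome(sim, seed = 65)
  st <- synteny_setup(sim, contigs)
  lay <- sim$layout
  lay$group <- st$groups$group_id[match(lay$copy_id, st$groups$gene_id)]
  target <- data.frame(seq_id = lay$chromosome, group_id = lay$group,
                       strand = lay$strand)
  null <- monte_carlo_fragmentation(target, st$rank_map,
                                    c(`1` = 0.5, `2` = 0.5),
                                    n_fragments = 100, rounds = 3, seed = 2)
  cmp <- compare_block_distributions(c(1, 1, 1, 2), null)
  for (src in c("observed", "null")) {
    expect_equal(sum(cmp$frequency[cmp$source == src]), 1)
  }
  expect_equal(cmp$frequency[cmp$source == "observed" & cmp$blocks == 2],
               0.25)
})
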