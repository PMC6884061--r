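test_that("ancestor genes satisfy the CDS and upstream invariants", {
  a <- generate_ancestor(5, 1, c(`300` = 1), seed = 1)
  expect_equal(nrow(a$genes), 5L)
  expect_equal(a$genes$order_index, 0:4)
  stops <- c("TAA", "TAG", "TGA")
  for (g in a$genes$gene_id) {
    cds <- as.character(a$cds[[g]])
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% stops)
    expect_false(any(codons[-length(codons)] %in% stops))
    expect_equal(nchar(as.character(a$upstream[[g]])), 1000L)
  }
})

test_that("ancestor generation is deterministic and splits chromosomes evenly", {
  a1 <- generate_ancestor(100, 2, seed = 9)
  a2 <- generate_ancestor(100, 2, seed = 9)
  expect_identical(as.character(a1$cds), as.character(a2$cds))
  expect_identical(as.character(a1$upstream), as.character(a2$upstream))
  expect_identical(a1$genes, a2$genes)
  expect_equal(unname(table(a1$genes$chromosome)["chr1"]), 50,
               ignore_attr = TRUE)
  expect_equal(unname(table(a1$genes$chromosome)["chr2"]), 50,
               ignore_attr = TRUE)
  expect_error(generate_ancestor(0), "n_genes")
  expect_error(generate_ancestor(5, cds_len_dist = c(`301` = 1)),
               "multiples of 3")
})

test_that("zero-rate configurations reproduce the ancestor byte for byte", {
  anc <- generate_ancestor(8, 1, seed = 3)
  cfg <- polyploid_config(copy_count_dist = c(`3` = 1),
                          sub_rate_cds = 0, sub_rate_up100 = 0,
                          sub_rate_up500 = 0, sub_rate_up1000 = 0,
                          indel_rate = 0, snv_sites_per_gene = 0,
                          large_effect_rate = 0, seed = 3)
  sim <- polyploidize(anc, cfg)
  expect_true(all(sim$truth$copy_counts$k == 3))
  expect_equal(nrow(sim$truth$mutations), 0L)
  for (i in seq_len(nrow(sim$copies))) {
    g <- sim$copies$gene_id[i]
    cid <- sim$copies$copy_id[i]
    expect_identical(as.character(sim$copy_cds[[cid]]),
                     as.character(anc$cds[[g]]))
    expect_identical(as.character(sim$copy_upstream[[cid]]),
                     as.character(anc$upstream[[g]]))
  }
})

test_that("polyploidize is deterministic under a fixed seed", {
  anc <- generate_ancestor(10, 1, seed = 4)
  s1 <- polyploidize(anc, polyploid_config(seed = 11))
  s2 <- polyploidize(anc, polyploid_config(seed = 11))
  expect_identical(as.character(s1$copy_cds), as.character(s2$copy_cds))
  expect_identical(s1$truth$mutations, s2$truth$mutations)
})

test_that("per-copy substitution counts follow the binomial model", {
  ## 1,000 copies of 300-nt CDS at rate 0.01: mean substitutions/copy
  ## within 3 standard errors of Binomial(300, 0.01) (interior positions
  ## are 294 of 300; the model excludes first/last codons)
  anc <- generate_ancestor(250, 1, c(`300` = 1), seed = 21)
  cfg <- polyploid_config(copy_count_dist = c(`4` = 1), sub_rate_cds = 0.01,
                          sub_rate_up100 = 0, sub_rate_up500 = 0,
                          sub_rate_up1000 = 0, indel_rate = 0,
                          snv_sites_per_gene = 0, large_effect_rate = 0,
                          seed = 21)
  sim <- polyploidize(anc, cfg)
  n_copies <- nrow(sim$copies)
  expect_equal(n_copies, 1000L)
  n_eff <- 294  # 300 minus first and last codon
  mean_subs <- nrow(sim$truth$mutations) / n_copies
  se <- sqrt(n_eff * 0.01 * 0.99 / n_copies)
  expect_lt(abs(mean_subs - n_eff * 0.01), 3 * se)
})

test_that("degenerate multiplicity distribution plants exactly 2 alleles", {
  anc <- generate_ancestor(30, 1, seed = 5)
  cfg <- polyploid_config(copy_count_dist = c(`4` = 1),
                          multiplicity_dist = c(`2` = 1),
                          snv_sites_per_gene = 3,
                          sub_rate_cds = 0, sub_rate_up100 = 0,
                          sub_rate_up500 = 0, sub_rate_up1000 = 0,
                          indel_rate = 0, large_effect_rate = 0, seed = 5)
  sim <- polyploidize(anc, cfg)
  expect_gt(nrow(sim$truth$sites), 0L)
  expect_true(all(sim$truth$sites$multiplicity == 2L))
})

test_that("every emitted copy is reconstructible from the ground truth", {
  sim <- small_sim()
  for (cid in sample(sim$copies$copy_id, 20)) {
    rc <- reconstruct_copy(sim, cid)
    expect_identical(rc$cds, as.character(sim$copy_cds[[cid]]), info = cid)
    expect_identical(rc$upstream, as.character(sim$copy_upstream[[cid]]),
                     info = cid)
  }
})

test_that("config validation rejects malformed distributions and rates", {
  expect_error(polyploid_config(copy_count_dist = c(`1` = 0.5, `2` = 0.4)),
               "sum")
  expect_error(polyploid_config(multiplicity_dist = c(`5` = 1)), "1..4")
  expect_error(polyploid_config(expressed_frac = 1.5), "\\[0, 1\\]")
  expect_error(polyploid_config(indel_rate = -1), "non-negative")
})

test_that("rearrangements: zero rates leave the layout unchanged", {
  sim <- subs_only_sim()
  out <- plant_rearrangements(sim, 0, 0)
  expect_identical(out$layout, sim$layout)
  expect_equal(nrow(out$truth$breakpoints), 0L)
})

test_that("a planted inversion reverses the run, flips strands and records 2 breakpoints", {
  anc <- generate_ancestor(10, 1, seed = 6)
  cfg <- uniform_k_config(k = 1, seed = 6)
  sim <- polyploidize(anc, cfg)
  ## force exactly one inversion by rate choice and seed scan
  done <- FALSE
  for (sd in 1:30) {
    out <- plant_rearrangements(sim, inversion_rate = 12,
                                translocation_rate = 0, seed = sd)
    if (nrow(out$truth$breakpoints) == 2L) { done <- TRUE; break }
  }
  expect_true(done)
  expect_true(all(out$truth$breakpoints$type == "inversion"))
  moved <- out$layout$copy_id != sim$layout$copy_id
  run <- which(moved)
  expect_gte(length(run), 2L)
  ## the moved run is the reverse of the original and strand-flipped
  expect_identical(out$layout$copy_id[run], rev(sim$layout$copy_id[run]))
  orig_strand <- stats::setNames(sim$layout$strand, sim$layout$copy_id)
  expect_true(all(out$layout$strand[run] !=
                    orig_strand[out$layout$copy_id[run]]))
})

test_that("fragmentation respects degenerate genes-per-contig distributions", {
  anc <- generate_ancestor(10, 1, seed = 8)
  sim <- polyploidize(anc, uniform_k_config(k = 1, seed = 8))
  ctg1 <- fragment_genome(sim, c(`1` = 1), seed = 1)
  expect_true(all(ctg1$contigs$n_genes == 1L))
  expect_equal(nrow(ctg1$contigs), 10L)
  ctg2 <- fragment_genome(sim, c(`2` = 1), seed = 1)
  expect_equal(nrow(ctg2$contigs), 5L)
  expect_true(all(ctg2$contigs$n_genes == 2L))
  ## every copy lands on exactly one contig
  expect_equal(sort(ctg2$contig_map$copy_id), sort(sim$copies$copy_id))
})

test_that("genes-per-contig frequencies converge to the target", {
  anc <- generate_ancestor(3000, 1, c(`300` = 1), seed = 12)
  sim0 <- list(layout = data.frame(copy_id = anc$genes$gene_id,
                                   gene_id = anc$genes$gene_id,
                                   copy_index = 1L, chromosome = "chr1_h1",
                                   order_index = anc$genes$order_index,
                                   strand = anc$genes$strand,
                                   position = seq_len(3000)),
               copy_cds = anc$cds, copy_upstream = anc$upstream,
               config = polyploid_config(seed = 12))
  class(sim0) <- "polyploid_sim"
  ctg <- fragment_genome(sim0, c(`1` = 0.5, `3` = 0.5), seed = 12,
                         spacer_len = 1L)
  tab <- table(ctg$contigs$n_genes)
  n <- sum(tab)
  p1 <- tab[["1"]] / n
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(p1 - 0.5), 3 * se)
})

test_that("expression states respect fractions and truncation", {
  sim <- subs_only_sim()
  all_on <- simulate_expression(sim, expressed_frac = 1, antisense_frac = 0,
                                seed = 2)
  expect_true(all(all_on$abundance$fpkm > 1))
  expect_true(all(all_on$abundance$orientation == "sense"))
  all_off <- simulate_expression(sim, expressed_frac = 0, antisense_frac = 0,
                                 seed = 2)
  expect_true(all(all_off$abundance$fpkm <= 1))
  expect_true(all(all_off$truth$state == "none"))
  ## determinism
  e1 <- simulate_expression(sim, seed = 5)
  e2 <- simulate_expression(sim, seed = 5)
  expect_identical(e1$abundance, e2$abundance)
})

test_that("simulation outputs are written deterministically", {
  sim <- subs_only_sim()
  ctg <- fragment_genome(sim, seed = 1)
  expr <- simulate_expression(sim, seed = 1)
  d1 <- file.path(tempdir(), "simout1")
  d2 <- file.path(tempdir(), "simout2")
  write_simulation(sim, ctg, expr, d1)
  write_simulation(sim, ctg, expr, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  ## contig FASTA + GFF3 agree with the contig map
  seqs <- Biostrings::readDNAStringSet(file.path(d1, "contigs.fasta"))
  expect_equal(sort(names(seqs)), sort(ctg$contigs$contig_id))
  m <- ctg$contig_map[1, ]
  cds <- substr(as.character(seqs[[m$contig_id]]), m$cds_start, m$cds_end)
  if (m$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  expect_identical(cds, as.character(sim$copy_cds[[m$copy_id]]))
})
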