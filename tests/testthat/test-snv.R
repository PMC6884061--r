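# helper: wrap sequences in alignment objects against a reference
align_copies <- function(ref, copies, mapq = NULL) {
  alns <- lapply(names(copies), function(id) {
    a <- align_global(ref, copies[[id]], query_id = "G1", subject_id = id)
    if (!is.null(mapq)) a$map_quality <- mapq[[id]]
    a
  })
  alns
}

REF <- paste0("ATG", strrep("GGA", 40), "TAA")  # 126 nt

test_that("site multiplicity counts distinct observed alleles", {
  expect_equal(site_multiplicity(c("A", "A", "T")), 2L)
  expect_equal(site_multiplicity(c("A", "A", "A")), 1L)
  expect_equal(site_multiplicity(c("G", "A", "C", "T")), 4L)
  expect_error(site_multiplicity(character(0)), "no observed")
})

test_that("a single aligned copy yields no sites", {
  copies <- list(c1 = sub("GGA", "GTA", REF))   # one substitution
  sites <- call_sites(align_copies(REF, copies),
                      Biostrings::DNAStringSet(c(G1 = REF)))
  expect_equal(nrow(sites), 0L)
})

test_that("mapping-quality filter is strict at 20", {
  copies <- list(c1 = sub("GGA", "GTA", REF), c2 = REF, c3 = REF)
  ref_set <- Biostrings::DNAStringSet(c(G1 = REF))
  ## mapq exactly 20 excludes c1; only identical copies remain -> no sites
  s20 <- call_sites(align_copies(REF, copies,
                                 mapq = list(c1 = 20L, c2 = 30L, c3 = 30L)),
                    ref_set)
  expect_equal(nrow(s20), 0L)
  ## mapq 21 keeps c1 -> one bi-allelic site (alt T on c1, ref on c2/c3)
  s21 <- call_sites(align_copies(REF, copies,
                                 mapq = list(c1 = 21L, c2 = 30L, c3 = 30L)),
                    ref_set)
  expect_equal(nrow(s21), 1L)
  expect_equal(s21$multiplicity, 2L)
  expect_equal(s21$alts, "T")
})

test_that("copies identical to the reference produce an empty site list", {
  copies <- list(c1 = REF, c2 = REF)
  sites <- call_sites(align_copies(REF, copies),
                      Biostrings::DNAStringSet(c(G1 = REF)))
  expect_equal(nrow(sites), 0L)
})

test_that("fixed non-reference alleles are mono-allelic; indels are separate sites", {
  mut <- paste0(substr(REF, 1, 9), "T", substr(REF, 11, nchar(REF)))
  copies <- list(c1 = mut, c2 = mut, c3 = mut)
  sites <- call_sites(align_copies(REF, copies),
                      Biostrings::DNAStringSet(c(G1 = REF)))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$multiplicity, 1L)

  del2 <- paste0(substr(REF, 1, 50), substr(REF, 53, nchar(REF)))
  copies2 <- list(c1 = del2, c2 = REF)
  sites2 <- call_sites(align_copies(REF, copies2),
                       Biostrings::DNAStringSet(c(G1 = REF)))
  expect_equal(sites2$type, "del")
  expect_equal(sites2$length, 2L)
  expect_equal(sites2$effect, "frameshift")
})

test_that("planted multiplicities are recovered exactly under full coverage", {
  anc <- generate_ancestor(40, 1, seed = 51)
  cfg <- polyploid_config(copy_count_dist = c(`5` = 1),
                          snv_sites_per_gene = 4,
                          sub_rate_cds = 0, sub_rate_up100 = 0,
                          sub_rate_up500 = 0, sub_rate_up1000 = 0,
                          indel_rate = 0, large_effect_rate = 0, seed = 51)
  sim <- polyploidize(anc, cfg)
  alns <- list()
  for (i in seq_len(nrow(sim$copies))) {
    alns[[i]] <- align_global(
      as.character(sim$ancestor$cds[[sim$copies$gene_id[i]]]),
      as.character(sim$copy_cds[[sim$copies$copy_id[i]]]),
      query_id = sim$copies$gene_id[i],
      subject_id = sim$copies$copy_id[i])
  }
  sites <- call_sites(alns, sim$ancestor$cds)
  truth <- sim$truth$sites
  key <- paste(sites$gene_id, sites$pos)
  tkey <- paste(truth$gene_id, truth$cds_pos)
  expect_setequal(key, tkey)
  m <- match(tkey, key)
  expect_equal(sites$multiplicity[m], truth$multiplicity)
  ## partial coverage never increases multiplicity (monotone under loss)
  drop <- sites
  for (i in seq_len(nrow(drop))) {
    obs <- strsplit(drop$observed[i], ",", fixed = TRUE)[[1]]
    obs <- vapply(strsplit(obs, "=", fixed = TRUE), `[`, "", 2)
    expect_lte(site_multiplicity(obs[-1]), drop$multiplicity[i])
  }
})

test_that("per-gene tallies conserve the global site count", {
  anc <- generate_ancestor(15, 1, seed = 52)
  cfg <- polyploid_config(copy_count_dist = c(`4` = 1),
                          snv_sites_per_gene = 5, sub_rate_cds = 0.002,
                          sub_rate_up100 = 0, sub_rate_up500 = 0,
                          sub_rate_up1000 = 0, indel_rate = 0,
                          large_effect_rate = 0, seed = 52)
  sim <- polyploidize(anc, cfg)
  alns <- list()
  for (i in seq_len(nrow(sim$copies))) {
    alns[[i]] <- align_global(
      as.character(sim$ancestor$cds[[sim$copies$gene_id[i]]]),
      as.character(sim$copy_cds[[sim$copies$copy_id[i]]]),
      query_id = sim$copies$gene_id[i],
      subject_id = sim$copies$copy_id[i])
  }
  sites <- call_sites(alns, sim$ancestor$cds)
  tab <- count_snvs_per_gene(sites)
  expect_equal(sum(tab$n_total), nrow(sites))
  expect_equal(sum(tab$mult1 + tab$mult2 + tab$mult3 + tab$mult4),
               sum(sites$type == "sub"))
  ## base-change cells sum to the number of (site, alt allele) pairs
  change_cols <- grep(">", names(tab), fixed = TRUE, value = TRUE)
  n_alt <- sum(lengths(strsplit(sites$alts[sites$type == "sub"], ",")))
  expect_equal(sum(as.matrix(tab[, change_cols])), n_alt)
  ## collapsed 4-class table conserves the same total
  tab4 <- count_snvs_per_gene(sites, collapse_ref_base = TRUE)
  ref_cols <- grep("^ref[ACGT]$", names(tab4), value = TRUE)
  expect_equal(sum(as.matrix(tab4[, ref_cols])), n_alt)
})

test_that("binomial enrichment matches the exact tail sum", {
  bg <- data.frame(gene_id = sprintf("g%03d", 1:100),
                   term = rep(c("T1", "T2"), times = c(10, 90)))
  gs <- sprintf("g%03d", 1:10)        # all 10 T1 genes
  ann <- bg[bg$gene_id %in% gs, ]
  res <- binomial_enrichment(gs, ann, bg)
  r1 <- res[res$term == "T1", ]
  expect_equal(r1$k, 10)
  expect_equal(r1$p, 0.1)
  expect_equal(r1$p_value, exact_binom_upper(10, 10, 0.1), tolerance = 1e-12)
  ## p = 0.1, n = 10, k = 5 against the explicit summation
  expect_equal(stats::pbinom(4, 10, 0.1, lower.tail = FALSE),
               exact_binom_upper(5, 10, 0.1), tolerance = 1e-14)
})

test_that("enrichment degenerate cases: k = 0 and p = 1 give p-value 1", {
  bg <- data.frame(gene_id = sprintf("g%d", 1:20),
                   term = rep("ALL", 20))
  gs <- sprintf("g%d", 1:5)
  res <- binomial_enrichment(gs, bg[bg$gene_id %in% gs, ], bg)
  expect_equal(res$p_value[res$term == "ALL"], 1)   # p = 1
  expect_false(res$significant[res$term == "ALL"])
  expect_error(binomial_enrichment(c("absent"), bg, bg), "absent")
})

test_that("VCF output carries one record per site with INFO keys", {
  copies <- list(c1 = sub("GGA", "GCA", REF), c2 = REF)
  sites <- call_sites(align_copies(REF, copies),
                      Biostrings::DNAStringSet(c(G1 = REF)))
  path <- tempfile(fileext = ".vcf")
  write_sites_vcf(sites, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(sites))
  expect_match(body[1], "MULT=2;EFFECT=none;NCOPIES=2")
})
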