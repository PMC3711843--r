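# Synthetic-data generator: determinism, planted-truth bookkeeping and the
# statistical properties of the stated data regime.

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(cds_len_range = c(150, 300)), "201")
  expect_error(simulation_config(psv_rate = 0.2), "90%")
  expect_error(simulation_config(clean_flanks = TRUE, snp_rate = 0.01),
               "102 bp apart")
  expect_error(simulation_config(snps_per_gene = 1), "clean_flanks")
  expect_silent(simulation_config(clean_flanks = TRUE, snp_rate = 0.004))
})

test_that("a single intronless gene has identical coding and genomic copies", {
  cfg <- simulation_config(n_single = 1, n_two = 0, n_three = 0,
                           intron_count_range = c(0, 0), seed = 5)
  ref <- simulate_reference(cfg)
  expect_length(ref$gene_models, 1L)
  expect_identical(unname(ref$gene_models), unname(ref$genomic))
  expect_identical(nrow(ref$psv_sites), 0L)
  expect_identical(nrow(ref$junctions), 0L)
})

test_that("identical config and seed reproduce outputs byte-for-byte", {
  cfg <- simulation_config(n_single = 4, n_two = 2, n_three = 1, seed = 99)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$ref$gene_models, b2$ref$gene_models)
  expect_identical(b1$contigs, b2$contigs)
  expect_identical(b1$depth, b2$depth)
  expect_identical(b1$truth, b2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(b1$contigs, f1); write_fasta(b2$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted PSV counts follow the binomial expectation", {
  counts <- vapply(1:30, function(s) {
    cfg <- simulation_config(n_single = 0, n_two = 10, n_three = 0,
                             psv_rate = 0.01, cds_len_range = c(1000, 1000),
                             intron_count_range = c(0, 0), seed = 1000 + s)
    ref <- simulate_reference(cfg)
    length(unique(paste(ref$psv_sites$family_id, ref$psv_sites$position)))
  }, numeric(1))
  expected <- 10 * 1000 * 0.01
  sd3 <- 3 * sqrt(10 * 1000 * 0.01 * 0.99) / sqrt(30)
  expect_lt(abs(mean(counts) - expected), sd3)
})

test_that("paralog family members stay above 90% identity yet differ at PSVs", {
  cfg <- simulation_config(n_single = 0, n_two = 5, n_three = 3,
                           psv_rate = 0.05, seed = 17)
  ref <- simulate_reference(cfg)
  for (fam in unique(ref$paralog_table$family_id)) {
    genes <- ref$paralog_table$gene_id[ref$paralog_table$family_id == fam]
    s1 <- strsplit(ref$gene_models[[genes[1]]], "")[[1]]
    s2 <- strsplit(ref$gene_models[[genes[2]]], "")[[1]]
    ident <- mean(s1 == s2)
    expect_gte(ident, 0.90)
    psv <- ref$psv_sites[ref$psv_sites$family_id == fam, ]
    p1 <- psv$base[psv$gene_id == genes[1]]
    p2 <- psv$base[psv$gene_id == genes[2]]
    if (length(p1)) expect_true(any(p1 != p2))
  }
})

test_that("zero divergence yields alleles identical to the reference", {
  cfg <- simulation_config(n_single = 3, n_two = 1, n_three = 0,
                           snp_rate = 0, seed = 7)
  ref <- simulate_reference(cfg)
  sim <- simulate_line(ref, "lineX", snp_rate = 0, seed = 8)
  expect_identical(sim$alleles[names(ref$gene_models)],
                   setNames(ref$gene_models, names(ref$gene_models)))
  expect_identical(nrow(sim$truth_snps), 0L)
})

test_that("every inter-line difference is present in the ground truth", {
  cfg <- simulation_config(n_single = 6, n_two = 2, n_three = 1,
                           snp_rate = 0.01, seed = 31)
  ref <- simulate_reference(cfg)
  sim <- simulate_line(ref, "lineX", seed = 32)
  for (gid in names(ref$gene_models)) {
    a <- strsplit(ref$gene_models[[gid]], "")[[1]]
    b <- strsplit(sim$alleles[[gid]], "")[[1]]
    diffs <- which(a != b)
    truth <- sim$truth_snps[sim$truth_snps$gene_id == gid, ]
    expect_identical(diffs, truth$position, label = gid)
    if (nrow(truth)) {
      expect_identical(a[diffs], truth$ref_base)
      expect_identical(b[diffs], truth$alt_base)
    }
  }
})

test_that("planted SSR repeat counts differ per line at the same locus", {
  cfg <- simulation_config(
    n_single = 4, n_two = 0, n_three = 0, snp_rate = 0,
    ssr_spec = list(list(motif = "AG", counts = c(ref = 6, X = 6, Y = 8))),
    lines = c("X", "Y"), seed = 3)
  ref <- simulate_reference(cfg)
  sx <- simulate_line(ref, "X", seed = 4)
  sy <- simulate_line(ref, "Y", seed = 5)
  gid <- ref$ssr_plan$gene_id[1]
  st <- ref$ssr_plan$start[1]
  expect_identical(substr(sx$alleles[[gid]], st, st + 11), strrep("AG", 6))
  expect_identical(substr(sy$alleles[[gid]], st, st + 15), strrep("AG", 8))
  # flanks outside the repeat are identical between lines
  expect_identical(substr(sx$alleles[[gid]], st - 50, st - 1),
                   substr(sy$alleles[[gid]], st - 50, st - 1))
})

test_that("clean-flank mode spaces SNPs and respects junction margins", {
  cfg <- simulation_config(n_single = 20, n_two = 5, n_three = 0,
                           snp_rate = 0.004, clean_flanks = TRUE, seed = 50)
  ref <- simulate_reference(cfg)
  sim <- simulate_line(ref, "ln", seed = 51)
  truth <- sim$truth_snps
  expect_true(all(truth$flank_clean))
  expect_false(any(truth$junction_in_window))
  for (gid in unique(truth$gene_id)) {
    pos <- sort(truth$position[truth$gene_id == gid])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 102))
  }
})

test_that("fragmentation emits substrings with matching depth tracks", {
  cfg <- simulation_config(n_single = 6, n_two = 2, n_three = 0,
                           contig_coverage = 1, strand_random = FALSE,
                           depth_law = list(dist = "constant", value = 10),
                           seed = 60)
  ref <- simulate_reference(cfg)
  sim <- simulate_line(ref, "ln", seed = 61)
  frag <- fragment_to_contigs(sim, ref, seed = 62)
  expect_identical(length(frag$contigs), length(sim$alleles))
  expect_identical(unname(nchar(frag$contigs)), unname(lengths(frag$depth)))
  expect_true(all(unlist(frag$depth) == 10L))
  for (i in seq_len(nrow(frag$contig_info))) {
    ci <- frag$contig_info[i, ]
    expect_identical(unname(frag$contigs[[ci$contig_id]]),
                     substr(sim$alleles[[ci$gene_id]], ci$start, ci$end))
  }
})

test_that("partial coverage puts about that fraction of SNPs on contigs", {
  cfg <- simulation_config(n_single = 120, n_two = 0, n_three = 0,
                           snp_rate = 0.01, contig_coverage = 0.6,
                           cds_len_range = c(600, 600),
                           intron_count_range = c(0, 0), seed = 70)
  b <- simulate_bundle(cfg)
  frac <- mean(b$truth$snp_sites$on_contig)
  expect_lt(abs(frac - 0.6), 0.06)
})

test_that("planted depth failures receive depth 6 at the SNP base", {
  cfg <- simulation_config(n_single = 10, n_two = 0, n_three = 0,
                           clean_flanks = TRUE, snps_per_gene = 1,
                           contig_coverage = 1, fail_depth = 0.3, seed = 80)
  b <- simulate_bundle(cfg)
  t <- b$truth$snp_sites
  failed <- t[t$plant_depth_fail, ]
  expect_identical(nrow(failed), 3L)
  expect_true(all(failed$depth == 6L))
  expect_false(any(failed$depth_ok))
  for (i in seq_len(nrow(failed))) {
    expect_identical(b$depth[[failed$contig_id[i]]][failed$contig_pos[i]], 6L)
  }
})

test_that("RIL simulation honours linkage, independence and map checks", {
  map <- data.frame(marker_id = c("a", "b", "c"), group = c(1, 1, 2),
                    pos_cm = c(0, 0, 0))
  pop <- simulate_ril_population(map, n_individuals = 200, seed = 9)
  g <- pop$genotypes
  expect_identical(unname(g["a", ]), unname(g["b", ]))  # 0 cM apart
  inf <- g["a", ] %in% c("A", "B") & g["c", ] %in% c("A", "B")
  rf <- mean(g["a", inf] != g["c", inf])
  expect_lt(abs(rf - 0.5), 0.12)  # unlinked groups
  bad <- data.frame(marker_id = c("a", "b"), group = 1, pos_cm = c(5, 1))
  expect_error(simulate_ril_population(bad), "sorted")
  expect_error(simulate_ril_population(map, n_individuals = 1), ">= 2")
})

test_that("F7 residual heterozygosity is close to 1/64", {
  map <- data.frame(marker_id = sprintf("m%03d", 1:100),
                    group = 1:100, pos_cm = 0)
  pop <- simulate_ril_population(map, n_individuals = 100, generation = 7,
                                 seed = 12)
  het <- mean(pop$genotypes == "H")
  p <- 1 / 64
  se <- sqrt(p * (1 - p) / length(pop$genotypes))
  expect_lt(abs(het - p), 4 * se)
})
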