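# The three-criteria marker cascade: window geometry, flank conservation,
# junction detection, PSV classification and assay emission.

test_that("window extraction has exact 50+1+50 geometry", {
  set.seed(31)
  contig <- random_dna(101)
  w <- extract_window(contig, 51)
  expect_identical(w$status, "ok")
  expect_identical(w$window, contig)   # exact fit
  expect_identical(nchar(w$window), 101L)
  gene <- random_dna(300)
  w2 <- extract_window(gene, 150)
  expect_identical(w2$start, 100L)
  expect_identical(w2$end, 200L)
  expect_identical(substr(w2$window, 51, 51), substr(gene, 150, 150))
  expect_identical(extract_window(gene, 30)$status, "insufficient_flank")
  expect_identical(extract_window(gene, 251)$status, "insufficient_flank")
  expect_identical(extract_window(gene, 50)$status, "insufficient_flank")
  expect_identical(extract_window(gene, 51)$status, "ok")
  expect_error(extract_window(gene, 301), "outside")
})

test_that("flank conservation demands 50 identical gap-free columns", {
  set.seed(32)
  s <- random_dna(201)
  expect_true(check_flank_conservation(s, s, 101)$conserved)
  # substitution at flank offset -12
  q <- paste0(substr(s, 1, 88),
              setdiff(c("A", "C", "G", "T"), substr(s, 89, 89))[1],
              substr(s, 90, 201))
  fc <- check_flank_conservation(q, s, 101)
  expect_false(fc$conserved)
  expect_identical(fc$reason, "flank_mismatch")
  # gap column in a flank
  qg <- paste0(substr(s, 1, 120), "-", substr(s, 122, 201))
  expect_false(check_flank_conservation(qg, s, 101)$conserved)
  # substitution outside the 50-column flank does not matter
  q2 <- paste0(setdiff(c("A", "C", "G", "T"), substr(s, 1, 1))[1],
               substr(s, 2, 201))
  expect_true(check_flank_conservation(q2, s, 101)$conserved)
  # window running off the alignment
  expect_identical(check_flank_conservation(s, s, 30)$reason,
                   "uncovered_window")
})

test_that("junctions strictly inside the window reject, outside do not", {
  set.seed(33)
  cds <- random_dna(400)
  intron <- paste0("GT", random_dna(96), "AG")
  snp_pos <- 200L
  w <- extract_window(cds, snp_pos)$window
  # intronless gene: every window is junction-free
  expect_true(check_junctions(w, cds)$junction_free)
  # junction at window offset 70 (insertion after coding base 219)
  genomic_in <- paste0(substr(cds, 1, 219), intron, substr(cds, 220, 400))
  jc <- check_junctions(w, genomic_in)
  expect_false(jc$junction_free)
  expect_identical(jc$reason, "junction_in_window")
  # junction 10 bp outside the window (after base 260 > 250)
  genomic_out <- paste0(substr(cds, 1, 260), intron, substr(cds, 261, 400))
  expect_true(check_junctions(w, genomic_out)$junction_free)
  # window aligning nowhere
  nohit <- check_junctions(w, random_dna(300))
  expect_false(nohit$junction_free)
})

test_that("paralog-site classification matches the 256-case truth table", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(p1_l1 = bases, p1_l2 = bases, p2_l1 = bases,
                        p2_l2 = bases, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    b <- unlist(combos[i, ])
    seqs <- list(
      line1 = c(p1 = paste0("AC", b[["p1_l1"]], "GT"),
                p2 = paste0("AC", b[["p2_l1"]], "GT")),
      line2 = c(p1 = paste0("AC", b[["p1_l2"]], "GT"),
                p2 = paste0("AC", b[["p2_l2"]], "GT")))
    got <- classify_paralog_sites(seqs)
    row <- got$sites[got$sites$position == 3L, ]
    want <- oracle_classify_2x2(c(b[["p1_l1"]], b[["p1_l2"]],
                                  b[["p2_l1"]], b[["p2_l2"]]))
    if (want == "invariant") {
      expect_identical(nrow(row), 0L)
    } else {
      expect_identical(row$class, want)
      if (want == "allelic_snp") {
        expect_identical(row$paralog,
                         if (b[["p1_l1"]] != b[["p1_l2"]]) "p1" else "p2")
      }
    }
  }
})

test_that("classification rejects unusable inputs", {
  expect_error(classify_paralog_sites(list(l1 = c(p1 = "ACGT", p2 = "ACGT"))),
               "two lines")
  expect_error(classify_paralog_sites(list(l1 = c(p1 = "ACGT"),
                                           l2 = c(p1 = "ACGT"))),
               "two named paralogs")
  expect_error(classify_paralog_sites(list(l1 = c(p1 = "ACGT", p2 = "ACG"),
                                           l2 = c(p1 = "ACGT", p2 = "ACG"))),
               "equal length")
})

test_that("paralog-specific design requires a PSV inside a flank", {
  set.seed(34)
  target <- random_dna(300)
  pos <- 150L
  ok <- design_paralog_specific_marker(target, pos, "A", "G",
                                       psv_positions = c(170L))
  expect_identical(ok$status, "ok")
  expect_identical(ok$psv_offsets, 20L)
  far <- design_paralog_specific_marker(target, pos, "A", "G",
                                        psv_positions = c(230L))
  expect_identical(far$status, "no_discriminating_psv")
  both <- design_paralog_specific_marker(target, pos, "A", "G",
                                         psv_positions = c(130L, 170L),
                                         require_both_flanks = TRUE)
  expect_identical(both$status, "ok")
  onesided <- design_paralog_specific_marker(target, pos, "A", "G",
                                             psv_positions = c(170L),
                                             require_both_flanks = TRUE)
  expect_identical(onesided$status, "no_discriminating_psv")
  # bracket geometry: 101 window chars + "[X/Y]" replaces one base
  expect_identical(nchar(ok$target_sequence), 105L)
  expect_identical(substr(ok$target_sequence, 51, 55), "[A/G]")
})

test_that("residual variants are rendered as IUPAC degeneracy codes", {
  set.seed(35)
  target <- random_dna(300)
  resid_pos <- 120L
  resid_base <- substr(target, resid_pos, resid_pos)
  other <- setdiff(c("A", "C", "G", "T"), resid_base)[1]
  des <- design_paralog_specific_marker(
    target, 150L, "A", "G", psv_positions = 170L,
    residual = data.frame(position = resid_pos,
                          bases = I(list(other))))
  expect_identical(des$status, "ok")
  # window starts at 100; residual offset inside window = 21
  got <- substr(des$target_sequence, 21, 21)
  expect_false(got %in% c("A", "C", "G", "T"))
})

test_that("the cascade recovers exactly the planted expected markers", {
  b <- clean_bundle_small()
  res <- run_cascade(b$contigs, b$ref$gene_models, b$ref$genomic, b$depth,
                     b$ref$paralog_table, b$contig_lines)
  cand <- res$candidates
  expect_setequal(cand$snp_id[cand$accepted], b$truth$expected_marker_ids)
  expect_identical(nrow(res$markers), length(b$truth$expected_marker_ids))
})

test_that("funnel counts are non-increasing and shuffle-stable", {
  b <- clean_bundle_small()
  res <- run_cascade(b$contigs, b$ref$gene_models, b$ref$genomic, b$depth,
                     b$ref$paralog_table, b$contig_lines)
  expect_true(all(diff(res$funnel$n_sites) <= 0))
  expect_true(all(diff(res$funnel$n_genes) <= 0))
  perm <- sample(length(b$contigs))
  res2 <- run_cascade(b$contigs[perm], b$ref$gene_models, b$ref$genomic,
                      b$depth, b$ref$paralog_table, b$contig_lines)
  expect_identical(res$funnel, res2$funnel)
  expect_setequal(res$markers$marker_id, res2$markers$marker_id)
})

test_that("accepted set is invariant to criterion evaluation order", {
  b <- clean_bundle_small()
  res <- run_cascade(b$contigs, b$ref$gene_models, b$ref$genomic, b$depth,
                     b$ref$paralog_table, b$contig_lines)
  cand <- res$candidates
  # each criterion is an independent per-candidate flag; intersecting the
  # flags in any order gives the same accepted set
  orders <- list(c("flank_ok", "junction_free", "depth_ok"),
                 c("depth_ok", "flank_ok", "junction_free"),
                 c("junction_free", "depth_ok", "flank_ok"))
  base_ids <- cand$snp_id[cand$accepted]
  for (ord in orders) {
    keep <- rep(TRUE, nrow(cand))
    for (flag in ord) keep <- keep & cand[[flag]]
    expect_setequal(cand$snp_id[keep & cand$paralog_ok], base_ids)
  }
})

test_that("an extreme depth threshold empties the cascade monotonically", {
  b <- clean_bundle_small()
  res <- run_cascade(b$contigs, b$ref$gene_models, b$ref$genomic, b$depth,
                     b$ref$paralog_table, b$contig_lines, min_depth = 10^9)
  expect_identical(nrow(res$markers), 0L)
  expect_true(all(diff(res$funnel$n_sites) <= 0))
})

test_that("assay table round-trips and has bracketed 105-char targets", {
  b <- clean_bundle_small()
  res <- run_cascade(b$contigs, b$ref$gene_models, b$ref$genomic, b$depth,
                     b$ref$paralog_table, b$contig_lines)
  mk <- res$markers
  expect_true(all(nchar(mk$target_sequence) == 105L))
  expect_true(all(substr(mk$target_sequence, 51, 51) == "["))
  expect_identical(substr(mk$target_sequence, 52, 52), mk$ref_base)
  expect_identical(substr(mk$target_sequence, 54, 54), mk$alt_base)
  expect_true(all(vapply(gregexpr("\\[", mk$target_sequence), length,
                         integer(1)) == 1L))
  # per-base depth decomposition assigns the contig depth to the alt base
  picked <- vapply(seq_len(nrow(mk)), function(i) {
    mk[i, paste0("depth_", mk$alt_base[i])]
  }, integer(1))
  expect_identical(picked, mk$depth)
  # paralog markers carry PSV offsets
  par <- mk[mk$paralog_specific, ]
  if (nrow(par)) expect_true(all(!is.na(par$psv_offsets)))
  path <- tempfile()
  write_assay_table(mk, path)
  back <- read_assay_table(path)
  expect_identical(back$marker_id, mk$marker_id)
  expect_identical(back$target_sequence, mk$target_sequence)
  expect_identical(back$snp_pos_gene, mk$snp_pos_gene)
})
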