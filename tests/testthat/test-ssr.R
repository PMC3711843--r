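# SSR detection with MISA-style thresholds and the strict flank-identity
# polymorphism rule.

test_that("constructed repeats are detected with exact geometry", {
  set.seed(11)
  left <- "GACTGACCTG"; right <- "CTGACCTGAC"  # repeat-free flanks
  s <- c(x = paste0(left, strrep("A", 12), right))
  loci <- detect_ssrs(s)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$motif, "A")
  expect_identical(loci$repeat_count, 12L)
  expect_identical(loci$start, 11L)
  expect_identical(loci$end, 22L)
  # locus length invariant
  expect_identical(loci$end - loci$start + 1L, loci$unit * loci$repeat_count)
})

test_that("runs below the per-class minimum are not reported", {
  below <- c(x = paste0("GACTGACCTG", strrep("AG", 5), "CTGACCTGAC"))
  expect_identical(nrow(detect_ssrs(below)), 0L)
  at <- c(x = paste0("GACTGACCTG", strrep("AG", 6), "CTGACCTGAC"))
  expect_identical(detect_ssrs(at)$repeat_count, 6L)
})

test_that("motifs are canonicalised and periodic units suppressed", {
  s <- c(x = paste0("CCTGACCTGC", strrep("GA", 7), "TCCTGACCTG"))
  loci <- detect_ssrs(s)
  expect_identical(loci$motif, "AG")  # smallest rotation of GA
  expect_identical(loci$unit, 2L)    # never reported as GAGA at unit 4
  expect_identical(nrow(loci), 1L)
})

test_that("N bases break SSR runs", {
  s <- c(x = paste0("GACTGACCTG", strrep("A", 8), "N", strrep("A", 8),
                    "CTGACCTGAC"))
  expect_identical(nrow(detect_ssrs(s)), 0L)  # both halves below minimum 10
})

test_that("nearby SSRs are additionally reported as one complex locus", {
  s <- c(x = paste0("GACTGACCTG", strrep("AT", 8), "GACCTG",
                    strrep("CT", 7), "CTGACCTGAC"))
  loci <- detect_ssrs(s)
  expect_identical(sum(loci$kind == "simple"), 2L)
  cx <- loci[loci$kind == "complex", ]
  expect_identical(nrow(cx), 1L)
  expect_identical(cx$start, min(loci$start[loci$kind == "simple"]))
  expect_identical(cx$end, max(loci$end[loci$kind == "simple"]))
  # far apart -> no complex locus
  s2 <- c(x = paste0("GACTGACCTG", strrep("AT", 8), random_dna(150),
                     strrep("CT", 7), "CTGACCTGAC"))
  expect_identical(sum(detect_ssrs(s2)$kind == "complex"), 0L)
})

test_that("detection matches the regex oracle on random sequences", {
  set.seed(12)
  for (trial in 1:60) {
    s <- random_dna(2000)
    impl <- detect_ssrs(c(x = s))
    impl <- impl[impl$kind == "simple",
                 c("unit", "motif", "start", "end", "repeat_count")]
    rownames(impl) <- NULL
    oracle <- oracle_ssrs(s)
    rownames(oracle) <- NULL
    expect_identical(impl[order(impl$start, impl$unit), ],
                     oracle[order(oracle$start, oracle$unit),
                            c("unit", "motif", "start", "end", "repeat_count")])
  }
})

test_that("reverse-complement detection yields mirrored loci", {
  set.seed(13)
  for (trial in 1:20) {
    s <- random_dna(1500)
    fwd <- detect_ssrs(c(x = s))
    rev <- detect_ssrs(c(x = revcomp(s)))
    fwd <- fwd[fwd$kind == "simple", ]
    rev <- rev[rev$kind == "simple", ]
    expect_identical(nrow(fwd), nrow(rev))
    if (nrow(fwd)) {
      L <- nchar(s)
      mirrored <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L)
      mirrored <- mirrored[order(mirrored$start), ]
      expect_identical(fwd$start[order(fwd$start)], mirrored$start)
      expect_identical(fwd$end[order(fwd$start)], mirrored$end)
    }
  }
})

test_that("lowering a class minimum never removes a reported locus", {
  set.seed(14)
  s <- c(x = random_dna(3000))
  strict <- detect_ssrs(s)
  loose <- detect_ssrs(s, minima = c(8L, 5L, 4L, 4L, 4L, 4L))
  strict_keys <- with(strict[strict$kind == "simple", ],
                      paste(motif, start, end))
  loose_keys <- with(loose[loose$kind == "simple", ],
                     paste(motif, start, end))
  expect_true(all(strict_keys %in% loose_keys))
})

test_that("polymorphism requires identical flanks and different counts", {
  set.seed(15)
  flank_l <- random_dna(60); flank_r <- random_dna(60)
  a <- c(g1 = paste0(flank_l, strrep("AG", 6), flank_r))
  b_poly <- c(g1 = paste0(flank_l, strrep("AG", 8), flank_r))
  flank_l_mut <- paste0(substr(flank_l, 1, 47), "T",
                        substr(flank_l, 49, 60))
  if (substr(flank_l, 48, 48) == "T") {
    flank_l_mut <- paste0(substr(flank_l, 1, 47), "C", substr(flank_l, 49, 60))
  }
  b_flankmut <- c(g1 = paste0(flank_l_mut, strrep("AG", 8), flank_r))
  b_same <- a
  cmp <- compare_ssrs(detect_ssrs(a), detect_ssrs(b_poly))
  expect_true(cmp$polymorphic)
  cmp2 <- compare_ssrs(detect_ssrs(a), detect_ssrs(b_flankmut))
  expect_true(nrow(cmp2) == 0L || !any(cmp2$polymorphic))
  cmp3 <- compare_ssrs(detect_ssrs(a), detect_ssrs(b_same))
  expect_false(any(cmp3$polymorphic))
})

test_that("loci with short flanks are excluded and counted", {
  a <- c(g1 = paste0(strrep("AG", 6), random_dna(60)))  # no left flank
  b <- c(g1 = paste0(strrep("AG", 8), random_dna(60)))
  cmp <- compare_ssrs(detect_ssrs(a), detect_ssrs(b))
  expect_identical(nrow(cmp), 0L)
  expect_gte(attr(cmp, "excluded_short_flank"), 2L)
})

test_that("sharing summary is symmetric and matches planted truth", {
  cfg <- simulation_config(
    n_single = 6, n_two = 0, n_three = 0, snp_rate = 0,
    ssr_spec = list(list(motif = "AG", counts = c(ref = 6, X = 8, Y = 6)),
                    list(motif = "TTC", counts = c(ref = 5, X = 5, Y = 7))),
    lines = c("X", "Y"), contig_coverage = 1, seed = 16)
  b <- simulate_bundle(cfg)
  loci <- c(list(ref = detect_ssrs(b$ref$gene_models)),
            lapply(b$lines, function(l) detect_ssrs(l$alleles)))
  sh <- summarize_ssr_sharing(loci)
  expect_true(isSymmetric(sh$pairwise))
  # planted: ref-vs-X differs at AG locus, ref-vs-Y at TTC locus,
  # X-vs-Y at both
  expect_identical(sh$pairwise["ref", "X"], 1L)
  expect_identical(sh$pairwise["ref", "Y"], 1L)
  expect_identical(sh$pairwise["X", "Y"], 2L)
  # permuting line order leaves the summary unchanged
  sh2 <- summarize_ssr_sharing(loci[c(3, 1, 2)])
  expect_identical(sh$pairwise, sh2$pairwise[rownames(sh$pairwise),
                                             colnames(sh$pairwise)])
  # identical lines share nothing
  sh3 <- summarize_ssr_sharing(list(p = loci$ref, q = loci$ref))
  expect_identical(sh3$pairwise["p", "q"], 0L)
})
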