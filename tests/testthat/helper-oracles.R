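# Independent oracles and shared fixtures for the test suite. Every oracle
# is a separate computation route from the implementation it checks:
# alignment via Biostrings' aligner, SSRs via backreference regexes,
# classification via a hand-coded truth table, likelihoods via direct
# binomial evaluation.

# --- fixture cache (expensive bundles built once per test run) -------------

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- alignment oracle: Biostrings Smith-Waterman ---------------------------
# Same scoring scheme (match 2, mismatch -3, linear gap -5) but a wholly
# independent implementation.

oracle_local_align <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  a <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                     substitutionMatrix = mat,
                                     gapOpening = 0, gapExtension = 5)
  list(score = Biostrings::score(a),
       matches = Biostrings::nmatch(a),
       columns = nchar(as.character(Biostrings::alignedPattern(a))))
}

# --- SSR oracle: PCRE backreference enumeration ----------------------------

oracle_ssrs <- function(s, minima = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  rows <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, minima[u] - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      unit <- substr(s, m[i], m[i] + u - 1L)
      periodic <- FALSE
      if (u > 1L) {
        for (d in seq_len(u - 1L)) {
          if (u %% d == 0L && strrep(substr(unit, 1L, d), u %/% d) == unit) {
            periodic <- TRUE
            break
          }
        }
      }
      if (periodic) next
      count <- lens[i] %/% u
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, motif = oracle_canonical(unit), start = m[i],
        end = m[i] + count * u - 1L, repeat_count = count,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(unit = integer(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      repeat_count = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit), ]
}

oracle_canonical <- function(unit) {
  u <- nchar(unit)
  min(vapply(seq_len(u), function(i) {
    paste0(substr(unit, i, u), substr(unit, 1L, i - 1L))
  }, character(1)))
}

# --- paralog-site truth table (2 paralogs x 2 lines) -----------------------
# b = c(p1_line1, p1_line2, p2_line1, p2_line2); hand-coded case logic.

oracle_classify_2x2 <- function(b) {
  p1_varies <- b[1L] != b[2L]
  p2_varies <- b[3L] != b[4L]
  if (!p1_varies && !p2_varies) {
    if (b[1L] == b[3L]) return("invariant")
    return("psv")
  }
  if (p1_varies && p2_varies) return("conflict")
  "allelic_snp"
}

# --- direct binomial log-likelihood ratio for the LOD score ----------------

oracle_lod <- function(R, n) {
  k <- round(R * n)
  l1 <- stats::dbinom(k, n, max(R, 1e-12), log = TRUE)
  l0 <- stats::dbinom(k, n, 0.5, log = TRUE)
  (l1 - l0) / log(10)
}

# --- FASTQ writing for read-QC fixtures ------------------------------------

write_fastq_file <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                 intToUtf8(quals[[i]] + 33L)), con)
  }
  invisible(path)
}

# small clean bundle reused across tests
clean_bundle_small <- function() {
  cached_fixture("clean_small", function() {
    cfg <- simulation_config(n_single = 12, n_two = 4, n_three = 2,
                             snp_rate = 0.004, clean_flanks = TRUE,
                             contig_coverage = 1,
                             cds_len_range = c(400L, 900L), seed = 421L)
    b <- simulate_bundle(cfg)
    b$contig_lines <- setNames(b$contig_info$line, b$contig_info$contig_id)
    b
  })
}
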