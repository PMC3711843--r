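# Synthetic reference + line + contig generator with planted, machine-readable
# ground truth. The generator states a data regime -- gene families with one,
# two or three paralogs carrying fixed inter-paralog differences (PSVs),
# line-specific allelic SNPs, SSR repeat-length variants, intron-bearing
# genomic copies and partial contigs with per-base read depth -- so that every
# downstream stage of the marker pipeline can be tested against known truth.

#' Build a simulation configuration
#'
#' Collects and validates all knobs of the synthetic-data generator. Counts
#' are family counts (a two-paralog family contributes two gene models).
#' Identical configuration and seed reproduce every simulated output
#' byte-for-byte.
#'
#' @param n_single,n_two,n_three number of single-copy genes, two-paralog
#'   families and three-paralog families.
#' @param cds_len_range min/max coding length in bp; the minimum must be at
#'   least 201 so a centered 101 bp assay window always fits.
#' @param intron_count_range introns per genomic gene copy (min/max).
#' @param intron_len_range intron length range in bp; the minimum must be at
#'   least 60 so a junction inside an assay window reliably breaks the
#'   window's alignment to the genomic copy.
#' @param psv_rate per-base probability of a fixed inter-paralog difference;
#'   capped at 0.08 so family members keep >= 90\% identity.
#' @param snp_rate per-base probability of an inter-line allelic difference.
#' @param ssr_spec list of planted SSR loci, each a list with `motif` (1-6 bp
#'   unit) and `counts` (named integer vector of repeat counts per line; the
#'   name `"ref"` addresses the reference line). Each entry occupies one
#'   single-copy gene, which then carries no SNPs.
#' @param contig_coverage fraction of each coding sequence represented by the
#'   emitted contig, in (0, 1].
#' @param depth_law per-base depth distribution: `list(dist = "nbinom",
#'   mu, size)` or `list(dist = "constant", value)`.
#' @param lines character vector of non-reference line ids.
#' @param clean_flanks if `TRUE`, planted SNPs are spaced >= 102 bp apart and
#'   kept >= 51 bp away from exon-intron junctions and sequence ends, so each
#'   marker criterion can be evaluated in isolation.
#' @param snps_per_gene optional fixed number of SNPs per gene (clean-flank
#'   mode only); `NULL` draws a binomial count from `snp_rate`.
#' @param fail_flank,fail_junction,fail_depth fractions of single-copy genes
#'   deliberately planted to fail exactly one marker criterion (clean-flank
#'   mode only; the three sets are disjoint).
#' @param strand_random if `TRUE`, contigs are emitted on a random strand.
#' @param seed integer random seed (< 2^31 - 10^6).
#' @return an object of class `transmark_config` (a validated list).
#' @export
simulation_config <- function(n_single = 60, n_two = 25, n_three = 15,
                              cds_len_range = c(400L, 1600L),
                              intron_count_range = c(1L, 5L),
                              intron_len_range = c(80L, 300L),
                              psv_rate = 0.03, snp_rate = 0.01,
                              ssr_spec = list(),
                              contig_coverage = 0.8,
                              depth_law = list(dist = "nbinom", mu = 120, size = 5),
                              lines = "tetra",
                              clean_flanks = FALSE,
                              snps_per_gene = NULL,
                              fail_flank = 0, fail_junction = 0, fail_depth = 0,
                              strand_random = TRUE,
                              seed = 1L) {
  stopifnot(n_single >= 0, n_two >= 0, n_three >= 0,
            length(cds_len_range) == 2L, cds_len_range[1] <= cds_len_range[2],
            length(intron_count_range) == 2L,
            intron_count_range[1] >= 0,
            intron_count_range[1] <= intron_count_range[2],
            length(intron_len_range) == 2L,
            psv_rate >= 0, psv_rate <= 1, snp_rate >= 0, snp_rate <= 1,
            contig_coverage > 0, contig_coverage <= 1,
            length(lines) >= 1, !anyDuplicated(lines))
  if (cds_len_range[1] < 201L) {
    stop("cds_len_range minimum must be >= 201 bp so a centered 101 bp ",
         "window with 50 bp flanks always fits", call. = FALSE)
  }
  if (intron_count_range[2] > 0 && intron_len_range[1] < 60L) {
    stop("intron_len_range minimum must be >= 60 bp for reliable junction ",
         "detection", call. = FALSE)
  }
  if (psv_rate > 0.08) {
    stop("psv_rate > 0.08 would push paralog identity below the 90% floor",
         call. = FALSE)
  }
  if (clean_flanks && is.null(snps_per_gene) && snp_rate > 1 / 204) {
    stop("clean_flanks mode requires snp_rate <= 1/204 so planted SNPs can ",
         "be spaced >= 102 bp apart", call. = FALSE)
  }
  if (!is.null(snps_per_gene)) {
    stopifnot(snps_per_gene >= 0)
    if (!clean_flanks) stop("snps_per_gene requires clean_flanks = TRUE",
                            call. = FALSE)
  }
  for (entry in ssr_spec) {
    if (is.null(entry$motif) || !nchar(entry$motif) %in% 1:6) {
      stop("ssr_spec motifs must be 1-6 bp", call. = FALSE)
    }
    if (length(setdiff(DNA_BASES, seq_chars(entry$motif))) == 0L) {
      stop("ssr_spec motif uses all four bases; no guard base available",
           call. = FALSE)
    }
    if (is.null(entry$counts) || is.null(names(entry$counts))) {
      stop("each ssr_spec entry needs a named `counts` vector", call. = FALSE)
    }
  }
  if (length(ssr_spec) > n_single) {
    stop("not enough single-copy genes to host ssr_spec entries", call. = FALSE)
  }
  if (fail_flank + fail_junction + fail_depth > 1) {
    stop("planted failure fractions must sum to <= 1", call. = FALSE)
  }
  if (seed >= 2^31 - 1e6 || seed < 0) {
    stop("seed must be a non-negative integer below 2^31 - 10^6", call. = FALSE)
  }
  cfg <- list(n_single = as.integer(n_single), n_two = as.integer(n_two),
              n_three = as.integer(n_three),
              cds_len_range = as.integer(cds_len_range),
              intron_count_range = as.integer(intron_count_range),
              intron_len_range = as.integer(intron_len_range),
              psv_rate = psv_rate, snp_rate = snp_rate, ssr_spec = ssr_spec,
              contig_coverage = contig_coverage, depth_law = depth_law,
              lines = lines, clean_flanks = clean_flanks,
              snps_per_gene = if (is.null(snps_per_gene)) NULL else as.integer(snps_per_gene),
              fail_flank = fail_flank, fail_junction = fail_junction,
              fail_depth = fail_depth,
              strand_random = strand_random, seed = as.integer(seed))
  class(cfg) <- "transmark_config"
  cfg
}

#' Simulate the reference gene set
#'
#' Generates gene-model coding sequences organised into paralog families,
#' genomic copies with introns inserted strictly between coding bases, a
#' paralog-group table, planted PSV sites and planted reference SSR loci.
#' PSVs are fixed differences between family members: at each PSV column
#' every paralog carries one base, and at least two paralogs differ.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `transmark_ref`: a list with `gene_models` and
#'   `genomic` (named character vectors), `paralog_table`, `junctions`
#'   (`gene_id`, `offset`: intron inserted between coding bases `offset` and
#'   `offset + 1`), `psv_sites` (`family_id`, `gene_id`, `paralog_index`,
#'   `position`, `base`), `ssr_plan` and the echoed `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "transmark_config"))
  with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(config) {
  n_fam <- config$n_single + config$n_two + config$n_three
  copy_class <- rep(c(1L, 2L, 3L),
                    c(config$n_single, config$n_two, config$n_three))
  family_id <- sprintf("fam%04d", seq_len(n_fam))
  ssr_hosts <- if (length(config$ssr_spec)) {
    family_id[seq_along(config$ssr_spec)]  # single-copy by construction
  } else character(0)

  gene_rows <- list(); models <- character(0); genomic <- character(0)
  junctions <- list(); psv <- list(); ssr_plan <- list()

  for (f in seq_len(n_fam)) {
    k <- copy_class[f]
    L <- sample_range(config$cds_len_range[1], config$cds_len_range[2])
    base <- rand_dna(L)
    host_idx <- match(family_id[f], ssr_hosts)
    if (!is.na(host_idx)) {
      entry <- config$ssr_spec[[host_idx]]
      ref_count <- if ("ref" %in% names(entry$counts)) entry$counts[["ref"]] else max(entry$counts)
      guard <- setdiff(DNA_BASES, seq_chars(entry$motif))[1L]
      ins <- floor(L / 2)
      rep_seq <- strrep(entry$motif, ref_count)
      base <- paste0(substr(base, 1L, ins), guard, rep_seq, guard,
                     substr(base, ins + 1L, L))
      L <- nchar(base)
      ssr_plan[[length(ssr_plan) + 1L]] <- data.frame(
        gene_id = sprintf("%s.p1", family_id[f]), family_id = family_id[f],
        motif = entry$motif, unit = nchar(entry$motif),
        start = ins + 2L, ref_count = ref_count,
        stringsAsFactors = FALSE)
    }
    # PSV columns: per-base Bernoulli; at each chosen column paralog 1 keeps
    # the base and paralog 2 gets a different one; a third paralog draws
    # uniformly from the remaining options so mixed patterns occur.
    base_chars <- seq_chars(base)
    psv_pos <- integer(0); psv_bases <- NULL
    if (k >= 2L && config$psv_rate > 0) {
      psv_pos <- which(runif(L) < config$psv_rate)
      if (length(psv_pos)) {
        psv_bases <- matrix("", nrow = length(psv_pos), ncol = k)
        for (ii in seq_along(psv_pos)) {
          b1 <- base_chars[psv_pos[ii]]
          b2 <- sample(setdiff(DNA_BASES, b1), 1L)
          row <- c(b1, b2)
          if (k == 3L) row <- c(row, sample(c(b1, b2, setdiff(DNA_BASES, c(b1, b2))), 1L))
          psv_bases[ii, ] <- row
        }
      }
    }
    for (p in seq_len(k)) {
      gid <- sprintf("%s.p%d", family_id[f], p)
      chars <- base_chars
      if (length(psv_pos)) chars[psv_pos] <- psv_bases[, p]
      cds <- paste(chars, collapse = "")
      models[gid] <- cds
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, family_id = family_id[f], copy_class = k,
        paralog_index = p, stringsAsFactors = FALSE)
      # genomic copy: introns only strictly between coding bases
      n_int <- if (config$intron_count_range[2] == 0L) 0L else
        sample_range(config$intron_count_range[1], config$intron_count_range[2])
      offs <- if (n_int > 0L) sort(resample(seq_len(L - 1L), n_int)) else integer(0)
      gseq <- cds
      if (n_int > 0L) {
        pieces <- character(0); prev <- 0L
        for (o in offs) {
          ilen <- sample_range(config$intron_len_range[1], config$intron_len_range[2])
          intron <- paste0("GT", rand_dna(ilen - 4L), "AG")
          pieces <- c(pieces, substr(cds, prev + 1L, o), intron)
          prev <- o
        }
        pieces <- c(pieces, substr(cds, prev + 1L, L))
        gseq <- paste(pieces, collapse = "")
      }
      genomic[gid] <- gseq
      if (n_int > 0L) {
        junctions[[length(junctions) + 1L]] <- data.frame(
          gene_id = gid, offset = offs, stringsAsFactors = FALSE)
      }
      if (length(psv_pos)) {
        psv[[length(psv) + 1L]] <- data.frame(
          family_id = family_id[f], gene_id = gid, paralog_index = p,
          position = psv_pos, base = psv_bases[, p], stringsAsFactors = FALSE)
      }
    }
  }
  empty <- function(...) {
    d <- data.frame(...)
    d[0L, , drop = FALSE]
  }
  ref <- list(
    gene_models = models, genomic = genomic,
    paralog_table = do.call(rbind, gene_rows),
    junctions = if (length(junctions)) do.call(rbind, junctions) else
      empty(gene_id = "", offset = 0L),
    psv_sites = if (length(psv)) do.call(rbind, psv) else
      empty(family_id = "", gene_id = "", paralog_index = 0L,
            position = 0L, base = ""),
    ssr_plan = if (length(ssr_plan)) do.call(rbind, ssr_plan) else
      empty(gene_id = "", family_id = "", motif = "", unit = 0L,
            start = 0L, ref_count = 0L),
    config = config)
  class(ref) <- "transmark_ref"
  ref
}

# Sample `n` positions in [51, L - 50] with pairwise spacing >= 102,
# avoiding forbidden windows. Returns fewer than n if infeasible.
place_clean_positions <- function(n, L, forbidden_lo, forbidden_hi,
                                  max_tries = 400L) {
  lo <- 51L; hi <- L - 50L
  if (hi < lo || n == 0L) return(integer(0))
  candidates <- lo:hi
  if (length(forbidden_lo)) {
    bad <- unlist(Map(function(a, b) seq(max(a, lo), min(b, hi)),
                      forbidden_lo[forbidden_lo <= hi & forbidden_hi >= lo],
                      forbidden_hi[forbidden_lo <= hi & forbidden_hi >= lo]))
    candidates <- setdiff(candidates, bad)
  }
  if (!length(candidates)) return(integer(0))
  best <- integer(0)
  for (t in seq_len(max_tries)) {
    want <- max(n - (t - 1L) %/% 100L, 0L)  # relax target every 100 tries
    if (want <= length(best)) break
    pos <- sort(resample(candidates, min(want, length(candidates))))
    if (all(diff(pos) >= 102L)) { best <- pos; if (length(best) >= n) break }
  }
  best
}

#' Simulate one line's alleles
#'
#' Derives a line's allele for every gene model by planting allelic SNPs
#' (substitutions only) and applying SSR repeat-length edits, and records the
#' complete ground truth for each planted difference. In clean-flank mode,
#' designated disjoint subsets of single-copy genes are planted to fail
#' exactly one marker criterion: an extra SNP inside the target SNP's 50 bp
#' flank, an exon-intron junction inside the 101 bp window, or sub-threshold
#' read depth (realised later by [fragment_to_contigs()]).
#'
#' @param ref a [simulate_reference()] bundle.
#' @param line_id unique line identifier.
#' @param snp_rate per-base SNP probability; defaults to the configured rate.
#' @param seed integer seed for this line.
#' @return a list with `line_id`, `alleles` (named character vector),
#'   `truth_snps` and `truth_ssrs` data frames. `truth_snps` flags per SNP:
#'   `flank_clean` (>= 50 bp to ends, no other planted SNP within 50 bp),
#'   `junction_in_window`, `psv_in_flank` (always `TRUE` for single-copy
#'   genes) and `plant_depth_fail`.
#' @export
simulate_line <- function(ref, line_id, snp_rate = NULL, seed = 1L) {
  stopifnot(inherits(ref, "transmark_ref"))
  config <- ref$config
  if (is.null(snp_rate)) snp_rate <- config$snp_rate
  if (config$clean_flanks && is.null(config$snps_per_gene) && snp_rate > 1 / 204) {
    stop("clean_flanks mode requires snp_rate <= 1/204 so planted SNPs can ",
         "be spaced >= 102 bp apart", call. = FALSE)
  }
  with_seed(seed, simulate_line_impl(ref, line_id, snp_rate))
}

simulate_line_impl <- function(ref, line_id, snp_rate) {
  config <- ref$config
  pt <- ref$paralog_table
  ssr_genes <- ref$ssr_plan$gene_id
  alleles <- character(0)
  snp_rows <- list(); ssr_rows <- list()

  # deliberate criterion failures live on single-copy, non-SSR genes
  single_ids <- pt$gene_id[pt$copy_class == 1L & !(pt$gene_id %in% ssr_genes)]
  fail_mode <- setNames(rep("none", nrow(pt)), pt$gene_id)
  if (config$clean_flanks && length(single_ids)) {
    n_ff <- round(config$fail_flank * length(single_ids))
    n_jf <- round(config$fail_junction * length(single_ids))
    n_df <- round(config$fail_depth * length(single_ids))
    picks <- single_ids[seq_len(min(n_ff + n_jf + n_df, length(single_ids)))]
    fail_mode[picks] <- rep(c("flank", "junction", "depth"),
                            c(n_ff, n_jf, n_df))[seq_along(picks)]
  }

  junc_by_gene <- split(ref$junctions$offset, ref$junctions$gene_id)
  psv_by_gene <- split(ref$psv_sites$position, ref$psv_sites$gene_id)
  # columns already used by sibling paralogs; a SNP planted at the same
  # column in two paralogs would be a doubly-segregating (conflict) pattern
  fam_used <- list()

  for (i in seq_len(nrow(pt))) {
    gid <- pt$gene_id[i]
    cds <- ref$gene_models[[gid]]
    L <- nchar(cds)
    if (gid %in% ssr_genes) {
      plan <- ref$ssr_plan[ref$ssr_plan$gene_id == gid, ]
      entry <- config$ssr_spec[[match(gid, ssr_genes)]]
      cnt <- if (line_id %in% names(entry$counts)) entry$counts[[line_id]] else plan$ref_count
      ref_len <- plan$unit * plan$ref_count
      allele <- paste0(substr(cds, 1L, plan$start - 1L),
                       strrep(plan$motif, cnt),
                       substr(cds, plan$start + ref_len, L))
      alleles[gid] <- allele
      ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
        gene_id = gid, family_id = plan$family_id, motif = plan$motif,
        unit = plan$unit, start_ref = plan$start, line = line_id,
        ref_count = plan$ref_count, count = cnt, stringsAsFactors = FALSE)
      next
    }
    juncs <- junc_by_gene[[gid]]
    if (is.null(juncs)) juncs <- integer(0)
    psvs <- psv_by_gene[[gid]]
    if (is.null(psvs)) psvs <- integer(0)
    mode <- fail_mode[[gid]]
    depth_fail <- FALSE
    fam <- pt$family_id[i]
    sib_used <- fam_used[[fam]]
    if (is.null(sib_used)) sib_used <- integer(0)
    if (config$clean_flanks) {
      n_target <- if (!is.null(config$snps_per_gene)) config$snps_per_gene
                  else rbinom(1L, L, snp_rate)
      # keep clean SNPs out of junction windows, off PSV columns and off
      # columns already carrying a sibling paralog's SNP
      f_lo <- c(juncs - 49L, psvs, sib_used)
      f_hi <- c(juncs + 50L, psvs, sib_used)
      if (mode == "junction") {
        pos <- integer(0)
        for (o in juncs) {  # junction strictly inside the window, near center
          cand <- c(o + 10L, o - 10L)
          cand <- cand[cand >= 51L & cand <= L - 50L & !(cand %in% psvs)]
          if (length(cand)) { pos <- cand[1L]; break }
        }
        if (!length(pos)) mode <- "none"
      }
      if (mode != "junction") {
        pos <- place_clean_positions(max(n_target, if (mode == "none") 0L else 1L),
                                     L, f_lo, f_hi)
      }
      if (mode == "flank" && length(pos)) {
        comp <- pos[1L] + 25L
        if (comp <= L - 50L && !(comp %in% psvs)) pos <- sort(c(pos, comp))
      }
      if (mode == "depth" && length(pos)) depth_fail <- TRUE
    } else {
      pos <- which(runif(L) < snp_rate)
      pos <- setdiff(pos, psvs)
    }
    if (pt$copy_class[i] >= 2L && length(pos)) {
      fam_used[[fam]] <- c(sib_used, pos)
    }
    chars <- seq_chars(cds)
    if (length(pos)) {
      alt <- vapply(chars[pos],
                    function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
      chars[pos] <- alt
      iso <- if (length(pos) == 1L) rep(TRUE, 1L) else {
        vapply(seq_along(pos),
               function(j) all(abs(pos[-j] - pos[j]) >= 51L), logical(1))
      }
      in_win <- vapply(pos, function(p) any(juncs >= p - 50L & juncs <= p + 49L),
                       logical(1))
      psv_flank <- if (pt$copy_class[i] == 1L) rep(TRUE, length(pos)) else
        vapply(pos, function(p) any(abs(psvs - p) >= 1L & abs(psvs - p) <= 50L),
               logical(1))
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp_id = sprintf("%s:%s:%d", line_id, gid, pos),
        line = line_id, gene_id = gid, family_id = pt$family_id[i],
        copy_class = pt$copy_class[i], paralog_index = pt$paralog_index[i],
        position = pos, ref_base = seq_chars(cds)[pos], alt_base = alt,
        flank_clean = (pos >= 51L & pos <= L - 50L) & iso,
        junction_in_window = in_win, psv_in_flank = psv_flank,
        plant_depth_fail = depth_fail, stringsAsFactors = FALSE)
    }
    alleles[gid] <- paste(chars, collapse = "")
  }
  empty_snps <- data.frame(snp_id = character(0), line = character(0),
                           gene_id = character(0), family_id = character(0),
                           copy_class = integer(0), paralog_index = integer(0),
                           position = integer(0), ref_base = character(0),
                           alt_base = character(0), flank_clean = logical(0),
                           junction_in_window = logical(0),
                           psv_in_flank = logical(0),
                           plant_depth_fail = logical(0),
                           stringsAsFactors = FALSE)
  list(line_id = line_id, alleles = alleles,
       truth_snps = if (length(snp_rows)) do.call(rbind, snp_rows) else empty_snps,
       truth_ssrs = if (length(ssr_rows)) do.call(rbind, ssr_rows) else
         data.frame(gene_id = character(0), family_id = character(0),
                    motif = character(0), unit = integer(0),
                    start_ref = integer(0), line = character(0),
                    ref_count = integer(0), count = integer(0)))
}

draw_depth <- function(n, law) {
  switch(law$dist,
         constant = rep(as.integer(law$value), n),
         nbinom = rnbinom(n, mu = law$mu, size = law$size),
         stop("unknown depth law: ", law$dist, call. = FALSE))
}

#' Fragment line alleles into contigs with per-base depth
#'
#' Emits one contig per gene as a substring of the line allele covering
#' `contig_coverage` of its length (a whole-allele contig at coverage 1),
#' on a random strand when configured, with a per-base depth track drawn
#' from the configured depth law. Fragments shorter than 100 bp are dropped
#' and logged, mirroring the assembler's minimum contig length. SNPs planted
#' as depth failures receive depth 6 (just below the >= 7 criterion) at the
#' SNP base. The returned truth table annotates each planted SNP with its
#' contig coordinates, realised depth and whether the full 101 bp window
#' fits on the contig.
#'
#' @param line_sim a [simulate_line()] result.
#' @param ref the [simulate_reference()] bundle.
#' @param contig_coverage,depth_law,strand_random override the configured
#'   values (defaults taken from `ref$config`).
#' @param seed integer seed.
#' @return list with `contigs` (named character), `depth` (named list of
#'   integer vectors), `contig_info` (`contig_id`, `line`, `gene_id`,
#'   `start`, `end`, `strand`), `dropped` (gene ids whose fragment was
#'   < 100 bp) and the annotated `truth_snps`.
#' @export
fragment_to_contigs <- function(line_sim, ref, contig_coverage = NULL,
                                depth_law = NULL, strand_random = NULL,
                                seed = 1L) {
  config <- ref$config
  if (is.null(contig_coverage)) contig_coverage <- config$contig_coverage
  if (is.null(depth_law)) depth_law <- config$depth_law
  if (is.null(strand_random)) strand_random <- config$strand_random
  stopifnot(contig_coverage > 0, contig_coverage <= 1)
  with_seed(seed, fragment_impl(line_sim, contig_coverage, depth_law,
                                strand_random))
}

fragment_impl <- function(line_sim, coverage, depth_law, strand_random) {
  alleles <- line_sim$alleles
  truth <- line_sim$truth_snps
  nt <- nrow(truth)
  truth$contig_id <- rep(NA_character_, nt)
  truth$contig_pos <- rep(NA_integer_, nt)
  truth$on_contig <- rep(FALSE, nt)
  truth$window_on_contig <- rep(FALSE, nt)
  truth$depth <- rep(NA_integer_, nt)
  truth$depth_ok <- rep(FALSE, nt)
  contigs <- character(0); depth <- list(); info <- list(); dropped <- character(0)
  for (i in seq_along(alleles)) {
    gid <- names(alleles)[i]
    allele <- alleles[[i]]
    L <- nchar(allele)
    flen <- if (coverage >= 1) L else max(as.integer(round(coverage * L)), 0L)
    if (flen < 100L) { dropped <- c(dropped, gid); next }
    start <- if (flen == L) 1L else sample.int(L - flen + 1L, 1L)
    strand <- if (strand_random) sample(c("+", "-"), 1L) else "+"
    frag <- substr(allele, start, start + flen - 1L)
    if (strand == "-") frag <- revcomp(frag)
    cid <- sprintf("ctg_%s_%05d", line_sim$line_id, i)
    d <- as.integer(pmax(draw_depth(flen, depth_law), 0L))
    rows <- which(truth$gene_id == gid)
    for (r in rows) {
      p <- truth$position[r]
      if (p >= start && p <= start + flen - 1L) {
        fwd <- p - start + 1L
        emit <- if (strand == "-") flen - fwd + 1L else fwd
        if (truth$plant_depth_fail[r]) d[emit] <- 6L
        truth$contig_id[r] <- cid
        truth$contig_pos[r] <- emit
        truth$on_contig[r] <- TRUE
        truth$window_on_contig[r] <- fwd > 50L && fwd + 50L <= flen
        truth$depth[r] <- d[emit]
        truth$depth_ok[r] <- d[emit] >= 7L
      }
    }
    contigs[cid] <- frag
    depth[[cid]] <- as.integer(d)
    info[[length(info) + 1L]] <- data.frame(
      contig_id = cid, line = line_sim$line_id, gene_id = gid,
      start = start, end = start + flen - 1L, strand = strand,
      stringsAsFactors = FALSE)
  }
  list(contigs = contigs, depth = depth,
       contig_info = if (length(info)) do.call(rbind, info) else
         data.frame(contig_id = character(0), line = character(0),
                    gene_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0)),
       dropped = dropped, truth_snps = truth)
}

#' Simulate a complete marker-design test bundle
#'
#' Convenience orchestration: builds the reference, simulates every
#' configured line, fragments alleles into contigs and assembles the global
#' ground truth, including `expected_marker_ids` -- the planted SNPs that
#' satisfy all three marker criteria (conserved 50 bp flanks, no junction in
#' the 101 bp window, depth >= 7) plus, for paralog families, at least one
#' PSV within the flanks, and whose full window lies on an emitted contig.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `transmark_sim`: `ref`, per-line results
#'   (`lines`), merged `contigs`, `depth`, `contig_info`, and `truth` with
#'   `snp_sites`, `psv_sites`, `ssr_loci`, `junctions` and
#'   `expected_marker_ids`.
#' @export
simulate_bundle <- function(config) {
  ref <- simulate_reference(config)
  lines <- list(); contigs <- character(0); depth <- list()
  info <- list(); snps <- list(); ssrs <- list()
  for (j in seq_along(config$lines)) {
    ln <- config$lines[j]
    sim <- simulate_line(ref, ln, seed = config$seed + j)
    frag <- fragment_to_contigs(sim, ref, seed = config$seed + 1000L + j)
    sim$contigs <- frag$contigs
    lines[[ln]] <- sim
    contigs <- c(contigs, frag$contigs)
    depth <- c(depth, frag$depth)
    info[[j]] <- frag$contig_info
    snps[[j]] <- frag$truth_snps
    ssrs[[j]] <- sim$truth_ssrs
  }
  snp_sites <- do.call(rbind, snps)
  # a column carrying SNPs in two paralogs of one family is a
  # doubly-segregating (conflict) pattern, not a usable allelic SNP
  col_key <- paste(snp_sites$line, snp_sites$family_id, snp_sites$position)
  multi_paralog <- ave(as.integer(snp_sites$copy_class >= 2L), col_key,
                       FUN = length) > 1L & snp_sites$copy_class >= 2L
  expected <- snp_sites$snp_id[
    snp_sites$flank_clean & !snp_sites$junction_in_window &
      snp_sites$psv_in_flank & snp_sites$on_contig &
      snp_sites$window_on_contig & snp_sites$depth_ok & !multi_paralog]
  out <- list(ref = ref, lines = lines, contigs = contigs, depth = depth,
              contig_info = do.call(rbind, info),
              truth = list(snp_sites = snp_sites,
                           psv_sites = ref$psv_sites,
                           ssr_loci = do.call(rbind, ssrs),
                           junctions = ref$junctions,
                           expected_marker_ids = expected),
              config = config)
  class(out) <- "transmark_sim"
  out
}

#' Simulate a selfed RIL genotype matrix
#'
#' Simulates a biparental recombinant inbred population by single-seed
#' descent: the F1 is heterozygous at every locus; each later generation is
#' one round of selfing with meioses following the Haldane (no-interference)
#' crossover process, so adjacent-marker recombination probability is
#' `0.5 * (1 - exp(-2 d / 100))` for map distance `d` cM. Markers in
#' different linkage groups segregate independently. Residual per-locus
#' heterozygosity halves each selfing generation (about 1/64 at F7).
#'
#' @param map data.frame with columns `marker_id`, `group` and `pos_cm`;
#'   positions must be sorted non-decreasing within each group.
#' @param n_individuals population size (>= 2); default 93.
#' @param generation filial generation (>= 2); default 7 (F7 = six selfing
#'   generations after the F1).
#' @param seed integer seed.
#' @param missing_rate per-call probability of a missing genotype (`"-"`).
#' @param parents two-character vector of parental call codes.
#' @return list with `genotypes` (markers x individuals character matrix
#'   with calls in `parents`, `"H"`, `"-"`), `map`, `generation` and
#'   `n_individuals`.
#' @export
simulate_ril_population <- function(map, n_individuals = 93L, generation = 7L,
                                    seed = 1L, missing_rate = 0,
                                    parents = c("A", "B")) {
  stopifnot(is.data.frame(map),
            all(c("marker_id", "group", "pos_cm") %in% names(map)))
  if (n_individuals < 2L) stop("n_individuals must be >= 2", call. = FALSE)
  if (generation < 2L) stop("generation must be >= 2 (F2)", call. = FALSE)
  for (g in split(map$pos_cm, map$group)) {
    if (is.unsorted(g)) stop("map positions must be sorted within each group",
                             call. = FALSE)
  }
  with_seed(seed, {
    L <- nrow(map); n <- as.integer(n_individuals)
    d <- c(0, diff(map$pos_cm))
    new_group <- c(TRUE, map$group[-1L] != map$group[-L])
    p_switch <- 0.5 * (1 - exp(-2 * d / 100))
    p_switch[new_group] <- 0.5  # independent start per linkage group
    meiosis <- function(h1, h2) {
      draws <- matrix(runif(n * L) < rep(p_switch, each = n), n, L)
      state <- t(apply(draws, 1L, cumsum)) %% 2L
      gam <- h1; pick <- state == 1L; gam[pick] <- h2[pick]
      gam
    }
    h1 <- matrix(0L, n, L); h2 <- matrix(1L, n, L)  # F1
    for (g in seq_len(generation - 1L)) {
      nh1 <- meiosis(h1, h2); nh2 <- meiosis(h1, h2)
      h1 <- nh1; h2 <- nh2
    }
    calls <- matrix("H", n, L)
    calls[h1 == 0L & h2 == 0L] <- parents[1L]
    calls[h1 == 1L & h2 == 1L] <- parents[2L]
    if (missing_rate > 0) calls[runif(n * L) < missing_rate] <- "-"
    geno <- t(calls)
    dimnames(geno) <- list(map$marker_id,
                           sprintf("ind%03d", seq_len(n)))
    list(genotypes = geno, map = map, generation = as.integer(generation),
         n_individuals = n)
  })
}
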