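# The three-criteria marker filter cascade: conserved 50 bp flanks around
# the SNP, no exon-intron junction inside the 101 bp target window, and read
# depth >= 7 -- plus PSV-aware paralog-specific design and KASP-style
# bracketed assay output.

#' Extract the 101 bp assay window around a variant
#'
#' The window is `flank` + 1 + `flank` bases with the variable base at
#' 1-based offset `flank + 1` (position 51 for the default 50 bp flanks).
#'
#' @param seq a single sequence string.
#' @param pos 1-based variant position within `seq`.
#' @param flank flank length on each side (default 50).
#' @return list with `status` (`"ok"` or `"insufficient_flank"`) and, when
#'   ok, `window`, `start`, `end` (1-based in `seq`).
#' @export
extract_window <- function(seq, pos, flank = 50L) {
  L <- nchar(seq)
  pos <- as.integer(pos); flank <- as.integer(flank)
  if (pos < 1L || pos > L) stop("position ", pos, " outside sequence of length ",
                                L, call. = FALSE)
  if (pos - flank < 1L || pos + flank > L) {
    return(list(status = "insufficient_flank"))
  }
  list(status = "ok", window = substr(seq, pos - flank, pos + flank),
       start = pos - flank, end = pos + flank)
}

#' Check flank conservation around an aligned variant column
#'
#' True when all `flank` alignment columns on each side of the variant
#' column are identical between the two lines: no substitution, no gap, no
#' `N`. Windows running off the alignment fail (reason `uncovered_window`).
#'
#' @param q_aln,s_aln gapped aligned strings of the homolog pair.
#' @param col alignment column index of the variant.
#' @param flank flank length in columns (default 50).
#' @return list with `conserved` (logical) and `reason` (`NA`, a flank
#'   defect description, or `"uncovered_window"`).
#' @export
check_flank_conservation <- function(q_aln, s_aln, col, flank = 50L) {
  qa <- seq_chars(q_aln); sa <- seq_chars(s_aln)
  n <- length(qa)
  if (col - flank < 1L || col + flank > n) {
    return(list(conserved = FALSE, reason = "uncovered_window"))
  }
  idx <- c((col - flank):(col - 1L), (col + 1L):(col + flank))
  ok <- qa[idx] == sa[idx] & qa[idx] %in% DNA_BASES
  if (all(ok)) list(conserved = TRUE, reason = NA_character_)
  else list(conserved = FALSE, reason = "flank_mismatch")
}

#' Check an assay window for exon-intron junctions
#'
#' Aligns the 101 bp window against the gene's genomic (intron-bearing)
#' copy. The window is junction-free when it aligns as a single contiguous
#' block: a gap-free local alignment covering the full window. An intron
#' insertion point strictly inside the window splits the alignment and
#' fails the check.
#'
#' @param window the extracted target window sequence.
#' @param genomic_seq genomic sequence of the gene (with introns).
#' @param match,mismatch,gap alignment scoring.
#' @return list with `junction_free` (logical) and `reason` (`NA`,
#'   `"junction_in_window"` or `"no_genomic_hit"`).
#' @export
check_junctions <- function(window, genomic_seq,
                            match = 2L, mismatch = -3L, gap = -5L) {
  a <- sw_align(window, genomic_seq, match, mismatch, gap)
  if (a$columns < 20L) {
    return(list(junction_free = FALSE, reason = "no_genomic_hit"))
  }
  covered <- a$q_end - a$q_start + 1L
  if (a$gaps == 0L && covered == nchar(window)) {
    list(junction_free = TRUE, reason = NA_character_)
  } else {
    list(junction_free = FALSE, reason = "junction_in_window")
  }
}

#' Classify segregating columns as allelic SNP, PSV or conflict
#'
#' Takes column-aligned sequences for every paralog of a family in two or
#' more lines and classifies each segregating column: `psv` when the
#' paralogs differ but each paralog is identical across lines (a fixed
#' inter-paralog difference), `allelic_snp` when exactly one paralog
#' differs between lines while every other paralog is line-invariant, and
#' `conflict` for any other segregating pattern. Columns containing a
#' non-ACGT base in any sequence are skipped and counted as `unresolved`.
#' The three labels are exhaustive and mutually exclusive over resolved
#' segregating columns.
#'
#' @param seq_by_line named list (one element per line) of named character
#'   vectors (one sequence per paralog, all the same length and sharing
#'   paralog names across lines).
#' @return list with `sites` (data.frame `position`, `class`, `paralog`
#'   -- the varying paralog for allelic SNPs, `NA` otherwise) and
#'   `unresolved` (count of skipped columns).
#' @export
classify_paralog_sites <- function(seq_by_line) {
  if (length(seq_by_line) < 2L) {
    stop("cannot classify: need sequences from at least two lines",
         call. = FALSE)
  }
  paralogs <- names(seq_by_line[[1L]])
  if (is.null(paralogs) || length(paralogs) < 2L) {
    stop("need at least two named paralogs per line", call. = FALSE)
  }
  for (ln in seq_by_line) {
    if (!identical(sort(names(ln)), sort(paralogs))) {
      stop("paralog names must agree across lines", call. = FALSE)
    }
    if (length(unique(nchar(ln))) != 1L ||
        nchar(ln[[1L]]) != nchar(seq_by_line[[1L]][[1L]])) {
      stop("sequences must be column-aligned (equal length)", call. = FALSE)
    }
  }
  L <- nchar(seq_by_line[[1L]][[1L]])
  lines <- names(seq_by_line)
  # bases[paralog, line, column]
  mats <- lapply(lines, function(ln) {
    do.call(rbind, lapply(seq_by_line[[ln]][paralogs], seq_chars))
  })
  rows <- list(); unresolved <- 0L
  for (pos in seq_len(L)) {
    bm <- vapply(mats, function(m) m[, pos], character(length(paralogs)))
    if (length(paralogs) == 1L) bm <- matrix(bm, nrow = 1L)
    # bm: paralogs x lines
    if (!all(bm %in% DNA_BASES)) {
      if (length(unique(bm[bm %in% DNA_BASES])) > 1L) unresolved <- unresolved + 1L
      next
    }
    if (length(unique(as.vector(bm))) == 1L) next  # invariant column
    varies <- apply(bm, 1L, function(x) length(unique(x)) > 1L)
    if (sum(varies) == 0L) {
      cls <- "psv"; par <- NA_character_
    } else if (sum(varies) == 1L) {
      cls <- "allelic_snp"; par <- paralogs[which(varies)]
    } else {
      cls <- "conflict"; par <- NA_character_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, class = cls, paralog = par, stringsAsFactors = FALSE)
  }
  list(sites = if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), class = character(0),
               paralog = character(0), stringsAsFactors = FALSE),
    unresolved = unresolved)
}

#' Design a paralog-specific assay from an allelic SNP
#'
#' An allelic SNP in a duplicated gene is usable only when its 50 bp flanks
#' contain at least one paralog-specific variation, so that locus-specific
#' primers can anchor on the target copy. The emitted target sequence uses
#' the target paralog's own bases at PSV positions (the discriminators are
#' never degenerate); residual non-target variable flank positions receive
#' IUPAC degeneracy codes.
#'
#' @param target_seq the target paralog's sequence (gene-model frame).
#' @param pos 1-based allelic SNP position in `target_seq`.
#' @param ref_base,alt_base the two alleles (reference line base first).
#' @param psv_positions integer positions of the family's PSV columns.
#' @param residual optional data.frame (`position`, `bases` list or
#'   comma-separated string) of non-discriminating variable positions to
#'   degenerate.
#' @param flank flank length (default 50).
#' @param require_both_flanks if `TRUE`, demand at least one PSV in each
#'   flank rather than in either (default `FALSE`, the permissive reading).
#' @return list with `status` (`"ok"`, `"insufficient_flank"` or
#'   `"no_discriminating_psv"`) and, when ok, `target_sequence` (with one
#'   `[X/Y]` bracket), `psv_offsets` (signed offsets from the SNP).
#' @export
design_paralog_specific_marker <- function(target_seq, pos, ref_base, alt_base,
                                           psv_positions, residual = NULL,
                                           flank = 50L,
                                           require_both_flanks = FALSE) {
  w <- extract_window(target_seq, pos, flank)
  if (w$status != "ok") return(list(status = w$status))
  offs <- psv_positions - pos
  in_left <- offs >= -flank & offs <= -1L
  in_right <- offs >= 1L & offs <= flank
  ok <- if (require_both_flanks) any(in_left) && any(in_right)
        else any(in_left | in_right)
  if (!ok) return(list(status = "no_discriminating_psv"))
  seq_out <- bracket_window(w$window, flank + 1L, ref_base, alt_base,
                            residual_offsets = if (is.null(residual)) NULL else
                              residual$position - w$start + 1L,
                            residual_bases = if (is.null(residual)) NULL else
                              residual$bases)
  list(status = "ok", target_sequence = seq_out,
       psv_offsets = sort(offs[in_left | in_right]))
}

# Render a window with a [X/Y] bracket at `center` (1-based within window)
# and IUPAC degeneracy at residual variable offsets.
bracket_window <- function(window, center, ref_base, alt_base,
                           residual_offsets = NULL, residual_bases = NULL) {
  chars <- seq_chars(window)
  if (!is.null(residual_offsets)) {
    for (i in seq_along(residual_offsets)) {
      o <- residual_offsets[i]
      if (o >= 1L && o <= length(chars) && o != center) {
        bases <- unlist(strsplit(residual_bases[[i]], ",", fixed = TRUE))
        chars[o] <- iupac_code(c(chars[o], bases))
      }
    }
  }
  paste0(paste(chars[seq_len(center - 1L)], collapse = ""),
         "[", ref_base, "/", alt_base, "]",
         paste(chars[seq(center + 1L, length(chars))], collapse = ""))
}

#' Run the three-criteria marker cascade
#'
#' End-to-end marker selection: contigs are assigned to gene models, SNPs
#' are called for pairs at or above the `min_pair_identity` comparison
#' floor, and each candidate is evaluated against the three criteria in the
#' stated order -- (1) strictly conserved 50 bp flanks on both sides of the
#' SNP, (2) no exon-intron junction inside the 101 bp window, (3) read
#' depth >= `min_depth` (and quality >= `min_quality`). Candidates in
#' two-/three-paralog families must additionally classify as allelic SNPs
#' with at least one PSV inside the flanks before a paralog-specific assay
#' is designed. All three criterion flags are computed for every candidate,
#' so the accepted set is independent of stage order; only the funnel's
#' intermediate counts follow the stated order.
#'
#' @param contigs named character vector of contig sequences.
#' @param gene_models named character vector of reference coding sequences.
#' @param genomic named character vector of genomic (intron-bearing) copies.
#' @param depth named list of per-base depth tracks.
#' @param paralog_table the paralog-group table.
#' @param contig_lines named character vector mapping contig id to line id.
#' @param min_pair_identity identity floor for SNP comparison (default 0.90).
#' @param flank flank length (default 50; window is `2 * flank + 1` bp).
#' @param min_depth,min_quality depth/quality criterion (defaults 7, 40).
#' @param min_assign_identity,min_assign_length homolog assignment
#'   thresholds (defaults 0.80, 100).
#' @param gap_guard columns around alignment gaps excluded from SNP calling.
#' @param k seed k-mer length for alignment.
#' @param require_both_flanks PSV placement rule for paralog markers.
#' @return list with `markers` (assay table, see [emit_assay_table()]),
#'   `funnel` (data.frame `stage`, `n_sites`, `n_genes` for stages
#'   eligible/flank/junction/depth), `candidates` (every called site with
#'   its `flank_ok`, `junction_free`, `depth_ok`, `paralog_ok` flags and
#'   `accepted`), `groups`, `unassigned` and `skipped_pairs`.
#' @export
run_cascade <- function(contigs, gene_models, genomic, depth, paralog_table,
                        contig_lines, min_pair_identity = 0.90, flank = 50L,
                        min_depth = 7L, min_quality = 40L,
                        min_assign_identity = 0.80, min_assign_length = 100L,
                        gap_guard = 5L, k = 15L,
                        require_both_flanks = FALSE) {
  hits <- align_contigs(contigs, gene_models, min_identity = min_assign_identity,
                        min_length = min_assign_length, k = k)
  asg <- assign_homologs(hits, paralog_table, contig_lines,
                         contig_ids = names(contigs),
                         min_identity = min_assign_identity,
                         min_length = min_assign_length)
  cs <- call_snps(asg$groups, contigs, gene_models, depth,
                  min_identity = min_pair_identity, gap_guard = gap_guard)
  cand <- cs$sites
  n <- nrow(cand)
  cand$flank_ok <- logical(n)
  cand$junction_free <- logical(n)
  cand$depth_ok <- logical(n)
  cand$paralog_ok <- rep(TRUE, n)
  cand$psv_offsets <- rep(NA_character_, n)
  cand$reject_reason <- rep(NA_character_, n)
  cand$direction <- rep("+", n)

  for (i in seq_len(n)) {
    aln <- cs$alignments[[cand$contig_id[i]]]
    cand$direction[i] <- aln$strand
    fc <- check_flank_conservation(aln$q_aln, aln$s_aln, cand$aln_col[i], flank)
    cand$flank_ok[i] <- fc$conserved
    q_oriented <- if (aln$strand == "-") revcomp(contigs[[cand$contig_id[i]]])
                  else contigs[[cand$contig_id[i]]]
    qpos <- if (aln$strand == "-") aln$contig_len - cand$contig_pos[i] + 1L
            else cand$contig_pos[i]
    w <- extract_window(q_oriented, qpos, flank)
    if (w$status == "ok") {
      jc <- check_junctions(w$window, genomic[[cand$gene_id[i]]])
      cand$junction_free[i] <- isTRUE(jc$junction_free)
      if (!cand$junction_free[i]) cand$reject_reason[i] <- jc$reason
    } else {
      cand$junction_free[i] <- FALSE
      cand$reject_reason[i] <- w$status
    }
    if (!cand$flank_ok[i] && is.na(cand$reject_reason[i])) {
      cand$reject_reason[i] <- fc$reason
    }
  }
  cand$depth_ok <- !is.na(cand$depth) & cand$depth >= min_depth &
    !is.na(cand$quality) & cand$quality >= min_quality

  # paralog families: require allelic classification plus a PSV in the flanks
  multi <- which(cand$copy_class >= 2L)
  if (length(multi)) {
    fams <- unique(cand$family_id[multi])
    for (fam in fams) {
      idx <- multi[cand$family_id[multi] == fam]
      prof <- family_profile(fam, paralog_table, gene_models, cs$alignments,
                             asg$groups)
      if (is.null(prof)) {
        cand$paralog_ok[idx] <- FALSE
        cand$reject_reason[idx] <- ifelse(is.na(cand$reject_reason[idx]),
                                          "family_unalignable",
                                          cand$reject_reason[idx])
        next
      }
      cls <- classify_paralog_sites(prof)
      psv_pos <- cls$sites$position[cls$sites$class == "psv"]
      for (i in idx) {
        row <- cls$sites[cls$sites$position == cand$position[i], ]
        if (nrow(row) != 1L || row$class != "allelic_snp" ||
            row$paralog != cand$gene_id[i]) {
          cand$paralog_ok[i] <- FALSE
          if (is.na(cand$reject_reason[i])) {
            cand$reject_reason[i] <- if (nrow(row) == 1L && row$class == "conflict")
              "conflict_pattern" else "not_allelic"
          }
          next
        }
        des <- design_paralog_specific_marker(
          gene_models[[cand$gene_id[i]]], cand$position[i],
          cand$ref_base[i], cand$alt_base[i], psv_pos, flank = flank,
          require_both_flanks = require_both_flanks)
        if (des$status != "ok") {
          cand$paralog_ok[i] <- FALSE
          if (is.na(cand$reject_reason[i])) cand$reject_reason[i] <- des$status
        } else {
          cand$psv_offsets[i] <- paste(des$psv_offsets, collapse = ",")
        }
      }
    }
  }

  cand$accepted <- cand$flank_ok & cand$junction_free & cand$depth_ok &
    cand$paralog_ok
  funnel <- data.frame(
    stage = c("eligible", "flank", "junction", "depth"),
    n_sites = c(n, sum(cand$flank_ok),
                sum(cand$flank_ok & cand$junction_free),
                sum(cand$flank_ok & cand$junction_free & cand$depth_ok)),
    n_genes = c(length(unique(cand$gene_id)),
                length(unique(cand$gene_id[cand$flank_ok])),
                length(unique(cand$gene_id[cand$flank_ok & cand$junction_free])),
                length(unique(cand$gene_id[cand$flank_ok & cand$junction_free &
                                             cand$depth_ok]))),
    stringsAsFactors = FALSE)
  markers <- emit_assay_table(cand[cand$accepted, , drop = FALSE],
                              gene_models, cand, flank = flank)
  list(markers = markers, funnel = funnel, candidates = cand,
       groups = asg$groups, unassigned = asg$unassigned,
       skipped_pairs = cs$skipped)
}

# Column-aligned per-line paralog sequences for one family, reconstructed
# from the contig alignments; NULL when family members differ in length
# (no common coordinate frame without a multiple alignment).
family_profile <- function(fam, paralog_table, gene_models, alignments,
                           groups) {
  members <- paralog_table$gene_id[paralog_table$family_id == fam]
  lens <- nchar(gene_models[members])
  if (length(unique(lens)) != 1L) return(NULL)
  L <- lens[[1L]]
  lines <- unique(groups$line[groups$gene_id %in% members])
  if (!length(lines)) return(NULL)
  prof <- list(ref = setNames(gene_models[members], members))
  for (ln in lines) {
    seqs <- setNames(rep(strrep("N", L), length(members)), members)
    for (g in members) {
      rows <- groups[groups$gene_id == g & groups$line == ln, ]
      for (cid in rows$contig_id) {
        aln <- alignments[[cid]]
        if (is.null(aln) || aln$gene_id != g) next
        qa <- seq_chars(aln$q_aln); sa <- seq_chars(aln$s_aln)
        keep <- qa != "-" & sa != "-"
        spos <- cumsum(sa != "-") + aln$s_start - 1L
        chars <- seq_chars(seqs[[g]])
        chars[spos[keep]] <- qa[keep]
        seqs[[g]] <- paste(chars, collapse = "")
      }
    }
    prof[[ln]] <- seqs
  }
  if (length(prof) < 2L) return(NULL)
  prof
}

#' Build the assay table for accepted markers
#'
#' One row per accepted marker: identifiers, alignment direction, SNP
#' positions in both the gene-model and contig coordinate frames, the
#' per-base (A/T/G/C) depth decomposition at the SNP, and the target
#' sequence rendered with a single `[X/Y]` bracket (reference-line base
#' first). Residual variable flank positions of the same homolog pair are
#' written as IUPAC degeneracy codes; for paralog-specific markers the PSV
#' offsets are carried in `psv_offsets`.
#'
#' @param accepted accepted candidate rows (from [run_cascade()]).
#' @param gene_models named character vector of reference sequences.
#' @param all_candidates full candidate table (used to locate residual
#'   variants inside windows); defaults to `accepted`.
#' @param flank flank length (default 50).
#' @return data.frame with columns `marker_id`, `gene_id`, `contig_id`,
#'   `line`, `direction`, `snp_pos_gene`, `snp_pos_contig`, `ref_base`,
#'   `alt_base`, `depth`, `depth_A`, `depth_T`, `depth_G`, `depth_C`,
#'   `quality`, `copy_class`, `paralog_specific`, `psv_offsets`,
#'   `target_sequence`.
#' @export
emit_assay_table <- function(accepted, gene_models, all_candidates = accepted,
                             flank = 50L) {
  n <- nrow(accepted)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x <- accepted[i, ]
    w <- extract_window(gene_models[[x$gene_id]], x$position, flank)
    if (w$status != "ok") stop("accepted marker without full flank: ", x$snp_id,
                               call. = FALSE)
    others <- all_candidates[all_candidates$gene_id == x$gene_id &
                               all_candidates$line == x$line &
                               all_candidates$position != x$position &
                               abs(all_candidates$position - x$position) <= flank, ]
    residual_offsets <- if (nrow(others)) others$position - w$start + 1L else NULL
    residual_bases <- if (nrow(others))
      as.list(paste(others$ref_base, others$alt_base, sep = ",")) else NULL
    target <- bracket_window(w$window, flank + 1L, x$ref_base, x$alt_base,
                             residual_offsets, residual_bases)
    dvec <- c(A = 0L, T = 0L, G = 0L, C = 0L)
    if (!is.na(x$depth) && x$alt_base %in% names(dvec)) {
      dvec[x$alt_base] <- x$depth
    }
    rows[[i]] <- data.frame(
      marker_id = sprintf("KM_%s_%06d", x$gene_id, x$position),
      gene_id = x$gene_id, contig_id = x$contig_id, line = x$line,
      direction = if ("direction" %in% names(x)) x$direction else "+",
      snp_pos_gene = x$position, snp_pos_contig = x$contig_pos,
      ref_base = x$ref_base, alt_base = x$alt_base,
      depth = x$depth, depth_A = dvec[["A"]], depth_T = dvec[["T"]],
      depth_G = dvec[["G"]], depth_C = dvec[["C"]],
      quality = x$quality, copy_class = x$copy_class,
      paralog_specific = x$copy_class >= 2L,
      psv_offsets = if ("psv_offsets" %in% names(x)) x$psv_offsets else NA_character_,
      target_sequence = target, stringsAsFactors = FALSE)
  }
  out <- if (n) do.call(rbind, rows) else data.frame(
    marker_id = character(0), gene_id = character(0), contig_id = character(0),
    line = character(0), direction = character(0), snp_pos_gene = integer(0),
    snp_pos_contig = integer(0), ref_base = character(0),
    alt_base = character(0), depth = integer(0), depth_A = integer(0),
    depth_T = integer(0), depth_G = integer(0), depth_C = integer(0),
    quality = integer(0), copy_class = integer(0),
    paralog_specific = logical(0), psv_offsets = character(0),
    target_sequence = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read the assay marker table
#'
#' The writer/reader pair round-trips exactly.
#'
#' @param markers assay table from [emit_assay_table()].
#' @param path TSV path.
#' @return `path` invisibly (writer); the marker data.frame (reader).
#' @export
write_assay_table <- function(markers, path) {
  write_schema_tsv(markers, path, "assay")
}

#' @rdname write_assay_table
#' @export
read_assay_table <- function(path) {
  df <- read_schema_tsv(path, "assay")
  df$psv_offsets <- as.character(df$psv_offsets)
  df
}
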