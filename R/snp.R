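# Inter-line SNP calling from homolog alignments, depth/quality filtering
# and partition of results by paralog copy class.

#' Call SNPs from homolog pair alignments
#'
#' For every contig assigned to a gene model with alignment identity at or
#' above `min_identity` (the comparison floor for SNP mining), scans the
#' alignment columns and emits one variant site per mismatching column.
#' Columns within `gap_guard` columns of an alignment gap are excluded, the
#' alignment-route analogue of discarding indel-containing stretches. Depth
#' is attached from the contig's per-base depth track; when no quality
#' column exists, a deterministic stand-in `min(60, 10 + 5 * depth)` is
#' imputed (flagged by `quality_imputed`). Depth of the reference line
#' (gene models carry no reads) is treated as unbounded: the filter applies
#' to the contig line's depth.
#'
#' @param groups assignment table from [assign_homologs()].
#' @param contigs named character vector of contig sequences.
#' @param gene_models named character vector of reference coding sequences.
#' @param depth named list of per-base depth tracks (contig coordinates as
#'   emitted); `NULL` leaves depth `NA`.
#' @param min_identity identity floor for a pair to be compared
#'   (default 0.90).
#' @param gap_guard columns around an alignment gap to exclude (default 5).
#' @param match,mismatch,gap alignment scoring (must match the homology
#'   stage).
#' @return list with `sites` (data.frame: `gene_id`, `family_id`,
#'   `copy_class`, `paralog_index`, `position` in gene coordinates,
#'   `ref_base`, `alt_base`, `line`, `contig_id`, `contig_pos`, `aln_col`,
#'   `depth`, `quality`, `quality_imputed`, `snp_id`), `alignments` (per
#'   contig: gapped strings and offsets, reused by the marker stage) and
#'   `skipped` (pairs below the identity floor).
#' @export
call_snps <- function(groups, contigs, gene_models, depth = NULL,
                      min_identity = 0.90, gap_guard = 5L,
                      match = 2L, mismatch = -3L, gap = -5L) {
  site_rows <- list(); alignments <- list(); skipped <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    cseq <- contigs[[g$contig_id]]
    if (is.null(cseq)) stop("contig ", g$contig_id, " not supplied",
                            call. = FALSE)
    L <- nchar(cseq)
    if (!is.null(depth)) {
      d <- depth[[g$contig_id]]
      if (!is.null(d) && length(d) < L) {
        stop("depth track shorter than contig ", g$contig_id, call. = FALSE)
      }
    }
    q <- if (g$strand == "-") revcomp(cseq) else cseq
    a <- sw_align(q, gene_models[[g$gene_id]], match, mismatch, gap)
    if (a$identity < min_identity) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        contig_id = g$contig_id, gene_id = g$gene_id,
        identity = a$identity, reason = "below_identity_floor",
        stringsAsFactors = FALSE)
      next
    }
    qa <- seq_chars(a$q_aln); sa <- seq_chars(a$s_aln)
    ncols <- length(qa)
    gap_col <- qa == "-" | sa == "-"
    near_gap <- rep(FALSE, ncols)
    for (gc in which(gap_col)) {
      lo <- max(1L, gc - gap_guard); hi <- min(ncols, gc + gap_guard)
      near_gap[lo:hi] <- TRUE
    }
    qpos <- cumsum(qa != "-") + a$q_start - 1L
    spos <- cumsum(sa != "-") + a$s_start - 1L
    mism <- which(!gap_col & qa != sa & qa %in% DNA_BASES &
                    sa %in% DNA_BASES & !near_gap)
    alignments[[g$contig_id]] <- list(
      contig_id = g$contig_id, gene_id = g$gene_id, line = g$line,
      strand = g$strand, q_aln = a$q_aln, s_aln = a$s_aln,
      q_start = a$q_start, s_start = a$s_start, identity = a$identity,
      contig_len = L)
    if (!length(mism)) next
    cp_oriented <- qpos[mism]
    cp <- if (g$strand == "-") L - cp_oriented + 1L else cp_oriented
    dep <- rep(NA_integer_, length(mism))
    if (!is.null(depth) && !is.null(depth[[g$contig_id]])) {
      dep <- depth[[g$contig_id]][cp]
    }
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, family_id = g$family_id,
      copy_class = g$copy_class,
      paralog_index = if ("paralog_index" %in% names(g)) g$paralog_index else NA_integer_,
      position = spos[mism], ref_base = sa[mism], alt_base = qa[mism],
      line = g$line, contig_id = g$contig_id, contig_pos = cp,
      aln_col = mism, depth = dep,
      quality = pmin(60L, 10L + 5L * dep),
      quality_imputed = TRUE,
      snp_id = sprintf("%s:%s:%d", g$line, g$gene_id, spos[mism]),
      stringsAsFactors = FALSE)
  }
  empty_sites <- data.frame(
    gene_id = character(0), family_id = character(0), copy_class = integer(0),
    paralog_index = integer(0), position = integer(0), ref_base = character(0),
    alt_base = character(0), line = character(0), contig_id = character(0),
    contig_pos = integer(0), aln_col = integer(0), depth = integer(0),
    quality = integer(0), quality_imputed = logical(0), snp_id = character(0),
    stringsAsFactors = FALSE)
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else empty_sites
  rownames(sites) <- NULL
  list(sites = sites, alignments = alignments,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(contig_id = character(0), gene_id = character(0),
                    identity = numeric(0), reason = character(0),
                    stringsAsFactors = FALSE))
}

#' Filter SNP sites on read depth and quality
#'
#' A site is retained when its (contig-line) depth is at least `min_depth`
#' and its quality score at least `min_quality`; both boundaries are
#' inclusive, so depth 7 / quality 40 survive the defaults and depth 6 or
#' quality 39 do not.
#'
#' @param sites data.frame of variant sites from [call_snps()].
#' @param min_depth minimum read depth (default 7).
#' @param min_quality minimum quality score (default 40).
#' @return list with `sites` (retained rows) and `report` (named counts:
#'   `input`, `depth_fail`, `quality_fail`, `retained`). Sites with `NA`
#'   depth or quality fail the respective criterion.
#' @export
filter_snps <- function(sites, min_depth = 7L, min_quality = 40L) {
  depth_ok <- !is.na(sites$depth) & sites$depth >= min_depth
  qual_ok <- !is.na(sites$quality) & sites$quality >= min_quality
  keep <- depth_ok & qual_ok
  list(sites = sites[keep, , drop = FALSE],
       report = c(input = nrow(sites), depth_fail = sum(!depth_ok),
                  quality_fail = sum(!qual_ok), retained = sum(keep)))
}

#' Partition SNP counts by paralog copy class
#'
#' @param sites data.frame of variant sites.
#' @param paralog_table the paralog-group table.
#' @return named integer vector `total`, `single`, `two`, `three`,
#'   `unclassified` (sites in genes absent from the table).
#' @export
partition_by_copy_class <- function(sites, paralog_table) {
  cc <- paralog_table$copy_class[match(sites$gene_id, paralog_table$gene_id)]
  c(total = nrow(sites),
    single = sum(cc == 1L, na.rm = TRUE),
    two = sum(cc == 2L, na.rm = TRUE),
    three = sum(cc == 3L, na.rm = TRUE),
    unclassified = sum(is.na(cc)))
}

#' Fraction of genes taggable with at least one SNP
#'
#' Computes, per copy class, the fraction of gene families (present in the
#' homolog grouping) that carry at least one retained SNP -- the numerator
#' counts genes, not sites. An empty class yields `NA`, not zero.
#'
#' @param sites retained variant sites.
#' @param groups assignment table from [assign_homologs()].
#' @return data.frame `copy_class`, `n_genes`, `n_with_snp`, `fraction`.
#' @export
per_gene_snp_presence <- function(sites, groups) {
  out <- data.frame(copy_class = 1:3, n_genes = 0L, n_with_snp = 0L,
                    fraction = NA_real_)
  for (cc in 1:3) {
    fams <- unique(groups$family_id[groups$copy_class == cc])
    hit <- unique(sites$family_id[sites$copy_class == cc])
    out$n_genes[cc] <- length(fams)
    out$n_with_snp[cc] <- length(intersect(fams, hit))
    if (length(fams)) out$fraction[cc] <- out$n_with_snp[cc] / length(fams)
  }
  out
}

#' Write variant sites as TSV
#'
#' @param sites data.frame of variant sites.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(sites, path) {
  write_schema_tsv(sites, path, "snp")
}
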