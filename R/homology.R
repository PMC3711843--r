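# Homolog grouping: assign each line's contigs to reference gene models by
# seeded local alignment and classify genes by paralog copy number.

#' Pairwise local alignment
#'
#' Smith-Waterman local alignment with a linear gap penalty (compiled).
#' Identity is computed over aligned columns, gap columns included, and `N`
#' never counts as a match.
#'
#' @param query,subject uppercase A/C/G/T/N strings.
#' @param match,mismatch,gap scoring parameters (gap is per gap column).
#' @return list with `score`, `identity`, `matches`, `columns`, `gaps`,
#'   1-based `q_start`/`q_end`/`s_start`/`s_end` and the gapped aligned
#'   strings `q_aln`, `s_aln`.
#' @export
sw_align <- function(query, subject, match = 2L, mismatch = -3L, gap = -5L) {
  stopifnot(length(query) == 1L, length(subject) == 1L)
  res <- sw_align_cpp(query, subject, match, mismatch, gap)
  res$identity <- if (res$columns > 0L) res$matches / res$columns else 0
  res
}

# Exact k-mer index over the gene-model set: list(kmers = unique k-mer
# vector, genes = list of gene index vectors, k).
build_kmer_index <- function(gene_models, k) {
  kms <- lapply(gene_models, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  all_k <- unlist(kms, use.names = FALSE)
  gene_of <- rep(seq_along(gene_models), lengths(kms))
  uk <- unique(all_k)
  list(kmers = uk, genes = split(gene_of, factor(all_k, levels = uk)), k = k)
}

#' Align contigs against reference gene models
#'
#' Seeds candidate contig/gene pairs with exact shared k-mers on both
#' strands, extends each candidate with full Smith-Waterman dynamic
#' programming, and keeps hits meeting the identity and length thresholds.
#' Identity is matches over aligned columns (gaps count as columns). Query
#' intervals are reported in original (plus-strand) contig coordinates; a
#' `-` strand hit means the reverse complement of the contig aligned.
#'
#' @param contigs named character vector of contig sequences.
#' @param gene_models named character vector of reference coding sequences.
#' @param min_identity minimum identity fraction (default 0.80).
#' @param min_length minimum aligned length in columns (default 100).
#' @param k seed k-mer length (default 15; lower it to approach exhaustive
#'   all-vs-all search).
#' @param match,mismatch,gap alignment scoring.
#' @return data.frame of hits: `query_id`, `subject_id`, `identity`,
#'   `matches`, `aligned_length`, `gaps`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `strand`, `score`.
#' @export
align_contigs <- function(contigs, gene_models, min_identity = 0.80,
                          min_length = 100L, k = 15L,
                          match = 2L, mismatch = -3L, gap = -5L) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), matches = integer(0),
                      aligned_length = integer(0), gaps = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), score = integer(0),
                      stringsAsFactors = FALSE)
  if (length(contigs) == 0L) return(empty)
  short <- nchar(gene_models) < min_length
  if (any(short)) {
    warning("skipping gene model(s) shorter than min_length: ",
            paste(utils::head(names(gene_models)[short], 5L), collapse = ", "),
            call. = FALSE)
    gene_models <- gene_models[!short]
  }
  if (length(gene_models) == 0L) return(empty)
  idx <- build_kmer_index(gene_models, k)
  rows <- vector("list", length(contigs) * 2L)
  nrow_out <- 0L
  for (i in seq_along(contigs)) {
    qid <- names(contigs)[i]
    fwd <- contigs[[i]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") fwd else revcomp(fwd)
      if (L < idx$k) next
      qk <- unique(substring(q, 1:(L - idx$k + 1L), idx$k:L))
      hit_genes <- unique(unlist(idx$genes[stats::na.omit(match(qk, idx$kmers))],
                                 use.names = FALSE))
      for (g in hit_genes) {
        a <- sw_align(q, gene_models[[g]], match, mismatch, gap)
        if (a$columns < min_length || a$identity < min_identity) next
        qs <- a$q_start; qe <- a$q_end
        if (strand == "-") { qs <- L - a$q_end + 1L; qe <- L - a$q_start + 1L }
        nrow_out <- nrow_out + 1L
        rows[[nrow_out]] <- data.frame(
          query_id = qid, subject_id = names(gene_models)[g],
          identity = a$identity, matches = a$matches,
          aligned_length = a$columns, gaps = a$gaps,
          q_start = qs, q_end = qe, s_start = a$s_start, s_end = a$s_end,
          strand = strand, score = a$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow_out == 0L) return(empty)
  do.call(rbind, rows[seq_len(nrow_out)])
}

#' Assign contigs to their best gene model
#'
#' Each contig with at least one qualifying hit (identity >= `min_identity`
#' over >= `min_length` aligned columns) is assigned to a single best gene:
#' highest identity, then longest aligned length, then lexicographically
#' smallest gene id. The tie-break is order-independent, so permuting the
#' input never changes assignments. Contigs with no qualifying hit are
#' listed unassigned.
#'
#' @param hits data.frame from [align_contigs()].
#' @param paralog_table data.frame with `gene_id`, `family_id`, `copy_class`,
#'   `paralog_index`.
#' @param contig_lines named character vector mapping contig id to line id.
#' @param contig_ids optional character vector of all contig ids considered
#'   (so contigs without any hit can be reported unassigned); defaults to
#'   the contigs present in `hits` or in `contig_lines`.
#' @param min_identity,min_length assignment thresholds (defaults 0.80, 100).
#' @return list with `groups` (data.frame: `gene_id`, `family_id`,
#'   `copy_class`, `line`, `contig_id`, `identity`, `aligned_length`,
#'   `strand`, `q_start`, `q_end`, `s_start`, `s_end`) and `unassigned`
#'   (character vector of contig ids).
#' @export
assign_homologs <- function(hits, paralog_table, contig_lines,
                            contig_ids = NULL,
                            min_identity = 0.80, min_length = 100L) {
  if (is.null(contig_ids)) {
    contig_ids <- if (!is.null(names(contig_lines))) names(contig_lines)
                  else unique(hits$query_id)
  }
  ok <- hits[hits$identity >= min_identity & hits$aligned_length >= min_length, ]
  if (nrow(ok)) {
    unknown <- setdiff(ok$subject_id, paralog_table$gene_id)
    if (length(unknown)) {
      stop("gene(s) missing from paralog table: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    ord <- order(ok$query_id, -ok$identity, -ok$aligned_length, ok$subject_id)
    ok <- ok[ord, ]
    best <- ok[!duplicated(ok$query_id), ]
    m <- match(best$subject_id, paralog_table$gene_id)
    groups <- data.frame(
      gene_id = best$subject_id,
      family_id = paralog_table$family_id[m],
      copy_class = paralog_table$copy_class[m],
      line = unname(contig_lines[best$query_id]),
      contig_id = best$query_id,
      identity = best$identity, aligned_length = best$aligned_length,
      strand = best$strand,
      q_start = best$q_start, q_end = best$q_end,
      s_start = best$s_start, s_end = best$s_end,
      stringsAsFactors = FALSE)
    groups <- groups[order(groups$gene_id, groups$line, groups$contig_id), ]
    rownames(groups) <- NULL
  } else {
    groups <- data.frame(gene_id = character(0), family_id = character(0),
                         copy_class = integer(0), line = character(0),
                         contig_id = character(0), identity = numeric(0),
                         aligned_length = integer(0), strand = character(0),
                         q_start = integer(0), q_end = integer(0),
                         s_start = integer(0), s_end = integer(0),
                         stringsAsFactors = FALSE)
  }
  list(groups = groups,
       unassigned = sort(setdiff(contig_ids, groups$contig_id)))
}

#' Summarise homolog grouping by paralog copy class
#'
#' Counts, per line, the gene families with at least one assigned contig,
#' split by copy class -- the per-line analogue of a homology-based
#' grouping table. On full-coverage synthetic data the counts equal the
#' configured family counts.
#'
#' @param groups the `groups` data.frame from [assign_homologs()].
#' @param paralog_table the paralog-group table.
#' @return data.frame with columns `line`, `single`, `two`, `three`.
#' @export
summarize_copy_classes <- function(groups, paralog_table) {
  unknown <- setdiff(groups$gene_id, paralog_table$gene_id)
  if (length(unknown)) {
    stop("gene(s) missing from paralog table: ", unknown[1L], call. = FALSE)
  }
  lines <- sort(unique(groups$line))
  out <- data.frame(line = lines, single = 0L, two = 0L, three = 0L,
                    stringsAsFactors = FALSE)
  cls_name <- c("single", "two", "three")
  for (i in seq_along(lines)) {
    g <- groups[groups$line == lines[i], ]
    for (cc in 1:3) {
      out[[cls_name[cc]]][i] <-
        length(unique(g$family_id[g$copy_class == cc]))
    }
  }
  out
}

#' Write alignment hits in 12-column tabular format
#'
#' BLAST outfmt-6 dialect: identity as a percentage, mismatches as
#' non-match columns, gap columns in the gapopen slot, e-value and bitscore
#' replaced by 0 and the raw alignment score.
#'
#' @param hits data.frame from [align_contigs()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                   pident = round(100 * hits$identity, 2),
                   length = hits$aligned_length,
                   mismatch = hits$aligned_length - hits$matches - hits$gaps,
                   gapopen = hits$gaps,
                   qstart = hits$q_start, qend = hits$q_end,
                   sstart = hits$s_start, send = hits$s_end,
                   evalue = 0, bitscore = hits$score)
  write_schema_tsv(df, path, "hits")
}
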