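# Readers and writers for the formats the pipeline touches, plus the
# raw-read quality filter applied before assembly.

#' Read a FASTA file
#'
#' Parses with [Biostrings::readDNAStringSet()] (wrapped and unwrapped line
#' dialects, gzip-transparent) and returns a named character vector of
#' uppercase sequences. Record ids are the first whitespace-delimited token
#' of the description line and must be unique.
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @param strict if `TRUE` (default) sequences may contain only A/C/G/T/N;
#'   the first offending character is reported with its position. Set to
#'   `FALSE` to admit IUPAC ambiguity codes (assay exports).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, strict = TRUE) {
  # Biostrings drops invalid one-letter codes with only a warning, so
  # validate the raw text first and report the offending offset.
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  rec_id <- NA_character_; offset <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      rec_id <- sub("\\s.*$", "", substring(ln, 2L))
      offset <- 0L
    } else if (nzchar(ln)) {
      bad <- regexpr("[^ACGTNRYSWKMBDHVacgtnryswkmbdhv.-]", ln)
      if (bad > 0L) {
        stop("malformed FASTA '", path, "': invalid character '",
             substr(ln, bad, bad), "' in record '", rec_id,
             "' at sequence offset ", offset + bad, call. = FALSE)
      }
      offset <- offset + nchar(ln)
    }
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  if (strict) {
    bad <- regexpr("[^ACGTN]", seqs)
    hit <- which(bad > 0L)
    if (length(hit)) {
      stop("non-ACGTN character in record '", ids[hit[1L]],
           "' at position ", bad[hit[1L]], call. = FALSE)
    }
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences (names become ids).
#' @param path destination file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return a list with `id` (character), `seq` (character) and `qual`
#'   (list of integer Phred vectors), one element per read.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # harmless: names metadata dropped when binding quality to sequence
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  qual <- as(Biostrings::quality(x), "IntegerList")
  list(id = sub("\\s.*$", "", names(x)),
       seq = unname(as.character(x)),
       qual = unname(lapply(as.list(qual), unname)))
}

#' Quality-filter raw reads
#'
#' Reproduces the pre-assembly read QC: a read is dropped when more than
#' `max_lowq_fraction` of its bases (evaluated on the full, untrimmed read)
#' have Phred quality below `lowq_threshold`; surviving reads then have the
#' final `tail_trim` low-quality tail bases removed. The "more than" is
#' strict, so a read at exactly the boundary fraction is kept. Reads too
#' short to survive trimming are dropped and counted separately. Output
#' order of surviving reads matches input order.
#'
#' @param reads a read set as returned by [read_fastq()].
#' @param max_lowq_fraction maximum tolerated fraction of low-quality bases
#'   (strictly greater fails); default 0.30.
#' @param lowq_threshold Phred score below which a base is low quality
#'   (default 20).
#' @param tail_trim number of tail bases removed from surviving reads
#'   (default 31).
#' @return list with `reads` (filtered and trimmed, same shape as input) and
#'   `counts` (`input`, `dropped_lowq`, `dropped_short`, `kept`).
#' @export
filter_reads <- function(reads, max_lowq_fraction = 0.30,
                         lowq_threshold = 20L, tail_trim = 31L) {
  n <- length(reads$id)
  if (n == 0L) {
    return(list(reads = reads,
                counts = c(input = 0L, dropped_lowq = 0L,
                           dropped_short = 0L, kept = 0L)))
  }
  lens <- nchar(reads$seq)
  if (!all(lengths(reads$qual) == lens)) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  frac <- vapply(reads$qual, function(q) mean(q < lowq_threshold), numeric(1))
  fail_q <- frac > max_lowq_fraction
  too_short <- !fail_q & lens < (tail_trim + 1L)
  keep <- !fail_q & !too_short
  out <- list(
    id = reads$id[keep],
    seq = substr(reads$seq[keep], 1L, lens[keep] - tail_trim),
    qual = lapply(which(keep), function(i) {
      reads$qual[[i]][seq_len(lens[i] - tail_trim)]
    })
  )
  list(reads = out,
       counts = c(input = n, dropped_lowq = sum(fail_q),
                  dropped_short = sum(too_short), kept = sum(keep)))
}

#' Quality-filter a read pair, dropping orphaned mates
#'
#' Applies [filter_reads()] to both mates and keeps only pairs where both
#' reads survive, mirroring the removal of single-end reads before assembly.
#'
#' @param reads1,reads2 mate read sets as returned by [read_fastq()]; must
#'   be position-paired (read i of `reads1` mates read i of `reads2`).
#' @inheritParams filter_reads
#' @return list with `reads1`, `reads2` (surviving pairs, trimmed) and
#'   `counts` (`input_pairs`, `kept_pairs`, `dropped_pairs`).
#' @export
filter_read_pairs <- function(reads1, reads2, max_lowq_fraction = 0.30,
                              lowq_threshold = 20L, tail_trim = 31L) {
  if (length(reads1$id) != length(reads2$id)) {
    stop("mate files differ in read count", call. = FALSE)
  }
  keep_of <- function(r) {
    lens <- nchar(r$seq)
    frac <- vapply(r$qual, function(q) mean(q < lowq_threshold), numeric(1))
    frac <= max_lowq_fraction & lens >= (tail_trim + 1L)
  }
  keep <- keep_of(reads1) & keep_of(reads2)
  trim <- function(r) {
    lens <- nchar(r$seq)
    list(id = r$id[keep],
         seq = substr(r$seq[keep], 1L, lens[keep] - tail_trim),
         qual = lapply(which(keep), function(i) r$qual[[i]][seq_len(lens[i] - tail_trim)]))
  }
  list(reads1 = trim(reads1), reads2 = trim(reads2),
       counts = c(input_pairs = length(keep), kept_pairs = sum(keep),
                  dropped_pairs = sum(!keep)))
}

#' Read a per-base depth table
#'
#' Expects tab-separated columns `contig_id`, `position` (1-based,
#' contiguous from 1 within each contig) and `depth`.
#'
#' @param path path to the TSV file.
#' @param contigs optional named character vector of contig sequences; when
#'   supplied, each depth track must have exactly one entry per contig base.
#' @return named list of integer depth vectors, one per contig.
#' @export
read_depth_table <- function(path, contigs = NULL) {
  df <- read_schema_tsv(path)
  need <- c("contig_id", "position", "depth")
  if (!all(need %in% names(df))) {
    stop("depth table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$position < 1L)) {
    stop("depth positions are 1-based; found position ",
         min(df$position), call. = FALSE)
  }
  if (any(df$depth < 0L)) stop("negative depth", call. = FALSE)
  out <- lapply(split(df[c("position", "depth")], df$contig_id), function(d) {
    d <- d[order(d$position), ]
    gaps <- setdiff(seq_len(max(d$position)), d$position)
    if (length(gaps)) {
      stop("depth track has missing position(s): ",
           paste(utils::head(gaps, 5L), collapse = ", "), call. = FALSE)
    }
    as.integer(d$depth)
  })
  if (!is.null(contigs)) {
    common <- intersect(names(out), names(contigs))
    bad <- common[lengths(out[common]) != nchar(contigs[common])]
    if (length(bad)) {
      stop("depth track length disagrees with contig length for: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Write a per-base depth table
#'
#' @param depth named list of integer depth vectors.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depth, path) {
  df <- data.frame(
    contig_id = rep(names(depth), lengths(depth)),
    position = unlist(lapply(depth, seq_along), use.names = FALSE),
    depth = unlist(depth, use.names = FALSE)
  )
  write_schema_tsv(df, path, "depth")
}

#' Read a paralog-group table
#'
#' Expects columns `gene_id`, `family_id`, `copy_class` (1, 2 or 3) and
#' `paralog_index`; each gene belongs to exactly one family.
#'
#' @param path path to the TSV file.
#' @return data.frame with the four columns above.
#' @export
read_paralog_table <- function(path) {
  df <- read_schema_tsv(path)
  need <- c("gene_id", "family_id", "copy_class", "paralog_index")
  if (!all(need %in% names(df))) {
    stop("paralog table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("gene(s) listed twice in paralog table: ",
         df$gene_id[duplicated(df$gene_id)][1L], call. = FALSE)
  }
  if (!all(df$copy_class %in% 1:3)) {
    stop("copy_class outside {1,2,3}", call. = FALSE)
  }
  df[need]
}

#' Write a paralog-group table
#'
#' @param paralog_table data.frame as returned by [read_paralog_table()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_paralog_table <- function(paralog_table, path) {
  write_schema_tsv(paralog_table, path, "paralog")
}
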