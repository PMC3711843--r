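# SSR (microsatellite) detection with MISA-style perfect-repeat semantics
# and cross-line polymorphism comparison under the strict flank-identity rule.

# Lexicographically smallest rotation of a repeat unit.
canonical_motif <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(unit)
  rots <- vapply(seq_len(u), function(i) {
    paste0(substr(unit, i, u), substr(unit, 1L, i - 1L))
  }, character(1))
  min(rots)
}

# TRUE when `unit` is a whole-number repetition of a shorter unit
# (such runs are reported at the shorter unit length only).
is_periodic_unit <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(FALSE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && strrep(substr(unit, 1L, d), u %/% d) == unit) return(TRUE)
  }
  FALSE
}

#' Detect SSR loci
#'
#' Finds maximal perfect tandem repeats of 1-6 bp units with per-class
#' minimum repeat counts (MISA-style defaults 10/6/5/5/5/5 for mono- through
#' hexanucleotide motifs). A run whose unit is itself a repetition of a
#' shorter unit is reported only at the shortest unit; runs containing `N`
#' are broken at the `N`. Motifs are canonicalised to the lexicographically
#' smallest rotation (detection is strand-specific, as transcripts have a
#' defined strand). Two qualifying SSRs on the same sequence separated by at
#' most `max_interruption` bases are additionally reported as one `complex`
#' locus.
#'
#' @param seqs named character vector of uppercase sequences.
#' @param minima integer vector of minimum repeat counts for unit lengths
#'   1-6.
#' @param max_interruption maximum gap (bp) between two SSRs merged into a
#'   complex locus (default 100, the MISA default).
#' @param flank_len number of flanking bases to extract on each side
#'   (default 50).
#' @return data.frame with `sequence_id`, `motif` (canonical), `unit`,
#'   `repeat_count`, `start`, `end` (1-based inclusive;
#'   `end - start + 1 == unit * repeat_count` for simple loci),
#'   `left_flank`, `right_flank`, `full_flanks`, `kind` (simple/complex).
#' @export
detect_ssrs <- function(seqs, minima = c(10L, 6L, 5L, 5L, 5L, 5L),
                        max_interruption = 100L, flank_len = 50L) {
  stopifnot(length(minima) == 6L)
  empty <- data.frame(sequence_id = character(0), motif = character(0),
                      unit = integer(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0),
                      left_flank = character(0), right_flank = character(0),
                      full_flanks = logical(0), kind = character(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  out <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    L <- nchar(s)
    chars <- seq_chars(s)
    valid <- chars %in% DNA_BASES
    loci <- list()
    for (u in 1:6) {
      if (L < u * minima[u]) next
      m <- chars[seq_len(L - u)] == chars[(u + 1L):L] &
        valid[seq_len(L - u)] & valid[(u + 1L):L]
      r <- rle(m)
      pos <- 1L
      for (j in seq_along(r$lengths)) {
        if (r$values[j]) {
          region_len <- r$lengths[j] + u
          count <- region_len %/% u
          if (count >= minima[u]) {
            unit_seq <- substr(s, pos, pos + u - 1L)
            if (!is_periodic_unit(unit_seq)) {
              st <- pos; en <- pos + count * u - 1L
              loci[[length(loci) + 1L]] <- data.frame(
                sequence_id = sid, motif = canonical_motif(unit_seq),
                unit = u, repeat_count = count, start = st, end = en,
                left_flank = substr(s, max(1L, st - flank_len), st - 1L),
                right_flank = substr(s, en + 1L, min(L, en + flank_len)),
                full_flanks = (st - flank_len >= 1L) && (en + flank_len <= L),
                kind = "simple", stringsAsFactors = FALSE)
            }
          }
        }
        pos <- pos + r$lengths[j]
      }
    }
    if (length(loci)) {
      df <- do.call(rbind, loci)
      df <- df[order(df$start, df$unit), ]
      # chain nearby SSRs into complex loci (reported in addition)
      if (nrow(df) >= 2L) {
        # new chain whenever the gap to the previous locus exceeds the cutoff
        gap_prev <- c(Inf, df$start[-1L] - df$end[-nrow(df)] - 1L)
        chain_id <- cumsum(gap_prev > max_interruption)
        for (cid in unique(chain_id)) {
          members <- df[chain_id == cid, ]
          if (nrow(members) >= 2L) {
            st <- min(members$start); en <- max(members$end)
            loci[[length(loci) + 1L]] <- data.frame(
              sequence_id = sid,
              motif = paste(members$motif, collapse = "+"),
              unit = NA_integer_, repeat_count = NA_integer_,
              start = st, end = en,
              left_flank = substr(s, max(1L, st - flank_len), st - 1L),
              right_flank = substr(s, en + 1L, min(L, en + flank_len)),
              full_flanks = (st - flank_len >= 1L) && (en + flank_len <= L),
              kind = "complex", stringsAsFactors = FALSE)
          }
        }
      }
      out[[length(out) + 1L]] <- do.call(rbind, loci)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$sequence_id, res$start, res$kind), ]
  rownames(res) <- NULL
  res
}

#' Compare SSR loci between two lines
#'
#' Pairs simple SSR loci from two lines on corresponding sequences by
#' canonical motif and rank order, then applies the strict polymorphism
#' rule: a pair is polymorphic if and only if the motifs are identical, the
#' repeat counts differ, and the `flank_len` bases on both sides of the
#' repeat are exactly identical between the lines. Loci with less than
#' `flank_len` available flank are excluded and counted in the
#' `excluded_short_flank` attribute.
#'
#' @param loci_a,loci_b data.frames from [detect_ssrs()].
#' @param correspondence optional named character vector mapping
#'   `loci_b` sequence ids onto `loci_a` sequence ids (e.g. contig to gene
#'   model, from the homology stage); by default sequence ids are matched
#'   directly.
#' @param flank_len flank length that must match exactly (default 50).
#' @return data.frame with `sequence_id`, `motif`, `count_a`, `count_b`,
#'   `flank_identical`, `polymorphic`; attribute `excluded_short_flank`
#'   counts loci skipped for insufficient flank.
#' @export
compare_ssrs <- function(loci_a, loci_b, correspondence = NULL,
                         flank_len = 50L) {
  a <- loci_a[loci_a$kind == "simple", ]
  b <- loci_b[loci_b$kind == "simple", ]
  if (!is.null(correspondence)) {
    b$sequence_id <- unname(correspondence[b$sequence_id])
    b <- b[!is.na(b$sequence_id), ]
  }
  if (flank_len > 50L) stop("flank_len above the stored 50 bp flanks",
                            call. = FALSE)
  clip <- function(df) {
    df$left_flank <- substr(df$left_flank,
                            pmax(1L, nchar(df$left_flank) - flank_len + 1L),
                            nchar(df$left_flank))
    df$right_flank <- substr(df$right_flank, 1L, flank_len)
    df
  }
  a <- clip(a); b <- clip(b)
  excluded <- sum(nchar(a$left_flank) < flank_len |
                    nchar(a$right_flank) < flank_len) +
    sum(nchar(b$left_flank) < flank_len | nchar(b$right_flank) < flank_len)
  a <- a[nchar(a$left_flank) >= flank_len & nchar(a$right_flank) >= flank_len, ]
  b <- b[nchar(b$left_flank) >= flank_len & nchar(b$right_flank) >= flank_len, ]
  rows <- list()
  keys <- intersect(unique(a$sequence_id), unique(b$sequence_id))
  for (key in keys) {
    ka <- a[a$sequence_id == key, ]
    kb <- b[b$sequence_id == key, ]
    for (mo in intersect(unique(ka$motif), unique(kb$motif))) {
      ma <- ka[ka$motif == mo, ]; mb <- kb[kb$motif == mo, ]
      for (r in seq_len(min(nrow(ma), nrow(mb)))) {
        ident <- ma$left_flank[r] == mb$left_flank[r] &&
          ma$right_flank[r] == mb$right_flank[r]
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = key, motif = mo,
          count_a = ma$repeat_count[r], count_b = mb$repeat_count[r],
          flank_identical = ident,
          polymorphic = ident && ma$repeat_count[r] != mb$repeat_count[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(0), motif = character(0),
               count_a = integer(0), count_b = integer(0),
               flank_identical = logical(0), polymorphic = logical(0),
               stringsAsFactors = FALSE)
  attr(res, "excluded_short_flank") <- excluded
  res
}

#' Summarise polymorphic-SSR sharing across lines
#'
#' Runs [compare_ssrs()] on every unordered pair of lines and reports the
#' symmetric pairwise polymorphic-locus counts plus the per-marker pair
#' membership from which multi-way (Venn) counts follow by
#' inclusion-exclusion.
#'
#' @param loci_by_line named list mapping line id to a [detect_ssrs()]
#'   table; sequence ids must be on a shared key (e.g. gene ids).
#' @param flank_len flank length for the identity rule (default 50).
#' @return list with `pairwise` (symmetric integer matrix of polymorphic
#'   counts) and `membership` (data.frame `marker`, `line_a`, `line_b`).
#' @export
summarize_ssr_sharing <- function(loci_by_line, flank_len = 50L) {
  lines <- names(loci_by_line)
  if (length(lines) < 2L) stop("need at least two lines", call. = FALSE)
  lines <- sort(lines)
  pw <- matrix(0L, length(lines), length(lines),
               dimnames = list(lines, lines))
  mem <- list()
  for (i in seq_along(lines)) {
    for (j in seq_along(lines)) {
      if (j <= i) next
      cmp <- compare_ssrs(loci_by_line[[lines[i]]], loci_by_line[[lines[j]]],
                          flank_len = flank_len)
      poly <- cmp[cmp$polymorphic, , drop = FALSE]
      pw[i, j] <- pw[j, i] <- nrow(poly)
      if (nrow(poly)) {
        mem[[length(mem) + 1L]] <- data.frame(
          marker = paste(poly$sequence_id, poly$motif, sep = ":"),
          line_a = lines[i], line_b = lines[j], stringsAsFactors = FALSE)
      }
    }
  }
  list(pairwise = pw,
       membership = if (length(mem)) do.call(rbind, mem) else
         data.frame(marker = character(0), line_a = character(0),
                    line_b = character(0), stringsAsFactors = FALSE))
}

#' Write SSR loci in MISA-style tabular form
#'
#' @param loci data.frame from [detect_ssrs()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(loci, path) {
  df <- data.frame(ID = loci$sequence_id,
                   SSR.nr = stats::ave(seq_len(nrow(loci)), loci$sequence_id,
                                       FUN = seq_along),
                   SSR.type = ifelse(loci$kind == "complex", "c",
                                     paste0("p", loci$unit)),
                   SSR = ifelse(loci$kind == "complex", loci$motif,
                                sprintf("(%s)%d", loci$motif, loci$repeat_count)),
                   size = loci$end - loci$start + 1L,
                   start = loci$start, end = loci$end)
  write_schema_tsv(df, path, "ssr")
}
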