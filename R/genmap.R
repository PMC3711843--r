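# Two-point genetic-mapping utilities for validating designed markers on
# RIL genotypes: segregation-distortion screening, recombination-fraction
# estimation with the selfed-RIL correction, LOD scores, Kosambi distances
# and LOD-threshold linkage grouping.

#' Test a marker for segregation distortion
#'
#' Chi-square test (1 df) of the observed A:B counts against the 1:1
#' expectation of a RIL population. Heterozygous and missing calls are
#' excluded. A marker with fewer than 20 informative calls is flagged
#' low-power rather than rejected.
#'
#' @param calls character vector of genotype calls (`A`/`B`/`H`/`-`).
#' @param alpha significance level for the distorted flag (default 0.01).
#' @param parents the two parental call codes.
#' @return list with `n_a`, `n_b`, `chisq`, `p_value`, `distorted`,
#'   `low_power`.
#' @export
test_segregation_distortion <- function(calls, alpha = 0.01,
                                        parents = c("A", "B")) {
  n_a <- sum(calls == parents[1L]); n_b <- sum(calls == parents[2L])
  n <- n_a + n_b
  if (n == 0L) {
    return(list(n_a = 0L, n_b = 0L, chisq = NA_real_, p_value = NA_real_,
                distorted = FALSE, low_power = TRUE))
  }
  e <- n / 2
  chisq <- (n_a - e)^2 / e + (n_b - e)^2 / e
  p <- pchisq(chisq, df = 1L, lower.tail = FALSE)
  list(n_a = n_a, n_b = n_b, chisq = chisq, p_value = p,
       distorted = p < alpha, low_power = n < 20L)
}

#' Expected recombinant fraction among fixed selfed-RIL lines
#'
#' Exact two-locus expectation for a population derived from an F1 by
#' `generation - 1` rounds of selfing, computed by iterating the
#' 16-state diplotype Markov chain (gametes recombine with probability `r`
#' per meiosis, no interference) and conditioning on lines homozygous at
#' both loci. As `generation` grows this converges to the
#' Haldane-Waterman fixation value `2r / (1 + 2r)`, which is returned
#' directly for `generation = Inf`.
#'
#' @param r per-meiosis recombination fraction in `[0, 0.5]`.
#' @param generation filial generation (>= 2), or `Inf` for fixation.
#' @return expected observable recombinant fraction.
#' @export
ril_expected_R <- function(r, generation = 7L) {
  stopifnot(r >= 0, r <= 0.5)
  if (is.infinite(generation)) return(2 * r / (1 + 2 * r))
  stopifnot(generation >= 2)
  # haplotypes 1:(A,A) 2:(A,B) 3:(B,A) 4:(B,B); allele index per locus
  al1 <- c(1L, 1L, 2L, 2L); al2 <- c(1L, 2L, 1L, 2L)
  hap_of <- matrix(0L, 2L, 2L)
  hap_of[1, 1] <- 1L; hap_of[1, 2] <- 2L; hap_of[2, 1] <- 3L; hap_of[2, 2] <- 4L
  gamete_probs <- function(i, j) {
    p <- numeric(4L)
    p[i] <- p[i] + (1 - r) / 2
    p[j] <- p[j] + (1 - r) / 2
    p[hap_of[al1[i], al2[j]]] <- p[hap_of[al1[i], al2[j]]] + r / 2
    p[hap_of[al1[j], al2[i]]] <- p[hap_of[al1[j], al2[i]]] + r / 2
    p
  }
  dist <- matrix(0, 4L, 4L)  # ordered diplotypes (hap1, hap2)
  dist[1L, 4L] <- 1          # F1 = (A,A)/(B,B)
  for (g in seq_len(generation - 1L)) {
    nxt <- matrix(0, 4L, 4L)
    for (i in 1:4) for (j in 1:4) {
      if (dist[i, j] > 0) {
        p <- gamete_probs(i, j)
        nxt <- nxt + dist[i, j] * outer(p, p)
      }
    }
    dist <- nxt
  }
  fixed <- c(dist[1L, 1L], dist[2L, 2L], dist[3L, 3L], dist[4L, 4L])
  (fixed[2L] + fixed[3L]) / sum(fixed)
}

# memoised numeric inversion of ril_expected_R (all-pairs scans revisit
# the same observed fractions many times)
.rf_cache <- new.env(parent = emptyenv())

invert_ril_R <- function(R, generation) {
  r_cap <- 0.5 - 1e-9
  if (R <= 0) return(0)
  if (is.infinite(generation)) return(min(R / (2 * (1 - R)), r_cap))
  key <- sprintf("%.12g|%d", R, as.integer(generation))
  hit <- .rf_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(x) ril_expected_R(x, generation) - R
  r <- if (f(r_cap) <= 0) r_cap else stats::uniroot(f, c(0, r_cap),
                                                    tol = 1e-9)$root
  .rf_cache[[key]] <- r
  r
}

#' Estimate the two-point recombination fraction for a RIL marker pair
#'
#' The observed recombinant fraction `R` is the proportion of jointly
#' informative individuals (both calls parental) whose calls differ,
#' capped at 0.5. The per-meiosis fraction `r` is recovered by numerically
#' inverting the exact finite-generation expectation [ril_expected_R()]
#' for the population's generation; with `generation = Inf` this reduces
#' to inverting the fixation expectation `R = 2r / (1 + 2r)`, i.e.
#' `r = R / (2 (1 - R))`. The estimate is capped just below 0.5.
#'
#' @param g1,g2 genotype call vectors for the two markers.
#' @param generation filial generation of the population (default 7);
#'   `Inf` applies the fixation correction.
#' @param parents the two parental call codes.
#' @return list with `n_informative`, `R` (observed), `r` (meiotic), `lod`
#'   and `kosambi_cm`.
#' @export
estimate_rf <- function(g1, g2, generation = 7L, parents = c("A", "B")) {
  stopifnot(length(g1) == length(g2))
  inf <- g1 %in% parents & g2 %in% parents
  n <- sum(inf)
  if (n == 0L) stop("no jointly informative individuals", call. = FALSE)
  R <- min(sum(g1[inf] != g2[inf]) / n, 0.5)
  r <- invert_ril_R(R, generation)
  list(n_informative = n, R = R, r = r,
       lod = lod_score(R, n), kosambi_cm = kosambi_cm(r))
}

#' Two-point LOD score for linkage
#'
#' Binomial log10 likelihood ratio of the observed recombinant fraction
#' against independence (R = 0.5):
#' `LOD = k log10(R/0.5) + (n - k) log10((1 - R)/0.5)` with
#' `k = round(R n)`; terms with zero counts contribute zero, so `R = 0`
#' gives `n log10(2)` and `R = 0.5` gives 0.
#'
#' @param R observed recombinant fraction in `[0, 0.5]`.
#' @param n number of informative individuals.
#' @return the LOD score (non-negative).
#' @export
lod_score <- function(R, n) {
  stopifnot(R >= 0, R <= 0.5, n >= 1)
  k <- round(R * n)
  t1 <- if (k > 0) k * log10(R / 0.5) else 0
  t2 <- if (n - k > 0) (n - k) * log10((1 - R) / 0.5) else 0
  max(t1 + t2, 0)
}

#' Kosambi map distance
#'
#' `d = 25 ln((1 + 2r) / (1 - 2r))` centiMorgans: zero at `r = 0`,
#' strictly increasing, approximately `100 r` for small `r`, and undefined
#' at `r >= 0.5`.
#'
#' @param r per-meiosis recombination fraction in `[0, 0.5)`.
#' @return distance in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0) || any(r >= 0.5)) {
    stop("Kosambi distance is defined for 0 <= r < 0.5", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Haldane map distance
#'
#' `d = -50 ln(1 - 2r)` cM (no interference); upper bound for the Kosambi
#' distance at the same `r`.
#'
#' @inheritParams kosambi_cm
#' @return distance in cM.
#' @export
haldane_cm <- function(r) {
  if (any(r < 0) || any(r >= 0.5)) {
    stop("Haldane distance is defined for 0 <= r < 0.5", call. = FALSE)
  }
  -50 * log(1 - 2 * r)
}

#' All-pairs two-point linkage scan
#'
#' @param genotypes markers x individuals character matrix.
#' @param generation filial generation for the RIL correction (default 7).
#' @param parents the two parental call codes.
#' @return data.frame with `marker_a`, `marker_b`, `n_informative`, `R`,
#'   `r`, `lod`, `kosambi_cm` for every unordered marker pair.
#' @export
two_point_scan <- function(genotypes, generation = 7L,
                           parents = c("A", "B")) {
  mk <- rownames(genotypes)
  n <- length(mk)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      est <- estimate_rf(genotypes[i, ], genotypes[j, ], generation, parents)
      rows[[length(rows) + 1L]] <- data.frame(
        marker_a = mk[i], marker_b = mk[j],
        n_informative = est$n_informative, R = est$R, r = est$r,
        lod = est$lod, kosambi_cm = est$kosambi_cm,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group markers into linkage groups by LOD threshold
#'
#' Linkage groups are the connected components of the marker graph with an
#' edge wherever the pairwise LOD exceeds `lod_threshold` (and the observed
#' recombinant fraction is below `rf_ceiling`). Group labels are the
#' lexicographically smallest member marker id, so the partition is
#' independent of input order.
#'
#' @param two_point data.frame from [two_point_scan()].
#' @param lod_threshold LOD cutoff for an edge (default 6.0; edges require
#'   LOD strictly greater).
#' @param rf_ceiling maximum observed recombinant fraction for an edge.
#' @param markers optional character vector of all marker ids (singletons
#'   appear as their own groups).
#' @return data.frame with `marker`, `group` (label of smallest member).
#' @export
group_markers <- function(two_point, lod_threshold = 6.0, rf_ceiling = 0.5,
                          markers = NULL) {
  if (is.null(markers)) {
    markers <- sort(unique(c(two_point$marker_a, two_point$marker_b)))
  } else {
    markers <- sort(unique(markers))
  }
  edges <- two_point[two_point$lod > lod_threshold &
                       two_point$R < rf_ceiling, , drop = FALSE]
  # union-find with path compression
  parent <- seq_along(markers)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (e in seq_len(nrow(edges))) {
    i <- find(match(edges$marker_a[e], markers))
    j <- find(match(edges$marker_b[e], markers))
    if (i != j) parent[max(i, j)] <- min(i, j)
  }
  roots <- vapply(seq_along(markers), find, integer(1))
  data.frame(marker = markers, group = markers[roots],
             stringsAsFactors = FALSE)
}
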