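#' @title Cis/trans classification of expression-trait hits
#' @name cis_trans
#' @description An expression trait whose robustness maps to a marker near
#'   the measured gene itself most likely has a cis-acting basis; a marker
#'   far away or on another chromosome indicates trans action.  The window
#'   defaults to 5 Mb (5,000,000 bp exactly), inclusive at the boundary.
NULL

#' Classify a gene/marker pair as cis or trans
#'
#' @param gene_chrom,gene_pos chromosome and 1-based bp position of the
#'   measured gene (a single representative coordinate, e.g. probe or TSS).
#' @param marker_chrom,marker_pos marker coordinates.
#' @param window bp window (default 5e6); cis iff same chromosome and
#'   `|marker_pos - gene_pos| <= window`.
#' @return character vector over `{"cis", "trans", "unknown"}` (`unknown`
#'   when either side is unmapped).  Vectorised.
#' @export
classify_position <- function(gene_chrom, gene_pos, marker_chrom,
                              marker_pos, window = 5e6) {
  stopifnot(window > 0)
  n <- max(length(gene_chrom), length(marker_chrom))
  gene_chrom <- rep_len(as.character(gene_chrom), n)
  marker_chrom <- rep_len(as.character(marker_chrom), n)
  gene_pos <- rep_len(as.numeric(gene_pos), n)
  marker_pos <- rep_len(as.numeric(marker_pos), n)
  out <- rep("unknown", n)
  ok <- !is.na(gene_chrom) & !is.na(marker_chrom) &
    !is.na(gene_pos) & !is.na(marker_pos)
  out[ok] <- ifelse(gene_chrom[ok] == marker_chrom[ok] &
                      abs(marker_pos[ok] - gene_pos[ok]) <= window,
                    "cis", "trans")
  out
}

#' Annotate a hit table with cis/trans flags
#'
#' @param hits a `robust_hits` table.
#' @param features `genome_map` of trait/gene positions.
#' @param markers `genome_map` of marker positions (only needed when the
#'   table lacks coordinates).
#' @param window bp window, default 5e6.
#' @return the hit table with `cis_flag` filled in (and marker coordinates
#'   added where missing).
#' @export
classify_hits <- function(hits, features, markers = NULL, window = 5e6) {
  stopifnot(inherits(hits, "robust_hits"))
  if (!nrow(hits)) return(hits)
  if (!is.null(markers)) {
    loc <- .map_lookup(hits$marker_id, markers)
    fill <- is.na(hits$chrom)
    hits$chrom[fill] <- loc$chrom[fill]
    hits$pos[fill] <- loc$pos[fill]
  }
  gene <- .map_lookup(hits$trait_id, features)
  hits$cis_flag <- classify_position(gene$chrom, gene$pos,
                                     hits$chrom, hits$pos, window)
  hits
}

#' Trait-level cis classification
#'
#' A trait counts as cis-classified if at least one of its hit markers is
#' within the window of the gene; `unknown` when none of its markers could
#' be classified.
#'
#' @param hits a cis-annotated `robust_hits` table (see [classify_hits()]).
#' @param significant_only classify from hit rows only (default `TRUE`).
#' @return named character vector (per trait) over
#'   `{"cis", "trans", "unknown"}`.
#' @export
trait_level_cis <- function(hits, significant_only = TRUE) {
  h <- if (significant_only && "hit" %in% names(hits))
    significant_hits(hits) else hits
  if (!nrow(h)) return(stats::setNames(character(0), character(0)))
  vapply(split(h$cis_flag, h$trait_id), function(fl) {
    if (any(fl == "cis")) "cis"
    else if (any(fl == "trans")) "trans"
    else "unknown"
  }, character(1))
}

#' Expected chance cis count from permutation hit lists
#'
#' The number of cis classifications expected in a hit list of a given
#' size under no true cis signal, estimated as the mean number of
#' cis-classified traits across permutation-derived hit lists (each
#' truncated or taken as-is to match the observed list size profile).
#'
#' @param perm_hits list of cis-annotated `robust_hits` tables from scans
#'   of permuted panels.
#' @param level `"trait"` (count cis traits, default) or `"pair"`.
#' @return list with `expected` (mean cis count) and `per_perm` counts.
#' @export
expected_cis_null <- function(perm_hits, level = c("trait", "pair")) {
  level <- match.arg(level)
  if (!length(perm_hits)) stop("no permutation hit lists supplied")
  counts <- vapply(perm_hits, function(h) {
    if (!nrow(h)) return(0)
    if (level == "pair") {
      hh <- if ("hit" %in% names(h)) significant_hits(h) else h
      sum(hh$cis_flag == "cis")
    } else sum(trait_level_cis(h) == "cis")
  }, numeric(1))
  list(expected = mean(counts), per_perm = counts)
}

#' Expected chance cis count from random marker placement
#'
#' Alternative estimator: for each trait in the hit list, draws markers
#' uniformly at random from the eligible marker map and counts how often a
#' drawn marker falls within the window of the gene.
#'
#' @param trait_ids traits of the observed hit list.
#' @param markers_per_trait markers per trait (recycled).
#' @param features,markers `genome_map`s.
#' @param window bp window.
#' @param n_draws Monte-Carlo draws.
#' @param seed optional seed.
#' @return list with `expected` cis-trait count and `per_draw` counts.
#' @export
expected_cis_random <- function(trait_ids, markers_per_trait, features,
                                markers, window = 5e6, n_draws = 1000L,
                                seed = NULL) {
  k <- rep_len(markers_per_trait, length(trait_ids))
  gene <- .map_lookup(trait_ids, features)
  .with_seed(seed, {
    per_draw <- vapply(seq_len(n_draws), function(d) {
      sum(vapply(seq_along(trait_ids), function(i) {
        pick <- markers[sample(nrow(markers), min(k[i], nrow(markers))), ]
        any(classify_position(gene$chrom[i], gene$pos[i],
                              pick$chrom, pick$pos, window) == "cis")
      }, logical(1)))
    }, numeric(1))
    list(expected = mean(per_draw), per_draw = per_draw)
  })
}

#' Fraction of true-positive hits acting in cis
#'
#' False positives inflate both the total and the cis hit counts, so the
#' cis fraction among true positives is estimated as
#' `(cis_hits - fp_cis) / (total_hits - fp_total)`: expected false
#' positives (from permutation) are subtracted from both numerator and
#' denominator.  The numerator is clamped at zero (an observed cis count
#' slightly below its chance expectation means an estimated cis fraction
#' of zero, not a negative one); the result is NA when the estimated
#' true-positive total is not positive.
#'
#' @param total_hits observed hit count.
#' @param fp_total expected false positives among them.
#' @param cis_hits observed cis-classified count.
#' @param fp_cis expected false cis classifications.
#' @return proportion in `[0, 1]`, or NA with a warning.
#' @export
cis_tp_fraction <- function(total_hits, fp_total, cis_hits, fp_cis) {
  stopifnot(total_hits >= 0, fp_total >= 0, cis_hits >= 0, fp_cis >= 0)
  denom <- total_hits - fp_total
  if (denom <= 0) {
    warning("no estimated true positives; cis fraction undefined")
    return(NA_real_)
  }
  min(1, max(0, cis_hits - fp_cis) / denom)
}
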