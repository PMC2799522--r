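#' @title Confounding diagnostics for robustness scans
#' @name scan_diagnostics
#' @description Checks for the systematic artifacts that could fake
#'   robustness QTL: inflated nominal p-values (population structure),
#'   excess genotype-class co-occurrence of closely related strains,
#'   cage/shipment batch effects, and enrichment of technically flagged
#'   traits (e.g. probes overlapping SNPs) among hits.  All diagnostics
#'   are pure functions of their inputs.
NULL

#' Cumulative p-value inflation curve
#'
#' Under the assumption that true associations are rare, the cumulative
#' distribution of scan p-values should follow the uniform diagonal
#' (slope 1); systematic inflation of small p-values bends the curve
#' upward.  Reports the empirical CDF against the diagonal and the maximum
#' vertical deviation, which equals the classical one-sample
#' Kolmogorov-Smirnov statistic against the uniform distribution.
#'
#' @param pvals vector of nominal p-values in `[0, 1]` (non-empty).
#' @param warn_deviation deviation above which the flag is `"warn"`
#'   (default 0.05, appropriate from about 1e4 p-values).
#' @return object of class `inflation_curve`: list with `curve` (data
#'   frame `p`, `ecdf`), `max_deviation`, `flag`.
#' @export
pvalue_inflation_curve <- function(pvals, warn_deviation = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  s <- sort(pvals)
  n <- length(s)
  ecdf_hi <- seq_len(n) / n
  ecdf_lo <- (seq_len(n) - 1) / n
  dev <- max(pmax(abs(ecdf_hi - s), abs(ecdf_lo - s)))
  structure(list(curve = data.frame(p = s, ecdf = ecdf_hi),
                 max_deviation = dev,
                 flag = if (dev > warn_deviation) "warn" else "pass",
                 n = n, warn_deviation = warn_deviation),
            class = "inflation_curve")
}

#' @export
print.inflation_curve <- function(x, ...) {
  cat(sprintf("p-value inflation check: max deviation %.4f over %d p-values [%s]\n",
              x$max_deviation, x$n, x$flag))
  invisible(x)
}

#' @export
plot.inflation_curve <- function(x, ...) {
  graphics::plot(x$curve$p, x$curve$ecdf, type = "s",
                 xlab = "nominal p", ylab = "cumulative fraction", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}

#' Genotype-class co-occurrence versus phylogenetic distance
#'
#' Population structure would make closely related strains land in the
#' same genotype class at hit markers more often than expected.  For every
#' strain pair this computes the phylogenetic distance (number of
#' differing genotype calls across all markers) and the frequency of
#' sharing a genotype class at the hit markers, and reports their Spearman
#' rank correlation.  A strong negative correlation (related pairs
#' co-occur in excess) triggers a warning flag.
#'
#' @param geno a `genotype_panel`.
#' @param hits a `robust_hits` table (its significant markers are used);
#'   an empty table yields an empty report.
#' @param warn_rho negative rank correlation beyond which the flag is
#'   `"warn"` (default -0.3).
#' @return object of class `cooccurrence_check`: per-pair data frame
#'   (`strain1`, `strain2`, `distance`, `cooccurrence`), `rho`, `flag`.
#' @export
cooccurrence_vs_distance <- function(geno, hits, warn_rho = -0.3) {
  stopifnot(inherits(geno, "genotype_panel"))
  if (nrow(geno$calls) < 3) stop("need at least 3 strains")
  h <- if ("hit" %in% names(hits)) significant_hits(hits) else hits
  mk <- unique(h$marker_id)
  mk <- intersect(mk, colnames(geno$calls))
  if (!length(mk))
    return(structure(list(pairs = data.frame(), rho = NA_real_,
                          flag = "pass", n_hit_markers = 0L),
                     class = "cooccurrence_check"))
  calls <- geno$calls
  strains <- rownames(calls)
  pair_idx <- utils::combn(length(strains), 2)
  dist <- coocc <- numeric(ncol(pair_idx))
  for (k in seq_len(ncol(pair_idx))) {
    a <- calls[pair_idx[1, k], ]; b <- calls[pair_idx[2, k], ]
    ok <- !is.na(a) & !is.na(b)
    dist[k] <- sum(a[ok] != b[ok])
    ah <- calls[pair_idx[1, k], mk]; bh <- calls[pair_idx[2, k], mk]
    okh <- !is.na(ah) & !is.na(bh)
    coocc[k] <- if (any(okh)) mean(ah[okh] == bh[okh]) else NA_real_
  }
  rho <- suppressWarnings(stats::cor(dist, coocc, method = "spearman",
                                     use = "complete.obs"))
  structure(list(
    pairs = data.frame(strain1 = strains[pair_idx[1, ]],
                       strain2 = strains[pair_idx[2, ]],
                       distance = dist, cooccurrence = coocc,
                       stringsAsFactors = FALSE),
    rho = rho,
    flag = if (!is.na(rho) && rho < warn_rho) "warn" else "pass",
    n_hit_markers = length(mk)), class = "cooccurrence_check")
}

#' @export
print.cooccurrence_check <- function(x, ...) {
  cat(sprintf("structure check: %d pairs, %d hit markers, rho = %.3f [%s]\n",
              nrow(x$pairs), x$n_hit_markers,
              if (is.na(x$rho)) NA else x$rho, x$flag))
  invisible(x)
}

#' Batch-effect check via paired sample correlations
#'
#' Pairs of same-strain, same-sex samples are grouped by a batch category
#' (e.g. shared cage, shared shipment, neither).  If batches affected the
#' data, pairs sharing a batch would show systematically higher trait
#' profile correlations.  Reports per-category mean Pearson correlation
#' (with SD and pair count) and flags the check when the categories
#' differ (one-way ANOVA at `warn_alpha` on Fisher-z transformed
#' correlations).
#'
#' @param panel a `phenotype_panel`.
#' @param pairs data frame with columns `sample1`, `sample2`, `category`.
#' @param warn_alpha significance level for the category-difference test.
#' @return object of class `batch_check`: per-category summary plus the
#'   ANOVA p.
#' @export
paired_group_correlation <- function(panel, pairs, warn_alpha = 0.01) {
  stopifnot(inherits(panel, "phenotype_panel"))
  .required(pairs, c("sample1", "sample2", "category"), "pairs table",
            "<in-memory>")
  rmat <- panel$traits
  rr <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- rmat[pairs$sample1[i], ]; b <- rmat[pairs$sample2[i], ]
    suppressWarnings(stats::cor(a, b, use = "pairwise.complete.obs"))
  }, numeric(1))
  bycat <- split(rr, pairs$category)
  summ <- data.frame(
    category = names(bycat),
    n_pairs = lengths(bycat),
    mean_r = vapply(bycat, mean, numeric(1), na.rm = TRUE),
    sd_r = vapply(bycat, stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  p_equal <- NA_real_
  if (length(bycat) >= 2 && all(lengths(bycat) >= 2)) {
    z <- atanh(pmin(pmax(rr, -0.9999), 0.9999))
    p_equal <- summary(stats::aov(z ~ factor(pairs$category)))[[1]][
      "factor(pairs$category)", "Pr(>F)"]
  }
  structure(list(summary = summ, p_equal = p_equal,
                 flag = if (!is.na(p_equal) && p_equal < warn_alpha)
                   "warn" else "pass"),
            class = "batch_check")
}

#' @export
print.batch_check <- function(x, ...) {
  cat("batch-effect check [", x$flag, "]\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$p_equal))
    cat(sprintf("  category-equality p = %.3g\n", x$p_equal))
  invisible(x)
}

#' Enrichment of flagged traits among scan hits
#'
#' Hypergeometric test of whether technically suspect traits (e.g.
#' microarray probes overlapping known SNPs) are over-represented among
#' hit traits, computed against a background set and optionally against a
#' restricted background (e.g. the most variable traits only) since
#' eligibility filters already skew the scanned universe.
#'
#' @param hit_traits character vector of hit trait ids.
#' @param flagged_traits flagged subset of the background.
#' @param background all candidate trait ids (non-empty); `hit_traits`
#'   and `flagged_traits` are intersected with it.
#' @param restricted_background optional second background.
#' @return data frame with one row per background: overlap counts and the
#'   hypergeometric enrichment p (upper tail, at least the observed
#'   overlap).
#' @export
flagged_feature_enrichment <- function(hit_traits, flagged_traits,
                                       background,
                                       restricted_background = NULL) {
  if (!length(background)) stop("empty background")
  one <- function(bg, label) {
    hits <- intersect(hit_traits, bg)
    flagged <- intersect(flagged_traits, bg)
    q <- length(intersect(hits, flagged))
    p <- stats::phyper(q - 1, length(flagged),
                       length(bg) - length(flagged), length(hits),
                       lower.tail = FALSE)
    data.frame(background = label, n_background = length(bg),
               n_hits = length(hits), n_flagged = length(flagged),
               overlap = q, enrichment_p = p, stringsAsFactors = FALSE)
  }
  out <- one(background, "full")
  if (!is.null(restricted_background))
    out <- rbind(out, one(restricted_background, "restricted"))
  out
}
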