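#' Scan configuration
#'
#' Bundles every threshold used by the robustness scans.  Defaults follow
#' the mouse liver analysis settings: a trait-variability floor of
#' sigma = 0.15, markers restricted to the most balanced allele splits
#' (minor homozygote in at least `floor(n_strains / 2)` strains, i.e. 9 of
#' 19), median-QTL exclusion at nominal p < 0.01, an ER hit threshold of
#' r^2 >= 0.5 (two-sided p ~ 0.00085 at 19 strains), and a 5 Mb cis window.
#'
#' @param sigma_min trait variability floor (between-strain SD of strain
#'   medians for GR; median within-strain SD for ER).
#' @param min_minor_strains minimum number of strains carrying the minor
#'   homozygote; `NULL` means `floor(n_strains / 2)` at scan time.
#' @param median_qtl_alpha nominal p-value below which a trait/marker pair
#'   with a median (mean-effect) association is excluded from robustness
#'   scanning.
#' @param er_r2_min fraction of within-strain-variability variance the
#'   genotype must explain for an ER hit.
#' @param gr_alpha nominal chi-squared p at which a GR pair is flagged as a
#'   hit (genome-wide significance still comes from permutation).  With two
#'   genotype classes of 9 and 10 strains the FK statistic saturates near
#'   d = 11.8 (nominal p ~ 6e-4), so the default 1e-3 flags only
#'   near-maximal dispersion separations.
#' @param dispersion_metric `"sd"` (default) or `"cv"`
#'   (SD / |mean|, for panels reported as coefficients of variation).
#' @param cv_mean_floor |mean| below which a CV is not computed (guards
#'   against division by values near zero).
#' @param min_replicates minimum replicates per strain/stratum for a
#'   within-strain dispersion to be computed.
#' @param min_class_strains minimum strains per genotype class for a pair
#'   to be testable.
#' @param cis_window bp window for cis classification.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(sigma_min = 0.15,
                        min_minor_strains = NULL,
                        median_qtl_alpha = 0.01,
                        er_r2_min = 0.5,
                        gr_alpha = 1e-3,
                        dispersion_metric = c("sd", "cv"),
                        cv_mean_floor = 0.1,
                        min_replicates = 3L,
                        min_class_strains = 3L,
                        cis_window = 5e6) {
  dispersion_metric <- match.arg(dispersion_metric)
  stopifnot(sigma_min >= 0, median_qtl_alpha > 0, median_qtl_alpha <= 1,
            er_r2_min > 0, er_r2_min <= 1, gr_alpha > 0, gr_alpha <= 1,
            min_replicates >= 2, min_class_strains >= 2, cis_window > 0)
  structure(list(sigma_min = sigma_min,
                 min_minor_strains = min_minor_strains,
                 median_qtl_alpha = median_qtl_alpha,
                 er_r2_min = er_r2_min,
                 gr_alpha = gr_alpha,
                 dispersion_metric = dispersion_metric,
                 cv_mean_floor = cv_mean_floor,
                 min_replicates = as.integer(min_replicates),
                 min_class_strains = as.integer(min_class_strains),
                 cis_window = cis_window),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("scan_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "(auto)" else format(x[[nm]])))
  invisible(x)
}

# subset a phenotype panel's sample rows by a stratum spec like
# c(sex = "M") or list(sex = "M", condition = "LD"); NULL keeps all.
.stratum_rows <- function(panel, stratum) {
  keep <- rep(TRUE, nrow(panel$samples))
  for (nm in names(stratum)) {
    if (!nm %in% names(panel$samples))
      stop(sprintf("stratum column '%s' not present in panel", nm))
    keep <- keep & !is.na(panel$samples[[nm]]) &
      panel$samples[[nm]] == stratum[[nm]]
  }
  keep
}

.stratum_label <- function(stratum) {
  if (is.null(stratum)) "all"
  else paste(unlist(stratum), collapse = "/")
}

#' Per-strain trait summaries
#'
#' Computes, per strain (within an optional stratum such as one sex), the
#' median of each trait across replicate individuals -- the quantity GR
#' mapping works on, since taking medians suppresses micro-environmental
#' noise -- and the within-strain dispersion (SD, or CV) that ER mapping
#' works on.  Dispersions are only computed where at least
#' `min_replicates` non-missing replicates exist.
#'
#' @param panel a `phenotype_panel`.
#' @param stratum optional named list/vector selecting samples, e.g.
#'   `c(sex = "M")`.
#' @param config a [scan_config()].
#' @return object of class `strain_summary`: list with `medians` and
#'   `dispersion` (strains x traits matrices), `n` (replicate counts) and
#'   `strains`.
#' @export
strain_summaries <- function(panel, stratum = NULL, config = scan_config()) {
  stopifnot(inherits(panel, "phenotype_panel"))
  rows <- .stratum_rows(panel, stratum)
  if (!any(rows)) stop("stratum selects no samples")
  X <- panel$traits[rows, , drop = FALSE]
  strain <- panel$samples$strain[rows]
  strains <- sort(unique(strain))
  nt <- ncol(X)
  med <- disp <- nmat <- matrix(NA_real_, length(strains), nt,
                                dimnames = list(strains, colnames(X)))
  for (i in seq_along(strains)) {
    Xi <- X[strain == strains[i], , drop = FALSE]
    n_ok <- colSums(!is.na(Xi))
    nmat[i, ] <- n_ok
    med[i, ] <- apply(Xi, 2, stats::median, na.rm = TRUE)
    s <- apply(Xi, 2, stats::sd, na.rm = TRUE)
    s[n_ok < config$min_replicates] <- NA_real_
    if (config$dispersion_metric == "cv") {
      m <- colMeans(Xi, na.rm = TRUE)
      s <- ifelse(abs(m) < config$cv_mean_floor, NA_real_, s / abs(m))
    }
    disp[i, ] <- s
  }
  med[is.nan(med)] <- NA_real_
  structure(list(strains = strains, medians = med, dispersion = disp,
                 n = nmat, stratum = .stratum_label(stratum)),
            class = "strain_summary")
}

#' Traits eligible for robustness scanning
#'
#' Traits with little variability overall cannot show variability
#' differences between genotype classes, so scans are restricted to traits
#' whose relevant sigma exceeds `config$sigma_min`: the between-strain SD
#' of strain medians for GR mode, the median within-strain SD for ER mode.
#'
#' @param summaries a [strain_summaries()] result.
#' @param config a [scan_config()].
#' @param mode `"GR"` or `"ER"`.
#' @return character vector of eligible trait ids.
#' @export
eligible_traits <- function(summaries, config = scan_config(),
                            mode = c("GR", "ER")) {
  mode <- match.arg(mode)
  sig <- if (mode == "GR")
    apply(summaries$medians, 2, stats::sd, na.rm = TRUE)
  else
    apply(summaries$dispersion, 2, stats::median, na.rm = TRUE)
  colnames(summaries$medians)[!is.na(sig) & sig > config$sigma_min]
}

#' Markers eligible for robustness scanning
#'
#' Power to detect a dispersion difference is maximal when the two genotype
#' classes are balanced, so scans keep markers whose minor homozygote is
#' carried by at least `min_minor_strains` strains (default
#' `floor(n_strains / 2)`, i.e. a 9/10 split in a 19-strain panel).
#'
#' @param panel a `genotype_panel`.
#' @param config a [scan_config()]; `min_minor_strains = NULL` uses the
#'   maximal-balance default.
#' @param strains optional subset of strains to count within.
#' @return character vector of eligible marker ids.
#' @export
eligible_markers <- function(panel, config = scan_config(), strains = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  if (!is.null(strains)) calls <- calls[rownames(calls) %in% strains, ,
                                        drop = FALSE]
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  minor <- pmin(n0, n1)
  floor_n <- config$min_minor_strains
  if (is.null(floor_n)) floor_n <- floor(nrow(calls) / 2)
  colnames(calls)[minor >= floor_n & pmax(n0, n1) >= 1]
}

# two-sided p of a Pearson correlation via the t transform, vectorised
.cor_t_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  r2 <- pmin(r[ok]^2, 1)
  tt <- abs(r[ok]) * sqrt((n[ok] - 2) / pmax(1 - r2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(tt, n[ok] - 2, lower.tail = FALSE)
  p[ok][r2 >= 1] <- 0
  pmin(p, 1)
}

#' Median-QTL exclusion filter
#'
#' Robustness scans must not mistake ordinary mean-effect ("typical") QTL
#' for dispersion effects, so any trait/marker pair whose strain medians
#' associate with genotype at even marginal significance is discarded
#' before dispersion testing.  The association is a Pearson correlation
#' between strain medians and the 0/1 genotype (equivalent to a t-test),
#' with a two-sided p on `n - 2` degrees of freedom; pairs with
#' `p < alpha` are excluded.  Using an uncorrected alpha across millions of
#' pairs is deliberately conservative: it can only exclude more pairs.
#'
#' @param medians numeric vector of per-strain trait medians.
#' @param genotype matching 0/1 genotype vector (NA = untyped/het).
#' @param alpha exclusion threshold (default 0.01).
#' @return list with `keep` (logical), `p`, `r`, `n`, and `flagged`
#'   (`TRUE` when the correlation is undefined, e.g. constant medians --
#'   such pairs are kept, since there is no mean signal).
#' @export
median_qtl_filter <- function(medians, genotype, alpha = 0.01) {
  ok <- !is.na(medians) & !is.na(genotype)
  m <- medians[ok]; g <- genotype[ok]
  if (length(m) < 3 || stats::sd(m) == 0 || stats::sd(g) == 0)
    return(list(keep = TRUE, p = NA_real_, r = NA_real_,
                n = length(m), flagged = TRUE))
  r <- stats::cor(m, g)
  p <- .cor_t_p(r, length(m))
  list(keep = p >= alpha, p = p, r = r, n = length(m), flagged = FALSE)
}

# map lookup helper: returns chrom/pos for ids (NA when unmapped)
.map_lookup <- function(ids, map) {
  if (is.null(map))
    return(data.frame(chrom = rep(NA_character_, length(ids)),
                      pos = rep(NA_real_, length(ids))))
  i <- match(ids, map$id)
  data.frame(chrom = map$chrom[i], pos = map$pos[i],
             stringsAsFactors = FALSE)
}

# align genotype calls to the summary's strain set
.aligned_calls <- function(gpanel, strains) {
  common <- intersect(strains, rownames(gpanel$calls))
  if (length(common) < 4)
    stop("fewer than 4 strains shared between phenotype and genotype panels")
  gpanel$calls[common, , drop = FALSE]
}

#' Genetic-robustness (GR) genome scan
#'
#' For every eligible trait and marker, groups the per-strain trait medians
#' by marker genotype class and tests for a difference in their dispersion
#' with the median-variant Fligner-Killeen test ([fk_test()]).  A
#' difference in the spread of strain medians between genotype classes --
#' with no difference in the medians themselves, which the median-QTL
#' filter guarantees -- is the signature of a polymorphic buffer of genetic
#' background variation.
#'
#' @param pheno a `phenotype_panel`.
#' @param geno a `genotype_panel` (strain-level calls).
#' @param config a [scan_config()].
#' @param stratum optional stratum spec (e.g. `c(sex = "M")`); strata are
#'   scanned separately by default, pass `NULL` for a pooled scan.
#' @param markers optional `genome_map` for marker coordinates.
#' @param summaries optional precomputed [strain_summaries()] (skips
#'   recomputation, e.g. inside permutation loops).
#' @return a `robust_hits` table of all tested pairs with columns
#'   `statistic` (the FK d), `nominal_p` and logical `hit`
#'   (`nominal_p <= config$gr_alpha`).  Attribute `"counts"` records
#'   eligibility and exclusion tallies.
#' @export
gr_scan <- function(pheno, geno, config = scan_config(), stratum = NULL,
                    markers = NULL, summaries = NULL) {
  if (is.null(summaries)) summaries <- strain_summaries(pheno, stratum, config)
  calls <- .aligned_calls(geno, summaries$strains)
  med <- summaries$medians[rownames(calls), , drop = FALSE]
  traits <- eligible_traits(summaries, config, "GR")
  mk <- eligible_markers(geno, config, rownames(calls))
  counts <- c(eligible_traits = length(traits), eligible_markers = length(mk),
              excluded_median_qtl = 0L, skipped_small_class = 0L)
  rows <- vector("list", length(mk))
  for (j in seq_along(mk)) {
    g <- calls[, mk[j]]
    res <- .gr_pairs(med[, traits, drop = FALSE], g, config)
    counts["excluded_median_qtl"] <- counts["excluded_median_qtl"] +
      res$n_excluded
    counts["skipped_small_class"] <- counts["skipped_small_class"] +
      res$n_skipped
    if (length(res$trait))
      rows[[j]] <- data.frame(trait_id = res$trait, marker_id = mk[j],
                              statistic = res$d, nominal_p = res$p,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(trait_id = character(), marker_id = character(),
                      statistic = numeric(), nominal_p = numeric())
  loc <- .map_lookup(out$marker_id, markers)
  hits <- robust_hits(data.frame(scan_type = rep("GR", nrow(out)),
                                 stratum = rep(summaries$stratum, nrow(out)),
                                 out["trait_id"], out["marker_id"],
                                 loc, out["statistic"], out["nominal_p"],
                                 hit = out$nominal_p <= config$gr_alpha,
                                 stringsAsFactors = FALSE))
  attr(hits, "counts") <- counts
  hits
}

# per-marker GR worker: median filter then FK on the two genotype groups
.gr_pairs <- function(med, g, config) {
  ok_g <- !is.na(g)
  trait_ids <- colnames(med)
  d <- p <- numeric(0); keep_ids <- character(0)
  n_excl <- 0L; n_skip <- 0L
  for (tid in trait_ids) {
    m <- med[, tid]
    ok <- ok_g & !is.na(m)
    g0 <- m[ok & g == 0L & !is.na(g)]
    g1 <- m[ok & g == 1L & !is.na(g)]
    if (length(g0) < config$min_class_strains ||
        length(g1) < config$min_class_strains) {
      n_skip <- n_skip + 1L
      next
    }
    mf <- median_qtl_filter(m[ok], g[ok], config$median_qtl_alpha)
    if (!mf$keep) {
      n_excl <- n_excl + 1L
      next
    }
    fk <- .fk_d2(g0, g1)
    keep_ids <- c(keep_ids, tid)
    d <- c(d, fk[["d"]]); p <- c(p, fk[["p"]])
  }
  list(trait = keep_ids, d = d, p = p, n_excluded = n_excl,
       n_skipped = n_skip)
}

# shared ER machinery: correlate a dispersion matrix with genotype calls.
# disp, med: strains x traits; calls: strains x markers (same row order).
.er_core <- function(disp, med, calls, config, scan_type, stratum_label,
                     markers_map) {
  mk <- colnames(calls)
  counts <- c(excluded_median_qtl = 0L, skipped_small_class = 0L,
              skipped_constant_dispersion = 0L)
  rows <- vector("list", length(mk))
  for (j in seq_along(mk)) {
    g <- calls[, j]
    ok_g <- !is.na(g)
    S <- disp[ok_g, , drop = FALSE]
    M <- med[ok_g, , drop = FALSE]
    gg <- g[ok_g]
    ok_S <- !is.na(S)
    n0 <- colSums(ok_S & gg == 0L)
    n1 <- colSums(ok_S & gg == 1L)
    testable <- n0 >= config$min_class_strains & n1 >= config$min_class_strains
    counts["skipped_small_class"] <- counts["skipped_small_class"] +
      sum(!testable)
    if (!any(testable)) next
    suppressWarnings({
      r_med <- as.vector(stats::cor(M, gg, use = "pairwise.complete.obs"))
      r_disp <- as.vector(stats::cor(S, gg, use = "pairwise.complete.obs"))
    })
    n_med <- colSums(!is.na(M))
    p_med <- .cor_t_p(r_med, n_med)
    # constant medians: no mean signal, keep (flagged); median QTL: drop
    excl <- testable & !is.na(p_med) & p_med < config$median_qtl_alpha
    counts["excluded_median_qtl"] <- counts["excluded_median_qtl"] + sum(excl)
    const_disp <- testable & !excl & is.na(r_disp)
    counts["skipped_constant_dispersion"] <-
      counts["skipped_constant_dispersion"] + sum(const_disp)
    use <- testable & !excl & !is.na(r_disp)
    if (!any(use)) next
    n_pair <- n0 + n1
    p_disp <- .cor_t_p(r_disp, n_pair)
    rows[[j]] <- data.frame(trait_id = colnames(disp)[use],
                            marker_id = mk[j],
                            statistic = r_disp[use],
                            nominal_p = p_disp[use],
                            hit = r_disp[use]^2 >= config$er_r2_min,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(trait_id = character(), marker_id = character(),
                      statistic = numeric(), nominal_p = numeric(),
                      hit = logical())
  loc <- .map_lookup(out$marker_id, markers_map)
  hits <- robust_hits(data.frame(scan_type = rep(scan_type, nrow(out)),
                                 stratum = rep(stratum_label, nrow(out)),
                                 out["trait_id"], out["marker_id"], loc,
                                 out["statistic"], out["nominal_p"],
                                 hit = out$hit, stringsAsFactors = FALSE))
  attr(hits, "counts") <- counts
  hits
}

#' Environmental-robustness (ER) genome scan
#'
#' Correlates per-strain within-strain dispersions (SD by default) with the
#' 0/1 marker genotype -- a Pearson correlation, equivalent in this
#' two-class setting to a t-test.  A pair is a hit when the genotype
#' explains at least `config$er_r2_min` of the variation in within-strain
#' variability (r^2 >= 0.5 corresponds to a two-sided nominal p of about
#' 0.00085 at 19 strains).  Mean-effect QTL are excluded beforehand by the
#' median filter, exactly as in [gr_scan()].
#'
#' @inheritParams gr_scan
#' @return a `robust_hits` table (statistic = r, two-sided `nominal_p`,
#'   logical `hit` at the r^2 threshold) with a `"counts"` attribute.
#' @export
er_scan <- function(pheno, geno, config = scan_config(), stratum = NULL,
                    markers = NULL, summaries = NULL) {
  if (is.null(summaries)) summaries <- strain_summaries(pheno, stratum, config)
  calls <- .aligned_calls(geno, summaries$strains)
  traits <- eligible_traits(summaries, config, "ER")
  mk <- eligible_markers(geno, config, rownames(calls))
  hits <- .er_core(summaries$dispersion[rownames(calls), traits, drop = FALSE],
                   summaries$medians[rownames(calls), traits, drop = FALSE],
                   calls[, mk, drop = FALSE], config, "ER",
                   summaries$stratum, markers)
  attr(hits, "counts") <- c(eligible_traits = length(traits),
                            eligible_markers = length(mk),
                            attr(hits, "counts"))
  hits
}

#' Macro-environmental robustness scan
#'
#' Whereas [er_scan()] measures sensitivity to micro-environmental
#' fluctuation within one condition, this scan measures sensitivity to
#' defined condition changes: for each strain the trait median is taken
#' within each experimental condition (removing micro-environmental noise),
#' and the dispersion input is the SD of those condition medians.  With k
#' conditions each macro dispersion rests on only k data points, so
#' estimates are noisy but independent of micro-environmental variation.
#' Strains missing any condition are dropped for that trait.
#'
#' @inheritParams gr_scan
#' @return a `robust_hits` table with `scan_type = "MACRO_ER"`.
#' @export
macro_er_scan <- function(pheno, geno, config = scan_config(),
                          markers = NULL) {
  stopifnot(inherits(pheno, "phenotype_panel"))
  if (!"condition" %in% names(pheno$samples))
    stop("macro-ER scan needs a 'condition' column")
  conds <- sort(unique(stats::na.omit(pheno$samples$condition)))
  if (length(conds) < 2) stop("macro-ER scan needs >= 2 conditions")
  per_cond <- lapply(conds, function(cc)
    strain_summaries(pheno, list(condition = cc), config)$medians)
  strains <- sort(Reduce(union, lapply(per_cond, rownames)))
  traits <- colnames(per_cond[[1]])
  # strains x traits stack of condition medians -> SD across conditions
  disp <- med <- matrix(NA_real_, length(strains), length(traits),
                        dimnames = list(strains, traits))
  for (i in seq_along(strains)) {
    cm <- vapply(per_cond, function(m)
      if (strains[i] %in% rownames(m)) m[strains[i], ] else
        rep(NA_real_, length(traits)), numeric(length(traits)))
    cm <- matrix(cm, nrow = length(traits))
    complete <- rowSums(is.na(cm)) == 0
    disp[i, complete] <- apply(cm[complete, , drop = FALSE], 1, stats::sd)
    med[i, ] <- apply(cm, 1, stats::median, na.rm = TRUE)
  }
  med[is.nan(med)] <- NA_real_
  # trait eligibility on the macro dispersions themselves
  sig <- apply(disp, 2, stats::median, na.rm = TRUE)
  keep_tr <- !is.na(sig) & sig > config$sigma_min
  calls <- .aligned_calls(geno, strains)
  mk <- eligible_markers(geno, config, rownames(calls))
  hits <- .er_core(disp[rownames(calls), keep_tr, drop = FALSE],
                   med[rownames(calls), keep_tr, drop = FALSE],
                   calls[, mk, drop = FALSE], config, "MACRO_ER", "all",
                   markers)
  attr(hits, "counts") <- c(eligible_traits = sum(keep_tr),
                            eligible_markers = length(mk),
                            attr(hits, "counts"))
  hits
}

#' Significant hits of a scan
#'
#' @param hits a `robust_hits` table from [gr_scan()], [er_scan()] or
#'   [macro_er_scan()].
#' @return the subset of rows flagged as hits.
#' @export
significant_hits <- function(hits) {
  stopifnot(inherits(hits, "robust_hits"))
  if (!nrow(hits)) return(hits)
  out <- hits[!is.na(hits$hit) & hits$hit, ]
  class(out) <- class(hits)
  out
}

#' Collapse redundant markers in a hit count
#'
#' Markers with identical genotype vectors carry the same information; for
#' reporting, hits on such markers are counted once ("non-redundant"
#' markers), while all markers remain listed in the table.
#'
#' @param hits a `robust_hits` table.
#' @param geno the `genotype_panel` scanned.
#' @return integer: number of distinct genotype signatures among hit
#'   markers, per trait (named vector).
#' @export
nonredundant_marker_counts <- function(hits, geno) {
  sig <- .marker_signature(geno)
  h <- significant_hits(hits)
  if (!nrow(h)) return(stats::setNames(integer(0), character(0)))
  vapply(split(h$marker_id, h$trait_id),
         function(m) length(unique(sig[m])), integer(1))
}

#' Plot a robustness scan
#'
#' Simple genome-order plot of -log10 nominal p per tested pair, one point
#' per pair, hit pairs emphasised.  Needs marker coordinates in the table
#' (scan run with a `markers` map).
#'
#' @param x a `robust_hits` table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.robust_hits <- function(x, ...) {
  if (!nrow(x)) {
    graphics::plot.new()
    return(invisible(x))
  }
  if (all(is.na(x$pos)))
    stop("no marker coordinates in hit table; rerun scan with a marker map")
  ord <- order(x$chrom, x$pos)
  h <- x[ord, ]
  idx <- seq_len(nrow(h))
  graphics::plot(idx, -log10(pmax(h$nominal_p, 1e-300)),
                 col = ifelse(!is.na(h$hit) & h$hit, "red", "grey40"),
                 pch = 20, xlab = "marker order (genome)",
                 ylab = expression(-log[10](p)), ...)
  invisible(x)
}
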