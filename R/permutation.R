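#' @title Permutation-based significance, FDR and power
#' @name permutation_engine
#' @description Strain-label permutation machinery: empirical significance
#'   of scan-wide hit counts, permutation FDR, bootstrap confidence
#'   intervals on nominal p-values, the random-partition sex-specificity
#'   test, split-half power estimation, and expected-overlap arithmetic.
NULL

# evaluate code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(code)
}

# deterministic child seed below 2^31, derived from a parent seed + index
.child_seed <- function(seed, index) {
  (as.double(seed) * 69069 + index * 104729) %% 2147483647
}

#' Permute strain labels of a genotype panel
#'
#' Draws a single strain-to-strain bijection and re-pairs genotypes with
#' phenotypes accordingly: strain X's phenotypes become paired with strain
#' Y's genotypes.  Because one bijection is applied to the whole panel, all
#' correlation structure between markers (and, on the phenotype side,
#' between traits) is preserved -- only the genotype/phenotype pairing is
#' broken.  Reusing the returned panel across strata (e.g. scanning males
#' and females against the same permuted panel) is exactly the joint
#' permutation needed when combining per-stratum results, since the strata
#' share their genotypes.
#'
#' @param geno a `genotype_panel`.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return a `genotype_panel` whose rows are re-assigned; the bijection is
#'   stored in attribute `"bijection"` (named character vector, names =
#'   phenotype strain, values = donor genotype strain).
#' @export
permute_strain_labels <- function(geno, seed = NULL) {
  stopifnot(inherits(geno, "genotype_panel"))
  strains <- rownames(geno$calls)
  perm <- .with_seed(seed, sample(strains))
  calls <- geno$calls[perm, , drop = FALSE]
  het <- geno$het[perm, , drop = FALSE]
  rownames(calls) <- rownames(het) <- strains
  out <- genotype_panel(calls, het)
  attr(out, "bijection") <- stats::setNames(perm, strains)
  out
}

#' Empirical scan-wide p-value and permutation FDR
#'
#' Compares the observed number of scan hits to the hit counts obtained on
#' permuted data.  The empirical p uses the add-one estimator
#' `(# permuted >= observed + 1) / (B + 1)` (never exactly zero); the
#' false-discovery rate is estimated as `mean(permuted) / observed`,
#' capped at 1, and is undefined (NA) when no hits were observed.
#'
#' @param observed observed hit count.
#' @param permuted integer vector of per-permutation hit counts.
#' @return list with `empirical_p`, `fdr`, `observed`, `B`.
#' @export
empirical_scan_p <- function(observed, permuted) {
  stopifnot(observed >= 0, length(permuted) >= 1)
  B <- length(permuted)
  p <- (sum(permuted >= observed) + 1) / (B + 1)
  fdr <- if (observed > 0) min(1, mean(permuted) / observed) else NA_real_
  list(empirical_p = p, fdr = fdr, observed = observed, B = B)
}

#' Permutation test of a robustness scan
#'
#' Runs a scan on the observed strain pairing and on `B` strain-label
#' permutations, per stratum, and summarises hit counts with
#' [empirical_scan_p()].  With several strata (e.g. male and female) the
#' SAME bijection is applied to every stratum within each permutation, and
#' the count of pairs hit in every stratum (`overlap`) is tracked as well:
#' separate per-stratum permutations would overstate the significance of
#' an intersected hit list, because strata share their genotypes.
#'
#' @param pheno a `phenotype_panel`.
#' @param geno a `genotype_panel`.
#' @param mode `"gr"` or `"er"`.
#' @param strata list of stratum specs (e.g.
#'   `list(c(sex = "M"), c(sex = "F"))`); `list(NULL)` for a pooled scan.
#' @param config a [scan_config()].
#' @param B number of permutations.
#' @param seed integer seed; permutation b uses a child seed derived from
#'   it, so runs are reproducible and extendable.
#' @param markers optional marker `genome_map`.
#' @return object of class `scan_permutation`: per-stratum observed
#'   counts, B x strata matrix of permuted counts, empirical p and FDR per
#'   stratum (and for the overlap when several strata are given).
#' @export
scan_permutation <- function(pheno, geno, mode = c("gr", "er"),
                             strata = list(NULL), config = scan_config(),
                             B = 1000L, seed = 1L, markers = NULL) {
  mode <- match.arg(mode)
  scan_fun <- if (mode == "gr") gr_scan else er_scan
  stopifnot(B >= 1)
  # precompute per-stratum summaries once; permutation only moves genotypes
  summaries <- lapply(strata, function(s)
    strain_summaries(pheno, s, config))
  labels <- vapply(summaries, function(s) s$stratum, character(1))
  hit_keys <- function(g) lapply(summaries, function(ss) {
    h <- significant_hits(scan_fun(pheno, g, config, summaries = ss,
                                   markers = markers))
    paste(h$trait_id, h$marker_id)
  })
  obs_keys <- hit_keys(geno)
  observed <- lengths(obs_keys)
  perm_counts <- matrix(0L, B, length(strata),
                        dimnames = list(NULL, labels))
  perm_overlap <- integer(B)
  for (b in seq_len(B)) {
    gp <- permute_strain_labels(geno, .child_seed(seed, b))
    keys <- hit_keys(gp)
    perm_counts[b, ] <- lengths(keys)
    if (length(strata) > 1)
      perm_overlap[b] <- length(Reduce(intersect, keys))
  }
  res <- lapply(seq_along(strata), function(i)
    empirical_scan_p(observed[i], perm_counts[, i]))
  names(res) <- labels
  out <- list(mode = mode, strata = labels, observed = observed,
              permuted = perm_counts, per_stratum = res, B = B, seed = seed,
              joint = length(strata) > 1)
  if (length(strata) > 1) {
    obs_ov <- length(Reduce(intersect, obs_keys))
    out$overlap <- empirical_scan_p(obs_ov, perm_overlap)
    out$permuted_overlap <- perm_overlap
  }
  class(out) <- "scan_permutation"
  out
}

#' @export
print.scan_permutation <- function(x, ...) {
  cat(sprintf("scan_permutation (%s scan, B = %d)\n", toupper(x$mode), x$B))
  for (nm in names(x$per_stratum)) {
    r <- x$per_stratum[[nm]]
    cat(sprintf("  stratum %-10s observed %5d  empirical p = %.4g  FDR = %s\n",
                nm, r$observed, r$empirical_p,
                if (is.na(r$fdr)) "NA" else sprintf("%.1f%%", 100 * r$fdr)))
  }
  if (!is.null(x$overlap))
    cat(sprintf("  overlap            observed %5d  empirical p = %.4g\n",
                x$overlap$observed, x$overlap$empirical_p))
  invisible(x)
}

#' Bootstrap confidence interval for a nominal p-value
#'
#' Resamples the data points of each group with replacement, re-evaluates
#' the test statistic's nominal p on every bootstrap data set and returns a
#' percentile confidence interval.  Degenerate resamples (any group drawn
#' constant, where the statistic is undefined) are redrawn and counted.
#'
#' @param groups list of numeric vectors (e.g. the replicate values of one
#'   trait/environment combination per group).
#' @param stat_fn function taking a list of groups, returning a nominal p.
#' @param n_boot number of bootstrap replicates (>= 1000 for reported
#'   intervals; the default enforces this).
#' @param level confidence level, 0.95 or 0.99.
#' @param seed optional seed.
#' @return list with `ci` (named lower/upper), `level`, `p_boot` (all
#'   bootstrap p-values), `n_degenerate_redrawn`.
#' @export
bootstrap_pvalue_ci <- function(groups, stat_fn, n_boot = 1000L,
                                level = 0.95, seed = NULL) {
  stopifnot(is.list(groups), n_boot >= 1, level %in% c(0.95, 0.99))
  .with_seed(seed, {
    p_boot <- numeric(n_boot)
    n_degen <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        res <- lapply(groups, function(v) sample(v, replace = TRUE))
        if (all(vapply(res, function(v) length(unique(v)) > 1, logical(1))))
          break
        n_degen <- n_degen + 1L
        if (n_degen > 100L * n_boot)
          stop("too many degenerate bootstrap resamples")
      }
      p_boot[b] <- stat_fn(res)
    }
    alpha <- 1 - level
    ci <- stats::quantile(p_boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    list(ci = c(lower = ci[1], upper = ci[2]), level = level,
         p_boot = p_boot, n_degenerate_redrawn = n_degen)
  })
}

# split sample indices into two halves of given sizes, optionally
# balancing strains across the halves as evenly as possible
.split_halves <- function(strain, sizes = NULL, balance = FALSE) {
  n <- length(strain)
  if (is.null(sizes)) sizes <- c(floor(n / 2), ceiling(n / 2))
  stopifnot(sum(sizes) == n)
  if (!balance) {
    idx <- sample(n)
    return(list(idx[seq_len(sizes[1])], idx[(sizes[1] + 1):n]))
  }
  h1 <- integer(0)
  for (s in unique(strain)) {
    i <- sample(which(strain == s))
    h1 <- c(h1, i[seq_len(floor(length(i) / 2))])
    # odd strains: assign the leftover alternately via global rebalance below
  }
  rest <- setdiff(sample(n), h1)
  need <- sizes[1] - length(h1)
  if (need > 0) h1 <- c(h1, rest[seq_len(need)])
  if (need < 0) h1 <- h1[seq_len(sizes[1])]
  list(sort(h1), sort(setdiff(seq_len(n), h1)))
}

.subset_panel <- function(panel, rows) {
  phenotype_panel(panel$samples[rows, , drop = FALSE],
                  panel$traits[rows, , drop = FALSE])
}

#' Random-partition test of sex specificity
#'
#' If a class of robustness QTL is not sex-specific, splitting the panel
#' into random halves irrespective of sex should yield about as many hits
#' per half as the true male/female split does.  This test repeatedly
#' partitions the samples into random halves of the same sizes as the sex
#' split, scans each half, and compares the true-split hit counts to the
#' random-split distribution via a z-score.
#'
#' @inheritParams scan_permutation
#' @param n_partitions number of random partitions (>= 2).
#' @return object of class `partition_test`: random-split mean and SD of
#'   per-half hit counts, the per-sex observed counts, and z-scores.
#' @export
sex_specificity_partition <- function(pheno, geno, mode = c("gr", "er"),
                                      config = scan_config(),
                                      n_partitions = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (n_partitions < 2) stop("n_partitions must be >= 2")
  scan_fun <- if (mode == "gr") gr_scan else er_scan
  sex <- pheno$samples$sex
  if (all(is.na(sex))) stop("panel has no sex labels")
  sizes <- c(sum(sex == "F", na.rm = TRUE), sum(sex == "M", na.rm = TRUE))
  count_hits <- function(p) nrow(significant_hits(
    scan_fun(p, geno, config, stratum = NULL)))
  true_counts <- c(F = count_hits(.subset_panel(pheno, which(sex == "F"))),
                   M = count_hits(.subset_panel(pheno, which(sex == "M"))))
  rand <- .with_seed(seed, {
    out <- numeric(2L * n_partitions)
    for (r in seq_len(n_partitions)) {
      halves <- .split_halves(pheno$samples$strain, sizes)
      out[2 * r - 1] <- count_hits(.subset_panel(pheno, halves[[1]]))
      out[2 * r] <- count_hits(.subset_panel(pheno, halves[[2]]))
    }
    out
  })
  mu <- mean(rand); sdev <- stats::sd(rand)
  structure(list(mode = mode, random_counts = rand, random_mean = mu,
                 random_sd = sdev, true_counts = true_counts,
                 z = (true_counts - mu) / sdev,
                 n_partitions = n_partitions, seed = seed),
            class = "partition_test")
}

#' @export
print.partition_test <- function(x, ...) {
  cat(sprintf("random-partition test (%s scan, %d partitions)\n",
              toupper(x$mode), x$n_partitions))
  cat(sprintf("  random halves: mean %.1f hits (sd %.1f)\n",
              x$random_mean, x$random_sd))
  for (nm in names(x$true_counts))
    cat(sprintf("  sex %s: %d hits (z = %.2f)\n", nm, x$true_counts[[nm]],
                x$z[[nm]]))
  invisible(x)
}

#' Split-half power estimation
#'
#' Estimates the power of a robustness scan from internal replication:
#' samples are repeatedly split into two strain-balanced halves, each half
#' is scanned, and the overlap between the two hit lists is decomposed into
#' true-positive and false-positive overlap.  Genotype randomizations of
#' both halves (with a shared bijection, since the halves share genotypes)
#' estimate each half's false-discovery rate and the frequency of overlaps
#' among false positives; power is then
#' `(observed overlaps - expected FP overlaps) / (total true positives)`,
#' averaged over repeats, where total true positives is the mean of the two
#' halves' estimated true-positive counts.
#'
#' @inheritParams scan_permutation
#' @param n_repeats number of half-splits.
#' @param n_randomizations genotype randomizations per repeat (>= 100 for
#'   reported figures).
#' @return object of class `power_estimate` with `power` (mean over
#'   repeats), per-repeat estimates, mean FDRs and FP-overlap rate.
#' @export
power_by_split <- function(pheno, geno, mode = c("er", "gr"),
                           config = scan_config(), n_repeats = 10L,
                           n_randomizations = 100L, seed = 1L) {
  mode <- match.arg(mode)
  scan_fun <- if (mode == "gr") gr_scan else er_scan
  # summaries depend only on phenotypes, so they are computed once per half
  # and reused across all genotype randomizations
  keys <- function(ss, g) {
    h <- significant_hits(scan_fun(NULL, g, config, summaries = ss))
    paste(h$trait_id, h$marker_id)
  }
  per_rep <- data.frame(power = numeric(0), fdr1 = numeric(0),
                        fdr2 = numeric(0), fp_overlap_rate = numeric(0))
  skipped <- 0L
  for (r in seq_len(n_repeats)) {
    halves <- .with_seed(.child_seed(seed, r),
                         .split_halves(pheno$samples$strain, balance = TRUE))
    ss1 <- strain_summaries(.subset_panel(pheno, halves[[1]]), NULL, config)
    ss2 <- strain_summaries(.subset_panel(pheno, halves[[2]]), NULL, config)
    k1 <- keys(ss1, geno); k2 <- keys(ss2, geno)
    obs_overlap <- length(intersect(k1, k2))
    rand_n1 <- rand_n2 <- rand_ov <- numeric(n_randomizations)
    for (b in seq_len(n_randomizations)) {
      gp <- permute_strain_labels(geno, .child_seed(seed, r * 100000 + b))
      rk1 <- keys(ss1, gp); rk2 <- keys(ss2, gp)
      rand_n1[b] <- length(rk1); rand_n2[b] <- length(rk2)
      rand_ov[b] <- length(intersect(rk1, rk2))
    }
    fp1 <- mean(rand_n1); fp2 <- mean(rand_n2)
    tp1 <- length(k1) - fp1; tp2 <- length(k2) - fp2
    tp_total <- mean(c(tp1, tp2))
    if (!is.finite(tp_total) || tp_total <= 0) {
      skipped <- skipped + 1L
      next
    }
    exp_fp_overlap <- mean(rand_ov)
    pw <- (obs_overlap - exp_fp_overlap) / tp_total
    per_rep <- rbind(per_rep, data.frame(
      power = pw,
      fdr1 = if (length(k1)) min(1, fp1 / length(k1)) else NA_real_,
      fdr2 = if (length(k2)) min(1, fp2 / length(k2)) else NA_real_,
      fp_overlap_rate = if (mean(c(fp1, fp2)) > 0)
        exp_fp_overlap / mean(c(fp1, fp2)) else NA_real_))
  }
  power <- if (nrow(per_rep)) mean(pmin(pmax(per_rep$power, 0), 1))
           else NA_real_
  structure(list(mode = mode, power = power, per_repeat = per_rep,
                 n_repeats = n_repeats, skipped = skipped,
                 n_randomizations = n_randomizations, seed = seed),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("split-half power estimate (%s scan): %s\n",
              toupper(x$mode),
              if (is.na(x$power)) "NA (no true positives)" else
                sprintf("%.1f%%", 100 * x$power)))
  cat(sprintf("  %d repeats (%d skipped), %d randomizations each\n",
              x$n_repeats, x$skipped, x$n_randomizations))
  invisible(x)
}

#' Expected overlap between two hit lists
#'
#' Expected number of overlapping hits between two lists given the size of
#' one list, its true-positive fraction, the power to re-detect a true
#' positive, and the rate at which false positives overlap:
#' `n_pairs * (tp_frac * power + (1 - tp_frac) * fp_overlap)`.
#'
#' @param n_pairs number of significant trait/marker pairs in the list.
#' @param tp_frac fraction of true positives (1 - FDR).
#' @param power probability a true positive is re-detected.
#' @param fp_overlap overlap rate among false positives.
#' @return expected overlap count.
#' @export
expected_overlap <- function(n_pairs, tp_frac, power, fp_overlap) {
  stopifnot(n_pairs >= 0, tp_frac >= 0, tp_frac <= 1,
            power >= 0, power <= 1, fp_overlap >= 0, fp_overlap <= 1)
  n_pairs * (tp_frac * power + (1 - tp_frac) * fp_overlap)
}

#' Expected cross-scan overlap
#'
#' Conservative companion form for overlap between two different scan
#' types (e.g. how many GR transcripts should also appear as ER hits if
#' the two classes of QTL co-localized): `n * tp_frac * power`, assuming
#' no overlap among false positives.
#'
#' @param n number of transcripts in the source list.
#' @param tp_frac its true-positive fraction.
#' @param power the target scan's power.
#' @return expected overlap count.
#' @export
expected_cross_overlap <- function(n, tp_frac, power) {
  stopifnot(n >= 0, tp_frac >= 0, tp_frac <= 1, power >= 0, power <= 1)
  n * tp_frac * power
}

#' Probability of observing zero overlaps
#'
#' Under a Poisson model for the overlap count with the given expectation,
#' the chance of seeing none is `exp(-mean)`.
#'
#' @param mean expected overlap count (>= 0).
#' @return probability of zero overlaps.
#' @examples
#' poisson_zero_prob(14)  # < 1e-6
#' @export
poisson_zero_prob <- function(mean) {
  if (any(mean < 0)) stop("mean must be non-negative")
  exp(-mean)
}
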