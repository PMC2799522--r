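#' @title Replication of ER-QTL predictions in an independent panel
#' @name replication_stats
#' @description An ER QTL whose genotype differs between two strains
#'   predicts which strain should show the larger within-strain variance
#'   for the affected trait.  These tools test such predictions in an
#'   independent two-strain panel: per-gene variance-ratio F-tests,
#'   the critical ratio for a given sample size, expected chance
#'   agreement counts, baseline correction for global variability
#'   differences between the strains, and a comparison of the two
#'   predicted sets' ratio distributions.
NULL

#' Variance-ratio F-test
#'
#' Tests whether one group's variance exceeds another's.  `F = var_hi /
#' var_lo` on `(n1 - 1, n2 - 1)` degrees of freedom; the upper-tail
#' probability is the one-sided p (used for per-gene calls in the
#' predicted direction), doubled and capped at 1 for a two-sided test.
#'
#' @param var_hi variance of the group predicted (or observed) to be more
#'   variable; `n1` its sample size.
#' @param var_lo the other group's variance; `n2` its sample size.
#' @param n1,n2 sample sizes (>= 2).
#' @param sided `"one"` or `"two"`.
#' @return p-value.  A zero `var_lo` with positive `var_hi` gives p = 0
#'   with a `degenerate` attribute set.
#' @examples
#' variance_ratio_ftest(5.8, 1, 7, 7, "two")   # ~ 0.05
#' variance_ratio_ftest(194, 1, 7, 7, "one")   # ~ 1.3e-6
#' @export
variance_ratio_ftest <- function(var_hi, var_lo, n1, n2,
                                 sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(var_hi >= 0, var_lo >= 0, n1 >= 2, n2 >= 2)
  if (var_lo == 0) {
    p <- if (var_hi == 0) 1 else 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  p <- stats::pf(var_hi / var_lo, n1 - 1, n2 - 1, lower.tail = FALSE)
  if (sided == "two") p <- min(1, 2 * min(p, 1 - p))
  p
}

#' Critical variance ratio for a given significance level
#'
#' The smallest variance ratio that reaches significance `alpha` by the
#' F-test at the given sample sizes -- e.g. with seven samples per strain
#' a ratio of about 5.8 is needed for two-sided p = 0.05.
#'
#' @param n1,n2 sample sizes.
#' @param alpha significance level in (0, 1].
#' @param sided `"one"` or `"two"`.
#' @return the critical ratio (the appropriate upper F quantile).
#' @examples
#' critical_variance_ratio(7, 7, 0.05, "two")  # ~ 5.8
#' @export
critical_variance_ratio <- function(n1, n2, alpha = 0.05,
                                    sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha <= 1, n1 >= 2, n2 >= 2)
  tail <- if (sided == "two") alpha / 2 else alpha
  stats::qf(tail, n1 - 1, n2 - 1, lower.tail = FALSE)
}

#' Expected chance confirmations
#'
#' With two-sided threshold `alpha`, a gene with no true strain difference
#' lands in either significance direction with probability `alpha / 2`;
#' among `n_genes` tested one therefore expects `n_genes * alpha / 2`
#' chance agreements with the predicted direction, and as many chance
#' disagreements.
#'
#' @param n_genes number of genes tested.
#' @param alpha two-sided significance threshold.
#' @return expected count per direction.
#' @examples
#' expected_chance_confirmations(83, 0.05)  # ~ 2.1
#' @export
expected_chance_confirmations <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 0, alpha > 0, alpha <= 1)
  n_genes * alpha / 2
}

#' Exact binomial p for an excess of confirmations
#'
#' Upper-tail binomial probability of observing at least `observed`
#' significant agreements among `n_genes` genes when each agrees by
#' chance with probability `alpha / 2`.
#'
#' @param observed observed number of significant agreements.
#' @param n_genes genes tested.
#' @param alpha two-sided per-gene threshold.
#' @return binomial tail probability.
#' @export
confirmation_excess_p <- function(observed, n_genes, alpha = 0.05) {
  stopifnot(observed >= 0, observed <= n_genes)
  stats::pbinom(observed - 1, n_genes, alpha / 2, lower.tail = FALSE)
}

#' Baseline-corrected log2 variance ratios
#'
#' One strain may simply be globally more variable than the other, which
#' would skew raw confirmation calls.  Genes NOT predicted to differ
#' between the strains provide a baseline: their mean log2 variance ratio
#' is subtracted from every predicted gene's ratio, and a prediction is
#' confirmed when the adjusted ratio has the predicted sign.  A global
#' rescaling of one strain's variances shifts predicted and background
#' ratios equally and so cancels.
#'
#' @param predicted_log2_ratios named numeric vector of log2 variance
#'   ratios (strainA : strainB) for the predicted genes.
#' @param background_log2_ratios log2 ratios of the background (unpredicted)
#'   gene set; must be non-empty.
#' @param predicted_sign numeric vector of +1/-1: the sign the adjusted
#'   ratio should have if the prediction holds.
#' @return data frame with `gene`, `log2_ratio`, `adjusted`, `agree`.
#' @export
baseline_adjusted_ratios <- function(predicted_log2_ratios,
                                     background_log2_ratios,
                                     predicted_sign) {
  if (!length(background_log2_ratios))
    stop("background gene set is empty")
  stopifnot(all(predicted_sign %in% c(-1, 1)),
            length(predicted_sign) == length(predicted_log2_ratios))
  base <- mean(background_log2_ratios, na.rm = TRUE)
  adj <- predicted_log2_ratios - base
  data.frame(
    gene = if (is.null(names(predicted_log2_ratios)))
      as.character(seq_along(adj)) else names(predicted_log2_ratios),
    log2_ratio = unname(predicted_log2_ratios),
    adjusted = unname(adj),
    agree = unname(sign(adj) == predicted_sign),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two distributions of variance ratios
#'
#' Two-sided two-sample t-test on log2 within-strain variance ratios --
#' used to ask whether the genes predicted more variable in strain A and
#' those predicted more variable in strain B indeed show shifted ratio
#' distributions.
#'
#' @param ratios_a,ratios_b numeric vectors of log2 variance ratios
#'   (>= 2 values each).
#' @return list with `p`, `statistic`, `estimate` (group means), and
#'   `degenerate` flag (both groups constant).
#' @export
compare_ratio_distributions <- function(ratios_a, ratios_b) {
  stopifnot(length(ratios_a) >= 2, length(ratios_b) >= 2)
  if (stats::sd(ratios_a) == 0 && stats::sd(ratios_b) == 0)
    return(list(p = if (mean(ratios_a) == mean(ratios_b)) 1 else 0,
                statistic = NA_real_,
                estimate = c(mean(ratios_a), mean(ratios_b)),
                degenerate = TRUE))
  tt <- stats::t.test(ratios_a, ratios_b)
  list(p = tt$p.value, statistic = unname(tt$statistic),
       estimate = unname(tt$estimate), degenerate = FALSE)
}

#' Test ER-QTL predictions in an independent two-strain panel
#'
#' Driver tying the pieces together.  For every predicted gene present in
#' the replication panel and meeting the missing-data rule (at most one
#' missing value per strain group), computes the within-strain variances,
#' the log2 variance ratio, the baseline-adjusted ratio (baseline from
#' `background_genes`, genes not predicted to differ), the agreement flag,
#' and a one-sided F-test p in the predicted direction.
#'
#' @param predictions data frame with columns `gene_id` and
#'   `predicted_variable_strain`.
#' @param panel a `phenotype_panel` containing the two strains.
#' @param strains length-2 character vector; ratios are reported as
#'   `strains[1] : strains[2]` on the log2 scale.
#' @param background_genes trait ids for the baseline set; defaults to all
#'   panel traits not in `predictions`.
#' @param max_missing maximum missing values tolerated per strain group
#'   (default 1).
#' @return object of class `replication_test`: per-gene records plus the
#'   distribution comparison of [compare_ratio_distributions()].
#' @export
test_replication <- function(predictions, panel, strains,
                             background_genes = NULL, max_missing = 1L) {
  stopifnot(inherits(panel, "phenotype_panel"), length(strains) == 2)
  .required(predictions, c("gene_id", "predicted_variable_strain"),
            "predictions table", "<in-memory>")
  if (!all(predictions$predicted_variable_strain %in% strains))
    stop("predicted strains must be one of: ", paste(strains, collapse = ", "))
  rows1 <- panel$samples$strain == strains[1]
  rows2 <- panel$samples$strain == strains[2]
  if (!any(rows1) || !any(rows2))
    stop("replication panel lacks one of the target strains")
  gene_vars <- function(gene) {
    v1 <- panel$traits[rows1, gene]; v2 <- panel$traits[rows2, gene]
    if (sum(is.na(v1)) > max_missing || sum(is.na(v2)) > max_missing)
      return(NULL)
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2) return(NULL)
    list(var1 = stats::var(v1), var2 = stats::var(v2),
         n1 = length(v1), n2 = length(v2))
  }
  if (is.null(background_genes))
    background_genes <- setdiff(colnames(panel$traits), predictions$gene_id)
  bg_ratio <- unlist(lapply(intersect(background_genes,
                                      colnames(panel$traits)), function(g) {
    gv <- gene_vars(g)
    if (is.null(gv) || gv$var1 == 0 || gv$var2 == 0) return(NULL)
    log2(gv$var1 / gv$var2)
  }))
  if (!length(bg_ratio)) stop("no usable background genes for the baseline")
  recs <- lapply(seq_len(nrow(predictions)), function(i) {
    g <- predictions$gene_id[i]
    if (!g %in% colnames(panel$traits)) return(NULL)
    gv <- gene_vars(g)
    if (is.null(gv) || gv$var1 == 0 || gv$var2 == 0) return(NULL)
    pred1 <- predictions$predicted_variable_strain[i] == strains[1]
    ratio <- log2(gv$var1 / gv$var2)
    f_p <- if (pred1)
      variance_ratio_ftest(gv$var1, gv$var2, gv$n1, gv$n2, "one")
    else
      variance_ratio_ftest(gv$var2, gv$var1, gv$n2, gv$n1, "one")
    data.frame(gene_id = g,
               predicted_variable_strain =
                 predictions$predicted_variable_strain[i],
               log2_ratio = ratio,
               n1 = gv$n1, n2 = gv$n2, f_p_one_sided = as.numeric(f_p),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records)) stop("no predicted genes were testable")
  sign_pred <- ifelse(records$predicted_variable_strain == strains[1], 1, -1)
  adj <- baseline_adjusted_ratios(
    stats::setNames(records$log2_ratio, records$gene_id), bg_ratio, sign_pred)
  records$adjusted_log2_ratio <- adj$adjusted
  records$agree <- adj$agree
  a <- records$log2_ratio[sign_pred == 1]
  b <- records$log2_ratio[sign_pred == -1]
  cmp <- if (length(a) >= 2 && length(b) >= 2)
    compare_ratio_distributions(a, b) else NULL
  structure(list(records = records, baseline = mean(bg_ratio),
                 n_background = length(bg_ratio), strains = strains,
                 distribution_test = cmp),
            class = "replication_test")
}

#' @export
print.replication_test <- function(x, ...) {
  r <- x$records
  cat(sprintf("replication test, %s : %s (%d genes, baseline %.3f from %d genes)\n",
              x$strains[1], x$strains[2], nrow(r), x$baseline,
              x$n_background))
  for (s in x$strains) {
    sel <- r$predicted_variable_strain == s
    if (any(sel))
      cat(sprintf("  predicted more variable in %s: %d/%d confirmed (%.0f%%)\n",
                  s, sum(r$agree[sel]), sum(sel),
                  100 * mean(r$agree[sel])))
  }
  if (!is.null(x$distribution_test))
    cat(sprintf("  ratio distributions differ: t-test p = %.3g\n",
                x$distribution_test$p))
  invisible(x)
}
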