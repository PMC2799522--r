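# Independent step-by-step oracle for the median-variant FK statistic:
# absolute deviations from each group's median, pooled midranks computed
# by explicit counting (no rank()), half-normal scores, and the
# score-variance-scaled between-group sum of squares.
fk_oracle <- function(groups) {
  devs <- lapply(groups, function(v) abs(v - median(v)))
  # same declared tie convention as the package: deviations equal to 8
  # significant digits are tied and share a midrank
  pooled <- signif(unlist(devs, use.names = FALSE), 8)
  N <- length(pooled)
  midrank <- vapply(pooled, function(x)
    sum(pooled < x) + (sum(pooled == x) + 1) / 2, numeric(1))
  a <- qnorm(0.5 + midrank / (2 * (N + 1)))
  abar <- sum(a) / N
  v2 <- sum((a - abar)^2) / (N - 1)
  sizes <- lengths(devs)
  grp <- rep(seq_along(groups), sizes)
  ai <- vapply(seq_along(groups), function(i) mean(a[grp == i]), numeric(1))
  d <- sum(sizes * (ai - abar)^2) / v2
  list(d = d, p = pchisq(d, length(groups) - 1, lower.tail = FALSE))
}

# random small FK instances (two to four groups, sizes 3..12).  With
# odd_only = TRUE every group has odd size: continuous data then contain no
# ties beyond the exact structural zeros, so rankings are unambiguous and
# results are comparable to implementations with other floating-point
# tie-breaking (an even-sized group's two middle deviations are equal by
# construction, and different implementations may or may not see that tie).
random_fk_instance <- function(odd_only = FALSE) {
  k <- sample(2:4, 1)
  sizes <- if (odd_only) c(3, 5, 7, 9, 11) else 3:12
  lapply(seq_len(k), function(i)
    rnorm(sample(sizes, 1), sd = runif(1, 0.5, 3)))
}

# a deterministic phenotype panel: one row per sample, traits from a
# strains x traits matrix of medians plus fixed within-strain offsets
panel_from_medians <- function(medians, reps = 4, offsets = NULL,
                               sex = NULL) {
  strains <- rownames(medians)
  if (is.null(offsets))
    offsets <- seq(-0.015, 0.015, length.out = reps)
  samples <- data.frame(
    sample_id = sprintf("%s_r%d", rep(strains, each = reps),
                        rep(seq_len(reps), length(strains))),
    strain = rep(strains, each = reps), stringsAsFactors = FALSE)
  if (!is.null(sex)) samples$sex <- rep_len(sex, nrow(samples))
  traits <- medians[samples$strain, , drop = FALSE] +
    rep(offsets, length(strains))
  rownames(traits) <- samples$sample_id
  phenotype_panel(samples, traits)
}

# a balanced one-marker genotype panel: first n1 strains class 1
split_geno <- function(strains, n1 = floor(length(strains) / 2),
                       marker = "M1") {
  calls <- matrix(rep(c(1L, 0L), c(n1, length(strains) - n1)), ncol = 1,
                  dimnames = list(strains, marker))
  genotype_panel(calls)
}

strain_names <- function(n) sprintf("S%02d", seq_len(n))
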