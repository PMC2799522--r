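test_that("strain-label permutation is a seeded bijection", {
  g <- split_geno(strain_names(19), 9)
  p1 <- permute_strain_labels(g, seed = 11)
  p2 <- permute_strain_labels(g, seed = 11)
  expect_identical(attr(p1, "bijection"), attr(p2, "bijection"))
  expect_identical(p1$calls, p2$calls)
  bij <- attr(p1, "bijection")
  expect_setequal(unname(bij), rownames(g$calls))
  expect_identical(rownames(p1$calls), rownames(g$calls))
  # applying the inverse bijection restores the original pairing
  inv <- setNames(names(bij), bij)
  restored <- p1$calls[unname(inv[rownames(g$calls)]), , drop = FALSE]
  rownames(restored) <- rownames(g$calls)
  expect_identical(restored, g$calls)
})

test_that("empirical p and FDR follow the add-one and ratio formulas", {
  r <- empirical_scan_p(500, rep(0, 10000))
  expect_equal(r$empirical_p, 1 / 10001)
  expect_lt(r$empirical_p, 1e-4)
  r2 <- empirical_scan_p(100, c(rep(63, 9), 63.9))
  expect_equal(r2$fdr, mean(c(rep(63, 9), 63.9)) / 100)
  # observed equal to every permuted count -> p = 1
  r3 <- empirical_scan_p(7, rep(7, 50))
  expect_equal(r3$empirical_p, 1)
  # no observed hits -> FDR undefined
  expect_true(is.na(empirical_scan_p(0, c(1, 2))$fdr))
})

test_that("joint permutation shares one bijection across strata", {
  set.seed(61)
  cfg <- sim_config(n_individuals = 380, n_traits = 12, scenario = "GR",
                    seed = 41)
  sim <- simulate_panel(cfg, n_null_markers = 2)
  # alternate sexes within strain so both strata cover all strains
  sex <- character(nrow(sim$pheno$samples))
  for (s in unique(sim$pheno$samples$strain)) {
    i <- which(sim$pheno$samples$strain == s)
    sex[i] <- rep_len(c("F", "M"), length(i))
  }
  sim$pheno$samples$sex <- sex
  pm <- scan_permutation(sim$pheno, sim$geno, "gr",
                         strata = list(c(sex = "F"), c(sex = "M")),
                         B = 12, seed = 3)
  expect_true(pm$joint)
  expect_equal(dim(pm$permuted), c(12L, 2L))
  # the planted effect is sex-independent: both strata see it, and the
  # permuted panels essentially never reproduce the observed hit counts
  expect_true(all(pm$observed > 0))
  expect_lt(pm$per_stratum[[1]]$empirical_p, 0.2)
  key <- function(stratum) {
    h <- significant_hits(gr_scan(sim$pheno, sim$geno, stratum = stratum))
    paste(h$trait_id, h$marker_id)
  }
  expect_equal(pm$overlap$observed,
               length(intersect(key(c(sex = "F")), key(c(sex = "M")))))
  # determinism
  pm2 <- scan_permutation(sim$pheno, sim$geno, "gr",
                          strata = list(c(sex = "F"), c(sex = "M")),
                          B = 12, seed = 3)
  expect_identical(pm$permuted, pm2$permuted)
})

test_that("bootstrap p-value CIs are percentile-based and nested", {
  groups <- list(a = c(1, 2, 3, 4, 2.5, 3.5), b = c(1, 5, -2, 6, 0.5, 4))
  stat_p <- function(gr) fk_test(gr)$p.value
  ci95 <- bootstrap_pvalue_ci(groups, stat_p, n_boot = 200, level = 0.95,
                              seed = 5)
  ci99 <- bootstrap_pvalue_ci(groups, stat_p, n_boot = 200, level = 0.99,
                              seed = 5)
  expect_lte(ci99$ci["lower"], ci95$ci["lower"])
  expect_gte(ci99$ci["upper"], ci95$ci["upper"])
  expect_true(all(ci95$p_boot >= 0 & ci95$p_boot <= 1))
  # constant statistic -> zero-width interval
  cic <- bootstrap_pvalue_ci(groups, function(gr) 0.42, n_boot = 50,
                             level = 0.95, seed = 6)
  expect_equal(unname(diff(cic$ci)), 0)
})

test_that("random-partition test sees sex-independent planted effects", {
  # moderate shift so per-half detection is partial and counts vary
  cfg <- sim_config(n_individuals = 380, n_traits = 15, scenario = "GR",
                    seed = 55, gr_shift = 1.2)
  sim <- simulate_panel(cfg, n_null_markers = 1)
  sex <- character(nrow(sim$pheno$samples))
  for (s in unique(sim$pheno$samples$strain)) {
    i <- which(sim$pheno$samples$strain == s)
    sex[i] <- rep_len(c("F", "M"), length(i))
  }
  sim$pheno$samples$sex <- sex
  pt <- sex_specificity_partition(sim$pheno, sim$geno, "gr",
                                  n_partitions = 8, seed = 9)
  # a sex-independent effect: true-split counts close to random-split mean
  expect_true(all(abs(pt$z) < 3))
  pt2 <- sex_specificity_partition(sim$pheno, sim$geno, "gr",
                                   n_partitions = 8, seed = 9)
  expect_identical(pt$random_counts, pt2$random_counts)
  expect_error(sex_specificity_partition(sim$pheno, sim$geno, "gr",
                                         n_partitions = 1), "n_partitions")
})

test_that("a strictly female-only effect inflates only the female half", {
  # construct directly: female samples carry an ER effect, males are null
  strains <- strain_names(19)
  cls <- rep(c(1, 0), c(10, 9))
  set.seed(71)
  n_rep <- 10
  samples <- data.frame(
    sample_id = sprintf("s%04d", seq_len(19 * 2 * n_rep)),
    strain = rep(strains, each = 2 * n_rep),
    sex = rep(rep(c("F", "M"), each = n_rep), 19),
    stringsAsFactors = FALSE)
  n_traits <- 25
  sdv <- ifelse(samples$sex == "F" & cls[match(samples$strain, strains)] == 1,
                2.5, 1)
  traits <- matrix(rnorm(nrow(samples) * n_traits, 0, sdv),
                   nrow(samples), n_traits,
                   dimnames = list(samples$sample_id,
                                   sprintf("T%02d", 1:n_traits)))
  pheno <- phenotype_panel(samples, traits)
  geno <- split_geno(strains, 10)
  f_hits <- nrow(significant_hits(er_scan(pheno, geno,
                                          stratum = c(sex = "F"))))
  m_hits <- nrow(significant_hits(er_scan(pheno, geno,
                                          stratum = c(sex = "M"))))
  expect_gt(f_hits, m_hits)
  expect_gt(f_hits, n_traits / 2)
})

test_that("overlap expectation and Poisson zero probability compose", {
  expect_equal(expected_overlap(100, 1, 1, 0), 100)
  expect_equal(expected_overlap(100, 0.5, 0, 0), 0)
  expect_equal(expected_overlap(200, 0.4, 0.3, 0.082),
               200 * (0.4 * 0.3 + 0.6 * 0.082))
  expect_equal(expected_cross_overlap(78, 0.63, 0.285), 78 * 0.63 * 0.285)
  expect_equal(poisson_zero_prob(0), 1)
  expect_equal(poisson_zero_prob(2), exp(-2), tolerance = 1e-12)
  expect_lt(poisson_zero_prob(14), 1e-6)
  expect_error(poisson_zero_prob(-1), "non-negative")
})

test_that("split-half power is undefined on a null panel", {
  set.seed(81)
  sim <- simulate_panel(sim_config(n_individuals = 380, n_traits = 10,
                                   scenario = "NULL", seed = 13),
                        n_null_markers = 1)
  pw <- power_by_split(sim$pheno, sim$geno, "er", n_repeats = 2,
                       n_randomizations = 10, seed = 2)
  expect_true(is.na(pw$power))
})
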