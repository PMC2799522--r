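# deterministic 19-strain toy panels used across scan tests
med_matrix <- function(values, traits = "t1", n = 19) {
  matrix(values, nrow = n,
         dimnames = list(strain_names(n), traits))
}

test_that("trait eligibility separates between- and within-strain sigma", {
  strains <- strain_names(6)
  # t_gr: strain medians spread (sd 0.2-ish), tight replicates
  # t_er: identical medians, within-strain sd ~0.2; t_flat: constant
  med <- med_matrix(c(seq(-0.3, 0.3, length.out = 6),
                      rep(0, 6), rep(1, 6)),
                    c("t_gr", "t_er", "t_flat"), n = 6)
  p <- panel_from_medians(med, reps = 4, offsets = c(-0.015, -0.005, 0.005, 0.015))
  # inflate within-strain spread for t_er only, with a slight (sub-floor)
  # between-strain spread so relaxed thresholds can pick it up
  p$traits[, "t_er"] <- rep(c(-0.3, -0.1, 0.1, 0.3), 6) +
    rep(seq(0, 0.05, length.out = 6), each = 4)
  ss <- strain_summaries(p)
  expect_setequal(eligible_traits(ss, mode = "GR"), "t_gr")
  expect_setequal(eligible_traits(ss, mode = "ER"), "t_er")
  # lowering the floor only grows the eligible set
  loose <- scan_config(sigma_min = 0.001)
  expect_true(all(eligible_traits(ss, mode = "GR") %in%
                    eligible_traits(ss, loose, "GR")))
  expect_gt(length(eligible_traits(ss, loose, "GR")), 1)
})

test_that("marker eligibility follows the maximal-balance rule", {
  strains <- strain_names(19)
  calls <- cbind(split_geno(strains, 9)$calls,
                 M2 = rep(c(1L, 0L), c(2, 17)),
                 M3 = rep(c(1L, 0L), c(10, 9)))
  g <- genotype_panel(calls)
  expect_setequal(eligible_markers(g), c("M1", "M3"))
  expect_setequal(eligible_markers(g, scan_config(min_minor_strains = 1)),
                  c("M1", "M2", "M3"))
})

test_that("median-QTL filter excludes mean effects and keeps balanced ones", {
  g <- rep(c(0, 1), c(9, 10))
  # medians perfectly ordered by genotype class -> excluded
  ordered <- c(seq(0.01, 0.09, by = 0.01), 1 + seq(0.01, 0.10, by = 0.01))
  expect_false(median_qtl_filter(ordered, g)$keep)
  # alternating medians, class means equal -> no mean signal
  mf <- median_qtl_filter(rep(c(-1, 1), length.out = 19), g)
  expect_true(mf$keep)
  expect_gt(mf$p, 0.5)
  cst <- median_qtl_filter(rep(1, 19), g)
  expect_true(cst$keep)
  expect_true(cst$flagged)
})

test_that("GR scan recovers a planted dispersion effect", {
  set.seed(31)
  sim <- simulate_panel(sim_config(n_traits = 10, scenario = "GR", seed = 77),
                        n_null_markers = 4)
  h <- gr_scan(sim$pheno, sim$geno)
  planted <- h[h$marker_id == "M1", ]
  expect_equal(nrow(planted), 10)      # all planted traits tested at M1
  # the planted marker attains the scan's smallest nominal p per trait
  best <- vapply(split(h, h$trait_id),
                 function(df) df$marker_id[which.min(df$nominal_p)],
                 character(1))
  expect_gte(mean(best == "M1"), 0.9)
  expect_true(all(planted$nominal_p < 0.01))
})

test_that("GR scan sees only strain medians", {
  set.seed(32)
  sim <- simulate_panel(sim_config(n_traits = 5, scenario = "GR", seed = 5))
  h1 <- gr_scan(sim$pheno, sim$geno)
  # permute replicate rows within each strain: medians unchanged
  idx <- unlist(lapply(split(seq_len(nrow(sim$pheno$samples)),
                             sim$pheno$samples$strain),
                       sample), use.names = FALSE)
  p2 <- phenotype_panel(
    data.frame(sample_id = sim$pheno$samples$sample_id,
               strain = sim$pheno$samples$strain[idx],
               stringsAsFactors = FALSE),
    sim$pheno$traits[idx, , drop = FALSE])
  h2 <- gr_scan(p2, sim$geno)
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-12)
  expect_equal(h1$nominal_p, h2$nominal_p, tolerance = 1e-12)
})

test_that("a tight-vs-bimodal pair with equal medians is reported, not excluded", {
  strains <- strain_names(19)
  # genotype-1 strains (10): medians straddle the genotype-0 cluster at +-2
  med <- med_matrix(c(rep(c(-2, 2), 5), seq(-0.1, 0.1, length.out = 9)))
  p <- panel_from_medians(med, reps = 3)
  g <- split_geno(strains, 10)
  h <- gr_scan(p, g, scan_config(min_replicates = 3))
  expect_equal(nrow(h), 1)
  expect_true(h$hit)
  # every wide-group deviation exceeds every tight-group deviation, so the
  # statistic attains the (9,10) maximum computed by the oracle
  o <- fk_oracle(list(seq(-0.1, 0.1, length.out = 9), rep(c(-2, 2), 5)))
  expect_equal(h$statistic, o$d, tolerance = 1e-9)
})

test_that("ER scan hit rule matches the exact correlation p", {
  strains <- strain_names(19)
  g <- split_geno(strains, 10)
  gv <- g$calls[strains, "M1"]
  # construct within-strain SDs with exact r^2 = 0.5 against genotype
  u <- gv - mean(gv)
  e <- c(rep(0, 10), seq(-4, 4))       # orthogonal to the class indicator
  stopifnot(abs(sum(e * u)) < 1e-12)
  beta <- sqrt(sum(u^2) / sum(e^2))
  s <- 1 + 0.25 * u + 0.25 * beta * e  # cor(s, gv)^2 = 0.5 exactly
  expect_equal(cor(s, gv)^2, 0.5, tolerance = 1e-12)
  # replicates {-s, 0, +s} around a common median give SD exactly s
  samples <- data.frame(
    sample_id = sprintf("%s_%d", rep(strains, each = 3), 1:3),
    strain = rep(strains, each = 3), stringsAsFactors = FALSE)
  traits <- matrix(as.vector(rbind(-s, 0, s)), ncol = 1,
                   dimnames = list(samples$sample_id, "t1"))
  p <- phenotype_panel(samples, traits)
  h <- er_scan(p, g, scan_config(min_replicates = 3))
  expect_equal(nrow(h), 1)
  expect_equal(h$statistic^2, 0.5, tolerance = 1e-9)
  # exact two-sided t oracle: below the stated 0.00085 bound
  r <- sqrt(0.5)
  p_oracle <- 2 * pt(r * sqrt(17 / (1 - r^2)), 17, lower.tail = FALSE)
  expect_equal(h$nominal_p, p_oracle, tolerance = 1e-9)
  expect_lt(h$nominal_p, 0.00085)
  expect_true(h$hit)
  # identical dispersions across strains -> pair skipped, no rows
  traits2 <- matrix(as.vector(rbind(rep(-1, 19), 0, rep(1, 19))), ncol = 1,
                    dimnames = list(samples$sample_id, "t1"))
  h2 <- er_scan(phenotype_panel(samples, traits2), g,
                scan_config(min_replicates = 3))
  expect_equal(nrow(h2), 0)
})

test_that("ER scan with SD metric ignores per-strain location shifts", {
  set.seed(33)
  sim <- simulate_panel(sim_config(n_traits = 6, scenario = "ER", seed = 9))
  h1 <- er_scan(sim$pheno, sim$geno)
  shift <- rnorm(19, sd = 5)
  names(shift) <- sort(unique(sim$pheno$samples$strain))
  p2 <- sim$pheno
  p2$traits <- p2$traits + shift[p2$samples$strain]
  h2 <- er_scan(p2, sim$geno)
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-9)
})

test_that("relaxing the median-QTL alpha only grows the reported set", {
  set.seed(34)
  sim <- simulate_panel(sim_config(n_traits = 40, scenario = "NULL",
                                   seed = 21, regenerate = FALSE))
  strict <- gr_scan(sim$pheno, sim$geno, scan_config(median_qtl_alpha = 0.2,
                                                     sigma_min = 0))
  relaxed <- gr_scan(sim$pheno, sim$geno, scan_config(median_qtl_alpha = 0.01,
                                                      sigma_min = 0))
  key <- function(h) paste(h$trait_id, h$marker_id)
  expect_true(all(key(strict) %in% key(relaxed)))
  expect_gte(nrow(relaxed), nrow(strict))
})

test_that("macro-ER scan uses per-condition medians", {
  strains <- strain_names(8)
  conds <- c("A", "B", "C")
  # strain i has condition medians -d_i, 0, +d_i: macro dispersion d_i
  # with no overall median signal for the filter to catch
  d <- seq(0.2, 1.6, length.out = 8)
  rows <- expand.grid(rep = 1:3, cond = conds, strain = strains,
                      stringsAsFactors = FALSE)
  base <- d[match(rows$strain, strains)] *
    (match(rows$cond, conds) - 2)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(nrow(rows))),
    strain = rows$strain, condition = rows$cond, stringsAsFactors = FALSE)
  traits <- matrix(base + rep(c(-0.01, 0, 0.01), nrow(rows) / 3), ncol = 1,
                   dimnames = list(samples$sample_id, "t1"))
  p <- phenotype_panel(samples, traits)
  g <- split_geno(strains, 4)
  h <- macro_er_scan(p, g, scan_config(min_replicates = 3,
                                       min_class_strains = 2))
  expect_equal(nrow(h), 1)
  # macro dispersion per strain is the SD of exactly its 3 condition medians
  disp_expected <- vapply(d, function(di) sd(c(-di, 0, di)), numeric(1))
  gv <- g$calls[strains, "M1"]
  expect_equal(h$statistic, cor(disp_expected, gv), tolerance = 1e-6)
  # identical medians in all conditions -> zero macro dispersion, no rows
  traits0 <- matrix(rep(c(-0.01, 0, 0.01), nrow(rows) / 3), ncol = 1,
                    dimnames = list(samples$sample_id, "t1"))
  h0 <- macro_er_scan(phenotype_panel(samples, traits0), g,
                      scan_config(min_replicates = 3, min_class_strains = 2))
  expect_equal(nrow(h0), 0)
})

test_that("non-redundant marker counting collapses identical genotypes", {
  strains <- strain_names(19)
  calls <- cbind(split_geno(strains, 9)$calls,
                 M1b = rep(c(1L, 0L), c(9, 10)),
                 M2 = rep(c(0L, 1L), c(9, 10)))
  g <- genotype_panel(calls)
  h <- robust_hits(data.frame(
    scan_type = "GR", stratum = "all", trait_id = "t1",
    marker_id = c("M1", "M1b", "M2"), statistic = 11, nominal_p = 1e-4,
    hit = TRUE, stringsAsFactors = FALSE))
  counts <- nonredundant_marker_counts(h, g)
  expect_equal(unname(counts["t1"]), 2L)   # M1 and M1b collapse
})
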