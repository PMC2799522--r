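test_that("inflation curve equals the KS statistic against uniform", {
  set.seed(201)
  for (p in list(runif(500), runif(300)^2, rbeta(200, 2, 1))) {
    curve <- pvalue_inflation_curve(p)
    ks <- suppressWarnings(ks.test(p, "punif"))
    expect_equal(curve$max_deviation, unname(ks$statistic),
                 tolerance = 1e-12)
  }
  # squared p-values pile near zero: analytic CDF sqrt(t) deviates by 0.25
  pv <- pvalue_inflation_curve(runif(20000)^2)
  expect_equal(pv$max_deviation, 0.25, tolerance = 0.02)
  expect_equal(pv$flag, "warn")
  big <- pvalue_inflation_curve(runif(20000))
  expect_lt(big$max_deviation, 0.02)
  expect_equal(big$flag, "pass")
  single <- pvalue_inflation_curve(0.5)
  expect_equal(single$max_deviation, 0.5)
  expect_error(pvalue_inflation_curve(numeric(0)), "empty")
  expect_error(pvalue_inflation_curve(c(0.5, 1.2)), "0, 1")
})

test_that("co-occurrence check is null for random genotypes, 171 pairs at 19 strains", {
  set.seed(202)
  strains <- strain_names(19)
  # dense marker set: the hit markers are a negligible fraction of the
  # markers defining phylogenetic distance, as in a real panel (otherwise
  # distance and co-occurrence share markers and anticorrelate trivially)
  calls <- matrix(rbinom(19 * 600, 1, 0.5), 19, 600,
                  dimnames = list(strains, sprintf("m%03d", 1:600)))
  g <- genotype_panel(calls)
  hits <- robust_hits(data.frame(
    scan_type = "GR", stratum = "all", trait_id = "t",
    marker_id = sample(colnames(calls), 10), statistic = 11,
    nominal_p = 1e-4, hit = TRUE, stringsAsFactors = FALSE))
  cc <- cooccurrence_vs_distance(g, hits)
  expect_equal(nrow(cc$pairs), choose(19, 2))   # all 171 strain pairs
  expect_equal(cc$flag, "pass")
  expect_lt(abs(cc$rho), 0.35)
  # no hits -> empty report
  empty <- cooccurrence_vs_distance(g, robust_hits())
  expect_equal(empty$n_hit_markers, 0L)
})

test_that("clade-aligned hit markers trigger the structure warning", {
  strains <- strain_names(12)
  # two clades with many fixed differences; hit markers split by clade
  clade <- rep(c(0L, 1L), each = 6)
  set.seed(203)
  calls <- cbind(
    matrix(rep(clade, 30), 12, 30),                     # clade-aligned
    matrix(rbinom(12 * 10, 1, 0.5), 12, 10))            # background noise
  colnames(calls) <- sprintf("m%02d", seq_len(ncol(calls)))
  rownames(calls) <- strains
  g <- genotype_panel(calls)
  hits <- robust_hits(data.frame(
    scan_type = "GR", stratum = "all", trait_id = "t",
    marker_id = sprintf("m%02d", 1:10), statistic = 11, nominal_p = 1e-4,
    hit = TRUE, stringsAsFactors = FALSE))
  cc <- cooccurrence_vs_distance(g, hits)
  expect_lt(cc$rho, -0.3)
  expect_equal(cc$flag, "warn")
})

test_that("paired correlations separate batch-affected panels", {
  set.seed(204)
  n_traits <- 150
  samples <- data.frame(sample_id = sprintf("s%02d", 1:24),
                        strain = rep(strain_names(6), each = 4),
                        stringsAsFactors = FALSE)
  strain_effect <- matrix(rnorm(6 * n_traits, 0, 1), 6)
  traits <- strain_effect[rep(1:6, each = 4), ] +
    matrix(rnorm(24 * n_traits, 0, 0.6), 24)
  dimnames(traits) <- list(samples$sample_id, sprintf("T%03d", 1:n_traits))
  p <- phenotype_panel(samples, traits)
  # same-strain pairs labelled cage (first two per strain) vs neither
  pairs <- do.call(rbind, lapply(seq(1, 24, 4), function(i)
    data.frame(sample1 = samples$sample_id[c(i, i + 2)],
               sample2 = samples$sample_id[c(i + 1, i + 3)],
               category = c("cage", "neither"), stringsAsFactors = FALSE)))
  ok <- paired_group_correlation(p, pairs)
  expect_equal(ok$flag, "pass")
  expect_equal(ok$summary$mean_r[1], ok$summary$mean_r[2], tolerance = 0.1)
  # planted cage effect: shared offset within cage pairs
  cage_shift <- matrix(rnorm(6 * n_traits, 0, 1.2), 6)
  traits2 <- traits
  for (s in 1:6) {
    rows <- (s - 1) * 4 + 1:2
    traits2[rows, ] <- traits2[rows, ] + rep(cage_shift[s, ], each = 2)
  }
  p2 <- phenotype_panel(samples, traits2)
  warned <- paired_group_correlation(p2, pairs)
  expect_equal(warned$flag, "warn")
  expect_gt(warned$summary$mean_r[warned$summary$category == "cage"],
            warned$summary$mean_r[warned$summary$category == "neither"])
  # identical samples correlate perfectly
  p3 <- phenotype_panel(samples, traits[rep(1, 24), , drop = FALSE] +
                          0 * traits)
  all_one <- paired_group_correlation(p3, pairs)
  expect_equal(all_one$summary$mean_r, c(1, 1), tolerance = 1e-12)
})

test_that("flagged-trait enrichment matches the hypergeometric tail", {
  background <- sprintf("t%04d", 1:1000)
  flagged <- background[1:36]                     # 3.6% of traits flagged
  hits <- background[101:200]                     # no flagged among hits
  enr <- flagged_feature_enrichment(hits, flagged, background)
  expect_equal(enr$overlap, 0)
  expect_equal(enr$enrichment_p, 1, tolerance = 1e-9)
  # restricted background changes the universe, not the formula
  both <- flagged_feature_enrichment(hits, flagged, background,
                                     restricted_background = background[1:500])
  expect_equal(nrow(both), 2)
  expect_equal(both$enrichment_p[2],
               phyper(0 - 1, 36, 500 - 36, 100, lower.tail = FALSE),
               tolerance = 1e-12)
  # uniform draws give uniform-ish p under the null
  set.seed(205)
  ps <- replicate(300, {
    h <- sample(background, 50)
    flagged_feature_enrichment(h, flagged, background)$enrichment_p
  })
  expect_gt(mean(ps > 0.5), 0.3)     # no systematic enrichment
  expect_error(flagged_feature_enrichment(hits, flagged, character(0)),
               "empty")
})
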