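write_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("phenotype panels round-trip through TSV", {
  f <- write_lines(c(
    "sample_id\tstrain\tsex\tt1\tt2\tt3",
    "m1\tA\tF\t1.5\t2\tNA",
    "m2\tA\tM\t1.25\t2.5\t0.125",
    "m3\tB\tF\t-1\t0\t3",
    "m4\tB\tM\t-1.5\t0.5\t3.5"))
  p <- read_phenotype_panel(f)
  expect_equal(nrow(p$samples), 4)
  expect_equal(length(unique(p$samples$strain)), 2)
  expect_equal(ncol(p$traits), 3)
  expect_true(is.na(p$traits["m1", "t3"]))
  out <- tempfile(fileext = ".tsv")
  write_phenotype_panel(p, out)
  p2 <- read_phenotype_panel(out)
  expect_equal(p2$samples, p$samples)
  expect_equal(p2$traits, p$traits, tolerance = 1e-9)
  # per-strain sample counts sum to the total
  expect_equal(sum(table(p$samples$strain)), nrow(p$samples))
})

test_that("phenotype reader validates columns and cells", {
  f <- write_lines(c("sample_id\tline\tt1", "m1\tA\t1"))
  expect_error(read_phenotype_panel(f), "strain")
  f2 <- write_lines(c("sample_id\tstrain\tt1", "m1\tA\tx7"))
  err <- tryCatch(read_phenotype_panel(f2), error = conditionMessage)
  expect_match(err, "row 1")
  expect_match(err, "t1")
  f3 <- write_lines(c("sample_id\tstrain\tt1", "m1\tA\t1", "m1\tB\t2"))
  expect_error(read_phenotype_panel(f3), "duplicate")
  # schema remapping recovers a renamed strain column
  p <- read_phenotype_panel(f, schema = list(strain = "line"))
  expect_equal(p$samples$strain, "A")
})

test_that("genotype panels decode tokens and round-trip", {
  f <- write_lines(c(
    "strain\tm1\tm2\tm3",
    "A\tA\tB\tH",
    "B\tB\tB\tNA",
    "C\tA\tB\tA"))
  g <- read_genotype_panel(f)
  expect_equal(g$counts$n0, c(2L, 0L, 1L))
  expect_equal(g$counts$n1, c(1L, 3L, 0L))
  expect_equal(g$counts$n_het, c(0L, 0L, 1L))
  expect_equal(g$counts$n_missing, c(0L, 0L, 1L))
  expect_true(g$counts$monomorphic[2])   # all-identical calls flagged
  out <- tempfile(fileext = ".tsv")
  write_genotype_panel(g, out)
  g2 <- read_genotype_panel(out)
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$het, g$het)
  f_bad <- write_lines(c("strain\tm1", "A\tZ"))
  err <- tryCatch(read_genotype_panel(f_bad), error = conditionMessage)
  expect_match(err, "Z")
  expect_match(err, "m1")
})

test_that("a 9/10 split in 19 strains has minor-allele count 9", {
  g <- split_geno(strain_names(19), n1 = 9)
  expect_equal(min(g$counts$n0, g$counts$n1), 9L)
  expect_true("M1" %in% eligible_markers(g))
})

test_that("marker QC drops high-missing markers and is idempotent", {
  calls <- matrix(c(0L, 1L, NA, NA, NA,    # 60% missing -> dropped at 0.5
                    0L, 1L, 0L, 1L, 0L,
                    0L, 1L, NA, 0L, 1L),
                  nrow = 5,
                  dimnames = list(strain_names(5), c("hi", "full", "het1")))
  het <- matrix(FALSE, 5, 3, dimnames = dimnames(calls))
  het[3, "het1"] <- TRUE
  g <- genotype_panel(calls, het)
  qc <- qc_markers(g, 0.5)
  expect_false("hi" %in% colnames(qc$panel$calls))
  expect_true(all(c("full", "het1") %in% colnames(qc$panel$calls)))
  expect_true(qc$report$dropped[qc$report$marker_id == "hi"])
  # the heterozygous strain is excluded for that marker only
  expect_true(is.na(qc$panel$calls[3, "het1"]))
  expect_false(is.na(qc$panel$calls[3, "full"]))
  qc2 <- qc_markers(qc$panel, 0.5)
  expect_identical(qc2$panel$calls, qc$panel$calls)
  # fully typed panel is unchanged
  full <- genotype_panel(calls[, "full", drop = FALSE])
  expect_identical(qc_markers(full)$panel$calls, full$calls)
  all_missing <- genotype_panel(matrix(NA_integer_, 5, 1,
                                       dimnames = list(strain_names(5), "x")))
  expect_error(qc_markers(all_missing), "every marker")
})

test_that("hit tables write deterministically and round-trip", {
  h <- robust_hits(data.frame(
    scan_type = c("GR", "GR", "ER"),
    stratum = "all",
    trait_id = c("t1", "t1", "t2"),
    marker_id = c("m2", "m1", "m3"),
    chrom = c("chr2", "chr1", "chr1"),
    pos = c(5e6, 1e6, 2e6),
    statistic = c(8.1, 9.2, 0.77),
    nominal_p = c(0.004, 0.002, 1e-4),
    cis_flag = c("trans", "cis", NA), stringsAsFactors = FALSE))
  expect_equal(h$cis_flag[3], "unknown")
  out <- tempfile(fileext = ".tsv")
  write_hits(h, out)
  back <- read_hits(out)
  # sorted by scan type then trait then genomic position
  expect_equal(back$marker_id, c("m3", "m1", "m2"))
  expect_equal(sort(back$statistic), sort(h$statistic))
  # byte-stable across writes
  out2 <- tempfile(fileext = ".tsv")
  write_hits(back, out2)
  expect_identical(readLines(out), readLines(out2))
  # empty table -> header-only file
  out3 <- tempfile(fileext = ".tsv")
  write_hits(robust_hits(), out3)
  expect_length(readLines(out3), 1L)
  expect_error(robust_hits(data.frame(scan_type = "GR", trait_id = "t",
                                      marker_id = "m", nominal_p = 1.5)),
               "nominal_p")
})

test_that("maps validate coordinates and BED starts shift to 1-based", {
  f <- write_lines(c("id\tchrom\tpos", "g1\tchr1\t100", "g2\tchr2\t5"))
  m <- read_marker_map(f)
  expect_s3_class(m, "genome_map")
  expect_equal(m$pos, c(100, 5))
  fb <- write_lines(c("chr1\t99\t200\tg1"))
  mb <- read_bed_map(fb)
  expect_equal(mb$pos, 100)   # 0-based half-open start -> 1-based
  f_bad <- write_lines(c("id\tchrom\tpos", "g1\tchr1\t0"))
  expect_error(read_marker_map(f_bad), ">= 1")
})
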