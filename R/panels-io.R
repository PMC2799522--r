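#' @title Phenotype and genotype panel IO
#' @description Readers, writers and validators for the tab-delimited panel
#'   formats used throughout the package, plus marker-level quality control.
#' @name panels_io
NULL

.required <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Construct a phenotype panel
#'
#' A phenotype panel holds replicated per-sample trait measurements together
#' with the strain (and optionally sex / condition) label of every sample.
#' Traits are continuous (e.g. log2 expression); missing values are allowed.
#'
#' @param samples data frame with columns `sample_id`, `strain` and
#'   optionally `sex` (levels `"F"`/`"M"`) and `condition`.
#' @param traits numeric matrix, samples x traits, rownames matching
#'   `samples$sample_id`, unique column names.
#' @return object of class `phenotype_panel`.
#' @export
phenotype_panel <- function(samples, traits) {
  stopifnot(is.data.frame(samples), is.matrix(traits))
  .required(samples, c("sample_id", "strain"), "samples table", "<in-memory>")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (any(is.na(samples$strain)) || any(!nzchar(samples$strain)))
    stop("every sample must have a strain label")
  if (anyDuplicated(colnames(traits)))
    stop("trait ids must be unique")
  if (!is.numeric(traits))
    stop("trait matrix must be numeric")
  if (any(is.infinite(traits)))
    stop("trait values must be finite or missing (NA)")
  if (nrow(traits) != nrow(samples))
    stop("trait matrix rows must match samples")
  rownames(traits) <- samples$sample_id
  if ("sex" %in% names(samples)) {
    bad <- !is.na(samples$sex) & !samples$sex %in% c("F", "M")
    if (any(bad)) stop("sex must be 'F' or 'M' (or NA)")
  }
  samples$strain <- as.character(samples$strain)
  structure(list(samples = samples, traits = traits),
            class = "phenotype_panel")
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat(sprintf("phenotype_panel: %d samples, %d strains, %d traits\n",
              nrow(x$samples), length(unique(x$samples$strain)),
              ncol(x$traits)))
  if ("sex" %in% names(x$samples) && any(!is.na(x$samples$sex)))
    cat("  strata (sex):", paste(names(table(x$samples$sex)), collapse = ", "),
        "\n")
  if ("condition" %in% names(x$samples) && any(!is.na(x$samples$condition)))
    cat("  conditions:",
        paste(unique(stats::na.omit(x$samples$condition)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Read a phenotype panel from a tab-delimited file
#'
#' Expected layout: a header row, then one row per sample with columns
#' `sample_id  strain  [sex]  [condition]  <trait_1> ... <trait_T>`.
#' All columns that are not recognised label columns are treated as traits
#' and must be numeric (missing token allowed).
#'
#' @param path file path.
#' @param na character token marking missing values (default `"NA"`).
#' @param schema optional named list remapping label column names, e.g.
#'   `list(sample_id = "mouse", strain = "line")`.
#' @return a [phenotype_panel()].
#' @export
read_phenotype_panel <- function(path, na = "NA", schema = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = na,
                          colClasses = "character")
  for (key in names(schema)) {
    idx <- match(schema[[key]], names(df))
    if (is.na(idx)) stop(sprintf("schema column '%s' (for '%s') not in '%s'",
                                 schema[[key]], key, path))
    names(df)[idx] <- key
  }
  .required(df, c("sample_id", "strain"), "phenotype file", path)
  label_cols <- intersect(c("sample_id", "strain", "sex", "condition"),
                          names(df))
  trait_cols <- setdiff(names(df), label_cols)
  tm <- matrix(NA_real_, nrow(df), length(trait_cols),
               dimnames = list(df$sample_id, trait_cols))
  for (j in seq_along(trait_cols)) {
    raw <- df[[trait_cols[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad))
      stop(sprintf(
        "non-numeric trait value '%s' at row %d, column '%s' of '%s'",
        raw[bad[1]], bad[1], trait_cols[j], path))
    tm[, j] <- val
  }
  phenotype_panel(df[label_cols], tm)
}

#' Write a phenotype panel to a tab-delimited file
#'
#' Inverse of [read_phenotype_panel()]; a written panel reads back
#' identically up to floating-point formatting.
#'
#' @param panel a `phenotype_panel`.
#' @param path output path.
#' @export
write_phenotype_panel <- function(panel, path) {
  stopifnot(inherits(panel, "phenotype_panel"))
  out <- cbind(panel$samples,
               as.data.frame(panel$traits, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype panel
#'
#' Strain-level homozygous biallelic genotypes for an inbred panel.  Calls
#' are coded 0/1 for the two homozygous alleles; heterozygous and missing
#' calls are tracked separately and are excluded per marker during scans
#' (never recoded).
#'
#' @param calls integer/numeric matrix, strains x markers, entries 0, 1 or
#'   NA (NA = heterozygous or missing; see `het`); rownames are strain ids.
#' @param het logical matrix of the same shape flagging heterozygous calls
#'   (a subset of the NA entries of `calls`); default all `FALSE`.
#' @return object of class `genotype_panel` with per-marker class counts.
#' @export
genotype_panel <- function(calls, het = NULL) {
  stopifnot(is.matrix(calls))
  if (is.null(rownames(calls))) stop("calls must have strain rownames")
  if (anyDuplicated(rownames(calls))) stop("strain ids must be unique")
  storage.mode(calls) <- "integer"
  ok <- is.na(calls) | calls == 0L | calls == 1L
  if (!all(ok)) stop("genotype calls must be 0, 1 or NA")
  if (is.null(het)) het <- matrix(FALSE, nrow(calls), ncol(calls),
                                  dimnames = dimnames(calls))
  stopifnot(identical(dim(het), dim(calls)))
  if (any(het & !is.na(calls)))
    stop("heterozygous flags must correspond to NA calls")
  counts <- data.frame(
    marker_id = colnames(calls),
    n0 = colSums(calls == 0L, na.rm = TRUE),
    n1 = colSums(calls == 1L, na.rm = TRUE),
    n_het = colSums(het),
    n_missing = colSums(is.na(calls) & !het),
    row.names = NULL, stringsAsFactors = FALSE)
  counts$monomorphic <- counts$n0 == 0L | counts$n1 == 0L
  structure(list(calls = calls, het = het, counts = counts),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d strains, %d markers (%d monomorphic)\n",
              nrow(x$calls), ncol(x$calls), sum(x$counts$monomorphic)))
  invisible(x)
}

#' Read a strain x marker genotype panel
#'
#' Expected layout: header `strain  <marker_1> ... <marker_M>`, one row per
#' strain.  Raw symbols are mapped to genotype classes through `coding`.
#'
#' @param path file path.
#' @param coding named character vector mapping raw tokens to classes
#'   `"0"`, `"1"`, `"HET"`, `"MISSING"`; default
#'   `c(A = "0", B = "1", H = "HET", "NA" = "MISSING")`.
#' @return a [genotype_panel()].  A panel whose markers are all monomorphic
#'   triggers a warning, not an error.
#' @export
read_genotype_panel <- function(path,
                                coding = c(A = "0", B = "1",
                                           H = "HET", "NA" = "MISSING")) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  .required(df, "strain", "genotype file", path)
  markers <- setdiff(names(df), "strain")
  calls <- matrix(NA_integer_, nrow(df), length(markers),
                  dimnames = list(df$strain, markers))
  het <- matrix(FALSE, nrow(df), length(markers),
                dimnames = list(df$strain, markers))
  for (j in seq_along(markers)) {
    raw <- df[[markers[j]]]
    raw[is.na(raw)] <- "NA"
    cls <- coding[raw]
    bad <- which(is.na(cls))
    if (length(bad))
      stop(sprintf(
        "unknown genotype token '%s' (marker '%s', strain '%s') in '%s'",
        raw[bad[1]], markers[j], df$strain[bad[1]], path))
    calls[cls == "0", j] <- 0L
    calls[cls == "1", j] <- 1L
    het[cls == "HET", j] <- TRUE
  }
  g <- genotype_panel(calls, het)
  if (all(g$counts$monomorphic))
    warning("all markers are monomorphic; nothing is scannable")
  g
}

#' Write a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @param coding the token coding to write with (inverse of the reader's).
#' @export
write_genotype_panel <- function(panel, path,
                                 coding = c(A = "0", B = "1",
                                            H = "HET", "NA" = "MISSING")) {
  stopifnot(inherits(panel, "genotype_panel"))
  inv <- names(coding)[match(c("0", "1", "HET", "MISSING"), coding)]
  sym <- matrix(inv[4], nrow(panel$calls), ncol(panel$calls))
  sym[which(panel$calls == 0L)] <- inv[1]
  sym[which(panel$calls == 1L)] <- inv[2]
  sym[which(panel$het)] <- inv[3]
  out <- data.frame(strain = rownames(panel$calls), sym,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("strain", colnames(panel$calls))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker or feature map
#'
#' Plain TSV with columns `id  chrom  pos`; positions are 1-based base
#' pairs.  Used both for genetic markers and for trait/gene features (the
#' representative coordinate used in cis/trans classification).
#'
#' @param path file path.
#' @return data frame `id, chrom, pos` with class `genome_map`.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character", "character", "numeric"))
  .required(df, c("id", "chrom", "pos"), "map file", path)
  genome_map(df)
}

#' Construct a genome map from a data frame
#' @param df data frame with columns `id`, `chrom`, `pos` (1-based bp).
#' @return the validated data frame, classed `genome_map`.
#' @export
genome_map <- function(df) {
  .required(df, c("id", "chrom", "pos"), "map", "<in-memory>")
  if (anyDuplicated(df$id)) stop("map ids must be unique")
  if (any(df$pos < 1)) stop("map positions must be >= 1 (1-based bp)")
  df$pos <- as.numeric(df$pos)
  class(df) <- c("genome_map", "data.frame")
  df
}

#' Read a BED file as a genome map
#'
#' Converts 0-based half-open BED starts to the 1-based point coordinates
#' used everywhere else (the interval start becomes the representative
#' position).
#'
#' @param path BED file (>= 4 columns: chrom, start, end, name).
#' @return a `genome_map`.
#' @export
read_bed_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, check.names = FALSE)
  if (ncol(df) < 4) stop("BED map needs at least 4 columns (incl. name)")
  genome_map(data.frame(id = as.character(df[[4]]),
                        chrom = as.character(df[[1]]),
                        pos = as.numeric(df[[2]]) + 1,
                        stringsAsFactors = FALSE))
}

#' Marker-level quality control
#'
#' Drops markers whose fraction of missing strain calls exceeds
#' `max_missing_frac` (default 0.5, i.e. markers missing in more than half
#' the strains are discarded).  Heterozygous calls are never recoded:
#' heterozygous or missing strains are simply excluded from the analysis of
#' that one marker, which the panel representation already encodes (such
#' calls are NA in `calls`).  The operation is idempotent.
#'
#' @param panel a `genotype_panel`.
#' @param max_missing_frac proportion in (0, 1]; markers with
#'   `missing fraction > max_missing_frac` are removed.
#' @return list with `panel` (filtered `genotype_panel`) and `report`
#'   (data frame of per-marker missing fractions and a `dropped` flag).
#' @export
qc_markers <- function(panel, max_missing_frac = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"),
            max_missing_frac > 0, max_missing_frac <= 1)
  n <- nrow(panel$calls)
  miss_frac <- colSums(is.na(panel$calls)) / n
  drop <- miss_frac > max_missing_frac
  if (all(drop))
    stop("marker QC removed every marker (all exceed the missing threshold)")
  report <- data.frame(marker_id = colnames(panel$calls),
                       missing_frac = unname(miss_frac),
                       n_het = panel$counts$n_het,
                       dropped = unname(drop),
                       row.names = NULL, stringsAsFactors = FALSE)
  keep <- !drop
  list(panel = genotype_panel(panel$calls[, keep, drop = FALSE],
                              panel$het[, keep, drop = FALSE]),
       report = report)
}

.hit_cols <- c("scan_type", "stratum", "trait_id", "marker_id", "chrom",
               "pos", "statistic", "nominal_p", "cis_flag")

#' Construct a hit table
#'
#' The common result container for all scans: one row per tested
#' trait/marker pair that passed eligibility and median-QTL filters.
#'
#' @param df data frame with (a subset of) columns `scan_type`, `stratum`,
#'   `trait_id`, `marker_id`, `chrom`, `pos`, `statistic`, `nominal_p`,
#'   `cis_flag`; missing columns are filled with NA.
#' @return data frame of class `robust_hits` with canonical column order.
#' @export
robust_hits <- function(df = NULL) {
  if (is.null(df)) df <- data.frame()
  for (col in .hit_cols)
    if (!col %in% names(df))
      df[[col]] <- if (nrow(df)) NA else
        vector(if (col %in% c("pos", "statistic", "nominal_p"))
                 "numeric" else "character", 0L)
  df <- df[c(.hit_cols, setdiff(names(df), .hit_cols))]
  if (nrow(df)) {
    p <- df$nominal_p
    if (any(!is.na(p) & (p < 0 | p > 1)))
      stop("nominal_p must lie in [0, 1]")
    df$cis_flag[is.na(df$cis_flag)] <- "unknown"
  }
  class(df) <- c("robust_hits", "data.frame")
  df
}

#' @export
print.robust_hits <- function(x, n = 10L, ...) {
  cat(sprintf("robust_hits: %d tested pair(s)", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" [%s]", paste(unique(x$scan_type), collapse = ", ")))
    cat("\n")
    print.data.frame(utils::head(as.data.frame(x), n))
    if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  } else cat("\n")
  invisible(x)
}

#' Summarise a hit table
#'
#' Counts tested pairs, traits and markers per scan type and stratum, and
#' the number of non-redundant markers hit (markers with identical genotype
#' vectors collapsed to one representative) when a genotype panel is given.
#'
#' @param object a `robust_hits` table.
#' @param genotypes optional `genotype_panel` for non-redundant counting.
#' @param ... unused.
#' @export
summary.robust_hits <- function(object, genotypes = NULL, ...) {
  if (!nrow(object)) {
    cat("empty hit table\n")
    return(invisible(NULL))
  }
  key <- interaction(object$scan_type, object$stratum, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(object)), key), function(i) {
    h <- object[i, ]
    nr <- if (!is.null(genotypes))
      length(unique(.marker_signature(genotypes)[h$marker_id])) else NA_integer_
    data.frame(scan_type = h$scan_type[1], stratum = h$stratum[1],
               pairs = nrow(h),
               traits = length(unique(h$trait_id)),
               markers = length(unique(h$marker_id)),
               nonredundant_markers = nr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# genotype-vector fingerprint used for non-redundant marker counting
.marker_signature <- function(panel) {
  sig <- apply(panel$calls, 2, paste, collapse = "/")
  stats::setNames(match(sig, unique(sig)), colnames(panel$calls))
}

#' Write a hit table
#'
#' Deterministic output: canonical column order, rows sorted by
#' `(scan_type, trait_id, chrom, pos)`, so repeated runs are byte-stable.
#'
#' @param hits a `robust_hits` table.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  hits <- robust_hits(as.data.frame(hits))
  if (nrow(hits)) {
    if (any(hits$cis_flag != "unknown" & is.na(hits$chrom)))
      warning("hits with cis_flag but no mapped position written as unknown")
    ord <- order(hits$scan_type, hits$trait_id, hits$chrom, hits$pos,
                 hits$marker_id)
    hits <- hits[ord, ]
  }
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a written hit table
#' @param path file written by [write_hits()].
#' @return a `robust_hits` table.
#' @export
read_hits <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  for (col in c("pos", "statistic", "nominal_p"))
    df[[col]] <- as.numeric(df[[col]])
  robust_hits(df)
}
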