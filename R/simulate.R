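#' Simulation configuration
#'
#' Generative parameters for synthetic strain panels with planted
#' robustness effects.  Defaults reproduce the mouse-like study design:
#' 182 individuals from 19 strains, 91 individuals in each of two marker
#' genotype classes; baseline individuals drawn Normal(0, 1); an ER effect
#' raises the affected class's sigma to 1.5; a GR effect moves the affected
#' class's strain means to +2 for half of its strains and -2 for the other
#' half (so the class medians are bimodal while the class-level median
#' matches the baseline); a combined ER+GR effect applies both.
#'
#' Strains are split into genotype classes first (the affected class gets
#' `ceiling(n_strains / 2)` strains, 10 of 19 by default) and each class's
#' individuals are then balanced round-robin across its strains; balancing
#' across all strains before splitting cannot give 91 individuals per
#' class with 19 strains.
#'
#' @param n_strains number of inbred strains.
#' @param n_individuals total individuals (split as evenly as possible
#'   between the two genotype classes).
#' @param base_sigma within-strain SD of the baseline class.
#' @param er_sigma within-strain SD of the affected class under an ER
#'   effect.
#' @param gr_shift magnitude of the strain-level mean shift under a GR
#'   effect (+shift for the first half of affected strains, -shift for the
#'   rest; assignment is deterministic given the seed).
#' @param n_traits number of traits to generate.
#' @param scenario one of `"NULL"`, `"ER"`, `"GR"`, `"ERGR"`.
#' @param regenerate replace (rather than drop) traits discarded by the
#'   median-association filter, keeping class sizes exact.
#' @param seed mandatory integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 19L, n_individuals = 182L,
                       base_sigma = 1, er_sigma = 1.5, gr_shift = 2,
                       n_traits = 100L,
                       scenario = c("NULL", "ER", "GR", "ERGR"),
                       regenerate = TRUE, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_strains >= 4, n_individuals >= 2 * n_strains,
            base_sigma > 0, er_sigma > 0, gr_shift >= 0, n_traits >= 1)
  structure(list(n_strains = as.integer(n_strains),
                 n_individuals = as.integer(n_individuals),
                 base_sigma = base_sigma, er_sigma = er_sigma,
                 gr_shift = gr_shift, n_traits = as.integer(n_traits),
                 scenario = scenario, regenerate = isTRUE(regenerate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# strain / individual / genotype layout implied by a sim_config.
# Affected class = genotype 1 (the wider class), ceiling(n/2) strains.
.sim_layout <- function(cfg) {
  ns <- cfg$n_strains
  strains <- sprintf("S%02d", seq_len(ns))
  n_aff <- ceiling(ns / 2)
  class_of <- stats::setNames(c(rep(1L, n_aff), rep(0L, ns - n_aff)),
                              strains)
  per_class <- c(floor(cfg$n_individuals / 2), ceiling(cfg$n_individuals / 2))
  # individuals: class 1 gets per_class[2] (the larger share when odd)
  alloc <- function(cls, n_ind) {
    s <- strains[class_of == cls]
    base <- rep(floor(n_ind / length(s)), length(s))
    extra <- n_ind - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    rep(s, base)
  }
  strain_of_ind <- c(alloc(1L, per_class[2]), alloc(0L, per_class[1]))
  # GR sign: first half of affected strains +1, rest -1
  aff <- strains[class_of == 1L]
  sign_of <- stats::setNames(rep(NA_real_, ns), strains)
  sign_of[aff] <- rep(c(1, -1), c(ceiling(length(aff) / 2),
                                  floor(length(aff) / 2)))
  list(strains = strains, class_of = class_of,
       strain_of_ind = strain_of_ind,
       class_of_ind = class_of[strain_of_ind],
       sign_of = sign_of,
       strain_rows = split(seq_along(strain_of_ind), strain_of_ind))
}

# per-individual mean / sd vectors for a scenario
.sim_moments <- function(cfg, layout, scenario = cfg$scenario) {
  n <- length(layout$strain_of_ind)
  mu <- rep(0, n); sdv <- rep(cfg$base_sigma, n)
  aff <- layout$class_of_ind == 1L
  if (scenario %in% c("ER", "ERGR")) sdv[aff] <- cfg$er_sigma
  if (scenario %in% c("GR", "ERGR"))
    mu[aff] <- cfg$gr_shift * layout$sign_of[layout$strain_of_ind[aff]]
  list(mu = mu, sd = sdv)
}

# draw an individuals x m trait matrix for a scenario
.sim_traits <- function(cfg, layout, m, scenario = cfg$scenario) {
  mo <- .sim_moments(cfg, layout, scenario)
  n <- length(mo$mu)
  matrix(stats::rnorm(n * m), n, m) * mo$sd + mo$mu
}

# per-strain medians and SDs of a trait matrix (rows grouped by layout)
.strain_stats <- function(X, layout) {
  strains <- layout$strains
  m <- ncol(X)
  med <- sds <- matrix(NA_real_, length(strains), m,
                       dimnames = list(strains, colnames(X)))
  for (i in seq_along(strains)) {
    idx <- layout$strain_rows[[strains[i]]]
    Xi <- X[idx, , drop = FALSE]
    med[i, ] <- apply(Xi, 2, stats::median)
    n <- length(idx)
    mu <- colMeans(Xi)
    sds[i, ] <- sqrt(pmax(colSums(Xi^2) - n * mu^2, 0) / (n - 1))
  }
  list(medians = med, sds = sds)
}

# two-sided p of the median-genotype correlation for every trait column
.median_filter_p <- function(med, layout) {
  cls <- layout$class_of[rownames(med)]
  r <- suppressWarnings(as.vector(stats::cor(med, cls)))
  .cor_t_p(r, rep(nrow(med), ncol(med)))
}

#' Simulate a strain panel with planted robustness effects
#'
#' Generates a replicated inbred-strain phenotype panel plus a one-marker
#' genotype panel according to a [sim_config()] scenario, applying the
#' same median-association filter used by the scans: traits whose strain
#' medians correlate with genotype at nominal p < 0.01 are discarded (and,
#' by default, regenerated so class sizes stay exact); the discard count
#' is reported.
#'
#' @param cfg a [sim_config()].
#' @param n_null_markers additional unplanted markers with random balanced
#'   genotype splits (default 0).
#' @return list with `pheno` (a `phenotype_panel`), `geno` (a
#'   `genotype_panel`; the planted marker is `"M1"`), `truth` (data frame:
#'   trait, scenario, planted marker), `n_discarded` and `layout`.
#' @export
simulate_panel <- function(cfg, n_null_markers = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  layout <- .sim_layout(cfg)
  .with_seed(cfg$seed, {
    m <- cfg$n_traits
    X <- .sim_traits(cfg, layout, m)
    colnames(X) <- sprintf("T%05d", seq_len(m))
    n_disc <- 0L
    for (round in seq_len(100L)) {
      p <- .median_filter_p(.strain_stats(X, layout)$medians, layout)
      bad <- which(!is.na(p) & p < 0.01)
      if (!length(bad)) break
      n_disc <- n_disc + length(bad)
      if (!cfg$regenerate) {
        X <- X[, -bad, drop = FALSE]
        break
      }
      X[, bad] <- .sim_traits(cfg, layout, length(bad))
    }
    samples <- data.frame(
      sample_id = sprintf("ind%03d", seq_along(layout$strain_of_ind)),
      strain = layout$strain_of_ind, stringsAsFactors = FALSE)
    calls <- matrix(layout$class_of, ncol = 1,
                    dimnames = list(layout$strains, "M1"))
    if (n_null_markers > 0) {
      ns <- length(layout$strains)
      nm <- vapply(seq_len(n_null_markers), function(j) {
        g <- integer(ns)
        g[sample(ns, floor(ns / 2))] <- 1L
        g
      }, integer(ns))
      colnames(nm) <- sprintf("N%03d", seq_len(n_null_markers))
      calls <- cbind(calls, nm)
    }
    rownames(X) <- samples$sample_id
    list(pheno = phenotype_panel(samples, X),
         geno = genotype_panel(calls),
         truth = data.frame(trait_id = colnames(X),
                            scenario = cfg$scenario,
                            marker_id = "M1", stringsAsFactors = FALSE),
         n_discarded = n_disc, layout = layout)
  })
}

# fast per-class detection machinery used by the interference study:
# generates traits in chunks, applies the median filter with regeneration,
# and accumulates ER (|r| >= cutoffs) and GR (d >= cutoffs) detections.
.detection_rates <- function(cfg, scenario, n_traits, er_thresholds,
                             gr_thresholds, need_er, need_gr, chunk = 4000L) {
  layout <- .sim_layout(cfg)
  cls <- layout$class_of[layout$strains]
  i0 <- which(cls == 0L); i1 <- which(cls == 1L)
  er_hits <- numeric(length(er_thresholds))
  gr_hits <- numeric(length(gr_thresholds))
  done <- 0L
  while (done < n_traits) {
    m <- min(chunk, n_traits - done)
    X <- .sim_traits(cfg, layout, m, scenario)
    st <- .strain_stats(X, layout)
    for (round in seq_len(100L)) {
      p <- .median_filter_p(st$medians, layout)
      bad <- which(!is.na(p) & p < 0.01)
      if (!length(bad)) break
      Xb <- .sim_traits(cfg, layout, length(bad), scenario)
      X[, bad] <- Xb
      stb <- .strain_stats(Xb, layout)
      st$medians[, bad] <- stb$medians
      st$sds[, bad] <- stb$sds
    }
    if (need_er) {
      r <- abs(as.vector(stats::cor(st$sds, cls)))
      for (t in seq_along(er_thresholds))
        er_hits[t] <- er_hits[t] + sum(r >= er_thresholds[t])
    }
    if (need_gr) {
      d <- vapply(seq_len(m), function(j)
        .fk_d2(st$medians[i0, j], st$medians[i1, j])[["d"]], numeric(1))
      for (t in seq_along(gr_thresholds))
        gr_hits[t] <- gr_hits[t] + sum(d >= gr_thresholds[t])
    }
    done <- done + m
  }
  list(er_rate = er_hits / n_traits, gr_rate = gr_hits / n_traits,
       n = n_traits)
}

#' Interference-ratio study
#'
#' Measures whether the presence of a GR effect interferes with detecting
#' an ER effect (and vice versa).  Three trait classes are simulated --
#' ER-only, GR-only, and combined ER+GR -- and each mapping method's
#' detection rate is evaluated over a ladder of thresholds: correlation
#' cutoffs r = 0.20 to 0.65 (step 0.05) for ER mapping and chi-squared
#' cutoffs 2 to 11 (step 1) for GR mapping.  At each cutoff the ratio of
#' the single-effect detection rate to the combined-effect detection rate
#' is reported; ratios near one at every threshold mean the two effect
#' types do not mask each other, i.e. joint ER+GR QTL are detectable by
#' both scans when they exist.
#'
#' @param n_traits traits per class (>= 10,000 recommended for stable
#'   ratios).
#' @param cfg a [sim_config()] providing panel geometry and effect sizes
#'   (its `scenario` and `n_traits` fields are ignored).
#' @param er_thresholds,gr_thresholds the cutoff ladders.
#' @param seed integer seed.
#' @return object of class `interference_study`: data frames `er` and
#'   `gr` with per-threshold detection rates of each class, the ratio and
#'   a normal-approximation 95% Monte-Carlo CI on it, plus `max_er_ratio`
#'   / `max_gr_ratio`.
#' @export
interference_ratio_study <- function(n_traits = 30000L,
                                     cfg = sim_config(n_traits = 1, seed = 1),
                                     er_thresholds = seq(0.20, 0.65, 0.05),
                                     gr_thresholds = 2:11,
                                     seed = 1L) {
  res <- list(
    ER = .with_seed(.child_seed(seed, 1),
      .detection_rates(cfg, "ER", n_traits, er_thresholds, gr_thresholds,
                       need_er = TRUE, need_gr = FALSE)),
    GR = .with_seed(.child_seed(seed, 2),
      .detection_rates(cfg, "GR", n_traits, er_thresholds, gr_thresholds,
                       need_er = FALSE, need_gr = TRUE)),
    ERGR = .with_seed(.child_seed(seed, 3),
      .detection_rates(cfg, "ERGR", n_traits, er_thresholds, gr_thresholds,
                       need_er = TRUE, need_gr = TRUE)))
  ratio_tab <- function(thresholds, single, combined, n) {
    ratio <- ifelse(combined > 0, single / combined, NA_real_)
    # delta-method MC standard error of the rate ratio
    se <- sqrt(ifelse(single > 0, (1 - single) / (single * n), NA_real_) +
                 ifelse(combined > 0, (1 - combined) / (combined * n),
                        NA_real_))
    data.frame(threshold = thresholds, rate_single = single,
               rate_combined = combined, ratio = ratio,
               ci_lo = ratio * exp(-1.96 * se),
               ci_hi = ratio * exp(1.96 * se))
  }
  er <- ratio_tab(er_thresholds, res$ER$er_rate, res$ERGR$er_rate, n_traits)
  gr <- ratio_tab(gr_thresholds, res$GR$gr_rate, res$ERGR$gr_rate, n_traits)
  structure(list(er = er, gr = gr,
                 max_er_ratio = max(er$ratio, na.rm = TRUE),
                 max_gr_ratio = max(gr$ratio, na.rm = TRUE),
                 n_traits = n_traits, seed = seed),
            class = "interference_study")
}

#' @export
print.interference_study <- function(x, ...) {
  cat(sprintf("interference-ratio study (%d traits/class)\n", x$n_traits))
  cat(sprintf("  ER side: ratios %.3f..%.3f (max %.3f)\n",
              min(x$er$ratio, na.rm = TRUE), max(x$er$ratio, na.rm = TRUE),
              x$max_er_ratio))
  cat(sprintf("  GR side: ratios %.3f..%.3f (max %.3f)\n",
              min(x$gr$ratio, na.rm = TRUE), max(x$gr$ratio, na.rm = TRUE),
              x$max_gr_ratio))
  invisible(x)
}

#' Mean-QTL masquerade simulation
#'
#' A mean-effect ("typical") QTL could mimic a GR QTL if the causal allele
#' were present in about half of the high-dispersion genotype class's
#' strains but absent from the other class: the class carrying it would
#' show extra spread of strain medians.  This simulation plants exactly
#' that scenario over a grid of mean shifts and measures, per shift, how
#' often the median-association filter catches the pair (nominal p < 0.01
#' on the median/genotype correlation) versus how often the FK dispersion
#' test would flag it at the GR hit level.  When the carrier split is
#' asymmetric the mean effect is detected far more easily than its side
#' effect on dispersion, which is why the p < 0.01 exclusion keeps
#' ordinary QTL out of the GR scan; see `causal_freq` for the degenerate
#' even-split geometry where no marginal mean test can.
#'
#' @param shifts numeric grid of mean shifts (in units of the base sigma).
#' @param n_sims simulated traits per shift.
#' @param cfg a [sim_config()] for panel geometry.
#' @param causal_freq fraction of affected-class strains carrying the
#'   hidden causal allele (default 0.5).  Note the degenerate geometry at
#'   an exactly even split of an even-sized class: the carriers' shift then
#'   produces a symmetric bimodal spread of strain medians whose
#'   association with the class genotype saturates just above p = 0.01, so
#'   the filter cannot catch it -- at that knife edge the configuration is
#'   a true dispersion difference at the scanned marker and no marginal
#'   mean test can distinguish it from genuine genetic-robustness
#'   variation.  Any asymmetric carrier split restores the filter's
#'   dominance.
#' @param alpha nominal level of the median filter.
#' @param fk_alpha nominal chi-squared level at which the FK test counts
#'   as flagging the pair (the GR-scan hit level).
#' @param seed integer seed.
#' @return data frame with per-shift detection rates
#'   `median_filter_rate` and `fk_rate`.
#' @export
simulate_mean_masquerade <- function(shifts = c(0, 0.5, 1, 1.5, 2, 3),
                                     n_sims = 500L,
                                     cfg = sim_config(n_traits = 1, seed = 1),
                                     causal_freq = 0.5, alpha = 0.01,
                                     fk_alpha = 1e-3, seed = 1L) {
  layout <- .sim_layout(cfg)
  cls <- layout$class_of[layout$strains]
  aff <- names(cls)[cls == 1L]
  carriers <- aff[seq_len(round(causal_freq * length(aff)))]
  i0 <- which(cls == 0L); i1 <- which(cls == 1L)
  mu_strain <- stats::setNames(rep(0, length(cls)), names(cls))
  out <- lapply(seq_along(shifts), function(si) {
    mu_strain[carriers] <- shifts[si] * cfg$base_sigma
    mu <- mu_strain[layout$strain_of_ind]
    .with_seed(.child_seed(seed, si), {
      med_hit <- fk_hit <- logical(n_sims)
      for (s in seq_len(n_sims)) {
        x <- stats::rnorm(length(mu), mu, cfg$base_sigma)
        st <- .strain_stats(matrix(x, ncol = 1), layout)
        p_med <- .median_filter_p(st$medians, layout)
        med_hit[s] <- !is.na(p_med) && p_med < alpha
        fk_hit[s] <- .fk_d2(st$medians[i0, 1],
                            st$medians[i1, 1])[["p"]] <= fk_alpha
      }
      data.frame(shift = shifts[si],
                 median_filter_rate = mean(med_hit),
                 fk_rate = mean(fk_hit), n = n_sims)
    })
  })
  do.call(rbind, out)
}

#' Write a miniature end-to-end study fixture to disk
#'
#' Produces a complete small study: a phenotype panel mixing null traits
#' with planted ER, GR and ER+GR traits; a multi-marker genotype panel
#' (the planted marker, optional duplicated-genotype markers exercising
#' non-redundant counting, and random null markers); marker and feature
#' maps over several chromosomes, with planted "cis" traits placed within
#' the cis window of their marker; and a truth table in JSON.  The same
#' seed yields byte-identical files.
#'
#' @param dir output directory (created; must not already contain fixture
#'   files).
#' @param cfg a [sim_config()]; its `n_traits` is used per planted class.
#' @param n_null_traits additional unplanted traits.
#' @param n_null_markers random markers beyond the planted one.
#' @param n_redundant duplicated copies of the planted marker.
#' @param cis_fraction fraction of planted traits whose feature is placed
#'   within 5 Mb of the planted marker.
#' @return invisible named vector of the file paths written.
#' @export
make_fixture <- function(dir, cfg = sim_config(n_traits = 5, seed = 1),
                         n_null_traits = 10L, n_null_markers = 6L,
                         n_redundant = 1L, cis_fraction = 0.4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pheno = file.path(dir, "phenotypes.tsv"),
             geno = file.path(dir, "genotypes.tsv"),
             markers = file.path(dir, "markers.tsv"),
             features = file.path(dir, "features.tsv"),
             truth = file.path(dir, "truth.json"))
  if (any(file.exists(paths)))
    stop("fixture files already exist in ", dir)
  scen <- c("ER", "GR", "ERGR")
  panels <- lapply(seq_along(scen), function(i) {
    ci <- cfg; ci$scenario <- scen[i]; ci$seed <- cfg$seed + i
    simulate_panel(ci)
  })
  null_cfg <- cfg; null_cfg$scenario <- "NULL"
  null_cfg$n_traits <- as.integer(n_null_traits)
  null_cfg$seed <- cfg$seed + 17L
  null_panel <- simulate_panel(null_cfg, n_null_markers = n_null_markers)
  layout <- null_panel$layout
  traits <- do.call(cbind, c(lapply(seq_along(panels), function(i) {
    m <- panels[[i]]$pheno$traits
    colnames(m) <- sprintf("%s_%02d", tolower(scen[i]), seq_len(ncol(m)))
    m
  }), list(local({
    m <- null_panel$pheno$traits
    colnames(m) <- sprintf("null_%02d", seq_len(ncol(m)))
    m
  }))))
  samples <- null_panel$pheno$samples
  if (!"sex" %in% names(samples)) {
    # deterministic alternating sex labels within each strain
    sex <- character(nrow(samples))
    for (s in unique(samples$strain)) {
      i <- which(samples$strain == s)
      sex[i] <- rep_len(c("F", "M"), length(i))
    }
    samples$sex <- sex
  }
  pheno <- phenotype_panel(samples, traits)
  calls <- null_panel$geno$calls
  if (n_redundant > 0) {
    dup <- calls[, rep("M1", n_redundant), drop = FALSE]
    colnames(dup) <- sprintf("M1dup%d", seq_len(n_redundant))
    calls <- cbind(calls, dup)
  }
  geno <- genotype_panel(calls)
  # maps: markers spread over 4 chromosomes; planted marker on chr1 at 50Mb
  mk_ids <- colnames(calls)
  mk_map <- genome_map(data.frame(
    id = mk_ids,
    chrom = paste0("chr", rep_len(1:4, length(mk_ids))),
    pos = 5e7 + 1e6 * seq_along(mk_ids), stringsAsFactors = FALSE))
  mk_map$chrom[mk_map$id == "M1"] <- "chr1"
  mk_map$pos[mk_map$id == "M1"] <- 5e7
  mk_map$chrom[grepl("^M1dup", mk_map$id)] <- "chr1"
  m1_pos <- 5e7
  planted <- colnames(traits)[!grepl("^null_", colnames(traits))]
  n_cis <- round(cis_fraction * length(planted))
  cis_traits <- planted[seq_len(n_cis)]
  # cis features sit within +-2 Mb of the planted marker (inside the 5 Mb
  # window); all others live far away on other chromosomes
  cis_offset <- (match(colnames(traits), cis_traits) - 1) %% 5 - 2
  ft_map <- genome_map(data.frame(
    id = colnames(traits),
    chrom = ifelse(colnames(traits) %in% cis_traits, "chr1",
                   paste0("chr", 2 + (seq_along(colnames(traits)) %% 3))),
    pos = ifelse(colnames(traits) %in% cis_traits,
                 m1_pos + 1e6 * cis_offset,
                 2e8 + 1e6 * seq_along(colnames(traits))),
    stringsAsFactors = FALSE))
  write_phenotype_panel(pheno, paths["pheno"])
  write_genotype_panel(geno, paths["geno"])
  utils::write.table(as.data.frame(mk_map), paths["markers"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(ft_map), paths["features"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    planted_marker = "M1",
    traits = data.frame(
      trait_id = colnames(traits),
      scenario = sub("_.*$", "", toupper(colnames(traits))),
      cis = colnames(traits) %in% cis_traits, stringsAsFactors = FALSE),
    seed = cfg$seed)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
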