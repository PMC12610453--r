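#' Planted differential-expression effect
#'
#' @param assay_id target assay carrying the effect.
#' @param contrast `"cancer_vs_healthy"` or `"pole_vs_wildtype"`.
#' @param log2_effect planted log2 fold regulation; positive means
#'   up-regulated in the first-named group (cancer, or POLE-mutant).
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(assay_id, contrast = c("cancer_vs_healthy",
                                               "pole_vs_wildtype"),
                        log2_effect) {
  contrast <- match.arg(contrast)
  stopifnot(is.character(assay_id), length(assay_id) == 1L,
            is.numeric(log2_effect), length(log2_effect) == 1L,
            is.finite(log2_effect))
  structure(list(assay_id = assay_id, contrast = contrast,
                 log2_effect = log2_effect), class = "effect_spec")
}

#' Simulation configuration
#'
#' The defaults are the study design: 40 cancer and 20 healthy samples
#' (7 of the cancer samples POLE-mutant), 84 target assays with ΔCt
#' dispersion SD 1.8, three low-variance housekeeping references near
#' Ct 20, and per-assay baseline ΔCt drawn inside a LOD-safe range so
#' default panels have 0% missingness.
#'
#' @param n_cancer,n_healthy group sizes (default 40 / 20).
#' @param n_pole_mutant POLE-mutant tumors, subset of cancer (default 7).
#' @param n_target_assays number of target assays (default 84).
#' @param dct_sd additive Gaussian ΔCt dispersion in cycles (= log2 units;
#'   default 1.8, the study's representative dispersion).
#' @param hk_mean_ct mean housekeeping Ct in cycles (default 20).
#' @param hk_sd housekeeping Ct dispersion (default 0.25; stably expressed).
#' @param baseline_dct_range range the per-assay baseline ΔCt is drawn
#'   from, cycles (default c(0, 8): with housekeeping near 20 all target
#'   Ct stay clear of the LOD at 35).
#' @param effects list of [effect_spec()] (default none).
#' @param confound_bmi strength of a planted BMI confounder: 0 (default)
#'   simulates covariates independent of ΔCt; positive values shift BMI by
#'   group and add `confound_bmi * centered BMI` cycles to effect-bearing
#'   assays, making covariate adjustment falsifiable.
#' @param seed integer seed; a fixed seed makes the panel bit-reproducible.
#' @param layout optional `panel_layout`; default is
#'   [default_panel_layout()] with `n_target_assays` targets.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cancer = 40, n_healthy = 20, n_pole_mutant = 7,
                       n_target_assays = 84, dct_sd = 1.8,
                       hk_mean_ct = 20, hk_sd = 0.25,
                       baseline_dct_range = c(0, 8),
                       effects = list(), confound_bmi = 0,
                       seed = 1L, layout = NULL) {
  stopifnot(n_cancer >= 2, n_healthy >= 2,
            n_pole_mutant >= 0, n_pole_mutant <= n_cancer,
            dct_sd > 0, hk_sd > 0,
            length(baseline_dct_range) == 2L,
            baseline_dct_range[1] <= baseline_dct_range[2])
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, logical(1), "effect_spec")))
  if (is.null(layout)) layout <- default_panel_layout(n_target_assays)
  structure(
    list(n_cancer = n_cancer, n_healthy = n_healthy,
         n_pole_mutant = n_pole_mutant, n_target_assays = n_target_assays,
         dct_sd = dct_sd, hk_mean_ct = hk_mean_ct, hk_sd = hk_sd,
         baseline_dct_range = baseline_dct_range, effects = effects,
         confound_bmi = confound_bmi, seed = as.integer(seed),
         layout = layout),
    class = "sim_config"
  )
}

#' Study-shaped default simulation configuration
#'
#' 60 samples (40 cancer of which 7 POLE-mutant, 20 healthy), 84 target
#' assays, 3 housekeeping references, ΔCt SD 1.8, LOD-safe baselines
#' (0% missingness), no planted effects.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_study_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

#' Simulate a Ct panel and its sample metadata
#'
#' Target-assay ΔCt values are drawn Gaussian about per-assay baselines
#' with dispersion `dct_sd`; for each planted effect the first-named
#' group's mean ΔCt is shifted by `-log2_effect`, so the recovered log2
#' fold regulation (−ΔΔCt) matches the planted sign. Housekeeping assays
#' are generated with low variance, and Ct is reconstructed as
#' ΔCt + per-sample housekeeping mean. POLE effects apply only within
#' cancer samples. Covariates (age, BMI, grade) are drawn independently
#' of expression unless `confound_bmi > 0`.
#'
#' @param config a [sim_config()].
#' @return list with elements `ct` (a [ct_table()]) and `meta`
#'   (a [sample_meta()] data.frame).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  targets <- assays_by_role(layout, "target")
  hks <- assays_by_role(layout, "housekeeping")
  ctrls <- assays_by_role(layout, "control")
  for (ef in config$effects)
    if (!ef$assay_id %in% targets)
      stop("effect references unknown target assay: ", ef$assay_id)

  set.seed(config$seed)
  n_c <- config$n_cancer; n_h <- config$n_healthy
  n <- n_c + n_h
  sample_ids <- c(sprintf("EC%02d", seq_len(n_c)),
                  sprintf("HC%02d", seq_len(n_h)))
  group <- c(rep("cancer", n_c), rep("healthy", n_h))
  pole <- c(rep("mutant", config$n_pole_mutant),
            rep("wildtype", n_c - config$n_pole_mutant),
            rep("not_applicable", n_h))

  # covariates; grade is assigned to every sample so the covariate model
  # is estimable on synthetic panels (see vignette)
  age <- round(stats::rnorm(n, mean = ifelse(group == "cancer", 63, 58),
                            sd = 8))
  age <- pmin(pmax(age, 35), 90)
  bmi <- round(stats::rnorm(n, mean = 29, sd = 5), 1)
  bmi <- pmin(pmax(bmi, 17), 55)
  if (config$confound_bmi > 0)
    bmi <- bmi + ifelse(group == "cancer", 4, 0)
  grade <- sample(c("G1", "G2", "G3"), n, replace = TRUE,
                  prob = c(0.3, 0.4, 0.3))

  baseline <- stats::runif(length(targets), config$baseline_dct_range[1],
                           config$baseline_dct_range[2])
  names(baseline) <- targets

  dct <- matrix(stats::rnorm(n * length(targets), sd = config$dct_sd),
                n, length(targets),
                dimnames = list(sample_ids, targets))
  dct <- sweep(dct, 2L, -baseline)   # add baseline per assay

  for (ef in config$effects) {
    shifted <- if (ef$contrast == "cancer_vs_healthy")
      group == "cancer" else pole == "mutant"
    dct[shifted, ef$assay_id] <- dct[shifted, ef$assay_id] - ef$log2_effect
  }
  if (config$confound_bmi > 0) {
    # BMI pushes expression in the direction of each planted effect, so the
    # unadjusted group estimate is inflated and adjustment attenuates it
    bmi_c <- bmi - mean(bmi)
    for (ef in config$effects)
      dct[, ef$assay_id] <- dct[, ef$assay_id] -
        config$confound_bmi * bmi_c * sign(ef$log2_effect)
  }

  hk_ct <- matrix(stats::rnorm(n * length(hks), mean = config$hk_mean_ct,
                               sd = config$hk_sd),
                  n, length(hks), dimnames = list(sample_ids, hks))
  hk_mean <- rowMeans(hk_ct)
  target_ct <- dct + hk_mean
  ctrl_ct <- matrix(stats::rnorm(n * length(ctrls), mean = 25, sd = 1),
                    n, length(ctrls), dimnames = list(sample_ids, ctrls))

  ct <- cbind(target_ct, hk_ct, ctrl_ct)[, layout$assay_ids, drop = FALSE]
  meta <- sample_meta(data.frame(
    sample_id = sample_ids, group = group, pole_status = pole,
    age = age, bmi = bmi, grade = grade, stringsAsFactors = FALSE))
  list(ct = ct_table(ct, layout), meta = meta)
}

#' Fixture generator: validated miRNA-to-gene interaction snapshot
#'
#' Emits a small synthetic interaction table in the snapshot format
#' [load_interactions()] reads. Each miRNA targets a random subset of the
#' gene pool; a fraction of rows are duplicated across sources and a
#' fraction carry non-functional support labels so the filters are
#' exercised.
#'
#' @param mirnas character vector of miRNA names.
#' @param genes character vector of gene symbols (the pool).
#' @param mean_targets expected targets per miRNA.
#' @param weak_frac fraction of rows labelled "Functional MTI (Weak)".
#' @param seed integer seed.
#' @return data.frame with columns mirna, gene_symbol, support_type, source.
#' @export
simulate_interactions <- function(mirnas, genes, mean_targets = 8,
                                  weak_frac = 0.2, seed = 1L) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(mirnas, function(m) {
    k <- max(1L, stats::rpois(1L, mean_targets))
    g <- sample(genes, min(k, length(genes)))
    data.frame(mirna = m, gene_symbol = g, stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  rows$support_type <- ifelse(stats::runif(n) < weak_frac,
                              "Functional MTI (Weak)", "Functional MTI")
  rows$source <- sample(c("mirtarbase", "tarbase"), n, replace = TRUE)
  # duplicate a few pairs under the other source to exercise dedup
  dup <- rows[sample(n, max(1L, n %/% 10L)), ]
  dup$source <- ifelse(dup$source == "mirtarbase", "tarbase", "mirtarbase")
  rbind(rows, dup)
}

#' Fixture generator: gene-to-term mapping
#'
#' @param genes gene symbols to distribute over terms.
#' @param n_terms number of terms.
#' @param mean_size expected genes per term.
#' @param seed integer seed.
#' @return data.frame with columns term_id, term_name, gene_symbol.
#' @export
simulate_term_map <- function(genes, n_terms = 15, mean_size = 10,
                              seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_terms), function(i) {
    k <- max(2L, stats::rpois(1L, mean_size))
    data.frame(term_id = sprintf("TERM:%04d", i),
               term_name = sprintf("synthetic process %d", i),
               gene_symbol = sample(genes, min(k, length(genes))),
               stringsAsFactors = FALSE)
  }))
}

#' Fixture generator: external (sequencing-derived) DE table
#'
#' Builds a synthetic stand-in for an external differential-expression
#' table with a configurable sign-agreement rate against a panel DE table.
#'
#' @param panel_de a DE table from [run_contrast()].
#' @param agree_frac fraction of matched miRNAs whose external log2FC sign
#'   agrees with the panel sign (default 0.75).
#' @param extra_mirnas names present only in the external table.
#' @param seed integer seed.
#' @return data.frame with columns mirna, log2fc, fdr.
#' @export
simulate_external_de <- function(panel_de, agree_frac = 0.75,
                                 extra_mirnas = character(0), seed = 1L) {
  set.seed(seed)
  panel_de <- panel_de[is.finite(panel_de$log2_fold_reg), , drop = FALSE]
  sgn <- sign(panel_de$log2_fold_reg)
  sgn[sgn == 0] <- 1
  flip <- stats::runif(nrow(panel_de)) >= agree_frac
  mag <- abs(stats::rnorm(nrow(panel_de), mean = 2, sd = 1)) + 0.1
  ext <- data.frame(
    mirna = panel_de$mirna,
    log2fc = ifelse(flip, -sgn, sgn) * mag,
    fdr = stats::runif(nrow(panel_de)),
    stringsAsFactors = FALSE)
  if (length(extra_mirnas))
    ext <- rbind(ext, data.frame(
      mirna = extra_mirnas,
      log2fc = stats::rnorm(length(extra_mirnas)),
      fdr = stats::runif(length(extra_mirnas)),
      stringsAsFactors = FALSE))
  ext
}
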