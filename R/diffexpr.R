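#' ΔCt normalization against housekeeping references
#'
#' For each sample, ΔCt of a target assay is its Ct minus the arithmetic
#' mean Ct of the detected housekeeping references in that sample;
#' relative expression is 2^-ΔCt. Housekeeping and control assays are
#' excluded from the result. Undetected target cells propagate as NA.
#'
#' @param ct a [ct_table()].
#' @return object of class `dct_table`: `sample_ids`, `target_assay_ids`,
#'   matrices `dct` and `rel_expr` (samples x targets).
#' @export
normalize_delta_ct <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  layout <- ct$layout
  hks <- assays_by_role(layout, "housekeeping")
  targets <- assays_by_role(layout, "target")
  if (length(hks) == 0L) stop("layout has no housekeeping assays")
  hk_ct <- ct$ct[, hks, drop = FALSE]
  hk_ct[!ct$detected[, hks, drop = FALSE]] <- NA
  n_hk <- rowSums(!is.na(hk_ct))
  if (any(n_hk == 0L))
    stop("no detected housekeeping assay in sample(s): ",
         paste(ct$sample_ids[n_hk == 0L], collapse = ", "))
  hk_mean <- rowMeans(hk_ct, na.rm = TRUE)
  tct <- ct$ct[, targets, drop = FALSE]
  tct[!ct$detected[, targets, drop = FALSE]] <- NA
  dct <- tct - hk_mean
  structure(
    list(sample_ids = ct$sample_ids, target_assay_ids = targets,
         dct = dct, rel_expr = 2^(-dct)),
    class = "dct_table"
  )
}

#' @export
print.dct_table <- function(x, ...) {
  cat("dct_table:", length(x$sample_ids), "samples x",
      length(x$target_assay_ids), "target assays\n")
  invisible(x)
}

#' Two-group contrast definition
#'
#' Group A is the reported-up direction: positive log2 fold regulation
#' means higher expression in A.
#'
#' @param name contrast label.
#' @param group_a_ids,group_b_ids disjoint, non-empty sample-id sets with
#'   at least 2 samples each.
#' @return list of class `de_contrast`.
#' @export
contrast <- function(name, group_a_ids, group_b_ids) {
  group_a_ids <- as.character(group_a_ids)
  group_b_ids <- as.character(group_b_ids)
  if (length(group_a_ids) < 2L || length(group_b_ids) < 2L)
    stop("each contrast group needs at least 2 samples")
  if (length(intersect(group_a_ids, group_b_ids)))
    stop("contrast groups must be disjoint")
  structure(list(name = name, group_a_ids = group_a_ids,
                 group_b_ids = group_b_ids), class = "de_contrast")
}

#' Contrasts used in the study design
#'
#' `cancer_vs_healthy` compares all cancer samples against healthy
#' controls; `pole` compares POLE-mutant against POLE-wild-type strictly
#' within the cancer samples (healthy samples never enter it).
#'
#' @param meta a [sample_meta()] data.frame.
#' @param which `"cancer_vs_healthy"` or `"pole"`.
#' @return A [contrast()].
#' @export
study_contrast <- function(meta, which = c("cancer_vs_healthy", "pole")) {
  which <- match.arg(which)
  if (which == "cancer_vs_healthy")
    contrast("cancer_vs_healthy",
             meta$sample_id[meta$group == "cancer"],
             meta$sample_id[meta$group == "healthy"])
  else
    contrast("pole_vs_wildtype",
             meta$sample_id[meta$group == "cancer" &
                              meta$pole_status == "mutant"],
             meta$sample_id[meta$group == "cancer" &
                              meta$pole_status == "wildtype"])
}

#' Welch's two-sample t-test
#'
#' Two-sided test on the difference of means with the Welch-Satterthwaite
#' degrees of freedom; accommodates unequal variances and unpaired
#' sampling. When both groups have zero variance and equal means the test
#' is degenerate and p = 1 by convention.
#'
#' @param a,b numeric vectors (NAs dropped); each needs >= 2 values.
#' @return list with `t_stat` (sign convention mean(a) - mean(b)),
#'   `welch_df`, and two-sided `p`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_test needs >= 2 non-missing values per group")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) return(list(t_stat = 0, welch_df = na + nb - 2, p = 1))
    return(list(t_stat = sign(d) * Inf, welch_df = na + nb - 2, p = 0))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(t_stat = t_stat, welch_df = df, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply by m/rank, enforce
#' monotonicity from the largest rank down, cap at 1. Equal p-values
#' receive equal adjusted values.
#'
#' @param p numeric vector of raw p-values in [0, 1] (NA not allowed).
#' @return vector of FDR-adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no NA")
  m <- length(p)
  o <- order(p)                       # stable in R
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Run a two-group differential-expression contrast
#'
#' Per target assay: group-mean ΔCt, ΔΔCt = mean(A) - mean(B), fold
#' regulation 2^-ΔΔCt reported on the log2 scale (log2 fold regulation =
#' -ΔΔCt; positive = up in group A), Welch test on pairwise-complete ΔCt,
#' BH adjustment across all tested assays, and the dual significance
#' filter |log2 fold regulation| > lfc_threshold and FDR < fdr_threshold.
#'
#' Assays with fewer than 2 non-missing values in either group are
#' excluded from testing (and from the BH multiplicity m) and returned
#' with `tested = FALSE`.
#'
#' @param dct a `dct_table` from [normalize_delta_ct()].
#' @param ctr a [contrast()].
#' @param lfc_threshold significance threshold on |log2 fold regulation|
#'   (default 1).
#' @param fdr_threshold significance threshold on FDR (default 0.05).
#' @return data.frame of class `de_table`, one row per target assay, with
#'   columns mirna, n_a, n_b, mean_dct_a, mean_dct_b, ddct, log2_fold_reg,
#'   fold_reg, t_stat, welch_df, p, fdr, significant, tested. Attribute
#'   `contrast` holds the contrast name.
#' @export
run_contrast <- function(dct, ctr, lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(inherits(dct, "dct_table"), inherits(ctr, "de_contrast"))
  missing_ids <- setdiff(c(ctr$group_a_ids, ctr$group_b_ids),
                         dct$sample_ids)
  if (length(missing_ids))
    stop("contrast sample id(s) not in ΔCt table: ",
         paste(missing_ids, collapse = ", "))
  A <- dct$dct[ctr$group_a_ids, , drop = FALSE]
  B <- dct$dct[ctr$group_b_ids, , drop = FALSE]
  assays <- dct$target_assay_ids
  rows <- lapply(assays, function(id) {
    a <- A[, id]; b <- B[, id]
    na <- sum(!is.na(a)); nb <- sum(!is.na(b))
    if (na < 2L || nb < 2L)
      return(data.frame(mirna = id, n_a = na, n_b = nb,
                        mean_dct_a = NA_real_, mean_dct_b = NA_real_,
                        ddct = NA_real_, log2_fold_reg = NA_real_,
                        fold_reg = NA_real_, t_stat = NA_real_,
                        welch_df = NA_real_, p = NA_real_,
                        tested = FALSE, stringsAsFactors = FALSE))
    ma <- mean(a, na.rm = TRUE); mb <- mean(b, na.rm = TRUE)
    ddct <- ma - mb
    w <- welch_test(a, b)
    data.frame(mirna = id, n_a = na, n_b = nb,
               mean_dct_a = ma, mean_dct_b = mb, ddct = ddct,
               log2_fold_reg = -ddct, fold_reg = 2^(-ddct),
               t_stat = w$t_stat, welch_df = w$welch_df, p = w$p,
               tested = TRUE, stringsAsFactors = FALSE)
  })
  de <- do.call(rbind, rows)
  de$fdr <- NA_real_
  de$fdr[de$tested] <- bh_adjust(de$p[de$tested])
  de$significant <- de$tested &
    abs(de$log2_fold_reg) > lfc_threshold & de$fdr < fdr_threshold
  de <- de[, c("mirna", "n_a", "n_b", "mean_dct_a", "mean_dct_b", "ddct",
               "log2_fold_reg", "fold_reg", "t_stat", "welch_df", "p",
               "fdr", "significant", "tested")]
  attr(de, "contrast") <- ctr$name
  attr(de, "lfc_threshold") <- lfc_threshold
  attr(de, "fdr_threshold") <- fdr_threshold
  class(de) <- c("de_table", "data.frame")
  de
}

#' Covariate-adjusted group effect per miRNA
#'
#' Ordinary least-squares fit of ΔCt on group plus age, BMI and
#' histological grade (unordered categorical) for each selected miRNA.
#' The reported group coefficient is on the -ΔCt scale flipped to log2
#' fold regulation units (positive = up in group A), so with covariates
#' independent of expression it estimates the unadjusted -ΔΔCt.
#'
#' @param dct a `dct_table`.
#' @param meta a [sample_meta()] data.frame covering the contrast samples;
#'   age, BMI and grade must be non-missing for every included sample.
#' @param ctr a [contrast()].
#' @param mirnas assays to fit (default: all target assays).
#' @return data.frame with columns mirna, group_coef (log2 fold regulation
#'   units), group_se, group_p, age_p, bmi_p, grade_p (minimum across
#'   grade dummies).
#' @export
covariate_adjustment <- function(dct, meta, ctr, mirnas = NULL) {
  stopifnot(inherits(dct, "dct_table"), inherits(meta, "sample_meta"),
            inherits(ctr, "de_contrast"))
  if (is.null(mirnas)) mirnas <- dct$target_assay_ids
  ids <- c(ctr$group_a_ids, ctr$group_b_ids)
  m <- meta[match(ids, meta$sample_id), ]
  if (anyNA(m$sample_id)) stop("metadata missing for contrast samples")
  if (anyNA(m$age) || anyNA(m$bmi) || anyNA(m$grade))
    stop("age, BMI and grade must be available for all included samples")
  dat <- data.frame(
    group = factor(ifelse(ids %in% ctr$group_a_ids, "A", "B"),
                   levels = c("B", "A")),
    age = m$age, bmi = m$bmi, grade = factor(m$grade))
  const <- names(dat)[vapply(dat, function(x) length(unique(x)) < 2L,
                             logical(1))]
  if (length(const))
    stop("rank-deficient design; constant column(s): ",
         paste(const, collapse = ", "))
  rows <- lapply(mirnas, function(id) {
    dat$y <- dct$dct[ids, id]
    fit <- stats::lm(y ~ group + age + bmi + grade, data = dat)
    cf <- stats::coef(fit)
    if (anyNA(cf))
      stop("rank-deficient design; collinear column(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    sm <- stats::coef(summary(fit))
    gp <- grep("^grade", rownames(sm), value = TRUE)
    data.frame(
      mirna = id,
      group_coef = -sm["groupA", "Estimate"],  # flip ΔCt to log2 fold reg
      group_se = sm["groupA", "Std. Error"],
      group_p = sm["groupA", "Pr(>|t|)"],
      age_p = sm["age", "Pr(>|t|)"],
      bmi_p = sm["bmi", "Pr(>|t|)"],
      grade_p = min(sm[gp, "Pr(>|t|)"]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
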