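# Post hoc sensitivity analysis: representative ΔCt dispersion, pi0
# estimation, Bonferroni / BH-effective alpha, noncentral-t power, and
# minimal detectable effect size (MDES) per contrast and power level.

#' Representative ΔCt dispersion for a contrast
#'
#' Per target assay, the two-group pooled SD
#' sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)); the
#' representative dispersion is the median over assays with at least two
#' values per group.
#'
#' @param dct a `dct_table`.
#' @param ctr a [contrast()].
#' @return median pooled SD in cycles (= log2 units).
#' @export
representative_sd <- function(dct, ctr) {
  stopifnot(inherits(dct, "dct_table"), inherits(ctr, "de_contrast"))
  A <- dct$dct[ctr$group_a_ids, , drop = FALSE]
  B <- dct$dct[ctr$group_b_ids, , drop = FALSE]
  pooled <- vapply(dct$target_assay_ids, function(id) {
    a <- A[, id]; a <- a[!is.na(a)]
    b <- B[, id]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
           (length(a) + length(b) - 2))
  }, numeric(1))
  pooled <- pooled[!is.na(pooled)]
  if (length(pooled) == 0L)
    stop("no assay with >= 2 values per group")
  stats::median(pooled)
}

#' Estimate the proportion of null hypotheses (pi0)
#'
#' Fixed-lambda estimator #\{p > lambda\} / (m (1 - lambda)), clamped to
#' [floor, 1]. The smoother variant evaluates the estimator over a lambda
#' grid, fits a cubic smoothing spline of pi0(lambda), and takes the
#' fitted value at the largest lambda (the limit in which the estimate is
#' least biased by the alternative component).
#'
#' @param p raw p-values in [0, 1].
#' @param lambda tail threshold in (0, 1) (default 0.5; fixed method).
#' @param method `"fixed"` or `"smoother"`.
#' @param lambda_grid grid for the smoother (default seq(0.05, 0.95, 0.05)).
#' @param floor lower clamp; defaults to 1/m so a downstream BH-effective
#'   alpha never collapses to zero.
#' @return pi0 estimate in [floor, 1].
#' @export
estimate_pi0 <- function(p, lambda = 0.5, method = c("fixed", "smoother"),
                         lambda_grid = seq(0.05, 0.95, by = 0.05),
                         floor = NULL) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (is.null(floor)) floor <- 1 / m
  est_at <- function(l) sum(p > l) / (m * (1 - l))
  pi0 <- if (method == "fixed") {
    if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
    est_at(lambda)
  } else {
    raw <- vapply(lambda_grid, est_at, numeric(1))
    fit <- stats::smooth.spline(lambda_grid, raw, df = 3)
    stats::predict(fit, x = max(lambda_grid))$y
  }
  min(max(pi0, floor), 1)
}

#' BH-effective significance level
#'
#' alpha_eff = base_alpha * (1 - pi0), the per-test level approximating
#' the average BH rejection threshold. Floored at `floor` (default
#' base_alpha / m when `m` is given, else base_alpha * 1e-6) so a
#' degenerate pi0 = 1 never yields a zero-width rejection region; the
#' default floor equals the Bonferroni level.
#'
#' @param pi0 estimated proportion of nulls in [0, 1].
#' @param base_alpha familywise level (default 0.05).
#' @param m number of tests, used for the default floor.
#' @param floor explicit lower bound on the returned level.
#' @return effective per-test alpha.
#' @export
effective_alpha <- function(pi0, base_alpha = 0.05, m = NULL, floor = NULL) {
  stopifnot(pi0 >= 0, pi0 <= 1, base_alpha > 0, base_alpha < 1)
  if (is.null(floor))
    floor <- if (!is.null(m)) base_alpha / m else base_alpha * 1e-6
  max(base_alpha * (1 - pi0), floor)
}

#' Two-sided power of a two-sample t test
#'
#' Power is computed from the noncentral t distribution with
#' noncentrality delta / (sd * sqrt(1/n_a + 1/n_b)). The degrees of
#' freedom follow `df_convention`: `"pooled"` uses n_a + n_b - 2 (the
#' convention of standard two-group power tools); `"welch_equal_variance"`
#' uses the Welch-Satterthwaite df evaluated at equal group variances.
#'
#' @param delta true mean difference (log2 units).
#' @param sd common within-group SD (log2 units).
#' @param n_a,n_b group sizes.
#' @param alpha two-sided significance level in (0, 1).
#' @param df_convention `"pooled"` or `"welch_equal_variance"`.
#' @return rejection probability; equals `alpha` exactly at delta = 0.
#' @export
power_two_sample_t <- function(delta, sd, n_a, n_b, alpha = 0.05,
                               df_convention = c("pooled",
                                                 "welch_equal_variance")) {
  df_convention <- match.arg(df_convention)
  stopifnot(sd > 0, n_a >= 2, n_b >= 2)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- if (df_convention == "pooled") n_a + n_b - 2
  else (1 / n_a + 1 / n_b)^2 /
    ((1 / n_a)^2 / (n_a - 1) + (1 / n_b)^2 / (n_b - 1))
  ncp <- delta / (sd * sqrt(1 / n_a + 1 / n_b))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Minimal detectable effect size (MDES)
#'
#' Smallest true |log2 fold change| at which the two-sample t test
#' attains the required power at level alpha, found by inverting
#' [power_two_sample_t()] with uniroot on the bracket
#' [1e-6, 20 * sd] to a tolerance of 1e-9 log2 units.
#'
#' @param sd within-group SD (log2 units).
#' @param n_a,n_b group sizes.
#' @param alpha per-test two-sided level in (0, 1).
#' @param power required power, in (alpha, 1).
#' @param df_convention passed to [power_two_sample_t()].
#' @return MDES in log2 units.
#' @export
mdes_solve <- function(sd, n_a, n_b, alpha, power = 0.80,
                       df_convention = "pooled") {
  stopifnot(sd > 0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= alpha || power >= 1)
    stop("required power must be in (alpha, 1)")
  f <- function(d) power_two_sample_t(d, sd, n_a, n_b, alpha,
                                      df_convention) - power
  lo <- 1e-6; hi <- 20 * sd
  if (f(hi) < 0) stop("no bracket: power unattainable below 20*sd")
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Power and MDES report for one or more contrasts
#'
#' For each contrast: the representative pooled SD of ΔCt, pi0 from that
#' contrast's raw p-values, the Bonferroni level base_alpha/m and the
#' BH-effective level base_alpha*(1-pi0), and the MDES at each requested
#' power level under both alpha policies, plus a sampled
#' power-versus-effect-size curve per policy.
#'
#' @param dct a `dct_table`.
#' @param de_tables named list of `de_table` results, one per contrast
#'   (names irrelevant; contrast name is read from the table attribute).
#' @param contrasts list of [contrast()] objects matching `de_tables`.
#' @param base_alpha familywise level (default 0.05).
#' @param power_levels required power levels (default c(0.80, 0.90)).
#' @param sd_override use this SD instead of the estimate (e.g. 1.8).
#' @param pi0_method passed to [estimate_pi0()].
#' @param df_convention passed to the power computations.
#' @param curve_deltas effect sizes for the exported power curve.
#' @return list with `mdes` (data.frame: contrast, sd, pi0, alpha_policy,
#'   alpha_used, power_level, mdes_log2, mdes_fold) and `curves`
#'   (data.frame: contrast, alpha_policy, delta_log2, power).
#' @export
mdes_report <- function(dct, de_tables, contrasts, base_alpha = 0.05,
                        power_levels = c(0.80, 0.90), sd_override = NULL,
                        pi0_method = "fixed", df_convention = "pooled",
                        curve_deltas = seq(0.1, 6, by = 0.1)) {
  stopifnot(length(de_tables) == length(contrasts))
  mdes_rows <- list(); curve_rows <- list()
  for (i in seq_along(contrasts)) {
    ctr <- contrasts[[i]]; de <- de_tables[[i]]
    n_a <- length(ctr$group_a_ids); n_b <- length(ctr$group_b_ids)
    sd_rep <- if (is.null(sd_override)) representative_sd(dct, ctr)
    else sd_override
    p <- de$p[de$tested]
    m <- length(p)
    pi0 <- estimate_pi0(p, method = pi0_method)
    alphas <- c(bonferroni = base_alpha / m,
                bh_effective = effective_alpha(pi0, base_alpha, m = m))
    for (pol in names(alphas)) {
      for (pw in power_levels) {
        mdes <- mdes_solve(sd_rep, n_a, n_b, alphas[[pol]], pw,
                           df_convention)
        mdes_rows[[length(mdes_rows) + 1L]] <- data.frame(
          contrast = ctr$name, n_a = n_a, n_b = n_b, sd = sd_rep,
          m = m, pi0 = pi0, alpha_policy = pol,
          alpha_used = alphas[[pol]], power_level = pw,
          mdes_log2 = mdes, mdes_fold = 2^mdes,
          stringsAsFactors = FALSE)
      }
      curve_rows[[length(curve_rows) + 1L]] <- data.frame(
        contrast = ctr$name, alpha_policy = pol,
        delta_log2 = curve_deltas,
        power = vapply(curve_deltas, power_two_sample_t, numeric(1),
                       sd = sd_rep, n_a = n_a, n_b = n_b,
                       alpha = alphas[[pol]],
                       df_convention = df_convention),
        stringsAsFactors = FALSE)
    }
  }
  list(mdes = do.call(rbind, mdes_rows),
       curves = do.call(rbind, curve_rows))
}
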