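test_that("representative_sd is the median per-assay pooled SD", {
  # equal-variance groups: pooled SD equals the common SD
  a <- rep(c(-2, 0, 2), 4)          # sd 1.906 in each group if same values
  dm <- cbind(c(a[1:6]), c(a[1:6]), c(a[1:6]))
  ct <- tiny_ct(dm, tiny_layout(3))
  dct <- normalize_delta_ct(ct)
  ctr <- contrast("ab", c("S01", "S02", "S03"), c("S04", "S05", "S06"))
  s <- sd(a[1:3])
  expect_equal(representative_sd(dct, ctr), s)

  # median over assays with different pooled SDs {1, 1.8, 3}
  mk <- function(s) c(-s, 0, s, -s, 0, s) / sd(c(-1, 0, 1))
  dm2 <- cbind(mk(1), mk(1.8), mk(3))
  dct2 <- normalize_delta_ct(tiny_ct(dm2, tiny_layout(3)))
  expect_equal(representative_sd(dct2, ctr), 1.8)

  # no eligible assay
  dm3 <- matrix(NA_real_, 6, 2) + 36  # all over LOD
  dct3 <- normalize_delta_ct(tiny_ct(matrix(36, 6, 2) - 21, tiny_layout(2)))
  expect_error(representative_sd(dct3, ctr), "no assay")
})

test_that("pi0 estimation: fixed-lambda formula, clamps and mixtures", {
  # m = 10, five p > 0.5 -> 5 / (10 * 0.5) = 1
  p <- c(0.6, 0.7, 0.8, 0.9, 0.95, 0.1, 0.2, 0.3, 0.4, 0.45)
  expect_equal(estimate_pi0(p, lambda = 0.5), 1)
  # all p <= lambda: clamped to floor (default 1/m)
  expect_equal(estimate_pi0(rep(0.01, 10), lambda = 0.5), 0.1)
  expect_equal(estimate_pi0(rep(0.01, 10), lambda = 0.5, floor = 0.02),
               0.02)
  expect_error(estimate_pi0(numeric(0)), "empty")
  expect_error(estimate_pi0(c(0.5, 2)), "\\[0, 1\\]")

  # 70% uniform nulls + 30% near-zero alternatives
  set.seed(8)
  pm <- c(runif(7000), rbeta(3000, 0.2, 20))
  expect_equal(estimate_pi0(pm, lambda = 0.5), 0.7, tolerance = 0.05)
  expect_equal(estimate_pi0(pm, method = "smoother"), 0.7,
               tolerance = 0.05)
})

test_that("pi0 fixed-lambda estimator is unbiased under uniform nulls", {
  set.seed(81)
  pi0_true <- 0.8
  est <- replicate(300, {
    p <- c(runif(800), rbeta(200, 0.2, 20))
    estimate_pi0(p, lambda = 0.5)
  })
  # alternatives barely exceed lambda, so bias is tiny; MC tolerance
  expect_equal(mean(est), pi0_true, tolerance = 0.02)
})

test_that("effective_alpha arithmetic, bounds and floor", {
  expect_equal(effective_alpha(0.4, 0.05), 0.03)
  expect_equal(effective_alpha(0, 0.05), 0.05)
  # pi0 = 1 returns the floor, never 0; default floor = Bonferroni
  expect_equal(effective_alpha(1, 0.05, m = 84), 0.05 / 84)
  expect_gt(effective_alpha(1, 0.05), 0)
})

test_that("power_two_sample_t matches the numerical-integration oracle", {
  # null effect gives exactly alpha
  expect_equal(power_two_sample_t(0, 1.8, 40, 20, 0.05), 0.05)
  expect_equal(power_two_sample_t(0, 1, 5, 9, 0.01), 0.01)

  # d = 1, n 20/20, alpha 0.05, pooled df: ≈ 0.869
  expect_equal(power_two_sample_t(1, 1, 20, 20, 0.05),
               power_numint_oracle(1, 1, 20, 20, 0.05, 38),
               tolerance = 1e-8)
  expect_equal(power_two_sample_t(1, 1, 20, 20, 0.05), 0.869,
               tolerance = 5e-4)

  set.seed(9)
  for (i in 1:40) {
    delta <- runif(1, 0, 4); sd <- runif(1, 0.5, 3)
    na <- sample(3:40, 1); nb <- sample(3:40, 1)
    alpha <- runif(1, 0.001, 0.2)
    expect_equal(
      power_two_sample_t(delta, sd, na, nb, alpha),
      power_numint_oracle(delta, sd, na, nb, alpha, na + nb - 2),
      tolerance = 1e-7)
  }

  # strictly increasing in delta
  d <- seq(0, 5, by = 0.25)
  pw <- vapply(d, power_two_sample_t, numeric(1), sd = 1.8,
               n_a = 40, n_b = 20, alpha = 0.01)
  expect_true(all(diff(pw) > 0))
  expect_error(power_two_sample_t(1, 1, 10, 10, alpha = 1.2), "alpha")
})

test_that("welch_equal_variance df convention reproduces Welch df", {
  # at equal variances and sizes the Satterthwaite df is n1 + n2 - 2
  p1 <- power_two_sample_t(1, 1, 15, 15, 0.05, "pooled")
  p2 <- power_two_sample_t(1, 1, 15, 15, 0.05, "welch_equal_variance")
  expect_equal(p1, p2)
  # unequal sizes: Welch-equal-variance df < pooled df, so less power
  p3 <- power_two_sample_t(1.5, 1.8, 7, 33, 0.01, "welch_equal_variance")
  p4 <- power_two_sample_t(1.5, 1.8, 7, 33, 0.01, "pooled")
  expect_lt(p3, p4)
})

test_that("mdes_solve inverts the power function", {
  set.seed(10)
  for (i in 1:30) {
    sd <- runif(1, 0.5, 3)
    na <- sample(3:50, 1); nb <- sample(3:50, 1)
    alpha <- runif(1, 1e-4, 0.1)
    power <- runif(1, 0.5, 0.95)
    d <- mdes_solve(sd, na, nb, alpha, power)
    expect_equal(power_two_sample_t(d, sd, na, nb, alpha), power,
                 tolerance = 1e-6)
  }
  expect_error(mdes_solve(1, 10, 10, alpha = 0.05, power = 0.04),
               "power")
})

test_that("MDES exceeds the normal-approximation lower bound", {
  # alpha 0.05, power 0.80, sd 1, n 20/20: ≈ 0.909, above the
  # closed-form normal bound (z_{1-a/2} + z_{power}) * sd * sqrt(1/na+1/nb)
  d <- mdes_solve(1, 20, 20, 0.05, 0.80)
  z_bound <- (qnorm(0.975) + qnorm(0.80)) * sqrt(1 / 20 + 1 / 20)
  expect_equal(z_bound, 0.886, tolerance = 5e-4)
  expect_gt(d, z_bound)
  expect_equal(d, 0.909, tolerance = 5e-3)
})

test_that("MDES is antitone in alpha and n, monotone in power and sd", {
  set.seed(11)
  for (i in 1:15) {
    sd <- runif(1, 0.8, 2.5)
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    alpha <- runif(1, 1e-4, 0.05)
    d80 <- mdes_solve(sd, na, nb, alpha, 0.80)
    # increasing in required power
    expect_gt(mdes_solve(sd, na, nb, alpha, 0.90), d80)
    # antitone in alpha
    expect_lt(mdes_solve(sd, na, nb, alpha * 2, 0.80), d80)
    # decreasing in total n
    expect_lt(mdes_solve(sd, na + 10, nb + 10, alpha, 0.80), d80)
    # increasing in sd
    expect_gt(mdes_solve(sd * 1.5, na, nb, alpha, 0.80), d80)
  }
})

test_that("mdes_report assembles per-contrast results with the right
           shape and monotonicity", {
  sim <- simulate_panel(sim_config(seed = 12))
  dct <- normalize_delta_ct(sim$ct)
  contrasts <- list(study_contrast(sim$meta, "cancer_vs_healthy"),
                    study_contrast(sim$meta, "pole"))
  des <- lapply(contrasts, function(ctr) run_contrast(dct, ctr))
  rep <- mdes_report(dct, des, contrasts)
  # 2 contrasts x 2 policies x 2 power levels
  expect_equal(nrow(rep$mdes), 8L)
  expect_setequal(unique(rep$mdes$alpha_policy),
                  c("bonferroni", "bh_effective"))
  expect_equal(rep$mdes$mdes_fold, 2^rep$mdes$mdes_log2)
  # MDES(90%) > MDES(80%) within every contrast x policy
  sp <- split(rep$mdes, paste(rep$mdes$contrast, rep$mdes$alpha_policy))
  for (g in sp) {
    g <- g[order(g$power_level), ]
    expect_true(all(diff(g$mdes_log2) > 0))
  }
  # BH-effective alpha >= Bonferroni alpha, so its MDES is <=
  wide <- merge(
    rep$mdes[rep$mdes$alpha_policy == "bonferroni",
             c("contrast", "power_level", "mdes_log2")],
    rep$mdes[rep$mdes$alpha_policy == "bh_effective",
             c("contrast", "power_level", "mdes_log2")],
    by = c("contrast", "power_level"), suffixes = c("_bonf", "_bh"))
  expect_true(all(wide$mdes_log2_bh <= wide$mdes_log2_bonf))
  # curve table covers both contrasts and policies
  expect_setequal(unique(rep$curves$contrast),
                  c("cancer_vs_healthy", "pole_vs_wildtype"))
  expect_true(all(rep$curves$power >= 0 & rep$curves$power <= 1))
})
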