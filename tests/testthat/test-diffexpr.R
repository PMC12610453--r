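test_that("ΔCt normalization follows the housekeeping-mean definition", {
  lay <- tiny_layout(2)
  # housekeeping Cts {20, 21, 22} per sample -> mean 21
  m <- matrix(c(25, 21,    # miR-01: ΔCt 4; miR-02: ΔCt 0
                27, 23,
                rep(c(20, 21, 22), each = 2)),
              nrow = 2,
              dimnames = list(c("S1", "S2"), lay$assay_ids))
  m[, "miR-01"] <- c(25, 27); m[, "miR-02"] <- c(21, 23)
  dct <- normalize_delta_ct(ct_table(m, lay))
  expect_equal(dct$dct["S1", "miR-01"], 4)
  expect_equal(dct$rel_expr["S1", "miR-01"], 0.0625)
  expect_equal(dct$dct["S1", "miR-02"], 0)   # Ct equal to hk mean
  expect_equal(dct$rel_expr["S1", "miR-02"], 1)
  expect_equal(unname(dct$rel_expr), unname(2^(-dct$dct)))
  # housekeeping and control assays excluded from the result
  expect_setequal(dct$target_assay_ids, c("miR-01", "miR-02"))
})

test_that("undetected cells propagate and absent housekeeping errors", {
  lay <- tiny_layout(2)
  m <- matrix(21, 2, 5, dimnames = list(c("S1", "S2"), lay$assay_ids))
  m["S1", "miR-01"] <- 36   # over LOD: undetected
  dct <- normalize_delta_ct(ct_table(m, lay))
  expect_true(is.na(dct$dct["S1", "miR-01"]))
  expect_false(anyNA(dct$dct["S2", ]))

  m2 <- m
  m2["S2", c("SNORD38B", "U6-snRNA", "SNORD49A")] <- 40  # all hk undetected
  expect_error(normalize_delta_ct(ct_table(m2, lay)), "S2")
})

test_that("welch_test matches the hand-derived example and conventions", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t_stat, -1.224745, tolerance = 1e-6)
  expect_equal(w$welch_df, 4)
  expect_equal(w$p, 0.2878641, tolerance = 1e-6)

  # identical groups: t = 0, p = 1
  w0 <- welch_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(w0$t_stat, 0)
  expect_equal(w0$p, 1)

  # equal variances and equal n: Welch df = pooled df
  set.seed(1)
  a <- rnorm(8); b <- a + 1   # same sample variance
  expect_equal(welch_test(a, b)$welch_df, 14)

  # degenerate zero-variance equal-mean case: p = 1 by convention
  wd <- welch_test(c(2, 2, 2), c(2, 2))
  expect_equal(wd$p, 1)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("welch_test and bh_adjust match reference implementations", {
  set.seed(20)
  for (i in 1:300) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -2, 2),
               sd = runif(1, 0.5, 3))
    w <- welch_test(a, b)
    ref <- t.test(a, b)
    expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$welch_df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)

    p <- runif(sample(1:40, 1))
    if (i %% 3 == 0) p[1] <- p[length(p)]   # exercise ties
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-15)
  }
})

test_that("bh_adjust edge cases and validation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("run_contrast applies the sign convention and dual filter", {
  # 4 targets, 3 vs 3; miR-01 lower ΔCt in A by 2 (up in A), miR-02 equal
  dm <- rbind(c(1, 5, 2, 3), c(2, 5, 3, 2), c(3, 5, 2.5, 4),
              c(3, 5, 8, 3), c(4, 5, 9, 2), c(5, 5, 8.5, 4))
  ct <- tiny_ct(dm)
  dct <- normalize_delta_ct(ct)
  ctr <- contrast("ab", c("S01", "S02", "S03"), c("S04", "S05", "S06"))
  de <- run_contrast(dct, ctr)
  expect_s3_class(de, "de_table")
  r1 <- de[de$mirna == "miR-01", ]
  expect_equal(r1$ddct, -2)
  expect_equal(r1$log2_fold_reg, 2)        # positive = up in group A
  expect_equal(r1$fold_reg, 4)
  r2 <- de[de$mirna == "miR-02", ]
  expect_equal(r2$ddct, 0)
  expect_equal(r2$fold_reg, 1)
  expect_false(r2$significant)
  # invariants: log2_fold_reg = -ddct, fold_reg * 2^ddct = 1
  expect_equal(de$log2_fold_reg, -de$ddct)
  expect_equal(de$fold_reg * 2^de$ddct, rep(1, nrow(de)))
  # BH m equals number of tested assays
  expect_equal(de$fdr[de$tested], bh_adjust(de$p[de$tested]))

  expect_error(run_contrast(dct, contrast("bad", c("S01", "S02"),
                                          c("S98", "S99"))),
               "S98")
})

test_that("assays short on data are excluded from testing and from m", {
  dm <- matrix(rnorm(24), 6, 4)
  dm[1:5, 2] <- NA   # only 1 value in group A for miR-02
  ct <- tiny_ct(dm)
  # force NA through the LOD path: set those raw Ct over LOD instead
  m <- ct$ct; m[1:5, "miR-02"] <- 36
  ct <- ct_table(m, ct$layout)
  dct <- normalize_delta_ct(ct)
  ctr <- contrast("ab", c("S01", "S02", "S03"), c("S04", "S05", "S06"))
  de <- run_contrast(dct, ctr)
  expect_false(de$tested[de$mirna == "miR-02"])
  expect_true(is.na(de$fdr[de$mirna == "miR-02"]))
  expect_false(de$significant[de$mirna == "miR-02"])
  expect_equal(sum(de$tested), 3L)
  expect_equal(de$fdr[de$tested], bh_adjust(de$p[de$tested]))
})

test_that("one planted +5 effect: unique-call rate matches the step-up
           oracle", {
  # With one overwhelming true effect (p ~ 1e-11, always called), the
  # planted assay is the unique significant call iff BH step-up rejects
  # none of the 83 nulls. Oracle: simulate uniform null p-values directly
  # and apply the step-up rule over ranks 2..84 — independent of the Ct
  # panel path. At this signal-to-noise the |lfc| > 1 filter never saves
  # a null (p < 2q/m forces |estimate| > 2).
  set.seed(70)
  oracle <- mean(vapply(seq_len(20000), function(i) {
    p <- sort(runif(83))
    !any(p <= (2:84) * 0.05 / 84)
  }, logical(1)))                     # ≈ 0.906

  hits <- vapply(1:60, function(s) {
    sim <- simulate_panel(sim_config(
      seed = 1000 + s,
      effects = list(effect_spec("hsa-miR-181a-5p",
                                 "cancer_vs_healthy", 5))))
    de <- run_contrast(normalize_delta_ct(sim$ct),
                       study_contrast(sim$meta, "cancer_vs_healthy"))
    identical(de$mirna[de$significant], "hsa-miR-181a-5p")
  }, logical(1))
  # always called, and uniqueness rate consistent with the oracle
  expect_equal(mean(hits), oracle,
               tolerance = 3 * sqrt(oracle * (1 - oracle) / 60) / oracle)
})

test_that("covariate adjustment recovers the group effect and flags
           degenerate designs", {
  set.seed(55)
  # covariates independent of expression: adjusted ≈ unadjusted
  sim <- simulate_panel(sim_config(
    seed = 56, n_target_assays = 6,
    effects = list(effect_spec("hsa-miR-181a-5p",
                               "cancer_vs_healthy", 3))))
  dct <- normalize_delta_ct(sim$ct)
  ctr <- study_contrast(sim$meta, "cancer_vs_healthy")
  adj <- covariate_adjustment(dct, sim$meta, ctr,
                              mirnas = "hsa-miR-181a-5p")
  de <- run_contrast(dct, ctr)
  un <- de$log2_fold_reg[de$mirna == "hsa-miR-181a-5p"]
  expect_lt(abs(adj$group_coef - un), 3 * adj$group_se)

  # constant grade: rank-deficiency error naming the column
  meta2 <- sim$meta; meta2$grade <- "G2"
  expect_error(covariate_adjustment(dct, meta2, ctr), "grade")
})

test_that("a planted BMI confounder attenuates the adjusted effect", {
  reps <- vapply(1:10, function(s) {
    sim <- simulate_panel(sim_config(
      seed = 600 + s, n_target_assays = 4, confound_bmi = 0.4,
      effects = list(effect_spec("hsa-miR-181a-5p",
                                 "cancer_vs_healthy", 3))))
    dct <- normalize_delta_ct(sim$ct)
    ctr <- study_contrast(sim$meta, "cancer_vs_healthy")
    de <- run_contrast(dct, ctr)
    adj <- covariate_adjustment(dct, sim$meta, ctr,
                                mirnas = "hsa-miR-181a-5p")
    un <- de$log2_fold_reg[de$mirna == "hsa-miR-181a-5p"]
    abs(adj$group_coef) < abs(un)
  }, logical(1))
  expect_gte(mean(reps), 0.8)
})
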