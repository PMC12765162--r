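test_that("Welch test matches its closed form and degenerates sensibly", {
  g <- rep(c("x", "y"), each = 5)
  same <- c(1:5, 1:5)
  r0 <- welch_t(same, g)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  two <- c(1:5, 2:6)
  r <- welch_t(two, g)
  or <- welch_oracle(1:5, 2:6)
  expect_equal(r$mean_diff, -1)
  expect_equal(r$t, or$t, tolerance = 1e-12)
  expect_equal(r$df, or$df, tolerance = 1e-12)
  expect_equal(r$p, or$p, tolerance = 1e-12)

  # scaling both groups scales the difference, not the p-value
  rs <- welch_t(two * 4.2, g)
  expect_equal(rs$mean_diff, -4.2, tolerance = 1e-12)
  expect_equal(rs$p, r$p, tolerance = 1e-12)

  expect_error(welch_t(1:4, c("a", "a", "a", "a")), "two levels")
})

test_that("one-way ANOVA with Tukey HSD flags only true separations", {
  # equal group means with within-group spread: F exactly 0
  m <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- anova_tukey(m, g)
  expect_lt(abs(r$F), 1e-20)

  set.seed(1)
  y <- c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 5))
  g3 <- rep(c("g1", "g2", "g3"), each = 50)
  r3 <- anova_tukey(y, g3)
  expect_lt(r3$p, 1e-6)
  sig <- r3$pairwise$p_adj < 0.05
  involves3 <- grepl("g3", r3$pairwise$pair)
  expect_identical(sig, involves3)

  # Tukey adjustment never reports less than the raw pairwise t-test
  for (i in seq_len(nrow(r3$pairwise))) {
    gs <- strsplit(r3$pairwise$pair[i], "-")[[1]]
    raw <- t.test(y[g3 == gs[1]], y[g3 == gs[2]], var.equal = TRUE)$p.value
    expect_gte(r3$pairwise$p_adj[i] + 1e-12, raw)
  }
  expect_error(anova_tukey(1:3, c("a", "a", "b")), "at least 2")
})

test_that("staged linear models reproduce injected coefficients and the OLS oracle", {
  # generate noiselessly from exactly the design each stage fits, so the
  # fit interpolates: no age-sex interaction for the full model, no group
  # effects for the interaction model
  b_full <- c(intercept = 550, age = -2.29, sex = -129.0, age_sex = 0,
              scd = -17.4, mci = -31.8, fazekas1 = -6.72, fazekas2 = -16.9,
              fazekas3 = -7.42, amyloid = 3.29)
  cfg <- cohort_gen_config(
    coefficients = list(gm_tex = b_full,
                        gm_cbf = b_full, gm_att = b_full),
    residual_sd = c(gm_tex = 1e-9, gm_cbf = 1e-9, gm_att = 1e-9))
  co <- gen_cohort(cfg, seed = 3)
  full <- staged_lm(co, "gm_tex", "full")
  b <- cfg$coefficients$gm_tex
  expect_equal(lm_term(full, "cogstageSCD"), unname(b["scd"]), tolerance = 1e-6)
  expect_equal(lm_term(full, "cogstageMCI"), unname(b["mci"]), tolerance = 1e-6)
  expect_equal(lm_term(full, "fazekas3"), unname(b["fazekas3"]), tolerance = 1e-6)
  expect_equal(lm_term(full, "amyloidA+"), unname(b["amyloid"]), tolerance = 1e-5)
  expect_equal(attr(full, "n"), 156L)   # 4 amyloid-NA rows dropped

  b_ixn <- c(intercept = 550, age = -2.29, sex = -129.0, age_sex = 1.57,
             scd = 0, mci = 0, fazekas1 = 0, fazekas2 = 0, fazekas3 = 0,
             amyloid = 0)
  cfg2 <- cohort_gen_config(
    coefficients = list(gm_tex = b_ixn, gm_cbf = b_ixn, gm_att = b_ixn),
    residual_sd = c(gm_tex = 1e-9, gm_cbf = 1e-9, gm_att = 1e-9))
  co2 <- gen_cohort(cfg2, seed = 3)
  ixn <- staged_lm(co2, "gm_tex", "age_sex_interaction")
  expect_equal(lm_term(ixn, "age"), -2.29, tolerance = 1e-6)
  expect_equal(lm_term(ixn, "age:sexmale"), 1.57, tolerance = 1e-6)
  expect_equal(attr(ixn, "n"), 160L)    # no amyloid in this model

  # every stage agrees with the normal-equations oracle
  noisy <- gen_cohort(cohort_gen_config(), seed = 4)
  for (st in c("crude", "age_sex", "full", "age_sex_interaction")) {
    res <- staged_lm(noisy, "gm_cbf", st, predictor = "cogstage")
    fit <- attr(res, "fit")
    X <- model.matrix(fit)
    beta <- ols_oracle(X, fit$model[[1]])
    expect_lt(max(abs(res$estimate - beta) / pmax(abs(beta), 1e-8)), 1e-10)
  }
})

test_that("reference levels follow the cohort conventions", {
  co <- gen_cohort(seed = 5)
  full <- staged_lm(co, "gm_tex", "full")
  expect_true(all(c("amyloidA+", "cogstageSCD", "cogstageMCI", "fazekas1",
                    "sexmale") %in% full$term))
  expect_false(any(grepl("amyloidA-|cogstageCN|fazekas0|sexfemale",
                         full$term)))
})

test_that("rank-deficient designs are rejected with the aliased terms named", {
  cfg <- cohort_gen_config(
    n = 40L, stage_counts = c(CN = 40L, SCD = 0L, MCI = 0L),
    fazekas_counts = c(`0` = 10L, `1` = 10L, `2` = 10L, `3` = 10L),
    amyloid_by_stage = list(CN = c(pos = 10L, neg = 30L, na = 0L),
                            SCD = c(pos = 0L, neg = 0L, na = 0L),
                            MCI = c(pos = 0L, neg = 0L, na = 0L)))
  co <- gen_cohort(cfg, seed = 6)
  expect_error(staged_lm(co, "gm_tex", "full"), "aliased.*cogstage")
})

test_that("Benjamini-Hochberg adjustment matches the hand-applied step-up", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_bh(0.037), 0.037)
  expect_equal(fdr_bh(rep(0.2, 6)), rep(0.2, 6))
  set.seed(8)
  p <- runif(25)
  expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-15)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})
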