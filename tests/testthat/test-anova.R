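test_that("a perfect endurance-only signal is recovered exactly", {
  cfg <- sim_config(n_transcripts = 3, sigma_noise = 0, sigma_subject = 0,
                    seed = 1, class_proportions = c("specific:Endurance" = 1))
  d <- generate_dataset(cfg)
  r <- normalize_to_pre(d$expression, d$design)
  a <- fit_all(r, d$design)
  expect_equal(a$E2.5h.est, rep(1, 3))
  expect_equal(a$E5h.est, rep(1, 3))
  expect_equal(a$C2.5h.est, rep(0, 3))
  expect_identical(a$E5h.p, rep(0, 3))      # zero noise: certainty
  expect_identical(a$C5h.p, rep(1, 3))      # unchanged cell, zero variance
  expect_identical(a$TimexGroup.p, rep(0, 3))
})

test_that("null ratios give null estimates and calibrated effect p", {
  d <- generate_dataset(sim_config(n_transcripts = 400, seed = 6))
  r <- normalize_to_pre(d$expression, d$design)
  a <- fit_all(r, d$design)
  expect_true(all(a$converged))
  expect_lt(abs(mean(a$E5h.est)), 0.05)
  expect_gt(ks.test(a$Time.p, "punif")$p.value, 0.01)
})

test_that("balanced closed form and iterative REML agree", {
  cfg <- sim_config(n_transcripts = 25, seed = 21,
                    class_proportions = c(null = 0.6,
                                          "specific:Endurance" = 0.2,
                                          time_all_groups = 0.2))
  d <- generate_dataset(cfg)
  r <- normalize_to_pre(d$expression, d$design)
  ab <- fit_all(r, d$design, engine = "balanced")
  ag <- fit_all(r, d$design, engine = "general")
  for (cn in c("sigma2_subject", "sigma2_resid", "Time.F", "Group.F",
               "TimexGroup.F", "E2.5h.est", "E2.5h.se", "SvE5h.est",
               "SvE5h.se")) {
    expect_equal(ab[[cn]], ag[[cn]], tolerance = 1e-7, label = cn)
  }
  # contrast p-values use the same Satterthwaite logic in both paths
  expect_equal(ab$E5h.p, ag$E5h.p, tolerance = 1e-6)
  expect_equal(ab$SvC2.5h.p, ag$SvC2.5h.p, tolerance = 1e-6)
})

test_that("REML matches lme4 on single transcripts", {
  skip_if_not_installed("lme4")
  d <- generate_dataset(sim_config(n_transcripts = 5, seed = 33,
                                   class_proportions = c(null = 0.4,
                                                         general_dependent = 0.6)))
  r <- normalize_to_pre(d$expression, d$design)
  a <- fit_all(r, d$design, engine = "general")
  postd <- d$design[d$design$time_h != 0, ]
  for (i in c(1, 4)) {
    dd <- data.frame(y = r[i, postd$sample_id],
                     g = factor(postd$group),
                     t = factor(postd$time_h),
                     s = factor(postd$subject_id))
    fm <- lme4::lmer(y ~ 0 + g:t + (1 | s), data = dd, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fm))$vcov
    expect_equal(a$sigma2_subject[i], vc[1], tolerance = 1e-6)
    expect_equal(a$sigma2_resid[i], vc[2], tolerance = 1e-6)
    fe <- lme4::fixef(fm)
    expect_equal(a$E2.5h.est[i], unname(fe["gEndurance:t2.5"]),
                 tolerance = 1e-8)
    expect_equal(a$SvE5h.est[i],
                 unname(fe["gResistance:t5"] - fe["gEndurance:t5"]),
                 tolerance = 1e-8)
  }
})

test_that("results are order-invariant and row-consistent", {
  d <- generate_dataset(sim_config(n_transcripts = 40, seed = 12))
  r <- normalize_to_pre(d$expression, d$design)
  a <- fit_all(r, d$design)
  perm <- rev(seq_len(nrow(r)))
  ap <- fit_all(r[perm, ], d$design)
  expect_equal(as.data.frame(ap[match(a$transcript_id,
                                      ap$transcript_id), ]),
               as.data.frame(a), ignore_attr = TRUE)
  single <- fit_transcript(r[7, ], d$design)
  expect_equal(as.data.frame(single)[, -1],
               as.data.frame(a[7, ])[, -1], ignore_attr = TRUE)
})

test_that("incomplete designs fall back to iterative REML and converge", {
  d <- generate_dataset(sim_config(n_transcripts = 30, seed = 5,
                                   class_proportions = c(null = 0.5,
                                                         "specific:Resistance" = 0.5)))
  keep <- d$design$sample_id != d$design$sample_id[d$design$time_h == 5][1]
  design2 <- study_design(as.data.frame(d$design[keep, ]))
  x2 <- d$expression[, design2$sample_id]
  r2 <- normalize_to_pre(x2, design2)
  a2 <- fit_all(r2, design2)
  expect_true(all(a2$converged))
  expect_true(all(a2$S5h.p >= 0 & a2$S5h.p <= 1))
  # planted resistance effect still detected
  planted <- d$truth$planted_class == "specific:Resistance"
  expect_gt(mean(a2$S5h.est[planted]), 0.7)
  expect_lt(max(a2$S5h.p[planted]), 0.01)
})

test_that("planted effect sizes are recovered within sampling error", {
  cfg <- sim_config(n_transcripts = 300, seed = 14,
                    class_proportions = c("specific:Endurance" = 1))
  d <- generate_dataset(cfg)
  r <- normalize_to_pre(d$expression, d$design)
  a <- fit_all(r, d$design)
  se_mean <- mean(a$E5h.se) / sqrt(nrow(a))
  expect_lt(abs(mean(a$E5h.est) - 1), 3 * se_mean)
  # shrinking the noise (same seed) shrinks the estimation error
  cfg2 <- sim_config(n_transcripts = 300, seed = 14, sigma_noise = 0.05,
                     class_proportions = c("specific:Endurance" = 1))
  d2 <- generate_dataset(cfg2)
  a2 <- fit_all(normalize_to_pre(d2$expression, d2$design), d2$design)
  expect_lt(mean(abs(a2$E5h.est - 1)), mean(abs(a$E5h.est - 1)))
})

test_that("model preconditions are enforced", {
  d <- generate_dataset(sim_config(n_transcripts = 4, seed = 1))
  r <- normalize_to_pre(d$expression, d$design)
  expect_error(fit_all(r, d$design, spec = model_spec(post_times = 2.5)),
               ">= 2 post time")
  expect_error(model_spec(post_times = c(0, 5)), "exclude Pre")
  expect_error(model_spec(groups = "One"), "2 groups")
  # engine = 'balanced' refuses unbalanced data
  keep <- d$design$sample_id != d$design$sample_id[d$design$time_h == 5][1]
  design2 <- study_design(as.data.frame(d$design[keep, ]))
  expect_error(fit_all(r[, design2$sample_id], design2,
                       engine = "balanced"), "balanced")
})

test_that("containment df is available and more conservative", {
  d <- generate_dataset(sim_config(n_transcripts = 100, seed = 3))
  r <- normalize_to_pre(d$expression, d$design)
  sat <- fit_all(r, d$design,
                 spec = model_spec(df_method = "satterthwaite"))
  con <- fit_all(r, d$design, spec = model_spec(df_method = "containment"))
  expect_identical(sat$E5h.est, con$E5h.est)
  # same t statistic, smaller df -> containment p no smaller on average
  expect_gt(mean(con$E5h.p - sat$E5h.p), 0)
})
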