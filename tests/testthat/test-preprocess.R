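small_study <- function(seed = 1, m = 10) {
  generate_dataset(sim_config(n_transcripts = m, n_subjects_per_group = 3,
                              seed = seed))
}

test_that("normalization subtracts each subject's own Pre on log2 scale", {
  d <- small_study()
  r <- normalize_to_pre(d$expression, d$design)
  pre_cols <- d$design$sample_id[d$design$time_h == 0]
  expect_true(all(r[, pre_cols] == 0))
  s <- d$design$subject_id[1]
  five <- d$design$sample_id[d$design$subject_id == s & d$design$time_h == 5]
  pre <- d$design$sample_id[d$design$subject_id == s & d$design$time_h == 0]
  expect_identical(r[, five], d$expression[, five] - d$expression[, pre])
  # worked example: Pre 8.0, 5 h 9.0 -> ratio +1
  expect_identical((9 - 8), 1)
  x2 <- d$expression; x2[, five] <- x2[, pre] + 1
  expect_equal(unname(normalize_to_pre(x2, d$design)[, five]),
               rep(1, nrow(x2)), tolerance = 1e-12)
})

test_that("an all-identical-column matrix normalizes to all zeros", {
  d <- small_study()
  x <- d$expression
  x[] <- rep(x[, 1], ncol(x))
  expect_true(all(normalize_to_pre(x, d$design) == 0))
})

test_that("re-normalizing a ratio matrix is the identity", {
  d <- small_study()
  r <- normalize_to_pre(d$expression, d$design)
  expect_identical(normalize_to_pre(r, d$design), r)
})

test_that("per-subject constants cancel to machine precision", {
  # exact cancellation up to IEEE rounding of the added constant
  d <- small_study(seed = 8)
  r0 <- normalize_to_pre(d$expression, d$design)
  shift <- stats::setNames(seq_along(unique(d$design$subject_id)) * 0.37,
                           unique(d$design$subject_id))
  x2 <- d$expression
  for (s in names(shift)) {
    cols <- d$design$sample_id[d$design$subject_id == s]
    x2[, cols] <- x2[, cols] + shift[s]
  }
  expect_lt(max(abs(normalize_to_pre(x2, d$design) - r0)), 1e-13)
})

test_that("baseline one-way ANOVA matches the closed-form worked case", {
  # two groups of 3 Pre samples, {1,2,3} vs {4,5,6}: F = 13.5, p ~ 0.0213
  df <- data.frame(sample_id = paste0("s", 1:6, "_Pre"),
                   subject_id = paste0("s", 1:6),
                   group = rep(c("A", "B"), each = 3),
                   time_h = 0)
  # give each subject a post sample so the design validates
  post <- df; post$sample_id <- sub("Pre", "5h", post$sample_id)
  post$time_h <- 5
  design <- study_design(rbind(df, post))
  x <- matrix(c(1, 2, 3, 4, 5, 6, rep(0, 6)), nrow = 1,
              dimnames = list("t1", c(df$sample_id, post$sample_id)))
  res <- suppressWarnings(baseline_group_test(expression_matrix(x), design))
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)
  # independent oracle: lm/anova on the same values
  ora <- anova(lm(c(1, 2, 3, 4, 5, 6) ~ rep(c("A", "B"), each = 3)))
  expect_equal(res$F, ora$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, ora$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("degenerate baselines use the F = 0, p = 1 convention", {
  df <- data.frame(sample_id = paste0("s", 1:6, "_Pre"),
                   subject_id = paste0("s", 1:6),
                   group = rep(c("A", "B"), each = 3), time_h = 0)
  post <- df; post$sample_id <- sub("Pre", "5h", post$sample_id)
  post$time_h <- 5
  design <- study_design(rbind(df, post))
  x <- expression_matrix(matrix(7, 1, 12,
                                dimnames = list("t1",
                                                c(df$sample_id,
                                                  post$sample_id))))
  res <- baseline_group_test(x, design)
  expect_identical(res$F, 0)
  expect_identical(res$p, 1)
  expect_identical(res$q, 1)
})

test_that("baseline test rejects groups without within-group variance", {
  df <- data.frame(sample_id = c("a_Pre", "a_5", "b_Pre", "b_5",
                                 "c_Pre", "c_5"),
                   subject_id = rep(c("a", "b", "c"), each = 2),
                   group = rep(c("A", "A", "B"), each = 2),
                   time_h = rep(c(0, 5), 3))
  design <- study_design(df)
  x <- expression_matrix(matrix(rnorm(12), 2, 6,
                                dimnames = list(c("t1", "t2"),
                                                df$sample_id)))
  expect_error(baseline_group_test(x, design), "fewer than 2 Pre")
})

test_that("a baseline hit warns but does not abort", {
  d <- small_study(seed = 2, m = 5)
  x <- d$expression
  pre_a <- d$design$sample_id[d$design$time_h == 0 &
                                d$design$group == "Endurance"]
  x[1, pre_a] <- x[1, pre_a] + 50      # gross baseline difference
  expect_warning(res <- baseline_group_test(x, d$design),
                 "differ between groups at baseline")
  expect_identical(attr(res, "n_significant"), 1L)
})
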