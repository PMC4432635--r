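test_that("config validation names the offending field", {
  expect_error(sim_config(n_transcripts = 0), "n_transcripts")
  expect_error(sim_config(sigma_noise = -1), "sigma_noise")
  expect_error(sim_config(times_h = c(2.5, 5)), "Pre")
  expect_error(sim_config(groups = "OnlyOne"), "groups")
  expect_error(sim_config(class_proportions = c(null = 0.5)), "sum to 1")
  expect_error(sim_config(class_proportions = c(0.5, 0.5)), "named")
  expect_error(sim_config(class_proportions = c(wiggly = 1)),
               "unknown effect class")
})

test_that("plant_effect encodes the effect taxonomy", {
  groups <- c("Control", "Endurance", "Resistance")
  times <- c(0, 2.5, 5)
  sp <- plant_effect("specific:Endurance", 1.0, groups, times)
  expect_setequal(paste(sp$group, sp$time_h, sp$shift),
                  c("Endurance 2.5 1", "Endurance 5 1"))
  expect_identical(nrow(plant_effect("null", 1.0, groups, times)), 0L)
  gd <- plant_effect("general_dependent", 1.0, groups, times)
  expect_setequal(gd$shift[gd$group == "Endurance"], 1)
  expect_setequal(gd$shift[gd$group == "Resistance"], -1)
  expect_false("Control" %in% gd$group)
  tg <- plant_effect("time_all_groups", 1.0, groups, times)
  expect_setequal(unique(tg$group), groups)
  expect_true(all(tg$shift == 1))
  # Pre cells are never planted, in any class
  for (cl in c("specific:Control", "general_independent",
               "general_dependent", "time_all_groups")) {
    expect_false(0 %in% plant_effect(cl, 1, groups, times)$time_h)
  }
  expect_error(plant_effect("bogus", 1, groups, times), "unknown")
  expect_error(plant_effect("specific:Swimming", 1, groups, times),
               "unknown group")
})

test_that("zero-noise all-null data is the baseline vector everywhere", {
  cfg <- sim_config(n_transcripts = 20, sigma_noise = 0, sigma_subject = 0,
                    seed = 4)
  d <- generate_dataset(cfg)
  expect_identical(ncol(d$expression), 54L)
  for (j in seq_len(ncol(d$expression))) {
    expect_identical(d$expression[, j], d$expression[, 1],
                     ignore_attr = TRUE)
  }
})

test_that("the generator reproduces the three-group array study shape", {
  cfg <- sim_config(n_transcripts = 28869, seed = 2)
  d <- generate_dataset(cfg)
  expect_identical(dim(d$expression), c(28869L, 54L))
  expect_identical(nrow(d$design), 54L)
  expect_true(is_balanced(d$design))
  expect_identical(sort(unique(d$design$group)),
                   c("Control", "Endurance", "Resistance"))
  expect_identical(sort(unique(d$design$time_h)), c(0, 2.5, 5))
  expect_identical(sum(d$design$time_h == 0), 18L)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_transcripts = 500, seed = 1,
                    class_proportions = c(null = 0.8,
                                          "specific:Endurance" = 0.2))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(sim_config(n_transcripts = 500, seed = 2,
                                    class_proportions = c(null = 0.8,
                                                          "specific:Endurance" = 0.2)))
  expect_false(identical(d1$expression, d3$expression))
})

test_that("planted shifts are recovered as noise vanishes", {
  cfg <- sim_config(n_transcripts = 50, sigma_noise = 1e-8,
                    sigma_subject = 0.7, seed = 9,
                    class_proportions = c("specific:Resistance" = 1))
  d <- generate_dataset(cfg)
  ratios <- normalize_to_pre(d$expression, d$design)
  res_5h <- d$design$sample_id[d$design$group == "Resistance" &
                                 d$design$time_h == 5]
  con_5h <- d$design$sample_id[d$design$group == "Control" &
                                 d$design$time_h == 5]
  expect_equal(unname(rowMeans(ratios[, res_5h])), rep(1, 50),
               tolerance = 1e-6)
  expect_equal(unname(rowMeans(ratios[, con_5h])), rep(0, 50),
               tolerance = 1e-6)
})

test_that("class apportionment follows the largest remainder", {
  cfg <- sim_config(n_transcripts = 10, seed = 1,
                    class_proportions = c(null = 0.55,
                                          time_all_groups = 0.45))
  d <- generate_dataset(cfg)
  expect_identical(as.integer(table(d$truth$planted_class)[
    c("null", "time_all_groups")]), c(6L, 4L))
})

test_that("truth tables serialize with their planted cells", {
  cfg <- sim_config(n_transcripts = 6, seed = 3,
                    class_proportions = c(null = 0.5,
                                          "specific:Endurance" = 0.5))
  d <- generate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(d$truth, path)
  back <- utils::read.delim(path)
  back$affected_cells[is.na(back$affected_cells)] <- ""
  expect_identical(nrow(back), 6L)
  planted <- back$affected_cells[back$planted_class == "specific:Endurance"]
  expect_true(all(grepl("Endurance@2.5h:\\+1", planted)))
  expect_true(all(back$affected_cells[back$planted_class == "null"] == ""))
})
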