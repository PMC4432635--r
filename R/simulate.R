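#' Configuration for the planted-effect expression simulator
#'
#' The simulator emulates the structure of a subject-paired,
#' multi-group, multi-timepoint array study: three groups of six
#' subjects, each sampled at baseline (Pre) and two post-exercise
#' recovery times, log2-scale intensities with a per-subject random
#' intercept shared across that subject's samples, homoscedastic
#' Gaussian noise on the log2 scale, and labelled planted effect classes
#' mirroring the categories the classifier recovers:
#'
#' * `null` — no effect;
#' * `specific:<group>` — only that group's post cells shifted;
#' * `general_independent` — both exercise groups shifted equally;
#' * `general_dependent` — the two exercise groups shifted in opposite
#'   directions;
#' * `time_all_groups` — every group's post cells shifted equally.
#'
#' Pre cells never carry planted shifts.  Default magnitudes
#' (`effect_size` 1 log2 unit, `sigma_noise` 0.25, `sigma_subject` 0.5)
#' give high but not trivial power at n = 6 per group; baseline level
#' defaults (mean 8, SD 1.5 log2) are typical of RMA-summarized arrays.
#'
#' @param n_transcripts number of transcripts.
#' @param n_subjects_per_group subjects per group (default 6).
#' @param groups ordered group labels; first entry is the non-exercise
#'   control unless `exercise_groups` says otherwise.
#' @param exercise_groups which groups the `general_*` classes affect
#'   (default: all but the first).
#' @param times_h time points in hours, including Pre = 0.
#' @param sigma_noise residual SD, log2 units.
#' @param sigma_subject subject random-intercept SD, log2 units.
#' @param baseline_mean,baseline_sd distribution of per-transcript Pre
#'   level, log2 units.
#' @param class_proportions named numeric mapping effect class to the
#'   fraction of transcripts planted with it; must sum to 1.
#' @param effect_size planted shift per affected group x time cell,
#'   log2 units.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 1000L,
                       n_subjects_per_group = 6L,
                       groups = c("Control", "Endurance", "Resistance"),
                       exercise_groups = groups[-1L],
                       times_h = c(0, 2.5, 5),
                       sigma_noise = 0.25,
                       sigma_subject = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       class_proportions = c(null = 1),
                       effect_size = 1.0,
                       seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              n_subjects_per_group = as.integer(n_subjects_per_group),
              groups = as.character(groups),
              exercise_groups = as.character(exercise_groups),
              times_h = as.numeric(times_h),
              sigma_noise = sigma_noise, sigma_subject = sigma_subject,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              class_proportions = class_proportions,
              effect_size = effect_size, seed = as.integer(seed))
  if (cfg$n_transcripts < 1L) input_error("n_transcripts must be positive")
  if (cfg$n_subjects_per_group < 1L) {
    input_error("n_subjects_per_group must be positive")
  }
  if (length(cfg$groups) < 2L) input_error("groups: need at least 2")
  if (anyDuplicated(cfg$groups)) input_error("groups: duplicate label")
  if (!all(cfg$exercise_groups %in% cfg$groups)) {
    input_error("exercise_groups must be a subset of groups")
  }
  if (!PRE_TIME %in% cfg$times_h) {
    input_error("times_h must include the Pre level (0)")
  }
  if (length(cfg$times_h) < 2L) input_error("times_h: need Pre plus >= 1 post")
  for (f in c("sigma_noise", "sigma_subject", "baseline_sd")) {
    if (cfg[[f]] < 0) input_error(f, " must be >= 0")
  }
  if (is.null(names(cfg$class_proportions)) ||
      any(!nzchar(names(cfg$class_proportions)))) {
    input_error("class_proportions must be a named vector")
  }
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9) {
    input_error("class_proportions must sum to 1 (got ",
                sum(cfg$class_proportions), ")")
  }
  if (any(cfg$class_proportions < 0)) {
    input_error("class_proportions must be >= 0")
  }
  for (cl in names(cfg$class_proportions)) {
    plant_effect(cl, cfg$effect_size, cfg$groups, cfg$times_h,
                 cfg$exercise_groups)  # validates the label
  }
  structure(cfg, class = "sim_config")
}

#' Planted cells for one effect class
#'
#' Encodes each effect class as the set of (group, time) cells it
#' shifts, with the signed log2 shift.  Pre cells are never affected;
#' control-group cells are affected only by `time_all_groups`.
#' `general_dependent` realizes "responds to both exercise types, but in
#' different ways" as equal-magnitude, opposite-sign shifts in the two
#' exercise groups.
#'
#' @param class_label one of `"null"`, `"specific:<group>"`,
#'   `"general_independent"`, `"general_dependent"`,
#'   `"time_all_groups"`.
#' @param effect_size shift magnitude, log2 units.
#' @param groups,times_h design labels (times include Pre = 0).
#' @param exercise_groups the two exercise groups used by the
#'   `general_*` classes (default: all but the first group).
#' @return data.frame with columns `group`, `time_h`, `shift`
#'   (zero rows for `"null"`).
#' @export
plant_effect <- function(class_label, effect_size, groups, times_h,
                         exercise_groups = groups[-1L]) {
  post <- setdiff(times_h, PRE_TIME)
  cells <- function(gs, shifts) {
    data.frame(group = rep(gs, each = length(post)),
               time_h = rep(post, length(gs)),
               shift = rep(shifts, each = length(post)),
               stringsAsFactors = FALSE)
  }
  empty <- data.frame(group = character(), time_h = numeric(),
                      shift = numeric(), stringsAsFactors = FALSE)
  if (class_label == "null") return(empty)
  if (startsWith(class_label, "specific:")) {
    g <- sub("^specific:", "", class_label)
    if (!g %in% groups) {
      input_error("unknown group in effect class '", class_label, "'")
    }
    return(cells(g, effect_size))
  }
  if (class_label == "general_independent") {
    if (length(exercise_groups) < 2L) {
      input_error("general classes need >= 2 exercise groups")
    }
    return(cells(exercise_groups, rep(effect_size, length(exercise_groups))))
  }
  if (class_label == "general_dependent") {
    if (length(exercise_groups) < 2L) {
      input_error("general classes need >= 2 exercise groups")
    }
    signs <- rep(c(1, -1), length.out = length(exercise_groups))
    return(cells(exercise_groups, effect_size * signs))
  }
  if (class_label == "time_all_groups") {
    return(cells(groups, rep(effect_size, length(groups))))
  }
  input_error("unknown effect class label '", class_label, "'")
}

#' Generate a labelled synthetic expression study
#'
#' Draws one dataset under `config`.  Each value is
#' `baseline_transcript + subject_intercept + planted_shift(group, time)
#' + N(0, sigma_noise)`.  The RNG draw order is fixed and documented for
#' reproducibility: transcript baselines first, then subject intercepts,
#' then the noise matrix row-major (transcript by transcript).  The same
#' config (including seed) yields bit-identical output.
#'
#' Effect classes are assigned to contiguous transcript blocks using
#' largest-remainder rounding of `class_proportions`; the truth table
#' records every transcript's class and its planted cells.
#'
#' @param config a [sim_config()].
#' @return list with elements `expression` (log2 matrix, see
#'   [expression_matrix()]), `design` (a [study_design()]) and `truth`
#'   (data.frame `transcript_id`, `planted_class`, plus the per-class
#'   planted cells in attribute `"planted_cells"`).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  m <- config$n_transcripts
  n <- config$n_subjects_per_group
  groups <- config$groups
  times <- sort(config$times_h)
  G <- length(groups); Tn <- length(times)
  prefixes <- make.unique(substr(groups, 1L, 3L), sep = "")
  subj_ids <- unlist(lapply(prefixes, function(p) {
    sprintf("%s%02d", p, seq_len(n))
  }))
  subj_group <- rep(groups, each = n)
  design_df <- data.frame(
    sample_id = paste0(rep(subj_ids, each = Tn), "_",
                       rep(time_label(times), G * n)),
    subject_id = rep(subj_ids, each = Tn),
    group = rep(subj_group, each = Tn),
    time_h = rep(times, G * n),
    stringsAsFactors = FALSE)
  design <- study_design(design_df, groups = groups)
  # class assignment: largest-remainder apportionment, contiguous blocks
  prop <- config$class_proportions
  exact <- prop * m
  cnt <- floor(exact)
  rem <- m - sum(cnt)
  if (rem > 0) {
    top <- order(exact - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[top] <- cnt[top] + 1
  }
  classes <- rep(names(prop), times = cnt)
  transcript_ids <- sprintf("TC%06d", seq_len(m))
  # planted shift per class x sample
  N <- nrow(design_df)
  class_levels <- names(prop)
  shift_by_class <- matrix(0, length(class_levels), N,
                           dimnames = list(class_levels, design_df$sample_id))
  planted_cells <- stats::setNames(vector("list", length(class_levels)),
                                   class_levels)
  for (cl in class_levels) {
    cells <- plant_effect(cl, config$effect_size, groups, times,
                          config$exercise_groups)
    planted_cells[[cl]] <- cells
    if (nrow(cells)) {
      for (k in seq_len(nrow(cells))) {
        hit <- design_df$group == cells$group[k] &
          design_df$time_h == cells$time_h[k]
        shift_by_class[cl, hit] <- cells$shift[k]
      }
    }
  }
  set.seed(config$seed)
  baseline <- stats::rnorm(m, config$baseline_mean, config$baseline_sd)
  b_subj <- stats::rnorm(length(subj_ids), 0, config$sigma_subject)
  noise <- matrix(stats::rnorm(m * N, 0, config$sigma_noise),
                  nrow = m, byrow = TRUE)
  cls_idx <- match(classes, class_levels)
  subj_idx <- match(design_df$subject_id, subj_ids)
  values <- baseline +
    matrix(b_subj[subj_idx], m, N, byrow = TRUE) +
    shift_by_class[cls_idx, , drop = FALSE] +
    noise
  dimnames(values) <- list(transcript_ids, design_df$sample_id)
  truth <- data.frame(transcript_id = transcript_ids,
                      planted_class = classes,
                      stringsAsFactors = FALSE)
  attr(truth, "planted_cells") <- planted_cells
  list(expression = expression_matrix(values), design = design,
       truth = truth)
}

#' Write a simulation truth table as TSV
#'
#' Columns `transcript_id`, `planted_class`, `affected_cells`; the cell
#' list is serialized as `group@time:+shift` entries separated by `;`
#' (empty for null transcripts).
#'
#' @param truth truth table from [generate_dataset()].
#' @param path output file path.
#' @export
write_truth <- function(truth, path) {
  cells <- attr(truth, "planted_cells")
  enc <- vapply(truth$planted_class, function(cl) {
    df <- cells[[cl]]
    if (is.null(df) || !nrow(df)) return("")
    paste(sprintf("%s@%s:%+g", df$group, time_label(df$time_h), df$shift),
          collapse = ";")
  }, character(1))
  out <- data.frame(transcript_id = truth$transcript_id,
                    planted_class = truth$planted_class,
                    affected_cells = enc, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
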