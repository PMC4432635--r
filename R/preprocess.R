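#' Normalize every sample to its subject's own Pre value
#'
#' The quantity of interest in a paired time-course design is the change
#' from each subject's own baseline, so each log2 expression value has
#' the same transcript's log2 value in that subject's Pre sample
#' subtracted (equivalently: division of linear intensities).  Pre
#' columns become identically zero.  Any per-subject additive constant —
#' a subject random intercept, an array-level offset — cancels exactly,
#' which is what makes the downstream repeated-measures model on the
#' ratios well posed.
#'
#' @param x log2-scale expression matrix (see [expression_matrix()]).
#' @param design matching [study_design()]; every subject must have a
#'   Pre sample (enforced at design validation, re-asserted here).
#' @return matrix of log2 fold changes versus own Pre, same shape and
#'   dimnames as `x` (the `gene_symbols` attribute is carried over).
#' @export
normalize_to_pre <- function(x, design) {
  check_samples_match(x, design)
  pre <- design$sample_id[design$time_h == PRE_TIME]
  pre_of_subject <- stats::setNames(pre,
                                    design$subject_id[design$time_h == PRE_TIME])
  if (!all(design$subject_id %in% names(pre_of_subject))) {
    input_error("subject without Pre sample: ",
                setdiff(design$subject_id, names(pre_of_subject))[1L])
  }
  ref_col <- pre_of_subject[design$subject_id]
  ratios <- x[, design$sample_id, drop = FALSE] -
    x[, ref_col, drop = FALSE]
  colnames(ratios) <- design$sample_id
  attr(ratios, "gene_symbols") <- attr(x, "gene_symbols")
  ratios
}

#' Baseline group-difference check on Pre samples only
#'
#' Before analysing post-exercise changes, the Pre samples alone are
#' screened for unintended between-group differences with a
#' per-transcript one-way fixed-effects ANOVA across groups, followed by
#' Benjamini-Hochberg adjustment across transcripts.  In a sound
#' randomized design no transcript should reach FDR < `alpha`; the check
#' is a descriptive gate, so a hit raises a warning rather than an
#' error.
#'
#' Transcripts with (numerically) zero total variance across the Pre
#' samples get `F = 0`, `p = 1` by convention.
#'
#' @param x log2 expression matrix.
#' @param design matching `study_design`; needs >= 2 groups with >= 2
#'   Pre samples each.
#' @param alpha FDR level of the gate (default 0.05).
#' @return data.frame with columns `transcript_id`, `F`, `p`, `q`, and
#'   attribute `n_significant` = number of transcripts with `q < alpha`.
#' @export
baseline_group_test <- function(x, design, alpha = 0.05) {
  check_samples_match(x, design)
  pre <- design[design$time_h == PRE_TIME, , drop = FALSE]
  grp <- factor(pre$group, levels = attr(design, "groups"))
  counts <- table(grp)
  if (length(counts) < 2L) input_error("baseline test needs >= 2 groups")
  if (any(counts < 2L)) {
    input_error("group '", names(counts)[counts < 2L][1L],
                "' has fewer than 2 Pre samples (no within-group variance)")
  }
  y <- x[, pre$sample_id, drop = FALSE]
  n <- ncol(y)
  k <- length(counts)
  # vectorized one-way ANOVA across all transcripts
  gmeans <- y %*% stats::model.matrix(~ grp - 1) %*%
    diag(1 / as.numeric(counts), k)
  grand <- rowMeans(y)
  ss_between <- as.numeric((gmeans - grand)^2 %*% as.numeric(counts))
  fitted <- gmeans[, as.integer(grp), drop = FALSE]
  ss_within <- rowSums((y - fitted)^2)
  ss_total <- ss_between + ss_within
  Fstat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ss_total < 1e-12 | ss_within < 1e-12 & ss_between < 1e-12
  Fstat[degenerate] <- 0
  p[degenerate] <- 1
  q <- bh_fdr(p)
  out <- data.frame(transcript_id = rownames(x), F = Fstat, p = p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  n_sig <- sum(q < alpha, na.rm = TRUE)
  if (n_sig > 0L) {
    warning(n_sig, " transcript(s) differ between groups at baseline ",
            "(FDR < ", alpha, "); check randomization", call. = FALSE)
  }
  attr(out, "n_significant") <- n_sig
  out
}
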