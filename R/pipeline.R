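#' Run the full analysis pipeline
#'
#' Convenience wrapper chaining the stages: baseline group check on Pre
#' samples, per-subject Pre-normalization, per-transcript
#' repeated-measures model fit, per-family BH-FDR, and rule-based
#' classification with count report.
#'
#' @param x log2 expression matrix (see [expression_matrix()]).
#' @param design matching [study_design()].
#' @param spec optional [model_spec()] (derived from the design by
#'   default).
#' @param alpha FDR threshold used throughout (default 0.05).
#' @param p_interaction_floor,p_vs_pre raw-p thresholds of the
#'   time-regulated rule.
#' @param exercise_groups the two exercise groups (default: all but the
#'   first group).
#' @param baseline_check run the Pre-only between-group gate (default
#'   TRUE; it warns, never aborts).
#' @return an `exertome_run` list: `ratios`, `baseline`, `anova`
#'   (q-augmented), `classification`, `counts`.
#' @export
run_pipeline <- function(x, design, spec = NULL, alpha = 0.05,
                         p_interaction_floor = 0.1, p_vs_pre = 0.05,
                         exercise_groups = NULL, baseline_check = TRUE) {
  baseline <- if (baseline_check) baseline_group_test(x, design, alpha)
  ratios <- normalize_to_pre(x, design)
  anova <- apply_families(fit_all(ratios, design, spec))
  classification <- classify_transcripts(
    anova, alpha = alpha, p_interaction_floor = p_interaction_floor,
    p_vs_pre = p_vs_pre, exercise_groups = exercise_groups)
  structure(list(ratios = ratios, baseline = baseline, anova = anova,
                 classification = classification,
                 counts = build_count_report(classification)),
            class = "exertome_run")
}

#' @export
print.exertome_run <- function(x, ...) {
  cat("exertome pipeline run: ", nrow(x$anova), " transcripts, ",
      sum(!x$anova$converged), " non-converged\n", sep = "")
  if (!is.null(x$baseline)) {
    cat("Baseline Pre-only check: ", attr(x$baseline, "n_significant"),
        " transcript(s) at FDR < 0.05\n\n", sep = "")
  }
  print(x$counts)
  invisible(x)
}
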