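# rule sets turning the per-transcript q/p table into biological labels

#' @keywords internal
get_spec <- function(anova) {
  spec <- attr(anova, "spec")
  if (is.null(spec)) input_error("table lacks its model spec attribute")
  spec
}

#' @keywords internal
need_cols <- function(anova, cols) {
  miss <- setdiff(cols, names(anova))
  if (length(miss)) {
    input_error("missing column(s) ", paste(miss, collapse = ", "),
                "; run fit_all() and apply_families() first")
  }
}

#' Changed-versus-Pre flags
#'
#' A transcript is changed in group g at time t when the q-value of the
#' corresponding versus-Pre contrast is below `alpha` (default: FDR
#' 0.05, the pipeline's blanket significance scale).
#'
#' @param anova an `anova_table` with q columns ([apply_families()]).
#' @param alpha FDR threshold.
#' @return logical matrix, transcripts x vs-Pre contrasts (`NA` for
#'   non-converged transcripts).
#' @export
changed_vs_pre <- function(anova, alpha = 0.05) {
  spec <- get_spec(anova)
  ctr <- spec$contrasts[spec$contrasts$type == "vs_pre", ]
  need_cols(anova, paste0(ctr$name, ".q"))
  out <- sapply(ctr$name, function(nm) anova[[paste0(nm, ".q")]] < alpha)
  out <- matrix(out, nrow = nrow(anova),
                dimnames = list(anova$transcript_id, ctr$name))
  out
}

#' Changed-between-groups flags
#'
#' Flag is set for a group pair at a time point when that between-group
#' contrast's q-value is below `alpha`.
#'
#' @inheritParams changed_vs_pre
#' @return logical matrix, transcripts x between-group contrasts.
#' @export
changed_between_groups <- function(anova, alpha = 0.05) {
  spec <- get_spec(anova)
  ctr <- spec$contrasts[spec$contrasts$type == "between", ]
  need_cols(anova, paste0(ctr$name, ".q"))
  out <- sapply(ctr$name, function(nm) anova[[paste0(nm, ".q")]] < alpha)
  matrix(out, nrow = nrow(anova),
         dimnames = list(anova$transcript_id, ctr$name))
}

# name of the between contrast for an unordered group pair at time t
#' @keywords internal
pair_contrast <- function(spec, ga, gb, time_h) {
  ctr <- spec$contrasts
  hit <- ctr$type == "between" & ctr$time_h == time_h &
    ((ctr$g1 == ga & ctr$g2 == gb) | (ctr$g1 == gb & ctr$g2 == ga))
  ctr$name[hit][1L]
}

#' Group-specific transcript labels
#'
#' A transcript is specific to group g when (i) at one or more time
#' points it is significantly different from Pre in g *and* from both
#' other groups at that same time, and (ii) it is never significantly
#' different from Pre in any other group at any time.  All clauses use
#' FDR q < `alpha`.  At most one group can satisfy the rule (the
#' exclusion clause forbids any second changed group).
#'
#' @param cvp changed-vs-Pre matrix from [changed_vs_pre()].
#' @param cbg between-group matrix from [changed_between_groups()].
#' @param spec the `model_spec` the tables were built under.
#' @return character vector of labels: a group name, `"none"`, or `NA`
#'   for transcripts with missing flags (non-converged).
#' @export
group_specific <- function(cvp, cbg, spec) {
  groups <- spec$groups
  times <- spec$post_times
  codes <- spec$group_codes
  tl <- time_label(times)
  label <- rep("none", nrow(cvp))
  undecided <- rowSums(is.na(cvp)) > 0 | rowSums(is.na(cbg)) > 0
  for (g in groups) {
    others <- setdiff(groups, g)
    hit_any <- rep(FALSE, nrow(cvp))
    for (ti in seq_along(times)) {
      own <- cvp[, paste0(codes[g], tl[ti])]
      sep <- Reduce(`&`, lapply(others, function(o) {
        cbg[, pair_contrast(spec, g, o, times[ti])]
      }))
      hit_any <- hit_any | (own & sep)
    }
    quiet_elsewhere <- !Reduce(`|`, lapply(others, function(o) {
      Reduce(`|`, lapply(tl, function(t) cvp[, paste0(codes[o], t)]))
    }))
    label[which(hit_any & quiet_elsewhere)] <- g
  }
  label[undecided] <- NA_character_
  label
}

#' Exercise-general transcript labels
#'
#' A transcript responds generally to exercise when it is changed
#' versus Pre (q < `alpha`) in *both* exercise groups, each at one or
#' more time points.  Among these, the response is *dependent* of
#' exercise type when the two exercise groups differ from each other
#' (between-group q < `alpha`) at one or more time points, and
#' *independent* otherwise.
#'
#' @inheritParams group_specific
#' @param exercise_groups the two exercise group labels (default: all
#'   model groups except the first, which is taken as control).
#' @return character vector: `"independent"`, `"dependent"`, `"none"`,
#'   or `NA` for undecidable transcripts.
#' @export
exercise_general <- function(cvp, cbg, spec,
                             exercise_groups = spec$groups[-1L]) {
  if (length(exercise_groups) != 2L) {
    input_error("exercise_general needs exactly 2 exercise groups")
  }
  codes <- spec$group_codes
  tl <- time_label(spec$post_times)
  changed_in <- function(g) {
    Reduce(`|`, lapply(tl, function(t) cvp[, paste0(codes[g], t)]))
  }
  candidate <- changed_in(exercise_groups[1L]) & changed_in(exercise_groups[2L])
  differs <- Reduce(`|`, lapply(spec$post_times, function(t) {
    cbg[, pair_contrast(spec, exercise_groups[1L], exercise_groups[2L], t)]
  }))
  label <- ifelse(candidate & differs, "dependent",
                  ifelse(candidate & !differs, "independent", "none"))
  label[is.na(candidate) | (candidate & is.na(differs))] <- NA_character_
  label
}

#' Time-regulated transcript flags
#'
#' Transcripts regulated over time irrespective of exercise: no
#' interaction signal (raw Time x Group p > `p_interaction_floor`), an
#' overall Time effect at FDR < `alpha_fdr`, and — to guard against a
#' shared exercise effect masquerading as a time effect when two thirds
#' of the samples are exercise samples — *all* groups significantly
#' different from Pre (raw p < `p_vs_pre`) at the same time point.
#'
#' @param anova `anova_table` with q columns.
#' @param alpha_fdr FDR threshold on the Time effect (default 0.05).
#' @param p_interaction_floor raw interaction p-value floor
#'   (default 0.1).
#' @param p_vs_pre raw vs-Pre p-value threshold (default 0.05).
#' @return logical matrix with one column per post time plus a final
#'   `any` column.
#' @export
time_regulated <- function(anova, alpha_fdr = 0.05,
                           p_interaction_floor = 0.1, p_vs_pre = 0.05) {
  spec <- get_spec(anova)
  need_cols(anova, c("Time.q", "TimexGroup.p"))
  codes <- spec$group_codes
  tl <- time_label(spec$post_times)
  base <- anova$TimexGroup.p > p_interaction_floor & anova$Time.q < alpha_fdr
  per_time <- sapply(tl, function(t) {
    allg <- Reduce(`&`, lapply(spec$groups, function(g) {
      anova[[paste0(codes[g], t, ".p")]] < p_vs_pre
    }))
    base & allg
  })
  per_time <- matrix(per_time, nrow = nrow(anova),
                     dimnames = list(anova$transcript_id, tl))
  cbind(per_time, any = apply(per_time, 1L, function(x) {
    if (any(x, na.rm = TRUE)) TRUE else if (anyNA(x)) NA else FALSE
  }))
}

#' Classify every transcript under all rule sets
#'
#' Applies the four rule families — changed versus Pre, changed between
#' groups, group-specific, exercise-general, time-regulated — to a
#' q-augmented model table.  The classification is a pure function of
#' that table; non-converged transcripts are left unlabelled (`NA`).
#'
#' @param anova `anova_table` with q columns ([apply_families()]).
#' @param alpha FDR threshold used by every FDR clause (default 0.05).
#' @param p_interaction_floor,p_vs_pre raw-p thresholds of the
#'   time-regulated rule.
#' @param exercise_groups the two exercise groups (default: all model
#'   groups except the first).
#' @return a `classification_table` data.frame: per transcript the
#'   boolean flag columns (named by the contrast vocabulary), the
#'   `specific_label`, `general_label` and time-regulated columns.
#'   Thresholds are recorded in the `"thresholds"` attribute.
#' @export
classify_transcripts <- function(anova, alpha = 0.05,
                                 p_interaction_floor = 0.1,
                                 p_vs_pre = 0.05,
                                 exercise_groups = NULL) {
  spec <- get_spec(anova)
  exercise_groups <- exercise_groups %||% spec$groups[-1L]
  cvp <- changed_vs_pre(anova, alpha)
  cbg <- changed_between_groups(anova, alpha)
  tr <- time_regulated(anova, alpha, p_interaction_floor, p_vs_pre)
  out <- data.frame(transcript_id = anova$transcript_id,
                    converged = anova$converged,
                    stringsAsFactors = FALSE)
  for (nm in colnames(cvp)) out[[paste0("changed.", nm)]] <- cvp[, nm]
  for (nm in colnames(cbg)) out[[paste0("diff.", nm)]] <- cbg[, nm]
  out$specific_label <- group_specific(cvp, cbg, spec)
  out$general_label <- exercise_general(cvp, cbg, spec, exercise_groups)
  for (nm in setdiff(colnames(tr), "any")) {
    out[[paste0("time_regulated.", nm)]] <- tr[, nm]
  }
  out$time_regulated <- tr[, "any"]
  structure(out, spec = spec,
            thresholds = list(alpha = alpha,
                              p_interaction_floor = p_interaction_floor,
                              p_vs_pre = p_vs_pre),
            exercise_groups = exercise_groups,
            class = c("classification_table", "data.frame"))
}

#' Count report over all classifications
#'
#' Summarizes a classification table into the study's six count tables:
#' changed versus Pre per group x time; pairwise between-group counts
#' per time (symmetric matrices); group-specific counts; exercise-
#' general counts split independent/dependent; and time-regulated
#' counts (total and per time).
#'
#' @param classif a `classification_table`.
#' @return a `count_report` list with elements `changed_vs_pre`,
#'   `between` (one matrix per time), `group_specific`,
#'   `exercise_general`, `time_regulated`, `n_transcripts`,
#'   `n_unlabelled`.
#' @export
build_count_report <- function(classif) {
  spec <- attr(classif, "spec")
  codes <- spec$group_codes
  tl <- time_label(spec$post_times)
  G <- length(spec$groups)
  cvp_counts <- matrix(0L, G, length(tl),
                       dimnames = list(spec$groups, tl))
  for (g in seq_len(G)) for (t in seq_along(tl)) {
    cvp_counts[g, t] <- sum(classif[[paste0("changed.", codes[g], tl[t])]],
                            na.rm = TRUE)
  }
  between <- lapply(seq_along(tl), function(t) {
    mat <- matrix(NA_integer_, G, G, dimnames = list(spec$groups, spec$groups))
    for (a in seq_len(G - 1L)) for (b in (a + 1L):G) {
      nm <- pair_contrast(spec, spec$groups[a], spec$groups[b],
                          spec$post_times[t])
      cnt <- sum(classif[[paste0("diff.", nm)]], na.rm = TRUE)
      mat[a, b] <- mat[b, a] <- cnt
    }
    mat
  })
  names(between) <- tl
  specific <- vapply(spec$groups, function(g) {
    sum(classif$specific_label == g, na.rm = TRUE)
  }, integer(1))
  general <- c(independent = sum(classif$general_label == "independent",
                                 na.rm = TRUE),
               dependent = sum(classif$general_label == "dependent",
                               na.rm = TRUE))
  tr_per_time <- vapply(tl, function(t) {
    sum(classif[[paste0("time_regulated.", t)]], na.rm = TRUE)
  }, integer(1))
  tregs <- c(total = sum(classif$time_regulated, na.rm = TRUE), tr_per_time)
  structure(list(changed_vs_pre = cvp_counts, between = between,
                 group_specific = specific, exercise_general = general,
                 time_regulated = tregs,
                 n_transcripts = nrow(classif),
                 n_unlabelled = sum(is.na(classif$specific_label)),
                 thresholds = attr(classif, "thresholds")),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("Changed mRNA versus Pre (FDR < ", x$thresholds$alpha, ")\n", sep = "")
  print(x$changed_vs_pre)
  for (t in names(x$between)) {
    cat("\nChanged mRNA between groups at ", t, "\n", sep = "")
    print(x$between[[t]])
  }
  cat("\nChanged versus Pre, specific to only one group\n")
  print(x$group_specific)
  cat("\nChanged versus Pre in both exercise groups\n")
  print(x$exercise_general)
  cat("\nTime regulated (unrelated to exercise)\n")
  print(x$time_regulated)
  cat("\n", x$n_transcripts, " transcripts analysed\n", sep = "")
  invisible(x)
}

#' Write a classification table as TSV
#'
#' @param classif a `classification_table`.
#' @param path output file path.
#' @export
write_classification <- function(classif, path) {
  utils::write.table(as.data.frame(classif), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
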