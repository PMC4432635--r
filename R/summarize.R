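# per-gene summaries, symbol queries and spreadsheet-style export

#' Geometric mean with back-transformed s.e.m. band
#'
#' Summaries of fold changes are presented as the geometric mean with a
#' multiplicative error band: the arithmetic mean `m` and its standard
#' error `s` (sample SD / sqrt(n), 0 when n = 1) are computed on the
#' log2 scale and back-transformed, giving `(2^m, 2^(m-s), 2^(m+s))`.
#' The band is symmetric on the log scale by construction.
#'
#' @param log2_values numeric vector of log2 ratios (>= 1 finite value).
#' @return named numeric: `geo_mean`, `lower`, `upper` (linear fold
#'   scale).
#' @export
geo_mean_sem <- function(log2_values) {
  x <- log2_values[is.finite(log2_values)]
  if (!length(x)) input_error("geo_mean_sem: no finite values")
  m <- mean(x)
  s <- if (length(x) == 1L) 0 else stats::sd(x) / sqrt(length(x))
  c(geo_mean = 2^m, lower = 2^(m - s), upper = 2^(m + s))
}

# group x time summary table (incl. Pre = exactly 1-fold) for one
# transcript's ratio row
#' @keywords internal
summarize_cells <- function(ratio_row, design) {
  groups <- attr(design, "groups")
  times <- attr(design, "times_h")
  out <- expand.grid(group = groups, time_h = times,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats <- t(apply(out, 1L, function(r) {
    sel <- design$group == r[["group"]] &
      design$time_h == as.numeric(r[["time_h"]])
    geo_mean_sem(ratio_row[design$sample_id[sel]])
  }))
  cbind(out, as.data.frame(stats))
}

#' Query the pipeline results by gene symbol
#'
#' The spreadsheet-style access pattern: give a gene symbol, get back —
#' for every transcript annotated with it — the group x time geometric
#' mean fold changes with back-transformed s.e.m. bands, the individual
#' per-subject log2 ratios, the significant statistical flags in the
#' field's vocabulary (`E2.5h`, `EvC2.5h`, ...) and the transcript's
#' classification labels.  Matching is exact but case-insensitive.  An
#' unknown symbol returns an empty list with a message, not an error.
#'
#' @param symbol gene symbol to look up.
#' @param ratios Pre-normalized log2 ratio matrix.
#' @param design matching `study_design`.
#' @param anova q-augmented `anova_table`.
#' @param classif `classification_table`.
#' @param annotation data.frame `transcript_id`, `gene_symbol`.
#' @param alpha flag threshold on q-values (default 0.05).
#' @return list of `gene_summary` objects, one per matching transcript.
#' @export
query_gene <- function(symbol, ratios, design, anova, classif, annotation,
                       alpha = 0.05) {
  hits <- annotation$transcript_id[
    tolower(annotation$gene_symbol) == tolower(symbol)]
  hits <- intersect(hits, rownames(ratios))
  if (!length(hits)) {
    message("symbol '", symbol, "' not found in the annotation")
    return(list())
  }
  spec <- get_spec(anova)
  lapply(hits, function(id) {
    row <- ratios[id, ]
    arow <- anova[anova$transcript_id == id, , drop = FALSE]
    crow <- classif[classif$transcript_id == id, , drop = FALSE]
    qcols <- grep("\\.q$", names(arow), value = TRUE)
    flags <- sub("\\.q$", "", qcols[!is.na(arow[1, qcols]) &
                                      arow[1, qcols] < alpha])
    individual <- data.frame(subject_id = design$subject_id,
                             group = design$group,
                             time_h = design$time_h,
                             log2_ratio = as.numeric(row[design$sample_id]),
                             stringsAsFactors = FALSE)
    structure(list(transcript_id = id, symbol = symbol,
                   means = summarize_cells(row, design),
                   individual = individual,
                   flags = flags,
                   specific_label = crow$specific_label,
                   general_label = crow$general_label,
                   time_regulated = crow$time_regulated,
                   stats = arow),
              class = "gene_summary")
  })
}

#' @export
print.gene_summary <- function(x, ...) {
  cat("Transcript ", x$transcript_id, " (", x$symbol, ")\n", sep = "")
  cat("Significant flags: ",
      if (length(x$flags)) paste(x$flags, collapse = ", ") else "none",
      "\n", sep = "")
  cat("Specific: ", x$specific_label, "; general: ", x$general_label,
      "; time-regulated: ", x$time_regulated, "\n\n", sep = "")
  means <- x$means
  means[, c("geo_mean", "lower", "upper")] <-
    round(means[, c("geo_mean", "lower", "upper")], 3)
  print(means, row.names = FALSE)
  invisible(x)
}

#' Export the full result set as a spreadsheet-equivalent file bundle
#'
#' Writes the deterministic TSV equivalent of the study's five-sheet
#' workbook into `out_dir`:
#'
#' * `INSTRUCTIONS.txt` — how to filter and read the tables;
#' * `stats_and_means.tsv` — per transcript: every effect/contrast
#'   estimate, SE, raw p and q, the classification flags and labels,
#'   and the group x time geometric-mean fold changes with s.e.m.
#'   bands;
#' * `individual_data.tsv` — per transcript x subject x time log2
#'   ratios (long format);
#' * `MANIFEST.dcf` — thresholds, package version, model settings.
#'
#' Re-exporting unchanged inputs yields byte-identical files.
#'
#' @param ratios Pre-normalized log2 ratio matrix.
#' @param design matching `study_design`.
#' @param anova q-augmented `anova_table`.
#' @param classif `classification_table`.
#' @param annotation optional annotation data.frame.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
export_workbook <- function(ratios, design, anova, classif,
                            annotation = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory '", out_dir, "'",
                  call. = FALSE)
  }
  spec <- get_spec(anova)
  groups <- attr(design, "groups")
  times <- attr(design, "times_h")
  ids <- anova$transcript_id
  sym <- rep("", length(ids))
  if (!is.null(annotation)) {
    idx <- match(ids, annotation$transcript_id)
    sym[!is.na(idx)] <- annotation$gene_symbol[idx[!is.na(idx)]]
  }
  # geometric means per cell, vectorized over transcripts
  geo <- list()
  R <- ratios[ids, design$sample_id, drop = FALSE]
  for (g in groups) for (t in times) {
    sel <- design$group == g & design$time_h == t
    sub <- R[, sel, drop = FALSE]
    mm <- rowMeans(sub)
    ss <- if (sum(sel) > 1L) {
      sqrt(pmax(rowSums((sub - mm)^2) / (sum(sel) - 1L), 0) / sum(sel))
    } else {
      rep(0, nrow(sub))
    }
    key <- paste0(g, ".", time_label(t))
    geo[[paste0("geomean.", key)]] <- 2^mm
    geo[[paste0("geolower.", key)]] <- 2^(mm - ss)
    geo[[paste0("geoupper.", key)]] <- 2^(mm + ss)
  }
  stats_df <- cbind(data.frame(transcript_id = ids, gene_symbol = sym,
                               stringsAsFactors = FALSE),
                    as.data.frame(anova)[, -1L],
                    as.data.frame(classif)[
                      match(ids, classif$transcript_id), -(1:2)],
                    as.data.frame(geo))
  f_stats <- file.path(out_dir, "stats_and_means.tsv")
  utils::write.table(format(stats_df, digits = 15, trim = TRUE),
                     f_stats, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  long <- data.frame(
    transcript_id = rep(ids, each = nrow(design)),
    subject_id = rep(design$subject_id, length(ids)),
    group = rep(design$group, length(ids)),
    time_h = rep(design$time_h, length(ids)),
    log2_ratio = as.numeric(t(R)),
    stringsAsFactors = FALSE)
  f_ind <- file.path(out_dir, "individual_data.tsv")
  utils::write.table(format(long, digits = 15, trim = TRUE), f_ind,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  thr <- attr(classif, "thresholds")
  f_man <- file.path(out_dir, "MANIFEST.dcf")
  write.dcf(data.frame(
    package = "exertome",
    version = as.character(utils::packageVersion("exertome")),
    alpha_fdr = thr$alpha,
    p_interaction_floor = thr$p_interaction_floor,
    p_vs_pre = thr$p_vs_pre,
    df_method = spec$df_method,
    groups = paste(groups, collapse = ","),
    post_times_h = paste(spec$post_times, collapse = ","),
    n_transcripts = nrow(anova)), f_man)
  f_ins <- file.path(out_dir, "INSTRUCTIONS.txt")
  writeLines(c(
    "exertome result bundle",
    "======================",
    "",
    "stats_and_means.tsv : one row per transcript.  Filter the q columns",
    "  (e.g. E2.5h.q < 0.05) to list transcripts changed under a condition,",
    "  or filter specific_label / general_label / time_regulated for the",
    "  rule-based classes.  geomean.* columns hold the geometric-mean fold",
    "  change per group x time with back-transformed s.e.m. bands",
    "  (geolower/geoupper).",
    "individual_data.tsv : per-subject log2 fold changes versus own Pre,",
    "  long format, for dot plots of individual trajectories.",
    "MANIFEST.dcf        : thresholds and model settings used.",
    "",
    "Flag vocabulary: E/S/C = endurance / strength (resistance) / control;",
    "E5h = Endurance at 5 h versus Pre; SvE2.5h = Strength versus Endurance",
    "at 2.5 h.  All q values are Benjamini-Hochberg FDR across transcripts",
    "within one statistical family."), f_ins)
  invisible(c(f_ins, f_stats, f_ind, f_man))
}
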