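#' Construct and validate an expression matrix
#'
#' The pipeline's core container is a plain numeric matrix of log2-scale
#' expression values with transcripts in rows and samples in columns.
#' Row names are transcript identifiers (e.g. array probeset IDs), column
#' names are sample identifiers.  Gene symbols, when available, travel in
#' the `"gene_symbols"` attribute as a character vector parallel to the
#' rows (empty string where unannotated).
#'
#' Values must be finite log2 intensities; missing values are not
#' permitted (array summarization yields complete rows — incomplete
#' *designs* are allowed instead and handled by the model engine).
#'
#' @param values numeric matrix, transcripts x samples.
#' @param transcript_ids,sample_ids optional ID vectors; default to the
#'   existing dimnames.
#' @param gene_symbols optional character vector of gene symbols, one per
#'   transcript ("" where unknown).
#' @return a validated expression matrix.
#' @export
expression_matrix <- function(values, transcript_ids = rownames(values),
                              sample_ids = colnames(values),
                              gene_symbols = attr(values, "gene_symbols")) {
  if (!is.matrix(values) || !is.numeric(values)) {
    input_error("expression values must be a numeric matrix")
  }
  if (is.null(transcript_ids) || is.null(sample_ids)) {
    input_error("expression matrix needs transcript and sample IDs")
  }
  transcript_ids <- as.character(transcript_ids)
  sample_ids <- as.character(sample_ids)
  if (length(transcript_ids) != nrow(values)) {
    input_error("transcript_ids length (", length(transcript_ids),
                ") does not match row count (", nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    input_error("sample_ids length (", length(sample_ids),
                ") does not match column count (", ncol(values), ")")
  }
  if (anyDuplicated(transcript_ids)) {
    input_error("duplicate transcript ID: ",
                transcript_ids[duplicated(transcript_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    input_error("duplicate sample ID: ",
                sample_ids[duplicated(sample_ids)][1L])
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    input_error("non-finite expression value at transcript '",
                transcript_ids[i], "' (row ", i, "), sample '",
                sample_ids[j], "' (column ", j, ")")
  }
  dimnames(values) <- list(transcript_ids, sample_ids)
  if (!is.null(gene_symbols)) {
    if (length(gene_symbols) != nrow(values)) {
      input_error("gene_symbols length does not match transcript count")
    }
    attr(values, "gene_symbols") <- as.character(gene_symbols)
  }
  values
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of transcript
#' IDs.  The delimiter is auto-detected from the file extension
#' (`.csv` = comma, anything else = tab).  Malformed input (duplicate
#' IDs, non-numeric or blank cells, ragged rows) is rejected with the
#' offending row/column coordinates.
#'
#' @param path file path.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 2L) input_error("expression file '", path,
                                      "' has no data rows")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  widths <- lengths(fields[-1L])
  if (any(widths != ncol_expected)) {
    r <- which(widths != ncol_expected)[1L]
    input_error("ragged row ", r + 1L, " in '", path, "': ", widths[r],
                " fields, expected ", ncol_expected)
  }
  sample_ids <- header[-1L]
  body <- fields[-1L]
  transcript_ids <- vapply(body, `[[`, character(1), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !(cells %in% c("NA", "NaN")))
  if (length(bad)) {
    n <- ncol_expected - 1L
    r <- ((bad[1L] - 1L) %/% n) + 1L
    cc <- ((bad[1L] - 1L) %% n) + 1L
    input_error("non-numeric cell '", cells[bad[1L]], "' at row ", r + 1L,
                " (transcript '", transcript_ids[r], "'), column ", cc + 1L,
                " (sample '", sample_ids[cc], "') of '", path, "'")
  }
  m <- matrix(vals, nrow = length(body), byrow = TRUE,
              dimnames = list(transcript_ids, sample_ids))
  expression_matrix(m)
}

#' Write an expression (or log2-ratio) matrix as TSV
#'
#' First column `transcript_id`, one column per sample.  Values are
#' written with 15 significant digits so a read/write round trip is
#' lossless at double precision.
#'
#' @param x expression matrix.
#' @param path output file path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(transcript_id = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct and validate a study design
#'
#' Maps each sample to a subject, a group and a time point.  `Pre`
#' (baseline) samples are encoded as `time_h == 0`.  Validation enforces
#' that each subject belongs to exactly one group and has exactly one
#' Pre sample.  The returned object carries balance/completeness
#' metadata: `is_balanced(design)` is `TRUE` when every subject has
#' exactly one sample at every time point and all groups have the same
#' number of subjects; `completeness(design)` is a subject x time
#' logical matrix of which cells are present.
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `group`,
#'   `time_h`.  `time_h` accepts numbers or the literal "Pre"
#'   (case-insensitive, mapped to 0).
#' @param groups optional explicit group level order (default: order of
#'   first appearance).
#' @return a `study_design` data.frame.
#' @export
study_design <- function(df, groups = NULL) {
  need <- c("sample_id", "subject_id", "group", "time_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) input_error("design is missing column(s): ",
                                paste(miss, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  raw_t <- as.character(df$time_h)
  t_num <- suppressWarnings(as.numeric(raw_t))
  t_num[tolower(trimws(raw_t)) == "pre"] <- PRE_TIME
  if (anyNA(t_num)) {
    input_error("unrecognized time value '", raw_t[which(is.na(t_num))[1L]],
                "' in design row ", which(is.na(t_num))[1L])
  }
  df$time_h <- t_num
  if (anyDuplicated(df$sample_id)) {
    input_error("duplicate sample ID in design: ",
                df$sample_id[duplicated(df$sample_id)][1L])
  }
  grp_per_subj <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  if (any(grp_per_subj > 1L)) {
    input_error("subject '", names(grp_per_subj)[grp_per_subj > 1L][1L],
                "' is assigned to more than one group")
  }
  n_pre <- tapply(df$time_h == PRE_TIME, df$subject_id, sum)
  if (any(n_pre != 1L)) {
    bad <- names(n_pre)[n_pre != 1L][1L]
    input_error("subject '", bad, "' has ", n_pre[[bad]],
                " Pre samples (exactly one required)")
  }
  if (is.null(groups)) groups <- unique(df$group)
  if (!all(df$group %in% groups)) {
    input_error("group level(s) not in `groups`: ",
                paste(setdiff(df$group, groups), collapse = ", "))
  }
  subjects <- unique(df$subject_id)
  times <- sort(unique(df$time_h))
  comp <- matrix(FALSE, length(subjects), length(times),
                 dimnames = list(subjects, time_label(times)))
  for (k in seq_len(nrow(df))) {
    comp[df$subject_id[k], time_label(df$time_h[k])] <- TRUE
  }
  per_cell <- table(factor(df$subject_id, subjects),
                    factor(df$time_h, times))
  n_per_group <- table(factor(df$group[!duplicated(df$subject_id)], groups))
  balanced <- all(per_cell == 1L) && length(unique(as.integer(n_per_group))) == 1L
  structure(df,
            groups = groups,
            times_h = times,
            is_balanced = balanced,
            completeness = comp,
            class = c("study_design", "data.frame"))
}

#' @rdname study_design
#' @param design a `study_design`.
#' @export
is_balanced <- function(design) attr(design, "is_balanced")

#' @rdname study_design
#' @export
completeness <- function(design) attr(design, "completeness")

#' Read a study design TSV
#'
#' Expects columns `sample_id`, `subject_id`, `group`, `time_h`; "Pre"
#' (any case) or 0 in the time column marks the baseline sample.
#'
#' @param path file path.
#' @inheritParams study_design
#' @return a validated `study_design`.
#' @export
read_design <- function(path, groups = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  study_design(df, groups = groups)
}

#' @rdname read_design
#' @param design a `study_design`.
#' @export
write_design <- function(design, path) {
  out <- as.data.frame(design)
  out$time_h <- ifelse(out$time_h == PRE_TIME, "Pre", out$time_h)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a transcript annotation table
#'
#' Two-column TSV mapping `transcript_id` to `gene_symbol`; several
#' transcripts may share one symbol (the query layer returns all of
#' them).
#'
#' @param path file path.
#' @return data.frame with columns `transcript_id`, `gene_symbol`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (!all(c("transcript_id", "gene_symbol") %in% names(df))) {
    input_error("annotation needs columns transcript_id, gene_symbol")
  }
  if (anyDuplicated(df$transcript_id)) {
    input_error("duplicate transcript ID in annotation: ",
                df$transcript_id[duplicated(df$transcript_id)][1L])
  }
  df[, c("transcript_id", "gene_symbol")]
}

#' Attach gene symbols to an expression matrix
#'
#' Symbols are matched by transcript ID; transcripts without a match
#' keep an empty symbol.  Matching is a pure left join — no error on
#' partial coverage.
#'
#' @param x expression matrix.
#' @param annotation data.frame as returned by [read_annotation()].
#' @return the matrix with its `"gene_symbols"` attribute filled in.
#' @export
join_annotation <- function(x, annotation) {
  sym <- rep("", nrow(x))
  idx <- match(rownames(x), annotation$transcript_id)
  hit <- !is.na(idx)
  sym[hit] <- annotation$gene_symbol[idx[hit]]
  attr(x, "gene_symbols") <- sym
  x
}

#' @rdname join_annotation
#' @export
gene_symbols <- function(x) attr(x, "gene_symbols")

# check that a design covers exactly the matrix's samples
#' @keywords internal
check_samples_match <- function(x, design) {
  miss <- setdiff(design$sample_id, colnames(x))
  if (length(miss)) input_error("design sample(s) absent from matrix: ",
                                paste(utils::head(miss, 3), collapse = ", "))
  invisible(TRUE)
}
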