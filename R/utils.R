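# internal helpers shared across modules

# "Pre" time points are encoded as time_h == 0 throughout.
PRE_TIME <- 0

#' @keywords internal
time_label <- function(time_h) {
  ifelse(time_h == PRE_TIME, "Pre",
         paste0(sub("\\.?0+$", "", sprintf("%.10f", time_h)), "h"))
}

# Short group codes used in contrast/flag names (E2.5h, SvE5h, ...).
# The canonical three-group exercise design uses C / E / S
# (S = strength, the field's code for resistance training).
#' @keywords internal
default_group_codes <- function(groups) {
  canonical <- c(Control = "C", Endurance = "E", Resistance = "S")
  if (all(groups %in% names(canonical))) {
    return(stats::setNames(unname(canonical[groups]), groups))
  }
  codes <- toupper(substr(groups, 1L, 1L))
  k <- 2L
  while (anyDuplicated(codes) && k <= max(nchar(groups))) {
    dup <- duplicated(codes) | duplicated(codes, fromLast = TRUE)
    codes[dup] <- toupper(substr(groups[dup], 1L, k))
    k <- k + 1L
  }
  if (anyDuplicated(codes)) {
    stop("cannot derive unique group codes from group labels; ",
         "supply `group_codes` explicitly", call. = FALSE)
  }
  stats::setNames(codes, groups)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix for user-input problems
#' @keywords internal
input_error <- function(...) stop(..., call. = FALSE)
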