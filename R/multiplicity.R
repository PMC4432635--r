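#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Standard step-up FDR adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.  Missing entries
#' are excluded before adjustment — the effective family size `m` is the
#' number of non-missing p-values — and returned as `NA` in place.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (NA allowed).
#' @return numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    input_error("p-value outside [0, 1]: ",
                p[ok][p[ok] < 0 | p[ok] > 1][1L])
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Add BH q-value columns to a model results table
#'
#' FDR control is applied *within each statistical family across
#' transcripts* — one family per overall effect and one per contrast —
#' never across contrasts.  Each raw-p column (`*.p`) gains a companion
#' `*.q` column.  Non-converged transcripts carry `NA` p-values and are
#' excluded, reducing the family size `m` accordingly.
#'
#' @param anova an `anova_table` from [fit_all()].
#' @return the table with a `.q` column appended after every `.p`
#'   column; attribute `family_sizes` records each family's effective
#'   `m`.
#' @export
apply_families <- function(anova) {
  pcols <- grep("\\.p$", names(anova), value = TRUE)
  m_eff <- integer(0)
  for (pc in pcols) {
    qc <- sub("\\.p$", ".q", pc)
    anova[[qc]] <- bh_fdr(anova[[pc]])
    m_eff[pc] <- sum(!is.na(anova[[pc]]))
    if (m_eff[pc] == 0L) {
      warning("family '", pc, "' has no usable p-values", call. = FALSE)
    }
  }
  attr(anova, "family_sizes") <- m_eff
  anova
}
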