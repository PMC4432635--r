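#' Model specification for the repeated-measures engine
#'
#' Describes the per-transcript model fitted to Pre-normalized log2
#' ratios: a cell-means two-way layout over group x post-time with a
#' subject random intercept,
#' `y_{gts} = mu_{gt} + b_s + e`, `b_s ~ N(0, sigma2_subject)`,
#' `e ~ N(0, sigma2_resid)`, variance components estimated by REML.
#'
#' After per-subject normalization every Pre value is identically zero,
#' so Pre cannot enter the model as an observed factor level; it is the
#' *known* reference level `mu_{g,Pre} = 0`.  The model is therefore
#' fitted on post time points only, and the three overall effects are
#' the hypotheses the baseline-anchored two-way ANOVA tests:
#'
#' * **Time** — the group-averaged response profile is flat at the
#'   baseline: `mean_g mu_{gt} = 0` for every post time (numerator df =
#'   number of post times).  A sustained uniform elevation is a Time
#'   effect, exactly as when baseline is a level of the time factor.
#' * **Group** — the post-time-averaged group means are equal
#'   (numerator df = groups - 1).
#' * **Time x Group** — all groups share one response profile:
#'   `mu_{gt} = mu_t` (numerator df = (groups - 1) x post times).
#'   Any group-dependent response, including a group-specific sustained
#'   induction, is an interaction in the anchored parameterization.
#'
#' Each "versus Pre" contrast is the test of `H0: mu_{gt} = 0`;
#' between-group contrasts test `mu_{g1,t} = mu_{g2,t}`.
#'
#' `df_method` selects the denominator degrees of freedom for the
#' contrast t-tests.  Named contrasts compare cell means and therefore
#' mix the between-subject and within-subject error strata; the default
#' `"satterthwaite"` combines the two mean squares with Satterthwaite's
#' approximation, while `"containment"` uses the subject-stratum df.
#' In balanced designs the Time and Time x Group statistics decompose
#' exactly into independent between- and within-stratum classical F
#' ratios, and their p-values are computed from the exact distribution
#' of that mixture; the Group test is the classical exact split-plot F.
#'
#' @param post_times ordered numeric vector of non-Pre time points in
#'   hours (default 2.5 and 5).
#' @param groups ordered group labels (default Control, Endurance,
#'   Resistance).
#' @param group_codes named character vector of short codes used in
#'   contrast names; defaults to C/E/S for the canonical labels, unique
#'   initials otherwise.
#' @param df_method `"satterthwaite"` or `"containment"`.
#' @param reml_tol convergence tolerance of the REML variance-ratio
#'   search (default 1e-8).
#' @param reml_max_iter iteration cap of that search (default 200).
#' @return a `model_spec` list.
#' @export
model_spec <- function(post_times = c(2.5, 5),
                       groups = c("Control", "Endurance", "Resistance"),
                       group_codes = NULL,
                       df_method = c("satterthwaite", "containment"),
                       reml_tol = 1e-8, reml_max_iter = 200L) {
  df_method <- match.arg(df_method)
  if (length(groups) < 2L) input_error("need at least 2 groups")
  if (length(post_times) < 1L) input_error("need at least 1 post time point")
  if (any(post_times == PRE_TIME)) input_error("post_times must exclude Pre (0)")
  if (reml_tol <= 0) input_error("reml_tol must be > 0")
  codes <- group_codes %||% default_group_codes(groups)
  if (!all(groups %in% names(codes))) {
    input_error("group_codes must name every group")
  }
  spec <- list(post_times = as.numeric(post_times), groups = groups,
               group_codes = codes[groups], df_method = df_method,
               reml_tol = reml_tol, reml_max_iter = as.integer(reml_max_iter))
  spec$contrasts <- build_contrasts(spec)
  class(spec) <- "model_spec"
  spec
}

# enumerate the named contrasts in the field's flag vocabulary:
# vs-Pre per cell (E2.5h, S5h, ...), then between-group per time
# (EvC2.5h, SvE5h, ...; later group versus earlier group)
#' @keywords internal
build_contrasts <- function(spec) {
  G <- length(spec$groups); Tn <- length(spec$post_times)
  codes <- spec$group_codes
  tl <- time_label(spec$post_times)
  out <- list()
  for (g in seq_len(G)) for (t in seq_len(Tn)) {
    out[[length(out) + 1L]] <- data.frame(
      name = paste0(codes[g], tl[t]), type = "vs_pre",
      g1 = spec$groups[g], g2 = NA_character_, time_h = spec$post_times[t],
      stringsAsFactors = FALSE)
  }
  if (G >= 2L) {
    for (j in 2:G) for (i in seq_len(j - 1L)) for (t in seq_len(Tn)) {
      out[[length(out) + 1L]] <- data.frame(
        name = paste0(codes[j], "v", codes[i], tl[t]), type = "between",
        g1 = spec$groups[j], g2 = spec$groups[i], time_h = spec$post_times[t],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fit the repeated-measures model to every transcript
#'
#' Dispatches to a closed-form split-plot solver when the post-time
#' design is balanced and complete (the common case; fully vectorized
#' across transcripts), and to a per-transcript profiled-REML solver
#' otherwise.  For balanced data the two agree: ANOVA method-of-moments
#' variance components coincide with REML, and the Wald statistics
#' reduce to the classical sums-of-squares ratios of the split-plot
#' strata.
#'
#' @param ratios matrix of Pre-normalized log2 ratios (from
#'   [normalize_to_pre()]); Pre columns may be present and are ignored.
#' @param design matching `study_design`.
#' @param spec a [model_spec()]; defaults are derived from the design
#'   (all non-Pre times, design group order).
#' @param engine `"auto"` (default: closed form when balanced),
#'   `"balanced"` (closed form; error if the design is not balanced) or
#'   `"general"` (per-transcript iterative REML regardless of balance).
#' @param max_fail_frac abort if more than this fraction of transcripts
#'   fails to converge (default 0.5).
#' @return an `anova_table` data.frame: per transcript the variance
#'   components, convergence flag, F and raw p for Time, Group and
#'   Time x Group, and estimate/SE/raw p for every named contrast
#'   (columns `E2.5h.est`, `E2.5h.se`, `E2.5h.p`, ...).
#' @export
fit_all <- function(ratios, design, spec = NULL,
                    engine = c("auto", "balanced", "general"),
                    max_fail_frac = 0.5) {
  engine <- match.arg(engine)
  check_samples_match(ratios, design)
  if (is.null(spec)) {
    spec <- model_spec(post_times = setdiff(attr(design, "times_h"), PRE_TIME),
                       groups = attr(design, "groups"))
  }
  postd <- design[design$time_h %in% spec$post_times, , drop = FALSE]
  if (!all(postd$group %in% spec$groups)) {
    input_error("design contains group(s) absent from model spec: ",
                paste(setdiff(postd$group, spec$groups), collapse = ", "))
  }
  if (length(spec$post_times) < 2L) {
    input_error("the two-way model needs >= 2 post time points")
  }
  grp <- factor(postd$group, levels = spec$groups)
  tim <- factor(postd$time_h, levels = spec$post_times)
  subj_tab <- unique(postd[, c("subject_id", "group")])
  n_per_group <- table(factor(subj_tab$group, spec$groups))
  if (any(n_per_group < 2L)) {
    input_error("every group needs >= 2 subjects with post observations")
  }
  subj <- factor(postd$subject_id,
                 levels = subj_tab$subject_id[order(match(subj_tab$group,
                                                          spec$groups))])
  Rp <- ratios[, postd$sample_id, drop = FALSE]
  balanced <- all(table(subj, tim) == 1L) &&
    length(unique(as.integer(n_per_group))) == 1L
  if (engine == "balanced" && !balanced) {
    input_error("engine = 'balanced' requires a balanced complete design")
  }
  use_balanced <- balanced && engine != "general"
  tab <- if (use_balanced) {
    fit_balanced(Rp, grp, subj, tim, spec)
  } else {
    if (any(table(grp, tim) == 0L)) {
      input_error("empty group x time cell(s); cell means not estimable")
    }
    fit_general(Rp, grp, subj, tim, spec)
  }
  fail <- sum(!tab$converged)
  if (fail > max_fail_frac * nrow(tab)) {
    stop(fail, "/", nrow(tab), " transcripts failed to converge ",
         "(> max_fail_frac); aborting", call. = FALSE)
  }
  if (fail > 0L) {
    message(fail, " transcript(s) did not converge; excluded from FDR families")
  }
  structure(tab, spec = spec, class = c("anova_table", "data.frame"))
}

#' Fit the repeated-measures model to one transcript
#'
#' Convenience wrapper: identical to the matching row of [fit_all()] on
#' a one-row matrix.
#'
#' @param ratios_row named numeric vector (names = sample IDs) of one
#'   transcript's Pre-normalized log2 ratios, or a one-row matrix.
#' @inheritParams fit_all
#' @return one-row `anova_table`.
#' @export
fit_transcript <- function(ratios_row, design, spec = NULL) {
  if (!is.matrix(ratios_row)) {
    ratios_row <- matrix(ratios_row, nrow = 1,
                         dimnames = list("transcript",
                                         names(ratios_row)))
  }
  fit_all(ratios_row, design, spec)
}

# ---- exact p-value of a two-stratum Wald mixture ------------------------

# 64-point Gauss-Legendre rule on (0, 1), computed once (Golub-Welsch)
#' @keywords internal
gauss_legendre_01 <- local({
  rule <- NULL
  function() {
    if (is.null(rule)) {
      n <- 64L
      i <- seq_len(n - 1L)
      b <- i / sqrt(4 * i^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1L)] <- b
      J[cbind(i + 1L, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      x <- rev(e$values)
      w <- 2 * rev(e$vectors[1L, ])^2
      rule <<- list(u = (x + 1) / 2, w = w / 2)
    }
    rule
  }
})

# P(A + B > w) where A = d1a * F(d1a, dfa) and B = d1b * F(d1b, dfb) are
# independent scaled F variates (numerator chi-squares over independent
# stratum mean squares).  Exact up to quadrature error; the substitution
# b = w u^2 removes the integrable b^{-1/2} singularity when d1b = 1.
#' @keywords internal
mixture_tail_p <- function(w, d1a, d1b, dfa, dfb) {
  p <- rep(NA_real_, length(w))
  p[!is.na(w) & w <= 0] <- 1
  p[is.infinite(w)] <- 0
  ok <- which(is.finite(w) & w > 0)
  if (length(ok)) {
    gl <- gauss_legendre_01()
    wv <- w[ok]
    tailB <- stats::pf(wv / d1b, d1b, dfb, lower.tail = FALSE)
    acc <- 0
    for (k in seq_along(gl$u)) {
      u <- gl$u[k]
      b <- wv * u^2
      term <- stats::pf((wv - b) / d1a, d1a, dfa, lower.tail = FALSE) *
        stats::df(b / d1b, d1b, dfb) / d1b * 2 * wv * u
      acc <- acc + gl$w[k] * term
    }
    p[ok] <- pmin(pmax(tailB + acc, 0), 1)
  }
  p
}

# ---- balanced closed-form split-plot path -------------------------------

# Exact ANOVA decomposition for the balanced complete design:
# G groups x n subjects x T post times.  REML variance components have
# the closed form sigma2_e = MS_error, sigma2_b = (MS_subj - MS_error)/T
# (truncated at 0 with a fixed-effects refit).  The anchored-baseline
# Wald statistics decompose into independent classical F ratios:
#   Time:        T * F = SS_elev/MS_subj + SS_time/MS_err
#   Time x Group: (G-1)*T * F = SS_group/MS_subj + SS_int/MS_err
#   Group:       F = MS_group/MS_subj  (exact split-plot F)
# where SS_elev = G*n*T*(grand post mean)^2 tests overall elevation.
#' @keywords internal
fit_balanced <- function(Rp, grp, subj, tim, spec) {
  G <- nlevels(grp); Tn <- nlevels(tim); S <- nlevels(subj)
  n <- S / G
  m <- nrow(Rp)
  cellf <- interaction(grp, tim, lex.order = TRUE)  # group-major cells
  Mc <- stats::model.matrix(~ cellf - 1) / n
  Ms <- stats::model.matrix(~ subj - 1) / Tn
  cellm <- Rp %*% Mc                     # m x (G*T), (g,t) with t fastest
  subjm <- Rp %*% Ms                     # m x S
  grand <- rowMeans(Rp)
  Kg <- kronecker(diag(G), matrix(1 / Tn, Tn, 1))   # (G*T) x G
  Kt <- kronecker(matrix(1 / G, G, 1), diag(Tn))    # (G*T) x T
  groupm <- cellm %*% Kg
  timem <- cellm %*% Kt
  grp_of_subj <- as.integer(factor(
    tapply(as.character(grp), subj, `[`, 1L)[levels(subj)],
    levels = levels(grp)))
  df_g <- G - 1L; df_s <- G * (n - 1L)
  df_t <- Tn - 1L; df_i <- (G - 1L) * (Tn - 1L)
  df_e <- G * (n - 1L) * (Tn - 1L)
  ss_elev <- n * G * Tn * grand^2
  ss_group <- n * Tn * rowSums((groupm - grand)^2)
  ss_time <- n * G * rowSums((timem - grand)^2)
  ss_cell <- n * rowSums((cellm - grand)^2)
  ss_int <- pmax(ss_cell - ss_group - ss_time, 0)
  ss_subj <- Tn * rowSums((subjm - groupm[, grp_of_subj, drop = FALSE])^2)
  cell_of_sample <- (as.integer(grp) - 1L) * Tn + as.integer(tim)
  resid <- Rp - cellm[, cell_of_sample, drop = FALSE] -
    subjm[, as.integer(subj), drop = FALSE] +
    groupm[, as.integer(grp), drop = FALSE]
  ss_err <- rowSums(resid^2)
  ms_subj <- ss_subj / df_s; ms_err <- ss_err / df_e
  trunc <- ms_subj < ms_err
  deg <- (ss_elev + ss_group + ss_time + ss_int + ss_subj + ss_err) < 1e-20
  sigma2_e <- ifelse(trunc, (ss_subj + ss_err) / (df_s + df_e), ms_err)
  sigma2_b <- ifelse(trunc, 0, (ms_subj - ms_err) / Tn)
  df_pool <- df_s + df_e
  q_time <- Tn; q_int <- (G - 1L) * Tn
  # anchored-baseline Wald statistics; a zero sum of squares contributes
  # zero evidence even when the matching mean square is also zero
  sdiv <- function(ss, ms) ifelse(ss == 0, 0, ss / ms)
  wald_time <- ifelse(trunc, sdiv(ss_elev + ss_time, sigma2_e),
                      sdiv(ss_elev, ms_subj) + sdiv(ss_time, ms_err))
  wald_int <- ifelse(trunc, sdiv(ss_group + ss_int, sigma2_e),
                     sdiv(ss_group, ms_subj) + sdiv(ss_int, ms_err))
  F_time <- wald_time / q_time
  F_int <- wald_int / q_int
  F_group <- ifelse(trunc, sdiv(ss_group / df_g, sigma2_e),
                    sdiv(ss_group / df_g, ms_subj))
  p_time <- p_int <- rep(NA_real_, m)
  untr <- which(!trunc)
  if (length(untr)) {
    p_time[untr] <- mixture_tail_p(wald_time[untr], 1, df_t, df_s, df_e)
    p_int[untr] <- mixture_tail_p(wald_int[untr], df_g, df_i, df_s, df_e)
  }
  tr <- which(trunc)
  if (length(tr)) {
    p_time[tr] <- stats::pf(F_time[tr], q_time, df_pool, lower.tail = FALSE)
    p_int[tr] <- stats::pf(F_int[tr], q_int, df_pool, lower.tail = FALSE)
  }
  p_group <- ifelse(trunc,
                    stats::pf(F_group, df_g, df_pool, lower.tail = FALSE),
                    stats::pf(F_group, df_g, df_s, lower.tail = FALSE))
  # contrast machinery: all named contrasts live at a single time point
  s_tot2 <- sigma2_b + sigma2_e                # var of one observation
  nu <- if (spec$df_method == "satterthwaite") {
    ifelse(trunc, df_pool,
           (ms_subj + (Tn - 1) * ms_err)^2 /
             (ms_subj^2 / df_s + ((Tn - 1) * ms_err)^2 / df_e))
  } else {
    ifelse(trunc, df_pool, df_s)
  }
  ctr <- spec$contrasts
  est <- se <- pv <- matrix(NA_real_, m, nrow(ctr),
                            dimnames = list(rownames(Rp), ctr$name))
  for (k in seq_len(nrow(ctr))) {
    ti <- match(ctr$time_h[k], spec$post_times)
    gi <- match(ctr$g1[k], spec$groups)
    c1 <- (gi - 1L) * Tn + ti
    if (ctr$type[k] == "vs_pre") {
      est[, k] <- cellm[, c1]
      se[, k] <- sqrt(s_tot2 / n)
    } else {
      gj <- match(ctr$g2[k], spec$groups)
      c2 <- (gj - 1L) * Tn + ti
      est[, k] <- cellm[, c1] - cellm[, c2]
      se[, k] <- sqrt(2 * s_tot2 / n)
    }
    tstat <- est[, k] / se[, k]
    pk <- 2 * stats::pt(-abs(tstat), nu)
    z <- se[, k] == 0                 # zero-variance transcript
    pk[z] <- ifelse(est[z, k] == 0, 1, 0)
    pv[, k] <- pk
  }
  F_time[deg] <- 0; p_time[deg] <- 1
  F_int[deg] <- 0; p_int[deg] <- 1
  F_group[deg] <- 0; p_group[deg] <- 1
  assemble_table(rownames(Rp), converged = rep(TRUE, m),
                 sigma2_b, sigma2_e,
                 F_time, p_time, F_group, p_group, F_int, p_int,
                 est, se, pv)
}

# ---- general profiled-REML path (unbalanced / incomplete designs) -------

#' @keywords internal
fit_general <- function(Rp, grp, subj, tim, spec) {
  G <- nlevels(grp); Tn <- nlevels(tim); S <- nlevels(subj)
  N <- ncol(Rp); m <- nrow(Rp)
  cellf <- interaction(grp, tim, lex.order = TRUE)
  X <- stats::model.matrix(~ cellf - 1)
  Z <- stats::model.matrix(~ subj - 1)
  ZZt <- tcrossprod(Z)
  p <- ncol(X)
  # cells are group-major (time fastest), matching interaction(lex.order)
  cell_idx <- function(g, t) (g - 1L) * Tn + t
  # Time: group-averaged marginal mean = 0 at every post time
  L_time <- matrix(0, Tn, p)
  for (t in seq_len(Tn)) for (g in seq_len(G)) {
    L_time[t, cell_idx(g, t)] <- 1 / G
  }
  # Group: post-averaged group means equal
  L_group <- matrix(0, G - 1L, p)
  for (g in seq_len(G - 1L)) for (t in seq_len(Tn)) {
    L_group[g, cell_idx(g, t)] <- 1 / Tn
    L_group[g, cell_idx(G, t)] <- L_group[g, cell_idx(G, t)] - 1 / Tn
  }
  # Time x Group: every group's profile equals the group-averaged profile
  L_int <- matrix(0, (G - 1L) * Tn, p)
  r <- 0L
  for (g in seq_len(G - 1L)) for (t in seq_len(Tn)) {
    r <- r + 1L
    L_int[r, cell_idx(g, t)] <- 1
    for (g2 in seq_len(G)) {
      L_int[r, cell_idx(g2, t)] <- L_int[r, cell_idx(g2, t)] - 1 / G
    }
  }
  ctr <- spec$contrasts
  Cmat <- matrix(0, nrow(ctr), p)
  for (k in seq_len(nrow(ctr))) {
    ti <- match(ctr$time_h[k], spec$post_times)
    gi <- match(ctr$g1[k], spec$groups)
    Cmat[k, cell_idx(gi, ti)] <- 1
    if (ctr$type[k] == "between") {
      gj <- match(ctr$g2[k], spec$groups)
      Cmat[k, cell_idx(gj, ti)] <- -1
    }
  }
  df2_group <- S - G
  df2_within <- N - S - G * (Tn - 1L)
  df2_ols <- N - p
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    rows[[i]] <- reml_one(Rp[i, ], X, ZZt, L_time, L_group, L_int, Cmat,
                          ctr, spec, df2_group, df2_within, df2_ols)
  }
  conv <- vapply(rows, `[[`, logical(1), "converged")
  est <- do.call(rbind, lapply(rows, `[[`, "est"))
  se <- do.call(rbind, lapply(rows, `[[`, "se"))
  pv <- do.call(rbind, lapply(rows, `[[`, "p"))
  dimnames(est) <- dimnames(se) <- dimnames(pv) <-
    list(rownames(Rp), ctr$name)
  getv <- function(f) vapply(rows, `[[`, numeric(1), f)
  assemble_table(rownames(Rp), conv, getv("sigma2_b"), getv("sigma2_e"),
                 getv("F_time"), getv("p_time"), getv("F_group"),
                 getv("p_group"), getv("F_int"), getv("p_int"),
                 est, se, pv)
}

# one-transcript REML fit: profile sigma2_e out of the likelihood, then
# solve the REML score equation in the variance ratio
# lambda = sigma2_b / sigma2_e by bracketed root-finding (score-based:
# far sharper near the optimum than minimizing the flat profiled
# criterion).  lambda = 0 (boundary) falls back to the fixed-effects fit.
#' @keywords internal
reml_one <- function(y, X, ZZt, L_time, L_group, L_int, Cmat, ctr, spec,
                     df2_group, df2_within, df2_ols) {
  N <- length(y); p <- ncol(X)
  crit_parts <- function(lambda) {
    V <- diag(N) + lambda * ZZt
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XtVi <- crossprod(X, Vi)
    A <- XtVi %*% X
    b <- solve(A, XtVi %*% y)
    r <- y - X %*% b
    qf <- as.numeric(crossprod(r, Vi %*% r))
    list(b = b, Vi = Vi, Ainv = solve(A), qf = qf, XtVi = XtVi)
  }
  # REML score in lambda (up to a positive factor): positive while the
  # restricted likelihood is increasing, zero at the optimum
  score <- function(lambda) {
    fp <- crit_parts(lambda)
    P <- fp$Vi - t(fp$XtVi) %*% fp$Ainv %*% fp$XtVi
    Py <- as.numeric(P %*% y)
    qf <- sum(y * Py)
    if (qf < 1e-300) return(NA_real_)
    (N - p) * sum(Py * (ZZt %*% Py)) / qf - sum(P * ZZt)
  }
  ols_rss <- crit_parts(0)$qf
  degenerate <- !is.finite(ols_rss) || ols_rss < 1e-20
  lambda <- 0
  converged <- TRUE
  if (!degenerate) {
    s0 <- score(0)
    if (!is.finite(s0)) {
      converged <- FALSE
    } else if (s0 > 0) {
      # interior optimum: bracket then root-find the score
      hi <- 1; it <- 0L
      while (it < 60L && {
        sh <- score(hi)
        is.finite(sh) && sh > 0 && hi < 1e8
      }) {
        hi <- hi * 4; it <- it + 1L
      }
      if (hi >= 1e8) {
        lambda <- 1e8            # essentially pure between-subject variance
      } else {
        root <- tryCatch(
          stats::uniroot(score, c(0, hi), tol = min(spec$reml_tol, 1e-10),
                         maxiter = spec$reml_max_iter),
          error = function(e) NULL)
        if (is.null(root)) converged <- FALSE else lambda <- root$root
      }
    }                            # s0 <= 0: boundary, lambda stays 0
  }
  if (!converged) {
    na <- rep(NA_real_, nrow(ctr))
    return(list(converged = FALSE, sigma2_b = NA_real_, sigma2_e = NA_real_,
                F_time = NA_real_, p_time = NA_real_, F_group = NA_real_,
                p_group = NA_real_, F_int = NA_real_, p_int = NA_real_,
                est = na, se = na, p = na))
  }
  fit <- crit_parts(lambda)
  sigma2_e <- fit$qf / (N - p)
  sigma2_b <- lambda * sigma2_e
  Vb <- sigma2_e * fit$Ainv
  b <- fit$b
  at_boundary <- lambda == 0
  sdf <- function(L) {
    mean(satterthwaite_df(L, fit$Ainv, X, fit$Vi, ZZt, sigma2_b, sigma2_e))
  }
  wald <- function(L, df2) {
    q <- nrow(L)
    Lb <- L %*% b
    M <- L %*% Vb %*% t(L)
    Fst <- if (max(abs(M)) < 1e-300) {
      if (max(abs(Lb)) < 1e-150) 0 else Inf   # zero-variance transcript
    } else {
      as.numeric(crossprod(Lb, solve(M, Lb))) / q
    }
    c(Fst, stats::pf(Fst, q, df2, lower.tail = FALSE))
  }
  wt <- wald(L_time, if (at_boundary) df2_ols else sdf(L_time))
  wg <- wald(L_group, if (at_boundary) df2_ols else df2_group)
  wi <- wald(L_int, if (at_boundary) df2_ols else sdf(L_int))
  est <- as.numeric(Cmat %*% b)
  se <- sqrt(pmax(rowSums((Cmat %*% Vb) * Cmat), 0))
  nu <- if (at_boundary) {
    rep(df2_ols, nrow(Cmat))
  } else if (spec$df_method == "containment") {
    rep(df2_group, nrow(Cmat))
  } else {
    satterthwaite_df(Cmat, fit$Ainv, X, fit$Vi, ZZt, sigma2_b, sigma2_e)
  }
  pv <- 2 * stats::pt(-abs(est / se), nu)
  pv[se == 0] <- ifelse(est[se == 0] == 0, 1, 0)
  list(converged = TRUE, sigma2_b = sigma2_b, sigma2_e = sigma2_e,
       F_time = wt[1], p_time = wt[2], F_group = wg[1], p_group = wg[2],
       F_int = wi[1], p_int = wi[2], est = est, se = se, p = pv)
}

# Satterthwaite df for contrast variances via the REML information of
# (sigma2_b, sigma2_e); Vi is the inverse correlation-scale V, so absolute
# quantities are rescaled by sigma2_e
#' @keywords internal
satterthwaite_df <- function(Cmat, Ainv, X, Vi, ZZt, sigma2_b, sigma2_e) {
  N <- nrow(Vi)
  Vi_abs <- Vi / sigma2_e
  XtVi <- crossprod(X, Vi_abs)
  Ainv_abs <- Ainv * sigma2_e
  P <- Vi_abs - t(XtVi) %*% Ainv_abs %*% XtVi
  G1 <- ZZt
  PG1 <- P %*% G1
  info <- matrix(0, 2, 2)
  info[1, 1] <- sum(PG1 * t(PG1)) / 2
  info[1, 2] <- info[2, 1] <- sum(PG1 * t(P)) / 2
  info[2, 2] <- sum(P * t(P)) / 2
  Acov <- tryCatch(solve(info), error = function(e) NULL)
  H <- Ainv_abs %*% XtVi            # p x N
  vapply(seq_len(nrow(Cmat)), function(k) {
    cc <- Cmat[k, ]
    v <- as.numeric(cc %*% Ainv_abs %*% cc)
    if (is.null(Acov)) return(N - ncol(X))
    h <- as.numeric(cc %*% H)       # length N
    g1 <- as.numeric(h %*% G1 %*% h)
    g2 <- sum(h * h)
    g <- c(g1, g2)
    nu <- 2 * v^2 / as.numeric(g %*% Acov %*% g)
    if (!is.finite(nu) || nu <= 0) N - ncol(X) else nu
  }, numeric(1))
}

#' @keywords internal
assemble_table <- function(ids, converged, sigma2_b, sigma2_e,
                           F_time, p_time, F_group, p_group,
                           F_int, p_int, est, se, pv) {
  tab <- data.frame(transcript_id = ids, converged = converged,
                    sigma2_subject = sigma2_b, sigma2_resid = sigma2_e,
                    Time.F = F_time, Time.p = p_time,
                    Group.F = F_group, Group.p = p_group,
                    TimexGroup.F = F_int, TimexGroup.p = p_int,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (nm in colnames(est)) {
    tab[[paste0(nm, ".est")]] <- est[, nm]
    tab[[paste0(nm, ".se")]] <- se[, nm]
    tab[[paste0(nm, ".p")]] <- pv[, nm]
  }
  tab
}

#' Write a model results table as TSV
#'
#' One row per transcript; contrast columns use the flag vocabulary
#' (`E2.5h.est`, `EvC2.5h.p`, `SvE5h.q`, ...).
#'
#' @param anova an `anova_table`.
#' @param path output file path.
#' @export
write_anova <- function(anova, path) {
  utils::write.table(format(as.data.frame(anova), digits = 15, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
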