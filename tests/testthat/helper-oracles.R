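# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals.

# Brute-force Benjamini-Hochberg step-up adjusted values: sort p
# ascending, adj_j = p_(j) * m / j, q_(k) = min over j >= k of adj_j
# (literal minimum loop), cap at 1, map back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- po * m / seq_len(m)
  q_sorted <- numeric(m)
  for (k in seq_len(m)) q_sorted[k] <- min(adj[k:m])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Classical split-plot sums-of-squares oracle for one transcript's
# post-time ratios under the balanced design: explicit loops over
# groups, subjects and times.  Returns the classical mean squares and
# the baseline-anchored Wald F statistics assembled from them:
#   F_time = (SS_elev/MS_subj + SS_time/MS_err) / T
#   F_int  = (SS_group/MS_subj + SS_int/MS_err) / ((G-1) T)
#   F_group = MS_group / MS_subj
ss_oracle <- function(y, postd) {
  groups <- unique(postd$group)
  times <- sort(unique(postd$time_h))
  subjects <- unique(postd$subject_id)
  G <- length(groups); Tn <- length(times)
  n <- length(subjects) / G
  val <- function(s, t) y[postd$sample_id[postd$subject_id == s &
                                            postd$time_h == t]]
  grand <- mean(y[postd$sample_id])
  gmean <- sapply(groups, function(g) {
    mean(y[postd$sample_id[postd$group == g]])
  })
  tmean <- sapply(times, function(t) {
    mean(y[postd$sample_id[postd$time_h == t]])
  })
  cmean <- outer(groups, times, Vectorize(function(g, t) {
    mean(y[postd$sample_id[postd$group == g & postd$time_h == t]])
  }))
  smean <- sapply(subjects, function(s) {
    mean(y[postd$sample_id[postd$subject_id == s]])
  })
  grp_of <- sapply(subjects, function(s) {
    postd$group[postd$subject_id == s][1]
  })
  ss_elev <- G * n * Tn * grand^2
  ss_group <- n * Tn * sum((gmean - grand)^2)
  ss_time <- G * n * sum((tmean - grand)^2)
  ss_cell <- n * sum((cmean - grand)^2)
  ss_int <- ss_cell - ss_group - ss_time
  ss_subj <- Tn * sum((smean - gmean[match(grp_of, groups)])^2)
  ss_err <- 0
  for (s in subjects) for (t in times) {
    g <- grp_of[[s]]
    ss_err <- ss_err + (val(s, t) - cmean[match(g, groups), match(t, times)] -
                          smean[[s]] + gmean[[match(g, groups)]])^2
  }
  df_s <- G * (n - 1)
  df_e <- G * (n - 1) * (Tn - 1)
  ms_subj <- ss_subj / df_s
  ms_err <- ss_err / df_e
  if (ms_subj >= ms_err) {
    list(F_time = (ss_elev / ms_subj + ss_time / ms_err) / Tn,
         F_int = (ss_group / ms_subj + ss_int / ms_err) / ((G - 1) * Tn),
         F_group = (ss_group / (G - 1)) / ms_subj,
         sigma2_resid = ms_err,
         sigma2_subject = (ms_subj - ms_err) / Tn)
  } else {
    # negative subject component: fixed-effects refit with pooled error
    s2 <- (ss_subj + ss_err) / (df_s + df_e)
    list(F_time = (ss_elev + ss_time) / (Tn * s2),
         F_int = (ss_group + ss_int) / ((G - 1) * Tn * s2),
         F_group = (ss_group / (G - 1)) / s2,
         sigma2_resid = s2, sigma2_subject = 0)
  }
}

# minimal q/p table for exercising the rule engine directly: all flags
# start insignificant (p 0.5, q 1), tests override individual cells
fake_anova <- function(n, spec = model_spec()) {
  tab <- data.frame(transcript_id = sprintf("T%02d", seq_len(n)),
                    converged = TRUE, sigma2_subject = 0.1,
                    sigma2_resid = 0.1,
                    Time.F = 1, Time.p = 0.5, Time.q = 1,
                    Group.F = 1, Group.p = 0.5, Group.q = 1,
                    TimexGroup.F = 1, TimexGroup.p = 0.5, TimexGroup.q = 1,
                    stringsAsFactors = FALSE)
  for (nm in spec$contrasts$name) {
    tab[[paste0(nm, ".est")]] <- 0
    tab[[paste0(nm, ".se")]] <- 0.1
    tab[[paste0(nm, ".p")]] <- 0.5
    tab[[paste0(nm, ".q")]] <- 1
  }
  structure(tab, spec = spec, class = c("anova_table", "data.frame"))
}

# hand-built q/p fixture exercising every clause of the rule sets;
# expected labels enumerated by hand from the rule definitions
rule_fixture <- function() {
  a <- fake_anova(5)
  # T01: endurance-specific at 5 h (changed, separated from both, others
  #      never changed vs Pre)
  a$E5h.q[1] <- 0.01
  a$EvC5h.q[1] <- 0.02
  a$SvE5h.q[1] <- 0.03
  # T02: same signal but resistance also changed at 2.5 h -> specific
  #      exclusion clause; still an exercise-general (dependent) hit
  a$E5h.q[2] <- 0.01
  a$EvC5h.q[2] <- 0.02
  a$SvE5h.q[2] <- 0.03
  a$S2.5h.q[2] <- 0.04
  # T03: both exercise groups changed, never different from each other
  a$E5h.q[3] <- 0.01
  a$S5h.q[3] <- 0.02
  # T04: both changed, opposite ways (SvE significant at 5 h)
  a$E2.5h.q[4] <- 0.01
  a$S5h.q[4] <- 0.02
  a$SvE5h.q[4] <- 0.01
  # T05: time regulated at 2.5 h only (no interaction, Time FDR hit,
  #      all three groups raw p < 0.05 at 2.5 h but not at 5 h)
  a$TimexGroup.p[5] <- 0.5
  a$Time.q[5] <- 0.01
  a$C2.5h.p[5] <- 0.01
  a$E2.5h.p[5] <- 0.01
  a$S2.5h.p[5] <- 0.01
  a$C5h.p[5] <- 0.2
  a$E5h.p[5] <- 0.01
  a$S5h.p[5] <- 0.01
  a
}

# hand-enumerated expected labels for rule_fixture()
rule_fixture_expected <- function() {
  list(specific = c("Endurance", "none", "none", "none", "none"),
       general = c("none", "dependent", "independent", "dependent",
                   "none"),
       time_reg_25 = c(FALSE, FALSE, FALSE, FALSE, TRUE),
       time_reg_5 = rep(FALSE, 5))
}

# standard planted-class mixture used by several tests
planted_config <- function(n_transcripts, seed,
                           prop = c(null = 0.5,
                                    "specific:Endurance" = 0.1,
                                    "specific:Resistance" = 0.1,
                                    general_independent = 0.1,
                                    general_dependent = 0.1,
                                    time_all_groups = 0.1)) {
  sim_config(n_transcripts = n_transcripts, seed = seed,
             class_proportions = prop)
}
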