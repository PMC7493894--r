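# Independent oracles used to cross-check package implementations.

# Mass-action right-hand side written directly in R, independent of the
# compiled code path.  Takes the named parameter vector of a
# reaction_system and a named state vector.
rhs_oracle <- function(y, p) {
  atp_f <- p[["ATP"]] / (p[["ATP"]] + p[["K_ATP"]])
  v_asm <- p[["k_asm"]] * y[["APAF1"]] * y[["CytC"]] * atp_f
  v1f <- p[["kon_primary"]] * y[["Apop"]] * y[["PC9"]]
  v1r <- p[["koff_primary"]] * y[["Apop_PC9"]]
  v2f <- p[["kon_secondary"]] * y[["Apop_PC9"]] * y[["PC9"]]
  v2r <- p[["koff_secondary"]] * y[["Apop_PC9_2"]]
  v_auto <- p[["k_auto"]] * y[["Apop_PC9_2"]]
  v5f <- p[["kon_C9"]] * y[["Apop"]] * y[["C9"]]
  v5r <- p[["koff_C9"]] * y[["Apop_C9"]]
  v6f <- p[["kon_XIAP_C9"]] * y[["XIAP"]] * y[["C9"]]
  v6r <- p[["koff_XIAP_C9"]] * y[["XIAP_C9"]]
  v7f <- p[["kon_XIAP_C9"]] * y[["XIAP"]] * y[["Apop_C9"]]
  v7r <- p[["koff_XIAP_C9"]] * y[["Apop_C9_XIAP"]]
  v8f <- p[["kon_XIAP_C3"]] * y[["XIAP"]] * y[["C3"]]
  v8r <- p[["koff_XIAP_C3"]] * y[["XIAP_C3"]]
  v9f <- p[["kon_SMAC_XIAP"]] * y[["SMAC"]] * y[["XIAP"]]
  v9r <- p[["koff_SMAC_XIAP"]] * y[["SMAC_XIAP"]]
  v_ietd <- (p[["k_PC9"]] * (y[["Apop_PC9"]] + 2 * y[["Apop_PC9_2"]]) +
               p[["k_C9"]] * y[["Apop_C9"]]) * y[["PC3"]]
  v_devd <- p[["k_cat_DEVD"]] * y[["C3"]] * y[["Sub"]]
  dy <- c(
    CytC_mito = 0, SMAC_mito = 0,
    CytC = -v_asm,
    SMAC = -v9f + v9r,
    APAF1 = -v_asm + p[["s_APAF1"]] - p[["k_deg"]] * y[["APAF1"]],
    Apop = v_asm - v1f + v1r - v5f + v5r,
    PC9 = -v1f + v1r - v2f + v2r + p[["s_PC9"]] - p[["k_deg"]] * y[["PC9"]],
    Apop_PC9 = v1f - v1r - v2f + v2r,
    Apop_PC9_2 = v2f - v2r - v_auto,
    C9 = v_auto - v5f + v5r - v6f + v6r - p[["k_deg"]] * y[["C9"]],
    Apop_C9 = v_auto + v5f - v5r - v7f + v7r,
    XIAP = -v6f + v6r - v7f + v7r - v8f + v8r - v9f + v9r +
      p[["s_XIAP"]] - p[["k_deg"]] * y[["XIAP"]],
    XIAP_C9 = v6f - v6r,
    Apop_C9_XIAP = v7f - v7r,
    SMAC_XIAP = v9f - v9r,
    PC3 = -v_ietd + p[["s_PC3"]] - p[["k_deg"]] * y[["PC3"]],
    C3 = v_ietd - v8f + v8r - p[["k_deg"]] * y[["C3"]],
    XIAP_C3 = v8f - v8r,
    Sub = -v_devd, cSub = v_devd)
  dy
}

# Kaplan-Meier product-limit by direct computation
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(event & time == ut[i])
    n <- sum(time >= ut[i])
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# ROC AUC by O(n^2) pair counting with half-credit ties
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# permutation p-value for the logrank statistic
logrank_perm_oracle <- function(time, event, group, n_perm = 2000,
                                seed = 1) {
  stat <- function(g) {
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  }
  obs <- stat(group)
  set.seed(seed)
  ge <- 0
  for (i in seq_len(n_perm)) {
    if (stat(sample(group)) >= obs) ge <- ge + 1
  }
  (ge + 1) / (n_perm + 1)
}

# random virtual-cell initial state after MOMP, for property tests
random_fixture_state <- function(seed, momp_fraction = 1) {
  cell <- sample_cohort(n = 1, seed = seed)
  apply_momp(initial_state(APAF1 = cell$apaf1, PC9 = cell$pc9,
                           PC3 = cell$pc3, XIAP = cell$xiap,
                           SMAC = cell$smac), momp_fraction)
}

# hand-built trajectory object with a prescribed cleavage fraction curve
fake_cleavage_trajectory <- function(time, cleav_frac, sub_total = 10) {
  conc <- matrix(0, length(time), length(apoptimer:::.species_names),
                 dimnames = list(NULL, apoptimer:::.species_names))
  conc[, "cSub"] <- cleav_frac * sub_total
  conc[, "Sub"] <- (1 - cleav_frac) * sub_total
  structure(list(time = time, conc = conc), class = "trajectory")
}
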