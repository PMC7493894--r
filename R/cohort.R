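# Virtual-cell cohort screens: sampling, four-variant simulation, survival
# curves, logrank, apoptosis/timer classification, ROC and Webb synergy.

#' Default physiological sampling ranges (uM)
#'
#' Uniform ranges for the five sampled execution proteins, spanning reported
#' expression across common cell lines; CytC and ATP are fixed at HeLa-like
#' 10 and 920 uM (non-limiting).
#'
#' @export
default_ranges <- function() {
  list(APAF1 = c(0.05, 1), PC9 = c(0.005, 0.25), PC3 = c(0.05, 1),
       XIAP = c(0.01, 0.6), SMAC = c(0.05, 1.5))
}

#' Sample a virtual-cell cohort
#'
#' Draws `n` entirely unique protein combinations, each protein sampled
#' independently and uniformly (or log-uniformly) over its range.
#'
#' @param ranges named list of length-2 ranges as from [default_ranges()].
#' @param n cohort size.
#' @param seed RNG seed.
#' @param log_scale sample log-uniformly instead of uniformly.
#' @return data.frame `id`, `apaf1`, `pc9`, `pc3`, `xiap`, `smac` with
#'   attribute `seed`.
#' @export
sample_cohort <- function(ranges = default_ranges(), n = 1000, seed = 1,
                          log_scale = FALSE) {
  stopifnot(n >= 1)
  need <- c("APAF1", "PC9", "PC3", "XIAP", "SMAC")
  stopifnot(all(need %in% names(ranges)))
  for (nm in need)
    if (any(ranges[[nm]] <= 0) && log_scale)
      stop("log-scale sampling needs positive range limits")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(rg) {
    if (log_scale) exp(runif(n, log(rg[1]), log(rg[2])))
    else runif(n, rg[1], rg[2])
  }
  for (attempt in 1:10) {
    d <- data.frame(id = seq_len(n),
                    apaf1 = draw(ranges$APAF1), pc9 = draw(ranges$PC9),
                    pc3 = draw(ranges$PC3), xiap = draw(ranges$XIAP),
                    smac = draw(ranges$SMAC))
    if (!anyDuplicated(d[, -1])) {
      attr(d, "seed") <- seed
      return(d)
    }
  }
  stop("could not draw unique combinations; degenerate ranges?")
}

.cell_state <- function(cell, momp_fraction) {
  apply_momp(initial_state(APAF1 = cell$apaf1, PC9 = cell$pc9,
                           PC3 = cell$pc3, XIAP = cell$xiap,
                           SMAC = cell$smac), momp_fraction)
}

#' Simulate a cohort under the four screening conditions
#'
#' Runs every cell under the `normal`, `no_xiap`, `no_timer` and
#' `no_xiap_no_timer` variants after (partial) MOMP, recording the death
#' event (cleavage > `threshold`, censoring at `horizon`) and the cleavage
#' fractions at the 15/30/60/240-min checkpoints.  Cells are independent;
#' per-cell failures are dropped with a reported count.
#'
#' @param cohort a [sample_cohort()] data.frame.
#' @param momp_fraction release fraction (1 or 0.05).
#' @param horizon censoring horizon (min).
#' @param threshold death threshold on cleavage.
#' @param params kinetic parameters.
#' @param variants which named variants to run.
#' @return data.frame of class `condition_outcomes`: `id`, `variant`,
#'   `died`, `event_time`, `cleav15`, `cleav30`, `cleav60`, `cleav240`
#'   (the last checkpoint tracks `horizon` when it differs from 240).
#' @export
run_conditions <- function(cohort, momp_fraction = 1, horizon = 240,
                           threshold = 0.25,
                           params = default_parameters(),
                           variants = c("normal", "no_xiap", "no_timer",
                                        "no_xiap_no_timer")) {
  checkpoints <- pmin(c(15, 30, 60, 240), horizon)
  systems <- lapply(variants, function(v)
    build_network(params, variant_by_name(v)))
  names(systems) <- variants
  rows <- vector("list", nrow(cohort) * length(variants))
  k <- 0L; failed <- 0L
  for (i in seq_len(nrow(cohort))) {
    s0 <- .cell_state(cohort[i, ], momp_fraction)
    for (v in variants) {
      k <- k + 1L
      res <- try({
        tr <- simulate_network(systems[[v]], s0, t_end = horizon,
                               n_out = max(241L, horizon + 1L))
        ev <- detect_death_event(tr, threshold = threshold,
                                 censor_at = horizon)
        cl <- c3_substrate_cleavage(tr, checkpoints)
        data.frame(id = cohort$id[i], variant = v, died = ev$died,
                   event_time = ev$event_time,
                   cleav15 = cl[1], cleav30 = cl[2], cleav60 = cl[3],
                   cleav240 = cl[4])
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        failed <- failed + 1L
        rows[k] <- list(NULL)
      } else rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (failed > 0)
    warning(failed, " cell x variant simulations failed and were excluded")
  attr(out, "failed") <- failed
  attr(out, "momp_fraction") <- momp_fraction
  attr(out, "threshold") <- threshold
  class(out) <- c("condition_outcomes", "data.frame")
  out
}

#' Kaplan-Meier survival curve for one variant
#'
#' Product-limit estimate (via \pkg{survival}) of the fraction of cells not
#' yet past the death threshold, censoring at the horizon.
#'
#' @param outcomes a [run_conditions()] result.
#' @param variant variant name to extract.
#' @return a `survival::survfit` object.
#' @export
survival_curve <- function(outcomes, variant = "normal") {
  d <- outcomes[outcomes$variant == variant, ]
  if (nrow(d) == 0) stop("no outcomes for variant ", variant)
  survival::survfit(survival::Surv(d$event_time, d$died) ~ 1)
}

#' Survival fraction at a checkpoint
#'
#' Fraction of cells with no death event by time `t` (deterministic
#' censoring at the horizon makes this the empirical survivor function).
#'
#' @param outcomes a [run_conditions()] result.
#' @param variant variant name.
#' @param t checkpoint (min).
#' @export
survival_fraction <- function(outcomes, variant, t) {
  d <- outcomes[outcomes$variant == variant, ]
  if (nrow(d) == 0) stop("no outcomes for variant ", variant)
  mean(!(d$died & d$event_time <= t))
}

#' Logrank test between two groups of outcomes
#'
#' @param a,b `condition_outcomes` subsets (single variant each) or any
#'   data.frames with `event_time` and `died`.
#' @return list `chisq`, `df`, `p`.
#' @export
logrank_test <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("both groups must be nonempty")
  time <- c(a$event_time, b$event_time)
  status <- c(a$died, b$died)
  grp <- rep(c("A", "B"), c(nrow(a), nrow(b)))
  if (!any(status)) {
    warning("no events in either group; logrank undefined, p = 1")
    return(list(chisq = 0, df = 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  list(chisq = sd$chisq, df = length(sd$n) - 1L,
       p = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE))
}

#' Classify cells as apoptosis capable/resistant and timer dependent
#'
#' A cell is apoptosis resistant when its C3-substrate cleavage under the
#' normal model stays at or below `threshold` at `t_eval`; a resistant cell
#' is molecular-timer dependent when removing the timer pushes cleavage
#' above the threshold.
#'
#' @param outcomes a [run_conditions()] result containing the `normal` and
#'   `no_timer` variants.
#' @param threshold cleavage cut-off (0.25 default; 0.8 for the less
#'   stringent screen).
#' @param t_eval evaluation time: one of the recorded checkpoints
#'   (default 60 min).
#' @return data.frame `id`, `capable`, `timer_dependent` (NA for capable
#'   cells).
#' @export
classify_cells <- function(outcomes, threshold = 0.25, t_eval = 60) {
  col <- paste0("cleav", t_eval)
  if (!col %in% names(outcomes)) stop("no checkpoint recorded at ", t_eval)
  norm <- outcomes[outcomes$variant == "normal", c("id", col)]
  nt <- outcomes[outcomes$variant == "no_timer", c("id", col)]
  if (nrow(norm) == 0 || nrow(nt) == 0)
    stop("outcomes must contain the normal and no_timer variants")
  m <- merge(norm, nt, by = "id", suffixes = c("_normal", "_no_timer"))
  capable <- m[[paste0(col, "_normal")]] > threshold
  timer_dep <- ifelse(capable, NA,
                      m[[paste0(col, "_no_timer")]] > threshold)
  data.frame(id = m$id, capable = capable, timer_dependent = timer_dep)
}

#' XIAP-SMAC balance score
#'
#' `log10(XIAP / SMAC)`: 0 at equimolarity, positive for XIAP excess.
#'
#' @param xiap,smac concentrations (> 0), vectorised.
#' @export
xiap_smac_balance <- function(xiap, smac) {
  if (any(xiap <= 0) || any(smac <= 0))
    stop("balance needs positive concentrations")
  log10(xiap / smac)
}

#' ROC AUC by Mann-Whitney pair counting
#'
#' AUC is the probability that a randomly chosen positive outranks a random
#' negative (ties count 1/2), computed from rank sums.  Orientation is
#' chosen so the reported AUC is >= 0.5 and recorded.
#'
#' @param scores numeric predictor (e.g. an input concentration or the
#'   XIAP-SMAC balance).
#' @param labels logical or 0/1 positive-class indicator.
#' @param name classifier name carried through.
#' @return list of class `roc_result`: `auc`, `orientation` (`"+"` if high
#'   scores predict the positive class, `"-"` otherwise), `n_pos`, `n_neg`,
#'   `name`.
#' @export
roc_auc <- function(scores, labels, name = deparse(substitute(scores))) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  orientation <- if (auc >= 0.5) "+" else "-"
  structure(list(auc = max(auc, 1 - auc), orientation = orientation,
                 n_pos = n_pos, n_neg = n_neg, name = name),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC [%s]: AUC = %.3f (%s orientation; %d pos / %d neg)\n",
              x$name, x$auc, x$orientation, x$n_pos, x$n_neg))
  invisible(x)
}

#' Webb's fractional product synergy score
#'
#' Independence-based synergy of XIAP and the molecular timer from survival
#' fractions at a checkpoint:
#' `(S_both / S_normal) / ((S_noXIAP / S_normal) * (S_noTimer / S_normal))`.
#' Scores strictly below 0.9 are flagged synergistic.
#'
#' @param outcomes a [run_conditions()] result with all four variants, or
#'   `NULL` when the four survival fractions are given directly.
#' @param t checkpoint (min).
#' @param s_normal,s_no_xiap,s_no_timer,s_both survival fractions
#'   overriding `outcomes`.
#' @return list of class `synergy_score`: `t`, the four survivals, `score`,
#'   `synergistic`.
#' @export
webb_synergy <- function(outcomes = NULL, t = 60, s_normal = NULL,
                         s_no_xiap = NULL, s_no_timer = NULL,
                         s_both = NULL) {
  if (!is.null(outcomes)) {
    s_normal <- survival_fraction(outcomes, "normal", t)
    s_no_xiap <- survival_fraction(outcomes, "no_xiap", t)
    s_no_timer <- survival_fraction(outcomes, "no_timer", t)
    s_both <- survival_fraction(outcomes, "no_xiap_no_timer", t)
  }
  s <- c(s_normal, s_no_xiap, s_no_timer, s_both)
  if (any(s < 0) || any(s > 1)) stop("survival fractions must lie in [0,1]")
  if (s_normal <= 0 || s_no_xiap <= 0 || s_no_timer <= 0) {
    score <- NA_real_
    warning("zero survival in a reference condition; synergy undefined")
  } else {
    score <- (s_both / s_normal) /
      ((s_no_xiap / s_normal) * (s_no_timer / s_normal))
  }
  structure(list(t = t, s_normal = s_normal, s_no_xiap = s_no_xiap,
                 s_no_timer = s_no_timer, s_both = s_both, score = score,
                 synergistic = is.finite(score) && score < 0.9),
            class = "synergy_score")
}

#' @export
print.synergy_score <- function(x, ...) {
  cat(sprintf("Webb synergy at %g min: score = %.4f (%s)\n", x$t, x$score,
              if (isTRUE(x$synergistic)) "synergistic" else
                "not synergistic"))
  invisible(x)
}

#' Timer contribution to substrate cleavage
#'
#' Difference in C3-substrate cleavage without vs with the molecular timer
#' at a checkpoint (nonnegative up to solver tolerance).
#'
#' @param outcomes a [run_conditions()] result.
#' @param t checkpoint (min), one of the recorded checkpoints.
#' @return data.frame `id`, `delta` (cleavage fraction).
#' @export
timer_contribution <- function(outcomes, t = 60) {
  col <- paste0("cleav", t)
  if (!col %in% names(outcomes)) stop("no checkpoint recorded at ", t)
  norm <- outcomes[outcomes$variant == "normal", c("id", col)]
  nt <- outcomes[outcomes$variant == "no_timer", c("id", col)]
  if (nrow(norm) == 0 || nrow(nt) == 0) stop("missing variant")
  m <- merge(norm, nt, by = "id", suffixes = c("_n", "_t"))
  data.frame(id = m$id,
             delta = m[[paste0(col, "_t")]] - m[[paste0(col, "_n")]])
}
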