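# End-to-end population screen: classification ROC, timer rescue and Webb
# synergy after full and minority MOMP.

#' Run the full virtual-cell population screen
#'
#' Samples a cohort, classifies apoptosis capability and molecular-timer
#' dependence at 60 min (normal vs timer-off variants) after full MOMP and
#' minMOMP, computes ROC AUCs of every input protein and the XIAP-SMAC
#' balance for both classifications, and on a (smaller) survival cohort
#' runs all four variants to the 240-min horizon for timer-rescue fractions
#' and Webb synergy scores.
#'
#' @param n classification cohort size.
#' @param seed RNG seed (controls both cohorts).
#' @param n_survival survival cohort size (four variants, 240 min).
#' @param params kinetic parameters.
#' @param ranges sampling ranges.
#' @param threshold cleavage cut-off for resistance.
#' @return list of class `screen_report`:
#'   `auc` — data.frame (momp, target, score, auc);
#'   `rescue` — data.frame (momp, n_rescued, n_deaths_no_timer, fraction);
#'   `webb` — data.frame (momp, t, score, synergistic);
#'   `resistant_fraction` — named vector; `n`, `n_survival`, `seed`.
#' @export
screen_report <- function(n = 5000, seed = 1, n_survival = 1000,
                          params = default_parameters(),
                          ranges = default_ranges(), threshold = 0.25) {
  co <- sample_cohort(ranges, n = n, seed = seed)
  co_s <- sample_cohort(ranges, n = n_survival, seed = seed + 1)
  scores <- list(apaf1 = co$apaf1, pc9 = co$pc9, pc3 = co$pc3,
                 xiap = co$xiap, smac = co$smac,
                 balance = xiap_smac_balance(co$xiap, co$smac))
  auc_rows <- list()
  rescue_rows <- list()
  webb_rows <- list()
  resistant_fraction <- c()
  for (momp in c(1, 0.05)) {
    tag <- if (momp == 1) "momp" else "minmomp"
    oc <- run_conditions(co, momp_fraction = momp, horizon = 60,
                         threshold = threshold, params = params,
                         variants = c("normal", "no_timer"))
    cls <- classify_cells(oc, threshold = threshold, t_eval = 60)
    cls <- cls[match(co$id, cls$id), ]
    resistant <- !cls$capable
    resistant_fraction[tag] <- mean(resistant)
    for (s in names(scores)) {
      auc_rows[[length(auc_rows) + 1]] <- data.frame(
        momp = tag, target = "resistance", score = s,
        auc = roc_auc(scores[[s]], resistant, name = s)$auc)
    }
    td <- cls$timer_dependent[resistant]
    if (length(unique(td[!is.na(td)])) == 2) {
      for (s in names(scores)) {
        auc_rows[[length(auc_rows) + 1]] <- data.frame(
          momp = tag, target = "timer_dependence", score = s,
          auc = roc_auc(scores[[s]][resistant], td, name = s)$auc)
      }
    }
    # survival cohort: all four variants to the censoring horizon
    oc4 <- run_conditions(co_s, momp_fraction = momp, horizon = 240,
                          threshold = threshold, params = params)
    nrm <- oc4[oc4$variant == "normal", c("id", "died")]
    ntm <- oc4[oc4$variant == "no_timer", c("id", "died")]
    m <- merge(nrm, ntm, by = "id", suffixes = c("_normal", "_no_timer"))
    n_deaths <- sum(m$died_no_timer)
    n_resc <- sum(!m$died_normal & m$died_no_timer)
    rescue_rows[[length(rescue_rows) + 1]] <- data.frame(
      momp = tag, n_rescued = n_resc, n_deaths_no_timer = n_deaths,
      fraction = if (n_deaths > 0) n_resc / n_deaths else NA_real_)
    for (t in c(15, 30, 60, 240)) {
      ws <- suppressWarnings(webb_synergy(oc4, t))
      webb_rows[[length(webb_rows) + 1]] <- data.frame(
        momp = tag, t = t, score = ws$score,
        synergistic = isTRUE(ws$synergistic))
    }
  }
  structure(list(auc = do.call(rbind, auc_rows),
                 rescue = do.call(rbind, rescue_rows),
                 webb = do.call(rbind, webb_rows),
                 resistant_fraction = resistant_fraction,
                 n = n, n_survival = n_survival, seed = seed),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Population screen (n = %d classification, %d survival, seed %d)\n",
              x$n, x$n_survival, x$seed))
  cat("  resistant fraction:",
      paste(names(x$resistant_fraction),
            round(x$resistant_fraction, 3), collapse = ", "), "\n")
  a <- x$auc[x$auc$target == "resistance" & x$auc$momp == "momp", ]
  cat("  resistance AUC after full MOMP:\n")
  for (i in order(-a$auc))
    cat(sprintf("    %-8s %.3f\n", a$score[i], a$auc[i]))
  r <- x$rescue
  for (i in seq_len(nrow(r)))
    cat(sprintf("  timer rescue (%s): %d/%d = %.3f\n", r$momp[i],
                r$n_rescued[i], r$n_deaths_no_timer[i], r$fraction[i]))
  w <- stats::aggregate(score ~ momp, data = x$webb[is.finite(x$webb$score), ],
                        FUN = stats::median)
  for (i in seq_len(nrow(w)))
    cat(sprintf("  median Webb score (%s): %.3f\n", w$momp[i], w$score[i]))
  invisible(x)
}

#' Extract one AUC from a screen report
#'
#' @param report a [screen_report()].
#' @param momp `"momp"` or `"minmomp"`.
#' @param target `"resistance"` or `"timer_dependence"`.
#' @param score protein name or `"balance"`.
#' @return the AUC, or `NA` if that combination was not computed.
#' @export
screen_auc <- function(report, momp, target, score) {
  a <- report$auc
  hit <- a$momp == momp & a$target == target & a$score == score
  if (!any(hit)) return(NA_real_)
  a$auc[hit][1]
}
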