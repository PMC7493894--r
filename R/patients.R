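# Apoptosis-competency classification of patient tumour protein profiles
# and its relation to disease-free / overall survival.

#' Load a patient protein/survival table
#'
#' Reads a CSV with columns `id`, `pc9`, `pc3`, `xiap`, `smac`, optional
#' `apaf1`, and survival columns `dfs_time`, `dfs_event`, `os_time`,
#' `os_event`.  Concentrations must already be in uM (the unit conversion
#' from RPPA-derived measurements is cohort-specific and must be applied
#' upstream); missing APAF1 is filled with the colorectal tumour median of
#' 0.123 uM.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @param apaf1_default APAF1 fill-in value (uM).
#' @return validated data.frame of patient records.
#' @export
load_patient_table <- function(path, apaf1_default = 0.123) {
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("id", "pc9", "pc3", "xiap", "smac",
            "dfs_time", "dfs_event", "os_time", "os_event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"apaf1" %in% names(d)) d$apaf1 <- apaf1_default
  d$apaf1[is.na(d$apaf1)] <- apaf1_default
  conc <- c("apaf1", "pc9", "pc3", "xiap", "smac")
  for (cc in conc) {
    bad <- which(!is.finite(d[[cc]]) | d[[cc]] < 0)
    if (length(bad))
      stop("negative or unparseable ", cc, " in row(s): ",
           paste(bad, collapse = ", "))
  }
  for (cc in c("dfs_time", "os_time")) {
    bad <- which(!is.finite(d[[cc]]) | d[[cc]] <= 0)
    if (length(bad))
      stop("unparseable survival time in row(s): ",
           paste(bad, collapse = ", "))
  }
  d
}

#' Classify one patient profile by simulation
#'
#' Simulates full MOMP under the normal model for `horizon` minutes;
#' C3-substrate cleavage at or below `threshold` marks the tumour
#' apoptosis resistant.  For resistant profiles the simulation is repeated
#' with the molecular timer off to determine timer dependence and the
#' timer's cleavage contribution at the horizon.
#'
#' @param record one-row data.frame (or list) with `apaf1`, `pc9`, `pc3`,
#'   `xiap`, `smac` in uM.
#' @param horizon simulation time (min), default 300.
#' @param threshold cleavage cut-off, default 0.25.
#' @param params kinetic parameters.
#' @param timer_dependence also run the timer-off variant for resistant
#'   profiles.
#' @return list of class `patient_classification`: `class`
#'   (`"capable"`/`"resistant"`), `cleavage` (normal model, at horizon),
#'   `timer_dependent` (NA for capable tumours), `timer_contribution`.
#' @export
classify_patient <- function(record, horizon = 300, threshold = 0.25,
                             params = default_parameters(),
                             timer_dependence = TRUE) {
  s0 <- apply_momp(initial_state(APAF1 = record$apaf1, PC9 = record$pc9,
                                 PC3 = record$pc3, XIAP = record$xiap,
                                 SMAC = record$smac), 1)
  sim_cleav <- function(variant) {
    sys <- build_network(params, variant_by_name(variant))
    tr <- simulate_network(sys, s0, t_end = horizon,
                           times = c(0, horizon / 2, horizon))
    c3_substrate_cleavage(tr, horizon)
  }
  cl <- sim_cleav("normal")
  resistant <- cl <= threshold
  timer_dep <- NA
  contrib <- NA_real_
  if (resistant && timer_dependence) {
    cl_nt <- sim_cleav("no_timer")
    timer_dep <- cl_nt > threshold
    contrib <- cl_nt - cl
  }
  structure(list(class = if (resistant) "resistant" else "capable",
                 cleavage = cl, timer_dependent = timer_dep,
                 timer_contribution = contrib),
            class = "patient_classification")
}

#' Classify every patient in a table
#'
#' @param records a [load_patient_table()] data.frame.
#' @inheritParams classify_patient
#' @return the records with appended columns `class`, `cleavage`,
#'   `timer_dependent`, `timer_contribution`; failed simulations yield NA
#'   with a warning.
#' @export
classify_patients <- function(records, horizon = 300, threshold = 0.25,
                              params = default_parameters()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    res <- try(classify_patient(records[i, ], horizon, threshold, params),
               silent = TRUE)
    if (inherits(res, "try-error"))
      list(class = NA_character_, cleavage = NA_real_,
           timer_dependent = NA, timer_contribution = NA_real_)
    else res
  })
  records$class <- vapply(out, `[[`, character(1), "class")
  records$cleavage <- vapply(out, `[[`, numeric(1), "cleavage")
  records$timer_dependent <- vapply(out, function(x)
    as.logical(x$timer_dependent), logical(1))
  records$timer_contribution <- vapply(out, `[[`, numeric(1),
                                       "timer_contribution")
  n_fail <- sum(is.na(records$class))
  if (n_fail) warning(n_fail, " patient classification(s) failed")
  records
}

#' Kaplan-Meier curves by apoptosis class
#'
#' Product-limit curves for resistant vs capable patients on the chosen
#' endpoint, with a logrank test when both classes are present.
#'
#' @param classified a [classify_patients()] result.
#' @param endpoint `"dfs"` or `"os"`.
#' @return list `fit` (a `survfit` stratified by class), `logrank`
#'   (`NULL` with a single class), `n` per class.
#' @export
km_by_class <- function(classified, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  d <- classified[!is.na(classified$class), ]
  if (nrow(d) == 0) stop("no classified patients")
  time <- d[[paste0(endpoint, "_time")]]
  event <- d[[paste0(endpoint, "_event")]]
  cls <- factor(d$class, levels = c("capable", "resistant"))
  fit <- survival::survfit(survival::Surv(time, event) ~ cls)
  lr <- NULL
  if (nlevels(droplevels(cls)) == 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ cls)
    lr <- list(chisq = sd$chisq,
               p = stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
  }
  list(fit = fit, logrank = lr, n = table(cls))
}

#' Hazard ratio of resistant vs capable patients
#'
#' Two-group Cox proportional-hazards fit on the class indicator.
#'
#' @inheritParams km_by_class
#' @return list `hr`, `ci` (95%), `p`, `model` (the `coxph` fit).
#' @export
hazard_ratio <- function(classified, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  d <- classified[!is.na(classified$class), ]
  time <- d[[paste0(endpoint, "_time")]]
  event <- d[[paste0(endpoint, "_event")]]
  cls <- factor(d$class, levels = c("capable", "resistant"))
  if (nlevels(droplevels(cls)) < 2)
    stop("both classes needed for a hazard ratio")
  if (sum(event) == 0) stop("no events; hazard ratio undefined")
  fit <- survival::coxph(survival::Surv(time, event) ~ cls)
  sm <- summary(fit)
  list(hr = unname(sm$conf.int[1, "exp(coef)"]),
       ci = unname(sm$conf.int[1, c("lower .95", "upper .95")]),
       p = unname(sm$coefficients[1, "Pr(>|z|)"]),
       model = fit)
}

#' APAF1 sensitivity of patient classification
#'
#' Re-classifies every patient at alternative APAF1 concentrations and
#' reports how many class labels change relative to the reference
#' classification.
#'
#' @param records a patient table.
#' @param apaf1_values APAF1 concentrations to scan (uM).
#' @inheritParams classify_patient
#' @return data.frame `apaf1`, `n_changed`.
#' @export
apaf1_sensitivity <- function(records, apaf1_values = c(0.0123, 0.123, 1.23),
                              horizon = 300, threshold = 0.25,
                              params = default_parameters()) {
  ref <- classify_patients(records, horizon, threshold, params)$class
  n_changed <- vapply(apaf1_values, function(a) {
    r <- records
    r$apaf1 <- a
    cls <- classify_patients(r, horizon, threshold, params)$class
    sum(cls != ref, na.rm = TRUE)
  }, numeric(1))
  data.frame(apaf1 = apaf1_values, n_changed = n_changed)
}
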