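# Synthetic data generators: SPR-like dissociation traces, calibration
# training sets, and patient cohorts with survival.  Every generator is a
# pure function of its arguments and seed.

#' Generate a synthetic dissociation trace
#'
#' Samples the one-phase decay `y = (y0 - plateau) exp(-k_off t) + plateau`
#' on an even grid with seeded Gaussian noise, emulating the dissociation
#' phase of an SPR sensorgram.
#'
#' @param k_off decay rate (> 0), per time unit of `t_end`.
#' @param y0,plateau response at time 0 and asymptote (response units).
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param n_points number of samples (>= 5).
#' @param seed RNG seed.
#' @param t_end trace duration; default covers ~5 half-lives.
#' @param label optional label.
#' @return data.frame `time`, `response`, `label`.
#' @export
generate_spr_trace <- function(k_off, y0 = 10, plateau = 0, noise_sd = 0,
                               n_points = 50, seed = 1, t_end = NULL,
                               label = "trace") {
  if (!is.finite(k_off) || k_off <= 0) stop("k_off must be positive")
  if (n_points < 5) stop("need at least 5 points")
  if (is.null(t_end)) t_end <- 5 * log(2) / k_off
  tt <- seq(0, t_end, length.out = n_points)
  yy <- (y0 - plateau) * exp(-k_off * tt) + plateau
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    yy <- yy + rnorm(n_points, sd = noise_sd)
  }
  data.frame(time = tt, response = yy, label = label)
}

# save/restore global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a calibration training set
#'
#' Emulates the two training data sets of the calibration step: a
#' Boltzmann-shaped C3-substrate cleavage time course (as measured by
#' DEVD-FRET probes in HeLa cells) and molecular-timer points (maximal
#' substrate-cleavage rate after 5-30 min apoptosome pre-incubation,
#' normalised to the shortest delay).
#'
#' @param boltzmann named list/vector with `bottom`, `top`, `v50`, `slope`
#'   (cleavage %, min).
#' @param timer named list/vector with `t_half` (min) of the decay of the
#'   maximal cleavage rate with pre-incubation delay, and `plateau`
#'   (relative rate floor).
#' @param noise_cleavage,noise_timer Gaussian noise SDs (cleavage %,
#'   relative rate).
#' @param cleavage_times,delays sampling grids (min).
#' @param seed RNG seed.
#' @return list of class `training_set`: `cleavage` (data.frame t,
#'   cleavage_pct), `timer` (data.frame delay, rel_rate), `boltzmann`,
#'   `timer_truth`, `weights`.
#' @export
generate_training_set <- function(boltzmann = list(bottom = 0, top = 95,
                                                   v50 = 25, slope = 6),
                                  timer = list(t_half = 15, plateau = 0.1),
                                  noise_cleavage = 0, noise_timer = 0,
                                  cleavage_times = seq(0, 60, by = 2.5),
                                  delays = seq(5, 30, by = 5),
                                  seed = 1) {
  b <- as.list(boltzmann); tm <- as.list(timer)
  stopifnot(all(c("bottom", "top", "v50", "slope") %in% names(b)),
            all(c("t_half", "plateau") %in% names(tm)))
  if (b$slope == 0) stop("Boltzmann slope must be nonzero")
  if (tm$t_half <= 0) stop("timer t_half must be positive")
  if (any(delays < 5 - 1e-9) || any(delays > 30 + 1e-9))
    stop("pre-incubation delays must lie in the 5-30 min protocol window")
  cl <- boltzmann_curve(cleavage_times, b$bottom, b$top, b$v50, b$slope)
  k <- log(2) / tm$t_half
  rr <- tm$plateau + (1 - tm$plateau) * exp(-k * (delays - delays[1]))
  if (noise_cleavage > 0 || noise_timer > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    if (noise_cleavage > 0) cl <- cl + rnorm(length(cl), sd = noise_cleavage)
    if (noise_timer > 0) rr <- rr + rnorm(length(rr), sd = noise_timer)
  }
  cl <- pmin(pmax(cl, 0), 100)
  structure(list(
    cleavage = data.frame(t = cleavage_times, cleavage_pct = cl),
    timer = data.frame(delay = delays, rel_rate = rr),
    boltzmann = b, timer_truth = tm, weights = c(cleavage = 1, timer = 1)),
    class = "training_set")
}

#' Default cohort specification for synthetic patients
#'
#' Log-normal protein concentrations parameterised by median and coefficient
#' of variation; the CVs default to those observed in the stage III
#' colorectal cohort (XIAP 100%, PC9 154%, PC3 144%, SMAC 135%).  Survival
#' is exponential with a class-dependent hazard (resistant vs capable) and
#' independent exponential censoring.
#'
#' @param n number of patients.
#' @param medians named medians (uM) for PC9, PC3, XIAP, SMAC.
#' @param cvs named coefficients of variation (sd/mean) for the same
#'   proteins.
#' @param apaf1 fixed APAF1 concentration (uM), default the colorectal
#'   median 0.123.
#' @param base_rate baseline event hazard per month for apoptosis-capable
#'   patients.
#' @param hazard_ratio hazard ratio of resistant vs capable patients.
#' @param censor_rate independent censoring hazard per month.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 120,
                        medians = c(PC9 = 0.04, PC3 = 0.2, XIAP = 0.12,
                                    SMAC = 0.4),
                        cvs = c(PC9 = 1.54, PC3 = 1.44, XIAP = 1.00,
                                SMAC = 1.35),
                        apaf1 = 0.123, base_rate = 0.01,
                        hazard_ratio = 2, censor_rate = 0.012) {
  stopifnot(n >= 1, all(cvs > 0), hazard_ratio > 0, all(medians > 0),
            base_rate > 0, censor_rate >= 0)
  structure(list(n = as.integer(n), medians = medians, cvs = cvs,
                 apaf1 = apaf1, base_rate = base_rate,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws log-normal protein profiles per [cohort_spec()], classifies each
#' simulated profile as apoptosis capable or resistant with
#' [classify_patient()] (full MOMP, 300 min, 25% cleavage), then draws
#' disease-free and overall survival times from class-dependent exponential
#' hazards with independent censoring.  A log-normal with CV `c` uses
#' `sdlog = sqrt(log(1 + c^2))` around the median (`meanlog = log(median)`).
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @param params,classify model parameters for the classification step;
#'   `classify = FALSE` skips simulation and draws survival from a
#'   concentration-free coin flip (for quick statistical tests of the
#'   generator itself).
#' @return data.frame with columns id, apaf1, pc9, pc3, xiap, smac,
#'   sim_class, dfs_time, dfs_event, os_time, os_event (times in months).
#' @export
generate_patient_cohort <- function(spec = cohort_spec(), seed = 1,
                                    params = default_parameters(),
                                    classify = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- spec$n
  draw <- function(med, cv) {
    rlnorm(n, meanlog = log(med), sdlog = sqrt(log(1 + cv^2)))
  }
  d <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    apaf1 = rep(spec$apaf1, n),
    pc9 = draw(spec$medians[["PC9"]], spec$cvs[["PC9"]]),
    pc3 = draw(spec$medians[["PC3"]], spec$cvs[["PC3"]]),
    xiap = draw(spec$medians[["XIAP"]], spec$cvs[["XIAP"]]),
    smac = draw(spec$medians[["SMAC"]], spec$cvs[["SMAC"]]))
  if (classify) {
    cls <- vapply(seq_len(n), function(i) {
      pc <- classify_patient(d[i, ], params = params,
                             timer_dependence = FALSE)
      pc$class
    }, character(1))
  } else {
    cls <- ifelse(runif(n) < 0.5, "resistant", "capable")
  }
  d$sim_class <- cls
  if (all(cls == cls[1]))
    warning("synthetic cohort contains a single apoptosis class; ",
            "consider widening the concentration spec")
  rate <- ifelse(cls == "resistant", spec$base_rate * spec$hazard_ratio,
                 spec$base_rate)
  ev_dfs <- rexp(n, rate)
  ev_os <- ev_dfs + rexp(n, rate)  # death follows relapse
  cens <- if (spec$censor_rate > 0) rexp(n, spec$censor_rate) else
    rep(Inf, n)
  d$dfs_time <- pmin(ev_dfs, cens)
  d$dfs_event <- as.integer(ev_dfs <= cens)
  d$os_time <- pmin(ev_os, cens)
  d$os_event <- as.integer(ev_os <= cens)
  d
}
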