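# Global least-squares calibration of the PC9/C9 apoptosome binding
# kinetics against C3-substrate cleavage and molecular-timer training data,
# under SPR-derived bounds.

#' Boltzmann sigmoid
#'
#' `bottom + (top - bottom) / (1 + exp((v50 - t)/slope))` — the functional
#' form used to summarise DEVD-FRET cleavage time courses.
#'
#' @param t time (min), vectorised.
#' @param bottom,top asymptotes (cleavage %).
#' @param v50 half-maximal time (min).
#' @param slope steepness (min); must be nonzero.
#' @export
boltzmann_curve <- function(t, bottom, top, v50, slope) {
  if (slope == 0) stop("Boltzmann slope must be nonzero")
  bottom + (top - bottom) / (1 + exp((v50 - t) / slope))
}

#' SPR-anchored bounds for the estimated binding constants
#'
#' Primary PC9 binding is assumed weaker than the SPR-measured kinetics
#' (`kon_primary < kon_SPR`, `koff_primary > koff_SPR`) and cooperative
#' secondary binding stronger (`kon_secondary > kon_SPR`,
#' `koff_secondary < koff_SPR`), reflecting that an SPR readout mixes the
#' two binding modes.  C9 rebinding is bounded to be weaker (in affinity)
#' than secondary PC9 binding.
#'
#' @param spr a [binding_kinetics()] for the cleavage-competent PC9 trace.
#' @param span multiplicative width of each bound interval on the free side.
#' @return list of class `parameter_bounds` with `lower`/`upper` named
#'   vectors over the estimated constants.
#' @export
default_bounds <- function(spr = binding_kinetics(t_half = 2/3, K_D = 0.1,
                                                  label = "PC9-TM"),
                           span = 1e3) {
  stopifnot(inherits(spr, "binding_kinetics"), span > 1)
  lower <- c(kon_primary = spr$k_on / span, koff_primary = spr$k_off,
             kon_secondary = spr$k_on, koff_secondary = spr$k_off / span,
             kon_C9 = spr$k_on / span, koff_C9 = spr$k_off,
             k_auto = 1e-3, k_PC9 = 1e-2, k_C9 = 1e-1)
  upper <- c(kon_primary = spr$k_on, koff_primary = spr$k_off * span,
             kon_secondary = spr$k_on * span, koff_secondary = spr$k_off,
             kon_C9 = spr$k_on, koff_C9 = spr$k_off * span,
             k_auto = 10, k_PC9 = 1e3, k_C9 = 1e4)
  structure(list(lower = lower, upper = upper, spr = spr),
            class = "parameter_bounds")
}

#' Maximal substrate-cleavage rate after apoptosome pre-incubation
#'
#' Reproduces the reconstituted-apoptosome timer protocol: APAF1 (0.3 uM),
#' PC9 (0.0125 uM), CytC (10 uM) and ATP (1 mM) are incubated for `delay`
#' minutes without PC3 or substrate; PC3 (0.5 uM) and C3-substrate (15 uM)
#' are then added and the maximal rate of substrate cleavage is read out.
#'
#' @param params kinetic parameter set.
#' @param delay pre-incubation time (min, >= 0).
#' @param variant model variant (no XIAP in the reconstituted system, so
#'   the default variant behaves identically to `no_xiap`).
#' @param readout_min observation window after substrate addition (min).
#' @param apaf1,pc9 reconstituted protein concentrations (uM).
#' @return maximal d(cleavage fraction)/dt (min^-1).
#' @export
timer_protocol_observable <- function(params = default_parameters(),
                                      delay, variant = model_variant(),
                                      readout_min = 20, apaf1 = 0.3,
                                      pc9 = 0.0125) {
  if (delay < 0) stop("delay must be >= 0")
  p <- params
  p["ATP"] <- 1000
  sys <- build_network(p, variant)
  s0 <- initial_state(APAF1 = apaf1, PC9 = pc9, PC3 = 0, XIAP = 0,
                      SMAC = 0, CytC = 0, Sub = 0)
  s0["CytC"] <- 10  # reconstituted: CytC supplied directly in the cytosol
  if (delay > 0) {
    tr <- simulate_network(sys, s0, t_end = delay, n_out = 61)
    y <- tr$conc[nrow(tr$conc), ]
    s1 <- s0
    s1[names(y)] <- y
  } else {
    s1 <- s0
  }
  s1["PC3"] <- 0.5
  s1["Sub"] <- 15
  tr2 <- simulate_network(sys, s1, t_end = readout_min, n_out = 271)
  cl <- tr2$conc[, "cSub"] / 15
  max(diff(cl) / diff(tr2$time))
}

# cleavage curve under HeLa conditions (full MOMP), percent
.hela_cleavage_curve <- function(params, times) {
  sys <- build_network(params, model_variant())
  s0 <- apply_momp(initial_state(), 1)
  tr <- simulate_network(sys, s0, times = times)
  100 * tr$conc[, "cSub"] / (tr$conc[, "Sub"] + tr$conc[, "cSub"])
}

.apply_candidate <- function(params, candidate) {
  params[names(candidate)] <- candidate
  params
}

#' Calibration objective (sum of squared residuals)
#'
#' Simulates the HeLa cleavage curve and the timer pre-incubation protocol
#' under a candidate parameter set and sums squared residuals against the
#' training set.  Each data set's residuals are normalised by its dynamic
#' range before the equal-weight sum, so "equal weighting" is well defined
#' across observables with different scales.  Failed simulations return a
#' large penalty.
#'
#' @param candidate named vector over (a subset of) the estimated constants.
#' @param training a [generate_training_set()] result.
#' @param params base parameter set overridden by `candidate`.
#' @param penalty value returned on simulation failure.
#' @return scalar SSE.
#' @export
calibration_objective <- function(candidate, training,
                                  params = default_parameters(),
                                  penalty = 1e6) {
  stopifnot(inherits(training, "training_set"))
  if (nrow(training$cleavage) == 0 && nrow(training$timer) == 0)
    stop("empty training set")
  p <- try(validate_quiet(.apply_candidate(params, candidate)),
           silent = TRUE)
  if (inherits(p, "try-error")) return(penalty)
  out <- try({
    sse <- 0
    if (nrow(training$cleavage) > 0) {
      obs <- training$cleavage$cleavage_pct
      sim <- .hela_cleavage_curve(p, times = c(0, training$cleavage$t))
      sim <- sim[-1]
      rng <- max(diff(range(obs)), 1)
      sse <- sse + training$weights[["cleavage"]] *
        sum(((sim - obs) / rng)^2)
    }
    if (nrow(training$timer) > 0) {
      rates <- vapply(training$timer$delay, function(d)
        timer_protocol_observable(p, d), numeric(1))
      rel <- rates / rates[1]
      obs <- training$timer$rel_rate
      rng <- max(diff(range(obs)), 0.1)
      sse <- sse + training$weights[["timer"]] *
        sum(((rel - obs) / rng)^2)
    }
    sse
  }, silent = TRUE)
  if (inherits(out, "try-error") || !is.finite(out)) penalty else out
}

validate_quiet <- function(p) {
  validate_parameters(p)
  p
}

#' Global parameter estimation under SPR-derived bounds
#'
#' Multi-start bounded least squares in log10-parameter space: Latin
#' hypercube starts over the box, local refinement with L-BFGS-B, best of
#' starts returned.  Deterministic for a fixed seed.
#'
#' @param bounds a [default_bounds()] object; estimation runs over the
#'   constants it names (or `subset` of them).
#' @param training a [generate_training_set()] result.
#' @param n_starts number of Latin-hypercube starts.
#' @param seed RNG seed.
#' @param params base parameter set for constants not being estimated.
#' @param subset optional character vector restricting the estimated
#'   constants.
#' @return list of class `calibration_fit`: `estimate` (named vector),
#'   `params` (full parameter set with the estimate applied), `sse`,
#'   `per_start` (SSE per start), `at_bound` (logical per constant),
#'   `seed`.
#' @export
estimate_parameters <- function(bounds, training, n_starts = 10, seed = 1,
                                params = default_parameters(),
                                subset = NULL) {
  stopifnot(inherits(bounds, "parameter_bounds"))
  nm <- names(bounds$lower)
  if (!is.null(subset)) nm <- intersect(nm, subset)
  if (!length(nm)) stop("no constants to estimate")
  lo <- log10(bounds$lower[nm]); hi <- log10(bounds$upper[nm])
  obj <- function(logp) {
    calibration_objective(stats::setNames(10^logp, nm), training,
                          params = params)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, length(nm))
  starts <- sweep(sweep(starts, 2, hi - lo, `*`), 2, lo, `+`)
  best <- NULL
  per_start <- numeric(n_starts)
  for (i in seq_len(n_starts)) {
    fit <- try(optim(starts[i, ], obj, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 60, factr = 1e10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      per_start[i] <- NA_real_
      next
    }
    per_start[i] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  est <- stats::setNames(10^best$par, nm)
  tol <- 1e-6
  at_bound <- (best$par - lo < tol) | (hi - best$par < tol)
  structure(list(estimate = est,
                 params = .apply_candidate(params, est),
                 sse = best$value, per_start = per_start,
                 at_bound = stats::setNames(at_bound, nm), seed = seed),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration fit (multi-start bounded least squares)\n")
  cat(sprintf("  SSE = %.6g over %d starts (seed %d)\n", x$sse,
              length(x$per_start), x$seed))
  est <- signif(x$estimate, 4)
  for (nm in names(est))
    cat(sprintf("  %-16s %s%s\n", nm, format(est[[nm]]),
                if (x$at_bound[[nm]]) "  [at bound]" else ""))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) object$estimate
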