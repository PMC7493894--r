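# One-phase-decay fitting and binding-kinetics conversion.
#
# The shared fitter behind SPR dissociation traces and IETDase decay
# half-lives:  y = (y0 - plateau) * exp(-k * x) + plateau,  t_half = ln(2)/k.

#' Fit a one-phase exponential decay
#'
#' Nonlinear least squares fit of `y = (y0 - plateau) exp(-k x) + plateau`
#' using a bounded Levenberg-Marquardt optimiser (\pkg{minpack.lm}) from a
#' deterministic start (`y0` = first value, `plateau` = last value, `k` from
#' a log-linear fit of the first third of the trace), so repeated fits are
#' identical.  `y0` and/or `plateau` can be fixed, as when fitting the
#' post-maximum segment of an activity trace with `y0` pinned to the
#' maximum.
#'
#' @param time,response the trace; at least 5 points, time strictly
#'   increasing.  Time unit is whatever the trace uses; `k` and `t_half`
#'   come back in that unit.
#' @param fix_y0,fix_plateau optional fixed values.
#' @param label optional trace label carried through.
#' @return object of class `one_phase_decay` with elements `y0`, `plateau`,
#'   `k`, `t_half`, `r_squared`, `valid` (FALSE when `k` is not
#'   identifiable, e.g. a flat trace), `label` and the data.
#' @examples
#' tr <- generate_spr_trace(k_off = 0.05, y0 = 10, plateau = 2,
#'                          noise_sd = 0, n_points = 40, seed = 1)
#' fit <- fit_one_phase_decay(tr$time, tr$response)
#' coef(fit)
#' @export
fit_one_phase_decay <- function(time, response, fix_y0 = NULL,
                                fix_plateau = NULL, label = NULL) {
  if (length(time) < 5) stop("a decay trace needs at least 5 points")
  if (length(time) != length(response)) stop("time/response length mismatch")
  if (is.unsorted(time, strictly = TRUE)) stop("time must strictly increase")
  x <- time - time[1]
  y <- as.numeric(response)
  amp0 <- y[1] - y[length(y)]
  rng <- diff(range(y))
  if (rng <= .Machine$double.eps * max(abs(y), 1) || amp0 <= 0) {
    fit <- list(y0 = y[1], plateau = y[length(y)], k = NA_real_,
                t_half = NA_real_, r_squared = NA_real_, valid = FALSE,
                label = label, time = time, response = y)
    class(fit) <- "one_phase_decay"
    return(fit)
  }
  # start heuristic: log-linear slope over the first third
  n1 <- max(3L, ceiling(length(x) / 3))
  pl0 <- if (is.null(fix_plateau)) min(y) - 0.05 * rng else fix_plateau
  z <- pmax(y[seq_len(n1)] - pl0, 1e-12 * rng)
  k0 <- max(-stats::coef(stats::lm(log(z) ~ x[seq_len(n1)]))[[2]], 1e-6)
  start <- c(if (is.null(fix_y0)) c(y0 = y[1]),
             if (is.null(fix_plateau)) c(plateau = min(y)),
             k = as.numeric(k0))
  model <- function(p) {
    y0 <- if (is.null(fix_y0)) p[["y0"]] else fix_y0
    pl <- if (is.null(fix_plateau)) p[["plateau"]] else fix_plateau
    (y0 - pl) * exp(-p[["k"]] * x) + pl
  }
  lower <- rep(-Inf, length(start)); names(lower) <- names(start)
  lower["k"] <- 1e-9
  if ("plateau" %in% names(start)) lower["plateau"] <- min(0, min(y))
  res <- minpack.lm::nls.lm(par = start, lower = lower,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- res$par
  yhat <- model(p)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  k <- p[["k"]]
  fit <- list(
    y0 = if (is.null(fix_y0)) p[["y0"]] else fix_y0,
    plateau = if (is.null(fix_plateau)) p[["plateau"]] else fix_plateau,
    k = k, t_half = log(2) / k,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    valid = is.finite(k) && k > 1e-8,
    label = label, time = time, response = y)
  class(fit) <- "one_phase_decay"
  fit
}

#' @export
print.one_phase_decay <- function(x, ...) {
  cat("One-phase decay fit")
  if (!is.null(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n")
  if (!x$valid) {
    cat("  invalid: decay coefficient not identifiable\n")
  } else {
    cat(sprintf("  y0 = %.4g, plateau = %.4g, k = %.4g per time unit\n",
                x$y0, x$plateau, x$k))
    cat(sprintf("  t_half = %.4g, R^2 = %.4f\n", x$t_half, x$r_squared))
  }
  invisible(x)
}

#' @export
coef.one_phase_decay <- function(object, ...) {
  c(y0 = object$y0, plateau = object$plateau, k = object$k,
    t_half = object$t_half)
}

#' @export
predict.one_phase_decay <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else
    if (is.list(newdata)) newdata$time else newdata
  if (!object$valid) return(rep(NA_real_, length(t)))
  (object$y0 - object$plateau) * exp(-object$k * (t - object$time[1])) +
    object$plateau
}

#' @export
plot.one_phase_decay <- function(x, ...) {
  plot(x$time, x$response, xlab = "time", ylab = "response", ...)
  if (x$valid) {
    tt <- seq(min(x$time), max(x$time), length.out = 200)
    lines(tt, predict(x, tt), col = 2)
  }
  invisible(x)
}

#' Dissociation rate from a half-life
#'
#' `k_off = ln(2) / t_half`, in the reciprocal of the half-life's unit.
#'
#' @param t_half dissociation half-life (> 0).
#' @export
koff_from_halftime <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop("t_half must be positive")
  log(2) / t_half
}

#' Association rate from k_off and K_D
#'
#' `k_on = k_off / K_D` (uM^-1 per time unit for K_D in uM).
#'
#' @param k_off dissociation rate.
#' @param K_D equilibrium dissociation constant (> 0), uM.
#' @export
kon_from_kd <- function(k_off, K_D) {
  if (any(!is.finite(K_D)) || any(K_D <= 0)) stop("K_D must be positive")
  k_off / K_D
}

#' Assemble a consistent kon/koff/K_D triple
#'
#' @param t_half dissociation half-life (min).
#' @param K_D equilibrium dissociation constant (uM).
#' @param label source label (e.g. the PC9 variant of the trace).
#' @return list of class `binding_kinetics` with `k_on` (uM^-1 min^-1),
#'   `k_off` (min^-1), `K_D` (uM), `label`; `K_D = k_off / k_on` by
#'   construction.
#' @export
binding_kinetics <- function(t_half, K_D, label = NULL) {
  k_off <- koff_from_halftime(t_half)
  k_on <- kon_from_kd(k_off, K_D)
  structure(list(k_on = k_on, k_off = k_off, K_D = K_D, label = label),
            class = "binding_kinetics")
}

#' @export
print.binding_kinetics <- function(x, ...) {
  cat("Binding kinetics")
  if (!is.null(x$label)) cat(" [", x$label, "]", sep = "")
  cat(sprintf("\n  k_on = %.4g uM^-1 min^-1, k_off = %.4g min^-1, K_D = %.4g uM\n",
              x$k_on, x$k_off, x$K_D))
  invisible(x)
}

#' Fit all traces in a dissociation-trace table
#'
#' Convenience wrapper over [fit_one_phase_decay()] for a CSV-style table
#' with columns `time`, `response`, `label` (one trace per label), as
#' shipped in `inst/extdata/spr_traces_synthetic.csv`.
#'
#' @param traces data.frame with `time`, `response`, `label`.
#' @param time_unit `"min"` or `"s"`; seconds are converted to the package's
#'   canonical minutes before fitting.
#' @return named list of `one_phase_decay` fits.
#' @export
fit_spr_traces <- function(traces, time_unit = c("min", "s")) {
  time_unit <- match.arg(time_unit)
  stopifnot(all(c("time", "response", "label") %in% names(traces)))
  scale <- if (time_unit == "s") 1 / 60 else 1
  lapply(split(traces, traces$label), function(d) {
    d <- d[order(d$time), ]
    fit_one_phase_decay(d$time * scale, d$response, label = d$label[1])
  })
}
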