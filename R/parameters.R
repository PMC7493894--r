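# Kinetic parameter sets, model variants and initial states.
# Canonical units: concentrations in uM, time in minutes.

.param_names <- c(
  "k_asm",                       # platform formation APAF1 + CytC
  "kon_primary",  "koff_primary",
  "kon_secondary", "koff_secondary",
  "kon_C9", "koff_C9",           # weak C9-35/12 rebinding (molecular timer)
  "k_auto",                      # homodimer autocleavage
  "k_PC9", "k_C9",               # IETDase rates toward PC3
  "k_cat_DEVD",                  # C3 on the DEVD substrate
  "kon_XIAP_C9", "koff_XIAP_C9",
  "kon_XIAP_C3", "koff_XIAP_C3",
  "kon_SMAC_XIAP", "koff_SMAC_XIAP",
  "ATP", "K_ATP",
  "k_deg", "s_APAF1", "s_PC9", "s_PC3", "s_XIAP"
)

.species_names <- c(
  "CytC_mito", "SMAC_mito", "CytC", "SMAC", "APAF1", "Apop",
  "PC9", "Apop_PC9", "Apop_PC9_2", "C9", "Apop_C9",
  "XIAP", "XIAP_C9", "Apop_C9_XIAP", "SMAC_XIAP",
  "PC3", "C3", "XIAP_C3", "Sub", "cSub"
)

#' Default kinetic parameter set
#'
#' Rate constants of the cooperative-recruitment apoptosis-execution network,
#' in uM and minutes.  Association rates are uM^-1 min^-1, first-order rates
#' min^-1.  The PC9/C9 apoptosome binding constants are the package's
#' calibration against the training curves produced by
#' [generate_training_set()] under the SPR-derived bounds of
#' [default_bounds()]; XIAP and SMAC binding constants use the
#' well-characterised nanomolar affinities of the BIR2/BIR3 interactions.
#'
#' @param ... named overrides for individual constants.
#' @return a named numeric vector of class `kinetic_parameters`.
#' @examples
#' p <- default_parameters(koff_C9 = 30)
#' p[["koff_C9"]]
#' @export
default_parameters <- function(...) {
  p <- c(
    k_asm = 0.035,
    kon_primary = 1.6,   koff_primary = 5,
    kon_secondary = 1000, koff_secondary = 0.1,
    kon_C9 = 1,          koff_C9 = 100,
    k_auto = 0.7,
    k_PC9 = 6, k_C9 = 6,
    k_cat_DEVD = 0.6,
    kon_XIAP_C9 = 156,   koff_XIAP_C9 = 1.56,
    kon_XIAP_C3 = 156,   koff_XIAP_C3 = 0.156,
    kon_SMAC_XIAP = 420, koff_SMAC_XIAP = 0.168,
    ATP = 920, K_ATP = 100,
    k_deg = 0, s_APAF1 = 0, s_PC9 = 0, s_PC3 = 0, s_XIAP = 0
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .param_names)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_parameters(p)
  class(p) <- c("kinetic_parameters", "numeric")
  p
}

validate_parameters <- function(p) {
  p <- unclass(p)
  miss <- setdiff(.param_names, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(p)) || any(p < 0))
    stop("all rate constants must be finite and >= 0")
  if (p[["kon_primary"]] >= p[["kon_secondary"]])
    stop("cooperativity requires kon_primary < kon_secondary")
  if (p[["koff_primary"]] <= p[["koff_secondary"]])
    stop("cooperativity requires koff_primary > koff_secondary")
  kd_c9 <- p[["koff_C9"]] / p[["kon_C9"]]
  kd_2 <- p[["koff_secondary"]] / p[["kon_secondary"]]
  if (kd_c9 <= kd_2)
    stop("molecular timer requires C9 apoptosome affinity weaker than ",
         "secondary PC9 affinity (koff_C9/kon_C9 > koff_secondary/kon_secondary)")
  invisible(TRUE)
}

#' Model variants
#'
#' Switches of the execution network: `timer_enabled` (weak C9 rebinding;
#' off assigns C9 the secondary PC9 binding kinetics so apoptosome-bound
#' activity no longer decays), `xiap_present` (XIAP pool zeroed when FALSE),
#' `pc9_cleavable` (autocleavage rate zeroed when FALSE, so no C9 is ever
#' formed and XIAP cannot engage the apoptosome), and
#' `synthesis_degradation_enabled` (protein turnover, off by default).
#'
#' @param timer_enabled,xiap_present,pc9_cleavable,synthesis_degradation_enabled
#'   logical flags.
#' @return a list of class `model_variant`.
#' @export
model_variant <- function(timer_enabled = TRUE, xiap_present = TRUE,
                          pc9_cleavable = TRUE,
                          synthesis_degradation_enabled = FALSE) {
  if (!pc9_cleavable && !timer_enabled)
    warning("pc9_cleavable = FALSE already removes the molecular timer; ",
            "timer_enabled = FALSE is redundant")
  structure(list(timer_enabled = isTRUE(timer_enabled),
                 xiap_present = isTRUE(xiap_present),
                 pc9_cleavable = isTRUE(pc9_cleavable),
                 synthesis_degradation_enabled =
                   isTRUE(synthesis_degradation_enabled)),
            class = "model_variant")
}

#' Named survival-screen variants
#'
#' The four conditions used throughout the population screens.
#'
#' @param name one of `"normal"`, `"no_xiap"`, `"no_timer"`,
#'   `"no_xiap_no_timer"`, `"noncleavable"`.
#' @return a `model_variant`.
#' @export
variant_by_name <- function(name) {
  switch(match.arg(name, c("normal", "no_xiap", "no_timer",
                           "no_xiap_no_timer", "noncleavable")),
    normal = model_variant(),
    no_xiap = model_variant(xiap_present = FALSE),
    no_timer = model_variant(timer_enabled = FALSE),
    no_xiap_no_timer = model_variant(timer_enabled = FALSE,
                                     xiap_present = FALSE),
    noncleavable = model_variant(pc9_cleavable = FALSE))
}

#' Initial state of the execution network
#'
#' Pre-MOMP state: CytC and SMAC sit in the mitochondrial pools; all complex
#' species start at zero.  Defaults approximate a HeLa cell.
#'
#' @param APAF1,PC9,PC3,XIAP,SMAC,CytC free-protein and mitochondrial pool
#'   concentrations (uM).  `SMAC` and `CytC` are the mitochondrial totals.
#' @param Sub uncleaved DEVD reporter substrate (uM).
#' @return named numeric vector over all network species, class
#'   `initial_state`.
#' @examples
#' s0 <- initial_state()
#' s0[["CytC_mito"]]
#' @export
initial_state <- function(APAF1 = 0.4, PC9 = 0.04, PC3 = 0.2, XIAP = 0.12,
                          SMAC = 0.9, CytC = 10, Sub = 15) {
  v <- c(APAF1 = APAF1, PC9 = PC9, PC3 = PC3, XIAP = XIAP,
         SMAC = SMAC, CytC = CytC, Sub = Sub)
  if (any(!is.finite(v)) || any(v < 0))
    stop("initial concentrations must be finite and >= 0")
  y <- stats::setNames(numeric(length(.species_names)), .species_names)
  y["CytC_mito"] <- CytC
  y["SMAC_mito"] <- SMAC
  y["APAF1"] <- APAF1
  y["PC9"] <- PC9
  y["PC3"] <- PC3
  y["XIAP"] <- XIAP
  y["Sub"] <- Sub
  class(y) <- c("initial_state", "numeric")
  y
}

#' Apply (partial) mitochondrial outer membrane permeabilisation
#'
#' Moves a fraction of the mitochondrial CytC and SMAC pools into the
#' cytosol, instantaneously.  `fraction = 1` is complete MOMP;
#' `fraction = 0.05` is minority MOMP (minMOMP).
#'
#' @param state an [initial_state()].
#' @param fraction release fraction in \[0, 1\].
#' @return the modified state.
#' @examples
#' s <- apply_momp(initial_state(CytC = 10), 0.05)
#' s[["CytC"]]; s[["CytC_mito"]]  # 0.5 and 9.5
#' @export
apply_momp <- function(state, fraction = 1) {
  stopifnot(inherits(state, "initial_state"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("release fraction must be a single number in [0, 1]")
  rel_c <- fraction * state[["CytC_mito"]]
  rel_s <- fraction * state[["SMAC_mito"]]
  state["CytC"] <- state[["CytC"]] + rel_c
  state["CytC_mito"] <- state[["CytC_mito"]] - rel_c
  state["SMAC"] <- state[["SMAC"]] + rel_s
  state["SMAC_mito"] <- state[["SMAC_mito"]] - rel_s
  state
}
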