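# Two-phase one-compartment toxicokinetic model.
#
# Internal concentration C_I(t) follows first-order uptake from food at
# external concentration C_E (assimilation rate constant kA, day^-1) and
# first-order elimination (kE, day^-1).  During uptake (t <= t_C):
#   C_I(t) = C_I0 * exp(-kE1 t) + C_Eu * (kA1/kE1) * (1 - exp(-kE1 t))
# and during depuration (t > t_C) the same form restarts from the predicted
# switch concentration C_ItC with the clean-food concentration C_Ed and its
# own rate pair (kA2, kE2).  Continuity at t_C holds by construction.

#' Exposure schedule of a two-phase feeding experiment
#'
#' Bundles the fixed constants of the design: the internal concentration at
#' the start of the uptake phase (`C_I0`, conventionally the mean of the
#' day-0 colonies), the cadmium concentration of the food during the
#' contamination phase (`C_Eu`) and the decontamination phase (`C_Ed`), and
#' the day the food is switched (`t_C`).
#'
#' @param C_I0 internal concentration at t = 0, mg/kg dry tissue.
#' @param C_Eu food concentration during contamination, mg/kg. Default 100.
#' @param C_Ed food concentration during decontamination, mg/kg. Default 1.
#' @param t_C day of the food switch, days. Default 21.
#' @return An object of class `exposure_schedule`.
#' @examples
#' exposure_schedule(C_I0 = 2)
#' @export
exposure_schedule <- function(C_I0 = 2, C_Eu = 100, C_Ed = 1, t_C = 21) {
  vals <- c(C_I0 = C_I0, C_Eu = C_Eu, C_Ed = C_Ed, t_C = t_C)
  if (!all(is.finite(vals)))
    stop("exposure_schedule: all constants must be finite numbers")
  if (any(vals[c("C_I0", "C_Eu", "C_Ed")] < 0))
    stop("exposure_schedule: concentrations must be >= 0")
  if (t_C <= 0)
    stop("exposure_schedule: t_C must be > 0")
  structure(list(C_I0 = as.numeric(C_I0), C_Eu = as.numeric(C_Eu),
                 C_Ed = as.numeric(C_Ed), t_C = as.numeric(t_C)),
            class = "exposure_schedule")
}

#' @export
print.exposure_schedule <- function(x, ...) {
  cat("Exposure schedule (mg/kg, days):\n")
  cat(sprintf("  C_I0 = %g, C_Eu = %g, C_Ed = %g, t_C = %g\n",
              x$C_I0, x$C_Eu, x$C_Ed, x$t_C))
  invisible(x)
}

#' Kinetic rate-constant pair for one phase
#'
#' @param kA assimilation rate constant, day^-1.
#' @param kE elimination rate constant, day^-1.
#' @param quiet suppress the warning emitted for non-positive rates.
#' @return An object of class `kinetic_params` with a `nonpositive` flag;
#'   non-positive rates are carried (never clipped) but flagged.
#' @examples
#' kinetic_params(kA = 0.871, kE = 1.119)
#' @export
kinetic_params <- function(kA, kE, quiet = FALSE) {
  if (!is.finite(kA) || !is.finite(kE))
    stop("kinetic_params: kA and kE must be finite")
  nonpos <- kA <= 0 || kE <= 0
  if (nonpos && !quiet)
    warning("kinetic_params: non-positive rate constant(s); ",
            "predictions may be unphysical", call. = FALSE)
  structure(list(kA = as.numeric(kA), kE = as.numeric(kE),
                 nonpositive = nonpos),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: kA = %g, kE = %g [day^-1]%s\n",
              x$kA, x$kE,
              if (x$nonpositive) "  (flagged: non-positive)" else ""))
  invisible(x)
}

#' Two-phase model: one rate pair per phase plus the schedule
#'
#' @param contamination,decontamination `kinetic_params` for each phase.
#' @param schedule an `exposure_schedule`.
#' @return An object of class `two_phase_model`. The predicted trajectory is
#'   continuous at `t_C` because the depuration branch starts from the
#'   contamination-branch prediction there ([concentration_at_switch()]).
#' @export
two_phase_model <- function(contamination, decontamination, schedule) {
  stopifnot(inherits(contamination, "kinetic_params"),
            inherits(decontamination, "kinetic_params"),
            inherits(schedule, "exposure_schedule"))
  structure(list(contamination = contamination,
                 decontamination = decontamination,
                 schedule = schedule),
            class = "two_phase_model")
}

# single-phase kernel; c0/ce may be vectors recycled against t
.onecomp <- function(t, c0, ce, kA, kE) {
  if (kE == 0)
    stop("degenerate kinetic parameters: kE = 0 has no exponential solution ",
         "(the limit form is linear accumulation c0 + ce*kA*t, which this ",
         "model class does not use)", call. = FALSE)
  E <- exp(-kE * t)
  c0 * E + ce * (kA / kE) * (1 - E)
}

#' Predicted internal concentration during the contamination phase
#'
#' Evaluates the uptake-phase solution
#' `C_I0 e^(-kE t) + C_Eu (kA/kE) (1 - e^(-kE t))`.
#'
#' @param params a `kinetic_params` (phase-1 pair).
#' @param schedule an `exposure_schedule`.
#' @param t time(s) in days, `t >= 0`; fractional days are allowed.
#' @return Predicted concentration(s), mg/kg.
#' @examples
#' sch <- exposure_schedule(C_I0 = 2)
#' predict_contamination(kinetic_params(0.871, 1.119), sch, t = c(0, 1, 21))
#' @export
predict_contamination <- function(params, schedule, t) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "exposure_schedule"))
  if (any(t < 0)) stop("predict_contamination: t must be >= 0")
  .onecomp(t, schedule$C_I0, schedule$C_Eu, params$kA, params$kE)
}

#' Internal concentration at the food switch
#'
#' The contamination-phase prediction at `t = t_C`; used as the starting
#' value of the decontamination phase so the two branches join continuously.
#'
#' @inheritParams predict_contamination
#' @return Concentration at `t_C`, mg/kg.
#' @export
concentration_at_switch <- function(params, schedule) {
  predict_contamination(params, schedule, schedule$t_C)
}

#' Predicted internal concentration during the decontamination phase
#'
#' Evaluates `C_ItC e^(-kE2 (t - t_C)) + C_Ed (kA2/kE2) (1 - e^(-kE2 (t - t_C)))`
#' where `C_ItC` is recomputed from the model's contamination parameters.
#'
#' @param model a `two_phase_model`.
#' @param t time(s) in days, `t > t_C` (t = t_C itself belongs to the
#'   contamination branch but is accepted here as the continuity limit).
#' @return Predicted concentration(s), mg/kg.
#' @export
predict_decontamination <- function(model, t) {
  stopifnot(inherits(model, "two_phase_model"))
  sch <- model$schedule
  if (any(t < sch$t_C))
    stop("predict_decontamination: t must be >= t_C")
  c_switch <- concentration_at_switch(model$contamination, sch)
  .onecomp(t - sch$t_C, c_switch, sch$C_Ed,
           model$decontamination$kA, model$decontamination$kE)
}

#' Predicted trajectory over both phases
#'
#' Piecewise dispatch: times `t <= t_C` use the contamination branch, later
#' times the decontamination branch; the curve is continuous at `t_C` by
#' construction.
#'
#' @param model a `two_phase_model`.
#' @param times vector of times in days, all `>= 0`.
#' @return Vector of predicted concentrations, mg/kg.
#' @examples
#' m <- two_phase_model(kinetic_params(0.871, 1.119),
#'                      kinetic_params(4.075, 0.33),
#'                      exposure_schedule(C_I0 = 2))
#' predict_trajectory(m, c(0, 5, 21, 22, 42))
#' @export
predict_trajectory <- function(model, times) {
  stopifnot(inherits(model, "two_phase_model"))
  if (any(times < 0)) stop("predict_trajectory: times must be >= 0")
  sch <- model$schedule
  out <- numeric(length(times))
  up <- times <= sch$t_C
  if (any(up))
    out[up] <- predict_contamination(model$contamination, sch, times[up])
  if (any(!up))
    out[!up] <- predict_decontamination(model, times[!up])
  out
}

#' Steady-state (plateau) concentration of one phase
#'
#' The asymptotic internal concentration `C_E * kA / kE` reached when uptake
#' from food at concentration `C_E` balances elimination.
#'
#' @param params a `kinetic_params`.
#' @param C_E external (food) concentration, mg/kg.
#' @return Plateau concentration, mg/kg.
#' @examples
#' steady_state(kinetic_params(0.871, 1.119), 100)  # ~77.84
#' @export
steady_state <- function(params, C_E) {
  stopifnot(inherits(params, "kinetic_params"))
  if (C_E < 0) stop("steady_state: C_E must be >= 0")
  if (params$kE <= 0)
    stop("steady_state: no steady state exists for kE <= 0")
  C_E * params$kA / params$kE
}
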