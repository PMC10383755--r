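# Unit contract (module-level, used everywhere downstream):
#   time            hours
#   concentration   ng/mL
#   dose            mg/kg FTC-equivalent (total across injection sites)
#   CL/F            L/h/kg
#   V/F             L/kg
# 1 mg/kg = 1e6 ng/kg and 1 L/kg = 1e3 mL/kg, so D [mg/kg] / (V/F) [L/kg]
# gives ng/mL via a net factor of 1e3.
.DOSE_TO_CONC <- 1e3

# Relative separation of ka and ke below which the analytic equal-rate limit
# replaces the Bateman form (avoids catastrophic cancellation).
.EQUAL_RATE_RTOL <- 1e-8

#' Apparent one-compartment depot-model parameters
#'
#' Container for the three apparent parameters of a one-compartment
#' disposition model with first-order absorption input from an intramuscular
#' depot: apparent clearance `CL/F`, apparent volume of distribution `V/F`,
#' and the first-order depot-release (absorption) rate constant `KA`.
#' Absolute bioavailability `F` is not a separate field: without intravenous
#' reference data only the apparent quantities are identifiable, which is why
#' clearance and volume carry the `/F` suffix.
#'
#' @param cl_f Apparent clearance, L/h/kg. Strictly positive.
#' @param v_f Apparent volume of distribution, L/kg. Strictly positive.
#' @param ka First-order depot release (absorption) rate constant, 1/h.
#'   Strictly positive.
#'
#' @return An object of class `pk_params`: a named list with elements
#'   `cl_f`, `v_f`, `ka`.
#'
#' @examples
#' p <- pk_params(cl_f = 2.44, v_f = 5.02, ka = 0.0078)
#' elimination_rate(p)
#' is_flip_flop(p)
#' terminal_half_life(p)
#' @export
pk_params <- function(cl_f, v_f, ka) {
  for (nm in c("cl_f", "v_f", "ka")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single finite positive number, got: ",
           paste(format(x), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(cl_f = as.numeric(cl_f), v_f = as.numeric(v_f),
                 ka = as.numeric(ka)),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("One-compartment depot model parameters\n")
  cat(sprintf("  CL/F: %g L/h/kg\n  V/F:  %g L/kg\n  KA:   %g 1/h\n",
              x$cl_f, x$v_f, x$ka))
  cat(sprintf("  ke = CL/V: %g 1/h  (%s kinetics)\n", elimination_rate(x),
              if (is_flip_flop(x)) "flip-flop" else "conventional"))
  invisible(x)
}

#' Dose event
#'
#' A single intramuscular administration. Simultaneous injections at several
#' sites are modelled as one depot holding the summed dose: per-site release
#' is not identifiable from plasma data, so the model sees a single depot.
#'
#' @param dose_per_kg Total drug-equivalent dose across all injection sites,
#'   mg/kg. Must be non-negative (zero is allowed as a degenerate case and
#'   yields an all-zero profile).
#' @param time Administration time, hours. Defaults to 0.
#'
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(dose_per_kg, time = 0) {
  if (!is.numeric(dose_per_kg) || length(dose_per_kg) != 1L ||
      !is.finite(dose_per_kg) || dose_per_kg < 0) {
    stop("`dose_per_kg` must be a single finite non-negative number",
         call. = FALSE)
  }
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time)) {
    stop("`time` must be a single finite number", call. = FALSE)
  }
  structure(list(dose_per_kg = as.numeric(dose_per_kg),
                 time = as.numeric(time)),
            class = "dose_event")
}

.assert_pk_params <- function(params) {
  if (!inherits(params, "pk_params")) {
    stop("`params` must be a `pk_params` object (see ?pk_params)",
         call. = FALSE)
  }
  invisible(params)
}

.assert_dose_event <- function(dose) {
  if (!inherits(dose, "dose_event")) {
    stop("`dose` must be a `dose_event` object (see ?dose_event)",
         call. = FALSE)
  }
  invisible(dose)
}

#' Elimination rate constant
#'
#' The first-order elimination rate constant `ke`, calculated as apparent
#' clearance divided by apparent volume: `ke = (CL/F) / (V/F)`, 1/h.
#'
#' @param params A [pk_params()] object.
#' @return Elimination rate constant, 1/h.
#' @examples
#' elimination_rate(pk_params(2.44, 5.02, 0.0078)) # ~0.486 1/h
#' @export
elimination_rate <- function(params) {
  .assert_pk_params(params)
  params$cl_f / params$v_f
}

#' Flip-flop kinetics diagnosis
#'
#' A depot formulation exhibits flip-flop kinetics when release from the
#' depot is slower than systemic elimination, i.e. `KA < ke`. The terminal
#' plasma slope then reflects depot release, not the drug's intrinsic
#' disposition.
#'
#' @param params A [pk_params()] object.
#' @return `TRUE` if `ka < cl_f / v_f`, else `FALSE`.
#' @export
is_flip_flop <- function(params) {
  .assert_pk_params(params)
  params$ka < elimination_rate(params)
}

#' Terminal half-life
#'
#' Half-life of the terminal log-linear phase, `ln(2) / min(KA, ke)`: the
#' slower of the two first-order rate constants governs the terminal slope.
#' Under flip-flop kinetics this is `ln(2) / KA`, the depot-release
#' half-life.
#'
#' @param params A [pk_params()] object.
#' @return Terminal half-life, hours.
#' @examples
#' terminal_half_life(pk_params(2.44, 5.02, 0.0078)) # ~89 h
#' @export
terminal_half_life <- function(params) {
  .assert_pk_params(params)
  log(2) / min(params$ka, elimination_rate(params))
}

#' Time of the model-predicted peak
#'
#' Closed-form time of maximum concentration,
#' `Tmax = ln(KA / ke) / (KA - ke)`, with the equal-rate limit `1 / ke`.
#'
#' @param params A [pk_params()] object.
#' @return Time of the predicted concentration maximum, hours after dosing.
#' @export
predicted_tmax <- function(params) {
  .assert_pk_params(params)
  ke <- elimination_rate(params)
  ka <- params$ka
  if (abs(ka - ke) / ke < .EQUAL_RATE_RTOL) 1 / ke else log(ka / ke) / (ka - ke)
}

#' Predict plasma concentrations from the depot model
#'
#' Closed-form (Bateman) solution of the one-compartment disposition model
#' with first-order absorption input from a depot:
#' \deqn{C(t) = \frac{D \, KA}{(V/F)\,(KA - ke)}
#'   \left(e^{-ke t} - e^{-KA t}\right), \quad ke = \frac{CL/F}{V/F}.}
#' Doses in mg/kg and volumes in L/kg combine to ng/mL through a factor of
#' 1e3 (1e6 ng/mg over 1e3 mL/L). When `KA` and `ke` are within a relative
#' separation of 1e-8 the analytically continuous equal-rate limit
#' `C(t) = (D / V) k t e^{-k t}` is used instead, avoiding catastrophic
#' cancellation.
#'
#' @param params A [pk_params()] object.
#' @param dose A [dose_event()] object.
#' @param times Numeric vector of sampling times, hours; all must be at or
#'   after `dose$time`.
#'
#' @return An object of class `predicted_profile`: a data.frame with columns
#'   `time` (h, ascending) and `conc` (ng/mL). Concentration at the dose
#'   time is exactly 0 and the profile is unimodal.
#'
#' @examples
#' p <- pk_params(2.44, 5.02, 0.0078)
#' d <- dose_event(40)
#' prof <- predict_concentration(p, d, c(0, 6, 24, 168, 336, 672))
#' prof
#' @export
predict_concentration <- function(params, dose, times) {
  .assert_pk_params(params)
  .assert_dose_event(dose)
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times))) {
    stop("`times` must be finite numeric", call. = FALSE)
  }
  if (any(times < dose$time)) {
    stop("all `times` must be at or after the dose time (", dose$time, " h)",
         call. = FALSE)
  }
  times <- sort(as.numeric(times))
  tau <- times - dose$time
  ke <- elimination_rate(params)
  ka <- params$ka
  d_over_v <- dose$dose_per_kg * .DOSE_TO_CONC / params$v_f # ng/mL
  if (abs(ka - ke) / ke < .EQUAL_RATE_RTOL) {
    conc <- d_over_v * ka * tau * exp(-ka * tau)
  } else {
    conc <- d_over_v * ka / (ka - ke) * (exp(-ke * tau) - exp(-ka * tau))
  }
  conc <- pmax(conc, 0) # clamp tiny negative round-off
  structure(data.frame(time = times, conc = conc),
            class = c("predicted_profile", "data.frame"))
}

#' Model-implied total exposure
#'
#' Area under the model concentration curve from dose time to infinity for a
#' linear one-compartment model: `AUC_inf = D / (CL/F)`, ng.h/mL. This is the
#' model-implied exposure, distinct from the observed trapezoidal
#' `AUC(0-last)` reported by noncompartmental analysis.
#'
#' @param params A [pk_params()] object.
#' @param dose A [dose_event()] object.
#' @return Model AUC from zero to infinity, ng.h/mL.
#' @examples
#' model_auc_infinity(pk_params(2.44, 5.02, 0.0078), dose_event(40)) # ~16393
#' @export
model_auc_infinity <- function(params, dose) {
  .assert_pk_params(params)
  .assert_dose_event(dose)
  dose$dose_per_kg * .DOSE_TO_CONC / params$cl_f
}
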