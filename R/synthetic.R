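# Synthetic study generator. Emulates the three intramuscular depot study
# designs (rat, rabbit, mouse) around the one-compartment depot model:
# lognormal inter-animal variability on the parameters, proportional plus
# additive residual error on the concentrations, LLOQ censoring, and a
# serial-sacrifice option where each animal contributes a single time point.

# Sampling schedules, hours post-dose. The rabbit schedule carries two extra
# late samples (408 and 576 h); mice share the rat schedule under a
# serial-sacrifice design.
.RAT_SCHEDULE    <- c(1.5, 3, 6, 24, 48, 96, 168, 240, 336, 504, 672)
.RABBIT_SCHEDULE <- c(1.5, 3, 6, 24, 48, 96, 168, 240, 336, 408, 504, 576, 672)
.MOUSE_SCHEDULE  <- .RAT_SCHEDULE

#' Study design
#'
#' Sampling schedule, dose, group size and censoring limit for one
#' species x formulation arm of a depot pharmacokinetic study.
#'
#' @param species `"rat"`, `"rabbit"` or `"mouse"`.
#' @param schedule Strictly increasing sampling times, hours post-dose.
#' @param dose A [dose_event()] (total mg/kg across injection sites).
#' @param n_animals Animals per group (>= 1). Under a serial-sacrifice
#'   design this is the number of animals sacrificed per time point.
#' @param serial_sacrifice Logical; `TRUE` for destructive sampling where
#'   each animal contributes exactly one time point (mouse design).
#' @param lloq Lower limit of quantification, ng/mL (default 2).
#' @return An object of class `study_design`.
#' @export
study_design <- function(species = c("rat", "rabbit", "mouse"), schedule,
                         dose, n_animals, serial_sacrifice = FALSE, lloq = 2) {
  species <- match.arg(species)
  .assert_dose_event(dose)
  if (any(diff(schedule) <= 0)) stop("`schedule` must be strictly increasing",
                                     call. = FALSE)
  if (n_animals < 1L) stop("`n_animals` must be >= 1", call. = FALSE)
  if (lloq <= 0) stop("`lloq` must be positive", call. = FALSE)
  structure(list(species = species, schedule = as.numeric(schedule),
                 dose = dose, n_animals = as.integer(n_animals),
                 serial_sacrifice = isTRUE(serial_sacrifice),
                 lloq = as.numeric(lloq)),
            class = "study_design")
}

#' Preset study designs
#'
#' The three long-term depot study designs: rats and rabbits at
#' 40 mg/kg total (two simultaneous intramuscular injections), mice at
#' 140 mg/kg under a serial-sacrifice design; three animals per group and a
#' 2 ng/mL LLOQ throughout.
#'
#' @param n_animals Animals per group (default 3).
#' @param dose_mg_kg Total dose, mg/kg FTC-equivalent.
#' @return A [study_design()].
#' @export
rat_design <- function(n_animals = 3L, dose_mg_kg = 40) {
  study_design("rat", .RAT_SCHEDULE, dose_event(dose_mg_kg), n_animals)
}

#' @rdname rat_design
#' @export
rabbit_design <- function(n_animals = 3L, dose_mg_kg = 40) {
  study_design("rabbit", .RABBIT_SCHEDULE, dose_event(dose_mg_kg), n_animals)
}

#' @rdname rat_design
#' @export
mouse_design <- function(n_animals = 3L, dose_mg_kg = 140) {
  study_design("mouse", .MOUSE_SCHEDULE, dose_event(dose_mg_kg), n_animals,
               serial_sacrifice = TRUE)
}

#' Residual and inter-animal error model
#'
#' Error structure of the generator: per-animal parameters are drawn
#' lognormally around the truth with coefficient of variation `iiv_cv`
#' (applied independently to each parameter), and each concentration is
#' perturbed as `c = pred * (1 + prop_cv * e1) + add_sd * e2` with standard
#' normal `e1`, `e2`. Negative perturbed concentrations are truncated to
#' zero (physical non-negativity) and values below the LLOQ are emitted as
#' censored records. The defaults (20% proportional, 0.5 ng/mL additive,
#' 25% inter-animal) are calibration choices that give group scatter of the
#' magnitude seen in small-n intramuscular depot studies; they are not
#' measured quantities.
#'
#' @param prop_cv Proportional residual coefficient of variation (>= 0).
#' @param add_sd Additive residual SD, ng/mL (>= 0).
#' @param iiv_cv Lognormal inter-animal CV per parameter (>= 0).
#' @param seed Integer seed; identical seed, design and truth give an
#'   identical dataset.
#' @return An object of class `error_model`.
#' @export
error_model <- function(prop_cv = 0.20, add_sd = 0.5, iiv_cv = 0.25,
                        seed = 1L) {
  for (nm in c("prop_cv", "add_sd", "iiv_cv")) {
    if (get(nm) < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  structure(list(prop_cv = prop_cv, add_sd = add_sd, iiv_cv = iiv_cv,
                 seed = as.integer(seed)),
            class = "error_model")
}

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  fn()
}

#' Simulate a depot pharmacokinetic study
#'
#' Draws per-animal parameters lognormally around `truth`, evaluates the
#' depot model on the design's schedule, applies proportional-plus-additive
#' residual error, and censors below the LLOQ. Under a serial-sacrifice
#' design a fresh animal (with its own parameters) is drawn for every
#' time point x replicate, so no within-animal correlation exists across
#' times.
#'
#' @param truth A [pk_params()] object: the simulation truth.
#' @param design A [study_design()].
#' @param error An [error_model()].
#' @param formulation Optional formulation label carried into the table.
#'
#' @return Tidy concentration table: `animal_id`, `species`, `formulation`,
#'   `dose_mg_kg`, `time_h`, `conc_ng_ml` (`NA` when censored), `blq`.
#' @export
simulate_pk_study <- function(truth, design, error, formulation = NA_character_) {
  .assert_pk_params(truth)
  if (!inherits(design, "study_design")) stop("`design` must be a `study_design`")
  if (!inherits(error, "error_model")) stop("`error` must be an `error_model`")

  .with_seed(error$seed, function() {
    sdlog <- sqrt(log(1 + error$iiv_cv^2))
    draw_params <- function() {
      pk_params(truth$cl_f * exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog)),
                truth$v_f * exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog)),
                truth$ka * exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog)))
    }
    noisy <- function(pred) {
      c_obs <- pred * (1 + error$prop_cv * stats::rnorm(length(pred))) +
        error$add_sd * stats::rnorm(length(pred))
      pmax(c_obs, 0)
    }
    rows <- list()
    emit <- function(id, times, conc) {
      blq <- conc < design$lloq
      rows[[length(rows) + 1L]] <<- data.frame(
        animal_id = id, species = design$species, formulation = formulation,
        dose_mg_kg = design$dose$dose_per_kg, time_h = times,
        conc_ng_ml = ifelse(blq, NA_real_, conc), blq = blq,
        stringsAsFactors = FALSE)
    }
    if (design$serial_sacrifice) {
      k <- 0L
      for (tt in design$schedule) {
        for (rep_i in seq_len(design$n_animals)) {
          k <- k + 1L
          p_i <- draw_params()
          pred <- predict_concentration(p_i, design$dose, tt)$conc
          emit(sprintf("%s_%03d", design$species, k), tt, noisy(pred))
        }
      }
    } else {
      for (i in seq_len(design$n_animals)) {
        p_i <- draw_params()
        pred <- predict_concentration(p_i, design$dose, design$schedule)$conc
        emit(sprintf("%s_%03d", design$species, i), design$schedule, noisy(pred))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a prevention-efficacy viral-load study
#'
#' Generates a tidy viral-load table for the humanised-mouse prevention
#' design: treatment groups crossed with challenge-day strata, sampled at
#' fixed days post-infection. Each animal in each stratum is detectable with
#' its group's probability; detectable loads are drawn from a lognormal
#' truncated above the detection limit, undetectable animals are emitted as
#' censored records carrying the limit.
#'
#' @param detect_prob Named numeric vector of per-group detection
#'   probabilities in `[0, 1]`; the names are the group labels.
#' @param n_per_group Animals per group per challenge stratum (default 8).
#' @param challenge_days Challenge times, days post-dose (default `c(7, 14)`).
#' @param days_post_infection Sampling days post-infection
#'   (default `c(14, 28)`).
#' @param tissues Tissue labels (default `"plasma"`).
#' @param detection_limit Assay detection limit, copies/mL (default 700).
#' @param vl_meanlog,vl_sdlog Lognormal parameters of detectable viral loads
#'   (defaults `log(5e4)` and 1, giving loads centred in the tens of
#'   thousands of copies/mL).
#' @param seed Integer seed; deterministic output.
#'
#' @return Tidy viral-load table (columns as consumed by
#'   [pairwise_panel()]).
#' @export
simulate_efficacy_study <- function(detect_prob = c("SSPN-9" = 0, "SSPN-10" = 0,
                                                    untreated = 1),
                                    n_per_group = 8L,
                                    challenge_days = c(7, 14),
                                    days_post_infection = c(14, 28),
                                    tissues = "plasma",
                                    detection_limit = 700,
                                    vl_meanlog = log(5e4), vl_sdlog = 1,
                                    seed = 1L) {
  if (is.null(names(detect_prob)) || any(!nzchar(names(detect_prob)))) {
    stop("`detect_prob` must be a named vector of group probabilities",
         call. = FALSE)
  }
  if (any(detect_prob < 0 | detect_prob > 1)) {
    stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  }
  .with_seed(seed, function() {
    rows <- list()
    for (cd in challenge_days) {
      for (grp in names(detect_prob)) {
        detected <- stats::runif(n_per_group) < detect_prob[[grp]]
        for (tis in tissues) {
          for (dpi in days_post_infection) {
            # truncated-lognormal draw above the detection limit
            lo <- stats::plnorm(detection_limit, vl_meanlog, vl_sdlog)
            u <- stats::runif(n_per_group, lo, 1)
            vl <- stats::qlnorm(u, vl_meanlog, vl_sdlog)
            rows[[length(rows) + 1L]] <- data.frame(
              animal_id = sprintf("c%d_%s_%02d", cd, grp, seq_len(n_per_group)),
              group = grp, challenge_day = cd, day_post_infection = dpi,
              tissue = tis,
              copies_per_ml = ifelse(detected, vl, detection_limit),
              censored = !detected, stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Published naive-pooled parameter estimates for the FTC SSPN formulations
#'
#' The naive-pooled one-compartment depot-model estimates reported for the
#' three lead semi-solid prodrug nanoparticle (SSPN) formulations of
#' emtricitabine across the preclinical species (Wistar rat, New Zealand
#' White rabbit, Balb/C mouse), together with the printed terminal
#' half-lives and total doses. The mouse SSPN-12 arm was not studied, so
#' eight rows are available. Values are transcribed at the precision of the
#' published table; `t_half_printed_h` is the published rounded terminal
#' half-life (derived from the unrounded fit, so recomputation from the
#' rounded `ka` can differ by up to ~1 h).
#'
#' @return Data frame: `formulation`, `species`, `dose_mg_kg`, `cl_f`
#'   (L/h/kg), `cl_f_rse`, `v_f` (L/kg), `v_f_rse`, `ka` (1/h), `ka_rse`
#'   (percent RSEs), `t_half_printed_h`.
#' @export
sspn_reference_parameters <- function() {
  data.frame(
    formulation = rep(c("SSPN-9", "SSPN-10", "SSPN-12"), c(3L, 3L, 2L)),
    species = c("rat", "rabbit", "mouse", "rat", "rabbit", "mouse",
                "rat", "rabbit"),
    dose_mg_kg = c(40, 40, 140, 40, 40, 140, 40, 40),
    cl_f = c(2.44, 1.05, 1.56, 2.06, 0.87, 1.97, 2.58, 1.33),
    cl_f_rse = c(11, 4, 12, 12, 10, 10, 9, 4),
    v_f = c(5.02, 10, 2.38, 8.72, 10.07, 9.99, 5.30, 12.85),
    v_f_rse = c(38, 1, 55, 30, 12, 27, 35, 11),
    ka = c(0.0078, 0.0129, 0.0064, 0.0061, 0.0117, 0.0047, 0.0069, 0.0122),
    ka_rse = c(7, 6, 9, 8, 4, 11, 6, 4),
    t_half_printed_h = c(89, 54, 109, 113, 59, 148, 100, 57),
    stringsAsFactors = FALSE)
}
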