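# Naive-pooled nonlinear least squares for the one-compartment depot model.
# All animals of one species x formulation group are concatenated into a
# single dataset and a single parameter set is estimated (no inter-animal
# random effects). Optimization runs in log-parameter space so positivity
# holds by construction; the Levenberg-Marquardt steps come from
# minpack.lm::nls.lm.

.FIT_TOL <- 1e-10     # relative function and step tolerances
.FIT_MAXFEV <- 2000L  # function evaluations per start
# log-uniform multi-start box (cl_f L/h/kg, v_f L/kg, ka 1/h)
.START_BOX <- list(cl_f = c(1e-3, 1e2), v_f = c(1e-2, 1e3), ka = c(1e-5, 1e1))

#' Pooled dataset for naive-pooled fitting
#'
#' Bundles the concentration records of every animal in one
#' species x formulation group with the common dose. Naive pooling treats
#' the composite profile across animals as if it came from a single subject.
#'
#' @param records Tidy concentration table for one group (columns `time_h`,
#'   `conc_ng_ml`, `blq`; `animal_id` recommended). Animals may contribute
#'   different subsets of the schedule (serial-sacrifice designs contribute
#'   one record per animal).
#' @param dose A [dose_event()] shared by every animal in the group.
#' @return An object of class `pooled_dataset`.
#' @export
pooled_dataset <- function(records, dose) {
  .assert_dose_event(dose)
  need <- c("time_h", "conc_ng_ml", "blq")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if ("species" %in% names(records) &&
      length(unique(records$species)) > 1L) {
    stop("a pooled dataset must hold a single species", call. = FALSE)
  }
  n_times <- length(unique(records$time_h[!records$blq]))
  if (n_times < 4L) {
    stop("need >= 4 distinct quantifiable time points, got ", n_times,
         call. = FALSE)
  }
  structure(list(records = records, dose = dose), class = "pooled_dataset")
}

#' Fit the depot model to naive-pooled data
#'
#' Minimizes the (optionally weighted) sum of squared differences between
#' quantifiable observed concentrations and [predict_concentration()] over
#' all pooled records. The optimizer works on `log(cl_f, v_f, ka)`, runs
#' from an NCA-informed starting point plus `n_starts` seeded log-uniform
#' random starts, and keeps the best objective. Because the Bateman form is
#' symmetric under exchange of `KA` and `ke` (with the volume rescaled), two
#' optima with identical fit quality exist; the flip-flop branch
#' (`ka < ke`) is returned, swapping the solution when the optimizer lands
#' on the conventional branch.
#'
#' Below-limit records are excluded from the objective by default
#' (`blq = "exclude"`); `blq = "half_lloq"` includes them at `lloq / 2`.
#'
#' @param data A [pooled_dataset()].
#' @param init Optional [pk_params()] starting value, used in addition to the
#'   automatic starts.
#' @param weighting Residual weighting: `"uniform"` (default, plain least
#'   squares on concentrations), `"1/yhat"` or `"1/yhat2"` (weights from the
#'   model prediction, recomputed each iteration).
#' @param seed Integer seed for the random starts (deterministic fits).
#' @param n_starts Number of random starts (default 10).
#' @param blq BLQ policy, `"exclude"` or `"half_lloq"`.
#' @param lloq LLOQ used by the `"half_lloq"` policy, ng/mL.
#'
#' @return An object of class `fit_result`: `params` ([pk_params()]),
#'   `rse_percent` (named, per parameter), `residual_sum_squares`, `n_obs`,
#'   `converged`, `flip_flop`, `terminal_half_life` (h), `weighting`,
#'   `branch_swapped`, `n_starts_tried`.
#' @export
fit_naive_pooled <- function(data, init = NULL,
                             weighting = c("uniform", "1/yhat", "1/yhat2"),
                             seed = 1L, n_starts = 10L,
                             blq = c("exclude", "half_lloq"), lloq = 2) {
  weighting <- match.arg(weighting)
  blq <- match.arg(blq)
  if (!inherits(data, "pooled_dataset")) {
    stop("`data` must be a `pooled_dataset`", call. = FALSE)
  }
  rec <- data$records
  dose <- data$dose
  obs_t <- rec$time_h[!rec$blq]
  obs_c <- rec$conc_ng_ml[!rec$blq]
  if (blq == "half_lloq") {
    obs_t <- c(obs_t, rec$time_h[rec$blq])
    obs_c <- c(obs_c, rep(lloq / 2, sum(rec$blq)))
  }
  n <- length(obs_c)
  if (n < 3L) stop("fewer observations (", n, ") than parameters (3)",
                   call. = FALSE)

  resid_fn <- function(lp) {
    p <- exp(lp)
    pred <- .bateman(p[1L], p[2L], p[3L], dose, obs_t)
    w <- .fit_weights(pred, weighting)
    sqrt(w) * (obs_c - pred)
  }

  starts <- .fit_starts(obs_t, obs_c, dose, init, seed, n_starts)
  best <- NULL
  n_tried <- 0L
  for (lp0 in starts) {
    n_tried <- n_tried + 1L
    fit <- tryCatch(
      minpack.lm::nls.lm(par = lp0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = .FIT_TOL, ptol = .FIT_TOL,
                           maxfev = .FIT_MAXFEV, maxiter = 1000L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, rse_percent = rep(NA_real_, 3L),
                          residual_sum_squares = NA_real_, n_obs = n,
                          converged = FALSE, flip_flop = NA,
                          terminal_half_life = NA_real_,
                          weighting = weighting, branch_swapped = FALSE,
                          n_starts_tried = n_tried),
                     class = "fit_result"))
  }

  theta <- exp(best$par)
  params <- pk_params(theta[1L], theta[2L], theta[3L])
  converged <- best$info %in% 1:4

  swapped <- FALSE
  if (!is_flip_flop(params)) {
    params <- .swap_branch(params)
    swapped <- TRUE
    if (abs(params$ka - elimination_rate(params)) / elimination_rate(params) < 1e-3) {
      warning("KA and ke nearly equal: the data cannot distinguish the ",
              "flip-flop and conventional branches", call. = FALSE)
    }
  }

  rse <- compute_rse(params, dose, obs_t, obs_c, weighting)
  structure(list(params = params, rse_percent = rse,
                 residual_sum_squares = best$deviance, n_obs = n,
                 converged = converged, flip_flop = is_flip_flop(params),
                 terminal_half_life = terminal_half_life(params),
                 weighting = weighting, branch_swapped = swapped,
                 n_starts_tried = n_tried),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Naive-pooled depot-model fit\n")
  if (is.null(x$params)) {
    cat("  did not converge from any start\n")
    return(invisible(x))
  }
  est <- unlist(x$params)
  cat(sprintf("  %-5s %12s %10s\n", "", "estimate", "%RSE"))
  lab <- c(cl_f = "CL/F", v_f = "V/F", ka = "KA")
  for (nm in names(est)) {
    cat(sprintf("  %-5s %12.4g %10.3g\n", lab[[nm]], est[[nm]],
                x$rse_percent[[nm]]))
  }
  cat(sprintf("  n_obs %d, RSS %.4g, converged %s\n", x$n_obs,
              x$residual_sum_squares, x$converged))
  cat(sprintf("  flip-flop %s; terminal half-life %.1f h\n", x$flip_flop,
              x$terminal_half_life))
  invisible(x)
}

# Bateman prediction on raw parameter values (vectorized over t).
.bateman <- function(cl_f, v_f, ka, dose, t) {
  predict_concentration(pk_params(cl_f, v_f, ka), dose, t)$conc[order(order(t))]
}

.fit_weights <- function(pred, weighting) {
  floor_pred <- pmax(pred, 1e-8)
  switch(weighting,
         uniform = rep(1, length(pred)),
         `1/yhat` = 1 / floor_pred,
         `1/yhat2` = 1 / floor_pred^2)
}

# The exchange KA <-> ke leaves C(t) invariant when V is rescaled so that
# KA/V is preserved: CL/F is unchanged, ka_new = ke_old, v_new = CL / ka_old.
.swap_branch <- function(params) {
  ke <- elimination_rate(params)
  pk_params(cl_f = params$cl_f, v_f = params$cl_f / params$ka, ka = ke)
}

# Starting points in log space: user-supplied, NCA-informed, then seeded
# log-uniform draws from .START_BOX. RNG state is restored on exit.
.fit_starts <- function(obs_t, obs_c, dose, init, seed, n_starts) {
  starts <- list()
  if (!is.null(init)) {
    .assert_pk_params(init)
    starts <- c(starts, list(log(c(init$cl_f, init$v_f, init$ka))))
  }
  nca_start <- tryCatch(.nca_informed_start(obs_t, obs_c, dose),
                        error = function(e) NULL)
  if (!is.null(nca_start)) starts <- c(starts, list(log(nca_start)))

  if (n_starts > 0L) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
    for (i in seq_len(n_starts)) {
      draw <- vapply(.START_BOX, function(b) {
        exp(stats::runif(1L, log(b[1L]), log(b[2L])))
      }, numeric(1L))
      starts <- c(starts, list(log(unname(draw))))
    }
  }
  starts
}

# Heuristic start: terminal slope of pooled means gives the slow rate
# (= KA under flip-flop); trapezoidal AUC gives CL/F; the observed Tmax
# pins ke through the peak-time relation when a root exists.
.nca_informed_start <- function(obs_t, obs_c, dose) {
  mt <- sort(unique(obs_t))
  mc <- vapply(mt, function(tt) mean(obs_c[obs_t == tt]), numeric(1L))
  pos <- mc > 0
  mt <- mt[pos]; mc <- mc[pos]
  if (length(mt) < 4L) stop("too few points")
  k_tail <- min(4L, length(mt) - 1L)
  tail_idx <- seq.int(length(mt) - k_tail + 1L, length(mt))
  sl <- stats::coef(stats::lm(log(mc[tail_idx]) ~ mt[tail_idx]))[[2L]]
  ka0 <- max(abs(sl), 1e-5)
  auc <- .auc_trapezoid(mt, mc)
  cl0 <- max(dose$dose_per_kg * .DOSE_TO_CONC / auc, 1e-4)
  tmax_obs <- mt[which.max(mc)]
  ke0 <- tryCatch({
    g <- function(ke) log(ke / ka0) / (ke - ka0) - tmax_obs
    stats::uniroot(g, lower = ka0 * 1.001, upper = 1e3)$root
  }, error = function(e) 10 * ka0)
  c(cl0, cl0 / ke0, ka0)
}

#' Percent relative standard errors by linearization
#'
#' Standard errors from the linearized covariance of the weighted
#' least-squares estimator, `s^2 (J^T W J)^-1`, with the Jacobian `J` of the
#' model predictions taken with respect to the log-parameters at the
#' optimum. Because `d theta = theta d log(theta)`, the standard error of
#' `log(theta)` is directly the relative standard error of `theta`;
#' multiplying by 100 gives the percent RSE reported alongside each
#' estimate.
#'
#' @param params Converged [pk_params()] estimates.
#' @param dose The [dose_event()] of the fitted dataset.
#' @param obs_t,obs_c Fitted observation times (h) and concentrations
#'   (ng/mL).
#' @param weighting Weighting scheme used in the fit.
#' @return Named numeric vector (`cl_f`, `v_f`, `ka`) of percent RSEs;
#'   `Inf` with a warning when the Jacobian is rank deficient.
#' @export
compute_rse <- function(params, dose, obs_t, obs_c,
                        weighting = c("uniform", "1/yhat", "1/yhat2")) {
  weighting <- match.arg(weighting)
  .assert_pk_params(params)
  lp <- log(c(params$cl_f, params$v_f, params$ka))
  J <- pracma::jacobian(function(l) {
    p <- exp(l)
    .bateman(p[1L], p[2L], p[3L], dose, obs_t)
  }, lp)
  pred <- .bateman(exp(lp)[1L], exp(lp)[2L], exp(lp)[3L], dose, obs_t)
  w <- .fit_weights(pred, weighting)
  r <- obs_c - pred
  se_log <- .linearized_se(J, r, w)
  rse <- 100 * se_log
  names(rse) <- c("cl_f", "v_f", "ka")
  rse
}

# SEs of the (possibly transformed) parameters from residuals, Jacobian and
# weights: s^2 = wRSS / (n - p), cov = s^2 (J^T W J)^-1.
.linearized_se <- function(J, resid, w = rep(1, length(resid))) {
  n <- length(resid)
  p <- ncol(J)
  if (n <= p) return(rep(Inf, p))
  s2 <- sum(w * resid^2) / (n - p)
  jtj <- crossprod(J * sqrt(w))
  cov <- tryCatch(s2 * solve(jtj), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    warning("rank-deficient Jacobian: standard errors are not estimable",
            call. = FALSE)
    return(rep(Inf, p))
  }
  sqrt(diag(cov))
}

#' Dense model curve from a converged fit
#'
#' Evaluates the fitted model on a dense time grid, for overlaying the model
#' curve on observed profiles.
#'
#' @param fit A converged [fit_naive_pooled()] result.
#' @param dose A [dose_event()].
#' @param grid Time grid, hours (may be empty, giving an empty profile).
#' @return A `predicted_profile` (see [predict_concentration()]).
#' @export
profile_from_fit <- function(fit, dose, grid) {
  if (!inherits(fit, "fit_result")) stop("`fit` must be a `fit_result`")
  if (is.null(fit$params) || !fit$converged) {
    stop("fit did not converge; no profile available", call. = FALSE)
  }
  if (!length(grid)) {
    return(structure(data.frame(time = numeric(), conc = numeric()),
                     class = c("predicted_profile", "data.frame")))
  }
  predict_concentration(fit$params, dose, grid)
}
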