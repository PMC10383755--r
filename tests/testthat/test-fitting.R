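# Naive-pooled nonlinear least squares and linearized %RSE.

noise_free_pool <- function(truth = rat_sspn9(), design = rat_design(),
                            seed = 2) {
  sim <- simulate_pk_study(truth, design, error_model(0, 0, 0, seed = seed))
  pooled_dataset(sim, design$dose)
}

test_that("noise-free data return the generating parameters to 1e-4 relative", {
  truth <- rat_sspn9()
  fit <- fit_naive_pooled(noise_free_pool(truth), seed = 11)
  expect_true(fit$converged)
  expect_true(fit$flip_flop)
  expect_equal(fit$params$cl_f, truth$cl_f, tolerance = 1e-4)
  expect_equal(fit$params$v_f, truth$v_f, tolerance = 1e-4)
  expect_equal(fit$params$ka, truth$ka, tolerance = 1e-4)
  expect_equal(fit$terminal_half_life, terminal_half_life(truth),
               tolerance = 1e-4)
  # noise-free: RSE collapses to the numerical floor
  expect_true(all(fit$rse_percent < 1e-3))
})

test_that("initialisation at the swapped branch still reports ka < ke", {
  truth <- rat_sspn9()
  ke <- elimination_rate(truth)
  swapped_init <- pk_params(cl_f = truth$cl_f, v_f = truth$cl_f / truth$ka,
                            ka = ke)
  fit <- fit_naive_pooled(noise_free_pool(truth), init = swapped_init,
                          n_starts = 0, seed = 1)
  expect_true(fit$flip_flop)
  expect_lt(fit$params$ka, elimination_rate(fit$params))
  expect_equal(fit$params$ka, truth$ka, tolerance = 1e-4)
  # terminal half-life of a flip-flop fit is ln 2 / ka
  expect_equal(fit$terminal_half_life, log(2) / fit$params$ka)
})

test_that("both branches achieve the same residual sum of squares", {
  pd <- noise_free_pool(seed = 4)
  truth <- rat_sspn9()
  obs_t <- pd$records$time_h[!pd$records$blq]
  obs_c <- pd$records$conc_ng_ml[!pd$records$blq]
  rss <- function(p) {
    pred <- predict_concentration(p, pd$dose, obs_t)$conc[order(order(obs_t))]
    sum((obs_c - pred)^2)
  }
  swapped <- pk_params(truth$cl_f, truth$cl_f / truth$ka,
                       elimination_rate(truth))
  expect_equal(rss(truth), rss(swapped), tolerance = 1e-10)
})

test_that("optimum beats a dense brute-force grid on the objective", {
  sim <- simulate_pk_study(rat_sspn9(), rat_design(),
                           error_model(0.15, 0.3, 0, seed = 31))
  pd <- pooled_dataset(sim, rat_design()$dose)
  fit <- fit_naive_pooled(pd, seed = 8)
  obs_t <- pd$records$time_h[!pd$records$blq]
  obs_c <- pd$records$conc_ng_ml[!pd$records$blq]
  obj <- function(cl, v, ka) {
    pred <- predict_concentration(pk_params(cl, v, ka), pd$dose,
                                  obs_t)$conc[order(order(obs_t))]
    sum((obs_c - pred)^2)
  }
  grid <- expand.grid(cl = 2.44 * c(0.5, 0.8, 1, 1.25, 2),
                      v = 5.02 * c(0.5, 0.8, 1, 1.25, 2),
                      ka = 0.0078 * c(0.5, 0.8, 1, 1.25, 2))
  grid_best <- min(mapply(obj, grid$cl, grid$v, grid$ka))
  expect_lte(fit$residual_sum_squares, grid_best + 1e-9)
})

test_that("stochastic replicates recover parameters with small median bias", {
  # 30 seeded replicates at 20% proportional CV, 3 rats: a fast-running
  # subset of the recovery study run in full by the acceptance suite
  truth <- rat_sspn9()
  des <- rat_design()
  rel_err <- replicate(30, NA_real_, simplify = FALSE)
  bias <- matrix(NA_real_, 30, 3)
  for (i in 1:30) {
    sim <- simulate_pk_study(truth, des,
                             error_model(0.20, 0.5, 0.25, seed = 1000 + i))
    fit <- tryCatch(fit_naive_pooled(pooled_dataset(sim, des$dose),
                                     seed = i, n_starts = 5),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    est <- unlist(fit$params)
    bias[i, ] <- (est - unlist(truth)) / unlist(truth)
  }
  med <- apply(bias, 2, median, na.rm = TRUE)
  expect_true(all(abs(med) < 0.15))
  expect_lt(mean(is.na(bias[, 1])), 0.2) # fits overwhelmingly converge
})

test_that("linearized SEs match the closed-form linear-model formula", {
  # straight-line harness: J for a linear model is the design matrix, so
  # .linearized_se must reproduce summary.lm's standard errors
  set.seed(5)
  x <- seq(0, 10, length.out = 25)
  y <- 2 + 0.7 * x + rnorm(25, sd = 0.4)
  fit <- lm(y ~ x)
  J <- cbind(1, x)
  se <- depotpk:::.linearized_se(J, resid(fit))
  expect_equal(unname(se), unname(summary(fit)$coefficients[, "Std. Error"]),
               tolerance = 1e-8)
})

test_that("duplicating every record shrinks RSE by about 1/sqrt(2)", {
  sim <- simulate_pk_study(rat_sspn9(), rat_design(),
                           error_model(0.15, 0.2, 0, seed = 12))
  pd1 <- pooled_dataset(sim, rat_design()$dose)
  sim2 <- rbind(sim, transform(sim, animal_id = paste0(animal_id, "_dup")))
  pd2 <- pooled_dataset(sim2, rat_design()$dose)
  f1 <- fit_naive_pooled(pd1, seed = 3)
  f2 <- fit_naive_pooled(pd2, seed = 3)
  ratio <- f2$rse_percent / f1$rse_percent
  n <- f1$n_obs
  # exact variance scaling: RSS and J'J double, s^2 = 2 RSS / (2n - 3)
  expected <- sqrt((n - 3) / (2 * n - 3))
  expect_equal(unname(ratio), rep(expected, 3), tolerance = 0.02)
})

test_that("degenerate pooled datasets are rejected", {
  sim <- simulate_pk_study(rat_sspn9(), rat_design(),
                           error_model(0, 0, 0, seed = 2))
  expect_error(pooled_dataset(sim[sim$time_h <= 6, ], dose_event(40)),
               "4 distinct")
  mixed <- sim
  mixed$species[1] <- "rabbit"
  expect_error(pooled_dataset(mixed, dose_event(40)), "single species")
})

test_that("profile from a converged fit is unimodal, decays below LLOQ, and respects the grid", {
  fit <- fit_naive_pooled(noise_free_pool(), seed = 6)
  prof <- profile_from_fit(fit, dose_event(40), seq(0, 672, by = 1))
  expect_s3_class(prof, "predicted_profile")
  dsign <- sign(diff(prof$conc))
  dsign <- dsign[dsign != 0]
  expect_lte(sum(diff(dsign) != 0), 1)
  # the fitted rat profile falls below the 2 ng/mL LLOQ before 28 days
  expect_lt(prof$conc[prof$time == 672], 2)
  empty <- profile_from_fit(fit, dose_event(40), numeric(0))
  expect_equal(nrow(empty), 0)
})
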