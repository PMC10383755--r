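# Shared fixtures built in code.

rat_sspn9 <- function() pk_params(cl_f = 2.44, v_f = 5.02, ka = 0.0078)

# one animal's tidy records from explicit vectors
conc_records <- function(time, conc, blq = rep(FALSE, length(time)),
                         id = "a1") {
  data.frame(animal_id = id, time_h = time, conc_ng_ml = conc, blq = blq,
             stringsAsFactors = FALSE)
}

# random valid parameter sets spanning flip-flop and conventional regimes
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pk_params(cl_f = exp(runif(1, log(0.1), log(10))),
              v_f = exp(runif(1, log(0.5), log(50))),
              ka = exp(runif(1, log(1e-4), log(1))))
  })
}

# independent ODE oracle: integrate the two-state depot -> central system
ode_concentration <- function(params, dose, times) {
  ke <- params$cl_f / params$v_f
  rhs <- function(t, y, parms) {
    list(c(-params$ka * y[1], params$ka * y[1] - ke * y[2]))
  }
  amt0 <- dose$dose_per_kg * 1e6 # ng per kg body weight
  out <- deSolve::lsoda(y = c(depot = amt0, central = 0),
                        times = union(0, times), func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  cen <- out[match(times, out[, "time"]), "central"]
  cen / (params$v_f * 1e3) # ng/mL
}
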