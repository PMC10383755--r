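# Pipeline orchestration: simulate (or read) -> NCA -> naive-pooled fit ->
# viral-load statistics -> report. Configured by a plain list or a YAML
# file; every stage writes tidy CSV and the report is reproducible from the
# seed and config alone.

#' Read and write tidy concentration tables
#'
#' The tidy concentration format has one row per plasma observation with
#' columns `animal_id`, `species`, `formulation`, `dose_mg_kg`, `time_h`,
#' `conc_ng_ml` (empty when censored) and logical `blq`.
#'
#' @param path CSV file path.
#' @param data Tidy concentration table.
#' @return `read_concentration_csv` returns the table; the writers return
#'   `path` invisibly.
#' @export
read_concentration_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time_h", "conc_ng_ml", "blq")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("concentration CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out$blq <- as.logical(out$blq)
  out
}

#' @rdname read_concentration_csv
#' @export
write_concentration_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tidy viral-load table
#'
#' Columns `animal_id`, `group`, `challenge_day`, `day_post_infection`,
#' `tissue`, `copies_per_ml`, logical `censored`.
#'
#' @param path CSV file path.
#' @return Viral-load data frame.
#' @export
read_viral_load_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "challenge_day", "day_post_infection",
            "tissue", "copies_per_ml", "censored")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("viral-load CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out$censored <- as.logical(out$censored)
  out
}

#' Round half away from zero
#'
#' Reporting convention for half-lives (integer hours), fold ratios (one
#' decimal) and tabulated estimates: exact halves round up in magnitude,
#' unlike the round-half-even rule of [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Half-life extension fold
#'
#' Fold extension of the terminal half-life of a long-acting formulation
#' over the oral reference half-life of the same species, reported at one
#' decimal (round half up).
#'
#' @param long_acting_t12 Terminal half-life of the depot formulation, h.
#' @param oral_t12 Oral reference half-life, h.
#' @return Fold ratio at one-decimal rounding.
#' @examples
#' half_life_extension(109, 5.6)  # 19.5
#' @export
half_life_extension <- function(long_acting_t12, oral_t12) {
  if (any(long_acting_t12 <= 0) || any(oral_t12 <= 0)) {
    stop("half-lives must be positive", call. = FALSE)
  }
  round_half_up(long_acting_t12 / oral_t12, 1)
}

#' Oral reference half-lives
#'
#' Species-level oral plasma half-lives of emtricitabine used as the
#' denominator of [half_life_extension()], stored with their provenance in
#' `inst/extdata/oral_reference_half_lives.yaml`.
#'
#' @param path Optional alternative YAML file.
#' @return Named list of half-lives (hours) per species.
#' @export
oral_reference_half_lives <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "oral_reference_half_lives.yaml",
                        package = "depotpk")
  }
  cfg <- yaml::read_yaml(path)
  lapply(cfg$species, function(x) x$t_half_h)
}

#' Run configuration
#'
#' Validated configuration for [run_pipeline()]. Exactly one of
#' `truth`/`designs` (simulation run) or `conc_csv` (analysis run) must be
#' given; a simulation run requires a seed.
#'
#' @param truth Named list of [pk_params()] per arm label (simulation runs).
#' @param designs Named list of [study_design()] per arm label, names
#'   matching `truth`.
#' @param conc_csv Path to a tidy concentration CSV (analysis runs).
#' @param viral_csv Optional path to a tidy viral-load CSV for the
#'   statistics stage; `viral_sim` may instead give arguments for
#'   [simulate_efficacy_study()].
#' @param viral_sim Optional named list of [simulate_efficacy_study()]
#'   arguments.
#' @param error An [error_model()] for simulation runs.
#' @param seed Integer seed (mandatory for simulation).
#' @param weighting,n_starts Fitting options (see [fit_naive_pooled()]).
#' @param c_at_time Nominal time for the reported concentration, h
#'   (default 336, i.e. day 14).
#' @param lloq LLOQ, ng/mL.
#' @param out_dir Optional output directory for CSV artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(truth = NULL, designs = NULL, conc_csv = NULL,
                       viral_csv = NULL, viral_sim = NULL,
                       error = error_model(), seed = NULL,
                       weighting = "uniform", n_starts = 10L,
                       c_at_time = 336, lloq = 2, out_dir = NULL) {
  simulating <- !is.null(truth)
  if (simulating && !is.null(conc_csv)) {
    stop("give either simulation truth or an input CSV path, not both",
         call. = FALSE)
  }
  if (!simulating && is.null(conc_csv)) {
    stop("one of `truth`+`designs` or `conc_csv` is required", call. = FALSE)
  }
  if (simulating) {
    if (is.null(designs) || !setequal(names(truth), names(designs))) {
      stop("`designs` must be a named list matching `truth`", call. = FALSE)
    }
    if (is.null(seed)) stop("`seed` is mandatory for simulation runs",
                            call. = FALSE)
  }
  if (!is.null(viral_csv) && !is.null(viral_sim)) {
    stop("give either `viral_csv` or `viral_sim`, not both", call. = FALSE)
  }
  structure(list(truth = truth, designs = designs, conc_csv = conc_csv,
                 viral_csv = viral_csv, viral_sim = viral_sim, error = error,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 weighting = weighting, n_starts = as.integer(n_starts),
                 c_at_time = c_at_time, lloq = lloq, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' YAML layout: top-level `seed`, optional `error` (prop_cv, add_sd,
#' iiv_cv), either `arms` (each with `species`, `dose_mg_kg`, `n_animals`,
#' and truth `cl_f`, `v_f`, `ka`) for simulation or `conc_csv` for
#' analysis; optional `viral_csv`, `weighting`, `c_at_time`, `lloq`,
#' `out_dir`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  truth <- designs <- NULL
  if (!is.null(y$arms)) {
    truth <- lapply(y$arms, function(a) pk_params(a$cl_f, a$v_f, a$ka))
    designs <- lapply(y$arms, function(a) {
      fn <- switch(a$species, rat = rat_design, rabbit = rabbit_design,
                   mouse = mouse_design,
                   stop("unknown species: ", a$species))
      fn(n_animals = if (is.null(a$n_animals)) 3L else a$n_animals,
         dose_mg_kg = a$dose_mg_kg)
    })
  }
  err <- if (is.null(y$error)) error_model(seed = if (is.null(y$seed)) 1L else y$seed)
         else error_model(prop_cv = y$error$prop_cv %||% 0.20,
                          add_sd = y$error$add_sd %||% 0.5,
                          iiv_cv = y$error$iiv_cv %||% 0.25,
                          seed = if (is.null(y$seed)) 1L else y$seed)
  run_config(truth = truth, designs = designs, conc_csv = y$conc_csv,
             viral_csv = y$viral_csv, error = err, seed = y$seed,
             weighting = y$weighting %||% "uniform",
             n_starts = y$n_starts %||% 10L,
             c_at_time = y$c_at_time %||% 336,
             lloq = y$lloq %||% 2, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> per-animal NCA -> group NCA summary ->
#' naive-pooled fit per arm -> half-life-extension ratios -> optional
#' viral-load statistics, and assembles a study report. Each stage fails
#' fast with a stage-labelled error; non-convergent fits are reported in
#' the fit table rather than raised. When `config$out_dir` is set, the tidy
#' data, NCA summary, fit table, statistics panel and a plain-text report
#' are written there.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return An object of class `study_report`: `data`, `nca`, `nca_summary`,
#'   `fit_table`, `fits`, `ratios`, `stats_panel`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("`config` must be a `run_config`")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- data stage ---------------------------------------------------------
  data <- stage("data", {
    if (!is.null(config$truth)) {
      arms <- names(config$truth)
      tabs <- lapply(seq_along(arms), function(i) {
        err_i <- config$error
        err_i$seed <- config$error$seed + i - 1L # distinct stream per arm
        simulate_pk_study(config$truth[[i]], config$designs[[i]], err_i,
                          formulation = arms[i])
      })
      do.call(rbind, tabs)
    } else {
      read_concentration_csv(config$conc_csv)
    }
  })

  arm_key <- if ("formulation" %in% names(data)) {
    interaction(data$species, data$formulation, drop = TRUE, sep = ":")
  } else factor(data$species)

  # --- NCA stage ----------------------------------------------------------
  nca <- stage("nca", nca_table(data, lloq = config$lloq,
                                c_at_time = config$c_at_time))
  nca_summary <- stage("nca", nca_summarize(nca))

  # --- fitting stage ------------------------------------------------------
  fits <- list()
  fit_rows <- list()
  for (lv in levels(arm_key)) {
    sub <- data[arm_key == lv, , drop = FALSE]
    dose <- dose_event(sub$dose_mg_kg[1L])
    fit <- stage("fit", {
      pd <- pooled_dataset(sub, dose)
      fit_naive_pooled(pd, weighting = config$weighting,
                       seed = config$seed %||% 1L,
                       n_starts = config$n_starts, lloq = config$lloq)
    })
    fits[[lv]] <- fit
    est <- if (is.null(fit$params)) rep(NA_real_, 3L)
           else unlist(fit$params)
    fit_rows[[lv]] <- data.frame(
      arm = lv, species = sub$species[1L],
      formulation = if ("formulation" %in% names(sub)) sub$formulation[1L] else NA,
      cl_f = est[1L], cl_f_rse = fit$rse_percent[1L],
      v_f = est[2L], v_f_rse = fit$rse_percent[2L],
      ka = est[3L], ka_rse = fit$rse_percent[3L],
      t_half_h = if (is.null(fit$params)) NA_real_
                 else round_half_up(fit$terminal_half_life),
      flip_flop = fit$flip_flop, n_obs = fit$n_obs,
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  fit_table <- do.call(rbind, fit_rows)
  rownames(fit_table) <- NULL

  # --- ratio stage --------------------------------------------------------
  ratios <- stage("ratios", {
    oral <- oral_reference_half_lives()
    rows <- lapply(seq_len(nrow(fit_table)), function(i) {
      sp <- fit_table$species[i]
      if (is.na(fit_table$t_half_h[i]) || is.null(oral[[sp]])) return(NULL)
      data.frame(arm = fit_table$arm[i], species = sp,
                 t_half_h = fit_table$t_half_h[i],
                 oral_t_half_h = oral[[sp]],
                 fold_extension = half_life_extension(fit_table$t_half_h[i],
                                                      oral[[sp]]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) rownames(out) <- NULL
    out
  })

  # --- statistics stage ---------------------------------------------------
  stats_panel <- NULL
  if (!is.null(config$viral_csv) || !is.null(config$viral_sim)) {
    stats_panel <- stage("stats", {
      vl <- if (!is.null(config$viral_csv)) read_viral_load_csv(config$viral_csv)
            else do.call(simulate_efficacy_study, config$viral_sim)
      grp <- unique(vl$group)
      pairwise_panel(vl, groups = c(setdiff(grp, "untreated"), "untreated"))
    })
  }

  provenance <- list(seed = config$seed, r_version = R.version.string,
                     package_version = as.character(utils::packageVersion("depotpk")),
                     config_hash = .config_hash(config),
                     timestamp = format(Sys.time(), tz = "UTC"))

  report <- structure(list(data = data, nca = nca, nca_summary = nca_summary,
                           fit_table = fit_table, fits = fits, ratios = ratios,
                           stats_panel = stats_panel, provenance = provenance),
                      class = "study_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

# Content hash of the configuration (timestamp-free provenance key).
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  cfg <- config
  cfg$out_dir <- NULL
  yaml::write_yaml(lapply(cfg, function(x) if (is.list(x)) rapply(x, unclass, how = "unlist") else x),
                   tmp)
  unname(tools::md5sum(tmp))
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_concentration_csv(report$data, file.path(out_dir, "concentrations.csv"))
  utils::write.csv(report$nca_summary, file.path(out_dir, "nca_summary.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$fit_table, file.path(out_dir, "fit_table.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(report$ratios)) {
    utils::write.csv(report$ratios, file.path(out_dir, "half_life_extension.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(report$stats_panel)) {
    utils::write.csv(report$stats_panel, file.path(out_dir, "stats_panel.csv"),
                     row.names = FALSE, na = "")
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Depot pharmacokinetics study report\n")
  cat(sprintf("  seed %s | config %s | %s\n",
              x$provenance$seed %||% "-", x$provenance$config_hash,
              x$provenance$timestamp))
  cat("\nNCA summary (mean / SD per group):\n")
  print(x$nca_summary, row.names = FALSE)
  cat("\nNaive-pooled model fits:\n")
  print(x$fit_table, row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat("\nHalf-life extension vs oral reference:\n")
    print(x$ratios, row.names = FALSE)
  }
  if (!is.null(x$stats_panel)) {
    cat("\nViral-load comparisons (one-sided exact MWW, Bonferroni x3):\n")
    print(x$stats_panel, row.names = FALSE)
  }
  invisible(x)
}
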