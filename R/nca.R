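# Noncompartmental analysis of per-animal concentration-time profiles with
# LLOQ censoring. Tidy-table conventions: one row per observation, columns
# animal_id, time_h, conc_ng_ml, blq (see read_concentration_csv()).

#' Noncompartmental analysis for one animal
#'
#' Model-free summary of a single animal's plasma concentration-time profile:
#' maximum concentration (`cmax`), earliest time attaining it (`tmax`),
#' minimum quantifiable concentration (`cmin`), trapezoidal area under the
#' curve to the last quantifiable point (`auc_last`), and the concentration
#' observed at a requested nominal time (`c_at`, e.g. 336 h for the
#' day-14 concentration).
#'
#' Below-limit (BLQ) handling under the default `blq_rule = "exclude"`: a BLQ
#' record at the dose time (t = 0) is imputed as 0 ng/mL (pre-dose sample);
#' embedded and trailing BLQ records are excluded from the trapezoid.
#' `blq_rule = "half_lloq"` instead imputes every BLQ record at `lloq / 2`.
#' The AUC uses the linear trapezoidal rule by default;
#' `auc_method = "linuplogdown"` switches to linear-up / log-down
#' interpolation on strictly decreasing positive segments.
#'
#' @param records Data frame for one animal with columns `time_h` (hours),
#'   `conc_ng_ml` (ng/mL, may be `NA` when censored) and logical `blq`
#'   (below the lower limit of quantification). An `animal_id` column, if
#'   present, is carried into the result and into error messages.
#' @param lloq Working lower limit of quantification, ng/mL (default 2).
#'   Any record below it is treated as BLQ regardless of its incoming flag
#'   (analysis-time censoring).
#' @param c_at_time Optional nominal time (h) at which to report the observed
#'   concentration; `NA` in the result when that time was not sampled or was
#'   BLQ.
#' @param blq_rule `"exclude"` (default) or `"half_lloq"`, see Details.
#' @param auc_method `"linear"` (default) or `"linuplogdown"`.
#'
#' @return One-row data.frame of class `nca_result`: `animal_id`, `cmax`,
#'   `tmax`, `cmin`, `auc_last`, `c_at`, `n_quantifiable`.
#'
#' @examples
#' rec <- data.frame(time_h = c(0, 1), conc_ng_ml = c(0, 10),
#'                   blq = c(FALSE, FALSE))
#' nca_single(rec, lloq = 0)  # auc_last = 5 ng.h/mL
#' @export
nca_single <- function(records, lloq = 2, c_at_time = NULL,
                       blq_rule = c("exclude", "half_lloq"),
                       auc_method = c("linear", "linuplogdown")) {
  blq_rule <- match.arg(blq_rule)
  auc_method <- match.arg(auc_method)
  id <- if ("animal_id" %in% names(records)) as.character(records$animal_id[1]) else NA_character_
  .validate_conc_records(records, lloq, id)
  records <- records[order(records$time_h), , drop = FALSE]

  # analysis-time censoring: any value below the working LLOQ is BLQ,
  # whatever the incoming flag says
  blq <- as.logical(records$blq) |
    (!is.na(records$conc_ng_ml) & records$conc_ng_ml < lloq)
  time <- records$time_h
  conc <- records$conc_ng_ml
  n_quant <- sum(!blq)
  if (n_quant < 2L) {
    stop(structure(class = c("depotpk_insufficient_data", "error", "condition"),
                   list(message = paste0("animal ", if (is.na(id)) "<unknown>" else id,
                                         ": fewer than 2 quantifiable records"),
                        call = NULL)))
  }

  # points entering the trapezoid
  if (blq_rule == "half_lloq") {
    keep <- rep(TRUE, length(time))
    conc[blq] <- lloq / 2
  } else {
    keep <- !blq
    lead0 <- blq & time == 0
    conc[lead0] <- 0
    keep[lead0] <- TRUE
  }
  tk <- time[keep]
  ck <- conc[keep]

  quant_conc <- records$conc_ng_ml[!blq]
  quant_time <- time[!blq]
  cmax <- max(quant_conc)
  tmax <- quant_time[which(quant_conc == cmax)[1L]] # earliest tie
  cmin <- min(quant_conc)

  auc <- .auc_trapezoid(tk, ck, method = auc_method)

  c_at <- NA_real_
  if (!is.null(c_at_time)) {
    hit <- which(!blq & time == c_at_time)
    if (length(hit)) c_at <- records$conc_ng_ml[hit[1L]]
  }

  structure(data.frame(animal_id = id, cmax = cmax, tmax = tmax, cmin = cmin,
                       auc_last = auc, c_at = c_at, n_quantifiable = n_quant,
                       stringsAsFactors = FALSE),
            class = c("nca_result", "data.frame"))
}

.validate_conc_records <- function(records, lloq, id = NA_character_) {
  need <- c("time_h", "conc_ng_ml", "blq")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("concentration records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$time_h < 0)) stop("negative sampling times", call. = FALSE)
  if (anyDuplicated(records$time_h)) {
    stop("duplicate sampling times for animal ",
         if (is.na(id)) "<unknown>" else id, call. = FALSE)
  }
  q <- !records$blq
  if (any(q & is.na(records$conc_ng_ml))) {
    stop("quantifiable record with missing concentration", call. = FALSE)
  }
  invisible(TRUE)
}

# Linear (or linear-up/log-down) trapezoid over ascending (t, c) pairs.
.auc_trapezoid <- function(t, c, method = "linear") {
  if (length(t) < 2L) return(0)
  dt <- diff(t)
  c1 <- c[-length(c)]
  c2 <- c[-1L]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linuplogdown") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      (log(c1[logdown]) - log(c2[logdown])) * dt[logdown]
  }
  sum(seg)
}

#' Per-animal NCA over a tidy concentration table
#'
#' Runs [nca_single()] on each animal of a tidy concentration table and
#' binds the results, carrying the grouping columns (`species`,
#' `formulation`, `dose_mg_kg`) when present. Animals with fewer than two
#' quantifiable records are dropped with a warning naming them.
#'
#' @param data Tidy concentration table (see [read_concentration_csv()]).
#' @inheritParams nca_single
#' @return Data frame with one row per analysable animal.
#' @export
nca_table <- function(data, lloq = 2, c_at_time = NULL,
                      blq_rule = c("exclude", "half_lloq"),
                      auc_method = c("linear", "linuplogdown")) {
  blq_rule <- match.arg(blq_rule)
  auc_method <- match.arg(auc_method)
  if (!"animal_id" %in% names(data)) stop("`data` needs an `animal_id` column")
  out <- list()
  dropped <- character()
  for (id in unique(data$animal_id)) {
    sub <- data[data$animal_id == id, , drop = FALSE]
    res <- tryCatch(
      nca_single(sub, lloq = lloq, c_at_time = c_at_time,
                 blq_rule = blq_rule, auc_method = auc_method),
      depotpk_insufficient_data = function(e) NULL)
    if (is.null(res)) {
      dropped <- c(dropped, as.character(id))
      next
    }
    for (col in intersect(c("species", "formulation", "dose_mg_kg"), names(sub))) {
      res[[col]] <- sub[[col]][1L]
    }
    out[[length(out) + 1L]] <- res
  }
  if (length(dropped)) {
    warning("dropped animal(s) with < 2 quantifiable records: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(out)) stop("no analysable animals", call. = FALSE)
  do.call(rbind, out)
}

#' Group summaries of NCA results
#'
#' Per-group mean and sample standard deviation (n - 1 denominator) of each
#' NCA quantity, matching the mean (SD) presentation of study summary
#' tables. Groups of a single animal report the mean (the value itself) and
#' an absent (`NA`) SD.
#'
#' @param results Data frame of per-animal NCA results ([nca_table()]).
#' @param by Character vector of grouping columns present in `results`
#'   (default `c("species", "formulation")`, intersected with what exists).
#' @return Data frame with one row per group: `n` plus `<quantity>_mean` and
#'   `<quantity>_sd` for cmax, tmax, cmin, auc_last and c_at.
#' @export
nca_summarize <- function(results, by = c("species", "formulation")) {
  by <- intersect(by, names(results))
  if (!nrow(results)) stop("empty NCA result set", call. = FALSE)
  key <- if (length(by)) interaction(results[by], drop = TRUE) else factor(rep("all", nrow(results)))
  quantities <- c("cmax", "tmax", "cmin", "auc_last", "c_at")
  rows <- lapply(levels(key), function(lv) {
    sub <- results[key == lv, , drop = FALSE]
    row <- if (length(by)) sub[1L, by, drop = FALSE] else data.frame(group = lv)
    row$n <- nrow(sub)
    for (q in quantities) {
      v <- sub[[q]]
      v <- v[!is.na(v)]
      row[[paste0(q, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(q, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
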