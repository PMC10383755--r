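# Exact rank-based group comparisons for viral-load data with a detection
# limit. The exact one-sided Mann-Whitney-Wilcoxon p-value is obtained by
# complete enumeration of group-label assignments conditional on the pooled
# observed values, which handles ties (mid-ranks) exactly; a tie-corrected
# normal approximation takes over above an enumeration cap.

.ENUM_CAP <- 1e6 # max choose(n1 + n2, n1) arrangements for exact enumeration

#' Exact Mann-Whitney-Wilcoxon test
#'
#' One-sided two-sample rank test. The U statistic uses mid-ranks for ties.
#' When `choose(n1 + n2, n1)` does not exceed `enum_cap`, the p-value is
#' exact: all assignments of group labels to the pooled values are
#' enumerated and the p-value is the fraction with a U at least as extreme
#' as observed (tie-correct by construction). Larger samples fall back to a
#' normal approximation with tie-corrected variance and continuity
#' correction, flagged in the result.
#'
#' @param group_a,group_b Numeric value vectors, both non-empty.
#' @param alternative `"less"` (default; alternative hypothesis that
#'   `group_a` is stochastically smaller than `group_b`) or `"greater"`.
#' @param enum_cap Maximum number of arrangements for exact enumeration.
#'
#' @return An object of class `mww_test`: `u_statistic` (U for `group_a`),
#'   `p_raw` (one-sided), `p_adjusted` (`NA` until adjusted), `n1`, `n2`,
#'   `alternative`, `method` (`"exact"` or `"normal_approx"`), `ties`.
#'
#' @examples
#' mww_exact(c(1, 2), c(3, 4), "less")  # p = 1/6
#' @export
mww_exact <- function(group_a, group_b, alternative = c("less", "greater"),
                      enum_cap = .ENUM_CAP) {
  alternative <- match.arg(alternative)
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) stop("missing values in groups",
                                             call. = FALSE)
  n1 <- length(group_a)
  n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled) # mid-ranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  n <- n1 + n2
  eps <- 1e-9
  if (choose(n, n1) <= enum_cap) {
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- if (alternative == "less") mean(u_all <= u_obs + eps)
         else mean(u_all >= u_obs - eps)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- if (alternative == "less") (u_obs - mu + 0.5) / sigma
         else (u_obs - mu - 0.5) / sigma
    p <- if (alternative == "less") stats::pnorm(z) else stats::pnorm(z, lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "normal_approx"
  }

  structure(list(u_statistic = u_obs, p_raw = p, p_adjusted = NA_real_,
                 n1 = n1, n2 = n2, alternative = alternative,
                 method = method, ties = ties),
            class = "mww_test")
}

#' @export
print.mww_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney-Wilcoxon (%s, one-sided '%s')\n", x$method,
              x$alternative))
  cat(sprintf("  U = %g (n1 = %d, n2 = %d%s), p = %.4g", x$u_statistic,
              x$n1, x$n2, if (x$ties) ", ties" else "", x$p_raw))
  if (!is.na(x$p_adjusted)) cat(sprintf(", adjusted p = %.4g", x$p_adjusted))
  cat("\n")
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, factor * p)` for a fixed family size. A family of three pairwise
#' comparisons per stratum uses `factor = 3`.
#'
#' @param p_raw Raw p-value(s) in (0, 1].
#' @param factor Positive integer correction factor (number of comparisons).
#' @return Adjusted p-value(s), capped at 1.
#' @examples
#' bonferroni_adjust(0.01, 3)   # 0.03
#' bonferroni_adjust(0.5, 3)    # 1
#' @export
bonferroni_adjust <- function(p_raw, factor = 3L) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(p_raw)) || any(p_raw <= 0) || any(p_raw > 1)) {
    stop("`p_raw` must lie in (0, 1]", call. = FALSE)
  }
  pmin(1, factor * p_raw)
}

#' Pairwise viral-load comparison panel
#'
#' Runs all three pairwise one-sided Mann-Whitney-Wilcoxon tests within each
#' stratum (challenge day x tissue x day post-infection) of a tidy
#' viral-load table and Bonferroni-adjusts each raw p-value with factor 3.
#' Censored records (below the detection limit) enter the ranks at the
#' detection limit under the default policy, tying every undetectable
#' animal; `censor_policy` can instead place them at 0 or at half the limit
#' (the rank ordering against detectable animals is identical under all
#' three).
#'
#' Comparisons are ordered treated-versus-untreated first; the default
#' alternative is that the first-named group is stochastically smaller
#' (protection lowers viral load). Strata missing one of the groups are
#' skipped with a warning.
#'
#' @param records Tidy viral-load table: `animal_id`, `group`,
#'   `challenge_day`, `day_post_infection`, `tissue`, `copies_per_ml`,
#'   logical `censored`.
#' @param groups Character vector of the three group labels, untreated label
#'   last by convention (default `c("SSPN-9", "SSPN-10", "untreated")`).
#' @param detection_limit Assay detection limit, copies/mL (default 700).
#' @param censor_policy `"limit"` (default), `"zero"` or `"half"`.
#' @param alternative One-sided direction for every pair (default `"less"`:
#'   first-named group smaller).
#'
#' @return Data frame: one row per stratum x comparison with `challenge_day`,
#'   `tissue`, `day_post_infection`, `comparison`, `u_statistic`, `p_raw`,
#'   `p_adjusted`, `n1`, `n2`, `method`.
#' @export
pairwise_panel <- function(records,
                           groups = c("SSPN-9", "SSPN-10", "untreated"),
                           detection_limit = 700,
                           censor_policy = c("limit", "zero", "half"),
                           alternative = c("less", "greater")) {
  censor_policy <- match.arg(censor_policy)
  alternative <- match.arg(alternative)
  need <- c("animal_id", "group", "challenge_day", "day_post_infection",
            "tissue", "copies_per_ml", "censored")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("viral-load table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(records$copies_per_ml < 0, na.rm = TRUE)) {
    stop("negative viral loads", call. = FALSE)
  }
  val <- records$copies_per_ml
  cens_val <- switch(censor_policy, limit = detection_limit, zero = 0,
                     half = detection_limit / 2)
  val[records$censored] <- cens_val

  strata <- unique(records[c("challenge_day", "tissue", "day_post_infection")])
  pairs <- list(c(groups[1L], groups[3L]), c(groups[2L], groups[3L]),
                c(groups[1L], groups[2L]))
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- records$challenge_day == strata$challenge_day[i] &
      records$tissue == strata$tissue[i] &
      records$day_post_infection == strata$day_post_infection[i]
    present <- unique(records$group[sel])
    if (!all(groups %in% present)) {
      warning(sprintf("stratum (challenge %s, %s, day %s) lacks group(s) %s; skipped",
                      strata$challenge_day[i], strata$tissue[i],
                      strata$day_post_infection[i],
                      paste(setdiff(groups, present), collapse = ", ")),
              call. = FALSE)
      next
    }
    for (pr in pairs) {
      a <- val[sel & records$group == pr[1L]]
      b <- val[sel & records$group == pr[2L]]
      tst <- mww_exact(a, b, alternative = alternative)
      out[[length(out) + 1L]] <- data.frame(
        challenge_day = strata$challenge_day[i],
        tissue = strata$tissue[i],
        day_post_infection = strata$day_post_infection[i],
        comparison = paste(pr, collapse = " vs "),
        u_statistic = tst$u_statistic,
        p_raw = tst$p_raw,
        p_adjusted = bonferroni_adjust(tst$p_raw, 3L),
        n1 = tst$n1, n2 = tst$n2, method = tst$method,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(challenge_day = numeric(), tissue = character(),
                      day_post_infection = numeric(), comparison = character(),
                      u_statistic = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), n1 = integer(), n2 = integer(),
                      method = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
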