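# Exact one-sided Mann-Whitney-Wilcoxon tests with Bonferroni correction.

test_that("hand-enumerable cases give exact p-values", {
  t1 <- mww_exact(c(1, 2), c(3, 4), "less")
  expect_equal(t1$p_raw, 1 / 6)
  expect_equal(t1$u_statistic, 0)
  expect_identical(t1$method, "exact")

  # all ties: no evidence in either direction
  t2 <- mww_exact(c(5, 5, 5), c(5, 5, 5), "less")
  expect_equal(t2$p_raw, 1)
  expect_equal(mww_exact(c(5, 5, 5), c(5, 5, 5), "greater")$p_raw, 1)

  # complete separation at 8 vs 8, all treated tied at the detection limit
  t3 <- mww_exact(rep(700, 8), 10^runif(8, 3.5, 6), "less")
  expect_equal(t3$p_raw, 1 / choose(16, 8))
  expect_equal(t3$u_statistic, 0)
})

test_that("exact p equals full enumeration for assorted sizes with ties", {
  # independent oracle: enumerate splits and recompute U from scratch
  enum_p <- function(a, b, alternative) {
    pooled <- c(a, b)
    n1 <- length(a)
    r <- rank(pooled)
    u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
    u_obs <- u_of(seq_len(n1))
    splits <- combn(length(pooled), n1)
    u_all <- apply(splits, 2, u_of)
    if (alternative == "less") mean(u_all <= u_obs + 1e-9)
    else mean(u_all >= u_obs - 1e-9)
  }
  set.seed(42)
  sizes <- list(c(2, 3), c(4, 4), c(5, 3), c(6, 6), c(8, 8), c(8, 5))
  for (sz in sizes) {
    for (rep_i in 1:4) {
      a <- sample(1:6, sz[1], replace = TRUE) # heavy ties
      b <- sample(1:6, sz[2], replace = TRUE)
      for (alt in c("less", "greater")) {
        expect_equal(mww_exact(a, b, alt)$p_raw, enum_p(a, b, alt),
                     info = paste(sz, collapse = "v"))
      }
    }
  }
})

test_that("exact p matches wilcox.test on tie-free data", {
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(7)
    b <- rnorm(6, mean = 0.5)
    expect_equal(mww_exact(a, b, "less")$p_raw,
                 wilcox.test(a, b, alternative = "less", exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("U statistics of the two orderings are complementary", {
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:10, 6, replace = TRUE)
    b <- sample(1:10, 7, replace = TRUE)
    u_ab <- mww_exact(a, b)$u_statistic
    u_ba <- mww_exact(b, a)$u_statistic
    expect_equal(u_ab + u_ba, length(a) * length(b))
    expect_gte(u_ab, 0)
    expect_lte(u_ab, length(a) * length(b))
  }
})

test_that("the exact p is invariant under strictly monotone transforms", {
  set.seed(17)
  a <- rlnorm(6, 3, 1)
  b <- rlnorm(8, 4, 1)
  base <- mww_exact(a, b, "less")$p_raw
  expect_equal(mww_exact(log(a), log(b), "less")$p_raw, base)
  expect_equal(mww_exact(a^3, b^3, "less")$p_raw, base)
  expect_equal(mww_exact(rank(c(a, b))[1:6], rank(c(a, b))[7:14],
                         "less")$p_raw, base)
})

test_that("under the null the exact p-value is stochastically valid", {
  set.seed(2024)
  p <- replicate(400, mww_exact(rnorm(8), rnorm(8), "less")$p_raw)
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(p <= alpha), alpha + 2.5 * sqrt(alpha * (1 - alpha) / 400))
  }
})

test_that("large samples fall back to a flagged, accurate normal approximation", {
  set.seed(66)
  a <- rnorm(40)
  b <- rnorm(40, 0.4)
  t_norm <- mww_exact(a, b, "less", enum_cap = 1e3)
  expect_identical(t_norm$method, "normal_approx")
  ref <- wilcox.test(a, b, alternative = "less", exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(t_norm$p_raw, ref, tolerance = 1e-6)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(1 / 6, 3), 0.5)
  expect_error(bonferroni_adjust(0, 3), "0, 1")
  expect_error(bonferroni_adjust(0.2, 0), "positive integer")
})

test_that("the pairwise panel runs three adjusted tests per stratum", {
  vl <- simulate_efficacy_study(detect_prob = c("SSPN-9" = 0, "SSPN-10" = 0,
                                                untreated = 1),
                                seed = 5)
  panel <- pairwise_panel(vl)
  strata <- unique(vl[c("challenge_day", "tissue", "day_post_infection")])
  expect_equal(nrow(panel), 3 * nrow(strata))
  expect_equal(unique(panel$method), "exact")
  # complete separation: treated vs untreated at the enumeration floor
  tvu <- panel[grepl("untreated", panel$comparison), ]
  expect_true(all(abs(tvu$p_raw - 1 / choose(16, 8)) < 1e-12))
  expect_true(all(tvu$p_adjusted == 3 / choose(16, 8)))
  # treated vs treated: identical all-censored groups, no evidence
  tvt <- panel[panel$comparison == "SSPN-9 vs SSPN-10", ]
  expect_true(all(tvt$p_raw == 1))
})

test_that("identical group distributions rarely reach adjusted significance", {
  vl <- simulate_efficacy_study(detect_prob = c("SSPN-9" = 0.5,
                                                "SSPN-10" = 0.5,
                                                untreated = 0.5),
                                seed = 77)
  panel <- pairwise_panel(vl)
  expect_lt(mean(panel$p_adjusted < 0.05), 0.05 + 0.1)
})

test_that("strata missing a group are skipped with a warning", {
  vl <- simulate_efficacy_study(seed = 1)
  vl <- vl[!(vl$group == "SSPN-10" & vl$challenge_day == 14), ]
  # one warning per skipped stratum (two sampling days in challenge 14)
  w <- capture_warnings(panel <- pairwise_panel(vl))
  expect_length(w, 2)
  expect_match(w, "lacks group", all = TRUE)
  expect_true(all(panel$challenge_day == 7))
})

test_that("censor policies preserve the ranking against detectable animals", {
  vl <- simulate_efficacy_study(detect_prob = c("SSPN-9" = 0.4,
                                                "SSPN-10" = 0.6,
                                                untreated = 1),
                                seed = 10)
  p_limit <- pairwise_panel(vl, censor_policy = "limit")$p_raw
  p_zero <- pairwise_panel(vl, censor_policy = "zero")$p_raw
  p_half <- pairwise_panel(vl, censor_policy = "half")$p_raw
  expect_equal(p_limit, p_zero)
  expect_equal(p_limit, p_half)
})
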