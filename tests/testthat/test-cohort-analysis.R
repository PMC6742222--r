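make_cohort <- function(n = 400, rho = 0.3, seed = 5) {
  d <- simulate_bivariate_scores(n, rho, seed = seed)
  d$maternal_quartile <- assign_quartiles(d$maternal_hei)
  d$offspring_top_q <- assign_quartiles(d$offspring_hei) == "Q4"
  d
}

test_that("exclusion flow drops rows in order and tallies first matches", {
  d <- tibble::tibble(
    maternal_energy = c(2000, 10000, 10000, 30000, 1000),
    multiple_birth = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    offspring_age = c(14, 14, 15, 14, 16)
  )
  kept <- apply_exclusions(d)
  tally <- exclusion_tally(kept)
  # rows 1 and 5 count under energy (first rule) even when multiply flagged
  expect_equal(unname(tally[c("implausible_energy", "multiple_birth",
                              "age_ge_15", "remaining")]),
               c(3, 1, 1, 0))
  clean <- tibble::tibble(maternal_energy = rep(10000, 3),
                          multiple_birth = FALSE, offspring_age = 14)
  kept2 <- apply_exclusions(clean)
  expect_equal(nrow(kept2), 3)
  expect_equal(sum(exclusion_tally(kept2)[1:3]), 0)
})

test_that("sensitivity exclusions match a hand enumeration", {
  d <- tibble::tibble(
    maternal_energy = c(5000, 7000, 7000, 7000, 5500, 9000, 7000, 7000, 7000, 7000),
    maternal_bmi    = c(22,   17,   NA,   22,   22,   18.5, 25,   21,   30,   23),
    vegetarian      = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  # hand count: energy drops rows 1, 5; bmi drops 2, 3, 6; vegetarian drops 4, 8
  kept <- apply_exclusions(d, sensitivity_exclusions())
  tally <- exclusion_tally(kept)
  expect_equal(unname(tally[c("low_energy", "low_or_na_bmi", "vegetarian",
                              "remaining")]), c(2, 3, 2, 3))
})

test_that("quartile assignment uses interpolated percentiles with ties to the lower quartile", {
  q <- assign_quartiles(1:8)
  expect_equal(as.vector(table(q)), rep(2, 4))
  expect_equal(attr(q, "cutpoints"), c(2.75, 4.5, 6.25))
  # ties exactly at a cutpoint fall into the lower quartile
  x <- c(1, 2, 3, 3, 3, 5, 6, 7, 8, 9, 10, 12)
  cp <- stats::quantile(x, 0.25, names = FALSE)
  qt <- assign_quartiles(x)
  expect_true(all(qt[x == cp] == "Q1"))
  # partition and determinism
  set.seed(9)
  y <- rnorm(19582, 24, 7)
  q1 <- assign_quartiles(y)
  expect_true(all(abs(as.vector(table(q1)) - length(y) / 4) <= 1))
  expect_identical(q1, assign_quartiles(y))
  expect_error(assign_quartiles(rep(3, 10)), "degenerate")
  expect_error(assign_quartiles(c(1, 2, NA, NA)), "at least 4")
})

test_that("covariate imputation uses median, mode and an explicit missing category", {
  d <- tibble::tibble(
    maternal_age = c(30, 31, NA),
    smoking = c("never", "never", NA),
    physical_activity = c("<4h", "<4h", "<4h"),
    parity = c("0", "1", "0"),
    maternal_bmi_cat = c("normal", NA, "obese")
  )
  out <- impute_covariates(d)
  expect_equal(out$maternal_age[3], 30.5)
  expect_equal(out$smoking[3], "never")
  expect_equal(as.character(out$maternal_bmi_cat), c("normal", "missing", "obese"))
  log <- attr(out, "imputation_log")
  expect_equal(unname(log[c("maternal_age", "smoking", "maternal_bmi_cat")]),
               c(1L, 1L, 1L))
  # mode with a clear winner
  d2 <- tibble::tibble(smoking = c(rep("never", 5), rep("daily", 2), NA))
  expect_equal(impute_covariates(d2, median_cols = character(),
                                 mode_cols = "smoking",
                                 missing_category_cols = character())$smoking[8],
               "never")
  # untouched when complete
  d3 <- tibble::tibble(maternal_age = c(30, 31))
  expect_equal(impute_covariates(d3)$maternal_age, c(30, 31))
  expect_warning(
    impute_covariates(tibble::tibble(maternal_age = c(1, NA, NA))),
    "missing")
})

test_that("unadjusted log-binomial fits equal closed-form proportion ratios", {
  counts <- tibble::tibble(maternal_quartile = c("Q1", "Q2"),
                           cases = c(10, 20), n = c(100, 100))
  fit <- fit_log_binomial(counts, exposure = "maternal_quartile")
  est <- tidy(fit)
  oracle <- oracle_rr(10, 100, 20, 100)
  expect_equal(est$rr[2], unname(oracle["rr"]))
  expect_equal(est$ci_low[2], unname(oracle["lo"]))
  expect_equal(est$ci_high[2], unname(oracle["hi"]))
  expect_false(fit$fallback_used)
  # identical proportions: RR 1 and CI covering 1
  eq <- fit_log_binomial(tibble::tibble(maternal_quartile = c("a", "b"),
                                        cases = c(30, 15), n = c(200, 100)),
                         exposure = "maternal_quartile")
  expect_equal(tidy(eq)$rr[2], 1)
  expect_true(tidy(eq)$ci_low[2] < 1 && tidy(eq)$ci_high[2] > 1)
})

test_that("per-subject and aggregated fits agree", {
  d <- make_cohort(n = 800)
  fit_subject <- fit_log_binomial(d)
  agg <- dplyr::summarise(dplyr::group_by(d, maternal_quartile),
                          cases = sum(offspring_top_q), n = dplyr::n(),
                          .groups = "drop")
  fit_agg <- fit_log_binomial(agg, exposure = "maternal_quartile")
  expect_equal(tidy(fit_subject)$rr, tidy(fit_agg)$rr, tolerance = 1e-8)
  expect_equal(tidy(fit_subject)$ci_low, tidy(fit_agg)$ci_low, tolerance = 1e-8)
})

test_that("separation raises an explicit error naming the level", {
  counts <- tibble::tibble(maternal_quartile = c("Q1", "Q2"),
                           cases = c(0, 20), n = c(100, 100))
  expect_error(fit_log_binomial(counts, exposure = "maternal_quartile"),
               "separation.*Q1")
})

test_that("trend test detects a planted gradient and passes medians through", {
  d <- simulate_bivariate_scores(2000, 0.3, seed = 21)
  d$offspring_top_q <- assign_quartiles(d$offspring_hei) == "Q4"
  res <- trend_test(d, score = "maternal_hei")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$estimate, 0)
  med <- res$medians[[1]]
  q <- assign_quartiles(d$maternal_hei)
  expect_equal(med, unname(tapply(d$maternal_hei, q, median)))
  expect_true(all(diff(med) > 0))
})

test_that("a single-stratum stratified fit equals the unstratified fit", {
  d <- make_cohort(n = 600)
  d$stratum_var <- "only"
  strat <- stratified_fit(d, "stratum_var")
  plain <- tidy(fit_log_binomial(d))
  expect_equal(strat$rr, plain$rr)
  expect_equal(strat$ci_low, plain$ci_low)
  expect_true(all(strat$stratum == "only"))
})

test_that("stratified fits on published stratum counts recover published RRs", {
  t6 <- readr::read_csv(system.file("extdata", "table6_counts.csv",
                                    package = "heicohort"),
                        show_col_types = FALSE)
  uw <- t6[t6$stratum == "underweight", ]
  fit <- fit_log_binomial(
    dplyr::select(uw, maternal_quartile = "quartile", "cases", "n"),
    exposure = "maternal_quartile")
  expect_equal(round(tidy(fit)$rr[4], 2), 2.69)
})

test_that("correlation panel honours methods, ranks and degeneracies", {
  d <- tibble::tibble(x = 1:20, y = 1:20)
  res <- correlate_pairs(d, tibble::tibble(x = "x", y = "y",
                                           method = c("pearson")))
  expect_equal(res$r, 1)
  res_s <- correlate_pairs(d, tibble::tibble(x = "x", y = "y",
                                             method = "spearman"))
  expect_equal(res_s$r, 1)
  # anti-monotone transform: Spearman is exactly -1 despite marginal distortion
  d2 <- tibble::tibble(x = runif(50), y = NA)
  d2$y <- exp(-5 * d2$x)
  expect_equal(correlate_pairs(d2, tibble::tibble(x = "x", y = "y",
                                                  method = "spearman"))$r, -1)
  expect_error(correlate_pairs(tibble::tibble(x = rep(1, 10), y = 1:10),
                               tibble::tibble(x = "x", y = "y")),
               "constant")
})

test_that("correlation recovery at scale matches the generating parameter", {
  d <- simulate_bivariate_scores(19582, 0.22, seed = 3)
  res <- correlate_pairs(d, tibble::tibble(x = "maternal_hei",
                                           y = "offspring_hei"))
  expect_lt(abs(res$r - 0.22), 0.02)
  expect_lt(res$p_value, 0.001)
})

test_that("attrition comparison matches textbook chi-square and recovers planted effects", {
  # hand-built 2x2: 520/1000 girls among participants vs 460/1000
  d <- tibble::tibble(
    participated = rep(c(TRUE, FALSE), each = 1000),
    sex = c(rep("girl", 520), rep("boy", 480), rep("girl", 460), rep("boy", 540))
  )
  res <- attrition_compare(d, categorical = "sex")
  o <- matrix(c(480, 520, 540, 460), ncol = 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  x2 <- sum((o - e)^2 / e)
  expect_equal(res$p_value, pchisq(x2, 1, lower.tail = FALSE))

  # identical groups: near-zero mean difference
  set.seed(13)
  d2 <- tibble::tibble(participated = rep(c(TRUE, FALSE), each = 2000),
                       age = rnorm(4000, 30, 4))
  res2 <- attrition_compare(d2, continuous = "age")
  expect_true(res2$ci_low < 0 && res2$ci_high > 0)

  # participation increasing in education is detected
  co <- simulate_pairs(
    n_pairs = 4000, seed = 17,
    attrition = function(d) plogis(-0.6 + 1.2 * (d$education == "high")))
  res3 <- attrition_compare(co, categorical = "education")
  expect_lt(res3$p_value, 0.001)
  props <- res3$proportions[[1]]
  expect_gt(props["high", "TRUE"], props["high", "FALSE"])
})

test_that("low expected cell counts attach a warning flag", {
  d <- tibble::tibble(participated = rep(c(TRUE, FALSE), each = 6),
                      g = rep(c("a", "b"), 6))
  expect_warning(res <- attrition_compare(d, categorical = "g"), "expected cell")
  expect_true(res$low_expected_cells)
})

test_that("component adjustment scan keeps order and shows collinear attenuation", {
  co <- simulate_pairs(n_pairs = 3000, seed = 23)
  co$maternal_quartile <- assign_quartiles(co$maternal_hei)
  co$offspring_top_q <- assign_quartiles(co$offspring_hei) == "Q4"
  co$noise_component <- rnorm(nrow(co))
  co$self_component <- co$maternal_hei
  base_rr <- tidy(fit_log_binomial(co))$rr[4]
  scan <- component_adjustment_scan(co, c("noise_component", "self_component"))
  expect_equal(scan$component, c("noise_component", "self_component"))
  expect_lt(abs(scan$rr_q4[1] - base_rr), 0.05)
  expect_lt(abs(scan$rr_q4[2] - 1), abs(base_rr - 1))
  full_scan <- component_adjustment_scan(
    co, grep("^maternal_score_", names(co), value = TRUE))
  expect_equal(nrow(full_scan), 8)
})

test_that("continuous association recovers exact and closed-form slopes", {
  d <- tibble::tibble(maternal_hei = seq(5, 40, length.out = 50))
  d$offspring_hei <- 0.23 * d$maternal_hei
  ca <- suppressWarnings(continuous_association(d))
  expect_equal(tidy(ca)$slope_per_10, 2.3)
  expect_equal(glance(ca)$r_squared, 1)
  # bivariate normal r = 0.22, SDx 7.4, SDy 9: slope per 10 = 10 r SDy/SDx
  d2 <- simulate_bivariate_scores(19582, 0.22, means = c(23.5, 23.9),
                                  sds = c(7.4, 9), seed = 31)
  ca2 <- continuous_association(d2)
  expect_lt(abs(tidy(ca2)$slope_per_10 - 10 * 0.22 * 9 / 7.4), 0.25)
  # planted positive confounder: adjustment moves the slope down
  set.seed(33)
  n <- 5000
  u <- rnorm(n)
  d3 <- tibble::tibble(confounder = u,
                       maternal_hei = 24 + 4 * u + rnorm(n, 0, 5),
                       offspring_hei = 24 + 3 * u + rnorm(n, 0, 8))
  adj <- continuous_association(d3, covariates = "confounder")
  unadj <- continuous_association(d3)
  expect_lt(tidy(adj)$slope_per_10, tidy(unadj)$slope_per_10)
  # rank-deficient design errors out
  d$dup <- d$maternal_hei
  expect_error(continuous_association(d, covariates = "dup"), "rank-deficient")
})

test_that("sex interaction test is calibrated under no interaction", {
  # the generator draws offspring sex independently of everything else, so
  # the interaction is null; over a few seeds the p-values should look
  # uniform, not concentrated near zero
  ps <- vapply(c(29, 30, 31), function(s) {
    co <- simulate_pairs(n_pairs = 4000, seed = s)
    co$maternal_quartile <- assign_quartiles(co$maternal_hei)
    co$offspring_top_q <- assign_quartiles(co$offspring_hei) == "Q4"
    res <- sex_interaction_test(co)
    expect_equal(res$df, 3)
    res$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.05)
  expect_gt(min(ps), 0.001)
})
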