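#' Covariate sets for the adjusted risk-ratio models
#'
#' `model_a_covariates()` lists the maternal adjustment set (age,
#' prepregnancy BMI category, parity, education, lactation, physical
#' activity, alcohol, smoking); `model_b_covariates()` extends it with
#' offspring sex and offspring energy-intake quartile.
#'
#' @return Character vector of covariate column names.
#' @export
model_a_covariates <- function() {
  c("maternal_age", "maternal_bmi_cat", "parity", "education", "lactation",
    "physical_activity", "alcohol", "smoking")
}

#' @rdname model_a_covariates
#' @export
model_b_covariates <- function() {
  c(model_a_covariates(), "offspring_sex", "offspring_energy_q")
}

#' Correlation panel over variable pairs
#'
#' Computes a correlation per requested pair, using Pearson for variables
#' flagged approximately normal and Spearman otherwise, with a two-sided
#' p-value from [stats::cor.test()].
#'
#' @param data Tibble of paired observations.
#' @param pairs Tibble (or data frame) with columns `x` and `y` naming the
#'   variable pairs, and optionally `method` ("pearson" or "spearman");
#'   `default_method` fills in where `method` is absent or `NA`.
#' @param default_method Method used when a pair does not declare one.
#' @return Tibble: `x`, `y`, `method`, `r`, `p_value`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(a = rnorm(50), b = rnorm(50))
#' correlate_pairs(d, tibble::tibble(x = "a", y = "b"))
correlate_pairs <- function(data, pairs, default_method = "pearson") {
  pairs <- tibble::as_tibble(pairs)
  if (!"method" %in% names(pairs)) pairs$method <- NA_character_
  purrr::pmap_dfr(pairs, function(x, y, method, ...) {
    m <- if (is.na(method)) default_method else method
    ok <- stats::complete.cases(data[[x]], data[[y]])
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ", x, " vs ", y,
                          call. = FALSE)
    if (stats::sd(data[[x]][ok]) == 0 || stats::sd(data[[y]][ok]) == 0) {
      stop("correlation undefined: '",
           if (stats::sd(data[[x]][ok]) == 0) x else y, "' is constant",
           call. = FALSE)
    }
    ct <- suppressWarnings(
      stats::cor.test(data[[x]][ok], data[[y]][ok], method = m, exact = FALSE)
    )
    tibble::tibble(x = x, y = y, method = m, r = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
  })
}

#' Compare characteristics of participants and nonparticipants
#'
#' Quantifies attrition bias: for each continuous characteristic the mean
#' difference (participants minus nonparticipants) with a 95% CI and a
#' one-way ANOVA p-value; for each categorical characteristic the per-group
#' proportions and a chi-square p-value. A warning flag is attached to
#' chi-square entries with any expected cell count below 5.
#'
#' @param data Tibble with a logical `participated` column plus the
#'   characteristics to compare.
#' @param continuous,categorical Character vectors of column names.
#' @param participation Name of the participation flag column.
#' @param correct Apply Yates continuity correction to 2x2 chi-square
#'   tables (default `FALSE`).
#' @return Tibble: `variable`, `type`, `mean_participants`,
#'   `mean_nonparticipants`, `mean_diff`, `ci_low`, `ci_high`, `p_value`,
#'   `low_expected_cells`; categorical rows carry the level proportions in
#'   the list column `proportions`.
#' @export
attrition_compare <- function(data, continuous = character(),
                              categorical = character(),
                              participation = "participated",
                              correct = FALSE) {
  data <- tibble::as_tibble(data)
  grp <- as.logical(data[[participation]])
  if (any(is.na(grp))) stop("participation flag has missing values", call. = FALSE)

  cont_rows <- purrr::map_dfr(continuous, function(v) {
    x <- data[[v]]
    fit <- stats::aov(x ~ factor(grp))
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    m1 <- mean(x[grp], na.rm = TRUE); m0 <- mean(x[!grp], na.rm = TRUE)
    se <- sqrt(stats::var(x[grp], na.rm = TRUE) / sum(grp & !is.na(x)) +
               stats::var(x[!grp], na.rm = TRUE) / sum(!grp & !is.na(x)))
    tibble::tibble(variable = v, type = "continuous",
                   mean_participants = m1, mean_nonparticipants = m0,
                   mean_diff = m1 - m0,
                   ci_low = m1 - m0 - 1.96 * se, ci_high = m1 - m0 + 1.96 * se,
                   p_value = p, low_expected_cells = FALSE,
                   proportions = list(NULL))
  })

  cat_rows <- purrr::map_dfr(categorical, function(v) {
    tab <- table(data[[v]], grp)
    use_correct <- correct && all(dim(tab) == 2)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = use_correct))
    low <- any(ct$expected < 5)
    if (low) warning("expected cell count < 5 for '", v, "'", call. = FALSE)
    props <- prop.table(tab, margin = 2)
    tibble::tibble(variable = v, type = "categorical",
                   mean_participants = NA_real_, mean_nonparticipants = NA_real_,
                   mean_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   p_value = ct$p.value, low_expected_cells = low,
                   proportions = list(props))
  })

  dplyr::bind_rows(cont_rows, cat_rows)
}
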