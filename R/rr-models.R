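#' Relative risk of a binary outcome across exposure quartiles
#'
#' Fits a log-linear binomial model (binomial family, log link) of a binary
#' outcome on an exposure factor, optionally adjusted for covariates, and
#' reports exponentiated coefficients as risk ratios with Wald 95%
#' confidence intervals on the log scale. The first exposure level is the
#' reference (RR = 1). For the unadjusted single-factor model the fit is
#' saturated, so the estimated risk ratios equal the observed-proportion
#' ratios exactly.
#'
#' Two input shapes are accepted:
#' * per-subject rows with a logical/0-1 `outcome` column, or
#' * an aggregated table with `cases` and `n` columns, one row per exposure
#'   level (as printed in study tables).
#'
#' Log-binomial likelihoods can fail to converge when many covariates push
#' fitted risks toward 1; in that case the model is refit as a Poisson
#' regression with a robust (HC0 sandwich) variance, and `fallback_used` is
#' set. Complete separation (an exposure level with zero cases in an
#' unadjusted fit) raises an error naming the level.
#'
#' @param data Tibble, per-subject or aggregated (see above).
#' @param outcome Name of the binary outcome column (per-subject shape).
#' @param exposure Name of the exposure factor column.
#' @param covariates Character vector of adjustment covariate columns, or
#'   `NULL` for the unadjusted model.
#' @return An object of class `rr_fit` with [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   maternal_quartile = paste0("Q", 1:4),
#'   cases = c(812, 1080, 1292, 1726),
#'   n = c(4879, 4948, 4898, 4857)
#' )
#' fit <- fit_log_binomial(counts, exposure = "maternal_quartile")
#' tidy(fit)
fit_log_binomial <- function(data, outcome = "offspring_top_q",
                             exposure = "maternal_quartile",
                             covariates = NULL) {
  data <- tibble::as_tibble(data)
  aggregated <- all(c("cases", "n") %in% names(data))
  if (!exposure %in% names(data)) {
    stop("exposure column '", exposure, "' not found", call. = FALSE)
  }

  if (aggregated) {
    if (any(data$cases > data$n)) stop("cases exceed n", call. = FALSE)
    model_data <- dplyr::mutate(
      data,
      .p = .data$cases / .data$n,
      .exposure = factor(.data[[exposure]])
    )
    rhs <- c(".exposure", covariates)
    formula <- stats::as.formula(paste(".p ~", paste(rhs, collapse = " + ")))
    weights <- model_data$n
    cell <- dplyr::summarise(dplyr::group_by(model_data, .data$.exposure),
                             cases = sum(.data$cases), n = sum(.data$n),
                             .groups = "drop")
  } else {
    if (!outcome %in% names(data)) {
      stop("outcome column '", outcome, "' not found", call. = FALSE)
    }
    y <- as.numeric(data[[outcome]])
    if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
    model_data <- dplyr::mutate(data, .p = y,
                                .exposure = factor(.data[[exposure]]))
    rhs <- c(".exposure", covariates)
    formula <- stats::as.formula(paste(".p ~", paste(rhs, collapse = " + ")))
    weights <- NULL
    cell <- dplyr::summarise(dplyr::group_by(model_data, .data$.exposure),
                             cases = sum(.data$.p), n = dplyr::n(),
                             .groups = "drop")
  }
  if (is.null(covariates) && any(cell$cases == 0)) {
    stop("complete separation: no cases in exposure level ",
         paste(cell$.exposure[cell$cases == 0], collapse = ", "), call. = FALSE)
  }

  fitted <- fit_log_link(formula, model_data, weights)
  levels_exp <- levels(model_data$.exposure)
  coef_names <- paste0(".exposure", levels_exp[-1])
  est <- stats::coef(fitted$fit)[coef_names]
  se <- sqrt(diag(fitted$vcov)[coef_names])
  table <- tibble::tibble(
    !!exposure := levels_exp,
    cases = cell$cases[match(levels_exp, as.character(cell$.exposure))],
    n = cell$n[match(levels_exp, as.character(cell$.exposure))],
    rr = unname(c(1, exp(est))),
    ci_low = unname(c(NA_real_, exp(est - 1.96 * se))),
    ci_high = unname(c(NA_real_, exp(est + 1.96 * se)))
  )
  structure(
    list(table = table, exposure = exposure, covariates = covariates,
         converged = fitted$converged, fallback_used = fitted$fallback,
         fit = fitted$fit, vcov = fitted$vcov),
    class = "rr_fit"
  )
}

# Fit a log-link risk model with binomial likelihood, falling back to
# Poisson + HC0 sandwich variance when the binomial fit will not converge.
fit_log_link <- function(formula, data, weights = NULL) {
  p0 <- if (is.null(weights)) mean(data$.p) else stats::weighted.mean(data$.p, weights)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  # weights/mustart expressions are resolved inside the model frame, so both
  # must live in `data` rather than in this function's environment
  data$.mustart <- rep(p0, nrow(data))
  try_binomial <- function(start = NULL) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        formula, data = data, family = stats::binomial(link = "log"),
        weights = .w, mustart = .mustart, start = start,
        control = stats::glm.control(maxit = 100, epsilon = 1e-10)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || any(!is.finite(stats::coef(fit)))) {
      NULL
    } else {
      fit
    }
  }
  # the Poisson solution is a reliable starting point for the log-binomial
  # IRLS (it is the exact MLE for a saturated model); nudge the intercept
  # down if any fitted risk starts at or above 1
  pois <- suppressWarnings(stats::glm(
    formula, data = data, family = stats::poisson(link = "log"),
    weights = .w, control = stats::glm.control(maxit = 100, epsilon = 1e-10)
  ))
  start <- stats::coef(pois)
  fit <- NULL
  if (all(is.finite(start))) {
    eta_max <- max(stats::predict(pois, type = "link"))
    if (eta_max >= 0) start[1] <- start[1] - eta_max - 1e-8
    fit <- try_binomial(start = start)
  }
  if (is.null(fit)) fit <- try_binomial()
  if (!is.null(fit)) {
    return(list(fit = fit, vcov = stats::vcov(fit), converged = TRUE,
                fallback = FALSE))
  }
  list(fit = pois, vcov = sandwich::vcovHC(pois, type = "HC0"),
       converged = pois$converged, fallback = TRUE)
}

#' @export
#' @importFrom generics tidy
tidy.rr_fit <- function(x, ...) x$table

#' @export
#' @importFrom generics glance
glance.rr_fit <- function(x, ...) {
  tibble::tibble(
    n = sum(x$table$n), cases = sum(x$table$cases),
    converged = x$converged, fallback_used = x$fallback_used,
    n_covariates = length(x$covariates)
  )
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("Log-binomial risk-ratio fit",
      if (x$fallback_used) "(Poisson/robust fallback)" else "", "\n")
  print(x$table)
  invisible(x)
}

#' Forest-style plot of per-quartile risk ratios
#'
#' @param object An `rr_fit` object.
#' @param ... Unused.
#' @return A ggplot object (log-scaled RR axis, reference line at 1).
#' @export
autoplot.rr_fit <- function(object, ...) {
  d <- object$table
  d$level <- factor(d[[object$exposure]], levels = d[[object$exposure]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$exposure, y = "risk ratio (95% CI)") +
    ggplot2::theme_minimal()
}

#' Median-coded trend test across exposure quartiles
#'
#' Replaces the quartile factor with a single continuous term equal to the
#' median score within each quartile of the analysis sample, and reports
#' the Wald two-sided p-value for that term in the log-binomial model -- a
#' test of a monotone exposure-response gradient.
#'
#' @param data Per-subject tibble.
#' @param score Name of the continuous exposure score column (quartiles and
#'   their medians are computed from it).
#' @param outcome Name of the binary outcome column.
#' @param covariates Optional adjustment covariates.
#' @return A one-row tibble: `estimate` (log-RR per score unit), `se`,
#'   `statistic`, `p_value`, `fallback_used`, and the quartile medians as a
#'   list column `medians`.
#' @export
trend_test <- function(data, score = "maternal_hei", outcome = "offspring_top_q",
                       covariates = NULL) {
  data <- tibble::as_tibble(data)
  q <- assign_quartiles(data[[score]])
  med <- tapply(data[[score]], q, stats::median)
  model_data <- dplyr::mutate(
    data,
    .p = as.numeric(.data[[outcome]]),
    .trend = as.numeric(med[as.character(q)])
  )
  rhs <- c(".trend", covariates)
  formula <- stats::as.formula(paste(".p ~", paste(rhs, collapse = " + ")))
  fitted <- fit_log_link(formula, model_data)
  est <- stats::coef(fitted$fit)[".trend"]
  se <- sqrt(diag(fitted$vcov)[".trend"])
  z <- est / se
  tibble::tibble(
    estimate = unname(est), se = unname(se), statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(z)),
    fallback_used = fitted$fallback,
    medians = list(unname(med))
  )
}

#' Risk-ratio fits within strata of a covariate
#'
#' Refits [fit_log_binomial()] independently within each level of a
#' stratification variable (e.g. prepregnancy BMI category). Quartile
#' labels are taken as given (ranked in the full analysis sample), matching
#' the convention of stratified cohort tables. Empty strata are skipped
#' with a message; strata smaller than `min_size` are flagged.
#'
#' @param data Per-subject tibble.
#' @param stratum_var Name of the categorical stratification column.
#' @inheritParams fit_log_binomial
#' @param min_size Strata with fewer rows are flagged `small_stratum`.
#' @return A tibble of tidied per-quartile results with a `stratum` column
#'   and a `small_stratum` flag; the underlying `rr_fit` objects are
#'   attached as attribute `"fits"`.
#' @export
stratified_fit <- function(data, stratum_var, outcome = "offspring_top_q",
                           exposure = "maternal_quartile", covariates = NULL,
                           min_size = 50) {
  data <- tibble::as_tibble(data)
  levels_s <- if (is.factor(data[[stratum_var]])) {
    levels(droplevels(data[[stratum_var]]))
  } else {
    sort(unique(data[[stratum_var]]))
  }
  fits <- list()
  rows <- purrr::map_dfr(levels_s, function(s) {
    d <- data[data[[stratum_var]] == s & !is.na(data[[stratum_var]]), ]
    if (nrow(d) == 0) {
      message("stratum '", s, "' is empty; skipped")
      return(NULL)
    }
    fit <- fit_log_binomial(d, outcome = outcome, exposure = exposure,
                            covariates = covariates)
    fits[[as.character(s)]] <<- fit
    dplyr::mutate(tidy(fit), stratum = as.character(s),
                  small_stratum = nrow(d) < min_size, .before = 1)
  })
  attr(rows, "fits") <- fits
  rows
}

#' One-at-a-time component adjustment scan
#'
#' Refits the adjusted risk-ratio model once per maternal index component,
#' adding that component's score as an extra covariate, to probe whether a
#' single component drives the association between maternal and offspring
#' diet quality. Reports the top-quartile risk ratio from each refit.
#'
#' @param data Per-subject tibble containing maternal component score
#'   columns.
#' @param components Character vector of component score columns to scan.
#' @inheritParams fit_log_binomial
#' @return A tibble: `component`, `rr_q4`, `ci_low`, `ci_high`,
#'   `fallback_used`, in the order given.
#' @export
component_adjustment_scan <- function(data,
                                      components,
                                      outcome = "offspring_top_q",
                                      exposure = "maternal_quartile",
                                      covariates = NULL) {
  purrr::map_dfr(components, function(comp) {
    fit <- fit_log_binomial(data, outcome = outcome, exposure = exposure,
                            covariates = c(covariates, comp))
    top <- dplyr::slice_tail(tidy(fit), n = 1)
    tibble::tibble(component = comp, rr_q4 = top$rr, ci_low = top$ci_low,
                   ci_high = top$ci_high, fallback_used = fit$fallback_used)
  })
}

#' Continuous maternal-offspring score association
#'
#' Linear model of the offspring score on the maternal score (plus optional
#' covariates). The slope is rescaled to a per-10-point increase of the
#' maternal score, with a Wald 95% CI, and the model's coefficient of
#' determination is reported.
#'
#' @param data Per-subject tibble.
#' @param response,predictor Names of the offspring and maternal score
#'   columns.
#' @param covariates Optional adjustment covariates.
#' @return Object of class `continuous_assoc` with `tidy()`/`glance()`
#'   methods; `tidy()` gives `slope_per_10`, `ci_low`, `ci_high`;
#'   `glance()` gives `r_squared` and `n`.
#' @export
continuous_association <- function(data, response = "offspring_hei",
                                   predictor = "maternal_hei",
                                   covariates = NULL) {
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  formula <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  b <- stats::coef(fit)[predictor]
  se <- sqrt(diag(stats::vcov(fit))[predictor])
  structure(
    list(slope_per_10 = unname(10 * b),
         ci_low = unname(10 * (b - 1.96 * se)),
         ci_high = unname(10 * (b + 1.96 * se)),
         r_squared = summary(fit)$r.squared,
         n = stats::nobs(fit), fit = fit),
    class = "continuous_assoc"
  )
}

#' @export
tidy.continuous_assoc <- function(x, ...) {
  tibble::tibble(slope_per_10 = x$slope_per_10, ci_low = x$ci_low,
                 ci_high = x$ci_high)
}

#' @export
glance.continuous_assoc <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n)
}

#' @export
print.continuous_assoc <- function(x, ...) {
  cat(sprintf("Per-10-unit slope %.2f (95%% CI %.2f, %.2f); R^2 = %.3f (n = %d)\n",
              x$slope_per_10, x$ci_low, x$ci_high, x$r_squared, x$n))
  invisible(x)
}

#' Wald test for exposure-by-sex interaction
#'
#' Adds exposure-by-sex product terms to the adjusted model and tests them
#' jointly with a Wald chi-square on the (possibly robust) covariance.
#'
#' @inheritParams fit_log_binomial
#' @param sex Name of the offspring sex column.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `fallback_used`.
#' @export
sex_interaction_test <- function(data, outcome = "offspring_top_q",
                                 exposure = "maternal_quartile",
                                 sex = "offspring_sex", covariates = NULL) {
  model_data <- dplyr::mutate(
    tibble::as_tibble(data),
    .p = as.numeric(.data[[outcome]]),
    .exposure = factor(.data[[exposure]]),
    .sex = factor(.data[[sex]])
  )
  rhs <- c(".exposure * .sex", covariates)
  formula <- stats::as.formula(paste(".p ~", paste(rhs, collapse = " + ")))
  fitted <- fit_log_link(formula, model_data)
  cn <- names(stats::coef(fitted$fit))
  ix <- grep("^\\.exposureQ?.*:\\.sex", cn)
  b <- stats::coef(fitted$fit)[ix]
  V <- fitted$vcov[ix, ix, drop = FALSE]
  w <- as.numeric(t(b) %*% solve(V) %*% b)
  tibble::tibble(statistic = w, df = length(ix),
                 p_value = stats::pchisq(w, length(ix), lower.tail = FALSE),
                 fallback_used = fitted$fallback)
}
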