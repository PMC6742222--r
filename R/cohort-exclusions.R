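#' Standard and sensitivity exclusion rule sets
#'
#' `exclusion_rules()` returns the primary exclusion flow applied before any
#' analysis, in its reporting order: implausible maternal energy intake
#' (< 2,500 or > 25,000 kJ/day), multiple pregnancies/births, and offspring
#' aged 15 years or older. `sensitivity_exclusions()` returns the
#' sensitivity set: low maternal energy (< 6.0 MJ/day), low or missing
#' prepregnancy BMI (<= 18.5 kg/m2), and vegetarian/vegan mothers.
#'
#' Each rule is a predicate over the cohort table returning `TRUE` for rows
#' to drop. Rules are applied in order and each dropped row is tallied under
#' the first rule it matches.
#'
#' @return Named list of predicate functions.
#' @export
exclusion_rules <- function() {
  list(
    implausible_energy = function(d) d$maternal_energy < 2500 | d$maternal_energy > 25000,
    multiple_birth     = function(d) as.logical(d$multiple_birth),
    age_ge_15          = function(d) d$offspring_age >= 15
  )
}

#' @rdname exclusion_rules
#' @export
sensitivity_exclusions <- function() {
  list(
    low_energy     = function(d) d$maternal_energy < 6000,
    low_or_na_bmi  = function(d) is.na(d$maternal_bmi) | d$maternal_bmi <= 18.5,
    vegetarian     = function(d) as.logical(d$vegetarian)
  )
}

#' Apply an exclusion flow to a cohort table
#'
#' Drops rows matching any rule and records an ordered tally: every dropped
#' row is counted once, under the first rule (in list order) that it
#' matches, mirroring how a study flowchart reports attrition at each step.
#'
#' @param data Cohort tibble (see [simulate_pairs()] for the schema).
#' @param rules Named list of predicates as from [exclusion_rules()].
#' @return The filtered tibble, with the tally attached as attribute
#'   `"exclusion_tally"` (retrieve with [exclusion_tally()]).
#' @export
#' @examples
#' cohort <- simulate_pairs(n_pairs = 200, seed = 1)
#' kept <- apply_exclusions(cohort)
#' exclusion_tally(kept)
apply_exclusions <- function(data, rules = exclusion_rules()) {
  data <- tibble::as_tibble(data)
  if (is.null(names(rules)) || any(names(rules) == "")) {
    stop("exclusion rules must be a named list", call. = FALSE)
  }
  dropped <- rep(FALSE, nrow(data))
  tally <- integer(length(rules))
  names(tally) <- names(rules)
  for (nm in names(rules)) {
    hit <- rules[[nm]](data)
    if (!is.logical(hit) || length(hit) != nrow(data)) {
      stop("exclusion rule '", nm, "' did not return one logical per row",
           call. = FALSE)
    }
    hit[is.na(hit)] <- FALSE
    new <- hit & !dropped
    tally[nm] <- sum(new)
    dropped <- dropped | new
  }
  out <- data[!dropped, ]
  attr(out, "exclusion_tally") <- c(tally, remaining = nrow(out))
  out
}

#' @rdname apply_exclusions
#' @param x A table returned by `apply_exclusions()`.
#' @export
exclusion_tally <- function(x) attr(x, "exclusion_tally")

#' Rank scores into quartiles
#'
#' Cutpoints are the empirical 25th/50th/75th percentiles of the input
#' (linear interpolation of order statistics, `stats::quantile()` type 7),
#' computed on the analysis sample itself. Ties at a cutpoint go to the
#' lower quartile (intervals are closed on the right). Re-running on the
#' same scores is bit-identical.
#'
#' @param x Numeric vector of scores; at least 4 non-missing values.
#' @return Factor with levels `Q1`..`Q4` and the cutpoints attached as
#'   attribute `"cutpoints"`; `NA` scores give `NA` labels.
#' @export
#' @examples
#' q <- assign_quartiles(1:8)
#' table(q)
#' attr(q, "cutpoints")
assign_quartiles <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 4) stop("need at least 4 non-missing scores to form quartiles",
                        call. = FALSE)
  cut_pts <- stats::quantile(x[ok], c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(cut_pts)) < 3 || stats::sd(x[ok]) == 0) {
    stop("degenerate quartiles: scores are too heavily tied to rank", call. = FALSE)
  }
  q <- cut(x, breaks = c(-Inf, cut_pts, Inf), labels = paste0("Q", 1:4),
           right = TRUE)
  attr(q, "cutpoints") <- cut_pts
  q
}

#' Impute missing model covariates
#'
#' Continuous covariates (maternal age) are imputed with the sample median;
#' categorical behaviour covariates (smoking, physical activity, parity)
#' with the mode. Prepregnancy BMI category keeps its own explicit
#' `"missing"` level rather than being imputed. A log of counts imputed per
#' covariate is attached as attribute `"imputation_log"`.
#'
#' @param data Cohort tibble.
#' @param median_cols,mode_cols,missing_category_cols Character vectors of
#'   column names routed to each strategy; defaults follow the cohort
#'   covariate plan.
#' @param warn_above Proportion of missingness above which a warning is
#'   raised (default 0.5).
#' @return The completed tibble with attribute `"imputation_log"`.
#' @export
impute_covariates <- function(data,
                              median_cols = "maternal_age",
                              mode_cols = c("smoking", "physical_activity", "parity"),
                              missing_category_cols = "maternal_bmi_cat",
                              warn_above = 0.5) {
  data <- tibble::as_tibble(data)
  log <- list()
  stat_mode <- function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    names(tab)[1]
  }
  for (col in intersect(median_cols, names(data))) {
    miss <- is.na(data[[col]])
    if (mean(miss) > warn_above) {
      warning("covariate '", col, "' is >", 100 * warn_above, "% missing",
              call. = FALSE)
    }
    if (any(miss)) data[[col]][miss] <- stats::median(data[[col]][!miss])
    log[[col]] <- sum(miss)
  }
  for (col in intersect(mode_cols, names(data))) {
    miss <- is.na(data[[col]])
    if (mean(miss) > warn_above) {
      warning("covariate '", col, "' is >", 100 * warn_above, "% missing",
              call. = FALSE)
    }
    if (any(miss)) {
      fill <- stat_mode(data[[col]][!miss])
      if (is.factor(data[[col]])) {
        data[[col]][miss] <- factor(fill, levels = levels(data[[col]]))
      } else {
        data[[col]][miss] <- fill
      }
    }
    log[[col]] <- sum(miss)
  }
  for (col in intersect(missing_category_cols, names(data))) {
    miss <- is.na(data[[col]])
    v <- as.character(data[[col]])
    v[miss] <- "missing"
    lev <- unique(c(setdiff(sort(unique(v)), "missing"), if (any(v == "missing")) "missing"))
    data[[col]] <- factor(v, levels = lev)
    log[[col]] <- sum(miss)
  }
  attr(data, "imputation_log") <- unlist(log)
  data
}
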