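# Run code with a local, restorable RNG state so package functions do not
# disturb the caller's random stream.
run_seeded <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed %% .Machine$integer.max)
  }
  force(code)
}

#' Default per-component marginal distributions and quality loadings
#'
#' One tibble per generation (mother, offspring) describing how each
#' dietary component is generated: the marginal family (`lognormal`, or
#' `normal` truncated at zero) with its parameters on the component's
#' scoring basis, and the signed Gaussian-copula loading `lambda` linking
#' the component's rank to the latent diet-quality variable (positive for
#' adequacy components, negative for moderation components, near zero for
#' sodium and energy, whose observed correlations with the total score are
#' essentially nil).
#'
#' Marginal parameters are matched to the cohort's printed dietary summary
#' statistics: medians and interquartile ranges for the skewed components,
#' means and SDs for the approximately normal ones. `sfa_epct` and
#' `added_sugar_epct` are generated as percent of energy and converted to
#' gram masses with the subject's energy intake and the Nordic energy
#' factors, so scoring them reconstructs the generated E% exactly.
#'
#' @return Named list with elements `mother` and `offspring`, each a tibble
#'   with columns `component`, `family`, `m`, `s`, `lambda`.
#' @export
default_margins <- function() {
  iqr_sdlog <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))
  mother <- tibble::tribble(
    ~component,         ~family,     ~m,          ~s,                      ~lambda,
    "fruit_veg",        "lognormal", log(165),    iqr_sdlog(107, 219),      0.55,
    "dietary_fibre",    "normal",    28,          10,                       0.45,
    "fish",             "lognormal", log(159),    iqr_sdlog(92, 250),       0.55,
    "red_meat",         "lognormal", log(479),    iqr_sdlog(349, 642),     -0.55,
    "sfa_epct",         "normal",    13,          3,                       -0.45,
    "sodium",           "normal",    3.3,         0.9,                      0.03,
    "ssb",              "lognormal", log(1510),   iqr_sdlog(820, 2560),    -0.35,
    "added_sugar_epct", "lognormal", log(7),      iqr_sdlog(5, 10),        -0.55,
    "energy",           "normal",    10600,       2700,                    -0.02
  )
  offspring <- tibble::tribble(
    ~component,         ~family,     ~m,          ~s,                      ~lambda,
    "fruit_veg",        "lognormal", log(279),    iqr_sdlog(169, 435),      0.55,
    "dietary_fibre",    "lognormal", log(26),     iqr_sdlog(19, 36),        0.42,
    "fish",             "lognormal", log(67),     iqr_sdlog(30, 120),       0.38,
    "red_meat",         "lognormal", log(666),    iqr_sdlog(463, 930),     -0.22,
    "sfa_epct",         "normal",    12,          2,                       -0.50,
    "sodium",           "normal",    3.3,         1.2,                      0.004,
    "ssb",              "lognormal", log(630),    iqr_sdlog(310, 1380),    -0.60,
    "added_sugar_epct", "lognormal", log(6),      iqr_sdlog(4, 9),         -0.65,
    "energy",           "normal",    9900,        3700,                     0.06
  )
  list(mother = mother, offspring = offspring)
}

#' Preset exclusion counts reproducing the study inclusion flow
#'
#' The cohort started from 21,082 matched pairs and removed, in order,
#' implausible maternal energy intakes (351), multiple pregnancies/births
#' (1,144) and offspring aged 15 or older (5), leaving 19,582 pairs.
#'
#' @return Named list: `total`, `implausible_energy`, `multiple_birth`,
#'   `age_ge_15`.
#' @export
paper_flow_preset <- function() {
  list(total = 21082, implausible_energy = 351, multiple_birth = 1144,
       age_ge_15 = 5)
}

# quantile function for a marginal row (value from a uniform rank)
marginal_quantile <- function(u, family, m, s) {
  if (family == "lognormal") {
    stats::qlnorm(u, meanlog = m, sdlog = s)
  } else {
    p0 <- stats::pnorm(0, mean = m, sd = s)   # truncate at zero
    stats::qnorm(p0 + u * (1 - p0), mean = m, sd = s)
  }
}

# generate one generation's intake columns from latent quality z
generate_intakes <- function(z, margins, energy_factors = hei_energy_factors(),
                             plausible_energy = c(2500, 25000)) {
  n <- length(z)
  vals <- purrr::pmap(margins, function(component, family, m, s, lambda) {
    noise <- stats::rnorm(n)
    u <- stats::pnorm(lambda * z + sqrt(1 - lambda^2) * noise)
    marginal_quantile(u, family, m, s)
  })
  names(vals) <- margins$component
  d <- tibble::as_tibble(vals)
  # keep generated energies inside the plausibility window so the exclusion
  # preset alone controls how many rows violate it
  d$energy <- pmin(pmax(d$energy, plausible_energy[1]), plausible_energy[2])
  # split combined fruit & veg; vegetable share centred on one half
  veg_share <- stats::rbeta(n, 8, 8)
  d$vegetables <- d$fruit_veg * veg_share
  d$fruit <- d$fruit_veg * (1 - veg_share)
  # energy-percent components become gram masses on the scoring basis
  d$sfa <- d$sfa_epct * d$energy / (100 * energy_factors[["sfa"]])
  d$added_sugar <- d$added_sugar_epct * d$energy / (100 * energy_factors[["added_sugar"]])
  d[c("fruit", "vegetables", "dietary_fibre", "fish", "red_meat", "sfa",
      "sodium", "ssb", "added_sugar", "energy")]
}

# correlation between the scored total and the latent quality for one
# margin, estimated once by a pilot simulation (used to inflate the latent
# correlation so the scored totals recover the target correlation)
score_attenuation <- function(margins, n_pilot = 20000) {
  z <- stats::rnorm(n_pilot)
  d <- generate_intakes(z, margins)
  stats::cor(hei_score(d)$hei_total, z)
}

#' Simulate matched mother-offspring dietary intake pairs
#'
#' Generates a cohort with the joint structure the analysis pipeline
#' assumes: latent mother and offspring diet-quality variables drawn from a
#' bivariate normal, component intakes generated through a Gaussian copula
#' (per-component loadings and marginals from [default_margins()]), scored
#' with [hei_score()], plus maternal covariates with quality gradients,
#' an optional participation (attrition) model, and an optional exclusion
#' preset that injects rows genuinely violating the exclusion filters.
#'
#' Because clamped piecewise-linear scoring attenuates the latent
#' correlation, the generator first estimates the attenuation of each
#' margin with a pilot simulation and inflates the latent correlation so
#' that the *scored totals* correlate at `rho`. The full generating
#' parameter set is attached as attribute `"truth"`.
#'
#' @param n_pairs Number of pairs (ignored when `exclusions` supplies a
#'   `total`).
#' @param rho Target Pearson correlation of the scored mother and offspring
#'   totals.
#' @param margins Marginal/loading specification, see [default_margins()].
#' @param exclusions Optional preset as from [paper_flow_preset()]; injects
#'   rows violating each exclusion filter.
#' @param attrition Optional function mapping the cohort tibble to a
#'   per-row participation probability; `NULL` marks every pair as
#'   participating.
#' @param seed Integer seed; same seed, same cohort, byte for byte.
#' @return Tibble with one row per pair: `pair_id`, `maternal_<component>`
#'   and `offspring_<component>` intakes on the scoring basis,
#'   `maternal_hei` / `offspring_hei` totals, maternal component score
#'   columns (`maternal_score_*`), covariates, exclusion fields and
#'   `participated`. Attribute `"truth"` records the generating
#'   parameters.
#' @export
#' @examples
#' cohort <- simulate_pairs(n_pairs = 500, seed = 42)
#' cor(cohort$maternal_hei, cohort$offspring_hei)
simulate_pairs <- function(n_pairs = 19582, rho = 0.22,
                           margins = default_margins(),
                           exclusions = NULL, attrition = NULL, seed = NULL) {
  stopifnot(rho > -1, rho < 1)
  run_seeded(seed, {
    n <- if (!is.null(exclusions)) exclusions$total else n_pairs

    c_m <- score_attenuation(margins$mother)
    c_o <- score_attenuation(margins$offspring)
    rho_latent <- max(min(rho / (c_m * c_o), 0.999), -0.999)

    z_m <- stats::rnorm(n)
    z_o <- rho_latent * z_m + sqrt(1 - rho_latent^2) * stats::rnorm(n)

    mi <- generate_intakes(z_m, margins$mother)
    oi <- generate_intakes(z_o, margins$offspring)
    ms <- hei_score(mi)
    os <- hei_score(oi)

    cohort <- dplyr::bind_cols(
      tibble::tibble(pair_id = seq_len(n)),
      dplyr::rename_with(mi, ~ paste0("maternal_", .x)),
      dplyr::rename_with(oi, ~ paste0("offspring_", .x))
    )
    cohort$maternal_hei <- ms$hei_total
    cohort$offspring_hei <- os$hei_total
    score_cols <- grep("^score_", names(ms), value = TRUE)
    for (sc in score_cols) cohort[[paste0("maternal_", sc)]] <- ms[[sc]]

    cohort <- dplyr::bind_cols(cohort, generate_covariates(z_m, n))
    cohort$offspring_age <- rep(14, n)
    cohort$multiple_birth <- rep(FALSE, n)
    cohort$vegetarian <- stats::runif(n) < 0.013

    if (!is.null(exclusions)) {
      cohort <- inject_exclusions(cohort, exclusions)
    }

    cohort$participated <- if (is.null(attrition)) {
      rep(TRUE, n)
    } else {
      stats::runif(n) < attrition(cohort)
    }

    attr(cohort, "truth") <- list(
      n = n, rho_target = rho, rho_latent = rho_latent,
      attenuation = c(mother = c_m, offspring = c_o),
      seed = seed, exclusions = exclusions
    )
    cohort
  })
}

# maternal covariates with gradients along the latent quality z
# (gradient coefficients chosen to reproduce the direction and rough size
# of the quartile contrasts in the cohort's characteristics table)
generate_covariates <- function(z, n) {
  age <- 30.7 + 0.7 * z + stats::rnorm(n, 0, 4.0)
  bmi <- 23.3 - 0.43 * z + stats::rnorm(n, 0, 3.85)
  bmi <- pmax(bmi, 14)
  bmi_cat <- cut(bmi, c(-Inf, 18.5, 25, 30, Inf),
                 labels = c("underweight", "normal", "overweight", "obese"),
                 right = FALSE)
  bmi_missing <- stats::runif(n) < 0.047
  bmi_cat[bmi_missing] <- NA
  bmi[bmi_missing] <- NA

  edu_latent <- 0.35 * z + stats::rnorm(n)
  edu_cuts <- stats::qnorm(c(0.14, 0.39, 0.75), sd = sqrt(1 + 0.35^2))
  education <- cut(edu_latent, c(-Inf, edu_cuts, Inf),
                   labels = c("unskilled", "skilled", "medium", "high"))

  lact_latent <- 0.2 * z + stats::rnorm(n)
  lact_cuts <- stats::qnorm(c(0.31, 0.51), sd = sqrt(1 + 0.2^2))
  lactation <- cut(lact_latent, c(-Inf, lact_cuts, Inf),
                   labels = c("<=1m", "2-6m", ">=7m"))

  smoke_latent <- -0.15 * z + stats::rnorm(n)
  smoke_cuts <- stats::qnorm(c(0.79, 0.89), sd = sqrt(1 + 0.15^2))
  smoking <- cut(smoke_latent, c(-Inf, smoke_cuts, Inf),
                 labels = c("never", "occasionally", "daily"))

  parous <- stats::runif(n) < stats::plogis(0.04 - 0.12 * z)
  parity <- ifelse(!parous, "0", ifelse(stats::runif(n) < 0.6, "1", "2+"))

  d <- tibble::tibble(
    maternal_age = age,
    maternal_bmi = bmi,
    maternal_bmi_cat = bmi_cat,
    education = education,
    lactation = lactation,
    smoking = smoking,
    parity = factor(parity, levels = c("0", "1", "2+")),
    physical_activity = factor(
      ifelse(stats::runif(n) < stats::plogis(stats::qlogis(0.09) + 0.3 * z),
             ">=4h", "<4h"), levels = c("<4h", ">=4h")),
    alcohol = factor(ifelse(stats::runif(n) < 0.47, "yes", "no"),
                     levels = c("no", "yes")),
    offspring_sex = factor(ifelse(stats::runif(n) < 0.526, "girl", "boy"),
                           levels = c("boy", "girl"))
  )
  # sprinkle the low levels of covariate missingness seen in practice
  for (col in c("smoking", "physical_activity", "parity")) {
    d[[col]][stats::runif(n) < 0.01] <- NA
  }
  d$maternal_age[stats::runif(n) < 0.0002] <- NA
  d
}

#' Inject exclusion-violating rows into a cohort
#'
#' Overwrites disjoint randomly chosen rows so that each genuinely violates
#' one exclusion filter: implausible maternal energy (drawn below 2,500 or
#' above 25,000 kJ/day), multiple birth, or offspring age of 15. Filters,
#' not flags, then drive [apply_exclusions()].
#'
#' @param data Cohort tibble.
#' @param preset Named counts as from [paper_flow_preset()] (the `total`
#'   element, if present, is ignored here).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The modified tibble.
#' @export
inject_exclusions <- function(data, preset, seed = NULL) {
  run_seeded(seed, {
    counts <- preset[setdiff(names(preset), "total")]
    total_inject <- sum(unlist(counts))
    if (total_inject > nrow(data)) {
      stop("exclusion preset asks for more rows than the table has", call. = FALSE)
    }
    rows <- sample(nrow(data), total_inject)
    split_rows <- split(rows, rep(names(counts), unlist(counts)))
    if (!is.null(split_rows$implausible_energy)) {
      i <- split_rows$implausible_energy
      low <- stats::runif(length(i)) < 0.5
      data$maternal_energy[i] <- ifelse(low,
                                        stats::runif(length(i), 500, 2499),
                                        stats::runif(length(i), 25001, 35000))
    }
    if (!is.null(split_rows$multiple_birth)) {
      data$multiple_birth[split_rows$multiple_birth] <- TRUE
    }
    if (!is.null(split_rows$age_ge_15)) {
      data$offspring_age[split_rows$age_ge_15] <- 15
    }
    unknown <- setdiff(names(counts),
                       c("implausible_energy", "multiple_birth", "age_ge_15"))
    if (length(unknown) > 0) {
      stop("unknown exclusion preset entries: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    data
  })
}

#' Simulate paired diet-quality scores directly from a bivariate normal
#'
#' Fast path bypassing component-level generation: draws mother and
#' offspring total scores from a bivariate normal with the given
#' correlation, means and SDs. Used for statistical-property checks of the
#' quartile/risk-ratio machinery.
#'
#' @param n Number of pairs.
#' @param rho Correlation of the pair.
#' @param means,sds Length-2 numeric vectors (mother, offspring).
#' @param seed Optional integer seed.
#' @return Tibble with columns `maternal_hei` and `offspring_hei`.
#' @export
#' @examples
#' d <- simulate_bivariate_scores(1000, rho = 0.22, seed = 1)
#' cor(d$maternal_hei, d$offspring_hei)
simulate_bivariate_scores <- function(n, rho, means = c(24, 24), sds = c(7, 9),
                                      seed = NULL) {
  stopifnot(rho >= -1, rho <= 1)
  if (any(sds <= 0)) stop("sds must be positive", call. = FALSE)
  run_seeded(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    tibble::tibble(maternal_hei = means[1] + sds[1] * z1,
                   offspring_hei = means[2] + sds[2] * z2)
  })
}

#' Quartile-ranked top-quartile risk ratio from paired scores
#'
#' Ranks both scores into quartiles of the sample and fits the unadjusted
#' log-binomial model of the offspring being in the top quartile across
#' maternal quartiles -- the primary analysis of the pipeline in one call.
#'
#' @param data Tibble with the two score columns.
#' @param maternal,offspring Score column names.
#' @return An `rr_fit` object (see [fit_log_binomial()]).
#' @export
#' @examples
#' d <- simulate_bivariate_scores(5000, rho = 0.22, seed = 1)
#' tidy(quartile_rr(d))
quartile_rr <- function(data, maternal = "maternal_hei",
                        offspring = "offspring_hei") {
  data <- tibble::as_tibble(data)
  data$maternal_quartile <- assign_quartiles(data[[maternal]])
  data$offspring_top_q <- assign_quartiles(data[[offspring]]) == "Q4"
  fit_log_binomial(data, outcome = "offspring_top_q",
                   exposure = "maternal_quartile")
}

#' Analytic quartile risk ratio under a bivariate normal
#'
#' Computes, by one-dimensional Gaussian quadrature, the probability that
#' the offspring score exceeds its 75th percentile given the maternal score
#' lies in its top versus bottom quartile, for a bivariate normal with
#' correlation `rho`; their ratio is the population analogue of the
#' quartile-ranked risk ratio and serves as the reference value for
#' simulation checks.
#'
#' @param rho Correlation in (-1, 1).
#' @return The risk ratio P(Y in Q4 | X in Q4) / P(Y in Q4 | X in Q1).
#' @export
#' @examples
#' bvn_quartile_rr(0.22)
bvn_quartile_rr <- function(rho) {
  stopifnot(rho > -1, rho < 1)
  a <- stats::qnorm(0.75)
  p_cond <- function(lo, hi) {
    f <- function(x) {
      stats::dnorm(x) *
        stats::pnorm((a - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
    }
    stats::integrate(f, lo, hi, rel.tol = 1e-10)$value /
      (stats::pnorm(hi) - stats::pnorm(lo))
  }
  p_cond(a, Inf) / p_cond(-Inf, stats::qnorm(0.25))
}
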