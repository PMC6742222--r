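#' Express a nutrient mass as percent of total energy
#'
#' Converts a daily nutrient mass to its share of total energy intake
#' (E%), the basis on which the saturated-fat and added-sugar components
#' are scored.
#'
#' @param mass Nutrient intake in g/day.
#' @param energy_factor Energy density of the nutrient in kJ/g (see
#'   [hei_energy_factors()]).
#' @param energy Total energy intake in kJ/day; must be positive.
#' @return Numeric vector of E% values (`100 * mass * energy_factor / energy`).
#' @export
#' @examples
#' energy_percent(27, 37, 10000)   # saturated fat just under 10 E%
energy_percent <- function(mass, energy_factor, energy) {
  if (any(!is.finite(energy) | energy <= 0)) {
    bad <- which(!is.finite(energy) | energy <= 0)
    stop("total energy must be positive to compute an energy percentage ",
         "(offending row(s): ", paste(utils::head(bad, 5), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(energy_factor <= 0)) stop("energy_factor must be positive", call. = FALSE)
  100 * mass * energy_factor / energy
}

#' Continuous component scoring between two cutoffs
#'
#' Linear interpolation between the zero-point (0 points) and the
#' full-point (10 points) of a component rule, clamped to \[0, 10\].
#' Values at or beyond the full-point in the favourable direction score 10;
#' values at or beyond the zero-point score 0. Works for both adequacy
#' rules (`full_point > zero_point`) and moderation rules
#' (`full_point < zero_point`); the formula
#' `10 * (value - zero_point) / (full_point - zero_point)` covers both.
#'
#' @param value Intake on the rule's basis (vectorised).
#' @param zero_point Intake scoring 0 points.
#' @param full_point Intake scoring 10 points.
#' @return Numeric vector of points in \[0, 10\].
#' @export
#' @examples
#' score_linear(350, 500, 200)  # red meat midway between cutoffs -> 5
#' score_linear(30, 0, 30)      # fibre at the full-point -> 10
score_linear <- function(value, zero_point, full_point) {
  pmin(10, pmax(0, 10 * (value - zero_point) / (full_point - zero_point)))
}

#' Score the combined fruit-and-vegetable component
#'
#' The component is scored on the fruit + vegetable sum; if fruit intake
#' exceeds vegetable intake the score is multiplied by 0.5 (the guideline
#' asks that at least half of the combined total be vegetables). Halving
#' is applied after clamping, so the maximum attainable score with
#' fruit > vegetables is 5.
#'
#' @param fruit,vegetables Intakes in g/day (vectorised).
#' @param zero_point,full_point Component cutoffs in g/day (defaults: 0 and
#'   600, the Danish HEI rule).
#' @return A tibble with columns `points` and `halved`.
#' @export
#' @examples
#' score_fruit_veg(300, 300)  # 10 points, not halved
#' score_fruit_veg(200, 100)  # 5 points halved to 2.5
score_fruit_veg <- function(fruit, vegetables, zero_point = 0, full_point = 600) {
  stopifnot(all(fruit >= 0), all(vegetables >= 0))
  base <- score_linear(fruit + vegetables, zero_point, full_point)
  halved <- fruit > vegetables
  tibble::tibble(points = ifelse(halved, 0.5 * base, base), halved = halved)
}

# columns an intake table must provide for each component under the
# gram-mass route (E% components may instead supply <component>_epct)
component_input_cols <- function(component) {
  switch(component,
    fruit_veg   = c("fruit", "vegetables"),
    sfa         = "sfa",
    added_sugar = "added_sugar",
    component
  )
}

#' Score intake profiles with a Healthy Eating Index
#'
#' Scores each row of an intake table on every component of the index and
#' sums the component points into a total. Columns must be expressed on the
#' rules' bases already (weekly components in g/week; see
#' [read_intake_csv()] for declared-unit conversion). Energy-percent
#' components are computed from gram masses (`sfa`, `added_sugar` in g/day)
#' together with `energy` (kJ/day) via [energy_percent()]; alternatively a
#' precomputed `sfa_epct` / `added_sugar_epct` column is used directly when
#' present.
#'
#' Rows with a missing value in any required column are dropped from the
#' result with a warning naming the subjects; they are never silently
#' scored as zero.
#'
#' @param data Tibble of intake profiles: `subject_id`, `fruit`,
#'   `vegetables`, `dietary_fibre` (g/day), `fish`, `red_meat`, `ssb`
#'   (g/week), `sfa`, `added_sugar` (g/day), `sodium` (g/day), `energy`
#'   (kJ/day).
#' @param index Component-rule tibble; defaults to [hei_components()].
#' @param energy_factors Named kJ/g factors; defaults to
#'   [hei_energy_factors()].
#' @return A tibble of class `hei_tbl`: `subject_id`, one `score_<component>`
#'   column per component, `fv_halved`, and `hei_total` in \[0, 80\].
#' @export
#' @examples
#' profiles <- tibble::tibble(
#'   subject_id = "a", fruit = 150, vegetables = 250, dietary_fibre = 28,
#'   fish = 200, red_meat = 400, sfa = 25, sodium = 3.1, ssb = 1200,
#'   added_sugar = 40, energy = 10500
#' )
#' hei_score(profiles)
hei_score <- function(data, index = hei_components(),
                      energy_factors = hei_energy_factors()) {
  validate_index(index)
  data <- tibble::as_tibble(data)
  if (!"subject_id" %in% names(data)) {
    data$subject_id <- seq_len(nrow(data))
  }

  needed <- unique(unlist(lapply(index$component, function(comp) {
    if (index$basis[index$component == comp] == "energy_percent" &&
        paste0(comp, "_epct") %in% names(data)) {
      paste0(comp, "_epct")
    } else {
      cols <- component_input_cols(comp)
      if (index$basis[index$component == comp] == "energy_percent") c(cols, "energy") else cols
    }
  })))
  absent <- setdiff(needed, names(data))
  if (length(absent) > 0) {
    stop("intake table lacks required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  neg <- intersect(needed, names(data))
  for (col in neg) {
    if (any(data[[col]] < 0, na.rm = TRUE)) {
      stop("negative intake in column '", col, "'", call. = FALSE)
    }
  }

  complete <- stats::complete.cases(data[needed])
  if (!all(complete)) {
    warning(sum(!complete), " profile(s) skipped for missing intake fields: ",
            paste(utils::head(data$subject_id[!complete], 5), collapse = ", "),
            call. = FALSE)
    data <- data[complete, ]
  }

  out <- tibble::tibble(subject_id = data$subject_id)
  out$fv_halved <- FALSE
  for (i in seq_len(nrow(index))) {
    comp <- index$component[i]
    if (comp == "fruit_veg") {
      fv <- score_fruit_veg(data$fruit, data$vegetables,
                            index$zero_point[i], index$full_point[i])
      pts <- fv$points
      out$fv_halved <- fv$halved
    } else {
      value <- if (index$basis[i] == "energy_percent") {
        if (paste0(comp, "_epct") %in% names(data)) {
          data[[paste0(comp, "_epct")]]
        } else {
          energy_percent(data[[comp]], energy_factors[[comp]], data$energy)
        }
      } else {
        data[[comp]]
      }
      pts <- score_linear(value, index$zero_point[i], index$full_point[i])
    }
    out[[paste0("score_", comp)]] <- pts
  }
  score_cols <- paste0("score_", index$component)
  out$hei_total <- rowSums(out[score_cols])
  out <- out[c("subject_id", score_cols, "fv_halved", "hei_total")]
  class(out) <- c("hei_tbl", class(out))
  out
}

#' Histogram of total index scores
#'
#' @param object A scored table from [hei_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hei_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hei_total)) +
    ggplot2::geom_histogram(binwidth = 2, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Healthy Eating Index total (0-80 points)", y = "subjects") +
    ggplot2::theme_minimal()
}
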