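#' The Danish Healthy Eating Index component definitions
#'
#' Returns the eight component rules of the Danish HEI as a tibble, one row
#' per component. Each component is scored continuously between a zero-point
#' (0 points) and a full-point (10 points) on its own basis:
#'
#' | component       | direction  | 0 points  | 10 points | basis            |
#' |-----------------|------------|-----------|-----------|------------------|
#' | fruit_veg       | adequacy   | 0 g/d     | 600 g/d   | grams, daily     |
#' | dietary_fibre   | adequacy   | 0 g/d     | 30 g/d    | grams, daily     |
#' | fish            | adequacy   | 0 g/wk    | 350 g/wk  | grams, weekly    |
#' | red_meat        | moderation | 500 g/wk  | 200 g/wk  | grams, weekly    |
#' | sfa             | moderation | 10 E%     | 0 E%      | percent of energy|
#' | sodium          | moderation | 2.4 g/d   | 1.6 g/d   | grams, daily     |
#' | ssb             | moderation | 500 g/wk  | 0 g/wk    | grams, weekly    |
#' | added_sugar     | moderation | 10 E%     | 0 E%      | percent of energy|
#'
#' Adequacy components score upward with intake, moderation components
#' downward. The fruit-and-vegetable component carries an extra rule: when
#' fruit intake exceeds vegetable intake the component score is halved
#' (vegetables should make up at least half of the combined total). The
#' total over the eight components ranges from 0 to 80 points.
#'
#' @return A tibble with columns `component`, `direction` ("adequacy" or
#'   "moderation"), `zero_point`, `full_point`, `basis` ("grams" or
#'   "energy_percent"), and `period` ("day" or "week").
#' @seealso [hei_score()], [score_linear()], [hei_index_write()]
#' @export
#' @examples
#' hei_components()
hei_components <- function() {
  tibble::tribble(
    ~component,      ~direction,   ~zero_point, ~full_point, ~basis,           ~period,
    "fruit_veg",     "adequacy",   0,           600,         "grams",          "day",
    "dietary_fibre", "adequacy",   0,           30,          "grams",          "day",
    "fish",          "adequacy",   0,           350,         "grams",          "week",
    "red_meat",      "moderation", 500,         200,         "grams",          "week",
    "sfa",           "moderation", 10,          0,           "energy_percent", "day",
    "sodium",        "moderation", 2.4,         1.6,         "grams",          "day",
    "ssb",           "moderation", 500,         0,           "grams",          "week",
    "added_sugar",   "moderation", 10,          0,           "energy_percent", "day"
  )
}

#' Energy conversion factors for energy-percent components
#'
#' Gram-to-kilojoule factors used to express a nutrient mass as a percent of
#' total energy intake. Defaults follow the Nordic convention: fat (hence
#' saturated fat) 37 kJ/g, carbohydrate (hence added sugar) 17 kJ/g, protein
#' 17 kJ/g. Pass a modified copy to [hei_score()] to use alternative
#' (e.g. Atwater kcal-derived) factors.
#'
#' @return Named numeric vector of kJ/g factors with entries `fat`, `sfa`,
#'   `carbohydrate`, `added_sugar`, `protein`.
#' @export
#' @examples
#' hei_energy_factors()
hei_energy_factors <- function() {
  c(fat = 37, sfa = 37, carbohydrate = 17, added_sugar = 17, protein = 17)
}

# validate a rules tibble; stops with an informative error
validate_index <- function(index) {
  stopifnot(is.data.frame(index))
  needed <- c("component", "direction", "zero_point", "full_point", "basis", "period")
  missing <- setdiff(needed, names(index))
  if (length(missing) > 0) {
    stop("index definition lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(index$zero_point == index$full_point)) {
    stop("component rule with zero_point == full_point is degenerate", call. = FALSE)
  }
  adequacy <- index$direction == "adequacy"
  if (any(adequacy & index$full_point <= index$zero_point)) {
    stop("adequacy components must have full_point > zero_point", call. = FALSE)
  }
  if (any(!adequacy & index$full_point >= index$zero_point)) {
    stop("moderation components must have full_point < zero_point", call. = FALSE)
  }
  invisible(index)
}

#' Read or write an index definition as YAML
#'
#' An index definition file is a YAML list with one entry per component
#' (fields `component`, `direction`, `zero_point`, `full_point`, `basis`,
#' `period`). `hei_index_write()` followed by `hei_index_read()` round-trips
#' exactly. The Danish HEI definition ships with the package at
#' `system.file("extdata", "danish_hei.yaml", package = "heicohort")`.
#'
#' @param path File path of the YAML index definition.
#' @param index A component-rule tibble as returned by [hei_components()].
#' @return `hei_index_read()` returns a component-rule tibble;
#'   `hei_index_write()` returns `path` invisibly.
#' @export
hei_index_read <- function(path) {
  raw <- yaml::read_yaml(path)
  index <- purrr::map_dfr(raw, tibble::as_tibble)
  validate_index(index)
  index
}

#' @rdname hei_index_read
#' @export
hei_index_write <- function(index, path) {
  validate_index(index)
  yaml::write_yaml(purrr::transpose(as.list(index)), path)
  invisible(path)
}
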