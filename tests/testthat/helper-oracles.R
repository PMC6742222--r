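# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force piecewise-linear component score: walk a fine grid and
# interpolate, treating adequacy and moderation segments explicitly
oracle_component_score <- function(value, zero_point, full_point) {
  lo <- min(zero_point, full_point)
  hi <- max(zero_point, full_point)
  vapply(value, function(v) {
    if (v <= lo) {
      if (zero_point < full_point) 0 else 10
    } else if (v >= hi) {
      if (zero_point < full_point) 10 else 0
    } else {
      frac <- (v - zero_point) / (full_point - zero_point)
      10 * frac
    }
  }, numeric(1))
}

# closed-form two-group risk ratio with a Wald CI on the log scale
oracle_rr <- function(x1, n1, x2, n2, z = 1.96) {
  rr <- (x2 / n2) / (x1 / n1)
  se <- sqrt(1 / x2 - 1 / n2 + 1 / x1 - 1 / n1)
  c(rr = rr, lo = rr * exp(-z * se), hi = rr * exp(z * se))
}

# all-favourable / all-unfavourable / all-midpoint intake profiles for the
# Danish index (vegetables >= fruits so the halving rule stays off)
profile_all_favourable <- function() {
  tibble::tibble(
    subject_id = "max", fruit = 300, vegetables = 300, dietary_fibre = 35,
    fish = 400, red_meat = 100, sfa = 0, sodium = 1.0, ssb = 0,
    added_sugar = 0, energy = 10000
  )
}

profile_all_unfavourable <- function() {
  # at/beyond every zero-point: 10 MJ/day energy, SFA/added sugar at 10 E%
  tibble::tibble(
    subject_id = "min", fruit = 0, vegetables = 0, dietary_fibre = 0,
    fish = 0, red_meat = 600, sfa = 10 * 10000 / (100 * 37),
    sodium = 3.0, ssb = 700, added_sugar = 10 * 10000 / (100 * 17),
    energy = 10000
  )
}

profile_all_midpoint <- function() {
  # exactly halfway between every pair of cutoffs; vegetables >= fruits
  tibble::tibble(
    subject_id = "mid", fruit = 100, vegetables = 200, dietary_fibre = 15,
    fish = 175, red_meat = 350, sfa = 5 * 10000 / (100 * 37),
    sodium = 2.0, ssb = 250, added_sugar = 5 * 10000 / (100 * 17),
    energy = 10000
  )
}

# random valid intake table for property tests
random_intakes <- function(n) {
  tibble::tibble(
    subject_id = seq_len(n),
    fruit = runif(n, 0, 500), vegetables = runif(n, 0, 500),
    dietary_fibre = runif(n, 0, 50), fish = runif(n, 0, 600),
    red_meat = runif(n, 0, 900), sfa = runif(n, 0, 60),
    sodium = runif(n, 0, 6), ssb = runif(n, 0, 3000),
    added_sugar = runif(n, 0, 120), energy = runif(n, 4000, 20000)
  )
}
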