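# Shared fixtures, built once per test run.

# small default-condition simulation used by several files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_omop(sim_config(n_persons = 250L, rng_seed = 7L))
    }
    cache
  }
})

# noise-free simulation: constant 0 refill gaps, no planted exclusions
noise_free_config <- function(n = 150L, seed = 11L, ...) {
  sim_config(n_persons = n, rng_seed = seed,
             gap_probs = c("0" = 1),
             exclusion_fractions = c(no_prior_history = 0,
                                     discontinuous = 0, age = 0,
                                     surgery = 0, pregnancy = 0, hcg = 0,
                                     no_baseline_bp = 0),
             ...)
}

# a tiny hand-built bundle: 3 persons, simple refill chains
toy_bundle <- function() {
  persons <- data.frame(person_id = 1:3, sex = c("M", "F", "F"),
                        birth_year = c(1950L, 1960L, 1945L),
                        race_flag = FALSE)
  de <- data.frame(
    person_id = c(rep(1L, 3), rep(2L, 2)),
    ingredient = c("losartan", "losartan", "losartan",
                   "amlodipine", "amlodipine"),
    drug_class = c("ARB", "ARB", "ARB", "CCB", "CCB"),
    daily_dose = c(50, 50, 50, 5, 5),
    start_day = c(400L, 430L, 460L, 500L, 531L),
    end_day = c(429L, 459L, 489L, 530L, 560L))
  meas <- data.frame(person_id = c(1L, 2L),
                     analyte = c("SBP", "SBP"),
                     value = c(135, 142), unit = "mmHg",
                     day = c(390L, 480L))
  omop_bundle(persons, de, measurements = meas)
}

# brute-force day-grid oracle: covered days and max uncovered run
day_grid_oracle <- function(starts, ends, lo, hi) {
  grid <- rep(FALSE, hi - lo + 1L)
  for (k in seq_along(starts)) {
    s <- max(starts[k], lo); e <- min(ends[k], hi)
    if (s <= e) grid[(s - lo + 1L):(e - lo + 1L)] <- TRUE
  }
  cov <- sum(grid)
  runs <- rle(grid)
  inner <- if (length(runs$values) > 2L) {
    keep <- !runs$values
    if (runs$values[1L] == FALSE) keep[1L] <- FALSE
    if (runs$values[length(runs$values)] == FALSE) {
      keep[length(keep)] <- FALSE
    }
    runs$lengths[keep]
  } else integer()
  list(coverage = cov,
       max_gap = if (length(inner)) max(inner) else 0L,
       grid = grid)
}
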