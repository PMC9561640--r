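mk_exp <- function(start, end, ing = "losartan", cls = "ARB", dose = 50) {
  data.frame(ingredient = ing, drug_class = cls, daily_dose = dose,
             start_day = as.integer(start), end_day = as.integer(end))
}

test_that("the index date is the first prescription with enough history", {
  expect_equal(find_index_date(mk_exp(400, 429), 0L), 400L)
  expect_true(is.na(find_index_date(mk_exp(100, 129), 0L)))
  two <- rbind(mk_exp(200, 229), mk_exp(500, 529))
  expect_equal(find_index_date(two, 0L), 500L)
  expect_true(is.na(find_index_date(mk_exp(0, 9)[0, ], 0L)))
})

test_that("continuity uses the day-grid union and the gap rule", {
  # one exposure spanning the whole window
  full <- assess_continuity(mk_exp(0, 1095), 0L, 1095L)
  expect_equal(full$coverage_days, 1096L)
  expect_equal(full$max_gap_days, 0L)
  expect_true(full$continuous)

  # ample coverage but one 31-day holiday: not continuous
  gap31 <- rbind(mk_exp(0, 500), mk_exp(532, 1095))
  g <- assess_continuity(gap31, 0L, 1095L)
  expect_gt(g$coverage_days, 875L)
  expect_equal(g$max_gap_days, 31L)
  expect_false(g$continuous)

  # 36 refills of 25 days with 5-day holidays: coverage 900, continuous
  starts <- (0:35) * 30L
  refills <- mk_exp(starts, starts + 24L)
  r <- assess_continuity(refills, 0L, 1095L)
  expect_equal(r$coverage_days, 900L)
  expect_equal(r$max_gap_days, 5L)
  expect_true(r$continuous)

  # empty exposures
  e <- assess_continuity(mk_exp(0, 1)[0, ], 0L, 1095L)
  expect_equal(e$coverage_days, 0L)
  expect_false(e$continuous)
})

test_that("continuity agrees with the brute-force day-grid oracle", {
  set.seed(404)
  for (rep in 1:120) {
    n <- sample(1:15, 1)
    starts <- sample(0:1900, n, replace = TRUE)
    lens <- sample(1:200, n, replace = TRUE)
    ex <- mk_exp(starts, starts + lens)
    lo <- sample(0:500, 1); hi <- lo + sample(500:1500, 1)
    got <- assess_continuity(ex, lo, hi)
    oracle <- day_grid_oracle(ex$start_day, ex$end_day, lo, hi)
    expect_equal(got$coverage_days, oracle$coverage)
    if (oracle$coverage > 0L) {
      expect_equal(got$max_gap_days, oracle$max_gap)
    }
  }
})

test_that("exclusion rules fire in order with exact boundaries", {
  no_cond <- data.frame(condition_category = character(), day = integer())
  bp <- data.frame(analyte = "SBP", value = 140, day = 350L)
  no_meas <- bp[0, ]
  expect_equal(apply_exclusions(17, no_cond, bp, 400L, 1495L), "age")
  expect_true(is.na(apply_exclusions(18, no_cond, bp, 400L, 1495L)))

  surg <- data.frame(condition_category = "major_surgery", day = 500L)
  expect_equal(apply_exclusions(50, surg, bp, 400L, 1495L), "surgery")
  # surgery outside the follow-up window does not fire
  surg_out <- data.frame(condition_category = "major_surgery", day = 100L)
  expect_true(is.na(apply_exclusions(50, surg_out, bp, 400L, 1495L)))

  # hCG exactly 5 passes (strictly greater required), 5.01 fails
  hcg5 <- rbind(bp, data.frame(analyte = "HCG", value = 5, day = 600L))
  expect_true(is.na(apply_exclusions(50, no_cond, hcg5, 400L, 1495L)))
  hcg51 <- rbind(bp, data.frame(analyte = "HCG", value = 5.01, day = 600L))
  expect_equal(apply_exclusions(50, no_cond, hcg51, 400L, 1495L), "hcg")

  expect_equal(apply_exclusions(50, no_cond, no_meas, 400L, 1495L),
               "no_baseline_bp")
  # age outranks surgery: first failing rule wins
  expect_equal(apply_exclusions(17, surg, no_meas, 400L, 1495L), "age")
})

test_that("group assignment requires a persisted event inside follow-up", {
  none <- data.frame(day = integer(), mode = character())
  expect_equal(assign_group(none, 0L, 1095L), "unchanged")
  one <- data.frame(day = 200L, mode = "DOSE_INCREASED")
  expect_equal(assign_group(one, 0L, 1095L), "changed")
  late <- data.frame(day = 1200L, mode = "DOSE_INCREASED")
  expect_equal(assign_group(late, 0L, 1095L), "unchanged")
})

test_that("baseline covariates respect the window and last-BP rule", {
  person <- data.frame(person_id = 1L, sex = "M", birth_year = 1950L,
                       race_flag = FALSE)
  idx <- 500L
  meas <- data.frame(analyte = c("SBP", "SBP", "DBP", "DBP"),
                     value = c(150, 140, 95, 88),
                     day = c(idx - 10L, idx - 2L, idx - 10L, idx - 2L))
  cond <- data.frame(condition_category = "diabetes", day = idx - 400L)
  cov <- build_baseline_covariates(person, meas, cond, idx,
                                   window_days = 365L)
  expect_equal(cov$sbp, 140)       # last before index, not the mean
  expect_equal(cov$dbp, 88)
  expect_null(cov$diabetes)        # outside the 365-day window
  expect_equal(cov$n_comorbidities, 0L)

  cond2 <- data.frame(condition_category = "diabetes", day = idx - 300L)
  cov2 <- build_baseline_covariates(person, meas, cond2, idx,
                                    window_days = 365L)
  expect_equal(cov2$diabetes, 1L)
  expect_equal(cov2$n_comorbidities, 1L)

  # age from anchor + index day year
  expect_equal(cov$age,
               as.integer(format(as.Date("2010-01-01") + idx, "%Y")) -
                 1950L)
  # rx: tokens become rx_ covariates and count as concomitant medications
  cond3 <- rbind(cond2, data.frame(condition_category = "rx:nsaids",
                                   day = idx - 100L))
  cov3 <- build_baseline_covariates(person, meas, cond3, idx, 365L)
  expect_equal(cov3$rx_nsaids, 1L)
  expect_equal(cov3$n_concomitant_meds, 1L)
})

test_that("tightening continuity parameters never grows the cohort", {
  sim <- shared_sim()
  base <- build_cohort(sim$bundle)
  tighter_gap <- build_cohort(sim$bundle, gap_tolerance = 3L)
  higher_floor <- build_cohort(sim$bundle, min_coverage = 1000L)
  expect_lte(nrow(tighter_gap), nrow(base))
  expect_lte(nrow(higher_floor), nrow(base))
})

test_that("attrition telescopes and groups match truth on default data", {
  sim <- shared_sim()
  co <- build_cohort(sim$bundle)
  at <- attrition_table(co)
  drops <- at$n[grepl("^excluded_", at$stage)]
  expect_equal(at$remaining[1L] - cumsum(drops),
               at$remaining[2:(length(drops) + 1L)])
  expect_equal(at$n[at$stage == "eligible"], nrow(co))

  tp <- sim$truth$persons
  m <- merge(as.data.frame(co)[, c("person_id", "group")],
             tp[, c("person_id", "changed")], by = "person_id")
  expect_equal(m$group == "changed", m$changed)
})

test_that("noise-free planted events are recovered exactly", {
  sim <- simulate_omop(noise_free_config(n = 120L, seed = 31L))
  co <- build_cohort(sim$bundle)
  expect_equal(nrow(co), 120L)
  det <- attr(co, "changes")
  pl <- sim$truth$changes
  key <- function(d) sort(paste(d$person_id, d$day, d$mode))
  expect_equal(key(det), key(pl))
})
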