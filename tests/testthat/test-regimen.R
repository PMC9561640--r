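mk_exp <- function(ingredient, class, dose, start, end) {
  data.frame(ingredient = ingredient, drug_class = class,
             daily_dose = dose, start_day = as.integer(start),
             end_day = as.integer(end))
}

test_that("drug eras merge across tolerable gaps and split on long ones", {
  refills <- rbind(mk_exp("losartan", "ARB", 50, 0, 29),
                   mk_exp("losartan", "ARB", 50, 35, 64))
  eras <- build_drug_eras(refills)
  expect_equal(nrow(eras), 1L)
  expect_equal(c(eras$start_day, eras$end_day), c(0L, 64L))

  refills2 <- rbind(mk_exp("losartan", "ARB", 50, 0, 29),
                    mk_exp("losartan", "ARB", 50, 65, 94))
  expect_equal(nrow(build_drug_eras(refills2)), 2L)

  # different doses never merge
  refills3 <- rbind(mk_exp("losartan", "ARB", 50, 0, 29),
                    mk_exp("losartan", "ARB", 100, 30, 59))
  expect_equal(nrow(build_drug_eras(refills3)), 2L)

  expect_error(build_drug_eras(mk_exp("a", "ARB", -1, 0, 10)), "negative")
})

test_that("era construction matches the day-grid oracle on random sets", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    starts <- sample(0:1900, n, replace = TRUE)
    lens <- sample(1:120, n, replace = TRUE)
    refills <- mk_exp("x", "ARB", 10, starts, pmin(starts + lens, 1999))
    eras <- build_drug_eras(refills, gap_tolerance = 0L)
    oracle <- day_grid_oracle(refills$start_day, refills$end_day, 0, 1999)
    # same covered day set
    grid2 <- rep(FALSE, 2000)
    for (k in seq_len(nrow(eras))) {
      grid2[(eras$start_day[k] + 1L):(eras$end_day[k] + 1L)] <- TRUE
    }
    expect_identical(grid2, oracle$grid)
  }
})

test_that("regimens partition the window and match pointwise membership", {
  eras <- rbind(mk_exp("losartan", "ARB", 50, 0, 500),
                mk_exp("amlodipine", "CCB", 5, 300, 1095))
  regs <- derive_regimens(eras, 0, 1095)
  expect_equal(length(regs), 3L)
  expect_equal(vapply(regs, `[[`, numeric(1), "start"), c(0, 300, 501))
  expect_equal(vapply(regs, `[[`, numeric(1), "end"), c(299, 500, 1095))
  expect_equal(vapply(regs, `[[`, character(1), "label"),
               c("ARB", "ARB+CCB", "CCB"))
  expect_equal(vapply(regs, `[[`, logical(1), "is_combination"),
               c(FALSE, TRUE, FALSE))

  # single era covering everything -> one monotherapy regimen
  one <- derive_regimens(mk_exp("losartan", "ARB", 50, 0, 1095), 0, 1095)
  expect_equal(length(one), 1L)
  expect_false(one[[1L]]$is_combination)
})

test_that("regimen membership equals the covering-era set at every day", {
  set.seed(303)
  drugs <- data.frame(ingredient = c("a", "b", "c", "d"),
                      drug_class = c("ARB", "CCB", "BB", "DU"),
                      daily_dose = c(50, 5, 10, 25))
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    pick <- sample(4, n, replace = TRUE)
    starts <- sample(0:900, n, replace = TRUE)
    lens <- sample(30:400, n, replace = TRUE)
    eras <- data.frame(ingredient = drugs$ingredient[pick],
                       drug_class = drugs$drug_class[pick],
                       daily_dose = drugs$daily_dose[pick],
                       start_day = starts,
                       end_day = pmin(starts + lens, 1000L))
    eras <- build_drug_eras(eras, gap_tolerance = 0L)  # coalesce overlaps
    lo <- min(eras$start_day)
    regs <- derive_regimens(eras, lo, 1000L)
    # partition: contiguous, no overlap, covers [lo, 1000]
    ss <- vapply(regs, `[[`, numeric(1), "start")
    ee <- vapply(regs, `[[`, numeric(1), "end")
    expect_equal(ss[1], lo)
    expect_equal(ee[length(ee)], 1000)
    if (length(regs) > 1L) expect_equal(ss[-1], ee[-length(ee)] + 1)
    # pointwise: sampled days match covering eras (carry-forward on gaps)
    last_members <- NULL
    for (d in sort(sample(lo:1000, 40))) {
      covering <- eras[eras$start_day <= d & eras$end_day >= d, ]
      r <- regs[[max(which(ss <= d))]]
      got <- sort(paste(r$members$ingredient, r$members$daily_dose))
      if (nrow(covering)) {
        exp_set <- sort(unique(paste(covering$ingredient,
                                     covering$daily_dose)))
        expect_equal(got, exp_set)
      }
    }
  }
})

test_that("transient regimens are absorbed and filtering is idempotent", {
  reg <- function(start, end, ing, cls, dose) {
    members <- data.frame(ingredient = ing, drug_class = cls,
                          daily_dose = dose)
    list(start = start, end = end, members = members,
         is_combination = nrow(members) > 1L,
         label = regimen_label(cls))
  }
  r <- list(reg(0, 100, "a", "ARB", 50),
            reg(101, 120, c("a", "b"), c("ARB", "CCB"), c(50, 5)),
            reg(121, 400, "a", "ARB", 50))
  f <- filter_transient_regimens(r)
  expect_equal(length(f), 1L)
  expect_equal(c(f[[1L]]$start, f[[1L]]$end), c(0, 400))

  r2 <- list(reg(0, 100, "a", "ARB", 50),
             reg(101, 200, c("a", "b"), c("ARB", "CCB"), c(50, 5)))
  expect_equal(length(filter_transient_regimens(r2)), 2L)

  # fixpoint on random sequences
  set.seed(99)
  for (rep in 1:25) {
    cuts <- sort(sample(1:999, sample(3:10, 1)))
    bounds <- c(0, cuts, 1000)
    rr <- lapply(seq_len(length(bounds) - 1L), function(i) {
      ing <- sample(letters[1:4], sample(1:2, 1))
      reg(bounds[i] + (i > 1), bounds[i + 1L], ing,
          c(a = "ARB", b = "CCB", c = "BB", d = "DU")[ing], 10)
    })
    once <- filter_transient_regimens(rr)
    twice <- filter_transient_regimens(once)
    expect_identical(twice, once)
    expect_true(all(vapply(once[-1], function(x) x$end - x$start + 1,
                           numeric(1)) >= 30))
  }
})

test_that("change modes follow the fixed precedence rules", {
  mem <- function(ing, cls, dose) {
    data.frame(ingredient = ing, drug_class = cls, daily_dose = dose)
  }
  expect_equal(classify_change(mem("a", "ARB", 50), mem("a", "ARB", 100)),
               "DOSE_INCREASED")
  expect_equal(classify_change(mem("a", "ARB", 100), mem("a", "ARB", 50)),
               "DOSE_REDUCED")
  expect_equal(classify_change(mem("c", "CCB", 5),
                               mem(c("c", "a"), c("CCB", "ARB"), c(5, 50))),
               "MEDICATION_ADDED")
  expect_equal(classify_change(mem(c("c", "a"), c("CCB", "ARB"), c(5, 50)),
                               mem("c", "CCB", 5)),
               "MEDICATION_REMOVED")
  expect_equal(classify_change(mem("a", "ARB", 50), mem("b", "ARB", 80)),
               "CHANGED_WITHIN_CLASS")
  expect_equal(classify_change(mem("x", "BB", 10), mem("y", "CCB", 5)),
               "CHANGED_TO_DIFFERENT_CLASS")
  # mixed dose moves fall through to cross-class change
  expect_equal(classify_change(mem(c("a", "b"), c("ARB", "CCB"), c(50, 5)),
                               mem(c("a", "b"), c("ARB", "CCB"), c(100, 2.5))),
               "CHANGED_TO_DIFFERENT_CLASS")
  expect_error(classify_change(mem("a", "ARB", 50), mem("a", "ARB", 50)),
               "identical")
})

test_that("classification is total and single-valued on a 4-drug universe", {
  universe <- data.frame(ingredient = c("a1", "a2", "c1", "b1"),
                         drug_class = c("ARB", "ARB", "CCB", "BB"),
                         daily_dose = c(50, 80, 5, 10))
  subsets <- lapply(1:15, function(mask) {
    universe[as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L), ,
             drop = FALSE]
  })
  n_checked <- 0L
  for (i in seq_along(subsets)) {
    for (j in seq_along(subsets)) {
      if (i == j) next
      mode <- classify_change(subsets[[i]], subsets[[j]])
      expect_true(mode %in% CHANGE_MODES)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 15L * 14L)
})

test_that("sequences collapse dose-only changes and truncate", {
  reg <- function(ing, cls, dose) {
    list(start = 0, end = 0,
         members = data.frame(ingredient = ing, drug_class = cls,
                              daily_dose = dose),
         is_combination = length(ing) > 1, label = regimen_label(cls))
  }
  r <- list(reg("a", "ARB", 50),
            reg(c("a", "c"), c("ARB", "CCB"), c(50, 5)))
  expect_equal(extract_sequence(r), c("ARB", "ARB+CCB"))
  # a dose-only change keeps the class label: collapsed
  r2 <- list(reg("a", "ARB", 50), reg("a", "ARB", 100),
             reg("c", "CCB", 5))
  expect_equal(extract_sequence(r2), c("ARB", "CCB"))
  # truncation to max_steps, earlier labels unchanged (monotonicity)
  r7 <- lapply(1:7, function(i) {
    reg(letters[i], HTN_CLASSES[(i %% 6) + 1L], 10)
  })
  s5 <- extract_sequence(r7, 5L)
  s7 <- extract_sequence(r7, 7L)
  expect_length(s5, 5L)
  expect_equal(s7[1:5], s5)
})

test_that("initial-regimen tabulation computes row percentages", {
  cohort <- data.frame(first_regimen = c("ARB", "ARB", "CCB"),
                       sex = c("M", "F", "M"))
  tab <- tabulate_initial_regimens(cohort, "sex")
  overall <- tab[tab$stratum == "(overall)", ]
  expect_equal(overall$n[overall$regimen == "ARB"], 2L)
  expect_equal(overall$pct[overall$regimen == "ARB"], 66.7)
  m <- tab[tab$stratum == "sex" & tab$level == "M", ]
  expect_equal(sort(m$pct), c(50, 50))
  one <- tabulate_initial_regimens(data.frame(first_regimen = "ARB"))
  expect_equal(one$pct, 100)
  expect_error(tabulate_initial_regimens(cohort, "nope"), "unknown")
})

test_that("change-mode tabulation conserves counts", {
  ev <- data.frame(prev_label = c("ARB", "ARB", "CCB"),
                   mode = c("MEDICATION_ADDED", "DOSE_INCREASED",
                            "MEDICATION_ADDED"))
  tab <- tabulate_change_modes(ev)
  expect_equal(tab$grand_total, 3L)
  expect_equal(sum(tab$counts), nrow(ev))
  expect_equal(sum(tab$mode_totals), tab$grand_total)
  expect_equal(unname(tab$row_totals["ARB"]), 2)

  empty <- tabulate_change_modes(ev[0, ])
  expect_equal(empty$grand_total, 0L)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("sankey links conserve person flow", {
  seqs <- rep(list(c("ARB", "ARB+CCB")), 10)
  sk <- export_sankey(seqs)
  expect_equal(nrow(sk$links), 1L)
  expect_equal(sk$links$value, 10L)

  expect_equal(nrow(export_sankey(list())$nodes), 0L)

  sim_seqs <- list(c("ARB", "CCB", "BB"), c("ARB", "CCB"), c("CCB", "BB"),
                   c("ARB", "BB", "CCB"), c("ARB"))
  sk2 <- export_sankey(sim_seqs)
  # for every intermediate node, inflow <= outflow + terminations means
  # inflow equals outflow plus sequences ending there
  for (nid in sk2$nodes$id) {
    step <- sk2$nodes$step[sk2$nodes$id == nid]
    label <- sk2$nodes$label[sk2$nodes$id == nid]
    inflow <- sum(sk2$links$value[sk2$links$target == nid])
    outflow <- sum(sk2$links$value[sk2$links$source == nid])
    ends_here <- sum(vapply(sim_seqs, function(s) {
      length(s) == step && s[step] == label
    }, logical(1)))
    if (step > 1L) expect_equal(inflow, outflow + ends_here)
  }
  expect_equal(sum(vapply(sim_seqs, length, integer(1)) >= 2L),
               sum(sk2$links$value[sk2$links$source %in%
                                     sk2$nodes$id[sk2$nodes$step == 1L]]))
})
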