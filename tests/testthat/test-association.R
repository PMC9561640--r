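test_that("the crude OR is the cross-product ratio with a logistic CI", {
  est <- crude_or(3, 294, 9, 288, covariate = "insomnia")
  expect_equal(round(est$or, 2), 0.33)
  expect_true(est$ci_low <= est$or && est$or <= est$ci_high)

  est2 <- crude_or(14, 283, 9, 288)
  expect_equal(round(est2$or, 2), 1.58)

  sym <- crude_or(10, 10, 10, 10)
  expect_equal(sym$or, 1)
})

test_that("OR inversion and zero-cell handling behave", {
  set.seed(5)
  for (rep in 1:20) {
    cells <- sample(1:200, 4)
    a <- crude_or(cells[1], cells[2], cells[3], cells[4])$or
    b <- crude_or(cells[3], cells[4], cells[1], cells[2])$or
    expect_lt(abs(a * b - 1), 1e-12)
  }
  expect_error(crude_or(0, 10, 10, 10), "zero cell")
  cc <- crude_or(0, 10, 10, 10, correct = TRUE)
  expect_equal(cc$or, (0.5 * 10.5) / (10.5 * 10.5))
  expect_error(crude_or(-1, 1, 1, 1), "non-negative")
})

test_that("univariate logistic on a binary covariate equals the 2x2 OR", {
  set.seed(6)
  n <- 400
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  cohort <- data.frame(group = ifelse(y == 1, "changed", "unchanged"),
                       x = x)
  a <- sum(y == 1 & x == 1); b <- sum(y == 1 & x == 0)
  c_ <- sum(y == 0 & x == 1); d <- sum(y == 0 & x == 0)
  fit <- fit_univariate(cohort, "x")
  expect_equal(fit$or, (a * d) / (b * c_), tolerance = 1e-6)
  expect_equal(fit$or, crude_or(a, b, c_, d)$or, tolerance = 1e-6)
})

test_that("baseline comparison picks the right test", {
  cohort <- data.frame(
    group = rep(c("changed", "unchanged"), each = 50),
    age = c(rnorm(50, 60, 5), rnorm(50, 60, 5)),
    rare = c(rep(1, 2), rep(0, 48), rep(1, 1), rep(0, 49)),
    common = rbinom(100, 1, 0.5),
    const = 1)
  expect_warning(tab <- compare_baseline(cohort,
                                         c("age", "rare", "common",
                                           "const")),
                 "constant")
  expect_equal(tab$test[tab$covariate == "age"], "t")
  expect_equal(tab$test[tab$covariate == "rare"], "fisher")
  expect_equal(tab$test[tab$covariate == "common"], "chisq")
  expect_equal(tab$p_value[tab$covariate == "const"], 1)

  # identical groups: categorical p-values are 1
  mirror <- data.frame(group = rep(c("changed", "unchanged"), each = 20),
                       flag = rep(c(rep(1, 8), rep(0, 12)), 2))
  tm <- compare_baseline(mirror, "flag")
  expect_equal(tm$p_value, 1)
})

test_that("the baseline t-test holds its type-I error under the null", {
  set.seed(8)
  reps <- 400
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    cohort <- data.frame(group = rep(c("changed", "unchanged"), each = 40),
                         x = rnorm(80))
    p[r] <- compare_baseline(cohort, "x")$p_value
  }
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("propensity scores reduce to closed forms in trivial models", {
  cohort <- data.frame(group = c(rep("changed", 30), rep("unchanged", 70)),
                       x = rbinom(100, 1, 0.5))
  s0 <- fit_propensity(cohort, character())
  expect_equal(unname(unique(round(s0, 10))), 0.3)

  s1 <- fit_propensity(cohort, "x")
  expect_equal(length(unique(round(s1, 10))), 2L)
  for (v in 0:1) {
    expect_equal(unique(round(s1[cohort$x == v], 10)),
                 round(mean(cohort$group[cohort$x == v] == "changed"), 10))
  }
})

test_that("matching pairs identical score multisets perfectly", {
  scores <- c(seq(0.2, 0.8, length.out = 20),
              seq(0.2, 0.8, length.out = 20))
  group <- rep(c("changed", "unchanged"), each = 20)
  m <- match_1to1(scores, group, seed = 2)
  expect_equal(nrow(m$pairs), 20L)
  expect_equal(sum(m$pairs$distance), 0)
  expect_length(m$discarded, 0L)
  # determinism under the same seed
  m2 <- match_1to1(scores, group, seed = 2)
  expect_identical(m$pairs, m2$pairs)
})

test_that("scores outside every caliper are discarded", {
  scores <- c(0.95, 0.5, 0.51, 0.49, 0.52)
  group <- c("changed", "changed", "unchanged", "unchanged", "unchanged")
  m <- match_1to1(scores, group, caliper_sd_logit = 0.2, seed = 1)
  expect_equal(nrow(m$pairs), 1L)
  expect_true("1" %in% m$discarded)
  expect_error(match_1to1(c(0.5, 0.6), c("changed", "changed")),
               "both groups")
})

test_that("matching shrinks the imbalance of planted confounders", {
  set.seed(10)
  worse <- 0L
  for (rep in 1:10) {
    n <- 2000
    conf <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.8 * conf))
    cohort <- data.frame(group = ifelse(y == 1, "changed", "unchanged"),
                         person_id = seq_len(n), conf = conf)
    pre <- abs(smd(cohort$conf, cohort$group))
    sc <- fit_propensity(cohort, "conf")
    m <- match_1to1(sc, cohort$group, ids = as.character(cohort$person_id),
                    seed = rep)
    keep <- cohort$person_id %in%
      as.integer(c(m$pairs$changed_id, m$pairs$unchanged_id))
    post <- abs(smd(cohort$conf[keep], cohort$group[keep]))
    if (post >= pre) worse <- worse + 1L
    expect_gt(nrow(m$pairs), 0L)
  }
  expect_lte(worse, 1L)
})

test_that("stepwise selection matches the exhaustive-AIC oracle", {
  set.seed(12)
  n <- 800
  X <- as.data.frame(matrix(rbinom(n * 5, 1, 0.5), ncol = 5))
  names(X) <- paste0("x", 1:5)
  y <- rbinom(n, 1, plogis(-0.2 + 1.5 * X$x1))
  cohort <- cbind(data.frame(group = ifelse(y == 1, "changed",
                                            "unchanged")), X)
  sel <- stepwise_aic(cohort, names(X), interactions = FALSE)
  terms_sel <- attr(stats::terms(sel$formula), "term.labels")
  expect_true("x1" %in% terms_sel)

  # exhaustive enumeration of all 32 main-effect subsets
  best_aic <- Inf; best_set <- NULL
  yy <- as.integer(cohort$group == "changed")
  for (mask in 0:31) {
    inc <- names(X)[as.logical(bitwAnd(mask, 2^(0:4)))]
    f <- if (length(inc)) paste("yy ~", paste(inc, collapse = "+"))
    else "yy ~ 1"
    a <- stats::AIC(stats::glm(stats::as.formula(f),
                               family = stats::binomial(),
                               data = cbind(data.frame(yy = yy), X)))
    if (a < best_aic) { best_aic <- a; best_set <- inc }
  }
  expect_equal(sort(terms_sel), sort(best_set))
  expect_equal(sel$aic, best_aic, tolerance = 1e-8)

  # endpoint AIC never exceeds the full or the null model's
  full <- stats::AIC(stats::glm(yy ~ ., family = stats::binomial(),
                                data = cbind(data.frame(yy = yy), X)))
  null <- stats::AIC(stats::glm(yy ~ 1, family = stats::binomial(),
                                data = data.frame(yy = yy)))
  expect_lte(sel$aic, full)
  expect_lte(sel$aic, null)
})

test_that("hierarchy keeps main effects under a planted interaction", {
  set.seed(13)
  n <- 1500
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 1.8 * x1 * x2))
  cohort <- data.frame(group = ifelse(y == 1, "changed", "unchanged"),
                       x1 = x1, x2 = x2)
  sel <- stepwise_aic(cohort, c("x1", "x2"), interactions = TRUE)
  terms_sel <- attr(stats::terms(sel$formula), "term.labels")
  expect_true("x1:x2" %in% terms_sel)
  expect_true(all(c("x1", "x2") %in% terms_sel))
})

test_that("adjusted estimates agree with univariate fits when orthogonal", {
  set.seed(14)
  n <- 1200
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.9 * x1 + 0 * x2))
  cohort <- data.frame(group = ifelse(y == 1, "changed", "unchanged"),
                       x1 = x1, x2 = x2)
  uni <- fit_univariate(cohort, "x1")
  fit <- stats::glm(I(group == "changed") ~ x1 + x2,
                    family = stats::binomial(), data = cohort)
  adj <- fit_multivariate(fit)
  expect_equal(log(adj$or[adj$covariate == "x1"]), log(uni$or),
               tolerance = 0.08)
  expect_true(all(adj$adjusted))
  # single-term multivariate equals the univariate fit exactly
  fit1 <- stats::glm(I(group == "changed") ~ x1,
                     family = stats::binomial(), data = cohort)
  adj1 <- fit_multivariate(fit1)
  expect_equal(adj1$or, uni$or, tolerance = 1e-10)
  expect_equal(adj1$ci_low, uni$ci_low, tolerance = 1e-6)
})

test_that("adjustment moves a confounded estimate toward the truth", {
  set.seed(15)
  n <- 4000
  conf <- rbinom(n, 1, 0.5)
  x <- rbinom(n, 1, plogis(-1 + 2 * conf))
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x + 1.2 * conf))
  cohort <- data.frame(group = ifelse(y == 1, "changed", "unchanged"),
                       x = x, conf = conf)
  crude <- log(fit_univariate(cohort, "x")$or)
  fit <- stats::glm(I(group == "changed") ~ x + conf,
                    family = stats::binomial(), data = cohort)
  adj <- log(fit_multivariate(fit)$or[1])
  expect_lt(abs(adj - 0.5), abs(crude - 0.5))
})

test_that("separation is detected and named", {
  cohort <- data.frame(group = rep(c("changed", "unchanged"), each = 20),
                       x = rep(c(1, 0), each = 20))
  expect_error(fit_univariate(cohort, "x"), "separation")
})
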