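## Association analysis: 2x2 odds ratios, baseline comparisons, propensity
## matching, logistic regression with AIC stepwise selection.

effect_row <- function(covariate, or, lo, hi, p, adjusted) {
  data.frame(covariate = covariate, or = or, ci_low = lo, ci_high = hi,
             p_value = p, adjusted = adjusted)
}

# 95% CI for a glm coefficient: profile likelihood, Wald fallback
coef_ci <- function(fit, parm, level = 0.95) {
  ci <- tryCatch(
    suppressWarnings(suppressMessages(
      stats::confint(fit, parm = parm, level = level))),
    error = function(e) NULL)
  if (is.null(ci) || anyNA(ci)) {
    est <- stats::coef(fit)[parm]
    se <- sqrt(diag(stats::vcov(fit)))[parm]
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(est - z * se, est + z * se)
  }
  as.numeric(ci)
}

check_separation <- function(fit, context) {
  cf <- stats::coef(fit)
  cf <- cf[names(cf) != "(Intercept)"]
  big <- names(cf)[!is.na(cf) & abs(cf) > 15]
  if (length(big)) {
    stop(context, ": (quasi-)separation detected for term(s) ",
         paste(big, collapse = ", "))
  }
  invisible(fit)
}

#' Crude odds ratio from a 2x2 table
#'
#' The point estimate is the cross-product ratio `(a*d)/(b*c)`; the
#' confidence interval and p-value come from the univariate logistic fit
#' of group on exposure (profile-likelihood CI with Wald fallback), which
#' has the same maximum-likelihood point estimate.
#'
#' @param a,b,c,d cell counts: (changed, exposed), (changed, unexposed),
#'   (unchanged, exposed), (unchanged, unexposed).
#' @param covariate label for the output row.
#' @param correct add 0.5 to every cell (Haldane-Anscombe) when a cell is
#'   zero; without it a zero cell is an error.
#' @param conf_level confidence level.
#' @return one-row data.frame: `covariate`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `adjusted = FALSE`.
#' @export
crude_or <- function(a, b, c, d, covariate = "exposure", correct = FALSE,
                     conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!correct) {
      stop("zero cell in 2x2 table; set correct = TRUE for the ",
           "continuity-corrected estimate")
    }
    cells <- cells + 0.5
    lo_hi <- log(cells[1] * cells[4] / (cells[2] * cells[3])) +
      c(-1, 1) * stats::qnorm(1 - (1 - conf_level) / 2) *
      sqrt(sum(1 / cells))
    est <- cells[1] * cells[4] / (cells[2] * cells[3])
    z <- log(est) / sqrt(sum(1 / cells))
    return(effect_row(covariate, est, exp(lo_hi[1]), exp(lo_hi[2]),
                      2 * stats::pnorm(-abs(z)), FALSE))
  }
  df <- data.frame(group = c(1, 1, 0, 0), exposed = c(1, 0, 1, 0),
                   w = cells)
  fit <- stats::glm(group ~ exposed, family = stats::binomial(),
                    data = df, weights = w)
  ci <- coef_ci(fit, "exposed", conf_level)
  p <- summary(fit)$coefficients["exposed", "Pr(>|z|)"]
  effect_row(covariate, (a * d) / (b * c), exp(ci[1]), exp(ci[2]), p,
             FALSE)
}

#' Compare baseline covariates between the changed and unchanged groups
#'
#' Continuous covariates are summarised as mean (SD) per group and tested
#' with a two-sample t-test; binary/categorical covariates as count (%)
#' and tested with a Pearson chi-square test, switching to Fisher's exact
#' test when any expected cell count is below 5. A covariate constant over
#' the whole cohort is reported with p = 1 and a warning.
#'
#' @param cohort data.frame with a `group` column
#'   (`"changed"`/`"unchanged"`).
#' @param covariates character vector of column names to compare.
#' @return data.frame: `covariate`, `type`, `test`, `changed`,
#'   `unchanged`, `p_value`.
#' @export
compare_baseline <- function(cohort, covariates) {
  g <- cohort$group
  if (length(unique(g)) < 2L) stop("both groups must be present")
  rows <- lapply(covariates, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("unknown covariate: ", v)
    if (length(unique(x)) == 1L) {
      warning("covariate '", v, "' is constant; p-value set to 1")
      return(data.frame(covariate = v, type = "constant", test = "none",
                        changed = as.character(x[1]),
                        unchanged = as.character(x[1]), p_value = 1))
    }
    if (is.numeric(x) && length(unique(x)) > 2L) {
      tt <- stats::t.test(x[g == "changed"], x[g == "unchanged"])
      fmt <- function(z) sprintf("%.1f ± %.1f", mean(z), stats::sd(z))
      data.frame(covariate = v, type = "continuous", test = "t",
                 changed = fmt(x[g == "changed"]),
                 unchanged = fmt(x[g == "unchanged"]),
                 p_value = tt$p.value)
    } else {
      tab <- table(factor(g, levels = c("changed", "unchanged")),
                   factor(x))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chisq"
      }
      fmt <- function(row) {
        n1 <- tab[row, ncol(tab)]
        sprintf("%d (%.1f)", n1, 100 * n1 / sum(tab[row, ]))
      }
      data.frame(covariate = v, type = "categorical", test = test,
                 changed = fmt("changed"), unchanged = fmt("unchanged"),
                 p_value = p)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the propensity-score model
#'
#' Main-effects logistic regression of group membership (changed = 1) on
#' the supplied baseline covariates; the fitted probabilities are the
#' propensity scores.
#'
#' @param cohort data.frame with `group` and the covariate columns.
#' @param covariates character vector of covariate names; empty gives the
#'   intercept-only model (all scores equal the changed prevalence).
#' @return numeric vector of scores in (0, 1), named by `person_id` when
#'   present, with the fitted `glm` attached as attribute `fit`.
#' @export
fit_propensity <- function(cohort, covariates = character()) {
  y <- as.integer(cohort$group == "changed")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ")
  else "1"
  f <- stats::as.formula(paste("y ~", rhs))
  dat <- cbind(data.frame(y = y),
               cohort[, covariates, drop = FALSE])
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(),
                                     data = dat))
  check_separation(fit, "propensity model")
  scores <- stats::fitted(fit)
  if (!is.null(cohort$person_id)) names(scores) <- cohort$person_id
  attr(scores, "fit") <- fit
  scores
}

#' Greedy 1:1 propensity-score matching
#'
#' Nearest-neighbour matching without replacement on the logit scale. The
#' smaller group drives the matching; its members are processed in
#' descending propensity order (ties broken by a seeded shuffle) and each
#' is paired with the nearest still-unmatched member of the other group
#' within the caliper. The caliper is `caliper_sd_logit` times the SD of
#' the logit scores of the whole sample.
#'
#' @param scores propensity scores from [fit_propensity()].
#' @param group character vector (`"changed"`/`"unchanged"`), same length.
#' @param ids person identifiers (defaults to score names or indices).
#' @param caliper_sd_logit caliper width in logit-score SDs; `Inf`
#'   disables the caliper.
#' @param seed integer seed for tie-breaking.
#' @return object of class `ps_match`: list with `pairs` (data.frame
#'   `changed_id`, `unchanged_id`, `distance`), `caliper`, `seed`,
#'   `discarded` (unmatched ids).
#' @export
match_1to1 <- function(scores, group, ids = NULL, caliper_sd_logit = 0.2,
                       seed = 1L) {
  stopifnot(length(scores) == length(group))
  if (!all(c("changed", "unchanged") %in% group)) {
    stop("both groups must be non-empty")
  }
  if (is.null(ids)) {
    ids <- if (!is.null(names(scores))) names(scores)
    else as.character(seq_along(scores))
  }
  lg <- stats::qlogis(pmin(pmax(as.numeric(scores), 1e-12), 1 - 1e-12))
  caliper <- caliper_sd_logit * stats::sd(lg)
  if (!is.finite(caliper) || is.na(caliper)) caliper <- Inf

  idx_c <- which(group == "changed")
  idx_u <- which(group == "unchanged")
  driver <- if (length(idx_c) <= length(idx_u)) "changed" else "unchanged"
  drv <- if (driver == "changed") idx_c else idx_u
  oth <- if (driver == "changed") idx_u else idx_c

  set.seed(seed)
  drv <- drv[sample(length(drv))]          # seeded tie-break ...
  drv <- drv[order(-lg[drv])]              # ... then descending score
  avail <- rep(TRUE, length(oth))
  pairs <- list()
  for (i in drv) {
    d <- abs(lg[oth] - lg[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      avail[j] <- FALSE
      pairs[[length(pairs) + 1L]] <-
        data.frame(driver = i, other = oth[j], distance = d[j])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(driver = integer(), other = integer(), distance = numeric())
  if (driver == "changed") {
    pm <- data.frame(changed_id = ids[pairs$driver],
                     unchanged_id = ids[pairs$other],
                     distance = pairs$distance)
  } else {
    pm <- data.frame(changed_id = ids[pairs$other],
                     unchanged_id = ids[pairs$driver],
                     distance = pairs$distance)
  }
  matched <- c(pm$changed_id, pm$unchanged_id)
  structure(list(pairs = pm, caliper = caliper, seed = seed,
                 discarded = setdiff(ids, matched)),
            class = "ps_match")
}

#' @export
print.ps_match <- function(x, ...) {
  cat(sprintf("1:1 propensity match: %d pairs, %d discarded (caliper %.4f)\n",
              nrow(x$pairs), length(x$discarded), x$caliper))
  invisible(x)
}

#' Standardized mean difference between groups
#'
#' `(mean_changed - mean_unchanged) / sqrt((var_changed + var_unchanged)/2)`;
#' the usual scale-free balance diagnostic for matching.
#'
#' @param x numeric covariate.
#' @param group character vector (`"changed"`/`"unchanged"`).
#' @return the SMD (0 when both variances vanish).
#' @export
smd <- function(x, group) {
  x1 <- x[group == "changed"]; x0 <- x[group == "unchanged"]
  s <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x1) - mean(x0)) / s
}

#' Univariate logistic association of one covariate with group
#'
#' For a binary covariate the odds ratio equals the 2x2 cross-product
#' ratio; for a continuous covariate it is per unit.
#'
#' @param cohort data.frame with `group` and the covariate.
#' @param covariate covariate column name.
#' @param conf_level confidence level (profile CI, Wald fallback).
#' @return one-row effect data.frame as in [crude_or()].
#' @export
fit_univariate <- function(cohort, covariate, conf_level = 0.95) {
  y <- as.integer(cohort$group == "changed")
  dat <- data.frame(y = y, x = cohort[[covariate]])
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     data = dat))
  check_separation(fit, paste0("univariate fit of '", covariate, "'"))
  ci <- coef_ci(fit, "x", conf_level)
  sm <- summary(fit)$coefficients
  effect_row(covariate, exp(stats::coef(fit)[["x"]]),
             exp(ci[1]), exp(ci[2]), sm["x", "Pr(>|z|)"], FALSE)
}

#' Stepwise AIC model selection over mains and pairwise interactions
#'
#' Starting from the main-effects logistic model, steps in both directions
#' between the intercept-only model and the model with all second-order
#' interactions of the main effects, choosing at each step the single-term
#' change with the lowest AIC and stopping at a local minimum. Model
#' hierarchy is enforced (an interaction can only enter with both mains
#' present, and a main cannot leave while one of its interactions stays).
#'
#' @param cohort data.frame with `group` and covariate columns.
#' @param covariates character vector of main-effect names.
#' @param interactions include the second-order interaction scope.
#' @return list with `fit` (the selected `glm`), `formula`, `aic`, and
#'   `trace` (the step log).
#' @export
stepwise_aic <- function(cohort, covariates, interactions = TRUE) {
  y <- as.integer(cohort$group == "changed")
  dat <- cbind(data.frame(y = y), cohort[, covariates, drop = FALSE])
  start <- stats::glm(
    stats::as.formula(paste("y ~", paste(covariates, collapse = " + "))),
    family = stats::binomial(), data = dat)
  upper <- if (interactions) {
    stats::as.formula(paste("~ (", paste(covariates, collapse = " + "),
                            ")^2"))
  } else {
    stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  }
  sel <- suppressWarnings(
    MASS::stepAIC(start, scope = list(lower = ~1, upper = upper),
                  direction = "both", trace = 0))
  list(fit = sel, formula = stats::formula(sel), aic = stats::AIC(sel),
       trace = sel$anova)
}

#' Adjusted odds ratios from a selected multivariate model
#'
#' Exponentiates every non-intercept coefficient with profile-likelihood
#' CIs (Wald fallback); interaction terms are reported as their own rows.
#'
#' @param fit a fitted binomial `glm` (e.g. from [stepwise_aic()]).
#' @param conf_level confidence level.
#' @return effect data.frame with `adjusted = TRUE` rows.
#' @export
fit_multivariate <- function(fit, conf_level = 0.95) {
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  rows <- lapply(terms, function(tm) {
    ci <- coef_ci(fit, tm, conf_level)
    effect_row(tm, exp(sm[tm, "Estimate"]), exp(ci[1]), exp(ci[2]),
               sm[tm, "Pr(>|z|)"], TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
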