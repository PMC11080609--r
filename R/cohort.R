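# Longitudinal and cross-sectional cohort statistics: expansion rate,
# mixed-effects EI~age model with per-group slopes and Tukey contrasts,
# correlations, residualized status comparisons, descriptive aggregates.

#' Per-individual expansion rate
#'
#' Simple linear regression of the EI values on the ages at successive
#' visits of one individual. The slope is the expansion rate (ER,
#' additional level of expansion per year); the intercept is a theoretical
#' baseline EI at birth.
#'
#' @param age,ei numeric vectors of equal length (one individual's visits).
#' @return object of class `er_result`: list with `slope`, `intercept`,
#'   `n_visits`.
#' @export
#' @examples
#' expansion_rate(c(17, 18, 33, 34), c(0.94, 0.79, 1.20, 1.20))$slope
expansion_rate <- function(age, ei) {
  stopifnot(length(age) == length(ei))
  ok <- is.finite(age) & is.finite(ei)
  age <- age[ok]; ei <- ei[ok]
  if (length(unique(age)) < 2)
    stop("insufficient data: expansion rate needs >= 2 visits at distinct ages")
  co <- stats::coef(stats::lm(ei ~ age))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 n_visits = length(age)),
            class = "er_result")
}

#' @export
print.er_result <- function(x, ...) {
  cat(sprintf("<er_result> ER = %.4f EI/year, intercept = %.4f (n = %d visits)\n",
              x$slope, x$intercept, x$n_visits))
  invisible(x)
}

#' Expansion rates for a whole visit table
#'
#' Applies [expansion_rate()] per individual. Individuals with fewer than
#' two visits at distinct ages carry no rate information and are excluded.
#'
#' @param visits data.frame with `individual_id`, `age`, `ei` and
#'   optionally `group`, `cag_n`.
#' @return data.frame with one row per retained individual: `individual_id`,
#'   `group`, `cag_n` (first visit), `slope`, `intercept`, `n_visits`.
#' @export
expansion_rates <- function(visits) {
  stopifnot(all(c("individual_id", "age", "ei") %in% names(visits)))
  rows <- lapply(split(visits, visits$individual_id), function(d) {
    d <- d[order(d$age), ]
    if (length(unique(d$age[is.finite(d$ei)])) < 2) return(NULL)
    er <- expansion_rate(d$age, d$ei)
    data.frame(individual_id = d$individual_id[1],
               group = if ("group" %in% names(d)) d$group[1] else NA_character_,
               cag_n = if ("cag_n" %in% names(d)) d$cag_n[1] else NA_real_,
               slope = er$slope, intercept = er$intercept,
               n_visits = er$n_visits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-effects model of EI over age
#'
#' Fits, by REML, `ei ~ age * cag_n * group + (1 | individual_id)` with age
#' and (CAG)n mean-centered by group on the characteristics at first visit,
#' so that per-group slopes are interpretable as the EI trend of a "mean
#' individual" of the group. The three-way interaction is tested with a
#' Type II Wald chi-square test. Per-group EI-per-year slopes (at the
#' group's mean covariates) and their pairwise Tukey-adjusted contrasts are
#' estimated from the fitted model.
#'
#' @param visits data.frame with `individual_id`, `group`, `age`, `cag_n`,
#'   `ei`.
#' @param df_method `"kenward-roger"` (default; small-sample degrees of
#'   freedom, requires pbkrtest) or `"asymptotic"` (large-sample normal).
#'   If pbkrtest is unavailable the asymptotic substitution is logged via a
#'   message. The difference is immaterial at cohort-scale n.
#' @return object of class `cag_lmm`: list with `model` (the lme4 fit),
#'   `fixed_effects`, `random_intercept_var`, `wald_interaction`
#'   (chisq/df/p), `group_slopes` (slope, SE, df, CI, p vs 0 per group),
#'   `contrasts` (Tukey-adjusted pairwise slope differences), `centering`
#'   (per-group centering table), `df_method`.
#' @export
fit_instability_lmm <- function(visits,
                                df_method = c("kenward-roger", "asymptotic")) {
  df_method <- match.arg(df_method)
  need <- c("individual_id", "group", "age", "cag_n", "ei")
  stopifnot(all(need %in% names(visits)))
  if (length(unique(visits$group)) < 2)
    stop("need >= 2 disease groups to fit the interaction model")
  if (df_method == "kenward-roger" &&
      !requireNamespace("pbkrtest", quietly = TRUE)) {
    message("pbkrtest not installed; substituting asymptotic (large-sample) df")
    df_method <- "asymptotic"
  }
  v <- visits[is.finite(visits$ei), ]
  # centering table: group means of first-visit age and (CAG)n
  first <- v[order(v$age), ]
  first <- first[!duplicated(first$individual_id), ]
  ctr <- do.call(rbind, lapply(split(first, first$group), function(d)
    data.frame(group = d$group[1], age_center = mean(d$age),
               cag_center = mean(d$cag_n), stringsAsFactors = FALSE)))
  v <- merge(v, ctr, by = "group")
  v$age_c <- v$age - v$age_center
  v$cag_c <- v$cag_n - v$cag_center
  v$group <- factor(v$group)
  fit <- lme4::lmer(ei ~ age_c * cag_c * group + (1 | individual_id),
                    data = v, REML = TRUE)
  if (lme4::isSingular(fit))
    warning("singular fit: random-intercept variance estimated at zero; ",
            "fixed effects equal pooled OLS")
  aov2 <- car::Anova(fit, type = 2, test.statistic = "Chisq")
  iw <- "age_c:cag_c:group"
  wald <- list(chisq = aov2[iw, "Chisq"], df = aov2[iw, "Df"],
               p = aov2[iw, "Pr(>Chisq)"])
  emm <- emmeans::emtrends(fit, ~group, var = "age_c", at = list(cag_c = 0),
                           lmer.df = df_method)
  slopes <- as.data.frame(summary(emm, infer = c(TRUE, TRUE)))
  names(slopes)[names(slopes) == "age_c.trend"] <- "slope"
  names(slopes)[names(slopes) == "SE"] <- "se"
  contr <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise"), adjust = "tukey",
    infer = c(TRUE, TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit,
                 fixed_effects = stats::coef(summary(fit)),
                 random_intercept_var = vc$vcov[vc$grp == "individual_id"],
                 wald_interaction = wald,
                 group_slopes = slopes,
                 contrasts = contr,
                 emtrends = emm,
                 centering = ctr,
                 df_method = df_method),
            class = "cag_lmm")
}

#' @export
print.cag_lmm <- function(x, ...) {
  cat("<cag_lmm> EI ~ age * (CAG)n * group + (1 | individual)\n")
  cat(sprintf("  three-way interaction: Wald chisq(%d) = %.1f, p = %.3g\n",
              x$wald_interaction$df, x$wald_interaction$chisq,
              x$wald_interaction$p))
  cat("  per-group EI/year slopes (at group-centered covariates):\n")
  print(x$group_slopes[, c("group", "slope", "se", "p.value")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pairwise comparison of group slopes
#'
#' Tukey-adjusted pairwise differences of the per-group EI-per-year slopes
#' of a [fit_instability_lmm()] fit (single-step studentized-range family
#' over the group estimates), using the fit's degrees-of-freedom method.
#'
#' @param fit a `cag_lmm`.
#' @return data.frame of contrasts with estimates, SEs, df, t and adjusted
#'   p-values.
#' @export
compare_group_slopes <- function(fit) {
  stopifnot(inherits(fit, "cag_lmm"))
  fit$contrasts
}

#' Pearson correlation with slope p-value
#'
#' Pearson's r plus the two-sided p-value of the regression slope (the
#' slope t-test is identical to the correlation t-test).
#'
#' @param x,y numeric vectors; pairs with non-finite entries are dropped.
#' @return list with `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("correlate needs >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Within-group OLS residuals
#'
#' Removes covariate effects separately within each disease group by
#' ordinary least squares with intercept (so residuals sum to zero within
#' group). Used to adjust EI for age and (CAG)n, and ER for (CAG)n, before
#' comparing disease statuses.
#'
#' @param values numeric response vector.
#' @param covariates data.frame of numeric covariates (same row count).
#' @param group grouping vector.
#' @return data.frame with `group` and `residual` in input order.
#' @export
residualize <- function(values, covariates, group) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(values) == nrow(covariates),
            length(values) == length(group))
  res <- rep(NA_real_, length(values))
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(i) <= ncol(covariates) + 1)
      stop("group '", g, "': n = ", length(i),
           " too small for ", ncol(covariates), " covariate(s)")
    d <- cbind(.y = values[i], covariates[i, , drop = FALSE])
    fit <- stats::lm(.y ~ ., data = d)
    co <- stats::coef(fit)
    if (anyNA(co))
      stop("rank-deficient design in group '", g, "': collinear column(s) ",
           paste(names(co)[is.na(co)], collapse = ", "))
    res[i] <- stats::residuals(fit)
  }
  data.frame(group = group, residual = res, stringsAsFactors = FALSE)
}

#' Test a quadratic age effect within groups
#'
#' Nested-model test of an added age-squared term in the within-group
#' regression of `values` on age (and any further covariates). Reported
#' only; never auto-selected into the residualization.
#'
#' @param values numeric response.
#' @param age numeric age vector.
#' @param covariates optional data.frame of further covariates.
#' @param group grouping vector.
#' @return data.frame with one row per group: `group`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
quadratic_age_test <- function(values, age, covariates = NULL, group) {
  out <- lapply(unique(group), function(g) {
    i <- which(group == g)
    base <- data.frame(.y = values[i], age = age[i])
    if (!is.null(covariates)) base <- cbind(base, covariates[i, , drop = FALSE])
    f0 <- stats::lm(.y ~ ., data = base)
    f1 <- stats::lm(.y ~ . + I(age^2), data = base)
    a <- stats::anova(f0, f1)
    data.frame(group = g, F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
               p = a$`Pr(>F)`[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare disease statuses on residual values
#'
#' Two-sided Wilcoxon rank-sum test of residual EI or ER between the two
#' status classes, separately per group. The exact distribution is used for
#' small samples without ties; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param residual numeric vector of residuals.
#' @param status two-level status vector (e.g. premanifest/manifest or
#'   preataxic/ataxic).
#' @param group optional grouping vector; a single pooled comparison when
#'   omitted.
#' @param exact_max use the exact distribution when both class sizes are at
#'   most this and there are no ties.
#' @return data.frame per group: `group`, the two class labels with sizes,
#'   `statistic` (Mann-Whitney W for the first class), `p`.
#' @export
compare_status <- function(residual, status, group = NULL, exact_max = 49) {
  if (is.null(group)) group <- rep("all", length(residual))
  lv <- sort(unique(stats::na.omit(status)))
  if (length(lv) != 2) stop("status must have exactly two levels, got: ",
                            paste(lv, collapse = ", "))
  rows <- lapply(unique(group), function(g) {
    i <- which(group == g & !is.na(status) & is.finite(residual))
    x <- residual[i][status[i] == lv[1]]
    y <- residual[i][status[i] == lv[2]]
    if (length(x) == 0 || length(y) == 0) {
      warning("group '", g, "': one status class empty, comparison skipped")
      return(NULL)
    }
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
    w <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    data.frame(group = g, class1 = lv[1], n1 = length(x),
               class2 = lv[2], n2 = length(y),
               statistic = unname(w$statistic), p = w$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Disease severity score
#'
#' SARA score divided by disease duration, in points per year. Undefined
#' (NA, with a warning) when the duration is not positive.
#'
#' @param sara SARA scores in [0, 40].
#' @param disease_duration years since onset.
#' @return numeric vector of severity values.
#' @export
severity_score <- function(sara, disease_duration) {
  stopifnot(length(sara) == length(disease_duration))
  if (any(sara < 0 | sara > 40, na.rm = TRUE))
    stop("SARA scores must lie in [0, 40]")
  bad <- !is.na(disease_duration) & disease_duration <= 0
  if (any(bad))
    warning(sum(bad), " record(s) with non-positive disease duration ",
            "flagged as undefined severity")
  out <- sara / disease_duration
  out[bad] <- NA_real_
  out
}

#' Descriptive aggregates by group
#'
#' n, mean and sample SD (n - 1 denominator) per group, reported to two
#' decimals with round-half-away-from-zero. SD is missing for singleton
#' groups.
#'
#' @param values numeric vector.
#' @param group grouping vector.
#' @param digits decimals for the report (default 2).
#' @return data.frame with `group`, `n`, `mean`, `sd`.
#' @export
#' @examples
#' describe_by_group(c(0.76, 0.77, 0.59, 0.42), rep("SCA3", 4))
describe_by_group <- function(values, group, digits = 2) {
  rows <- lapply(split(values, group), function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("empty group after removing non-finite values")
    data.frame(n = length(v),
               mean = round_half_away(mean(v), digits),
               sd = if (length(v) > 1) round_half_away(stats::sd(v), digits)
                    else NA_real_)
  })
  out <- cbind(group = names(rows), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
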