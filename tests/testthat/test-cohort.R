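test_that("expansion rate is the OLS slope of EI on age", {
  # flat series: zero rate, intercept at the common EI
  er <- expansion_rate(c(40, 50), c(0.8, 0.8))
  expect_equal(er$slope, 0)
  expect_equal(er$intercept, 0.8)
  # four-visit blood series checked against explicit normal equations
  age <- c(17, 18, 33, 34); ei <- c(0.94, 0.79, 1.20, 1.20)
  er <- expansion_rate(age, ei)
  ref <- oracle_ols(age, ei)
  expect_equal(er$slope, ref[2], tolerance = 1e-12)
  expect_equal(er$intercept, ref[1], tolerance = 1e-12)
  # translation covariance of the fitted line
  er10 <- expansion_rate(age + 10, ei)
  expect_equal(er10$slope, er$slope, tolerance = 1e-12)
  expect_equal(er10$intercept, er$intercept - 10 * er$slope,
               tolerance = 1e-12)
  expect_error(expansion_rate(c(30, 30), c(0.1, 0.2)), "insufficient")
})

test_that("cohort-level rates drop single-visit individuals", {
  visits <- data.frame(
    individual_id = c("a", "a", "b", "c", "c", "c"),
    group = c("SCA1", "SCA1", "SCA1", "SCA2", "SCA2", "SCA2"),
    cag_n = c(48, 48, 50, 40, 40, 40),
    age = c(30, 40, 35, 20, 25, 30),
    ei = c(0.5, 0.9, 0.7, 0.2, 0.4, 0.6))
  er <- expansion_rates(visits)
  expect_equal(er$individual_id, c("a", "c"))
  expect_equal(er$slope, c(0.04, 0.04), tolerance = 1e-12)
  expect_equal(er$n_visits, c(2L, 3L))
})

test_that("correlation returns Pearson r with the slope-test p-value", {
  x <- c(1, 2, 4, 7, 9)
  out <- correlate(x, 2 * x)
  expect_equal(out$r, 1, tolerance = 1e-12)
  out2 <- correlate(x, 5 - 3 * x)
  expect_equal(out2$r, -1, tolerance = 1e-12)
  # p identical to the regression slope t-test
  set.seed(9)
  y <- 0.4 * x + rnorm(5)
  out3 <- correlate(x, y)
  ref_p <- summary(lm(y ~ x))$coefficients["x", "Pr(>|t|)"]
  expect_equal(out3$p, ref_p, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate(1:2, 2:3), ">= 3")
})

test_that("independent data reject at roughly the nominal 5% level", {
  set.seed(31)
  rej <- mean(vapply(1:400, function(i)
    correlate(rnorm(74), rnorm(74))$p < 0.05, logical(1)))
  expect_gt(rej, 0.015)
  expect_lt(rej, 0.09)
})

test_that("residualization removes within-group covariate effects", {
  set.seed(5)
  g <- rep(c("A", "B"), each = 25)
  age <- runif(50, 25, 65); cag <- round(runif(50, 38, 52))
  # exact linear response: residuals vanish
  y_lin <- ifelse(g == "A", 1 + 0.2 * age - 0.1 * cag, -2 + 0.05 * age)
  r <- residualize(y_lin, data.frame(age = age, cag_n = cag), g)
  expect_equal(r$residual, rep(0, 50), tolerance = 1e-9)
  # residuals sum to zero within each group (OLS with intercept)
  y <- rnorm(50)
  r2 <- residualize(y, data.frame(age = age, cag_n = cag), g)
  expect_equal(as.numeric(tapply(r2$residual, g, sum)), c(0, 0),
               tolerance = 1e-9)
  # values already orthogonal to the covariates within each group pass
  # through unchanged up to the group mean
  ortho <- y
  for (gr in c("A", "B")) {
    i <- g == gr
    ortho[i] <- stats::residuals(lm(y[i] ~ age[i] + cag[i]))
  }
  r3 <- residualize(ortho, data.frame(age = age, cag_n = cag), g)
  expect_equal(r3$residual, ortho - ave(ortho, g), tolerance = 1e-9)
  # collinear covariates are reported by name
  expect_error(residualize(y, data.frame(age = age, age2 = 2 * age), g),
               "age2")
})

test_that("the quadratic age check reports per-group p-values", {
  set.seed(6)
  g <- rep(c("A", "B"), each = 40)
  age <- runif(80, 25, 65)
  y <- 0.02 * age + rnorm(80, 0, 0.1)
  y[g == "B"] <- y[g == "B"] + 0.004 * (age[g == "B"] - 45)^2
  q <- quadratic_age_test(y, age, group = g)
  expect_equal(q$group, c("A", "B"))
  expect_gt(q$p[1], 0.05) # no curvature simulated
  expect_lt(q$p[2], 0.01) # strong curvature simulated
})

test_that("status comparisons use the exact Wilcoxon distribution", {
  # complete separation of 5 vs 5: the most extreme of C(10,5) assignments
  res <- c(1:5, 11:15)
  status <- rep(c("preataxic", "ataxic"), each = 5)
  out <- compare_status(res, status)
  expect_equal(out$p, 2 / choose(10, 5), tolerance = 1e-12)
  # enumeration oracle across all two-group sizes with n1 + n2 <= 12
  set.seed(77)
  for (n1 in 1:6) for (n2 in n1:(12 - n1)) {
    x <- rnorm(n1); y <- rnorm(n2, 1)
    got <- compare_status(c(x, y), rep(c("a", "b"), c(n1, n2)))$p
    expect_equal(got, oracle_wilcox_p(x, y), tolerance = 1e-12,
                 label = sprintf("exact p for n1=%d n2=%d", n1, n2))
  }
  # label swap leaves the two-sided p unchanged
  out_sw <- compare_status(res, rev(status))
  expect_equal(out_sw$p, out$p, tolerance = 1e-12)
  # empty class: skipped with a warning
  expect_warning(
    none <- compare_status(c(res, 1), c(status, "ataxic"),
                           group = c(rep("g1", 10), "g2")),
    "empty")
  expect_equal(none$group, "g1")
  # ties fall back to the corrected normal approximation, silently
  expect_silent(compare_status(c(1, 1, 2, 2, 3, 3), rep(c("a", "b"), 3)))
})

test_that("severity is SARA per year of disease, guarded for zero duration", {
  expect_equal(severity_score(10, 5), 2)
  expect_equal(severity_score(0, 4), 0)
  expect_warning(s <- severity_score(c(12, 8), c(6, 0)), "non-positive")
  expect_equal(s, c(2, NA))
  expect_error(severity_score(45, 5), "\\[0, 40\\]")
})

test_that("descriptive aggregates report mean and sample SD to 2 decimals", {
  d <- describe_by_group(c(0.76, 0.77, 0.59, 0.42), rep("SCA3", 4))
  expect_equal(d$mean, 0.64)
  expect_equal(d$sd, 0.17)
  expect_equal(d$n, 4L)
  # half-away rounding visible on a two-value group
  d2 <- describe_by_group(c(1.72, 2.71), rep("SCA7", 2))
  expect_equal(d2$mean, 2.22)
  expect_equal(d2$sd, 0.70)
  # degenerate groups
  expect_equal(describe_by_group(rep(0.5, 3), rep("g", 3))$sd, 0)
  expect_true(is.na(describe_by_group(3.52, "SCA1")$sd))
})
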