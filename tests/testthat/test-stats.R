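test_that("within-group centering removes group means and zeroes controls", {
  v <- c(10, 20, 30)
  expect_equal(center_within_group(v, rep("A", 3)), c(-10, 0, 10))

  g <- c("HC", "HC", "A", "A", "B", "B")
  v <- c(NA, NA, 1, 3, 10, 30)
  expect_equal(center_within_group(v, g), c(0, 0, -1, 1, -10, 10))

  # absent patient value imputed at own group mean (centered 0)
  expect_equal(center_within_group(c(NA, 4, 8), rep("A", 3)), c(0, -2, 2))
  expect_error(center_within_group(c(NA, NA), c("A", "A")), "degenerate")
})

test_that("design matrix has the documented structure", {
  rec <- toy_records(n = 6)
  d <- build_design(rec)
  expect_equal(ncol(d$X), 1 + 4 + 5)
  expect_equal(levels(d$group)[1], "HC")
  expect_equal(d$group_cols, 2:5)
  # centered clinical covariates: per-group means 0, HC exactly 0
  for (cv in c("illness_duration", "cpz")) {
    v <- d$X[, cv]
    expect_equal(unname(v[d$group == "HC"]), rep(0, 6))
    for (g in setdiff(levels(d$group), "HC"))
      expect_lt(abs(mean(v[d$group == g])), 1e-12)
  }
  expect_false("sex" %in% colnames(d$X))
})

test_that("patient-only contrasts keep raw clinical covariates", {
  rec <- toy_records(n = 6)
  d <- build_design(rec, contrast_groups = c("OCD", "SZ"))
  raw <- rec$illness_duration_years[rec$diagnosis %in% c("OCD", "SZ")]
  expect_equal(unname(d$X[, "illness_duration"]), raw)
  expect_false(d$centered)
  # HC contrasts center
  dhc <- build_design(rec, contrast_groups = c("OCD", "HC"))
  expect_true(dhc$centered)
})

test_that("collinear designs are rejected with the offending column named", {
  rec <- toy_records(n = 6)
  rec$education_years <- rec$age_years   # inject duplicate covariate
  expect_error(build_design(rec), "collinear.*education")
})

test_that("BH adjustment matches the explicit step-up oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.25), q = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  allone <- bh_fdr(rep(1, 10))
  expect_equal(allone$p_adjusted, rep(1, 10))
  expect_false(any(allone$reject))

  set.seed(101)
  for (i in 1:25) {
    m <- sample(1:200, 1)
    p <- switch(sample(3, 1),
                runif(m),
                rbeta(m, 0.3, 4),
                round(runif(m), 2))       # ties
    q <- runif(1, 0.01, 0.2)
    got <- bh_fdr(p, q)
    want <- oracle_bh(p, q)
    expect_equal(got$p_adjusted, want$p_adjusted)
    expect_identical(got$reject, want$reject)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("FDR rejections are monotone in q", {
  set.seed(7)
  p <- rbeta(80, 0.4, 3)
  qs <- sort(runif(10, 0.01, 0.3))
  prev <- rep(FALSE, 80)
  for (q in qs) {
    rej <- bh_fdr(p, q)$reject
    expect_true(all(prev <= rej))   # lowering q never adds a rejection
    prev <- rej
  }
})

test_that("omnibus F matches the normal-equations oracle on toy data", {
  rec <- toy_records(groups = c("OCD", "SZ", "HC"), n = 7)
  set.seed(33)
  Y <- matrix(rnorm(21 * 5, mean = 3), 21, 5,
              dimnames = list(rec$subject_id, NULL))
  cfg <- analysis_config(n_points = 5)
  d <- build_design(rec, cfg)
  res <- fit_pointwise_omnibus(Y, d, cfg)
  for (i in 1:5) {
    o <- oracle_f_test(Y[d$subject_id, i], d$X, d$group_cols)
    expect_equal(res$statistic[i], o$statistic, tolerance = 1e-8)
    expect_equal(res$p_raw[i], o$p, tolerance = 1e-8)
  }
  expect_equal(unique(res$df1), 2)
  expect_equal(unique(res$df2), 21 - ncol(d$X))
})

test_that("omnibus F agrees with lm/anova and is shift invariant", {
  rec <- toy_records(n = 5)
  set.seed(44)
  Y <- matrix(rnorm(25 * 3, 3), 25, 3, dimnames = list(rec$subject_id, NULL))
  cfg <- analysis_config(n_points = 3)
  d <- build_design(rec, cfg)
  res <- fit_pointwise_omnibus(Y, d, cfg)
  for (i in 1:3) {
    df <- data.frame(y = Y[d$subject_id, i], g = d$group,
                     d$X[, d$covariate_cols])
    full <- lm(y ~ ., data = df)
    red <- lm(y ~ . - g, data = df)
    expect_equal(res$statistic[i], anova(red, full)$F[2], tolerance = 1e-10)
  }
  res2 <- fit_pointwise_omnibus(Y + 17.3, d, cfg)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-9)
})

test_that("df bookkeeping matches the full-cohort design", {
  cohort <- simulate_cohort(simulation_config(seed = 2))
  Y <- cdv_matrix(compute_profiles(cohort$contours))
  d <- build_design(cohort$records)
  res <- fit_pointwise_omnibus(Y, d)
  expect_equal(unique(res$df1), 4)
  expect_equal(unique(res$df2), 150 - 10)
})

test_that("post-hoc F equals the squared t statistic at every position", {
  cohort <- simulate_cohort(simulation_config(
    groups = c("OCD", "HC"), n_per_group = 15, seed = 6))
  Y <- cdv_matrix(compute_profiles(cohort$contours))
  res <- fit_pointwise_posthoc(Y, cohort$records, "OCD", "HC")
  d <- build_design(cohort$records, contrast_groups = c("OCD", "HC"))
  for (i in seq(1, 100, by = 7)) {
    fit <- lm(Y[d$subject_id, i] ~ d$X - 1)
    tv <- summary(fit)$coefficients["d$XdiagOCD", "t value"]
    expect_equal(res$statistic[i], tv^2, tolerance = 1e-10)
  }
  expect_equal(unique(res$df1), 1)
  expect_error(fit_pointwise_posthoc(Y, cohort$records, "HC", "HC"), "differ")
})

test_that("summary-statistics ANOVA reproduces raw-data omnibus F", {
  set.seed(55)
  g <- rep(c("A", "B", "C"), times = c(12, 15, 9))
  y <- rnorm(36, ave(seq_along(g), g))
  means <- tapply(y, g, mean); sds <- tapply(y, g, sd)
  ns <- as.vector(table(g)[names(means)])
  got <- anova_from_summary(means, sds, ns)
  want <- anova(lm(y ~ g))
  expect_equal(got$statistic, want$`F value`[1], tolerance = 1e-8)
  expect_equal(got$p_value, want$`Pr(>F)`[1], tolerance = 1e-8)

  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 2, 3), c(10, 10, 10))$statistic, 0)
  expect_error(anova_from_summary(c(1, 1), c(0, 0), c(5, 5)), "undefined")
})

test_that("adjusted means reduce to raw group means without covariates", {
  cohort <- simulate_cohort(simulation_config(
    groups = c("OCD", "HC"), n_per_group = 10, seed = 12))
  Y <- cdv_matrix(compute_profiles(cohort$contours))
  cfg0 <- analysis_config(covariates = "age")
  cfg0$covariates <- character(0)      # zero-covariate configuration
  d0 <- build_design(cohort$records, cfg0)
  adj <- adjusted_group_means(Y, d0, cfg0)
  for (g in c("OCD", "HC")) {
    raw <- colMeans(Y[cohort$records$subject_id[cohort$records$diagnosis == g], ])
    expect_equal(adj$adjusted_mean_cdv_mm[adj$group == g], unname(raw),
                 tolerance = 1e-10)
  }
})

test_that("adjusted means separate thinned groups and not null ones", {
  eff <- preset_effectmaps()$null
  eff["OCD", ] <- 0.8                  # uniform global thinning
  deltas <- sapply(1:3, function(s) {
    cohort <- simulate_cohort(simulation_config(seed = s + 400), eff)
    Y <- cdv_matrix(compute_profiles(cohort$contours))
    d <- build_design(cohort$records)
    adj <- adjusted_group_means(Y, d)
    ocd <- adj$adjusted_mean_cdv_mm[adj$group == "OCD"]
    hc <- adj$adjusted_mean_cdv_mm[adj$group == "HC"]
    mean(ocd < hc)
  })
  expect_gte(mean(deltas), 0.95)
})

test_that("noncentral-F power behaves as theory requires", {
  expect_identical(anova_power(5, 150, 0, alpha = 0.05), 0.05)
  pw <- sapply(c(100, 140, 180, 250), function(N) anova_power(5, N, 0.25))
  expect_true(all(diff(pw) > 0))
  expect_error(anova_power(5, 6, 0.2, n_covariates = 5), "degrees of freedom")
})
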