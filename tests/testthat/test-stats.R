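test_that("HOMA-IR formula matches hand arithmetic", {
  expect_identical(homa_ir(22.5, 1), 1)
  expect_equal(homa_ir(10, 5), 10 * 5 / 22.5, tolerance = 1e-15)
  expect_identical(homa_ir(0, 5), 0)
  expect_identical(homa_ir(c(22.5, 10), c(1, 5)), c(1, 10 * 5 / 22.5))
  expect_error(homa_ir(-1, 5), "non-negative")
  expect_true(is.na(homa_ir(NA, 5)))
})

test_that("group summary medians, IQRs and reference differences are exact", {
  # six-subject fixture with hand-computable order statistics
  lv <- c("NGT", "IFG", "IGT", "CGI", "T2D")
  d <- data.frame(
    glucose_group = factor(rep(c("NGT", "T2D"), each = 3), levels = lv),
    eatv_ml = c(90, 100, 120, 130, 150, 160))
  s <- summarize_groups(d, continuous = "eatv_ml", categorical = character())
  sc <- s$continuous
  expect_equal(sc$median[sc$group == "NGT"], 100)
  expect_equal(sc$median[sc$group == "T2D"], 150)
  expect_equal(sc$iqr[sc$group == "NGT"], 15)   # quantile type 7
  expect_equal(sc$diff_vs_ref[sc$group == "T2D"], 50)
  expect_true(is.na(sc$diff_vs_ref[sc$group == "NGT"]))
  # identical groups: zero difference, Kruskal-Wallis p of 1
  d2 <- data.frame(glucose_group = factor(rep(c("NGT", "IGT"), each = 4),
                                          levels = lv),
                   eatv_ml = rep(c(1, 2, 3, 4), 2))
  s2 <- summarize_groups(d2, continuous = "eatv_ml",
                         categorical = character())$continuous
  expect_identical(s2$diff_vs_ref[s2$group == "IGT"], 0)
  expect_equal(s2$p_vs_ref[s2$group == "IGT"], 1, tolerance = 1e-12)
})

test_that("kendall tau-b equals the exhaustive all-pairs oracle under ties", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(10:60, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- round(rnorm(n), sample(0:1, 1))  # induce y ties half the time
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    d <- data.frame(group_ordinal = x, v = y)
    kt <- kendall_trend(d, "v", ci_method = "normal")
    oracle <- kendall_allpairs(x, y)
    expect_equal(kt$tau, oracle$tau, tolerance = 1e-12)
    # independent cross-check against the C implementation in base R
    expect_equal(kt$tau, cor(x, y, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("kendall trend handles perfect order, constants and bootstrap CIs", {
  d <- data.frame(group_ordinal = 1:12, v = 1:12)  # no tied pairs at all
  kt <- kendall_trend(d, "v", ci_method = "normal")
  expect_equal(kt$tau, 1, tolerance = 1e-12)
  expect_lt(kt$p, 0.01)
  expect_error(kendall_trend(data.frame(group_ordinal = rep(1, 5), v = 1:5),
                             "v"), "distinct ordinal levels")
  expect_error(kendall_trend(data.frame(group_ordinal = 0:4,
                                        v = rep(2, 5)), "v"), "constant")
  set.seed(1)
  d2 <- data.frame(group_ordinal = sample(0:3, 120, TRUE),
                   v = rnorm(120))
  b1 <- kendall_trend(d2, "v", n_boot = 300, seed = 9)
  b2 <- kendall_trend(d2, "v", n_boot = 300, seed = 9)
  expect_identical(b1$ci, b2$ci)      # seeded bootstrap reproducibility
  expect_lt(b1$ci[1], b1$tau)
  expect_gt(b1$ci[2], b1$tau)
})

test_that("confounders with built-in partial effects qualify; inert ones do not", {
  coh <- generate_cohort(seed = 3)
  q <- qualify_confounders(coh)
  qualified <- attr(q, "qualified")
  expect_true(all(c("age", "sex", "smoking", "physical_activity") %in%
                    qualified))
  expect_false("lipid_med" %in% qualified)   # no built-in effect
  expect_false("alcohol" %in% qualified)
  expect_identical(nrow(qualify_confounders(coh,
                                            candidates = character())), 0L)
  expect_error(qualify_confounders(coh[0, ]), "no rows")
})

test_that("staged OLS recovers exact coefficients and the normal equations", {
  # noiseless line: slope recovered exactly
  d <- data.frame(eatv_ml = 2 + 3 * (1:10), homa_ir = 1:10)
  f <- suppressWarnings(fit_staged_models(d, "eatv", "homa_ir", models = 1))
  expect_equal(f$model1$coefficients$estimate,
               c(2, 3), tolerance = 1e-12)
  # five-row fixture against the closed-form normal equations
  set.seed(42)
  d5 <- data.frame(eatv_ml = rnorm(5, 100, 20), homa_ir = runif(5, 1, 4),
                   bmi = runif(5, 22, 33))
  f5 <- fit_staged_models(d5, "eatv", "homa_ir", models = 2)
  X <- cbind(1, d5$homa_ir, d5$bmi)
  beta <- ols_normal_equations(X, d5$eatv_ml)
  expect_equal(f5$model2$coefficients$estimate, unname(beta),
               tolerance = 1e-10)
})

test_that("model stages use the published covariate progression", {
  coh <- generate_cohort(seed = 6)
  fits <- fit_staged_models(coh, "eatv", "groups",
                            confounders = c("age", "sex"))
  expect_named(fits, paste0("model", 1:5))
  terms_of <- function(m) attr(terms(m$fit), "term.labels")
  expect_identical(terms_of(fits$model1), "glucose_group")
  expect_identical(terms_of(fits$model2), c("glucose_group", "bmi"))
  expect_identical(terms_of(fits$model3), c("glucose_group", "waist_cm"))
  expect_identical(terms_of(fits$model4), c("glucose_group", "vat_cm2"))
  expect_identical(terms_of(fits$model5),
                   c("glucose_group", "vat_cm2", "age", "sex"))
  # model 6 exists for EATA only and additionally adjusts for EATV
  f6 <- fit_staged_models(coh, "eata", "groups", confounders = "age",
                          models = 6)
  expect_identical(terms_of(f6$model6),
                   c("glucose_group", "vat_cm2", "age", "eatv_ml"))
  expect_error(fit_staged_models(coh, "eatv", "groups", models = 6),
               "only defined for the EATA outcome")
})

test_that("rank-deficient designs raise a collinearity error naming the column", {
  coh <- generate_cohort(sized_specs(200, 50, 50, 30, 20), seed = 7)
  coh$waist_cm <- coh$bmi * 2          # exact linear dependence
  fits <- fit_staged_models(coh, "eatv", "groups", models = c(2, 3))
  expect_s3_class(fits$model2, "eat_model_fit")
  coh$vat_cm2 <- coh$bmi               # duplicate under another name
  expect_error(fit_staged_models(coh, "eatv", "groups",
                                 confounders = "bmi", models = 5),
               "collinearity")
})

test_that("adding a covariate never increases the residual sum of squares", {
  coh <- generate_cohort(sized_specs(300, 80, 80, 40, 30), seed = 8)
  fits <- fit_staged_models(coh, "eatv", "groups", confounders = "age")
  rss <- function(m) sum(residuals(m$fit)^2)
  expect_lte(rss(fits$model4), rss(fits$model1) + 1e-9)
  expect_lte(rss(fits$model5), rss(fits$model4) + 1e-9)
})

test_that("complete-case n matches the missingness bookkeeping per model", {
  coh <- generate_cohort(seed = 9)
  coh <- inject_missingness(coh, c(homa_ir = 28, vat_cm2 = 4), seed = 2)
  fits <- fit_staged_models(coh, "eatv", "homa_ir", models = c(1, 4))
  expect_identical(fits$model1$n, sum(!is.na(coh$homa_ir)))
  expect_identical(fits$model4$n,
                   sum(complete.cases(coh[, c("eatv_ml", "homa_ir",
                                              "vat_cm2")])))
})

test_that("group test keeps its nominal size on null data", {
  specs <- sized_specs(80, 80, 80, 80, 80)
  for (g in names(specs)) {                 # identical marginals: no effect
    specs[[g]]$continuous <- specs[["NGT"]]$continuous
    specs[[g]]$rates <- specs[["NGT"]]$rates
  }
  rejections <- vapply(1:500, function(s) {
    coh <- generate_cohort(specs, seed = 20000 + s)
    fit <- lm(eatv_ml ~ glucose_group, data = coh)
    anova(fit)[["Pr(>F)"]][1] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("pairwise depot regressions report slope, CI and R", {
  # zero-noise linear relation: R = 1 and exact slope
  d <- data.frame(eatv_ml = seq(50, 200, length.out = 40))
  d$eata_hu <- -60 - 0.1 * d$eatv_ml
  d$vat_hu <- -80 - 0.2 * d$eatv_ml
  pr <- suppressWarnings(pairwise_regressions(d))  # zero-residual fits warn
  expect_equal(pr$B[pr$response == "eata_hu" &
                      pr$predictor == "eatv_ml"], -0.1, tolerance = 1e-12)
  expect_equal(pr$R, c(1, 1, 1), tolerance = 1e-12)
})
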