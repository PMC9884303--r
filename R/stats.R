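#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `insulin * glucose / 22.5`, with fasting insulin in uU/mL and capillary
#' glucose in mmol/L. Vectorised; `NA`s propagate; negative inputs are a
#' domain error.
#'
#' @param insulin fasting insulin (uU/mL), >= 0.
#' @param glucose fasting capillary glucose (mmol/L), >= 0.
#' @return HOMA-IR index.
#' @examples
#' homa_ir(22.5, 1)  # 1
#' homa_ir(10, 5)    # 2.2222...
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE))
    stop("insulin and glucose must be non-negative", call. = FALSE)
  insulin * glucose / 22.5
}

#' Group summaries with differences versus the reference group
#'
#' Median and IQR of each continuous variable per glucose group, the
#' difference of medians versus the reference (NGT) group, and two-group
#' Kruskal-Wallis p-values (each non-reference group against NGT, no
#' multiplicity correction). Categorical variables get a Pearson chi-square
#' test across all groups plus per-group rates.
#'
#' @param table cohort `data.frame` with a `glucose_group` factor.
#' @param continuous character vector of continuous column names.
#' @param categorical character vector of categorical column names.
#' @param ref reference group label, default `"NGT"`.
#' @return A `group_summary`: list with data frames `continuous`
#'   (`variable, group, n, median, iqr, diff_vs_ref, p_vs_ref`) and
#'   `categorical` (`variable, p_chisq`), plus `rates` (a list of
#'   per-variable proportion tables).
#' @export
summarize_groups <- function(table,
                             continuous = c("age", "homa_ir", "bmi",
                                            "waist_cm", "vat_cm2",
                                            "eatv_ml", "eata_hu"),
                             categorical = c("sex", "smoking", "education",
                                             "physical_activity", "alcohol",
                                             "season", "lipid_med"),
                             ref = "NGT") {
  stopifnot("glucose_group" %in% names(table))
  grp <- factor(table$glucose_group)
  groups <- levels(grp)
  if (!ref %in% groups) stop("reference group '", ref, "' absent",
                             call. = FALSE)
  continuous <- intersect(continuous, names(table))
  categorical <- intersect(categorical, names(table))

  cont <- do.call(rbind, lapply(continuous, function(v) {
    do.call(rbind, lapply(groups, function(glev) {
      x <- table[[v]][grp == glev]
      x <- x[!is.na(x)]
      xr <- table[[v]][grp == ref]
      xr <- xr[!is.na(xr)]
      if (length(x) == 0)
        return(data.frame(variable = v, group = glev, n = 0L,
                          median = NA_real_, iqr = NA_real_,
                          diff_vs_ref = NA_real_, p_vs_ref = NA_real_))
      med <- stats::median(x)
      dd <- if (glev == ref) NA_real_ else med - stats::median(xr)
      pv <- if (glev == ref || length(xr) == 0) NA_real_
            else kruskal.test(list(xr, x))$p.value
      data.frame(variable = v, group = glev, n = length(x), median = med,
                 iqr = IQR(x), diff_vs_ref = dd, p_vs_ref = pv)
    }))
  }))

  cat_p <- do.call(rbind, lapply(categorical, function(v) {
    tab <- table(table[[v]], grp)
    p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    data.frame(variable = v, p_chisq = p)
  }))
  rates <- lapply(setNames(categorical, categorical), function(v)
    prop.table(table(table[[v]], grp), margin = 2))

  structure(list(continuous = cont, categorical = cat_p, rates = rates,
                 ref = ref),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> reference group:", x$ref, "\n")
  print(x$continuous, row.names = FALSE, digits = 4)
  invisible(x)
}

# tie-corrected Kendall statistics: S, tau-b, variance of S
kendall_core <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least two complete observations", call. = FALSE)
  lev <- sort(unique(x))
  if (length(lev) < 2)
    stop("undefined tau: fewer than two distinct ordinal levels",
         call. = FALSE)
  if (length(unique(y)) < 2)
    stop("undefined tau: value variable is constant", call. = FALSE)
  ygrp <- split(y, factor(x, levels = lev))
  S <- 0
  for (k in seq_len(length(lev) - 1)) {
    sya <- sort(ygrp[[k]])
    na <- length(sya)
    for (l in seq(k + 1, length(lev))) {
      yb <- ygrp[[l]]
      n_lt <- findInterval(yb, sya, left.open = TRUE)  # ya <  yb
      n_le <- findInterval(yb, sya)                    # ya <= yb
      S <- S + sum(n_lt) - sum(na - n_le)
    }
  }
  tx <- lengths(ygrp)
  ty <- as.integer(table(y))
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2)
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2)) else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  list(S = S, tau = S / denom, var_s = var_s, n = n)
}

#' Kendall tau-b ordinal trend test
#'
#' Tie-corrected Kendall rank correlation between a continuous variable and
#' the ordered glucose groups (NGT = 0, IFG/IGT = 1 sharing a rank, CGI = 2,
#' T2D = 3). The p-value uses the tie-corrected normal approximation of the
#' concordance statistic; the confidence interval is a seeded bootstrap
#' percentile interval by default (the approximation in use is recorded in
#' the result).
#'
#' @param table cohort `data.frame`.
#' @param value_var column name of the continuous variable.
#' @param ordinal_var column name of the ordinal coding (default
#'   `"group_ordinal"`).
#' @param ci_method `"bootstrap"` (default) or `"normal"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return A `kendall_trend` list: `tau`, `ci`, `p`, `n`, `ci_method`.
#' @export
kendall_trend <- function(table, value_var, ordinal_var = "group_ordinal",
                          ci_method = c("bootstrap", "normal"),
                          n_boot = 2000, conf = 0.95, seed = 1) {
  ci_method <- match.arg(ci_method)
  x <- table[[ordinal_var]]
  y <- table[[value_var]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  core <- kendall_core(x, y)
  z <- core$S / sqrt(core$var_s)
  p <- 2 * pnorm(-abs(z))
  alpha <- 1 - conf
  if (ci_method == "bootstrap") {
    set.seed(as.integer(seed))
    taus <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(core$n, core$n, replace = TRUE)
      tryCatch(kendall_core(x[i], y[i])$tau, error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(quantile(taus, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  } else {
    se_tau <- abs(core$tau / z)
    ci <- core$tau + c(-1, 1) * qnorm(1 - alpha / 2) * se_tau
  }
  structure(list(tau = core$tau, ci = ci, p = p, n = core$n,
                 ci_method = ci_method),
            class = "kendall_trend")
}

#' @export
print.kendall_trend <- function(x, ...) {
  cat("<kendall_trend> tau-b = ", format(x$tau, digits = 3), ", 95% CI [",
      format(x$ci[1], digits = 3), ", ", format(x$ci[2], digits = 3),
      "] (", x$ci_method, "), p = ", format.pval(x$p, digits = 3),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Qualify confounders against the reference group
#'
#' For each candidate, fits `outcome ~ candidate + adjust` on the reference
#' (NGT) rows and keeps candidates whose term is associated with the outcome
#' independently of the adjuster at `p < alpha` (F-test for the whole term,
#' so multi-level factors are handled).
#'
#' @param table cohort `data.frame`.
#' @param candidates character vector of candidate column names.
#' @param outcome outcome column, default `"eatv_ml"`.
#' @param adjust adjustment column, default `"vat_cm2"`.
#' @param alpha qualification threshold, default 0.10.
#' @param group restrict to this glucose group before fitting (`NULL` uses
#'   all rows).
#' @return Data frame `(candidate, p_value, qualified)`; qualified names in
#'   attribute `qualified`.
#' @export
qualify_confounders <- function(table,
                                candidates = c("sex", "age",
                                               "physical_activity",
                                               "lipid_med", "smoking",
                                               "alcohol", "education",
                                               "season"),
                                outcome = "eatv_ml", adjust = "vat_cm2",
                                alpha = 0.10, group = "NGT") {
  if (!is.null(group) && "glucose_group" %in% names(table))
    table <- table[table$glucose_group == group, , drop = FALSE]
  if (nrow(table) == 0) stop("no rows to qualify confounders on",
                             call. = FALSE)
  candidates <- intersect(candidates, names(table))
  res <- do.call(rbind, lapply(candidates, function(v) {
    d <- table[, c(outcome, v, adjust)]
    d <- d[complete.cases(d), , drop = FALSE]
    fit <- lm(as.formula(paste(outcome, "~", v, "+", adjust)), data = d)
    a <- drop1(fit, scope = as.formula(paste("~", v)), test = "F")
    data.frame(candidate = v, p_value = a[v, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) res <- data.frame(candidate = character(),
                                      p_value = numeric())
  res$qualified <- !is.na(res$p_value) & res$p_value < alpha
  attr(res, "qualified") <- res$candidate[res$qualified]
  res
}

# internal: fit one OLS model with complete cases and collinearity check
fit_one_model <- function(table, outcome_var, terms, model_id, outcome,
                          exposure, conf = 0.95) {
  vars <- c(outcome_var, terms)
  d <- table[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) <= length(terms) + 1)
    stop("too few complete cases for model ", model_id, call. = FALSE)
  f <- as.formula(paste(outcome_var, "~", paste(terms, collapse = " + ")))
  fit <- lm(f, data = d)
  if (anyNA(coef(fit)))
    stop("collinearity error in model ", model_id, ": aliased columns ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  ci <- confint(fit, level = conf)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      ci_lo = ci[, 1], ci_hi = ci[, 2], p = sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model_id = model_id, outcome = outcome,
                 exposure = exposure, n = nrow(d), coefficients = coefs,
                 fit = fit),
            class = "eat_model_fit")
}

#' @export
print.eat_model_fit <- function(x, ...) {
  cat("<eat_model_fit> model ", x$model_id, ": ", x$outcome, " ~ ",
      x$exposure, " (+ covariates), n = ", x$n, "\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Staged regression models for EATV or EATA
#'
#' Model 1 regresses the outcome on the exposure alone; models 2-4 add one
#' anthropometric at a time (BMI, waist, VAT area - each alone with the
#' exposure, not cumulatively); model 5 adds the qualified confounders to
#' the VAT-adjusted model; model 6 (EATA only) additionally adjusts for
#' EATV. The exposure is either the four non-NGT glucose-group indicators
#' (NGT reference) or HOMA-IR (untransformed by default). Ordinary least
#' squares with analytic 95 % confidence intervals; each model uses its own
#' complete cases.
#'
#' @param table cohort `data.frame`.
#' @param outcome `"eatv"` or `"eata"`.
#' @param exposure `"groups"` or `"homa_ir"`.
#' @param confounders character vector of qualified confounder columns
#'   (used in models 5-6).
#' @param models integer vector of model ids to fit; default 1-5 (1-6 for
#'   EATA).
#' @param log_homa transform HOMA-IR to log scale before use.
#' @return Named list of `eat_model_fit` objects (`model1`, `model2`, ...).
#' @export
fit_staged_models <- function(table, outcome = c("eatv", "eata"),
                              exposure = c("groups", "homa_ir"),
                              confounders = character(), models = NULL,
                              log_homa = FALSE) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  outcome_var <- switch(outcome, eatv = "eatv_ml", eata = "eata_hu")
  if (is.null(models)) models <- if (outcome == "eata") 1:6 else 1:5
  if (any(models == 6L) && outcome != "eata")
    stop("model 6 is only defined for the EATA outcome", call. = FALSE)
  if (exposure == "homa_ir" && log_homa) {
    table$log_homa_ir <- log(table$homa_ir)
    exp_var <- "log_homa_ir"
  } else exp_var <- switch(exposure, groups = "glucose_group",
                           homa_ir = "homa_ir")
  if (exp_var == "glucose_group")
    table$glucose_group <- stats::relevel(factor(table$glucose_group,
                                                 levels = GROUP_LEVELS),
                                          ref = "NGT")
  stages <- list(
    `1` = character(),
    `2` = "bmi",
    `3` = "waist_cm",
    `4` = "vat_cm2",
    `5` = c("vat_cm2", confounders),
    `6` = c("vat_cm2", confounders, "eatv_ml"))
  fits <- lapply(models, function(m) {
    fit_one_model(table, outcome_var, c(exp_var, stages[[as.character(m)]]),
                  m, outcome, exposure)
  })
  names(fits) <- paste0("model", models)
  fits
}

#' Pairwise simple regressions among fat depots
#'
#' The three simple OLS fits relating attenuation and volume across depots:
#' EATA on EATV, VAT attenuation on EATV, and EATA on VAT attenuation.
#' Reports the unstandardised slope B with its 95 % CI, the correlation
#' magnitude R, p-value and complete-case n.
#'
#' @param table cohort `data.frame` with `eatv_ml`, `eata_hu`, `vat_hu`.
#' @return Data frame, one row per fit:
#'   `(response, predictor, B, ci_lo, ci_hi, R, p, n)`.
#' @export
pairwise_regressions <- function(table) {
  pairs <- list(c("eata_hu", "eatv_ml"), c("vat_hu", "eatv_ml"),
                c("eata_hu", "vat_hu"))
  do.call(rbind, lapply(pairs, function(pr) {
    d <- table[, pr]
    d <- d[complete.cases(d), , drop = FALSE]
    fit <- lm(as.formula(paste(pr[1], "~", pr[2])), data = d)
    ci <- confint(fit)[2, ]
    data.frame(response = pr[1], predictor = pr[2],
               B = unname(coef(fit)[2]), ci_lo = unname(ci[1]),
               ci_hi = unname(ci[2]),
               R = abs(cor(d[[1]], d[[2]])),
               p = summary(fit)$coefficients[2, 4], n = nrow(d),
               stringsAsFactors = FALSE)
  }))
}

#' Forest-plot-ready coefficient table
#'
#' Flattens a list of staged model fits into one data frame of exposure
#' coefficients (B with CI) per model, the shape used for forest plots of
#' uni- versus multivariable adjustment.
#'
#' @param fits result of [fit_staged_models()].
#' @param exposure_prefix keep only coefficient rows whose term starts with
#'   this prefix (default `"glucose_group"`; use `"homa_ir"` for the
#'   insulin-resistance exposure).
#' @return Data frame `(model_id, term, estimate, ci_lo, ci_hi, p, n)`.
#' @export
model_forest_table <- function(fits, exposure_prefix = "glucose_group") {
  do.call(rbind, lapply(fits, function(f) {
    cf <- f$coefficients
    cf <- cf[startsWith(cf$term, exposure_prefix), , drop = FALSE]
    if (nrow(cf) == 0) return(NULL)
    data.frame(model_id = f$model_id, cf, n = f$n, row.names = NULL)
  }))
}
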