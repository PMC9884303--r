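#' Specification of one glucose-tolerance group
#'
#' Marginal targets (median and interquartile range) for the continuous
#' variables and category rates for the discrete ones, for one of the five
#' glucose groups: normal glucose tolerance (NGT), impaired fasting glucose
#' (IFG), impaired glucose tolerance (IGT), combined glucose intolerance
#' (CGI) and type-2 diabetes (T2D).
#'
#' @param name group label, one of `"NGT"`, `"IFG"`, `"IGT"`, `"CGI"`,
#'   `"T2D"`.
#' @param n group size (>= 0).
#' @param continuous named list; each element `c(median = , iqr = )` with
#'   `iqr > 0`. Expected names: `age`, `homa_ir`, `bmi`, `waist_cm`,
#'   `vat_cm2`, `eatv_ml`, `eata_hu`, `vat_hu`, `sat_hu`.
#' @param rates named list of category probabilities; scalar entries are
#'   Bernoulli rates, vector entries are renormalised to sum to 1.
#' @param glucose_mmol typical fasting capillary glucose (mmol/L) used to
#'   decompose HOMA-IR into insulin and glucose.
#' @return A `group_spec` list.
#' @export
group_spec <- function(name, n, continuous, rates, glucose_mmol) {
  stopifnot(name %in% c("NGT", "IFG", "IGT", "CGI", "T2D"), n >= 0)
  for (v in names(continuous)) {
    x <- continuous[[v]]
    if (!all(c("median", "iqr") %in% names(x)) || x[["iqr"]] <= 0)
      stop("continuous spec for ", v, " needs median and iqr > 0",
           call. = FALSE)
  }
  rates <- lapply(rates, function(r) {
    if (any(r < 0) || any(r > 1)) stop("rates must lie in [0, 1]",
                                       call. = FALSE)
    if (length(r) > 1) r / sum(r) else r
  })
  structure(list(name = name, n = as.integer(n), continuous = continuous,
                 rates = rates, glucose_mmol = glucose_mmol),
            class = "group_spec")
}

# ordinal trend coding: IFG and IGT share a rank
GROUP_LEVELS <- c("NGT", "IFG", "IGT", "CGI", "T2D")
GROUP_ORDINAL <- c(NGT = 0L, IFG = 1L, IGT = 1L, CGI = 2L, T2D = 3L)

#' Default five-group cohort specification
#'
#' Group sizes, continuous medians/IQRs and categorical rates calibrated to
#' the published cohort characteristics (n = 1948). Visceral and
#' subcutaneous attenuation medians are published only for NGT and IGT; the
#' remaining groups follow the published monotone trend and are assumptions.
#'
#' @return Named list of five [group_spec()] objects.
#' @export
default_group_specs <- function() {
  mk <- function(name, n, age, homa, bmi, waist, vat, eatv, eata,
                 vathu, sathu, glu, sex, smoke, act, lipid, edu, alc, seas) {
    group_spec(name, n,
      continuous = list(
        age = c(median = age[1], iqr = age[2]),
        homa_ir = c(median = homa[1], iqr = homa[2]),
        bmi = c(median = bmi[1], iqr = bmi[2]),
        waist_cm = c(median = waist[1], iqr = waist[2]),
        vat_cm2 = c(median = vat[1], iqr = vat[2]),
        eatv_ml = c(median = eatv[1], iqr = eatv[2]),
        eata_hu = c(median = eata[1], iqr = eata[2]),
        vat_hu = c(median = vathu[1], iqr = vathu[2]),
        sat_hu = c(median = sathu[1], iqr = sathu[2])),
      rates = list(sex_male = sex, smoking = smoke, physical_activity = act,
                   lipid_med = lipid, education = edu, alcohol = alc,
                   season = seas),
      glucose_mmol = glu)
  }
  list(
    NGT = mk("NGT", 1012, c(57.5, 7.8), c(1.33, 1.0), c(26.8, 5.7),
             c(96, 16), c(137.9, 102), c(104.9, 53.4), c(-69, 8.0),
             c(-88, 13), c(-106, 5), 5.2,
             0.617, 0.083, 0.047, 0.076, c(0.070, 0.458, 0.472),
             c(0.042, 0.136, 0.420, 0.351, 0.051),
             c(0.262, 0.303, 0.124, 0.310)),
    IFG = mk("IFG", 414, c(58.4, 7.8), c(1.73, 1.3), c(27.1, 5.1),
             c(98, 15), c(165.2, 119), c(114.7, 56.0), c(-69, 6.0),
             c(-89, 13), c(-106, 5), 6.3,
             0.430, 0.092, 0.049, 0.068, c(0.061, 0.522, 0.417),
             c(0.029, 0.118, 0.394, 0.394, 0.065),
             c(0.263, 0.292, 0.109, 0.336)),
    IGT = mk("IGT", 321, c(60.5, 8.6), c(1.48, 1.4), c(26.9, 6.1),
             c(97, 20), c(166.7, 110), c(112.2, 62.8), c(-71, 6.0),
             c(-92, 12), c(-107, 4), 5.4,
             0.564, 0.078, 0.043, 0.121, c(0.131, 0.523, 0.346),
             c(0.075, 0.121, 0.355, 0.358, 0.090),
             c(0.231, 0.299, 0.153, 0.318)),
    CGI = mk("CGI", 128, c(60.4, 6.2), c(2.70, 2.5), c(29.9, 6.5),
             c(105, 16), c(219.8, 113), c(134.6, 65.3), c(-71, 6.0),
             c(-92, 12), c(-107, 4), 6.5,
             0.430, 0.102, 0.039, 0.094, c(0.109, 0.469, 0.422),
             c(0.039, 0.205, 0.402, 0.276, 0.079),
             c(0.250, 0.328, 0.094, 0.328)),
    T2D = mk("T2D", 73, c(60.0, 6.9), c(3.22, 2.2), c(30.6, 7.8),
             c(107, 19), c(247.2, 179), c(146.6, 63.0), c(-72, 7.5),
             c(-94, 13), c(-107, 5), 7.3,
             0.370, 0.123, 0.039, 0.260, c(0.137, 0.521, 0.342),
             c(0.068, 0.192, 0.466, 0.178, 0.096),
             c(0.260, 0.438, 0.082, 0.219)))
}

#' Default latent correlation matrix for the copula
#'
#' Latent-normal correlations among `(eatv, vat_cm2, bmi, waist_cm,
#' homa_ir, age)`, chosen so that sample rank correlations land near the
#' published anthropometric correlation range (EATV-BMI ~ 0.58 up to
#' EATV-VAT ~ 0.74 in the NGT group); the joint structure beyond the
#' published pairwise values is an explicit, editable assumption.
#'
#' @return A 6 x 6 positive-definite correlation matrix.
#' @export
default_copula_corr <- function() {
  v <- c("eatv_ml", "vat_cm2", "bmi", "waist_cm", "homa_ir", "age")
  m <- diag(6)
  dimnames(m) <- list(v, v)
  set_ <- function(a, b, r) { m[a, b] <<- r; m[b, a] <<- r }
  set_("eatv_ml", "vat_cm2", 0.75)
  set_("eatv_ml", "bmi", 0.59)
  set_("eatv_ml", "waist_cm", 0.66)
  set_("eatv_ml", "homa_ir", 0.30)
  set_("eatv_ml", "age", 0.15)
  set_("vat_cm2", "bmi", 0.70)
  set_("vat_cm2", "waist_cm", 0.80)
  set_("vat_cm2", "homa_ir", 0.45)
  set_("vat_cm2", "age", 0.10)
  set_("bmi", "waist_cm", 0.85)
  set_("bmi", "homa_ir", 0.45)
  set_("bmi", "age", 0.00)
  set_("waist_cm", "homa_ir", 0.45)
  set_("waist_cm", "age", 0.05)
  set_("homa_ir", "age", 0.05)
  m
}

#' Default partial confounder effects built into the generator
#'
#' Additive effects on log-EATV (so the confounder-qualification step has
#' known ground truth): men carry more epicardial fat, smokers slightly
#' more, physically active subjects less, and EATV drifts up with age.
#' Season, education, alcohol and lipid-lowering medication have no built-in
#' effect.
#'
#' @return Named list of log-scale effect sizes.
#' @export
default_confounder_effects <- function() {
  list(sex_male = 0.15, smoking = 0.08, physical_activity = -0.10,
       age_per_year = 0.006)
}

# lognormal quantile matched to (median, iqr)
q_lognormal <- function(u, med, iqr) {
  sigma <- asinh(iqr / (2 * med)) / qnorm(0.75)
  exp(log(med) + sigma * qnorm(u))
}

# normal quantile matched to (median, iqr)
q_normal <- function(u, med, iqr) med + iqr / (2 * qnorm(0.75)) * qnorm(u)

# age: uniform 50-64 warped so the median matches the group target
q_age <- function(u, med, lo = 50, hi = 64) {
  ifelse(u <= 0.5, lo + u * 2 * (med - lo), med + (u - 0.5) * 2 * (hi - med))
}

rcat <- function(n, probs, labels) {
  labels[1L + findInterval(runif(n), cumsum(probs)[-length(probs)])]
}

#' Generate a synthetic five-group cohort
#'
#' Continuous variables are drawn through a Gaussian copula with
#' per-variable marginal transforms (log-normal for EATV, VAT area and
#' HOMA-IR; normal for BMI and waist; a median-matched warp of uniform
#' 50-64 for age), all matched to group medians and IQRs. EATA and VAT
#' attenuation are tied to EATV through linear links with slopes
#' `beta_eata_eatv` and `beta_vathu_eatv`, with residual noise sized so the
#' group IQRs still hit their targets; SAT attenuation is drawn
#' independently. Known partial confounder effects (see
#' [default_confounder_effects()]) are added, mean-centred, to log-EATV,
#' with the copula component shrunk so the total spread still matches the
#' target IQR. Insulin is derived from HOMA-IR and glucose so that
#' `homa_ir == insulin * glucose / 22.5` holds row by row. Categorical
#' variables are drawn independently at group rates. Fully deterministic
#' per seed.
#'
#' @param specs list of [group_spec()] objects.
#' @param copula_corr latent correlation matrix over
#'   `(eatv_ml, vat_cm2, bmi, waist_cm, homa_ir, age)`.
#' @param seed integer seed.
#' @param beta_eata_eatv built-in EATA-on-EATV slope (HU per ml).
#' @param beta_vathu_eatv built-in VAT-attenuation-on-EATV slope.
#' @param effects named list of log-EATV confounder effects.
#' @return A `data.frame` cohort table, one row per subject, with attribute
#'   `generator` recording the built-in slopes.
#' @export
generate_cohort <- function(specs = default_group_specs(),
                            copula_corr = default_copula_corr(),
                            seed,
                            beta_eata_eatv = -0.082,
                            beta_vathu_eatv = -0.129,
                            effects = default_confounder_effects()) {
  stopifnot(!missing(seed))
  ev <- eigen(copula_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("copula correlation matrix is not positive semi-definite",
         call. = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  offset <- 0L
  for (g in specs) {
    n <- g$n
    if (n == 0L) next
    Z <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = copula_corr)
    if (n == 1L) Z <- matrix(Z, nrow = 1)
    U <- pnorm(Z)
    cs <- g$continuous
    age <- q_age(U[, 6], cs$age[["median"]])
    vat <- q_lognormal(U[, 2], cs$vat_cm2[["median"]], cs$vat_cm2[["iqr"]])
    bmi <- q_normal(U[, 3], cs$bmi[["median"]], cs$bmi[["iqr"]])
    waist <- q_normal(U[, 4], cs$waist_cm[["median"]], cs$waist_cm[["iqr"]])
    homa <- q_lognormal(U[, 5], cs$homa_ir[["median"]], cs$homa_ir[["iqr"]])

    sex <- runif(n) < g$rates$sex_male
    smoking <- runif(n) < g$rates$smoking
    activity <- runif(n) < g$rates$physical_activity
    lipid <- runif(n) < g$rates$lipid_med
    education <- rcat(n, g$rates$education,
                      c("elementary", "high_school", "university"))
    alcohol <- rcat(n, g$rates$alcohol,
                    c("low", "low_moderate", "moderate", "moderate_high",
                      "high"))
    season <- rcat(n, g$rates$season,
                   c("winter", "spring", "summer", "fall"))

    # confounder effects on log-EATV, mean-centred; shrink the copula
    # component so the total log-scale spread still matches the target IQR
    eff <- effects$sex_male * (sex - mean(sex)) +
      effects$smoking * (smoking - mean(smoking)) +
      effects$physical_activity * (activity - mean(activity)) +
      effects$age_per_year * (age - mean(age))
    sigma_t <- asinh(cs$eatv_ml[["iqr"]] / (2 * cs$eatv_ml[["median"]])) /
      qnorm(0.75)
    var_eff <- if (n > 1) stats::var(eff) else 0
    sigma_c <- sqrt(max(sigma_t^2 - var_eff, (0.2 * sigma_t)^2))
    eatv <- exp(log(cs$eatv_ml[["median"]]) + sigma_c * qnorm(U[, 1]) + eff)

    # EATA and VAT attenuation tied to EATV via linear links
    tied_normal <- function(med_y, iqr_y, beta) {
      sd_t <- iqr_y / (2 * qnorm(0.75))
      var_x <- if (n > 1) stats::var(eatv) else 0
      sd_eps <- sqrt(max(sd_t^2 - beta^2 * var_x, (0.2 * sd_t)^2))
      (med_y - beta * cs$eatv_ml[["median"]]) + beta * eatv +
        rnorm(n, 0, sd_eps)
    }
    eata <- tied_normal(cs$eata_hu[["median"]], cs$eata_hu[["iqr"]],
                        beta_eata_eatv)
    vathu <- tied_normal(cs$vat_hu[["median"]], cs$vat_hu[["iqr"]],
                         beta_vathu_eatv)
    sathu <- q_normal(runif(n), cs$sat_hu[["median"]], cs$sat_hu[["iqr"]])

    glucose <- g$glucose_mmol * exp(rnorm(n, 0, 0.05))
    insulin <- homa * 22.5 / glucose

    rows[[g$name]] <- data.frame(
      subject_id = sprintf("S%04d", offset + seq_len(n)),
      glucose_group = factor(g$name, levels = GROUP_LEVELS),
      group_ordinal = GROUP_ORDINAL[[g$name]],
      age = age,
      sex = factor(ifelse(sex, "male", "female"),
                   levels = c("male", "female")),
      smoking = factor(ifelse(smoking, "current", "never"),
                       levels = c("never", "current")),
      physical_activity = factor(ifelse(activity, "yes", "no"),
                                 levels = c("no", "yes")),
      education = factor(education, levels = c("high_school", "elementary",
                                               "university")),
      alcohol = factor(alcohol, levels = c("moderate", "low", "low_moderate",
                                           "moderate_high", "high")),
      season = factor(season, levels = c("fall", "winter", "spring",
                                         "summer")),
      lipid_med = factor(ifelse(lipid, "yes", "no"), levels = c("no", "yes")),
      bmi = bmi, waist_cm = waist, vat_cm2 = vat, vat_hu = vathu,
      sat_hu = sathu, eatv_ml = eatv, eata_hu = eata,
      insulin = insulin, glucose = glucose, homa_ir = homa,
      stringsAsFactors = FALSE)
    offset <- offset + n
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame()
  attr(out, "generator") <- list(beta_eata_eatv = beta_eata_eatv,
                                 beta_vathu_eatv = beta_vathu_eatv,
                                 effects = effects, seed = as.integer(seed))
  out
}

#' Mask values completely at random
#'
#' Missing-completely-at-random masking for selected columns, emulating
#' incomplete measurements; downstream analyses are complete-case. A rate
#' entry in \[0, 1) is a per-row probability; an entry >= 1 is an absolute
#' number of rows to mask (so published missingness counts can be injected
#' exactly).
#'
#' @param table a cohort `data.frame`.
#' @param rates named numeric vector, names are column names.
#' @param seed integer seed.
#' @return The table with `NA`s injected; masked counts in attribute
#'   `n_masked`.
#' @export
inject_missingness <- function(table, rates, seed) {
  stopifnot(!missing(seed), all(names(rates) %in% names(table)),
            all(rates >= 0))
  set.seed(as.integer(seed))
  n <- nrow(table)
  masked <- integer(0)
  for (v in names(rates)) {
    r <- rates[[v]]
    avail <- which(!is.na(table[[v]]))
    k <- if (r >= 1) min(as.integer(round(r)), length(avail))
         else sum(runif(length(avail)) < r)
    if (k > 0) {
      hit <- sample(avail, k)
      table[[v]][hit] <- NA
      masked[v] <- k
    } else masked[v] <- 0L
  }
  attr(table, "n_masked") <- masked
  table
}
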