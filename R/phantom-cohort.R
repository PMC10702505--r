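#' Synthetic cohort specification
#'
#' Describes a five-category occupational-lung-disease cohort with
#' category-dependent confounding (higher categories are older, shorter,
#' more often smokers and COPD-positive) and category-dependent imaging
#' effects (thicker tracheal/Bronint walls, narrower TriLUL bifurcation,
#' lower Bronint circularity, more emphysema/consolidation/fibrosis, a
#' smaller small-vessel volume share, and lower spirometric indices).
#' The defaults reproduce the demographic structure of a real
#' pre-matching severity cohort (group sizes 110/108/54/10/98, age means
#' rising from 67 to 75 years, smoking prevalence 0.83-0.92, COPD
#' prevalence 0.42-1.0).  Structural-variable effect sizes are plausible
#' rather than calibrated: the source material reports group differences
#' only graphically.
#'
#' @param n subjects per category 0..4.
#' @param age_mean,age_sd,height_mean,height_sd per-category normal
#'   parameters (years, cm).
#' @param smoking_p,copd_p,female_p per-category prevalences.
#' @param bmi_mean,bmi_sd per-category BMI parameters.
#' @param fev1_mean,fev1_sd,fvc_mean,fvc_sd per-category percent-predicted
#'   spirometry parameters.
#' @param missing_rate per-category probability that any one structural
#'   metric of a subject is missing (opacity-obscured airway); must be
#'   in \[0, 1).
#' @param effect_scale scales every imaging/PFT category effect away from
#'   the category-0 value (0 = no imaging effects, categories identical).
#' @param confounding_scale likewise for the confounder distributions
#'   (0 = identical confounder distributions in all categories).
#' @param seed integer seed driving all draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(110, 108, 54, 10, 98),
                        age_mean = c(67.1, 72.3, 73.8, 72.2, 75.0),
                        age_sd = c(7.7, 7.5, 6.7, 8.8, 7.2),
                        height_mean = c(166.4, 164.1, 164.8, 163.4, 164.4),
                        height_sd = c(6.0, 5.8, 5.9, 5.9, 5.9),
                        smoking_p = c(0.827, 0.815, 0.907, 0.900, 0.918),
                        copd_p = c(0.418, 0.602, 0.796, 1.0, 0.854),
                        female_p = c(0.0, 0.009, 0.0, 0.0, 0.02),
                        bmi_mean = c(24.3, 23.7, 23.7, 24.3, 22.7),
                        bmi_sd = c(3.4, 3.0, 2.8, 1.9, 2.9),
                        fev1_mean = c(83.5, 74.1, 63.5, 64.8, 56.9),
                        fev1_sd = c(16.1, 20.0, 19.5, 21.5, 20.9),
                        fvc_mean = c(81.2, 71.5, 65.4, 63.8, 61.9),
                        fvc_sd = c(13.8, 17.6, 15.7, 10.1, 17.9),
                        missing_rate = c(0.03, 0.06, 0.09, 0.12, 0.15),
                        effect_scale = 1,
                        confounding_scale = 1,
                        seed = 1) {
  probs <- c(smoking_p, copd_p, female_p, missing_rate)
  if (any(probs < 0) || any(smoking_p > 1) || any(copd_p > 1) ||
      any(female_p > 1) || any(missing_rate >= 1))
    stop("prevalences must be in [0,1] and missing rates in [0,1)")
  if (any(n < 0)) stop("sample sizes must be nonnegative")
  spec <- list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
               height_mean = height_mean, height_sd = height_sd,
               smoking_p = smoking_p, copd_p = copd_p, female_p = female_p,
               bmi_mean = bmi_mean, bmi_sd = bmi_sd,
               fev1_mean = fev1_mean, fev1_sd = fev1_sd,
               fvc_mean = fvc_mean, fvc_sd = fvc_sd,
               missing_rate = missing_rate,
               effect_scale = effect_scale,
               confounding_scale = confounding_scale,
               seed = seed)
  class(spec) <- "cohort_spec"
  spec
}

# reporting units and per-variable base level / per-category slope / noise
structural_config <- function() {
  central <- c("Trachea", "LMB", "RMB", "Bronint", "TriRUL", "TriRLL",
               "TriLUL", "TriLLB")
  subs <- c("sRUL", "sRML", "sRLL", "sLUL", "sLLL")
  theta <- data.frame(
    var = paste0("theta_", central),
    base = c(74, 100, 96, 92, 98, 95, 97, 94),
    slope = ifelse(central == "TriLUL", -2.0, 0),
    sd = 6)
  dh <- data.frame(
    var = paste0("Dh_", c(central, subs)),
    base = c(16.5, 11.5, 12.5, 10.0, 8.0, 8.2, 8.0, 8.3,
             5.6, 5.2, 5.8, 5.5, 5.4),
    slope = 0,
    sd = c(rep(1.3, 8), rep(0.8, 5)))
  wt <- data.frame(
    var = paste0("WT_", c(central, subs)),
    base = c(2.0, 1.6, 1.65, 1.5, 1.35, 1.35, 1.3, 1.35,
             1.1, 1.05, 1.1, 1.05, 1.1),
    slope = c(0.06, 0, 0, 0.05, 0, 0, 0, 0, rep(0, 5)),
    sd = 0.15)
  cr <- data.frame(
    var = paste0("Cr_", c(central, subs)),
    base = c(0.95, 0.94, 0.94, 0.95, 0.93, 0.93, 0.93, 0.93,
             0.92, 0.92, 0.92, 0.92, 0.92),
    slope = c(0, 0, 0, -0.012, 0, 0, 0, 0, rep(0, 5)),
    sd = 0.03)
  rbind(theta, dh, wt, cr)
}

#' Generate a synthetic cohort table
#'
#' One row per subject: severity category, confounders, spirometry,
#' per-branch structural metrics (with category-dependent
#' missing-at-random gaps, emulating opacity-obscured airway segments),
#' parenchymal volume fractions and vessel volume ratios.  Couplings are
#' built in so that downstream correlation analyses see the expected
#' physiology: FEV1/FVC falls with the emphysema fraction, and the
#' small-vessel share BV5/TBV falls with the fibrosis fraction.
#' Deterministic given `spec$seed` (stream order: per category 0..4,
#' confounders, then parenchyma, vessels, spirometry, structural metrics,
#' then missingness masks).
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame of class `cohort_table`; the column dictionary is
#'   in `attr(, "dictionary")`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$n == 0))
    stop("zero subjects requested in category ",
         paste(which(spec$n == 0) - 1, collapse = ", "))
  cfg <- structural_config()
  es <- spec$effect_scale
  cs <- spec$confounding_scale
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  # category-c parameter = cat0 value + scale * (cat value - cat0 value)
  eff <- function(v, scale) v[1] + scale * (v - v[1])

  rows <- with_seed(spec$seed, lapply(0:4, function(cat) {
    k <- cat + 1L
    nk <- spec$n[k]
    age <- rnorm(nk, eff(spec$age_mean, cs)[k], spec$age_sd[k])
    height <- rnorm(nk, eff(spec$height_mean, cs)[k], spec$height_sd[k])
    female <- rbinom(nk, 1, clamp(eff(spec$female_p, cs)[k], 0, 1))
    smoking <- rbinom(nk, 1, clamp(eff(spec$smoking_p, cs)[k], 0, 1))
    copd <- rbinom(nk, 1, clamp(eff(spec$copd_p, cs)[k], 0, 1))
    bmi <- rnorm(nk, eff(spec$bmi_mean, cs)[k], spec$bmi_sd[k])

    emph <- clamp(rnorm(nk, 0.04 + es * 0.035 * cat, 0.025), 0.001, 0.6)
    ggo <- clamp(rnorm(nk, 0.02, 0.01), 0, 0.3)
    semi <- clamp(rnorm(nk, 0.01 + es * 0.010 * cat, 0.008), 0, 0.4)
    conso <- clamp(rnorm(nk, 0.005 + es * 0.005 * cat, 0.004), 0, 0.3)
    fibr <- clamp(rnorm(nk, 0.02 + es * 0.025 * cat, 0.015), 0, 0.5)
    normal <- pmax(1 - emph - ggo - semi - conso, 0)

    bv5 <- clamp(0.58 - es * 0.02 * cat - 0.8 * (fibr - 0.02) +
                   rnorm(nk, 0, 0.04), 0.05, 0.95)
    bv1 <- clamp(0.35 * bv5 + rnorm(nk, 0, 0.02), 0.01, bv5)
    bv10 <- clamp(bv5 + (1 - bv5) * 0.55 + rnorm(nk, 0, 0.03), bv5, 1)

    fev1 <- pmax(rnorm(nk, eff(spec$fev1_mean, es)[k], spec$fev1_sd[k]), 10)
    fvc <- pmax(rnorm(nk, eff(spec$fvc_mean, es)[k], spec$fvc_sd[k]), 10)
    fev1_fvc <- clamp(75.5 - 62 * emph - es * 0.8 * cat + rnorm(nk, 0, 8),
                      20, 95)

    strc <- sapply(seq_len(nrow(cfg)), function(i)
      rnorm(nk, cfg$base[i] + es * cfg$slope[i] * cat, cfg$sd[i]))
    strc <- matrix(strc, nrow = nk)
    colnames(strc) <- cfg$var
    cr_cols <- grepl("^Cr_", cfg$var)
    strc[, cr_cols] <- clamp(strc[, cr_cols], 0.5, 1)

    miss <- matrix(rbinom(nk * nrow(cfg), 1, spec$missing_rate[k]) == 1,
                   nrow = nk)
    strc[miss] <- NA_real_

    cbind(data.frame(category = cat, age = age, height = height,
                     female = female, smoking = smoking, copd = copd,
                     bmi = bmi, fev1_pp = fev1, fvc_pp = fvc,
                     fev1_fvc = fev1_fvc),
          as.data.frame(strc),
          data.frame(emph_frac = emph, normal_frac = normal,
                     ggo_frac = ggo, semi_frac = semi, conso_frac = conso,
                     fibr_frac = fibr, bv1_tbv = bv1, bv5_tbv = bv5,
                     bv10_tbv = bv10))
  }))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(id = seq_len(nrow(out))), out)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "dictionary") <- c(
    id = "subject identifier",
    category = "severity category 0-4 (input label)",
    age = "years", height = "cm", female = "0/1", smoking = "ever-smoker 0/1",
    copd = "COPD present 0/1", bmi = "kg/m^2",
    fev1_pp = "FEV1 % predicted", fvc_pp = "FVC % predicted",
    fev1_fvc = "FEV1/FVC %",
    theta_ = "bifurcation angle, degrees (central branches)",
    Dh_ = "hydraulic diameter, mm", WT_ = "wall thickness, mm",
    Cr_ = "circularity (0,1]",
    emph_frac = "emphysema volume fraction",
    normal_frac = "normal-lung volume fraction",
    ggo_frac = "ground-glass opacity fraction",
    semi_frac = "semi consolidation fraction",
    conso_frac = "consolidation fraction",
    fibr_frac = "fibrosis fraction (overlapping class)",
    bv1_tbv = "BV1/TBV", bv5_tbv = "BV5/TBV", bv10_tbv = "BV10/TBV")
  out
}

#' Names of the structural metric columns of a cohort table
#'
#' These are the columns subject to missingness and E-M imputation.
#'
#' @param cohort a `cohort_table`.
#' @return Character vector of column names.
#' @export
structural_columns <- function(cohort) {
  grep("^(theta|Dh|WT|Cr)_", names(cohort), value = TRUE)
}
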