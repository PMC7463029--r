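#' Simulate cohort covariates
#'
#' Draws age, sex, BMI, clinical systolic blood pressure and hypertension
#' status for every pedigree member. Marginal moments follow the cohort
#' summary the pipeline is calibrated against: BMI ~ N(25.88, 3.77^2),
#' systolic BP ~ N(139.71, 21.83^2), about 49\% male, and roughly 39\%
#' hypertension prevalence among phenotyped members once the proband (who
#' is hypertensive by ascertainment) is forced positive. Ages descend
#' through the generations: founder parents around 70 years, grandparents
#' at the top of the permitted range, and each child's age is the parental
#' midpoint minus a Normal(26, 4) generation gap, clipped to the permitted
#' range (19-73 by default).
#'
#' @param ped A `pedigree` data frame.
#' @param seed Integer seed.
#' @param bmi_mean,bmi_sd,sbp_mean,sbp_sd Marginal moments of BMI (kg/m^2)
#'   and clinical systolic blood pressure (mmHg).
#' @param ht_nonproband Hypertension probability for non-probands,
#'   calibrated so the phenotyped-cohort prevalence is about 0.39 under the
#'   default family structure.
#' @param age_range Permitted age range (years).
#'
#' @return A `data.frame` of class `covariate_table` with columns `id`,
#'   `family`, `age`, `age2`, `sex`, `male` (0/1), `bmi`, `sbp`,
#'   `hypertension` (0/1).
#' @export
simulate_covariates <- function(ped, seed = NULL,
                                bmi_mean = 25.88, bmi_sd = 3.77,
                                sbp_mean = 139.71, sbp_sd = 21.83,
                                ht_nonproband = 0.107,
                                age_range = c(19, 73)) {
  if (nrow(ped) == 0) stop("pedigree is empty")
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  ord <- topo_order(ped$id, ped$father, ped$mother)
  with_seed(seed, {
    age <- numeric(n)
    for (j in ord) {
      fa <- ped$father[j]
      mo <- ped$mother[j]
      if (is.na(fa) && is.na(mo)) {
        gen <- if ("generation" %in% names(ped)) ped$generation[j] else 1L
        age[j] <- if (gen == 0L) rnorm(1, 86, 5) else rnorm(1, 70, 4)
      } else {
        pa_age <- mean(age[idx[c(fa, mo)[!is.na(c(fa, mo))]]])
        age[j] <- pa_age - rnorm(1, 26, 4)
      }
    }
    age <- pmin(pmax(age, age_range[1]), age_range[2])
    bmi <- pmax(rnorm(n, bmi_mean, bmi_sd), 14)
    sbp <- rnorm(n, sbp_mean, sbp_sd)
    hyper <- as.integer(runif(n) < ht_nonproband)
    hyper[ped$proband] <- 1L
    out <- data.frame(id = ped$id, family = ped$family,
                      age = age, age2 = age^2,
                      sex = ped$sex,
                      male = as.integer(ped$sex == "male"),
                      bmi = bmi, sbp = sbp, hypertension = hyper,
                      stringsAsFactors = FALSE)
    class(out) <- c("covariate_table", "data.frame")
    out
  })
}
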