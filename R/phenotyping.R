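#' Baseline-normalised tolerance-test AUC
#'
#' Subtracts the pre-bolus baseline glucose from all post-bolus samples and
#' integrates the excursion by the trapezoidal rule over the post-bolus
#' timepoints. Negative excursions are retained, so the result is a net
#' (signed) area in mg/dL * min; it is invariant to shifting the whole curve
#' by a constant.
#'
#' @param curve A [tolerance_curve()] with a baseline sample and at least
#'   two post-bolus points.
#' @return Net AUC above baseline (mg/dL * min).
#' @export
mtt_auc <- function(curve) {
  stopifnot(inherits(curve, "tolerance_curve"))
  baseline <- curve$glucose_mgdl[curve$baseline_index]
  post <- which(curve$time_min >= 0)
  if (length(post) < 2L) stop("need at least 2 post-bolus points")
  pracma::trapz(curve$time_min[post],
                curve$glucose_mgdl[post] - baseline)
}

#' Glucose disappearance rate (Kitt)
#'
#' The constant rate of glucose disappearance during an insulin tolerance
#' test: the ordinary least-squares slope of the natural log of glucose
#' against time, over samples between 0 and 60 minutes, sign-flipped and
#' expressed in %/min (positive for falling glucose).
#'
#' @param curve A [tolerance_curve()] with at least 3 samples in [0, 60]
#'   minutes.
#' @return List with `kitt` (%/min), `se` (standard error of kitt from the
#'   regression, %/min), `slope` (per minute), and `n_points`.
#' @export
kitt <- function(curve) {
  stopifnot(inherits(curve, "tolerance_curve"))
  win <- curve$time_min >= 0 & curve$time_min <= 60
  if (sum(win) < 3L) stop("need at least 3 points within [0, 60] min")
  t <- curve$time_min[win]
  g <- curve$glucose_mgdl[win]
  if (any(g <= 0)) stop("glucose must be > 0 for the log transform")
  fit <- stats::lm(log(g) ~ t)
  # slope SE computed directly: summary.lm warns on noise-free (exact) fits,
  # which are legitimate inputs here
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  cov_unscaled <- chol2inv(qr.R(fit$qr))
  list(kitt = -unname(stats::coef(fit)[2]) * 100,
       se = sqrt(s2 * cov_unscaled[2, 2]) * 100,
       slope = unname(stats::coef(fit)[2]),
       n_points = length(t))
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = fasting glucose (mmol/L) x fasting insulin (mU/L) / 22.5`,
#' using the conventional normalisation constant.
#'
#' @param fasting_glucose_mmol Fasting glucose in mmol/L (> 0).
#' @param fasting_insulin_mU Fasting insulin in mU/L (> 0).
#' @return HOMA-IR (dimensionless), vectorised.
#' @examples
#' homa_ir(5.0, 10)  # 2.222
#' @export
homa_ir <- function(fasting_glucose_mmol, fasting_insulin_mU) {
  stopifnot(is.numeric(fasting_glucose_mmol), is.numeric(fasting_insulin_mU))
  if (any(fasting_glucose_mmol <= 0) || any(fasting_insulin_mU <= 0))
    stop("fasting glucose and insulin must be > 0")
  fasting_glucose_mmol * fasting_insulin_mU / 22.5
}

#' Calorie-restriction ration schedule
#'
#' Computes the daily ration for a restricted group from the ad-libitum
#' (AL) group's measured intake: at steady state the ration is
#' `(1 - restriction)` times the mean AL daily intake (the modelled
#' protocol feeds 80% of AL consumption, i.e. 20% restriction). Restriction
#' is introduced gradually, stepping by 0.10 per week until the target is
#' reached, to avoid abrupt weight loss.
#'
#' @param al_intake_kcal Numeric vector of AL daily intakes (kcal/day), or
#'   a data frame with column `intake_kcal`.
#' @param restriction Target restriction fraction in [0, 1) (default 0.20).
#' @param n_weeks Length of the schedule to emit (default 8).
#' @return List with `steady_state` (kcal/day) and `schedule` (data frame
#'   `week`, `restriction`, `ration_kcal`).
#' @examples
#' cr_ration(rep(15, 7))$steady_state  # 12
#' @export
cr_ration <- function(al_intake_kcal, restriction = 0.20, n_weeks = 8) {
  if (is.data.frame(al_intake_kcal)) {
    stopifnot("intake_kcal" %in% names(al_intake_kcal))
    al_intake_kcal <- al_intake_kcal$intake_kcal
  }
  stopifnot(is.numeric(al_intake_kcal), length(al_intake_kcal) >= 1L,
            all(al_intake_kcal >= 0))
  if (restriction < 0 || restriction >= 1)
    stop("restriction must be in [0, 1)")
  al_mean <- mean(al_intake_kcal)
  weeks <- seq_len(n_weeks)
  r_week <- pmin(restriction, 0.10 * weeks)
  schedule <- data.frame(week = weeks,
                         restriction = r_week,
                         ration_kcal = (1 - r_week) * al_mean)
  list(steady_state = (1 - restriction) * al_mean, schedule = schedule,
       al_mean_intake = al_mean)
}

#' Digested energy from intake and fecal energy
#'
#' `digested = intake - fecal`, both in kcal/day; fecal energy exceeding
#' intake is rejected as inconsistent input.
#'
#' @param intake_kcal_per_day Energy intake (>= 0), vectorised.
#' @param fecal_kcal_per_day Fecal energy (>= 0), vectorised.
#' @return Digested energy in kcal/day.
#' @export
digested_energy <- function(intake_kcal_per_day, fecal_kcal_per_day) {
  stopifnot(is.numeric(intake_kcal_per_day), is.numeric(fecal_kcal_per_day))
  if (any(intake_kcal_per_day < 0) || any(fecal_kcal_per_day < 0))
    stop("energies must be >= 0")
  if (any(fecal_kcal_per_day > intake_kcal_per_day))
    stop("inconsistent input: fecal energy exceeds intake")
  intake_kcal_per_day - fecal_kcal_per_day
}

#' Convert food mass to energy intake
#'
#' @param grams Food mass consumed (g/day).
#' @param diet `"chow"` or `"hfd"`, selecting the shipped energy density
#'   (4.11 or 5.10 kcal/g), or a numeric kcal/g value.
#' @return Energy intake in kcal/day.
#' @export
intake_energy <- function(grams, diet = "chow") {
  stopifnot(is.numeric(grams), all(grams >= 0))
  dens <- if (is.numeric(diet)) diet
          else ENERGY_DENSITY_KCAL_PER_G[[match.arg(diet, c("chow", "hfd"))]]
  grams * dens
}
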