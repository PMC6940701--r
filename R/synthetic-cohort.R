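#' @importFrom stats rlnorm rnorm runif rbinom
NULL

# deterministic per-subject seed derived from the master seed, so cohorts are
# extensible without reshuffling existing subjects; kept below 2^31
subject_seed <- function(master_seed, i, stream = 0L) {
  (as.integer(master_seed) %% 1000003L) * 2011L + i * 7919L + stream * 104729L
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Distribution configuration for the synthetic ALS cohort
#'
#' Defaults emulate the clinical structure of a cross-sectional ALS cohort:
#' D50 lognormal with median 30 months and sdlog 0.6, truncated to
#' [8, 176] months (empirical mean around 36 months, SD around 25); the
#' sigmoid time-scale is tied to D50 (ratio 4:1) with mild lognormal jitter
#' so fast progressors also decline steeply; bulbar onset with probability
#' 0.28; patient ages normal 60 +/- 11.5 years, control ages 54 +/- 12.8,
#' clipped to [18, 90]; the reference disease covered at MRI (rD50) is drawn
#' truncated-normal 0.27 +/- 0.13 on [0.02, 0.75], from which the MRI time is
#' mri_t = 2 * rd50 * D50 — this spans all three phases with Phases I/II
#' holding the large majority of patients.
#'
#' @param d50_median,d50_sdlog,d50_range lognormal D50 parameters (months)
#' @param slope_ratio D50/slope ratio
#' @param slope_jitter_sdlog lognormal jitter sdlog on the slope
#' @param p_bulbar probability of bulbar onset
#' @param age_patient,age_control c(mean, sd) in years
#' @param age_range plausible clipping range in years
#' @param rd50_at_mri c(mean, sd) of the target rD50 at MRI
#' @param rd50_range truncation range for the target rD50 at MRI
#' @param tiv_mean,tiv_sd total intracranial volume (mL)
#' @param n_visits number of ALSFRS-R visits per patient
#' @param visit_interval months between visits (first visit at the MRI date)
#' @export
cohort_params <- function(d50_median = 30, d50_sdlog = 0.6,
                          d50_range = c(8, 176),
                          slope_ratio = 4, slope_jitter_sdlog = 0.15,
                          p_bulbar = 0.28,
                          age_patient = c(60, 11.5),
                          age_control = c(54, 12.8),
                          age_range = c(18, 90),
                          rd50_at_mri = c(0.27, 0.13),
                          rd50_range = c(0.02, 0.75),
                          tiv_mean = 1450, tiv_sd = 120,
                          n_visits = 4L, visit_interval = 3) {
  p <- list(d50_median = d50_median, d50_sdlog = d50_sdlog,
            d50_range = d50_range, slope_ratio = slope_ratio,
            slope_jitter_sdlog = slope_jitter_sdlog, p_bulbar = p_bulbar,
            age_patient = age_patient, age_control = age_control,
            age_range = age_range, rd50_at_mri = rd50_at_mri,
            rd50_range = rd50_range, tiv_mean = tiv_mean, tiv_sd = tiv_sd,
            n_visits = as.integer(n_visits), visit_interval = visit_interval)
  with(p, {
    if (d50_median <= 0 || d50_sdlog <= 0 || d50_range[1] <= 0 ||
        diff(d50_range) <= 0 || slope_ratio <= 0 || p_bulbar < 0 ||
        p_bulbar > 1 || n_visits < 1 || visit_interval <= 0 ||
        rd50_range[1] <= 0 || diff(rd50_range) <= 0)
      stop("invalid cohort distribution parameters", call. = FALSE)
  })
  p
}

#' Sample a synthetic ground-truth cohort
#'
#' @param n_patients,n_controls subject counts (> 0 patients; controls may be 0)
#' @param seed master seed; all randomness flows from it via per-subject
#'   derived seeds
#' @param params a \code{\link{cohort_params}} list
#' @return list with \code{patients} (list of ground-truth patient lists with
#'   d50_true, slope_true, onset_type, age, sex, tiv, mri_t, visit_times) and
#'   \code{controls} (data.frame patient_id, age, sex, tiv)
#' @export
sample_cohort <- function(n_patients, n_controls = 0, seed = 1,
                          params = cohort_params()) {
  stopifnot(n_patients >= 1, n_controls >= 0)
  patients <- lapply(seq_len(n_patients), function(i) {
    set.seed(subject_seed(seed, i, stream = 1L))
    d50 <- 0
    while (d50 < params$d50_range[1] || d50 > params$d50_range[2])
      d50 <- rlnorm(1, meanlog = log(params$d50_median),
                    sdlog = params$d50_sdlog)
    slope <- d50 / params$slope_ratio *
      rlnorm(1, 0, params$slope_jitter_sdlog)
    rd50_mri <- rtruncnorm1(1, params$rd50_at_mri[1], params$rd50_at_mri[2],
                            params$rd50_range[1], params$rd50_range[2])
    mri_t <- 2 * rd50_mri * d50
    visits <- mri_t + (seq_len(params$n_visits) - 1) * params$visit_interval
    list(patient_id = sprintf("P%03d", i),
         d50_true = d50, slope_true = slope,
         onset_type = if (rbinom(1, 1, params$p_bulbar) == 1) "bulbar" else "limb",
         age = min(max(rnorm(1, params$age_patient[1], params$age_patient[2]),
                       params$age_range[1]), params$age_range[2]),
         sex = if (runif(1) < 0.424) "female" else "male",
         tiv = rnorm(1, params$tiv_mean, params$tiv_sd),
         mri_t = mri_t, visit_times = visits)
  })
  controls <- if (n_controls > 0) {
    do.call(rbind, lapply(seq_len(n_controls), function(i) {
      set.seed(subject_seed(seed, i, stream = 2L))
      data.frame(
        patient_id = sprintf("C%03d", i),
        age = min(max(rnorm(1, params$age_control[1], params$age_control[2]),
                      params$age_range[1]), params$age_range[2]),
        sex = if (runif(1) < 0.565) "female" else "male",
        tiv = rnorm(1, params$tiv_mean, params$tiv_sd),
        stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(patient_id = character(), age = numeric(),
               sex = character(), tiv = numeric())
  }
  list(patients = patients, controls = controls)
}

#' Simulate a noisy ALSFRS-R series for one ground-truth patient
#'
#' Scores are the true sigmoid evaluated at the visit times plus i.i.d.
#' discrete-uniform noise on {-noise_width..noise_width} points, rounded and
#' clipped to [0, 48].
#'
#' @param patient a ground-truth patient from \code{\link{sample_cohort}}
#' @param noise_width half-width of the discrete visit noise in points
#'   (default 2; 0 disables noise)
#' @param seed seed for the visit noise
#' @param round_scores round simulated scores to integers (default TRUE)
#' @return an \code{\link{alsfrs_series}}
#' @export
simulate_alsfrs_series <- function(patient, noise_width = 2, seed = 1,
                                   round_scores = TRUE) {
  stopifnot(noise_width >= 0)
  set.seed(seed)
  t <- patient$visit_times
  true <- sigmoid_value(t, patient$d50_true, patient$slope_true)
  eps <- if (noise_width > 0)
    sample(seq(-noise_width, noise_width), length(t), replace = TRUE)
  else rep(0, length(t))
  score <- pmin(pmax(true + eps, 0), 48)
  if (round_scores) score <- round(score)
  alsfrs_series(patient$patient_id, t, score,
                onset_type = patient$onset_type, sex = patient$sex,
                age_at_mri = patient$age, mri_t = patient$mri_t,
                tiv = patient$tiv)
}

#' Simulate noisy series for a whole cohort
#'
#' @param cohort result of \code{\link{sample_cohort}}
#' @param noise_width visit noise half-width in points
#' @param seed master seed (split per patient)
#' @return named list of \code{\link{alsfrs_series}}
#' @export
simulate_cohort_series <- function(cohort, noise_width = 2, seed = 1) {
  out <- lapply(seq_along(cohort$patients), function(i)
    simulate_alsfrs_series(cohort$patients[[i]], noise_width = noise_width,
                           seed = subject_seed(seed, i, stream = 3L)))
  names(out) <- vapply(cohort$patients, `[[`, "", "patient_id")
  out
}
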