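#' @importFrom stats chisq.test t.test sd
NULL

DAYS_PER_MONTH <- 30.4375

#' Pick the ALSFRS-R observation closest to the MRI
#'
#' Returns the observation with the smallest absolute gap to the MRI
#' acquisition time, provided the gap is at most \code{window_days}
#' (months are converted at 30.4375 days/month). Two equidistant
#' observations are broken toward the earlier (pre-scan) visit.
#'
#' @param series an \code{\link{alsfrs_series}} with a valid \code{mri_t}
#' @param window_days maximum tolerated gap in days (default 100)
#' @return a one-row data.frame (t, score) or NULL if no observation falls
#'   inside the window
#' @export
select_alsfrs_for_mri <- function(series, window_days = 100) {
  stopifnot(inherits(series, "alsfrs_series"))
  if (is.na(series$mri_t)) return(NULL)
  obs <- series$observations
  gap_days <- abs(obs$t - series$mri_t) * DAYS_PER_MONTH
  # order() is stable and obs is sorted by t, so ties resolve to the earlier visit
  best <- order(gap_days)[1]
  if (gap_days[best] > window_days) return(NULL)
  obs[best, , drop = FALSE]
}

#' Natural log transform for strictly positive disease descriptors
#'
#' D50, rD50, cFS and cFL are log-transformed before entering any regression
#' or covariate slot, to achieve approximate normality. A value of zero
#' (rD50 exactly at onset) is a domain error, not an imputation.
#'
#' @param value strictly positive numeric
#' @export
log_transform <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop("log_transform requires strictly positive finite values", call. = FALSE)
  log(value)
}

#' Build the cohort analysis table
#'
#' One row per subject. For patients, descriptors are evaluated at the MRI
#' acquisition time and natural-log transformed; controls carry demographics
#' only. Patients whose fit did not converge are flagged and excluded from
#' downstream statistics.
#'
#' @param patients list of entries, each a list with \code{series}
#'   (\code{alsfrs_series}) and \code{fit} (\code{d50_fit})
#' @param controls optional data.frame with columns patient_id, age, sex, tiv
#' @param d50_cut aggressiveness cut-off in months
#' @param window_days ALSFRS-R/MRI matching window in days
#' @return a data.frame of class \code{cohort_table}
#' @export
build_cohort_table <- function(patients, controls = NULL, d50_cut = 30,
                               window_days = 100) {
  rows <- lapply(patients, function(p) {
    s <- p$series; f <- p$fit
    stopifnot(inherits(s, "alsfrs_series"), inherits(f, "d50_fit"))
    des <- derive_descriptors(f, s$mri_t, d50_cut = d50_cut)
    near <- select_alsfrs_for_mri(s, window_days = window_days)
    data.frame(
      patient_id = s$patient_id, group = "ALS",
      phase = des$phase, aggressiveness = des$aggressiveness,
      onset_type = s$onset_type, age = s$age_at_mri, sex = s$sex,
      tiv = s$tiv,
      d50 = f$d50, rd50 = des$rd50, cfs = des$cfs, cfl = des$cfl,
      log_d50 = log_transform(f$d50),
      log_rd50 = if (des$rd50 > 0) log_transform(des$rd50) else NA_real_,
      log_cfs = log_transform(des$cfs), log_cfl = log_transform(des$cfl),
      pr = if (is.null(near)) NA_real_ else
        progression_rate(near$score, max(near$t, 1e-9)),
      alsfrs_at_mri = if (is.null(near)) NA_real_ else near$score,
      converged = f$converged,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_bad <- sum(!tab$converged)
  if (n_bad > 0)
    message(n_bad, " patient(s) with non-converged fits flagged; ",
            "they are excluded from cohort statistics")
  if (!is.null(controls) && nrow(controls) > 0) {
    ctl <- data.frame(
      patient_id = controls$patient_id, group = "control",
      phase = NA_character_, aggressiveness = NA_character_,
      onset_type = NA_character_, age = controls$age, sex = controls$sex,
      tiv = controls$tiv,
      d50 = NA_real_, rd50 = NA_real_, cfs = NA_real_, cfl = NA_real_,
      log_d50 = NA_real_, log_rd50 = NA_real_, log_cfs = NA_real_,
      log_cfl = NA_real_, pr = NA_real_, alsfrs_at_mri = NA_real_,
      converged = NA, stringsAsFactors = FALSE)
    tab <- rbind(tab, ctl)
  }
  tab <- tab[order(tab$group, tab$patient_id), ]
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Descriptive cohort summary in the style of a clinical Table 1
#'
#' Means, SDs and ranges of the D50-model descriptors plus phase and
#' aggressiveness counts, computed over converged ALS rows.
#'
#' @param tab a \code{cohort_table}
#' @return a list with \code{stats} (data.frame of variable summaries),
#'   \code{phase_counts}, \code{aggressiveness_counts}, \code{onset_counts},
#'   \code{n_als}, \code{n_controls}
#' @export
cohort_summary <- function(tab) {
  stopifnot(inherits(tab, "data.frame"))
  als <- tab[tab$group == "ALS" & tab$converged %in% TRUE, ]
  msr <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x))
      return(c(mean = NA_real_, sd = NA_real_, min = NA_real_,
               max = NA_real_))
    c(mean = mean(x), sd = sd(x), min = min(x), max = max(x))
  }
  vars <- c("age", "d50", "rd50", "cfs", "cfl", "pr", "alsfrs_at_mri")
  stats <- do.call(rbind, lapply(vars, function(v) {
    s <- msr(als[[v]])
    data.frame(variable = v, mean = s["mean"], sd = s["sd"],
               min = s["min"], max = s["max"], row.names = NULL)
  }))
  list(stats = stats,
       phase_counts = table(factor(als$phase, levels = c("I", "II", "III/IV"))),
       aggressiveness_counts = table(factor(als$aggressiveness,
                                            levels = c("high", "low"))),
       onset_counts = table(factor(als$onset_type,
                                   levels = c("limb", "bulbar"))),
       n_als = nrow(als),
       n_controls = sum(tab$group == "control"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d ALS, %d control subject(s)\n",
              sum(x$group == "ALS"), sum(x$group == "control")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Group comparisons of demographics (reporting utility)
#'
#' Two-sample t-test for age and chi-square test for sex between ALS and
#' control rows, mirroring how case-control cohorts are conventionally
#' described. Reporting only, not an analysis endpoint.
#'
#' @param tab a \code{cohort_table} containing both groups
#' @return list with \code{age_test} (htest) and \code{sex_test} (htest)
#' @export
compare_demographics <- function(tab) {
  stopifnot(all(c("ALS", "control") %in% tab$group))
  age_test <- t.test(age ~ group, data = tab)
  sex_test <- suppressWarnings(chisq.test(table(tab$group, tab$sex)))
  list(age_test = age_test, sex_test = sex_test)
}

#' Read a clinical ALSFRS-R CSV into a list of series
#'
#' Expected columns: patient_id, t_months, alsfrs_r, onset_type, sex,
#' age_at_mri, mri_t_months, tiv; one row per observation.
#'
#' @param path CSV path
#' @return named list of \code{\link{alsfrs_series}}
#' @export
read_alsfrs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "t_months", "alsfrs_r", "onset_type", "sex",
            "age_at_mri", "mri_t_months", "tiv")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  lapply(split(df, df$patient_id), function(d)
    alsfrs_series(d$patient_id[1], d$t_months, d$alsfrs_r,
                  onset_type = d$onset_type[1], sex = d$sex[1],
                  age_at_mri = d$age_at_mri[1], mri_t = d$mri_t_months[1],
                  tiv = d$tiv[1]))
}

#' Write a list of ALSFRS-R series to the clinical CSV dialect
#'
#' @param series_list list of \code{\link{alsfrs_series}}
#' @param path output CSV path
#' @export
write_alsfrs_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(patient_id = s$patient_id, t_months = s$observations$t,
               alsfrs_r = s$observations$score, onset_type = s$onset_type,
               sex = s$sex, age_at_mri = s$age_at_mri, mri_t_months = s$mri_t,
               tiv = s$tiv, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Fit the D50 model to every patient and tabulate descriptors
#'
#' @param series_list list of \code{\link{alsfrs_series}}
#' @param control a \code{\link{d50_fit_control}}
#' @param d50_cut aggressiveness cut-off in months
#' @return list with \code{fits} (per-patient list of series+fit) and
#'   \code{table} (per-patient descriptor data.frame)
#' @export
fit_cohort <- function(series_list, control = d50_fit_control(),
                       d50_cut = 30) {
  fits <- lapply(series_list, function(s)
    list(series = s, fit = fit_d50(s, control = control)))
  tab <- build_cohort_table(fits, d50_cut = d50_cut)
  list(fits = fits, table = tab)
}
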