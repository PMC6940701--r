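#' The D50 disease-progression model
#'
#' The model describes an ALS patient's functional decline as a sigmoidal
#' transition from full health (ALSFRS-R = 48) to complete functional loss
#' (ALSFRS-R = 0):
#' \deqn{F(t) = \frac{48}{1 + \exp\{(t - D50)/s\}}}
#' where \code{t} is months since symptom onset, \code{D50} is the time at
#' which half of the functionality is lost (F = 24) and \code{s} is a
#' time-scale (steepness) parameter in months. \code{D50} summarises overall
#' disease aggressiveness; normalising time by \code{2 * D50} gives the
#' unitless rD50 scale of individual disease covered (0 = onset, 0.5 = half
#' of functionality lost).
#'
#' @param t months since symptom onset (numeric, vectorised)
#' @param d50 D50 in months, > 0
#' @param slope time-scale parameter in months, > 0
#' @return model ALSFRS-R value(s) in (0, 48)
#' @examples
#' sigmoid_value(30, d50 = 30, slope = 7.5) # exactly 24 at the midpoint
#' @export
sigmoid_value <- function(t, d50, slope) {
  check_sigmoid_params(d50, slope)
  stopifnot(is.numeric(t), all(is.finite(t)))
  48 / (1 + exp((t - d50) / slope))
}

check_sigmoid_params <- function(d50, slope) {
  if (!is.numeric(d50) || length(d50) != 1L || !is.finite(d50) || d50 <= 0)
    stop("`d50` must be a single positive finite number", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0)
    stop("`slope` must be a single positive finite number", call. = FALSE)
  invisible(TRUE)
}

#' Construct one patient's timed ALSFRS-R series
#'
#' @param patient_id opaque identifier
#' @param t months since symptom onset for each observation (>= 0)
#' @param score ALSFRS-R total score for each observation (0-48)
#' @param onset_type "limb" or "bulbar"
#' @param sex "female" or "male"
#' @param age_at_mri age in years at MRI acquisition
#' @param mri_t months since onset at MRI acquisition (>= 0)
#' @param tiv total intracranial volume (arbitrary volume units)
#' @return an object of class \code{alsfrs_series}; observations are stored
#'   sorted by time
#' @export
alsfrs_series <- function(patient_id, t, score,
                          onset_type = c("limb", "bulbar"),
                          sex = c("female", "male"),
                          age_at_mri = NA_real_, mri_t = NA_real_,
                          tiv = NA_real_) {
  onset_type <- match.arg(onset_type)
  sex <- match.arg(sex)
  stopifnot(length(t) == length(score), length(t) >= 1L)
  if (!all(is.finite(t)) || any(t < 0))
    stop("observation times must be finite and >= 0", call. = FALSE)
  if (any(score < 0 | score > 48))
    stop("ALSFRS-R scores must lie in [0, 48]", call. = FALSE)
  if (!is.na(mri_t) && mri_t < 0)
    stop("`mri_t` must be >= 0", call. = FALSE)
  ord <- order(t, score)
  structure(
    list(patient_id = patient_id,
         observations = data.frame(t = as.numeric(t)[ord],
                                   score = as.numeric(score)[ord]),
         onset_type = onset_type, sex = sex,
         age_at_mri = as.numeric(age_at_mri),
         mri_t = as.numeric(mri_t), tiv = as.numeric(tiv)),
    class = "alsfrs_series")
}

#' @export
print.alsfrs_series <- function(x, ...) {
  cat(sprintf("<alsfrs_series> patient %s: %d observation(s), %s onset, %s\n",
              x$patient_id, nrow(x$observations), x$onset_type, x$sex))
  invisible(x)
}

#' Fitting options for the D50 model
#'
#' @param anchor_onset append a pseudo-observation (t = 0, score = 48); the
#'   model's premise of full functionality at symptom onset, and what makes
#'   single-visit series fittable. Default TRUE.
#' @param d50_bounds,slope_bounds box constraints in months for the two
#'   parameters
#' @param max_score the upper plateau of the sigmoid (48 for the ALSFRS-R)
#' @param tol convergence tolerance on the objective
#' @param max_iter optimizer iteration budget
#' @export
d50_fit_control <- function(anchor_onset = TRUE,
                            d50_bounds = c(0.1, 1200),
                            slope_bounds = c(0.1, 600),
                            max_score = 48,
                            tol = 1e-8, max_iter = 500L) {
  stopifnot(d50_bounds[1] > 0, diff(d50_bounds) > 0,
            slope_bounds[1] > 0, diff(slope_bounds) > 0,
            max_score > 0, tol > 0, max_iter >= 1)
  list(anchor_onset = isTRUE(anchor_onset), d50_bounds = d50_bounds,
       slope_bounds = slope_bounds, max_score = max_score,
       tol = tol, max_iter = as.integer(max_iter))
}

#' Fit the D50 sigmoid to an ALSFRS-R series
#'
#' Bounded nonlinear least squares in (D50, slope), minimising the residual
#' sum of squares between observed scores and the sigmoid. Deterministic
#' multi-start: one start from linear extrapolation of the progression rate
#' to score 24, one from the last observation time. Integer scores are fitted
#' as reals.
#'
#' @param series an \code{\link{alsfrs_series}}
#' @param control a \code{\link{d50_fit_control}} list
#' @return an object of class \code{d50_fit} with elements \code{d50},
#'   \code{slope}, \code{converged}, \code{rss}, \code{n_obs}
#' @export
fit_d50 <- function(series, control = d50_fit_control()) {
  stopifnot(inherits(series, "alsfrs_series"))
  obs <- series$observations
  if (control$anchor_onset)
    obs <- rbind(data.frame(t = 0, score = control$max_score), obs)
  if (all(obs$score >= control$max_score))
    stop("degenerate fit: all observations at the plateau (score ",
         control$max_score, "); D50 is unidentifiable", call. = FALSE)

  fmax <- control$max_score
  rss_fun <- function(par) {
    pred <- fmax / (1 + exp((obs$t - par[1]) / par[2]))
    sum((obs$score - pred)^2)
  }

  # start 1: PR-style linear extrapolation to the midpoint score
  last <- obs[nrow(obs), ]
  pr <- (fmax - last$score) / max(last$t, 1e-6)
  d50_start1 <- if (pr > 1e-6) (fmax / 2) / pr else 2 * max(last$t, 1)
  # start 2: the last observation time
  starts <- list(c(d50_start1, d50_start1 / 4), c(max(last$t, 1), max(last$t, 1) / 4))
  lower <- c(control$d50_bounds[1], control$slope_bounds[1])
  upper <- c(control$d50_bounds[2], control$slope_bounds[2])
  clip <- function(p) pmin(pmax(p, lower), upper)

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(clip(p0), rss_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = control$max_iter,
                                  factr = control$tol / .Machine$double.eps,
                                  pgtol = 0)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(d50 = d50_start1, slope = d50_start1 / 4,
                          converged = FALSE, rss = rss_fun(clip(starts[[1]])),
                          n_obs = nrow(obs), max_score = fmax),
                     class = "d50_fit"))
  structure(list(d50 = best$par[1], slope = best$par[2],
                 converged = best$convergence == 0,
                 rss = best$value, n_obs = nrow(obs), max_score = fmax),
            class = "d50_fit")
}

#' @export
print.d50_fit <- function(x, ...) {
  cat(sprintf("<d50_fit> D50 = %.3f mo, slope = %.3f mo, rss = %.4g (n = %d, %s)\n",
              x$d50, x$slope, x$rss, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Derive D50-model descriptors at a reference time
#'
#' At reference time \code{t_ref} (e.g. MRI acquisition):
#' rD50 = t_ref / (2 D50), the unitless disease covered;
#' cFS = F(t_ref), the calculated functional state in ALSFRS-R points;
#' cFL = -dF/dt at t_ref, the calculated functional loss rate in points lost
#' per month; the phase (I, II, III/IV) from rD50; and the aggressiveness
#' class from D50 against the cut-off.
#'
#' @param fit a \code{d50_fit}
#' @param t_ref reference time in months since onset, >= 0
#' @param d50_cut aggressiveness cut-off in months (default 30)
#' @return a one-row data.frame with rd50, cfs, cfl, phase, aggressiveness
#' @export
derive_descriptors <- function(fit, t_ref, d50_cut = 30) {
  stopifnot(inherits(fit, "d50_fit"))
  if (!is.numeric(t_ref) || length(t_ref) != 1L || !is.finite(t_ref) ||
      t_ref < 0)
    stop("`t_ref` must be a single finite number >= 0", call. = FALSE)
  x <- (t_ref - fit$d50) / fit$slope
  ex <- exp(x)
  data.frame(
    rd50 = t_ref / (2 * fit$d50),
    cfs = fit$max_score / (1 + ex),
    cfl = (fit$max_score / fit$slope) / (ex + 2 + exp(-x)),
    phase = assign_phase(t_ref / (2 * fit$d50)),
    aggressiveness = classify_aggressiveness(fit$d50, d50_cut),
    stringsAsFactors = FALSE)
}

#' Assign the rD50-derived disease phase
#'
#' Half-open intervals, lower bound inclusive: Phase I for rD50 in [0, 0.25),
#' Phase II for [0.25, 0.5), Phases III/IV (pooled) for rD50 >= 0.5.
#'
#' @param rd50 relative D50 value(s), >= 0
#' @return character vector with levels "I", "II", "III/IV"
#' @export
assign_phase <- function(rd50) {
  if (!is.numeric(rd50) || any(!is.finite(rd50)) || any(rd50 < 0))
    stop("`rd50` must be finite and >= 0", call. = FALSE)
  ifelse(rd50 < 0.25, "I", ifelse(rd50 < 0.5, "II", "III/IV"))
}

#' Classify overall disease aggressiveness from D50
#'
#' @param d50 D50 value(s) in months, > 0
#' @param d50_cut cut-off in months; D50 < cut is "high", D50 >= cut is "low"
#' @return character vector with levels "high", "low"
#' @export
classify_aggressiveness <- function(d50, d50_cut = 30) {
  if (!is.numeric(d50) || any(!is.finite(d50)) || any(d50 <= 0))
    stop("`d50` must be finite and > 0", call. = FALSE)
  stopifnot(is.numeric(d50_cut), d50_cut > 0)
  ifelse(d50 < d50_cut, "high", "low")
}

#' Linear progression rate
#'
#' The classical linear-decline index the D50 model refines:
#' PR = (48 - current ALSFRS-R) / months since symptom onset.
#'
#' @param current_score ALSFRS-R total (0-48)
#' @param t months since symptom onset, > 0
#' @return points lost per month
#' @export
progression_rate <- function(current_score, t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be finite and > 0", call. = FALSE)
  if (any(current_score < 0 | current_score > 48))
    stop("`current_score` must lie in [0, 48]", call. = FALSE)
  (48 - current_score) / t
}
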