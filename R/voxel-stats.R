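#' Design matrix with a contrast
#'
#' A subjects-by-predictors real matrix (ANCOVA-style: effects of interest
#' plus nuisance covariates and an intercept) together with a contrast weight
#' vector over its columns. The matrix must be of full column rank; a
#' rank-deficient design raises an error naming the collinear columns.
#'
#' @param X numeric matrix or data.frame (coerced); columns must be named
#' @param contrast numeric weight vector, one entry per column, or a single
#'   column name (weight 1 on it)
#' @return object of class \code{vbm_design}
#' @export
vbm_design <- function(X, contrast) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)) || any(colnames(X) == ""))
    stop("all design columns must be named", call. = FALSE)
  if (is.character(contrast) && length(contrast) == 1L) {
    w <- rep(0, ncol(X)); names(w) <- colnames(X)
    if (!contrast %in% colnames(X))
      stop("contrast column not in design: ", contrast, call. = FALSE)
    w[contrast] <- 1
    contrast <- w
  }
  if (length(contrast) != ncol(X))
    stop("contrast length must equal the number of design columns",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, contrast = as.numeric(contrast)),
            class = "vbm_design")
}

#' @export
print.vbm_design <- function(x, ...) {
  cat(sprintf("<vbm_design> %d subjects x %d columns (%s); contrast: %s\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              paste(x$contrast, collapse = " ")))
  invisible(x)
}

#' TFCE parameters
#'
#' Height exponent H, extent exponent E, integration step dh and the voxel
#' connectivity. Defaults H = 2, E = 0.5, connectivity 26 are the
#' field-standard TFCE settings; dh = NULL means max(statistic)/100, chosen
#' per map.
#'
#' @param H height exponent (>= 0)
#' @param E extent exponent (>= 0)
#' @param dh integration step in statistic units (> 0), or NULL for max/100
#' @param connectivity 6, 18 or 26
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 26) {
  stopifnot(H >= 0, E >= 0, is.null(dh) || dh > 0,
            connectivity %in% c(6, 18, 26))
  list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity))
}

#' Voxel-wise GLM t-map
#'
#' Ordinary least squares per in-mask voxel with a common design:
#' t = c'beta_hat / sqrt(sigma2_hat * c'(X'X)^{-1}c), df = n - rank(X).
#' Out-of-mask voxels are zero.
#'
#' @param Y subjects-by-voxels matrix (see \code{\link{stack_volumes}})
#' @param design a \code{\link{vbm_design}}
#' @param mask 3D logical array (or NULL for all voxels)
#' @return list with \code{t} (3D array), \code{df}, \code{dim3}
#' @export
fit_glm_tmap <- function(Y, design, mask = NULL) {
  stopifnot(inherits(design, "vbm_design"))
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("Y rows must match design rows", call. = FALSE)
  if (n < p + 2) stop("need at least p + 2 subjects", call. = FALSE)
  dim3 <- data_dim3(Y, mask)
  keep <- if (is.null(mask)) seq_len(ncol(Y)) else which(as.logical(mask))
  if (!length(keep)) stop("mask is empty", call. = FALSE)
  tvals <- glm_tvals(Y[, keep, drop = FALSE], X, design$contrast)
  tmap <- array(0, dim3)
  tmap[keep] <- tvals
  list(t = tmap, df = n - p, dim3 = dim3)
}

# grid dimensions from the data attribute (dropped by row subsetting) or the mask
data_dim3 <- function(Y, mask) {
  dim3 <- attr(Y, "dim3")
  if (is.null(dim3) && !is.null(mask)) dim3 <- dim(mask)
  if (is.null(dim3))
    stop("Y must carry a dim3 attribute (see stack_volumes) or a mask must ",
         "be supplied", call. = FALSE)
  if (prod(dim3) != ncol(Y))
    stop("grid dimensions do not match the number of voxels", call. = FALSE)
  dim3
}

# vectorised OLS t-values across voxels for a common design
glm_tvals <- function(Ym, X, contrast) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  pinv <- XtXinv %*% t(X)
  beta <- pinv %*% Ym
  res <- Ym - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  varc <- drop(t(contrast) %*% XtXinv %*% contrast)
  num <- drop(crossprod(contrast, beta))
  denom <- sqrt(sigma2 * varc)
  tv <- ifelse(denom > 0, num / denom, 0)
  tv
}

#' Threshold-free cluster enhancement
#'
#' TFCE(p) = sum over thresholds h <= stat(p) of e_p(h)^E h^H dh, where
#' e_p(h) is the voxel count of the connected suprathreshold component at
#' height h containing p. Thresholds are sampled at midpoints
#' h = dh/2, 3dh/2, ..., which keeps the discrete integral second-order
#' accurate in dh. Only the positive support of the map is enhanced; for
#' two-sided inference apply the transform to -map separately.
#'
#' @param stat_map 3D numeric array (a t-map)
#' @param mask 3D logical array or NULL
#' @param params a \code{\link{tfce_params}}
#' @return 3D array of TFCE scores (>= 0, zero where stat <= 0)
#' @export
tfce_transform <- function(stat_map, mask = NULL, params = tfce_params()) {
  d <- dim(stat_map)
  stopifnot(length(d) == 3)
  s <- stat_map
  if (!is.null(mask)) s[!mask] <- 0
  dh <- params$dh
  if (is.null(dh)) {
    mx <- max(s)
    if (mx <= 0) return(array(0, d))
    dh <- mx / 100
  }
  array(.tfce_cpp(as.numeric(s), as.integer(d), params$H, params$E, dh,
                  params$connectivity), d)
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical array
#' @param connectivity 6, 18 or 26
#' @return 3D integer array of component labels (0 = background)
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3, connectivity %in% c(6, 18, 26))
  array(.label_components_cpp(as.logical(mask), as.integer(d),
                              as.integer(connectivity)), d)
}

#' Max-TFCE permutation FWE correction (Freedman-Lane)
#'
#' The nuisance part of the design (columns with zero contrast weight,
#' including the intercept) is regressed out of the data; the residuals are
#' row-permuted, the nuisance fit added back, and the full model refitted.
#' The maximum in-mask TFCE score per permutation forms the null
#' distribution; fwe_p(voxel) = (1 + #{perm max >= observed}) / (n_perm + 1).
#' Deterministic under \code{seed}.
#'
#' @param Y subjects-by-voxels matrix with \code{dim3} attribute
#' @param design a \code{\link{vbm_design}}
#' @param mask 3D logical array or NULL
#' @param params a \code{\link{tfce_params}}
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed
#' @param alpha nominal FWE level, used only to warn when the permutation
#'   count cannot resolve it (alpha needs n_perm >= 1/alpha - 1)
#' @return object of class \code{voxel_stat_result}: t_map, tfce_map,
#'   fwe_p_map, max_null, n_perm, df, dim3, mask
#' @export
permutation_fwe <- function(Y, design, mask = NULL, params = tfce_params(),
                            n_perm = 1000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(design, "vbm_design"), n_perm >= 100)
  if (n_perm < 1 / alpha - 1)
    warning(sprintf("n_perm = %d cannot resolve alpha = %g (needs >= %d)",
                    n_perm, alpha, ceiling(1 / alpha - 1)), call. = FALSE)
  X <- design$X
  n <- nrow(X)
  dim3 <- data_dim3(Y, mask)
  keep <- if (is.null(mask)) seq_len(prod(dim3)) else which(as.logical(mask))
  if (!length(keep)) stop("mask is empty", call. = FALSE)
  Ym <- Y[, keep, drop = FALSE]

  # observed statistic and its TFCE; dh is frozen from the observed map so
  # permuted maps are enhanced on the same scale
  t_obs <- glm_tvals(Ym, X, design$contrast)
  tmap <- array(0, dim3); tmap[keep] <- t_obs
  dh <- params$dh
  if (is.null(dh)) dh <- if (max(tmap) > 0) max(tmap) / 100 else 1e-3
  params_run <- params; params_run$dh <- dh
  tfce_obs <- tfce_transform(tmap, mask, params_run)

  # Freedman-Lane: partition into nuisance (zero contrast weight) columns
  nuis <- which(design$contrast == 0)
  if (length(nuis)) {
    Z <- X[, nuis, drop = FALSE]
    gamma <- chol2inv(chol(crossprod(Z))) %*% t(Z) %*% Ym
    fit_z <- Z %*% gamma
    resid_z <- Ym - fit_z
  } else {
    fit_z <- matrix(0, n, ncol(Ym))
    resid_z <- Ym
  }

  set.seed(seed)
  max_null <- numeric(n_perm)
  pm <- array(0, dim3)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Yb <- fit_z + resid_z[perm, , drop = FALSE]
    tb <- glm_tvals(Yb, X, design$contrast)
    pm[] <- 0; pm[keep] <- tb
    tfce_b <- tfce_transform(pm, mask, params_run)
    max_null[b] <- max(tfce_b)
  }
  fwe_p <- array(1, dim3)
  obs_in <- tfce_obs[keep]
  # vectorised exceedance count against the sorted null maxima
  srt <- sort(max_null)
  ge <- n_perm - findInterval(obs_in, srt, left.open = TRUE)
  fwe_p[keep] <- (1 + ge) / (n_perm + 1)
  structure(list(t_map = tmap, tfce_map = tfce_obs, fwe_p_map = fwe_p,
                 max_null = max_null, n_perm = n_perm,
                 df = n - ncol(X), dim3 = dim3,
                 mask = if (is.null(mask)) array(TRUE, dim3) else mask,
                 params = params_run, seed = seed),
            class = "voxel_stat_result")
}

#' @export
print.voxel_stat_result <- function(x, ...) {
  cat(sprintf(
    "<voxel_stat_result> %s grid, %d permutations, min FWE p = %.4g\n",
    paste(x$dim3, collapse = "x"), x$n_perm, min(x$fwe_p_map[x$mask])))
  invisible(x)
}

#' Voxel-wise regression restricted to a mask
#'
#' Slope t-map for a (log-transformed) disease descriptor with optional
#' covariates, computed within \code{restrict_mask} only (e.g. the
#' significant clusters of a prior case-control contrast), then TFCE and
#' max-statistic permutation as in \code{\link{permutation_fwe}}.
#'
#' @param Y subjects-by-voxels matrix
#' @param predictor numeric vector, the regressor of interest
#' @param covariates data.frame / matrix of nuisance covariates or NULL
#' @param restrict_mask 3D logical array; must be nonempty
#' @param ... passed to \code{\link{permutation_fwe}}
#' @param negative test for negative slopes (density decreasing with the
#'   predictor) if TRUE (default), positive slopes otherwise
#' @return a \code{voxel_stat_result}
#' @export
masked_regression <- function(Y, predictor, covariates = NULL, restrict_mask,
                              ..., negative = TRUE) {
  if (!any(restrict_mask)) stop("restrict mask is empty", call. = FALSE)
  df <- data.frame(intercept = 1, predictor = as.numeric(predictor))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  w <- rep(0, ncol(df)); names(w) <- names(df)
  w["predictor"] <- if (negative) -1 else 1
  design <- vbm_design(df, w)
  permutation_fwe(Y, design, mask = restrict_mask, ...)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal level in (0, 1)
#' @param n_tests number of tests in the family (>= 1)
#' @return alpha / n_tests
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (n_tests < 1) stop("`n_tests` must be >= 1", call. = FALSE)
  alpha / n_tests
}

#' Extract significant clusters from a permutation result
#'
#' Connected components of {fwe_p < alpha} within the analysis mask, sorted
#' by size descending, ties by peak TFCE then lexicographic peak coordinate.
#'
#' @param result a \code{voxel_stat_result}
#' @param alpha FWE significance level
#' @param connectivity 6, 18 or 26 (default: the result's TFCE connectivity)
#' @return data.frame with label, n_voxels, peak_x, peak_y, peak_z,
#'   peak_tfce, fwe_p; zero rows if nothing is significant
#' @export
extract_clusters <- function(result, alpha = 0.05, connectivity = NULL) {
  stopifnot(inherits(result, "voxel_stat_result"))
  if (is.null(connectivity)) connectivity <- result$params$connectivity
  sig <- result$fwe_p_map < alpha & result$mask
  empty <- data.frame(label = integer(), n_voxels = integer(),
                      peak_x = integer(), peak_y = integer(),
                      peak_z = integer(), peak_tfce = numeric(),
                      fwe_p = numeric())
  if (!any(sig)) return(empty)
  labels <- label_components(sig, connectivity)
  rows <- lapply(seq_len(max(labels)), function(l) {
    vox <- which(labels == l)
    peak <- vox[order(-result$tfce_map[vox], vox)][1]
    co <- arrayInd(peak, result$dim3)
    data.frame(label = l, n_voxels = length(vox),
               peak_x = co[1], peak_y = co[2], peak_z = co[3],
               peak_tfce = result$tfce_map[peak],
               fwe_p = result$fwe_p_map[peak])
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$n_voxels, -tab$peak_tfce,
               tab$peak_x, tab$peak_y, tab$peak_z)
  tab <- tab[ord, ]
  tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
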