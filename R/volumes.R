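#' A 3D tissue-density volume
#'
#' A scalar field in [0, 1] (a smoothed tissue-probability segment) on a
#' regular grid, with voxel size in mm and a tissue label.
#'
#' @param grid 3D numeric array with values in [0, 1]
#' @param voxel_size voxel edge length(s) in mm (length 1 or 3)
#' @param tissue "GM" or "WM"
#' @param subject_id optional subject identifier
#' @export
density_volume <- function(grid, voxel_size = 4, tissue = c("GM", "WM"),
                           subject_id = NA_character_) {
  tissue <- match.arg(tissue)
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > 1))
    stop("density values must be finite and in [0, 1]", call. = FALSE)
  structure(list(grid = grid,
                 voxel_size = rep(as.numeric(voxel_size), length.out = 3),
                 tissue = tissue, subject_id = subject_id),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("<density_volume> %s, %s grid @ %s mm, subject %s\n",
              x$tissue, paste(dim(x$grid), collapse = "x"),
              paste(x$voxel_size, collapse = "x"), x$subject_id))
  invisible(x)
}

#' A region carrying a planted group effect
#'
#' @param mask 3D logical array (nonempty)
#' @param tissue "GM" or "WM"
#' @param effect_size fractional density reduction per unit predictor (>= 0)
#' @param name optional label
#' @export
effect_region <- function(mask, tissue = c("GM", "WM"), effect_size = 0.1,
                          name = NA_character_) {
  tissue <- match.arg(tissue)
  stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask))
  if (!any(mask)) stop("effect region mask is empty", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  structure(list(mask = mask, tissue = tissue,
                 effect_size = effect_size, name = name),
            class = "effect_region")
}

#' Axis-aligned box mask
#'
#' @param dim3 grid dimensions
#' @param x,y,z index ranges of the box
#' @return 3D logical array
#' @export
box_mask <- function(dim3, x, y, z) {
  m <- array(FALSE, dim3)
  m[x, y, z] <- TRUE
  m
}

#' Default planted-effect regions on the synthetic grid
#'
#' Three disjoint axis-aligned boxes standing in for the anatomy the field
#' reports in ALS: two GM boxes ("frontal", "temporal") and one WM box
#' ("tract").
#'
#' @param dim3 grid dimensions (default 32^3)
#' @param effect_size fractional reduction per unit predictor for each box
#' @return named list of \code{\link{effect_region}}
#' @export
default_effect_regions <- function(dim3 = c(32, 32, 32), effect_size = 0.1) {
  frac <- function(axis, lo, hi) {
    i <- max(1, round(lo * dim3[axis])):min(dim3[axis], round(hi * dim3[axis]))
    i
  }
  list(
    frontal = effect_region(
      box_mask(dim3, frac(1, 0.19, 0.34), frac(2, 0.63, 0.78),
               frac(3, 0.50, 0.66)), "GM", effect_size, "frontal"),
    temporal = effect_region(
      box_mask(dim3, frac(1, 0.63, 0.78), frac(2, 0.25, 0.41),
               frac(3, 0.31, 0.47)), "GM", effect_size, "temporal"),
    tract = effect_region(
      box_mask(dim3, frac(1, 0.41, 0.56), frac(2, 0.44, 0.59),
               frac(3, 0.56, 0.72)), "WM", effect_size, "tract"))
}

#' Generate a smooth tissue template
#'
#' A seeded random blob field: white noise smoothed to the requested FWHM
#' and linearly rescaled into [lo, hi]. Stands in for a normalised mean
#' tissue-probability segment.
#'
#' @param tissue "GM" or "WM"
#' @param dim3 grid dimensions
#' @param voxel_size mm per voxel edge
#' @param fwhm_mm smoothness of the blob field
#' @param range density range c(lo, hi) of the template
#' @param seed RNG seed
#' @return a \code{\link{density_volume}}
#' @export
make_template <- function(tissue = c("GM", "WM"), dim3 = c(32, 32, 32),
                          voxel_size = 4, fwhm_mm = 24,
                          range = c(0.25, 0.85), seed = 1) {
  tissue <- match.arg(tissue)
  set.seed(seed + if (tissue == "GM") 0L else 101L)
  raw <- array(rnorm(prod(dim3)), dim3)
  vol <- density_volume(array(0.5, dim3), voxel_size, tissue, "template")
  vol$grid <- raw
  sm <- gaussian_smooth(vol, fwhm_mm = fwhm_mm)$grid
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  vol$grid <- range[1] + sm * diff(range)
  vol
}

#' Generate one subject's density volume with planted effects
#'
#' density = template * prod over regions (1 - effect_size * predictor)
#' inside each region of the template's tissue, plus i.i.d. Gaussian noise,
#' clipped to [0, 1]. The per-region predictor is the subject's value of
#' whatever variable drives the planted effect (e.g. a group indicator or a
#' scaled descriptor). If an effect would push density negative before
#' clipping, a warning is issued.
#'
#' @param template a \code{\link{density_volume}}
#' @param predictors numeric vector, one value per region (recycled if 1)
#' @param regions list of \code{\link{effect_region}}
#' @param noise_sd Gaussian noise SD in density units
#' @param seed RNG seed
#' @param subject_id identifier stamped on the output
#' @return a \code{\link{density_volume}}
#' @export
generate_subject_volume <- function(template, predictors, regions,
                                    noise_sd = 0.05, seed = 1,
                                    subject_id = NA_character_) {
  stopifnot(inherits(template, "density_volume"), noise_sd >= 0)
  predictors <- rep(as.numeric(predictors), length.out = max(length(regions), 1))
  same_tissue <- vapply(regions, function(r) r$tissue == template$tissue, TRUE)
  regions <- regions[same_tissue]
  predictors <- predictors[same_tissue]
  g <- template$grid
  for (i in seq_along(regions)) {
    fac <- 1 - regions[[i]]$effect_size * predictors[i]
    if (fac < 0)
      warning("effect drives density negative before clipping in region ",
              regions[[i]]$name, call. = FALSE)
    g[regions[[i]]$mask] <- g[regions[[i]]$mask] * fac
  }
  set.seed(seed)
  if (noise_sd > 0) g <- g + rnorm(length(g), 0, noise_sd)
  density_volume(pmin(pmax(g, 0), 1), template$voxel_size, template$tissue,
                 subject_id)
}

reflect_index <- function(idx, n) {
  # edge-inclusive reflection (DCT-II boundary): ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
  idx <- ifelse(idx < 1, 1 - idx, idx)
  idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
  # a second fold suffices for kernels narrower than the axis
  idx <- ifelse(idx < 1, 1 - idx, idx)
  ifelse(idx > n, 2 * n + 1 - idx, idx)
}

conv1d_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(kernel) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kernel)) {
    idx <- reflect_index(seq_len(da[1]) + (j - r - 1), da[1])
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  aperm(array(out, da), order(perm))
}

#' Gaussian smoothing of a density volume
#'
#' Separable convolution with a normalised sampled Gaussian,
#' sigma = FWHM / (2 sqrt(2 ln 2)) per axis in voxel units, with reflective
#' (edge-inclusive) boundary handling, which preserves the field mean.
#'
#' @param vol a \code{\link{density_volume}} (or a bare 3D array, in which
#'   case \code{voxel_size} must be supplied)
#' @param fwhm_mm full width at half maximum in mm (default 8; 0 = identity)
#' @param voxel_size only used when \code{vol} is a bare array
#' @return same type as the input
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 8, voxel_size = NULL) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  is_dv <- inherits(vol, "density_volume")
  g <- if (is_dv) vol$grid else vol
  vs <- if (is_dv) vol$voxel_size else rep(voxel_size, length.out = 3)
  if (fwhm_mm > 0) {
    for (axis in 1:3) {
      sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs[axis]
      radius <- max(1L, ceiling(4 * sigma))
      k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
      k <- k / sum(k)
      g <- conv1d_axis(g, k, axis)
    }
  }
  if (is_dv) { vol$grid <- g; vol } else g
}

#' Implicit analysis mask from a set of volumes
#'
#' A voxel enters the analysis iff the mean density across subjects is at
#' least the absolute threshold. (Applied on the cohort mean rather than
#' per-image, for determinism.)
#'
#' @param volumes list of \code{\link{density_volume}} on a common grid
#' @param threshold absolute density threshold (default 0.2)
#' @return 3D logical array
#' @export
implicit_mask <- function(volumes, threshold = 0.2) {
  stopifnot(length(volumes) >= 1)
  d <- dim(volumes[[1]]$grid)
  acc <- array(0, d)
  for (v in volumes) {
    if (!identical(dim(v$grid), d))
      stop("volumes do not share a common grid", call. = FALSE)
    acc <- acc + v$grid
  }
  acc / length(volumes) >= threshold
}

#' Stack volumes into a subjects-by-voxels matrix
#'
#' @param volumes list of \code{\link{density_volume}} on a common grid
#' @return matrix with one row per subject; attribute \code{dim3} carries the
#'   grid dimensions, rownames the subject ids
#' @export
stack_volumes <- function(volumes) {
  d <- dim(volumes[[1]]$grid)
  Y <- do.call(rbind, lapply(volumes, function(v) {
    if (!identical(dim(v$grid), d))
      stop("volumes do not share a common grid", call. = FALSE)
    as.numeric(v$grid)
  }))
  rownames(Y) <- vapply(volumes, function(v) as.character(v$subject_id), "")
  attr(Y, "dim3") <- d
  Y
}
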