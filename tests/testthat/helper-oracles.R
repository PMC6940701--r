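# Independent pure-R oracles and small fixture builders used across tests.

# noiseless series generated from known sigmoid parameters
noiseless_series <- function(d50, slope, times, id = "p", ...) {
  alsfrs_series(id, times, sigmoid_value(times, d50, slope), ...)
}

# brute-force grid-search fit over (d50, slope); oracle for fit_d50
grid_fit_oracle <- function(series, d50_grid, slope_grid, anchor = TRUE) {
  obs <- series$observations
  if (anchor) obs <- rbind(data.frame(t = 0, score = 48), obs)
  best <- c(NA, NA, Inf)
  for (d in d50_grid) for (s in slope_grid) {
    rss <- sum((obs$score - 48 / (1 + exp((obs$t - d) / s)))^2)
    if (rss < best[3]) best <- c(d, s, rss)
  }
  list(d50 = best[1], slope = best[2], rss = best[3])
}

# precompute the neighbour index list of every voxel of a 3D grid
neighbour_list <- function(dim3, connectivity = 26) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  co <- arrayInd(seq_len(prod(dim3)), dim3)
  lapply(seq_len(nrow(co)), function(v) {
    nb <- sweep(offs, 2, co[v, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
      nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
      nb[, 3] >= 1 & nb[, 3] <= dim3[3]
    nb <- nb[ok, , drop = FALSE]
    nb[, 1] + dim3[1] * (nb[, 2] - 1) + dim3[1] * dim3[2] * (nb[, 3] - 1)
  })
}

# full relabelling at every threshold: BFS connected components
flood_label <- function(sup, nbrs, n) {
  lab <- integer(n)
  insup <- logical(n)
  insup[sup] <- TRUE
  cur <- 0L
  for (v0 in sup) {
    if (lab[v0] != 0L) next
    cur <- cur + 1L
    queue <- v0
    lab[v0] <- cur
    while (length(queue)) {
      x <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- nbrs[[x]]
      nb <- nb[insup[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# brute-force TFCE reference: explicit loop over midpoint thresholds with
# full relabelling at each height
tfce_reference <- function(map, H = 2, E = 0.5, dh, connectivity = 26,
                           nbrs = NULL) {
  dim3 <- dim(map)
  n <- prod(dim3)
  out <- array(0, dim3)
  mx <- max(map)
  if (mx <= 0) return(out)
  if (is.null(nbrs)) nbrs <- neighbour_list(dim3, connectivity)
  insup <- logical(n)
  nsteps <- floor(mx / dh + 0.5)
  for (k in seq_len(nsteps)) {
    h <- (k - 0.5) * dh
    sup <- which(map >= h)
    if (!length(sup)) break
    lab <- flood_label(sup, nbrs, n)
    sizes <- tabulate(lab[sup])
    out[sup] <- out[sup] + sizes[lab[sup]]^E * h^H * dh
  }
  out
}

# smooth positive random t-like maps for TFCE oracle comparisons
random_stat_map <- function(dim3 = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  m <- array(rnorm(prod(dim3)), dim3)
  m <- gaussian_smooth(m, fwhm_mm = 3, voxel_size = 1)
  m * 3
}

# subjects-x-voxels noise matrix with the dim3 attribute set
noise_data <- function(n, dim3, sd = 1, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm(n * prod(dim3), sd = sd), n)
  attr(Y, "dim3") <- dim3
  Y
}

two_group_design <- function(n_per_group, direction = 1) {
  g <- rep(0:1, each = n_per_group)
  vbm_design(data.frame(intercept = 1, group = g), c(0, direction))
}
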