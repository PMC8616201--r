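# shared fixtures and independent oracles (kept deliberately naive)

# minimal custom tissue tables for targeted transport regimes
toy_table <- function(mu_a, mu_s, g, label = 1L, tissue = "toy") {
  validate_tissue_table(data.frame(
    label = label, tissue = tissue, mu_a = mu_a, mu_s = mu_s, g = g,
    n_ri = 1.4))
}

# in-grid length of a ray from a point inside an axis-aligned box
# [0, dims*h]^3 (slab clipping) — brute-force oracle for traverse_voxels
slab_ray_length <- function(origin, dir, dims, h) {
  lo <- rep(0, 3); hi <- dims * h
  tmax <- Inf
  for (a in 1:3) {
    if (dir[a] > 0) tmax <- min(tmax, (hi[a] - origin[a]) / dir[a])
    else if (dir[a] < 0) tmax <- min(tmax, (lo[a] - origin[a]) / dir[a])
  }
  tmax
}

# nested grid-search oracle for the segment-segment minimum distance:
# dense parameter sampling refined around the running optimum
segment_distance_oracle <- function(a, b, n = 101L, levels = 4L) {
  pa <- a[1, ]; ua <- a[2, ] - a[1, ]
  pb <- b[1, ]; ub <- b[2, ] - b[1, ]
  slo <- 0; shi <- 1; tlo <- 0; thi <- 1
  best <- Inf
  for (lev in seq_len(levels)) {
    s <- seq(slo, shi, length.out = n)
    t <- seq(tlo, thi, length.out = n)
    A <- outer(s, rep(1, n))
    B <- outer(rep(1, n), t)
    dx <- pa[1] + A * ua[1] - pb[1] - B * ub[1]
    dy <- pa[2] + A * ua[2] - pb[2] - B * ub[2]
    dz <- pa[3] + A * ua[3] - pb[3] - B * ub[3]
    d2 <- dx * dx + dy * dy + dz * dz
    k <- arrayInd(which.min(d2), dim(d2))
    best <- sqrt(min(d2))
    ds <- (shi - slo) / (n - 1); dt <- (thi - tlo) / (n - 1)
    slo2 <- max(0, s[k[1]] - ds); shi2 <- min(1, s[k[1]] + ds)
    tlo2 <- max(0, t[k[2]] - dt); thi2 <- min(1, t[k[2]] + dt)
    slo <- slo2; shi <- shi2; tlo <- tlo2; thi <- thi2
  }
  best
}

# per-voxel radial distance from a world point, for shell-averaged
# comparisons against closed-form radial profiles
voxel_radii <- function(grid, center) {
  d <- grid$dims
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  ctr <- voxel_to_world(idx - 1, grid)
  list(idx = idx, r = sqrt(colSums((t(ctr) - center)^2)))
}

shell_mean <- function(map, radii, r0, halfwidth = 0.5) {
  sel <- abs(radii$r - r0) < halfwidth
  mean(map[radii$idx[sel, , drop = FALSE]])
}

# mean of a closed-form radial function over the same shell voxels,
# volume-averaged within each voxel (2x2x2 midpoint rule) because the
# track-length tally estimates the voxel-average fluence, not the value at
# the voxel centre — the distinction matters where the profile is convex
shell_mean_fn <- function(fn, grid, center, radii, r0, halfwidth = 0.5) {
  sel <- abs(radii$r - r0) < halfwidth
  ctrs <- voxel_to_world(radii$idx[sel, , drop = FALSE] - 1, grid)
  offs <- as.matrix(expand.grid(x = c(-0.25, 0.25), y = c(-0.25, 0.25),
                                z = c(-0.25, 0.25)))
  offs <- offs * matrix(grid$voxel_size, nrow(offs), 3, byrow = TRUE)
  vals <- 0
  for (k in seq_len(nrow(offs))) {
    p <- sweep(ctrs, 2, offs[k, ], `+`)
    vals <- vals + fn(sqrt(colSums((t(p) - center)^2)))
  }
  mean(vals / nrow(offs))
}
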