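# synthetic direction fields and an independent FACT oracle

# uniform straight field along `dir` on an nx x ny x nz grid
straight_field <- function(dim3, dir = c(1, 0, 0), qa = 1,
                           voxel_size = c(1, 1, 1)) {
  arr <- array(0, c(dim3, 3))
  for (k in 1:3) arr[, , , k] <- dir[k]
  synthetic_peak_map(arr, qa = qa, voxel_size = voxel_size)
}

# 90-degree elbow: fibers along +x for x <= bend, along +y after it
elbow_field <- function(dim3, bend, voxel_size = c(1, 1, 1)) {
  arr <- array(0, c(dim3, 3))
  for (x in seq_len(dim3[1])) {
    if (x <= bend) arr[x, , , 1] <- 1 else arr[x, , , 2] <- 1
  }
  synthetic_peak_map(arr, qa = 1, voxel_size = voxel_size)
}

# smooth mildly-curved single-fiber field (perturbations well under the
# angular threshold), seeded for reproducibility
curved_field <- function(dim3, seed = 1, wobble = 8,
                         voxel_size = c(1, 1, 1)) {
  set.seed(seed)
  arr <- array(0, c(dim3, 3))
  for (x in seq_len(dim3[1])) for (y in seq_len(dim3[2]))
    for (z in seq_len(dim3[3])) {
      th <- wobble * pi / 180 * sin(2 * pi * x / dim3[1]) +
        stats::rnorm(1, 0, 0.02)
      arr[x, y, z, ] <- c(cos(th), sin(th), 0)
    }
  synthetic_peak_map(arr, qa = 1, voxel_size = voxel_size)
}

# ---- independent FACT oracle -------------------------------------------
# Classic fiber assignment by continuous tracking: inside each voxel the
# path is a straight ray along that voxel's orientation; the direction is
# re-selected at each voxel boundary.  Exact ray-grid traversal, entirely
# independent of the package's Euler/interpolation machinery.
fact_oracle_half <- function(peaks, seed, u, theta_deg = 60, thr = 0,
                             max_pts = 10000) {
  d <- peaks$dim
  cos_th <- cos(theta_deg * pi / 180)
  dir_of <- function(V) {
    vi <- V[1] + d[1] * (V[2] - 1) + d[1] * d[2] * (V[3] - 1)
    if (peaks$n_peaks[vi] == 0L) return(NULL)
    if (peaks$qa[vi, 1] <= thr) return(NULL)
    peaks$hemi_dirs[peaks$dir_index[vi, 1], ]
  }
  p <- seed
  pts <- list(p)
  repeat {
    V <- round(p)
    if (any(V < 1 | V > d)) break
    a <- dir_of(V)
    if (is.null(a)) break
    dt <- sum(a * u)
    if (abs(dt) <= cos_th) break
    u <- if (dt >= 0) a else -a
    # exact exit point of the current voxel (faces at V +/- 0.5)
    tmin <- Inf
    for (ax in 1:3) {
      if (abs(u[ax]) < 1e-12) next
      bound <- V[ax] + 0.5 * sign(u[ax])
      t <- (bound - p[ax]) / u[ax]
      if (t > 1e-9 && t < tmin) tmin <- t
    }
    if (!is.finite(tmin)) break
    p <- p + (tmin + 1e-6) * u
    pts[[length(pts) + 1L]] <- p
    if (length(pts) >= max_pts) break
  }
  do.call(rbind, pts)
}

fact_oracle <- function(peaks, seed, u, theta_deg = 60, thr = 0) {
  fwd <- fact_oracle_half(peaks, seed, u, theta_deg, thr)
  bwd <- fact_oracle_half(peaks, seed, -u, theta_deg, thr)
  if (nrow(bwd) > 1L)
    rbind(bwd[rev(seq(2L, nrow(bwd))), , drop = FALSE], fwd)
  else fwd
}

# densify a polyline to a point spacing <= h (in the same units)
densify <- function(pts, h = 0.05) {
  if (nrow(pts) < 2L) return(pts)
  out <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / h))
    s <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]),
                      a[3] + s * (b[3] - a[3]))
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}

hausdorff <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}
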