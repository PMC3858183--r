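#' Tracking parameters for the generalized deterministic tracker
#'
#' @param index_threshold Termination/filter threshold on the chosen
#'   index.  No default: comparable thresholds are acquisition-dependent
#'   and should be calibrated (see [calibrate_threshold()]).
#' @param index_name Which index gates fiber orientations: `"qa"`
#'   (per-orientation) or the voxel-level `"fa"`, `"gfa"`, `"anatomy"`.
#' @param angular_threshold Maximum turning angle in degrees (0, 90].
#' @param step_size Euler step in mm; default half the smallest voxel
#'   dimension (resolved against the peak map at run time).
#' @param min_length,max_length Accepted streamline length range in mm;
#'   tracks shorter than `min_length` are discarded as fragments and each
#'   half-track is stopped at `max_length` as a runaway guard.
#' @param termination_weight Propagation stops when the summed
#'   interpolation weight of voxels contributing a selected fiber falls
#'   below this value (default 0.5).
#' @param interpolation `"trilinear"` (8-voxel weighted neighbourhood) or
#'   `"nearest"` (single nearest voxel; with a vanishing step size this
#'   reduces the tracker to FACT).
#' @param init_dir Seed initial direction rule: `"max"` = qualifying peak
#'   with the largest index value, or `"random"` = seeded random choice
#'   among qualifying peaks.
#' @param target_track_count Number of accepted streamlines to generate.
#' @param seed_budget Maximum seeds tried (default `200 *
#'   target_track_count`).
#' @param rng_seed Integer seed for the deterministic pseudorandom seed
#'   sequence.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(index_threshold,
                            index_name = c("qa", "fa", "gfa", "anatomy"),
                            angular_threshold = 60,
                            step_size = NULL,
                            min_length = 40,
                            max_length = 300,
                            termination_weight = 0.5,
                            interpolation = c("trilinear", "nearest"),
                            init_dir = c("max", "random"),
                            target_track_count = 2000,
                            seed_budget = NULL,
                            rng_seed = 1) {
  index_name <- match.arg(index_name)
  interpolation <- match.arg(interpolation)
  init_dir <- match.arg(init_dir)
  if (missing(index_threshold)) stop("index_threshold must be given")
  if (!(angular_threshold > 0 && angular_threshold <= 90))
    stop("angular_threshold must be in (0, 90] degrees")
  if (!is.null(step_size) && step_size <= 0) stop("step_size must be > 0")
  if (!(termination_weight > 0 && termination_weight <= 1))
    stop("termination_weight must be in (0, 1]")
  if (min_length < 0 || max_length <= 0 || max_length < min_length)
    stop("invalid min_length/max_length")
  structure(list(index_threshold = index_threshold,
                 index_name = index_name,
                 angular_threshold = angular_threshold,
                 step_size = step_size, min_length = min_length,
                 max_length = max_length,
                 termination_weight = termination_weight,
                 interpolation = interpolation, init_dir = init_dir,
                 target_track_count = target_track_count,
                 seed_budget = seed_budget, rng_seed = rng_seed),
            class = "tracking_params")
}

# ---- internal tracker context: flat-grid views of a peak map -----------

.tracker_context <- function(peaks, params) {
  nvox <- prod(peaks$dim)
  mp <- peaks$max_peaks
  Dx <- matrix(NA_real_, nvox, mp)
  Dy <- matrix(NA_real_, nvox, mp)
  Dz <- matrix(NA_real_, nvox, mp)
  Q <- matrix(-Inf, nvox, mp)
  npk <- integer(nvox)
  rows <- peaks$voxels
  npk[rows] <- peaks$n_peaks
  for (p in seq_len(mp)) {
    di <- peaks$dir_index[, p]
    has <- !is.na(di)
    Dx[rows[has], p] <- peaks$hemi_dirs[di[has], 1]
    Dy[rows[has], p] <- peaks$hemi_dirs[di[has], 2]
    Dz[rows[has], p] <- peaks$hemi_dirs[di[has], 3]
    Q[rows[has], p] <- peaks$qa[has, p]
  }
  idxval <- NULL
  if (params$index_name != "qa") {
    v <- peaks$indices[[params$index_name]]
    if (is.null(v))
      stop("peak map has no attached '", params$index_name,
           "' index; see attach_scalar_indices()")
    idxval <- rep(-Inf, nvox)
    idxval[rows] <- ifelse(is.na(v), -Inf, v)
  }
  step <- params$step_size
  if (is.null(step)) step <- min(peaks$voxel_size) / 2
  list(dim = peaks$dim, vs = peaks$voxel_size, mp = mp,
       Dx = Dx, Dy = Dy, Dz = Dz, Q = Q, npk = npk, idxval = idxval,
       cos_th = cos(params$angular_threshold * pi / 180),
       thr = params$index_threshold, tw = params$termination_weight,
       nearest = params$interpolation == "nearest",
       step = step, max_steps = ceiling(params$max_length / step))
}

# core selection at one linear voxel index; returns c(vx, vy, vz, qa) or NULL
.select_at <- function(ctx, vi, u) {
  k <- ctx$npk[vi]
  if (k == 0L) return(NULL)
  ks <- seq_len(k)
  dx <- ctx$Dx[vi, ks]; dy <- ctx$Dy[vi, ks]; dz <- ctx$Dz[vi, ks]
  qa <- ctx$Q[vi, ks]
  pass <- if (is.null(ctx$idxval)) qa > ctx$thr
          else rep(ctx$idxval[vi] > ctx$thr, k)
  dt <- dx * u[1] + dy * u[2] + dz * u[3]
  adt <- abs(dt)
  pass <- pass & adt > ctx$cos_th
  if (!any(pass)) return(NULL)
  w <- which(pass)
  best <- w[order(-adt[w], -qa[w])[1]]
  s <- if (dt[best] >= 0) 1 else -1
  c(s * dx[best], s * dy[best], s * dz[best], qa[best])
}

#' Select the fiber orientation of one voxel for a propagation direction
#'
#' Implements the filtering-selection rule: among the voxel's fiber
#' orientations whose index exceeds the threshold, keep those whose
#' (sign-invariant) turning angle with the incoming direction `u` is below
#' the angular threshold, and return the one with the smallest turning
#' angle, sign-flipped so it points along `u` (ties broken toward larger
#' QA).  For voxel-level indices (`fa`, `gfa`, `anatomy`) the threshold
#' test uses the voxel scalar for every fiber, so it removes all of the
#' voxel's fibers or none.
#'
#' @param voxel Integer length-3 voxel grid coordinate (1-based).
#' @param u Unit 3-vector, current propagation direction.
#' @param peaks A `peak_map`.
#' @param params A [tracking_params()].
#' @return Unit 3-vector, or `NULL` when no fiber qualifies.
#' @export
select_fiber <- function(voxel, u, peaks, params) {
  ctx <- .tracker_context(peaks, params)
  d <- ctx$dim
  if (any(voxel < 1 | voxel > d)) return(NULL)
  vi <- voxel[1] + d[1] * (voxel[2] - 1) + d[1] * d[2] * (voxel[3] - 1)
  out <- .select_at(ctx, vi, u / sqrt(sum(u^2)))
  if (is.null(out)) NULL else out[1:3]
}

#' Trilinear neighbourhood of a continuous voxel coordinate
#'
#' Voxel centers sit at integer coordinates, so the cell containing `r`
#' is spanned by `floor(r)` and `floor(r) + 1` on each axis: up to 8
#' lattice voxels.  The weight of voxel `R` is
#' `(1 - |dx|) (1 - |dy|) (1 - |dz|)` with `d = r - R`.
#'
#' @param r Numeric length-3 continuous voxel coordinate.
#' @return List with `voxels` (8 x 3 integer matrix) and `weights`
#'   (length 8, summing to 1).  Voxels with zero weight (exact lattice
#'   coordinates) are retained.
#' @export
trilinear_neighborhood <- function(r) {
  f <- floor(r)
  vox <- .cell_offsets + rep(f, each = 8L)
  d <- abs(vox - rep(r, each = 8L))
  list(voxels = vox, weights = (1 - d[, 1]) * (1 - d[, 2]) * (1 - d[, 3]))
}

.cell_offsets <- cbind(rep(0:1, 4), rep(rep(0:1, each = 2), 2),
                       rep(0:1, each = 4))

# propagation core against a prebuilt context; r in voxel coords, u unit mm
.propagate_at <- function(ctx, r, u) {
  d <- ctx$dim
  if (ctx$nearest) {
    R <- round(r)
    if (any(R < 1 | R > d)) return(list(dir = NULL, w = 0))
    vi <- R[1] + d[1] * (R[2] - 1) + d[1] * d[2] * (R[3] - 1)
    sel <- .select_at(ctx, vi, u)
    if (is.null(sel)) return(list(dir = NULL, w = 0))
    v <- sel[1:3]
    return(list(dir = v / sqrt(sum(v^2)), w = 1))
  }
  f <- floor(r)
  w <- 0
  acc <- c(0, 0, 0)
  for (dzi in 0:1) for (dyi in 0:1) for (dxi in 0:1) {
    Rx <- f[1] + dxi; Ry <- f[2] + dyi; Rz <- f[3] + dzi
    if (Rx < 1 || Ry < 1 || Rz < 1 || Rx > d[1] || Ry > d[2] || Rz > d[3])
      next
    fw <- (1 - abs(r[1] - Rx)) * (1 - abs(r[2] - Ry)) *
      (1 - abs(r[3] - Rz))
    if (fw <= 0) next
    vi <- Rx + d[1] * (Ry - 1) + d[1] * d[2] * (Rz - 1)
    sel <- .select_at(ctx, vi, u)
    if (is.null(sel)) next
    w <- w + fw
    acc <- acc + fw * sel[1:3]
  }
  if (w < ctx$tw) return(list(dir = NULL, w = w))
  n <- sqrt(sum(acc^2))
  if (n == 0) return(list(dir = NULL, w = w))
  list(dir = acc / n, w = w)
}

#' Estimate the propagation direction at a continuous position
#'
#' Applies [select_fiber()] to every voxel of the trilinear (or nearest)
#' neighbourhood of `r`, accumulates the interpolation weights of voxels
#' that yielded a fiber, and returns the normalized weighted mean
#' direction.  When the accumulated weight falls below the termination
#' weight the direction is `NULL` (track termination).
#'
#' @param r Continuous voxel coordinate (1-based, integer = voxel center).
#' @param u Current unit propagation direction.
#' @param peaks A `peak_map`; @param params A [tracking_params()].
#' @return List with `dir` (unit 3-vector or `NULL`) and `w` (summed
#'   weight of contributing voxels).
#' @export
propagation_direction <- function(r, u, peaks, params) {
  ctx <- .tracker_context(peaks, params)
  .propagate_at(ctx, r, u / sqrt(sum(u^2)))
}

# one half-track; returns matrix of voxel-coordinate points (seed first)
.track_half <- function(ctx, seed, u) {
  pts <- matrix(NA_real_, ctx$max_steps + 1L, 3)
  step_vox <- ctx$step / ctx$vs
  r <- seed
  n <- 0L
  while (n <= ctx$max_steps) {
    n <- n + 1L
    pts[n, ] <- r
    res <- .propagate_at(ctx, r, u)
    if (is.null(res$dir)) break
    u <- res$dir
    r <- r + step_vox * u
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Track one streamline from a seed
#'
#' Runs Euler propagation from `seed` along `init_dir` until the weight
#' criterion (or the length guard) terminates it, runs again along
#' `-init_dir`, and concatenates the two half-tracks with the seed shared
#' once.  Points are recorded in mm.
#'
#' @param seed Continuous voxel coordinate of the seed (1-based).
#' @param init_dir Unit 3-vector initial direction (mm frame).
#' @param peaks A `peak_map`; @param params A [tracking_params()].
#' @return Matrix (n x 3) of mm coordinates, or `NULL` when the total
#'   length is below `min_length`.
#' @export
track_from_seed <- function(seed, init_dir, peaks, params) {
  ctx <- .tracker_context(peaks, params)
  u <- init_dir / sqrt(sum(init_dir^2))
  pts <- .track_bidirectional(ctx, seed, u)
  len <- (nrow(pts) - 1L) * ctx$step
  if (len < params$min_length) return(NULL)
  sweep(pts - 1, 2, ctx$vs, "*")
}

.track_bidirectional <- function(ctx, seed, u) {
  fwd <- .track_half(ctx, seed, u)
  bwd <- .track_half(ctx, seed, -u)
  if (nrow(bwd) > 1L) {
    rbind(bwd[rev(seq(2L, nrow(bwd))), , drop = FALSE], fwd)
  } else fwd
}

#' Generate a tractogram by seeded deterministic tracking
#'
#' Seeds are drawn uniformly at random (voxel plus sub-voxel offset) from
#' the seed region by a seeded pseudorandom generator, so the seed
#' sequence -- and therefore the whole tractogram -- is deterministically
#' reproducible from `rng_seed`.  Each seed's initial direction is its
#' voxel's qualifying peak chosen by the `init_dir` rule; seeds whose
#' voxel has no qualifying fiber are discarded.  Tracks shorter than
#' `min_length` or failing an ROI filter are rejected.  Generation stops
#' at `target_track_count` accepted tracks or when the seed budget is
#' exhausted (partial result with a warning record).
#'
#' @param peaks A `peak_map`.
#' @param params A [tracking_params()].
#' @param seed_region 3-D logical array (or vector of linear voxel
#'   indices); default: all voxels carrying at least one peak.
#' @param roi_filters Optional list of ROI filters, each
#'   `list(center = c(x, y, z) mm, radius = mm, mode = "pass"` (any point
#'   inside) `or "endpoints"` (either endpoint inside)`)`.
#' @return A `tractogram`: list with `streamlines` (list of n x 3 mm
#'   matrices), `seeds` (mm), `lengths` (mm), `n_seeds_used`,
#'   `voxel_size`, `params`, `warnings`.
#' @export
generate_tractography <- function(peaks, params, seed_region = NULL,
                                  roi_filters = NULL) {
  stopifnot(inherits(peaks, "peak_map"), inherits(params, "tracking_params"))
  ctx <- .tracker_context(peaks, params)
  if (is.null(seed_region)) {
    region <- peaks$voxels[peaks$n_peaks > 0]
  } else if (is.array(seed_region) || is.logical(seed_region)) {
    region <- which(as.vector(seed_region) != 0)
  } else {
    region <- as.integer(seed_region)
  }
  if (length(region) == 0L) stop("seed region is empty")
  budget <- params$seed_budget
  if (is.null(budget)) budget <- 200L * params$target_track_count
  d <- ctx$dim
  rx <- ((region - 1) %% d[1]) + 1
  ry <- ((region - 1) %/% d[1]) %% d[2] + 1
  rz <- (region - 1) %/% (d[1] * d[2]) + 1

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(params$rng_seed)

  streamlines <- list()
  seeds <- list()
  used <- 0L
  while (length(streamlines) < params$target_track_count &&
         used < budget) {
    used <- used + 1L
    i <- sample.int(length(region), 1L)
    seed <- c(rx[i], ry[i], rz[i]) + stats::runif(3, -0.5, 0.5)
    vi <- region[i]
    u0 <- .initial_direction(ctx, vi, params$init_dir)
    if (is.null(u0)) next
    pts <- .track_bidirectional(ctx, seed, u0)
    len <- (nrow(pts) - 1L) * ctx$step
    if (len < params$min_length) next
    mm <- sweep(pts - 1, 2, ctx$vs, "*")
    if (!is.null(roi_filters) && !.passes_rois(mm, roi_filters)) next
    streamlines[[length(streamlines) + 1L]] <- mm
    seeds[[length(seeds) + 1L]] <- (seed - 1) * ctx$vs
  }
  warnings <- character(0)
  if (length(streamlines) < params$target_track_count)
    warnings <- sprintf(
      "seed budget exhausted: %d of %d tracks generated from %d seeds",
      length(streamlines), params$target_track_count, used)
  structure(list(streamlines = streamlines,
                 seeds = do.call(rbind, seeds),
                 lengths = vapply(streamlines,
                                  function(s) (nrow(s) - 1L) * ctx$step,
                                  numeric(1)),
                 n_seeds_used = used, voxel_size = ctx$vs,
                 dim = ctx$dim, params = params, warnings = warnings),
            class = "tractogram")
}

# initial direction at a seed voxel: qualifying peak by rule
.initial_direction <- function(ctx, vi, rule) {
  k <- ctx$npk[vi]
  if (k == 0L) return(NULL)
  ks <- seq_len(k)
  qa <- ctx$Q[vi, ks]
  pass <- if (is.null(ctx$idxval)) qa > ctx$thr
          else rep(ctx$idxval[vi] > ctx$thr, k)
  if (!any(pass)) return(NULL)
  cand <- which(pass)
  # peaks are stored in descending QA order, so cand[1] is the largest
  # index value both for per-orientation QA and (trivially) voxel scalars
  p <- if (rule == "random" && length(cand) > 1L)
    cand[sample.int(length(cand), 1L)] else cand[1L]
  c(ctx$Dx[vi, p], ctx$Dy[vi, p], ctx$Dz[vi, p])
}

.passes_rois <- function(mm, roi_filters) {
  for (f in roi_filters) {
    mode <- if (is.null(f$mode)) "pass" else f$mode
    pts <- if (mode == "endpoints") mm[c(1L, nrow(mm)), , drop = FALSE]
           else mm
    d2 <- (pts[, 1] - f$center[1])^2 + (pts[, 2] - f$center[2])^2 +
      (pts[, 3] - f$center[3])^2
    if (!any(d2 <= f$radius^2)) return(FALSE)
  }
  TRUE
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf(
    "Tractogram: %d streamlines (%d seeds tried), length %.1f-%.1f mm (median %.1f)\n",
    length(x$streamlines), x$n_seeds_used,
    if (length(x$lengths)) min(x$lengths) else NA,
    if (length(x$lengths)) max(x$lengths) else NA,
    if (length(x$lengths)) stats::median(x$lengths) else NA))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}
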