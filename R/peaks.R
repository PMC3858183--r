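#' Extract fiber orientations and quantitative anisotropy from SDFs
#'
#' A tessellation vertex is a fiber peak when its SDF value is strictly
#' greater than that of every 1-ring neighbour (after folding the full
#' sphere onto the hemisphere, since diffusion is antipodally symmetric).
#' Each peak orientation `a` carries its own quantitative anisotropy
#'
#'   QA(a) = z0 * ( psi(a) - iso(psi) )
#'
#' where `iso` is the voxel's minimum SDF sample and `z0` the global
#' free-water scaling constant (see [compute_z0()]).  QA is therefore a
#' per-orientation quantity: within one voxel, a salient peak can survive
#' a QA threshold that removes a spurious one.  Voxel-level indices (FA,
#' GFA, anatomy) attached via [attach_scalar_indices()] are, by contrast,
#' shared by all orientations of the voxel.
#'
#' @param sdf An `sdf_volume` from [gqi_sdf()] (its `z0` field is used;
#'   run [compute_z0()] first for calibrated values).
#' @param tess The same tessellation the SDF was sampled on.
#' @param max_peaks Maximum number of peaks kept per voxel, largest QA
#'   first (default 3: three-way crossings are the deepest routinely
#'   resolved in vivo).
#' @return A `peak_map` object: list with `dir_index` (nvox x max_peaks
#'   matrix of hemisphere vertex slots, `NA`-padded), `qa` (matching QA
#'   values), `n_peaks` (per-voxel count), `voxels` (linear indices for
#'   rows), plus grid metadata and the scalar index maps slot (initially
#'   absent).  Orientation unit vectors are recovered via
#'   `peak_directions()`.
#' @export
extract_peaks <- function(sdf, tess, max_peaks = 3) {
  stopifnot(inherits(sdf, "sdf_volume"), inherits(tess, "sphere_tess"))
  if (sdf$tess_level != tess$level)
    stop("sdf was reconstructed on a different tessellation level")
  if (max_peaks < 1) stop("max_peaks must be >= 1")
  psi <- sdf$psi
  nh <- ncol(psi)
  nb_max <- .hemi_neighbor_max(psi, tess)
  is_peak <- psi > nb_max  # strict: plateaus yield no peak
  nvox <- nrow(psi)
  dir_index <- matrix(NA_integer_, nvox, max_peaks)
  qa <- matrix(NA_real_, nvox, max_peaks)
  iso_v <- sdf$iso[sdf$voxels]
  n_peaks <- integer(nvox)
  for (i in seq_len(nvox)) {
    pk <- which(is_peak[i, ])
    if (length(pk) == 0L) next
    amp <- psi[i, pk] - iso_v[i]
    ord <- order(amp, decreasing = TRUE)
    keep <- ord[seq_len(min(max_peaks, length(pk)))]
    n_peaks[i] <- length(keep)
    dir_index[i, seq_along(keep)] <- pk[keep]
    qa[i, seq_along(keep)] <- sdf$z0 * amp[keep]
  }
  structure(list(dir_index = dir_index, qa = qa, n_peaks = n_peaks,
                 voxels = sdf$voxels, z0 = sdf$z0, sigma = sdf$sigma,
                 tess_level = tess$level, max_peaks = max_peaks,
                 hemi_dirs = tess$vertices[tess$hemi_vertices, ,
                                           drop = FALSE],
                 dim = sdf$dim, voxel_size = sdf$voxel_size),
            class = "peak_map")
}

# per-voxel max of psi over the hemisphere-folded 1-ring of each vertex
.hemi_neighbor_max <- function(psi, tess) {
  hv <- tess$hemi_vertices
  out <- matrix(-Inf, nrow(psi), length(hv))
  for (j in seq_along(hv)) {
    nb <- unique(tess$hemi_index[tess$adjacency[[hv[j]]]])
    nb <- nb[nb != j]
    for (k in nb) out[, j] <- pmax(out[, j], psi[, k])
  }
  out
}

#' Peak orientation unit vectors of one voxel
#'
#' @param peaks A `peak_map`.
#' @param voxel Row index into the peak map (position in `peaks$voxels`).
#' @return Matrix (n_peaks x 3) of unit vectors, zero rows if none.
#' @export
peak_directions <- function(peaks, voxel) {
  idx <- peaks$dir_index[voxel, ]
  idx <- idx[!is.na(idx)]
  peaks$hemi_dirs[idx, , drop = FALSE]
}

#' Free-water scaling constant
#'
#' The SDF amplitude scales with spin density, so absolute values are
#' scanner- and subject-dependent.  The scaling constant `z0` maps free
#' water diffusion to 1: it is the reciprocal of the mean (over a
#' free-water-dominated region) of each voxel's maximum SDF sample.
#' Phantoms know their water region; for in vivo data the `"auto"` rule
#' takes the voxels with the largest isotropic background (top 0.1% of
#' `iso`, at least one voxel) as the free-water region.
#'
#' @param sdf An `sdf_volume`.
#' @param free_water_region `"auto"` or a vector of linear voxel indices
#'   (into the full grid) known to be free water.
#' @return The `sdf_volume` with `z0` set (and recorded region size);
#'   the numeric constant is in `$z0`.
#' @export
compute_z0 <- function(sdf, free_water_region = "auto") {
  stopifnot(inherits(sdf, "sdf_volume"))
  if (identical(free_water_region, "auto")) {
    iso_v <- sdf$iso[sdf$voxels]
    k <- max(1L, ceiling(0.001 * length(iso_v)))
    rows <- order(iso_v, decreasing = TRUE)[seq_len(k)]
  } else {
    rows <- match(free_water_region, sdf$voxels)
    rows <- rows[!is.na(rows)]
  }
  if (length(rows) == 0L)
    stop("free-water region is empty or outside the reconstructed mask")
  m <- mean(apply(sdf$psi[rows, , drop = FALSE], 1, max))
  if (m <= 0) stop("free-water region has zero SDF amplitude")
  sdf$z0 <- 1 / m
  sdf$z0_region_size <- length(rows)
  sdf
}

#' Attach voxel-level scalar indices to a peak map
#'
#' Makes FA, GFA and/or an anatomy (white-matter) mask available to the
#' tracker so the same algorithm can threshold on any of `qa`, `fa`,
#' `gfa`, `anatomy`.  Voxel-level indices are shared by every orientation
#' in the voxel, so thresholding on them removes all of a voxel's fibers
#' or none.
#'
#' @param peaks A `peak_map`.
#' @param fa,gfa 3-D arrays on the peak map's grid (optional).
#' @param anatomy 3-D array or logical mask; values > 0 count as white
#'   matter (optional).
#' @return The `peak_map` with an `indices` list of per-voxel-row vectors.
#' @export
attach_scalar_indices <- function(peaks, fa = NULL, gfa = NULL,
                                  anatomy = NULL) {
  stopifnot(inherits(peaks, "peak_map"))
  grab <- function(m, name) {
    if (is.null(m)) return(NULL)
    m <- as.array(m)
    if (!identical(dim(m)[1:3], as.integer(peaks$dim)))
      stop(name, " map grid ", paste(dim(m), collapse = "x"),
           " does not match peak map grid ",
           paste(peaks$dim, collapse = "x"))
    as.numeric(m[peaks$voxels])
  }
  if (is.null(peaks$indices)) peaks$indices <- list()
  if (!is.null(fa)) peaks$indices$fa <- grab(fa, "fa")
  if (!is.null(gfa)) peaks$indices$gfa <- grab(gfa, "gfa")
  if (!is.null(anatomy)) peaks$indices$anatomy <- grab(anatomy + 0,
                                                       "anatomy")
  peaks
}

#' @export
print.peak_map <- function(x, ...) {
  cat(sprintf(
    "Peak map: %s grid, %d voxels, <= %d peaks/voxel (%.1f%% with >= 1), z0 = %.4g\n",
    paste(x$dim, collapse = " x "), length(x$voxels), x$max_peaks,
    100 * mean(x$n_peaks > 0), x$z0))
  if (!is.null(x$indices))
    cat("  attached voxel indices:", paste(names(x$indices),
                                           collapse = ", "), "\n")
  invisible(x)
}

#' Persist / load a peak map as NIfTI volumes plus a JSON sidecar
#'
#' Writes `<prefix>_index.nii.gz` (4-D integer volume of hemisphere
#' vertex slots, 0 = none), `<prefix>_qa.nii.gz` (matching QA values) and
#' `<prefix>.json` (z0, sigma, tessellation level, max_peaks).
#'
#' @param peaks A `peak_map`.
#' @param prefix Output path prefix.
#' @export
write_peak_map <- function(peaks, prefix) {
  stopifnot(inherits(peaks, "peak_map"))
  d <- c(peaks$dim, peaks$max_peaks)
  idx <- array(0, d)
  qa <- array(0, d)
  for (p in seq_len(peaks$max_peaks)) {
    slab_i <- array(0, peaks$dim)
    slab_q <- array(0, peaks$dim)
    di <- peaks$dir_index[, p]
    slab_i[peaks$voxels] <- ifelse(is.na(di), 0, di)
    slab_q[peaks$voxels] <- ifelse(is.na(di), 0, peaks$qa[, p])
    idx[, , , p] <- slab_i
    qa[, , , p] <- slab_q
  }
  write_nifti_map(idx, paste0(prefix, "_index.nii.gz"), peaks$voxel_size)
  write_nifti_map(qa, paste0(prefix, "_qa.nii.gz"), peaks$voxel_size)
  jsonlite::write_json(
    list(z0 = peaks$z0, sigma = peaks$sigma,
         tessellation_level = peaks$tess_level,
         max_peaks = peaks$max_peaks, dim = peaks$dim,
         voxel_size = peaks$voxel_size),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Build a peak map directly from a known orientation field
#'
#' Wraps a ground-truth fiber direction field (e.g. a synthetic test
#' field) in the `peak_map` structure the tracker consumes, bypassing
#' reconstruction.  Orientations are stored as given (no tessellation
#' quantization); each voxel gets one peak.
#'
#' @param orientations 4-D array `(x, y, z, 3)` of direction vectors;
#'   all-zero rows mean "no fiber in this voxel".
#' @param qa QA value assigned to every fiber (scalar or 3-D array).
#' @param voxel_size Voxel size in mm.
#' @return A `peak_map` with one orientation per voxel.
#' @export
synthetic_peak_map <- function(orientations, qa = 1,
                               voxel_size = c(1, 1, 1)) {
  d <- dim(orientations)
  if (length(d) != 4L || d[4] != 3L)
    stop("orientations must be an (x, y, z, 3) array")
  d3 <- d[1:3]
  nvox <- prod(d3)
  dirs <- matrix(orientations, nvox, 3)
  nrm <- sqrt(rowSums(dirs^2))
  has <- nrm > 1e-12
  dirs[has, ] <- dirs[has, , drop = FALSE] / nrm[has]
  qa_arr <- if (length(qa) == 1L) rep(qa, nvox) else as.vector(qa)
  hemi <- dirs[has, , drop = FALSE]
  dir_index <- matrix(NA_integer_, nvox, 1)
  dir_index[has, 1] <- seq_len(sum(has))
  qam <- matrix(NA_real_, nvox, 1)
  qam[has, 1] <- qa_arr[has]
  structure(list(dir_index = dir_index, qa = qam,
                 n_peaks = as.integer(has), voxels = seq_len(nvox),
                 z0 = 1, sigma = NA_real_, tess_level = NA_integer_,
                 max_peaks = 1L, hemi_dirs = hemi, dim = d3,
                 voxel_size = as.numeric(voxel_size)),
            class = "peak_map")
}

#' @rdname write_peak_map
#' @details `read_peak_map()` restores a peak map written by
#'   `write_peak_map()`; the tessellation is rebuilt from the recorded
#'   subdivision level.
#' @export
read_peak_map <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  tess <- build_tessellation(side$tessellation_level)
  idx <- as.array(RNifti::readNifti(paste0(prefix, "_index.nii.gz")))
  qa <- as.array(RNifti::readNifti(paste0(prefix, "_qa.nii.gz")))
  d3 <- dim(idx)[1:3]
  mp <- dim(idx)[4]
  nvox <- prod(d3)
  dir_index <- matrix(as.integer(round(idx)), nvox, mp)
  qam <- matrix(as.numeric(qa), nvox, mp)
  none <- dir_index == 0L
  dir_index[none] <- NA_integer_
  qam[none] <- NA_real_
  structure(list(dir_index = dir_index, qa = qam,
                 n_peaks = as.integer(rowSums(!none)),
                 voxels = seq_len(nvox), z0 = side$z0, sigma = side$sigma,
                 tess_level = side$tessellation_level, max_peaks = mp,
                 hemi_dirs = tess$vertices[tess$hemi_vertices, ,
                                           drop = FALSE],
                 dim = d3, voxel_size = as.numeric(side$voxel_size)),
            class = "peak_map")
}
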