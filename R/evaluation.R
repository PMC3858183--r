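#' Calibrate an index threshold against a reference mask
#'
#' Comparable thresholds for different anisotropy indices are found by
#' binarizing the index map at each candidate threshold and scoring the
#' overlap with a reference (white-matter or phantom-fiber) mask; the
#' threshold with the best coverage wins.  Dice is the default score
#' because it balances coverage against leakage; Jaccard is available.
#'
#' @param index_map 3-D numeric array (`NA` treated as below threshold).
#' @param reference_mask 3-D logical (or 0/1) array on the same grid.
#' @param candidate_thresholds Numeric vector of thresholds to sweep.
#' @param score `"dice"` or `"jaccard"`.
#' @return List with `best_threshold`, `best_score`, and `overlap_scores`
#'   (named numeric vector, one score per candidate).  Ties go to the
#'   smallest threshold.
#' @export
calibrate_threshold <- function(index_map, reference_mask,
                                candidate_thresholds,
                                score = c("dice", "jaccard")) {
  score <- match.arg(score)
  m <- as.array(reference_mask) != 0
  if (!identical(dim(as.array(index_map)), dim(m)))
    stop("index_map and reference_mask grids differ")
  if (!any(m)) stop("reference mask is empty")
  x <- as.vector(index_map)
  x[is.na(x)] <- -Inf
  mv <- as.vector(m)
  n_mask <- sum(mv)
  scores <- vapply(candidate_thresholds, function(t) {
    bin <- x > t
    inter <- sum(bin & mv)
    if (score == "dice") {
      denom <- sum(bin) + n_mask
      if (denom == 0) 0 else 2 * inter / denom
    } else {
      uni <- sum(bin | mv)
      if (uni == 0) 0 else inter / uni
    }
  }, numeric(1))
  names(scores) <- format(candidate_thresholds, trim = TRUE)
  best <- which.max(scores)  # first max = smallest threshold on ties
  list(best_threshold = candidate_thresholds[best],
       best_score = scores[[best]], overlap_scores = scores)
}

#' Quartiles of an index per labeled region
#'
#' First quartile, median and third quartile of the index values inside
#' each region of a label array, using the linear-interpolation quantile
#' definition (R type 7).  Regions with fewer than 4 voxels are flagged
#' low-confidence.
#'
#' @param index_map 3-D numeric array.
#' @param region_labels 3-D array of region labels (character or factor);
#'   `NA` voxels are skipped.
#' @return Data frame with columns `region`, `n_voxels`, `q1`, `median`,
#'   `q3`, `low_confidence`.
#' @export
region_distribution <- function(index_map, region_labels) {
  x <- as.vector(as.array(index_map))
  lab <- as.vector(as.array(region_labels))
  if (length(x) != length(lab))
    stop("index_map and region_labels grids differ")
  keep <- !is.na(lab)
  out <- lapply(sort(unique(lab[keep])), function(lv) {
    vals <- x[keep & lab == lv]
    vals <- vals[!is.na(vals)]
    q <- if (length(vals)) stats::quantile(vals, c(0.25, 0.5, 0.75),
                                           type = 7, names = FALSE)
         else rep(NA_real_, 3)
    data.frame(region = lv, n_voxels = length(vals),
               q1 = q[1], median = q[2], q3 = q[3],
               low_confidence = length(vals) < 4L)
  })
  do.call(rbind, out)
}

#' Bootstrap confidence interval for a false-track proportion
#'
#' Each track of a tractogram is generated independently, so a percentile
#' bootstrap over tracks gives a confidence interval for the percentage
#' labeled false: `n_bootstrap` resamples of `resample_size` tracks drawn
#' with replacement, CI from the 2.5th and 97.5th percentiles of the
#' resampled percentages.
#'
#' @param labels Logical vector, `TRUE` = false track.
#' @param n_bootstrap Number of bootstrap resamples (default 1000).
#' @param resample_size Tracks per resample (default `length(labels)`).
#' @param rng_seed Seed for the resampling generator.
#' @return List with `estimate`, `ci_low`, `ci_high` (percentages),
#'   `n_tracks`, `n_bootstrap`.
#' @export
bootstrap_false_track_ci <- function(labels, n_bootstrap = 1000,
                                     resample_size = length(labels),
                                     rng_seed = 1) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (n < 1L) stop("need at least one labeled track")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(rng_seed)
  props <- vapply(seq_len(n_bootstrap), function(i)
    100 * mean(labels[sample.int(n, resample_size, replace = TRUE)]),
    numeric(1))
  ci <- stats::quantile(props, c(0.025, 0.975), names = FALSE)
  list(estimate = 100 * mean(labels), ci_low = ci[1], ci_high = ci[2],
       n_tracks = n, n_bootstrap = n_bootstrap)
}

#' Label tracks as false against phantom ground truth
#'
#' Stands in for expert judgment on synthetic data: a track's source
#' strand is the ground-truth label at its seed voxel, and the track is
#' labeled false when more than `outside_fraction` of its points fall
#' outside that strand's mask dilated by `dilate` voxels (26-connected),
#' i.e. it left its strand (bleeding, bridging or noise-driven wandering).
#' Tracks seeded outside any strand are labeled false outright.
#'
#' @param tract A `tractogram` from [generate_tractography()].
#' @param region_labels 3-D array of strand labels; `background_label`
#'   marks non-strand voxels.
#' @param background_label Labels of non-strand voxels (default `"gel"`
#'   and `"core"`, the spindle phantom's background).
#' @param dilate Dilation radius in voxels (default 1).
#' @param outside_fraction Tolerated fraction of points outside the
#'   dilated source mask (default 0.1).
#' @return Logical vector, one entry per streamline (`TRUE` = false
#'   track), with the per-track source label as attribute `source`.
#' @export
label_false_tracks <- function(tract, region_labels,
                               background_label = c("gel", "core"),
                               dilate = 1, outside_fraction = 0.1) {
  stopifnot(inherits(tract, "tractogram"))
  lab <- as.array(region_labels)
  d <- dim(lab)
  strands <- setdiff(unique(as.vector(lab)), background_label)
  masks <- lapply(strands, function(s)
    .dilate_mask(lab == s, dilate))
  names(masks) <- strands
  vs <- tract$voxel_size
  src <- character(length(tract$streamlines))
  false <- logical(length(tract$streamlines))
  for (i in seq_along(tract$streamlines)) {
    # seed provenance if recorded, else the first streamline point
    seed_mm <- if (!is.null(tract$seeds)) tract$seeds[i, ]
               else tract$streamlines[[i]][1, ]
    seed_vox <- pmin(pmax(round(seed_mm / vs + 1), 1), d)
    s <- lab[seed_vox[1], seed_vox[2], seed_vox[3]]
    src[i] <- s
    if (!(s %in% strands)) {
      false[i] <- TRUE
      next
    }
    pts <- round(sweep(tract$streamlines[[i]], 2, vs, "/") + 1)
    pts[, 1] <- pmin(pmax(pts[, 1], 1), d[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 1), d[2])
    pts[, 3] <- pmin(pmax(pts[, 3], 1), d[3])
    inside <- masks[[s]][cbind(pts[, 1], pts[, 2], pts[, 3])]
    false[i] <- mean(!inside) > outside_fraction
  }
  structure(false, source = src)
}

# 26-connected binary dilation by `by` voxels
.dilate_mask <- function(mask, by = 1) {
  m <- mask
  d <- dim(m)
  for (it in seq_len(by)) {
    out <- m
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
      out <- out | m[xs, ys, zs]
    }
    m <- out
  }
  m
}
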