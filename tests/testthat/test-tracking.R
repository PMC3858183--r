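two_fiber_voxel <- function(dirs, qas) {
  arr <- array(0, c(1, 1, 1, 3)); arr[1, 1, 1, ] <- dirs[[1]]
  pk <- synthetic_peak_map(arr)
  pk$max_peaks <- length(dirs)
  pk$hemi_dirs <- do.call(rbind, dirs)
  pk$dir_index <- matrix(seq_along(dirs), 1)
  pk$qa <- matrix(qas, 1)
  pk$n_peaks <- length(dirs)
  pk
}

test_that("fiber selection flips antipodes and minimizes the turning angle", {
  p <- tracking_params(0.1, "qa", angular_threshold = 60)
  # antipodal fiber: delta flips it onto the propagation direction
  pk <- two_fiber_voxel(list(c(-1, 0, 0)), 1)
  expect_equal(select_fiber(c(1, 1, 1), c(1, 0, 0), pk, p), c(1, 0, 0))
  # fibers at 30 and 70 degrees from u: the 30-degree one is selected
  f30 <- c(cos(pi / 6), sin(pi / 6), 0)
  f70 <- c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  pk2 <- two_fiber_voxel(list(f70, f30), c(1, 1))
  expect_equal(select_fiber(c(1, 1, 1), c(1, 0, 0), pk2, p), f30)
  # both out of the cone: nothing qualifies
  pk3 <- two_fiber_voxel(list(f70), 1)
  expect_null(select_fiber(c(1, 1, 1), c(1, 0, 0), pk3, p))
  # below the QA threshold: filtered out even at a perfect angle
  pk4 <- two_fiber_voxel(list(c(1, 0, 0)), 0.05)
  expect_null(select_fiber(c(1, 1, 1), c(1, 0, 0), pk4, p))
})

test_that("equal-angle ties break toward the larger QA", {
  p <- tracking_params(0.1, "qa", angular_threshold = 60)
  fA <- c(cos(pi / 6), sin(pi / 6), 0)
  fB <- c(cos(pi / 6), -sin(pi / 6), 0)
  pk <- two_fiber_voxel(list(fA, fB), c(0.5, 0.9))
  expect_equal(select_fiber(c(1, 1, 1), c(1, 0, 0), pk, p), fB)
  pk2 <- two_fiber_voxel(list(fA, fB), c(0.9, 0.5))
  expect_equal(select_fiber(c(1, 1, 1), c(1, 0, 0), pk2, p), fA)
  # exhaustive check against brute-force enumeration of the rule
  set.seed(7)
  for (rep in 1:20) {
    dirs <- lapply(1:3, function(i) {
      v <- rnorm(3); v / sqrt(sum(v^2))
    })
    qas <- round(runif(3), 3)
    pkr <- two_fiber_voxel(dirs, qas)
    u <- c(1, 0, 0)
    got <- select_fiber(c(1, 1, 1), u, pkr, p)
    # oracle: filter, then order by (|dot|, qa)
    dots <- vapply(dirs, function(a) sum(a * u), numeric(1))
    ok <- qas > 0.1 & abs(dots) > cos(pi / 3)
    if (!any(ok)) {
      expect_null(got)
    } else {
      best <- which(ok)[order(-abs(dots)[ok], -qas[ok])[1]]
      expect_equal(got, sign(dots[best]) * dirs[[best]],
                   tolerance = 1e-12)
    }
  }
})

test_that("the trilinear neighborhood is the 8-voxel lattice cell", {
  nb <- trilinear_neighborhood(c(32.3, 12.4, 16.9))
  expect_equal(sort(unique(nb$voxels[, 1])), c(32, 33))
  expect_equal(sort(unique(nb$voxels[, 2])), c(12, 13))
  expect_equal(sort(unique(nb$voxels[, 3])), c(16, 17))
  expect_equal(nrow(nb$voxels), 8)
  expect_equal(sum(nb$weights), 1, tolerance = 1e-12)
  # cell midpoint: all eight weights are (1/2)^3
  nbm <- trilinear_neighborhood(c(2.5, 3.5, 4.5))
  expect_equal(nbm$weights, rep(0.125, 8))
})

test_that("propagation direction accumulates weights and terminates on w < 0.5", {
  field <- straight_field(c(5, 5, 5))
  p <- tracking_params(0.1, "qa")
  # at a voxel center all weight sits on that voxel
  res <- propagation_direction(c(3, 3, 3), c(1, 0, 0), field, p)
  expect_equal(res$w, 1)
  expect_equal(res$dir, c(1, 0, 0))
  # at the cell midpoint eight identical fibers average to the same dir
  res2 <- propagation_direction(c(2.5, 2.5, 2.5), c(1, 0, 0), field, p)
  expect_equal(res2$w, 1, tolerance = 1e-12)
  expect_equal(res2$dir, c(1, 0, 0))
  # outside the grid: zero weight, no direction
  res3 <- propagation_direction(c(40, 3, 3), c(1, 0, 0), field, p)
  expect_null(res3$dir)
  expect_equal(res3$w, 0)
  # near the mask edge the accumulated weight drops below 0.5
  res4 <- propagation_direction(c(5.6, 3, 3), c(1, 0, 0), field, p)
  expect_null(res4$dir)
  expect_lt(res4$w, 0.5)
})

test_that("a straight field yields a straight full-span streamline", {
  field <- straight_field(c(40, 5, 5))
  p <- tracking_params(0.1, "qa", step_size = 0.5, min_length = 5,
                       max_length = 100)
  sl <- track_from_seed(c(20, 3, 3), c(1, 0, 0), field, p)
  # spans the bundle: extent/step + 1 points, within edge effects
  expect_gt(nrow(sl), 39 / 0.5)
  expect_lt(nrow(sl), 41 / 0.5 + 3)
  expect_equal(sd(sl[, 2]), 0)
  expect_equal(sd(sl[, 3]), 0)
  # consecutive points are exactly one step apart
  seg <- sqrt(rowSums(diff(sl)^2))
  expect_equal(max(abs(seg - 0.5)), 0, tolerance = 1e-9)
})

test_that("a bend sharper than the angular threshold terminates the track", {
  field <- elbow_field(c(21, 21, 3), bend = 10)
  p <- tracking_params(0.1, "qa", angular_threshold = 60, step_size = 0.25,
                       min_length = 0, max_length = 60)
  sl <- track_from_seed(c(3, 5, 2), c(1, 0, 0), field, p)
  # the track never crosses the elbow into the +y arm
  expect_lt(max(sl[, 1]), 11)
  expect_lt(diff(range(sl[, 2])), 1.5)
})

test_that("nearest-neighbor weighting with a tiny step reproduces FACT", {
  field <- curved_field(c(5, 5, 5), seed = 3)
  p <- tracking_params(0.1, "qa", interpolation = "nearest",
                       step_size = 0.01, min_length = 0, max_length = 20)
  set.seed(11)
  for (i in 1:5) {
    seed <- runif(3, 1.6, 4.4)
    u0 <- peak_directions(field,
                          sum((round(seed) - 1) * c(1, 5, 25)) + 1)[1, ]
    ours <- track_from_seed(seed, u0, field, p)
    # oracle works in voxel coordinates; convert to mm (unit voxels here)
    oracle <- densify(fact_oracle(field, seed, u0) - 1, 0.01)
    expect_lt(hausdorff(ours, oracle), 1)
  }
})

test_that("tractogram generation is deterministic and respects its stopping rule", {
  field <- straight_field(c(40, 6, 6))
  p <- tracking_params(0.1, "qa", step_size = 0.5, min_length = 5,
                       target_track_count = 40, rng_seed = 99)
  tg1 <- generate_tractography(field, p)
  tg2 <- generate_tractography(field, p)
  expect_identical(tg1$streamlines, tg2$streamlines)
  expect_length(tg1$streamlines, 40)
  expect_length(tg1$warnings, 0)
  # different seed, different seeds/tracks
  p3 <- p; p3$rng_seed <- 100
  tg3 <- generate_tractography(field, p3)
  expect_false(identical(tg1$streamlines, tg3$streamlines))
})

test_that("minimum length filtering removes fragments", {
  # a 12-voxel fiber fragment inside an empty volume: ~11 mm of track
  arr <- array(0, c(40, 5, 5, 3))
  arr[10:21, 3, 3, 1] <- 1
  field <- synthetic_peak_map(arr)
  p <- tracking_params(0.1, "qa", step_size = 0.5, min_length = 40,
                       target_track_count = 10, seed_budget = 500,
                       rng_seed = 1)
  tg <- generate_tractography(field, p)
  expect_length(tg$streamlines, 0)
  expect_match(tg$warnings, "budget exhausted")
  p2 <- p; p2$min_length <- 5
  tg2 <- generate_tractography(field, p2)
  expect_length(tg2$streamlines, 10)
  expect_true(all(tg2$lengths >= 5))
})

test_that("every streamline obeys the angular constraint and termination rule", {
  field <- curved_field(c(20, 20, 5), seed = 5, wobble = 15)
  p <- tracking_params(0.1, "qa", angular_threshold = 60, step_size = 0.5,
                       min_length = 3, target_track_count = 30,
                       rng_seed = 2)
  tg <- generate_tractography(field, p)
  expect_gt(length(tg$streamlines), 0)
  cos_th <- cos(p$angular_threshold * pi / 180)
  for (s in tg$streamlines) {
    if (nrow(s) < 3) next
    segs <- diff(s)
    segs <- segs / sqrt(rowSums(segs^2))
    dots <- rowSums(segs[-nrow(segs), , drop = FALSE] *
                    segs[-1, , drop = FALSE])
    expect_gte(min(dots), cos_th - 1e-9)
    # termination soundness at the last point
    last_vox <- s[nrow(s), ] / field$voxel_size + 1
    u_last <- segs[nrow(segs), ]
    res <- propagation_direction(last_vox, u_last, field, p)
    len <- (nrow(s) - 1) * p$step_size
    expect_true(res$w < 0.5 || any(last_vox < 1 | last_vox > field$dim) ||
                  len >= p$max_length - 2 * p$step_size)
  }
})

test_that("raising the index threshold never widens the traversed voxel set", {
  # straight field whose QA ramps up along x
  arr <- array(0, c(40, 5, 5, 3)); arr[, , , 1] <- 1
  qa <- array(rep(seq(0.1, 1, length.out = 40), 25), c(40, 5, 5))
  field <- synthetic_peak_map(arr, qa = qa)
  visited <- function(thr) {
    # fixed seed budget so both runs process the identical seed sequence
    p <- tracking_params(thr, "qa", step_size = 0.5, min_length = 0,
                         target_track_count = 1000, seed_budget = 300,
                         rng_seed = 7)
    tg <- suppressWarnings(generate_tractography(
      field, p, seed_region = array(TRUE, c(40, 5, 5))))
    vox <- unique(do.call(rbind, lapply(tg$streamlines, function(s)
      round(sweep(s, 2, field$voxel_size, "/") + 1))))
    apply(vox, 1, paste, collapse = ",")
  }
  v_lo <- visited(0.2)
  v_hi <- visited(0.5)
  expect_true(all(v_hi %in% v_lo))
  expect_lt(length(v_hi), length(v_lo))
})

test_that("ROI filters select passing tracks or endpoint tracks", {
  field <- straight_field(c(40, 6, 6))
  p <- tracking_params(0.1, "qa", step_size = 0.5, min_length = 5,
                       target_track_count = 20, seed_budget = 2000,
                       rng_seed = 3)
  roi_mid <- list(list(center = c(19.5, 2, 2), radius = 3, mode = "pass"))
  tg <- generate_tractography(field, p, roi_filters = roi_mid)
  expect_length(tg$streamlines, 20)
  for (s in tg$streamlines) {
    d <- sqrt(rowSums(sweep(s, 2, c(19.5, 2, 2))^2))
    expect_lte(min(d), 3)
  }
  # an ROI out in empty space passes nothing
  roi_far <- list(list(center = c(100, 100, 100), radius = 3))
  tg0 <- generate_tractography(field, p, roi_filters = roi_far)
  expect_length(tg0$streamlines, 0)
})

test_that("tracking parameter validation catches bad configurations", {
  expect_error(tracking_params(), "index_threshold")
  expect_error(tracking_params(0.1, angular_threshold = 0), "angular")
  expect_error(tracking_params(0.1, angular_threshold = 91), "angular")
  expect_error(tracking_params(0.1, step_size = -1), "step_size")
  expect_error(tracking_params(0.1, termination_weight = 0), "termination")
  expect_error(tracking_params(0.1, min_length = 50, max_length = 40),
               "length")
})
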