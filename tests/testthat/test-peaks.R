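test_that("QA is z0 * (psi(peak) - iso) and plateaus yield no peak", {
  tess <- build_tessellation(1)
  nh <- length(tess$hemi_vertices)
  # one clear peak at slot 5: psi = 0.3 background, 0.8 at the peak
  psi <- rep(0.3, nh); psi[5] <- 0.8
  sdf <- manual_sdf(psi, tess)
  pk <- extract_peaks(sdf, tess)
  expect_equal(pk$n_peaks, 1L)
  expect_equal(pk$qa[1, 1], 0.5)
  expect_equal(pk$dir_index[1, 1], 5L)
  # constant psi: no strict local maximum anywhere
  pk0 <- extract_peaks(manual_sdf(rep(0.7, nh), tess), tess)
  expect_equal(pk0$n_peaks, 0L)
  expect_true(all(is.na(pk0$qa)))
})

test_that("peaks are sorted by descending QA and capped at max_peaks", {
  tess <- build_tessellation(2)
  nh <- length(tess$hemi_vertices)
  psi <- rep(0.1, nh)
  # three separated peaks of different height
  # pick three pairwise non-adjacent, well-separated hemisphere slots
  folded_ring <- function(slot) {
    v <- tess$hemi_vertices[slot]
    unique(tess$hemi_index[tess$adjacency[[v]]])
  }
  slots <- c(3L)
  for (cand in seq_len(nh)) {
    if (length(slots) == 3L) break
    rings <- unique(unlist(lapply(slots, folded_ring)))
    if (!(cand %in% c(slots, rings)) &&
        !any(slots %in% folded_ring(cand)))
      slots <- c(slots, cand)
  }
  psi[slots] <- c(0.5, 0.9, 0.7)
  sdf <- manual_sdf(psi, tess)
  pk <- extract_peaks(sdf, tess, max_peaks = 2)
  expect_equal(pk$n_peaks, 2L)
  expect_equal(pk$dir_index[1, ], c(slots[2], slots[3]))
  expect_true(all(diff(na.omit(pk$qa[1, ])) <= 0))
  pk3 <- extract_peaks(sdf, tess, max_peaks = 3)
  expect_equal(pk3$dir_index[1, ], c(slots[2], slots[3], slots[1]))
  expect_equal(pk3$qa[1, ], c(0.8, 0.6, 0.4))
})

test_that("simulated 90-degree crossing voxels resolve two peaks 90 deg apart", {
  fx <- fx_crossing_clean()
  rows <- which(fx$lab[fx$pk$voxels] == "b")
  expect_true(all(fx$pk$n_peaks[rows] == 2L))
  for (i in rows[seq(1, length(rows), by = 7)]) {
    d <- peak_directions(fx$pk, i)
    ang <- acos(min(1, abs(sum(d[1, ] * d[2, ])))) * 180 / pi
    expect_gte(ang, 81)
    expect_lte(ang, 99)
  }
})

test_that("z0 scales free water to 1 and makes QA spin-density invariant", {
  fx <- fx_crossing_clean()
  water <- which(fx$lab == "water")
  # after scaling, mean max-psi over the water region is exactly 1
  scaled_max <- fx$sdf$z0 * apply(
    fx$sdf$psi[match(water, fx$sdf$voxels), ], 1, max)
  expect_equal(mean(scaled_max), 1, tolerance = 1e-12)
  # pure free-water voxels: QA of any sample is ~ 0
  wrows <- match(water, fx$pk$voxels)
  wqa <- fx$pk$qa[wrows, ]
  expect_lt(max(wqa, na.rm = TRUE), 0.02)
  # doubling the input signal leaves post-scaling QA unchanged
  ds2 <- fx$ds
  ds2$signal <- 2 * ds2$signal
  sdf2 <- compute_z0(gqi_sdf(ds2, fx$tess), free_water_region = water)
  pk2 <- extract_peaks(sdf2, fx$tess)
  expect_equal(pk2$qa, fx$pk$qa, tolerance = 1e-9)
  expect_equal(sdf2$z0, fx$sdf$z0 / 2, tolerance = 1e-12)
})

test_that("z0 'auto' picks a free-water region resembling the known one", {
  fx <- fx_crossing_clean()
  auto <- compute_z0(gqi_sdf(fx$ds, fx$tess), "auto")
  expect_equal(auto$z0, fx$sdf$z0, tolerance = 0.05)
  expect_error(compute_z0(gqi_sdf(fx$ds, fx$tess),
                          free_water_region = integer(0)),
               "empty")
})

test_that("adding isotropic volume depresses FA but barely moves peak QA", {
  # one fiber alone vs the same fiber plus free water: spin density of
  # the fiber is unchanged, so its QA should move by < 15% while FA drops
  tess <- build_tessellation(3)
  bt <- shell_btable(160, 4000)
  dim3 <- c(2, 1, 1)
  comp <- rbind(
    data.frame(voxel = 1:2, type = "fiber", fraction = 0.5,
               ox = 1, oy = 0, oz = 0),
    data.frame(voxel = 2, type = "free_water", fraction = 0.5,
               ox = NA, oy = NA, oz = NA))
  spec <- phantom_spec(dim3, c(1, 1, 1), comp, bt$bvalues, bt$bvectors,
                       snr = Inf)
  ds <- simulate_signal(spec, noiseless = TRUE)
  sdf <- gqi_sdf(ds, tess)
  pk <- extract_peaks(sdf, tess)
  qa_dry <- pk$qa[1, 1]; qa_wet <- pk$qa[2, 1]
  expect_lt(abs(qa_wet - qa_dry) / qa_dry, 0.15)
  fa <- fit_dti(ds)$fa
  # FA drops by clearly more than the QA change
  expect_lt(fa[2], 0.9 * fa[1])
  expect_gt((fa[1] - fa[2]) / fa[1], abs(qa_wet - qa_dry) / qa_dry)
})

test_that("attached voxel indices are validated and stored per voxel", {
  fx <- fx_crossing_clean()
  d3 <- fx$pk$dim
  fa <- array(0.5, d3)
  pk <- attach_scalar_indices(fx$pk, fa = fa, anatomy = array(1, d3))
  expect_equal(unique(pk$indices$fa), 0.5)
  expect_equal(unique(pk$indices$anatomy), 1)
  expect_error(attach_scalar_indices(fx$pk, fa = array(0.5, d3 + 1)),
               "does not match")
})

test_that("voxel-level filtering is all-or-nothing; QA filtering is per-orientation", {
  # two peaks with different QA in one voxel
  dirs <- array(0, c(1, 1, 1, 3)); dirs[1, 1, 1, ] <- c(1, 0, 0)
  pk <- synthetic_peak_map(dirs)
  pk$max_peaks <- 2L
  pk$hemi_dirs <- rbind(c(1, 0, 0), c(0, 1, 0))
  pk$dir_index <- matrix(c(1L, 2L), 1)
  pk$qa <- matrix(c(0.9, 0.2), 1)
  pk$n_peaks <- 2L
  pk <- attach_scalar_indices(pk, fa = array(0.5, c(1, 1, 1)),
                              anatomy = array(0, c(1, 1, 1)))
  # QA threshold between the two peaks removes exactly one
  p_qa <- tracking_params(0.5, "qa", angular_threshold = 90)
  expect_equal(select_fiber(c(1, 1, 1), c(1, 0, 0), pk, p_qa), c(1, 0, 0))
  expect_null(select_fiber(c(1, 1, 1), c(0, 1, 0), pk, p_qa))
  # FA threshold removes both peaks or neither
  p_fa_lo <- tracking_params(0.4, "fa", angular_threshold = 90)
  p_fa_hi <- tracking_params(0.6, "fa", angular_threshold = 90)
  expect_equal(select_fiber(c(1, 1, 1), c(0, 1, 0), pk, p_fa_lo),
               c(0, 1, 0))
  expect_null(select_fiber(c(1, 1, 1), c(0, 1, 0), pk, p_fa_hi))
  expect_null(select_fiber(c(1, 1, 1), c(1, 0, 0), pk, p_fa_hi))
  # anatomy mask 0: every fiber fails regardless of orientation
  p_an <- tracking_params(0, "anatomy", angular_threshold = 90)
  expect_null(select_fiber(c(1, 1, 1), c(1, 0, 0), pk, p_an))
  expect_null(select_fiber(c(1, 1, 1), c(0, 1, 0), pk, p_an))
})

test_that("peak maps persist as NIfTI pair plus JSON sidecar", {
  fx <- fx_crossing_clean()
  prefix <- file.path(withr::local_tempdir(), "peaks")
  write_peak_map(fx$pk, prefix)
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(side$z0, fx$pk$z0, tolerance = 1e-6)
  expect_equal(side$tessellation_level, 3)
  idx <- RNifti::readNifti(paste0(prefix, "_index.nii.gz"))
  expect_equal(dim(idx), c(fx$pk$dim, fx$pk$max_peaks))
})
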