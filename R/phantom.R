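#' Multi-compartment DWI phantom specification
#'
#' A phantom is a voxel grid where each voxel holds a list of
#' compartments: axially symmetric Gaussian `fiber` tensors with an
#' orientation, isotropic `free_water`, and `non_diffusive` material that
#' contributes no signal.  Volume fractions per voxel must lie in [0, 1]
#' and sum to at most 1.
#'
#' @param dim Integer length-3 grid dimensions.
#' @param voxel_size Length-3 voxel size in mm.
#' @param compartments Data frame with columns `voxel` (linear index),
#'   `type` (`"fiber"`, `"free_water"`, `"non_diffusive"`), `fraction`,
#'   and `ox`, `oy`, `oz` (orientation, fibers only).
#' @param bvalues,bvectors The b-table to simulate.
#' @param S0 Unweighted signal level (default 100).
#' @param snr Rician signal-to-noise ratio defined on `S0` (default 30);
#'   `Inf` for noiseless data.
#' @param lambda_axial,lambda_radial Fiber compartment diffusivities in
#'   mm^2/s (defaults 1.7e-3 / 0.2e-3).
#' @param d_water Free-water diffusivity (default 2.5e-3, matching the
#'   reconstruction kernel's body-temperature convention).
#' @param rng_seed Seed for the noise generator.
#' @param labels Optional 3-D array of region label strings.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dim, voxel_size, compartments, bvalues, bvectors,
                         S0 = 100, snr = 30, lambda_axial = 1.7e-3,
                         lambda_radial = 0.2e-3, d_water = 2.5e-3,
                         rng_seed = 1, labels = NULL) {
  compartments <- as.data.frame(compartments)
  stopifnot(all(c("voxel", "type", "fraction") %in% names(compartments)))
  if (any(compartments$fraction < 0 | compartments$fraction > 1))
    stop("compartment fractions must lie in [0, 1]")
  tot <- tapply(compartments$fraction, compartments$voxel, sum)
  if (any(tot > 1 + 1e-9))
    stop("compartment fractions must sum to <= 1 per voxel")
  if (is.infinite(snr) || snr > 0) NULL else stop("snr must be > 0")
  structure(list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
                 compartments = compartments, bvalues = as.numeric(bvalues),
                 bvectors = as.matrix(bvectors), S0 = S0, snr = snr,
                 lambda_axial = lambda_axial, lambda_radial = lambda_radial,
                 d_water = d_water, rng_seed = rng_seed, labels = labels),
            class = "phantom_spec")
}

#' Simulate the DWI signal of a phantom
#'
#' Noiseless per-voxel signal
#' `S(b, g) = S0 * [ sum_fibers f_k exp(-b g' D_k g)
#'                   + f_water exp(-b D_water) ]`
#' (non-diffusive compartments contribute nothing), followed by Rician
#' noise: the magnitude of the signal perturbed by two independent
#' Gaussian channels of standard deviation `S0 / snr`, drawn from the
#' seeded generator.
#'
#' @param spec A [phantom_spec()].
#' @param noiseless Set `TRUE` to skip the noise stage.
#' @return A [dwi_dataset()]; the phantom's region labels travel along as
#'   attribute `labels`.
#' @export
simulate_signal <- function(spec, noiseless = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  b <- spec$bvalues
  g <- spec$bvectors
  nacq <- length(b)
  nvox <- prod(spec$dim)
  S <- matrix(0, nvox, nacq)
  comp <- spec$compartments
  fib <- comp[comp$type == "fiber", , drop = FALSE]
  if (nrow(fib) > 0) {
    o <- as.matrix(fib[, c("ox", "oy", "oz")])
    o <- o / sqrt(rowSums(o^2))
    proj <- (o %*% t(g))^2                        # nfib x nacq
    adc <- spec$lambda_radial +
      (spec$lambda_axial - spec$lambda_radial) * proj
    att <- exp(-sweep(adc, 2, b, "*")) * fib$fraction
    for (grp in split(seq_len(nrow(fib)), fib$voxel)) {
      vi <- fib$voxel[grp[1]]
      S[vi, ] <- S[vi, ] + colSums(att[grp, , drop = FALSE])
    }
  }
  wat <- comp[comp$type == "free_water", , drop = FALSE]
  if (nrow(wat) > 0) {
    att_w <- exp(-b * spec$d_water)
    fw <- tapply(wat$fraction, wat$voxel, sum)
    rows <- as.integer(names(fw))
    S[rows, ] <- S[rows, ] + outer(as.numeric(fw), att_w)
  }
  S <- spec$S0 * S
  if (!noiseless && is.finite(spec$snr)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(spec$rng_seed)
    sdv <- spec$S0 / spec$snr
    e1 <- matrix(stats::rnorm(length(S), 0, sdv), nrow(S))
    e2 <- matrix(stats::rnorm(length(S), 0, sdv), nrow(S))
    S <- sqrt((S + e1)^2 + e2^2)
  }
  ds <- dwi_dataset(array(S, c(spec$dim, nacq)), b, g, spec$voxel_size)
  attr(ds, "labels") <- spec$labels
  ds
}

#' Uniformly distributed gradient direction table
#'
#' Deterministic golden-spiral (Fibonacci) points on the sphere, a
#' standard stand-in for an electrostatically optimized single-shell
#' scheme.
#'
#' @param n Number of diffusion directions.
#' @param bvalue Shell b-value in s/mm^2.
#' @param n_b0 Number of b = 0 volumes prepended.
#' @return List with `bvalues` and `bvectors`.
#' @export
shell_btable <- function(n = 160, bvalue = 4000, n_b0 = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z, deparse.level = 0)
  list(bvalues = c(rep(0, n_b0), rep(bvalue, n)),
       bvectors = rbind(matrix(0, n_b0, 3), g))
}

#' Grid (DSI-style) q-space sampling table
#'
#' Half-grid scheme: the `n - 1` innermost non-zero integer q-space
#' lattice points of one hemisphere (antipodal duplicates removed,
#' ordered by |q| with lexicographic tie-break), plus the origin as b0.
#' The b-value of each point is proportional to |q|^2 up to `bmax`.  The
#' default `n = 203` mirrors the common 203-point grid acquisition.
#'
#' @param n Total number of sampling points including the b0.
#' @param bmax Maximum b-value in s/mm^2.
#' @return List with `bvalues` and `bvectors`.
#' @export
grid_btable <- function(n = 203, bmax = 4000) {
  rng <- -6:6
  q <- as.matrix(expand.grid(x = rng, y = rng, z = rng))
  q2 <- rowSums(q^2)
  # half grid: antipodal duplicates removed (diffusion is symmetric)
  rep_half <- q2 > 0 & (q[, 3] > 0 | (q[, 3] == 0 & (q[, 2] > 0 |
                (q[, 2] == 0 & q[, 1] > 0))))
  q <- q[rep_half, , drop = FALSE]
  q2 <- q2[rep_half]
  ord <- order(q2, q[, 1], q[, 2], q[, 3])
  if (n - 1L > length(ord)) stop("n too large for the lattice range")
  keep <- ord[seq_len(n - 1L)]
  q <- q[keep, , drop = FALSE]
  q2 <- q2[keep]
  b <- bmax * q2 / max(q2)
  g <- unname(q / sqrt(q2))
  list(bvalues = c(0, b), bvectors = rbind(c(0, 0, 0), g))
}

#' The 90-degree crossing phantom in a water bath
#'
#' Two capillary-bundle placeholders stacked at right angles and immersed
#' in free water, with non-diffusive inserts, emulating three partial
#' volume conditions along the bundles: (a) fiber + free water,
#' (b) two fibers crossing, (c) fiber + non-diffusive material, plus
#' reference single-fiber segments, pure water, and pure solid regions.
#' Each region's voxel set is queryable from the label array.
#'
#' Per-voxel fractions (fixed by construction; the fiber content of a
#' bundle is the same in every condition so that only the surrounding
#' partial volume changes):
#' single 0.4 fiber / 0.3 water / 0.3 solid; (a) 0.4 fiber / 0.6 water;
#' (b) 0.4 + 0.4 crossing fibers / 0.2 water; (c) 0.4 fiber / 0.6 solid.
#'
#' @param crossing_angle Angle between the two bundles in degrees
#'   (default 90; the second bundle is rotated in-plane).
#' @param dim Grid size (default 32 x 32 x 4).
#' @param bundle Integer range of in-plane indices covered by each bundle.
#' @param voxel_size Voxel size in mm (default 0.78 mm, a 25 mm
#'   field-of-view over a 32 grid).
#' @param btable b-table; default 160-direction shell at b = 4000 s/mm^2
#'   (the small-bore high-field phantom protocol).
#' @param snr,rng_seed,S0 Passed to [phantom_spec()].
#' @return A [phantom_spec()] whose `labels` array marks `water`,
#'   `single`, `a`, `b`, `c`, `solid`.
#' @export
make_crossing_phantom <- function(crossing_angle = 90,
                                  dim = c(32, 32, 4),
                                  bundle = 13:20,
                                  voxel_size = rep(25 / 32, 3),
                                  btable = shell_btable(160, 4000, 1),
                                  snr = 30, rng_seed = 1, S0 = 100) {
  if (!(crossing_angle > 0 && crossing_angle <= 90))
    stop("crossing_angle must be in (0, 90] degrees")
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  labels <- array("water", dim)
  th <- crossing_angle * pi / 180
  dir1 <- c(1, 0, 0)                      # horizontal bundle, along x
  dir2 <- c(cos(th), sin(th), 0)          # second bundle
  a_seg <- 2:9; c_seg <- (nx - 8):(nx - 1)
  labels[, bundle, ] <- "single"
  labels[bundle, , ] <- "single"
  labels[a_seg, bundle, ] <- "a"
  labels[c_seg, bundle, ] <- "c"
  labels[bundle, bundle, ] <- "b"
  labels[c_seg, c(bundle[1] - 3:1, bundle[length(bundle)] + 1:3), ] <-
    "solid"
  comp <- list()
  add <- function(vox, type, fraction, o = c(NA, NA, NA)) {
    comp[[length(comp) + 1L]] <<- data.frame(
      voxel = vox, type = type, fraction = fraction,
      ox = o[1], oy = o[2], oz = o[3])
  }
  lab <- as.vector(labels)
  add(which(lab == "water"), "free_water", 1)
  add(which(lab == "solid"), "non_diffusive", 1)
  sing <- which(lab == "single")
  # orientation of a 'single' voxel follows whichever bundle it lies in
  yy <- ((sing - 1) %/% nx) %% ny + 1
  in_h <- yy %in% bundle
  add(sing[in_h], "fiber", 0.4, dir1)
  if (any(!in_h)) add(sing[!in_h], "fiber", 0.4, dir2)
  add(sing, "free_water", 0.3)
  add(sing, "non_diffusive", 0.3)
  av <- which(lab == "a")
  add(av, "fiber", 0.4, dir1)
  add(av, "free_water", 0.6)
  bv <- which(lab == "b")
  add(bv, "fiber", 0.4, dir1)
  add(bv, "fiber", 0.4, dir2)
  add(bv, "free_water", 0.2)
  cv <- which(lab == "c")
  add(cv, "fiber", 0.4, dir1)
  add(cv, "non_diffusive", 0.6)
  compartments <- do.call(rbind, comp)
  phantom_spec(dim, voxel_size, compartments, btable$bvalues,
               btable$bvectors, S0 = S0, snr = snr, rng_seed = rng_seed,
               labels = labels)
}

#' The multi-strand spindle phantom
#'
#' A cylinder-shaped plastic spindle with `n_strands` ring-shaped fiber
#' strands wound around its perimeter at different heights, of decreasing
#' fiber volume fraction (emulating decreasing strand size), embedded in
#' an isotropic gel.  The spindle body itself is non-diffusive plastic:
#' it contributes no signal, so its voxels carry pure noise -- the source
#' of the noisy anisotropy values at the phantom center that ratio-based
#' indices are susceptible to.  Strand voxel sets are pairwise disjoint
#' and separated by at least one background slice; fibers run
#' tangentially, so each ring is a closed trackable loop.
#'
#' @param n_strands Number of strands (default 6).
#' @param fraction_ladder Strictly decreasing fiber fractions in (0, 1],
#'   one per strand (default 0.8 down to 0.3).
#' @param dim Grid size (default 30 x 30 x `2 * n_strands + 1`).
#' @param ring_radius Ring radius in voxels (default 10).
#' @param voxel_size Voxel size in mm (default 2.5 mm isotropic).
#' @param btable b-table; default 180 directions at b = 1000 s/mm^2 plus
#'   20 b0 volumes (the clinical spindle protocol).
#' @param d_gel Gel diffusivity in mm^2/s (default 2.0e-3).
#' @param snr,rng_seed,S0 Passed to [phantom_spec()].
#' @return A [phantom_spec()]; `labels` holds `"gel"`, `"core"` (the
#'   plastic body) or `"strand<k>"`, and attribute `strand_z` records
#'   each strand's slice.
#' @export
make_spindle_phantom <- function(n_strands = 6,
                                 fraction_ladder = seq(0.8, 0.3,
                                                       length.out = 6),
                                 dim = c(30, 30, 2 * n_strands + 1),
                                 ring_radius = 10,
                                 voxel_size = c(2.5, 2.5, 2.5),
                                 btable = shell_btable(180, 1000, 20),
                                 d_gel = 2.0e-3, snr = 30, rng_seed = 1,
                                 S0 = 100) {
  if (length(fraction_ladder) != n_strands)
    stop("fraction_ladder must have one entry per strand")
  if (any(diff(fraction_ladder) >= 0))
    stop("fraction_ladder must be strictly decreasing")
  if (any(fraction_ladder <= 0 | fraction_ladder > 1))
    stop("fraction_ladder values must lie in (0, 1]")
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  if (nz < 2 * n_strands + 1)
    stop("grid too shallow for ", n_strands, " separated strands")
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  labels <- array("gel", dim)
  # the plastic spindle body the strands are wound on: signal-free
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (sqrt((x - cx)^2 + (y - cy)^2) <= ring_radius - 1)
      labels[x, y, ] <- "core"
  }
  comp <- list()
  strand_z <- integer(n_strands)
  for (k in seq_len(n_strands)) {
    z <- 2 * k                           # every other slice: >= 1 gel gap
    strand_z[k] <- z
    for (x in seq_len(nx)) for (y in seq_len(ny)) {
      rr <- sqrt((x - cx)^2 + (y - cy)^2)
      if (abs(rr - ring_radius) <= 0.9) {
        vox <- x + nx * (y - 1) + nx * ny * (z - 1)
        tang <- c(-(y - cy), x - cx, 0) / rr
        labels[x, y, z] <- paste0("strand", k)
        comp[[length(comp) + 1L]] <- data.frame(
          voxel = vox, type = "fiber", fraction = fraction_ladder[k],
          ox = tang[1], oy = tang[2], oz = tang[3])
        comp[[length(comp) + 1L]] <- data.frame(
          voxel = vox, type = "free_water",
          fraction = 1 - fraction_ladder[k], ox = NA, oy = NA, oz = NA)
      }
    }
  }
  gel <- which(as.vector(labels) == "gel")
  comp[[length(comp) + 1L]] <- data.frame(
    voxel = gel, type = "free_water", fraction = 1,
    ox = NA, oy = NA, oz = NA)
  core <- which(as.vector(labels) == "core")
  comp[[length(comp) + 1L]] <- data.frame(
    voxel = core, type = "non_diffusive", fraction = 1,
    ox = NA, oy = NA, oz = NA)
  spec <- phantom_spec(dim, voxel_size, do.call(rbind, comp),
                       btable$bvalues, btable$bvectors, S0 = S0,
                       snr = snr, d_water = d_gel, rng_seed = rng_seed,
                       labels = labels)
  attr(spec, "strand_z") <- strand_z
  spec
}

#' Write a phantom to disk as NIfTI + bval/bvec + JSON ground truth
#'
#' @param spec A [phantom_spec()].
#' @param prefix Output prefix; writes the simulated DWI volume, b-table,
#'   a label volume (`<prefix>_labels.nii.gz`, integer codes) and a JSON
#'   ground-truth sidecar (label code table, compartments, seed).
#' @param noiseless Passed to [simulate_signal()].
#' @export
write_phantom <- function(spec, prefix, noiseless = FALSE) {
  ds <- simulate_signal(spec, noiseless = noiseless)
  write_dwi(ds, prefix)
  lab <- spec$labels
  codes <- NULL
  if (!is.null(lab)) {
    lv <- sort(unique(as.vector(lab)))
    codes <- stats::setNames(seq_along(lv), lv)
    write_nifti_map(array(codes[as.vector(lab)], spec$dim),
                    paste0(prefix, "_labels.nii.gz"), spec$voxel_size)
  }
  jsonlite::write_json(
    list(dim = spec$dim, voxel_size = spec$voxel_size,
         label_codes = as.list(codes), S0 = spec$S0, snr = spec$snr,
         rng_seed = spec$rng_seed,
         lambda_axial = spec$lambda_axial,
         lambda_radial = spec$lambda_radial, d_water = spec$d_water,
         compartments = spec$compartments),
    paste0(prefix, "_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
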