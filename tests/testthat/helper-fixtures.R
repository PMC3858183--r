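# shared heavy fixtures, computed once per test run

# hand-built SDF volume on a given tessellation (for direct peak tests)
manual_sdf <- function(psi, tess, dim3 = NULL, z0 = 1,
                       voxel_size = c(1, 1, 1)) {
  if (!is.matrix(psi)) psi <- matrix(psi, nrow = 1)
  n <- nrow(psi)
  if (is.null(dim3)) dim3 <- c(n, 1, 1)
  iso <- array(apply(psi, 1, min), dim3)
  structure(list(psi = psi, iso = iso, voxels = seq_len(n), z0 = z0,
                 sigma = 1.25, tess_level = tess$level, dim = dim3,
                 voxel_size = voxel_size),
            class = "sdf_volume")
}

# crossing phantom at SNR 30 with full reconstruction (FA, GFA, QA peaks)
fx_crossing <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- make_crossing_phantom(snr = 30, rng_seed = 1)
    ds <- simulate_signal(spec)
    tess <- build_tessellation(3)
    lab <- as.vector(spec$labels)
    sdf <- compute_z0(gqi_sdf(ds, tess),
                      free_water_region = which(lab == "water"))
    pk <- extract_peaks(sdf, tess)
    dti <- fit_dti(ds)
    qb <- qball_gfa(ds, tess)
    cache <<- list(spec = spec, ds = ds, tess = tess, lab = lab,
                   sdf = sdf, pk = pk, dti = dti, qb = qb)
    cache
  }
})

# noiseless crossing phantom (for exact peak-geometry checks)
fx_crossing_clean <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- make_crossing_phantom(snr = Inf, rng_seed = 1)
    ds <- simulate_signal(spec, noiseless = TRUE)
    tess <- build_tessellation(3)
    lab <- as.vector(spec$labels)
    sdf <- compute_z0(gqi_sdf(ds, tess),
                      free_water_region = which(lab == "water"))
    pk <- extract_peaks(sdf, tess)
    cache <<- list(spec = spec, ds = ds, tess = tess, lab = lab,
                   sdf = sdf, pk = pk)
    cache
  }
})

# spindle phantom with calibrated QA and FA thresholds
fx_spindle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- make_spindle_phantom(rng_seed = 1)
    ds <- simulate_signal(spec)
    lab <- spec$labels
    tess <- build_tessellation(3)
    sdf <- compute_z0(gqi_sdf(ds, tess),
                      free_water_region = which(as.vector(lab) == "gel"))
    pk <- extract_peaks(sdf, tess)
    dti <- fit_dti(ds)
    strand_mask <- array(!(as.vector(lab) %in% c("gel", "core")),
                         dim(lab))
    qa_map <- array(NA_real_, dim(lab))
    qa_map[pk$voxels] <- ifelse(is.na(pk$qa[, 1]), 0, pk$qa[, 1])
    cal_qa <- calibrate_threshold(qa_map, strand_mask,
                                  seq(0.05, 1.5, by = 0.05))
    cal_fa <- calibrate_threshold(dti$fa, strand_mask,
                                  seq(0.02, 0.6, by = 0.02))
    pk <- attach_scalar_indices(pk, fa = dti$fa)
    cache <<- list(spec = spec, lab = lab, pk = pk, dti = dti,
                   strand_mask = strand_mask, qa_map = qa_map,
                   cal_qa = cal_qa, cal_fa = cal_fa)
    cache
  }
})
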