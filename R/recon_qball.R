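#' Analytic q-ball ODFs and generalized fractional anisotropy
#'
#' Reconstructs orientation distribution functions from a single-shell
#' subset of the b-table by the analytic spherical-harmonic Funk-Radon
#' transform: the shell signal is fit with a real, even-order spherical
#' harmonic basis under Laplace-Beltrami regularization, the coefficients
#' are multiplied by `2 * pi * P_l(0)` (Legendre polynomial at zero), and
#' the ODF is evaluated on the tessellation hemisphere.  Negative ODF
#' samples are clipped to zero.  GFA is the standard deviation / RMS
#' ratio over the n hemisphere samples:
#'
#'   GFA = sqrt( n * sum((psi_i - mean)^2) / ((n - 1) * sum(psi_i^2)) )
#'
#' @param dwi A [dwi_dataset()].  For multi-b (grid) data the outermost
#'   shell is used and a warning is recorded on the result.
#' @param tess A [build_tessellation()] result.
#' @param sh_order Even spherical-harmonic order (default 8).
#' @param lambda Laplace-Beltrami regularization weight (default 0.006).
#' @param shell_tolerance Relative b-value spread accepted within a shell.
#' @return An `odf_volume` object: list with `odf` (nvox x n_hemisphere),
#'   `gfa` (3-D array), `voxels`, `shell_b`, `sh_order`, `dim`,
#'   `voxel_size`, and `warnings` (character vector).
#' @export
qball_gfa <- function(dwi, tess, sh_order = 8, lambda = 0.006,
                      shell_tolerance = 0.05) {
  stopifnot(inherits(dwi, "dwi_dataset"), inherits(tess, "sphere_tess"))
  if (sh_order %% 2 != 0 || sh_order < 0)
    stop("sh_order must be a non-negative even integer")
  b <- dwi$bvalues
  nz <- which(b > 0)
  if (length(nz) == 0L) stop("no diffusion-weighted volumes in the b-table")
  bmax <- max(b[nz])
  shell <- nz[abs(b[nz] - bmax) <= shell_tolerance * bmax]
  warnings <- character(0)
  if (length(shell) < length(nz))
    warnings <- sprintf(
      "multi-b data: using the outermost shell (b ~ %g, %d of %d volumes)",
      bmax, length(shell), length(nz))
  K <- (sh_order + 1) * (sh_order + 2) / 2
  if (length(shell) < K)
    stop(sprintf("shell has %d directions but order-%d fit needs >= %d",
                 length(shell), sh_order, K))
  g <- dwi$bvectors[shell, , drop = FALSE]
  d3 <- dim(dwi$signal)[1:3]
  vox <- .grid_voxels(d3, dwi$mask)
  S <- matrix(dwi$signal, prod(d3), length(b))[vox, shell, drop = FALSE]

  B <- .sh_basis(g, sh_order)
  ldeg <- .sh_degrees(sh_order)
  L2 <- (ldeg * (ldeg + 1))^2
  # regularized least squares fit, then Funk-Radon transform
  fit <- solve(crossprod(B) + lambda * diag(L2), t(B))
  frt <- 2 * pi * .legendre_p0(ldeg)
  u <- tess$vertices[tess$hemi_vertices, , drop = FALSE]
  Bu <- .sh_basis(u, sh_order)
  coef <- S %*% t(fit)
  odf <- pmax(coef %*% (t(Bu) * frt), 0)
  gfa_v <- apply(odf, 1, .gfa_from_samples)
  gfa <- array(NA_real_, d3)
  gfa[vox] <- gfa_v
  structure(list(odf = odf, gfa = gfa, voxels = vox, shell_b = bmax,
                 sh_order = sh_order, dim = d3,
                 voxel_size = dwi$voxel_size, warnings = warnings),
            class = "odf_volume")
}

#' Generalized fractional anisotropy of one set of ODF samples
#'
#' @param psi Numeric vector of non-negative ODF samples.
#' @return GFA in [0, 1]; 0 for an all-zero or constant ODF.
#' @examples
#' gfa_from_samples(c(1, rep(0, 9)))  # 1
#' @export
gfa_from_samples <- function(psi) .gfa_from_samples(as.numeric(psi))

.gfa_from_samples <- function(psi) {
  n <- length(psi)
  ss <- sum(psi^2)
  if (ss <= 0 || n < 2L) return(0)
  val <- sqrt(n * sum((psi - mean(psi))^2) / ((n - 1) * ss))
  min(val, 1)
}

# real even spherical-harmonic basis (descending into pracma's associated
# Legendre functions, Condon-Shortley phase included there):
#   m < 0: sqrt(2) * N * P_l^|m|(cos t) * sin(|m| p)
#   m = 0:           N * P_l^0(cos t)
#   m > 0: sqrt(2) * N * P_l^m(cos t) * cos(m p)
.sh_basis <- function(dirs, order) {
  theta <- acos(pmin(1, pmax(-1, dirs[, 3])))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  cols <- list()
  for (l in seq(0, order, by = 2)) {
    P <- if (l == 0) matrix(1, 1, n) else pracma::legendre(l, cos(theta))
    if (is.null(dim(P))) P <- matrix(P, ncol = 1)  # n = 1 edge case
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- N * P[am + 1, ]
      cols[[length(cols) + 1L]] <-
        if (m < 0) sqrt(2) * base * sin(am * phi)
        else if (m == 0) base
        else sqrt(2) * base * cos(m * phi)
    }
  }
  do.call(cbind, cols)
}

# degree l of each basis column, in .sh_basis order
.sh_degrees <- function(order) {
  unlist(lapply(seq(0, order, by = 2), function(l) rep(l, 2 * l + 1)))
}

# P_l(0) for even l: (-1)^(l/2) (l-1)!! / l!!
.legendre_p0 <- function(l) {
  vapply(l, function(li) {
    if (li == 0) return(1)
    k <- li / 2
    (-1)^k * exp(lgamma(li + 1) - 2 * k * log(2) - 2 * lgamma(k + 1))
  }, numeric(1))
}

#' @export
print.odf_volume <- function(x, ...) {
  cat(sprintf(
    "q-ball ODF volume: %s grid, shell b = %g, SH order %d, median GFA %.3f\n",
    paste(x$dim, collapse = " x "), x$shell_b, x$sh_order,
    stats::median(x$gfa, na.rm = TRUE)))
  invisible(x)
}
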