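#' Diffusion tensor fit and fractional anisotropy
#'
#' Weighted least-squares log-linear tensor fit per voxel.  The signal
#' model is `S = S0 * exp(-b g' D g)`; taking logs gives a linear system
#' in the six tensor elements plus `log(S0)`, solved in two passes:
#' ordinary least squares first, then weighted least squares with weights
#' equal to the squared *predicted* signal (the standard first-order
#' variance stabilization for log-transformed magnitudes; predicted
#' rather than observed weights avoid biasing the fit toward upward noise
#' excursions in low-signal voxels).  Multiple b = 0 volumes
#' are averaged before fitting.  FA is computed from the eigenvalues,
#' negative eigenvalues clipped to zero first so FA stays in [0, 1]:
#' `FA = sqrt(3/2 * sum((l_i - lbar)^2) / sum(l_i^2))`.
#'
#' @param dwi A [dwi_dataset()] with at least one b = 0 volume and at
#'   least six distinct non-zero-b directions.
#' @return A `tensor_volume` object: list with `tensors` (nvox x 6 matrix
#'   of Dxx, Dyy, Dzz, Dxy, Dxz, Dyz per in-mask voxel), `eigenvalues`
#'   (nvox x 3, sorted descending), `evec1` (nvox x 3 principal
#'   directions), `fa` (3-D array, `NA` outside the mask or where the b0
#'   signal is non-positive), `md` (mean diffusivity map), `dim`,
#'   `voxel_size`.
#' @export
fit_dti <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  dwi <- .collapse_b0(dwi)
  b <- dwi$bvalues
  g <- dwi$bvectors
  if (length(b) < 7L)
    stop("tensor fit needs at least 6 diffusion-weighted volumes plus b0")
  nz <- b > 0
  if (qr(g[nz, , drop = FALSE])$rank < 3L ||
      length(unique(apply(round(g[nz, , drop = FALSE], 6), 1, paste,
                          collapse = ","))) < 6L)
    stop("tensor fit needs >= 6 distinct non-collinear gradient directions")
  d3 <- dim(dwi$signal)[1:3]
  vox <- .grid_voxels(d3, dwi$mask)
  S <- matrix(dwi$signal, prod(d3), length(b))[vox, , drop = FALSE]

  # design: log S = log S0 - b * (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
  #                               + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  ok_b0 <- S[, which(b == 0)[1]] > 0
  floor_sig <- 1e-8
  logS <- log(pmax(S, floor_sig))

  n_in <- length(vox)
  tensors <- matrix(NA_real_, n_in, 6)
  evals <- matrix(NA_real_, n_in, 3)
  evec1 <- matrix(NA_real_, n_in, 3)
  fa_v <- rep(NA_real_, n_in)
  md_v <- rep(NA_real_, n_in)
  XtX_inv_Xt <- solve(crossprod(X), t(X))  # OLS operator, shared
  for (i in seq_len(n_in)) {
    if (!ok_b0[i]) next
    beta0 <- XtX_inv_Xt %*% logS[i, ]
    w <- exp(2 * pmin(as.vector(X %*% beta0), 50))  # predicted-signal^2
    Xw <- X * w
    beta <- tryCatch(solve(crossprod(Xw, X), crossprod(Xw, logS[i, ])),
                     error = function(e) NULL)
    if (is.null(beta)) next
    Dm <- matrix(c(beta[2], beta[5], beta[6],
                   beta[5], beta[3], beta[7],
                   beta[6], beta[7], beta[4]), 3, 3)
    eg <- eigen(Dm, symmetric = TRUE)
    tensors[i, ] <- beta[2:7]
    evals[i, ] <- eg$values
    evec1[i, ] <- eg$vectors[, 1]
    lam <- pmax(eg$values, 0)
    fa_v[i] <- .fa_from_eigenvalues(lam)
    md_v[i] <- mean(eg$values)
  }
  fa <- array(NA_real_, d3); fa[vox] <- fa_v
  md <- array(NA_real_, d3); md[vox] <- md_v
  structure(list(tensors = tensors, eigenvalues = evals, evec1 = evec1,
                 voxels = vox, fa = fa, md = md, dim = d3,
                 voxel_size = dwi$voxel_size),
            class = "tensor_volume")
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' @param lambda Numeric length-3 eigenvalues (any order); negative values
#'   should be clipped by the caller if a [0, 1] range is required.
#' @return FA value; 0 for an all-zero tensor.
#' @examples
#' fa_from_eigenvalues(c(2, 1, 1) * 1e-3)  # sqrt(1/6)
#' @export
fa_from_eigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 3L)
  .fa_from_eigenvalues(as.numeric(lambda))
}

.fa_from_eigenvalues <- function(lam) {
  ss <- sum(lam^2)
  if (ss <= 0) return(0)
  lbar <- mean(lam)
  sqrt(1.5 * sum((lam - lbar)^2) / ss)
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("Tensor volume: %s grid, %d fitted voxels, median FA %.3f\n",
              paste(x$dim, collapse = " x "), sum(!is.na(x$fa)),
              stats::median(x$fa, na.rm = TRUE)))
  invisible(x)
}
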