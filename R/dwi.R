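#' Assemble a diffusion-weighted imaging dataset
#'
#' Bundles the 4-D signal grid with its b-table and voxel geometry and
#' validates the pieces against each other.  The b-table follows the FSL
#' dialect: one b-value and one unit gradient direction per volume, the
#' zero vector allowed (and preserved) for b = 0 volumes.
#'
#' @param signal 4-D numeric array, dimensions x, y, z, acquisition.
#' @param bvalues Numeric vector of b-values in s/mm^2, one per volume.
#' @param bvectors n x 3 numeric matrix of gradient directions; non-zero
#'   rows are normalized to unit length.
#' @param voxel_size Length-3 positive numeric, voxel edge lengths in mm.
#' @param mask Optional 3-D logical array restricting reconstruction.
#' @return A `dwi_dataset` object.
#' @export
dwi_dataset <- function(signal, bvalues, bvectors, voxel_size = c(1, 1, 1),
                        mask = NULL) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4-D array (x, y, z, acquisition)")
  n <- dim(signal)[4]
  bvalues <- as.numeric(bvalues)
  bvectors <- as.matrix(bvectors)
  if (ncol(bvectors) != 3L)
    stop("bvectors must have 3 columns")
  if (length(bvalues) != n || nrow(bvectors) != n)
    stop(sprintf(
      "b-table mismatch: %d volumes but %d b-values and %d b-vectors",
      n, length(bvalues), nrow(bvectors)))
  if (any(!is.finite(signal)))
    stop("signal contains non-finite values")
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  if (!any(bvalues == 0)) stop("at least one b = 0 acquisition is required")
  dimnames(bvectors) <- NULL
  nrm <- sqrt(rowSums(bvectors^2))
  nz <- nrm > 1e-12
  bvectors[nz, ] <- bvectors[nz, , drop = FALSE] / nrm[nz]
  bvectors[!nz, ] <- 0
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (mm)")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(signal)[1:3])
  }
  structure(list(signal = signal, bvalues = bvalues, bvectors = bvectors,
                 voxel_size = voxel_size, mask = mask),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI dataset: %d x %d x %d grid, %d volumes (%d b0), voxel %s mm\n",
              d[1], d[2], d[3], d[4], sum(x$bvalues == 0),
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

# averaged-b0 view of a dataset: all b = 0 volumes collapsed to one
.collapse_b0 <- function(dwi) {
  b0 <- dwi$bvalues == 0
  if (sum(b0) <= 1L) return(dwi)
  d <- dim(dwi$signal)
  sig <- dwi$signal
  flat <- matrix(sig, prod(d[1:3]), d[4])
  b0_mean <- rowMeans(flat[, b0, drop = FALSE])
  keep <- which(!b0)
  out <- array(cbind(b0_mean, flat[, keep, drop = FALSE]),
               dim = c(d[1:3], length(keep) + 1L))
  dwi_dataset(out, c(0, dwi$bvalues[keep]),
              rbind(c(0, 0, 0), dwi$bvectors[keep, , drop = FALSE]),
              dwi$voxel_size, dwi$mask)
}

.grid_voxels <- function(dim3, mask = NULL) {
  if (is.null(mask)) seq_len(prod(dim3)) else which(as.vector(mask))
}

#' Read a DWI dataset from NIfTI + FSL bval/bvec files
#'
#' @param nifti_path Path to a 4-D NIfTI volume.
#' @param bval_path,bvec_path FSL-dialect b-table text files (`bvec` has 3
#'   rows, one column per volume, in the image frame).
#' @param mask_path Optional 3-D NIfTI mask (non-zero = inside).
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, mask_path = NULL) {
  img <- RNifti::readNifti(nifti_path)
  bt <- read_btable(bval_path, bvec_path)
  sig <- as.array(img)
  if (length(dim(sig)) != 4L)
    stop("expected a 4-D NIfTI volume: ", nifti_path)
  vs <- RNifti::pixdim(img)[1:3]
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path)) != 0
  }
  ds <- dwi_dataset(sig, bt$bvalues, bt$bvectors, vs, mask)
  ds$affine <- structure(RNifti::xform(img), class = NULL)
  ds
}

#' Read / write FSL-dialect b-tables
#'
#' `bval` is one row of b-values; `bvec` is three rows (x, y, z), one
#' column per volume.
#'
#' @param bval_path,bvec_path Text file paths.
#' @return `read_btable`: list with `bvalues` and `bvectors` (n x 3).
#' @export
read_btable <- function(bval_path, bvec_path) {
  bvalues <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
  if (nrow(bv) == 3L && ncol(bv) == 3L) bv <- t(bv)  # 3x3: rows are x,y,z
  if (ncol(bv) != 3L)
    stop("bvec file must have 3 rows (x, y, z components)")
  if (length(bvalues) != nrow(bv))
    stop(sprintf("b-table mismatch: %d b-values but %d b-vectors",
                 length(bvalues), nrow(bv)))
  list(bvalues = bvalues, bvectors = unname(bv))
}

#' @rdname read_btable
#' @param bvalues,bvectors b-table to write.
#' @export
write_btable <- function(bvalues, bvectors, bval_path, bvec_path) {
  cat(paste(format(bvalues, scientific = FALSE, trim = TRUE),
            collapse = " "), "\n", file = bval_path, sep = "")
  write(t(format(t(bvectors), digits = 17)), file = bvec_path,
        ncolumns = nrow(bvectors))
  invisible(NULL)
}

#' Write a 3-D map or 4-D volume as 32-bit float NIfTI
#'
#' @param x Numeric array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size Length-3 voxel size in mm (used when no template).
#' @param template Optional NIfTI image whose geometry is copied.
#' @export
write_nifti_map <- function(x, path, voxel_size = c(1, 1, 1),
                            template = NULL) {
  x[!is.finite(x)] <- 0
  if (!is.null(template)) {
    img <- RNifti::asNifti(x, reference = template)
  } else {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(x)) - 3L))
  }
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a DWI dataset as NIfTI + bval/bvec
#'
#' @param dwi A [dwi_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`, and `<prefix>_mask.nii.gz` if a
#'   mask is present.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  write_nifti_map(dwi$signal, paste0(prefix, ".nii.gz"), dwi$voxel_size)
  write_btable(dwi$bvalues, dwi$bvectors,
               paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  if (!is.null(dwi$mask))
    write_nifti_map(dwi$mask + 0, paste0(prefix, "_mask.nii.gz"),
                    dwi$voxel_size)
  invisible(prefix)
}
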