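#' Write a tractogram to TRK or TCK
#'
#' TRK (TrackVis) carries the voxel size, grid dimensions and a
#' voxel-to-RAS affine in its 1000-byte header and stores points in
#' "voxmm" convention (corner-origin voxel coordinates scaled by the
#' voxel size); TCK (MRtrix) stores raw RAS mm coordinates after a text
#' header.  Both writers emit little-endian float32, so read-back
#' reproduces coordinates to float32 precision, and the two formats
#' decode to identical mm coordinates.
#'
#' @param tract A `tractogram`.
#' @param path Output path; the format is chosen by extension unless
#'   `format` is given.
#' @param format `"trk"` or `"tck"`.
#' @export
write_tractogram <- function(tract, path, format = NULL) {
  stopifnot(inherits(tract, "tractogram"))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("trk", "tck"))
    stop("unknown tractogram format '", format, "' (use trk or tck)")
  if (format == "trk") .write_trk(tract, path) else .write_tck(tract, path)
  invisible(path)
}

#' Read a TRK or TCK file
#'
#' @param path Input path; format by extension unless `format` is given.
#' @param format `"trk"` or `"tck"`.
#' @return A `tractogram` (streamlines in mm; voxel size and dimensions
#'   populated from the TRK header, unit defaults for TCK).
#' @export
read_tractogram <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("trk", "tck"))
    stop("unknown tractogram format '", format, "'")
  if (format == "trk") .read_trk(path) else .read_tck(path)
}

.write_trk <- function(tract, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, what, size) writeBin(x, con, size = size,
                                         endian = "little")
  vs <- as.numeric(tract$voxel_size)
  dims <- as.integer(if (is.null(tract$dim)) c(0, 0, 0) else tract$dim)
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  wb(as.raw(0), "raw", 1)
  wb(dims, "integer", 2)
  wb(vs, "double", 4)
  wb(rep(0, 3), "double", 4)                    # origin
  wb(0L, "integer", 2)                          # n_scalars
  wb(raw(200), "raw", 1)                        # scalar names
  wb(0L, "integer", 2)                          # n_properties
  wb(raw(200), "raw", 1)                        # property names
  # vox_to_ras: RAS mm = (vox0 * vs); voxmm stores (vox0 + 0.5) * vs,
  # so the affine carries a -0.5 * vs translation (row-major rows)
  aff <- rbind(cbind(diag(vs), -0.5 * vs), c(0, 0, 0, 1))
  wb(as.numeric(t(aff)), "double", 4)
  wb(raw(444), "raw", 1)                        # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL)
  wb(raw(1), "raw", 1)
  wb(raw(4), "raw", 1)                          # pad2
  wb(c(1, 0, 0, 0, 1, 0), "double", 4)          # image orientation
  wb(raw(2), "raw", 1)                          # pad1
  wb(raw(6), "raw", 1)                          # invert/swap flags
  wb(length(tract$streamlines), "integer", 4)   # n_count
  wb(2L, "integer", 4)                          # version
  wb(1000L, "integer", 4)                       # hdr_size
  for (s in tract$streamlines) {
    wb(nrow(s), "integer", 4)
    voxmm <- sweep(s, 2, vs, "/") + 0.5
    voxmm <- sweep(voxmm, 2, vs, "*")
    wb(as.numeric(t(voxmm)), "double", 4)
  }
}

.read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rb <- function(n, what, size)
    readBin(con, what, n = n, size = size, endian = "little")
  magic <- rawToChar(rb(6, "raw", 1)[1:5])
  if (magic != "TRACK") stop("not a TRK file: ", path)
  dims <- rb(3, "integer", 2)
  vs <- rb(3, "double", 4)
  invisible(rb(3, "double", 4))                 # origin
  n_scalars <- rb(1, "integer", 2)
  invisible(rb(200, "raw", 1))
  n_props <- rb(1, "integer", 2)
  invisible(rb(200, "raw", 1))
  invisible(rb(16, "double", 4))                # vox_to_ras
  invisible(rb(444, "raw", 1))
  invisible(rb(8, "raw", 1))                    # voxel_order + pad2
  invisible(rb(6, "double", 4))
  invisible(rb(8, "raw", 1))                    # pad1 + flags
  n_count <- rb(1, "integer", 4)
  invisible(rb(2, "integer", 4))                # version, hdr_size
  streamlines <- list()
  repeat {
    npts <- rb(1, "integer", 4)
    if (length(npts) == 0L) break
    vals <- rb(npts * (3 + n_scalars), "double", 4)
    if (n_props > 0) invisible(rb(n_props, "double", 4))
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3,
                                                          drop = FALSE]
    mm <- sweep(sweep(m, 2, vs, "/") - 0.5, 2, vs, "*")
    streamlines[[length(streamlines) + 1L]] <- mm
    if (n_count > 0 && length(streamlines) >= n_count) break
  }
  .as_tractogram(streamlines, vs, dims)
}

.write_tck <- function(tract, path) {
  hdr <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                length(tract$streamlines), "\n")
  # fixed-width offset so the header length is stable
  base <- nchar(hdr, type = "bytes")
  off <- base + nchar("file: . 000000\nEND\n", type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, sprintf("file: . %06d\nEND\n", off)), con,
            eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}

.read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.info(path)$size)
  # header is ASCII up to the 'END\n' sentinel; scan bytes (the binary
  # payload may contain nul bytes, so no blanket rawToChar)
  pat <- charToRaw("END\n")
  hdr_end <- NA_integer_
  for (p in which(raw_all == pat[1])) {
    if (p + 3 <= length(raw_all) &&
        identical(raw_all[p:(p + 3)], pat)) { hdr_end <- p + 3; break }
  }
  if (is.na(hdr_end)) stop("not a TCK file: ", path)
  header <- rawToChar(raw_all[seq_len(hdr_end)])
  if (!grepl("^mrtrix tracks", header)) stop("not a TCK file: ", path)
  off_m <- regmatches(header, regexpr("file: \\. *[0-9]+", header))
  off <- as.integer(sub("file: \\. *", "", off_m))
  vals <- readBin(raw_all[(off + 1):length(raw_all)], "double",
                  n = (length(raw_all) - off) / 4, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur))
        streamlines[[length(streamlines) + 1L]] <- do.call(rbind, cur)
      cur <- NULL
    } else cur <- c(cur, list(p))
  }
  if (!is.null(cur))
    streamlines[[length(streamlines) + 1L]] <- do.call(rbind, cur)
  .as_tractogram(streamlines, c(1, 1, 1), NULL)
}

.as_tractogram <- function(streamlines, voxel_size, dims) {
  step <- NA_real_
  structure(list(streamlines = streamlines, seeds = NULL,
                 lengths = vapply(streamlines, function(s) {
                   if (nrow(s) < 2) return(0)
                   sum(sqrt(rowSums(diff(s)^2)))
                 }, numeric(1)),
                 n_seeds_used = NA_integer_, voxel_size = voxel_size,
                 dim = dims, params = NULL, warnings = character(0)),
            class = "tractogram")
}

#' Write a JSON run manifest
#'
#' Records every parameter, threshold and RNG seed of a tracking run so
#' the run can be reproduced bitwise.
#'
#' @param path Output JSON path.
#' @param params A [tracking_params()].
#' @param extra Named list of additional fields (input paths, ROI
#'   definitions, calibration results, ...).
#' @export
write_run_manifest <- function(path, params, extra = list()) {
  payload <- c(list(package = "qatrack",
                    version = as.character(utils::packageVersion("qatrack")),
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    params = unclass(params)), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
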