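# MRC volume I/O (mode 2, 32-bit float) and CSV dataset manifests. The
# MRC data block stores the fastest-varying axis first (columns); volumes
# are held in memory as (height, width, depth) arrays, with the file's
# (nx, ny, nz) mapped to (width, height, depth): nx = width, ny = height,
# nz = depth.

#' Write a volume to an MRC file
#'
#' Writes a standard-conformant MRC2014 file with mode 2 (IEEE 32-bit
#' float) data.
#'
#' @param volume 3D numeric array `(height, width, depth)`, finite values
#'   only.
#' @param path Output file path.
#' @param voxel_size Voxel spacing in Angstrom, carried in the cell
#'   dimensions.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, voxel_size = 1) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("invalid input: expected a 3D array", call. = FALSE)
  if (!all(is.finite(volume)))
    stop("invalid input: non-finite voxel values", call. = FALSE)
  d <- dim(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(d[2L], d[1L], d[3L]))        # nx (width), ny (height), nz (depth)
  wi(2L)                            # mode 2: float32
  wi(c(0L, 0L, 0L))                 # nxstart, nystart, nzstart
  wi(c(d[2L], d[1L], d[3L]))        # mx, my, mz
  wf(c(d[2L], d[1L], d[3L]) * voxel_size)  # cell dimensions (A)
  wf(c(90, 90, 90))                 # cell angles
  wi(c(1L, 2L, 3L))                 # mapc, mapr, maps
  wf(c(min(volume), max(volume), mean(volume)))
  wi(c(0L, 0L))                     # ispg, nsymbt
  writeBin(raw(100L), con)          # extra
  wf(c(0, 0, 0))                    # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(volume))             # rms
  wi(0L)                            # nlabl
  writeBin(raw(800L), con)          # labels
  dat <- aperm(volume, c(2L, 1L, 3L))  # x fastest in the file
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC volume
#'
#' Supports mode 2 (float32) files as written by [write_volume()] and
#' standard tomography tooling. The file's `(nx, ny, nz)` axes map to the
#' in-memory `(height, width, depth)` array as `ny, nx, nz`.
#'
#' @param path MRC file path.
#' @return 3D numeric array with attribute `voxel_size`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("format error: no such file ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (sz < 1024) stop("format error: file shorter than the 1024-byte header (",
                      sz, " bytes)", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4L, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4L, endian = "little")
  nxyz <- ri(3L)
  mode <- ri(1L)
  ri(3L); mxyz <- ri(3L)
  cella <- rf(3L); rf(3L)
  ri(3L); rf(3L); ri(2L)
  seek(con, 208L)
  map <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(map, "MAP "))
    stop("format error: missing 'MAP ' stamp at byte offset 208", call. = FALSE)
  if (mode != 2L)
    stop("format error: unsupported mode ", mode, " (only mode 2 float32)",
         call. = FALSE)
  if (any(nxyz < 1L))
    stop("format error: non-positive dimensions in header", call. = FALSE)
  need <- 1024 + prod(nxyz) * 4
  if (sz < need)
    stop("format error: truncated data block (need ", need, " bytes, file has ",
         sz, ")", call. = FALSE)
  seek(con, 1024L)
  dat <- readBin(con, "numeric", n = prod(nxyz), size = 4L, endian = "little")
  vol <- aperm(array(dat, dim = nxyz), c(2L, 1L, 3L))  # -> (h, w, d)
  attr(vol, "voxel_size") <- if (mxyz[1L] > 0) cella[1L] / mxyz[1L] else NA_real_
  vol
}

#' Save a dataset manifest as CSV
#'
#' @param manifest data.frame with at least `sample_id`, `label`, `split`
#'   (a `path` column is kept if present, as are any extra columns).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
save_manifest <- function(manifest, path) {
  if (anyDuplicated(manifest$sample_id))
    stop("validation error: duplicate sample_id", call. = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a dataset manifest
#'
#' @param path CSV path with header columns including `sample_id`,
#'   `label`, `split`.
#' @param n_classes If given, ID labels must lie in `1..n_classes`.
#' @param strict_paths If `TRUE` and a `path` column exists, every
#'   referenced file must exist.
#' @return The manifest data.frame.
#' @export
load_manifest <- function(path, n_classes = NULL, strict_paths = FALSE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "label", "split")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("validation error: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("validation error: duplicate sample_id", call. = FALSE)
  lab <- m$label[!is.na(m$label)]
  if (!is.null(n_classes) && length(lab) &&
      (any(lab < 1) || any(lab > n_classes)))
    stop("validation error: label outside 1..", n_classes, call. = FALSE)
  if (strict_paths && "path" %in% names(m)) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing))
      stop("validation error: missing files: ",
           paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  }
  m
}
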