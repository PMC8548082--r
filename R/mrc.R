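# Minimal MRC2014 I/O (mode 2, 32-bit float), with an FEI-style extended
# header for tilt series carrying per-image tilt angle, defocus, exposure,
# accumulated dose and pixel size. Metadata are additionally mirrored to a
# plain-text TSV sidecar so generic tooling can read them.

FEI_FIELDS <- 32L # float32 slots per image in the extended header
# slot layout (1-based): 1 tilt angle (deg), 2 defocus (A), 3 exposure (s),
# 4 accumulated dose (e-/A^2), 5 pixel size (A); remaining slots reserved.

#' Write a volume or image stack to an MRC file
#'
#' Writes MRC2014 mode-2 (float32) with voxel size in the header. When
#' `meta` is supplied (or `data` is a `tilt_series`), an FEI-style extended
#' header with 32 float fields per image records tilt angle, defocus,
#' exposure, accumulated dose and pixel size, and the same table is written
#' to `<path>.meta.tsv`.
#'
#' @param data A 2D/3D numeric array, `twin_volume`, or `tilt_series`.
#' @param path Output path.
#' @param voxel Voxel/pixel size in Angstroms (taken from the object when
#'   available).
#' @param meta Optional per-image metadata data.frame (see
#'   [simulate_tilt_series()]).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, voxel = NULL, meta = NULL) {
  if (inherits(data, "tilt_series")) {
    meta <- meta %||% data$meta
    voxel <- voxel %||% data$pixel
    data <- data$images
  }
  voxel <- voxel %||% attr(data, "voxel") %||% 1
  dm <- dim(data)
  if (length(dm) == 2) dm <- c(dm, 1L)
  arr <- array(as.numeric(data), dm)

  ext <- raw(0)
  if (!is.null(meta)) {
    slots <- matrix(0, FEI_FIELDS, dm[3])
    n <- min(nrow(meta), dm[3])
    slots[1, seq_len(n)] <- meta$angle[seq_len(n)]
    slots[2, seq_len(n)] <- meta$defocus[seq_len(n)]
    slots[3, seq_len(n)] <- meta$exposure[seq_len(n)]
    slots[4, seq_len(n)] <- meta$accumulated_dose[seq_len(n)]
    slots[5, seq_len(n)] <- rep(voxel, n)
    ext <- writeBin(as.numeric(slots), raw(), size = 4, endian = "little")
    utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dm)                         # nx ny nz
  wi(2)                          # mode 2: float32
  wi(c(0, 0, 0))                 # nxstart
  wi(dm)                         # mx my mz
  wf(dm * voxel)                 # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1, 2, 3))                 # mapc mapr maps
  wf(c(min(arr), max(arr), mean(arr))) # dmin dmax dmean
  wi(0)                          # ispg
  wi(length(ext))                # nsymbt: extended header bytes
  writeBin(raw(100), con)        # extra (25 words); includes exttyp slot
  # overwrite exttyp/nversion words (bytes 105-112 of header)
  wf(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(stats::sd(as.numeric(arr))) # rms
  wi(1)                          # nlabl
  lab <- sprintf("%-80s", "cryotwin simulated data")
  writeChar(substr(lab, 1, 80), con, 80, eos = NULL)
  writeBin(raw(80 * 9), con)     # remaining labels
  if (length(ext) > 0) writeBin(ext, con)
  wf(arr)
  invisible(path)
}

#' Read an MRC file written by [write_mrc()] (or any mode-0/1/2 MRC volume)
#'
#' @param path MRC file path.
#' @return A `twin_volume` array with attributes `voxel` and, when an
#'   extended header is present, `meta` (data.frame of the FEI-style
#'   fields).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  ri(3)              # nxstart
  mx <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3) # cellb, map axes, dmin/dmax/dmean
  ri(1)              # ispg
  nsymbt <- ri(1)
  seek(con, 1024)
  ext <- if (nsymbt > 0) readBin(con, "raw", nsymbt) else raw(0)
  n <- prod(dm)
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode)
  )
  vol <- array(data, dm)
  attr(vol, "voxel") <- if (mx[1] > 0) cella[1] / mx[1] else 1
  if (length(ext) >= 4 * FEI_FIELDS && dm[3] >= 1) {
    vals <- readBin(ext, "numeric", length(ext) / 4, size = 4,
                    endian = "little")
    nimg <- min(dm[3], length(vals) %/% FEI_FIELDS)
    slots <- matrix(vals[seq_len(FEI_FIELDS * nimg)], FEI_FIELDS, nimg)
    attr(vol, "meta") <- data.frame(
      angle = slots[1, ], defocus = slots[2, ], exposure = slots[3, ],
      accumulated_dose = slots[4, ], pixel = slots[5, ]
    )
  }
  class(vol) <- c("twin_volume", "array")
  vol
}
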