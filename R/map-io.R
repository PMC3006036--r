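#' Read a CCP4/MRC electron-density map
#'
#' Reads a mode-2 (32-bit float) CCP4/MRC volume covering the full unit cell
#' in P1. The axis-order header words (MAPC/MAPR/MAPS) are honoured: values
#' are re-indexed so that the returned array's first index runs along the
#' crystallographic a axis. Crystallographic symmetry is never expanded;
#' supply P1-expanded maps.
#'
#' @param path Path to the map file.
#' @param format `"ccp4"` or `"mrc"` (same container; kept for clarity).
#' @return A [density_grid()].
#' @export
read_map <- function(path, format = c("ccp4", "mrc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) {
    stop(sprintf("format error in '%s': file has %d bytes but the header needs 1024",
                 path, ifelse(is.na(sz), 0L, sz)), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  endian <- "little"
  word_i <- function(k) readBin(hdr_raw[(4 * (k - 1) + 1):(4 * k)], "integer",
                                1, size = 4, endian = endian)
  # detect byte order from the MODE word (must be a small integer)
  if (!word_i(4) %in% 0:6) {
    endian <- "big"
    if (!word_i(4) %in% 0:6) {
      stop(sprintf("format error in '%s' at byte offset 12: unrecognized MODE word", path),
           call. = FALSE)
    }
  }
  word_f <- function(k) readBin(hdr_raw[(4 * (k - 1) + 1):(4 * k)], "numeric",
                                1, size = 4, endian = endian)
  nc <- word_i(1); nr <- word_i(2); ns <- word_i(3)
  mode <- word_i(4)
  if (mode != 2) {
    stop(sprintf("unsupported feature in '%s': MODE %d (only mode-2 float maps are supported)",
                 path, mode), call. = FALSE)
  }
  start <- c(word_i(5), word_i(6), word_i(7))
  nxyz <- c(word_i(8), word_i(9), word_i(10))
  cellp <- vapply(11:16, word_f, numeric(1))
  mapcrs <- c(word_i(17), word_i(18), word_i(19))
  nsymbt <- word_i(24)
  if (!all(sort(mapcrs) == 1:3)) {
    stop(sprintf("unsupported feature in '%s': MAPC/MAPR/MAPS = %s is not an axis permutation",
                 path, paste(mapcrs, collapse = ",")), call. = FALSE)
  }
  ndata <- as.double(nc) * nr * ns
  need <- 1024 + nsymbt + 4 * ndata
  if (sz < need) {
    stop(sprintf("format error in '%s' at byte offset %d: expected %.0f data bytes, file truncated",
                 path, 1024 + nsymbt, 4 * ndata), call. = FALSE)
  }
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- readBin(con, "numeric", ndata, size = 4, endian = endian)
  arr <- array(vals, dim = c(nc, nr, ns))   # col, row, section storage
  # permute storage axes (c,r,s) onto crystal axes (x,y,z)
  perm <- order(mapcrs)   # position of crystal axis d within (c,r,s)
  arr <- aperm(arr, perm)
  dims_xyz <- c(nc, nr, ns)[perm]
  origin_xyz <- start[perm]
  if (!all(dims_xyz == nxyz)) {
    stop(sprintf(
      "unsupported feature in '%s': sampling %s does not cover exactly one cell %s; expand to P1 full cell first",
      path, paste(dims_xyz, collapse = "x"), paste(nxyz, collapse = "x")),
      call. = FALSE)
  }
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])
  density_grid(arr, cell, origin = origin_xyz)
}

#' Write a density grid as a CCP4/MRC map
#'
#' Writes a mode-2 little-endian map with axis order X, Y, Z (MAPC=1,
#' MAPR=2, MAPS=3) covering the full cell.
#'
#' @param map A [density_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.vector(map$values)
  n <- map$dims
  wI(n)                                   # NC NR NS
  wI(2)                                   # MODE 2 = float
  wI(map$origin)                          # NCSTART NRSTART NSSTART
  wI(n)                                   # NX NY NZ sampling
  wF(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wI(1:3)                                 # MAPC MAPR MAPS
  wF(c(min(v), max(v), mean(v)))          # AMIN AMAX AMEAN
  wI(1)                                   # ISPG = P1
  wI(0)                                   # NSYMBT
  wI(rep(0L, 25))                         # EXTRA words 25..49
  wF(c(0, 0, 0))                          # ORIGIN (MRC-2000 words 50..52)
  writeBin(charToRaw("MAP "), con)        # word 53
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machine stamp, LE
  wF(sqrt(mean((v - mean(v))^2)))         # RMS
  wI(0)                                   # NLABL
  writeBin(raw(800), con)                 # labels
  wF(v)
  invisible(path)
}
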