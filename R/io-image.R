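# Image I/O for projection images and spectra: MRC (mode 2, float32) and a
# plain tab-separated grid. No R package on hand reads MRC, so the minimal
# 1024-byte-header reader/writer is implemented directly with readBin /
# writeBin; it covers the subset of the format these tools produce.

#' Write a 2D image to an MRC file (mode 2, float32)
#'
#' Image rows map to MRC rows (ny), columns to nx; nz = 1. The pixel size is
#' stored in the cell dimensions.
#'
#' @param image A `projection_image` or plain matrix.
#' @param path Output path.
#' @param pixel_size Angstrom per pixel (taken from the image when absent).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(image, path, pixel_size = NULL) {
  if (inherits(image, "projection_image")) {
    grid <- image$grid
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
  } else grid <- image
  if (is.null(pixel_size)) pixel_size <- 1.0
  nr <- nrow(grid); nc <- ncol(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nc, nr, 1L))                     # nx ny nz
  wi(2L)                                # mode 2 = float32
  wi(c(0L, 0L, 0L))                     # nxstart nystart nzstart
  wi(c(nc, nr, 1L))                     # mx my mz
  wf(c(nc * pixel_size, nr * pixel_size, pixel_size))  # cell a b c
  wf(c(90, 90, 90))                     # cell angles
  wi(c(1L, 2L, 3L))                     # axis order
  wf(c(min(grid), max(grid), mean(grid)))
  wi(c(0L, 0L))                         # ispg, nsymbt
  writeBin(raw(100), con)               # extra
  wf(c(0, 0, 0))                        # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(grid)))
  wi(0L)                                # nlabl
  writeBin(raw(800), con)               # labels
  # data: x fastest -> write row-major (transpose of R's column-major)
  writeBin(as.numeric(t(grid)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 2D image from an MRC file
#'
#' Supports single-section mode 0/1/2 files with default axis order.
#'
#' @param path MRC file path.
#' @return A `projection_image`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  ri(3); mx <- ri(3)
  cell <- rf(3)
  seek(con, 1024)
  nc <- dims[1]; nr <- dims[2]; nz <- dims[3]
  if (nz != 1L) stop("only single-section MRC images are supported")
  n <- nc * nr
  data <- switch(as.character(mode),
                 "0" = as.numeric(readBin(con, "integer", n, size = 1,
                                          signed = TRUE)),
                 "1" = as.numeric(readBin(con, "integer", n, size = 2,
                                          endian = "little")),
                 "2" = readBin(con, "numeric", n, size = 4,
                               endian = "little"),
                 stop("unsupported MRC mode: ", mode))
  grid <- t(matrix(data, nrow = nc, ncol = nr))  # x fastest in file
  px <- if (mx[1] > 0 && cell[1] > 0) cell[1] / mx[1] else 1.0
  structure(list(grid = grid, pixel_size = px, blur_sigma = NA_real_),
            class = "projection_image")
}

#' Write an image as a plain tab-separated grid
#'
#' A text alternative to MRC: one matrix row per line, preceded by a single
#' comment line `# pixel_size <value>`.
#'
#' @param image A `projection_image` or matrix.
#' @param path Output path.
#' @param pixel_size Angstrom per pixel.
#' @return `path`, invisibly.
#' @export
write_image_tsv <- function(image, path, pixel_size = NULL) {
  if (inherits(image, "projection_image")) {
    grid <- image$grid
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
  } else grid <- image
  if (is.null(pixel_size)) pixel_size <- 1.0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size %.10g", pixel_size), con)
  utils::write.table(grid, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  px <- 1.0
  skip <- 0
  if (grepl("^#\\s*pixel_size", first)) {
    px <- as.numeric(sub("^#\\s*pixel_size\\s+", "", first))
    skip <- 1
  }
  grid <- as.matrix(utils::read.table(path, sep = "\t", skip = skip))
  dimnames(grid) <- NULL
  structure(list(grid = grid, pixel_size = px, blur_sigma = NA_real_),
            class = "projection_image")
}

#' Read a projection image, dispatching on file extension
#'
#' `.mrc` goes through [read_mrc()], anything else through
#' [read_image_tsv()].
#' @param path Image path.
#' @return A `projection_image`.
#' @export
read_image <- function(path) {
  if (grepl("\\.mrc$", path, ignore.case = TRUE)) read_mrc(path)
  else read_image_tsv(path)
}
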