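#' @include AllClasses.R utils.R
NULL

#' Read a multi-page TIFF z-stack
#'
#' Pages become planes ordered shallowest-first; intensities are preserved
#' bit-exactly (no rescaling). The maximum representable value is taken from
#' the file's bits-per-sample tag (255 for 8-bit, 65535 for 16-bit) rather
#' than assumed.
#'
#' @param path multi-page TIFF file
#' @param spacing a \linkS4class{VoxelSpacing}
#' @param channel channel tag: "vessel", "plaque" or "thg"
#' @param sessionId session identifier stored with the stack
#' @return an \linkS4class{ImageStack} whose z-extent equals the page count
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, spacing = voxelSpacing(), channel = "vessel",
                      sessionId = "s1") {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (length(shp) != 2L)
    stop("page 1 of ", path, " is not single-sample grayscale")
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp))
      stop("page ", i, " of ", path, " has inconsistent shape (",
           paste(dim(pages[[i]]), collapse = "x"), " vs ",
           paste(shp, collapse = "x"), ")")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(unlist(pages)) > 255) 16L else 8L
  vox <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  imageStack(vox, spacing = spacing, channel = channel,
             sessionId = sessionId, bitDepthMax = 2^bits - 1)
}

#' Write a stack as a multi-page TIFF
#'
#' Planes are written shallowest-first at 8 or 16 bits according to the
#' stack's \code{bitDepthMax}; integer-valued intensities survive a
#' write/read round trip bit-exactly (non-integer intensities are rounded).
#'
#' @param stack an \linkS4class{ImageStack}
#' @param path output file
#' @return invisibly, the path
#' @export
writeStack <- function(stack, path) {
  bits <- if (bitDepthMax(stack) <= 255) 8L else 16L
  denom <- 2^bits - 1
  v <- voxels(stack)
  planes <- lapply(seq_len(dim(v)[1]),
                   function(z) round(v[z, , ]) / denom)
  ok <- tiff::writeTIFF(planes, path, bits.per.sample = bits,
                        compression = "none")
  invisible(path)
}

#' Read a binary mask from an 8-bit TIFF
#'
#' Any nonzero pixel (the convention is {0, 255}) maps to foreground.
#'
#' @param path TIFF file
#' @param spacing a \linkS4class{VoxelSpacing}
#' @return a \linkS4class{BinaryMask}
#' @export
readMask <- function(path, spacing = voxelSpacing()) {
  st <- readStack(path, spacing = spacing, channel = "vessel")
  binaryMask(voxels(st) != 0, spacing = spacing)
}

#' Write a binary mask as an 8-bit {0, 255} TIFF
#'
#' @param mask a \linkS4class{BinaryMask} or \linkS4class{LabelVolume}
#'   (labels are collapsed to foreground)
#' @param path output file
#' @return invisibly, the path
#' @export
writeMask <- function(mask, path) {
  v <- voxels(mask)
  st <- imageStack(array(255 * (v != 0), dim = dim(v)),
                   spacing = spacing(mask), channel = "vessel",
                   bitDepthMax = 255)
  writeStack(st, path)
}

#' Write metric records to CSV
#'
#' One row per record, header always present, floats at full precision so a
#' parsed-back table reproduces the source within float round-trip.
#'
#' @param records a data.frame of metric records sharing one schema
#' @param path output CSV
#' @return invisibly, the path
#' @export
writeTable <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  utils::write.csv(format(records, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metric table written by \code{\link{writeTable}}
#'
#' @param path CSV file
#' @return data.frame
#' @export
readTable <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
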