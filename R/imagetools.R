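# Minimal MRC (mode 2, 32-bit float) reader/writer.  Little-endian
# throughout; pixel size is stored in / recovered from the cell dimensions
# (cella / mx).  Only the fields the symmetry pipeline needs are handled;
# extended headers are skipped on read.

.MRC_HEADER_BYTES <- 1024L

#' Write a particle stack as mode-2 MRC
#'
#' @param images list of [ParticleImage-class] (all the same box size), or a
#'   3-D numeric array (x, y, slice)
#' @param path output file
#' @param pixelSizeA pixel size recorded in the header; defaults to the
#'   pixel size of the first image
#' @return the path, invisibly
#' @export
writeStack <- function(images, path, pixelSizeA = NULL) {
  if (is.array(images) && length(dim(images)) == 3L) {
    arr <- images
    if (is.null(pixelSizeA)) pixelSizeA <- 1
  } else {
    stopifnot(is.list(images))
    if (length(images) == 0L) {
      arr <- array(numeric(0), dim = c(0L, 0L, 0L))
      if (is.null(pixelSizeA)) pixelSizeA <- 1
    } else {
      box <- nrow(images[[1]]@pixels)
      arr <- array(0, dim = c(box, box, length(images)))
      for (i in seq_along(images)) {
        if (nrow(images[[i]]@pixels) != box)
          stop("all images in a stack must share the box size")
        arr[, , i] <- images[[i]]@pixels
      }
      if (is.null(pixelSizeA)) pixelSizeA <- images[[1]]@pixelSizeA
    }
  }
  nx <- dim(arr)[1]; ny <- dim(arr)[2]; nz <- dim(arr)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wFlt <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wInt(c(nx, ny, nz))                     # 1-3   dimensions
  wInt(2L)                                # 4     mode 2 = float32
  wInt(c(0L, 0L, 0L))                     # 5-7   start
  wInt(c(nx, ny, nz))                     # 8-10  sampling grid
  wFlt(c(nx, ny, nz) * pixelSizeA)        # 11-13 cell (A)
  wFlt(c(90, 90, 90))                     # 14-16 angles
  wInt(c(1L, 2L, 3L))                     # 17-19 axis order
  if (length(arr)) wFlt(c(min(arr), max(arr), mean(arr)))
  else wFlt(c(0, 0, 0))                   # 20-22 dmin/dmax/dmean
  wInt(0L)                                # 23    ispg
  wInt(0L)                                # 24    nsymbt
  wInt(rep(0L, 25L))                      # 25-49 extra
  wFlt(c(0, 0, 0))                        # 50-52 origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)   # 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # 54 machine stamp (LE)
  if (length(arr)) wFlt(stats::sd(arr)) else wFlt(0)  # 55 rms
  wInt(0L)                                # 56    nlabl
  writeBin(raw(800L), con)                # 57-256 labels
  if (length(arr))
    writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a particle stack
#'
#' Reads MRC/MRCS (mode 2) stacks, or a single TIFF/PNG image.  The pixel
#' size is taken from the MRC header (cell edge / sampling) and can be
#' overridden; TIFF/PNG carry no pixel size and require
#' \code{pixelSizeA}.  TIFF/PNG intensities are mapped to [0, 1].
#'
#' @param path input file (.mrc/.mrcs/.tif/.tiff/.png)
#' @param pixelSizeA optional pixel-size override (Angstrom per pixel)
#' @param invert multiply intensities by -1 (for stain-dark contrast)
#' @return list of [ParticleImage-class], slice order preserved
#' @export
readStack <- function(path, pixelSizeA = NULL, invert = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff", "png")) {
    v <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(v)) == 3L) v <- apply(v, c(1, 2), mean)
    rng <- range(v)
    if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
    if (is.null(pixelSizeA))
      stop("TIFF/PNG input carries no pixel size; supply pixelSizeA")
    if (invert) v <- -v
    if (nrow(v) != ncol(v)) stop("format error: non-square image")
    return(list(new("ParticleImage", pixels = v, pixelSizeA = pixelSizeA,
                    particleId = basename(path))))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rFlt <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  dims <- rInt(3L)
  mode <- rInt(1L)
  if (length(dims) < 3L || any(dims < 0L))
    stop("format error: malformed MRC header")
  if (mode != 2L)
    stop("format error: only mode-2 (float32) MRC is supported, got mode ", mode)
  rInt(3L)                 # start
  m <- rInt(3L)            # sampling
  cella <- rFlt(3L)
  headerPx <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else NA_real_
  seek(con, 92L)
  nsymbt <- rInt(1L)
  seek(con, .MRC_HEADER_BYTES + max(0L, nsymbt))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (nz > 0L && nx != ny) stop("format error: non-square slices (", nx, " x ", ny, ")")
  px <- if (!is.null(pixelSizeA)) pixelSizeA else headerPx
  if (nz == 0L) return(list())
  if (is.na(px) || px <= 0)
    stop("pixel size missing from header; supply pixelSizeA")
  out <- vector("list", nz)
  for (k in seq_len(nz)) {
    v <- rFlt(nx * ny)
    if (length(v) < nx * ny) stop("format error: truncated pixel data")
    if (any(is.nan(v))) stop("format error: NaN pixels in slice ", k)
    mat <- matrix(v, nrow = nx, ncol = ny)
    if (invert) mat <- -mat
    out[[k]] <- new("ParticleImage", pixels = mat, pixelSizeA = px,
                    particleId = sprintf("p%05d", k))
  }
  out
}

#' Normalize an image to zero mean and unit standard deviation
#'
#' Idempotent, and invariant to affine intensity changes:
#' \code{normalizeImage(a*I + b)} equals \code{normalizeImage(I)} for
#' \code{a > 0}.
#'
#' @param image a [ParticleImage-class]
#' @return a normalized [ParticleImage-class]
#' @export
normalizeImage <- function(image) {
  v <- image@pixels
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12 * max(1, abs(mean(v))))
    stop("degenerate input: constant image cannot be normalized")
  new("ParticleImage", pixels = (v - mean(v)) / s,
      pixelSizeA = image@pixelSizeA, particleId = image@particleId)
}

#' Estimate the particle center
#'
#' The image is Gaussian-smoothed (default s.d. 2 px) and values below a
#' noise floor -- \code{noiseFloorK} times the median absolute deviation of
#' the smoothed image, zero for a clean image -- are clipped to zero.  The
#' center is then a weighted algebraic circle fit (Kasa fit) through the
#' remaining density, which is exact for density on a circle and, unlike a
#' plain centroid, insensitive to uneven weight among the ring blobs; when
#' the fit is degenerate (e.g. a single compact blob) the intensity
#' centroid of the clipped image is returned instead.  Deterministic;
#' coordinates are 0-based with pixel centers at integers.
#'
#' @param image a normalized [ParticleImage-class]
#' @param smoothSigmaPx smoothing s.d. in pixels
#' @param noiseFloorK noise-floor multiplier (in smoothed-image MADs)
#' @return named numeric vector \code{c(cx, cy)}
#' @export
estimateCenter <- function(image, smoothSigmaPx = 2, noiseFloorK = 3) {
  sm <- EBImage::gblur(image@pixels, sigma = smoothSigmaPx)
  tau <- max(0, noiseFloorK * stats::mad(sm))
  w <- pmax(sm - tau, 0)
  total <- sum(w)
  if (total <= 0)
    stop("centering error: no positive density after smoothing and clipping")
  g <- .coordGrids(nrow(w))
  centroid <- c(cx = sum(g$x * w) / total, cy = sum(g$y * w) / total)
  fit <- .kasaCircle(w, g)
  if (is.null(fit)) return(centroid)
  ctr <- c(cx = fit[1], cy = fit[2])
  box <- nrow(w)
  # a center outside the box means the density carries no usable curvature
  if (any(ctr < 0) || any(ctr > box - 1)) return(centroid)
  ctr
}

# weighted algebraic (Kasa) circle fit; returns c(cx, cy, R) or NULL
.kasaCircle <- function(w, g) {
  sel <- w > 0
  if (sum(sel) < 3L) return(NULL)
  x <- g$x[sel]; y <- g$y[sel]; ww <- w[sel]
  X <- cbind(x, y, 1)
  beta <- tryCatch(
    solve(crossprod(X, ww * X), crossprod(X, ww * -(x^2 + y^2))),
    error = function(e) NULL)
  if (is.null(beta) || !all(is.finite(beta))) return(NULL)
  r2 <- sum(beta[1:2]^2) / 4 - beta[3]
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  c(-beta[1] / 2, -beta[2] / 2, sqrt(r2))
}

#' Flip the contrast of an image
#' @param image a [ParticleImage-class]
#' @return the image with negated pixel values
#' @export
invertImage <- function(image) {
  new("ParticleImage", pixels = -image@pixels,
      pixelSizeA = image@pixelSizeA, particleId = image@particleId)
}
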