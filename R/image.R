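#' Normalize gray levels to the unit interval
#'
#' Rescales an arbitrary gray-level matrix \eqn{C} affinely to the feature
#' scale \eqn{c = (C - \min C) / (\max C - \min C) \in [0,1]}, so that 1 is
#' the brightest pixel of the image and 0 the darkest. A constant image has no
#' contrast to segment: it is mapped to all zeros with a warning.
#'
#' @param raw numeric matrix of gray levels (any integer or float range), or a
#'   [GrayImage-class] (returned after re-normalization, a no-op when the
#'   values already span \eqn{[0,1]}).
#' @return A [GrayImage-class] with the original levels kept in `raw`.
#' @examples
#' img <- normalizeGray(matrix(c(0, 128, 255, 255), 2, 2))
#' range(grayValues(img))
#' @export
normalizeGray <- function(raw) {
  if (is(raw, "GrayImage")) raw <- raw@values
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("'raw' must be a numeric matrix")
  if (any(!is.finite(raw))) stop("'raw' must be finite-valued")
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stop("image must be at least 2x2 pixels")
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) {
    warning("constant image: all features set to 0; segmentation is meaningless")
    vals <- matrix(0, nrow(raw), ncol(raw))
  } else {
    vals <- (raw - lo) / (hi - lo)
  }
  new("GrayImage", values = vals, raw = raw)
}

#' @describeIn normalizeGray Access the normalized feature matrix.
#' @param x a [GrayImage-class].
#' @export
grayValues <- function(x) {
  stopifnot(is(x, "GrayImage"))
  x@values
}

#' @describeIn normalizeGray Access the original gray-level matrix (or `NULL`).
#' @export
rawValues <- function(x) {
  stopifnot(is(x, "GrayImage"))
  x@raw
}

#' Build the scaled pixel lattice
#'
#' Associates every pixel (i, j) of a `height x width` image with a position
#' in \eqn{[-1,1]^2}: the column index maps affinely to the x axis and the row
#' index to the y axis (each axis onto the full interval). The lattice pitch
#' \eqn{\Delta x = 2/(\max(h, w) - 1)} is the distance between adjacent
#' initial pixel positions along the longer axis; it doubles as the default
#' cluster cutoff ("pixel size") and the lower bound of the
#' \eqn{\Delta_1} search range.
#'
#' @param height,width image dimensions in pixels (each >= 2).
#' @return A [PixelGrid-class].
#' @examples
#' g <- makePixelGrid(3, 3)
#' pixelSpacing(g)  # 1
#' @export
makePixelGrid <- function(height, width) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 2L || width < 2L) stop("'height' and 'width' must be >= 2")
  x <- -1 + 2 * (seq_len(width) - 1) / (width - 1)
  y <- -1 + 2 * (seq_len(height) - 1) / (height - 1)
  # column-major pixel order: pixel (i, j) -> row (j-1)*height + i
  pos <- cbind(x = rep(x, each = height), y = rep(y, times = width))
  new("PixelGrid", positions = pos, dim = c(height, width),
      spacing = 2 / (max(height, width) - 1))
}

#' @describeIn makePixelGrid Lattice pitch \eqn{\Delta x} of a grid, ensemble
#'   or image-derived object.
#' @param x a [PixelGrid-class] or [ParticleEnsemble-class].
#' @export
pixelSpacing <- function(x) {
  if (is(x, "PixelGrid") || is(x, "ParticleEnsemble")) return(x@spacing)
  stop("no pixel spacing for objects of class ", class(x))
}

#' Spawn the particle ensemble of an image
#'
#' Every pixel becomes one particle: its initial position is the scaled
#' lattice node and its static feature is the normalized gray value. Features
#' stay constant for the whole simulation.
#'
#' @param image a [GrayImage-class].
#' @return A [ParticleEnsemble-class].
#' @export
particlesFromImage <- function(image) {
  stopifnot(is(image, "GrayImage"))
  d <- dim(image@values)
  grid <- makePixelGrid(d[1], d[2])
  new("ParticleEnsemble",
      positions = grid@positions,
      features = as.vector(image@values),
      pixelIndex = seq_len(prod(d)),
      dim = grid@dim, spacing = grid@spacing)
}

#' Generate a geometric test image with ground truth
#'
#' Builds the classic synthetic segmentation benchmark: a flat white geometric
#' shape (square or disk) centered on a blurry dim background, together with
#' the exact ground-truth mask of the shape. The background is a seeded white
#' noise field smoothed with a Gaussian kernel and rescaled into
#' \eqn{[0.1, 0.6]}; with `blurScale = 0` it degenerates to a constant level
#' and the image is piecewise constant. The output image is normalized, so
#' the foreground feature is exactly 1.
#'
#' @param shape `"square"` (side `size/2`) or `"circle"` (radius `size/4`).
#' @param size image side in pixels (>= 32); the image is `size x size`.
#' @param blurScale smoothing length of the background field as a fraction of
#'   `size` (Gaussian sigma in pixels is `blurScale * size`); 0 gives a
#'   constant background.
#' @param seed integer seed making the background reproducible.
#' @return A list with components `image` ([GrayImage-class]) and `mask`
#'   ([BinaryMask-class]).
#' @examples
#' fx <- makeGeometricFixture("square", size = 64, seed = 1)
#' sum(maskValues(fx$mask))  # 32^2
#' @export
makeGeometricFixture <- function(shape = c("square", "circle"), size = 256,
                                 blurScale = 0.1, seed = 1L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 32L) stop("'size' must be >= 32")
  if (blurScale < 0) stop("'blurScale' must be nonnegative")

  if (blurScale == 0) {
    bg <- matrix(0.35, size, size)
  } else {
    rng <- .withSeed(seed, {
      noise <- matrix(rnorm(size * size), size, size)
      as.matrix(gblur(noise, sigma = blurScale * size))
    })
    bg <- rng
    lo <- min(bg); hi <- max(bg)
    bg <- if (hi > lo) 0.1 + 0.5 * (bg - lo) / (hi - lo) else
      matrix(0.35, size, size)
  }

  ctr <- (size + 1) / 2
  if (shape == "square") {
    side <- size %/% 2L
    from <- (size - side) %/% 2L + 1L
    idx <- from:(from + side - 1L)
    mask <- matrix(0L, size, size)
    mask[idx, idx] <- 1L
  } else {
    r <- size / 4
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    mask <- matrix(as.integer((rows - ctr)^2 + (cols - ctr)^2 <= r^2),
                   size, size)
  }
  rawImg <- bg
  rawImg[mask == 1L] <- 1.0
  list(image = normalizeGray(rawImg), mask = new("BinaryMask", values = mask))
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Read and write binary masks
#'
#' Masks are stored as 8-bit grayscale PNG (or TIFF) with on-disk values
#' \{0, 255\} mapped losslessly to \{0, 1\} in memory. Reading a file holding
#' any other gray level is an error (it is not a binary mask).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param mask a [BinaryMask-class] (or 0/1 matrix) to write.
#' @return `readMask` returns a [BinaryMask-class]; `writeMask` returns
#'   `path` invisibly.
#' @export
readMask <- function(path) {
  v <- .readImageFile(path)
  bad <- setdiff(unique(as.vector(v)), c(0, 1))
  if (length(bad) > 0)
    stop("file is not a binary mask; offending gray values (0-1 scale): ",
         paste(signif(bad, 4), collapse = ", "))
  new("BinaryMask", values = matrix(as.integer(v), nrow(v), ncol(v)))
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  if (is(mask, "BinaryMask")) mask <- mask@values
  if (!all(mask %in% c(0L, 1L))) stop("'mask' must contain only 0 and 1")
  .writeImageFile(mask + 0, path)  # 0/1 doubles -> 0/255 on disk
  invisible(path)
}

#' @describeIn readMask Accessor for the 0/1 matrix of a mask.
#' @param x a [BinaryMask-class].
#' @export
maskValues <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  x@values
}

#' Read a grayscale image file
#'
#' Reads a PNG or TIFF image as a raw gray-level matrix (in the reader's 0-1
#' scale). Multichannel images are reduced to their channel mean with a
#' warning. Use [normalizeGray()] on the result before segmenting.
#'
#' @param path file path (`.png`, `.tif` or `.tiff`).
#' @return A numeric matrix of gray levels.
#' @export
readGrayImage <- function(path) .readImageFile(path)

#' Write a gray image to disk
#'
#' Multilevel masks and other \eqn{[0,1]} images are written as 32-bit TIFF
#' or 16-bit PNG, chosen by extension.
#'
#' @param image a [GrayImage-class] or numeric matrix in \eqn{[0,1]}.
#' @inheritParams readGrayImage
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  if (is(image, "GrayImage")) image <- image@values
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(round(image * 65535) / 65535, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

.readImageFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path)
      if (is.list(x)) x[[1]] else x
    },
    stop("unsupported image extension: ", ext))
  if (length(dim(v)) == 3L) {
    nch <- dim(v)[3]
    chans <- if (nch >= 3L) 1:3 else 1L  # drop alpha
    warning("multichannel image reduced to channel mean")
    v <- apply(v[, , chans, drop = FALSE], c(1, 2), mean)
  }
  v
}

.writeImageFile <- function(v, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path),
    stop("unsupported image extension: ", ext))
  invisible(path)
}

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("GrayImage %d x %d, features in [%.3f, %.3f]\n",
              d[1], d[2], min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask %d x %d, %d foreground pixels\n",
              d[1], d[2], sum(object@values)))
})

setMethod("show", "ParticleEnsemble", function(object) {
  cat(sprintf("ParticleEnsemble of %d particles (image %d x %d, spacing %.4g)\n",
              nrow(object@positions), object@dim[1], object@dim[2],
              object@spacing))
})
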