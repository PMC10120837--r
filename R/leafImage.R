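#' Specification of a parametric lobed leaf
#'
#' The leaf outline is the polar curve rho(theta) = E(theta) * (1 + alpha *
#' |cos(k*theta/2)|^p), where E is the ellipse with semi-axes L/2 and W/2.
#' With this parameterization \code{lobeCount} equals the number of visible
#' lobes on [0, 2*pi) and maps directly onto the manually counted lobe trait.
#'
#' @param length leaf length L, cm (major axis of the base ellipse).
#' @param width leaf width W, cm (minor axis).
#' @param lobeCount integer k >= 0.
#' @param lobeDepth alpha in [0, 0.6); must be 0 when k = 0.
#' @param lobeSharpness p > 0; larger values give narrower lobes.
#' @param color leaf RGB, each in [0, 255].
#' @param pixelScale cm per pixel.
#' @param noiseSd per-channel Gaussian colour noise, 0-255 units.
#' @return A list of class \code{LeafShapeSpec}.
#' @export
leafShapeSpec <- function(length = 15, width = 13, lobeCount = 3, lobeDepth = 0.15,
                          lobeSharpness = 2, color = c(57, 74, 36),
                          pixelScale = 0.02, noiseSd = 5) {
  stopifnot(length > 0, width > 0, lobeCount >= 0, lobeSharpness > 0,
            pixelScale > 0, noiseSd >= 0,
            all(color >= 0 & color <= 255), base::length(color) == 3)
  if (lobeDepth < 0 || lobeDepth >= 0.6)
    stop("lobeDepth must lie in [0, 0.6) (self-intersection risk)")
  if (lobeCount == 0 && lobeDepth != 0)
    stop("lobeDepth must be 0 when lobeCount = 0")
  structure(list(length = length, width = width, lobeCount = as.integer(lobeCount),
                 lobeDepth = lobeDepth, lobeSharpness = lobeSharpness,
                 color = color, pixelScale = pixelScale, noiseSd = noiseSd),
            class = "LeafShapeSpec")
}

## Radial extent of the leaf outline at angle theta (length axis along x).
.leaf_rho <- function(spec, theta) {
  a <- spec$length / 2
  b <- spec$width / 2
  e <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  lobe <- if (spec$lobeCount > 0)
    1 + spec$lobeDepth * abs(cos(spec$lobeCount * theta / 2))^spec$lobeSharpness
  else 1
  e * lobe
}

#' Ground-truth outline polygon of a leaf spec
#'
#' @param spec a \code{\link{leafShapeSpec}}.
#' @param nVertices number of polygon vertices.
#' @return data.frame with columns x, y (cm, centred on the leaf).
#' @export
leafOutline <- function(spec, nVertices = 4096) {
  theta <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  rho <- .leaf_rho(spec, theta)
  data.frame(x = rho * cos(theta), y = rho * sin(theta))
}

.polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

.polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Generate a synthetic leaf image with ground truth
#'
#' Rasterizes the spec's outline on a pixel grid (interior = mask), colours
#' interior pixels with the spec colour plus clipped Gaussian noise, and
#' computes ground-truth traits from a 4096-vertex polygon of the same curve:
#' area (shoelace), perimeter (polyline length), length/width (axis extents),
#' lobe count, the derived shape indices, and the noise-free colour values.
#'
#' @param spec a \code{\link{leafShapeSpec}}.
#' @param seed integer seed for the colour noise.
#' @param imageFile,maskFile optional PNG paths to export the raster.
#' @return list(image = H x W x 3 array in 0-255, mask = H x W 0/1 matrix,
#'   truth = one-row data.frame of ground-truth traits).
#' @examples
#' leaf <- generateLeafImage(leafShapeSpec(length = 4, width = 2, lobeCount = 0,
#'                                         lobeDepth = 0, pixelScale = 0.01))
#' leaf$truth$LA  # ~ pi * 2 * 1
#' @export
generateLeafImage <- function(spec, seed = 1, imageFile = NULL, maskFile = NULL) {
  stopifnot(inherits(spec, "LeafShapeSpec"))
  if (spec$length / spec$pixelScale < 200)
    stop("raster resolution must be >= 200 px on the long axis; reduce pixelScale")
  poly <- leafOutline(spec)
  scale <- spec$pixelScale
  margin <- 8 * scale
  xr <- range(poly$x) + c(-margin, margin)
  yr <- range(poly$y) + c(-margin, margin)
  nx <- ceiling(diff(xr) / scale)
  ny <- ceiling(diff(yr) / scale)
  xc <- xr[1] + (seq_len(nx) - 0.5) * scale
  yc <- yr[1] + (seq_len(ny) - 0.5) * scale
  # star-shaped outline: a pixel is interior iff its radius <= rho(theta)
  X <- matrix(xc, ny, nx, byrow = TRUE)
  Y <- matrix(yc, ny, nx)
  theta <- atan2(Y, X)
  mask <- (sqrt(X^2 + Y^2) <= .leaf_rho(spec, theta)) * 1

  set.seed(stageSeed(seed, "leaf-color"))
  img <- array(255, dim = c(ny, nx, 3))
  npx <- sum(mask)
  for (ch in 1:3) {
    plane <- img[, , ch]
    noise <- if (spec$noiseSd > 0) stats::rnorm(npx, 0, spec$noiseSd) else 0
    plane[mask == 1] <- pmin(255, pmax(0, spec$color[ch] + noise))
    img[, , ch] <- plane
  }

  LA <- .polygon_area(poly$x, poly$y)
  LP <- .polygon_perimeter(poly$x, poly$y)
  LL <- diff(range(poly$x))
  LW <- diff(range(poly$y))
  if (LW > LL) { tmp <- LL; LL <- LW; LW <- tmp }
  shp <- deriveShape(LA, LP, LL, LW)
  truth <- data.frame(LA = LA, LP = LP, LL = LL, LW = LW, LLo = spec$lobeCount,
                      AR = shp$AR, P_L = shp$P_L, P_LW = shp$P_LW,
                      Rect = shp$Rect, Cir = shp$Cir,
                      R = spec$color[1], G = spec$color[2], B = spec$color[3],
                      CV = 65536 * spec$color[1] + 256 * spec$color[2] + spec$color[3])
  if (!is.null(imageFile)) png::writePNG(img / 255, imageFile)
  if (!is.null(maskFile)) png::writePNG(mask, maskFile)
  list(image = img, mask = mask, truth = truth)
}

#' Read a leaf RGB image / binary mask from PNG
#'
#' @param path PNG file.
#' @return \code{readLeafImage}: H x W x 3 array in 0-255.
#' @export
readLeafImage <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname readLeafImage
#' @return \code{readMask}: H x W matrix of 0/1.
#' @export
readMask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  (a > 0.5) * 1
}
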