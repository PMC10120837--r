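## Image-based leaf trait measurement.
##
## Size traits come from the binary mask: area by pixel counting, perimeter by
## a sub-pixel contour trace (marching squares on a box-smoothed copy of the
## mask, so interpolated vertices fall on the true edge rather than the pixel
## staircase -- plain boundary-pixel counting overestimates perimeter by
## ~5-8% and would bias circularity), and length/width as extents along the
## principal axes of the foreground pixel cloud. Colour traits are masked
## channel means.

## 3x3 box mean with zero padding (vectorized shifts).
.box_smooth <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  s <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    s <- s + p[(1:nr) + di, (1:nc) + dj]
  s / 9
}

## Sub-pixel contour length of a binary mask, in pixels.
.contour_length <- function(mask, smoothPasses = 2) {
  f <- mask * 1
  for (i in seq_len(smoothPasses)) f <- .box_smooth(f)
  segs <- grDevices::contourLines(x = seq_len(nrow(f)), y = seq_len(ncol(f)),
                                  z = f, levels = 0.5)
  if (!length(segs)) stop("no contour found; mask may be empty")
  sum(vapply(segs, function(s) {
    x <- s$x; y <- s$y
    len <- sum(sqrt(diff(x)^2 + diff(y)^2))
    # close the loop if contourLines left it open
    if (x[1] != x[length(x)] || y[1] != y[length(y)])
      len <- len + sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
    len
  }, 0))
}

.check_mask <- function(mask) {
  mask <- (as.matrix(mask) > 0.5) * 1
  if (sum(mask) == 0) stop("empty mask")
  mask
}

#' Measure leaf size traits from a binary mask
#'
#' @param mask binary matrix (1 = leaf). Must contain exactly one connected
#'   foreground component after hole filling.
#' @param pixelScale cm per pixel.
#' @param smoothPasses box-smoothing passes before contour extraction.
#' @return list(LA, LP, LL, LW): area (cm^2), perimeter (cm), and the extents
#'   along the first and second principal axes (cm), with LW <= LL.
#' @examples
#' m <- outer(1:300, 1:500, function(i, j) (i - 150)^2 + (j - 250)^2 <= 100^2) * 1
#' measureSize(m, pixelScale = 0.01)$LA  # ~ pi
#' @export
measureSize <- function(mask, pixelScale, smoothPasses = 2) {
  stopifnot(pixelScale > 0)
  mask <- .check_mask(mask)
  filled <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(filled)
  ncomp <- max(lab)
  if (ncomp > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    stop(sprintf("mask has %d connected components (sizes: %s); expected one",
                 ncomp, paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  }
  filled <- as.matrix(filled)

  LA <- sum(filled) * pixelScale^2
  LP <- .contour_length(filled, smoothPasses) * pixelScale

  idx <- which(filled == 1, arr.ind = TRUE)
  xy <- cbind(idx[, 2], idx[, 1])  # x = column, y = row
  ctr <- colMeans(xy)
  xy <- sweep(xy, 2, ctr)
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
  proj <- xy %*% ev
  # +1 px: pixel centres underestimate the footprint by half a pixel each side
  ext <- apply(proj, 2, function(v) diff(range(v)) + 1) * pixelScale
  list(LA = LA, LP = LP, LL = max(ext), LW = min(ext))
}

#' Derive the leaf shape indices from size primitives
#'
#' AR = LL/LW, P_L = LP/LL, P_LW = LP/(LL + LW), Rect = LA/(LL * LW),
#' Cir = 4*pi*LA/LP^2.
#'
#' @param LA area, cm^2. @param LP perimeter, cm.
#' @param LL,LW major/minor axis lengths, cm.
#' @param LLo lobe count (passed through, not used by the indices).
#' @return list(AR, P_L, P_LW, Rect, Cir).
#' @examples
#' deriveShape(LA = pi, LP = 2 * pi, LL = 2, LW = 2)$Cir  # 1
#' @export
deriveShape <- function(LA, LP, LL, LW, LLo = NA) {
  if (any(c(LA, LP, LL, LW) <= 0)) stop("all size inputs must be positive")
  list(AR = LL / LW,
       P_L = LP / LL,
       P_LW = LP / (LL + LW),
       Rect = LA / (LL * LW),
       Cir = 4 * pi * LA / LP^2)
}

#' Measure leaf colour traits
#'
#' Means of the R, G, B channels over foreground pixels, plus the composite
#' colour value CV = 65536*R + 256*G + B computed from the (possibly
#' fractional) channel means.
#'
#' @param image H x W x 3 array on the 0-255 scale.
#' @param mask binary matrix of matching dimensions.
#' @return list(R, G, B, CV).
#' @export
measureColor <- function(image, mask) {
  mask <- .check_mask(mask)
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask dimensions differ")
  fg <- mask == 1
  R <- mean(image[, , 1][fg])
  G <- mean(image[, , 2][fg])
  B <- mean(image[, , 3][fg])
  list(R = R, G = G, B = B, CV = 65536 * R + 256 * G + B)
}

#' Measure all image-derived leaf traits
#'
#' Runs \code{\link{measureSize}}, \code{\link{deriveShape}} and
#' \code{\link{measureColor}} and assembles a one-row trait record. The lobe
#' count is supplied (it is counted manually, not computed from the image).
#'
#' @param image H x W x 3 array on the 0-255 scale.
#' @param mask binary matrix.
#' @param pixelScale cm per pixel.
#' @param lobes lobe count for this leaf.
#' @return one-row data.frame with LA, LP, LL, LW, LLo, AR, P_L, P_LW, Rect,
#'   Cir, R, G, B, CV.
#' @export
measureLeaf <- function(image, mask, pixelScale, lobes = NA) {
  sz <- measureSize(mask, pixelScale)
  shp <- deriveShape(sz$LA, sz$LP, sz$LL, sz$LW)
  col <- measureColor(image, mask)
  data.frame(LA = sz$LA, LP = sz$LP, LL = sz$LL, LW = sz$LW, LLo = lobes,
             AR = shp$AR, P_L = shp$P_L, P_LW = shp$P_LW, Rect = shp$Rect,
             Cir = shp$Cir, R = col$R, G = col$G, B = col$B, CV = col$CV)
}
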