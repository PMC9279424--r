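# Class-average to template-bank matching by masked, normalized
# cross-correlation with in-plane rotation and integer-pixel translation
# search, plus particle-length measurement on binarized images.

#' Rotate a 2D image about its center
#'
#' Bilinear resampling on the same pixel lattice; content outside the
#' source is filled with zero.
#'
#' @param m numeric matrix.
#' @param degrees in-plane rotation angle (counterclockwise in matrix
#'   row/column coordinates).
#' @return matrix of the same dimensions.
#' @export
rotateImage <- function(m, degrees) {
  if (degrees %% 360 == 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  th <- -degrees * pi / 180  # inverse map: output -> source
  co <- cos(th); si <- sin(th)
  i <- rep(seq_len(n1), n2) - c1
  j <- rep(seq_len(n2), each = n1) - c2
  si1 <- co * i - si * j + c1
  sj1 <- si * i + co * j + c2
  i0 <- floor(si1); j0 <- floor(sj1)
  fi <- si1 - i0; fj <- sj1 - j0
  ok <- i0 >= 1 & i0 < n1 & j0 >= 1 & j0 < n2
  out <- numeric(n1 * n2)
  i0 <- i0[ok]; j0 <- j0[ok]; fi <- fi[ok]; fj <- fj[ok]
  idx <- i0 + (j0 - 1) * n1
  out[ok] <- (1 - fi) * (1 - fj) * m[idx] +
    fi * (1 - fj) * m[idx + 1] +
    (1 - fi) * fj * m[idx + n1] +
    fi * fj * m[idx + n1 + 1]
  matrix(out, n1, n2)
}

# center-crop or zero-pad a matrix to target dimensions
.padCrop <- function(m, dims) {
  out <- matrix(0, dims[1], dims[2])
  sr <- floor((nrow(m) - dims[1]) / 2)
  sc <- floor((ncol(m) - dims[2]) / 2)
  ri <- seq_len(dims[1]) + sr
  ci <- seq_len(dims[2]) + sc
  okR <- ri >= 1 & ri <= nrow(m)
  okC <- ci >= 1 & ci <= ncol(m)
  out[okR, okC] <- m[ri[okR], ci[okC]]
  out
}

#' Match an image against a projection template bank
#'
#' For every template, searches in-plane rotations (at the bank's angular
#' step) and integer-pixel translations, scoring each by the Pearson
#' normalized cross-correlation between image and template over a circular
#' mask, after zero-mean/unit-variance normalization of the image under the
#' mask. Returns the best orientation and the full score table.
#'
#' @param img a [ProjectionImage-class] (e.g. a class average). Its pixel
#'   size must equal the bank's.
#' @param bank list of templates from [buildTemplateBank()].
#' @param maskRadius circular mask radius in Angstrom; default 90% of the
#'   image half-width.
#' @param inPlaneStep in-plane rotation step in degrees; defaults to the
#'   bank's angular step.
#' @param shiftMax translational search half-range in pixels (default 4;
#'   class averages are assumed pre-centered).
#' @return A [MatchResult-class].
#' @export
matchImage <- function(img, bank, maskRadius = NULL, inPlaneStep = NULL,
                       shiftMax = 4L) {
  ps <- img@pixelSize
  if (any(abs(vapply(bank, function(t) t@pixelSize, 0) - ps) > 1e-6 * ps))
    stop("image and templates must share a common pixel size")
  if (is.null(inPlaneStep)) {
    inPlaneStep <- attr(bank, "angularStep")
    if (is.null(inPlaneStep)) inPlaneStep <- 15
  }
  dims <- dim(img@pixels)
  if (is.null(maskRadius)) maskRadius <- 0.45 * min(dims) * ps
  c1 <- (dims[1] + 1) / 2; c2 <- (dims[2] + 1) / 2
  rr <- outer(seq_len(dims[1]) - c1, rep(1, dims[2]))
  cc <- outer(rep(1, dims[1]), seq_len(dims[2]) - c2)
  mask <- which(sqrt(rr^2 + cc^2) * ps <= maskRadius)
  v <- img@pixels[mask]
  if (stats::sd(v) < 1e-12)
    stop("undefined correlation: image has zero variance under the mask")
  v <- (v - mean(v)) / stats::sd(v)
  mi <- ((mask - 1) %% dims[1]) + 1
  mj <- ((mask - 1) %/% dims[1]) + 1
  psis <- seq(0, 360 - inPlaneStep, by = inPlaneStep)
  shifts <- expand.grid(dx = -shiftMax:shiftMax, dy = -shiftMax:shiftMax)
  rows <- vector("list", length(bank) * length(psis))
  ri <- 0L
  for (ti in seq_along(bank)) {
    tm0 <- .padCrop(bank[[ti]]@pixels, dims)
    ori <- bank[[ti]]@orientation
    for (psi in psis) {
      rt <- rotateImage(tm0, psi)
      best <- c(cc = -Inf, dx = 0, dy = 0)
      for (si in seq_len(nrow(shifts))) {
        ris <- mi - shifts$dy[si]
        cjs <- mj - shifts$dx[si]
        ok <- ris >= 1 & ris <= dims[1] & cjs >= 1 & cjs <= dims[2]
        tv <- numeric(length(mask))
        tv[ok] <- rt[cbind(ris[ok], cjs[ok])]
        s <- stats::sd(tv)
        if (s < 1e-12) next
        r <- mean(v * (tv - mean(tv))) / s * length(tv) / (length(tv) - 1)
        if (r > best["cc"])
          best <- c(cc = r, dx = shifts$dx[si], dy = shifts$dy[si])
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(template = ti, theta = ori[1], phi = ori[2],
                               psi = psi, dx = best["dx"], dy = best["dy"],
                               cc = best["cc"])
    }
  }
  tab <- do.call(rbind, rows[seq_len(ri)])
  rownames(tab) <- NULL
  tab$cc <- pmin(1, pmax(-1, tab$cc))
  ib <- which.max(tab$cc)
  new("MatchResult",
      bestOrientation = c(tab$theta[ib], tab$phi[ib], tab$psi[ib]),
      bestCC = tab$cc[ib], ccTable = tab)
}

#' @rdname matchImage
#' @param x a MatchResult.
#' @export
bestOrientation <- function(x) x@bestOrientation

#' @rdname matchImage
#' @export
bestCC <- function(x) x@bestCC

#' @rdname matchImage
#' @export
ccTable <- function(x) x@ccTable

#' Measure a particle length on a projection image
#'
#' Binarizes at `thresholdFrac` of the image maximum, keeps the largest
#' connected foreground component and returns the maximal pairwise distance
#' between its pixel centers, scaled to Angstrom.
#'
#' @param img a [ProjectionImage-class].
#' @param thresholdFrac binarization threshold as a fraction of the maximum
#'   pixel value (default 0.2).
#' @return length in Angstrom.
#' @export
particleLength <- function(img, thresholdFrac = 0.2) {
  px <- img@pixels
  thr <- thresholdFrac * max(px)
  fg <- px >= thr & px > 0
  if (!any(fg)) stop("no foreground pixels above the threshold")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  sizes <- tabulate(lab[lab > 0])
  coords <- which(lab == which.max(sizes), arr.ind = TRUE)
  if (nrow(coords) < 2L) return(0)
  hull <- tryCatch(grDevices::chull(coords), error = function(e) NULL)
  pts <- if (!is.null(hull) && length(hull) >= 2L)
    coords[hull, , drop = FALSE] else coords
  max(stats::dist(pts)) * img@pixelSize
}
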