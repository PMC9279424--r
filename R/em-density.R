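# Model-to-density synthesis and projection for negative-stain template
# matching: Gaussian-atom density, Fourier cosine-edge low-pass, real-space
# projection with trilinear resampling, and a quasi-uniform hemisphere
# orientation grid.

.atomicNumbers <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                    SE = 34, FE = 26, ZN = 30, MG = 12, CA = 20, MN = 25,
                    NA. = 11, K = 19, CL = 17)

.elementZ <- function(element) {
  z <- .atomicNumbers[toupper(element)]
  z[is.na(z)] <- 6  # unknown elements counted as carbon
  unname(z)
}

#' Construct a DensityGrid
#'
#' @param voxels 3D numeric array.
#' @param voxelSize voxel edge, Angstrom.
#' @param origin Cartesian position of the center of voxel (1,1,1).
#' @param resolution low-pass resolution the grid was filtered to, Angstrom.
#' @return A [DensityGrid-class].
#' @export
densityGrid <- function(voxels, voxelSize, origin = c(0, 0, 0),
                        resolution = NA_real_) {
  new("DensityGrid", voxels = voxels, voxelSize = voxelSize,
      origin = origin, resolution = resolution)
}

#' @rdname densityGrid
#' @param x a DensityGrid.
#' @export
gridVoxels <- function(x) x@voxels

#' @rdname densityGrid
#' @export
voxelSize <- function(x) x@voxelSize

#' Synthesize a low-pass-filtered density from an atomic model
#'
#' Each non-hydrogen atom contributes an isotropic Gaussian of integrated
#' weight equal to its atomic number with sigma = resolution/(pi*sqrt(2)),
#' sampled on a cubic grid padded so no atom lies within 2 sigma of an
#' edge. The grid is then low-pass filtered in Fourier space with a
#' cosine-edge mask that falls from 1 at 0.75/resolution to 0 at
#' 1/resolution (full attenuation beyond).
#'
#' @param x an AtomStructure.
#' @param resolution low-pass target, Angstrom (default 25).
#' @param voxelSize Angstrom per voxel; must satisfy
#'   `voxelSize <= resolution/3` (default `resolution/3`).
#' @return A [DensityGrid-class].
#' @export
synthesizeDensity <- function(x, resolution = 25,
                              voxelSize = resolution / 3) {
  if (voxelSize > resolution / 3 + 1e-9)
    stop("voxelSize must be <= resolution/3 to sample the density")
  a <- x@atoms
  a <- a[a$element != "H", , drop = FALSE]
  if (nrow(a) == 0L) stop("no non-hydrogen atoms")
  sigma <- resolution / (pi * sqrt(2))
  pad <- 2.5 * sigma
  xyz <- cbind(a$x, a$y, a$z)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  n <- as.integer(ceiling(max(hi - lo) / voxelSize)) + 1L
  center <- (lo + hi) / 2
  origin <- center - (n - 1) / 2 * voxelSize
  vox <- array(0, dim = c(n, n, n))
  z <- .elementZ(a$element)
  amp <- z / ((2 * pi)^1.5 * sigma^3)
  reach <- ceiling(4 * sigma / voxelSize)
  ax <- origin[1] + (seq_len(n) - 1) * voxelSize
  ay <- origin[2] + (seq_len(n) - 1) * voxelSize
  az <- origin[3] + (seq_len(n) - 1) * voxelSize
  for (i in seq_len(nrow(a))) {
    ci <- round((xyz[i, ] - origin) / voxelSize) + 1
    ix <- max(1, ci[1] - reach):min(n, ci[1] + reach)
    iy <- max(1, ci[2] - reach):min(n, ci[2] + reach)
    iz <- max(1, ci[3] - reach):min(n, ci[3] + reach)
    gx <- exp(-(ax[ix] - xyz[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ay[iy] - xyz[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-(az[iz] - xyz[i, 3])^2 / (2 * sigma^2))
    vox[ix, iy, iz] <- vox[ix, iy, iz] +
      amp[i] * (gx %o% gy %o% gz)
  }
  g <- densityGrid(vox, voxelSize, origin, resolution)
  lowPassGrid(g, resolution)
}

#' Low-pass filter a density grid
#'
#' Fourier cosine-edge mask: unity below 0.75/resolution, cosine falloff to
#' zero at 1/resolution, zero beyond.
#'
#' @param g a [DensityGrid-class].
#' @param resolution cutoff resolution, Angstrom.
#' @return Filtered [DensityGrid-class].
#' @export
lowPassGrid <- function(g, resolution) {
  v <- g@voxels
  dn <- dim(v)
  fr <- lapply(dn, function(n) {
    k <- seq_len(n) - 1
    k[k > n / 2] <- k[k > n / 2] - n
    k / (n * g@voxelSize)
  })
  f2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  f <- sqrt(f2)
  fc <- 1 / resolution
  f1 <- 0.75 * fc
  H <- ifelse(f <= f1, 1,
              ifelse(f >= fc, 0, 0.5 * (1 + cos(pi * (f - f1) / (fc - f1)))))
  filt <- Re(stats::fft(stats::fft(v) * H, inverse = TRUE)) / prod(dn)
  densityGrid(filt, g@voxelSize, g@origin, resolution)
}

#' Construct a ProjectionImage
#'
#' @param pixels 2D numeric matrix.
#' @param pixelSize Angstrom per pixel.
#' @param orientation angles (theta, phi, psi) in degrees.
#' @param label character.
#' @return A [ProjectionImage-class].
#' @export
projectionImage <- function(pixels, pixelSize, orientation = c(0, 0, 0),
                            label = "") {
  new("ProjectionImage", pixels = pixels, pixelSize = pixelSize,
      orientation = orientation, label = label)
}

#' @rdname projectionImage
#' @param x a ProjectionImage.
#' @export
imagePixels <- function(x) x@pixels

#' @rdname projectionImage
#' @export
pixelSize <- function(x) x@pixelSize

#' @rdname projectionImage
#' @export
imageOrientation <- function(x) x@orientation

# ZYZ rotation: object is rotated by R = Rz(psi) Ry(theta) Rz(phi) and then
# projected along the laboratory z axis; the viewing direction in the
# object frame is R^T e_z.
.orientationMatrix <- function(orientation) {
  r <- orientation * pi / 180
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                             sin(a), 0, cos(a)), 3, 3)
  Rz(r[3]) %*% Ry(r[1]) %*% Rz(r[2])
}

#' Viewing direction of an orientation
#'
#' @param orientation (theta, phi, psi) in degrees.
#' @return unit 3-vector in the object frame.
#' @export
viewingDirection <- function(orientation) {
  as.numeric(t(.orientationMatrix(orientation)) %*% c(0, 0, 1))
}

#' Angle between two viewing directions, modulo Friedel symmetry
#'
#' @param o1,o2 orientations (theta, phi, psi) in degrees.
#' @return angle in degrees, in [0, 90].
#' @export
viewingAngleError <- function(o1, o2) {
  d <- abs(sum(viewingDirection(o1) * viewingDirection(o2)))
  acos(min(1, d)) * 180 / pi
}

#' Project a density grid along a viewing direction
#'
#' The density is rigidly rotated to the requested orientation (trilinear
#' resampling) and summed along the laboratory z axis. Pixel size equals the
#' voxel size and total intensity is conserved to interpolation accuracy.
#'
#' @param g a [DensityGrid-class].
#' @param orientation (theta, phi, psi) in degrees.
#' @param outSize output image side in pixels; default covers any rotation
#'   of the grid (`ceiling(n*sqrt(3))`).
#' @return A [ProjectionImage-class].
#' @export
projectDensity <- function(g, orientation = c(0, 0, 0), outSize = NULL) {
  v <- g@voxels
  n <- dim(v)[1]
  if (is.null(outSize)) outSize <- as.integer(ceiling(n * sqrt(3)))
  m <- outSize
  Rt <- t(.orientationMatrix(orientation))
  cin <- (n + 1) / 2
  cout <- (m + 1) / 2
  ij <- cbind(rep(seq_len(m), m) - cout, rep(seq_len(m), each = m) - cout)
  img <- numeric(m * m)
  nn <- as.numeric(n)
  for (k in seq_len(m)) {
    q <- cbind(ij[, 1], ij[, 2], k - cout) %*% t(Rt)
    q <- sweep(q, 2, c(cin, cin, cin), "+")
    i0 <- floor(q)
    fr <- q - i0
    # keep any sample with at least one interpolation corner on the grid;
    # corners falling outside contribute zero
    ok <- i0[, 1] >= 0 & i0[, 1] <= nn & i0[, 2] >= 0 & i0[, 2] <= nn &
      i0[, 3] >= 0 & i0[, 3] <= nn
    if (!any(ok)) next
    i0 <- i0[ok, , drop = FALSE]
    fr <- fr[ok, , drop = FALSE]
    val <- numeric(sum(ok))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      cx <- i0[, 1] + dx; cy <- i0[, 2] + dy; cz <- i0[, 3] + dz
      inside <- cx >= 1 & cx <= nn & cy >= 1 & cy <= nn & cz >= 1 & cz <= nn
      if (!any(inside)) next
      w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
           (if (dy) fr[, 2] else 1 - fr[, 2]) *
           (if (dz) fr[, 3] else 1 - fr[, 3])
      idx <- cx[inside] + (cy[inside] - 1) * n + (cz[inside] - 1) * n * n
      val[inside] <- val[inside] + w[inside] * v[idx]
    }
    img[ok] <- img[ok] + val
  }
  projectionImage(matrix(img, m, m), g@voxelSize, orientation)
}

#' Orientations of a quasi-uniform hemisphere grid
#'
#' Ring construction: polar rings at theta = 0, step, 2*step, ... up to 90
#' degrees; each ring carries `ceiling(360*sin(theta)/step)` equispaced
#' azimuths (half that span on the equator, which is self-redundant under
#' Friedel symmetry). Nearest-neighbor spacing is at most `step`.
#'
#' @param step angular step in degrees, in (0, 30].
#' @return data.frame with columns `theta`, `phi` (degrees).
#' @export
hemisphereGrid <- function(step) {
  if (step <= 0 || step > 30) stop("angular step must be in (0, 30] degrees")
  thetas <- seq(0, 90, by = step)
  out <- lapply(thetas, function(th) {
    if (th == 0) return(data.frame(theta = 0, phi = 0))
    span <- if (th == 90) 180 else 360
    nphi <- ceiling(span * sin(th * pi / 180) / step)
    data.frame(theta = th, phi = (seq_len(nphi) - 1) * span / nphi)
  })
  do.call(rbind, out)
}

#' Build a projection template bank
#'
#' Projects the density at every orientation of the hemisphere grid
#' (in-plane rotation is searched at match time, so psi = 0 throughout).
#'
#' @param g a [DensityGrid-class].
#' @param angularStep degrees, in (0, 30].
#' @param outSize passed to [projectDensity()].
#' @return list of [ProjectionImage-class] with attribute `angularStep`.
#' @export
buildTemplateBank <- function(g, angularStep, outSize = NULL) {
  grid <- hemisphereGrid(angularStep)
  bank <- lapply(seq_len(nrow(grid)), function(i)
    projectDensity(g, c(grid$theta[i], grid$phi[i], 0), outSize = outSize))
  attr(bank, "angularStep") <- angularStep
  bank
}
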