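# Seeded synthetic-data generators with known ground truth for every
# analysis stage: rod-like multi-domain structures, rigid domain motions,
# noisy projections, protein-conjugate chromatograms and two-state melt
# curves. Each generator drives its own pseudo-random stream from a single
# integer seed and leaves the global RNG state untouched.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a rod-like multi-domain Calpha structure
#'
#' Builds a collinear chain of helical Calpha domains along z with
#' consecutive author numbering on chain A: an idealized stand-in for an
#' extended multi-domain fusogen rod. The overall extent equals
#' `nDomains * domainLength` to within a few percent.
#'
#' @param nDomains number of domains (>= 2).
#' @param domainLength per-domain length along the rod axis, Angstrom
#'   (default 38.75, i.e. a 155 Angstrom four-domain rod).
#' @param residuesPerDomain Calpha count per domain (default 30).
#' @param helixRadius helix radius, Angstrom.
#' @param jitter Gaussian coordinate jitter sigma, Angstrom (default 0).
#' @param seed integer seed (used only when `jitter > 0`).
#' @return list with `structure` (an [AtomStructure-class]) and `domains`
#'   (named list of [DomainDefinition-class], "D1" ... "Dn").
#' @export
genRodStructure <- function(nDomains = 4, domainLength = 38.75,
                            residuesPerDomain = 30, helixRadius = 2.3,
                            jitter = 0, seed = 1) {
  if (nDomains < 2) stop("need at least 2 domains")
  if (residuesPerDomain < 4) stop("need at least 4 residues per domain")
  m <- residuesPerDomain
  ntot <- nDomains * m
  j <- seq_len(ntot)
  zspan <- nDomains * domainLength
  turn <- 2 * pi / 3.6  # ~alpha-helical phase advance per residue
  xyz <- cbind(helixRadius * cos(j * turn),
               helixRadius * sin(j * turn),
               (j - 1) * zspan / (ntot - 1))
  if (jitter > 0)
    xyz <- xyz + .withSeed(seed, matrix(stats::rnorm(3 * ntot, sd = jitter),
                                        ncol = 3))
  atoms <- data.frame(type = "ATOM", chain = "A", resno = j, insert = "",
                      resid = "ALA", elety = "CA", element = "C", occ = 1,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  domains <- lapply(seq_len(nDomains), function(d)
    domainDefinition(paste0("D", d), "A", (d - 1L) * m + 1L, d * m))
  names(domains) <- vapply(domains, domainName, character(1))
  list(structure = atomStructure(atoms, label = "synthetic rod"),
       domains = domains)
}

#' Apply a known rigid motion to one domain
#'
#' Rotates the atoms of the chosen domain about their centroid by a given
#' axis-angle rotation, then translates the centroid by a given distance:
#' the ground-truth factory for the domain-motion decomposition. Optional
#' Gaussian noise is added to the moved domain's coordinates.
#'
#' @param x an [AtomStructure-class].
#' @param domain a [DomainDefinition-class].
#' @param angle rotation angle, degrees in [0, 180].
#' @param axis unit rotation axis (within 1e-6).
#' @param comDisplacement centroid displacement, Angstrom.
#' @param direction unit vector of the centroid displacement (default +x).
#' @param noise Calpha Gaussian noise sigma on the moved domain, Angstrom.
#' @param seed integer seed (used only when `noise > 0`).
#' @return The modified [AtomStructure-class].
#' @export
applyMotion <- function(x, domain, angle, axis = c(0, 0, 1),
                        comDisplacement = 0, direction = c(1, 0, 0),
                        noise = 0, seed = 1) {
  if (angle < 0 || angle > 180) stop("angle must lie in [0, 180] degrees")
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6)
    stop("axis must be a unit vector (within 1e-6)")
  a <- x@atoms
  iv <- domain@intervals
  sel <- logical(nrow(a))
  for (i in seq_len(nrow(iv)))
    sel <- sel | (a$chain == iv$chain[i] &
                  a$resno >= iv$start[i] & a$resno <= iv$end[i])
  if (!any(sel)) stop("domain '", domain@name, "' selects no atoms")
  xyz <- cbind(a$x[sel], a$y[sel], a$z[sel])
  ctr <- colMeans(xyz)
  R <- rotationMatrix(axis, angle)
  moved <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  if (comDisplacement != 0) {
    u <- direction / sqrt(sum(direction^2))
    moved <- sweep(moved, 2, comDisplacement * u, "+")
  }
  if (noise > 0)
    moved <- moved + .withSeed(seed, matrix(stats::rnorm(length(moved),
                                                         sd = noise),
                                            ncol = 3))
  a$x[sel] <- moved[, 1]; a$y[sel] <- moved[, 2]; a$z[sel] <- moved[, 3]
  atomStructure(a, label = x@label)
}

#' Generate a noisy class-average-like projection
#'
#' Projects a density at a known orientation and adds seeded Gaussian noise
#' scaled to the requested signal-to-noise ratio, where SNR is the standard
#' deviation of the noise-free pixels over the particle support (pixels
#' above 1% of the maximum) divided by the noise sigma.
#'
#' @param g a [DensityGrid-class].
#' @param orientation (theta, phi, psi), degrees.
#' @param snr signal-to-noise ratio (> 0; `Inf` for noise-free).
#' @param seed integer seed.
#' @param outSize passed to [projectDensity()].
#' @return A [ProjectionImage-class]; ground truth in attribute `truth`.
#' @export
genClassAverage <- function(g, orientation, snr = 3, seed = 1,
                            outSize = NULL) {
  if (snr <= 0) stop("snr must be > 0")
  img <- projectDensity(g, orientation, outSize = outSize)
  px <- img@pixels
  if (is.finite(snr)) {
    support <- px > 0.01 * max(px)
    sigma <- stats::sd(px[support]) / snr
    px <- px + .withSeed(seed, matrix(stats::rnorm(length(px), sd = sigma),
                                      nrow(px), ncol(px)))
  }
  out <- projectionImage(px, img@pixelSize, orientation,
                         label = "synthetic class average")
  attr(out, "truth") <- list(orientation = orientation, snr = snr,
                             seed = seed)
  out
}

#' Generate a protein-conjugate SEC-MALS chromatogram
#'
#' Gaussian elution peak of a conjugate complex (absorbing glycoprotein of
#' mass `mConjugate` plus non-absorbing modifier of mass `mModifier`,
#' co-eluting at fixed stoichiometric mass ratio), forward-modelled through
#' the protein-conjugate detector equations with additive seeded Gaussian
#' noise at `noiseFrac` of each channel's peak signal.
#'
#' @param conjugate,modifier [OpticalComponent-class] objects.
#' @param mConjugate,mModifier component molar masses, Da (defaults: a
#'   trimeric glycoprotein of 186300 Da with a 75770 Da detergent micelle).
#' @param peakCenter,peakSigma elution peak position and width, mL.
#' @param peakMaxConc conjugate concentration at the peak apex, g/L.
#' @param nSlices number of slices across +/- 4 sigma.
#' @param noiseFrac Gaussian noise sigma as a fraction of each channel's
#'   maximum (default 0.01).
#' @param seed integer seed.
#' @param calibration detector constants, as in [malsChromatogram()].
#' @return A [MalsChromatogram-class]; ground truth in attribute `truth`.
#' @export
genChromatogram <- function(conjugate, modifier,
                            mConjugate = 186300, mModifier = 75770,
                            peakCenter = 12.5, peakSigma = 0.25,
                            peakMaxConc = 0.5, nSlices = 81,
                            noiseFrac = 0.01, seed = 1,
                            calibration = list(kLS = 1, kUV = 1, kRI = 1)) {
  if (mConjugate <= 0 || mModifier < 0) stop("invalid component masses")
  vol <- seq(peakCenter - 4 * peakSigma, peakCenter + 4 * peakSigma,
             length.out = nSlices)
  cConj <- peakMaxConc * exp(-(vol - peakCenter)^2 / (2 * peakSigma^2))
  cMod <- cConj * mModifier / mConjugate
  cTot <- cConj + cMod
  mTot <- mConjugate + mModifier
  dndcW <- (conjugate@dndc * cConj + modifier@dndc * cMod) / cTot
  uv <- calibration$kUV * conjugate@epsilon * cConj
  ri <- calibration$kRI * (conjugate@dndc * cConj + modifier@dndc * cMod)
  ls <- calibration$kLS * mTot * dndcW^2 * cTot
  if (noiseFrac > 0) {
    noise <- .withSeed(seed, list(
      uv = stats::rnorm(nSlices, sd = noiseFrac * max(uv)),
      ri = stats::rnorm(nSlices, sd = noiseFrac * max(ri)),
      ls = stats::rnorm(nSlices, sd = noiseFrac * max(ls))))
    uv <- uv + noise$uv; ri <- ri + noise$ri; ls <- ls + noise$ls
    uv <- pmax(uv, 0); ri <- pmax(ri, 0); ls <- pmax(ls, 0)
  }
  out <- malsChromatogram(vol, ls, uv, ri, calibration)
  attr(out, "truth") <- list(mConjugate = mConjugate, mModifier = mModifier,
                             mTotal = mTot, peakCenter = peakCenter,
                             peakSigma = peakSigma, seed = seed)
  out
}

#' Generate a two-state melt curve with linear baselines
#'
#' FIR follows a two-state sigmoid between linear folded and unfolded
#' baselines, on a linear thermal ramp, with additive seeded Gaussian noise
#' at `noiseFrac` of the curve's amplitude. Channels are emitted as a
#' constant F330 with F350 = FIR * F330.
#'
#' @param tm true midpoint, degrees C (default 60).
#' @param tRange ramp limits, degrees C (default 20 to 95).
#' @param step grid spacing, degrees C (default 0.5).
#' @param width sigmoid width parameter, degrees C (default 1.5).
#' @param baselineFolded,baselineUnfolded `c(intercept, slope)` of the
#'   folded/unfolded FIR baselines.
#' @param noiseFrac Gaussian noise sigma as a fraction of the FIR amplitude
#'   (default 0.01).
#' @param seed integer seed.
#' @param label condition label.
#' @return A [MeltCurve-class]; ground truth in attribute `truth`.
#' @export
genMeltCurve <- function(tm = 60, tRange = c(20, 95), step = 0.5,
                         width = 1.5,
                         baselineFolded = c(0.85, 2e-4),
                         baselineUnfolded = c(1.15, 1e-4),
                         noiseFrac = 0.01, seed = 1, label = "synthetic") {
  if (tm <= tRange[1] || tm >= tRange[2])
    stop("tm must lie inside the scanned range")
  temp <- seq(tRange[1], tRange[2], by = step)
  p <- 1 / (1 + exp(-(temp - tm) / width))
  fir <- (baselineFolded[1] + baselineFolded[2] * temp) * (1 - p) +
    (baselineUnfolded[1] + baselineUnfolded[2] * temp) * p
  if (noiseFrac > 0)
    fir <- fir + .withSeed(seed,
      stats::rnorm(length(fir), sd = noiseFrac * (max(fir) - min(fir))))
  f330 <- rep(1000, length(temp))
  out <- meltCurve(temp, f350 = fir * f330, f330 = f330, label = label)
  attr(out, "truth") <- list(tm = tm, width = width, seed = seed)
  out
}
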