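#' @import methods
NULL

.finite3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

#' AtomStructure: an ordered set of atom records
#'
#' Container for atomic coordinates addressed by author (deposited) residue
#' numbering. The `atoms` slot is a data frame with one row per atom and
#' columns `type` ("ATOM"/"HETATM"), `chain`, `resno` (integer, author
#' numbering), `insert` (insertion code, `""` if none), `resid` (3-letter
#' residue name), `elety` (atom name, e.g. "CA"), `element`, `occ`
#' (occupancy), and Cartesian coordinates `x`, `y`, `z` in Angstrom.
#'
#' @slot atoms data.frame of atom records (see Description).
#' @slot label character scalar naming the structure.
#' @exportClass AtomStructure
setClass("AtomStructure",
  representation(atoms = "data.frame", label = "character"))

setValidity("AtomStructure", function(object) {
  a <- object@atoms
  need <- c("type", "chain", "resno", "insert", "resid", "elety",
            "element", "occ", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("empty structure")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$occ < 0 | a$occ > 1, na.rm = TRUE))
    return("occupancy outside [0,1]")
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  if (anyDuplicated(key))
    return("duplicate (chain, resno, insert, atom name) after altloc resolution")
  TRUE
})

#' DomainDefinition: a named set of residue intervals
#'
#' Binds a domain name (D1, D2.1, D3, FL1, J0, ...) to one or more inclusive
#' author-numbering residue intervals on specific chains.
#'
#' @slot name character scalar.
#' @slot intervals data.frame with columns `chain`, `start`, `end`
#'   (inclusive on both ends).
#' @exportClass DomainDefinition
setClass("DomainDefinition",
  representation(name = "character", intervals = "data.frame"))

setValidity("DomainDefinition", function(object) {
  iv <- object@intervals
  if (!all(c("chain", "start", "end") %in% names(iv)))
    return("intervals must have columns chain, start, end")
  if (nrow(iv) == 0L) return("no intervals")
  if (any(iv$start > iv$end)) return("interval with start > end")
  for (ch in unique(iv$chain)) {
    sub <- iv[iv$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)]))
      return(sprintf("overlapping intervals on chain %s", ch))
  }
  TRUE
})

#' ResidueCorrespondence: paired residues between two structures
#'
#' @slot pairs data.frame with columns `chain_a`, `res_a`, `chain_b`,
#'   `res_b`; one row per paired residue, one-to-one.
#' @slot mode character: "identity", "alignment" or "table".
#' @exportClass ResidueCorrespondence
setClass("ResidueCorrespondence",
  representation(pairs = "data.frame", mode = "character"))

setValidity("ResidueCorrespondence", function(object) {
  p <- object@pairs
  if (!all(c("chain_a", "res_a", "chain_b", "res_b") %in% names(p)))
    return("pairs must have columns chain_a, res_a, chain_b, res_b")
  if (nrow(p) == 0L) return("empty correspondence")
  if (anyDuplicated(paste(p$chain_a, p$res_a)) ||
      anyDuplicated(paste(p$chain_b, p$res_b)))
    return("correspondence is not one-to-one")
  TRUE
})

#' RigidTransform: a proper rotation plus translation
#'
#' Acts on column coordinate vectors as `rotation %*% x + translation`.
#'
#' @slot rotation 3x3 proper orthogonal matrix (det = +1 within 1e-6).
#' @slot translation length-3 numeric, Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation is not orthogonal within 1e-6")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation determinant differs from +1 (improper rotation?)")
  if (!.finite3(object@translation)) return("translation must be finite length-3")
  TRUE
})

#' DomainMotion: rigid-body motion of a domain between two states
#'
#' The readout of the domain-motion decomposition: after superposing the two
#' states on a reference domain, the motion of a mobile domain is summarized
#' as the displacement between its Calpha centroids and the axis-angle
#' rotation carrying one state's domain onto the other.
#'
#' @slot comPre,comPost centroid of the mobile domain in the pre/post state
#'   (reference-aligned frame), Angstrom.
#' @slot comDisplacement Euclidean distance between centroids, Angstrom.
#' @slot rotationAngle rotation in degrees, in [0, 180].
#' @slot rotationAxis unit 3-vector (sign convention: largest-magnitude
#'   component positive).
#' @slot axisAnchor point the axis is drawn through (the post centroid).
#' @slot transform the underlying [RigidTransform-class].
#' @exportClass DomainMotion
setClass("DomainMotion",
  representation(comPre = "numeric", comPost = "numeric",
                 comDisplacement = "numeric", rotationAngle = "numeric",
                 rotationAxis = "numeric", axisAnchor = "numeric",
                 transform = "RigidTransform"))

setValidity("DomainMotion", function(object) {
  if (!.finite3(object@comPre) || !.finite3(object@comPost))
    return("centroids must be finite length-3")
  d <- sqrt(sum((object@comPost - object@comPre)^2))
  if (abs(d - object@comDisplacement) > 1e-6)
    return("comDisplacement inconsistent with centroids")
  if (object@rotationAngle < 0 || object@rotationAngle > 180)
    return("rotationAngle outside [0, 180]")
  if (abs(sqrt(sum(object@rotationAxis^2)) - 1) > 1e-6)
    return("rotationAxis is not a unit vector")
  TRUE
})

#' DensityGrid: a 3D density on a cubic voxel lattice
#'
#' @slot voxels 3D numeric array of densities.
#' @slot voxelSize voxel edge, Angstrom.
#' @slot origin Cartesian position of voxel (1,1,1) center, Angstrom.
#' @slot resolution low-pass resolution target, Angstrom.
#' @exportClass DensityGrid
setClass("DensityGrid",
  representation(voxels = "array", voxelSize = "numeric",
                 origin = "numeric", resolution = "numeric"))

setValidity("DensityGrid", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  if (!all(is.finite(object@voxels))) return("non-finite densities")
  if (sum(object@voxels) <= 0) return("total density must be > 0")
  TRUE
})

#' ProjectionImage: a 2D projection with physical pixel size
#'
#' @slot pixels 2D numeric matrix.
#' @slot pixelSize Angstrom per pixel.
#' @slot orientation three angles (theta, phi, psi) in degrees: polar and
#'   azimuthal angles of the viewing direction plus in-plane rotation.
#' @slot label character.
#' @exportClass ProjectionImage
setClass("ProjectionImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 orientation = "numeric", label = "character"))

setValidity("ProjectionImage", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (!all(is.finite(object@pixels))) return("non-finite pixels")
  if (length(object@orientation) != 3L) return("orientation must be 3 angles")
  TRUE
})

#' MatchResult: outcome of projection matching
#'
#' @slot bestOrientation (theta, phi, psi) of the best-scoring template,
#'   with psi the best in-plane rotation, degrees.
#' @slot bestCC the maximal normalized cross-correlation, in [-1, 1].
#' @slot ccTable data.frame with one row per (template, in-plane angle):
#'   columns `template`, `theta`, `phi`, `psi`, `dx`, `dy`, `cc` (cc is the
#'   best over the translational search).
#' @exportClass MatchResult
setClass("MatchResult",
  representation(bestOrientation = "numeric", bestCC = "numeric",
                 ccTable = "data.frame"))

setValidity("MatchResult", function(object) {
  if (abs(object@bestCC) > 1 + 1e-9) return("|cc| > 1")
  if (nrow(object@ccTable) &&
      abs(object@bestCC - max(object@ccTable$cc)) > 1e-12)
    return("bestCC is not the maximum of ccTable")
  TRUE
})

#' OpticalComponent: optical constants of one solute component
#'
#' @slot name character.
#' @slot dndc refractive-index increment, mL/g.
#' @slot epsilon A280 mass extinction coefficient, mL mg^-1 cm^-1.
#' @exportClass OpticalComponent
setClass("OpticalComponent",
  representation(name = "character", dndc = "numeric", epsilon = "numeric"))

setValidity("OpticalComponent", function(object) {
  if (object@dndc < 0) return("dndc must be >= 0")
  if (object@epsilon < 0) return("epsilon must be >= 0")
  TRUE
})

#' WeightFractions: protein/glycan weight fractions of a glycoprotein
#'
#' @slot fProt protein weight fraction.
#' @slot fGlycan glycan weight fraction; fProt + fGlycan = 1.
#' @exportClass WeightFractions
setClass("WeightFractions",
  representation(fProt = "numeric", fGlycan = "numeric"))

setValidity("WeightFractions", function(object) {
  if (object@fProt < 0 || object@fProt > 1 ||
      object@fGlycan < 0 || object@fGlycan > 1)
    return("fractions must lie in [0,1]")
  if (abs(object@fProt + object@fGlycan - 1) > 1e-9)
    return("fractions must sum to 1 within 1e-9")
  TRUE
})

#' MalsChromatogram: per-slice SEC-MALS detector traces
#'
#' @slot slices data.frame with columns `volume` (mL), `ls` (excess Rayleigh
#'   signal), `uv` (A280 absorbance), `ri` (differential refractive index
#'   signal).
#' @slot calibration named list with positive constants `kLS`, `kUV`
#'   (includes path length), `kRI`; all default 1 in dimensionless test mode.
#' @exportClass MalsChromatogram
setClass("MalsChromatogram",
  representation(slices = "data.frame", calibration = "list"))

setValidity("MalsChromatogram", function(object) {
  s <- object@slices
  if (!all(c("volume", "ls", "uv", "ri") %in% names(s)))
    return("slices must have columns volume, ls, uv, ri")
  k <- object@calibration
  if (!all(c("kLS", "kUV", "kRI") %in% names(k)))
    return("calibration must contain kLS, kUV, kRI")
  if (any(unlist(k[c("kLS", "kUV", "kRI")]) <= 0))
    return("calibration constants must be > 0")
  TRUE
})

#' ConjugateMassResult: peak-averaged conjugate analysis summary
#'
#' @slot mwConjugate weight-average molar mass of the absorbing
#'   (glycoprotein) component over the peak, Da.
#' @slot mwModifier weight-average molar mass of the non-absorbing
#'   (glycan/detergent) component, Da.
#' @slot fConjugate,fModifier mass fractions of the two components.
#' @slot nSlices number of slices averaged.
#' @slot peakRange elution-volume interval used, mL.
#' @exportClass ConjugateMassResult
setClass("ConjugateMassResult",
  representation(mwConjugate = "numeric", mwModifier = "numeric",
                 fConjugate = "numeric", fModifier = "numeric",
                 nSlices = "integer", peakRange = "numeric"))

#' MeltCurve: a thermal-unfolding fluorescence curve
#'
#' @slot data data.frame with columns `temperature` (degrees C, strictly
#'   increasing), `f350`, `f330` (intensities; may be NA if only the ratio
#'   is known) and `fir` (the 350/330 fluorescence intensity ratio).
#' @slot label condition label (e.g. "pH 4.3").
#' @exportClass MeltCurve
setClass("MeltCurve",
  representation(data = "data.frame", label = "character"))

setValidity("MeltCurve", function(object) {
  d <- object@data
  if (!all(c("temperature", "fir") %in% names(d)))
    return("data must have columns temperature and fir")
  if (any(diff(d$temperature) <= 0))
    return("temperatures must be strictly increasing")
  if (!all(is.finite(d$fir))) return("non-finite FIR values")
  TRUE
})

#' TmResult: melting temperature and onset of a melt curve
#'
#' @slot tm midpoint temperature of unfolding (derivative peak), degrees C.
#' @slot onset onset of denaturation, degrees C (NA if undetected).
#' @slot derivativePeakHeight height of the FIR derivative peak, per degree C.
#' @slot allTm temperatures of all qualifying transitions (multi-transition
#'   curves are flagged by length > 1).
#' @slot spread replicate half-range, degrees C (NA for single curves).
#' @exportClass TmResult
setClass("TmResult",
  representation(tm = "numeric", onset = "numeric",
                 derivativePeakHeight = "numeric", allTm = "numeric",
                 spread = "numeric"))

setValidity("TmResult", function(object) {
  if (is.finite(object@onset) && object@onset > object@tm)
    return("onset must be <= tm")
  TRUE
})
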