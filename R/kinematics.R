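# Rigid-body kinematics: least-squares superposition, axis-angle
# decomposition of inter-state domain motion, RMSD and maximal extent.

#' Construct a RigidTransform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric (Angstrom).
#' @return A [RigidTransform-class] acting as `rotation %*% x + translation`.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = translation)
}

#' @rdname rigidTransform
#' @param x a RigidTransform.
#' @export
transformRotation <- function(x) x@rotation

#' @rdname rigidTransform
#' @export
transformTranslation <- function(x) x@translation

#' Rotation matrix from axis and angle
#'
#' Rodrigues construction for a right-handed rotation by `angle` degrees
#' about the unit vector `axis`.
#'
#' @param axis length-3 numeric; must be unit within 1e-6.
#' @param angle degrees.
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6)
    stop("axis must be a unit vector (within 1e-6)")
  th <- angle * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis-angle decomposition of a rotation matrix
#'
#' Angle is reported in [0, 180] degrees. For generic angles the axis comes
#' from the skew-symmetric part; near 0 or 180 degrees it is taken as the
#' +1 eigenvector. The axis sign is normalized so its largest-magnitude
#' component is positive (rotation angle is unsigned, so the axis is
#' reported up to sign).
#'
#' @param R 3x3 rotation matrix.
#' @return list with `angle` (degrees) and `axis` (unit 3-vector).
#' @export
axisAngle <- function(R) {
  tr <- sum(diag(R))
  angle <- acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
  s <- sin(angle * pi / 180)
  if (s > 1e-6 && angle < 179.9) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * s)
  } else {
    e <- eigen(R)
    i <- which.min(abs(e$values - 1))
    axis <- Re(e$vectors[, i])
  }
  axis <- axis / sqrt(sum(axis^2))
  if (axis[which.max(abs(axis))] < 0) axis <- -axis
  list(angle = angle, axis = axis)
}

# Kabsch: proper-rotation least squares carrying points X onto Y
# (n x 3 matrices). Reflections forbidden via the determinant correction.
.kabsch <- function(X, Y) {
  if (nrow(X) < 3L) stop("need at least 3 paired atoms for superposition")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Xc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: paired atoms are (nearly) collinear")
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  rigidTransform(R, t)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x an AtomStructure or an n x 3 coordinate matrix.
#' @param transform a [RigidTransform-class].
#' @return Object of the same class as `x`, transformed.
#' @export
applyTransform <- function(x, transform) {
  if (is(x, "AtomStructure")) {
    xyz <- applyTransform(atomCoords(x), transform)
    a <- x@atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    return(atomStructure(a, label = x@label))
  }
  sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
}

#' Least-squares superposition of one structure onto another
#'
#' Finds the proper rotation + translation minimizing the Calpha RMSD of
#' `mobile` onto `reference` over the paired residues of `corr`
#' (chain_a/res_a referring to `mobile`).
#'
#' @param mobile,reference AtomStructures.
#' @param corr a [ResidueCorrespondence-class]; default identity pairing.
#' @return list with `transform` (a [RigidTransform-class]) and `rmsd`
#'   (Angstrom over the paired Calpha after superposition).
#' @export
superpose <- function(mobile, reference, corr = NULL) {
  if (is.null(corr)) corr <- buildCorrespondence(mobile, reference, "identity")
  pc <- .pairedCoords(mobile, reference, corr)
  tr <- .kabsch(pc$xa, pc$xb)
  fitted <- applyTransform(pc$xa, tr)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((fitted - pc$xb)^2))))
}

#' Decompose the motion of a domain between two conformational states
#'
#' Implements the two-step domain-motion readout: (1) the post state is
#' superposed onto the pre state over the reference domain Calpha; (2) in
#' that reference-aligned frame, the least-squares rigid transform carrying
#' the pre-state mobile-domain Calpha set onto the post-state set is
#' decomposed into the displacement between the two Calpha centroids and an
#' axis-angle rotation (angle = arccos((trace - 1)/2), reported in
#' [0, 180] degrees; axis drawn through the post-state centroid).
#'
#' @param pre,post AtomStructures of the two states.
#' @param refDomain,mobileDomain [DomainDefinition-class] objects. When the
#'   two structures use different numbering per state, pass separate
#'   definitions via `refDomainPost`/`mobileDomainPost`.
#' @param corrRef,corrMobile [ResidueCorrespondence-class] objects pairing
#'   pre (side a) with post (side b) residues inside each domain; default
#'   identity pairing on the domain selections.
#' @param refDomainPost,mobileDomainPost optional definitions addressing the
#'   post structure (default: same as for pre).
#' @return A [DomainMotion-class].
#' @export
domainMotion <- function(pre, post, refDomain, mobileDomain,
                         corrRef = NULL, corrMobile = NULL,
                         refDomainPost = refDomain,
                         mobileDomainPost = mobileDomain) {
  preRef <- selectDomain(pre, refDomain, "calpha")
  postRef <- selectDomain(post, refDomainPost, "calpha")
  if (is.null(corrRef))
    corrRef <- buildCorrespondence(preRef, postRef, "identity")
  # step 1: align post onto pre over the reference domain
  fit <- superpose(postRef, preRef, .swapCorr(corrRef))
  postAligned <- applyTransform(post, fit$transform)
  # step 2: transform of the mobile domain in the reference-aligned frame
  preMob <- selectDomain(pre, mobileDomain, "calpha")
  postMob <- selectDomain(postAligned, mobileDomainPost, "calpha")
  if (is.null(corrMobile))
    corrMobile <- buildCorrespondence(preMob, postMob, "identity")
  pc <- .pairedCoords(preMob, postMob, corrMobile)
  tr <- .kabsch(pc$xa, pc$xb)
  aa <- axisAngle(tr@rotation)
  comPre <- colMeans(pc$xa)
  comPost <- colMeans(pc$xb)
  new("DomainMotion",
      comPre = comPre, comPost = comPost,
      comDisplacement = sqrt(sum((comPost - comPre)^2)),
      rotationAngle = aa$angle, rotationAxis = aa$axis,
      axisAnchor = comPost, transform = tr)
}

#' @rdname domainMotion
#' @param x a DomainMotion.
#' @export
rotationAngle <- function(x) x@rotationAngle

#' @rdname domainMotion
#' @export
rotationAxis <- function(x) x@rotationAxis

#' @rdname domainMotion
#' @export
comDisplacement <- function(x) x@comDisplacement

#' Maximal extent of a structure
#'
#' Maximum pairwise atom-atom distance after filtering; the default
#' Calpha-only filter excludes glycans and other heteroatoms, matching the
#' convention used for rod-length measurements.
#'
#' @param x an AtomStructure.
#' @param atomFilter "calpha" (default) or "all".
#' @return length in Angstrom.
#' @export
maxExtent <- function(x, atomFilter = c("calpha", "all")) {
  atomFilter <- match.arg(atomFilter)
  a <- x@atoms
  if (atomFilter == "calpha")
    a <- a[a$elety == "CA" & a$type == "ATOM", , drop = FALSE]
  if (nrow(a) < 2L) stop("need at least 2 atoms to measure an extent")
  xyz <- cbind(a$x, a$y, a$z)
  max(stats::dist(xyz))
}

#' Calpha RMSD between two structures
#'
#' @param a,b AtomStructures.
#' @param corr a [ResidueCorrespondence-class] (chain_a/res_a referring to
#'   `a`); default identity pairing.
#' @param superposeFirst superpose `a` onto `b` by least squares before
#'   measuring (default TRUE).
#' @return RMSD in Angstrom over the paired Calpha atoms.
#' @export
rmsdBetween <- function(a, b, corr = NULL, superposeFirst = TRUE) {
  if (is.null(corr)) corr <- buildCorrespondence(a, b, "identity")
  pc <- .pairedCoords(a, b, corr)
  xa <- pc$xa
  if (superposeFirst) xa <- applyTransform(xa, .kabsch(xa, pc$xb))
  sqrt(mean(rowSums((xa - pc$xb)^2)))
}
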