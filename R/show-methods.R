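setMethod("show", "AtomStructure", function(object) {
  a <- object@atoms
  cat("AtomStructure '", object@label, "': ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resno, a$insert))), " residues, chains ",
      paste(unique(a$chain), collapse = ","), "\n", sep = "")
})

setMethod("show", "DomainDefinition", function(object) {
  iv <- object@intervals
  cat("DomainDefinition '", object@name, "': ",
      paste(sprintf("%s:%d-%d", iv$chain, iv$start, iv$end),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "ResidueCorrespondence", function(object) {
  cat("ResidueCorrespondence (", object@mode, "): ", nrow(object@pairs),
      " residue pairs\n", sep = "")
})

setMethod("show", "RigidTransform", function(object) {
  aa <- axisAngle(object@rotation)
  cat(sprintf(
    "RigidTransform: rotation %.2f deg about (%.3f, %.3f, %.3f), |t| = %.2f A\n",
    aa$angle, aa$axis[1], aa$axis[2], aa$axis[3],
    sqrt(sum(object@translation^2))))
})

setMethod("show", "DomainMotion", function(object) {
  cat(sprintf(
    "DomainMotion: %.1f A center-of-mass displacement, %.1f deg rotation\n",
    object@comDisplacement, object@rotationAngle))
  cat(sprintf("  axis (%.3f, %.3f, %.3f) anchored at (%.1f, %.1f, %.1f)\n",
              object@rotationAxis[1], object@rotationAxis[2],
              object@rotationAxis[3], object@axisAnchor[1],
              object@axisAnchor[2], object@axisAnchor[3]))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "DensityGrid: %d x %d x %d voxels at %.2f A/voxel, low-passed to %s A\n",
    d[1], d[2], d[3], object@voxelSize,
    ifelse(is.na(object@resolution), "?", format(object@resolution))))
})

setMethod("show", "ProjectionImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "ProjectionImage%s: %d x %d px at %.2f A/px, orientation (%g, %g, %g) deg\n",
    ifelse(nzchar(object@label), paste0(" '", object@label, "'"), ""),
    d[1], d[2], object@pixelSize, object@orientation[1],
    object@orientation[2], object@orientation[3]))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult: best cc %.3f at orientation (%g, %g, %g) deg [%d scored]\n",
    object@bestCC, object@bestOrientation[1], object@bestOrientation[2],
    object@bestOrientation[3], nrow(object@ccTable)))
})

setMethod("show", "OpticalComponent", function(object) {
  cat(sprintf(
    "OpticalComponent '%s': dn/dc %.3f mL/g, eps280 %.3f mL/mg/cm\n",
    object@name, object@dndc, object@epsilon))
})

setMethod("show", "ConjugateMassResult", function(object) {
  cat(sprintf(
    "ConjugateMassResult over %d slices: conjugate %.0f Da (f %.3f), modifier %.0f Da (f %.3f)\n",
    object@nSlices, object@mwConjugate, object@fConjugate,
    object@mwModifier, object@fModifier))
})

setMethod("show", "MeltCurve", function(object) {
  d <- object@data
  cat(sprintf("MeltCurve%s: %d points, %.1f-%.1f C, FIR %.3f-%.3f\n",
              ifelse(nzchar(object@label),
                     paste0(" '", object@label, "'"), ""),
              nrow(d), min(d$temperature), max(d$temperature),
              min(d$fir), max(d$fir)))
})

setMethod("show", "TmResult", function(object) {
  cat(sprintf("TmResult: Tm %.2f C%s, onset %s C%s\n", object@tm,
              ifelse(is.finite(object@spread),
                     sprintf(" +/- %.2f", object@spread), ""),
              ifelse(is.finite(object@onset),
                     sprintf("%.2f", object@onset), "NA"),
              ifelse(length(object@allTm) > 1,
                     sprintf(" [%d transitions]", length(object@allTm)), "")))
})
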