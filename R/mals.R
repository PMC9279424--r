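# SEC-MALS protein-conjugate analysis: weight-fraction mixing of optical
# constants, per-slice two-component concentration solving from UV/RI, and
# molar-mass determination from zero-angle light scattering.

#' Construct an OpticalComponent
#'
#' @param name component name.
#' @param dndc refractive-index increment, mL/g.
#' @param epsilon A280 mass extinction coefficient, mL mg^-1 cm^-1
#'   (default 0: non-absorbing, as for glycans and detergents).
#' @return An [OpticalComponent-class].
#' @export
opticalComponent <- function(name, dndc, epsilon = 0) {
  new("OpticalComponent", name = name, dndc = dndc, epsilon = epsilon)
}

#' Construct WeightFractions
#'
#' @param fProt protein weight fraction.
#' @param fGlycan glycan weight fraction (default `1 - fProt`).
#' @return A [WeightFractions-class].
#' @export
weightFractions <- function(fProt, fGlycan = 1 - fProt) {
  new("WeightFractions", fProt = fProt, fGlycan = fGlycan)
}

#' Weight fractions from component masses
#'
#' @param mProt,mGlycan protein and glycan masses (Da); must be > 0 in sum
#'   and each >= 0.
#' @return A [WeightFractions-class] with `fProt = mProt/(mProt+mGlycan)`.
#' @export
fractionsFromMasses <- function(mProt, mGlycan) {
  if (mProt < 0 || mGlycan < 0 || mProt + mGlycan <= 0)
    stop("masses must be non-negative and sum to a positive value")
  weightFractions(mProt / (mProt + mGlycan), mGlycan / (mProt + mGlycan))
}

#' Weight-fraction mixing of refractive-index increments
#'
#' `(dn/dc)_glycoprotein = (dn/dc)_prot * fProt + (dn/dc)_glycan * fGlycan`.
#'
#' @param prot,glycan [OpticalComponent-class] objects (or bare dn/dc
#'   numbers).
#' @param f a [WeightFractions-class].
#' @return mixed dn/dc, mL/g.
#' @export
mixDndc <- function(prot, glycan, f) {
  dp <- if (is(prot, "OpticalComponent")) prot@dndc else prot
  dg <- if (is(glycan, "OpticalComponent")) glycan@dndc else glycan
  dp * f@fProt + dg * f@fGlycan
}

#' Weight-fraction mixing of extinction coefficients
#'
#' `epsilon_glycoprotein = epsilon_prot * fProt + epsilon_glycan * fGlycan`;
#' the glycan term is zero unless an absorbing glycan component is supplied.
#'
#' @param prot,glycan [OpticalComponent-class] objects (or bare extinction
#'   coefficients).
#' @param f a [WeightFractions-class].
#' @return mixed extinction coefficient, mL mg^-1 cm^-1.
#' @export
mixExtinction <- function(prot, glycan, f) {
  ep <- if (is(prot, "OpticalComponent")) prot@epsilon else prot
  eg <- if (is(glycan, "OpticalComponent")) glycan@epsilon else glycan
  ep * f@fProt + eg * f@fGlycan
}

#' Combine protein and glycan into a glycoprotein conjugate component
#'
#' @param prot,glycan [OpticalComponent-class] objects.
#' @param f a [WeightFractions-class].
#' @param name component name.
#' @return An [OpticalComponent-class] with mixed dn/dc and extinction.
#' @export
conjugateComponent <- function(prot, glycan, f, name = "glycoprotein") {
  opticalComponent(name, mixDndc(prot, glycan, f),
                   mixExtinction(prot, glycan, f))
}

#' Construct a MalsChromatogram
#'
#' @param volume elution volumes, mL.
#' @param ls,uv,ri light-scattering, UV absorbance and differential
#'   refractive index signals per slice.
#' @param calibration named list `kLS`, `kUV`, `kRI` of positive detector
#'   constants (default all 1: dimensionless test mode).
#' @return A [MalsChromatogram-class].
#' @export
malsChromatogram <- function(volume, ls, uv, ri,
                             calibration = list(kLS = 1, kUV = 1, kRI = 1)) {
  new("MalsChromatogram",
      slices = data.frame(volume = volume, ls = ls, uv = uv, ri = ri),
      calibration = calibration)
}

#' Read a SEC-MALS slice table from CSV/TSV
#'
#' Expects columns `volume`, `LS`, `UV`, `RI` (case-insensitive).
#'
#' @param path file path (.csv or .tsv/.txt, sniffed from the extension).
#' @param calibration detector constants, as in [malsChromatogram()].
#' @return A [MalsChromatogram-class].
#' @export
readMalsTable <- function(path,
                          calibration = list(kLS = 1, kUV = 1, kRI = 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep)
  names(d) <- tolower(names(d))
  need <- c("volume", "ls", "uv", "ri")
  if (!all(need %in% names(d)))
    stop("table must have columns volume, LS, UV, RI")
  malsChromatogram(d$volume, d$ls, d$uv, d$ri, calibration)
}

#' Solve per-slice two-component composition and molar masses
#'
#' Protein-conjugate model with a UV-absorbing conjugate (glycoprotein) and
#' a non-absorbing modifier (detergent micelle or glycan):
#' `UV = kUV * eps_conj * c_conj` (modifier non-absorbing),
#' `RI = kRI * (dndc_conj*c_conj + dndc_mod*c_mod)`, and
#' `LS = kLS * M_total * dndc_w^2 * c_total` with
#' `dndc_w = (dndc_conj*c_conj + dndc_mod*c_mod)/c_total`.
#' The conjugate concentration comes from UV, the modifier concentration
#' from the RI residual, the total molar mass from LS, and component masses
#' are partitioned by solved mass (concentration) fractions:
#' `M_conj = M_total * c_conj/c_total`.
#'
#' @param chrom a [MalsChromatogram-class].
#' @param conjugate [OpticalComponent-class] of the absorbing component
#'   (epsilon > 0), e.g. from [conjugateComponent()].
#' @param modifier [OpticalComponent-class] of the non-absorbing component
#'   (dndc > 0).
#' @param clampTol negative-concentration clamp tolerance, g/L (default
#'   1e-6): solved concentrations in (-clampTol, 0) are clamped to zero,
#'   below -clampTol raise an inconsistent-signals error. For noisy data
#'   set this to a few times the propagated concentration noise.
#' @param lsTol light-scattering tolerance (same units as the LS channel,
#'   default `clampTol`): a slice with zero solved concentration errors
#'   only if its LS signal exceeds this.
#' @return data.frame with one row per slice: `volume`, `cConjugate`,
#'   `cModifier` (g/L), `dndcWeighted` (mL/g), `mTotal`, `mConjugate`,
#'   `mModifier` (Da).
#' @export
solveSlices <- function(chrom, conjugate, modifier, clampTol = 1e-6,
                        lsTol = clampTol) {
  if (conjugate@epsilon <= 0)
    stop("conjugate component must absorb (epsilon > 0)")
  if (modifier@dndc <= 0)
    stop("modifier component must have dndc > 0")
  s <- chrom@slices
  k <- chrom@calibration
  cConj <- s$uv / (k$kUV * conjugate@epsilon)
  cMod <- (s$ri / k$kRI - conjugate@dndc * cConj) / modifier@dndc
  if (any(cConj < -clampTol) || any(cMod < -clampTol))
    stop("inconsistent signals: UV implies more RI than measured ",
         "(negative solved concentration)")
  cConj <- pmax(cConj, 0)
  cMod <- pmax(cMod, 0)
  cTot <- cConj + cMod
  empty <- cTot <= 0
  if (any(empty & s$ls > lsTol))
    stop("zero solved concentration in a slice with nonzero light scattering")
  dndcW <- ifelse(empty, NA_real_,
                  (conjugate@dndc * cConj + modifier@dndc * cMod) /
                    ifelse(empty, 1, cTot))
  mTot <- ifelse(empty, 0, s$ls / (k$kLS * dndcW^2 * cTot))
  data.frame(volume = s$volume, cConjugate = cConj, cModifier = cMod,
             dndcWeighted = dndcW, mTotal = mTot,
             mConjugate = ifelse(empty, 0, mTot * cConj / cTot),
             mModifier = ifelse(empty, 0, mTot * cMod / cTot))
}

#' Peak-averaged component molar masses
#'
#' Concentration-weighted (weight-average) molar masses of conjugate and
#' modifier over the slices inside a peak interval.
#'
#' @param compositions data.frame from [solveSlices()].
#' @param peakRange length-2 elution-volume interval in mL (default: all
#'   slices with solute).
#' @return A [ConjugateMassResult-class].
#' @export
peakMasses <- function(compositions, peakRange = NULL) {
  d <- compositions
  if (!is.null(peakRange))
    d <- d[d$volume >= peakRange[1] & d$volume <= peakRange[2], , drop = FALSE]
  d <- d[d$cConjugate + d$cModifier > 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 slices inside the peak range")
  wc <- sum(d$cConjugate)
  wm <- sum(d$cModifier)
  new("ConjugateMassResult",
      mwConjugate = if (wc > 0) sum(d$cConjugate * d$mConjugate) / wc else 0,
      mwModifier = if (wm > 0) sum(d$cModifier * d$mModifier) / wm else 0,
      fConjugate = wc / (wc + wm), fModifier = wm / (wc + wm),
      nSlices = nrow(d),
      peakRange = if (is.null(peakRange)) range(d$volume) else peakRange)
}

#' @rdname peakMasses
#' @param x a ConjugateMassResult.
#' @export
mwConjugate <- function(x) x@mwConjugate

#' @rdname peakMasses
#' @export
mwModifier <- function(x) x@mwModifier
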