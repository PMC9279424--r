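# Pipeline entry point: validated stage configs, JSON reports with input
# digests, and a simulate stage that writes fixtures in the same formats
# the analysis stages read.

.stages <- c("simulate", "kinematics", "extent", "emmatch", "mals", "melt")

#' Read and validate a run configuration
#'
#' YAML with keys `stage`, `inputs` (named file paths), `params` (stage
#' parameters), `out_dir`, `seed` and `log_level`.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validateRunConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param config a config list.
#' @export
validateRunConfig <- function(config) {
  bad <- character()
  if (is.null(config$stage) || !config$stage %in% .stages)
    bad <- c(bad, paste0("stage (must be one of ",
                         paste(.stages, collapse = ", "), ")"))
  for (nm in names(config$inputs))
    if (!file.exists(config$inputs[[nm]]))
      bad <- c(bad, paste0("inputs$", nm, " (missing file ",
                           config$inputs[[nm]], ")"))
  if (!is.null(config$seed) && !is.finite(as.numeric(config$seed)))
    bad <- c(bad, "seed (not a number)")
  if (length(bad))
    stop("invalid config: ", paste(bad, collapse = "; "))
  if (is.null(config$params)) config$params <- list()
  if (is.null(config$out_dir)) config$out_dir <- "."
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.param <- function(config, name, default) {
  v <- config$params[[name]]
  if (is.null(v)) default else v
}

.inputDigests <- function(config) {
  paths <- unlist(config$inputs)
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

#' Run one pipeline stage
#'
#' Executes the configured stage and writes a JSON report (`<stage>.json`
#' in `out_dir`) containing the tool version, parameters, input digests and
#' results. Available stages: `simulate` (write a synthetic fixture and its
#' ground truth), `kinematics` (domain-motion decomposition between two
#' structures), `extent` (maximal extent), `emmatch` (class-average
#' projection matching), `mals` (protein-conjugate analysis), `melt`
#' (Tm extraction).
#'
#' @param config a config list (see [readRunConfig()]) or a YAML path.
#' @param quiet suppress stage-boundary messages.
#' @return the report list, invisibly; the JSON path in attribute `path`.
#' @export
runStage <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  if (!quiet) message("[fusemotion] stage ", config$stage, " started")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- switch(config$stage,
    simulate = .stageSimulate(config),
    kinematics = .stageKinematics(config),
    extent = .stageExtent(config),
    emmatch = .stageEmmatch(config),
    mals = .stageMals(config),
    melt = .stageMelt(config))
  report <- list(
    tool = "fusemotion",
    version = as.character(utils::packageVersion("fusemotion")),
    report_schema = 1L,
    stage = config$stage,
    seed = config$seed,
    parameters = config$params,
    inputs = .inputDigests(config),
    results = results)
  path <- file.path(config$out_dir, paste0(config$stage, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  if (!quiet) message("[fusemotion] stage ", config$stage, " finished: ",
                      path)
  attr(report, "path") <- path
  invisible(report)
}

.stageSimulate <- function(config) {
  scen <- .param(config, "scenario", "domain_motion")
  seed <- as.integer(config$seed)
  od <- config$out_dir
  if (scen %in% c("rod_structure", "domain_motion")) {
    rod <- genRodStructure(
      nDomains = .param(config, "n_domains", 4),
      domainLength = .param(config, "domain_length", 38.75),
      residuesPerDomain = .param(config, "residues_per_domain", 30),
      seed = seed)
    truth <- list(scenario = scen, seed = seed,
                  extent = maxExtent(rod$structure))
    writeStructure(rod$structure, file.path(od, "rod_pre.pdb"))
    writeDomainDefinitions(rod$domains, file.path(od, "domains.yaml"))
    files <- c("rod_pre.pdb", "domains.yaml")
    if (scen == "domain_motion") {
      angle <- .param(config, "angle", 168)
      disp <- .param(config, "displacement", 76)
      mobile <- .param(config, "mobile_domain",
                       paste0("D", length(rod$domains)))
      post <- applyMotion(rod$structure, rod$domains[[mobile]],
                          angle = angle, axis = c(0, 1, 0),
                          comDisplacement = disp,
                          noise = .param(config, "noise", 0), seed = seed)
      writeStructure(post, file.path(od, "rod_post.pdb"))
      files <- c(files, "rod_post.pdb")
      truth <- c(truth, list(angle = angle, displacement = disp,
                             mobile_domain = mobile))
    }
  } else if (scen == "class_average") {
    rod <- genRodStructure(seed = seed)
    g <- synthesizeDensity(rod$structure,
                           resolution = .param(config, "resolution", 25))
    ori <- as.numeric(.param(config, "orientation", c(60, 30, 0)))
    img <- genClassAverage(g, ori, snr = .param(config, "snr", 3),
                           seed = seed)
    writeStructure(rod$structure, file.path(od, "model.pdb"))
    writeMRC(g, file.path(od, "density.mrc"))
    writeMRC(img, file.path(od, "class_average.mrc"))
    files <- c("model.pdb", "density.mrc", "class_average.mrc")
    truth <- list(scenario = scen, seed = seed, orientation = ori,
                  snr = .param(config, "snr", 3))
  } else if (scen == "chromatogram") {
    prot <- opticalComponent("protein", 0.185, 1.411)
    glyc <- opticalComponent("glycan", 0.145, 0)
    conj <- conjugateComponent(prot, glyc, weightFractions(0.877, 0.123))
    ddm <- opticalComponent("DDM", 0.133, 0)
    chrom <- genChromatogram(conj, ddm,
      mConjugate = .param(config, "m_conjugate", 186300),
      mModifier = .param(config, "m_modifier", 75770),
      noiseFrac = .param(config, "noise", 0.01), seed = seed)
    utils::write.csv(chrom@slices,
                     file.path(od, "chromatogram.csv"), row.names = FALSE)
    files <- "chromatogram.csv"
    truth <- c(attr(chrom, "truth"), list(scenario = scen))
  } else if (scen == "melt_curve") {
    curve <- genMeltCurve(tm = .param(config, "tm", 60),
                          noiseFrac = .param(config, "noise", 0.01),
                          seed = seed)
    utils::write.csv(curve@data[, c("temperature", "f350", "f330")],
                     file.path(od, "melt.csv"), row.names = FALSE)
    files <- "melt.csv"
    truth <- c(attr(curve, "truth"), list(scenario = scen))
  } else stop("unknown scenario: ", scen)
  jsonlite::write_json(truth, file.path(od, "truth.json"),
                       auto_unbox = TRUE, digits = 10)
  list(scenario = scen, files = files, truth = truth)
}

.stageKinematics <- function(config) {
  pre <- readStructure(config$inputs$pre)
  post <- readStructure(config$inputs$post)
  doms <- if (!is.null(config$inputs$domains))
    readDomainDefinitions(config$inputs$domains) else hap2Domains()
  refName <- .param(config, "ref_domain", "D1")
  mobName <- .param(config, "mobile_domain", "D3")
  if (is.null(doms[[refName]]) || is.null(doms[[mobName]]))
    stop("domain definitions missing for ", refName, " or ", mobName,
         "; supply inputs$domains")
  motion <- domainMotion(pre, post, doms[[refName]], doms[[mobName]])
  list(ref_domain = refName, mobile_domain = mobName,
       com_pre = motion@comPre, com_post = motion@comPost,
       com_displacement = motion@comDisplacement,
       rotation_angle = motion@rotationAngle,
       rotation_axis = motion@rotationAxis,
       axis_anchor = motion@axisAnchor)
}

.stageExtent <- function(config) {
  s <- readStructure(config$inputs$structure)
  filt <- .param(config, "atom_filter", "calpha")
  list(atom_filter = filt, extent = maxExtent(s, filt))
}

.stageEmmatch <- function(config) {
  model <- readStructure(config$inputs$model)
  img <- readMRC(config$inputs$classavg)
  res <- .param(config, "resolution", 25)
  g <- synthesizeDensity(model, resolution = res,
                         voxelSize = .param(config, "voxel_size", res / 3))
  bank <- buildTemplateBank(g, .param(config, "step", 15))
  m <- matchImage(img, bank,
                  maskRadius = .param(config, "mask_radius", NULL),
                  shiftMax = .param(config, "shift_max", 4))
  list(best_orientation = m@bestOrientation, best_cc = m@bestCC,
       n_templates = length(bank),
       particle_length = particleLength(img,
         .param(config, "threshold_frac", 0.2)))
}

.stageMals <- function(config) {
  chrom <- readMalsTable(config$inputs$table)
  prot <- opticalComponent("protein", .param(config, "dndc_prot", 0.185),
                           .param(config, "epsilon_prot", 1.411))
  glyc <- opticalComponent("glycan", .param(config, "dndc_glycan", 0.145),
                           .param(config, "epsilon_glycan", 0))
  f <- weightFractions(.param(config, "f_prot", 0.877))
  conj <- conjugateComponent(prot, glyc, f)
  mod <- opticalComponent("modifier", .param(config, "dndc_modifier", 0.133))
  clampTol <- .param(config, "clamp_tol", 1e-6)
  comp <- solveSlices(chrom, conj, mod, clampTol = clampTol,
                      lsTol = .param(config, "ls_tol", clampTol))
  pk <- peakMasses(comp, .param(config, "peak_range", NULL))
  list(dndc_conjugate = conj@dndc, epsilon_conjugate = conj@epsilon,
       mw_conjugate = pk@mwConjugate, mw_modifier = pk@mwModifier,
       f_conjugate = pk@fConjugate, f_modifier = pk@fModifier,
       n_slices = pk@nSlices)
}

.stageMelt <- function(config) {
  d <- utils::read.csv(config$inputs$table)
  names(d) <- tolower(names(d))
  curve <- if (all(c("f350", "f330") %in% names(d)))
    meltCurve(d$temperature, f350 = d$f350, f330 = d$f330,
              label = .param(config, "label", ""))
  else meltCurve(d$temperature, fir = d$fir,
                 label = .param(config, "label", ""))
  r <- findTm(curve,
              smoothWindow = .param(config, "smooth_window", 2.5),
              minProminence = .param(config, "min_prominence", 0.25),
              onsetThreshold = .param(config, "onset_threshold", 0.1))
  list(label = curve@label, tm = r@tm, onset = r@onset,
       derivative_peak_height = r@derivativePeakHeight,
       all_tm = r@allTm)
}
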