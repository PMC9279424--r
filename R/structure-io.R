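#' Construct an AtomStructure from an atom table
#'
#' @param atoms data.frame with columns `type`, `chain`, `resno`, `insert`,
#'   `resid`, `elety`, `element`, `occ`, `x`, `y`, `z`. Missing `type`,
#'   `insert`, `element` or `occ` columns are filled with defaults
#'   ("ATOM", "", guessed from atom name, 1).
#' @param label character label for the structure.
#' @return An [AtomStructure-class].
#' @export
atomStructure <- function(atoms, label = "structure") {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(trimws(atoms$elety), 1L, 1L))
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("AtomStructure", atoms = atoms, label = as.character(label))
}

#' @rdname atomStructure
#' @param x an AtomStructure.
#' @export
atomData <- function(x) x@atoms

#' @rdname atomStructure
#' @export
structureLabel <- function(x) x@label

#' @rdname atomStructure
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' Cartesian coordinates of an AtomStructure
#'
#' @param x an AtomStructure.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
atomCoords <- function(x) {
  a <- x@atoms
  cbind(x = a$x, y = a$y, z = a$z)
}

.isWater <- function(resid) toupper(resid) %in% c("HOH", "WAT", "H2O", "DOD")

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses ATOM and HETATM records. Where alternate locations are present,
#' only the highest-occupancy conformer of each atom is kept (ties broken by
#' record order). Waters and hydrogens are dropped by default; other
#' heteroatoms (e.g. glycans) are retained.
#'
#' @param path file path.
#' @param format "pdb", "cif" or "auto" (by file extension).
#' @param keepWaters,keepHydrogens logicals, default FALSE.
#' @param label structure label; defaults to the file name.
#' @return An [AtomStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          keepWaters = FALSE, keepHydrogens = FALSE,
                          label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e)
      stop("could not parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in ", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- toupper(substr(trimws(a$elety), 1L, 1L))
  elem <- toupper(trimws(elem))
  at <- data.frame(
    type = a$type, chain = a$chain, resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert), resid = a$resid,
    elety = a$elety, element = elem,
    occ = ifelse(is.na(a$o), 1, pmin(1, pmax(0, a$o))),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  alt <- a$alt
  if (!is.null(alt)) {
    alt[is.na(alt)] <- ""
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    keep <- !logical(nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      keep[idx] <- FALSE
      keep[idx[which.max(at$occ[idx])]] <- TRUE
    }
    at <- at[keep, , drop = FALSE]
  }
  if (!keepWaters) at <- at[!.isWater(at$resid), , drop = FALSE]
  if (!keepHydrogens) at <- at[at$element != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after filtering in ", path)
  atomStructure(at, label = if (is.null(label)) basename(path) else label)
}

#' Write an AtomStructure to a PDB file
#'
#' @param x an AtomStructure.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  a <- x@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(atomCoords(x))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Define a domain by residue intervals
#'
#' @param name domain name (e.g. "D1", "D3", "FL1").
#' @param chain chain identifier(s), recycled against `start`/`end`.
#' @param start,end inclusive author-numbering residue bounds (vectors for
#'   multi-interval domains).
#' @return A [DomainDefinition-class].
#' @export
domainDefinition <- function(name, chain, start, end) {
  iv <- data.frame(chain = as.character(chain),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  new("DomainDefinition", name = as.character(name), intervals = iv)
}

#' @rdname domainDefinition
#' @param x a DomainDefinition.
#' @export
domainName <- function(x) x@name

#' @rdname domainDefinition
#' @export
domainIntervals <- function(x) x@intervals

#' Load domain definitions from a YAML file
#'
#' The file holds a top-level `domains` list; each entry has `name` plus
#' either `chain`/`start`/`end` or an `intervals` list of such triples.
#'
#' @param path YAML file path.
#' @return Named list of [DomainDefinition-class] objects.
#' @export
readDomainDefinitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$domains)) y$domains else y
  defs <- lapply(entries, function(e) {
    if (is.null(e$name)) stop("domain entry without a name in ", path)
    if (!is.null(e$intervals)) {
      iv <- do.call(rbind, lapply(e$intervals, function(i)
        data.frame(chain = as.character(i$chain), start = i$start,
                   end = i$end)))
      domainDefinition(e$name, iv$chain, iv$start, iv$end)
    } else {
      domainDefinition(e$name, e$chain, e$start, e$end)
    }
  })
  names(defs) <- vapply(defs, domainName, character(1))
  defs
}

#' Write domain definitions to a YAML file
#'
#' Inverse of [readDomainDefinitions()].
#'
#' @param defs list of [DomainDefinition-class] objects.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeDomainDefinitions <- function(defs, path) {
  entries <- lapply(defs, function(d) {
    iv <- d@intervals
    list(name = d@name,
         intervals = lapply(seq_len(nrow(iv)), function(i)
           list(chain = iv$chain[i], start = iv$start[i], end = iv$end[i])))
  })
  names(entries) <- NULL
  yaml::write_yaml(list(domains = entries), path)
  invisible(path)
}

#' Reference domain intervals for the Cyanidioschyzon merolae HAP2 ectodomain
#'
#' Author-numbered (RefSeq XP_005536505.1) residue intervals: the ectodomain
#' construct (28-564), the D1D2 fragment (28-457), D3 (458-564, inferred
#' from the D1D2 construct boundary), the three fusion loops FL1 (190-198),
#' FL2 (209-214) and FL3 (143-149), the J0 strand (447-456) and the
#' interim-sheet C'0/C''0 segment (84-105). The exact D1/D2 boundary is not
#' part of this set and must be supplied by the user (see
#' [readDomainDefinitions()]); `D1` here is a placeholder equal to the D1D2
#' fragment.
#'
#' @param chain chain identifier the intervals apply to (default "A").
#' @return Named list of [DomainDefinition-class] objects.
#' @export
hap2Domains <- function(chain = "A") {
  defs <- list(
    domainDefinition("ectodomain", chain, 28L, 564L),
    domainDefinition("D1D2", chain, 28L, 457L),
    domainDefinition("D1", chain, 28L, 457L),  # placeholder: override boundary
    domainDefinition("D3", chain, 458L, 564L),
    domainDefinition("FL1", chain, 190L, 198L),
    domainDefinition("FL2", chain, 209L, 214L),
    domainDefinition("FL3", chain, 143L, 149L),
    domainDefinition("J0", chain, 447L, 456L),
    domainDefinition("interimC", chain, 84L, 105L))
  names(defs) <- vapply(defs, domainName, character(1))
  defs
}

#' Select the atoms of a domain
#'
#' Keeps atoms whose (chain, residue number) falls inside any interval of
#' the definition, preserving record order. The "calpha" filter keeps only
#' Calpha atoms of ATOM records, which excludes glycans and other
#' heteroatoms by construction.
#'
#' @param x an AtomStructure.
#' @param domain a [DomainDefinition-class].
#' @param atomFilter "all" or "calpha".
#' @return An [AtomStructure-class] restricted to the domain.
#' @export
selectDomain <- function(x, domain, atomFilter = c("all", "calpha")) {
  atomFilter <- match.arg(atomFilter)
  a <- x@atoms
  iv <- domain@intervals
  inDom <- logical(nrow(a))
  for (i in seq_len(nrow(iv)))
    inDom <- inDom | (a$chain == iv$chain[i] &
                      a$resno >= iv$start[i] & a$resno <= iv$end[i])
  if (atomFilter == "calpha")
    inDom <- inDom & a$elety == "CA" & a$type == "ATOM"
  if (!any(inDom))
    stop("domain '", domain@name, "' selects no atoms in ", x@label)
  atomStructure(a[inDom, , drop = FALSE],
                label = paste0(x@label, ":", domain@name))
}

.caTable <- function(x) {
  a <- x@atoms
  a[a$elety == "CA" & a$type == "ATOM", , drop = FALSE]
}

.chainSequence <- function(ca) {
  # one-letter sequence of a CA table, in record order
  bio3d::aa321(ca$resid)
}

#' Build a residue correspondence between two structures
#'
#' Mode "identity" pairs residues sharing (chain, residue number) keys that
#' have a Calpha atom in both structures. Mode "alignment" globally aligns
#' the one-letter Calpha sequences of paired chains (Needleman-Wunsch via
#' Biostrings, match +1, mismatch -1, linear gap -2 by default) and turns
#' aligned non-gap columns into pairs. Mode "table" accepts a user-supplied
#' pair table (e.g. derived from a structure-based alignment).
#'
#' @param a,b AtomStructures; `chain_a`/`res_a` of the result refer to `a`.
#' @param mode "identity", "alignment" or "table".
#' @param chainPairs optional data.frame with columns `a`, `b` naming which
#'   chains to pair (alignment mode). Default: shared chain IDs, or chains
#'   paired in sorted order when the two structures share none.
#' @param match,mismatch,gap alignment scores (alignment mode).
#' @param pairs data.frame with columns `chain_a`, `res_a`, `chain_b`,
#'   `res_b` (table mode).
#' @return A [ResidueCorrespondence-class].
#' @export
buildCorrespondence <- function(a, b,
                                mode = c("identity", "alignment", "table"),
                                chainPairs = NULL,
                                match = 1, mismatch = -1, gap = 2,
                                pairs = NULL) {
  mode <- match.arg(mode)
  caA <- .caTable(a)
  caB <- .caTable(b)
  if (nrow(caA) == 0L || nrow(caB) == 0L)
    stop("both structures need Calpha atoms to build a correspondence")
  if (mode == "identity") {
    keyA <- paste(caA$chain, caA$resno, caA$insert)
    keyB <- paste(caB$chain, caB$resno, caB$insert)
    common <- intersect(keyA, keyB)
    if (length(common) == 0L)
      stop("no shared (chain, residue) keys between ", a@label, " and ",
           b@label)
    ia <- base::match(common, keyA)
    p <- data.frame(chain_a = caA$chain[ia], res_a = caA$resno[ia],
                    chain_b = caA$chain[ia], res_b = caA$resno[ia],
                    stringsAsFactors = FALSE)
  } else if (mode == "table") {
    if (is.null(pairs)) stop("mode 'table' requires a pairs data.frame")
    p <- pairs[, c("chain_a", "res_a", "chain_b", "res_b")]
  } else {
    if (is.null(chainPairs)) {
      shared <- intersect(unique(caA$chain), unique(caB$chain))
      chainPairs <- if (length(shared))
        data.frame(a = shared, b = shared)
      else {
        ca <- sort(unique(caA$chain)); cb <- sort(unique(caB$chain))
        n <- min(length(ca), length(cb))
        data.frame(a = ca[seq_len(n)], b = cb[seq_len(n)])
      }
    }
    p <- do.call(rbind, lapply(seq_len(nrow(chainPairs)), function(i) {
      sa <- caA[caA$chain == chainPairs$a[i], , drop = FALSE]
      sb <- caB[caB$chain == chainPairs$b[i], , drop = FALSE]
      if (nrow(sa) == 0L || nrow(sb) == 0L) return(NULL)
      .alignChains(sa, sb, match, mismatch, gap)
    }))
    if (is.null(p) || nrow(p) == 0L)
      stop("sequence alignment produced no residue pairs")
  }
  new("ResidueCorrespondence", pairs = p, mode = mode)
}

.alignChains <- function(sa, sb, match, mismatch, gap) {
  seqA <- .chainSequence(sa)
  seqB <- .chainSequence(sb)
  letters <- unique(c(seqA, seqB, "X"))
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seqA, collapse = "")),
    Biostrings::AAString(paste(seqB, collapse = "")),
    substitutionMatrix = m, gapOpening = 0, gapExtension = abs(gap),
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  data.frame(chain_a = sa$chain[ia[keep]], res_a = sa$resno[ia[keep]],
             chain_b = sb$chain[ib[keep]], res_b = sb$resno[ib[keep]],
             stringsAsFactors = FALSE)
}

#' @rdname buildCorrespondence
#' @param x a ResidueCorrespondence.
#' @export
correspondencePairs <- function(x) x@pairs

#' @rdname buildCorrespondence
#' @export
nPairs <- function(x) nrow(x@pairs)

# Paired Calpha coordinate matrices for a correspondence; errors if a pair
# cannot be resolved to a CA atom in either structure.
.pairedCoords <- function(a, b, corr) {
  caA <- .caTable(a)
  caB <- .caTable(b)
  p <- corr@pairs
  ia <- base::match(paste(p$chain_a, p$res_a), paste(caA$chain, caA$resno))
  ib <- base::match(paste(p$chain_b, p$res_b), paste(caB$chain, caB$resno))
  if (anyNA(ia) || anyNA(ib))
    stop("correspondence contains residues without a Calpha atom")
  list(xa = cbind(caA$x[ia], caA$y[ia], caA$z[ia]),
       xb = cbind(caB$x[ib], caB$y[ib], caB$z[ib]))
}

.swapCorr <- function(corr) {
  p <- corr@pairs
  new("ResidueCorrespondence",
      pairs = data.frame(chain_a = p$chain_b, res_a = p$res_b,
                         chain_b = p$chain_a, res_b = p$res_a,
                         stringsAsFactors = FALSE),
      mode = corr@mode)
}
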