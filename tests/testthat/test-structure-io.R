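test_that("reads coordinates verbatim and resolves altlocs by occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(miniPdbLines(), f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 2L)
  expect_equal(atomCoords(s)[1, ], c(x = 11.104, y = 13.207, z = 9.5))
  expect_equal(atomData(s)$resno, c(10L, 11L))

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(altlocPdbLines(), f2)
  s2 <- readStructure(f2)
  # altloc B dropped, water dropped
  expect_equal(nAtoms(s2), 2L)
  expect_equal(atomCoords(s2)[1, ], c(x = 1, y = 2, z = 3))
  expect_equal(atomData(s2)$occ[1], 0.6)
  # waters kept on request
  expect_equal(nAtoms(readStructure(f2, keepWaters = TRUE)), 3L)

  expect_error(readStructure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("PDB and mmCIF dialects parse to the same structure", {
  s <- helixStructure(c("ALA", "CYS", "GLY", "TRP"), resno = 5:8)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeStructure(s, fp)
  writeMiniCif(s, fc)
  sp <- readStructure(fp)
  sc <- readStructure(fc)
  expect_equal(atomData(sp)$resno, atomData(sc)$resno)
  expect_equal(atomData(sp)$resid, atomData(sc)$resid)
  expect_equal(atomCoords(sp), atomCoords(sc), tolerance = 1e-9)
})

test_that("write-then-read round-trips coordinates at printed precision", {
  set.seed(42)
  a <- atomData(helixStructure(rep("ALA", 15)))
  a$x <- a$x + rnorm(15); a$y <- a$y + rnorm(15); a$z <- a$z + rnorm(15)
  s <- atomStructure(a)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(atomCoords(s2), round(atomCoords(s), 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("domain selection uses inclusive author intervals", {
  s <- helixStructure(rep("ALA", 537), resno = 28:564)
  d1d2 <- domainDefinition("D1D2", "A", 28, 457)
  sel <- selectDomain(s, d1d2)
  expect_equal(range(atomData(sel)$resno), c(28L, 457L))
  expect_equal(nAtoms(sel), 430L)  # inclusive on both ends
  # residues beyond the construct are absent
  expect_false(any(atomData(sel)$resno > 457))
  # FL1 190-198 selects exactly 9 residues
  fl1 <- selectDomain(s, domainDefinition("FL1", "A", 190, 198))
  expect_equal(nAtoms(fl1), 9L)
  # whole-structure interval is the identity
  all <- selectDomain(s, domainDefinition("all", "A", 1, 600))
  expect_equal(atomData(all)[, -1], atomData(s)[, -1], ignore_attr = TRUE)
  # idempotent, and commutes with the atom filter
  expect_equal(atomCoords(selectDomain(sel, d1d2)), atomCoords(sel))
  expect_equal(
    atomCoords(selectDomain(selectDomain(s, d1d2), d1d2, "calpha")),
    atomCoords(selectDomain(s, d1d2, "calpha")))
  expect_error(selectDomain(s, domainDefinition("none", "B", 1, 5)),
               "selects no atoms")
})

test_that("domain definitions validate and round-trip through YAML", {
  expect_error(domainDefinition("bad", "A", 10, 5), "start > end")
  expect_error(domainDefinition("bad", c("A", "A"), c(1, 5), c(6, 9)),
               "overlapping")
  defs <- hap2Domains()
  expect_equal(domainIntervals(defs$D1D2)$end, 457L)
  expect_equal(domainIntervals(defs$D3)$start, 458L)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeDomainDefinitions(defs, f)
  defs2 <- readDomainDefinitions(f)
  expect_equal(names(defs2), names(defs))
  expect_equal(domainIntervals(defs2$FL1), domainIntervals(defs$FL1))
})

test_that("identity correspondence of a structure with itself is a bijection", {
  s <- helixStructure(rep("ALA", 25), resno = 101:125)
  corr <- buildCorrespondence(s, s, "identity")
  expect_equal(nPairs(corr), 25L)
  p <- correspondencePairs(corr)
  expect_equal(p$res_a, p$res_b)
  expect_false(anyDuplicated(p$res_a) > 0)
})

test_that("fallback aligner matches the brute-force alignment oracle", {
  # ACDEF vs ACEF at match +1 / mismatch -1 / gap -2
  sa <- c("ALA", "CYS", "ASP", "GLU", "PHE")
  sb <- c("ALA", "CYS", "GLU", "PHE")
  oracle <- bruteForceAlign(c("A", "C", "D", "E", "F"),
                            c("A", "C", "E", "F"))
  expect_equal(oracle$score, 2)          # 4 matches - one gap
  expect_equal(nrow(oracle$pairs), 4L)
  a <- helixStructure(sa)
  b <- helixStructure(sb)
  corr <- buildCorrespondence(a, b, "alignment")
  expect_equal(nPairs(corr), nrow(oracle$pairs))
  p <- correspondencePairs(corr)
  expect_equal(p$res_a, c(1L, 2L, 4L, 5L))  # D (residue 3) unpaired
  expect_equal(p$res_b, c(1L, 2L, 3L, 4L))
})

test_that("disjoint residue numbering in identity mode is an error", {
  a <- helixStructure(rep("ALA", 5), resno = 1:5)
  b <- helixStructure(rep("ALA", 5), resno = 101:105)
  expect_error(buildCorrespondence(a, b, "identity"), "no shared")
})
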