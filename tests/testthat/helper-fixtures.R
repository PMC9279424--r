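# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary files.

# Calpha-only helical chain with arbitrary residue names/numbers.
helixStructure <- function(resid3 = rep("ALA", 20), chain = "A",
                           resno = seq_along(resid3), radius = 2.3,
                           rise = 1.5, label = "helix") {
  n <- length(resid3)
  j <- seq_len(n)
  atomStructure(data.frame(
    type = "ATOM", chain = chain, resno = resno, insert = "",
    resid = resid3, elety = "CA", element = "C", occ = 1,
    x = radius * cos(j * 2 * pi / 3.6),
    y = radius * sin(j * 2 * pi / 3.6),
    z = (j - 1) * rise, stringsAsFactors = FALSE), label = label)
}

# A rod with a perpendicular arm: breaks axial symmetry so that projection
# orientations are identifiable.
lShapeStructure <- function(nDomains = 4, residuesPerDomain = 30,
                            armLength = 50) {
  rod <- genRodStructure(nDomains = nDomains,
                         residuesPerDomain = residuesPerDomain)
  a <- atomData(rod$structure)
  narm <- 20L
  arm <- a[seq_len(narm), ]
  arm$resno <- arm$resno + 1000L
  arm$x <- arm$x + seq(4, armLength, length.out = narm)
  arm$z <- 40
  atomStructure(rbind(a, arm), label = "synthetic L-shape")
}

# Brute-force global alignment over all monotone pairings (independent of
# the package's Biostrings-backed aligner). Returns the optimal score and
# the number of aligned (non-gap) columns of one optimal alignment.
bruteForceAlign <- function(sa, sb, match = 1, mismatch = -1, gap = -2) {
  na <- length(sa); nb <- length(sb)
  best <- list(score = -Inf, pairs = NULL)
  rec <- function(i, j, score, pairs) {
    if (i > na && j > nb) {
      if (score > best$score) best <<- list(score = score, pairs = pairs)
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1, j + 1,
          score + if (sa[i] == sb[j]) match else mismatch,
          rbind(pairs, c(i, j)))
    if (i <= na) rec(i + 1, j, score + gap, pairs)
    if (j <= nb) rec(i, j + 1, score + gap, pairs)
  }
  rec(1L, 1L, 0, NULL)
  best
}

# Uniform random rotation matrices via quaternions.
randomRotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    a <- q[i, 1]; b <- q[i, 2]; c <- q[i, 3]; d <- q[i, 4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
             2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
             2 * (b * d + a * c), 2 * (c * d - a * b),
             a^2 - b^2 - c^2 + d^2), 3, 3)
  })
}

# Best RMSD achievable over a set of candidate rotations with optimal
# translation (centroid matching): the brute-force superposition oracle.
bruteForceRotationRmsd <- function(X, Y, rotations) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  min(vapply(rotations, function(R)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2))), numeric(1)))
}

# O(n^2) maximal pairwise distance oracle.
bruteForceMaxDist <- function(xyz) {
  n <- nrow(xyz)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    best <- max(best, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  best
}

# Minimal hand-written PDB fixture text.
miniPdbLines <- function() {
  c(paste0("ATOM      1  CA  ALA A  10      11.104  13.207   9.500",
           "  1.00 20.00           C"),
    paste0("ATOM      2  CA  GLY A  11      14.104  12.207   8.250",
           "  1.00 20.00           C"),
    "END")
}

# PDB fixture with an altloc pair (A occ 0.60, B occ 0.40) and a water.
altlocPdbLines <- function() {
  c(paste0("ATOM      1  CA AALA A  10       1.000   2.000   3.000",
           "  0.60 20.00           C"),
    paste0("ATOM      2  CA BALA A  10       9.000   9.000   9.000",
           "  0.40 20.00           C"),
    paste0("ATOM      3  CA  GLY A  11       4.000   5.000   6.000",
           "  1.00 20.00           C"),
    paste0("HETATM    4  O   HOH A 101       0.000   0.000   0.000",
           "  1.00 30.00           O"),
    "END")
}

# mmCIF rendering of an AtomStructure (atom_site loop only).
writeMiniCif <- function(x, path) {
  a <- atomData(x)
  hdr <- c("data_fixture", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
                  a$type, seq_len(nrow(a)), a$element, a$elety, a$resid,
                  a$chain, a$resno, a$x, a$y, a$z, a$occ, a$resno, a$resid,
                  a$chain, a$elety)
  writeLines(c(hdr, rows), path)
  path
}

# Isotropic 3D Gaussian density on a cubic grid, from the closed form.
gaussianBlobGrid <- function(sigma = 10, voxel = 4, half = 40) {
  ax <- seq(-half, half, by = voxel)
  n <- length(ax)
  g1 <- exp(-ax^2 / (2 * sigma^2))
  densityGrid(g1 %o% g1 %o% g1, voxel, origin = c(-half, -half, -half),
              resolution = 25)
}

# Paper-derived optical constants used across the MALS tests.
malsComponents <- function() {
  prot <- opticalComponent("protein", 0.185, 1.411)
  glyc <- opticalComponent("glycan", 0.145, 0)
  f <- weightFractions(0.877, 0.123)
  list(prot = prot, glyc = glyc, f = f,
       conj = conjugateComponent(prot, glyc, f),
       ddm = opticalComponent("DDM", 0.133))
}
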