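test_that("superposition recovers known transforms exactly", {
  s <- helixStructure(rep("ALA", 20))
  # self: identity rotation, zero translation, zero rmsd
  f <- superpose(s, s)
  expect_equal(transformRotation(f$transform), diag(3), tolerance = 1e-9)
  expect_equal(transformTranslation(f$transform), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(f$rmsd, 0, tolerance = 1e-12)
  # copy moved by 30 degrees about z plus (10, 0, 0): recovered inverse
  tr <- rigidTransform(rotationMatrix(c(0, 0, 1), 30), c(10, 0, 0))
  moved <- applyTransform(s, tr)
  f2 <- superpose(moved, s)
  expect_lt(f2$rmsd, 1e-6)
  expect_equal(transformRotation(f2$transform) %*% tr@rotation, diag(3),
               tolerance = 1e-9)
})

test_that("superposition beats a brute-force random-rotation oracle", {
  set.seed(301)
  s <- helixStructure(rep("ALA", 15))
  X <- atomCoords(s)
  Y <- applyTransform(X, rigidTransform(rotationMatrix(c(0, 1, 0), 75),
                                        c(3, -8, 2))) +
    matrix(rnorm(45, sd = 0.4), ncol = 3)
  corr <- buildCorrespondence(s, s, "identity")
  a2 <- atomData(s); a2$x <- Y[, 1]; a2$y <- Y[, 2]; a2$z <- Y[, 3]
  fit <- superpose(s, atomStructure(a2))
  oracle <- bruteForceRotationRmsd(X, Y, randomRotations(2000))
  expect_lte(fit$rmsd, oracle)
})

test_that("degenerate geometry is rejected", {
  line <- atomStructure(data.frame(
    type = "ATOM", chain = "A", resno = 1:5, insert = "", resid = "ALA",
    elety = "CA", element = "C", occ = 1, x = 1:5, y = 0, z = 0))
  expect_error(superpose(line, line), "collinear")
  two <- helixStructure(rep("ALA", 2))
  expect_error(superpose(two, two), "at least 3")
})

test_that("axis-angle decomposition inverts the Rodrigues construction", {
  set.seed(17)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 1, 179)
    aa <- axisAngle(rotationMatrix(ax, ang))
    expect_equal(aa$angle, ang, tolerance = 1e-9)
    expect_equal(abs(sum(aa$axis * ax)), 1, tolerance = 1e-9)
  }
  # angle near 180: eigenvector branch
  aa <- axisAngle(rotationMatrix(c(1, 0, 0), 180))
  expect_equal(aa$angle, 180, tolerance = 1e-6)
  expect_equal(abs(aa$axis[1]), 1, tolerance = 1e-6)
  expect_gt(aa$axis[which.max(abs(aa$axis))], 0)
})

test_that("domain motion recovers constructed ground truth", {
  rod <- genRodStructure(nDomains = 3, residuesPerDomain = 40)
  s <- rod$structure
  # pre == post: no motion
  m0 <- domainMotion(s, s, rod$domains$D1, rod$domains$D3)
  expect_lt(rotationAngle(m0), 1e-4)
  expect_lt(comDisplacement(m0), 1e-9)
  # headline-magnitude construction: 168 degrees, 76 Angstrom
  post <- applyMotion(s, rod$domains$D3, angle = 168, axis = c(0, 1, 0),
                      comDisplacement = 76)
  m <- domainMotion(s, post, rod$domains$D1, rod$domains$D3)
  expect_equal(rotationAngle(m), 168, tolerance = 1e-3)
  expect_equal(comDisplacement(m), 76, tolerance = 1e-3)
  expect_equal(m@axisAnchor, m@comPost)
  # swapping pre and post leaves angle and displacement unchanged
  msw <- domainMotion(post, s, rod$domains$D1, rod$domains$D3)
  expect_equal(rotationAngle(msw), rotationAngle(m), tolerance = 1e-6)
  expect_equal(comDisplacement(msw), comDisplacement(m), tolerance = 1e-6)
  # conjugation invariance under a global rigid transform of both states
  g <- rigidTransform(rotationMatrix(c(1, 2, 2) / 3, 57), c(12, -4, 31))
  mg <- domainMotion(applyTransform(s, g), applyTransform(post, g),
                     rod$domains$D1, rod$domains$D3)
  expect_equal(rotationAngle(mg), rotationAngle(m), tolerance = 1e-6)
  expect_equal(comDisplacement(mg), comDisplacement(m), tolerance = 1e-6)
})

test_that("domain-motion parameters are recovered across random transforms", {
  rod <- genRodStructure(nDomains = 3, residuesPerDomain = 40)
  s <- rod$structure
  set.seed(99)
  for (i in 1:15) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    ang <- runif(1, 1, 179)
    disp <- runif(1, 0, 100)
    post <- applyMotion(s, rod$domains$D3, angle = ang, axis = ax,
                        comDisplacement = disp, direction = dir)
    m <- domainMotion(s, post, rod$domains$D1, rod$domains$D3)
    expect_equal(rotationAngle(m), ang, tolerance = 1e-3)
    expect_equal(comDisplacement(m), disp, tolerance = 1e-3)
  }
})

test_that("noisy domain-motion recovery stays within a degree (median)", {
  rod <- genRodStructure(nDomains = 3, residuesPerDomain = 40)
  s <- rod$structure
  errs <- vapply(1:50, function(seed) {
    post <- applyMotion(s, rod$domains$D3, angle = 120, axis = c(0, 1, 0),
                        comDisplacement = 60, noise = 0.5, seed = seed)
    abs(rotationAngle(domainMotion(s, post, rod$domains$D1,
                                   rod$domains$D3)) - 120)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("maximal extent matches closed forms and the O(n^2) oracle", {
  two <- atomStructure(data.frame(
    type = "ATOM", chain = "A", resno = 1:3, insert = "", resid = "ALA",
    elety = "CA", element = "C", occ = 1,
    x = c(0, 50, 100), y = 0, z = 0))
  expect_equal(maxExtent(two), 100)
  set.seed(7)
  cloud <- atomStructure(data.frame(
    type = "ATOM", chain = "A", resno = 1:50, insert = "", resid = "ALA",
    elety = "CA", element = "C", occ = 1,
    x = rnorm(50, sd = 30), y = rnorm(50, sd = 10), z = rnorm(50, sd = 50)))
  expect_equal(maxExtent(cloud), bruteForceMaxDist(atomCoords(cloud)))
  one <- atomStructure(atomData(two)[1, ])
  expect_error(maxExtent(one), "at least 2")
})

test_that("RMSD matches the closed form for a single displaced residue", {
  n <- 25
  s <- helixStructure(rep("ALA", n))
  expect_equal(rmsdBetween(s, s), 0, tolerance = 1e-12)
  a <- atomData(s)
  a$x[10] <- a$x[10] + 2
  s2 <- atomStructure(a)
  expect_equal(rmsdBetween(s, s2, superposeFirst = FALSE), 2 / sqrt(n))
  # superposition can only reduce it
  expect_lte(rmsdBetween(s, s2), 2 / sqrt(n) + 1e-12)
})
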