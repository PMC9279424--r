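test_that("a single carbon atom gives a unit Gaussian of weight 6", {
  s <- atomStructure(data.frame(
    type = "ATOM", chain = "A", resno = 1, insert = "", resid = "ALA",
    elety = "CA", element = "C", occ = 1, x = 1.2, y = -3.4, z = 0.7))
  g <- synthesizeDensity(s, resolution = 25)
  v <- gridVoxels(g)
  expect_equal(sum(v) * voxelSize(g)^3, 6, tolerance = 0.01)
  # unique maximum at the atom position
  imax <- which(v == max(v), arr.ind = TRUE)
  pos <- g@origin + (imax[1, ] - 1) * voxelSize(g)
  expect_lt(sqrt(sum((pos - c(1.2, -3.4, 0.7))^2)), voxelSize(g))
  expect_equal(nrow(imax), 1L)
})

test_that("two atoms 50 A apart at 25 A resolution stay resolved", {
  s <- atomStructure(data.frame(
    type = "ATOM", chain = "A", resno = 1:2, insert = "", resid = "ALA",
    elety = "CA", element = "C", occ = 1, x = c(0, 50), y = 0, z = 0))
  g <- synthesizeDensity(s, resolution = 25)
  v <- gridVoxels(g)
  # local maxima along the interatomic axis
  mid <- which(v == max(v), arr.ind = TRUE)[1, ]
  prof <- v[, mid[2], mid[3]]
  locmax <- which(diff(sign(diff(prof))) < 0) + 1
  expect_equal(length(locmax), 2L)
})

test_that("the low-pass filter fully attenuates beyond 1/resolution", {
  rod <- genRodStructure(nDomains = 2, residuesPerDomain = 20)
  g <- synthesizeDensity(rod$structure, resolution = 25, voxelSize = 5)
  v <- gridVoxels(g)
  n <- dim(v)[1]
  fcomp <- abs(fft(v))
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  fr <- k / (n * voxelSize(g))
  f <- sqrt(outer(outer(fr^2, fr^2, "+"), fr^2, "+"))
  beyond <- fcomp[f > 1 / 25 + 1e-12]
  expect_lt(max(beyond), 1e-3 * max(fcomp))
})

test_that("projection conserves mass and is linear", {
  rod <- genRodStructure(nDomains = 4, residuesPerDomain = 30)
  g <- synthesizeDensity(rod$structure, resolution = 25)
  for (o in list(c(0, 0, 0), c(60, 40, 0), c(37, 211, 15))) {
    p <- projectDensity(g, o)
    expect_equal(sum(imagePixels(p)), sum(gridVoxels(g)), tolerance = 0.005)
  }
  # linearity: projection of g1 + g2 equals the sum of projections
  g2 <- densityGrid(2.5 * gridVoxels(g), voxelSize(g), g@origin, 25)
  gsum <- densityGrid(gridVoxels(g) + gridVoxels(g2), voxelSize(g),
                      g@origin, 25)
  o <- c(50, 120, 30)
  expect_equal(imagePixels(projectDensity(gsum, o)),
               imagePixels(projectDensity(g, o)) +
                 imagePixels(projectDensity(g2, o)),
               tolerance = 1e-6)
})

test_that("a spherical Gaussian projects identically at all orientations", {
  g <- gaussianBlobGrid(sigma = 10, voxel = 4, half = 36)
  p0 <- projectDensity(g, c(0, 0, 0))
  # trilinear resampling smooths rotated projections slightly, so the
  # interpolation tolerance is a few percent of the peak
  for (o in list(c(90, 0, 0), c(45, 66, 12), c(60, 300, 77))) {
    p <- projectDensity(g, o)
    expect_lt(max(abs(imagePixels(p) - imagePixels(p0))),
              0.03 * max(imagePixels(p0)))
  }
  # two obliquely rotated views agree much more closely with each other
  pa <- imagePixels(projectDensity(g, c(45, 66, 12)))
  pb <- imagePixels(projectDensity(g, c(71, 213, 40)))
  expect_lt(max(abs(pa - pb)), 0.01 * max(pa))
})

test_that("projecting a 3D Gaussian of sigma 10 yields a 2D Gaussian of sigma 10", {
  g <- gaussianBlobGrid(sigma = 10, voxel = 4, half = 40)
  p <- projectDensity(g, c(35, 80, 0))
  px <- imagePixels(p)
  n <- nrow(px)
  ax <- (seq_len(n) - (n + 1) / 2) * pixelSize(p)
  w <- px / sum(px)
  mx <- sum(w * ax)           # marginal means/variances via image moments
  my <- sum(t(w) * ax)
  sx <- sqrt(sum(w * (ax - mx)^2))
  sy <- sqrt(sum(t(w) * (ax - my)^2))
  expect_equal(sx, 10, tolerance = 0.02)
  expect_equal(sy, 10, tolerance = 0.02)
})

test_that("hemisphere grid matches its enumerated construction and scales", {
  for (step in c(30, 15, 10)) {
    grid <- hemisphereGrid(step)
    # independent enumeration of the ring construction
    count <- 0L
    for (th in seq(0, 90, by = step)) {
      count <- count + if (th == 0) 1L else
        ceiling((if (th == 90) 180 else 360) * sin(th * pi / 180) / step)
    }
    expect_equal(nrow(grid), count)
    # nearest-neighbor spacing bounded by the step
    dirs <- t(vapply(seq_len(nrow(grid)), function(i)
      viewingDirection(c(grid$theta[i], grid$phi[i], 0)), numeric(3)))
    dots <- abs(dirs %*% t(dirs))
    diag(dots) <- 0
    nn <- acos(pmin(1, apply(dots, 1, max))) * 180 / pi
    expect_lte(max(nn), step + 1e-6)
  }
  # halving the step grows the bank roughly fourfold (areal scaling)
  r <- nrow(hemisphereGrid(15)) / nrow(hemisphereGrid(30))
  expect_gt(r, 4 * 0.8)
  expect_lt(r, 4 * 1.2)
  expect_error(hemisphereGrid(0), "angular step")
  expect_error(hemisphereGrid(45), "angular step")
})

test_that("templates of a symmetric blob all correlate near unity", {
  g <- gaussianBlobGrid(sigma = 10, voxel = 4, half = 32)
  bank <- buildTemplateBank(g, 30)
  expect_equal(length(bank), nrow(hemisphereGrid(30)))
  ref <- as.numeric(imagePixels(bank[[1]]))
  ccs <- vapply(bank[-1], function(t)
    stats::cor(ref, as.numeric(imagePixels(t))), numeric(1))
  expect_gte(min(ccs), 0.99)
})

test_that("MRC mode 2 files round-trip grids and images", {
  rod <- genRodStructure(nDomains = 2, residuesPerDomain = 15)
  g <- synthesizeDensity(rod$structure, resolution = 25)
  f <- withr::local_tempfile(fileext = ".mrc")
  writeMRC(g, f)
  g2 <- readMRC(f)
  expect_s4_class(g2, "DensityGrid")
  expect_equal(voxelSize(g2), voxelSize(g), tolerance = 1e-6)
  expect_equal(gridVoxels(g2), gridVoxels(g), tolerance = 1e-6,
               ignore_attr = TRUE)
  p <- projectDensity(g, c(45, 10, 0))
  f2 <- withr::local_tempfile(fileext = ".mrc")
  writeMRC(p, f2)
  p2 <- readMRC(f2)
  expect_s4_class(p2, "ProjectionImage")
  expect_equal(imagePixels(p2), imagePixels(p), tolerance = 1e-6,
               ignore_attr = TRUE)
})
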