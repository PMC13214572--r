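test_that("spherical parcels match brute-force ball enumeration", {
  grid <- volumeGrid(c(12L, 12L, 12L), voxelSize = 2)
  spec <- data.frame(name = c("A", "B"), x = c(4, 9), y = c(4, 9),
                     z = c(4, 9), radius = c(3, 3))
  atlas <- makeAtlas(grid, spec)
  # independent enumeration of the discrete ball
  for (p in 1:2) {
    cnt <- 0L
    for (i in 1:12) for (j in 1:12) for (k in 1:12)
      if ((i - spec$x[p])^2 + (j - spec$y[p])^2 + (k - spec$z[p])^2 <=
          spec$radius[p]^2) cnt <- cnt + 1L
    expect_equal(length(parcelVoxels(atlas, spec$name[p])), cnt)
  }
  # radius 0 labels exactly the center voxel
  a0 <- makeAtlas(grid, data.frame(name = "C", x = 6, y = 6, z = 6,
                                   radius = 0))
  expect_equal(parcelVoxels(a0, "C"),
               froikit:::ijkToLinear(c(6, 6, 6), c(12L, 12L, 12L)))
  # determinism and error paths
  expect_identical(makeAtlas(grid, spec)@labels, atlas@labels)
  expect_error(makeAtlas(grid, data.frame(name = "D", x = 40, y = 6, z = 6,
                                          radius = 1)), "geometry error")
  expect_error(makeAtlas(grid, data.frame(name = "D", x = 11, y = 6, z = 6,
                                          radius = 3)), "geometry error")
})

test_that("overlapping parcel requests resolve by first-come priority", {
  grid <- volumeGrid(c(12L, 12L, 12L), voxelSize = 2)
  spec <- data.frame(name = c("A", "B"), x = c(5, 7), y = c(6, 6),
                     z = c(6, 6), radius = c(2, 2))
  atlas <- makeAtlas(grid, spec)
  ballA <- sum(sapply(1:12, function(i) sum(outer(
    (i - 5)^2 + (seq_len(12) - 6)^2, (seq_len(12) - 6)^2, "+") <= 4)))
  expect_equal(length(parcelVoxels(atlas, "A")), ballA)  # A keeps its ball
  expect_true(length(parcelVoxels(atlas, "B")) < ballA)  # B loses overlap
  expect_equal(length(intersect(parcelVoxels(atlas, "A"),
                                parcelVoxels(atlas, "B"))), 0L)
})

test_that("selective masks are the top-fraction of the weight field", {
  atlas <- lineParcelAtlas(500)
  truth <- makeSubjectTruth(atlas, languageOnlyAmplitudes(),
                            selectiveFraction = 0.2, seed = 3)
  expect_equal(length(selectiveVoxels(truth, "standard", "P1")), 100L)
  # fraction 1: every parcel voxel selective
  t1 <- makeSubjectTruth(atlas, languageOnlyAmplitudes(),
                         selectiveFraction = 1, seed = 3)
  expect_setequal(selectiveVoxels(t1, "standard", "P1"),
                  parcelVoxels(atlas, "P1"))
  # deterministic under seed; zero version jitter => identical masks
  t2 <- makeSubjectTruth(atlas, languageOnlyAmplitudes(),
                         selectiveFraction = 0.2, versionJitterMm = 0,
                         seed = 3)
  expect_identical(selectiveVoxels(t2, "standard", "P1"),
                   selectiveVoxels(t2, "speeded", "P1"))
  t3 <- makeSubjectTruth(atlas, languageOnlyAmplitudes(),
                         selectiveFraction = 0.2, seed = 3)
  expect_identical(selectiveVoxels(t3, "standard", "P1"),
                   selectiveVoxels(truth, "standard", "P1"))
  expect_error(
    makeSubjectTruth(atlas, list(language = list(standard = c(foo = 1)))),
    "config error")
})

test_that("null forward model is constant at baseline", {
  atlas <- smallAtlas()
  truth <- makeSubjectTruth(atlas, nullAmplitudes(), seed = 1)
  sched <- makeSched("standard")
  ns <- noiseSpec(sigma = 1e-9, driftAmplitude = 0, baseline = 500)
  img <- simulateBold(truth, sched, noise = ns, seed = 1)
  expect_equal(nScans(img), 179L)
  expect_lt(max(abs(img@data - 500)), 1e-5)
})

test_that("simulated noise has the requested lag-1 autocorrelation", {
  atlas <- smallAtlas()
  truth <- makeSubjectTruth(atlas, nullAmplitudes(), seed = 1)
  sched <- makeSched("standard")
  for (rho in c(0.2, 0.6)) {
    ns <- noiseSpec(sigma = 1, arRho = rho, driftAmplitude = 0)
    img <- simulateBold(truth, sched, noise = ns, seed = 9)
    e <- img@data / ns@baseline - 1  # noise in percent/100 units
    dim(e) <- c(1000, 179)
    e <- e[1:100, ]  # 100 voxels x 178 lags >> 10,000 points
    r1 <- cor(as.vector(e[, -1]), as.vector(e[, -179]))
    expect_lt(abs(r1 - rho), 0.03)
  }
})

test_that("a noiseless simulation round-trips through the GLM exactly", {
  atlas <- smallAtlas()
  truth <- makeSubjectTruth(atlas, languageOnlyAmplitudes(),
                            selectiveFraction = 0.2, seed = 5)
  sched <- makeSched("standard")
  ns <- noiseSpec(sigma = 1e-9, driftAmplitude = 0)
  img <- simulateBold(truth, sched, noise = ns, seed = 2)
  opts <- glmOptions(smoothingFwhm = 0, scaling = "none")
  X <- buildDesignMatrix(sched, nScans(img), 2, opts)
  fit <- fitGlm(img, X, opts, mask = parcelVoxels(atlas, "P1"))
  cm <- contrast(fit, c(sentences = 1, nonwords = -1))
  sel <- selectiveVoxels(truth, "standard", "P1")
  # raw-unit effects back to percent of baseline
  rec <- 100 * effectMap(cm)[sel] / ns@baseline
  injected <- 2.0 - 0.5
  expect_lt(max(abs(rec - injected)) / injected, 1e-6)
  # non-selective voxels carry no effect
  other <- setdiff(parcelVoxels(atlas, "P1"), sel)
  expect_lt(max(abs(effectMap(cm)[other])) / ns@baseline, 1e-8)
})

test_that("simulations are finite and seed-deterministic", {
  atlas <- smallAtlas()
  truth <- makeSubjectTruth(atlas, languageOnlyAmplitudes(), seed = 4)
  sched <- makeSched("speeded")
  a <- simulateBold(truth, sched, seed = 77)
  b <- simulateBold(truth, sched, seed = 77)
  expect_identical(a@data, b@data)
  expect_true(all(is.finite(a@data)))
  d <- simulateBold(truth, sched, seed = 78)
  expect_false(identical(a@data, d@data))
  expect_error(simulateBold(truth, sched, nScans = 1e4, seed = 1),
               "schedule shorter")
})

test_that("cropping an atlas preserves parcels and world coordinates", {
  atlas <- defaultAtlas()
  cr <- froikit:::cropAtlas(atlas, 3L)
  expect_true(all(gridDim(cr@grid) <= gridDim(atlas@grid)))
  for (p in parcelNames(atlas)) {
    expect_equal(length(parcelVoxels(cr, p)), length(parcelVoxels(atlas, p)))
    wOrig <- voxelToWorld(atlas@grid, froikit:::linearToIjk(
      parcelVoxels(atlas, p), gridDim(atlas@grid)) - 1L)
    wCrop <- voxelToWorld(cr@grid, froikit:::linearToIjk(
      parcelVoxels(cr, p), gridDim(cr@grid)) - 1L)
    expect_equal(wCrop, wOrig)
  }
})
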