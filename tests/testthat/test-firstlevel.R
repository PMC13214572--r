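test_that("canonical HRF has the expected shape", {
  h <- canonicalHrf(0.001)
  expect_equal(h[1], 0)           # gamma density vanishes at 0 for shape > 1
  expect_equal(max(h), 1)         # peak-normalized
  # dense-grid maximization of the closed-form double gamma peaks at ~5 s
  expect_lt(abs((which.max(h) - 1) * 0.001 - 5.0), 0.001 + 1e-9)
  # refining dt only resamples the same function
  h1 <- canonicalHrf(0.2)
  h2 <- canonicalHrf(0.1)
  expect_equal(h2[seq(1, length(h2), by = 2)], h1, tolerance = 1e-9)
  expect_error(canonicalHrf(0.1, peakDisp = 0), "parameter error")
})

test_that("drift basis spans exactly the periods above the cutoff", {
  sched <- makeSched("standard")
  countByEnumeration <- function(nScans, tr, cutoff) {
    k <- 1L; cnt <- 0L
    while (2 * nScans * tr / k > cutoff) { cnt <- cnt + 1L; k <- k + 1L }
    cnt
  }
  X <- buildDesignMatrix(sched, 179, 2)
  expect_equal(length(X@driftCols), countByEnumeration(179, 2, 128))
  expect_equal(length(X@driftCols), floor(2 * 179 * 2 / 128))
  spd <- makeSched("speeded")
  X2 <- buildDesignMatrix(spd, 107, 2, glmOptions(highpassCutoff = 100))
  expect_equal(length(X2@driftCols), countByEnumeration(107, 2, 100))
  expect_equal(length(X@constantCol), 1L)
  expect_error(buildDesignMatrix(sched, 179, 2, glmOptions(highpassCutoff = 3)),
               "cutoff")
})

test_that("condition columns are orthogonal to the constant after drift projection", {
  sched <- makeSched("standard")
  X <- buildDesignMatrix(sched, 179, 2)@values
  drift <- X[, grep("^drift", colnames(X)), drop = FALSE]
  base <- cbind(drift, constant = 1)
  P <- base %*% solve(crossprod(base), t(base))
  for (cnd in c("sentences", "nonwords")) {
    res <- X[, cnd] - P %*% X[, cnd]
    expect_lt(abs(sum(res)), 1e-9)  # orthogonal to the constant
  }
})

test_that("singular designs raise a rank error naming the columns", {
  sched <- makeSched("standard")
  X <- buildDesignMatrix(sched, 179, 2)
  dup <- X@values[, "sentences", drop = FALSE]
  expect_error(buildDesignMatrix(sched, 179, 2, nuisance = dup),
               "rank error.*collinear")
})

test_that("whitening with rho = 0 reduces to ordinary least squares", {
  set.seed(1)
  n <- 40
  X <- cbind(rnorm(n), rnorm(n), 1)
  Y <- matrix(rnorm(n * 5), n, 5)
  D <- makeToyDesign(X, c("a", "b"))
  fit <- fitGlm(toyImage(Y), D, glmOptions(arCoef = 0, scaling = "none"))
  ols <- qr.coef(qr(X), Y)
  expect_lt(max(abs(fit@beta - ols)), 1e-10)
})

test_that("prewhitened estimates equal the dense GLS oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:20) {
    n <- 20
    X <- cbind(rnorm(n), rnorm(n), 1)
    y <- as.numeric(X %*% c(1, -0.5, 3)) + rnorm(n)
    D <- makeToyDesign(X, c("a", "b"))
    fit <- fitGlm(toyImage(cbind(y)), D,
                  glmOptions(arCoef = 0.2, scaling = "none"))
    or <- glsOracle(X, y, 0.2)
    worst <- max(worst, max(abs(fit@beta[, 1] - or$beta)))
    # marginal t of a single condition matches the oracle
    cm <- contrast(fit, c(a = 1))
    expect_equal(tMap(cm)[1, 1, 1], or$t[1], tolerance = 1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("contrasts are antisymmetric and scale-invariant in t", {
  set.seed(7)
  n <- 60
  X <- cbind(rnorm(n), rnorm(n), 1)
  D <- makeToyDesign(X, c("a", "b"))
  # data with identical true coefficients on both conditions
  y <- as.numeric(X %*% c(2, 2, 1)) + rnorm(n, sd = 0.1)
  fit <- fitGlm(toyImage(cbind(y)), D, glmOptions(scaling = "none"))
  c1 <- contrast(fit, c(a = 1, b = -1))
  c2 <- contrast(fit, c(a = 2, b = -2))
  expect_equal(effectMap(c2)[1, 1, 1], 2 * effectMap(c1)[1, 1, 1])
  expect_equal(tMap(c2)[1, 1, 1], tMap(c1)[1, 1, 1], tolerance = 1e-12)
  b <- contrast(fit, c(b = 1, a = -1))
  expect_equal(effectMap(b)[1, 1, 1], -effectMap(c1)[1, 1, 1])
  expect_error(contrast(fit, c(zz = 1)), "contrast error")
})

test_that("adding drift-span signal leaves condition contrasts unchanged", {
  atlas <- smallAtlas()
  truth <- makeSubjectTruth(atlas, languageOnlyAmplitudes(), seed = 2)
  sched <- makeSched("standard")
  img <- simulateBold(truth, sched, seed = 6)
  opts <- glmOptions(smoothingFwhm = 0, scaling = "none")
  X <- buildDesignMatrix(sched, 179, 2, opts)
  mask <- parcelVoxels(atlas, "P1")
  fit1 <- fitGlm(img, X, opts, mask = mask)
  cm1 <- contrast(fit1, c(sentences = 1, nonwords = -1))
  # add the same drift-basis combination to every voxel's series
  driftSig <- X@values[, X@driftCols] %*% c(20, -10, 5, 10, -20)
  img2 <- img
  arr <- img@data
  dim(arr) <- c(1000, 179)
  arr <- arr + matrix(driftSig, 1000, 179, byrow = TRUE)
  dim(arr) <- dim(img@data)
  img2@data <- arr
  fit2 <- fitGlm(img2, X, opts, mask = mask)
  cm2 <- contrast(fit2, c(sentences = 1, nonwords = -1))
  expect_lt(max(abs(effectMap(cm2)[mask] - effectMap(cm1)[mask])), 1e-8)
})

test_that("percent scaling makes effects invariant to the baseline level", {
  atlas <- smallAtlas()
  truth <- makeSubjectTruth(atlas, languageOnlyAmplitudes(), seed = 2)
  sched <- makeSched("standard")
  opts <- glmOptions(smoothingFwhm = 0)
  X <- buildDesignMatrix(sched, 179, 2, opts)
  mask <- parcelVoxels(atlas, "P1")
  eff <- lapply(c(100, 5000), function(b) {
    img <- simulateBold(truth, sched,
                        noise = noiseSpec(baseline = b), seed = 31)
    effectMap(contrast(fitGlm(img, X, opts, mask = mask),
                       c(sentences = 1, nonwords = -1)))[mask]
  })
  expect_equal(eff[[1]], eff[[2]], tolerance = 1e-10)
})

test_that("gaussian smoothing is normalized, local and matches the closed form", {
  grid <- volumeGrid(c(11L, 11L, 11L), voxelSize = 2)
  arr <- array(0, dim = c(11, 11, 11))
  cm0 <- new("ContrastMap", grid = grid, effect = arr + 3, t = arr + 3,
             name = "c", sourceRun = "r")
  expect_identical(gaussianSmooth(cm0, 0), cm0)       # fwhm 0 = identity
  smc <- gaussianSmooth(cm0, 4)
  expect_lt(max(abs(effectMap(smc) - 3)), 1e-9)       # constants preserved
  # single impulse: center / face-neighbor ratio is exp(1/(2 sigma_vox^2))
  arr[6, 6, 6] <- 1
  cmI <- new("ContrastMap", grid = grid, effect = arr, t = arr,
             name = "c", sourceRun = "r")
  smI <- effectMap(gaussianSmooth(cmI, 4))
  sigmaVox <- 4 / (2 * sqrt(2 * log(2))) / 2
  expect_lt(abs(smI[6, 6, 6] / smI[7, 6, 6] - exp(1 / (2 * sigmaVox^2))) /
              exp(1 / (2 * sigmaVox^2)), 0.01)
})

test_that("compiled smoothing equals the dense-matrix reference", {
  set.seed(3)
  a <- array(rnorm(9 * 8 * 7 * 4), dim = c(9, 8, 7, 4))
  expect_equal(froikit:::smoothArray(a, 5, 2),
               froikit:::smoothArrayReference(a, 5, 2), tolerance = 1e-12)
  a3 <- array(rnorm(9 * 8 * 7), dim = c(9, 8, 7))
  expect_equal(froikit:::smoothArray(a3, 3, 2),
               froikit:::smoothArrayReference(a3, 3, 2), tolerance = 1e-12)
})
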