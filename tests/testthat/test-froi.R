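test_that("fROI selection equals a brute-force top-k sort", {
  set.seed(11)
  atlas <- lineParcelAtlas(500)
  tv <- rnorm(1000)
  tmap <- mapFromValues(atlas@grid, tv)
  froi <- defineFroi(tmap, atlas, "P1", froiConfig(fraction = 0.1))
  vox <- parcelVoxels(atlas, "P1")
  oracle <- sort(vox[order(-tv[vox], vox)][1:50])
  expect_identical(froiVoxels(froi), as.integer(oracle))
  expect_equal(froi@nParcelVoxels, 500L)
  # top-100% is the whole parcel
  all100 <- defineFroi(tmap, atlas, "P1", froiConfig(fraction = 1))
  expect_identical(froiVoxels(all100), as.integer(vox))
})

test_that("ties break by ascending linear voxel index", {
  atlas <- lineParcelAtlas(40)
  tmap <- mapFromValues(atlas@grid, rep(1, 1000))
  froi <- defineFroi(tmap, atlas, "P1", froiConfig(fraction = 0.1))
  expect_identical(froiVoxels(froi), 1:4)
  # singleton floor: a tiny parcel still yields one voxel
  a1 <- lineParcelAtlas(3)
  expect_equal(froiSize(defineFroi(tmap, a1, "P1",
                                   froiConfig(fraction = 0.1))), 1L)
})

test_that("fROI errors: empty-ish parcels and undefined t-values", {
  atlas <- lineParcelAtlas(50)
  tmap <- mapFromValues(atlas@grid, rep(NA_real_, 1000))
  expect_error(defineFroi(tmap, atlas, "P1"), "data error")
  expect_error(defineFroi(tmap, atlas, "nope"), "unknown parcel")
  other <- mapFromValues(volumeGrid(c(5L, 5L, 5L)), rnorm(125))
  expect_error(defineFroi(other, atlas, "P1"), "share the grid")
})

test_that("mirroring reflects across the x mid-plane and is an involution", {
  grid <- volumeGrid(c(24L, 12L, 12L), voxelSize = 2)
  labels <- array(0L, dim = c(24, 12, 12))
  labels[4, 6, 6] <- 1L  # 1-based x = 4 (0-based 3)
  atlas <- new("ParcelAtlas", grid = grid, labels = labels,
               parcelNames = c("1" = "LDot"),
               networks = c(LDot = "language"))
  mir <- mirrorParcels(atlas)
  idx <- which(mir@labels == 1L, arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(21, 6, 6))  # 0-based: 23 - 3 = 20
  expect_equal(parcelNames(mir), "RDot")
  back <- mirrorParcels(mir)
  expect_identical(back@labels, atlas@labels)
  expect_identical(parcelNames(back), parcelNames(atlas))
  # a slab symmetric about the mid-plane maps onto itself
  labels2 <- array(0L, dim = c(24, 12, 12))
  labels2[12:13, 5, 5] <- 1L
  atlas2 <- new("ParcelAtlas", grid = grid, labels = labels2,
                parcelNames = c("1" = "Mid"), networks = c(Mid = "MD"))
  expect_identical(mirrorParcels(atlas2)@labels, labels2)
  # rotated affines are rejected
  rot <- atlas
  rot@grid@affine[1, 2] <- 0.5
  expect_error(mirrorParcels(rot), "geometry error")
})

test_that("cross-validated extraction averages held-out runs symmetrically", {
  set.seed(21)
  atlas <- lineParcelAtlas(200)
  mkRun <- function(tv, effS, effN, run) list(
    tmap = mapFromValues(atlas@grid, tv, sourceRun = run),
    effects = list(sentences = mapFromValues(atlas@grid, effS),
                   nonwords = mapFromValues(atlas@grid, effN)))
  tv <- rnorm(1000); eS <- rnorm(1000); eN <- rnorm(1000)
  runA <- mkRun(tv, eS, eN, "1")
  cfg <- froiConfig(parcels = "P1")
  # identical runs: cross-validated equals circular
  cv <- crossvalResponse(list(runA, runA), atlas, cfg)
  circ <- crossvalResponse(list(runA, runA), atlas, cfg, circular = TRUE)
  expect_equal(cv$response, circ$response)
  # fold symmetry: swapping run labels changes nothing
  runB <- mkRun(rnorm(1000), rnorm(1000), rnorm(1000), "2")
  ab <- crossvalResponse(list(runA, runB), atlas, cfg)
  ba <- crossvalResponse(list(runB, runA), atlas, cfg)
  expect_equal(ab$response, ba$response)
  expect_equal(ab$n_voxels[1], 20L)
  expect_error(crossvalResponse(list(runA), atlas, cfg), "fold error")
})

test_that("fROI tables serialize with 0-based indices", {
  atlas <- lineParcelAtlas(100)
  tmap <- mapFromValues(atlas@grid, seq_len(1000))
  froi <- defineFroi(tmap, atlas, "P1", froiConfig(fraction = 0.1))
  f <- tempfile(fileext = ".tsv")
  writeFroiTable(froi, atlas@grid, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 10)
  expect_equal(sort(tab$voxel_index + 1L), froiVoxels(froi))
  expect_true(all(tab$i >= 0 & tab$i < 10))
})

test_that("simulated effects are recovered through cross-validated fROIs", {
  atlas <- smallAtlas()
  cfg <- froiConfig(parcels = "P1")
  vals <- replicate(3, {
    seed <- sample.int(1e6, 1)
    truth <- makeSubjectTruth(atlas, languageOnlyAmplitudes(),
                              selectiveFraction = 0.2,
                              versionJitterMm = 0, seed = seed)
    runs <- lapply(1:2, function(r)
      quickRun(truth, makeSched("standard", run = r, subjectSeed = seed),
               seed = seed + r, noise = noiseSpec(sigma = 0.2),
               mask = parcelVoxels(atlas, "P1")))
    rt <- crossvalResponse(runs, atlas, cfg)
    rt$response[rt$condition == "sentences"] -
      rt$response[rt$condition == "nonwords"]
  })
  expect_lt(abs(mean(vals) - 1.5) / 1.5, 0.05)
})
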