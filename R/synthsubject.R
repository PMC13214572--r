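#' Build a parcel atlas of disjoint spherical parcels
#'
#' Voxels within \code{radius} (voxel units, Euclidean) of each requested
#' center are labelled; overlapping requests are resolved by first-come
#' priority. Construction is deterministic.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param parcelSpec data.frame with columns \code{name}, \code{x},
#'   \code{y}, \code{z} (1-based voxel center), \code{radius} (voxels) and
#'   optionally \code{network}.
#' @param seed ignored (construction is deterministic); accepted for
#'   interface symmetry with the other generators.
#' @return A \linkS4class{ParcelAtlas}.
#' @export
makeAtlas <- function(grid, parcelSpec, seed = NULL) {
  dm <- grid@dim
  labels <- array(0L, dim = dm)
  if (any(parcelSpec$x < 1 | parcelSpec$x > dm[1] |
          parcelSpec$y < 1 | parcelSpec$y > dm[2] |
          parcelSpec$z < 1 | parcelSpec$z > dm[3]))
    stop("geometry error: parcel center outside the grid")
  if (any(parcelSpec$x - parcelSpec$radius < 1 |
          parcelSpec$x + parcelSpec$radius > dm[1] |
          parcelSpec$y - parcelSpec$radius < 1 |
          parcelSpec$y + parcelSpec$radius > dm[2] |
          parcelSpec$z - parcelSpec$radius < 1 |
          parcelSpec$z + parcelSpec$radius > dm[3]))
    stop("geometry error: sphere does not fit inside the grid")
  for (p in seq_len(nrow(parcelSpec))) {
    ctr <- c(parcelSpec$x[p], parcelSpec$y[p], parcelSpec$z[p])
    r <- parcelSpec$radius[p]
    lo <- pmax(1, floor(ctr - r)); hi <- pmin(dm, ceiling(ctr + r))
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    d2 <- outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, "+"),
                (gz - ctr[3])^2, "+")
    inside <- which(d2 <= r^2 + 1e-12, arr.ind = TRUE)
    ijk <- cbind(gx[inside[, 1]], gy[inside[, 2]], gz[inside[, 3]])
    lin <- ijkToLinear(ijk, dm)
    lin <- lin[labels[lin] == 0L]  # first-come priority
    labels[lin] <- p
  }
  nm <- stats::setNames(as.character(parcelSpec$name),
                        as.character(seq_len(nrow(parcelSpec))))
  networks <- if ("network" %in% names(parcelSpec)) {
    stats::setNames(as.character(parcelSpec$network),
                    as.character(parcelSpec$name))
  } else {
    stats::setNames(rep("language", nrow(parcelSpec)),
                    as.character(parcelSpec$name))
  }
  new("ParcelAtlas", grid = grid, labels = labels, parcelNames = nm,
      networks = networks)
}

#' Default synthetic atlas: five language and four MD spherical parcels
#'
#' A 24 x 24 x 24 grid at 2 mm with five left-hemisphere "language" parcels
#' (named after the canonical frontal/temporal parcels: LIFG, LIFGorb,
#' LMFG, LAntTemp, LPostTemp) and four "MD" parcels, all spheres of radius
#' 3 voxels (123 voxels each) placed pairwise disjoint in the left half of
#' the grid. This is a synthetic stand-in with the same role as the
#' group-derived parcels used in individual-subject localizer analyses
#' (available from https://evlab.mit.edu/funcloc/), not a copy of them.
#'
#' @return A \linkS4class{ParcelAtlas}.
#' @export
defaultAtlas <- function() {
  spec <- data.frame(
    name = c("LIFG", "LIFGorb", "LMFG", "LAntTemp", "LPostTemp",
             "MD1", "MD2", "MD3", "MD4"),
    x = c(6, 6, 6, 6, 6, 10, 9, 9, 10),
    y = c(5, 5, 13, 13, 20, 4, 20, 21, 12),
    z = c(16, 7, 20, 5, 12, 21, 21, 4, 12),
    radius = 3,
    network = c(rep("language", 5), rep("MD", 4)),
    stringsAsFactors = FALSE)
  makeAtlas(volumeGrid(c(24L, 24L, 24L), voxelSize = 2), spec)
}

# Crop an atlas to the bounding box of its parcels plus a margin (voxels).
# With margin >= the smoothing-kernel half-width, every parcel voxel keeps
# its complete smoothing neighbourhood, so analyses restricted to parcel
# voxels are unaffected by the crop.
cropAtlas <- function(atlas, margin = 0L) {
  lab <- atlas@labels
  dm <- dim(lab)
  idx <- which(lab != 0L, arr.ind = TRUE)
  lo <- pmax(1L, apply(idx, 2, min) - margin)
  hi <- pmin(dm, apply(idx, 2, max) + margin)
  if (all(lo == 1L) && all(hi == dm)) return(atlas)
  sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  aff <- atlas@grid@affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% (lo - 1)
  grid <- new("VolumeGrid", dim = as.integer(hi - lo + 1L),
              voxelSize = atlas@grid@voxelSize, affine = aff)
  new("ParcelAtlas", grid = grid, labels = sub,
      parcelNames = atlas@parcelNames, networks = atlas@networks)
}

#' Default ground-truth condition amplitudes (percent signal change)
#'
#' Selective voxels in language parcels respond more to sentences than
#' nonwords in both localizer versions, with a larger sentences response
#' and a smaller nonwords response under speeded presentation; MD-parcel
#' voxels respond more to the hard than the easy working-memory condition
#' and weakly (nonwords > sentences, more under speeded presentation) to
#' the reading conditions.
#'
#' @return Nested list: network -> version -> named condition amplitudes.
#' @export
defaultAmplitudes <- function() {
  list(
    language = list(
      standard = c(sentences = 2.0, nonwords = 0.5),
      speeded = c(sentences = 2.3, nonwords = 0.1),
      spatialWM = c(hard = 0, easy = 0)),
    MD = list(
      standard = c(sentences = 0.2, nonwords = 0.4),
      speeded = c(sentences = 0.5, nonwords = 0.7),
      spatialWM = c(hard = 2.0, easy = 1.0)))
}

knownConditions <- c("sentences", "nonwords", "hard", "easy", "fixation")

# Smooth per-parcel weight field: a mixture of Gaussian blobs whose centers
# are fixed per parcel and displaced by a per-subject (and optionally
# per-version) offset. Returns weights for the parcel's voxels.
parcelWeightField <- function(atlas, parcel, subjOffsetMm, verOffsetMm) {
  vox <- parcelVoxels(atlas, parcel)
  dm <- atlas@grid@dim
  vs <- atlas@grid@voxelSize
  ijk <- linearToIjk(vox, dm)
  xyz <- ijk * vs  # internal metric coordinates, offsets are in mm
  ctr <- colMeans(xyz)
  rEq <- (3 * length(vox) / (4 * pi))^(1 / 3) * vs  # equivalent radius, mm
  blobs <- withSeed(subSeed(977L, "blobs", parcel), {
    matrix(rnorm(9, sd = rEq / 2), 3, 3)
  })
  centers <- sweep(blobs, 2, ctr + subjOffsetMm + verOffsetMm, "+")
  s2 <- (rEq / 2)^2
  w <- rep(0, length(vox))
  for (k in 1:3) {
    d2 <- colSums((t(xyz) - centers[, k])^2)
    w <- w + exp(-d2 / (2 * s2))
  }
  w
}

#' Generate a ground-truth subject
#'
#' Within each parcel a smooth random weight field (a Gaussian-blob mixture
#' whose blob layout is fixed per parcel and displaced by a per-subject
#' jitter, emulating inter-individual differences in the precise locations
#' of functional areas) is thresholded to mark the top
#' \code{selectiveFraction} of voxels as selective. A smaller per-version
#' displacement (\code{versionJitterMm}) makes the selective topography
#' differ slightly between task versions, so that within-version map
#' reliability exceeds between-version similarity. Selective voxels carry
#' the configured (condition, version) amplitudes; all other voxels are 0.
#'
#' @param atlas a \linkS4class{ParcelAtlas} with parcel networks.
#' @param amplitudes nested list network -> version -> named condition
#'   amplitudes (percent signal change), as \code{\link{defaultAmplitudes}}.
#' @param selectiveFraction fraction of parcel voxels that are truly
#'   selective, in (0, 1].
#' @param jitterSdMm SD (mm, per axis) of the per-subject displacement.
#' @param versionJitterMm SD (mm, per axis) of the per-version displacement.
#' @param seed integer subject seed.
#' @param subjectId subject identifier string.
#' @return A \linkS4class{GroundTruthSubject}.
#' @export
makeSubjectTruth <- function(atlas, amplitudes = defaultAmplitudes(),
                             selectiveFraction = 0.2, jitterSdMm = 4,
                             versionJitterMm = 1.5, seed = 1L,
                             subjectId = sprintf("sub%05d", seed %% 100000L)) {
  if (selectiveFraction <= 0 || selectiveFraction > 1)
    stop("selectiveFraction must be in (0, 1]")
  conds <- unlist(lapply(amplitudes, function(net) lapply(net, names)))
  if (!all(conds %in% knownConditions))
    stop("config error: unknown condition(s): ",
         paste(setdiff(conds, knownConditions), collapse = ", "))
  versions <- unique(unlist(lapply(amplitudes, names)))
  subjOff <- withSeed(subSeed(seed, "jitter"), rnorm(3, sd = jitterSdMm))
  selective <- lapply(stats::setNames(nm = versions), function(ver) {
    verOff <- withSeed(subSeed(seed, "vjitter", ver),
                       rnorm(3, sd = versionJitterMm))
    sel <- lapply(stats::setNames(nm = parcelNames(atlas)), function(p) {
      vox <- parcelVoxels(atlas, p)
      w <- parcelWeightField(atlas, p, subjOff, verOff)
      k <- max(1L, floor(selectiveFraction * length(vox)))
      sort(vox[order(-w, vox)[seq_len(k)]])
    })
    sel
  })
  new("GroundTruthSubject", subjectId = subjectId, atlas = atlas,
      amplitudes = amplitudes, selective = selective,
      jitterSeed = as.integer(seed))
}

#' @describeIn makeSubjectTruth per-voxel true amplitude volume (3D array,
#'   percent signal change) for one condition and version.
#' @param truth a \linkS4class{GroundTruthSubject}.
#' @param condition condition name.
#' @export
amplitudeVolume <- function(truth, condition, version) {
  atlas <- truth@atlas
  vol <- array(0, dim = atlas@grid@dim)
  if (!version %in% names(truth@selective)) return(vol)
  for (p in parcelNames(atlas)) {
    net <- atlas@networks[[p]]
    amps <- truth@amplitudes[[net]][[version]]
    if (is.null(amps) || !condition %in% names(amps)) next
    a <- amps[[condition]]
    if (a != 0) vol[truth@selective[[version]][[p]]] <- a
  }
  vol
}

#' Simulate a 4D BOLD run
#'
#' Forward model: each voxel's series is
#' \code{baseline * (1 + sum_c amplitude_c/100 * x_c(t) + drift(t) +
#' sigma/100 * e(t))} where \code{x_c} is the condition boxcar convolved
#' with the canonical HRF (the same regressor construction the GLM uses),
#' \code{drift} is a low-frequency cosine, and \code{e} is AR(1) noise with
#' unit marginal variance, generated recursively from a stationary start.
#' The simulator generates only post-steady-state scans: the schedule clock
#' starts at 0 and no saturation scans are produced.
#'
#' @param truth a \linkS4class{GroundTruthSubject}.
#' @param schedule a \linkS4class{RunSchedule}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param tr repetition time in seconds.
#' @param nScans number of scans; default covers the schedule.
#' @param seed integer seed; identical seeds give identical volumes.
#' @param hrfParams HRF parameters passed to \code{\link{canonicalHrf}}.
#' @return A \linkS4class{TimeSeriesImage}.
#' @export
simulateBold <- function(truth, schedule, noise = noiseSpec(), tr = 2,
                         nScans = NULL, seed = 1L, hrfParams = list()) {
  grid <- truth@atlas@grid
  dm <- grid@dim
  if (is.null(nScans)) nScans <- floor(schedule@totalDuration / tr)
  nScans <- as.integer(nScans)
  if (schedule@totalDuration < nScans * tr - 1e-9)
    stop("schedule shorter than the requested acquisition")
  ver <- schedule@version@name
  regs <- conditionRegressors(schedule, nScans, tr, hrfParams = hrfParams)

  nvox <- prod(dm)
  tsec <- (seq_len(nScans) - 1) * tr
  # drift phase is arbitrary in a real acquisition; draw it per run so
  # its unremoved residue does not align identically across runs
  phase <- withSeed(subSeed(seed, "driftphase"), stats::runif(1, 0, 2 * pi))
  drift <- noise@driftAmplitude / 100 *
    cos(2 * pi * tsec / noise@driftPeriod + phase)

  dat <- withSeed(seed, rnorm(nvox * nScans))
  dim(dat) <- c(nvox, nScans)
  dat <- cppAr1Assemble(dat, noise@arRho, drift, noise@sigma,
                        noise@baseline)
  for (cond in colnames(regs)) {
    amp <- amplitudeVolume(truth, cond, ver)
    idx <- which(amp != 0)
    if (length(idx))
      dat[idx, ] <- dat[idx, ] +
        (noise@baseline * amp[idx] / 100) %o% regs[, cond]
  }
  dim(dat) <- c(dm, nScans)
  new("TimeSeriesImage", grid = grid, data = dat, tr = tr)
}
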