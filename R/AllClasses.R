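#' @import methods
#' @importFrom stats rnorm cor sd var qt pt pchisq logLik convolve dgamma
#'   setNames
#' @importFrom Rcpp evalCpp
#' @useDynLib froikit, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# VolumeGrid
# ---------------------------------------------------------------------------

#' Voxel grid geometry
#'
#' A \code{VolumeGrid} holds the shape of a 3D voxel grid together with the
#' 4x4 affine that maps 0-based voxel indices to world coordinates in mm
#' (RAS+ by default). Internally, R arrays are addressed 1-based; the affine
#' follows the NIfTI convention and applies to 0-based indices.
#'
#' @slot dim integer(3), grid shape (nx, ny, nz).
#' @slot voxelSize numeric(1), nominal isotropic voxel size in mm.
#' @slot affine 4x4 numeric matrix, 0-based voxel index -> world mm.
#' @export
setClass("VolumeGrid", representation(
  dim = "integer", voxelSize = "numeric", affine = "matrix"
))

setValidity("VolumeGrid", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be three integers >= 1")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be 4x4")
  if (abs(det(object@affine)) < .Machine$double.eps)
    return("affine must be invertible")
  TRUE
})

#' Construct a voxel grid
#'
#' @param dim integer(3) grid shape.
#' @param voxelSize voxel edge length in mm (isotropic).
#' @param origin world coordinate of voxel (0,0,0), length 3.
#' @return A \linkS4class{VolumeGrid}.
#' @examples
#' g <- volumeGrid(c(24L, 24L, 24L), voxelSize = 2)
#' voxelToWorld(g, c(3, 4, 5))  # c(6, 8, 10)
#' @export
volumeGrid <- function(dim, voxelSize = 2, origin = c(0, 0, 0)) {
  aff <- diag(c(rep(voxelSize, 3), 1))
  aff[1:3, 4] <- origin
  new("VolumeGrid", dim = as.integer(dim), voxelSize = as.numeric(voxelSize),
      affine = aff)
}

#' @describeIn volumeGrid grid shape accessor
#' @param grid a \linkS4class{VolumeGrid}.
#' @export
gridDim <- function(grid) grid@dim

#' @describeIn volumeGrid voxel size accessor (mm)
#' @export
voxelSize <- function(grid) grid@voxelSize

#' @describeIn volumeGrid affine accessor (0-based voxel index -> world mm)
#' @export
gridAffine <- function(grid) grid@affine

#' @describeIn volumeGrid map 0-based voxel indices to world mm; \code{idx}
#'   is a length-3 vector or an n x 3 matrix of 0-based indices.
#' @param idx 0-based voxel indices.
#' @export
voxelToWorld <- function(grid, idx) {
  idx <- rbind(idx)
  xyz <- cbind(idx, 1) %*% t(grid@affine)
  out <- xyz[, 1:3, drop = FALSE]
  if (nrow(out) == 1L) drop(out) else out
}

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid %s at %g mm\n",
              paste(object@dim, collapse = " x "), object@voxelSize))
})

sameGrid <- function(a, b) {
  identical(a@dim, b@dim) && isTRUE(all.equal(a@affine, b@affine))
}

# ---------------------------------------------------------------------------
# ParcelAtlas
# ---------------------------------------------------------------------------

#' Parcel atlas: labelled volume of disjoint parcels
#'
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot labels integer 3D array; 0 = background, positive values index
#'   \code{parcelNames}.
#' @slot parcelNames character, named by label value.
#' @slot networks character, network assignment (e.g. "language", "MD")
#'   named by parcel name.
#' @export
setClass("ParcelAtlas", representation(
  grid = "VolumeGrid", labels = "array", parcelNames = "character",
  networks = "character"
))

setValidity("ParcelAtlas", function(object) {
  if (!identical(dim(object@labels), as.integer(object@grid@dim)))
    return("label array shape must match grid")
  labs <- as.integer(names(object@parcelNames))
  present <- sort(unique(as.integer(object@labels)))
  if (!all(labs %in% present))
    return("every named label must occur in the volume")
  if (!all(names(object@networks) %in% object@parcelNames))
    return("networks must be named by parcel names")
  TRUE
})

#' @describeIn makeAtlas parcel names in label order
#' @export
parcelNames <- function(atlas) unname(atlas@parcelNames)

#' @describeIn makeAtlas 1-based linear voxel indices of one parcel
#' @param name parcel name.
#' @export
parcelVoxels <- function(atlas, name) {
  lab <- as.integer(names(atlas@parcelNames)[match(name, atlas@parcelNames)])
  if (is.na(lab)) stop("unknown parcel: ", name)
  which(as.integer(atlas@labels) == lab)
}

#' @describeIn makeAtlas network membership ("language"/"MD") per parcel
#' @export
parcelNetworks <- function(atlas) atlas@networks

setMethod("show", "ParcelAtlas", function(object) {
  sizes <- vapply(parcelNames(object),
                  function(p) length(parcelVoxels(object, p)), integer(1))
  cat(sprintf("ParcelAtlas: %d parcels on %s grid\n",
              length(sizes), paste(object@grid@dim, collapse = "x")))
  print(sizes)
})

# ---------------------------------------------------------------------------
# TaskVersion / RunSchedule / StimulusMaterials
# ---------------------------------------------------------------------------

#' Task version parameters
#'
#' Timing parameters of one localizer/task version. Shipped defaults
#' reproduce the blocked reading localizer in its standard (450 ms/word) and
#' speeded (200 ms/word) variants and the blocked spatial working-memory
#' task.
#'
#' @slot name one of "standard", "speeded", "spatialWM".
#' @slot wordDuration per-word presentation time in seconds (NA for
#'   spatialWM).
#' @slot trialDuration,blockDuration,fixationDuration durations in seconds.
#' @slot nExpBlocks,nFixBlocks,trialsPerBlock design counts.
#' @slot conditions the two condition names.
#' @export
setClass("TaskVersion", representation(
  name = "character", wordDuration = "numeric", trialDuration = "numeric",
  blockDuration = "numeric", fixationDuration = "numeric",
  nExpBlocks = "integer", nFixBlocks = "integer", trialsPerBlock = "integer",
  conditions = "character"
))

setValidity("TaskVersion", function(object) {
  if (length(object@conditions) != 2L)
    return("exactly two conditions per version")
  if (abs(object@blockDuration -
          object@trialsPerBlock * object@trialDuration) > 1e-9)
    return("block duration must equal trials per block x trial duration")
  if (object@nExpBlocks %% 2L != 0L)
    return("number of experimental blocks must be even")
  TRUE
})

setMethod("show", "TaskVersion", function(object) {
  cat(sprintf(
    "TaskVersion '%s': %d x %gs blocks (%d trials of %gs), %d x %gs fixation\n",
    object@name, object@nExpBlocks, object@blockDuration,
    object@trialsPerBlock, object@trialDuration, object@nFixBlocks,
    object@fixationDuration))
})

#' Timed events of one run
#'
#' The \code{events} slot is a data.frame with columns \code{onset},
#' \code{duration} (seconds), \code{condition} ("fixation" or a condition
#' name), \code{block_index} (0-based), \code{trial_index} (0-based within
#' block, NA for fixation) and \code{stimulus_id}. Events are sorted,
#' non-overlapping and tile the run without gaps.
#'
#' @slot version the \linkS4class{TaskVersion}.
#' @slot runIndex 1 or 2.
#' @slot events data.frame of timed events.
#' @slot totalDuration run length in seconds.
#' @export
setClass("RunSchedule", representation(
  version = "TaskVersion", runIndex = "integer", events = "data.frame",
  totalDuration = "numeric"
))

setValidity("RunSchedule", function(object) {
  ev <- object@events
  need <- c("onset", "duration", "condition", "block_index", "trial_index",
            "stimulus_id")
  if (!all(need %in% names(ev))) return("events missing required columns")
  if (is.unsorted(ev$onset)) return("events must be sorted by onset")
  ends <- ev$onset + ev$duration
  if (nrow(ev) > 1L && any(ev$onset[-1L] < ends[-nrow(ev)] - 1e-9))
    return("events must not overlap")
  if (abs(object@totalDuration - sum(ev$duration)) > 1e-6)
    return("totalDuration must equal the sum of event durations")
  v <- object@version
  expBlocks <- unique(ev$block_index[ev$condition != "fixation"])
  if (length(expBlocks) != v@nExpBlocks)
    return("wrong number of experimental blocks")
  nFix <- sum(ev$condition == "fixation")
  if (nFix != v@nFixBlocks) return("wrong number of fixation blocks")
  for (cnd in v@conditions) {
    nb <- length(unique(ev$block_index[ev$condition == cnd]))
    if (nb != v@nExpBlocks / 2L)
      return(sprintf("condition '%s' must occupy exactly %d blocks",
                     cnd, v@nExpBlocks / 2L))
  }
  TRUE
})

setMethod("show", "RunSchedule", function(object) {
  cat(sprintf("RunSchedule: %s run %d, %d events, %g s\n",
              object@version@name, object@runIndex, nrow(object@events),
              object@totalDuration))
})

#' Stimulus materials
#'
#' Five material sets, each of 48 sentence and 48 nonword-sequence items of
#' 12 whitespace-separated tokens. Texts are opaque pseudo-tokens: only the
#' timing and condition labels enter the analysis.
#'
#' @slot items data.frame with columns \code{set}, \code{condition},
#'   \code{item_id}, \code{text}.
#' @export
setClass("StimulusMaterials", representation(items = "data.frame"))

setValidity("StimulusMaterials", function(object) {
  it <- object@items
  if (!all(c("set", "condition", "item_id", "text") %in% names(it)))
    return("items missing required columns")
  ntok <- lengths(strsplit(it$text, "[[:space:]]+"))
  if (!all(ntok == 12L)) return("every item must have exactly 12 tokens")
  tab <- table(it$set, it$condition)
  if (!all(tab == 48L)) return("each set needs 48 items per condition")
  if (anyDuplicated(it$item_id)) return("item ids must be unique")
  TRUE
})

setMethod("show", "StimulusMaterials", function(object) {
  cat(sprintf("StimulusMaterials: %d sets, %d items\n",
              length(unique(object@items$set)), nrow(object@items)))
})

# ---------------------------------------------------------------------------
# NoiseSpec / GroundTruthSubject / TimeSeriesImage
# ---------------------------------------------------------------------------

#' Noise model specification
#'
#' @slot sigma noise standard deviation in percent-signal units.
#' @slot arRho lag-1 autoregressive coefficient, |rho| < 1.
#' @slot driftAmplitude low-frequency drift amplitude in percent of baseline.
#' @slot driftPeriod drift cosine period in seconds.
#' @slot baseline mean signal level in arbitrary scanner units.
#' @export
setClass("NoiseSpec", representation(
  sigma = "numeric", arRho = "numeric", driftAmplitude = "numeric",
  driftPeriod = "numeric", baseline = "numeric"
))

setValidity("NoiseSpec", function(object) {
  if (object@sigma <= 0) return("sigma must be positive")
  if (abs(object@arRho) >= 1) return("|arRho| must be < 1")
  if (object@driftPeriod <= 0) return("drift period must be positive")
  if (object@baseline <= 0) return("baseline must be positive")
  TRUE
})

#' Construct a noise specification
#'
#' Defaults define the reference simulation conditions: 1% temporal noise
#' with lag-1 autocorrelation 0.2 (matching the analysis whitening model),
#' a 0.5% cosine drift with a 200 s period (slow enough to be only partially
#' removed by the 128 s high-pass, exercising the drift regressors), and a
#' baseline of 1000 scanner units.
#'
#' @param sigma,arRho,driftAmplitude,driftPeriod,baseline see slots.
#' @return A \linkS4class{NoiseSpec}.
#' @export
noiseSpec <- function(sigma = 1.0, arRho = 0.2, driftAmplitude = 0.5,
                      driftPeriod = 200, baseline = 1000) {
  new("NoiseSpec", sigma = sigma, arRho = arRho,
      driftAmplitude = driftAmplitude, driftPeriod = driftPeriod,
      baseline = baseline)
}

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf(
    "NoiseSpec: sigma %g%%, AR(1) rho %g, drift %g%% @ %g s, baseline %g\n",
    object@sigma, object@arRho, object@driftAmplitude, object@driftPeriod,
    object@baseline))
})

#' Ground-truth subject
#'
#' Known condition amplitudes and selective voxel sets for one simulated
#' subject. \code{selective} maps version -> parcel -> 1-based linear voxel
#' indices of the truly selective voxels; \code{amplitudes} maps version ->
#' named condition amplitudes in percent signal change.
#'
#' @slot subjectId subject identifier.
#' @slot atlas the \linkS4class{ParcelAtlas} the truth lives on.
#' @slot amplitudes list: version -> named numeric (condition amplitudes, %).
#' @slot selective list: version -> named list of parcel voxel-index vectors.
#' @slot jitterSeed integer seed used for the topographic jitter.
#' @export
setClass("GroundTruthSubject", representation(
  subjectId = "character", atlas = "ParcelAtlas", amplitudes = "list",
  selective = "list", jitterSeed = "integer"
))

setValidity("GroundTruthSubject", function(object) {
  for (v in names(object@selective)) {
    sel <- object@selective[[v]]
    for (p in names(sel)) {
      if (!all(sel[[p]] %in% parcelVoxels(object@atlas, p)))
        return("selective voxels must lie inside their parcel")
    }
  }
  if (!all(is.finite(unlist(object@amplitudes))))
    return("amplitudes must be finite")
  TRUE
})

#' @describeIn makeSubjectTruth selective voxel indices for one version and
#'   parcel (1-based linear indices).
#' @param version version name.
#' @param parcel parcel name.
#' @export
selectiveVoxels <- function(truth, version, parcel) {
  truth@selective[[version]][[parcel]]
}

setMethod("show", "GroundTruthSubject", function(object) {
  cat(sprintf("GroundTruthSubject '%s': versions %s\n", object@subjectId,
              paste(names(object@amplitudes), collapse = ", ")))
})

#' 4D BOLD time-series image
#'
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot data 4D array (x, y, z, t) of signal values.
#' @slot tr repetition time in seconds.
#' @export
setClass("TimeSeriesImage", representation(
  grid = "VolumeGrid", data = "array", tr = "numeric"
))

setValidity("TimeSeriesImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be 4D")
  if (!identical(d[1:3], as.integer(object@grid@dim)))
    return("spatial dimensions must match grid")
  if (d[4] < 1L) return("need at least one scan")
  if (object@tr <= 0) return("tr must be positive")
  if (!all(is.finite(object@data))) return("data must be finite")
  TRUE
})

#' @describeIn simulateBold number of scans in a time-series image
#' @export
nScans <- function(img) dim(img@data)[4]

#' @describeIn simulateBold repetition time in seconds
#' @export
repTime <- function(img) img@tr

setMethod("show", "TimeSeriesImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("TimeSeriesImage: %s, %d scans @ TR %g s\n",
              paste(d[1:3], collapse = "x"), d[4], object@tr))
})

# ---------------------------------------------------------------------------
# DesignMatrix / GLMFit / ContrastMap
# ---------------------------------------------------------------------------

#' First-level design matrix
#'
#' @slot values n_scans x n_regressors matrix with named columns.
#' @slot conditionCols named integer, condition -> column index.
#' @slot derivCols named integer, condition -> temporal-derivative column.
#' @slot driftCols integer, discrete-cosine drift columns.
#' @slot constantCol integer, the constant column.
#' @slot nuisanceCols integer, user-supplied nuisance columns.
#' @slot tr repetition time in seconds.
#' @export
setClass("DesignMatrix", representation(
  values = "matrix", conditionCols = "integer", derivCols = "integer",
  driftCols = "integer", constantCol = "integer", nuisanceCols = "integer",
  tr = "numeric"
))

setValidity("DesignMatrix", function(object) {
  if (length(object@constantCol) != 1L) return("exactly one constant column")
  if (is.null(colnames(object@values))) return("columns must be named")
  TRUE
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d scans x %d regressors (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
})

#' Fitted first-level GLM
#'
#' @slot beta n_regressors x n_voxels coefficient matrix (percent-signal
#'   units).
#' @slot sigma2 per-voxel residual variance of the whitened residuals.
#' @slot dof residual degrees of freedom, n_scans - rank(X).
#' @slot xtxInv (X'X)^-1 of the whitened design.
#' @slot design the \linkS4class{DesignMatrix}.
#' @slot grid the source \linkS4class{VolumeGrid}.
#' @slot voxels 1-based linear indices of the fitted voxels.
#' @slot options the GLM options used.
#' @export
setClass("GLMFit", representation(
  beta = "matrix", sigma2 = "numeric", dof = "numeric", xtxInv = "matrix",
  design = "DesignMatrix", grid = "VolumeGrid", voxels = "integer",
  options = "list"
))

setValidity("GLMFit", function(object) {
  if (any(object@sigma2 < 0)) return("sigma2 must be nonnegative")
  if (object@dof <= 0) return("dof must be positive")
  TRUE
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit: %d voxels, %d regressors, dof %g\n",
              ncol(object@beta), nrow(object@beta), object@dof))
})

#' Per-voxel contrast effect and t maps
#'
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot effect 3D array of contrast effects (percent signal change); NA
#'   outside the fitted voxels.
#' @slot t 3D array of t-statistics; NA outside the fitted voxels.
#' @slot name contrast name.
#' @slot sourceRun identifier of the run the map came from.
#' @export
setClass("ContrastMap", representation(
  grid = "VolumeGrid", effect = "array", t = "array", name = "character",
  sourceRun = "character"
))

setValidity("ContrastMap", function(object) {
  if (!identical(dim(object@effect), as.integer(object@grid@dim)))
    return("effect map shape must match grid")
  if (!identical(dim(object@t), dim(object@effect)))
    return("t map shape must match effect map")
  ok <- !is.na(object@t)
  if (!all(is.finite(object@t[ok]))) return("t must be finite where defined")
  TRUE
})

#' @describeIn contrast effect-map accessor (3D array)
#' @export
effectMap <- function(map) map@effect

#' @describeIn contrast t-map accessor (3D array)
#' @export
tMap <- function(map) map@t

setMethod("show", "ContrastMap", function(object) {
  cat(sprintf("ContrastMap '%s' (run %s): %d voxels defined\n",
              object@name, object@sourceRun, sum(!is.na(object@t))))
})

# ---------------------------------------------------------------------------
# FROI
# ---------------------------------------------------------------------------

#' Subject-specific functional region of interest
#'
#' The voxels selected as the top fraction most responsive (by t-value)
#' within one parcel.
#'
#' @slot parcel parcel name.
#' @slot voxels 1-based linear voxel indices, ascending.
#' @slot definingContrast name of the defining contrast.
#' @slot definingRun identifier of the defining run.
#' @slot nParcelVoxels number of voxels in the parent parcel.
#' @export
setClass("FROI", representation(
  parcel = "character", voxels = "integer", definingContrast = "character",
  definingRun = "character", nParcelVoxels = "integer"
))

setValidity("FROI", function(object) {
  if (length(object@voxels) < 1L) return("fROI must contain >= 1 voxel")
  if (is.unsorted(object@voxels, strictly = TRUE))
    return("voxel indices must be strictly ascending")
  TRUE
})

#' @describeIn defineFroi fROI voxel indices (1-based linear, ascending)
#' @export
froiVoxels <- function(froi) froi@voxels

#' @describeIn defineFroi number of voxels in the fROI
#' @export
froiSize <- function(froi) length(froi@voxels)

setMethod("show", "FROI", function(object) {
  cat(sprintf("FROI %s: %d / %d voxels (contrast %s, run %s)\n",
              object@parcel, length(object@voxels), object@nParcelVoxels,
              object@definingContrast, object@definingRun))
})
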