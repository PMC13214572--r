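#' fROI definition configuration
#'
#' @param fraction fraction of parcel voxels selected, in (0, 1]; default
#'   0.10 (the conventional "top 10%" rule). The selected count is
#'   \code{max(1, floor(fraction * n))} — floor rounding with a floor of
#'   one voxel.
#' @param parcels parcel names to define fROIs in; defaults to the five
#'   left-hemisphere language parcels (the angular gyrus parcel is excluded
#'   from the default language set).
#' @param tieBreak tie-break rule on equal t-values; "index" = ascending
#'   linear voxel index (deterministic across platforms).
#' @return A list of class \code{FROIConfig}.
#' @export
froiConfig <- function(fraction = 0.10,
                       parcels = c("LIFG", "LIFGorb", "LMFG", "LAntTemp",
                                   "LPostTemp"),
                       tieBreak = "index") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  tieBreak <- match.arg(tieBreak)
  structure(list(fraction = fraction, parcels = parcels,
                 tieBreak = tieBreak), class = "FROIConfig")
}

#' Define a subject-specific fROI within a parcel
#'
#' Selects the top \code{max(1, floor(fraction * n))} voxels of the parcel
#' by t-value (descending), breaking ties by ascending linear voxel index.
#'
#' @param tmap a \linkS4class{ContrastMap} (its t map is used).
#' @param atlas a \linkS4class{ParcelAtlas} on the same grid.
#' @param parcel parcel name.
#' @param config a \code{\link{froiConfig}} list.
#' @return A \linkS4class{FROI}.
#' @export
defineFroi <- function(tmap, atlas, parcel, config = froiConfig()) {
  if (!sameGrid(tmap@grid, atlas@grid))
    stop("t map and atlas must share the grid")
  vox <- parcelVoxels(atlas, parcel)
  if (length(vox) == 0L) stop("atlas error: parcel '", parcel, "' is empty")
  tv <- tmap@t[vox]
  if (all(is.na(tv)))
    stop("data error: no defined t-values in parcel '", parcel, "'")
  k <- max(1L, floor(config$fraction * length(vox)))
  ord <- order(-tv, vox, na.last = TRUE)
  sel <- sort(vox[ord[seq_len(k)]])
  new("FROI", parcel = parcel, voxels = as.integer(sel),
      definingContrast = tmap@name, definingRun = tmap@sourceRun,
      nParcelVoxels = length(vox))
}

#' Mirror an atlas across the mid-sagittal plane
#'
#' Labels are reflected across the grid's x mid-plane (world x -> -x
#' relative to the grid center, through the affine), producing homotopic
#' right-hemisphere counterparts of left-hemisphere parcels. Parcel names
#' have their leading "L"/"R" toggled when present. Mirroring twice
#' returns the original atlas.
#'
#' @param atlas a \linkS4class{ParcelAtlas}. The affine must not mix the x
#'   axis with other axes (axis-aligned reflection), otherwise a geometry
#'   error is raised.
#' @return The mirrored \linkS4class{ParcelAtlas}.
#' @export
mirrorParcels <- function(atlas) {
  aff <- atlas@grid@affine
  if (any(aff[2:3, 1] != 0) || any(aff[1, 2:3] != 0))
    stop("geometry error: affine mixes the x axis with other axes; ",
         "mid-sagittal reflection is undefined")
  nx <- atlas@grid@dim[1]
  atlas@labels <- atlas@labels[rev(seq_len(nx)), , , drop = FALSE]
  flip <- function(nm) {
    first <- substr(nm, 1, 1)
    ifelse(first == "L", sub("^L", "R", nm),
           ifelse(first == "R", sub("^R", "L", nm), nm))
  }
  newNames <- flip(atlas@parcelNames)
  names(newNames) <- names(atlas@parcelNames)
  nets <- atlas@networks
  names(nets) <- flip(names(nets))
  atlas@parcelNames <- newNames
  atlas@networks <- nets
  validObject(atlas)
  atlas
}

#' Serialize fROIs as a TSV of voxel indices
#'
#' One row per voxel with 0-based linear indices and (i, j, k) voxel
#' coordinates (0-based, NIfTI convention), plus the parcel name and
#' defining run/contrast.
#'
#' @param frois a list of \linkS4class{FROI}s (or a single one).
#' @param grid the \linkS4class{VolumeGrid} the indices refer to.
#' @param path output file path.
#' @export
writeFroiTable <- function(frois, grid, path) {
  if (is(frois, "FROI")) frois <- list(frois)
  rows <- lapply(frois, function(fr) {
    ijk <- linearToIjk(froiVoxels(fr), gridDim(grid))
    data.frame(parcel = fr@parcel, voxel_index = froiVoxels(fr) - 1L,
               i = ijk[, 1] - 1L, j = ijk[, 2] - 1L, k = ijk[, 3] - 1L,
               defining_contrast = fr@definingContrast,
               defining_run = fr@definingRun, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Mean effect over a voxel set, for each condition map.
extractMean <- function(effects, voxels) {
  vapply(effects, function(m) mean(effectMap(m)[voxels]), numeric(1))
}

#' Cross-validated condition responses
#'
#' For each parcel, one run's t-map defines the fROI and the held-out
#' run's per-condition effect values are averaged (unweighted mean over
#' fROI voxels); the two folds are averaged into a single value per
#' (fROI, condition). With \code{circular = TRUE}, the fROI is defined and
#' read out on the same run — a deliberately biased estimator kept for
#' demonstrating selection (circularity) bias.
#'
#' @param runs list of exactly two elements, each
#'   \code{list(tmap = <ContrastMap>, effects = <named list of per-condition
#'   ContrastMaps>)}.
#' @param atlas a \linkS4class{ParcelAtlas}.
#' @param config a \code{\link{froiConfig}} list.
#' @param circular define and extract on the same run (default FALSE).
#' @return data.frame with columns \code{froi}, \code{condition},
#'   \code{response}, \code{n_voxels}.
#' @export
crossvalResponse <- function(runs, atlas, config = froiConfig(),
                             circular = FALSE) {
  if (length(runs) != 2L)
    stop("fold error: exactly two runs are required")
  out <- list()
  for (parcel in config$parcels) {
    folds <- lapply(1:2, function(def) {
      extr <- if (circular) def else 3L - def
      froi <- defineFroi(runs[[def]]$tmap, atlas, parcel, config)
      list(vals = extractMean(runs[[extr]]$effects, froiVoxels(froi)),
           n = froiSize(froi))
    })
    conds <- names(runs[[1]]$effects)
    vals <- (folds[[1]]$vals + folds[[2]]$vals) / 2
    out[[parcel]] <- data.frame(
      froi = parcel, condition = conds, response = as.numeric(vals[conds]),
      n_voxels = folds[[1]]$n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
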