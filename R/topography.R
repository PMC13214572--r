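#' Pearson correlation of two maps over a voxel mask
#'
#' @param mapA,mapB \linkS4class{ContrastMap}s on the same grid.
#' @param mask 1-based linear voxel indices (at least 3).
#' @param what correlate the contrast "effect" values (default; t maps
#'   conflate effect size and variance) or the "t" values.
#' @return Pearson r.
#' @export
maskedCorrelation <- function(mapA, mapB, mask, what = c("effect", "t")) {
  what <- match.arg(what)
  if (!sameGrid(mapA@grid, mapB@grid)) stop("maps must share the grid")
  if (length(mask) < 3L) stop("mask must contain at least 3 voxels")
  a <- slot(mapA, what)[mask]
  b <- slot(mapB, what)[mask]
  if (anyNA(a) || anyNA(b)) stop("undefined map values inside the mask")
  if (sd(a) == 0 || sd(b) == 0)
    stop("degenerate correlation: zero variance inside the mask")
  cor(a, b)
}

#' Fisher z-transform of a correlation
#'
#' \code{atanh} of r after clipping to |r| <= 1 - 1e-7, so degenerate
#' (perfect) correlations from noiseless simulations stay finite.
#'
#' @param r correlation value(s), |r| <= 1.
#' @return z value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("domain error: |r| > 1")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Within- and between-version spatial similarity (Fisher z)
#'
#' Within-version similarity correlates the two runs of the same version;
#' between-version similarity averages the Fisher-z values of the four
#' pairwise run combinations across versions. Values are computed per
#' parcel; aggregate them with \code{\link{similarityAggregate}} (the mean
#' over parcels).
#'
#' @param maps nested list: \code{maps[[version]][[run]]} is a
#'   \linkS4class{ContrastMap}; two versions x two runs.
#' @param atlas a \linkS4class{ParcelAtlas}.
#' @param parcels parcel names to restrict to.
#' @param what passed to \code{\link{maskedCorrelation}}.
#' @return data.frame (comparison, parcel, metric, value).
#' @export
versionSimilarity <- function(maps, atlas, parcels, what = "effect") {
  vers <- names(maps)
  if (length(vers) != 2L || !all(lengths(maps) == 2L))
    stop("completeness error: need two versions with two runs each")
  rows <- list()
  for (p in parcels) {
    mask <- parcelVoxels(atlas, p)
    for (v in vers) {
      z <- fisherZ(maskedCorrelation(maps[[v]][[1]], maps[[v]][[2]], mask,
                                     what))
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0("within_", v), parcel = p, metric = "fisher_z",
        value = z, stringsAsFactors = FALSE)
    }
    zb <- mean(vapply(1:2, function(i) {
      mean(vapply(1:2, function(j)
        fisherZ(maskedCorrelation(maps[[vers[1]]][[i]], maps[[vers[2]]][[j]],
                                  mask, what)), numeric(1)))
    }, numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = "between", parcel = p, metric = "fisher_z", value = zb,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-parcel similarity values
#'
#' The aggregate is the exact mean of the per-parcel values for each
#' comparison (and fraction, for Dice results).
#'
#' @param sim data.frame from \code{\link{versionSimilarity}} or
#'   \code{\link{diceProfile}}.
#' @return data.frame with one row per comparison (x fraction).
#' @export
similarityAggregate <- function(sim) {
  keys <- c("comparison", "metric", intersect("fraction", names(sim)))
  agg <- stats::aggregate(sim["value"], sim[keys], mean)
  agg[order(agg$comparison), , drop = FALSE]
}

#' Dice overlap coefficient of two fROIs
#'
#' \code{2 |A intersect B| / (|A| + |B|)}; 1 iff the (equal-sized) sets
#' coincide, 0 iff disjoint.
#'
#' @param froiA,froiB \linkS4class{FROI}s from the same parcel.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(froiA, froiB) {
  if (froiA@parcel != froiB@parcel)
    stop("comparison error: fROIs come from different parcels")
  a <- froiVoxels(froiA)
  b <- froiVoxels(froiB)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Dice overlap within and between versions across fROI size thresholds
#'
#' For each fraction, fROIs are defined per (version, run, parcel) and
#' Dice is computed between the two runs of each version (within) and
#' averaged over the four pairwise between-version run combinations
#' (between), per parcel.
#'
#' @param maps nested list as in \code{\link{versionSimilarity}} (the
#'   defining t-maps).
#' @param atlas a \linkS4class{ParcelAtlas}.
#' @param parcels parcel names.
#' @param fractions fROI size thresholds, e.g. \code{c(0.1, 0.2, 0.3)}.
#' @return data.frame (comparison, parcel, metric, fraction, value).
#' @export
diceProfile <- function(maps, atlas, parcels, fractions = c(0.1, 0.2, 0.3)) {
  vers <- names(maps)
  if (length(vers) != 2L || !all(lengths(maps) == 2L))
    stop("completeness error: need two versions with two runs each")
  rows <- list()
  for (f in fractions) {
    cfg <- froiConfig(fraction = f, parcels = parcels)
    frois <- lapply(maps, function(runs) lapply(runs, function(m)
      lapply(stats::setNames(nm = parcels), function(p)
        defineFroi(m, atlas, p, cfg))))
    for (p in parcels) {
      for (v in vers) {
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = paste0("within_", v), parcel = p, metric = "dice",
          fraction = f, value = dice(frois[[v]][[1]][[p]],
                                     frois[[v]][[2]][[p]]),
          stringsAsFactors = FALSE)
      }
      db <- mean(vapply(1:2, function(i) mean(vapply(1:2, function(j)
        dice(frois[[vers[1]]][[i]][[p]], frois[[vers[2]]][[j]][[p]]),
        numeric(1))), numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "between", parcel = p, metric = "dice", fraction = f,
        value = db, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
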