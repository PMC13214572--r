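#' Experiment configuration
#'
#' Bundles every parameter of the simulated localizer-comparison
#' experiment. The defaults are the reference study conditions: 24
#' subjects, two versions (standard, speeded) x two runs, TR 2 s, the
#' default 24^3 atlas, 1% AR(0.2) noise with 0.5% drift, 4 mm subject
#' topographic jitter with a 1.5 mm version-specific displacement, 20%
#' selective voxels, top-10% fROIs in the five language parcels, and the
#' 128 s high-pass / AR(0.2)-prewhitened GLM with 4 mm smoothing.
#'
#' @param nSubjects number of simulated subjects.
#' @param seed master seed; every stage draws from named substreams of it.
#' @param atlas a \linkS4class{ParcelAtlas}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param amplitudes nested amplitude list (see
#'   \code{\link{defaultAmplitudes}}).
#' @param froi a \code{\link{froiConfig}} list.
#' @param glm a \code{\link{glmOptions}} list.
#' @param tr repetition time in seconds.
#' @param jitterSdMm,versionJitterMm,selectiveFraction ground-truth
#'   topography parameters (see \code{\link{makeSubjectTruth}}).
#' @param includeWM simulate and analyse the spatial working-memory task.
#' @return A list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(nSubjects = 24, seed = 1L,
                             atlas = defaultAtlas(), noise = noiseSpec(),
                             amplitudes = defaultAmplitudes(),
                             froi = froiConfig(), glm = glmOptions(),
                             tr = 2, jitterSdMm = 4, versionJitterMm = 1.5,
                             selectiveFraction = 0.2, includeWM = TRUE) {
  conds <- unlist(lapply(amplitudes, function(net) lapply(net, names)))
  if (!all(conds %in% knownConditions))
    stop("config error: unknown condition(s) in amplitudes")
  structure(list(nSubjects = as.integer(nSubjects), seed = as.integer(seed),
                 atlas = atlas, noise = noise, amplitudes = amplitudes,
                 froi = froi, glm = glm, tr = tr, jitterSdMm = jitterSdMm,
                 versionJitterMm = versionJitterMm,
                 selectiveFraction = selectiveFraction,
                 includeWM = includeWM), class = "ExperimentConfig")
}

# Simulate, smooth and fit one run; returns the defining contrast map and
# per-condition effect maps, restricted to the given voxel mask.
analyzeRun <- function(truth, schedule, config, runLabel, seed, mask) {
  img <- simulateBold(truth, schedule, noise = config$noise, tr = config$tr,
                      seed = seed, hrfParams = config$glm$hrfParams)
  img <- gaussianSmooth(img, config$glm$smoothingFwhm)
  X <- buildDesignMatrix(schedule, nScans(img), config$tr, config$glm)
  fit <- fitGlm(img, X, config$glm, mask = mask)
  conds <- schedule@version@conditions
  w <- stats::setNames(c(1, -1), conds)
  list(
    tmap = contrast(fit, w, name = paste0(conds[1], "_gt_", conds[2]),
                    sourceRun = runLabel),
    effects = lapply(stats::setNames(nm = conds), function(cnd)
      contrast(fit, stats::setNames(1, cnd), name = cnd,
               sourceRun = runLabel)))
}

#' Run the full simulated localizer-comparison experiment
#'
#' For each subject: simulate two runs of each localizer version (and,
#' optionally, the working-memory task) from a ground-truth subject,
#' fit the per-run prewhitened GLM, define cross-validated fROIs and
#' extract condition responses, and compute within/between-version
#' Fisher-z map correlations and Dice overlap profiles. Then fit the
#' group-level mixed models: condition + version (response magnitudes),
#' the condition-by-version interaction LRT, the contrast-size version
#' comparison, and the within-vs-between similarity comparison.
#' Deterministic given \code{config$seed}.
#'
#' @param config an \code{\link{experimentConfig}} list.
#' @param tasks which task families to run: subset of
#'   \code{c("language", "wm")}.
#' @return A list of class \code{ReportBundle}: \code{responses} (language
#'   response table), \code{wmResponses} (if run), \code{similarity},
#'   \code{dice}, \code{models} (list of group-level results),
#'   \code{provenance}.
#' @export
runExperiment <- function(config, tasks = c("language", "wm")) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (!config$includeWM) tasks <- setdiff(tasks, "wm")
  # work on the parcel bounding box plus the smoothing-kernel support:
  # every analysed voxel keeps its full smoothing neighbourhood, so the
  # restriction does not change any analysed value
  margin <- 0L
  if (!is.null(config$glm$smoothingFwhm) && config$glm$smoothingFwhm > 0) {
    sigmaVox <- config$glm$smoothingFwhm / (2 * sqrt(2 * log(2))) /
      voxelSize(config$atlas@grid)
    margin <- max(1L, ceiling(3 * sigmaVox))
  }
  atlas <- cropAtlas(config$atlas, margin)
  languageParcels <- config$froi$parcels
  mdParcels <- names(parcelNetworks(atlas))[parcelNetworks(atlas) == "MD"]
  allMask <- sort(unlist(lapply(parcelNames(atlas), parcelVoxels,
                                atlas = atlas)))
  materials <- generatePlaceholderMaterials(subSeed(config$seed,
                                                    "materials"))
  responses <- list(); simRows <- list(); diceRows <- list()
  wmResponses <- list()

  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("sub%02d", s)
    subjectSeed <- subSeed(config$seed, "subject", sid)
    truth <- makeSubjectTruth(atlas, config$amplitudes,
                              config$selectiveFraction, config$jitterSdMm,
                              config$versionJitterMm, seed = subjectSeed,
                              subjectId = sid)
    maps <- list()
    for (ver in c("standard", "speeded")) {
      v <- taskVersion(ver)
      orders <- counterbalanceOrders(v@nExpBlocks, v@conditions,
                                     seed = subSeed(config$seed, "order",
                                                    sid, ver))
      maps[[ver]] <- lapply(1:2, function(run) {
        sched <- buildRunSchedule(v, run, orders[[paste0("run", run)]],
                                  materials, subjectSeed = subjectSeed)
        analyzeRun(truth, sched, config, paste(sid, ver, run, sep = "_"),
                   seed = subSeed(config$seed, "noise", sid, ver, run),
                   mask = allMask)
      })
      rt <- crossvalResponse(maps[[ver]], atlas, config$froi)
      rt$subject <- sid; rt$version <- ver
      responses[[paste(sid, ver)]] <- rt
    }
    tmaps <- lapply(maps, function(runs) lapply(runs, `[[`, "tmap"))
    sim <- versionSimilarity(tmaps, atlas, languageParcels)
    sim$subject <- sid
    simRows[[sid]] <- sim
    dp <- diceProfile(tmaps, atlas, languageParcels)
    dp$subject <- sid
    diceRows[[sid]] <- dp

    if ("wm" %in% tasks) {
      wmMaps <- lapply(1:2, function(run) {
        sched <- buildWMRunSchedule(run, seed = subSeed(config$seed,
                                                        "wmorder", sid))
        analyzeRun(truth, sched, config, paste(sid, "wm", run, sep = "_"),
                   seed = subSeed(config$seed, "noise", sid, "wm", run),
                   mask = allMask)
      })
      # hard/easy responses in MD fROIs, cross-validated across WM runs
      mdCfg <- froiConfig(fraction = config$froi$fraction,
                          parcels = mdParcels)
      wmRt <- crossvalResponse(wmMaps, atlas, mdCfg)
      wmRt$subject <- sid; wmRt$version <- "spatialWM"
      wmRt$network <- "MD"
      wmResponses[[paste(sid, "md")]] <- wmRt
      # language-condition responses in WM-defined MD fROIs: the defining
      # task is independent of the read-out task, so average both WM-run
      # definitions and both language runs
      for (p in mdParcels) {
        frois <- lapply(wmMaps, function(m)
          defineFroi(m$tmap, atlas, p, mdCfg))
        for (ver in c("standard", "speeded")) {
          vals <- Reduce(`+`, lapply(frois, function(fr)
            Reduce(`+`, lapply(maps[[ver]], function(run)
              extractMean(run$effects, froiVoxels(fr)))) / 2)) / 2
          wmResponses[[paste(sid, p, ver)]] <- data.frame(
            froi = p, condition = names(vals), response = as.numeric(vals),
            n_voxels = froiSize(frois[[1]]), subject = sid, version = ver,
            network = "MD", stringsAsFactors = FALSE)
        }
      }
    }
  }

  responses <- do.call(rbind, responses)
  rownames(responses) <- NULL
  responses$condition <- factor(responses$condition,
                                levels = c("nonwords", "sentences"))
  responses$version <- factor(responses$version,
                              levels = c("standard", "speeded"))
  similarity <- do.call(rbind, simRows); rownames(similarity) <- NULL
  diceTab <- do.call(rbind, diceRows); rownames(diceTab) <- NULL

  models <- list(
    condVersion = fitLmm(responses,
                         response ~ condition + version + (1 | subject) +
                           (1 | froi)),
    interaction = lrtInteraction(responses,
                                 response ~ condition * version +
                                   (1 | subject) + (1 | froi),
                                 response ~ condition + version +
                                   (1 | subject) + (1 | froi)))
  # sentences - nonwords contrast size per subject x froi x version
  wide <- merge(responses[responses$condition == "sentences", ],
                responses[responses$condition == "nonwords", ],
                by = c("subject", "froi", "version"),
                suffixes = c("_s", "_n"))
  wide$delta <- wide$response_s - wide$response_n
  models$contrastByVersion <- fitLmm(wide, delta ~ version + (1 | subject) +
                                       (1 | froi))
  # within vs between similarity (mean of the two within values per
  # subject x parcel against the between value)
  wb <- do.call(rbind, lapply(split(similarity,
                                    similarity[c("subject", "parcel")]),
                              function(d) data.frame(
    subject = d$subject[1], parcel = d$parcel[1],
    comparison = c("within", "between"),
    value = c(mean(d$value[startsWith(d$comparison, "within")]),
              d$value[d$comparison == "between"]),
    stringsAsFactors = FALSE)))
  wb$comparison <- factor(wb$comparison, levels = c("between", "within"))
  models$withinVsBetween <- fitLmm(wb, value ~ comparison + (1 | subject) +
                                     (1 | parcel))

  bundle <- list(responses = responses,
                 wmResponses = if (length(wmResponses))
                   do.call(rbind, c(wmResponses,
                                    list(make.row.names = FALSE))) else NULL,
                 similarity = similarity, dice = diceTab,
                 withinBetween = wb, models = models,
                 provenance = list(seed = config$seed,
                                   nSubjects = config$nSubjects,
                                   configDigest = configDigest(config),
                                   package = "froikit"))
  class(bundle) <- "ReportBundle"
  bundle
}

# Deterministic digest of a config: polynomial hash over its serialization.
configDigest <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  m <- 2147483647
  h <- 0
  for (chunk in split(as.integer(raw),
                      ceiling(seq_along(raw) / 4096))) {
    h <- (h * 31 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %% m
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat(sprintf("ReportBundle: %d subjects (seed %d, config %s)\n",
              x$provenance$nSubjects, x$provenance$seed,
              x$provenance$configDigest))
  agg <- similarityAggregate(x$similarity)
  cat("Fisher-z similarity (mean over parcels & subjects):\n")
  print(stats::aggregate(value ~ comparison, agg, mean), row.names = FALSE)
  cat("Condition + version model:\n")
  print(x$models$condVersion$coefficients, digits = 4)
  print(x$models$interaction)
  invisible(x)
}

#' Write the report tables of an experiment as TSV files
#'
#' @param bundle a \code{ReportBundle}.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writeTables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$responses, "responses.tsv")
  wt(bundle$similarity, "similarity.tsv")
  wt(bundle$dice, "dice.tsv")
  if (!is.null(bundle$wmResponses)) wt(bundle$wmResponses,
                                       "wm_responses.tsv")
  wt(bundle$models$condVersion$coefficients, "lmm_cond_version.tsv")
  writeLines(c(sprintf("seed\t%d", bundle$provenance$seed),
               sprintf("config\t%s", bundle$provenance$configDigest),
               sprintf("interaction_chisq\t%.6f",
                       bundle$models$interaction$chisq),
               sprintf("interaction_p\t%.6g",
                       bundle$models$interaction$p)),
             file.path(dir, "provenance.tsv"))
  invisible(dir)
}

# ---------------------------------------------------------------------------
# NIfTI I/O
# ---------------------------------------------------------------------------

#' Read and write volumes as NIfTI-1
#'
#' 4D BOLD volumes are stored as 32-bit float with the affine in the
#' sform/qform and the repetition time in the 4th pixdim; label volumes
#' as 16-bit integers. Round-trips preserve data (to float32 rounding),
#' affine and TR.
#'
#' @param img a \linkS4class{TimeSeriesImage}.
#' @param path file path (.nii or .nii.gz).
#' @return \code{readVolume} returns a \linkS4class{TimeSeriesImage}.
#' @export
writeVolume <- function(img, path) {
  ni <- RNifti::asNifti(img@data)
  RNifti::qform(ni) <- structure(img@grid@affine, code = 2L)
  RNifti::sform(ni) <- structure(img@grid@affine, code = 2L)
  RNifti::pixdim(ni) <- c(rep(img@grid@voxelSize, 3), img@tr)
  RNifti::pixunits(ni) <- c("mm", "s")
  RNifti::writeNifti(ni, path, datatype = "float")
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  ni <- RNifti::readNifti(path)
  d <- dim(ni)
  if (length(d) != 4L) stop("format error: expected a 4D NIfTI volume")
  aff <- structure(RNifti::xform(ni), class = NULL)
  vs <- RNifti::pixdim(ni)
  grid <- new("VolumeGrid", dim = as.integer(d[1:3]),
              voxelSize = as.numeric(vs[1]),
              affine = matrix(as.numeric(aff), 4, 4))
  new("TimeSeriesImage", grid = grid, data = array(as.numeric(ni), dim = d),
      tr = as.numeric(vs[4]))
}

#' @rdname writeVolume
#' @param atlas a \linkS4class{ParcelAtlas} (written as int16 labels).
#' @export
writeAtlasVolume <- function(atlas, path) {
  ni <- RNifti::asNifti(atlas@labels)
  RNifti::qform(ni) <- structure(atlas@grid@affine, code = 2L)
  RNifti::sform(ni) <- structure(atlas@grid@affine, code = 2L)
  RNifti::pixdim(ni) <- rep(atlas@grid@voxelSize, 3)
  RNifti::writeNifti(ni, path, datatype = "int16")
  invisible(path)
}

#' @rdname writeVolume
#' @param map a \linkS4class{ContrastMap}; its effect and t volumes are
#'   written as \code{<prefix>_effect.nii.gz} and \code{<prefix>_t.nii.gz}.
#' @param prefix output path prefix.
#' @export
writeContrastMap <- function(map, prefix) {
  for (part in c("effect", "t")) {
    ni <- RNifti::asNifti(slot(map, part))
    RNifti::qform(ni) <- structure(map@grid@affine, code = 2L)
    RNifti::sform(ni) <- structure(map@grid@affine, code = 2L)
    RNifti::pixdim(ni) <- rep(map@grid@voxelSize, 3)
    RNifti::writeNifti(ni, paste0(prefix, "_", part, ".nii.gz"),
                       datatype = "float")
  }
  invisible(prefix)
}
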