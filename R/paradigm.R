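#' Construct a task version with its shipped timing parameters
#'
#' The defaults reproduce the blocked designs exactly: the standard reading
#' localizer presents 12 words/nonwords at 450 ms each, each stimulus
#' preceded by a 100 ms blank and followed by a 400 ms button-press cue and
#' a final 100 ms blank (6 s trials, 18 s blocks of 3 trials, 16
#' experimental + 5 fixation blocks of 14 s, 358 s per run); the speeded
#' version presents each word for 200 ms (3 s trials, 9 s blocks, 214 s per
#' run); the spatial working-memory task has 8 s trials, 32 s blocks of 4
#' trials, and 12 experimental + 4 fixation blocks of 16 s (448 s per run).
#'
#' @param name "standard", "speeded" or "spatialWM".
#' @return A \linkS4class{TaskVersion}.
#' @examples
#' taskVersion("standard")
#' @export
taskVersion <- function(name = c("standard", "speeded", "spatialWM")) {
  name <- match.arg(name)
  switch(name,
    standard = new("TaskVersion", name = "standard", wordDuration = 0.45,
                   trialDuration = 6, blockDuration = 18,
                   fixationDuration = 14, nExpBlocks = 16L, nFixBlocks = 5L,
                   trialsPerBlock = 3L,
                   conditions = c("sentences", "nonwords")),
    speeded = new("TaskVersion", name = "speeded", wordDuration = 0.2,
                  trialDuration = 3, blockDuration = 9,
                  fixationDuration = 14, nExpBlocks = 16L, nFixBlocks = 5L,
                  trialsPerBlock = 3L,
                  conditions = c("sentences", "nonwords")),
    spatialWM = new("TaskVersion", name = "spatialWM",
                    wordDuration = NA_real_, trialDuration = 8,
                    blockDuration = 32, fixationDuration = 16,
                    nExpBlocks = 12L, nFixBlocks = 4L, trialsPerBlock = 4L,
                    conditions = c("hard", "easy")))
}

#' Within-trial event breakdown of one localizer trial
#'
#' A reading-localizer trial is a 100 ms blank screen, 12 words/nonwords at
#' the version's presentation rate, a 400 ms button-press cue, and a final
#' 100 ms blank — 15 contiguous events.
#'
#' @param version a reading-localizer \linkS4class{TaskVersion} ("standard"
#'   or "speeded").
#' @param stimulus a 12-token string (whitespace-separated).
#' @return data.frame with columns \code{onset}, \code{duration} (seconds,
#'   trial-relative), \code{part} ("blank", "word", "cue") and \code{token}.
#' @examples
#' tr <- buildLocalizerTrial(taskVersion("standard"),
#'                           paste(letters[1:12], collapse = " "))
#' sum(tr$duration)  # 6
#' @export
buildLocalizerTrial <- function(version, stimulus) {
  if (!version@name %in% c("standard", "speeded"))
    stop("trial structure is defined for the reading localizer versions only")
  tokens <- strsplit(trimws(stimulus), "[[:space:]]+")[[1]]
  if (length(tokens) != 12L)
    stop("invalid stimulus: expected 12 tokens, got ", length(tokens))
  durs <- c(0.1, rep(version@wordDuration, 12L), 0.4, 0.1)
  data.frame(
    onset = cumsum(c(0, durs[-length(durs)])),
    duration = durs,
    part = c("blank", rep("word", 12L), "cue", "blank"),
    token = c(NA, tokens, NA, NA),
    stringsAsFactors = FALSE)
}

#' Counterbalanced condition orders for two runs
#'
#' Run 1 is a seeded balanced pseudo-random order; under the default
#' "reverse" scheme run 2 is run 1 reversed, which cancels linear
#' time-in-run confounds across the two runs.
#'
#' @param nBlocks number of experimental blocks (even).
#' @param conditions the two condition names.
#' @param scheme counterbalancing scheme; only "reverse" is defined.
#' @param seed integer seed for the run-1 order.
#' @return list with elements \code{run1} and \code{run2}.
#' @export
counterbalanceOrders <- function(nBlocks, conditions, scheme = "reverse",
                                 seed = 1L) {
  scheme <- match.arg(scheme)
  if (nBlocks %% length(conditions) != 0L || nBlocks %% 2L != 0L)
    stop("balance error: nBlocks must split evenly across conditions")
  base <- rep(conditions, each = nBlocks / length(conditions))
  run1 <- withSeed(subSeed(seed, "counterbalance"), sample(base))
  list(run1 = run1, run2 = rev(run1))
}

#' Deterministic placeholder stimulus materials
#'
#' Generates 5 material sets of 48 sentence and 48 nonword-sequence items
#' (240 per condition overall), each item 12 pronounceable pseudo-tokens.
#' The texts are opaque stand-ins: only timing and condition labels enter
#' the analysis, so no linguistic structure is modelled.
#'
#' @param seed integer seed; identical seeds give byte-identical materials.
#' @return A \linkS4class{StimulusMaterials}.
#' @export
generatePlaceholderMaterials <- function(seed = 1L) {
  syll <- as.vector(outer(c("ba", "do", "ki", "lu", "me", "na", "po", "ri",
                            "se", "tu", "va", "zo"),
                          c("", "n", "s", "l"), paste0))
  items <- withSeed(subSeed(seed, "materials"), {
    do.call(rbind, lapply(1:5, function(set) {
      do.call(rbind, lapply(c("sentences", "nonwords"), function(cond) {
        data.frame(
          set = set, condition = cond,
          item_id = sprintf("set%d_%s_%02d", set, substr(cond, 1, 4), 1:48),
          text = vapply(1:48, function(i) {
            paste(vapply(1:12, function(j)
              paste(sample(syll, sample(2:3, 1), replace = TRUE),
                    collapse = ""), character(1)), collapse = " ")
          }, character(1)),
          stringsAsFactors = FALSE)
      }))
    }))
  })
  new("StimulusMaterials", items = items)
}

# Distribute nExp experimental blocks into the gaps between nFix fixation
# blocks (one fixation at run start, one at run end, the rest as evenly
# spaced as possible): returns the group sizes between consecutive fixations.
fixationGrouping <- function(nExp, nFix) {
  ngroups <- nFix - 1L
  if (ngroups < 1L) stop("need at least two fixation blocks")
  base <- nExp %/% ngroups
  extra <- nExp %% ngroups
  sizes <- rep(base, ngroups)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Shared blocked-schedule builder. stimuliByCondition: NULL, or a named list
# of per-condition data.frames with columns item_id (consumed in order).
buildBlockedSchedule <- function(version, runIndex, conditionOrder,
                                 stimuliByCondition = NULL) {
  if (length(conditionOrder) != version@nExpBlocks)
    stop("balance error: condition order must have ", version@nExpBlocks,
         " entries")
  tab <- table(factor(conditionOrder, levels = version@conditions))
  if (any(is.na(match(conditionOrder, version@conditions))))
    stop("unknown condition in condition order")
  if (length(unique(tab)) != 1L)
    stop("balance error: conditions must occupy equally many blocks")
  sizes <- fixationGrouping(version@nExpBlocks, version@nFixBlocks)

  # lay out the block sequence, then expand to per-event vectors
  blockCond <- character(0)
  expBlock <- 0L
  for (g in seq_along(sizes)) {
    blockCond <- c(blockCond, "fixation",
                   conditionOrder[expBlock + seq_len(sizes[g])])
    expBlock <- expBlock + sizes[g]
  }
  blockCond <- c(blockCond, "fixation")
  isFix <- blockCond == "fixation"
  nEv <- ifelse(isFix, 1L, version@trialsPerBlock)
  cond <- rep(blockCond, nEv)
  blockIdx <- rep(seq_along(blockCond) - 1L, nEv)
  trialIdx <- unlist(lapply(nEv, function(k)
    if (k == 1L) NA_integer_ else seq_len(k) - 1L), use.names = FALSE)
  trialIdx[rep(isFix, nEv)] <- NA_integer_
  dur <- ifelse(cond == "fixation", version@fixationDuration,
                version@trialDuration)
  onset <- cumsum(c(0, dur[-length(dur)]))

  stimId <- rep(NA_character_, length(cond))
  if (!is.null(stimuliByCondition)) {
    for (cnd in version@conditions) {
      at <- which(cond == cnd)
      pool <- stimuliByCondition[[cnd]]
      if (length(at) > nrow(pool))
        stop("stimulus exhaustion: no unused '", cnd, "' items left")
      stimId[at] <- pool$item_id[seq_along(at)]
    }
  }
  events <- data.frame(onset = onset, duration = dur, condition = cond,
                       block_index = blockIdx, trial_index = trialIdx,
                       stimulus_id = stimId, stringsAsFactors = FALSE)
  new("RunSchedule", version = version, runIndex = as.integer(runIndex),
      events = events, totalDuration = sum(dur))
}

#' Build one run of a reading localizer
#'
#' Lays out fixation and experimental blocks (one fixation at run start and
#' end, the rest spaced as evenly as possible between block groups) and
#' assigns stimuli deterministically: each subject draws from a single
#' material set, without item repetition across that subject's two runs of
#' the same version.
#'
#' @param version a reading-localizer \linkS4class{TaskVersion}.
#' @param runIndex 1 or 2.
#' @param conditionOrder condition name per experimental block (balanced).
#' @param materials a \linkS4class{StimulusMaterials}.
#' @param subjectSeed integer; determines the subject's material set and
#'   item order (shared across the subject's runs).
#' @return A \linkS4class{RunSchedule}; e.g. 358 s total for the standard
#'   version, 214 s for the speeded version.
#' @export
buildRunSchedule <- function(version, runIndex, conditionOrder, materials,
                             subjectSeed = 1L) {
  if (!version@name %in% c("standard", "speeded"))
    stop("use buildWMRunSchedule for the spatial working-memory task")
  if (!runIndex %in% 1:2) stop("runIndex must be 1 or 2")
  # trial duration derives from the within-trial event breakdown
  probe <- buildLocalizerTrial(version, paste(rep("x", 12), collapse = " "))
  stopifnot(abs(sum(probe$duration) - version@trialDuration) < 1e-9)

  it <- materials@items
  setId <- subSeed(subjectSeed, "materials-set") %% length(unique(it$set)) + 1L
  perRun <- version@nExpBlocks / 2L * version@trialsPerBlock
  stim <- lapply(stats::setNames(nm = version@conditions), function(cond) {
    pool <- it[it$set == setId & it$condition == cond, , drop = FALSE]
    ord <- withSeed(subSeed(subjectSeed, "materials-order", version@name,
                            cond), sample(nrow(pool)))
    pool <- pool[ord, , drop = FALSE]
    lo <- (runIndex - 1L) * perRun + 1L
    hi <- runIndex * perRun
    if (hi > nrow(pool))
      stop("stimulus exhaustion: set has too few '", cond, "' items")
    pool[lo:hi, , drop = FALSE]
  })
  buildBlockedSchedule(version, runIndex, conditionOrder, stim)
}

#' Build one run of the spatial working-memory task
#'
#' Trials are modelled as fixed 8 s events (the internal fixation cross,
#' location flashes, choice and feedback are collapsed because the GLM
#' models whole blocks, not sub-trial events).
#'
#' @param runIndex 1 or 2.
#' @param conditionOrder condition ("hard"/"easy") per experimental block;
#'   default is a counterbalanced order derived from \code{seed}.
#' @param seed seed for the default condition order.
#' @return A \linkS4class{RunSchedule} of 448 s.
#' @export
buildWMRunSchedule <- function(runIndex, conditionOrder = NULL, seed = 1L) {
  version <- taskVersion("spatialWM")
  if (is.null(conditionOrder)) {
    orders <- counterbalanceOrders(version@nExpBlocks, version@conditions,
                                   seed = seed)
    conditionOrder <- orders[[paste0("run", runIndex)]]
  }
  buildBlockedSchedule(version, runIndex, conditionOrder)
}

#' Write / read run events as tab-separated files
#'
#' The dialect is BIDS-events-compatible: columns \code{onset} and
#' \code{duration} in seconds (0 at run start, period decimal separator),
#' \code{trial_type}, \code{stimulus_id}, plus \code{block_index} and
#' \code{trial_index} bookkeeping columns.
#'
#' @param schedule a \linkS4class{RunSchedule}.
#' @param path file path.
#' @return \code{readEvents} returns the validated events data.frame.
#' @export
writeEvents <- function(schedule, path) {
  ev <- schedule@events
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$condition, stimulus_id = ev$stimulus_id,
                    block_index = ev$block_index,
                    trial_index = ev$trial_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("format error: events file needs columns ",
         paste(need, collapse = ", "))
  if (any(ev$duration <= 0))
    stop("unit error: nonpositive durations in rows ",
         paste(which(ev$duration <= 0), collapse = ", "),
         " (are onsets/durations in seconds?)")
  if (is.unsorted(ev$onset))
    stop("events must be sorted by onset")
  ends <- ev$onset + ev$duration
  bad <- which(ev$onset[-1L] < ends[-nrow(ev)] - 1e-9)
  if (length(bad))
    stop("overlapping events at rows ",
         paste(bad + 1L, collapse = ", "))
  ev
}
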