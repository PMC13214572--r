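# Shared fixtures and independent oracles, all built in code.

# --- small atlases -------------------------------------------------------

# one spherical 123-voxel "language" parcel on a 10^3 grid
smallAtlas <- function() {
  spec <- data.frame(name = "P1", x = 5, y = 5, z = 5, radius = 3,
                     network = "language", stringsAsFactors = FALSE)
  makeAtlas(volumeGrid(c(10L, 10L, 10L), voxelSize = 2), spec)
}

# two small spherical "language" parcels on a 12^3 grid (for models that
# need more than one fROI level)
smallAtlasPair <- function() {
  spec <- data.frame(name = c("P1", "P2"), x = c(4, 9), y = c(4, 9),
                     z = c(4, 9), radius = 2,
                     network = "language", stringsAsFactors = FALSE)
  makeAtlas(volumeGrid(c(12L, 12L, 12L), voxelSize = 2), spec)
}

# parcel made of the first n voxels (linear order) of a 10^3 grid
lineParcelAtlas <- function(n, name = "P1") {
  grid <- volumeGrid(c(10L, 10L, 10L), voxelSize = 2)
  labels <- array(0L, dim = gridDim(grid))
  labels[seq_len(n)] <- 1L
  new("ParcelAtlas", grid = grid, labels = labels,
      parcelNames = c("1" = name),
      networks = stats::setNames("language", name))
}

# a ContrastMap with given full-grid t (and optionally effect) values
mapFromValues <- function(grid, tvals, effvals = tvals, name = "toy",
                          sourceRun = "r1") {
  new("ContrastMap", grid = grid,
      effect = array(effvals, dim = gridDim(grid)),
      t = array(tvals, dim = gridDim(grid)), name = name,
      sourceRun = sourceRun)
}

# --- schedules -----------------------------------------------------------

stdMaterials <- generatePlaceholderMaterials(42)

makeSched <- function(version = "standard", run = 1, subjectSeed = 7,
                      orderSeed = 3) {
  v <- taskVersion(version)
  o <- counterbalanceOrders(v@nExpBlocks, v@conditions, seed = orderSeed)
  buildRunSchedule(v, run, o[[paste0("run", run)]], stdMaterials,
                   subjectSeed = subjectSeed)
}

# --- GLS oracle ----------------------------------------------------------

# dense generalized-least-squares fit under the stationary AR(1)
# correlation matrix rho^|i-j|; independent of the package's whitening path
glsOracle <- function(X, y, rho) {
  n <- nrow(X)
  R <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  Ri <- solve(R)
  XtRiX <- t(X) %*% Ri %*% X
  beta <- solve(XtRiX, t(X) %*% Ri %*% y)
  r <- y - X %*% beta
  sigma2 <- as.numeric(t(r) %*% Ri %*% r) / (n - ncol(X))
  se <- sqrt(sigma2 * diag(solve(XtRiX)))
  list(beta = as.numeric(beta), t = as.numeric(beta) / se)
}

# wrap a bare matrix as a DesignMatrix whose first columns are conditions
makeToyDesign <- function(X, condNames, tr = 2) {
  colnames(X) <- c(condNames,
                   rep("x", ncol(X) - length(condNames) - 1), "constant")
  colnames(X) <- make.unique(colnames(X))
  new("DesignMatrix", values = X,
      conditionCols = stats::setNames(seq_along(condNames), condNames),
      derivCols = integer(0), driftCols = integer(0),
      constantCol = ncol(X), nuisanceCols = integer(0), tr = tr)
}

# wrap an n x nvox data matrix as a TimeSeriesImage on an (nvox,1,1) grid
toyImage <- function(Y, tr = 2) {
  nvox <- ncol(Y)
  grid <- volumeGrid(c(nvox, 1L, 1L), voxelSize = 2)
  new("TimeSeriesImage", grid = grid,
      data = array(t(Y), dim = c(nvox, 1L, 1L, nrow(Y))), tr = tr)
}

# --- truths --------------------------------------------------------------

nullAmplitudes <- function() {
  list(language = list(standard = c(sentences = 0, nonwords = 0),
                       speeded = c(sentences = 0, nonwords = 0)))
}

languageOnlyAmplitudes <- function() {
  amps <- defaultAmplitudes()
  amps["MD"] <- NULL
  amps
}

# simulate + fit one localizer run on a small atlas, no smoothing;
# returns list(tmap=, effects=) for crossvalResponse
quickRun <- function(truth, sched, seed, noise = noiseSpec(),
                     opts = glmOptions(smoothingFwhm = 0), mask = NULL) {
  img <- simulateBold(truth, sched, noise = noise, seed = seed)
  X <- buildDesignMatrix(sched, nScans(img), repTime(img), opts)
  fit <- fitGlm(img, X, opts, mask = mask)
  conds <- sched@version@conditions
  w <- stats::setNames(c(1, -1), conds)
  list(tmap = contrast(fit, w, name = "def",
                       sourceRun = as.character(sched@runIndex)),
       effects = lapply(stats::setNames(nm = conds), function(cnd)
         contrast(fit, stats::setNames(1, cnd), name = cnd)))
}

# --- group-level simulation ---------------------------------------------

# long-format response table from the two-crossed-random-intercepts model
simulateResponseData <- function(nSubj = 24, nFroi = 5, beta0 = 1,
                                 betaCond = 1.5, betaVer = 0,
                                 betaInter = 0, sdSubj = 0.5, sdFroi = 0.3,
                                 sdResid = 0.4, versions = c("standard",
                                                             "speeded")) {
  d <- expand.grid(subject = sprintf("s%02d", seq_len(nSubj)),
                   froi = sprintf("f%d", seq_len(nFroi)),
                   condition = c("nonwords", "sentences"),
                   version = versions, stringsAsFactors = FALSE)
  bS <- stats::setNames(rnorm(nSubj, sd = sdSubj), unique(d$subject))
  bF <- stats::setNames(rnorm(nFroi, sd = sdFroi), unique(d$froi))
  isS <- as.numeric(d$condition == "sentences")
  isV <- as.numeric(d$version == "speeded")
  d$response <- beta0 + betaCond * isS + betaVer * isV +
    betaInter * isS * isV + bS[d$subject] + bF[d$froi] +
    rnorm(nrow(d), sd = sdResid)
  d$condition <- factor(d$condition, levels = c("nonwords", "sentences"))
  d$version <- factor(d$version, levels = c("standard", "speeded"))
  d
}
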