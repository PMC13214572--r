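#' Canonical double-gamma haemodynamic response function
#'
#' The kernel is the difference of two gamma densities (response peak minus
#' a scaled undershoot), sampled on [0, length] at \code{dt} and normalized
#' to peak height 1. Defaults are the de facto canonical parameterization:
#' peak delay 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot
#' ratio 6, 32 s kernel.
#'
#' @param dt sampling step in seconds.
#' @param peakDelay,undershootDelay gamma delays (s).
#' @param peakDisp,undershootDisp gamma dispersions (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length kernel length in seconds.
#' @return Numeric vector of kernel values at \code{seq(0, length, by = dt)}.
#' @export
canonicalHrf <- function(dt, peakDelay = 6, undershootDelay = 16,
                         peakDisp = 1, undershootDisp = 1, ratio = 6,
                         length = 32) {
  if (dt <= 0) stop("dt must be positive")
  if (peakDisp <= 0 || undershootDisp <= 0)
    stop("parameter error: dispersions must be positive")
  t <- seq(0, length, by = dt)
  h <- dgamma(t, shape = peakDelay / peakDisp, scale = peakDisp) -
    dgamma(t, shape = undershootDelay / undershootDisp,
           scale = undershootDisp) / ratio
  h / max(h)
}

#' First-level GLM options
#'
#' @param highpassCutoff high-pass cutoff period in seconds; the
#'   discrete-cosine drift basis spans all fluctuations slower than this.
#' @param arCoef fixed AR(1) prewhitening coefficient.
#' @param includeDerivatives add a temporal derivative per condition.
#' @param oversampleDt boxcar/HRF oversampling step in seconds.
#' @param smoothingFwhm spatial smoothing FWHM in mm (NULL or 0 for none).
#' @param scaling "percent" divides each voxel by its temporal mean and
#'   multiplies by 100 before fitting, so betas read as percent signal
#'   change; "none" fits raw values (useful for oracle comparisons).
#' @param hrfParams list of overrides for \code{\link{canonicalHrf}}.
#' @return A list of class \code{GLMOptions}.
#' @export
glmOptions <- function(highpassCutoff = 128, arCoef = 0.2,
                       includeDerivatives = TRUE, oversampleDt = 0.1,
                       smoothingFwhm = 4, scaling = c("percent", "none"),
                       hrfParams = list()) {
  if (abs(arCoef) >= 1) stop("|arCoef| must be < 1")
  structure(list(highpassCutoff = highpassCutoff, arCoef = arCoef,
                 includeDerivatives = includeDerivatives,
                 oversampleDt = oversampleDt, smoothingFwhm = smoothingFwhm,
                 scaling = match.arg(scaling), hrfParams = hrfParams),
            class = "GLMOptions")
}

# Condition regressors shared by the simulator and the design matrix:
# per condition, a unit boxcar at dt resolution convolved with the
# peak-normalized HRF, area-normalized (divided by sum(h)) so a sustained
# block plateaus at height ~1, then sampled at scan times (n-1)*tr.
conditionRegressors <- function(schedule, nScans, tr, dt = 0.1,
                                hrfParams = list()) {
  v <- schedule@version
  ev <- schedule@events
  nHi <- ceiling(nScans * tr / dt) + 1L
  h <- do.call(canonicalHrf, c(list(dt = dt), hrfParams))
  out <- matrix(0, nScans, length(v@conditions),
                dimnames = list(NULL, v@conditions))
  scanIdx <- round((seq_len(nScans) - 1) * tr / dt) + 1L
  for (cond in v@conditions) {
    u <- numeric(nHi)
    rows <- which(ev$condition == cond)
    for (r in rows) {
      a <- floor(ev$onset[r] / dt) + 1L
      b <- min(nHi, ceiling((ev$onset[r] + ev$duration[r]) / dt))
      if (a <= b) u[a:b] <- 1
    }
    x <- convolve(u, rev(h), type = "open")[seq_len(nHi)] / sum(h)
    out[, cond] <- x[scanIdx]
  }
  out
}

#' Build the first-level design matrix
#'
#' Per condition, a boxcar at \code{oversampleDt} resolution convolved with
#' the canonical HRF and sampled at scan times; fixation is modelled
#' implicitly (no column). Optionally a temporal derivative per condition
#' (centered finite difference of the convolved regressor, orthogonalized
#' against its parent so condition betas stay interpretable); a
#' discrete-cosine drift basis containing every basis function with period
#' longer than \code{highpassCutoff}; a constant column; and any
#' user-supplied nuisance regressors (e.g. motion or outlier-scan
#' indicators).
#'
#' @param schedule a \linkS4class{RunSchedule} covering the acquisition.
#' @param nScans number of scans.
#' @param tr repetition time in seconds.
#' @param options a \code{\link{glmOptions}} list.
#' @param nuisance optional numeric matrix of nuisance regressors
#'   (\code{nScans} rows).
#' @return A \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(schedule, nScans, tr, options = glmOptions(),
                              nuisance = NULL) {
  if (schedule@totalDuration < nScans * tr - 1e-9)
    stop("schedule does not cover the acquisition")
  if (options$highpassCutoff <= 2 * tr)
    stop("highpass cutoff must exceed 2 x TR")
  conds <- schedule@version@conditions
  X <- conditionRegressors(schedule, nScans, tr, dt = options$oversampleDt,
                           hrfParams = options$hrfParams)
  conditionCols <- stats::setNames(seq_along(conds), conds)
  derivCols <- integer(0)
  if (isTRUE(options$includeDerivatives)) {
    D <- apply(X, 2, function(x) {
      n <- length(x)
      d <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / tr
      d - x * sum(x * d) / sum(x * x)  # orthogonalize against parent
    })
    colnames(D) <- paste0(conds, "_deriv")
    derivCols <- stats::setNames(ncol(X) + seq_along(conds), conds)
    X <- cbind(X, D)
  }
  nDrift <- floor(2 * nScans * tr / options$highpassCutoff)
  driftCols <- integer(0)
  if (nDrift > 0) {
    n0 <- seq_len(nScans) - 1L
    dct <- sapply(seq_len(nDrift), function(k)
      sqrt(2 / nScans) * cos(pi * k * (2 * n0 + 1) / (2 * nScans)))
    colnames(dct) <- paste0("drift", seq_len(nDrift))
    driftCols <- ncol(X) + seq_len(nDrift)
    X <- cbind(X, dct)
  }
  constantCol <- ncol(X) + 1L
  X <- cbind(X, constant = 1)
  nuisanceCols <- integer(0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nScans)
      stop("nuisance matrix must have one row per scan")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    nuisanceCols <- ncol(X) + seq_len(ncol(nuisance))
    X <- cbind(X, nuisance)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank error: design is singular; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  new("DesignMatrix", values = X, conditionCols = conditionCols,
      derivCols = derivCols, driftCols = as.integer(driftCols),
      constantCol = as.integer(constantCol),
      nuisanceCols = as.integer(nuisanceCols), tr = tr)
}

#' Export a design matrix as a named-column TSV
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param path file path.
#' @export
writeDesignMatrix <- function(design, path) {
  utils::write.table(as.data.frame(design@values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# AR(1) prewhitening: row i becomes y_i - rho*y_{i-1}; the first row is
# scaled by sqrt(1 - rho^2) (stationary variance correction), so W V W' = I
# for the stationary AR(1) correlation structure.
whiten <- function(M, rho) {
  if (rho == 0) return(M)
  n <- nrow(M)
  W <- M
  W[-1, ] <- M[-1, , drop = FALSE] - rho * M[-n, , drop = FALSE]
  W[1, ] <- sqrt(1 - rho^2) * M[1, , drop = FALSE]
  W
}

#' Fit the prewhitened first-level GLM
#'
#' Data are scaled to percent of each voxel's temporal mean (unless
#' \code{options$scaling == "none"}), both data and design are
#' premultiplied by the fixed-coefficient AR(1) whitening matrix, and
#' ordinary least squares is run on the whitened system. Residual variance
#' comes from the whitened residuals with \code{dof = n - rank(X)}.
#'
#' @param img a \linkS4class{TimeSeriesImage}.
#' @param design a \linkS4class{DesignMatrix} built for the same run.
#' @param options a \code{\link{glmOptions}} list.
#' @param mask optional 1-based linear voxel indices to fit (default: all).
#' @return A \linkS4class{GLMFit}.
#' @export
fitGlm <- function(img, design, options = glmOptions(), mask = NULL) {
  X <- design@values
  n <- nrow(X)
  if (nScans(img) != n) stop("number of scans does not match the design")
  dm <- dim(img@data)
  voxels <- if (is.null(mask)) seq_len(prod(dm[1:3])) else as.integer(mask)
  flat <- img@data
  dim(flat) <- c(prod(dm[1:3]), dm[4])
  Y <- t(flat[voxels, , drop = FALSE])
  if (!all(is.finite(Y))) stop("data error: non-finite values in the data")
  if (options$scaling == "percent") {
    mu <- colMeans(Y)
    if (any(mu <= 0)) stop("data error: nonpositive voxel means; cannot ",
                           "express the series in percent signal change")
    Y <- 100 * sweep(Y, 2, mu, "/")
  }
  Xw <- whiten(X, options$arCoef)
  Yw <- whiten(Y, options$arCoef)
  xtx <- crossprod(Xw)
  xtxInv <- chol2inv(chol(xtx))
  beta <- xtxInv %*% crossprod(Xw, Yw)
  rownames(beta) <- colnames(X)
  resid <- Yw - Xw %*% beta
  dof <- n - qr(Xw)$rank
  sigma2 <- colSums(resid^2) / dof
  new("GLMFit", beta = beta, sigma2 = as.numeric(sigma2), dof = dof,
      xtxInv = xtxInv, design = design, grid = img@grid,
      voxels = voxels, options = unclass(options))
}

#' Compute a contrast map from a fitted GLM
#'
#' Effect is \code{c'beta} (percent-signal units under the default
#' scaling); t is \code{effect / sqrt(sigma2 * c'(X'X)^-1 c)} with the
#' whitened design. Weights address condition columns only; derivative,
#' drift and nuisance columns are weighted 0.
#'
#' @param fit a \linkS4class{GLMFit}.
#' @param weights named numeric, condition -> weight, e.g.
#'   \code{c(sentences = 1, nonwords = -1)}.
#' @param name contrast name.
#' @param sourceRun identifier stored in the map.
#' @return A \linkS4class{ContrastMap}.
#' @export
contrast <- function(fit, weights, name = paste(names(weights),
                                                collapse = "_"),
                     sourceRun = "run") {
  cc <- names(fit@design@conditionCols)
  unknown <- setdiff(names(weights), cc)
  if (length(unknown))
    stop("contrast error: unknown condition(s): ",
         paste(unknown, collapse = ", "))
  cvec <- numeric(nrow(fit@beta))
  cvec[fit@design@conditionCols[names(weights)]] <- weights
  eff <- as.numeric(crossprod(cvec, fit@beta))
  varfac <- as.numeric(crossprod(cvec, fit@xtxInv %*% cvec))
  tval <- ifelse(fit@sigma2 > 0, eff / sqrt(fit@sigma2 * varfac), NA_real_)
  dm <- fit@grid@dim
  effVol <- array(NA_real_, dim = dm)
  tVol <- array(NA_real_, dim = dm)
  effVol[fit@voxels] <- eff
  tVol[fit@voxels] <- tval
  new("ContrastMap", grid = fit@grid, effect = effVol, t = tVol,
      name = name, sourceRun = sourceRun)
}

# 1D truncated-Gaussian smoothing matrix, rows renormalized so constants
# are preserved at the edges.
smoothKernelMatrix <- function(n, sigmaVox) {
  hw <- max(1L, ceiling(3 * sigmaVox))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - hw):min(n, i + hw)
    w <- exp(-(j - i)^2 / (2 * sigmaVox^2))
    K[i, j] <- w / sum(w)
  }
  K
}

smoothArray <- function(a, fwhmMm, voxelSize) {
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSize
  cppSmoothSeparable(a, dim(a), sigmaVox)
}

# Dense-matrix reference implementation of the same separable smoothing
# (kept as the independent cross-check for the compiled routine).
smoothArrayReference <- function(a, fwhmMm, voxelSize) {
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSize
  d <- dim(a)
  nd <- length(d)
  Ks <- lapply(d[1:3], smoothKernelMatrix, sigmaVox = sigmaVox)
  a <- array(Ks[[1]] %*% matrix(a, d[1]), dim = d)
  perm <- c(2, 1, seq_len(nd)[-(1:2)])
  a <- aperm(a, perm)
  a <- array(Ks[[2]] %*% matrix(a, d[2]), dim = d[perm])
  a <- aperm(a, order(perm))
  perm <- c(3, seq_len(nd)[-3])
  a <- aperm(a, perm)
  a <- array(Ks[[3]] %*% matrix(a, d[3]), dim = d[perm])
  aperm(a, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian with sigma = fwhm / (2 * sqrt(2 * log 2)) per axis,
#' converted from mm to voxels; the kernel is truncated at 3 sigma and
#' renormalized, so constant volumes are preserved. \code{fwhm = 0} (or
#' NULL) is the identity.
#'
#' @param x a \linkS4class{TimeSeriesImage} or \linkS4class{ContrastMap}.
#' @param fwhmMm smoothing kernel FWHM in mm.
#' @return An object of the same class as \code{x}.
#' @export
setGeneric("gaussianSmooth", function(x, fwhmMm) standardGeneric("gaussianSmooth"))

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", "TimeSeriesImage", function(x, fwhmMm) {
  if (is.null(fwhmMm) || fwhmMm == 0) return(x)
  if (fwhmMm < 0) stop("fwhm must be nonnegative")
  x@data <- smoothArray(x@data, fwhmMm, x@grid@voxelSize)
  x
})

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", "ContrastMap", function(x, fwhmMm) {
  if (is.null(fwhmMm) || fwhmMm == 0) return(x)
  if (fwhmMm < 0) stop("fwhm must be nonnegative")
  x@effect <- smoothArray(x@effect, fwhmMm, x@grid@voxelSize)
  x@t <- smoothArray(x@t, fwhmMm, x@grid@voxelSize)
  x
})
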