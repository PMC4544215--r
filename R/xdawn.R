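#' Build Toeplitz design matrices for the evoked-response model
#'
#' The recorded signal X (samples x channels) is modeled as
#' `X = D1 A1 + D2 A2 + H`: a target-evoked prototype A1 superimposed at
#' every target onset via D1, a response A2 common to all stimuli
#' superimposed via D2, plus residual noise H. D1 and D2 are 0/1 Toeplitz
#' matrices: the first column holds ones exactly at the onset samples and
#' column k is column 1 shifted down by k - 1. Responses extending past the
#' end of the recording are truncated.
#'
#' @param nSamples number of rows (recording length in samples)
#' @param allOnsets 1-based onset sample indices of all stimuli
#' @param targetOnsets 1-based onset sample indices of target stimuli
#' @param n1,n2 modeled response lengths in samples (defaults: one epoch,
#'   32 samples at 32 Hz)
#' @return a [DesignMatrices-class] with sparse d1, d2
#' @export
buildDesign <- function(nSamples, allOnsets, targetOnsets,
                        n1 = 32L, n2 = 32L) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive")
  if (length(allOnsets) && (max(allOnsets) > nSamples || min(allOnsets) < 1))
    stop("onset sample indices must lie in 1..nSamples")
  if (!all(targetOnsets %in% allOnsets))
    stop("every target onset must also be a stimulus onset")
  toeplitz01 <- function(onsets, nc) {
    if (!length(onsets))
      return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                  dims = c(nSamples, nc)))
    i <- rep(onsets, each = nc) + rep(seq_len(nc) - 1L, length(onsets))
    j <- rep(seq_len(nc), length(onsets))
    keep <- i <= nSamples
    Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                         dims = c(nSamples, nc))
  }
  new("DesignMatrices", d1 = toeplitz01(targetOnsets, n1),
      d2 = toeplitz01(allOnsets, n2),
      n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Joint least-squares estimate of the evoked responses
#'
#' Solves `Ahat = ([D1;D2]' [D1;D2])^-1 [D1;D2]' X` and partitions the
#' result into the target response estimate A1 (first n1 rows) and the
#' common response A2. A rank-deficient normal matrix falls back to the
#' Moore-Penrose pseudoinverse with a warning.
#'
#' @param x samples x channels signal matrix
#' @param design a [DesignMatrices-class]
#' @return list with matrices `a1` (n1 x channels) and `a2`
#'   (n2 x channels)
#' @export
estimateResponses <- function(x, design) {
  x <- as.matrix(x)
  d <- cbind(design@d1, design@d2)
  g <- as.matrix(Matrix::crossprod(d))
  rhs <- as.matrix(Matrix::crossprod(d, x))
  a <- tryCatch({
    if (rcond(g) < 1e-12) stop("ill-conditioned")
    solve(g, rhs)
  }, error = function(e) {
    warning("rank-deficient design; using the Moore-Penrose pseudoinverse")
    MASS::ginv(g) %*% rhs
  })
  list(a1 = a[seq_len(design@n1), , drop = FALSE],
       a2 = a[design@n1 + seq_len(design@n2), , drop = FALSE])
}

# Signal to signal-plus-noise Rayleigh quotient of filter columns u:
# tr(u' B u) / tr(u' W u) with B the evoked-signal and W the total
# covariance.
ssnrQuotient <- function(u, b, w) {
  u <- as.matrix(u)
  sum(diag(crossprod(u, b %*% u))) / sum(diag(crossprod(u, w %*% u)))
}

# Top generalized eigenvectors of (b, w) via Cholesky whitening. Columns
# are normalized to u' w u = 1; eigenvalues returned in descending order.
rayleighFilters <- function(b, w, nFilters) {
  r <- chol(w)
  # K = R^-T B R^-1, symmetric whitened problem
  k <- backsolve(r, t(backsolve(r, b, transpose = TRUE)), transpose = TRUE)
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  v <- e$vectors[, seq_len(nFilters), drop = FALSE]
  list(u = backsolve(r, v), values = e$values[seq_len(nFilters)])
}

#' Fit SSNR-maximizing spatial filters
#'
#' Spatial filters are the top generalized eigenvectors of the pair
#' `(A1' D1' D1 A1, X' X)`: directions maximizing the signal to
#' signal-plus-noise Rayleigh quotient (SSNR). `X' X` receives a
#' trace-scaled ridge `lambda * tr(X'X)/channels * I` for numerical
#' stability, and filters are normalized to unit norm in that metric so
#' filtered time courses are comparable across filters. Reported SSNR
#' values are the Rayleigh quotients at the unregularized `X' X`,
#' descending.
#'
#' @param x samples x channels signal matrix
#' @param design a [DesignMatrices-class]
#' @param a1 n1 x channels target response estimate (from
#'   [estimateResponses()])
#' @param nFilters number of filters to keep (default 8)
#' @param lambda ridge scale for the data covariance
#' @param channelLabelsIn channel labels to record (default V1..Vn)
#' @return a [SpatialFilterSet-class]
#' @export
fitSpatialFilters <- function(x, design, a1, nFilters = 8L, lambda = 1e-9,
                              channelLabelsIn = NULL) {
  x <- as.matrix(x)
  ns <- ncol(x)
  if (nFilters > ns)
    stop("cannot fit more filters (", nFilters, ") than channels (", ns, ")")
  m <- as.matrix(design@d1 %*% a1)
  b <- crossprod(m)              # A1' D1' D1 A1
  w <- crossprod(x)              # X' X
  wr <- w + lambda * sum(diag(w)) / ns * diag(ns)
  fit <- rayleighFilters(b, wr, nFilters)
  ssnr <- apply(fit$u, 2, function(u) ssnrQuotient(u, b, w))
  ord <- order(ssnr, decreasing = TRUE)
  if (is.null(channelLabelsIn)) channelLabelsIn <- paste0("V", seq_len(ns))
  a2 <- estimateResponses(x, design)$a2
  new("SpatialFilterSet", u = fit$u[, ord, drop = FALSE], ssnr = ssnr[ord],
      a1 = a1, a2 = a2, channelLabels = channelLabelsIn)
}

#' Project epochs through spatial filters into feature vectors
#'
#' Each trial's channels x samples matrix is filtered to nFilters time
#' courses (`X_filt = X U` with X samples x channels) and concatenated
#' filter-major (all samples of filter 1, then filter 2, ...), giving one
#' vector of length nFilters x samples per trial.
#'
#' @param epochs an [EpochedData-class]
#' @param filters a [SpatialFilterSet-class] with matching channel count
#' @return trials x (nFilters * samples) feature matrix
#' @export
applyFilters <- function(epochs, filters) {
  d <- dim(epochs@data)
  if (d[2] != nrow(filters@u))
    stop("channel count mismatch: epochs have ", d[2], ", filters expect ",
         nrow(filters@u))
  nf <- ncol(filters@u)
  out <- matrix(0, d[1], nf * d[3])
  for (i in seq_len(d[1])) {
    xf <- crossprod(filters@u, epochs@data[i, , ])  # filters x samples
    out[i, ] <- as.vector(t(xf))                    # filter-major
  }
  out
}

#' Train xDAWN filters from epoched trials
#'
#' Assembles a pseudo-continuous signal by stacking the training epochs in
#' time order (trials x samples rows), marks every epoch start as a
#' stimulus onset and target-epoch starts in D1, then runs
#' [estimateResponses()] and [fitSpatialFilters()] with n1 = n2 = one epoch
#' length.
#'
#' @param epochs an [EpochedData-class] (training trials only)
#' @param positive class treated as the target response (default "target")
#' @param nFilters filters to keep
#' @param lambda ridge scale passed to [fitSpatialFilters()]
#' @return a [SpatialFilterSet-class]
#' @export
xdawnTrain <- function(epochs, positive = "target", nFilters = 8L,
                       lambda = 1e-9) {
  d <- dim(epochs@data)
  nSamp <- d[3]
  x <- matrix(0, d[1] * nSamp, d[2])
  for (i in seq_len(d[1]))
    x[(i - 1) * nSamp + seq_len(nSamp), ] <- t(epochs@data[i, , ])
  onsets <- (seq_len(d[1]) - 1L) * nSamp + 1L
  design <- buildDesign(nrow(x), onsets,
                        onsets[epochs@labels == positive],
                        n1 = nSamp, n2 = nSamp)
  a1 <- estimateResponses(x, design)$a1
  fitSpatialFilters(x, design, a1, nFilters, lambda,
                    channelLabelsIn = epochs@channelLabels)
}
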