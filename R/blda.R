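#' Fit a Bayesian linear discriminant model
#'
#' Bayesian linear regression onto class-balanced targets (+N/N1 for the
#' positive class, -N/N0 for the negative, which copes with the extreme
#' rare/frequent imbalance of RSVP data) with an isotropic Gaussian prior
#' of precision alpha over the augmented weight vector (features plus
#' intercept column) and Gaussian noise of precision beta. The weights are
#' the posterior mean; alpha and beta are set by iterating the standard
#' evidence-maximization fixed point (effective-degrees-of-freedom update
#' for alpha, residual update for beta) until
#' `|d log alpha| + |d log beta| < tol` or `maxIter`. Supplying `alpha` and
#' `beta` freezes them (no updates), in which case the weights equal the
#' ridge-regression solution with penalty alpha/beta.
#'
#' @param x trials x features matrix
#' @param y binary labels (logical, or 0/1)
#' @param maxIter maximum evidence-update iterations
#' @param tol fixed-point tolerance on `|d log alpha| + |d log beta|`
#' @param alpha,beta optional frozen hyperparameters
#' @return a [BLDAModel-class]
#' @export
fitBLDA <- function(x, y, maxIter = 100L, tol = 1e-6,
                    alpha = NULL, beta = NULL) {
  x <- as.matrix(x)
  y <- as.logical(y)
  n <- nrow(x)
  n1 <- sum(y); n0 <- n - n1
  if (n1 < 2L || n0 < 2L)
    stop("need at least two trials per class")
  if (max(apply(x, 2, function(col) max(col) - min(col))) == 0)
    stop("degenerate features: zero variance in every dimension")
  t <- ifelse(y, n / n1, -n / n0)
  phi <- cbind(x, 1)
  sv <- svd(phi)
  s2 <- sv$d^2
  uty <- as.vector(crossprod(sv$u, t))
  tt <- sum(t^2)
  frozen <- !is.null(alpha) && !is.null(beta)
  if (is.null(alpha)) alpha <- 1
  if (is.null(beta)) beta <- 1
  d <- ncol(phi)
  evidence <- function(a, bta, coefv, res, gamma) {
    # log marginal likelihood with the isotropic prior; |A| uses the d - k
    # prior-only directions when phi is rank deficient (k = length(s2))
    logDetA <- sum(log(a + bta * s2)) + (d - length(s2)) * log(a)
    0.5 * (d * log(a) + n * log(bta) - bta * res - a * sum(coefv^2) -
             logDetA - n * log(2 * pi))
  }
  coefUpdate <- function(a, bta) bta * sv$d * uty / (a + bta * s2)
  residual <- function(coefv) {
    fitted <- sv$d * coefv
    max(tt - 2 * sum(fitted * uty) + sum(fitted^2), 1e-12)
  }
  trace <- numeric()
  iter <- 0L; converged <- frozen
  coefv <- coefUpdate(alpha, beta)
  if (!frozen) {
    for (iter in seq_len(maxIter)) {
      coefv <- coefUpdate(alpha, beta)
      res <- residual(coefv)
      gamma <- sum(beta * s2 / (alpha + beta * s2))
      alphaNew <- gamma / max(sum(coefv^2), 1e-300)
      betaNew <- max(n - gamma, 1e-6) / res
      trace <- c(trace, evidence(alphaNew, betaNew,
                                 coefUpdate(alphaNew, betaNew),
                                 residual(coefUpdate(alphaNew, betaNew)),
                                 gamma))
      delta <- abs(log(alphaNew) - log(alpha)) + abs(log(betaNew) - log(beta))
      alpha <- alphaNew; beta <- betaNew
      if (delta < tol) { converged <- TRUE; break }
    }
    coefv <- coefUpdate(alpha, beta)
  }
  m <- as.vector(sv$v %*% coefv)
  new("BLDAModel", weights = m[-d], bias = m[d],
      alpha = alpha, beta = beta, nIterations = as.integer(iter),
      converged = converged, evidenceTrace = trace)
}

#' Score trials with a fitted model
#'
#' Affine projection `weights' x + bias`; higher scores indicate the
#' positive (target) class under the label coding used in [fitBLDA()].
#'
#' @param model a [BLDAModel-class]
#' @param x trials x features matrix (or a single feature vector)
#' @return numeric score per trial
#' @export
bldaScore <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model@weights))
    stop("feature dimension mismatch: model expects ",
         length(model@weights), ", got ", ncol(x))
  as.vector(x %*% model@weights) + model@bias
}
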