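#' Attribute button presses to stimuli
#'
#' A press falling in `(onset + 200, onset + 1000]` ms of a rare stimulus
#' (target or non-target) is attributed to that stimulus; when several rare
#' stimuli are eligible (impossible under the standard >= 2-background gap
#' at 2 Hz, but possible for arbitrary sequences) the most recent eligible
#' stimulus wins, on reaction-time plausibility grounds. Each press is
#' attributed at most once and each rare stimulus absorbs at most one
#' press; presses attributable to no rare stimulus count as background
#' false positives. Reaction times are recorded for hits.
#'
#' @param seq an [EventSequence-class] with presses filled
#' @param window attribution window in ms after onset (half-open on the
#'   left, closed on the right)
#' @return a [BehavioralCounts-class]
#' @export
attributePresses <- function(seq, window = c(200, 1000)) {
  lo <- window[1] / 1000; hi <- window[2] / 1000
  rare <- which(seq@classes != "background")
  consumed <- rep(FALSE, length(seq@onsets))
  hits <- 0L; rts <- numeric()
  fp <- c(nontarget = 0L, background = 0L)
  for (p in seq@presses) {
    dt <- p - seq@onsets[rare]
    elig <- rare[dt > lo & dt <= hi & !consumed[rare]]
    if (!length(elig)) {
      fp["background"] <- fp["background"] + 1L
      next
    }
    s <- max(elig)  # most recent eligible rare stimulus
    consumed[s] <- TRUE
    if (seq@classes[s] == "target") {
      hits <- hits + 1L
      rts <- c(rts, (p - seq@onsets[s]) * 1000)
    } else {
      fp["nontarget"] <- fp["nontarget"] + 1L
    }
  }
  nTarget <- sum(seq@classes == "target")
  nNontarget <- sum(seq@classes == "nontarget")
  nBackground <- sum(seq@classes == "background")
  new("BehavioralCounts",
      hits = hits, misses = nTarget - hits,
      fp = fp,
      cr = c(nontarget = nNontarget - fp[["nontarget"]],
             background = nBackground - fp[["background"]]),
      rts = rts)
}

#' Hit rate and false-positive rate
#'
#' HR = hits / (hits + misses); FPR = FP / (FP + CR) pooled over the
#' requested false-positive classes. Degenerate proportions (0 or 1) are
#' edge-corrected by the standard half-count rule, 1/(2N), so both rates
#' lie strictly in (0, 1) and [dPrime()] is always defined.
#'
#' @param counts a [BehavioralCounts-class]
#' @param fpClasses classes pooled into the false-positive rate
#' @return list with elements `HR` and `FPR`
#' @export
detectionRates <- function(counts,
                           fpClasses = c("nontarget", "background")) {
  fpClasses <- intersect(fpClasses, names(counts@fp))
  nT <- counts@hits + counts@misses
  fpN <- sum(counts@fp[fpClasses])
  crN <- sum(counts@cr[fpClasses])
  nF <- fpN + crN
  if (nT == 0 || nF == 0)
    stop("need at least one target and one non-rare stimulus of the requested classes")
  correct <- function(k, n) {
    p <- k / n
    if (p == 0) 1 / (2 * n) else if (p == 1) 1 - 1 / (2 * n) else p
  }
  list(HR = correct(counts@hits, nT), FPR = correct(fpN, nF))
}

#' Sensitivity index d-prime
#'
#' probit(HR) - probit(FPR), the signal-detection sensitivity index. Inputs
#' must lie strictly in (0, 1); edge-correct degenerate rates upstream
#' (see [detectionRates()]).
#'
#' @param HR hit rate in (0, 1)
#' @param FPR false-positive rate in (0, 1)
#' @return unitless sensitivity
#' @examples
#' dPrime(0.9, 0.1)   # 2.5631
#' @export
dPrime <- function(HR, FPR) {
  if (any(c(HR, FPR) <= 0) || any(c(HR, FPR) >= 1))
    stop("HR and FPR must lie strictly in (0, 1); apply edge correction first")
  qnorm(HR) - qnorm(FPR)
}

#' Behavioral summary of a session
#'
#' Runs attribution and emits a one-row data.frame with counts, per-class
#' and pooled rates, d-prime, and a reaction-time summary, suitable for
#' writing one CSV row per subject or session.
#'
#' @param seq an [EventSequence-class] with presses
#' @param window attribution window in ms
#' @return a one-row data.frame
#' @export
behavioralSummary <- function(seq, window = c(200, 1000)) {
  counts <- attributePresses(seq, window)
  pooled <- detectionRates(counts)
  hasNT <- (counts@fp[["nontarget"]] + counts@cr[["nontarget"]]) > 0
  ntRates <- if (hasNT) detectionRates(counts, "nontarget") else
    list(HR = NA_real_, FPR = NA_real_)
  bgRates <- detectionRates(counts, "background")
  data.frame(
    hits = counts@hits, misses = counts@misses,
    fp_nontarget = counts@fp[["nontarget"]],
    fp_background = counts@fp[["background"]],
    HR = pooled$HR, FPR_pooled = pooled$FPR,
    FPR_nontarget = ntRates$FPR, FPR_background = bgRates$FPR,
    d_prime_pooled = dPrime(pooled$HR, pooled$FPR),
    d_prime_background = dPrime(bgRates$HR, bgRates$FPR),
    rt_median_ms = if (length(counts@rts)) median(counts@rts) else NA_real_,
    rt_iqr_ms = if (length(counts@rts)) stats::IQR(counts@rts) else NA_real_,
    row.names = NULL)
}
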