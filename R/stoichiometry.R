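#' Isoform monomer fraction at a given expression ratio
#'
#' Converts an isoform:FLp53 expression ratio r (transfected plasmid amount
#' as the expression proxy) into the isoform fraction of the monomer pool,
#' \eqn{p = r / (1 + r)}. Co-transfection at 1:1, 1:5, 1:10 gives p = 1/2,
#' 5/6, 10/11.
#'
#' @param r non-negative ratio (vectorized).
#' @return isoform monomer fraction in [0, 1).
#' @examples
#' isoformFraction(c(0, 1, 5, 10))
#' @export
isoformFraction <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("ratios must be finite and non-negative")
  r / (1 + r)
}

#' Tetramer composition under random subunit mixing
#'
#' Assuming tetramers assemble by drawing four subunits independently from
#' a monomer pool with isoform fraction p, the number of isoform subunits
#' per tetramer is Binomial(4, p): \eqn{p_i = \binom{4}{i} p^i (1-p)^{4-i}}.
#'
#' @param p isoform monomer fraction in [0, 1].
#' @return numeric vector \code{p0..p4} (named), summing to 1.
#' @examples
#' compositionDistribution(0.5)   # (1,4,6,4,1)/16
#' @export
compositionDistribution <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("p must be a single fraction in [0, 1]")
  setNames(dbinom(0:4, size = 4, prob = p), paste0("p", 0:4))
}

.checkThreshold <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || !k %in% 1:5)
    stop("k must be an inactivation threshold in 1..4 (5 = never inactive)")
  k
}

#' Expected tetramer pool activity under an inactivation threshold
#'
#' A tetramer is inactivated when it contains at least k isoform subunits.
#' In \code{"step"} mode tetramers below the threshold are fully active;
#' in \code{"proportional"} mode a tetramer with i isoform subunits (i < k)
#' retains activity (4 - i)/4. Either way activity is 1 at p = 0. The
#' sentinel k = 5 means "never inactivated".
#'
#' @param p isoform monomer fraction in [0, 1].
#' @param k inactivation threshold in 1..4 (or sentinel 5).
#' @param mode \code{"step"} (default) or \code{"proportional"}.
#' @return expected relative activity in [0, 1].
#' @examples
#' tetramerActivity(0.5, k = 3)          # (1+4+6)/16
#' tetramerActivity(5/6, k = 2)          # 21/1296
#' @export
tetramerActivity <- function(p, k, mode = c("step", "proportional")) {
  mode <- match.arg(mode)
  k <- .checkThreshold(k)
  pr <- compositionDistribution(p)
  i <- 0:4
  act <- if (mode == "step") as.numeric(i < k)
         else as.numeric(i < k) * (4 - i) / 4
  sum(pr * act)
}

#' Theoretical inhibition curve for an inactivation threshold
#'
#' Relative transcriptional activity of the FLp53/isoform tetramer pool as
#' a function of the co-expression ratio, under the hypothesis that k
#' isoform subunits inactivate a tetramer. The experimental curves lying
#' above the k = 2 theoretical curve at every ratio is what argues that at
#' least three isoform subunits per tetramer are required to abolish FLp53
#' activity.
#'
#' @param k inactivation threshold in 1..4 (or sentinel 5).
#' @param ratios isoform:FLp53 ratios, starting at 0 and strictly
#'   increasing; default \code{c(0, 1, 5, 10)}.
#' @param mode \code{"step"} (default) or \code{"proportional"}.
#' @return an \linkS4class{InhibitionCurve} of kind \code{"theoretical"}.
#' @examples
#' curvePoints(theoreticalInhibitionCurve(3))
#' @export
theoreticalInhibitionCurve <- function(k, ratios = c(0, 1, 5, 10),
                                       mode = c("step", "proportional")) {
  mode <- match.arg(mode)
  k <- .checkThreshold(k)
  if (length(ratios) < 1L || ratios[1] != 0)
    stop("ratios must start at 0 (FLp53 alone)")
  if (any(diff(ratios) <= 0)) stop("ratios must be strictly increasing")
  act <- vapply(isoformFraction(ratios), tetramerActivity,
                numeric(1), k = k, mode = mode)
  new("InhibitionCurve", ratio = as.numeric(ratios), activity = act,
      kind = "theoretical")
}

#' Construct a SubunitMix
#'
#' @param eFL,eIso expression levels (>= 0, not both 0).
#' @param phiFL,phiIso nuclear fractions in [0, 1], default 1.
#' @param seqFL,seqIso aggregation-sequestered fractions in [0, 1],
#'   default 0.
#' @return a \linkS4class{SubunitMix}.
#' @examples
#' subunitMix(1, 5, phiFL = 0.5, phiIso = 0.25)
#' @export
subunitMix <- function(eFL, eIso, phiFL = 1, phiIso = 1,
                       seqFL = 0, seqIso = 0) {
  new("SubunitMix", eFL = eFL, eIso = eIso, phiFL = phiFL,
      phiIso = phiIso, seqFL = seqFL, seqIso = seqIso)
}

#' Effective nuclear isoform fraction of a compartment-adjusted pool
#'
#' Only nuclear, non-aggregated protein joins transcription-competent
#' tetramers. The effective pools are
#' \code{nFL = eFL * (1 - seqFL) * phiFL} and likewise for the isoform, and
#' the effective isoform fraction is \code{nIso / (nFL + nIso)}. Because the
#' isoforms partition more to the cytoplasm and aggregate more than FLp53,
#' this fraction is below the naive expression-ratio fraction — the
#' quantitative form of the argument that compartmentalization weakens
#' hetero-tetramer dilution.
#'
#' @param mix a \linkS4class{SubunitMix}.
#' @return effective nuclear isoform monomer fraction in [0, 1].
#' @examples
#' nuclearAdjustedFraction(subunitMix(1, 5, phiFL = 0.5, phiIso = 0.25))
#' @export
nuclearAdjustedFraction <- function(mix) {
  stopifnot(is(mix, "SubunitMix"))
  nFL <- mix@eFL * (1 - mix@seqFL) * mix@phiFL
  nIso <- mix@eIso * (1 - mix@seqIso) * mix@phiIso
  if (nFL + nIso <= 0)
    stop("both effective nuclear pools are zero")
  nIso / (nFL + nIso)
}

#' Infer the minimal inactivation threshold from an experimental curve
#'
#' For each threshold hypothesis k in 1..4, compares the experimental
#' inhibition curve with the theoretical step curve at the experimental
#' nonzero ratios. A hypothesis is rejected when it under-predicts the
#' observed activity, i.e. when the theoretical curve falls below
#' \code{experimental - tol} at any nonzero ratio. The inferred minimal
#' threshold is the smallest non-rejected k; if even k = 4 is rejected the
#' sentinel 5 ("tetramers are never inactivated") is returned. The
#' \code{strictlyAbove} flags report, per k, whether the experimental curve
#' lies strictly above the theoretical one at every nonzero ratio — the
#' curve-ordering criterion used to dismiss the two-subunit hypothesis.
#'
#' @param exp an \linkS4class{InhibitionCurve} of kind
#'   \code{"experimental"} (pre-normalized: ratio-0 activity close to 1),
#'   with at least two nonzero ratios.
#' @param tol absolute activity tolerance for rejection, default 0.05.
#' @return list with \code{kMin} (integer in 1..5), \code{rejected} (named
#'   logical over k1..k4), \code{strictlyAbove} (named logical) and
#'   \code{margins} (k-by-ratio matrix of theoretical minus experimental
#'   activity at the nonzero ratios).
#' @examples
#' theo <- theoreticalInhibitionCurve(3)
#' exp <- new("InhibitionCurve", ratio = theo@ratio,
#'            activity = theo@activity, kind = "experimental")
#' inferMinimalThreshold(exp)$kMin   # 3
#' @export
inferMinimalThreshold <- function(exp, tol = 0.05) {
  stopifnot(is(exp, "InhibitionCurve"))
  if (tol < 0) stop("tol must be non-negative")
  if (!any(exp@ratio == 0))
    stop("experimental curve must include the ratio-0 (FLp53 alone) point")
  act0 <- exp@activity[exp@ratio == 0]
  if (abs(act0 - 1) > 0.15)
    stop("experimental curve is not normalized: activity at ratio 0 is ",
         signif(act0, 3), " (expected ~1)")
  nz <- exp@ratio > 0
  if (sum(nz) < 2L)
    stop("at least two nonzero ratios are required")
  r <- exp@ratio[nz]
  obs <- exp@activity[nz]
  theo <- vapply(1:4, function(k)
    vapply(isoformFraction(r), tetramerActivity, numeric(1), k = k),
    numeric(length(r)))
  theo <- t(theo)                         # k by ratio
  dimnames(theo) <- list(paste0("k", 1:4), paste0("r", r))
  margins <- sweep(theo, 2, obs)
  rejected <- apply(margins < -tol, 1, any)
  strictlyAbove <- apply(sweep(theo, 2, obs) < 0, 1, all)
  kMin <- if (any(!rejected)) as.integer(which(!rejected)[1]) else 5L
  list(kMin = kMin, rejected = rejected, strictlyAbove = strictlyAbove,
       margins = margins)
}
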