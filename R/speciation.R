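# Henderson-Hasselbalch speciation: the forward map S0 -> S(pH), its
# inverse, and identification of the pKa's that matter at a given pH.
#
# The total-solubility / intrinsic-solubility ratio of an ionizable compound
# is Phi(pH) >= 1.  With relevant acidic pKa's a_1 <= ... <= a_na and basic
# pKa's b_1 >= ... >= b_nb, the cumulative speciation expansion is
#
#   Phi(pH) = 1 + sum_k 10^(k*pH - sum_{j<=k} a_j)
#               + sum_k 10^(sum_{j<=k} b_j - k*pH)
#
# which reproduces the classical mono-/di-/tri-protic acid, base and
# ordinary-ampholyte cases. Cross terms for simultaneously zwitterionic
# microspecies are not modelled (zwitterions are excluded upstream).

#' Log10 ionization factor at a pH
#'
#' Computes \eqn{\log_{10}\Phi(pH)} where \eqn{S(pH) = S_0 \cdot \Phi(pH)},
#' using only the pKa's relevant at this pH (ionized fraction of the group
#' at least \code{threshold}). Evaluated in log-sum-exp form so that
#' \eqn{|pH - pK_a|} differences of 20 or more do not overflow.
#'
#' @param model an \linkS4class{IonizationModel}.
#' @param ph pH value(s); finite.
#' @param threshold relevance threshold on the ionized fraction, in (0, 0.5).
#' @return list with \code{logPhi} (numeric, same length as \code{ph},
#'   always >= 0) and \code{nRelevant} (integer, pre-cap count of relevant
#'   pKa's at each pH).
#' @details If more than 3 pKa's are relevant at a pH an error of class
#'   \code{graphsol_too_many_pkas} is thrown, carrying the count in its
#'   \code{nRelevant} field; callers (curation, profiling) decide whether
#'   to discard the compound or mark the point undetermined.
#' @examples
#' ionizationFactor(IonizationModel(acidic = 4), 4)$logPhi  # log10(2)
#' @export
ionizationFactor <- function(model, ph, threshold = 0.01) {
  stopifnot(is(model, "IonizationModel"))
  if (!all(is.finite(ph))) stop("ph must be finite")
  logPhi <- numeric(length(ph))
  nRel <- integer(length(ph))
  for (i in seq_along(ph)) {
    rel <- relevantPkas(model, ph[i], threshold)
    nRel[i] <- rel$nRelevant
    if (rel$nRelevant > 3L) {
      cond <- structure(
        class = c("graphsol_too_many_pkas", "error", "condition"),
        list(message = sprintf("%d relevant pKa's at pH %.3g (max 3)",
                               rel$nRelevant, ph[i]),
             call = sys.call(-1), nRelevant = rel$nRelevant))
      stop(cond)
    }
    logPhi[i] <- .logPhiExact(acidicPkas(rel$model), basicPkas(rel$model), ph[i])
  }
  list(logPhi = logPhi, nRelevant = nRel)
}

# stable evaluation of log10(1 + sum 10^u + sum 10^v):
# factor out the largest exponent (>= 0 because of the leading 1)
.logPhiExact <- function(acidic, basic, ph) {
  expo <- 0
  if (length(acidic)) {
    k <- seq_along(acidic)
    expo <- c(expo, k * ph - cumsum(acidic))
  }
  if (length(basic)) {
    k <- seq_along(basic)
    expo <- c(expo, cumsum(basic) - k * ph)
  }
  m <- max(expo)
  m + log10(sum(10^(expo - m)))
}

#' Identify the pKa's relevant at a pH
#'
#' A pKa is relevant when its group is appreciably ionized at the pH:
#' the ionized fraction (acidic \eqn{1/(1+10^{pKa-pH})}, basic
#' \eqn{1/(1+10^{pH-pKa})}) is at least \code{threshold}. If more than
#' 3 pKa's pass, the 3 with the largest fractions are kept and the
#' pre-cap count is reported in \code{nRelevant}.
#'
#' @inheritParams ionizationFactor
#' @return list with \code{model} (the filtered \linkS4class{IonizationModel})
#'   and \code{nRelevant} (pre-cap count).
#' @export
relevantPkas <- function(model, ph, threshold = 0.01) {
  stopifnot(is(model, "IonizationModel"), length(ph) == 1L, is.finite(ph))
  if (!(threshold > 0 && threshold < 0.5)) stop("threshold must lie in (0, 0.5)")
  a <- acidicPkas(model); b <- basicPkas(model)
  fa <- 1 / (1 + 10^(a - ph))
  fb <- 1 / (1 + 10^(ph - b))
  keepA <- fa >= threshold
  keepB <- fb >= threshold
  nRel <- sum(keepA) + sum(keepB)
  if (nRel > 3L) {
    # keep the 3 with the largest ionized fractions
    frac <- c(fa[keepA], fb[keepB])
    type <- rep(c("a", "b"), c(sum(keepA), sum(keepB)))
    val <- c(a[keepA], b[keepB])
    ord <- order(frac, decreasing = TRUE)[1:3]
    mod <- IonizationModel(acidic = val[ord][type[ord] == "a"],
                           basic = val[ord][type[ord] == "b"])
  } else {
    mod <- IonizationModel(acidic = a[keepA], basic = b[keepB])
  }
  list(model = mod, nRelevant = as.integer(nRel))
}

#' Solubility at a pH from intrinsic solubility
#'
#' Forward Henderson-Hasselbalch map:
#' \eqn{\log S(pH) = \log S_0 + \log\Phi(pH)}. Never below \code{logS0}.
#'
#' @param logS0 intrinsic solubility, log10 molar.
#' @inheritParams ionizationFactor
#' @return log10 molar solubility, same length as \code{ph}.
#' @export
solubilityAtPh <- function(logS0, model, ph, threshold = 0.01) {
  stopifnot(is.finite(logS0))
  logS0 + ionizationFactor(model, ph, threshold)$logPhi
}

#' Intrinsic solubility from a measured solubility
#'
#' Exact inverse of \code{\link{solubilityAtPh}}:
#' \eqn{\log S_0 = \log S_{measured} - \log\Phi(pH)}. A compound with no
#' relevant pKa at the measurement pH has \eqn{\Phi = 1}, so the measured
#' solubility is the intrinsic solubility directly.
#'
#' @param logSMeasured measured solubility, log10 molar.
#' @inheritParams ionizationFactor
#' @return log10 molar intrinsic solubility.
#' @export
intrinsicFromMeasured <- function(logSMeasured, model, ph, threshold = 0.01) {
  stopifnot(all(is.finite(logSMeasured)))
  logSMeasured - ionizationFactor(model, ph, threshold)$logPhi
}
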