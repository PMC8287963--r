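#' @include methods.R
NULL

#' Competitive index from a mixed-inoculum infection
#'
#' CI = (output wild type / output mutant) / (input wild type / input
#' mutant). CI = 1 means no fitness difference between the strains; the
#' log10 CI is what group-level tests operate on. A zero mutant (or wild
#' type) output leaves the ratio undefined; such records are censored at
#' the detection limit (one CFU per plated volume by default) and flagged
#' rather than dropped, so the animal still contributes to the test.
#'
#' @param inputWt,inputMut Input CFU counts (strictly positive).
#' @param outputWt,outputMut Output CFU counts (>= 0).
#' @param detectionLimit Value substituted for a zero output count.
#' @return A data frame with columns `ci`, `log_ci` and `censored`.
#' @examples
#' competitiveIndex(1e7, 1e7, 1e5, 1e5)   # CI = 1
#' competitiveIndex(10, 10, 1000, 100)    # CI = 10
#' @export
competitiveIndex <- function(inputWt, inputMut, outputWt, outputMut,
                             detectionLimit = 1) {
  if (any(inputWt <= 0) || any(inputMut <= 0))
    stop("input CFU counts must be strictly positive")
  if (any(outputWt < 0) || any(outputMut < 0))
    stop("output CFU counts must be non-negative")
  censored <- (outputWt == 0) | (outputMut == 0)
  ow <- ifelse(outputWt == 0, detectionLimit, outputWt)
  om <- ifelse(outputMut == 0, detectionLimit, outputMut)
  ci <- (ow / om) / (inputWt / inputMut)
  data.frame(ci = ci, log_ci = log10(ci), censored = censored)
}

# exact null distribution of the signed-rank statistic W+ for given
# midranks: convolution over independent sign flips (handles ties, n <= 25
# comfortably; sums are tracked on a doubled-rank integer grid)
.signedRankExactP <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  maxS <- sum(r2)
  dist <- numeric(maxS + 1L)  # index s+1 holds P(2*W = s)
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(maxS + 1L - r)])
    dist <- (dist + shifted) / 2
  }
  w2 <- round(2 * w)
  s <- seq(0L, maxS)
  pLe <- sum(dist[s <= w2 + 1e-9])
  pGe <- sum(dist[s >= w2 - 1e-9])
  min(1, 2 * min(pLe, pGe))
}

#' Wilcoxon signed-rank test of log CI against zero
#'
#' Two-sided one-sample signed-rank test of whether the values (typically
#' log10 competitive indices) differ from zero. Zeros are dropped (the
#' standard convention); for n <= 25 the exact null distribution of the
#' rank sum is computed by convolution over all sign assignments (valid
#' with tied midranks), and above that a normal approximation with tie
#' correction is used. The two-sided P doubles the smaller tail, capped
#' at 1.
#'
#' @param values Numeric vector (e.g. log10 CI per mouse).
#' @param exactMax Largest n for which the exact distribution is used.
#' @return A list with `p`, the statistic `W` (rank sum of positive
#'   values), `nUsed` (non-zero values), `method` and `degenerate` (all
#'   values zero).
#' @examples
#' wilcoxonSignedRankVsZero(c(1, -1))$p                 # 1
#' wilcoxonSignedRankVsZero(c(1, 2, 3, 4, 5, 6))$p      # 2/64
#' @export
wilcoxonSignedRankVsZero <- function(values, exactMax = 25L) {
  if (length(values) < 1L) stop("need at least one value")
  v <- values[values != 0]
  if (length(v) == 0L)
    return(list(p = 1, W = 0, nUsed = 0L, method = "degenerate",
                degenerate = TRUE))
  n <- length(v)
  ranks <- rank(abs(v))
  W <- sum(ranks[v > 0])
  if (n <= exactMax) {
    p <- .signedRankExactP(W, ranks)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p = p, W = W, nUsed = n, method = method, degenerate = FALSE)
}

#' Transformation efficiency
#'
#' (cfu/ml on selective plates / cfu/ml on non-selective plates) per unit
#' amount of plasmid DNA. Zero selective counts give efficiency 0 with a
#' flag; group comparisons are run on log10-transformed values, so the
#' log10 is reported alongside.
#'
#' @param cfuSelective,cfuNonselective CFU/ml on the two plate types.
#' @param dnaAmount Plasmid DNA used, in ng.
#' @return A data frame with columns `efficiency`, `log_efficiency`
#'   (`-Inf` when efficiency is 0) and `zero_flag`.
#' @examples
#' transformationEfficiency(1e5, 1e7, 100)  # 1e-6 per ng
#' @export
transformationEfficiency <- function(cfuSelective, cfuNonselective,
                                     dnaAmount) {
  if (any(cfuNonselective <= 0) || any(dnaAmount <= 0))
    stop("non-selective CFU and DNA amount must be strictly positive")
  if (any(cfuSelective < 0))
    stop("selective CFU must be non-negative")
  eff <- (cfuSelective / cfuNonselective) / dnaAmount
  data.frame(efficiency = eff,
             log_efficiency = ifelse(eff > 0, log10(eff), -Inf),
             zero_flag = cfuSelective == 0)
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' Fold change `2^-((ctTargetTest - ctRefTest) - (ctTargetCtrl -
#' ctRefCtrl))`, quantifying a target gene against a reference gene (e.g.
#' the 16S rRNA gene) in a test versus a control condition. Invariant to
#' adding a constant to all four Ct values.
#'
#' @param ctTargetTest,ctRefTest Ct of target and reference in the test
#'   sample.
#' @param ctTargetCtrl,ctRefCtrl Ct of target and reference in the control
#'   sample.
#' @return Fold change (1 = no change).
#' @examples
#' ddctFoldChange(20, 15, 20, 15)  # 1
#' ddctFoldChange(21, 15, 20, 15)  # 0.5
#' @export
ddctFoldChange <- function(ctTargetTest, ctRefTest, ctTargetCtrl,
                           ctRefCtrl) {
  stopifnot(is.finite(ctTargetTest), is.finite(ctRefTest),
            is.finite(ctTargetCtrl), is.finite(ctRefCtrl))
  ddct <- (ctTargetTest - ctRefTest) - (ctTargetCtrl - ctRefCtrl)
  2^(-ddct)
}
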