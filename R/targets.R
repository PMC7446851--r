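#' @include AllClasses.R
NULL

#' Median-based outlier detection for raw B-factors
#'
#' Flags extreme raw B-factors with the modified z-score
#' \eqn{M_i = 0.6745 (x_i - \tilde{x}) / \mathrm{MAD}}, where \eqn{\tilde{x}}
#' is the median and MAD the median absolute deviation
#' \eqn{\mathrm{median}(|x_i - \tilde{x}|)}. Entries with \eqn{|M_i|}
#' above the threshold are masked out. A chain whose MAD is zero (at least
#' half the values identical) yields no removals: the rule is undefined there
#' and constant chains must survive untouched.
#'
#' @param raw numeric vector of raw B-factors (length >= 3).
#' @param threshold modified z-score cutoff (default 3.5, the usual
#'   Iglewicz-Hoaglin value).
#' @return logical keep-mask aligned with \code{raw} (TRUE = retained).
#' @export
removeOutliersMedian <- function(raw, threshold = 3.5) {
  if (length(raw) < 3L)
    stop("need at least 3 values for median-based outlier removal")
  if (!all(is.finite(raw))) stop("raw B-factors must be finite")
  med <- stats::median(raw)
  mad0 <- stats::median(abs(raw - med))
  if (mad0 == 0) return(rep(TRUE, length(raw)))
  m <- 0.6745 * (raw - med) / mad0
  abs(m) <= threshold
}

#' Per-chain z-normalization of B-factors
#'
#' Raw B-factors differ systematically between chains (refinement protocol,
#' chain size), so each chain's retained values are centred and scaled to
#' zero mean and unit *population* variance (divide by n), making the unit
#' variance exact on the retained set.
#'
#' @param raw numeric vector of retained raw B-factors (length >= 2).
#' @return numeric vector of normalized values; mean 0 and population sd 1 to
#'   machine precision.
#' @export
normalizeBfactors <- function(raw) {
  if (length(raw) < 2L) stop("need at least 2 values to normalize")
  if (!all(is.finite(raw))) stop("raw B-factors must be finite")
  mu <- mean(raw)
  sd_pop <- sqrt(mean((raw - mu)^2))
  if (sd_pop == 0)
    stop("zero-variance B-factors; chain cannot be normalized")
  (raw - mu) / sd_pop
}

# outlier removal on the raw scale first, then normalization of the retained
# values; returns values aligned with which(mask)
.chain_targets <- function(raw, threshold = 3.5) {
  mask <- removeOutliersMedian(raw, threshold)
  list(mask = mask, values = normalizeBfactors(raw[mask]))
}
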