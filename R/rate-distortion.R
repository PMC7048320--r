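#' Plug-in mutual information from a confusion matrix
#'
#' Treats the (presented, decoded) count matrix as an empirical joint
#' distribution and returns the plug-in estimate of `I(X; Xhat)` in
#' bits. No small-sample correction is applied; with the trial counts
#' used here (thousands per code) the bias is negligible for stimulus
#' sets up to a few hundred symbols.
#'
#' @param confusion Nonnegative count (or probability) matrix, rows =
#'   presented stimulus, columns = decoded stimulus.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(confusion) {
  cm <- as.matrix(confusion)
  if (any(cm < 0)) stop("confusion matrix must be nonnegative", call. = FALSE)
  tot <- sum(cm)
  if (tot <= 0) stop("degenerate confusion matrix: all zero", call. = FALSE)
  p <- cm / tot
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Rate-distortion bound for a uniform discrete source
#'
#' Minimum information rate (bits) needed to achieve symbol-error
#' probability `D` for a uniform source over `M` symbols under Hamming
#' (symbol-error) distortion:
#' `R(D) = log2(M) - Hb(D) - D * log2(M - 1)` for
#' `0 <= D <= 1 - 1/M`, where `Hb` is the binary entropy. `R(0) =
#' log2(M)` and `R(1 - 1/M) = 0`. A simulated code with error rate `PE`
#' and plug-in information `I` is feasible exactly when `I >= R(PE)`.
#'
#' @param M Number of source symbols (>= 2).
#' @param distortion Symbol-error probabilities in `[0, 1 - 1/M]`
#'   (vectorized).
#' @return Numeric vector of rates in bits.
#' @export
rate_distortion_bound <- function(M, distortion) {
  if (M < 2) stop("M must be >= 2", call. = FALSE)
  if (any(distortion < 0 | distortion > 1 - 1 / M + 1e-12))
    stop("distortion must lie in [0, 1 - 1/M]", call. = FALSE)
  hb <- function(d) ifelse(d <= 0 | d >= 1, 0,
                           -d * log2(d) - (1 - d) * log2(1 - d))
  pmax(0, log2(M) - hb(distortion) - distortion * log2(M - 1))
}
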