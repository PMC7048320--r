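#' Population size of a conjunctive code
#'
#' Number of coding units `D_O` needed for full coverage of the stimulus
#' space. For `rf_width = 1` this is `choose(K, O) * n^O`: one unit per
#' value combination in each feature subset. For `rf_width > 1` and
#' `O > 1` the closed form `choose(K, O) * rf_width * (n/rf_width + 1)^O`
#' is returned; for `O = 1` the population size does not change with
#' receptive-field width. The closed form for `rf_width > 1` slightly
#' overcounts the constructive lattice (see [build_rf_codebook()], which
#' reports both).
#'
#' @param space A [stimulus_space()].
#' @param spec A [code_spec()].
#' @return Numeric scalar `D_O`.
#' @export
population_size <- function(space, spec) {
  check_spec(space, spec)
  K <- space$K; n <- space$n; O <- spec$order; s <- spec$rf_width
  if (s == 1L || O == 1L) return(choose(K, O) * n^O)
  choose(K, O) * s * (n / s + 1)^O
}

#' Representation energy of a conjunctive code
#'
#' The metabolic cost of the active representation, under the variant set
#' in the spec:
#' \describe{
#'   \item{squared_distance}{Squared Euclidean norm of every codeword,
#'     `choose(K, O) * rf_width` (constant across stimuli).}
#'   \item{variance}{Summed across-stimulus response variance,
#'     `choose(K, O) * (1 - n^-O)` for `rf_width = 1`; computed
#'     constructively from the codebook for `rf_width > 1` (boundary
#'     truncation makes unit activation probabilities unequal).}
#'   \item{sum_of_spikes}{Count of active units per stimulus,
#'     `choose(K, O) * rf_width` (equal to the squared norm for binary
#'     codewords).}
#' }
#'
#' @inheritParams population_size
#' @return Numeric scalar `P_O`.
#' @export
representation_energy <- function(space, spec) {
  check_spec(space, spec)
  K <- space$K; n <- space$n; O <- spec$order; s <- spec$rf_width
  switch(spec$energy_variant,
    squared_distance = ,
    sum_of_spikes = choose(K, O) * s,
    variance = {
      if (s == 1L) {
        choose(K, O) * (1 - n^(-O))
      } else {
        p <- colMeans(codebook(space, spec)$words)
        sum(p * (1 - p))
      }
    })
}

#' Euclidean distance between codewords of stimuli differing in v features
#'
#' Closed-form distance spectrum `d(K, O, v) =
#' sqrt(2 * sum_i choose(v, i) * choose(K - v, O - i))` for codes with
#' `rf_width = 1`. Equals the brute-force Euclidean distance between the
#' codewords of any stimulus pair differing in exactly `v` features.
#'
#' @param K Number of features.
#' @param O Code order, `1 <= O <= K`.
#' @param v Number of differing features, `1 <= v <= K`.
#' @return Numeric distance (vectorized over `v`).
#' @export
pairwise_distance <- function(K, O, v) {
  if (O < 1 || O > K) stop("require 1 <= O <= K", call. = FALSE)
  if (any(v < 1 | v > K)) stop("require 1 <= v <= K", call. = FALSE)
  vapply(v, function(vv) {
    i <- seq_len(min(vv, O))
    sqrt(2 * sum(choose(vv, i) * choose(K - vv, O - i)))
  }, numeric(1))
}

#' Minimum distance of a conjunctive code
#'
#' `Delta_O = sqrt(2 * choose(K - 1, O - 1))`: the smallest Euclidean
#' distance between any two codewords, attained by stimulus pairs
#' differing in a single feature (the distance spectrum is non-decreasing
#' in the number of differing features). Does not depend on `n` or on the
#' receptive-field width.
#'
#' @param K Number of features.
#' @param O Code order.
#' @return Numeric minimum distance.
#' @export
min_distance <- function(K, O) {
  if (any(O < 1 | O > K)) stop("require 1 <= O <= K", call. = FALSE)
  sqrt(2 * choose(K - 1, O - 1))
}

#' Squared-minimum-distance per representation-energy ratio
#'
#' `Delta_O^2 / P_O = 2 * O / K` exactly (squared-distance energy
#' variant, `rf_width = 1`); strictly increasing with code order, the
#' core geometric advantage of mixing.
#'
#' @param K Number of features.
#' @param O Code order.
#' @return Numeric ratio `2 * O / K`.
#' @export
distance_ratio <- function(K, O) {
  if (any(O < 1 | O > K)) stop("require 1 <= O <= K", call. = FALSE)
  2 * O / K
}

#' Number of stimuli differing in exactly v features
#'
#' `N_all(v) = choose(K, v) * (n - 1)^v`; summing over `v = 1..K` gives
#' `M - 1`.
#'
#' @param space A [stimulus_space()].
#' @param v Number of differing features (vectorized).
#' @return Numeric count(s).
#' @export
count_at_distance <- function(space, v) {
  stopifnot(inherits(space, "stimulus_space"))
  if (any(v < 1 | v > space$K)) stop("require 1 <= v <= K", call. = FALSE)
  choose(space$K, v) * (space$n - 1)^v
}

#' Number of nearest neighbors (codewords at minimum distance)
#'
#' For `O < K`, only single-feature changes reach the minimum distance,
#' giving `K * (n - 1)` neighbors; for the fully mixed `O = K` code every
#' other stimulus is at minimum distance, giving `n^K - 1`.
#'
#' @param space A [stimulus_space()].
#' @param O Code order.
#' @return Numeric neighbor count.
#' @export
neighbors_at_min_distance <- function(space, O) {
  stopifnot(inherits(space, "stimulus_space"))
  if (O < 1 || O > space$K) stop("require 1 <= O <= K", call. = FALSE)
  if (O < space$K) space$K * (space$n - 1) else space$n^space$K - 1
}

#' Nearest neighbors with an incorrect value of one queried feature
#'
#' The count of minimum-distance error destinations that corrupt a given
#' single feature: `n - 1` for `O < K` and `(n - 1) * n^(K-1)` for
#' `O = K`. Drives the single-feature decoding error estimate
#' [feature_error()].
#'
#' @param space A [stimulus_space()].
#' @param O Code order.
#' @return Numeric count.
#' @export
feature_neighbors <- function(space, O) {
  stopifnot(inherits(space, "stimulus_space"))
  if (O < 1 || O > space$K) stop("require 1 <= O <= K", call. = FALSE)
  if (O < space$K) space$n - 1 else (space$n - 1) * space$n^(space$K - 1)
}
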