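#' Union-bound estimate of the decoding error rate
#'
#' Under additive isotropic Gaussian noise with maximum-likelihood
#' decoding, the probability that a codeword at Euclidean distance `d`
#' is preferred to the transmitted one is `Q(d / (2 sigma))`, with `Q`
#' the standard-normal upper-tail function. Summing over error
#' destinations gives the union-bound estimate (UBE):
#' \describe{
#'   \item{full_sum}{`sum_v N_all(v) * Q(0.5 * d(K, O, v) * sqrt(SNR / P_O))`
#'     over `v = 1..K` differing features -- an explicit upper bound on
#'     the error rate.}
#'   \item{nearest_only}{`N_Delta(O) * Q(sqrt(SNR * O / (2K)))`, keeping
#'     only the (exponentially dominant) minimum-distance terms.}
#' }
#' Here `P_O = choose(K, O)` (squared-distance energy variant) and
#' `SNR = V / sigma2`. `Q` is evaluated with the numerically stable
#' complementary tail (`pnorm(..., lower.tail = FALSE)`), since values at
#' high SNR are far below 1e-6.
#'
#' @param K Number of features.
#' @param n Values per feature.
#' @param O Code order.
#' @param snr Population signal-to-noise ratio(s), `>= 0` (vectorized).
#' @param mode `"full_sum"` or `"nearest_only"`.
#' @param energy_variant Which energy accounting defines the SNR:
#'   `"squared_distance"` (`P_O = choose(K, O)`; the closed-form default)
#'   or `"variance"` (`P_O = choose(K, O) * (1 - n^-O)`; use this when
#'   comparing against simulations, which rescale codewords under the
#'   variance accounting). With the squared-distance variant the
#'   `nearest_only` kernel reduces to `Q(sqrt(SNR * O / (2K)))`.
#' @return Numeric vector of PE estimates (not clipped at 1).
#' @export
ube_error <- function(K, n, O, snr, mode = c("full_sum", "nearest_only"),
                      energy_variant = c("squared_distance", "variance")) {
  mode <- match.arg(mode)
  energy_variant <- match.arg(energy_variant)
  if (any(snr < 0)) stop("snr must be >= 0", call. = FALSE)
  sp <- stimulus_space(K, n)
  P <- switch(energy_variant,
              squared_distance = choose(K, O),
              variance = choose(K, O) * (1 - n^(-O)))
  if (mode == "nearest_only") {
    nd <- neighbors_at_min_distance(sp, O)
    return(nd * qfun(0.5 * min_distance(K, O) * sqrt(snr / P)))
  }
  v <- seq_len(K)
  d <- pairwise_distance(K, O, v)
  Nv <- count_at_distance(sp, v)
  vapply(snr, function(s)
    sum(Nv * qfun(0.5 * d * sqrt(s / P))), numeric(1))
}

qfun <- function(y) stats::pnorm(y, lower.tail = FALSE)

#' Union-bound estimate of the single-feature decoding error rate
#'
#' `PE_f ~ N_Delta_f(O) * Q(sqrt(SNR * O / (2K)))`, counting only the
#' minimum-distance error destinations that corrupt the queried feature
#' (see [feature_neighbors()]).
#'
#' @inheritParams ube_error
#' @return Numeric vector of PE_f estimates.
#' @export
feature_error <- function(K, n, O, snr) {
  if (any(snr < 0)) stop("snr must be >= 0", call. = FALSE)
  sp <- stimulus_space(K, n)
  feature_neighbors(sp, O) * qfun(sqrt(snr * O / (2 * K)))
}

#' Allocate a total energy budget between maintenance and spiking
#'
#' The total energy of a code is `E = eps * V + D_O`: each of the `D_O`
#' units costs one unit of passive maintenance, and spiking costs `eps`
#' per unit of representation energy `V`. Given `E`, the code can afford
#' `V = (E - D_O) / eps`, yielding a squared post-transform minimum
#' distance `delta^2 = V * Delta_O^2 / P_O` (which, for `rf_width = 1`,
#' equals `(2 O / (K eps)) * (E - D_O)`). Budgets with `E <= D_O` are
#' infeasible and flagged rather than raised.
#'
#' @param E Total energy budget.
#' @param eps Spiking-cost ratio (> 0); experimental estimates put it
#'   around 10 to 100, and the relative ordering of code orders does not
#'   depend on it.
#' @param K,n,O,sigma_rf Code parameters.
#' @return An object of class `"energy_budget"`: list with `E`, `eps`,
#'   `D`, `P`, `V`, `delta2`, `feasible`.
#' @export
allocate_energy <- function(E, eps, K, n, O, sigma_rf = 1L) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  sp <- stimulus_space(K, n)
  spec <- code_spec(O, sigma_rf, energy_variant = "squared_distance")
  D <- population_size(sp, spec)
  P <- representation_energy(sp, spec)
  feasible <- E > D
  V <- if (feasible) (E - D) / eps else NA_real_
  delta2 <- if (feasible) V * min_distance(K, O)^2 / P else NA_real_
  structure(list(E = E, eps = eps, D = D, P = P, V = V, delta2 = delta2,
                 feasible = feasible),
            class = "energy_budget")
}

#' Total energy at which order O + 1 overtakes order O
#'
#' Setting `delta_O = delta_{O+1}` under the total-energy model gives the
#' closed-form crossover `E = (nK - (n + 1) O) * choose(K, O) * n^O`.
#' Above this energy the order-`O + 1` code achieves the larger minimum
#' distance.
#'
#' @param K,n Code parameters.
#' @param O Lower order of the pair, `1 <= O < K`.
#' @return Numeric crossover energy.
#' @export
transition_energy <- function(K, n, O) {
  if (O < 1 || O >= K) stop("require 1 <= O < K", call. = FALSE)
  (n * K - (n + 1) * O) * choose(K, O) * n^O
}

#' Total energy above which some mixed code beats the pure code
#'
#' `E_mixed = n^2 K^2 - n^2 K - n K`, which equals
#' [transition_energy()]`(K, n, 1)` and is always below `n^2 K^2`.
#'
#' @param K,n Code parameters.
#' @return Numeric energy threshold.
#' @export
mixed_beats_pure <- function(K, n) {
  n^2 * K^2 - n^2 * K - n * K
}

#' Optimal code order under a resource constraint
#'
#' With a fixed neuron pool of size `N`, the best order is the largest
#' `O` with `D_O <= N` (it yields the highest minimum distance for a
#' fixed amount of spiking). With a fixed total energy `(E, eps)`, the
#' best order maximizes the achievable `delta^2` over the feasible
#' orders, ties going to the lower order.
#'
#' @param K,n Code parameters.
#' @param neuron_pool Optional pool size `N`.
#' @param total_energy Optional list or vector with elements `E` and
#'   `eps`.
#' @return List with `order` (NA if nothing is feasible), `delta2`
#'   (achieved squared minimum distance, total-energy mode), and
#'   `feasible` (logical).
#' @export
optimal_order <- function(K, n, neuron_pool = NULL, total_energy = NULL) {
  if (is.null(neuron_pool) == is.null(total_energy))
    stop("supply exactly one of 'neuron_pool' or 'total_energy'",
         call. = FALSE)
  sp <- stimulus_space(K, n)
  orders <- seq_len(K)
  if (!is.null(neuron_pool)) {
    D <- vapply(orders, function(o)
      population_size(sp, code_spec(o)), numeric(1))
    ok <- D <= neuron_pool
    if (!any(ok)) return(list(order = NA_integer_, delta2 = NA_real_,
                              feasible = FALSE))
    return(list(order = max(orders[ok]), delta2 = NA_real_, feasible = TRUE))
  }
  te <- as.list(total_energy)
  d2 <- vapply(orders, function(o) {
    b <- allocate_energy(te$E, te$eps, K, n, o)
    if (b$feasible) b$delta2 else NA_real_
  }, numeric(1))
  if (all(is.na(d2)))
    return(list(order = NA_integer_, delta2 = NA_real_, feasible = FALSE))
  ## ties (within numerical noise) resolve to the lower order
  top <- max(d2, na.rm = TRUE)
  best <- which(!is.na(d2) & d2 >= top - 1e-9 * max(top, 1))[1L]
  list(order = orders[best], delta2 = d2[best], feasible = TRUE)
}

#' Closed-form analytic report for a code
#'
#' Collects the closed-form properties of a code -- population size,
#' representation energy (squared-distance variant), minimum distance,
#' distance spectrum, neighbor counts -- and the union-bound error curve
#' over an SNR grid. Everything is reproducible from `(K, n, O,
#' sigma_rf, snr)` alone.
#'
#' @param K,n,O,sigma_rf Code parameters.
#' @param snr SNR grid for the UBE curve.
#' @return A list of class `"analytic_report"`.
#' @export
analytic_report <- function(K, n, O, sigma_rf = 1L, snr = 2^(0:6)) {
  sp <- stimulus_space(K, n)
  spec <- code_spec(O, sigma_rf, energy_variant = "squared_distance")
  v <- seq_len(K)
  structure(list(
    K = K, n = n, O = O, sigma_rf = sigma_rf,
    D = population_size(sp, spec),
    P = representation_energy(sp, spec),
    min_distance = min_distance(K, O),
    distance_ratio = distance_ratio(K, O),
    distance_spectrum = data.frame(v = v,
                                   d = pairwise_distance(K, O, v),
                                   n_at_v = count_at_distance(sp, v)),
    n_min_distance = neighbors_at_min_distance(sp, O),
    n_feature = feature_neighbors(sp, O),
    ube = data.frame(snr = snr,
                     full_sum = ube_error(K, n, O, snr, "full_sum"),
                     nearest_only = ube_error(K, n, O, snr, "nearest_only"))),
    class = "analytic_report")
}
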