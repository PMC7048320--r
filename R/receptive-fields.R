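#' Build a receptive-field-widened codebook
#'
#' For `rf_width = s > 1`, units respond when each of their `O` features
#' falls in a contiguous interval of `s` values. Intervals tile each
#' feature axis with step `s` at `s` distinct lattice offsets (boundary
#' intervals truncated), so every stimulus activates exactly `s` units
#' within each of the `choose(K, O)` feature-subset subpopulations --
#' representation energy `choose(K, O) * s` -- and the joint activity
#' pattern still identifies the stimulus uniquely.
#'
#' The constructive unit count,
#' `choose(K, O) * ((n/s)^O + (s - 1) * (n/s + 1)^O)`, is reported
#' alongside the closed-form value `choose(K, O) * s * (n/s + 1)^O`
#' (see [population_size()]); the closed form treats every offset as
#' having `n/s + 1` intervals and therefore slightly overcounts the
#' lattice actually built. Any discrepancy is flagged, not forced.
#'
#' @param space A [stimulus_space()].
#' @param spec A [code_spec()] with `rf_width >= 1` dividing `n`.
#' @return A list with `codebook` (the [codebook()]),
#'   `constructive_size`, `formula_size`, `size_discrepancy` (logical),
#'   and `active_per_stimulus`.
#' @export
build_rf_codebook <- function(space, spec) {
  cb <- codebook(space, spec)
  constructive <- ncol(cb$words)
  formula <- population_size(space, spec)
  act <- rowSums(cb$words)
  stopifnot(all(act == act[1L]))
  list(codebook = cb,
       constructive_size = constructive,
       formula_size = formula,
       size_discrepancy = constructive != formula,
       active_per_stimulus = unname(act[1L]))
}

#' Sweep code order and receptive-field width at a fixed energy budget
#'
#' For each `(O, sigma_rf)` configuration: builds the RF codebook,
#' allocates the total energy budget `E` between per-unit maintenance
#' (using the constructive unit count) and spiking (`V = (E - D) /
#' eps`), simulates the Gaussian channel at `SNR = V / sigma2`, and
#' records the error rate, the mean squared feature-space error, and the
#' empirical distribution of squared errors. Infeasible configurations
#' (`E <= D`) are flagged, not fatal.
#'
#' @param space A [stimulus_space()].
#' @param orders Integer vector of code orders to sweep.
#' @param rf_widths Integer vector of receptive-field widths.
#' @param E Total energy budget.
#' @param eps Spiking-cost ratio.
#' @param sigma2 Gaussian noise variance.
#' @param n_trials Monte Carlo trials per configuration.
#' @param seed Master seed; per-configuration seeds are derived from it.
#' @param mse_metric Passed to [simulate_channel()].
#' @return A list with `results` (data frame: O, sigma_rf, D, E, V, PE,
#'   PE_se, MSE, MSE_se, feasible) and `squared_errors` (named list of
#'   per-configuration squared-error samples, for CDF comparisons).
#' @export
rf_sweep <- function(space, orders, rf_widths, E, eps = 50, sigma2 = 1,
                     n_trials = 10000L, seed = 1L,
                     mse_metric = c("linear", "circular")) {
  mse_metric <- match.arg(mse_metric)
  grid <- expand.grid(O = orders, sigma_rf = rf_widths,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- vector("list", nrow(grid))
  sqerr <- list()
  for (i in seq_len(nrow(grid))) {
    O <- grid$O[i]; s <- grid$sigma_rf[i]
    spec <- code_spec(O, s)
    rf <- build_rf_codebook(space, spec)
    D <- rf$constructive_size
    feasible <- E > D
    if (!feasible) {
      rows[[i]] <- data.frame(O = O, sigma_rf = s, D = D, E = E,
                              V = NA_real_, PE = NA_real_, PE_se = NA_real_,
                              MSE = NA_real_, MSE_se = NA_real_,
                              feasible = FALSE)
      next
    }
    V <- (E - D) / eps
    P <- representation_energy(space, spec)
    tr <- make_transform(D, D, V = V, P = P, style = "identity_scaled")
    cfg <- channel_config("gaussian", sigma2 = sigma2)
    res <- simulate_channel(space, spec, tr, cfg, n_trials = n_trials,
                            seed = grid$seed[i], mse_metric = mse_metric,
                            codebook_obj = rf$codebook)
    rows[[i]] <- data.frame(O = O, sigma_rf = s, D = D, E = E, V = V,
                            PE = res$pe, PE_se = res$pe_se,
                            MSE = res$mse, MSE_se = res$mse_se,
                            feasible = TRUE)
    sqerr[[paste0("O", O, "_s", s)]] <- res$squared_errors
  }
  list(results = do.call(rbind, rows), squared_errors = sqerr)
}
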