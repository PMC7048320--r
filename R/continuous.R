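#' Configuration for a continuous-stimulus conjunctive code
#'
#' Features live on the unit interval `[0, 1)`. Each feature axis is
#' covered by a lattice of `n_centers` base cells of width
#' `1 / n_centers`; receptive fields are boxcar (interval-membership)
#' responses of width `rf_scale` base cells, tiled at `rf_scale` lattice
#' offsets exactly as in the discrete construction, or Gaussian tuning
#' curves centered on the same lattice. With boxcar tuning the response
#' pattern is piecewise constant on base cells, so maximum-likelihood
#' decoding on the cell-center grid is exact; Gaussian tuning uses a
#' finer decode grid of `points_per_rf` points per receptive-field
#' width.
#'
#' @param K Number of features.
#' @param n_centers Base lattice cells per feature axis.
#' @param rf_scale Receptive-field width in base cells (integer >= 1,
#'   must divide `n_centers`).
#' @param tuning `"boxcar"` or `"gaussian"`.
#' @param points_per_rf Decode-grid resolution for Gaussian tuning.
#' @return An object of class `"continuous_code_config"`.
#' @export
continuous_code_config <- function(K, n_centers = 5L, rf_scale = 1L,
                                   tuning = c("boxcar", "gaussian"),
                                   points_per_rf = 10L) {
  tuning <- match.arg(tuning)
  if (n_centers %% rf_scale != 0L)
    stop("rf_scale must divide n_centers", call. = FALSE)
  structure(list(K = as.integer(K), n_centers = as.integer(n_centers),
                 rf_scale = as.integer(rf_scale), tuning = tuning,
                 points_per_rf = as.integer(points_per_rf)),
            class = "continuous_code_config")
}

#' Encode continuous stimuli through receptive-field tuning
#'
#' Encodes rows of `X` (stimuli in `[0, 1)^K`) for a given code order.
#' Boxcar tuning reduces to the discrete RF codebook evaluated on base
#' cells; Gaussian tuning evaluates graded tuning curves centered on the
#' same lattice (sd = half the RF width).
#'
#' @param config A [continuous_code_config()].
#' @param X Matrix of stimuli in rows, values in `[0, 1)`.
#' @param order Code order.
#' @return List with `responses` (stimuli x units) and `codebook` (the
#'   underlying lattice [codebook()]).
#' @export
encode_continuous <- function(config, X, order) {
  L <- config$n_centers
  sp <- stimulus_space(config$K, L)
  spec <- code_spec(order, config$rf_scale)
  cb <- codebook(sp, spec)
  cells <- pmin(floor(X * L) + 1L, L)
  if (config$tuning == "boxcar") {
    idx <- apply(cells, 1L, function(x) stimulus_index(sp, x))
    return(list(responses = cb$words[idx, , drop = FALSE], codebook = cb))
  }
  ## gaussian tuning: centers at interval midpoints, sd = half the RF width
  w0 <- 1 / L
  tau <- config$rf_scale * w0 / 2
  D <- nrow(cb$units)
  resp <- matrix(1, nrow(X), D)
  for (u in seq_len(D)) {
    A <- cb$units$subset[[u]]
    ctr <- (cb$units$lo[[u]] + cb$units$hi[[u]]) / 2 - 0.5
    for (j in seq_along(A))
      resp[, u] <- resp[, u] *
        exp(-(X[, A[j]] - ctr[j] * w0)^2 / (2 * tau^2))
  }
  list(responses = resp, codebook = cb)
}

#' Simulate continuous-stimulus codes under Gaussian noise
#'
#' Draws stimuli uniformly from `[0, 1)^K`, encodes them through the
#' continuous receptive-field code for each requested order and RF
#' scale, rescales to a common representation energy `V = snr * sigma2`
#' (identity-scaled transform), transmits with additive Gaussian noise,
#' ML-decodes on the decode grid, and reports the mean squared Euclidean
#' error in feature space (units: squared fraction of the axis length).
#'
#' @param config A [continuous_code_config()]; its `rf_scale` is
#'   overridden per entry of `rf_scales`.
#' @param orders Integer vector of code orders.
#' @param rf_scales Integer vector of RF widths (base cells).
#' @param snr Population signal-to-noise ratio `V / sigma2`.
#' @param n_trials Stimulus draws per configuration.
#' @param seed Master seed.
#' @return Data frame with columns `O`, `rf_scale`, `snr`, `MSE`,
#'   `MSE_se`, `PE_cell` (rate of decoding to the wrong base cell).
#' @export
continuous_simulate <- function(config, orders, rf_scales = config$rf_scale,
                                snr, n_trials = 2000L, seed = 1L) {
  stopifnot(inherits(config, "continuous_code_config"))
  grid <- expand.grid(O = orders, rf_scale = rf_scales,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  L <- config$n_centers
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- continuous_code_config(config$K, L, grid$rf_scale[i],
                                    config$tuning, config$points_per_rf)
    set.seed(grid$seed[i])
    X <- matrix(stats::runif(n_trials * config$K), n_trials, config$K)
    enc <- encode_continuous(cfg_i, X, grid$O[i])
    ## decode grid: base-cell centers (exact for boxcar tuning)
    sp <- stimulus_space(config$K, L)
    Xg <- (enumerate_stimuli(sp) - 0.5) / L
    genc <- encode_continuous(cfg_i, Xg, grid$O[i])
    P <- mean(rowSums(genc$responses^2))
    H <- sqrt(snr / P)  # sigma2 = 1, V = snr
    cfg_chan <- channel_config("gaussian", sigma2 = 1)
    resp <- transmit(H * enc$responses, cfg_chan)
    dec <- ml_decode(resp, H * genc$responses, cfg_chan)
    err2 <- rowSums((Xg[dec$index, , drop = FALSE] - X)^2)
    true_cell_idx <- apply(pmin(floor(X * L) + 1L, L), 1L,
                           function(x) stimulus_index(sp, x))
    rows[[i]] <- data.frame(
      O = grid$O[i], rf_scale = grid$rf_scale[i], snr = snr,
      MSE = mean(err2), MSE_se = stats::sd(err2) / sqrt(n_trials),
      PE_cell = mean(dec$index != true_cell_idx))
  }
  do.call(rbind, rows)
}
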