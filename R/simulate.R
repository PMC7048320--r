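#' Monte Carlo simulation of a code over a noisy channel
#'
#' Presents stimuli uniformly at random, encodes them (optionally after
#' input noise), applies the linear transform, transmits through the
#' configured noisy channel, decodes by maximum likelihood, and
#' accumulates the error rate (PE), mean squared feature-space error
#' (MSE), per-feature error rates, and the full confusion matrix. The
#' whole run is reproducible from `seed`.
#'
#' The per-feature error rate of feature `k` is the rate at which the
#' full-stimulus ML estimate, projected onto feature `k`, is wrong --
#' single-feature decoding is full-stimulus decoding followed by
#' projection.
#'
#' @param space A [stimulus_space()].
#' @param spec A [code_spec()].
#' @param transform A [make_transform()] object, or `NULL` for the
#'   identity transform (`H = 1`).
#' @param config A [channel_config()].
#' @param n_trials Number of Monte Carlo trials (>= 1). The simulations
#'   in the reference analyses use 5,000 to 10,000 trials per channel
#'   point; the default is 10,000.
#' @param seed Integer seed.
#' @param mse_metric `"linear"` (squared difference of integer value
#'   indices, summed over features) or `"circular"` (wrap-around feature
#'   topology for direction-like features).
#' @param codebook_obj Optional prebuilt [codebook()] for `space`/`spec`
#'   (avoids rebuilding inside parameter sweeps).
#' @return An object of class `"mc_result"`: list with `pe`, `pe_se`
#'   (binomial standard error), `mse`, `mse_se`, `pe_feature` (length
#'   `K`), `confusion` (`M x M` count matrix, rows = presented), `ties`,
#'   `n_trials`, `seed`.
#' @export
simulate_channel <- function(space, spec, transform = NULL, config,
                             n_trials = 10000L, seed = 1L,
                             mse_metric = c("linear", "circular"),
                             codebook_obj = NULL) {
  stopifnot(inherits(space, "stimulus_space"), inherits(spec, "code_spec"),
            inherits(config, "channel_config"))
  mse_metric <- match.arg(mse_metric)
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  cb <- if (is.null(codebook_obj)) codebook(space, spec) else codebook_obj
  M <- space$M; K <- space$K; n <- space$n
  Ct <- apply_transform(transform, cb$words)

  set.seed(seed)
  true_idx <- sample.int(M, n_trials, replace = TRUE)
  X <- enumerate_stimuli(space)
  stim <- X[true_idx, , drop = FALSE]

  ## input noise determines which codeword is actually emitted
  sent <- encode_with_input_noise(cb, stim, config)
  emitted <- if (is.matrix(sent)) apply_transform(transform, sent)
             else Ct[sent, , drop = FALSE]

  responses <- transmit(emitted, config)
  dec <- ml_decode(responses, Ct, config)

  err <- dec$index != true_idx
  pe <- mean(err)
  dx <- X[dec$index, , drop = FALSE] - stim
  if (mse_metric == "circular")
    dx <- pmin(abs(dx), n - abs(dx))
  sq <- rowSums(dx^2)
  conf <- matrix(tabulate((true_idx - 1L) * M + dec$index, nbins = M * M),
                 M, M, byrow = TRUE)
  dimnames(conf) <- list(true = rownames(cb$words),
                         decoded = rownames(cb$words))
  pe_feature <- colMeans(X[dec$index, , drop = FALSE] != stim)

  structure(list(
    pe = pe, pe_se = sqrt(pe * (1 - pe) / n_trials),
    mse = mean(sq), mse_se = stats::sd(sq) / sqrt(n_trials),
    squared_errors = sq,
    pe_feature = pe_feature,
    confusion = conf, ties = sum(dec$tie),
    n_trials = n_trials, seed = seed),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo result (%d trials): PE = %.4g (SE %.2g), MSE = %.4g\n",
              x$n_trials, x$pe, x$pe_se, x$mse))
  invisible(x)
}

## Returns either a vector of emitted stimulus indices (no input noise /
## local noise) or a matrix of emitted codewords (bit-flip noise, where
## the corrupted input representation need not be a valid stimulus).
encode_with_input_noise <- function(cb, stim, config) {
  space <- cb$space
  switch(config$input_noise,
    none = apply(stim, 1L, function(x) stimulus_index(space, x)),
    local = {
      pert <- perturb_input(stim, space, config)
      apply(pert, 1L, function(x) stimulus_index(space, x))
    },
    bitflip = {
      ## corrupt the order-1 input representation bit-by-bit
      o1 <- codebook(space, code_spec(1L))
      idx <- apply(stim, 1L, function(x) stimulus_index(space, x))
      B <- o1$words[idx, , drop = FALSE]
      flips <- matrix(stats::runif(length(B)) < config$p_flip,
                      nrow(B), ncol(B))
      B <- abs(B - flips)
      if (config$bitflip_pipeline == "clean") {
        cleaned <- clean_o1_bits(space, B)
        ci <- apply(cleaned, 1L, function(x) stimulus_index(space, x))
        return(ci)
      }
      conjunctions_from_bits(cb, B)
    })
}

## Snap a corrupted order-1 bit pattern to the nearest valid stimulus:
## per feature, the value whose one-hot pattern is closest in Hamming
## distance, i.e. the value with an active bit (ties to the lowest value).
clean_o1_bits <- function(space, B) {
  K <- space$K; n <- space$n
  out <- matrix(1L, nrow(B), K)
  for (k in seq_len(K)) {
    block <- B[, (k - 1L) * n + seq_len(n), drop = FALSE]
    out[, k] <- max.col(block, ties.method = "first")
  }
  out
}

## Evaluate the conjunctive encoder directly on (possibly corrupted)
## order-1 bits: each unit's response is the product of its per-feature
## value indicators. Only defined for rf_width = 1 codebooks.
conjunctions_from_bits <- function(cb, B) {
  space <- cb$space; n <- space$n
  if (cb$spec$rf_width != 1L)
    stop("bit-flip input noise requires rf_width = 1", call. = FALSE)
  D <- nrow(cb$units)
  out <- matrix(1, nrow(B), D)
  for (u in seq_len(D)) {
    A <- cb$units$subset[[u]]
    vals <- cb$units$lo[[u]]
    for (j in seq_along(A))
      out[, u] <- out[, u] * B[, (A[j] - 1L) * n + vals[j]]
  }
  out
}

#' Convenience wrapper: simulate a code at a given SNR
#'
#' Fixes the Gaussian noise variance at 1 and sets the transform target
#' energy to `V = snr` (only the ratio `V / sigma2` matters), with `H`
#' derived from the spec's energy variant (`variance` by default in
#' simulations). Uses the identity-scaled transform.
#'
#' @param space A [stimulus_space()].
#' @param spec A [code_spec()].
#' @param snr Population signal-to-noise ratio `V / sigma2`.
#' @param n_trials,seed,mse_metric,codebook_obj Passed to
#'   [simulate_channel()].
#' @param config Optional [channel_config()]; defaults to Gaussian output
#'   noise with `sigma2 = 1` and no input noise.
#' @return An `"mc_result"` (see [simulate_channel()]).
#' @export
simulate_code <- function(space, spec, snr, n_trials = 10000L, seed = 1L,
                          mse_metric = c("linear", "circular"),
                          config = NULL, codebook_obj = NULL) {
  if (is.null(config)) config <- channel_config("gaussian", sigma2 = 1)
  P <- representation_energy(space, spec)
  D <- if (is.null(codebook_obj)) {
    cb <- codebook(space, spec)
    codebook_obj <- cb
    ncol(cb$words)
  } else ncol(codebook_obj$words)
  tr <- make_transform(D, D, V = snr * config$sigma2, P = P,
                       style = "identity_scaled")
  simulate_channel(space, spec, tr, config, n_trials = n_trials, seed = seed,
                   mse_metric = mse_metric, codebook_obj = codebook_obj)
}
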