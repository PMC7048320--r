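#' Noisy channel configuration
#'
#' Describes the noise applied to a transmitted codeword (output noise)
#' and, optionally, to the stimulus before encoding (input noise).
#'
#' Output noise models:
#' \describe{
#'   \item{gaussian}{Independent additive normal deviates of variance
#'     `sigma2` per response coordinate; the population signal-to-noise
#'     ratio is `SNR = V / sigma2`.}
#'   \item{poisson}{Counts drawn with mean equal to each coordinate's
#'     (transformed) activity; zero activity means rate exactly zero.}
#'   \item{poisson_baseline}{Poisson counts with mean `activity +
#'     r_spont`; the Poisson SNR is `V / r_spont`.}
#' }
#'
#' Input noise models:
#' \describe{
#'   \item{none}{The stimulus is encoded as presented.}
#'   \item{local}{Each feature independently moves to the adjacent value
#'     above or below with total probability `p_shift` (half each way;
#'     at the ends of the value range the shift goes inward with the full
#'     probability mass, keeping the per-feature shift rate at `p_shift`).}
#'   \item{bitflip}{Bits of the stimulus's order-1 input representation
#'     are flipped independently with probability `p_flip`, and the
#'     downstream conjunctive encoder consumes the corrupted
#'     representation. With `bitflip_pipeline = "direct"` the conjunctive
#'     units compute indicator products of the corrupted bits directly;
#'     with `"clean"` the corrupted representation is first snapped to
#'     the nearest valid stimulus (per feature, the value whose one-hot
#'     pattern is closest in Hamming distance, ties to the lowest value)
#'     and then re-encoded.}
#' }
#'
#' @param output_noise One of `"gaussian"`, `"poisson"`,
#'   `"poisson_baseline"`.
#' @param sigma2 Gaussian noise variance (> 0).
#' @param r_spont Spontaneous (baseline) Poisson rate (> 0 for the
#'   baseline model).
#' @param input_noise One of `"none"`, `"local"`, `"bitflip"`.
#' @param p_shift Per-feature local shift probability in `[0, 1]`.
#' @param p_flip Per-bit flip probability in `[0, 1]`.
#' @param bitflip_pipeline `"direct"` or `"clean"` (see above).
#' @return An object of class `"channel_config"`.
#' @export
channel_config <- function(output_noise = c("gaussian", "poisson",
                                            "poisson_baseline"),
                           sigma2 = 1, r_spont = 0.2,
                           input_noise = c("none", "local", "bitflip"),
                           p_shift = 0, p_flip = 0,
                           bitflip_pipeline = c("direct", "clean")) {
  output_noise <- match.arg(output_noise)
  input_noise <- match.arg(input_noise)
  if (output_noise == "gaussian" && sigma2 <= 0)
    stop("sigma2 must be > 0 for gaussian noise", call. = FALSE)
  if (output_noise == "poisson_baseline" && r_spont <= 0)
    stop("r_spont must be > 0 for poisson_baseline noise", call. = FALSE)
  if (p_shift < 0 || p_shift > 1 || p_flip < 0 || p_flip > 1)
    stop("noise probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(output_noise = output_noise, sigma2 = sigma2,
                 r_spont = r_spont, input_noise = input_noise,
                 p_shift = p_shift, p_flip = p_flip,
                 bitflip_pipeline = match.arg(bitflip_pipeline)),
            class = "channel_config")
}

#' Transmit codewords through the noisy channel
#'
#' @param codewords Matrix of (transformed) codewords in rows, or a
#'   single codeword vector.
#' @param config A [channel_config()].
#' @return Noisy responses, same shape as the input.
#' @export
transmit <- function(codewords, config) {
  stopifnot(inherits(config, "channel_config"))
  vec <- is.null(dim(codewords))
  C <- if (vec) matrix(codewords, nrow = 1L) else as.matrix(codewords)
  out <- switch(config$output_noise,
    gaussian = C + matrix(stats::rnorm(length(C), sd = sqrt(config$sigma2)),
                          nrow(C), ncol(C)),
    poisson = {
      if (any(C < 0))
        stop("invalid configuration: negative Poisson means", call. = FALSE)
      matrix(stats::rpois(length(C), lambda = C), nrow(C), ncol(C))
    },
    poisson_baseline = {
      if (any(C + config$r_spont < 0))
        stop("invalid configuration: negative Poisson means", call. = FALSE)
      matrix(stats::rpois(length(C), lambda = C + config$r_spont),
             nrow(C), ncol(C))
    })
  if (vec) drop(out) else out
}

#' Perturb stimuli with input noise
#'
#' Applies the `local` input-noise model to a matrix of stimuli (rows).
#' Bit-flip input noise acts on the order-1 binary representation and is
#' applied inside [simulate_channel()], where the encoder is available.
#'
#' @param stimuli Matrix of stimuli in rows (or a single stimulus vector).
#' @param space A [stimulus_space()].
#' @param config A [channel_config()].
#' @return Perturbed stimuli, same shape.
#' @export
perturb_input <- function(stimuli, space, config) {
  stopifnot(inherits(config, "channel_config"))
  vec <- is.null(dim(stimuli))
  X <- if (vec) matrix(stimuli, nrow = 1L) else as.matrix(stimuli)
  if (config$input_noise == "local" && config$p_shift > 0) {
    shift <- matrix(stats::runif(length(X)) < config$p_shift, nrow(X), ncol(X))
    dir <- matrix(sample(c(-1L, 1L), length(X), replace = TRUE),
                  nrow(X), ncol(X))
    ## boundary values shift inward only (full mass goes to the one
    ## available neighbor)
    dir[X == 1L] <- 1L
    dir[X == space$n] <- -1L
    X <- X + shift * dir
    storage.mode(X) <- "integer"
  }
  if (vec) drop(X) else X
}

#' Maximum-likelihood decoding of noisy responses
#'
#' Under isotropic Gaussian noise the ML estimate is the codeword at
#' minimum Euclidean distance from the response; under the Poisson models
#' it maximizes the Poisson log-likelihood `sum(r * log(lambda) - lambda)`
#' with exact zero-rate handling (a codeword with `lambda = 0` at a
#' coordinate is impossible whenever a count was observed there). Ties
#' are broken toward the lowest stimulus index and flagged.
#'
#' @param responses Matrix of noisy responses in rows (or one vector).
#' @param code_matrix `M x N` matrix of (transformed) codewords: row `m`
#'   is the noiseless response to stimulus `m`.
#' @param config A [channel_config()].
#' @return List with `index` (decoded stimulus indices) and `tie`
#'   (logical: was the maximum attained by more than one codeword).
#' @export
ml_decode <- function(responses, code_matrix, config) {
  stopifnot(inherits(config, "channel_config"))
  if (nrow(code_matrix) < 1L) stop("codebook is empty", call. = FALSE)
  R <- if (is.null(dim(responses))) matrix(responses, nrow = 1L)
       else as.matrix(responses)
  C <- as.matrix(code_matrix)
  if (ncol(R) != ncol(C))
    stop("response dimensionality does not match codebook", call. = FALSE)
  scores <- switch(config$output_noise,
    gaussian = {
      ## argmin ||r - c||^2 == argmax r.c - |c|^2/2
      R %*% t(C) - rep(rowSums(C^2) / 2, each = nrow(R))
    },
    poisson = poisson_loglik(R, C),
    poisson_baseline = poisson_loglik(R, C + config$r_spont))
  idx <- max.col(scores, ties.method = "first")
  best <- scores[cbind(seq_len(nrow(scores)), idx)]
  tie <- rowSums(abs(scores - best) < 1e-9) > 1L
  list(index = idx, tie = tie)
}

## Poisson log-likelihood of responses (rows) under rate rows lambda;
## terms with lambda = 0 contribute 0 when the count is 0 and -Inf
## otherwise -- handled explicitly, no epsilon floor.
poisson_loglik <- function(R, L) {
  logL <- ifelse(L > 0, log(L), 0)
  s <- R %*% t(logL) - rep(rowSums(L), each = nrow(R))
  zero <- L == 0
  if (any(zero)) {
    impossible <- (R > 0) %*% t(zero) > 0
    s[impossible] <- -Inf
  }
  s
}
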