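## Independent brute-force oracles used to validate closed forms.
## These deliberately avoid the package's analytic code paths.

## All pairwise Euclidean codeword distances, grouped by the number of
## features in which the two stimuli differ.
bf_distance_by_v <- function(cb) {
  X <- enumerate_stimuli(cb$space)
  W <- cb$words
  M <- nrow(W)
  out <- list()
  for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
    v <- sum(X[i, ] != X[j, ])
    d <- sqrt(sum((W[i, ] - W[j, ])^2))
    out[[length(out) + 1L]] <- c(v = v, d = d)
  }
  as.data.frame(do.call(rbind, out))
}

## Count, for each stimulus, how many other codewords sit at the overall
## minimum distance; returns the per-stimulus counts.
bf_nearest_counts <- function(cb) {
  dm <- as.matrix(stats::dist(cb$words))
  dmin <- min(dm[dm > 1e-12])
  vapply(seq_len(nrow(dm)), function(i)
    sum(abs(dm[i, -i] - dmin) < 1e-9), integer(1))
}

## Blahut-Arimoto iteration for the rate-distortion function of a
## uniform M-ary source under symbol-error (Hamming) distortion.
## Returns the (distortion, rate-in-bits) point for slope parameter s < 0.
ba_rate_distortion <- function(M, s, iters = 2000, tol = 1e-12) {
  p <- rep(1 / M, M)
  d <- 1 - diag(M)
  q <- rep(1 / M, M)
  A <- exp(s * d)
  for (it in seq_len(iters)) {
    Z <- as.vector(A %*% q)            # Z(x) = sum_y q(y) exp(s d(x,y))
    Pyx <- t(t(A) * q) / Z             # P(y|x)
    qn <- as.vector(p %*% Pyx)
    if (max(abs(qn - q)) < tol) { q <- qn; break }
    q <- qn
  }
  Z <- as.vector(A %*% q)
  Pyx <- t(t(A) * q) / Z
  D <- sum(p * rowSums(Pyx * d))
  ratio <- Pyx / rep(q, each = M)
  R <- sum(p * rowSums(ifelse(Pyx > 0, Pyx * log2(ratio), 0)))
  c(distortion = D, rate = R)
}

## Exhaustive ML decoding by direct likelihood evaluation (no algebraic
## shortcuts), for cross-checking ml_decode on small instances.
bf_ml_decode <- function(response, rates, noise = c("gaussian", "poisson"),
                         sigma2 = 1) {
  noise <- match.arg(noise)
  ll <- apply(rates, 1L, function(lam) {
    if (noise == "gaussian")
      sum(stats::dnorm(response, mean = lam, sd = sqrt(sigma2), log = TRUE))
    else
      sum(stats::dpois(response, lambda = lam, log = TRUE))
  })
  which.max(ll)
}
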