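#' Construct an energy-rescaling linear transform
#'
#' Builds an `N x D` matrix `beta` mapping `D`-dimensional binary
#' codewords into an `N`-dimensional neural response space while setting
#' the representation energy to a target `V`. A valid transform satisfies
#' four constraints: (1) `N >= D`; (2) `pinv(beta) %*% beta = I`;
#' (3) every column has vector length `H = sqrt(V / P)`; (4) distinct
#' columns have zero mean cross-product. Under these, all pairwise
#' codeword distances scale by exactly `H` and every codeword attains
#' squared norm `V = H^2 * P`, so decoding performance depends on the
#' transform only through `V`.
#'
#' Styles: `"identity_scaled"` (H times the identity, zero-padded to `N`
#' rows; the default used throughout the simulations), `"random_rotation"`
#' and `"random_embedding"` (an exactly orthonormal random frame scaled by
#' `H`; the two names document intent for `N == D` vs `N > D`), and
#' `"gaussian"` (i.i.d. normal entries with columns renormalized to length
#' `H`; satisfies constraints 2 and 4 only approximately at finite `N`).
#'
#' @param D Codeword dimensionality (`D_O` of the codebook).
#' @param N Response dimensionality, `N >= D`.
#' @param V Target representation energy (> 0).
#' @param P Representation energy of the untransformed code (> 0).
#' @param style One of `"identity_scaled"`, `"random_rotation"`,
#'   `"random_embedding"`, `"gaussian"`.
#' @param seed Optional integer seed for the random styles.
#' @return An object of class `"linear_transform"`: list with `matrix`,
#'   `H`, `V`, `P`, `style`, `seed`.
#' @export
make_transform <- function(D, N = D, V, P,
                           style = c("identity_scaled", "random_rotation",
                                     "random_embedding", "gaussian"),
                           seed = NULL) {
  style <- match.arg(style)
  if (N < D)
    stop("embedding impossible: need N >= D", call. = FALSE)
  if (V <= 0 || P <= 0) stop("V and P must be positive", call. = FALSE)
  H <- sqrt(V / P)
  if (!is.null(seed)) set.seed(seed)
  mat <- switch(style,
    identity_scaled = rbind(H * diag(D), matrix(0, N - D, D)),
    random_rotation = ,
    random_embedding = {
      q <- qr.Q(qr(matrix(stats::rnorm(N * D), N, D)))
      H * q
    },
    gaussian = {
      m <- matrix(stats::rnorm(N * D), N, D)
      sweep(m, 2L, sqrt(colSums(m^2)) / H, "/")
    })
  structure(list(matrix = mat, H = H, V = V, P = P, style = style,
                 seed = seed),
            class = "linear_transform")
}

#' @export
print.linear_transform <- function(x, ...) {
  cat(sprintf("Linear transform: %d x %d, style = %s, H = %.4g (V = %.4g)\n",
              nrow(x$matrix), ncol(x$matrix), x$style, x$H, x$V))
  invisible(x)
}

#' Apply a linear transform to codewords
#'
#' @param transform A [make_transform()] object, or `NULL` for the
#'   identity (codewords returned unchanged).
#' @param codewords A [codebook()], or a matrix with codewords in rows.
#' @return `M x N` matrix of transformed codewords (rows).
#' @export
apply_transform <- function(transform, codewords) {
  W <- if (inherits(codewords, "codebook")) codewords$words else as.matrix(codewords)
  if (is.null(transform)) return(W)
  stopifnot(inherits(transform, "linear_transform"))
  if (ncol(transform$matrix) != ncol(W))
    stop(sprintf("shape mismatch: transform expects %d-dim codewords, got %d",
                 ncol(transform$matrix), ncol(W)), call. = FALSE)
  out <- W %*% t(transform$matrix)
  rownames(out) <- rownames(W)
  out
}

#' Verify the four transform constraints
#'
#' Checks, with measured residuals: (1) `N >= D`; (2) the pseudoinverse
#' relation `pinv(beta) beta = I` (relative residual, tolerance `tol`);
#' (3) equal column lengths `H`; (4) mean cross-product of distinct
#' columns near zero (within 3 standard errors of the cross-product
#' sample, the sampled-constraint analogue of exactness). An additional
#' `isometry` row reports the residual of `t(beta) beta = H^2 I`, the
#' property that makes distance scaling exact.
#'
#' @param transform A [make_transform()] object.
#' @param P Representation energy the transform was built for (defaults
#'   to the stored value).
#' @param tol Numerical tolerance for the deterministic constraints.
#' @return A data frame with columns `constraint`, `residual`, `pass`.
#' @export
verify_transform <- function(transform, P = transform$P, tol = 1e-8) {
  stopifnot(inherits(transform, "linear_transform"))
  b <- transform$matrix
  N <- nrow(b); D <- ncol(b)
  H <- sqrt(transform$V / P)

  ## constraint 2 via SVD pseudoinverse
  sv <- svd(b)
  pos <- sv$d > max(dim(b)) * .Machine$double.eps * sv$d[1]
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  r2 <- max(abs(pinv %*% b - diag(D)))

  ## constraint 3: column norms
  cn <- sqrt(colSums(b^2))
  r3 <- max(abs(cn - H)) / H

  ## constraint 4: mean cross-product of distinct columns vs 3 SE
  G <- crossprod(b)
  cross <- unlist(lapply(seq_len(D - 1L), function(j)
    as.vector(b[, j] * b[, (j + 1L):D, drop = FALSE])), use.names = FALSE)
  se <- if (length(cross) > 1) stats::sd(cross) / sqrt(length(cross)) else 0
  m4 <- if (D > 1) abs(mean(cross)) else 0
  pass4 <- if (D > 1) m4 <= max(3 * se, tol) else TRUE

  riso <- max(abs(G / H^2 - diag(D)))

  data.frame(
    constraint = c("N_ge_D", "pinv_identity", "equal_column_norms",
                   "zero_cross_products", "isometry"),
    residual = c(max(0, D - N), r2, r3, m4, riso),
    pass = c(N >= D, r2 <= tol * D, r3 <= tol,
             pass4, riso <= tol * D),
    stringsAsFactors = FALSE)
}
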