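#' Discrete multi-feature stimulus space
#'
#' A stimulus space is a grid of `K` features, each taking one of `n`
#' discrete values (uniform across features), for a total of `M = n^K`
#' stimuli. Feature values are represented as 1-based integer indices
#' `1..n`; what the values denote (orientations, colors, categories) is
#' immaterial, only equality between values matters.
#'
#' @param K Number of stimulus features (integer, >= 1).
#' @param n Number of values each feature can take (integer, >= 2).
#' @return An object of class `"stimulus_space"` with elements `K`, `n`,
#'   and `M = n^K`.
#' @examples
#' sp <- stimulus_space(3, 2)
#' sp$M  # 8
#' @export
stimulus_space <- function(K, n) {
  K <- as.integer(K)
  n <- as.integer(n)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("'K' must be a single integer >= 1", call. = FALSE)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  structure(list(K = K, n = n, M = as.integer(n^K)),
            class = "stimulus_space")
}

#' @export
print.stimulus_space <- function(x, ...) {
  cat(sprintf("Stimulus space: K = %d features x n = %d values (M = %d stimuli)\n",
              x$K, x$n, x$M))
  invisible(x)
}

#' Enumerate all stimuli of a space
#'
#' Stimuli are enumerated in a fixed deterministic order with the first
#' feature varying fastest (column-major), so stimulus `(1,1,...,1)` has
#' index 1 and `(n,n,...,n)` has index `M`. This ordering also fixes the
#' row order of every codebook.
#'
#' @param space A [stimulus_space()].
#' @return An `M x K` integer matrix; row `i` is the feature-value vector
#'   of the stimulus with index `i`.
#' @export
enumerate_stimuli <- function(space) {
  stopifnot(inherits(space, "stimulus_space"))
  g <- expand.grid(rep(list(seq_len(space$n)), space$K),
                   KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, paste0("f", seq_len(space$K)))
  storage.mode(m) <- "integer"
  m
}

#' Index of a stimulus in the enumeration order
#'
#' @param space A [stimulus_space()].
#' @param stimulus Length-`K` integer vector of feature values in `1..n`.
#' @return The 1-based index of the stimulus in [enumerate_stimuli()] order.
#' @export
stimulus_index <- function(space, stimulus) {
  validate_stimulus(space, stimulus)
  as.integer(1 + sum((stimulus - 1) * space$n^(seq_len(space$K) - 1)))
}

validate_stimulus <- function(space, stimulus) {
  if (length(stimulus) != space$K)
    stop(sprintf("stimulus must have length K = %d", space$K), call. = FALSE)
  if (any(stimulus < 1L | stimulus > space$n | stimulus != round(stimulus)))
    stop(sprintf("invalid stimulus: feature values must be integers in 1..%d",
                 space$n), call. = FALSE)
  invisible(TRUE)
}

#' Label stimuli by their feature values
#'
#' Produces compact labels such as `"211"` (or `"2-1-1"` when `n > 9`)
#' matching the presentation used for worked examples.
#'
#' @param space A [stimulus_space()].
#' @param stimuli Optional matrix of stimuli (default: full enumeration).
#' @return Character vector of labels.
#' @export
stimulus_labels <- function(space, stimuli = enumerate_stimuli(space)) {
  sep <- if (space$n > 9) "-" else ""
  apply(stimuli, 1L, paste, collapse = sep)
}
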