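#' Specification of a conjunctive code
#'
#' A code of order `O` has one coding unit per combination of `O` feature
#' values (one unit per value combination within each of the `choose(K, O)`
#' feature subsets). `O = 1` is a "pure" code (classical single-feature
#' selectivity); `O = K` is the fully mixed code where each unit is a
#' one-hot detector for a single stimulus. With receptive-field width
#' `rf_width > 1`, units respond to a contiguous interval of `rf_width`
#' values per feature instead of a single value.
#'
#' @param order Code order `O` (integer; validated against `K` when the
#'   spec is paired with a space).
#' @param rf_width Receptive-field width `sigma_rf` (integer >= 1,
#'   default 1). For `rf_width > 1`, the supported geometry requires
#'   `n` divisible by `rf_width`.
#' @param energy_variant How representation energy is measured:
#'   `"variance"` (summed across-stimulus response variance; the default
#'   in simulations, as it slightly favors pure codes and so is the
#'   conservative choice when demonstrating the benefit of mixing),
#'   `"squared_distance"` (squared norm of codewords; the variant used in
#'   the closed-form analytic expressions), or `"sum_of_spikes"` (count
#'   of active units).
#' @return An object of class `"code_spec"`.
#' @export
code_spec <- function(order, rf_width = 1L,
                      energy_variant = c("variance", "squared_distance",
                                         "sum_of_spikes")) {
  order <- as.integer(order)
  rf_width <- as.integer(rf_width)
  if (length(order) != 1L || is.na(order) || order < 1L)
    stop("'order' must be a single integer >= 1", call. = FALSE)
  if (length(rf_width) != 1L || is.na(rf_width) || rf_width < 1L)
    stop("'rf_width' must be a single integer >= 1", call. = FALSE)
  structure(list(order = order, rf_width = rf_width,
                 energy_variant = match.arg(energy_variant)),
            class = "code_spec")
}

#' @export
print.code_spec <- function(x, ...) {
  cat(sprintf("Code spec: order O = %d, rf_width = %d, energy variant = %s\n",
              x$order, x$rf_width, x$energy_variant))
  invisible(x)
}

check_spec <- function(space, spec) {
  if (spec$order > space$K)
    stop(sprintf("code order O = %d exceeds K = %d", spec$order, space$K),
         call. = FALSE)
  if (spec$rf_width > space$n)
    stop("rf_width cannot exceed n", call. = FALSE)
  if (spec$rf_width > 1L && space$n %% spec$rf_width != 0L)
    stop(sprintf(
      "unsupported geometry: rf_width = %d does not divide n = %d",
      spec$rf_width, space$n), call. = FALSE)
  invisible(TRUE)
}

## Per-axis value intervals at a given lattice offset. Offset 0 tiles
## 1..n exactly; offsets 1..(s-1) shift the tiling and truncate at both
## range ends, giving n/s + 1 intervals. Every value lies in exactly one
## interval per offset.
axis_intervals <- function(n, s, offset) {
  if (s == 1L)
    return(cbind(lo = seq_len(n), hi = seq_len(n)))
  if (offset == 0L) {
    lo <- seq(1L, n, by = s)
    cbind(lo = lo, hi = lo + s - 1L)
  } else {
    lo <- c(1L, seq(offset + 1L, n, by = s))
    cbind(lo = lo, hi = pmin(lo + s - 1L, c(offset, rep(n, length(lo) - 1L))))
  }
}

#' Build the codebook of a conjunctive code
#'
#' Constructs the full `M x D` binary stimulus-to-codeword map. Unit
#' (column) `k` corresponds to a feature subset `A` of size `O`, a lattice
#' offset (always 0 when `rf_width = 1`), and one value interval per
#' feature in `A`; its response to stimulus `x` is the product of interval
#' indicators, so it fires iff every feature in `A` falls in its interval.
#'
#' Columns are ordered by feature subset (lexicographic by default), then
#' lattice offset, then value combination with the first listed feature
#' varying fastest. Pass `subsets` to impose a different subset order
#' (e.g. to reproduce a particular printed table layout).
#'
#' @param space A [stimulus_space()].
#' @param spec A [code_spec()].
#' @param subsets Optional list of integer vectors: the ordered feature
#'   subsets of size `O` to use as subpopulations. Default: all
#'   `choose(K, O)` subsets in `utils::combn()` (lexicographic) order.
#' @return An object of class `"codebook"`: a list with `space`, `spec`,
#'   `words` (the `M x D` 0/1 matrix, rows named by stimulus label), and
#'   `units` (a data frame with one row per column: subset, offset, and
#'   interval bounds).
#' @examples
#' cb <- codebook(stimulus_space(3, 2), code_spec(2))
#' dim(cb$words)  # 8 x 12
#' @export
codebook <- function(space, spec, subsets = NULL) {
  stopifnot(inherits(space, "stimulus_space"), inherits(spec, "code_spec"))
  check_spec(space, spec)
  K <- space$K; n <- space$n; O <- spec$order; s <- spec$rf_width

  if (is.null(subsets)) {
    cmb <- utils::combn(K, O)
    subsets <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    subsets <- lapply(subsets, as.integer)
    ok <- vapply(subsets, function(a)
      length(a) == O && !anyDuplicated(a) && all(a >= 1L & a <= K), logical(1))
    if (!all(ok) || length(subsets) != choose(K, O) ||
        anyDuplicated(vapply(subsets, function(a) paste(sort(a), collapse = ","),
                             character(1))))
      stop("'subsets' must be an ordering of all size-O feature subsets",
           call. = FALSE)
  }

  X <- enumerate_stimuli(space)
  unit_subset <- list(); unit_offset <- integer(); unit_lo <- list(); unit_hi <- list()
  cols <- list()
  for (A in subsets) {
    for (off in 0:(s - 1L)) {
      iv <- axis_intervals(n, s, off)
      ## value-interval combinations, first listed feature fastest
      combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(iv))), O),
                                      KEEP.OUT.ATTRS = FALSE))
      for (r in seq_len(nrow(combos))) {
        lo <- iv[combos[r, ], "lo"]; hi <- iv[combos[r, ], "hi"]
        act <- rep(TRUE, space$M)
        for (j in seq_len(O))
          act <- act & X[, A[j]] >= lo[j] & X[, A[j]] <= hi[j]
        cols[[length(cols) + 1L]] <- as.integer(act)
        unit_subset[[length(unit_subset) + 1L]] <- A
        unit_offset <- c(unit_offset, off)
        unit_lo[[length(unit_lo) + 1L]] <- lo
        unit_hi[[length(unit_hi) + 1L]] <- hi
      }
    }
  }
  words <- do.call(cbind, cols)
  rownames(words) <- stimulus_labels(space, X)
  units <- data.frame(
    subset = I(unit_subset), offset = unit_offset,
    lo = I(unit_lo), hi = I(unit_hi))
  units$label <- vapply(seq_len(nrow(units)), function(k) {
    a <- unit_subset[[k]]
    iv <- vapply(seq_along(a), function(j) {
      if (unit_lo[[k]][j] == unit_hi[[k]][j]) as.character(unit_lo[[k]][j])
      else paste0(unit_lo[[k]][j], ":", unit_hi[[k]][j])
    }, character(1))
    paste0("f", paste(a, collapse = ","), "=", paste(iv, collapse = ","),
           if (s > 1L) paste0("|o", unit_offset[k]) else "")
  }, character(1))
  colnames(words) <- units$label
  structure(list(space = space, spec = spec, words = words, units = units),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf(
    "Conjunctive codebook: K = %d, n = %d, O = %d, rf_width = %d; %d stimuli x %d units\n",
    x$space$K, x$space$n, x$spec$order, x$spec$rf_width,
    nrow(x$words), ncol(x$words)))
  invisible(x)
}

#' Encode a stimulus into its binary codeword
#'
#' @param cb A [codebook()].
#' @param stimulus Length-`K` integer vector of feature values in `1..n`.
#' @return The binary codeword (length `D` integer vector).
#' @examples
#' cb <- codebook(stimulus_space(3, 2), code_spec(1))
#' encode(cb, c(1, 1, 1))  # 1 0 1 0 1 0
#' @export
encode <- function(cb, stimulus) {
  stopifnot(inherits(cb, "codebook"))
  idx <- stimulus_index(cb$space, stimulus)
  cw <- cb$words[idx, ]
  names(cw) <- NULL
  cw
}

#' Number of coordinates at which two codewords differ
#'
#' The worked examples quote "distance 2" between codewords; for binary
#' codewords that count of differing coordinates equals the squared
#' Euclidean distance and is exposed separately from the Euclidean
#' distance itself.
#'
#' @param a,b Codewords (numeric vectors of equal length).
#' @return Integer count of positions where `a` and `b` disagree.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("codewords differ in length", call. = FALSE)
  sum(a != b)
}

#' Export a codebook as CSV and JSON metadata
#'
#' Writes `<stem>.csv` (rows = stimuli labeled by feature-value tuple,
#' columns = unit labels) and `<stem>.json` (K, n, O, rf_width, D, P,
#' min distance).
#'
#' @param cb A [codebook()].
#' @param stem Output path stem (no extension).
#' @return Invisibly, the two file paths.
#' @export
export_codebook <- function(cb, stem) {
  df <- data.frame(stimulus = rownames(cb$words), cb$words,
                   check.names = FALSE)
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(K = cb$space$K, n = cb$space$n, O = cb$spec$order,
               rf_width = cb$spec$rf_width,
               D = ncol(cb$words),
               P = representation_energy(cb$space, cb$spec),
               min_distance = min_distance(cb$space$K, cb$spec$order))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
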