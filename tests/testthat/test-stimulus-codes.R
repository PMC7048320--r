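test_that("stimulus enumeration covers the space exactly once, in order", {
  sp <- stimulus_space(1, 3)
  X <- enumerate_stimuli(sp)
  expect_equal(nrow(X), 3L)
  expect_equal(X[, 1], 1:3)

  sp <- stimulus_space(2, 4)
  X <- enumerate_stimuli(sp)
  expect_equal(nrow(X), 16L)
  expect_equal(nrow(unique(X)), 16L)

  sp <- stimulus_space(3, 2)
  X <- enumerate_stimuli(sp)
  expect_equal(sp$M, 8L)
  ## first feature varies fastest; indices invert the enumeration
  expect_equal(X[2, ], c(f1 = 2L, f2 = 1L, f3 = 1L))
  for (i in seq_len(8)) expect_equal(stimulus_index(sp, X[i, ]), i)
})

test_that("invalid spaces and stimuli are rejected", {
  expect_error(stimulus_space(0, 3), "K")
  expect_error(stimulus_space(2, 1), "n")
  sp <- stimulus_space(2, 3)
  expect_error(stimulus_index(sp, c(1, 4)), "invalid stimulus")
  expect_error(stimulus_index(sp, c(1, 2, 3)), "length")
  expect_error(encode(codebook(sp, code_spec(1)), c(0, 2)), "invalid stimulus")
})

test_that("worked-example codewords match the printed tables", {
  fx <- make_fixtures()
  expect_equal(encode(fx$O1, c(1, 1, 1)), c(1, 0, 1, 0, 1, 0))
  expect_equal(encode(fx$O1, c(2, 1, 1)), c(0, 1, 1, 0, 1, 0))
  expect_equal(encode(fx$O1, c(1, 2, 2)), c(1, 0, 0, 1, 0, 1))
  expect_equal(encode(fx$O1, c(2, 2, 2)), c(0, 1, 0, 1, 0, 1))

  expect_equal(encode(fx$O2, c(1, 1, 1)),
               c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(encode(fx$O2, c(2, 1, 1)),
               c(0, 1, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(encode(fx$O2, c(1, 2, 2)),
               c(0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 1, 0))
  expect_equal(encode(fx$O2, c(2, 2, 2)),
               c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1))

  ## fully mixed code: one-hot rows in enumeration order
  expect_equal(unname(fx$O3$words), diag(8))
})

test_that("population size follows the closed form", {
  sp <- stimulus_space(3, 2)
  expect_equal(population_size(sp, code_spec(2)), 12)
  expect_equal(population_size(sp, code_spec(3)), 8)
  expect_equal(population_size(sp, code_spec(1)), 6)  # K * n
  for (K in 1:4) for (n in 2:4) for (O in 1:K) {
    spc <- stimulus_space(K, n)
    cb <- codebook(spc, code_spec(O))
    expect_equal(ncol(cb$words), choose(K, O) * n^O)
    expect_equal(population_size(spc, code_spec(O)), choose(K, O) * n^O)
  }
  ## rf geometry errors
  expect_error(codebook(stimulus_space(2, 5), code_spec(2, 2)),
               "unsupported geometry")
  ## O = 1 population size is rf-width independent by the closed form
  expect_equal(population_size(stimulus_space(3, 10), code_spec(1, 2)), 30)
})

test_that("representation energy matches its three accounting variants", {
  sp <- stimulus_space(3, 2)
  expect_equal(representation_energy(sp, code_spec(2, energy_variant = "squared_distance")), 3)
  expect_equal(representation_energy(sp, code_spec(1, energy_variant = "squared_distance")), 3)
  for (K in 2:4)
    expect_equal(representation_energy(stimulus_space(K, 3),
                                       code_spec(K, energy_variant = "squared_distance")), 1)
  ## variance variant equals summed Bernoulli variances of the codebook
  for (K in 2:3) for (n in 2:3) for (O in 1:K) {
    spc <- stimulus_space(K, n)
    cb <- codebook(spc, code_spec(O))
    p <- colMeans(cb$words)
    expect_equal(representation_energy(spc, code_spec(O, energy_variant = "variance")),
                 sum(p * (1 - p)))
  }
  ## sum of spikes equals the (constant) per-stimulus active count
  cb <- codebook(sp, code_spec(2))
  expect_equal(representation_energy(sp, code_spec(2, energy_variant = "sum_of_spikes")),
               unname(rowSums(cb$words)[1]))
})

test_that("codewords are distinct, constant-weight, with norm equal to P", {
  for (K in 1:4) for (n in 2:4) for (O in 1:K) {
    spc <- stimulus_space(K, n)
    cb <- codebook(spc, code_spec(O, energy_variant = "squared_distance"))
    expect_equal(nrow(unique(cb$words)), spc$M)
    w <- rowSums(cb$words)
    expect_true(all(w == choose(K, O)))
    expect_equal(unname(rowSums(cb$words^2)),
                 rep(representation_energy(spc, cb$spec), spc$M))
  }
})

test_that("distance spectrum matches brute force and is monotone in v", {
  expect_equal(pairwise_distance(3, 2, 1), 2.0)
  expect_equal(min_distance(3, 2), 2.0)
  expect_equal(min_distance(5, 1), sqrt(2))
  expect_equal(min_distance(6, 4), sqrt(2 * choose(5, 3)))
  for (K in 2:4)
    expect_equal(pairwise_distance(K, K, K), sqrt(2))

  for (K in 2:4) for (n in 2:4) for (O in 1:K) {
    spc <- stimulus_space(K, n)
    cb <- codebook(spc, code_spec(O))
    bf <- bf_distance_by_v(cb)
    for (v in unique(bf$v))
      expect_equal(unique(round(bf$d[bf$v == v], 10)),
                   round(pairwise_distance(K, O, v), 10))
    expect_equal(min(bf$d), min_distance(K, O))
    ## monotone non-decreasing spectrum; for O < K the single-feature
    ## distance is strictly the smallest, which pins the minimum at v = 1
    d <- pairwise_distance(K, O, seq_len(K))
    expect_true(all(diff(d) >= -1e-12))
    if (O < K && K > 1) expect_lt(d[1], d[2])
  }
})

test_that("distance-energy ratio is exactly 2 O / K", {
  expect_equal(distance_ratio(6, 3), 1.0)
  for (K in 1:8) for (O in 1:K) {
    expect_identical(distance_ratio(K, O), 2 * O / K)
    expect_equal(min_distance(K, O)^2 / choose(K, O), 2 * O / K)
  }
  expect_equal(distance_ratio(4, 4), 2)
  ## strictly increasing in O
  expect_true(all(diff(distance_ratio(6, 1:6)) > 0))
})

test_that("neighbor counts match brute force and closed forms", {
  sp <- stimulus_space(3, 5)
  expect_equal(count_at_distance(sp, 1), 12)
  expect_equal(sum(count_at_distance(sp, 1:3)), 124)
  expect_equal(count_at_distance(stimulus_space(1, 2), 1), 1)
  expect_equal(neighbors_at_min_distance(sp, 2), 12)
  expect_equal(neighbors_at_min_distance(sp, 3), 124)
  expect_equal(neighbors_at_min_distance(stimulus_space(1, 2), 1), 1)

  for (K in 2:3) for (n in 2:4) for (O in 1:K) {
    spc <- stimulus_space(K, n)
    counts <- bf_nearest_counts(codebook(spc, code_spec(O)))
    expect_true(all(counts == neighbors_at_min_distance(spc, O)))
  }
})

test_that("single-feature neighbor counts follow the O < K / O = K split", {
  expect_equal(feature_neighbors(stimulus_space(2, 2), 1), 1)
  expect_equal(feature_neighbors(stimulus_space(2, 2), 2), 2)
  expect_equal(feature_neighbors(stimulus_space(4, 3), 4), 54)
})

test_that("distance multisets are identical across stimuli (symmetry)", {
  for (O in 1:3) {
    cb <- codebook(stimulus_space(3, 3), code_spec(O))
    dm <- as.matrix(stats::dist(cb$words))
    ref <- unname(sort(round(dm[1, -1], 9)))
    for (i in 2:nrow(dm))
      expect_equal(unname(sort(round(dm[i, -i], 9))), ref)
  }
})

test_that("hamming distance counts differing coordinates", {
  expect_equal(hamming_distance(c(1, 0, 1), c(1, 1, 0)), 2)
  expect_error(hamming_distance(c(1, 0), c(1, 0, 1)), "length")
  ## worked example: one-feature-apart O = 1 codewords differ in 2 coords
  cb <- codebook(stimulus_space(3, 2), code_spec(1))
  expect_equal(hamming_distance(encode(cb, c(1, 1, 1)), encode(cb, c(2, 1, 1))), 2)
})

test_that("codebook export writes readable CSV and JSON", {
  tmp <- tempfile()
  cb <- codebook(stimulus_space(2, 2), code_spec(2))
  paths <- export_codebook(cb, tmp)
  df <- utils::read.csv(paths[1], check.names = FALSE)
  expect_equal(nrow(df), 4L)
  expect_equal(ncol(df), 5L)  # stimulus label + 4 units
  meta <- jsonlite::read_json(paths[2])
  expect_equal(meta$D, 4L)
  expect_equal(meta$K, 2L)
  unlink(paths)
})
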