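test_that("channel configs validate their parameters", {
  expect_error(channel_config("gaussian", sigma2 = 0), "sigma2")
  expect_error(channel_config("poisson_baseline", r_spont = 0), "r_spont")
  expect_error(channel_config(p_shift = 1.5), "probabilities")
})

test_that("gaussian transmission adds noise with the configured variance", {
  cfg <- channel_config("gaussian", sigma2 = 4)
  cw <- c(1, 0, 2)
  set.seed(1)
  R <- transmit(matrix(rep(cw, each = 10000), 10000, 3), cfg)
  expect_equal(unname(colMeans(R)), cw, tolerance = 0.1)
  expect_equal(unname(apply(R, 2, stats::var)), rep(4, 3), tolerance = 0.2)
  ## near-zero noise returns the codeword
  cfg0 <- channel_config("gaussian", sigma2 = 1e-20)
  expect_equal(transmit(cw, cfg0), cw, tolerance = 1e-8)
  ## reproducible given the seed
  set.seed(9); a <- transmit(cw, cfg)
  set.seed(9); b <- transmit(cw, cfg)
  expect_identical(a, b)
})

test_that("poisson transmission draws counts at the configured rates", {
  cfg <- channel_config("poisson")
  set.seed(2)
  R <- transmit(matrix(rep(c(0, 3), each = 5000), 5000, 2), cfg)
  expect_true(all(R[, 1] == 0))  # zero rate -> zero counts, exactly
  expect_equal(mean(R[, 2]), 3, tolerance = 0.1)
  expect_error(transmit(c(-1, 2), cfg), "negative Poisson means")
})

test_that("local input noise shifts features at the configured rate", {
  sp <- stimulus_space(1, 5)
  cfg <- channel_config(input_noise = "local", p_shift = 0.3)
  set.seed(3)
  X <- matrix(3L, 10000, 1)
  Y <- perturb_input(X, sp, cfg)
  expect_true(all(abs(Y - X) <= 1))
  expect_equal(mean(Y != X), 0.3, tolerance = 0.03)
  ## p = 0 is the identity
  cfg0 <- channel_config(input_noise = "local", p_shift = 0)
  expect_identical(perturb_input(X, sp, cfg0), X)
  ## boundary values always shift inward
  cfg1 <- channel_config(input_noise = "local", p_shift = 1)
  set.seed(4)
  Y1 <- perturb_input(matrix(1L, 500, 1), sp, cfg1)
  expect_true(all(Y1 == 2L))
  Yn <- perturb_input(matrix(5L, 500, 1), sp, cfg1)
  expect_true(all(Yn == 4L))
})

test_that("ML decoding is nearest-codeword under gaussian noise", {
  cb <- codebook(stimulus_space(2, 3), code_spec(2))
  cfg <- channel_config("gaussian", sigma2 = 1)
  ## noiseless responses decode to themselves
  dec <- ml_decode(cb$words, cb$words, cfg)
  expect_equal(dec$index, 1:9)
  expect_false(any(dec$tie))
  ## agreement with exhaustive likelihood evaluation
  set.seed(5)
  R <- transmit(cb$words[rep(1:9, 20), ], cfg)
  dec <- ml_decode(R, cb$words, cfg)
  bf <- apply(R, 1, bf_ml_decode, rates = cb$words, noise = "gaussian")
  expect_equal(dec$index, unname(bf))
})

test_that("midway responses tie toward the lowest index, flagged", {
  C <- rbind(c(1, 0), c(0, 1))
  cfg <- channel_config("gaussian")
  dec <- ml_decode(c(0.5, 0.5), C, cfg)
  expect_equal(dec$index, 1L)
  expect_true(dec$tie)
})

test_that("poisson ML decoding matches exhaustive likelihoods and handles zero rates", {
  cb <- codebook(stimulus_space(2, 3), code_spec(2))
  H <- 4
  rates <- H * cb$words
  cfg <- channel_config("poisson")
  set.seed(6)
  R <- transmit(rates[rep(1:9, 30), ], cfg)
  dec <- ml_decode(R, rates, cfg)
  bf <- apply(R, 1, bf_ml_decode, rates = rates, noise = "poisson")
  expect_equal(dec$index, unname(bf))
  ## a count observed at a zero-rate coordinate excludes that codeword:
  ## a single spike at stimulus 2's unit leaves only codeword 2 possible
  r <- numeric(ncol(rates)); r[which(rates[2, ] > 0)[1]] <- 1
  dec <- ml_decode(r, rates, cfg)
  expect_equal(dec$index, 2L)
  expect_false(dec$tie)
})

test_that("simulation is reproducible and near-perfect at extreme SNR", {
  sp <- stimulus_space(2, 3)
  r1 <- simulate_code(sp, code_spec(2), snr = 400, n_trials = 400, seed = 10)
  expect_equal(r1$pe, 0)
  expect_equal(r1$mse, 0)
  r2 <- simulate_code(sp, code_spec(2), snr = 400, n_trials = 400, seed = 10)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("confusion matrix accounting is self-consistent", {
  sp <- stimulus_space(2, 3)
  res <- simulate_code(sp, code_spec(1), snr = 5, n_trials = 2000, seed = 11)
  expect_equal(sum(res$confusion), 2000)
  expect_equal(1 - sum(diag(res$confusion)) / 2000, res$pe)
  expect_gte(res$pe, 0); expect_lte(res$pe, 1)
  ## errors cost at least one squared feature step
  expect_gte(res$mse, res$pe)
})

test_that("per-stimulus error rates are homogeneous (code symmetry)", {
  sp <- stimulus_space(2, 3)
  res <- simulate_code(sp, code_spec(2), snr = 6, n_trials = 6000, seed = 12)
  pres <- rowSums(res$confusion)
  errs <- pres - diag(res$confusion)
  ct <- suppressWarnings(stats::chisq.test(cbind(errs, pres - errs)))
  expect_gt(ct$p.value, 0.01)
})

test_that("PE is invariant to transform style at fixed V", {
  sp <- stimulus_space(2, 3)
  spec <- code_spec(2)
  cb <- codebook(sp, spec)
  P <- representation_energy(sp, spec)
  cfg <- channel_config("gaussian", sigma2 = 1)
  V <- 6
  pes <- ses <- numeric(0)
  for (style in c("identity_scaled", "random_rotation", "random_embedding")) {
    N <- if (style == "random_embedding") 18 else 9
    tr <- make_transform(9, N, V = V, P = P, style = style, seed = 21)
    res <- simulate_channel(sp, spec, tr, cfg, n_trials = 4000, seed = 22,
                            codebook_obj = cb)
    pes <- c(pes, res$pe); ses <- c(ses, res$pe_se)
  }
  for (i in 2:3)
    expect_lt(abs(pes[i] - pes[1]), 3 * sqrt(ses[i]^2 + ses[1]^2))
})

test_that("local input noise alone affects all orders equally", {
  sp <- stimulus_space(3, 5)
  cfg <- channel_config("gaussian", sigma2 = 1e-12,
                        input_noise = "local", p_shift = 0.2)
  ## vanishing output noise at finite V: errors come from the input alone
  pes <- vapply(1:3, function(O)
    simulate_code(sp, code_spec(O), snr = 1e12, n_trials = 3000, seed = 30,
                  config = cfg)$pe, numeric(1))
  ## PE equals the probability any feature shifted, independent of order
  expected <- 1 - (1 - 0.2)^3
  for (pe in pes) expect_equal(pe, expected, tolerance = 0.07)
  expect_lt(max(pes) - min(pes), 0.05)
})

test_that("bit-flip input noise feeds the conjunctive encoder (both pipelines)", {
  sp <- stimulus_space(2, 2)
  for (pipe in c("direct", "clean")) {
    cfg0 <- channel_config("gaussian", sigma2 = 1e-12, input_noise = "bitflip",
                           p_flip = 0, bitflip_pipeline = pipe)
    res <- simulate_code(sp, code_spec(2), snr = 1e12, n_trials = 300, seed = 31,
                         config = cfg0)
    expect_equal(res$pe, 0)  # p = 0 is the identity
    cfg <- channel_config("gaussian", sigma2 = 1e-12, input_noise = "bitflip",
                          p_flip = 0.2, bitflip_pipeline = pipe)
    res <- simulate_code(sp, code_spec(2), snr = 1e12, n_trials = 1500, seed = 32,
                         config = cfg)
    expect_gt(res$pe, 0.05)
    expect_lt(res$pe, 0.9)
  }
})

test_that("circular MSE metric wraps the feature topology", {
  sp <- stimulus_space(1, 6)
  lin <- simulate_code(sp, code_spec(1), snr = 3, n_trials = 4000, seed = 2,
                       mse_metric = "linear")
  cir <- simulate_code(sp, code_spec(1), snr = 3, n_trials = 4000, seed = 2,
                       mse_metric = "circular")
  ## same trials, same errors; wrap-around can only shrink distances
  expect_equal(cir$pe, lin$pe)
  expect_lt(cir$mse, lin$mse)
  ## circular squared distance is capped at (n/2)^2 per feature
  expect_lte(max(cir$squared_errors), 9)
})
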