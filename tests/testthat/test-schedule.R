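test_that("linear schedule matches an independent cumulative product", {
  sch <- build_noise_schedule(5L, beta_start = 0.02, beta_end = 0.1)
  expect_length(sch$betas, 5L)
  ## brute-force product oracle
  betas <- seq(0.02, 0.1, length.out = 5)
  ab <- numeric(5)
  acc <- 1
  for (t in 1:5) { acc <- acc * (1 - betas[t]); ab[t] <- acc }
  expect_equal(sch$alpha_bars, ab, tolerance = 1e-12)
  expect_true(all(diff(sch$alpha_bars) < 0))
  expect_true(all(sch$alpha_bars > 0 & sch$alpha_bars < 1))

  one <- build_noise_schedule(1L, beta_start = 0.1, beta_end = 0.1)
  expect_equal(one$alpha_bars, 0.9)

  big <- build_noise_schedule(1000L)
  expect_length(big$alpha_bars, 1000L)
  expect_true(all(diff(big$alpha_bars) < 0))
})

test_that("schedule construction rejects invalid inputs", {
  expect_error(build_noise_schedule(0L), "integer")
  expect_error(build_noise_schedule(10L, beta_start = 0, beta_end = 0.1), "betas")
  expect_error(build_noise_schedule(10L, beta_start = 0.5, beta_end = 1), "betas")
  expect_error(build_noise_schedule(10L, beta_start = 0.3, beta_end = 0.1), "betas")
})

test_that("q_sample follows the closed-form marginal", {
  sch <- build_noise_schedule(10L, beta_start = 0.01, beta_end = 0.1)
  set.seed(2)
  x0 <- random_patch(8L)
  ## zero noise
  expect_equal(q_sample(x0, 3L, x0 * 0, sch),
               sqrt(sch$alpha_bars[4]) * x0, tolerance = 1e-12)
  ## near-identity limit at tiny t with tiny beta
  sch2 <- build_noise_schedule(10L, beta_start = 1e-6, beta_end = 1e-5)
  eps <- random_patch(8L)
  expect_equal(q_sample(x0, 0L, eps, sch2), x0, tolerance = 1e-2)
  ## element-wise scalar-loop oracle at t = 7
  eps <- random_patch(8L)
  got <- q_sample(x0, 7L, eps, sch)
  ab <- sch$alpha_bars[8]
  want <- x0
  for (i in seq_along(x0)) want[i] <- sqrt(ab) * x0[i] + sqrt(1 - ab) * eps[i]
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(q_sample(x0, 10L, eps, sch), "range")
  expect_error(q_sample(x0, -1L, eps, sch), "range")
})

test_that("predict_x0 inverts q_sample and matches the scalar oracle", {
  sch <- build_noise_schedule(10L, beta_start = 0.01, beta_end = 0.1)
  set.seed(3)
  for (t in c(0L, 4L, 9L)) {
    x0 <- random_patch(8L)
    eps <- random_patch(8L)
    xt <- q_sample(x0, t, eps, sch)
    expect_equal(predict_x0(xt, eps, t, sch), x0, tolerance = 1e-10)
  }
  x0 <- random_patch(8L); eps_hat <- random_patch(8L)
  xt <- q_sample(x0, 5L, random_patch(8L), sch)
  ab <- sch$alpha_bars[6]
  want <- xt
  for (i in seq_along(xt)) want[i] <- (xt[i] - sqrt(1 - ab) * eps_hat[i]) / sqrt(ab)
  expect_equal(predict_x0(xt, eps_hat, 5L, sch), want, tolerance = 1e-12)
  ## eps_hat = 0 reduces to rescaling
  expect_equal(predict_x0(xt, xt * 0, 5L, sch), xt / sqrt(ab), tolerance = 1e-12)
})

test_that("round-trip identity holds over random triples", {
  sch <- build_noise_schedule(50L)
  set.seed(4)
  for (i in 1:25) {
    t <- sample.int(50L, 1L) - 1L
    x0 <- random_patch(8L)
    eps <- random_patch(8L)
    back <- predict_x0(q_sample(x0, t, eps, sch), eps, t, sch)
    expect_lt(max(abs(back - x0)) / max(abs(x0)), 1e-5)
  }
})

test_that("training loss of a zero-output model is the noise variance", {
  ## a freshly built denoiser has a zero-initialized output layer, so it
  ## predicts exactly zero noise: the MSE equals mean(eps^2) ~ 1
  reg <- condition_registry(c("A", "B"), c("G1", "G2"))
  cfg <- denoiser_config(8L, base_channels = 4L,
                         channel_multipliers = c(1L, 2L), embedding_dim = 8L)
  model <- build_denoiser(cfg, reg, seed = 0L)
  sch <- build_noise_schedule(20L)
  set.seed(9)
  batch <- lapply(1:8, function(i)
    list(id = paste0("it", i), x0 = random_patch(8L),
         bundle = full_bundle(sample(c("A", "B"), 1))))
  loss <- training_loss(model, batch, sch, rng_seed = 21L)
  expect_gt(loss, 0)
  ## d = 8*8*3*8 = 1536 noise draws; sd of mean(eps^2) ~ sqrt(2/1536)
  expect_lt(abs(loss - 1), 5 * sqrt(2 / 1536))
})

test_that("training loss is deterministic and batch-order invariant", {
  reg <- condition_registry(c("A", "B"), c("G1", "G2"))
  cfg <- denoiser_config(8L, base_channels = 4L,
                         channel_multipliers = c(1L, 2L), embedding_dim = 8L)
  model <- build_denoiser(cfg, reg, seed = 1L)
  sch <- build_noise_schedule(20L)
  set.seed(10)
  batch <- lapply(1:5, function(i)
    list(id = paste0("x", i), x0 = random_patch(8L), bundle = full_bundle("A")))
  l1 <- training_loss(model, batch, sch, rng_seed = 77L)
  l2 <- training_loss(model, batch, sch, rng_seed = 77L)
  expect_identical(l1, l2)
  l3 <- training_loss(model, rev(batch), sch, rng_seed = 77L)
  expect_equal(l1, l3, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(l1, training_loss(model, batch, sch, 78L))))
})
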