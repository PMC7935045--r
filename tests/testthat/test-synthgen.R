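test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(n_subjects = 0), "counts")
  expect_error(synth_config(within_block_mass = 1.2), "within_block_mass")
  expect_error(synth_config(behavior_coupling = 1.5), "behavior_coupling")
  expect_error(tiny_config(transition_blocks = list(1:2)), "partition")
  expect_error(generate_hmm_timeseries(tiny_config(noise_sd = 0)),
               "degenerate")
})

test_that("single-state chains are constant with unit occupancy", {
  cfg <- tiny_config(n_states = 1, transition_blocks = list(1L))
  sim <- generate_hmm_timeseries(cfg)
  for (p in sim$truth$state_paths) expect_true(all(p == 1L))
  expect_true(all(sim$truth$true_FO == 1))
})

test_that("full-scale design reproduces the study concatenation shape", {
  cfg <- synth_config(full_scale = TRUE, seed = 2)
  expect_equal(cfg$n_nodes, 439L)
  sim <- generate_hmm_timeseries(cfg)
  total_rows <- sum(vapply(sim$timeseries, function(t) nrow(t$data), 1L))
  expect_equal(total_rows, 360 * 23 + 360 * 23 + 360 * 18)
  expect_equal(ncol(sim$timeseries[[1]]$data), 439L)
})

test_that("long chains match the stationary distribution of the transition matrix", {
  cfg <- tiny_config(n_subjects = 1, sessions_per_subject = 1,
                     runs_per_session = 1, timepoints_per_run = 50000,
                     seed = 11)
  sim <- generate_hmm_timeseries(cfg)
  Theta <- sim$truth$true_model$transition
  freq <- sim$truth$true_FO[1, ]
  expect_lt(max(abs(freq - stationary_distribution(Theta))), 0.01)
})

test_that("transition counts of generated paths converge to the generating matrix", {
  cfg <- tiny_config(n_subjects = 1, sessions_per_subject = 1,
                     runs_per_session = 1, timepoints_per_run = 10000,
                     seed = 12)
  sim <- generate_hmm_timeseries(cfg)
  p <- sim$truth$state_paths[[1]]
  K <- cfg$n_states
  counts <- matrix(0, K, K)
  for (t in 2:length(p)) counts[p[t - 1], p[t]] <- counts[p[t - 1], p[t]] + 1
  emp <- counts / rowSums(counts)
  expect_lte(max(abs(emp - sim$truth$true_model$transition)), 0.05)
})

test_that("true fractional occupancies are simplex rows and regeneration is bit-identical", {
  cfg <- tiny_config()
  sim1 <- generate_hmm_timeseries(cfg)
  sim2 <- generate_hmm_timeseries(cfg)
  expect_equal(unname(rowSums(sim1$truth$true_FO)),
               rep(1, nrow(sim1$truth$true_FO)))
  expect_identical(sim1$truth$state_paths, sim2$truth$state_paths)
  expect_identical(sim1$timeseries[[1]]$data, sim2$timeseries[[1]]$data)
  b1 <- generate_behavior(sim1$truth, cfg)
  b2 <- generate_behavior(sim2$truth, cfg)
  expect_identical(b1, b2)
  m1 <- generate_motion(cfg)
  m2 <- generate_motion(cfg)
  expect_identical(m1, m2)
})

test_that("behavior coupling plants the requested brain-behavior correlation", {
  big <- function(rho, seed) {
    cfg <- tiny_config(n_subjects = 500, sessions_per_subject = 2,
                       runs_per_session = 1, timepoints_per_run = 30,
                       behavior_coupling = rho, seed = seed)
    beh <- generate_behavior(generate_hmm_timeseries(cfg)$truth, cfg)
    attr(beh, "planted")
  }
  p0 <- big(0, 21)
  expect_lt(abs(cor(p0$brain_score[1:300], p0$behavior_score[1:300])), 0.15)
  p85 <- big(0.85, 22)
  expect_lt(abs(cor(p85$brain_score, p85$behavior_score) - 0.85), 0.05)
  cfg1 <- tiny_config(behavior_coupling = 1)
  truth1 <- generate_hmm_timeseries(cfg1)$truth
  p1 <- attr(generate_behavior(truth1, cfg1, measure_noise = 0), "planted")
  expect_equal(cor(p1$brain_score, p1$behavior_score), 1.0, tolerance = 1e-12)
})

test_that("behavior table has the 31-measure battery with identifiers", {
  cfg <- tiny_config()
  beh <- generate_behavior(generate_hmm_timeseries(cfg)$truth, cfg)
  expect_equal(ncol(beh), 33)  # subject + session + 31 measures
  expect_true(all(c("subject", "session") %in% names(beh)))
  expect_equal(nrow(beh), sum(cfg$sessions_per_subject))
})

test_that("zero-amplitude motion is exactly still and spikes dominate FD", {
  cfg <- tiny_config(n_subjects = 1, sessions_per_subject = 1,
                     runs_per_session = 1)
  still <- generate_motion(cfg, translation_step = 0, rotation_step = 0,
                           spike_prob = 0)[[1]]
  expect_true(all(still == 0))
  expect_true(all(framewise_displacement(still) == 0))
  spiked <- still
  spiked[20, 1] <- 1          # 1 mm x-translation for one frame
  fd <- framewise_displacement(spiked)
  expect_equal(which.max(fd), 20)
  expect_equal(fd[20], 1)
})

test_that("phase randomization preserves amplitude spectrum, mean, and autocorrelation", {
  set.seed(9)
  n <- 2048
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), n))
  X <- cbind(x, stats::rnorm(n))
  Y <- phase_randomize(X, seed = 4)
  for (j in 1:2) {
    expect_lt(max(abs(Mod(stats::fft(Y[, j])) - Mod(stats::fft(X[, j])))),
              1e-8 * max(Mod(stats::fft(X[, j]))))
    expect_lt(abs(mean(Y[, j]) - mean(X[, j])), 1e-10)
  }
  ac <- function(v) stats::cor(v[-1], v[-length(v)])
  expect_lt(abs(ac(Y[, 1]) - ac(X[, 1])), 0.1)
  expect_error(phase_randomize(matrix(c(1, NA, 3, 4), 2)), "non-finite")
})
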