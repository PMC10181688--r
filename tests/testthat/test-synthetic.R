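# The synthetic experiment generator: ground truths, condition runs,
# channel expansion, and the block-design experiment.

test_that("ground truths are sparse, stable and reproducible", {
  t0 <- make_ground_truth(M = 5, K = 2, sparsity = 0, seed = 3)
  off <- t0$phi0[[1]][row(diag(5)) != col(diag(5))]
  expect_true(all(off == 0))                       # sparsity 0 -> diagonal only
  expect_true(all(vapply(t0$deltas, function(d) all(d[[1]] == 0), logical(1))))

  t1 <- make_ground_truth(seed = 42)
  t2 <- make_ground_truth(seed = 42)
  expect_identical(t1, t2)

  for (seed in 1:8) {
    tt <- make_ground_truth(M = 6, K = 4, sparsity = 0.3, effect_size = 0.5,
                            seed = seed)
    rads <- c(companion_spectral_radius(tt$phi0),
              vapply(seq_len(tt$K), function(k) {
                companion_spectral_radius(cdvar:::truth_phi(tt, k))
              }, numeric(1)))
    expect_true(all(rads < 0.95))
  }
})

test_that("condition runs reproduce known second-order properties", {
  # pure-noise truth: sample covariance approaches the innovation covariance
  tt <- make_ground_truth(M = 3, K = 0, sparsity = 0, diag_coef = 0,
                          resid_cov = diag(c(1, 2, 0.5)), seed = 1)
  g <- simulate_condition_run(tt, 0, 20000, seed = 2)
  expect_lt(max(abs(cov(t(g)) - diag(c(1, 2, 0.5)))) / 2, 0.1)

  # AR(1) with phi = 0.9: lag-1 autocorrelation ~ 0.9
  ar <- make_ground_truth(M = 1, K = 0, sparsity = 0, diag_coef = 0.9, seed = 1)
  x <- simulate_condition_run(ar, 0, 10000, seed = 3)[1, ]
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.9), 0.05)

  expect_identical(simulate_condition_run(tt, 0, 100, seed = 9),
                   simulate_condition_run(tt, 0, 100, seed = 9))
  expect_error(simulate_condition_run(tt, 3, 10, seed = 1),
               class = "cdvar_validation_error")

  unstable <- tt
  unstable$phi0[[1]] <- diag(1.05, 3)
  expect_error(simulate_condition_run(unstable, 0, 10, seed = 1),
               class = "cdvar_numerical_error")

  # heavy-tailed innovations keep unit scale but gain kurtosis
  y_g <- simulate_condition_run(ar, 0, 8000, seed = 4)[1, ]
  y_t <- simulate_condition_run(ar, 0, 8000, seed = 4, innovation_df = 3)[1, ]
  kurt <- function(v) mean((v - mean(v))^4) / stats::sd(v)^4
  expect_gt(kurt(y_t), kurt(y_g))
})

test_that("expand_to_channels inverts through the median projection", {
  set.seed(81)
  g <- matrix(rnorm(6 * 50), 6, 50)
  # no noise, no outliers: median projection restores the cluster signal
  ex <- expand_to_channels(g, channels_per_cluster = 5, channel_noise_sd = 0,
                           seed = 1)
  asg <- cdvar:::cluster_assignment(ex$labels, 6,
                                    cdvar:::default_anchors(6), seed = 1)
  expect_equal(project_median(ex$hb, asg)$g, g)
  # geometry pair midpoints coincide with the channel coordinates
  expect_equal(channel_midpoints(ex$geometry)[1:30, ], ex$coords,
               ignore_attr = TRUE)

  # outlier arithmetic: mean biased by offset/csize, median within noise
  ex2 <- expand_to_channels(g, channels_per_cluster = 5, channel_noise_sd = 0,
                            outlier_channels = 1, outlier_offset = 100,
                            seed = 1)
  mean_shift <- project_mean(ex2$hb, asg)$g - g
  expect_equal(mean_shift, matrix(20, 6, 50))
  med_shift <- project_median(ex2$hb, asg)$g - g
  expect_lt(max(abs(med_shift)), 1e-12)

  expect_warning(
    expand_to_channels(g, channels_per_cluster = 4, outlier_channels = 2,
                       seed = 1),
    "median robustness"
  )
})

test_that("spatial clustering recovers the spawning partition", {
  set.seed(82)
  g <- matrix(rnorm(6 * 30), 6, 30)
  ex <- expand_to_channels(g, channels_per_cluster = 5, seed = 2)
  asg <- cluster_channels(ex$coords, M = 6, seed = 3)
  # same partition up to label permutation
  tab <- table(ex$labels, asg$labels)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("simulated experiments have the paradigm's length and structure", {
  tt <- make_ground_truth(M = 3, K = 4, seed = 5)
  par <- paradigm_spec()
  # 17 + 4*22 + 3*10 + 17 = 152 s at 10.2 Hz
  expect_equal(cdvar:::paradigm_duration_s(par), 152)
  ex <- simulate_experiment(tt, par, conditions = 0:4,
                            channels_per_cluster = 2, as_intensity = FALSE,
                            seed = 6)
  expect_length(ex$runs, 5)
  expect_setequal(vapply(ex$runs, `[[`, "", "condition"),
                  c("barefoot", "flat_sole", "medial_wedge", "personal_shoes",
                    "sgl_shoes"))
  n <- ncol(ex$runs[[1]]$hb$hbo)
  expect_equal(n, round(152 * 10.2))
  expect_equal(nrow(ex$runs[[1]]$hb$events), 4)

  ex2 <- simulate_experiment(tt, par, conditions = 0:4,
                             channels_per_cluster = 2, as_intensity = FALSE,
                             seed = 6)
  for (r in 1:5) expect_identical(ex$runs[[r]]$hb$hbo, ex2$runs[[r]]$hb$hbo)

  # hrf envelope variant produces finite, nonzero signals
  ex3 <- simulate_experiment(tt, par, conditions = 0, envelope = "hrf",
                             channels_per_cluster = 2, as_intensity = FALSE,
                             seed = 7)
  expect_true(all(is.finite(ex3$runs[[1]]$hb$hbo)))
})

test_that("intensity runs survive the full preprocessing round trip", {
  tt <- make_ground_truth(M = 3, K = 0, seed = 8)
  ex <- simulate_experiment(tt, conditions = 0, channels_per_cluster = 2,
                            channel_noise_sd = 0.05, seed = 9)
  run <- ex$runs[[1]]
  # write to disk and back, then invert the Beer-Lambert forward model
  dir <- withr::local_tempdir()
  write_fnirs(run$geometry, run$recording, dir)
  back <- read_fnirs(dir)
  od <- optical_density(back$recording)
  hb <- mbll(od, back$geometry, fs = back$recording$fs,
             condition = back$recording$condition,
             events = back$recording$events)
  # optical density is computed against the run mean, so the recovered
  # series equals the generated one up to a per-channel constant
  delta <- hb$hbo - run$hb$hbo
  expect_lt(max(apply(delta, 1, function(r) diff(range(r)))), 1e-6)
  expect_identical(hb$condition, "barefoot")
})

test_that("task-gated dynamics are recoverable from a scaled-up experiment", {
  # long paradigm (20 trials), per-trial stacking, no trial averaging
  tt <- make_ground_truth(M = 3, K = 1, sparsity = 0.25, seed = 10)
  par <- paradigm_spec(trials = 20)
  ex <- simulate_experiment(tt, par, conditions = 0:1,
                            channels_per_cluster = 5,
                            channel_noise_sd = 0.05, as_intensity = FALSE,
                            seed = 11)
  asg <- cdvar:::cluster_assignment(ex$runs[[1]]$truth_labels, 3,
                                    cdvar:::default_anchors(3), seed = 1)
  fit_input <- list(); cond <- character(0)
  for (run in ex$runs) {
    ps <- project_median(run$hb, asg)
    for (ep in extract_task_epochs(ps)) {
      fit_input[[length(fit_input) + 1]] <- ep
      cond <- c(cond, run$condition)
    }
  }
  fit <- cdvar(fit_input, condition = cond, baseline = "barefoot")
  est0 <- fit$phi[["barefoot"]][[1]]
  true0 <- tt$phi0[[1]]
  nz <- true0 != 0
  expect_true(all(sign(est0[nz]) == sign(true0[nz])))
  expect_lt(max(abs(est0 - true0)), 0.15)
})
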