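# The condition-driven VAR estimator: design assembly, OLS, Wald inference,
# thresholding, stationarity guard, and its S3 surface.

test_that("trial_average is the pointwise mean across epochs", {
  set.seed(61)
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(trial_average(list(x))$g, x)              # single epoch
  expect_equal(trial_average(list(x, -x))$g, matrix(0, 3, 4))
  eps <- replicate(4, matrix(rnorm(12), 3, 4), simplify = FALSE)
  expect_equal(trial_average(eps)$g, Reduce(`+`, eps) / 4)
  expect_error(trial_average(list(x, matrix(0, 3, 5))),
               class = "cdvar_data_error")
})

test_that("build_design has the documented width and never crosses run boundaries", {
  # baseline only, p = 1, M = 2 -> no delta columns
  d0 <- build_design(list(matrix(rnorm(20), 2, 10)), condition = "base")
  expect_equal(ncol(d0$X), 2)
  expect_equal(ncol(d0$Y), 2)

  # five conditions, p = 1, M = 6 -> 6 * (1 + 4) = 30 predictor columns
  runs <- lapply(1:5, function(i) matrix(rnorm(60), 6, 10))
  d5 <- build_design(runs, condition = paste0("c", 0:4))
  expect_equal(ncol(d5$X), 30)
  expect_equal(nrow(d5$X), 5 * 9)

  # sentinel leak check: plant sentinels at run edges; they must never
  # appear among the predictors of another run's rows
  s <- 1e9
  r1 <- matrix(rnorm(12), 2, 6); r1[, 6] <- s
  r2 <- matrix(rnorm(12), 2, 6); r2[, 1] <- -s
  d <- build_design(list(r1, r2), condition = c("a", "a"))
  # rows from r2 (the last 5): lag-1 predictors are r2[, 1:5]; the first of
  # those is the sentinel -s itself, but r1's closing sentinel +s from the
  # other run must be absent from r2's rows and vice versa
  rows_r1 <- 1:5; rows_r2 <- 6:10
  expect_false(any(d$X[rows_r2, ] == s))
  expect_false(any(d$X[rows_r1, ] == -s))
  expect_false(any(d$Y[rows_r1, ] == -s))
})

test_that("noise-free data from known coefficients is recovered exactly", {
  set.seed(62)
  M <- 3
  truth <- make_ground_truth(M = M, K = 2, sparsity = 0.3, seed = 5)
  # exact noise-free trajectories: several short decays from random starts
  runs <- list(); cond <- character(0)
  for (k in 0:2) {
    phi <- cdvar:::truth_phi(truth, k)[[1]]
    for (r in 1:5) {
      g <- matrix(0, M, 8)
      g[, 1] <- rnorm(M)
      for (t in 2:8) g[, t] <- phi %*% g[, t - 1]
      runs[[length(runs) + 1]] <- g
      cond <- c(cond, paste0("c", k))
    }
  }
  fit <- suppressWarnings(cdvar(runs, condition = cond))
  expect_lt(max(abs(fit$phi[["c0"]][[1]] - truth$phi0[[1]])), 1e-8)
  for (k in 1:2) {
    expect_lt(max(abs(fit$phi[[paste0("c", k)]][[1]] - truth$deltas[[k]][[1]])),
              1e-8)
  }
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("fit_ols agrees with an independent pseudoinverse solve", {
  set.seed(63)
  for (rep in 1:5) {
    truth <- make_ground_truth(M = 2, K = 1, sparsity = 0.5, seed = rep)
    runs <- list(simulate_condition_run(truth, 0, 60, seed = rep * 2),
                 simulate_condition_run(truth, 1, 60, seed = rep * 2 + 1))
    design <- build_design(runs, condition = c("b", "d"))
    fit <- fit_ols(design)
    oracle <- pinv_solve(design$X, design$Y)
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)
    # residual covariance definition
    E <- design$Y - design$X %*% oracle
    expect_equal(fit$resid_cov,
                 crossprod(E) / (nrow(design$X) - ncol(design$X)),
                 tolerance = 1e-10)
    # Kronecker coefficient covariance: diagonal matches the reported SEs
    V <- vcov(fit)
    q <- ncol(design$X)
    se_vec <- sqrt(diag(V))
    # first q entries = all coefficients of equation 1, groups in design order
    expect_equal(se_vec[1:q],
                 unname(c(fit$se[["b"]][[1]][1, ], fit$se[["d"]][[1]][1, ])),
                 tolerance = 1e-10)
  }
})

test_that("a baseline-only fit reproduces a plain VAR fit", {
  set.seed(64)
  truth <- make_ground_truth(M = 3, K = 0, sparsity = 0.3, seed = 9)
  g <- simulate_condition_run(truth, 0, 300, seed = 17)
  fit <- cdvar(g, condition = "only")
  # ordinary VAR(1) by generic least squares
  Y <- t(g[, 2:300]); X <- t(g[, 1:299])
  B <- pinv_solve(X, Y)
  expect_lt(max(abs(fit$phi[["only"]][[1]] - t(B))), 1e-8)
  expect_equal(length(fit$conditions), 1)
})

test_that("joint-fit baseline matrices match a baseline-only refit within sampling error", {
  set.seed(65)
  truth <- make_ground_truth(M = 4, K = 2, seed = 11)
  runs <- lapply(0:2, function(k) simulate_condition_run(truth, k, 2000,
                                                         seed = 30 + k))
  joint <- cdvar(runs, condition = c("b", "c1", "c2"))
  alone <- cdvar(runs[[1]], condition = "b")
  expect_lt(max(abs(joint$phi[["b"]][[1]] - alone$phi[["b"]][[1]])), 1e-8)
})

test_that("rank deficiency is reported with the offending columns", {
  set.seed(66)
  g <- matrix(rnorm(40), 2, 20)
  g2 <- g; g2[2, ] <- g2[1, ]          # duplicated cluster -> collinear
  err <- tryCatch(cdvar(g2, condition = "b"), error = identity)
  expect_s3_class(err, "cdvar_numerical_error")
  expect_match(conditionMessage(err), "rank deficient")
})

test_that("higher-order fits use all requested lags", {
  set.seed(67)
  phi <- list(matrix(c(0.5, 0, 0.2, 0.3), 2, 2),
              matrix(c(-0.3, 0.1, 0, 0.2), 2, 2))
  g <- cdvar:::var_recursion(phi, diag(2), 3000, burn = 200)
  fit <- cdvar(g, condition = "b", order = 2)
  expect_length(fit$phi[["b"]], 2)
  expect_lt(max(abs(fit$phi[["b"]][[1]] - phi[[1]])), 0.1)
  expect_lt(max(abs(fit$phi[["b"]][[2]] - phi[[2]])), 0.1)
})

test_that("Wald machinery matches the standard normal law", {
  fit <- fake_fit(M = 2, estimates = list(base = matrix(0, 2, 2),
                                          condA = matrix(0.196, 2, 2)))
  wp <- wald_pvalues(fit)
  expect_equal(wp$p[["base"]][[1]], matrix(1, 2, 2))           # coef 0 -> p = 1
  expect_equal(wp$z[["condA"]][[1]], matrix(1.96, 2, 2))
  expect_equal(wp$p[["condA"]][[1]][1, 1], 2 * pnorm(-1.96))   # ~0.05
  # zero SE flagged, not silently set
  fit$se[["base"]][[1]][1, 1] <- 0
  expect_warning(wp2 <- wald_pvalues(fit), "zero standard error")
  expect_true(is.na(wp2$p[["base"]][[1]][1, 1]))
})

test_that("significant_edges thresholds and BH-adjusts correctly", {
  pv <- matrix(1, 3, 3)
  fit <- fake_fit(M = 3, pvalues = list(base = pv, condA = pv))
  tab <- significant_edges(fit, alpha = 0.05)
  expect_equal(sum(tab$significant), 0)

  pv2 <- pv; pv2[1, 2] <- 0.01; pv2[2, 3] <- 0.001; pv2[3, 3] <- 0.04
  fit2 <- fake_fit(M = 3, pvalues = list(base = pv2, condA = pv))
  tab2 <- significant_edges(fit2, alpha = 0.05)
  expect_equal(sum(tab2$significant), 3)
  expect_true(all(tab2$p[tab2$significant] <= 0.05))
  # self-loops flagged
  expect_true(tab2$self[tab2$significant & tab2$from == 3 & tab2$to == 3])

  # BH mode agrees with the independent step-up implementation in stats
  set.seed(68)
  pv3 <- matrix(runif(9), 3, 3)
  fit3 <- fake_fit(M = 3, pvalues = list(base = pv3, condA = pv))
  tab3 <- significant_edges(fit3, alpha = 0.2, correction = "bh")
  base_rows <- tab3$condition == "base"
  expect_equal(tab3$p_adj[base_rows],
               as.numeric(p.adjust(tab3$p[base_rows], method = "BH")))
  expect_error(significant_edges(fit3, alpha = 1.5),
               class = "cdvar_validation_error")
})

test_that("companion spectral radius matches an explicit eigen oracle", {
  M <- 6
  expect_equal(companion_spectral_radius(matrix(0, M, M)), 0)
  expect_equal(companion_spectral_radius(diag(0.9, M)), 0.9)
  set.seed(69)
  for (p in 1:2) {
    phi <- lapply(seq_len(p), function(l) matrix(rnorm(M * M, sd = 0.2), M, M))
    A <- matrix(0, p * M, p * M)
    for (l in seq_len(p)) A[1:M, (l - 1) * M + 1:M] <- phi[[l]]
    if (p > 1) A[(M + 1):(p * M), 1:((p - 1) * M)] <- diag((p - 1) * M)
    oracle <- max(Mod(eigen(A)$values))
    expect_lt(abs(companion_spectral_radius(phi) - oracle), 1e-10)
  }
})

test_that("white noise yields no spurious structure and calibrated z-values", {
  set.seed(70)
  hits <- 0; total <- 0
  for (rep in 1:20) {
    g <- matrix(rnorm(3 * 400), 3, 400)
    fit <- cdvar(g, condition = "b")
    z <- fit$zvalues[["b"]][[1]]
    hits <- hits + sum(abs(z) > 3)
    total <- total + length(z)
  }
  # P(|z| > 3) ~ 0.0027; allow generous slack over 180 coefficients
  expect_lt(hits / total, 0.03)
})

test_that("the fitted-model S3 surface behaves like a standard model object", {
  set.seed(71)
  truth <- make_ground_truth(M = 3, K = 1, seed = 13)
  runs <- list(simulate_condition_run(truth, 0, 800, seed = 1),
               simulate_condition_run(truth, 1, 800, seed = 2))
  fit <- cdvar(runs, condition = c("base", "flat"))

  expect_output(print(fit), "Condition-driven VAR\\(1\\)")
  expect_output(print(summary(fit)), "significant at alpha")
  expect_named(coef(fit), c("base", "flat"))
  expect_equal(coef(fit, "flat", total = TRUE)[[1]],
               fit$phi[["base"]][[1]] + fit$phi[["flat"]][[1]])
  expect_equal(dim(vcov(fit)), c(18, 18))
  expect_equal(nrow(residuals(fit)) , 2 * 799)
  expect_equal(fitted(fit) + residuals(fit),
               rbind(t(runs[[1]][, 2:800]), t(runs[[2]][, 2:800])))
  expect_s3_class(logLik(fit), "logLik")

  pred <- predict(fit, runs[[1]], condition = "base")
  expect_equal(dim(pred), c(3, 799))
  expect_equal(pred, fit$phi[["base"]][[1]] %*% runs[[1]][, 1:799])

  sim1 <- simulate(fit, seed = 99, n = 100)
  sim2 <- simulate(fit, seed = 99, n = 100)
  expect_identical(sim1, sim2)
  expect_equal(dim(sim1), c(3, 100))
})

test_that("task epochs are sliced by the event markers", {
  par <- paradigm_spec()
  n <- round(cdvar:::paradigm_duration_s(par) * par$fs)
  g <- matrix(rnorm(2 * n), 2, n)
  ps <- projected_series(g, par$fs, condition = "x",
                         events = cdvar:::paradigm_events(par, "x"))
  eps <- extract_task_epochs(ps)
  expect_length(eps, 4)
  len <- floor(22 * 10.2)
  expect_true(all(vapply(eps, ncol, 0L) == len))
  # first epoch starts right after the 17 s initial rest
  start <- floor(17 * 10.2) + 1
  expect_identical(eps[[1]], g[, start:(start + len - 1)])
})
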