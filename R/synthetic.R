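#' Ground-truth coefficient sets for simulation studies
#'
#' Draws a random sparse, stable condition-driven VAR ground truth: a
#' baseline coefficient set \eqn{\Phi_0} with autoregressive diagonal and a
#' fraction `sparsity` of nonzero off-diagonal entries of magnitude
#' `effect_size` (random sign), plus K per-condition delta sets whose
#' support is drawn, where possible, from off-diagonal entries not already
#' used by the baseline. All coefficient sets are rescaled until the
#' companion spectral radius of \eqn{\Phi_0} and of every
#' \eqn{\Phi_0 + \Phi_k} is below 0.95, guaranteeing weak stationarity of
#' every condition's dynamics.
#'
#' @param M number of clusters.
#' @param K number of non-baseline conditions.
#' @param p VAR order.
#' @param sparsity fraction of off-diagonal entries that are nonzero.
#' @param effect_size magnitude of nonzero off-diagonal entries.
#' @param diag_coef baseline self-coupling placed on the diagonal of the
#'   lag-1 matrix.
#' @param resid_cov innovation covariance (default identity).
#' @param seed integer seed.
#' @return An object of class `cdvar_truth`: `phi0` (list over lags),
#'   `deltas` (list of K lists over lags), `resid_cov`, `M`, `K`, `p`,
#'   `seed`, `sparsity`, `effect_size`.
#' @export
make_ground_truth <- function(M = 6, K = 4, p = 1, sparsity = 0.2,
                              effect_size = 0.4, diag_coef = 0.4,
                              resid_cov = NULL, seed = 1) {
  stopifnot_scalar_number(M, "M", lower = 1)
  stopifnot_scalar_number(K, "K", lower = 0)
  stopifnot_scalar_number(sparsity, "sparsity", lower = 0, upper = 1)
  resid_cov <- resid_cov %||% diag(M)
  with_seed(seed, {
    off <- which(row(diag(M)) != col(diag(M)))
    n_off <- max(0L, round(sparsity * length(off)))
    rand_sparse <- function(support_pool, base_diag) {
      lapply(seq_len(p), function(l) {
        m <- matrix(0, M, M)
        if (l == 1L) diag(m) <- base_diag
        if (n_off > 0L && length(support_pool)) {
          pick <- sample(support_pool, min(n_off, length(support_pool)))
          m[pick] <- effect_size * sample(c(-1, 1), length(pick), replace = TRUE)
        }
        m
      })
    }
    phi0 <- rand_sparse(off, diag_coef)
    base_support <- which(phi0[[1L]] != 0 & row(diag(M)) != col(diag(M)))
    delta_pool <- setdiff(off, base_support)
    if (length(delta_pool) < n_off) delta_pool <- off  # fall back when saturated
    deltas <- lapply(seq_len(K), function(k) rand_sparse(delta_pool, 0))

    for (iter in seq_len(25L)) {
      rads <- c(
        companion_spectral_radius(phi0),
        vapply(deltas, function(d) companion_spectral_radius(Map(`+`, phi0, d)),
               numeric(1))
      )
      if (max(rads) < 0.95) break
      scale <- 0.9 * 0.95 / max(rads)
      phi0 <- lapply(phi0, `*`, scale)
      deltas <- lapply(deltas, function(d) lapply(d, `*`, scale))
      if (iter == 25L) abort_numerical("could not stabilize ground truth")
    }
    structure(list(phi0 = phi0, deltas = deltas, resid_cov = resid_cov,
                   M = as.integer(M), K = as.integer(K), p = as.integer(p),
                   seed = seed, sparsity = sparsity, effect_size = effect_size),
              class = "cdvar_truth")
  })
}

#' @export
print.cdvar_truth <- function(x, ...) {
  cat(sprintf(
    "<cdvar_truth> M=%d clusters, K=%d deltas, VAR(%d), sparsity %.2f, effect %.2f\n",
    x$M, x$K, x$p, x$sparsity, x$effect_size
  ))
  invisible(x)
}

truth_phi <- function(truth, k) {
  if (k == 0) truth$phi0 else Map(`+`, truth$phi0, truth$deltas[[k]])
}

# VAR(p) recursion with Gaussian innovations; burn-in discarded.
var_recursion <- function(phi, resid_cov, n, burn = 200, innovations = NULL,
                          df = Inf) {
  p <- length(phi); M <- nrow(phi[[1L]])
  total <- n + burn
  if (is.null(innovations)) {
    Lc <- chol(resid_cov)
    eps <- matrix(stats::rnorm(M * total), M, total)
    if (is.finite(df)) {
      # scale-mixture Student-t innovations with unit variance
      w <- sqrt(df / stats::rchisq(total, df)) / sqrt(df / (df - 2))
      eps <- eps * rep(w, each = M)
    }
    innovations <- t(Lc) %*% eps
  }
  g <- matrix(0, M, total)
  for (t in seq(p + 1L, total)) {
    acc <- innovations[, t]
    for (l in seq_len(p)) acc <- acc + phi[[l]] %*% g[, t - l]
    g[, t] <- acc
  }
  g[, burn + seq_len(n), drop = FALSE]
}

#' Simulate one condition's cluster-level series
#'
#' Runs the condition-driven VAR recursion with coefficients
#' \eqn{\Phi_0} (baseline, `k = 0`) or \eqn{\Phi_0 + \Phi_k} and Gaussian
#' (optionally Student-t) innovations, discarding `burn` initial samples.
#'
#' @param truth a [make_ground_truth()] object.
#' @param k condition index: 0 = baseline, 1..K = delta conditions.
#' @param n number of retained samples.
#' @param seed integer seed.
#' @param burn burn-in length.
#' @param innovation_df degrees of freedom for Student-t innovations
#'   (`Inf` = Gaussian, the default).
#' @return M x n matrix.
#' @export
simulate_condition_run <- function(truth, k, n, seed = NULL, burn = 200,
                                   innovation_df = Inf) {
  stopifnot(inherits(truth, "cdvar_truth"))
  if (k < 0 || k > truth$K) {
    abort_validation(sprintf("condition index %d outside 0..%d", k, truth$K))
  }
  phi <- truth_phi(truth, k)
  if (companion_spectral_radius(phi) >= 1) {
    abort_numerical("refusing to simulate from unstable coefficients")
  }
  with_seed(seed, var_recursion(phi, truth$resid_cov, n, burn,
                                df = innovation_df))
}

#' Default cluster anchor positions on a sphere
#'
#' Six well-separated scalp-like anchor points on a sphere (radius in cm),
#' three per hemisphere, loosely emulating motoric / somatosensory /
#' temporal regions left and right.
#'
#' @param M number of anchors (up to 8 supported).
#' @param radius sphere radius in cm.
#' @return M x 3 matrix.
#' @export
default_anchors <- function(M = 6, radius = 9) {
  dirs <- rbind(
    c(-0.55,  0.45, 0.70), c(0.55,  0.45, 0.70),   # motoric L/R
    c(-0.65, -0.30, 0.70), c(0.65, -0.30, 0.70),   # somatosensory L/R
    c(-0.95,  0.00, 0.10), c(0.95,  0.00, 0.10),   # temporal L/R
    c(-0.30,  0.90, 0.30), c(0.30,  0.90, 0.30)
  )
  if (M > nrow(dirs)) abort_validation("at most 8 default anchors available")
  d <- dirs[seq_len(M), , drop = FALSE]
  d <- d / sqrt(rowSums(d^2))
  out <- d * radius
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Expand cluster-level signals into noisy channel-level recordings
#'
#' The inverse of the median projection, used to exercise the spatial
#' pipeline: each cluster spawns `channels_per_cluster` channels whose
#' coordinates jitter tightly around the cluster anchor and whose signal is
#' the cluster signal plus independent Gaussian channel noise. Designated
#' outlier channels (the first `outlier_channels` of each cluster) receive a
#' large constant additive offset, emulating low-SNR channels that the
#' median projection should resist.
#'
#' @param g M x T cluster-level matrix.
#' @param anchors M x 3 anchor coordinates (default [default_anchors()]).
#' @param channels_per_cluster channels spawned per cluster.
#' @param channel_noise_sd SD of per-channel additive Gaussian noise.
#' @param outlier_channels number of outlier channels per cluster.
#' @param outlier_offset constant offset added to outlier channels.
#' @param jitter_sd coordinate jitter SD; default 1/20 of the minimum
#'   inter-anchor distance so the spawning partition is identifiable.
#' @param seed integer seed.
#' @return list with `hb` (channels x T), `coords` (channels x 3),
#'   `geometry` (a [probe_geometry()] whose pair midpoints equal `coords`),
#'   `labels` (true spawning cluster per channel).
#' @export
expand_to_channels <- function(g, anchors = NULL, channels_per_cluster = 5,
                               channel_noise_sd = 0.1, outlier_channels = 0,
                               outlier_offset = 0, jitter_sd = NULL,
                               seed = NULL) {
  g <- as.matrix(g)
  M <- nrow(g)
  anchors <- anchors %||% default_anchors(M)
  if (nrow(anchors) != M) abort_validation("need one anchor per cluster")
  if (channels_per_cluster < 1) abort_validation("channels_per_cluster must be >= 1")
  if (outlier_channels >= channels_per_cluster / 2 && outlier_channels > 0) {
    warning("outlier channels are half or more of a cluster; median robustness not guaranteed",
            call. = FALSE)
  }
  if (is.null(jitter_sd)) {
    jitter_sd <- if (M > 1) min(stats::dist(anchors)) / 20 else 0.25
  }
  with_seed(seed, {
    L <- M * channels_per_cluster
    labels <- rep(seq_len(M), each = channels_per_cluster)
    coords <- anchors[labels, , drop = FALSE] +
      matrix(stats::rnorm(L * 3, sd = jitter_sd), L, 3)
    hb <- g[labels, , drop = FALSE] +
      matrix(stats::rnorm(L * ncol(g), sd = channel_noise_sd), L, ncol(g))
    if (outlier_channels > 0) {
      out_rows <- as.vector(outer(seq_len(outlier_channels),
                                  (seq_len(M) - 1L) * channels_per_cluster, `+`))
      hb[out_rows, ] <- hb[out_rows, ] + outlier_offset
    }
    list(hb = hb, coords = coords,
         geometry = geometry_from_midpoints(coords), labels = labels)
  })
}

# Build a two-wavelength montage whose pair midpoints equal the given
# channel coordinates: source/detector offset +-1.5 cm along x.
geometry_from_midpoints <- function(coords, separation = 3) {
  n <- nrow(coords)
  offset <- cbind(rep(separation / 2, n), 0, 0)
  probe_geometry(
    sources = coords - offset,
    detectors = coords + offset,
    channels = data.frame(source = rep(seq_len(n), 2L),
                          detector = rep(seq_len(n), 2L),
                          wavelength = rep(c(760, 850), each = n))
  )
}

#' Block-design paradigm specification
#'
#' The default reproduces the walking experiment's timing: 17 s initial and
#' final standing rests, 22 s task blocks (one figure-eight walk each),
#' 10 s standing rests between blocks, four trials, sampled at 10.2 Hz.
#'
#' @param initial_rest_s,task_s,inter_rest_s seconds.
#' @param trials number of task repetitions.
#' @param fs sampling frequency in Hz.
#' @return list of class `paradigm_spec`.
#' @export
paradigm_spec <- function(initial_rest_s = 17, task_s = 22, inter_rest_s = 10,
                          trials = 4, fs = 10.2) {
  for (v in c("initial_rest_s", "task_s", "inter_rest_s", "trials", "fs")) {
    stopifnot_scalar_number(get(v), v, lower = 0, strict = TRUE)
  }
  structure(list(initial_rest_s = initial_rest_s, task_s = task_s,
                 inter_rest_s = inter_rest_s, trials = as.integer(trials),
                 fs = fs),
            class = "paradigm_spec")
}

paradigm_duration_s <- function(par) {
  2 * par$initial_rest_s + par$trials * par$task_s +
    (par$trials - 1L) * par$inter_rest_s
}

paradigm_events <- function(par, label) {
  onset <- par$initial_rest_s +
    (seq_len(par$trials) - 1L) * (par$task_s + par$inter_rest_s)
  data.frame(onset = onset, duration = par$task_s, label = label,
             stringsAsFactors = FALSE)
}

# canonical double-gamma hemodynamic response, unit peak
hrf_kernel <- function(fs, length_s = 30) {
  t <- seq(0, length_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

block_envelope <- function(par, n, type = c("boxcar", "hrf")) {
  type <- match.arg(type)
  env <- numeric(n)
  ev <- paradigm_events(par, "task")
  for (i in seq_len(nrow(ev))) {
    a <- floor(ev$onset[i] * par$fs) + 1L
    b <- min(n, a + floor(ev$duration[i] * par$fs) - 1L)
    env[a:b] <- 1
  }
  if (type == "hrf") {
    h <- hrf_kernel(par$fs)
    env <- stats::convolve(env, rev(h), type = "open")[seq_len(n)]
    env <- env / max(env)
  }
  env
}

#' Simulate a full block-design experiment
#'
#' For each requested condition, simulates one run: condition-dependent VAR
#' dynamics gated by the task-block envelope (rest periods carry only
#' baseline white noise), expanded to noisy channels around spatial
#' anchors, and optionally forward-converted through the modified
#' Beer-Lambert model into two-wavelength raw intensities so the run can be
#' written with [write_fnirs()] and pushed through the whole pipeline.
#'
#' @param truth a [make_ground_truth()] object.
#' @param paradigm a [paradigm_spec()].
#' @param conditions integer vector of condition indices (0 = baseline).
#' @param condition_names labels for the runs; defaults to the footwear
#'   condition names of the motivating experiment when K = 4.
#' @param envelope `"boxcar"` or `"hrf"` task gating of the dynamics.
#' @param channels_per_cluster,channel_noise_sd,outlier_channels,
#'   outlier_offset passed to [expand_to_channels()].
#' @param as_intensity if `TRUE` (default) also return raw intensity
#'   recordings generated by the forward Beer-Lambert model.
#' @param seed integer seed; run r uses `seed + r`.
#' @return list of class `cdvar_experiment`: `runs` (each with `condition`,
#'   `hb` [hb_series], `geometry`, `recording` [fnirs_recording or NULL],
#'   `truth_labels`, `cluster_truth` M x n matrix), plus `truth`,
#'   `paradigm`, `anchors`.
#' @export
simulate_experiment <- function(truth, paradigm = paradigm_spec(),
                                conditions = 0:truth$K,
                                condition_names = NULL,
                                envelope = c("boxcar", "hrf"),
                                channels_per_cluster = 5,
                                channel_noise_sd = 0.1,
                                outlier_channels = 0, outlier_offset = 0,
                                as_intensity = TRUE, seed = 1) {
  stopifnot(inherits(truth, "cdvar_truth"), inherits(paradigm, "paradigm_spec"))
  envelope <- match.arg(envelope)
  condition_names <- condition_names %||% default_condition_names(truth$K)
  n <- round(paradigm_duration_s(paradigm) * paradigm$fs)
  anchors <- default_anchors(truth$M)
  env <- block_envelope(paradigm, n, envelope)

  runs <- lapply(seq_along(conditions), function(r) {
    k <- conditions[r]
    label <- condition_names[k + 1L]
    run_seed <- seed + r
    g_task <- simulate_condition_run(truth, k, n, seed = run_seed)
    rest_noise <- with_seed(run_seed * 31L + 7L, {
      t(chol(truth$resid_cov)) %*% matrix(stats::rnorm(truth$M * n), truth$M, n)
    })
    g <- g_task * rep(env, each = truth$M) +
      rest_noise * rep(1 - env, each = truth$M)
    ex <- expand_to_channels(
      g, anchors = anchors, channels_per_cluster = channels_per_cluster,
      channel_noise_sd = channel_noise_sd,
      outlier_channels = outlier_channels, outlier_offset = outlier_offset,
      seed = run_seed * 101L + 13L
    )
    events <- paradigm_events(paradigm, label)
    hb <- hb_series(ex$hb, -ex$hb / 3, fs = paradigm$fs, coords = ex$coords,
                    condition = label, events = events)
    recording <- if (as_intensity) {
      forward_mbll_recording(hb, ex$geometry, events)
    }
    list(condition = label, k = k, hb = hb, geometry = ex$geometry,
         recording = recording, truth_labels = ex$labels, cluster_truth = g)
  })
  structure(list(runs = runs, truth = truth, paradigm = paradigm,
                 anchors = anchors, condition_names = condition_names),
            class = "cdvar_experiment")
}

default_condition_names <- function(K) {
  full <- c("barefoot", "flat_sole", "medial_wedge", "personal_shoes",
            "sgl_shoes")
  if (K + 1L <= length(full)) full[seq_len(K + 1L)] else
    c(full, sprintf("condition_%d", seq(length(full), K)))
}

# forward modified Beer-Lambert: hemoglobin (uM) -> OD -> intensities
forward_mbll_recording <- function(hb, geometry, events, dpf = 6, i0 = 1e3) {
  ch <- geometry$channels
  dist <- channel_distances(geometry)
  n_pair <- nrow(hb$hbo)
  od <- matrix(0, nrow(ch), ncol(hb$hbo))
  for (i in seq_len(nrow(ch))) {
    pair <- if (i > n_pair) i - n_pair else i  # rows: all 760 then all 850
    eps <- default_extinction(c(760, 850))
    row <- if (ch$wavelength[i] == 760) 1L else 2L
    od[i, ] <- (eps[row, "hbo"] * hb$hbo[pair, ] +
                  eps[row, "hbr"] * hb$hbr[pair, ]) / 1000 * dist[i] * dpf
  }
  fnirs_recording(i0 * exp(-od), fs = hb$fs, condition = hb$condition,
                  events = events)
}

#' @export
print.cdvar_experiment <- function(x, ...) {
  cat(sprintf(
    "<cdvar_experiment> %d run(s) [%s], %d clusters x %d channels, %g Hz\n",
    length(x$runs), paste(vapply(x$runs, `[[`, "", "condition"), collapse = ", "),
    x$truth$M, nrow(x$runs[[1L]]$hb$hbo), x$paradigm$fs
  ))
  invisible(x)
}
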