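#' Fit a condition-driven vector autoregression
#'
#' The workhorse estimator of the package. The cluster-level series
#' \eqn{G(t) \in R^M} is assumed weakly stationary with a VAR(p)
#' representation
#' \deqn{G(t) = \sum_{\ell=1}^{p} \Phi(\ell) G(t-\ell) + \varepsilon_t}
#' whose coefficient matrices depend on the experimental condition through
#' dichotomic indicators \eqn{C_k}:
#' \deqn{\Phi(\ell) = \Phi_0(\ell) + \sum_{k=1}^{K} \Phi_k(\ell) C_k.}
#' The baseline condition (barefoot walking in the motivating experiment) is
#' the reference: its dynamics are \eqn{\Phi_0} alone, and each
#' \eqn{\Phi_k} is the connectivity *change* of condition k relative to that
#' baseline. Entry \eqn{[i, j]} of a coefficient matrix is the directed
#' (Granger-causal) effect of cluster j at lag \eqn{\ell} on cluster i.
#'
#' Estimation is equation-by-equation ordinary least squares on the stacked
#' design (identical to multivariate OLS since every equation shares the
#' predictors); runtime is linear in the number of time samples for fixed M.
#' Indicators are constant within a run, and lagged predictors never cross a
#' run boundary. Inference uses the asymptotic normal law of the vectorized
#' coefficients with covariance \eqn{\Sigma_\varepsilon \otimes (X'X)^{-1}}.
#'
#' @param x a [projected_series()], an M x T matrix, or a list of these
#'   (one element per run).
#' @param condition character vector with one condition label per run;
#'   defaults to the `condition` field of each `projected_series`.
#' @param order VAR order p. Default 1.
#' @param baseline label of the reference condition. Default: the first
#'   condition in order of appearance.
#' @return An object of class `cdvar`. Key fields: `phi` (per condition
#'   group, a list over lags of M x M coefficient matrices; group
#'   `"baseline"` is \eqn{\Phi_0}, the others are deltas), `se`, `zvalues`,
#'   `pvalues` (same shape), `resid_cov` (\eqn{\Sigma_\varepsilon}),
#'   `xtx_inv`, `residuals`, `fitted`, `n_obs` (per condition),
#'   `spectral_radius` (per condition, of \eqn{\Phi_0 + \Phi_k}).
#' @seealso [significant_edges()], [build_maps()], [simulate.cdvar()]
#' @examples
#' truth <- make_ground_truth(M = 3, K = 1, seed = 1)
#' runs <- list(simulate_condition_run(truth, 0, 500, seed = 2),
#'              simulate_condition_run(truth, 1, 500, seed = 3))
#' fit <- cdvar(runs, condition = c("baseline", "flat_sole"))
#' fit
#' @export
cdvar <- function(x, condition = NULL, order = 1, baseline = NULL) {
  stopifnot_scalar_number(order, "order", lower = 1)
  order <- as.integer(order)
  runs <- as_run_list(x)
  if (is.null(condition)) {
    condition <- vapply(runs, function(r) attr(r, "condition"), character(1))
  }
  condition <- as.character(condition)
  if (length(condition) != length(runs)) {
    abort_validation("`condition` must supply one label per run")
  }
  baseline <- baseline %||% condition[1L]
  if (!baseline %in% condition) {
    abort_validation(sprintf("baseline condition '%s' has no data", baseline))
  }
  design <- build_design(runs, condition, baseline = baseline, order = order)
  fit <- fit_ols(design)
  fit$call <- match.call()
  fit
}

as_run_list <- function(x) {
  if (inherits(x, "projected_series") || (is.matrix(x) && is.numeric(x))) {
    x <- list(x)
  }
  if (!is.list(x)) abort_validation("`x` must be a matrix, projected_series, or list of runs")
  lapply(x, function(r) {
    if (inherits(r, "projected_series")) {
      structure(r$g, condition = r$condition)
    } else if (is.matrix(r) && is.numeric(r)) {
      structure(r, condition = NA_character_)
    } else {
      abort_validation("each run must be a projected_series or numeric matrix")
    }
  })
}

#' Assemble the lagged regression design of the condition-driven VAR
#'
#' Builds the stacked response and predictor matrices. For a run in
#' condition k, each interior time point contributes response row
#' \eqn{G(t)'} and predictors: the p lagged blocks (baseline terms)
#' followed by, for every non-baseline condition j, the same lagged blocks
#' multiplied by the indicator \eqn{1\{k = j\}} (delta terms). Rows never
#' straddle run boundaries.
#'
#' @param runs list of M x T matrices (one per run).
#' @param condition condition label per run.
#' @param baseline reference condition label.
#' @param order VAR order p.
#' @return list with `X` (n x q predictors), `Y` (n x M responses),
#'   `col_map` (data frame: column, group, lag, from), `row_condition`,
#'   `conditions` (baseline first), `baseline`, `M`, `order`.
#' @export
build_design <- function(runs, condition, baseline = condition[1L], order = 1) {
  runs <- as_run_list(runs)
  p <- as.integer(order)
  M <- nrow(runs[[1L]])
  if (any(vapply(runs, nrow, 0L) != M)) {
    abort_validation("all runs must share the same number of clusters")
  }
  too_short <- which(vapply(runs, ncol, 0L) < p + 1L)
  if (length(too_short)) {
    abort_data(sprintf(
      "condition '%s' contributes fewer than %d time points",
      paste(unique(condition[too_short]), collapse = "', '"), p + 1L
    ))
  }
  deltas <- setdiff(unique(condition), baseline)
  groups <- c(baseline, deltas)
  K <- length(deltas)
  q <- M * p * (1L + K)

  blocks_x <- vector("list", length(runs))
  blocks_y <- vector("list", length(runs))
  row_cond <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    g <- runs[[r]]
    Tn <- ncol(g)
    ts <- seq(p + 1L, Tn)
    Y <- t(g[, ts, drop = FALSE])
    lagged <- do.call(cbind, lapply(seq_len(p), function(l) {
      t(g[, ts - l, drop = FALSE])
    }))
    X <- matrix(0, nrow(lagged), q)
    X[, seq_len(M * p)] <- lagged
    k <- match(condition[r], deltas)
    if (!is.na(k)) {
      X[, M * p * k + seq_len(M * p)] <- lagged
    }
    blocks_x[[r]] <- X
    blocks_y[[r]] <- Y
    row_cond[[r]] <- rep(condition[r], nrow(Y))
  }
  col_map <- data.frame(
    column = seq_len(q),
    group = rep(c("baseline", deltas), each = M * p),
    lag = rep(rep(seq_len(p), each = M), 1L + K),
    from = rep(seq_len(M), p * (1L + K))
  )
  list(
    X = do.call(rbind, blocks_x), Y = do.call(rbind, blocks_y),
    col_map = col_map, row_condition = unlist(row_cond),
    conditions = groups, baseline = baseline, M = M, order = p
  )
}

#' Ordinary least squares fit of an assembled design
#'
#' Equation-by-equation least squares via a QR decomposition shared across
#' the M response equations. The residual covariance uses the degrees-of-
#' freedom correction n - q; the coefficient covariance is the Kronecker
#' form \eqn{\Sigma_\varepsilon \otimes (X'X)^{-1}}.
#'
#' @param design output of [build_design()].
#' @return A `cdvar` object (see [cdvar()]).
#' @export
fit_ols <- function(design) {
  X <- design$X; Y <- design$Y
  n <- nrow(X); q <- ncol(X); M <- design$M
  qr_x <- qr(X)
  if (qr_x$rank < q) {
    dropped <- design$col_map[qr_x$pivot[seq(qr_x$rank + 1L, q)], , drop = FALSE]
    abort_numerical(sprintf(
      "design is rank deficient (rank %d < %d columns); collinear/empty columns: %s",
      qr_x$rank, q,
      paste(sprintf("%s:lag%d:from%d", dropped$group, dropped$lag, dropped$from),
            collapse = ", ")
    ))
  }
  B <- qr.coef(qr_x, Y)                       # q x M
  E <- Y - X %*% B
  df <- n - q
  if (df <= 0) abort_data("not enough observations for the requested order")
  resid_cov <- crossprod(E) / df
  inv_p <- chol2inv(qr.R(qr_x))               # (X'X)^-1 in pivoted order
  piv <- qr_x$pivot
  xtx_inv <- matrix(0, q, q)
  xtx_inv[piv, piv] <- inv_p
  se <- sqrt(outer(diag(xtx_inv), diag(resid_cov)))  # q x M
  z <- B / se
  pv <- 2 * stats::pnorm(-abs(z))

  if (n < 10 * q) {
    warning(sprintf(
      "only %d observations for %d coefficients per equation; estimates may be unstable",
      n, q
    ), call. = FALSE)
  }

  shape <- function(mat_qxM) {
    out <- lapply(seq_along(design$conditions), function(gi) {
      group <- if (gi == 1L) "baseline" else design$conditions[gi]
      lapply(seq_len(design$order), function(l) {
        sel <- design$col_map$group == group & design$col_map$lag == l
        t(mat_qxM[sel, , drop = FALSE])       # M x M, [i, j] = j -> i
      })
    })
    names(out) <- design$conditions
    out
  }

  phi <- shape(B)
  fit <- structure(list(
    phi = phi, se = shape(se), zvalues = shape(z), pvalues = shape(pv),
    resid_cov = resid_cov, xtx_inv = xtx_inv, coefficients = B,
    residuals = E, fitted = X %*% B,
    col_map = design$col_map, row_condition = design$row_condition,
    conditions = design$conditions, baseline = design$baseline,
    M = M, order = design$order, n_obs = table(design$row_condition),
    df_residual = df
  ), class = "cdvar")
  fit$spectral_radius <- vapply(design$conditions, function(cond) {
    companion_spectral_radius(phi_total(fit, cond))
  }, numeric(1))
  if (any(fit$spectral_radius >= 1)) {
    warning(sprintf(
      "estimated dynamics non-stationary for condition(s): %s",
      paste(names(which(fit$spectral_radius >= 1)), collapse = ", ")
    ), call. = FALSE)
  }
  fit
}

#' Total coefficient matrices of one condition
#'
#' \eqn{\Phi_0(\ell)} for the baseline, \eqn{\Phi_0(\ell) + \Phi_k(\ell)}
#' for condition k.
#'
#' @param fit a [cdvar()] fit.
#' @param condition condition label.
#' @return list over lags of M x M matrices.
#' @export
phi_total <- function(fit, condition) {
  stopifnot(inherits(fit, "cdvar"))
  if (!condition %in% fit$conditions) {
    abort_validation(sprintf("unknown condition '%s'", condition))
  }
  base <- fit$phi[[fit$baseline]]
  if (condition == fit$baseline) return(base)
  Map(`+`, base, fit$phi[[condition]])
}

#' Spectral radius of the VAR companion matrix
#'
#' Stacks the lag matrices \eqn{\Phi(1), \ldots, \Phi(p)} into the
#' pM x pM companion form and returns the largest eigenvalue modulus.
#' A value below 1 certifies a stable (weakly stationary) process.
#'
#' @param phi a single M x M matrix or a list of p of them.
#' @return nonnegative scalar.
#' @export
companion_spectral_radius <- function(phi) {
  if (is.matrix(phi)) phi <- list(phi)
  p <- length(phi); M <- nrow(phi[[1L]])
  A <- matrix(0, p * M, p * M)
  for (l in seq_len(p)) A[seq_len(M), (l - 1L) * M + seq_len(M)] <- phi[[l]]
  if (p > 1L) {
    A[M + seq_len((p - 1L) * M), seq_len((p - 1L) * M)] <- diag((p - 1L) * M)
  }
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Average epochs of equal length into a single trial-mean series
#'
#' Pointwise mean across repeated trials of the same condition; estimation
#' on the trial-averaged signal suppresses trial-specific noise when few
#' samples per trial are available.
#'
#' @param epochs list of [projected_series()] or M x T matrices, all of the
#'   same dimension.
#' @return a [projected_series()] (metadata taken from the first epoch).
#' @export
trial_average <- function(epochs) {
  if (inherits(epochs, "projected_series") || is.matrix(epochs)) epochs <- list(epochs)
  if (!length(epochs)) abort_validation("need at least one epoch")
  mats <- lapply(epochs, function(e) if (inherits(e, "projected_series")) e$g else as.matrix(e))
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
    abort_data("epochs have mismatched dimensions; cannot align trials")
  }
  g <- Reduce(`+`, mats) / length(mats)
  first <- epochs[[1L]]
  if (inherits(first, "projected_series")) {
    projected_series(g, first$fs, first$assignment, first$condition)
  } else {
    projected_series(g, fs = 1)
  }
}

#' Slice task-block epochs out of a projected run
#'
#' Uses the run's event markers to extract the task blocks (rest periods are
#' excluded by default, since the block design alternates task and rest).
#' All epochs are cut to the shortest marker duration so they can be
#' trial-averaged.
#'
#' @param ps a [projected_series()] with event markers.
#' @param labels optional character vector restricting which marker labels
#'   count as task blocks.
#' @return list of M x T_epoch matrices.
#' @export
extract_task_epochs <- function(ps, labels = NULL) {
  stopifnot(inherits(ps, "projected_series"))
  ev <- ps$events
  if (!is.null(labels)) ev <- ev[ev$label %in% labels, , drop = FALSE]
  if (!nrow(ev)) abort_data("run has no (matching) event markers")
  n_len <- floor(min(ev$duration) * ps$fs)
  lapply(seq_len(nrow(ev)), function(i) {
    start <- floor(ev$onset[i] * ps$fs) + 1L
    ps$g[, seq(start, start + n_len - 1L), drop = FALSE]
  })
}

#' Wald z-values and two-sided p-values of a fit
#'
#' Recomputes \eqn{z = \hat\phi / se(\hat\phi)} and the two-sided p-value
#' from the standard normal law of the vectorized coefficient estimator.
#' Entries with zero standard error are returned as `NA` with a warning
#' rather than silently set.
#'
#' @param fit a [cdvar()] fit.
#' @return list with elements `z` and `p`, each nested like `fit$phi`.
#' @export
wald_pvalues <- function(fit) {
  stopifnot(inherits(fit, "cdvar"))
  zero_se <- FALSE
  z <- lapply(fit$conditions, function(g) {
    lapply(seq_len(fit$order), function(l) {
      se <- fit$se[[g]][[l]]
      if (any(se == 0)) zero_se <<- TRUE
      out <- fit$phi[[g]][[l]] / se
      out[se == 0] <- NA_real_
      out
    })
  })
  names(z) <- fit$conditions
  if (zero_se) {
    warning("zero standard error for some coefficients; p-values set to NA",
            call. = FALSE)
  }
  p <- lapply(z, function(g) lapply(g, function(m) 2 * stats::pnorm(-abs(m))))
  list(z = z, p = p)
}

#' Threshold a fit into significant directed edges
#'
#' Marks coefficients with \eqn{p \le \alpha} as significant edges. No
#' multiple-testing correction is applied by default; Benjamini-Hochberg
#' step-up (applied within each condition group and lag) is available.
#' Self-loops (i -> i) are kept but flagged so cross-cluster edges can be
#' selected separately.
#'
#' @param fit a [cdvar()] fit (or a p-value array nested like `fit$pvalues`).
#' @param alpha significance level in (0, 1). Default 0.05.
#' @param correction `"none"` (default) or `"bh"`.
#' @return data frame with columns `condition`, `lag`, `from`, `to`,
#'   `estimate`, `se`, `z`, `p`, `p_adj`, `self`, `significant`.
#' @export
significant_edges <- function(fit, alpha = 0.05, correction = c("none", "bh")) {
  stopifnot(inherits(fit, "cdvar"))
  stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  correction <- match.arg(correction)
  tab <- coef_table(fit)
  tab$p_adj <- tab$p
  if (correction == "bh") {
    for (g in unique(tab$condition)) {
      for (l in unique(tab$lag)) {
        sel <- tab$condition == g & tab$lag == l
        tab$p_adj[sel] <- bh_adjust(tab$p[sel])
      }
    }
  }
  tab$self <- tab$from == tab$to
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj <= alpha
  attr(tab, "alpha") <- alpha
  attr(tab, "correction") <- correction
  tab
}

# Benjamini-Hochberg step-up adjusted p-values (monotone cumulative minimum)
bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}

coef_table <- function(fit) {
  rows <- list()
  for (g in fit$conditions) {
    for (l in seq_len(fit$order)) {
      est <- fit$phi[[g]][[l]]
      grid <- expand.grid(to = seq_len(fit$M), from = seq_len(fit$M))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = g,
        role = if (g == fit$baseline) "baseline" else "delta",
        lag = l, from = grid$from, to = grid$to,
        estimate = est[cbind(grid$to, grid$from)],
        se = fit$se[[g]][[l]][cbind(grid$to, grid$from)],
        z = fit$zvalues[[g]][[l]][cbind(grid$to, grid$from)],
        p = fit$pvalues[[g]][[l]][cbind(grid$to, grid$from)]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
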