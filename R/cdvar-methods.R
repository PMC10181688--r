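#' @export
print.cdvar <- function(x, ...) {
  K <- length(x$conditions) - 1L
  cat(sprintf(
    "Condition-driven VAR(%d), %d clusters, baseline '%s' + %d condition delta(s)\n",
    x$order, x$M, x$baseline, K
  ))
  cat(sprintf("Observations per condition: %s\n",
              paste(sprintf("%s=%d", names(x$n_obs), as.integer(x$n_obs)),
                    collapse = ", ")))
  cat(sprintf("Companion spectral radius: %s\n",
              paste(sprintf("%s=%.3f", names(x$spectral_radius),
                            x$spectral_radius), collapse = ", ")))
  invisible(x)
}

#' Extract coefficient matrices from a condition-driven VAR fit
#'
#' @param object a [cdvar()] fit.
#' @param condition `NULL` for all groups, a condition label for its delta
#'   matrices (baseline label returns \eqn{\Phi_0}).
#' @param total if `TRUE`, return \eqn{\Phi_0 + \Phi_k} instead of the delta.
#' @param ... unused.
#' @return list over lags of M x M matrices ([i, j] = effect of cluster j on
#'   cluster i), or the full nested list when `condition` is `NULL`.
#' @export
coef.cdvar <- function(object, condition = NULL, total = FALSE, ...) {
  if (is.null(condition)) return(object$phi)
  if (total) phi_total(object, condition) else {
    if (!condition %in% object$conditions) {
      abort_validation(sprintf("unknown condition '%s'", condition))
    }
    object$phi[[condition]]
  }
}

#' @export
vcov.cdvar <- function(object, ...) {
  # Sigma_eps %x% (X'X)^-1, covariance of vec(coefficients) stacked by equation
  object$resid_cov %x% object$xtx_inv
}

#' @export
residuals.cdvar <- function(object, ...) object$residuals

#' @export
fitted.cdvar <- function(object, ...) object$fitted

#' @export
logLik.cdvar <- function(object, ...) {
  n <- nrow(object$residuals); M <- object$M
  S <- crossprod(object$residuals) / n
  val <- -0.5 * n * (M * log(2 * pi) + determinant(S)$modulus + M)
  structure(as.numeric(val),
            df = length(object$coefficients) + M * (M + 1) / 2,
            class = "logLik")
}

#' @export
summary.cdvar <- function(object, alpha = 0.05, ...) {
  tab <- significant_edges(object, alpha = alpha)
  structure(list(fit = object, coefficients = tab, alpha = alpha),
            class = "summary.cdvar")
}

#' @export
print.summary.cdvar <- function(x, max_rows = 20L, ...) {
  print(x$fit)
  tab <- x$coefficients
  sig <- tab[tab$significant & tab$from != tab$to, , drop = FALSE]
  cat(sprintf("\n%d of %d cross-cluster coefficients significant at alpha = %g\n",
              nrow(sig), sum(tab$from != tab$to), x$alpha))
  if (nrow(sig)) {
    sig <- sig[order(sig$p), , drop = FALSE]
    print(utils::head(
      data.frame(condition = sig$condition, lag = sig$lag,
                 edge = sprintf("%d -> %d", sig$from, sig$to),
                 estimate = signif(sig$estimate, 4),
                 z = signif(sig$z, 3), p = signif(sig$p, 3)),
      max_rows
    ), row.names = FALSE)
  }
  invisible(x)
}

#' One-step-ahead predictions from a fitted condition-driven VAR
#'
#' @param object a [cdvar()] fit.
#' @param newdata M x T matrix or [projected_series()].
#' @param condition which condition's dynamics to use (default baseline).
#' @param ... unused.
#' @return M x (T - p) matrix of one-step-ahead predictions for time points
#'   p+1, ..., T.
#' @export
predict.cdvar <- function(object, newdata, condition = object$baseline, ...) {
  g <- if (inherits(newdata, "projected_series")) newdata$g else as.matrix(newdata)
  if (nrow(g) != object$M) {
    abort_validation(sprintf("`newdata` must have %d rows", object$M))
  }
  p <- object$order
  if (ncol(g) <= p) abort_data("`newdata` shorter than the VAR order")
  phi <- phi_total(object, condition)
  ts <- seq(p + 1L, ncol(g))
  pred <- matrix(0, object$M, length(ts))
  for (l in seq_len(p)) pred <- pred + phi[[l]] %*% g[, ts - l, drop = FALSE]
  pred
}

#' Simulate new series from a fitted condition-driven VAR
#'
#' Draws Gaussian innovations from the fitted residual covariance and runs
#' the estimated recursion for the requested condition, discarding a burn-in.
#'
#' @param object a [cdvar()] fit.
#' @param nsim number of series to simulate.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param condition condition label (default baseline).
#' @param n length of each simulated series.
#' @param burn burn-in samples discarded.
#' @param ... unused.
#' @return a list of `nsim` M x n matrices (a single matrix if `nsim = 1`).
#' @export
simulate.cdvar <- function(object, nsim = 1, seed = NULL,
                           condition = object$baseline, n = 500, burn = 200,
                           ...) {
  phi <- phi_total(object, condition)
  out <- with_seed(seed, lapply(seq_len(nsim), function(i) {
    var_recursion(phi, object$resid_cov, n, burn)
  }))
  if (nsim == 1) out[[1L]] else out
}

#' Plot coefficient matrices of a condition-driven VAR fit
#'
#' Image panels of the lag-1 coefficient matrices (baseline and deltas),
#' rows = target cluster, columns = source cluster.
#'
#' @param x a [cdvar()] fit.
#' @param lag which lag to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.cdvar <- function(x, lag = 1, ...) {
  groups <- x$conditions
  old <- graphics::par(mfrow = c(1, length(groups)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  for (g in groups) {
    m <- x$phi[[g]][[lag]]
    lim <- max(abs(m), 1e-12)
    graphics::image(
      seq_len(x$M), seq_len(x$M), t(m[rev(seq_len(x$M)), , drop = FALSE]),
      zlim = c(-lim, lim),
      col = grDevices::hcl.colors(64, "Blue-Red 3"),
      xlab = "source cluster", ylab = "target cluster",
      main = if (g == x$baseline) sprintf("baseline (%s)", g) else
        sprintf("delta: %s", g),
      ...
    )
  }
  invisible(x)
}
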