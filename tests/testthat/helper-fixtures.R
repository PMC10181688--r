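# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

toy_geometry <- function(n_pairs = 2) {
  probe_geometry(
    sources   = matrix(rnorm(3 * n_pairs), n_pairs, 3),
    detectors = matrix(rnorm(3 * n_pairs), n_pairs, 3),
    channels  = data.frame(source = rep(seq_len(n_pairs), 2),
                           detector = rep(seq_len(n_pairs), 2),
                           wavelength = rep(c(760, 850), each = n_pairs))
  )
}

toy_recording <- function(geometry, n = 200, fs = 10.2, condition = "barefoot",
                          events = empty_events()) {
  L <- nrow(geometry$channels)
  fnirs_recording(matrix(exp(rnorm(L * n, sd = 0.05)) * 1000, L, n),
                  fs = fs, condition = condition, events = events)
}

# A hand-built minimal cdvar object (M clusters, lag 1, baseline + deltas)
# for tests that exercise downstream consumers directly.
fake_fit <- function(M = 3, conditions = c("base", "condA"),
                     pvalues = NULL, estimates = NULL) {
  zero <- matrix(0, M, M)
  one <- matrix(1, M, M)
  shape <- lapply(conditions, function(g) list(zero))
  names(shape) <- conditions
  phi <- shape; se <- shape; pv <- shape; zv <- shape
  for (g in conditions) {
    phi[[g]][[1]] <- if (is.null(estimates)) zero else estimates[[g]]
    se[[g]][[1]] <- one * 0.1
    pv[[g]][[1]] <- if (is.null(pvalues)) one else pvalues[[g]]
    zv[[g]][[1]] <- phi[[g]][[1]] / se[[g]][[1]]
  }
  structure(list(
    phi = phi, se = se, zvalues = zv, pvalues = pv,
    resid_cov = diag(M), xtx_inv = diag(M),
    conditions = conditions, baseline = conditions[1],
    M = M, order = 1L,
    n_obs = table(rep(conditions, each = 10)),
    spectral_radius = setNames(rep(0, length(conditions)), conditions),
    df_residual = 10L
  ), class = "cdvar")
}

fake_assignment <- function(M) {
  cdvar:::cluster_assignment(seq_len(M), M, cdvar:::default_anchors(M), seed = 1)
}

# independent stacked-normal-equations least squares (pseudoinverse oracle)
pinv_solve <- function(X, Y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% Y) / sv$d[keep])
}
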