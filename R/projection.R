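#' Spatial clustering of channels by 3D coordinates
#'
#' Groups the L hemoglobin channels into M spatial clusters by K-means on
#' their 3D coordinates (Euclidean distance, random initialization driven by
#' `seed`, 10 restarts keeping the best within-cluster sum of squares).
#' The clusters define the low-rank projection used by [project_median()].
#'
#' @param coords L x 3 numeric matrix of channel coordinates.
#' @param M number of clusters. Default 6: three regions of interest
#'   (motoric, somatosensory, temporal) per hemisphere.
#' @param seed integer seed making the assignment reproducible.
#' @param nstart number of random restarts.
#' @return An object of class `cluster_assignment`: `labels` (length L,
#'   values 1..M), `M`, `centroids` (M x 3), `seed`.
#' @export
cluster_channels <- function(coords, M = 6, seed = 1, nstart = 10) {
  coords <- as_coord_matrix(coords, "coords")
  L <- nrow(coords)
  n_distinct <- nrow(unique(coords))
  stopifnot_scalar_number(M, "M", lower = 1)
  if (M > n_distinct) {
    abort_validation(sprintf(
      "M = %d exceeds the %d distinct coordinate points", M, n_distinct
    ))
  }
  if (M == L) {
    # saturated clustering: every channel its own cluster
    return(cluster_assignment(seq_len(L), M, coords, seed))
  }
  km <- with_seed(seed, stats::kmeans(coords, centers = M, nstart = nstart,
                                      iter.max = 100))
  cluster_assignment(km$cluster, M, km$centers, seed)
}

#' Construct a cluster assignment directly
#'
#' Usually produced by [cluster_channels()]; the constructor is exposed for
#' workflows where the channel-to-cluster mapping is known a priori (e.g.
#' synthetic experiments that spawn channels in cluster blocks).
#'
#' @param labels integer vector of cluster labels in 1..M, one per channel;
#'   every cluster must be non-empty.
#' @param M number of clusters.
#' @param centroids M x 3 cluster centroid coordinates.
#' @param seed seed recorded for provenance.
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, M, centroids, seed = NA_integer_) {
  labels <- as.integer(labels)
  if (!all(seq_len(M) %in% labels)) {
    abort_numerical("clustering produced an empty cluster")
  }
  centroids <- as.matrix(centroids)
  dimnames(centroids) <- list(NULL, c("x", "y", "z"))
  structure(list(labels = labels, M = as.integer(M), centroids = centroids,
                 seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d channels -> %d clusters (sizes: %s)\n",
              length(x$labels), x$M,
              paste(tabulate(x$labels, x$M), collapse = ", ")))
  invisible(x)
}

#' Cluster-summarized (projected) time series
#'
#' @param g M x time matrix of cluster-level signals.
#' @param fs sampling frequency in Hz.
#' @param assignment the [cluster_channels()] result that produced `g`.
#' @param condition run condition label.
#' @param events event marker data frame.
#' @return An object of class `projected_series`.
#' @export
projected_series <- function(g, fs, assignment = NULL, condition = "unknown",
                             events = empty_events()) {
  g <- as.matrix(g)
  structure(list(g = g, fs = fs, assignment = assignment,
                 condition = as.character(condition),
                 events = as_events(events)),
            class = "projected_series")
}

#' @export
print.projected_series <- function(x, ...) {
  cat(sprintf("<projected_series> %d clusters x %d samples @ %g Hz, condition '%s'\n",
              nrow(x$g), ncol(x$g), x$fs, x$condition))
  invisible(x)
}

#' Low-rank projection by cluster medians (or means)
#'
#' Maps an L-channel series to M cluster-level signals: at every time point,
#' cluster \eqn{\ell}'s value is the median (or mean) over the channels
#' assigned to \eqn{\ell}. The median is the default estimator because it
#' tolerates a minority of low signal-to-noise or outlier channels within a
#' cluster; the mean shifts proportionally to any corruption and is provided
#' for comparison. Even-size clusters use the mid-pair average.
#'
#' @param hb an [hb_series()] (its `hbo` matrix is projected) or a plain
#'   channels x time matrix.
#' @param assignment a `cluster_assignment` whose labels match the channel
#'   count.
#' @return A [projected_series()] with an M x time matrix `g`.
#' @export
project_median <- function(hb, assignment) {
  project_with(hb, assignment, function(x) apply(x, 2L, stats::median))
}

#' @rdname project_median
#' @export
project_mean <- function(hb, assignment) {
  project_with(hb, assignment, colMeans)
}

project_with <- function(hb, assignment, summarize) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  fs <- 1; condition <- "unknown"; events <- empty_events()
  if (inherits(hb, "hb_series")) {
    fs <- hb$fs; condition <- hb$condition; events <- hb$events
    x <- hb$hbo
  } else {
    x <- as.matrix(hb)
  }
  if (length(assignment$labels) != nrow(x)) {
    abort_validation(sprintf("assignment covers %d channels but series has %d",
                             length(assignment$labels), nrow(x)))
  }
  g <- matrix(0, assignment$M, ncol(x))
  for (l in seq_len(assignment$M)) {
    members <- which(assignment$labels == l)
    g[l, ] <- if (length(members) == 1L) x[members, ] else
      summarize(x[members, , drop = FALSE])
  }
  projected_series(g, fs, assignment, condition, events)
}
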