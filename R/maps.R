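#' Directed connectivity maps from a fitted condition-driven VAR
#'
#' Converts a fit into one map per condition group: the baseline map shows
#' the significant entries of \eqn{\hat\Phi_0}; each non-baseline map shows
#' the significant *delta* entries \eqn{\hat\Phi_k} (connectivity change
#' versus baseline), or \eqn{\hat\Phi_0 + \hat\Phi_k} when
#' `absolute = TRUE`. Nodes carry a hemisphere tag derived from the sign of
#' the cluster centroid's x coordinate (negative = left, positive = right,
#' zero = midline) and an optional region-of-interest label.
#'
#' @param fit a [cdvar()] fit.
#' @param assignment the [cluster_channels()] assignment used for the fit
#'   (supplies centroids for hemisphere tags).
#' @param roi_table optional character vector of length M naming each
#'   cluster's region of interest; defaults to `cluster<i>`.
#' @param alpha significance level for edge inclusion.
#' @param correction multiple-testing correction passed to
#'   [significant_edges()].
#' @param absolute render per-condition totals instead of deltas.
#' @return list of `connectivity_map` objects, one per condition group.
#'   Each has `condition`, `role`, `edges` (data frame: from, to, from_roi,
#'   to_roi, lag, weight, z, p, self), `hemisphere` (per cluster), `roi`,
#'   `alpha`.
#' @export
build_maps <- function(fit, assignment, roi_table = NULL, alpha = 0.05,
                       correction = "none", absolute = FALSE) {
  stopifnot(inherits(fit, "cdvar"), inherits(assignment, "cluster_assignment"))
  if (assignment$M != fit$M) {
    abort_validation("fit and assignment disagree on the number of clusters")
  }
  roi <- roi_table %||% sprintf("cluster%d", seq_len(fit$M))
  if (length(roi) != fit$M) {
    abort_data(sprintf("ROI table has %d entries for %d clusters",
                       length(roi), fit$M))
  }
  hemi <- hemisphere_of(assignment$centroids[, "x"])
  tab <- significant_edges(fit, alpha = alpha, correction = correction)

  lapply(fit$conditions, function(g) {
    sel <- tab[tab$condition == g & tab$significant, , drop = FALSE]
    weight <- sel$estimate
    if (absolute && g != fit$baseline) {
      base <- fit$phi[[fit$baseline]]
      weight <- weight + vapply(seq_len(nrow(sel)), function(i) {
        base[[sel$lag[i]]][sel$to[i], sel$from[i]]
      }, numeric(1))
    }
    edges <- data.frame(
      from = sel$from, to = sel$to,
      from_roi = roi[sel$from], to_roi = roi[sel$to],
      lag = sel$lag, weight = weight, z = sel$z, p = sel$p,
      self = sel$self, stringsAsFactors = FALSE
    )
    rownames(edges) <- NULL
    structure(list(
      condition = g,
      role = if (g == fit$baseline) "baseline" else
        if (absolute) "total" else "delta",
      edges = edges, hemisphere = hemi, roi = roi, alpha = alpha
    ), class = "connectivity_map")
  })
}

hemisphere_of <- function(x) {
  out <- ifelse(x < 0, "left", ifelse(x > 0, "right", "midline"))
  as.character(out)
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> condition '%s' (%s): %d edge(s) at alpha = %g\n",
              x$condition, x$role, nrow(x$edges), x$alpha))
  invisible(x)
}

#' Count edges by hemisphere category
#'
#' Classifies every edge of a map as intra-left, intra-right,
#' inter-hemispheric, or involving a midline node (counted separately).
#'
#' @param map a `connectivity_map` from [build_maps()].
#' @return named integer vector: `intra_left`, `intra_right`, `inter`,
#'   `midline`.
#' @export
interhemispheric_summary <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  h_from <- map$hemisphere[map$edges$from]
  h_to <- map$hemisphere[map$edges$to]
  mid <- h_from == "midline" | h_to == "midline"
  c(intra_left = sum(!mid & h_from == "left" & h_to == "left"),
    intra_right = sum(!mid & h_from == "right" & h_to == "right"),
    inter = sum(!mid & h_from != h_to),
    midline = sum(mid))
}

#' Export a connectivity map
#'
#' Lossless edge-list export as CSV, GraphML (node/edge attributes carried)
#' or JSON. CSV and JSON round-trip through [import_map()].
#'
#' @param map a `connectivity_map`.
#' @param path output file path.
#' @param format `"csv"`, `"graphml"` or `"json"`; default guessed from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
export_map <- function(map, path, format = NULL) {
  stopifnot(inherits(map, "connectivity_map"))
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("csv", "graphml", "json")) {
    abort_validation(sprintf("unknown export format '%s'", format))
  }
  if (format == "csv") {
    write_csv15(map$edges, path)
  } else if (format == "json") {
    jsonlite::write_json(
      list(condition = map$condition, role = map$role, alpha = map$alpha,
           roi = map$roi, hemisphere = map$hemisphere, edges = map$edges),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    g <- igraph::graph_from_data_frame(
      d = transform(map$edges, from = as.character(from), to = as.character(to)),
      directed = TRUE,
      vertices = data.frame(name = as.character(seq_along(map$roi)),
                            roi = map$roi, hemisphere = map$hemisphere)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_map
#' @export
import_map <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    abort_validation(sprintf("unknown import format '%s'", format))
  }
}

#' Quick-look plot of a connectivity map
#'
#' Scatter of cluster centroids in the x-y plane with arrows for each
#' significant edge (solid = positive weight, dashed = negative). A thin
#' rendering aid, not an interpolated topography.
#'
#' @param x a `connectivity_map`.
#' @param assignment the matching `cluster_assignment` (for centroid
#'   positions).
#' @param ... passed to [graphics::plot()].
#' @export
plot.connectivity_map <- function(x, assignment, ...) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cen <- assignment$centroids
  graphics::plot(cen[, "x"], cen[, "y"], pch = 19, cex = 1.5, asp = 1,
                 xlab = "x", ylab = "y",
                 main = sprintf("%s (%s)", x$condition, x$role), ...)
  graphics::text(cen[, "x"], cen[, "y"], labels = x$roi, pos = 3, cex = 0.8)
  e <- x$edges[!x$edges$self, , drop = FALSE]
  if (nrow(e)) {
    graphics::arrows(cen[e$from, "x"], cen[e$from, "y"],
                     cen[e$to, "x"], cen[e$to, "y"],
                     length = 0.1, lty = ifelse(e$weight >= 0, 1, 2))
  }
  invisible(x)
}
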