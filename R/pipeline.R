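#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their defaults:
#' simulation scale, filter specification, Beer-Lambert constants, cluster
#' count, VAR order and significance settings. Any subset can be overridden
#' via `run_pipeline(config = list(...))` or a YAML file with the same keys.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    input_dirs = NULL,          # existing run directories; NULL = simulate
    simulate = list(M = 6, K = 4, p = 1, sparsity = 0.2, effect_size = 0.4,
                    channels_per_cluster = 5, channel_noise_sd = 0.1,
                    outlier_channels = 0, outlier_offset = 0,
                    envelope = "boxcar"),
    dpf = 6,
    filter = list(order = 71, band_hz = c(0.010, 0.400)),
    filter_domain = "hb",       # filter after MBLL ("hb") or before ("od")
    clusters = 6,
    order = 1,
    alpha = 0.05,
    correction = "none",
    include_rest = FALSE,       # fit task blocks only
    per_trial = FALSE,          # stack trials instead of trial-averaging
    roi_table = NULL
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(base, config)
  stopifnot_scalar_number(cfg$alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  stopifnot_scalar_number(cfg$order, "order", lower = 1)
  stopifnot_scalar_number(cfg$clusters, "clusters", lower = 1)
  stopifnot_scalar_number(cfg$dpf, "dpf", lower = 0, strict = TRUE)
  if (!cfg$correction %in% c("none", "bh")) {
    abort_validation("`correction` must be 'none' or 'bh'")
  }
  if (!cfg$filter_domain %in% c("hb", "od")) {
    abort_validation("`filter_domain` must be 'hb' or 'od'")
  }
  cfg
}

#' Run the full connectivity pipeline
#'
#' Chains every stage behind one call: obtain runs (simulate a synthetic
#' experiment, or read run directories written by [write_fnirs()]), convert
#' intensities to hemoglobin via the modified Beer-Lambert law, band-pass
#' filter, cluster channels and project to cluster medians, fit the
#' condition-driven VAR, and export coefficient tables and per-condition
#' connectivity maps. Every artifact lands in a deterministic directory
#' layout under `out_dir` (`hb/`, `projected/`, `fit/`, `maps/`, `log.txt`);
#' identical config + seed give byte-identical coefficient tables.
#'
#' @param config named list of overrides of [default_config()], or the path
#'   of a YAML file containing them.
#' @param out_dir output directory.
#' @return (invisibly) list with `fit`, `assignment`, `maps`, `config`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("cdvar_run_")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("cdvar pipeline, package version %s\n",
              as.character(utils::packageVersion("cdvar"))),
      file = log_path)
  logf("config: %s", jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"))

  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    # --- acquire runs -----------------------------------------------------
    if (is.null(cfg$input_dirs)) {
      sim <- cfg$simulate
      truth <- make_ground_truth(M = sim$M, K = sim$K, p = sim$p,
                                 sparsity = sim$sparsity,
                                 effect_size = sim$effect_size,
                                 seed = cfg$seed)
      expt <- simulate_experiment(
        truth, conditions = 0:sim$K, envelope = sim$envelope,
        channels_per_cluster = sim$channels_per_cluster,
        channel_noise_sd = sim$channel_noise_sd,
        outlier_channels = sim$outlier_channels,
        outlier_offset = sim$outlier_offset,
        seed = cfg$seed
      )
      runs <- lapply(expt$runs, function(r) list(geometry = r$geometry,
                                                 recording = r$recording))
      jsonlite::write_json(
        list(phi0 = truth$phi0, deltas = truth$deltas, seed = cfg$seed),
        file.path(out_dir, "truth.json"), digits = NA
      )
      logf("simulated %d run(s), seed %d", length(runs), cfg$seed)
    } else {
      runs <- lapply(cfg$input_dirs, read_fnirs)
      logf("read %d run directorie(s)", length(runs))
    }

    # --- preprocess -------------------------------------------------------
    dir.create(file.path(out_dir, "hb"), showWarnings = FALSE)
    taps <- design_fir_bandpass(cfg$filter$order, cfg$filter$band_hz,
                                fs = runs[[1L]]$recording$fs)
    logf("FIR(%d) band-pass %g-%g Hz, zero-phase; DPF = %g; filtering %s",
         cfg$filter$order, cfg$filter$band_hz[1], cfg$filter$band_hz[2],
         cfg$dpf, cfg$filter_domain)
    hb_runs <- lapply(runs, function(r) {
      od <- optical_density(r$recording)
      if (cfg$filter_domain == "od") od <- apply_filter(od, taps)
      hb <- mbll(od, r$geometry, dpf = cfg$dpf, fs = r$recording$fs,
                 condition = r$recording$condition, events = r$recording$events)
      if (cfg$filter_domain == "hb") hb <- apply_filter(hb, taps)
      hb
    })
    for (i in seq_along(hb_runs)) {
      write_csv15(as.data.frame(t(hb_runs[[i]]$hbo)),
                  file.path(out_dir, "hb", sprintf("run%02d_hbo.csv", i)))
    }

    # --- project ----------------------------------------------------------
    dir.create(file.path(out_dir, "projected"), showWarnings = FALSE)
    assignment <- cluster_channels(hb_runs[[1L]]$coords, M = cfg$clusters,
                                   seed = cfg$seed)
    projected <- lapply(hb_runs, project_median, assignment = assignment)
    write_csv15(
      data.frame(channel = seq_along(assignment$labels),
                 label = assignment$labels,
                 roi = (cfg$roi_table %||%
                          sprintf("cluster%d", seq_len(assignment$M)))[assignment$labels]),
      file.path(out_dir, "projected", "assignment.csv")
    )
    logf("projected %d channels to %d cluster medians",
         length(assignment$labels), assignment$M)

    # --- fit --------------------------------------------------------------
    dir.create(file.path(out_dir, "fit"), showWarnings = FALSE)
    fit_input <- lapply(projected, function(ps) {
      if (cfg$include_rest || !nrow(ps$events)) return(ps)
      epochs <- extract_task_epochs(ps)
      if (cfg$per_trial) {
        lapply(epochs, projected_series, fs = ps$fs,
               assignment = ps$assignment, condition = ps$condition)
      } else {
        trial_average(lapply(epochs, projected_series, fs = ps$fs,
                             assignment = ps$assignment,
                             condition = ps$condition))
      }
    })
    if (cfg$per_trial) fit_input <- do.call(c, fit_input)
    fit <- cdvar(fit_input, order = cfg$order)
    logf("fit: %s", paste(utils::capture.output(print(fit)), collapse = " | "))
    edge_tab <- significant_edges(fit, alpha = cfg$alpha,
                                  correction = cfg$correction)
    write_csv15(edge_tab, file.path(out_dir, "fit", "coefficients.csv"))
    jsonlite::write_json(
      list(conditions = fit$conditions, baseline = fit$baseline,
           order = fit$order, M = fit$M,
           n_obs = as.list(stats::setNames(as.integer(fit$n_obs),
                                           names(fit$n_obs))),
           spectral_radius = as.list(fit$spectral_radius),
           alpha = cfg$alpha, correction = cfg$correction),
      file.path(out_dir, "fit", "summary.json"), auto_unbox = TRUE, digits = NA
    )

    # --- maps -------------------------------------------------------------
    dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
    maps <- build_maps(fit, assignment, roi_table = cfg$roi_table,
                       alpha = cfg$alpha, correction = cfg$correction)
    for (m in maps) {
      export_map(m, file.path(out_dir, "maps",
                              sprintf("%s.csv", m$condition)))
      export_map(m, file.path(out_dir, "maps",
                              sprintf("%s.graphml", m$condition)))
    }
    logf("wrote %d map(s)", length(maps))

    invisible(list(fit = fit, assignment = assignment, maps = maps,
                   config = cfg, out_dir = out_dir))
  }, cdvar_error = on_fail)
}
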