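#' Pipeline configuration
#'
#' Builds (or reads from YAML) the configuration for an end-to-end run:
#' probe geometry, component catalogue, at least two excitability profiles
#' to contrast, the protocols to simulate, noise/seed settings and analysis
#' parameters.
#'
#' @param geometry A [probe_geometry()].
#' @param components Component catalogue.
#' @param profiles Named list of >= 2 [excitability_profile()] objects.
#' @param ppi_ms Paired-pulse intervals to run, ms.
#' @param run_train,run_io Include the train / I/O-series protocols?
#' @param noise_sd,artifact_amp Simulator settings (mV).
#' @param seed Integer base seed; every stage derives its seed from it.
#' @param ps_k,reentry_window_ms,csd_smoothing,csd_interp_steps,drift_tol
#'   Analysis parameters (see [detect_ps()], [detect_reentrance()],
#'   [estimate_csd()], [interpolate_csd()], [exclude_unstable()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = probe_geometry(),
                            components = default_catalogue(geometry),
                            profiles = list(control = control_profile(),
                                            ad = ad_profile()),
                            ppi_ms = c(25, 50, 100, 200, 500, 1000),
                            run_train = TRUE, run_io = FALSE,
                            noise_sd = 0.1, artifact_amp = 2, seed = 1,
                            ps_k = 6, reentry_window_ms = c(12, 25),
                            csd_smoothing = 2, csd_interp_steps = 20,
                            drift_tol = 2) {
  stopifnot(length(profiles) >= 2, !is.null(names(profiles)),
            all(vapply(profiles, inherits, logical(1), "excitability_profile")))
  cfg <- list(geometry = geometry, components = components,
              profiles = profiles, ppi_ms = ppi_ms, run_train = run_train,
              run_io = run_io, noise_sd = noise_sd,
              artifact_amp = artifact_amp, seed = as.integer(seed),
              ps_k = ps_k, reentry_window_ms = reentry_window_ms,
              csd_smoothing = csd_smoothing,
              csd_interp_steps = csd_interp_steps, drift_tol = drift_tol)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; `geometry`,
#' `components` and `profiles` are nested maps (component fields as in
#' [csd_component()]; profile fields as in [excitability_profile()] with
#' `ppi_gain` keyed by interval).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  geometry <- if (is.null(y$geometry)) probe_geometry() else
    do.call(probe_geometry, y$geometry)
  components <- if (is.null(y$components)) default_catalogue(geometry) else
    lapply(y$components, function(cc) do.call(csd_component, cc))
  profiles <- if (is.null(y$profiles))
    list(control = control_profile(), ad = ad_profile()) else
    lapply(y$profiles, function(p) {
      p$ppi_gain <- unlist(p$ppi_gain)
      p$train_gain <- as.numeric(p$train_gain)
      do.call(excitability_profile, p)
    })
  args <- y[setdiff(names(y), c("geometry", "components", "profiles"))]
  do.call(pipeline_config,
          c(list(geometry = geometry, components = components,
                 profiles = profiles), args))
}

#' Run the full analysis pipeline
#'
#' For each configured excitability profile: simulate the protocols,
#' quality-screen and segment sweeps, extract the feature table, compute
#' paired-pulse and train plasticity curves, PS probabilities per interval,
#' re-entrance calls and the CSD map of the train average, and write
#' everything (CSV tables, HDF5 recordings, CSD PNG, Markdown report,
#' JSON manifest) under `out_dir`. The report contrasts the profiles
#' (short-interval facilitation vs depression; re-entrance onset pulse).
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param write_recordings Write the (large) HDF5 recordings?
#' @param quiet Suppress stage messages?
#' @return Invisibly, a list with per-profile results (`features`,
#'   `ppf`, `train`, `ps_prob`, `reentrance`, `csd`) and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("laminar_run_"),
                         write_recordings = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  results <- list()
  warnings_log <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("[%s] done in %.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  for (pi in seq_along(config$profiles)) {
    pname <- names(config$profiles)[pi]
    prof <- config$profiles[[pi]]
    say("=== profile '%s' ===", pname)
    feats <- list()

    for (ppi in config$ppi_ms) {
      rec <- stage(sprintf("%s/simulate ppi %g", pname, ppi),
        simulate_protocol(prof,
          stimulus_protocol("paired_pulse", ppi_ms = ppi),
          geometry = config$geometry, components = config$components,
          noise_sd = config$noise_sd, artifact_amp = config$artifact_amp,
          seed = config$seed + 1000 * pi + ppi))
      if (write_recordings)
        write_recording(rec, file.path(out_dir,
          sprintf("%s_ppi%g.h5", pname, ppi)))
      ss <- exclude_unstable(segment_sweeps(rec), config$drift_tol)
      excl <- attr(ss, "exclusions")
      if (nrow(excl) > 0)
        warnings_log <- c(warnings_log,
          sprintf("%s ppi %g: %d sweeps excluded", pname, ppi, nrow(excl)))
      feats[[length(feats) + 1L]] <- extract_features(ss, ps_k = config$ps_k)
    }
    pp_features <- do.call(rbind, feats)
    ppf <- paired_pulse_profile(pp_features)

    ps_tab <- do.call(rbind, lapply(config$ppi_ms, function(ppi) {
      f <- pp_features[pp_features$source == "per_sweep" &
                         pp_features$layer == "DG" &
                         pp_features$pulse_index == 2L &
                         pp_features$ppi_ms == ppi, ]
      p <- ps_probability(f$ps_flag)
      data.frame(ppi_ms = ppi, ps_probability = as.numeric(p),
                 n_ps = attr(p, "n_ps"), n_sweeps = attr(p, "n_sweeps"))
    }))

    train <- reent <- csd_map <- NULL
    train_features <- NULL
    if (config$run_train) {
      rec_t <- stage(sprintf("%s/simulate train", pname),
        simulate_protocol(prof, stimulus_protocol("train"),
          geometry = config$geometry, components = config$components,
          noise_sd = config$noise_sd, artifact_amp = config$artifact_amp,
          seed = config$seed + 1000 * pi + 7))
      ss_t <- segment_sweeps(rec_t)
      train_features <- extract_features(ss_t, ps_k = config$ps_k)
      train <- train_profile(train_features)
      reent <- detect_reentrance(ss_t, config$reentry_window_ms)
      avg <- average_sweeps(ss_t)
      csd_map <- interpolate_csd(
        estimate_csd(avg, config$geometry$spacing_um,
                     smoothing_degree = config$csd_smoothing,
                     depths_um = contact_depths(config$geometry),
                     t_ms = ss_t$t_ms),
        config$csd_interp_steps)
      grDevices::png(file.path(out_dir, sprintf("%s_train_csd.png", pname)),
                     width = 800, height = 600)
      plot(csd_map, main = sprintf("train-average CSD (%s)", pname))
      grDevices::dev.off()
    }

    all_features <- rbind(pp_features, train_features)
    write_feature_csv(all_features,
                      file.path(out_dir, sprintf("%s_features.csv", pname)),
                      session = pname)
    utils::write.csv(ppf, file.path(out_dir, sprintf("%s_ppf.csv", pname)),
                     row.names = FALSE)
    utils::write.csv(ps_tab, file.path(out_dir, sprintf("%s_ps.csv", pname)),
                     row.names = FALSE)
    if (!is.null(train)) {
      utils::write.csv(train,
                       file.path(out_dir, sprintf("%s_train.csv", pname)),
                       row.names = FALSE)
      utils::write.csv(reent,
                       file.path(out_dir, sprintf("%s_reentrance.csv", pname)),
                       row.names = FALSE)
    }
    n_lowconf <- sum(all_features$low_confidence, na.rm = TRUE)
    if (n_lowconf > 0)
      warnings_log <- c(warnings_log,
        sprintf("%s: %d low-confidence template placements", pname, n_lowconf))
    results[[pname]] <- list(features = all_features, ppf = ppf,
                             ps_prob = ps_tab, train = train,
                             reentrance = reent, csd = csd_map)
  }

  report <- render_report(results, config, warnings_log)
  writeLines(report, file.path(out_dir, "report.md"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("laminarephys")),
    r_version = R.version.string,
    seed = config$seed,
    profiles = names(config$profiles),
    ppi_ms = config$ppi_ms,
    noise_sd = config$noise_sd,
    config_hash = digest_config(config),
    outputs = list.files(out_dir),
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs"),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %s", out_dir)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}

# stable polynomial hash of the configuration's deparsed form (a
# non-cryptographic fingerprint; avoids an extra dependency)
digest_config <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

render_report <- function(results, config, warnings_log) {
  ln <- c("# Laminar evoked-response pipeline report", "")
  short <- c(25, 50)
  ln <- c(ln, "## Paired-pulse profile (DG amplitude, % change from P1)", "")
  ln <- c(ln, "| profile | " %+% paste(config$ppi_ms, "ms", collapse = " | ") %+% " |",
          "|" %+% paste(rep("---", length(config$ppi_ms) + 1), collapse = "|") %+% "|")
  for (pname in names(results)) {
    ppf <- results[[pname]]$ppf
    v <- vapply(config$ppi_ms, function(ppi) {
      r <- ppf[ppf$layer == "DG" & ppf$measure == "amplitude" &
                 ppf$ppi_ms == ppi, ]
      sprintf("%+.1f +- %.1f", r$pct_change, r$sem)
    }, character(1))
    ln <- c(ln, "| " %+% pname %+% " | " %+% paste(v, collapse = " | ") %+% " |")
  }
  ln <- c(ln, "")
  sgns <- vapply(names(results), function(pname) {
    ppf <- results[[pname]]$ppf
    mean(ppf$pct_change[ppf$layer == "DG" & ppf$measure == "amplitude" &
                          ppf$ppi_ms %in% short])
  }, numeric(1))
  ln <- c(ln, sprintf(
    "Short-interval (25/50 ms) DG percent change: %s.",
    paste(sprintf("%s %+0.1f%% (%s)", names(sgns), sgns,
                  ifelse(sgns < 0, "depression", "facilitation")),
          collapse = "; ")), "")
  ln <- c(ln, "## PS probability per interval (DG, pulse 2)", "")
  for (pname in names(results)) {
    pt <- results[[pname]]$ps_prob
    ln <- c(ln, sprintf("- %s: %s", pname,
      paste(sprintf("%g ms: %d/%d", pt$ppi_ms, pt$n_ps, pt$n_sweeps),
            collapse = ", ")))
  }
  ln <- c(ln, "")
  if (config$run_train) {
    ln <- c(ln, "## Re-entrance calls (train)", "")
    for (pname in names(results)) {
      rc <- results[[pname]]$reentrance
      called <- rc[!is.na(rc$first_pulse), ]
      ln <- c(ln, if (nrow(called) == 0)
        sprintf("- %s: none detected", pname)
        else sprintf("- %s: %s", pname,
          paste(sprintf("%s from pulse %d (latency %.1f ms, %.2f mV)",
                        called$layer, called$first_pulse, called$latency_ms,
                        called$amplitude_mv), collapse = "; ")))
    }
    ln <- c(ln, "")
  }
  if (length(warnings_log) > 0)
    ln <- c(ln, "## Warnings", "", paste("-", warnings_log), "")
  ln
}

`%+%` <- function(a, b) paste0(a, b)
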