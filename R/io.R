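#' Write / read a laminar recording (HDF5)
#'
#' Recordings are stored in an HDF5 container: datasets `potentials`
#' (channels x samples, float64) and `stim_times` (sample indices),
#' attributes `sampling_rate_hz`, `spacing_um` and `protocol` (JSON), a
#' `pulse_info` table, and the simulator ground truth under `/truth`
#' (component catalogue and profile as JSON, numeric arrays as datasets).
#' Write followed by read reproduces all arrays bit-exactly.
#'
#' @param rec A `laminar_recording`.
#' @param path Output `.h5` path (overwritten if present).
#' @return `write_recording`: `path`, invisibly. `read_recording`: a
#'   `laminar_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "laminar_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  rhdf5::h5write(rec$potentials, h5, "potentials")
  rhdf5::h5write(as.integer(rec$stim_times), h5, "stim_times")
  rhdf5::h5write(rec$pulse_info, h5, "pulse_info")
  ds <- rhdf5::H5Dopen(h5, "potentials")
  rhdf5::h5writeAttribute(rec$sampling_rate, ds, "sampling_rate_hz")
  rhdf5::h5writeAttribute(rec$geometry$spacing_um, ds, "spacing_um")
  rhdf5::h5writeAttribute(rec$geometry$depth_of_first_contact_um, ds,
                          "depth_of_first_contact_um")
  rhdf5::h5writeAttribute(rec$noise_sd, ds, "noise_sd")
  rhdf5::h5writeAttribute(rec$artifact_amp, ds, "artifact_amp")
  rhdf5::h5writeAttribute(rec$seed, ds, "seed")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(unclass(rec$protocol), auto_unbox = TRUE)),
    ds, "protocol")
  rhdf5::H5Dclose(ds)
  if (!is.null(rec$truth)) {
    rhdf5::h5createGroup(h5, "truth")
    tr <- rec$truth
    rhdf5::h5write(tr$base_amplitudes, h5, "truth/base_amplitudes")
    rhdf5::h5write(tr$gains, h5, "truth/gains")
    rhdf5::h5write(tr$clean_amplitudes, h5, "truth/clean_amplitudes")
    rhdf5::h5write(tr$ps_flags, h5, "truth/ps_flags")
    rhdf5::h5write(tr$reentry_flags, h5, "truth/reentry_flags")
    rhdf5::h5write(tr$base_window, h5, "truth/base_window")
    if (!is.null(tr$reentry_window))
      rhdf5::h5write(tr$reentry_window, h5, "truth/reentry_window")
    rhdf5::h5write(tr$t_window_ms, h5, "truth/t_window_ms")
    rhdf5::h5write(tr$ps_time_ms, h5, "truth/ps_time_ms")
    rhdf5::h5write(tr$layer_map, h5, "truth/layer_map")
    rhdf5::h5write(
      as.character(jsonlite::toJSON(lapply(tr$components, unclass),
                                    auto_unbox = TRUE)),
      h5, "truth/components_json")
    pr <- unclass(tr$profile)
    pr$ppi_gain <- as.list(pr$ppi_gain) # keep interval names in JSON
    if (is.infinite(pr$ps_threshold)) pr$ps_threshold <- NULL
    rhdf5::h5write(
      as.character(jsonlite::toJSON(pr, auto_unbox = TRUE, null = "null")),
      h5, "truth/profile_json")
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  stopifnot(file.exists(path))
  pot <- rhdf5::h5read(path, "potentials")
  at <- lapply(rhdf5::h5readAttributes(path, "potentials"), as.vector)
  proto <- jsonlite::fromJSON(at$protocol)
  protocol <- stimulus_protocol(
    kind = proto$kind, current_ua = proto$current_ua, ppi_ms = proto$ppi_ms,
    n_repeats = proto$n_repeats, train_len = proto$train_len,
    train_hz = proto$train_hz, pulse_width_ms = proto$pulse_width_ms,
    inter_pair_gap_s = proto$inter_pair_gap_s)
  geometry <- probe_geometry(
    n_contacts = nrow(pot), spacing_um = at$spacing_um,
    depth_of_first_contact_um = at$depth_of_first_contact_um)
  cn <- rhdf5::h5ls(path)$name
  truth <- NULL
  if ("truth" %in% cn) {
    comps <- jsonlite::fromJSON(rhdf5::h5read(path, "truth/components_json"),
                                simplifyVector = FALSE)
    components <- lapply(comps, function(cc)
      csd_component(cc$name, cc$center_depth_um, cc$spatial_sd_um,
                    cc$onset_ms, cc$tau_ms, cc$polarity, cc$peak_density,
                    cc$return_offset_um))
    pj <- jsonlite::fromJSON(rhdf5::h5read(path, "truth/profile_json"))
    profile <- excitability_profile(
      ppi_gain = unlist(pj$ppi_gain), train_gain = pj$train_gain,
      ps_threshold = if (is.null(pj$ps_threshold)) Inf
                     else as.numeric(pj$ps_threshold),
      ps_prob = pj$ps_prob, reentry_first_pulse = pj$reentry_first_pulse,
      reentry_latency_ms = pj$reentry_latency_ms,
      reentry_layer = pj$reentry_layer, reentry_gain = pj$reentry_gain,
      label = pj$label)
    base_amp <- rhdf5::h5read(path, "truth/base_amplitudes")
    lmap <- as.data.frame(rhdf5::h5read(path, "truth/layer_map"))
    names(base_amp) <- lmap$layer
    clean_amp <- rhdf5::h5read(path, "truth/clean_amplitudes")
    rownames(clean_amp) <- lmap$layer
    truth <- list(
      components = components, profile = profile, layer_map = lmap,
      base_amplitudes = base_amp, gains = as.vector(rhdf5::h5read(path, "truth/gains")),
      clean_amplitudes = clean_amp,
      ps_flags = as.logical(rhdf5::h5read(path, "truth/ps_flags")),
      reentry_flags = as.logical(rhdf5::h5read(path, "truth/reentry_flags")),
      base_window = rhdf5::h5read(path, "truth/base_window"),
      reentry_window = if ("reentry_window" %in% cn)
        rhdf5::h5read(path, "truth/reentry_window") else NULL,
      t_window_ms = as.vector(rhdf5::h5read(path, "truth/t_window_ms")),
      ps_time_ms = as.vector(rhdf5::h5read(path, "truth/ps_time_ms")))
  }
  rec <- list(potentials = pot, sampling_rate = as.vector(at$sampling_rate_hz),
              geometry = geometry,
              stim_times = as.integer(rhdf5::h5read(path, "stim_times")),
              protocol = protocol,
              pulse_info = as.data.frame(rhdf5::h5read(path, "pulse_info")),
              truth = truth, noise_sd = as.vector(at$noise_sd),
              artifact_amp = as.vector(at$artifact_amp),
              seed = as.vector(at$seed))
  class(rec) <- "laminar_recording"
  rec
}

#' Export a feature table as tidy CSV
#'
#' One row per sweep x layer x measure source, columns `session`,
#' `protocol`, `layer`, `pulse_index`, `ppi_ms`, `amplitude_mv`,
#' `latency_ms`, `ps_flag`, `pct_change` (when present).
#'
#' @param features A feature table from [extract_features()].
#' @param path Output CSV path.
#' @param session Session identifier written into the `session` column.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, session = "session1") {
  stopifnot(is.data.frame(features))
  out <- cbind(session = session, features)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
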