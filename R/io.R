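# File I/O: HDF5 as the canonical matrix container, CSV for tables and
# human-readable spectra, YAML run configs, JSON provenance sidecars.

h5_write_matrix <- function(obj, file, name) {
  rhdf5::h5write(obj, file, name)
}

#' Write a dataset (and optional ground truth) to HDF5
#'
#' Layout: `/X_T` (sensors x time), `/X_S` (frames x pixels), and when
#' truth is supplied `/truth/{S_T,S_S,A_T,A_S,pairing,image_shape}` plus a
#' `/truth/transfer_json` scalar holding the transfer configuration.
#'
#' @param path output file (overwritten).
#' @param X_T,X_S [data_matrix()] objects or plain matrices.
#' @param truth optional `ground_truth`.
#' @param snr optional scalar stored at `/snr`.
#' @return `path`, invisibly.
#' @export
write_bicar_dataset <- function(path, X_T, X_S, truth = NULL, snr = NULL) {
  X_T <- as_data_matrix(X_T, "temporal")
  X_S <- as_data_matrix(X_S, "spatial")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  h5_write_matrix(X_T$values, path, "X_T")
  h5_write_matrix(X_S$values, path, "X_S")
  if (!is.null(snr)) h5_write_matrix(snr, path, "snr")
  if (!is.null(truth)) {
    rhdf5::h5createGroup(path, "truth")
    h5_write_matrix(truth$temporal_sources, path, "truth/S_T")
    h5_write_matrix(truth$spatial_sources, path, "truth/S_S")
    h5_write_matrix(truth$temporal_mixing, path, "truth/A_T")
    h5_write_matrix(truth$spatial_mixing, path, "truth/A_S")
    h5_write_matrix(as.integer(truth$pairing), path, "truth/pairing")
    h5_write_matrix(as.integer(truth$image_shape), path,
                    "truth/image_shape")
    h5_write_matrix(as.character(jsonlite::toJSON(unclass(truth$transfer),
                                                  auto_unbox = TRUE,
                                                  digits = NA)),
                    path, "truth/transfer_json")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a dataset written by [write_bicar_dataset()] (or any HDF5 file
#' with `/X_T` and `/X_S`)
#'
#' @param path HDF5 file.
#' @return list `X_T`, `X_S` ([data_matrix()]), and `truth`/`snr` when
#'   present.
#' @export
read_bicar_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  contents <- rhdf5::h5ls(path)
  names_avail <- paste0(sub("^/$", "", contents$group), "/", contents$name)
  names_avail <- sub("^/", "", names_avail)
  for (required in c("X_T", "X_S")) {
    if (!required %in% names_avail) {
      stop(sprintf("dataset '/%s' missing from %s", required, path))
    }
  }
  out <- list(
    X_T = data_matrix(rhdf5::h5read(path, "X_T"), "temporal"),
    X_S = data_matrix(rhdf5::h5read(path, "X_S"), "spatial"))
  if ("snr" %in% names_avail) out$snr <- as.numeric(rhdf5::h5read(path, "snr"))
  if ("truth/S_T" %in% names_avail) {
    tr <- jsonlite::fromJSON(as.character(
      rhdf5::h5read(path, "truth/transfer_json")))
    out$truth <- structure(
      list(temporal_sources = rhdf5::h5read(path, "truth/S_T"),
           spatial_sources = rhdf5::h5read(path, "truth/S_S"),
           temporal_mixing = rhdf5::h5read(path, "truth/A_T"),
           spatial_mixing = rhdf5::h5read(path, "truth/A_S"),
           pairing = as.integer(rhdf5::h5read(path, "truth/pairing")),
           transfer = do.call(transfer_config,
                              tr[setdiff(names(tr), "identity")]),
           image_shape = as.integer(rhdf5::h5read(path,
                                                  "truth/image_shape"))),
      class = "ground_truth")
  }
  rhdf5::h5closeAll()
  out
}

#' Write a BICAR result
#'
#' HDF5 layout `/result/{S_T,S_S,A_T,A_S,reproducibility}`, a JSON
#' provenance sidecar (`<stem>_provenance.json`) and the reproducibility
#' spectrum as CSV (`<stem>_spectrum.csv`, columns component, R).
#'
#' @param result a `bicar_result`.
#' @param path output HDF5 file.
#' @return `path`, invisibly.
#' @export
write_bicar_result <- function(result, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "result")
  h5_write_matrix(result$temporal_sources, path, "result/S_T")
  h5_write_matrix(result$spatial_sources, path, "result/S_S")
  h5_write_matrix(result$temporal_mixing, path, "result/A_T")
  h5_write_matrix(result$spatial_mixing, path, "result/A_S")
  h5_write_matrix(result$reproducibility, path, "result/reproducibility")
  rhdf5::h5closeAll()
  stem <- sub("\\.h5$", "", path)
  jsonlite::write_json(result$provenance,
                       paste0(stem, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  spectrum <- data.frame(component = seq_along(result$reproducibility),
                         R = result$reproducibility)
  write.csv(spectrum, paste0(stem, "_spectrum.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a BICAR result written by [write_bicar_result()]
#'
#' @param path HDF5 result file.
#' @return a `bicar_result`.
#' @export
read_bicar_result <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  stem <- sub("\\.h5$", "", path)
  prov_path <- paste0(stem, "_provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::fromJSON(prov_path) else list()
  out <- structure(
    list(temporal_sources = rhdf5::h5read(path, "result/S_T"),
         spatial_sources = rhdf5::h5read(path, "result/S_S"),
         temporal_mixing = rhdf5::h5read(path, "result/A_T"),
         spatial_mixing = rhdf5::h5read(path, "result/A_S"),
         reproducibility = as.numeric(
           rhdf5::h5read(path, "result/reproducibility")),
         provenance = prov),
    class = "bicar_result")
  rhdf5::h5closeAll()
  out
}

#' Read a YAML run configuration
#'
#' Recognized keys: `n_components`, `n_realizations`, `master_seed`,
#' `weights: {w_T, w_S}`, `transfer: {a, b, delta, dt, q, conv_mode,
#' normalize}`, `paths: {input, output}`, `experiment: {...}`. Missing
#' keys fall back to package defaults (K = 30, w_T = w_S = 1/2, default
#' transfer).
#'
#' @param path YAML file.
#' @return validated list with a `transfer_config` in `$transfer` and a
#'   `config_hash` provenance fingerprint.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  raw <- yaml::yaml.load_file(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  cfg <- list(
    n_components = raw$n_components,
    n_realizations = raw$n_realizations %||% 30L,
    master_seed = raw$master_seed %||% 1L,
    w_T = raw$weights$w_T %||% 0.5,
    w_S = raw$weights$w_S %||% 0.5,
    paths = raw$paths %||% list(),
    experiment = raw$experiment %||% list())
  cfg$transfer <- do.call(transfer_config, raw$transfer %||% list())
  if (cfg$n_realizations < 2L) stop("n_realizations must be >= 2")
  if (cfg$w_T < 0 || cfg$w_S < 0 || cfg$w_T + cfg$w_S <= 0) {
    stop("weights must be nonnegative with positive sum")
  }
  cfg$config_hash <- fnv1a(jsonlite::toJSON(
    list(cfg$n_components, cfg$n_realizations, cfg$master_seed,
         cfg$w_T, cfg$w_S, unclass(cfg$transfer)),
    auto_unbox = TRUE, digits = NA, null = "null"))
  cfg
}
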