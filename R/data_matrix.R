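#' Construct a modality-tagged data matrix
#'
#' Wraps a numeric matrix together with its modality. Temporal data are
#' sensors x time samples (fast sampling, sparse coverage, e.g. EEG-like);
#' spatial data are time frames x pixels (slow sampling, dense coverage,
#' e.g. image volumes). In the intended regime the temporal matrix has more
#' time samples than the spatial matrix has frames, and the spatial matrix
#' has more pixels than the temporal matrix has sensors; violations warn
#' but do not fail.
#'
#' @param values numeric matrix with finite entries. Temporal: rows =
#'   sensors, columns = time samples. Spatial: rows = frames, columns =
#'   pixels.
#' @param modality `"temporal"` or `"spatial"`.
#' @param sampling_interval sample spacing in seconds (temporal) or the
#'   frame period (spatial); optional metadata.
#' @return an object of class `data_matrix`.
#' @export
data_matrix <- function(values, modality = c("temporal", "spatial"),
                        sampling_interval = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("data matrix must be numeric with finite entries")
  }
  structure(
    list(values = values, modality = modality,
         sampling_interval = sampling_interval),
    class = "data_matrix"
  )
}

#' @export
print.data_matrix <- function(x, ...) {
  roles <- if (x$modality == "temporal") c("sensors", "time samples")
           else c("frames", "pixels")
  cat(sprintf("<data_matrix: %s, %d %s x %d %s>\n", x$modality,
              nrow(x$values), roles[1], ncol(x$values), roles[2]))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

as_data_matrix <- function(x, modality) {
  if (inherits(x, "data_matrix")) return(x)
  data_matrix(x, modality)
}

# Warn when a temporal/spatial pair is not in the intended resolution regime
# (N_TT > N_ST and N_SS > N_TS).
check_resolution_regime <- function(temporal, spatial) {
  n_tt <- ncol(temporal$values)  # time samples
  n_ts <- nrow(temporal$values)  # sensors
  n_st <- nrow(spatial$values)   # frames
  n_ss <- ncol(spatial$values)   # pixels
  if (n_tt <= n_st) {
    warning(sprintf(paste0("temporal data has %d time samples but spatial ",
                           "data has %d frames; expected the temporal grid ",
                           "to be denser"), n_tt, n_st))
  }
  if (n_ss <= n_ts) {
    warning(sprintf(paste0("spatial data has %d pixels but temporal data ",
                           "has %d sensors; expected the spatial grid to ",
                           "be denser"), n_ss, n_ts))
  }
  invisible(NULL)
}
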