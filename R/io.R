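# File interfaces. Sweeps travel as long-format delimited text plus a JSON
# protocol sidecar; image stacks as multi-page TIFF plus a JSON metadata
# sidecar; results as TSV/JSON. No proprietary acquisition formats.

#' Write a sweep set to delimited text + JSON sidecar
#'
#' Long format: columns `sweep_id`, `time_s`, `current_pA` (tab-separated).
#' The protocol, sampling rate and filter setting go to `<path>.json`.
#'
#' @param sweeps A [sweep_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  n_sw <- ncol(sweeps$sweeps_pA)
  df <- data.frame(
    sweep_id = rep(seq_len(n_sw), each = nrow(sweeps$sweeps_pA)),
    time_s = rep(sweeps$time_s, n_sw),
    current_pA = as.vector(sweeps$sweeps_pA)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(protocol = sweeps$protocol,
               sampling_rate_Hz = sweeps$sampling_rate_Hz,
               filter_Hz = sweeps$filter_Hz)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a sweep set written by [write_sweeps()]
#'
#' @param path TSV path; `<path>.json` must hold the protocol sidecar.
#' @return A [sweep_set()].
#' @export
read_sweeps <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ids <- sort(unique(df$sweep_id))
  time_s <- df$time_s[df$sweep_id == ids[1]]
  m <- vapply(ids, function(i) df$current_pA[df$sweep_id == i],
              numeric(length(time_s)))
  sweep_set(time_s, matrix(m, ncol = length(ids)), as.list(meta$protocol),
            sampling_rate_Hz = meta$sampling_rate_Hz,
            filter_Hz = if (is.null(meta$filter_Hz)) NA_real_ else meta$filter_Hz)
}

#' Write an image stack as multi-page TIFF + JSON sidecar
#'
#' Intensities are scaled to [0, 1] by `scale` (default: the stack maximum)
#' for 16-bit TIFF storage; the scale is recorded in the sidecar so reading
#' restores the original units.
#'
#' @param stack An [image_stack()] or [two_channel_stack()] (written as
#'   `<path>_green.tif` / `<path>_red.tif`).
#' @param path Output TIFF path (for two-channel input, a path stem).
#' @param scale Intensity that maps to full scale.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = NULL) {
  write_one <- function(arr, p, meta) {
    sc <- if (is.null(scale)) max(arr, 1e-12) else scale
    pages <- lapply(seq_len(dim(arr)[3]), function(i) {
      pmin(pmax(arr[, , i] / sc, 0), 1)
    })
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    meta$intensity_scale <- sc
    jsonlite::write_json(meta, paste0(p, ".json"), auto_unbox = TRUE, digits = NA)
  }
  if (inherits(stack, "two_channel_stack")) {
    meta <- list(pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$frame_interval_s,
                 bit_depth = stack$bit_depth, scan_mode = stack$scan_mode)
    write_one(stack$green, paste0(path, "_green.tif"), meta)
    write_one(stack$red, paste0(path, "_red.tif"), meta)
  } else {
    write_one(stack$frames, path,
              list(pixel_size_um = stack$pixel_size_um,
                   frame_interval_s = stack$frame_interval_s))
  }
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (single-channel form).
#' @return An [image_stack()] in the original intensity units.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- simplify2array(pages) * meta$intensity_scale
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1L))
  image_stack(arr, frame_interval_s = meta$frame_interval_s,
              pixel_size_um = meta$pixel_size_um)
}

#' Read a two-channel stack written by [write_stack()]
#'
#' @param path_stem Path stem used when writing (`<stem>_green.tif`,
#'   `<stem>_red.tif`).
#' @return A [two_channel_stack()].
#' @export
read_two_channel_stack <- function(path_stem) {
  rd <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    meta <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
    arr <- simplify2array(pages) * meta$intensity_scale
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1L))
    list(arr = arr, meta = meta)
  }
  g <- rd(paste0(path_stem, "_green.tif"))
  r <- rd(paste0(path_stem, "_red.tif"))
  two_channel_stack(g$arr, r$arr, g$meta$pixel_size_um,
                    g$meta$frame_interval_s, bit_depth = g$meta$bit_depth,
                    scan_mode = g$meta$scan_mode)
}

#' Write a calibration curve (table TSV + Hill parameters JSON)
#'
#' @param curve A [calibration_curve()].
#' @param path_stem Writes `<stem>_table.tsv` and `<stem>_hill.json`.
#' @return `path_stem`, invisibly.
#' @export
write_calibration <- function(curve, path_stem) {
  stopifnot(inherits(curve, "calibration_curve"))
  utils::write.table(curve$table, paste0(path_stem, "_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  h <- curve$hill
  jsonlite::write_json(
    list(R_min = h$R_min, R_max = h$R_max, EC50_nM = h$EC50_nM, n_H = h$n_H,
         covariance = h$covariance),
    paste0(path_stem, "_hill.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(path_stem)
}

#' Write bead tracks as TSV
#'
#' @param tracks List of `bead_track` objects from [track_beads()].
#' @param path Output TSV (`track_id`, `frame`, `x_px`, `y_px`).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i, frame = tr$frame_indices,
               x_px = tr$x_px, y_px = tr$y_px)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read circuit/geometry parameters from a YAML config
#'
#' Reads the flat `circuit:` section (keys `c_m_pF`, `r_m_MOhm`,
#' `r_series_MOhm`, `length_um`, `radius_um`, `rho_ohm_cm`,
#' `spec_cap_uF_cm2`) and returns constructed model objects; missing keys
#' fall back to the constructors' defaults.
#'
#' @param path YAML file path.
#' @return List: `geometry` ([cilium_geometry()]), `constants`
#'   ([membrane_constants()]), `circuit` ([equivalent_circuit()] or NULL when
#'   capacitance/series keys are absent).
#' @export
read_circuit_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cc <- cfg$circuit
  if (is.null(cc)) stop("config has no `circuit:` section", call. = FALSE)
  geom <- cilium_geometry(
    length_um = if (!is.null(cc$length_um)) cc$length_um else 11.5,
    radius_um = if (!is.null(cc$radius_um)) cc$radius_um else 0.125)
  konst <- membrane_constants(
    spec_cap_uF_cm2 = if (!is.null(cc$spec_cap_uF_cm2)) cc$spec_cap_uF_cm2 else 1,
    rho_ohm_cm = if (!is.null(cc$rho_ohm_cm)) cc$rho_ohm_cm else 150)
  circ <- NULL
  if (!is.null(cc$c_m_pF) && !is.null(cc$r_series_MOhm)) {
    circ <- equivalent_circuit(
      c_m_pF = cc$c_m_pF, r_series_MOhm = cc$r_series_MOhm,
      r_m_MOhm = if (!is.null(cc$r_m_MOhm)) cc$r_m_MOhm else Inf)
  }
  list(geometry = geom, constants = konst, circuit = circ)
}
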