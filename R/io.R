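# Plain-text persistence: electrode CSV/JSON, EGM CSV, track CSV, density
# VTK + JSON summary, protocol report JSON, simulation CSV + JSON metadata.

#' Export electrodes as CSV
#' @param electrodes an \code{ElectrodeSet}.
#' @param path output CSV path.
#' @export
export_electrodes_csv <- function(electrodes, path) {
  df <- data.frame(id = electrodes$labels,
                   x = electrodes$positions[, 1],
                   y = electrodes$positions[, 2],
                   z = electrodes$positions[, 3],
                   wall_distance = electrodes$wall_distance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a catheter configuration from JSON
#'
#' Fields: \code{type} ("grid" or "basket") plus \code{n}/\code{spacing_mm}
#' (grid) or \code{diameter_mm}/\code{n_splines}/\code{electrodes_per_spline}
#' /\code{pole_axis}/\code{center} (basket), and optional placement fields
#' \code{roi_center}/\code{wall_distance_mm}.
#'
#' @param path JSON file.
#' @param mesh optional mesh; when given, grids are placed immediately.
#' @return an \code{ElectrodeSet}.
#' @export
read_catheter_json <- function(path, mesh = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(cfg$type, "grid")) {
    g <- build_grid(cfg$n, cfg$spacing_mm)
    if (!is.null(mesh) && !is.null(cfg$roi_center))
      g <- place_grid(mesh, g, cfg$roi_center,
                      wall_distance = cfg$wall_distance_mm %||% 0)
    g
  } else if (identical(cfg$type, "basket")) {
    place_basket(mesh,
                 diameter = cfg$diameter_mm %||% 48,
                 n_splines = cfg$n_splines %||% 8,
                 electrodes_per_spline = cfg$electrodes_per_spline %||% 8,
                 pole_axis = cfg$pole_axis %||% c(0, 0, 1),
                 center = cfg$center %||% c(0, 0, 0))
  } else stop("unknown catheter type in ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export electrograms as CSV with a JSON sidecar
#'
#' CSV: a time_ms column plus one column per electrode ID. Sidecar JSON
#' (same path + ".json"): electrode positions and sigma_blood.
#'
#' @param egms an \code{EGMSet}.
#' @param path output CSV path.
#' @export
export_egms_csv <- function(egms, path) {
  df <- data.frame(time_ms = egms$time)
  phi <- as.data.frame(egms$phi)
  names(phi) <- egms$electrodes$labels
  utils::write.csv(cbind(df, phi), path, row.names = FALSE)
  jsonlite::write_json(list(electrodes = data.frame(
    id = egms$electrodes$labels,
    x = egms$electrodes$positions[, 1],
    y = egms$electrodes$positions[, 2],
    z = egms$electrodes$positions[, 3]),
    sigma_blood = egms$sigma_blood),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export rotor tracks as CSV
#' @param tracks list of \code{RotorTrack}s.
#' @param path output CSV path.
#' @export
export_tracks_csv <- function(tracks, path) {
  rows <- lapply(seq_along(tracks), function(i)
    cbind(track_id = i, tracks[[i]]$obs))
  df <- do.call(rbind, rows)
  utils::write.csv(df[, c("time_ms", "x", "y", "z", "charge", "track_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a density map as VTK point data plus JSON summary
#' @param dmap a \code{DensityMap}.
#' @param mesh the mesh it was computed on.
#' @param path output VTK path (summary goes to path + ".json").
#' @export
export_density_vtk <- function(dmap, mesh, path) {
  save_mesh(mesh, path, point_data = list(density = dmap$values))
  jsonlite::write_json(list(peak_node = dmap$peak_node,
                            peak_position = as.numeric(dmap$peak_position),
                            window_ms = dmap$window, sigma_mm = dmap$sigma),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a simulation result (CSV + JSON metadata)
#'
#' \code{path} is a stem: voltages go to \code{<stem>_vm.csv} (nodes x
#' samples), metadata to \code{<stem>.json}.
#'
#' @param result a \code{SimulationResult}.
#' @param path file stem.
#' @export
save_simulation <- function(result, path) {
  utils::write.csv(as.data.frame(result$vm), paste0(path, "_vm.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(time = result$time, dt_ms = result$dt_ms,
                            model = result$model_name, t_end = result$t_end,
                            output_rate_hz = result$output_rate_hz),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a protocol report as JSON
#' @param report an \code{rb_report}.
#' @param path output JSON path.
#' @export
export_report_json <- function(report, path) {
  lst <- list(status = report$status, anchored = report$anchored,
              config = report$config,
              iterations = lapply(report$iterations, function(it) {
                it$density_peak <- as.numeric(it$density_peak)
                it$gt_peak <- as.numeric(it$gt_peak)
                it$lesion$center <- as.numeric(it$lesion$center)
                it
              }))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
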