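#' Write a simulation result to CSV (with a JSON metadata sidecar)
#'
#' Long format, one row per node and snapshot: `time` (min), `node_index`
#' (0-based), `position` (um), `density` (the mean of the adjacent cell
#' densities; edge nodes take their single neighbour), `velocity`
#' (um/min).  The JSON sidecar records the parameters and geometry so a
#' run is fully described by the pair of files.
#'
#' @param sim a [simulate_contraction()] result.
#' @param csv_path output CSV path.
#' @param json_path output JSON path (default: `csv_path` with a `.json`
#'   extension).
#' @return Invisibly, the CSV path.
#' @export
write_simulation_csv <- function(sim, csv_path,
                                 json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(sim, "simulation_result"))
  rows <- do.call(rbind, lapply(seq_along(sim$times), function(j) {
    st <- sim$states[[j]]
    rho <- st$cell_densities
    node_rho <- c(rho[1], (rho[-1] + rho[-length(rho)]) / 2, rho[length(rho)])
    data.frame(time = sim$times[j],
               node_index = seq_along(st$node_positions) - 1L,
               position = st$node_positions,
               density = node_rho,
               velocity = sim$velocities[, j])
  }))
  write.csv(rows, csv_path, row.names = FALSE)
  meta <- list(parameters = unclass(sim$params),
               geometry = unclass(sim$geometry),
               rho_init_ratio = sim$rho_init_ratio,
               n_cells = length(sim$states[[1]]$cell_densities),
               n_snapshots = length(sim$times),
               expanding = sim$expanding)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}

#' Write density profiles to CSV
#'
#' Long format: `time` (min), `position` (um), `intensity` (1/um).
#'
#' @param profiles list of [new_density_profile()] objects.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(time = p$time, position = p$positions, intensity = p$intensity)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read density profiles from CSV
#'
#' Inverse of [write_profiles_csv()].
#'
#' @param path CSV path with columns `time`, `position`, `intensity`.
#' @return List of [new_density_profile()] objects, ordered by time.
#' @export
read_profiles_csv <- function(path) {
  d <- read.csv(path)
  lapply(sort(unique(d$time)), function(tt) {
    s <- d[d$time == tt, ]
    new_density_profile(s$position, s$intensity, time = tt, normalize = FALSE)
  })
}

#' Write a PIV field to CSV
#'
#' Columns `x`, `y` (window centres, px), `u`, `v` (px/frame pair),
#' `valid`.
#'
#' @param field a [piv()] result.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_piv_csv <- function(field, path) {
  stopifnot(inherits(field, "piv_field"))
  write.csv(data.frame(x = field$x, y = field$y, u = field$u, v = field$v,
                       valid = field$valid),
            path, row.names = FALSE)
  invisible(path)
}

#' Read and write frame stacks as multi-page TIFF
#'
#' Frames are stored as 16-bit TIFF pages; intensities are divided by
#' `scale` on write and multiplied back on read, so values up to `scale`
#' survive the round trip at 16-bit quantization.
#'
#' @param stack a [frame_stack()].
#' @param path TIFF path.
#' @param scale full-scale intensity mapped to the 16-bit maximum
#'   (default 65535, i.e. raw a.u. stored directly).
#' @return `write_frame_stack()`: invisibly, the path;
#'   `read_frame_stack()`: a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path, scale = 65535) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(stack$frames, function(f) pmin(pmax(f / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_frame_stack
#' @param pixel_size,frame_interval,camera_offset metadata for the
#'   reconstructed stack (TIFF carries none).
#' @export
read_frame_stack <- function(path, pixel_size, frame_interval = 20,
                             camera_offset = 0, scale = 65535) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_mtc("mtc_io_error",
                               sprintf("cannot read TIFF '%s': %s", path,
                                       conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * scale
  })
  frame_stack(frames, pixel_size = pixel_size,
              frame_interval = frame_interval, camera_offset = camera_offset)
}

#' Write a scaling-scan report to CSV and JSON
#'
#' The per-width scan table (`W0`, `tau`, `eps_inf`, `Tc`) goes to CSV;
#' the determined constants, parameter ratios and protocol to JSON.
#'
#' @param constants a [determine_alpha_beta()] result.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_scaling_report <- function(constants, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(constants, "scaling_constants"))
  if (!is.null(csv_path))
    write.csv(attr(constants, "scan"), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(alpha = constants$alpha, beta = constants$beta,
                              fit_residual = constants$fit_residual,
                              protocol = attr(constants, "protocol")),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
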