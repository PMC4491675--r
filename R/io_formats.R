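# File formats: ASCII dose planes, field CSV/JSON, two-column depth-dose
# curves, and the JSON beam-library document.  Every format's reader and
# writer compose to the identity on valid files.

FORMAT_VERSION <- "1"

#' Write a dose plane as an ASCII grid
#'
#' Dialect: '#'-prefixed header lines \code{# depth_gcm2=}, \code{# origin_mm=},
#' \code{# spacing_mm=}, then whitespace-separated rows of the dose matrix
#' (first row = first y, i.e. the origin row).
#'
#' @param plane a \code{\link{dose_plane}}.
#' @param path output file.
#' @export
write_dose_plane <- function(plane, path) {
  stopifnot(inherits(plane, "dose_plane"))
  hdr <- c(sprintf("# protonqa_dose_plane v%s", FORMAT_VERSION),
           sprintf("# depth_gcm2=%.17g", plane$depth),
           sprintf("# origin_mm=%.17g %.17g", plane$origin_x, plane$origin_y),
           sprintf("# spacing_mm=%.17g", plane$spacing))
  rows <- apply(plane$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ASCII dose-plane grid
#'
#' @param path file written by \code{\link{write_dose_plane}} (comment lines
#'   tolerated anywhere).
#' @return a \code{\link{dose_plane}}.
#' @export
read_dose_plane <- function(path) {
  if (!file.exists(path)) stop("read_dose_plane: no such file: ", path)
  lines <- readLines(path)
  get_hdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)
    if (length(m) == 0L) stop("read_dose_plane: missing header '", key, "='")
    as.numeric(strsplit(sub(paste0("^#\\s*", key, "="), "", m[1]), "\\s+")[[1]])
  }
  depth <- get_hdr("depth_gcm2")
  origin <- get_hdr("origin_mm")
  spacing <- get_hdr("spacing_mm")
  data_lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  vals <- do.call(rbind, lapply(data_lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (any(!is.finite(vals))) stop("read_dose_plane: non-numeric grid values")
  dose_plane(vals, origin[1], origin[2], spacing, depth,
             meta = list(source = path))
}

#' Write a field as CSV plus a JSON metadata sidecar
#'
#' CSV header: \code{layer,energy_mev,x_mm,y_mm,mu}; the sidecar
#' (\code{<path>.json}) carries field id, gantry angle, range-shifter flag
#' and the per-row machine energy indices.
#'
#' @param field a \code{\link{pqa_field}}.
#' @param library beam library supplying the energy table.
#' @param path CSV path.
#' @export
write_field_csv <- function(field, library, path) {
  stopifnot(inherits(field, "pqa_field"))
  en <- library$machine$energies$energy_mev[field$spots$energy_index]
  df <- data.frame(layer = field$spots$layer, energy_mev = en,
                   x_mm = field$spots$x, y_mm = field$spots$y,
                   mu = field$spots$mu)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(format = "protonqa_field", version = FORMAT_VERSION,
               field_id = field$field_id, gantry_angle = field$gantry_angle,
               range_shifter = field$range_shifter,
               spot_index = field$spots$spot,
               energy_index = field$spots$energy_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field from CSV (+ JSON sidecar)
#'
#' @param path CSV path written by \code{\link{write_field_csv}}; the
#'   \code{<path>.json} sidecar must sit next to it.
#' @param library beam library used to map energies back to indices when the
#'   sidecar lacks them.
#' @return a \code{\link{pqa_field}}.
#' @export
read_field_csv <- function(path, library) {
  df <- utils::read.csv(path)
  req <- c("layer", "energy_mev", "x_mm", "y_mm", "mu")
  if (!all(req %in% names(df)))
    stop("read_field_csv: CSV must have header ", paste(req, collapse = ","))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  ei <- meta$energy_index
  if (is.null(ei)) {
    ei <- vapply(df$energy_mev, function(e)
      which.min(abs(library$machine$energies$energy_mev - e)), integer(1))
  }
  sp <- meta$spot_index
  if (is.null(sp)) sp <- stats::ave(df$layer, df$layer, FUN = seq_along) - 1L
  spots <- data.frame(layer = df$layer, spot = sp, energy_index = ei,
                      x = df$x_mm, y = df$y_mm, mu = df$mu)
  pqa_field(spots,
            field_id = if (!is.null(meta$field_id)) meta$field_id else "field",
            gantry_angle = if (!is.null(meta$gantry_angle)) meta$gantry_angle else 0,
            range_shifter = isTRUE(meta$range_shifter))
}

#' Write a depth-dose curve as two-column ASCII
#'
#' Columns: depth (g/cm^2) and value; '#' comment lines carry the energy
#' label.
#'
#' @param curve a \code{\link{depth_dose_curve}}.
#' @param path output file.
#' @export
write_depth_dose <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  hdr <- sprintf("# protonqa_depth_dose v%s energy_mev=%.17g",
                 FORMAT_VERSION, curve$energy_label)
  writeLines(c(hdr, sprintf("%.17g %.17g", curve$depths, curve$values)), path)
  invisible(path)
}

#' Read a two-column ASCII depth-dose curve
#'
#' @param path file (two whitespace-separated columns, '#' comments).
#' @return a \code{\link{depth_dose_curve}}.
#' @export
read_depth_dose <- function(path) {
  lines <- readLines(path)
  em <- grep("energy_mev=", lines, value = TRUE)
  energy <- if (length(em)) as.numeric(sub(".*energy_mev=", "", em[1])) else NA_real_
  data_lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  m <- do.call(rbind, lapply(data_lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  depth_dose_curve(m[, 1], m[, 2], energy_label = energy)
}

#' Serialize a beam library to JSON
#'
#' Versioned document holding the machine configuration and the per-energy
#' Bortfeld and lateral-kernel parameter sets.
#'
#' @param library a beam library (see \code{\link{make_beam_library}}).
#' @param path output JSON file.
#' @export
write_beam_library <- function(library, path) {
  doc <- list(
    format = "protonqa_beam_library", version = FORMAT_VERSION,
    machine = list(
      energies = library$machine$energies,
      max_field_cm = library$machine$max_field_cm,
      rs_wet = library$machine$rs_wet,
      rs_physical_cm = library$machine$rs_physical_cm,
      grid_spacing_mm = library$machine$grid_spacing_mm),
    alpha = library$alpha, p = library$p,
    bortfeld = lapply(library$bortfeld, unclass),
    kernels = lapply(library$kernels, unclass))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a beam library from JSON
#'
#' @param path JSON written by \code{\link{write_beam_library}}.
#' @return a beam library list (machine, bortfeld, kernels, alpha, p).
#' @export
read_beam_library <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "protonqa_beam_library"))
    stop("read_beam_library: not a beam-library document")
  machine <- machine_config(as.data.frame(doc$machine$energies),
                            max_field_cm = doc$machine$max_field_cm,
                            rs_wet = doc$machine$rs_wet,
                            rs_physical_cm = doc$machine$rs_physical_cm,
                            grid_spacing_mm = doc$machine$grid_spacing_mm)
  n <- nrow(machine$energies)
  bortfeld <- lapply(seq_len(n), function(i) {
    b <- doc$bortfeld[i, ]
    bortfeld_params(b$R0, b$sigma, b$epsilon, b$phi, b$p, b$alpha, b$energy)
  })
  kernels <- lapply(seq_len(n), function(i) {
    k <- doc$kernels[i, ]
    lateral_kernel_params(k$sigma_air1, k$sigma_air2, k$w_air,
                          unlist(k$growth1), unlist(k$growth2),
                          k$w2, k$wcl, k$s0, k$s1, k$R0)
  })
  list(machine = machine, bortfeld = bortfeld, kernels = kernels,
       alpha = doc$alpha, p = doc$p)
}
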