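# Spot-delivery log analysis: parsing, deviation statistics, delivered-dose
# reconstruction, and pattern-based periodic QA checks.

.SPOT_LOG_HEADER <- c("fraction", "layer", "spot", "planned_x_mm", "planned_y_mm",
                      "recorded_x_mm", "recorded_y_mm", "planned_mu", "recorded_mu")

#' Write a spot-delivery log CSV
#'
#' Schema: header \code{fraction,layer,spot,planned_x_mm,planned_y_mm,
#' recorded_x_mm,recorded_y_mm,planned_mu,recorded_mu}.  Values are written
#' with 17 significant digits so that write -> parse round-trips exactly.
#'
#' @param records data.frame of spot-log records (internal column names
#'   \code{fraction, layer, spot, planned_x, planned_y, recorded_x,
#'   recorded_y, planned_mu, recorded_mu}).
#' @param path output file.
#' @export
write_spot_log <- function(records, path) {
  cols <- c("fraction", "layer", "spot", "planned_x", "planned_y",
            "recorded_x", "recorded_y", "planned_mu", "recorded_mu")
  stopifnot(is.data.frame(records), all(cols %in% names(records)))
  lines <- c(paste(.SPOT_LOG_HEADER, collapse = ","),
             do.call(paste, c(lapply(records[cols], function(v) {
               ifelse(v == round(v), format(v, scientific = FALSE),
                      sprintf("%.17g", v))
             }), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a spot-delivery log CSV
#'
#' Validates the header and every row; malformed rows are reported with
#' their line numbers in a single parse error.
#'
#' @param path CSV file in the documented spot-log schema.
#' @return data.frame with columns \code{fraction, layer, spot, planned_x,
#'   planned_y, recorded_x, recorded_y, planned_mu, recorded_mu} (positions
#'   mm, MUs >= 0).
#' @export
parse_spot_log <- function(path) {
  if (!file.exists(path)) stop("parse_spot_log: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop("parse_spot_log: empty file (missing header)")
  hdr <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  if (!identical(hdr, .SPOT_LOG_HEADER))
    stop("parse_spot_log: header does not match the spot-log schema: ",
         paste(hdr, collapse = ","))
  n <- length(lines) - 1L
  out <- data.frame(fraction = integer(n), layer = integer(n), spot = integer(n),
                    planned_x = numeric(n), planned_y = numeric(n),
                    recorded_x = numeric(n), recorded_y = numeric(n),
                    planned_mu = numeric(n), recorded_mu = numeric(n))
  if (n == 0L) return(out)
  bad <- character(0)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(trimws(fields)))
    if (length(fields) != 9L || any(is.na(vals))) {
      bad <- c(bad, sprintf("line %d: %s", i + 1L, lines[i + 1L]))
      next
    }
    out[i, ] <- as.list(vals)
  }
  if (length(bad))
    stop("parse_spot_log: malformed rows:\n  ", paste(bad, collapse = "\n  "))
  for (cn in c("fraction", "layer", "spot")) {
    if (any(out[[cn]] != round(out[[cn]])))
      stop("parse_spot_log: non-integer ", cn, " index")
    out[[cn]] <- as.integer(out[[cn]])
  }
  if (any(out$fraction < 0 | out$layer < 0 | out$spot < 0))
    stop("parse_spot_log: indices must be >= 0")
  if (any(out$planned_mu < 0 | out$recorded_mu < 0))
    stop("parse_spot_log: MUs must be >= 0")
  out
}

# MU-weighted aggregation of multi-burst deliveries: one recorded position
# per (fraction, layer, spot)
.aggregate_bursts <- function(records) {
  key <- interaction(records$fraction, records$layer, records$spot, drop = TRUE)
  if (!anyDuplicated(key)) return(records)
  agg <- lapply(split(records, key), function(g) {
    w <- g$recorded_mu
    if (sum(w) <= 0) w <- rep(1, nrow(g))
    data.frame(fraction = g$fraction[1], layer = g$layer[1], spot = g$spot[1],
               planned_x = g$planned_x[1], planned_y = g$planned_y[1],
               recorded_x = sum(w * g$recorded_x) / sum(w),
               recorded_y = sum(w * g$recorded_y) / sum(w),
               planned_mu = g$planned_mu[1],
               recorded_mu = sum(g$recorded_mu))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$fraction, out$layer, out$spot), ]
}

#' Spot-position and MU deviation statistics
#'
#' Deviations are recorded minus planned, at the isocenter plane in mm.
#' Returns aggregate per-axis statistics, per-layer and per-fraction
#' breakdowns, per-spot cross-fraction reproducibility (SD of the recorded
#' position for spots observed in >= 2 fractions, with pooled per-axis
#' estimates and their degrees of freedom), deviation histograms, and MU
#' deviation statistics in %.
#'
#' @param records spot-log data.frame (see \code{\link{parse_spot_log}});
#'   multi-burst rows are MU-weighted pre-aggregated.
#' @param bin_mm histogram bin width, mm (default 0.1).
#' @param hist_range_mm nominal histogram half-range, mm (default 2;
#'   extended automatically so every deviation is counted).
#' @return object of class \code{deviation_report}.
#' @export
deviation_stats <- function(records, bin_mm = 0.1, hist_range_mm = 2) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("deviation_stats: need at least one record")
  records <- .aggregate_bursts(records)
  dx <- records$recorded_x - records$planned_x
  dy <- records$recorded_y - records$planned_y
  dmu_pct <- ifelse(records$planned_mu > 0,
                    100 * (records$recorded_mu - records$planned_mu) / records$planned_mu,
                    NA_real_)
  axis_stats <- function(d) c(mean = mean(d), sd = stats::sd(d), max_abs = max(abs(d)))
  sd0 <- function(d) if (length(d) > 1L) stats::sd(d) else 0
  by_group <- function(fac) {
    g <- split(data.frame(dx = dx, dy = dy), fac)
    do.call(rbind, lapply(names(g), function(k) {
      data.frame(group = as.numeric(k),
                 mean_dx = mean(g[[k]]$dx), sd_dx = sd0(g[[k]]$dx),
                 mean_dy = mean(g[[k]]$dy), sd_dy = sd0(g[[k]]$dy),
                 max_abs = max(abs(c(g[[k]]$dx, g[[k]]$dy))),
                 n = nrow(g[[k]]))
    }))
  }
  per_layer <- by_group(records$layer)
  names(per_layer)[1] <- "layer"
  per_fraction <- by_group(records$fraction)
  names(per_fraction)[1] <- "fraction"

  # cross-fraction reproducibility
  key <- interaction(records$layer, records$spot, drop = TRUE)
  gs <- split(records, key)
  multi <- gs[vapply(gs, nrow, integer(1)) >= 2L]
  if (length(multi)) {
    rep_df <- do.call(rbind, lapply(multi, function(g) {
      data.frame(layer = g$layer[1], spot = g$spot[1], n_fractions = nrow(g),
                 sd_x = stats::sd(g$recorded_x), sd_y = stats::sd(g$recorded_y))
    }))
    rownames(rep_df) <- NULL
    dof <- sum(rep_df$n_fractions - 1L)
    pooled_x <- sqrt(sum((rep_df$n_fractions - 1L) * rep_df$sd_x^2) / dof)
    pooled_y <- sqrt(sum((rep_df$n_fractions - 1L) * rep_df$sd_y^2) / dof)
  } else {
    rep_df <- NULL; pooled_x <- NA_real_; pooled_y <- NA_real_; dof <- 0L
  }

  make_hist <- function(d) {
    half <- max(hist_range_mm, ceiling(max(abs(d)) / bin_mm) * bin_mm + bin_mm)
    breaks <- seq(-half, half, by = bin_mm)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  # deviation as a function of the planned coordinate (profile)
  profile_vs <- function(coord, d) {
    br <- pretty(coord, n = 20)
    f <- cut(coord, br, include.lowest = TRUE)
    agg <- tapply(d, f, mean)
    data.frame(coord = (br[-1] + br[-length(br)]) / 2, mean_dev = as.numeric(agg))
  }

  structure(list(
    n_records = nrow(records),
    overall = rbind(dx = axis_stats(dx), dy = axis_stats(dy)),
    mu = c(mean_pct = mean(dmu_pct, na.rm = TRUE),
           sd_pct = stats::sd(dmu_pct[!is.na(dmu_pct)]),
           max_abs_pct = max(abs(dmu_pct), na.rm = TRUE)),
    per_layer = per_layer,
    per_fraction = per_fraction,
    reproducibility = list(per_spot = rep_df, pooled_sd_x = pooled_x,
                           pooled_sd_y = pooled_y, dof = dof),
    hist_dx = make_hist(dx), hist_dy = make_hist(dy),
    dev_vs_x = profile_vs(records$planned_x, dx),
    dev_vs_y = profile_vs(records$planned_y, dy)),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("Spot-log deviation report: %d records\n", x$n_records))
  cat(sprintf("  dx: mean %+.3f mm, SD %.3f mm, max |dev| %.3f mm\n",
              x$overall["dx", "mean"], x$overall["dx", "sd"], x$overall["dx", "max_abs"]))
  cat(sprintf("  dy: mean %+.3f mm, SD %.3f mm, max |dev| %.3f mm\n",
              x$overall["dy", "mean"], x$overall["dy", "sd"], x$overall["dy", "max_abs"]))
  cat(sprintf("  MU: mean %+.3f%%, SD %.3f%%\n", x$mu["mean_pct"], x$mu["sd_pct"]))
  if (is.finite(x$reproducibility$pooled_sd_x))
    cat(sprintf("  reproducibility (pooled SD across fractions): x %.3f mm, y %.3f mm\n",
                x$reproducibility$pooled_sd_x, x$reproducibility$pooled_sd_y))
  invisible(x)
}

#' Reconstruct a delivered field from log records
#'
#' Builds a field whose spots carry the recorded positions and MUs of one
#' fraction, preserving the planned field's layer/energy structure.
#'
#' @param records spot-log data.frame.
#' @param fraction fraction index to reconstruct.
#' @param planned a \code{\link{pqa_field}}: the planned field the log refers
#'   to (provides the layer -> energy mapping and spot order).
#' @return a \code{pqa_field} of the delivered fraction.
#' @export
reconstruct_field_from_log <- function(records, fraction, planned) {
  stopifnot(inherits(planned, "pqa_field"))
  sub <- records[records$fraction == fraction, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("reconstruct_field_from_log: fraction ", fraction, " not present in records")
  sub <- .aggregate_bursts(sub)
  spots <- planned$spots
  key_p <- paste(spots$layer, spots$spot)
  key_r <- paste(sub$layer, sub$spot)
  idx <- match(key_p, key_r)
  if (any(is.na(idx)))
    stop("reconstruct_field_from_log: log is missing ",
         sum(is.na(idx)), " planned spot(s) for fraction ", fraction)
  spots$x <- sub$recorded_x[idx]
  spots$y <- sub$recorded_y[idx]
  spots$mu <- sub$recorded_mu[idx]
  pqa_field(spots, field_id = paste0(planned$field_id, "_delivered_fx", fraction),
            gantry_angle = planned$gantry_angle,
            range_shifter = planned$range_shifter)
}

#' Compare planned and log-reconstructed delivered dose
#'
#' Computes the planned and delivered planes with the same engine and
#' returns normalized dose differences plus a gamma comparison.
#'
#' @inheritParams compute_dose_plane
#' @param records spot-log data.frame.
#' @param fraction fraction index.
#' @param criteria a \code{\link{gamma_criteria}}.
#' @return list with \code{planned}, \code{delivered} (dose planes),
#'   \code{max_diff_pct}, \code{mean_diff_pct} (% of the planned plane
#'   maximum), and \code{gamma} (a \code{gamma_result}).
#' @export
planned_vs_delivered_dose <- function(field, records, fraction, library,
                                      phantom = NULL, depth, grid,
                                      criteria = gamma_criteria()) {
  delivered_field <- reconstruct_field_from_log(records, fraction, field)
  planned <- compute_dose_plane(field, library, phantom, depth, grid)
  delivered <- compute_dose_plane(delivered_field, library, phantom, depth, grid)
  norm <- max(planned$values)
  diff <- abs(delivered$values - planned$values)
  list(planned = planned, delivered = delivered,
       max_diff_pct = 100 * max(diff) / norm,
       mean_diff_pct = 100 * mean(diff) / norm,
       gamma = gamma_2d(planned, delivered, criteria))
}

#' Pattern-based periodic QA check
#'
#' Compares the mean recorded deviation of every pattern spot (across
#' fractions) against a tolerance; spots whose mean deviation magnitude
#' exceeds it are flagged with the estimated perturbation vector.
#'
#' @param records spot-log data.frame covering the pattern's spots.
#' @param pattern a \code{\link{pattern_spec}} (used to verify coverage).
#' @param tolerance_mm flagging tolerance, mm (default 0.5).
#' @return data.frame with \code{layer, spot, dx_mm, dy_mm, magnitude_mm,
#'   flagged}.
#' @export
pattern_qa_check <- function(records, pattern, tolerance_mm = 0.5) {
  stopifnot(inherits(pattern, "pattern_spec"))
  records <- .aggregate_bursts(records)
  n_expected <- .pattern_n_spots(pattern)
  got <- unique(records$spot[records$layer == 0 | TRUE])
  if (length(unique(paste(records$layer, records$spot))) < n_expected)
    stop("pattern_qa_check: records cover ",
         length(unique(paste(records$layer, records$spot))),
         " spots but the pattern defines ", n_expected)
  key <- interaction(records$layer, records$spot, drop = TRUE)
  est <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(layer = g$layer[1], spot = g$spot[1],
               dx_mm = mean(g$recorded_x - g$planned_x),
               dy_mm = mean(g$recorded_y - g$planned_y))
  }))
  rownames(est) <- NULL
  est$magnitude_mm <- sqrt(est$dx_mm^2 + est$dy_mm^2)
  est$flagged <- est$magnitude_mm > tolerance_mm
  est[order(est$layer, est$spot), ]
}
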