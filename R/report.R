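# PSQA report assembly and serialization (JSON round-trips; markdown mirrors
# the draft report a clinic would review).

#' Assemble a per-field PSQA report
#'
#' @param field_id field label.
#' @param point_dose optional named list/vector of signed point-dose
#'   differences (%).
#' @param gamma_results named list of \code{gamma_result} objects (e.g.
#'   \code{"2/2"}, \code{"3/3"}).
#' @param table_25d optional data.frame (offset_mm, depth, pass_rate) from
#'   \code{\link{gamma_2p5d}}.
#' @param disposition output of \code{\link{qa_disposition}}.
#' @param log_summary optional \code{deviation_report} (its scalar summary is
#'   embedded).
#' @param config optional run configuration list.
#' @param inputs optional named character vector of input files; MD5 hashes
#'   are recorded for provenance.
#' @return object of class \code{psqa_report}.
#' @export
psqa_report <- function(field_id, point_dose = NULL, gamma_results = list(),
                        table_25d = NULL, disposition = NULL,
                        log_summary = NULL, config = NULL, inputs = NULL) {
  hashes <- if (!is.null(inputs)) {
    h <- tools::md5sum(inputs)
    stats::setNames(as.character(h), names(inputs))
  } else NULL
  gam <- lapply(gamma_results, function(g) {
    list(dose_pct = g$criteria$dose_pct, dta_mm = g$criteria$dta_mm,
         threshold_pct = g$criteria$threshold_pct,
         pass_rate = g$pass_rate, n_evaluated = g$n_evaluated)
  })
  logsum <- if (!is.null(log_summary)) {
    list(n_records = log_summary$n_records,
         mean_dx_mm = unname(log_summary$overall["dx", "mean"]),
         sd_dx_mm = unname(log_summary$overall["dx", "sd"]),
         mean_dy_mm = unname(log_summary$overall["dy", "mean"]),
         sd_dy_mm = unname(log_summary$overall["dy", "sd"]),
         max_abs_mm = max(log_summary$overall[, "max_abs"]),
         reproducibility_sd_x_mm = log_summary$reproducibility$pooled_sd_x,
         reproducibility_sd_y_mm = log_summary$reproducibility$pooled_sd_y)
  } else NULL
  structure(list(schema = "protonqa_psqa_report", version = FORMAT_VERSION,
                 field_id = field_id, point_dose = point_dose, gamma = gam,
                 table_25d = table_25d, disposition = disposition,
                 log_summary = logsum, config = config,
                 input_hashes = hashes),
            class = "psqa_report")
}

#' Write a PSQA report
#'
#' JSON round-trips through \code{\link{read_report}}; markdown renders the
#' same content as tables at fixed precision (pass rates 0.1%, positions
#' 0.01 mm).
#'
#' @param report a \code{\link{psqa_report}}.
#' @param path output file.
#' @param format \code{"json"} or \code{"markdown"}.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "psqa_report"))
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    return(invisible(path))
  }
  ln <- c(sprintf("# PSQA draft report: field %s", report$field_id), "")
  if (!is.null(report$disposition)) {
    ln <- c(ln, sprintf("**Disposition: %s** (route: %s)",
                        toupper(report$disposition$status),
                        report$disposition$route), "")
    ev <- report$disposition$evidence
    ln <- c(ln,
            sprintf("- 2%%/2 mm pass rate: %.1f%%", ev$pass22),
            sprintf("- 3%%/3 mm pass rate: %.1f%%", ev$pass33),
            if (is.finite(ev$best25d))
              sprintf("- best 2.5D pass rate: %.1f%%", ev$best25d),
            sprintf("- action level: %.0f%%", ev$action_level), "")
  }
  if (length(report$gamma)) {
    ln <- c(ln, "## Gamma analysis", "",
            "| criteria | threshold | pass rate | points |",
            "|---|---|---|---|")
    for (nm in names(report$gamma)) {
      g <- report$gamma[[nm]]
      ln <- c(ln, sprintf("| %g%%/%g mm | %g%% | %.1f%% | %d |",
                          g$dose_pct, g$dta_mm, g$threshold_pct,
                          g$pass_rate, g$n_evaluated))
    }
    ln <- c(ln, "")
  }
  if (!is.null(report$table_25d)) {
    ln <- c(ln, "## 2.5D depth search", "",
            "| offset (mm) | depth (g/cm^2) | pass rate |", "|---|---|---|")
    for (i in seq_len(nrow(report$table_25d))) {
      r <- report$table_25d[i, ]
      ln <- c(ln, sprintf("| %+.1f | %.3f | %.1f%% |",
                          r$offset_mm, r$depth, r$pass_rate))
    }
    ln <- c(ln, "")
  }
  if (!is.null(report$point_dose)) {
    ln <- c(ln, "## Point-dose differences", "")
    for (nm in names(report$point_dose))
      ln <- c(ln, sprintf("- %s: %+.2f%%", nm, report$point_dose[[nm]]))
    ln <- c(ln, "")
  }
  if (!is.null(report$log_summary)) {
    s <- report$log_summary
    ln <- c(ln, "## Delivery-log summary", "",
            sprintf("- records: %d", s$n_records),
            sprintf("- mean deviation: (%+.2f, %+.2f) mm", s$mean_dx_mm, s$mean_dy_mm),
            sprintf("- SD: (%.2f, %.2f) mm", s$sd_dx_mm, s$sd_dy_mm),
            sprintf("- max |deviation|: %.2f mm", s$max_abs_mm))
    if (is.finite(s$reproducibility_sd_x_mm))
      ln <- c(ln, sprintf("- cross-fraction reproducibility SD: (%.2f, %.2f) mm",
                          s$reproducibility_sd_x_mm, s$reproducibility_sd_y_mm))
    ln <- c(ln, "")
  }
  if (!is.null(report$input_hashes)) {
    ln <- c(ln, "## Provenance", "")
    for (nm in names(report$input_hashes))
      ln <- c(ln, sprintf("- %s: md5 %s", nm, report$input_hashes[[nm]]))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a JSON PSQA report back into a report object
#'
#' @param path JSON file written by \code{\link{write_report}}.
#' @return a \code{\link{psqa_report}}.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "protonqa_psqa_report"))
    stop("read_report: not a PSQA report document")
  if (!is.null(doc$table_25d)) doc$table_25d <- as.data.frame(doc$table_25d)
  structure(doc, class = "psqa_report")
}
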