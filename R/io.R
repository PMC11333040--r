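## CSV dialects for elastic scans, DSC thermograms and result tables.
## Long (tidy) layout, comma separator, '.' decimal, one header line;
## units are encoded in the column names so nothing is guessed on read.

.SCAN_COLS <- c("sample_id", "component", "state", "hydration_h",
                "resolution_ueV", "resolution_ps", "temperature_K",
                "q_invA", "intensity", "intensity_err")

#' Write elastic scans to the long CSV dialect
#'
#' One row per (scan, temperature, q).  Scans are written in list order;
#' column order is fixed so repeated writes are byte-identical.
#'
#' @param scans A single [elastic_scan()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path) {
  if (inherits(scans, "elastic_scan")) scans <- list(scans)
  rows <- lapply(scans, function(s) {
    grid <- expand.grid(ti = seq_along(s$temperatures),
                        qi = seq_along(s$q_values))
    data.frame(
      sample_id = s$sample_id, component = s$component, state = s$state,
      hydration_h = s$hydration_h,
      resolution_ueV = if (is.null(s$resolution_energy)) NA_real_ else s$resolution_energy,
      resolution_ps = s$resolution_time,
      temperature_K = s$temperatures[grid$ti],
      q_invA = s$q_values[grid$qi],
      intensity = s$intensities[cbind(grid$ti, grid$qi)],
      intensity_err = if (is.null(s$intensity_errors)) NA_real_
                      else s$intensity_errors[cbind(grid$ti, grid$qi)],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)[, .SCAN_COLS]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read elastic scans from the long CSV dialect
#'
#' Rows are grouped by (sample_id, component, state, hydration_h,
#' resolution_ps); each group must form a complete temperature x q grid.
#'
#' @param path CSV file written by [write_scans()] (or equivalent).
#' @return A list of [elastic_scan()] objects.
#' @export
read_scans <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SCAN_COLS, names(df))
  if (length(missing_cols)) {
    stop("scan file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$component), c("protein", "water"))
  if (length(bad)) stop("unknown component: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  key <- interaction(df$sample_id, df$component, df$state, df$hydration_h,
                     df$resolution_ps, drop = TRUE, lex.order = TRUE)
  lapply(split(df, key), function(g) {
    temps <- sort(unique(g$temperature_K))
    qs <- sort(unique(g$q_invA))
    if (nrow(g) != length(temps) * length(qs)) {
      stop("non-rectangular scan for sample ", g$sample_id[1], call. = FALSE)
    }
    ti <- match(g$temperature_K, temps)
    qi <- match(g$q_invA, qs)
    if (anyDuplicated(cbind(ti, qi))) {
      stop("non-rectangular scan for sample ", g$sample_id[1], call. = FALSE)
    }
    m <- matrix(NA_real_, length(temps), length(qs))
    m[cbind(ti, qi)] <- g$intensity
    err <- NULL
    if (!all(is.na(g$intensity_err))) {
      err <- matrix(NA_real_, length(temps), length(qs))
      err[cbind(ti, qi)] <- g$intensity_err
    }
    res_e <- g$resolution_ueV[1]
    elastic_scan(
      sample_id = g$sample_id[1], component = g$component[1],
      state = g$state[1], hydration_h = g$hydration_h[1],
      resolution_time = g$resolution_ps[1],
      resolution_energy = if (is.na(res_e)) NULL else res_e,
      temperatures = temps, q_values = qs,
      intensities = m, intensity_errors = err
    )
  })
}

#' Write a DSC thermogram to CSV
#'
#' @param curve A [dsc_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dsc <- function(curve, path) {
  df <- data.frame(sample_id = curve$sample_id,
                   heating_rate_K_min = curve$heating_rate,
                   temperature_K = curve$temperatures,
                   heat_flow_mW = curve$heat_flow)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DSC thermogram from CSV
#'
#' @param path CSV with columns `temperature_K`, `heat_flow_mW` and
#'   optionally `sample_id`, `heating_rate_K_min`.
#' @return A [dsc_curve()].
#' @export
read_dsc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temperature_K", "heat_flow_mW") %in% names(df))) {
    stop("DSC file needs columns temperature_K, heat_flow_mW", call. = FALSE)
  }
  if (any(diff(df$temperature_K) <= 0)) {
    stop("DSC temperatures must be strictly increasing", call. = FALSE)
  }
  dsc_curve(df$temperature_K, df$heat_flow_mW,
            heating_rate = if ("heating_rate_K_min" %in% names(df)) df$heating_rate_K_min[1] else 1,
            sample_id = if ("sample_id" %in% names(df)) df$sample_id[1] else NA_character_)
}

#' Write result tables to CSV
#'
#' Onset tables are laid out with one row per sample/hydration and one
#' column per resolution time, mirroring how fixed-window studies tabulate
#' onset temperatures.
#'
#' @param table A data frame (e.g. from [onset_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
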