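# CSV formats and provenance sidecars.
#
# Spectra table: column 1 "wavelength_nm", remaining columns "t_<minutes>"
# holding absorbance in AU; wavelengths strictly increasing, 1-nm step
# expected (a warning is issued otherwise). The assay data are small
# (<= 461 wavelengths x <= 181 timepoints), so plain CSV suffices.

#' Write a spectral time series to CSV
#'
#' @param ts A [time_series_spectra()].
#' @param path Output CSV path.
#' @param sidecar Write a machine-readable provenance sidecar
#'   (`<path>.provenance.json`) when the object carries provenance.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ts, path, sidecar = TRUE) {
  stopifnot(inherits(ts, "time_series_spectra"))
  df <- data.frame(wavelength_nm = ts$wavelengths, t(ts$absorbance),
                   check.names = FALSE)
  names(df)[-1] <- sprintf("t_%g", ts$times)
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar && !is.null(ts$provenance)) {
    prov <- ts$provenance
    if (!is.null(prov$config) && inherits(prov$config, "assay_config")) {
      prov$config <- serialize_config(prov$config)
    }
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a spectral time series from CSV
#'
#' Validates the header, numeric content and wavelength monotonicity;
#' malformed cells and offending rows are reported by position. A
#' provenance sidecar written by [write_spectra()] is re-attached when
#' present.
#'
#' @param path CSV path.
#' @return A [time_series_spectra()].
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("no such file: %s", path))
  if (file.size(path) == 0) abort_invalid(sprintf("empty file: %s", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) abort_invalid(sprintf("cannot parse %s: %s", path,
                                              conditionMessage(e)))
  )
  if (!ncol(df) || names(df)[1] != "wavelength_nm") {
    abort_invalid("missing header: first column must be 'wavelength_nm'")
  }
  tcols <- grep("^t_", names(df)[-1], value = TRUE)
  if (length(tcols) != ncol(df) - 1L) {
    abort_invalid("spectra columns must be labeled 't_<minutes>'")
  }
  num <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df)))
  )
  bad <- which(is.na(num) & !is.na(df), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_invalid(sprintf(
      "malformed numeric cell at row %d, column '%s'",
      bad[1, 1], names(df)[bad[1, 2]]
    ))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    abort_invalid(sprintf("missing value at row %d, column '%s'",
                          bad[1, 1], names(df)[bad[1, 2]]))
  }
  wl <- num[, 1]
  dv <- diff(wl)
  if (any(dv <= 0)) {
    abort_invalid(sprintf(
      "wavelengths not strictly increasing at row %d", which(dv <= 0)[1] + 1L
    ))
  }
  if (any(abs(dv - 1) > 1e-9)) {
    warning("wavelength grid is not a uniform 1-nm step")
  }
  times <- as.numeric(sub("^t_", "", tcols))
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path)
  time_series_spectra(times, wl, t(num[, -1, drop = FALSE]),
                      provenance = prov)
}

#' Write / read an ITC thermogram CSV
#'
#' Columns: `injection_index`, `injection_volume_ul`, `molar_ratio`,
#' `heat_ucal`, plus constant metadata columns `cell_conc_um`,
#' `syringe_conc_um`, `temperature_k`, `cell_volume_ml`.
#'
#' @param tg A [thermogram()].
#' @param path CSV path.
#' @return `path` ([write_thermogram()]) / a [thermogram()]
#'   ([read_thermogram()]).
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  df <- data.frame(
    injection_index = tg$injection_index,
    injection_volume_ul = tg$injection_volume,
    molar_ratio = tg$molar_ratio,
    heat_ucal = tg$heat,
    cell_conc_um = attr(tg, "cell_conc"),
    syringe_conc_um = attr(tg, "syringe_conc"),
    temperature_k = attr(tg, "temperature"),
    cell_volume_ml = attr(tg, "cell_volume")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  df <- read_table_checked(path, c(
    "injection_index", "injection_volume_ul", "molar_ratio", "heat_ucal",
    "cell_conc_um", "syringe_conc_um", "temperature_k", "cell_volume_ml"
  ))
  if (any(df$cell_conc_um <= 0) || any(df$syringe_conc_um <= 0)) {
    abort_invalid("concentrations must be positive")
  }
  thermogram(df$injection_index, df$injection_volume_ul, df$molar_ratio,
             df$heat_ucal, df$cell_conc_um[1], df$syringe_conc_um[1],
             df$temperature_k[1], df$cell_volume_ml[1])
}

#' Write / read a titration-curve CSV
#'
#' Columns: `ligand_conc_m` (molar), `response`, `replicate_id`.
#'
#' @param curve A [titration_curve()].
#' @param path CSV path.
#' @return `path` ([write_titration()]) / a [titration_curve()]
#'   ([read_titration()]).
#' @export
write_titration <- function(curve, path) {
  df <- data.frame(ligand_conc_m = curve$ligand_conc,
                   response = curve$response,
                   replicate_id = curve$replicate_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  df <- read_table_checked(path, c("ligand_conc_m", "response"))
  if (any(df$ligand_conc_m <= 0)) {
    abort_invalid("negative or zero ligand concentration in file")
  }
  titration_curve(df$ligand_conc_m, df$response,
                  if ("replicate_id" %in% names(df)) df$replicate_id else 1L)
}

# Shared CSV reader: checks existence, required columns (named in the
# error), and numeric content.
#' @noRd
read_table_checked <- function(path, required) {
  if (!file.exists(path)) abort_invalid(sprintf("no such file: %s", path))
  if (file.size(path) == 0) abort_invalid(sprintf("empty file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_invalid(sprintf("missing required column(s): %s",
                          paste(missing, collapse = ", ")))
  }
  for (col in required) {
    if (!is.numeric(df[[col]])) {
      abort_invalid(sprintf("column '%s' is not numeric", col))
    }
  }
  df
}

# Validate a config list against required/optional key sets; unknown
# keys are rejected outright to surface typos before computation.
#' @noRd
validate_config <- function(cfg, required, optional = character()) {
  if (!is.list(cfg)) abort_invalid("config must be a JSON object")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort_invalid(sprintf("config missing required field(s): %s",
                          paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(cfg), c(required, optional))
  if (length(unknown)) {
    abort_invalid(sprintf("config has unknown field(s): %s",
                          paste(unknown, collapse = ", ")))
  }
  cfg
}
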