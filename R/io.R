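# CSV schemas. All concentrations in mM (duplex counted as duplexes, not
# strands), shifts in ppm, diffusion coefficients in m^2/s, times in days.

schema_columns <- list(
  dilution = c("proton", "conc_mM", "shift_ppm"),
  titration = c("proton", "C_L_mM", "C_DNA_mM", "shift_ppm"),
  dosy = c("sample_id", "C_L_mM", "C_DNA_mM", "D_obs_L", "D_obs_DNA",
           "D_L_free", "D_DNA_free"),
  decay = c("time_days", "intact_fraction")
)

read_schema_csv <- function(path, schema_id) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  cols <- schema_columns[[schema_id]]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  id_cols <- intersect(c("proton", "sample_id"), cols)
  check_columns(df, cols, numeric_cols = setdiff(cols, id_cols),
                what = sprintf("%s file %s", schema_id, path))
  tibble::as_tibble(df[cols])
}

#' Read a dilution chemical-shift series from CSV
#'
#' Expects columns `proton`, `conc_mM`, `shift_ppm` (header mandatory,
#' decimal point, concentrations in mM).  Rows are sorted by proton and
#' concentration; duplicate (proton, concentration) keys and non-positive
#' concentrations are rejected.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble accepted by [fit_isodesmic()].
#' @export
read_dilution_csv <- function(path) {
  df <- read_schema_csv(path, "dilution")
  if (any(df$conc_mM <= 0)) {
    stop_schema("%s: non-positive conc_mM at row %d", path, which(df$conc_mM <= 0)[1])
  }
  df <- dplyr::arrange(df, .data$proton, .data$conc_mM)
  if (anyDuplicated(df[c("proton", "conc_mM")])) {
    stop_schema("%s: duplicate (proton, conc_mM) rows", path)
  }
  df
}

#' Read a titration series from CSV
#'
#' Expects columns `proton`, `C_L_mM`, `C_DNA_mM`, `shift_ppm`; the
#' `C_DNA_mM = 0` rows define the free-ligand baseline shift.
#'
#' @inheritParams read_dilution_csv
#' @return A validated tibble accepted by [fit_binding_titration()].
#' @export
read_titration_csv <- function(path) {
  df <- read_schema_csv(path, "titration")
  if (any(df$C_DNA_mM < 0) || any(df$C_L_mM <= 0)) {
    stop_schema("%s: needs C_L_mM > 0 and C_DNA_mM >= 0", path)
  }
  df <- dplyr::arrange(df, .data$proton, .data$C_DNA_mM)
  if (anyDuplicated(df[c("proton", "C_DNA_mM")])) {
    stop_schema("%s: duplicate (proton, C_DNA_mM) rows", path)
  }
  df
}

#' Read diffusion (DOSY) records from CSV
#'
#' Expects columns `sample_id`, `C_L_mM`, `C_DNA_mM`, `D_obs_L`, `D_obs_DNA`,
#' `D_L_free`, `D_DNA_free` (D in m^2/s).
#'
#' @inheritParams read_dilution_csv
#' @return A validated tibble accepted by [ka_from_diffusion()].
#' @export
read_dosy_csv <- function(path) {
  df <- read_schema_csv(path, "dosy")
  dcols <- c("D_obs_L", "D_obs_DNA", "D_L_free", "D_DNA_free")
  for (col in dcols) {
    if (any(df[[col]] <= 0)) stop_schema("%s: non-positive %s", path, col)
  }
  if (anyDuplicated(df$sample_id)) stop_schema("%s: duplicate sample_id", path)
  df
}

#' Read a degradation time course from CSV
#'
#' Expects columns `time_days`, `intact_fraction`; rows are sorted by time
#' and duplicate times rejected.
#'
#' @inheritParams read_dilution_csv
#' @return A validated tibble accepted by [fit_decay()].
#' @export
read_decay_csv <- function(path) {
  df <- read_schema_csv(path, "decay")
  if (any(df$time_days < 0)) stop_schema("%s: negative time_days", path)
  df <- dplyr::arrange(df, .data$time_days)
  if (anyDuplicated(df$time_days)) stop_schema("%s: duplicate time_days rows", path)
  df
}

#' Write an experiment table to CSV
#'
#' Plain RFC-4180 CSV with header; the exact inverse of the corresponding
#' reader, so write-then-read reproduces the tibble.
#'
#' @param data The experiment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a fit report to CSV
#'
#' Writes the [tidy()] per-proton (or per-sample) table of a fit object.
#'
#' @param fit An `isodesmic_fit`, `binding_fit` or `decay_fit` object, or a
#'   tibble such as the output of [ka_from_diffusion()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(fit, path) {
  tab <- if (is.data.frame(fit)) fit else tidy(fit)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}
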