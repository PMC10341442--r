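#' Absorbance spectrum of an RBC suspension or supernatant
#'
#' The unit of measurement: absorbance (AU) on a strictly increasing wavelength
#' grid (nm), with sample metadata describing the storage condition.
#'
#' @param wavelengths_nm strictly increasing numeric wavelengths (nm).
#' @param absorbance finite numeric absorbance values (AU), one per wavelength.
#' @param sample_id sample identifier (text).
#' @param day storage day (integer, days).
#' @param sts_pct storage-solution strength, percent of full-strength additive
#'   solution in the suspension medium (0–100).
#' @param tube `"closed"` (hypoxemia/anoxemia) or `"open"` (normoxemia).
#' @param kind `"suspension"` or `"supernatant"`.
#' @return An object of class `rbc_spectrum`.
#' @export
new_spectrum <- function(wavelengths_nm, absorbance, sample_id = NA_character_,
                         day = NA_integer_, sts_pct = NA_real_,
                         tube = NA_character_, kind = NA_character_) {
  wl <- as.numeric(wavelengths_nm)
  ab <- as.numeric(absorbance)
  if (length(wl) < 2L || any(diff(wl) <= 0))
    abort_rbc("spectrum wavelengths must be strictly increasing (>= 2 points)",
              "malformed_input")
  if (length(ab) != length(wl) || anyNA(ab) || any(!is.finite(ab)))
    abort_rbc("absorbance must be finite, one value per wavelength", "malformed_input")
  if (!is.na(tube) && !tube %in% c("closed", "open"))
    abort_rbc("tube must be 'closed' or 'open'", "validation")
  if (!is.na(kind) && !kind %in% c("suspension", "supernatant"))
    abort_rbc("kind must be 'suspension' or 'supernatant'", "validation")
  if (!is.na(sts_pct) && (sts_pct < 0 || sts_pct > 100))
    abort_rbc("sts_pct must be in [0, 100]", "validation")
  structure(list(wavelengths_nm = wl, absorbance = ab,
                 meta = list(sample_id = as.character(sample_id),
                             day = as.integer(day),
                             sts_pct = as.numeric(sts_pct),
                             tube = as.character(tube),
                             kind = as.character(kind))),
            class = "rbc_spectrum")
}

#' @export
print.rbc_spectrum <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<rbc_spectrum> %d points, %.0f-%.0f nm | id=%s day=%s StS=%s%% tube=%s kind=%s\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm),
              m$sample_id, m$day, m$sts_pct, m$tube, m$kind))
  invisible(x)
}

#' Crop a spectrum to a wavelength window
#'
#' Spectra are cropped (points outside the window dropped), never resampled.
#'
#' @param spectrum an [new_spectrum()] object.
#' @param window length-2 numeric, nm; default the measured 500–700 nm range.
#' @return An `rbc_spectrum` restricted to the window.
#' @export
crop_spectrum <- function(spectrum, window = c(500, 700)) {
  stopifnot(inherits(spectrum, "rbc_spectrum"))
  keep <- spectrum$wavelengths_nm >= window[1] & spectrum$wavelengths_nm <= window[2]
  if (sum(keep) < 2L)
    abort_rbc("fewer than 2 points remain after cropping", "validation")
  out <- spectrum
  out$wavelengths_nm <- spectrum$wavelengths_nm[keep]
  out$absorbance <- spectrum$absorbance[keep]
  out
}

#' Read a spectrum from delimited text
#'
#' Expects columns `wavelength_nm,absorbance`; metadata either as extra columns
#' (`sample_id,day,sts_pct,tube,kind`, constant within the file) or in a sidecar
#' JSON file `<path>.json` holding the same keys. Extra columns win over the
#' sidecar.
#'
#' @param path path to the spectrum file.
#' @return An `rbc_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    abort_rbc(sprintf("spectrum file not found: %s", path), "malformed_input")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.csv(path, sep = sep, check.names = TRUE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(tab)))
    abort_rbc("spectrum file must have columns wavelength_nm, absorbance",
              "malformed_input")
  meta <- list(sample_id = NA_character_, day = NA_integer_, sts_pct = NA_real_,
               tube = NA_character_, kind = NA_character_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (k in names(meta)) if (!is.null(sc[[k]])) meta[[k]] <- sc[[k]]
  }
  for (k in names(meta)) if (k %in% names(tab)) meta[[k]] <- tab[[k]][1]
  new_spectrum(tab$wavelength_nm, tab$absorbance,
               sample_id = meta$sample_id, day = meta$day, sts_pct = meta$sts_pct,
               tube = meta$tube, kind = meta$kind)
}

#' Write a spectrum to delimited text with metadata columns
#'
#' @param spectrum an `rbc_spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "rbc_spectrum"))
  m <- spectrum$meta
  tab <- data.frame(wavelength_nm = sprintf("%.17g", spectrum$wavelengths_nm),
                    absorbance = sprintf("%.17g", spectrum$absorbance),
                    sample_id = m$sample_id, day = m$day, sts_pct = m$sts_pct,
                    tube = m$tube, kind = m$kind)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
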