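# On-disk artifacts: TCSPC stacks as multi-page TIFF with a JSON sidecar,
# parametric maps as 32-bit float TIFF, condition summaries as CSV.
# Canonical internal units are SI seconds; nanoseconds appear only in reports.

MELFLIM_VERSION <- "0.1.0"

sidecar_path <- function(path) paste0(path, ".json")

acq_to_list <- function(acq) {
  list(rep_rate = acq$rep_rate, n_channels = acq$n_channels,
       channel_width = acq$channel_width,
       image_shape = acq$image_shape, harmonic = acq$harmonic)
}

acq_from_list <- function(x) {
  acquisition_params(x$rep_rate, x$n_channels, x$channel_width,
                     unlist(x$image_shape), x$harmonic)
}

#' Write / read a TCSPC image stack
#'
#' The stack is stored as a multi-page 16-bit unsigned TIFF (one page per time
#' channel, page order = increasing channel) together with a JSON sidecar
#' `<path>.json` holding the acquisition parameters, provenance (seed, preset,
#' photon bookkeeping) and software version. The round trip is exact.
#'
#' @param image A [tcspc_image()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_tcspc_stack()`: `path`, invisibly. `read_tcspc_stack()`: a
#'   [tcspc_image()].
#' @export
write_tcspc_stack <- function(image, path) {
  stopifnot(inherits(image, "tcspc_image"))
  write_tiff(path, image$counts, type = "uint16")
  meta <- list(kind = "tcspc_stack",
               acq = acq_to_list(image$acq),
               provenance = image$provenance,
               software_version = MELFLIM_VERSION)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tcspc_stack
#' @export
read_tcspc_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar '", sc, "' for TCSPC stack '", path, "'")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$kind, "tcspc_stack"))
    stop("sidecar '", sc, "' does not describe a TCSPC stack")
  arr <- read_tiff(path)
  if (attr(arr, "sample_type") != "uint16")
    stop("TCSPC stack must hold integer (uint16) pixel data")
  acq <- acq_from_list(meta$acq)
  if (dim(arr)[3] != acq$n_channels)
    stop("sidecar declares ", acq$n_channels, " channels but the TIFF has ",
         dim(arr)[3], " pages")
  if (!all(dim(arr)[1:2] == acq$image_shape))
    stop("sidecar image shape (", paste(acq$image_shape, collapse = "x"),
         ") does not match TIFF pages (", paste(dim(arr)[1:2], collapse = "x"),
         ")")
  attr(arr, "sample_type") <- NULL
  prov <- meta$provenance
  if (is.null(prov)) prov <- list()
  tcspc_image(arr, acq, provenance = as.list(prov))
}

#' Parametric map container
#'
#' One per-pixel real-valued parameter image (lifetime, phasor coordinate,
#' reduced chi-squared, ...). Pixels failing quality control carry `NA`.
#'
#' @param name Parameter identifier, one of the recognized set (`"tau1"`,
#'   `"tau2"`, `"a1_pct"`, `"a2_pct"`, `"tau_av_amp"`, `"tau_av_int"`, `"g"`,
#'   `"s"`, `"tau_phi"`, `"tau_m"`, `"fuva"`, `"chi2red"`, `"intensity"`).
#' @param values Numeric matrix of per-pixel values (NA = QC-failed/missing).
#' @param units `"s"` or `"dimensionless"`.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(name, values,
                           units = c("s", "dimensionless")) {
  known <- c("tau1", "tau2", "a1_pct", "a2_pct", "tau_av_amp", "tau_av_int",
             "g", "s", "tau_phi", "tau_m", "fuva", "chi2red", "intensity")
  if (!name %in% known)
    stop("unknown parameter name '", name, "'")
  units <- match.arg(units)
  stopifnot(is.matrix(values), is.numeric(values))
  structure(list(name = name, values = values, units = units),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("parametric map '%s' [%s]: %d x %d, %d valid px\n", x$name,
              x$units, nrow(x$values), ncol(x$values),
              sum(is.finite(x$values))))
  invisible(x)
}

#' Write / read a parametric map
#'
#' Stored as a single-page 32-bit float TIFF plus a JSON sidecar declaring the
#' parameter name and units; `NA` pixels are stored as NaN and restored as
#' `NA`. Values stay in SI units on disk; any nanosecond scaling happens at
#' presentation only.
#'
#' @param map A [parametric_map()].
#' @param path TIFF file path.
#' @param expect_units Optional declared units to validate on read-back.
#' @return `write_parametric_map()`: `path`, invisibly;
#'   `read_parametric_map()`: a [parametric_map()].
#' @export
write_parametric_map <- function(map, path) {
  stopifnot(inherits(map, "parametric_map"))
  vals <- map$values
  vals[!is.finite(vals)] <- NaN
  write_tiff(path, vals, type = "float32")
  jsonlite::write_json(
    list(kind = "parametric_map", name = map$name, units = map$units,
         shape = dim(map$values), n_valid = sum(is.finite(map$values)),
         software_version = MELFLIM_VERSION),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parametric_map
#' @export
read_parametric_map <- function(path, expect_units = NULL) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar '", sc, "'")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$kind, "parametric_map"))
    stop("sidecar '", sc, "' does not describe a parametric map")
  if (!is.null(expect_units) && !identical(meta$units, expect_units))
    stop("map '", meta$name, "' declares units '", meta$units,
         "' but '", expect_units, "' was expected")
  arr <- read_tiff(path)
  if (attr(arr, "sample_type") != "float32")
    stop("parametric map must hold float32 pixel data")
  vals <- arr[, , 1]
  vals[is.nan(vals)] <- NA_real_
  if (sum(is.finite(vals)) == 0L)
    message("parametric map '", meta$name, "' is empty (all pixels missing)")
  parametric_map(meta$name, vals, meta$units)
}

#' Write a condition summary table as CSV
#'
#' One row per (condition, ROI, parameter) with the ROI mean, SD and pixel
#' count. Column order is fixed and the file is byte-reproducible for
#' identical inputs.
#'
#' @param summary A data.frame as produced by the quantify stage, with columns
#'   `condition`, `roi`, `parameter`, `mean`, `sd`, `n`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  cols <- c("condition", "roi", "parameter", "mean", "sd", "n")
  missing_cols <- setdiff(cols, names(summary))
  if (length(missing_cols))
    stop("summary is missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- summary[, cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
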