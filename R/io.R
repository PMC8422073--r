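# Plain-text and TIFF round-tripping for the pipeline's data formats.
# Every writer embeds package version, seed and config hash as '#' comment
# header lines (CSV) or a metadata block (JSON/TIFF sidecar).

meta_lines <- function(metadata = list()) {
  c(paste0("# msotlipid ", as.character(utils::packageVersion("msotlipid"))),
    vapply(names(metadata), function(k) paste0("# ", k, "=", metadata[[k]]),
           character(1)))
}

write_csv_with_meta <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(metadata), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read and write ROI spectra as CSV
#'
#' Format: columns `wavelength_nm,intensity`, one row per wavelength;
#' `#` comment headers carry provenance metadata.
#'
#' @param spectrum a [tissue_spectrum()].
#' @param path file path.
#' @param metadata named list written into the comment header.
#' @param label label for the spectrum read back.
#' @return The path (write) or a [tissue_spectrum()] (read).
#' @export
write_spectrum_csv <- function(spectrum, path, metadata = list()) {
  stopifnot(inherits(spectrum, "tissue_spectrum"))
  df <- data.frame(wavelength_nm = spectrum$wavelengths_nm,
                   intensity = format_full(spectrum$intensity))
  write_csv_with_meta(df, path, metadata)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path, label = "") {
  df <- read_csv_checked(path, c("wavelength_nm", "intensity"), "spectrum")
  tissue_spectrum(df$wavelength_nm, df$intensity, label)
}

# Full-precision decimal rendering so CSV round-trips are lossless.
format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write graded cohort tables
#'
#' Format: `subject_id,grade,<score columns>`; grades must be integers in
#' 0-3 and scores finite.
#'
#' @param cohort cohort `data.frame` (as from [make_graded_cohort()]).
#' @param path file path.
#' @param metadata named list for the comment header.
#' @return The path (write) or the validated `data.frame` (read).
#' @export
write_cohort_csv <- function(cohort, path, metadata = list()) {
  stopifnot(is.data.frame(cohort), all(c("subject_id", "grade") %in% names(cohort)))
  out <- cohort
  for (nm in setdiff(names(out), c("subject_id", "grade"))) {
    out[[nm]] <- format_full(out[[nm]])
  }
  write_csv_with_meta(out, path, metadata)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read_csv_checked(path, c("subject_id", "grade"), "cohort")
  if (any(!df$grade %in% 0:3)) {
    bad <- unique(df$grade[!df$grade %in% 0:3])
    stop("cohort file ", path, " has grade(s) outside {0, 1, 2, 3}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  score_cols <- setdiff(names(df), c("subject_id", "grade"))
  if (!length(score_cols)) {
    stop("cohort file ", path, " has no score column", call. = FALSE)
  }
  for (nm in score_cols) {
    if (any(!is.finite(df[[nm]]))) {
      stop("cohort file ", path, ": non-finite values in score '", nm, "'",
           call. = FALSE)
    }
  }
  df
}

#' Read and write ICG clearance curves
#'
#' Format: `t_min,intensity` (raw a.u.), optionally a `normalized` column.
#'
#' @param curve a [clearance_curve()].
#' @param path file path.
#' @param metadata named list for the comment header.
#' @param baseline baseline override on read; default: mean of `t_min <= 0`
#'   samples.
#' @return The path (write) or a [clearance_curve()] (read).
#' @export
write_clearance_csv <- function(curve, path, metadata = list()) {
  stopifnot(inherits(curve, "clearance_curve"))
  df <- as.data.frame(curve)
  for (nm in setdiff(names(df), "t_min")) df[[nm]] <- format_full(df[[nm]])
  write_csv_with_meta(df, path, c(metadata, baseline = curve$baseline))
}

#' @rdname write_clearance_csv
#' @export
read_clearance_csv <- function(path, baseline = NULL) {
  df <- read_csv_checked(path, c("t_min", "intensity"), "clearance")
  clearance_curve(df$t_min, df$intensity, baseline = baseline)
}

#' Read and write multispectral stacks as TIFF + JSON sidecar
#'
#' The stack is stored as a multi-page 32-bit-float TIFF (one page per
#' wavelength) next to a JSON sidecar (`<path>.json`) carrying the
#' wavelength grid, an intensity scale factor (pages are stored divided by
#' it, keeping sample values in [0, 1]), ROI masks and provenance metadata.
#' Round-trips are exact to single (32-bit float) precision; use
#' [write_stack_csv()] for full-precision round-trips.
#'
#' @param image a [multispectral_image()].
#' @param path `.tif` file path; the sidecar is written at `<path>.json`.
#' @param metadata named list stored in the sidecar.
#' @return The path (write) or a [multispectral_image()] (read).
#' @export
write_stack_tiff <- function(image, path, metadata = list()) {
  stopifnot(inherits(image, "msot_image"))
  lo <- min(image$stack)
  if (lo < 0) stop("TIFF stack storage requires non-negative intensities", call. = FALSE)
  scale <- max(image$stack, 1e-300)
  pages <- lapply(seq_len(dim(image$stack)[1]),
                  function(i) image$stack[i, , , drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    wavelengths_nm = image$wavelengths_nm,
    scale = scale,
    rois = lapply(image$rois, function(m) unname(apply(m, 1, as.integer,
                                                       simplify = FALSE))),
    metadata = c(list(package = "msotlipid",
                      version = as.character(utils::packageVersion("msotlipid"))),
                 metadata))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar_path)) {
    stop("stack sidecar not found: ", sidecar_path, call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot read TIFF stack ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  wl <- as.numeric(sc$wavelengths_nm)
  if (length(pages) != length(wl)) {
    stop("stack ", path, ": ", length(pages), " pages but ",
         length(wl), " wavelengths in sidecar", call. = FALSE)
  }
  as_page <- function(p) if (length(dim(p)) == 3L) p[, , 1L] else p
  shape <- dim(as_page(pages[[1]]))[1:2]
  stack <- array(0, c(length(pages), shape))
  for (i in seq_along(pages)) stack[i, , ] <- as_page(pages[[i]]) * sc$scale
  rois <- list()
  if (length(sc$rois)) {
    rois <- lapply(sc$rois, function(rows) {
      # jsonlite may simplify the per-row lists into a matrix already
      if (is.matrix(rows)) rows == 1L
      else do.call(rbind, lapply(rows, as.integer)) == 1L
    })
  }
  multispectral_image(stack, wl, rois)
}

#' Read and write multispectral stacks as lossless long-format CSV
#'
#' Columns `wavelength_nm,row,col,intensity` with full-precision decimal
#' rendering; masks are not stored (use the TIFF sidecar format for ROIs).
#'
#' @param image a [multispectral_image()].
#' @param path file path.
#' @param metadata named list for the comment header.
#' @return The path (write) or a [multispectral_image()] (read).
#' @export
write_stack_csv <- function(image, path, metadata = list()) {
  stopifnot(inherits(image, "msot_image"))
  d <- dim(image$stack)
  idx <- expand.grid(wl = seq_len(d[1]), row = seq_len(d[2]), col = seq_len(d[3]))
  df <- data.frame(wavelength_nm = image$wavelengths_nm[idx$wl],
                   row = idx$row, col = idx$col,
                   intensity = format_full(image$stack[cbind(idx$wl, idx$row, idx$col)]))
  write_csv_with_meta(df, path, metadata)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  df <- read_csv_checked(path, c("wavelength_nm", "row", "col", "intensity"),
                         "stack")
  wl <- sort(unique(df$wavelength_nm))
  nr <- max(df$row); nc <- max(df$col)
  stack <- array(NA_real_, c(length(wl), nr, nc))
  stack[cbind(match(df$wavelength_nm, wl), df$row, df$col)] <- df$intensity
  if (anyNA(stack)) stop("stack file ", path, " is incomplete", call. = FALSE)
  multispectral_image(stack, wl)
}

#' Write a results list as JSON with provenance metadata
#'
#' @param results named list of results.
#' @param path output path.
#' @param metadata named list (seed, config hash, ...) stored under
#'   `$metadata` together with the package version.
#' @return The path, invisibly.
#' @export
write_results_json <- function(results, path, metadata = list()) {
  out <- c(list(metadata = c(
    list(package = "msotlipid",
         version = as.character(utils::packageVersion("msotlipid"))),
    metadata)), results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
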