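#' Measurement wavelength grid
#'
#' Construct the wavelength grid of a multispectral optoacoustic acquisition.
#' The default is the standard NIR protocol: 700 to 960 nm in 10 nm steps,
#' i.e. 27 wavelengths, covering haemoglobin contrast (700-900 nm), the
#' oxy-deoxy isosbestic point (800 nm) and the lipid absorption peak (930 nm).
#'
#' @param from,to,by grid limits and step in nanometres.
#' @return A strictly increasing numeric vector of wavelengths (nm).
#' @examples
#' length(wavelength_grid())  # 27
#' @export
wavelength_grid <- function(from = 700, to = 960, by = 10) {
  wl <- seq(from, to, by = by)
  assert_wavelengths(wl)
  wl
}

assert_wavelengths <- function(wl) {
  if (!is.numeric(wl) || length(wl) < 1L || anyNA(wl)) {
    stop("wavelengths must be a numeric vector without NA", call. = FALSE)
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(wl < 600) || any(wl > 1100)) {
    stop("wavelengths must lie within [600, 1100] nm", call. = FALSE)
  }
  invisible(wl)
}

#' Per-ROI tissue spectrum
#'
#' A mean optoacoustic intensity per wavelength for one region of interest
#' (liver, kidney, adipose tissue, vessel, phantom section, ...). Intensities
#' are in arbitrary units (a.u.); the scale is shared across wavelengths of
#' one acquisition but not across acquisitions.
#'
#' @param wavelengths_nm wavelength grid (nm), strictly increasing.
#' @param intensity finite numeric vector, same length as the grid.
#' @param label tissue name used in printing and output tables.
#' @return An object of class `tissue_spectrum`.
#' @export
tissue_spectrum <- function(wavelengths_nm, intensity, label = "") {
  assert_wavelengths(wavelengths_nm)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavelengths_nm)) {
    stop("intensity length (", length(intensity), ") does not match grid length (",
         length(wavelengths_nm), ")", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("intensity must be finite", call. = FALSE)
  }
  structure(
    list(wavelengths_nm = wavelengths_nm, intensity = intensity,
         label = as.character(label)),
    class = "tissue_spectrum"
  )
}

#' @export
print.tissue_spectrum <- function(x, ...) {
  cat("Tissue spectrum", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n  ", length(x$wavelengths_nm), " wavelengths: ",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm\n",
      "  intensity range: [", format(min(x$intensity), digits = 4), ", ",
      format(max(x$intensity), digits = 4), "] a.u.\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tissue_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths_nm, intensity = x$intensity,
             label = rep(x$label, length(x$intensity)))
}

#' Multispectral optoacoustic image stack
#'
#' A stack of co-registered 2-D optoacoustic images, one per wavelength,
#' with optional named boolean ROI masks. Arrays use (row, column) = (y, x)
#' indexing; the first array dimension indexes wavelength.
#'
#' @param stack numeric array of shape (n_wavelengths, height, width).
#' @param wavelengths_nm wavelength grid matching `dim(stack)[1]`.
#' @param rois named list of logical height x width matrices.
#' @return An object of class `msot_image`.
#' @export
multispectral_image <- function(stack, wavelengths_nm, rois = list()) {
  assert_wavelengths(wavelengths_nm)
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("stack must be a 3-D array (wavelength, height, width)", call. = FALSE)
  }
  if (dim(stack)[1] != length(wavelengths_nm)) {
    stop("stack first dimension (", dim(stack)[1],
         ") must equal grid length (", length(wavelengths_nm), ")", call. = FALSE)
  }
  if (any(!is.finite(stack))) stop("stack intensities must be finite", call. = FALSE)
  if (length(rois)) {
    if (is.null(names(rois)) || any(!nzchar(names(rois)))) {
      stop("ROI masks must be named", call. = FALSE)
    }
    for (nm in names(rois)) assert_mask(rois[[nm]], dim(stack)[2:3], nm)
  }
  structure(
    list(stack = stack, wavelengths_nm = wavelengths_nm, rois = rois),
    class = "msot_image"
  )
}

assert_mask <- function(mask, spatial_dim, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("ROI '", name, "' must be a logical matrix", call. = FALSE)
  }
  if (!identical(dim(mask), as.integer(spatial_dim))) {
    stop("ROI '", name, "' shape (", paste(dim(mask), collapse = "x"),
         ") does not match image slices (", paste(spatial_dim, collapse = "x"),
         ")", call. = FALSE)
  }
  invisible(mask)
}

#' @export
print.msot_image <- function(x, ...) {
  d <- dim(x$stack)
  cat("MSOT image stack: ", d[1], " wavelengths x ", d[2], " x ", d[3],
      " pixels\n", sep = "")
  if (length(x$rois)) cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}

#' Reference absorption spectral library
#'
#' Load a chromophore reference library: relative absorption spectra of
#' deoxy-haemoglobin (Hb), oxy-haemoglobin (HbO2), lipid, water (H2O) and
#' indocyanine green (ICG) on the measurement wavelength grid. The packaged
#' default is a literature-shaped compilation on the 700-960 nm / 10 nm grid
#' (haemoglobins on a whole-blood absorption scale, lipid peaking at 930 nm,
#' water rising beyond 900 nm, plasma ICG peaking at 800 nm). Only the
#' relative shapes matter for unmixing in arbitrary units.
#'
#' Load-time validation enforces: non-negative entries, no all-zero column,
#' and agreement of the Hb and HbO2 columns at the 800 nm isosbestic point
#' within `isosbestic_tol` relative difference, on which the 800 nm
#' normalisations of the pipeline rely.
#'
#' @param path CSV file with header `wavelength_nm,Hb,HbO2,Lipid,H2O,ICG`
#'   (`#` comment lines allowed); default: the packaged library.
#' @param isosbestic_tol maximum relative Hb/HbO2 mismatch at 800 nm.
#' @return An object of class `spectral_library` with fields
#'   `wavelengths_nm`, `components` and `spectra` (wavelength x component
#'   matrix).
#' @examples
#' lib <- spectral_library()
#' lib$components
#' @export
spectral_library <- function(path = NULL, isosbestic_tol = 0.05) {
  if (is.null(path)) {
    path <- system.file("extdata", "spectral_library.csv", package = "msotlipid")
  }
  if (!file.exists(path)) stop("spectral library file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"wavelength_nm" %in% names(tab)) {
    stop("spectral library must have a 'wavelength_nm' column", call. = FALSE)
  }
  wl <- tab$wavelength_nm
  assert_wavelengths(wl)
  comp <- setdiff(names(tab), "wavelength_nm")
  if (length(comp) < 1L) stop("spectral library has no component columns", call. = FALSE)
  spectra <- as.matrix(tab[, comp, drop = FALSE])
  storage.mode(spectra) <- "double"
  rownames(spectra) <- wl
  if (any(!is.finite(spectra)) || any(spectra < 0)) {
    stop("spectral library entries must be finite and >= 0", call. = FALSE)
  }
  zero <- comp[colSums(spectra) == 0]
  if (length(zero)) {
    stop("all-zero component column(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  if (all(c("Hb", "HbO2") %in% comp) && 800 %in% wl) {
    i <- match(800, wl)
    a <- spectra[i, "Hb"]; b <- spectra[i, "HbO2"]
    rel <- abs(a - b) / mean(c(a, b))
    if (rel > isosbestic_tol) {
      stop(sprintf(
        "Hb/HbO2 mismatch at the 800 nm isosbestic point: %.1f%% relative (tolerance %.1f%%)",
        100 * rel, 100 * isosbestic_tol), call. = FALSE)
    }
  }
  structure(
    list(wavelengths_nm = wl, components = comp, spectra = spectra),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("Spectral library: ", length(x$components), " components (",
      paste(x$components, collapse = ", "), ") on ",
      length(x$wavelengths_nm), " wavelengths ",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm\n", sep = "")
  invisible(x)
}

#' Normalize a tissue spectrum to its peak
#'
#' Divides all intensities by the maximum over the measured grid, so the
#' strongest optoacoustic signal in the acquired range maps to exactly 1.
#' Used to visualise spectral shape independent of the arbitrary intensity
#' scale; unmixing operates on raw spectra.
#'
#' @param spectrum a [tissue_spectrum()].
#' @return A `tissue_spectrum` with `max(intensity) == 1`.
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "tissue_spectrum"))
  m <- max(spectrum$intensity)
  if (m <= 0) {
    stop("cannot normalize: maximum intensity is not positive", call. = FALSE)
  }
  tissue_spectrum(spectrum$wavelengths_nm, spectrum$intensity / m, spectrum$label)
}

#' Mean ROI spectrum from an image stack
#'
#' Arithmetic mean of the stack over the mask pixels, per wavelength.
#'
#' @param image a [multispectral_image()].
#' @param mask logical matrix matching the image slices, or the name of a
#'   stored ROI.
#' @param label label for the resulting spectrum.
#' @return A [tissue_spectrum()].
#' @export
roi_mean_spectrum <- function(image, mask, label = "") {
  stopifnot(inherits(image, "msot_image"))
  if (is.character(mask) && length(mask) == 1L) {
    if (!mask %in% names(image$rois)) {
      stop("no ROI named '", mask, "' in image", call. = FALSE)
    }
    if (!nzchar(label)) label <- mask
    mask <- image$rois[[mask]]
  }
  assert_mask(mask, dim(image$stack)[2:3])
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  nwl <- dim(image$stack)[1]
  flat <- matrix(image$stack, nrow = nwl)  # columns are pixels in (y, x) order
  intensity <- rowMeans(flat[, as.vector(mask), drop = FALSE])
  tissue_spectrum(image$wavelengths_nm, intensity, label)
}

#' Robust refinement of a preliminary ROI on the Hb map
#'
#' A blood-rich tissue such as liver or kidney should show a fairly
#' homogeneous deoxy-haemoglobin distribution; pixels whose Hb unmixing value
#' is far from the in-mask bulk are likely vessels, artefacts or
#' depth-corrupted spectra. This automated surrogate for manual ROI
#' fine-tuning keeps pixels whose Hb value lies within median +/- k * MAD of
#' the in-mask Hb distribution (MAD with the usual 1.4826 normal-consistency
#' constant). If the filter would empty the mask, the preliminary mask is
#' returned unchanged with attribute `fallback = TRUE`.
#'
#' @param preliminary_mask logical matrix.
#' @param hb_map numeric matrix of Hb unmixing values, same shape.
#' @param k robustness multiplier (default 3).
#' @return A logical matrix (subset of the preliminary mask) with attribute
#'   `fallback` indicating whether the filter was abandoned.
#' @export
refine_roi <- function(preliminary_mask, hb_map, k = 3) {
  if (!is.matrix(hb_map) || !identical(dim(hb_map), dim(preliminary_mask))) {
    stop("hb_map shape does not match the preliminary mask", call. = FALSE)
  }
  assert_mask(preliminary_mask, dim(preliminary_mask))
  if (!any(preliminary_mask)) stop("preliminary mask is empty", call. = FALSE)
  vals <- hb_map[preliminary_mask]
  med <- stats::median(vals)
  mad <- stats::mad(vals)
  keep <- abs(hb_map - med) <= k * mad
  refined <- preliminary_mask & keep
  if (!any(refined)) {
    out <- preliminary_mask
    attr(out, "fallback") <- TRUE
    return(out)
  }
  attr(refined, "fallback") <- FALSE
  refined
}
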