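#' Three-wavelength difference analysis readout
#'
#' Label-free lipid statistic computed from only three wavelengths:
#' `(I700 - I930) / I800`. The 930 nm intensity tracks lipid content, the
#' 700 nm intensity is dominated by blood and stays comparatively constant,
#' so the difference `I700 - I930` falls as lipid accumulates; dividing by
#' the 800 nm (oxy-deoxy isosbestic) intensity removes the arbitrary
#' per-acquisition scale without sensitivity to oxygenation. The readout is
#' therefore scale-invariant and *decreases* with tissue lipid content.
#'
#' @param spectrum a [tissue_spectrum()] whose grid contains 700, 800 and
#'   930 nm exactly; intensity at 800 nm must be positive.
#' @return An object of class `difference_readout` with fields `value`,
#'   `i700`, `i800`, `i930` and `label`.
#' @examples
#' lib <- spectral_library()
#' difference_readout(forward_spectrum(liver_model(0), lib))
#' @export
difference_readout <- function(spectrum) {
  stopifnot(inherits(spectrum, "tissue_spectrum"))
  idx <- match(c(700, 800, 930), spectrum$wavelengths_nm)
  if (anyNA(idx)) {
    missing_wl <- c(700, 800, 930)[is.na(idx)]
    stop("spectrum grid lacks required wavelength(s): ",
         paste(missing_wl, collapse = ", "), " nm", call. = FALSE)
  }
  i700 <- spectrum$intensity[idx[1]]
  i800 <- spectrum$intensity[idx[2]]
  i930 <- spectrum$intensity[idx[3]]
  if (i800 <= 0) {
    stop("intensity at 800 nm must be > 0 for the difference readout", call. = FALSE)
  }
  structure(
    list(value = (i700 - i930) / i800, i700 = i700, i800 = i800, i930 = i930,
         label = spectrum$label),
    class = "difference_readout"
  )
}

#' @export
print.difference_readout <- function(x, digits = 4, ...) {
  cat("Difference readout",
      if (nzchar(x$label)) paste0("'", x$label, "'"), ": ",
      format(x$value, digits = digits),
      sprintf("  (I700 = %.4g, I800 = %.4g, I930 = %.4g)\n",
              x$i700, x$i800, x$i930), sep = "")
  invisible(x)
}

#' @export
as.double.difference_readout <- function(x, ...) x$value

#' Kidney-over-liver difference index
#'
#' The kidney is a fat-free internal reference adjacent to the liver, so
#' dividing the kidney difference readout by the liver one removes
#' individual variance and flips the orientation: the index *rises* with
#' hepatic steatosis (the liver readout falls while the kidney readout is
#' unaffected).
#'
#' @param kidney,liver [difference_readout()] objects (or spectra, which are
#'   converted).
#' @return An object of class `difference_index` with fields `value`,
#'   `kidney` and `liver`.
#' @export
difference_index <- function(kidney, liver) {
  if (inherits(kidney, "tissue_spectrum")) kidney <- difference_readout(kidney)
  if (inherits(liver, "tissue_spectrum")) liver <- difference_readout(liver)
  stopifnot(inherits(kidney, "difference_readout"),
            inherits(liver, "difference_readout"))
  if (liver$value == 0) {
    stop("liver difference readout is zero; index undefined", call. = FALSE)
  }
  structure(
    list(value = kidney$value / liver$value, kidney = kidney, liver = liver),
    class = "difference_index"
  )
}

#' @export
print.difference_index <- function(x, digits = 4, ...) {
  cat("Difference index (kidney/liver):", format(x$value, digits = digits), "\n")
  invisible(x)
}

#' @export
as.double.difference_index <- function(x, ...) x$value

#' Per-pixel difference readout map
#'
#' Applies the three-wavelength difference statistic pixel-wise to an image
#' stack, for visualisation of lipid-rich regions.
#'
#' @param image a [multispectral_image()] whose grid contains 700, 800 and
#'   930 nm.
#' @return A numeric matrix (height x width); pixels with non-positive
#'   800 nm intensity are `NA`.
#' @export
difference_map <- function(image) {
  stopifnot(inherits(image, "msot_image"))
  idx <- match(c(700, 800, 930), image$wavelengths_nm)
  if (anyNA(idx)) {
    missing_wl <- c(700, 800, 930)[is.na(idx)]
    stop("image grid lacks required wavelength(s): ",
         paste(missing_wl, collapse = ", "), " nm", call. = FALSE)
  }
  i700 <- image$stack[idx[1], , ]
  i800 <- image$stack[idx[2], , ]
  i930 <- image$stack[idx[3], , ]
  out <- (i700 - i930) / i800
  out[i800 <= 0] <- NA_real_
  out
}
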