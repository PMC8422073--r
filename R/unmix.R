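#' Linear-regression spectral unmixing
#'
#' Decomposes a measured optoacoustic spectrum into a non-intercept linear
#' combination of reference chromophore spectra by least squares: the fitted
#' coefficients minimise the sum of squared differences between the spectrum
#' and `X %*% beta`, where the columns of `X` are the selected library
#' spectra. Under `constraint = "nonnegative"` the minimisation is subject to
#' `beta >= 0` (coefficients in a.u. below zero are unphysical; the
#' unconstrained fit remains the default, matching plain linear regression).
#'
#' Derived blood metrics are attached when both haemoglobins are unmixed:
#' total blood volume `tbv = HbO2 + Hb` and oxygen saturation
#' `so2 = HbO2 / tbv` (undefined, flagged `NA`, when `tbv <= 0`).
#'
#' @param spectrum a [tissue_spectrum()] on the library grid (raw a.u.;
#'   normalised spectra destroy the scale that TBV comparisons use).
#' @param library a [spectral_library()].
#' @param components character subset (>= 2) of `library$components`.
#' @param constraint `"unconstrained"` (default) or `"nonnegative"`.
#' @return An object of class `msot_unmix` with components `coefficients`
#'   (named), `fitted`, `residuals`, `residual_norm` (RMS spectral residual),
#'   `tbv`, `so2`, plus the inputs. Supports `coef()`, `fitted()`,
#'   `residuals()`, `predict()`, `summary()`, `print()` and `plot()`.
#' @examples
#' lib <- spectral_library()
#' sp <- forward_spectrum(liver_model(0.2), lib)
#' fit <- unmix(sp, lib)
#' coef(fit)
#' @export
unmix <- function(spectrum, library,
                  components = c("Hb", "HbO2", "Lipid", "H2O"),
                  constraint = c("unconstrained", "nonnegative")) {
  stopifnot(inherits(spectrum, "tissue_spectrum"),
            inherits(library, "spectral_library"))
  constraint <- match.arg(constraint)
  if (!isTRUE(all.equal(spectrum$wavelengths_nm, library$wavelengths_nm))) {
    stop("spectrum grid does not match library grid", call. = FALSE)
  }
  missing_c <- setdiff(components, library$components)
  if (length(missing_c)) {
    stop("component(s) not in library: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  if (length(components) < 2L) stop("need at least 2 components", call. = FALSE)
  X <- library$spectra[, components, drop = FALSE]
  if (nrow(X) < ncol(X)) {
    stop("grid length must be >= number of components", call. = FALSE)
  }
  check_design_rank(X)
  y <- spectrum$intensity
  beta <- solve_unmix(X, y, constraint)
  fitted <- as.vector(X %*% beta)
  res <- y - fitted
  new_unmix(beta, fitted, res, spectrum, components, constraint)
}

# Singular-design guard: name the collinear components via QR pivoting.
check_design_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular unmixing design: component(s) collinear with the rest: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

solve_unmix <- function(X, y, constraint) {
  beta <- if (constraint == "nonnegative") {
    pracma::lsqnonneg(X, y)$x
  } else {
    qr.coef(qr(X), y)
  }
  stats::setNames(as.vector(beta), colnames(X))
}

new_unmix <- function(beta, fitted, res, spectrum, components, constraint) {
  tbv <- if (all(c("Hb", "HbO2") %in% components)) {
    unname(beta["Hb"] + beta["HbO2"])
  } else NA_real_
  so2 <- if (!is.na(tbv) && tbv > 0) unname(beta["HbO2"]) / tbv else NA_real_
  structure(
    list(coefficients = beta,
         fitted = fitted,
         residuals = res,
         residual_norm = sqrt(mean(res^2)),
         tbv = tbv, so2 = so2,
         spectrum = spectrum, components = components, constraint = constraint),
    class = "msot_unmix"
  )
}

#' @export
coef.msot_unmix <- function(object, ...) object$coefficients

#' @export
fitted.msot_unmix <- function(object, ...) object$fitted

#' @export
residuals.msot_unmix <- function(object, ...) object$residuals

#' Predicted (re-composed) spectrum of an unmixing fit
#'
#' @param object an `msot_unmix` fit.
#' @param ... unused.
#' @return The fitted spectrum as a [tissue_spectrum()].
#' @export
predict.msot_unmix <- function(object, ...) {
  tissue_spectrum(object$spectrum$wavelengths_nm, object$fitted,
                  label = paste0(object$spectrum$label, " (fit)"))
}

#' @export
print.msot_unmix <- function(x, digits = 4, ...) {
  cat("Spectral unmixing (", x$constraint, " least squares)\n", sep = "")
  print(round(x$coefficients, digits))
  if (!is.na(x$tbv)) {
    cat("TBV:", format(x$tbv, digits = digits),
        " sO2:", if (is.na(x$so2)) "undefined" else format(x$so2, digits = digits), "\n")
  }
  cat("RMS residual:", format(x$residual_norm, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.msot_unmix <- function(object, ...) {
  ynorm <- sqrt(mean(object$spectrum$intensity^2))
  structure(
    list(fit = object,
         relative_residual = if (ynorm > 0) object$residual_norm / ynorm else NA_real_),
    class = "summary.msot_unmix"
  )
}

#' @export
print.summary.msot_unmix <- function(x, ...) {
  print(x$fit)
  cat("Relative RMS residual:", format(x$relative_residual, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.msot_unmix <- function(x, ...) {
  wl <- x$spectrum$wavelengths_nm
  plot(wl, x$spectrum$intensity, pch = 16, xlab = "wavelength (nm)",
       ylab = "OA intensity (a.u.)",
       main = paste("Unmixing fit", x$spectrum$label), ...)
  graphics::lines(wl, x$fitted, col = "red3", lwd = 2)
  graphics::legend("topright", c("measured", "fit"), pch = c(16, NA),
                   lty = c(NA, 1), col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Per-pixel unmixing of an image stack
#'
#' Applies [unmix()] to every pixel of a multispectral stack. For the
#' unconstrained fit all pixels are solved in one QR decomposition; the
#' non-negative fit loops pixels. Output maps have the spatial shape of the
#' input slices.
#'
#' @inheritParams unmix
#' @param image a [multispectral_image()].
#' @return An object of class `msot_unmix_maps`: named list `coefficients`
#'   of per-component matrices, plus `tbv`, `so2` and `residual_norm`
#'   matrices.
#' @export
unmix_stack <- function(image, library,
                        components = c("Hb", "HbO2", "Lipid", "H2O"),
                        constraint = c("unconstrained", "nonnegative")) {
  stopifnot(inherits(image, "msot_image"), inherits(library, "spectral_library"))
  constraint <- match.arg(constraint)
  if (!isTRUE(all.equal(image$wavelengths_nm, library$wavelengths_nm))) {
    stop("image grid does not match library grid", call. = FALSE)
  }
  missing_c <- setdiff(components, library$components)
  if (length(missing_c)) {
    stop("component(s) not in library: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  X <- library$spectra[, components, drop = FALSE]
  check_design_rank(X)
  d <- dim(image$stack)
  Y <- matrix(image$stack, nrow = d[1])       # wavelengths x pixels
  B <- if (constraint == "unconstrained") {
    qr.coef(qr(X), Y)                          # components x pixels
  } else {
    apply(Y, 2, function(y) pracma::lsqnonneg(X, y)$x)
  }
  fittedY <- X %*% B
  resid2 <- colMeans((Y - fittedY)^2)
  shape <- d[2:3]
  maps <- lapply(seq_along(components), function(i) matrix(B[i, ], shape[1], shape[2]))
  names(maps) <- components
  tbv <- so2 <- NULL
  if (all(c("Hb", "HbO2") %in% components)) {
    tbv <- maps$Hb + maps$HbO2
    so2 <- maps$HbO2 / tbv
    so2[tbv <= 0] <- NA_real_
  }
  structure(
    list(coefficients = maps, tbv = tbv, so2 = so2,
         residual_norm = matrix(sqrt(resid2), shape[1], shape[2]),
         components = components, constraint = constraint),
    class = "msot_unmix_maps"
  )
}

#' @export
print.msot_unmix_maps <- function(x, ...) {
  d <- dim(x$residual_norm)
  cat("Per-pixel unmixing maps (", x$constraint, "): ",
      paste(x$components, collapse = ", "), " on ", d[1], " x ", d[2],
      " pixels\n", sep = "")
  invisible(x)
}

#' Normalize a tissue readout to an aorta reference
#'
#' Inter-animal comparisons of TBV and sO2 use the readout of the same
#' animal's aorta as reference; this is the plain ratio.
#'
#' @param tissue_value tissue readout (a.u. or fraction).
#' @param aorta_value reference readout of the same kind, > 0.
#' @return `tissue_value / aorta_value` (dimensionless).
#' @export
normalize_to_reference <- function(tissue_value, aorta_value) {
  if (any(aorta_value <= 0)) {
    stop("reference (aorta) readout must be > 0", call. = FALSE)
  }
  tissue_value / aorta_value
}
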