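lib <- the_library

test_that("exactly representable spectra are recovered at machine precision", {
  wl <- lib$wavelengths_nm
  sp <- tissue_spectrum(wl, 2 * lib$spectra[, "Lipid"])
  fit <- unmix(sp, lib)
  expect_equal(coef(fit)[["Lipid"]], 2, tolerance = 1e-12)
  expect_lt(max(abs(coef(fit)[c("Hb", "HbO2", "H2O")])), 1e-12)
  expect_lt(fit$residual_norm, 1e-10 * sqrt(mean(sp$intensity^2)))

  sp2 <- tissue_spectrum(wl, 0.3 * lib$spectra[, "Hb"] + 1.7 * lib$spectra[, "H2O"])
  fit2 <- unmix(sp2, lib, components = c("Hb", "H2O"))
  expect_equal(unname(coef(fit2)), c(0.3, 1.7), tolerance = 1e-12)
})

test_that("unmix agrees with an independent normal-equations oracle", {
  set.seed(14)
  X <- lib$spectra[, c("Hb", "HbO2", "Lipid", "H2O")]
  for (i in 1:25) {
    beta_true <- runif(4, 0, 2)
    y <- as.vector(X %*% beta_true) * (1 + rnorm(27, 0, 0.05))
    fit <- unmix(tissue_spectrum(lib$wavelengths_nm, y), lib)
    oracle <- normal_equations_fit(X, y)
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-8)
  }
})

test_that("nonnegative constraint clips unphysical coefficients", {
  set.seed(15)
  X <- lib$spectra[, c("Hb", "HbO2", "Lipid", "H2O")]
  # exactly representable nonnegative mixture: both modes agree
  y <- as.vector(X %*% c(0.5, 0.2, 0.1, 0.8))
  sp <- tissue_spectrum(lib$wavelengths_nm, y)
  expect_equal(coef(unmix(sp, lib, constraint = "nonnegative")),
               coef(unmix(sp, lib)), tolerance = 1e-8)
  # heavy noise can push unconstrained coefficients negative; nonneg cannot
  for (i in 1:10) {
    ynoisy <- as.vector(X %*% c(0.01, 0.01, 0.01, 0.02)) + rnorm(27, 0, 0.02)
    spn <- tissue_spectrum(lib$wavelengths_nm, pmax(ynoisy, 0))
    expect_true(all(coef(unmix(spn, lib, constraint = "nonnegative")) >= 0))
  }
})

test_that("singular designs fail loudly naming the collinear component", {
  tmp <- tempfile(fileext = ".csv")
  df <- utils::read.csv(system.file("extdata", "spectral_library.csv",
                                    package = "msotlipid"), comment.char = "#")
  df$Hb2 <- 2 * df$Hb
  utils::write.csv(df, tmp, row.names = FALSE)
  lib2 <- spectral_library(tmp)
  sp <- tissue_spectrum(lib2$wavelengths_nm, df$Hb)
  expect_error(unmix(sp, lib2, components = c("Hb", "Hb2")),
               "singular.*Hb")
})

test_that("unmix validates grid, components and counts", {
  sp_short <- tissue_spectrum(wavelength_grid(700, 950, 10), rep(1, 26))
  expect_error(unmix(sp_short, lib), "grid")
  sp <- tissue_spectrum(lib$wavelengths_nm, rep(1, 27))
  expect_error(unmix(sp, lib, components = c("Hb", "Melanin")), "Melanin")
  expect_error(unmix(sp, lib, components = "Hb"), "at least 2")
})

test_that("blood metrics follow their definitions", {
  wl <- lib$wavelengths_nm
  fit_hbo2 <- unmix(tissue_spectrum(wl, lib$spectra[, "HbO2"]), lib,
                    components = c("Hb", "HbO2"))
  expect_equal(fit_hbo2$so2, 1, tolerance = 1e-8)
  fit_hb <- unmix(tissue_spectrum(wl, lib$spectra[, "Hb"]), lib,
                  components = c("Hb", "HbO2"))
  expect_equal(fit_hb$so2, 0, tolerance = 1e-8)
  mix <- tissue_spectrum(wl, 0.5 * lib$spectra[, "Hb"] + 0.5 * lib$spectra[, "HbO2"])
  fit_mix <- unmix(mix, lib)
  expect_equal(fit_mix$so2, 0.5, tolerance = 1e-8)
  expect_equal(fit_mix$tbv,
               coef(fit_mix)[["Hb"]] + coef(fit_mix)[["HbO2"]])
  # without both haemoglobins the metrics are flagged undefined
  fit_nohb <- unmix(tissue_spectrum(wl, lib$spectra[, "H2O"]), lib,
                    components = c("Lipid", "H2O"))
  expect_true(is.na(fit_nohb$tbv) && is.na(fit_nohb$so2))
})

test_that("msot_unmix methods are coherent", {
  sp <- forward_spectrum(liver_model(0.2), lib)
  fit <- unmix(sp, lib)
  expect_s3_class(fit, "msot_unmix")
  expect_equal(fitted(fit) + residuals(fit), sp$intensity)
  expect_equal(predict(fit)$intensity, fitted(fit))
  expect_output(print(fit), "unconstrained")
  expect_output(print(summary(fit)), "Relative RMS residual")
})

test_that("unmix_stack matches a pixel-wise loop and preserves geometry", {
  set.seed(16)
  h <- 3; w <- 4
  stack <- array(0, c(27, h, w))
  for (r in 1:h) for (cc in 1:w) {
    beta <- runif(4, 0, 1)
    stack[, r, cc] <- lib$spectra[, c("Hb", "HbO2", "Lipid", "H2O")] %*% beta +
      rnorm(27, 0, 0.01)
  }
  img <- multispectral_image(abs(stack), lib$wavelengths_nm)
  maps <- unmix_stack(img, lib)
  for (r in 1:h) for (cc in 1:w) {
    fit <- unmix(tissue_spectrum(lib$wavelengths_nm, img$stack[, r, cc]), lib)
    for (comp in maps$components) {
      expect_equal(maps$coefficients[[comp]][r, cc], coef(fit)[[comp]],
                   tolerance = 1e-10)
    }
    expect_equal(maps$residual_norm[r, cc], fit$residual_norm, tolerance = 1e-10)
    expect_equal(maps$tbv[r, cc], fit$tbv, tolerance = 1e-10)
  }
})

test_that("uniform and two-region stacks unmix to their generating maps", {
  uni <- array(rep(lib$spectra[, "H2O"], 6), c(27, 2, 3))
  img <- multispectral_image(uni, lib$wavelengths_nm)
  maps <- unmix_stack(img, lib)
  expect_equal(unname(maps$coefficients$H2O), matrix(1, 2, 3), tolerance = 1e-10)
  expect_lt(max(abs(maps$coefficients$Lipid)), 1e-10)

  two <- array(0, c(27, 2, 2))
  two[, 1, ] <- lib$spectra[, "Lipid"]
  two[, 2, ] <- lib$spectra[, "Hb"]
  maps2 <- unmix_stack(multispectral_image(two, lib$wavelengths_nm), lib)
  expect_equal(unname(maps2$coefficients$Lipid[1, ]), c(1, 1), tolerance = 1e-10)
  expect_lt(max(abs(maps2$coefficients$Lipid[2, ])), 1e-10)
  expect_equal(unname(maps2$coefficients$Hb[2, ]), c(1, 1), tolerance = 1e-10)
  expect_lt(max(abs(maps2$coefficients$Hb[1, ])), 1e-10)
})

test_that("ROI-mean unmixing equals the mean of per-pixel coefficients", {
  # unconstrained least squares is linear in the spectrum, so the two
  # per-ROI conventions coincide
  set.seed(17)
  stack <- array(abs(rnorm(27 * 4 * 4, 1, 0.3)), c(27, 4, 4))
  img <- multispectral_image(stack, lib$wavelengths_nm)
  mask <- matrix(c(TRUE, FALSE), 4, 4)
  fit_mean <- unmix(roi_mean_spectrum(img, mask), lib)
  maps <- unmix_stack(img, lib)
  for (comp in maps$components) {
    expect_equal(coef(fit_mean)[[comp]],
                 mean(maps$coefficients[[comp]][mask]), tolerance = 1e-10)
  }
})

test_that("aorta normalization is a guarded ratio", {
  expect_equal(normalize_to_reference(0.75, 0.75), 1)
  expect_equal(normalize_to_reference(0.375, 0.75), 0.5)
  a <- 0.42; b <- 1.7; k <- 3.3
  expect_equal(normalize_to_reference(k * a, k * b), normalize_to_reference(a, b))
  expect_error(normalize_to_reference(1, 0), "> 0")
  expect_error(normalize_to_reference(1, -2), "> 0")
})
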