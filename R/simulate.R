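# Synthetic multispectral optoacoustic data: tissue forward model with
# diffusion-theory fluence, phantom dilution series, graded score cohorts
# and ICG clearance curves. All randomness is seeded through noise_model()
# or explicit seed arguments.

#' Tissue composition model
#'
#' Volume-fraction mixture of library chromophores with an overall a.u.
#' amplitude and a nominal depth used for fluence attenuation.
#'
#' @param fractions named non-negative weights per chromophore (names must be
#'   library components, e.g. `c(Hb = 0.2, HbO2 = 0.1, H2O = 0.6)`), summing
#'   to at most 1.
#' @param amplitude overall optoacoustic scale (a.u.), > 0.
#' @param depth_mm nominal tissue depth (mm), >= 0; 0 disables attenuation.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(fractions, amplitude = 1, depth_mm = 0) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be named by chromophore", call. = FALSE)
  }
  fractions <- unlist(fractions)
  if (any(fractions < 0)) stop("fractions must be >= 0", call. = FALSE)
  if (sum(fractions) > 1 + 1e-12) stop("fractions must sum to <= 1", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (depth_mm < 0) stop("depth_mm must be >= 0", call. = FALSE)
  structure(list(fractions = fractions, amplitude = amplitude,
                 depth_mm = depth_mm), class = "tissue_model")
}

#' Default liver, kidney and phantom-background compositions
#'
#' Convenience tissue models used by the simulation pipeline and examples:
#' a blood-rich, venous-dominated liver (total blood volume 0.30 at oxygen
#' saturation 0.30, the rest mostly water), a better-oxygenated kidney
#' (blood 0.25 at saturation 0.70) at a default 6 mm depth so fluence
#' attenuation gives it the descending in-vivo spectral shape of a deep
#' retroperitoneal organ, and a nearly transparent phantom background (weak
#' water-only absorption) emulating a lipid/solvent dilution carrier.
#'
#' @param lipid_fraction lipid volume fraction added to the liver mixture
#'   (remaining composition is scaled down accordingly).
#' @param amplitude,depth_mm passed to [tissue_model()].
#' @return A [tissue_model()].
#' @export
liver_model <- function(lipid_fraction = 0, amplitude = 1, depth_mm = 0) {
  if (lipid_fraction < 0 || lipid_fraction > 1) {
    stop("lipid_fraction must be in [0, 1]", call. = FALSE)
  }
  base <- c(Hb = 0.21, HbO2 = 0.09, H2O = 0.65)
  tissue_model(c(base * (1 - lipid_fraction), Lipid = lipid_fraction),
               amplitude = amplitude, depth_mm = depth_mm)
}

#' @rdname liver_model
#' @export
kidney_model <- function(amplitude = 1, depth_mm = 6) {
  tissue_model(c(Hb = 0.075, HbO2 = 0.175, H2O = 0.70),
               amplitude = amplitude, depth_mm = depth_mm)
}

#' @rdname liver_model
#' @export
phantom_background_model <- function(amplitude = 1, depth_mm = 0) {
  tissue_model(c(H2O = 0.05), amplitude = amplitude, depth_mm = depth_mm)
}

#' Acquisition noise model
#'
#' Multiplicative (relative) plus additive Gaussian noise, seeded. Defaults:
#' 2% multiplicative and additive with standard deviation 0.5% of the clean
#' signal's peak (resolved when the noise is applied, so the additive floor
#' scales with the a.u. range of each simulated signal).
#'
#' @param mult_sigma relative standard deviation of multiplicative noise.
#' @param add_sigma additive standard deviation in a.u.; `NULL` means
#'   0.5% of the peak of the clean signal being corrupted.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mult_sigma = 0.02, add_sigma = NULL, seed = NULL) {
  if (mult_sigma < 0) stop("mult_sigma must be >= 0", call. = FALSE)
  if (!is.null(add_sigma) && add_sigma < 0) stop("add_sigma must be >= 0", call. = FALSE)
  structure(list(mult_sigma = mult_sigma, add_sigma = add_sigma, seed = seed),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
no_noise <- function() noise_model(mult_sigma = 0, add_sigma = 0)

# Evaluate code with a temporarily-set seed, restoring the RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

apply_noise <- function(clean, noise) {
  add_sigma <- noise$add_sigma
  if (is.null(add_sigma)) add_sigma <- 0.005 * max(abs(clean))
  if (noise$mult_sigma == 0 && add_sigma == 0) return(clean)
  n <- length(clean)
  with_seed(noise$seed, {
    clean * (1 + stats::rnorm(n, 0, noise$mult_sigma)) +
      stats::rnorm(n, 0, add_sigma)
  })
}

#' Diffusion-theory fluence factor
#'
#' One-dimensional effective-attenuation fluence model
#' `Phi(lambda, d) = exp(-mu_eff(lambda) * d)` with
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`, where `mu_a` is the mixture
#' absorption coefficient (cm^-1) and `mu_s'` a constant reduced scattering
#' coefficient. This is only meant to distort deep-tissue spectra the way
#' light attenuation does in vivo; the analysis applies no fluence
#' correction.
#'
#' @param mu_a absorption coefficient(s), cm^-1.
#' @param depth_mm depth in millimetres.
#' @param mus_prime reduced scattering coefficient, cm^-1 (default 10).
#' @return Fluence factor(s) in (0, 1].
#' @export
fluence_factor <- function(mu_a, depth_mm, mus_prime = 10) {
  if (any(mu_a < 0)) stop("mu_a must be >= 0", call. = FALSE)
  if (depth_mm < 0) stop("depth_mm must be >= 0", call. = FALSE)
  mu_eff <- sqrt(3 * mu_a * (mu_a + mus_prime))
  exp(-mu_eff * depth_mm / 10)
}

#' Forward-simulate a tissue spectrum
#'
#' The optoacoustic intensity at each wavelength is
#' `amplitude * Phi(lambda, depth) * sum_c fraction_c * spectrum_c(lambda)`,
#' i.e. fluence-weighted mixture absorption, then corrupted by the seeded
#' multiplicative and additive Gaussian noise of `noise`. At depth 0 with
#' zero noise the model is exactly linear in the component fractions.
#'
#' @param model a [tissue_model()].
#' @param library a [spectral_library()] covering all model components.
#' @param noise a [noise_model()]; default none.
#' @param mus_prime reduced scattering (cm^-1) for the fluence factor.
#' @param label label of the output spectrum.
#' @return A [tissue_spectrum()] on the library grid.
#' @export
forward_spectrum <- function(model, library, noise = no_noise(),
                             mus_prime = 10, label = "") {
  stopifnot(inherits(model, "tissue_model"), inherits(library, "spectral_library"))
  unknown <- setdiff(names(model$fractions), library$components)
  if (length(unknown)) {
    stop("unknown component(s) not in library: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  X <- library$spectra[, names(model$fractions), drop = FALSE]
  mu_a <- as.vector(X %*% model$fractions)
  clean <- model$amplitude * fluence_factor(mu_a, model$depth_mm, mus_prime) * mu_a
  tissue_spectrum(library$wavelengths_nm, apply_noise(clean, noise), label)
}

#' Simulate a phantom dilution series
#'
#' For each lipid fraction `f`, the mixture has lipid weight `f` and the base
#' model's weights scaled by `(1 - f)`; `n_sections` replicate spectra are
#' generated per fraction (noise-independent across sections). Emulates
#' lipid/solvent phantoms (fractions 0-100%) and homogenised liver-lipid
#' phantoms (fractions 0-60%), measured as three sections each.
#'
#' @param fractions lipid fractions in `[0, 1]`.
#' @param base base [tissue_model()] (carrier or liver tissue).
#' @param library a [spectral_library()].
#' @param noise a [noise_model()]; its seed (if any) seeds the whole series.
#' @param n_sections replicate sections per fraction (default 3).
#' @return A list of [tissue_spectrum()] objects with attributes
#'   `lipid_fraction` and `section` on each element.
#' @export
make_phantom_series <- function(fractions, base, library, noise = no_noise(),
                                n_sections = 3) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("lipid fractions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(base, "tissue_model"))
  per_section <- noise_model(noise$mult_sigma, noise$add_sigma, seed = NULL)
  gen <- function() {
    out <- list()
    for (f in fractions) {
      w <- c(base$fractions * (1 - f), Lipid = unname(f))
      w <- tapply(w, names(w), sum)  # merge if base already contains Lipid
      model <- tissue_model(w[w > 0 | names(w) == "Lipid"],
                            amplitude = base$amplitude, depth_mm = base$depth_mm)
      for (s in seq_len(n_sections)) {
        sp <- forward_spectrum(model, library, per_section,
                               label = sprintf("lipid %.0f%% s%d", 100 * f, s))
        attr(sp, "lipid_fraction") <- f
        attr(sp, "section") <- s
        out[[length(out) + 1L]] <- sp
      }
    }
    out
  }
  with_seed(noise$seed, gen())
}

#' Simulate a graded steatosis cohort
#'
#' Draws per-subject lipid scores from grade-conditional lognormal
#' distributions: `score = m_g * exp(sdlog * Z)`, `Z ~ N(0, 1)`, so `m_g` is
#' the grade-g median and the scores are positive and right-skewed, as
#' optoacoustic unmixing readouts are. Defaults mirror a cross-sectional
#' steatosis study: grades 0-3 with n = 14/11/9/9 and a linear-unmixing
#' score spanning roughly three orders of magnitude plus a difference-index
#' score with a compressed dynamic range.
#'
#' @param n_per_grade subject counts for grades 0,1,2,3.
#' @param score_medians named list; each element is a length-4 vector of
#'   per-grade medians for one score column.
#' @param sdlog lognormal shape (log-scale standard deviation), > 0 unless 0
#'   for the degenerate noiseless cohort.
#' @param seed integer seed or `NULL`.
#' @return A `data.frame` with columns `subject_id`, `grade` and one column
#'   per score.
#' @export
make_graded_cohort <- function(n_per_grade = c(14, 11, 9, 9),
                               score_medians = list(
                                 score_linear = c(1.3, 30, 120, 675),
                                 score_difference_index = c(0.70, 1.00, 1.05, 1.10)),
                               sdlog = 0.8, seed = NULL) {
  if (length(n_per_grade) != 4L || any(n_per_grade < 1)) {
    stop("n_per_grade must give >= 1 subject for each grade 0-3", call. = FALSE)
  }
  if (sdlog < 0) stop("sdlog must be >= 0", call. = FALSE)
  if (!length(score_medians) || is.null(names(score_medians))) {
    stop("score_medians must be a named list of per-grade median vectors", call. = FALSE)
  }
  grade <- rep(0:3, times = n_per_grade)
  n <- length(grade)
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), grade = grade)
  with_seed(seed, {
    for (nm in names(score_medians)) {
      m <- score_medians[[nm]]
      if (length(m) != 4L || any(m <= 0)) {
        stop("score_medians$", nm, " must be 4 positive per-grade medians", call. = FALSE)
      }
      out[[nm]] <- m[grade + 1L] * exp(sdlog * stats::rnorm(n))
    }
  })
  out
}

#' Clearance-curve generator parameters
#'
#' Bi-exponential uptake/excretion model for hepatic indocyanine green:
#' `raw(t) = baseline + amplitude * (exp(-k_out * t) - exp(-k_in * t))`.
#' The curve rises from baseline (uptake, rate `k_in`), peaks at
#' `t* = log(k_in / k_out) / (k_in - k_out)` and decays (excretion, rate
#' `k_out`). Requires `k_in > k_out > 0` for the rise-then-decay shape.
#'
#' @param k_in uptake rate (1/min).
#' @param k_out excretion rate (1/min).
#' @param amplitude signal amplitude (a.u.), >= 0 (0 gives a flat curve at
#'   baseline, the degenerate no-dye limit).
#' @param baseline pre-injection signal (a.u.).
#' @param t_grid sampling times (min), non-negative increasing; default
#'   0-60 min every 5 min with t = 0 the pre-injection point.
#' @return An object of class `clearance_params`.
#' @export
clearance_params <- function(k_in = 0.5, k_out = 0.05, amplitude = 1,
                             baseline = 0.1, t_grid = seq(0, 60, by = 5)) {
  if (!(k_in > k_out && k_out > 0)) {
    stop("need k_in > k_out > 0 for a rise-then-decay clearance curve", call. = FALSE)
  }
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (any(t_grid < 0) || any(diff(t_grid) <= 0)) {
    stop("t_grid must be non-negative and strictly increasing", call. = FALSE)
  }
  structure(list(k_in = k_in, k_out = k_out, amplitude = amplitude,
                 baseline = baseline, t_grid = t_grid),
            class = "clearance_params")
}

#' Simulate an ICG clearance curve
#'
#' Evaluates the bi-exponential model of [clearance_params()] on its time
#' grid and adds the seeded noise. The pre-injection baseline is recorded on
#' the returned curve so downstream normalisation can subtract it.
#'
#' @param params a [clearance_params()].
#' @param noise a [noise_model()].
#' @return A [clearance_curve()].
#' @export
simulate_clearance <- function(params, noise = no_noise()) {
  stopifnot(inherits(params, "clearance_params"))
  t <- params$t_grid
  clean <- params$baseline +
    params$amplitude * (exp(-params$k_out * t) - exp(-params$k_in * t))
  clearance_curve(t, apply_noise(clean, noise), baseline = params$baseline)
}
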