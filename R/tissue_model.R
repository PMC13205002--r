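#' @title Four-layer fingertip tissue model
#' @description The fingertip skin is represented as a planar stack of
#'   stratum corneum, viable epidermis, dermis and subcutaneous tissue with
#'   fixed thicknesses (0.029, 0.089, 1.380, 3.500 mm). Each layer carries a
#'   Cole-Cole conductivity dispersion; subject descriptors (sex, age,
#'   height, weight) perturb the per-layer conductivities multiplicatively,
#'   never the geometry.
#' @name tissue_model
NULL

LAYER_NAMES <- c("stratum_corneum", "viable_epidermis", "dermis",
                 "subcutaneous")
LAYER_THICKNESS_MM <- c(0.029, 0.089, 1.380, 3.500)

#' Cole-Cole dispersion parameters
#'
#' @param sigma_inf dispersive conductivity magnitude in S/m (enters the
#'   low-frequency limit of the conductivity form used here)
#' @param sigma_0 baseline conductivity in S/m (the high-frequency limit)
#' @param tau relaxation time constant in s
#' @param alpha relaxation distribution parameter, in \[0, 1)
#' @return a `cole_cole_params` object
#' @export
cole_cole_params <- function(sigma_inf, sigma_0, tau, alpha) {
  stopifnot(sigma_inf >= 0, sigma_0 >= 0, tau > 0, alpha >= 0, alpha < 1)
  structure(list(sigma_inf = sigma_inf, sigma_0 = sigma_0,
                 tau = tau, alpha = alpha),
            class = "cole_cole_params")
}

#' Complex Cole-Cole conductivity
#'
#' Evaluates sigma_c(f) = sigma_inf / (1 + (j w tau)^(1 - alpha)) + sigma_0
#' with w = 2 pi f, using the principal branch of the fractional power. At
#' f = 0 this reduces to sigma_inf + sigma_0; as f grows the dispersive term
#' vanishes and sigma_c approaches sigma_0.
#'
#' @param p a `cole_cole_params`
#' @param f frequency in Hz, f >= 0 (vectorised)
#' @return complex conductivity in S/m
#' @export
cole_cole_conductivity <- function(p, f) {
  stopifnot(inherits(p, "cole_cole_params"))
  if (any(f < 0)) stop("frequency must be non-negative")
  w <- 2 * pi * f
  jwt <- complex(real = 0, imaginary = w * p$tau)
  term <- ifelse(w == 0, 0 + 0i, jwt^(1 - p$alpha))
  p$sigma_inf / (1 + term) + p$sigma_0
}

#' Real effective conductivity for the quasi-static solve
#'
#' The quasi-static potential equation uses a real conductivity; the real
#' part of the complex Cole-Cole value (conduction current) is taken.
#'
#' @inheritParams cole_cole_conductivity
#' @return Re(sigma_c(f)) in S/m
#' @export
effective_conductivity <- function(p, f) {
  Re(cole_cole_conductivity(p, f))
}

#' Construct a tissue layer
#'
#' @param name one of `stratum_corneum`, `viable_epidermis`, `dermis`,
#'   `subcutaneous`
#' @param thickness_mm layer thickness in mm
#' @param cole_cole a `cole_cole_params`
#' @param rel_permittivity relative permittivity (carried but unused by the
#'   default conduction-only solver)
#' @return a `tissue_layer` object
#' @export
tissue_layer <- function(name, thickness_mm, cole_cole,
                         rel_permittivity = 1e4) {
  stopifnot(name %in% LAYER_NAMES, thickness_mm > 0,
            inherits(cole_cole, "cole_cole_params"))
  structure(list(name = name, thickness_mm = thickness_mm,
                 cole_cole = cole_cole,
                 rel_permittivity = rel_permittivity),
            class = "tissue_layer")
}

#' Subject descriptors
#'
#' @param sex 0 = female, 1 = male
#' @param age years
#' @param height cm
#' @param weight kg
#' @param id optional subject identifier
#' @return `subject_descriptors` with derived `bmi` (kg/m^2)
#' @export
subject_descriptors <- function(sex, age, height, weight, id = NULL) {
  stopifnot(age > 0, height > 0, weight > 0)
  structure(list(id = id, sex = sex, age = age, height = height,
                 weight = weight, bmi = weight / (height / 100)^2),
            class = "subject_descriptors")
}

#' @export
print.subject_descriptors <- function(x, ...) {
  cat(sprintf(
    "<subject %s: sex=%s age=%g height=%g cm weight=%g kg bmi=%.1f>\n",
    if (is.null(x$id)) "?" else x$id,
    if (isTRUE(x$sex == 1)) "M" else if (isTRUE(x$sex == 0)) "F" else x$sex,
    x$age, x$height, x$weight, x$bmi))
  invisible(x)
}

#' Read a subject table from CSV
#'
#' Expects a header with columns `sex`, `age`, `height`, `weight`; `sex` may
#' be 0/1 or F/M (case-insensitive). An optional `id`/`subject` column names
#' the subjects.
#'
#' @param path CSV file path
#' @return list of `subject_descriptors`
#' @export
read_subjects_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("sex", "age", "height", "weight")
  if (!all(need %in% names(df)))
    stop("subject CSV must have columns sex, age, height, weight")
  sex <- df$sex
  if (is.character(sex))
    sex <- ifelse(toupper(substr(sex, 1, 1)) == "M", 1, 0)
  idcol <- intersect(c("id", "subject", "subject_id"), names(df))
  ids <- if (length(idcol)) as.character(df[[idcol[1]]])
         else paste0("S", seq_len(nrow(df)))
  lapply(seq_len(nrow(df)), function(i)
    subject_descriptors(sex[i], df$age[i], df$height[i], df$weight[i],
                        id = ids[i]))
}

#' Descriptor-driven conductivity scaling factor
#'
#' A smooth multiplicative factor
#' g = clamp(1 + a1 (bmi - 22)/22 + a2 (age - 25)/25 + a3 (sex - 0.5),
#'           g_min, g_max)
#' applied to per-layer sigma_inf and sigma_0. The mapping from descriptors
#' to electrical parameters is not biophysically identified; this linear,
#' monotone, clamped form is a documented modelling choice with all
#' coefficients exposed in the run configuration.
#'
#' @param subject a `subject_descriptors`
#' @param coefs list with `a1`, `a2`, `a3`, `g_min`, `g_max`
#' @return scalar factor in \[g_min, g_max\]
#' @export
personalization_factor <- function(subject,
                                   coefs = list(a1 = 0.15, a2 = -0.05,
                                                a3 = 0.05, g_min = 0.5,
                                                g_max = 1.5)) {
  stopifnot(inherits(subject, "subject_descriptors"))
  g <- 1 + coefs$a1 * (subject$bmi - 22) / 22 +
       coefs$a2 * (subject$age - 25) / 25 +
       coefs$a3 * (subject$sex - 0.5)
  min(max(g, coefs$g_min), coefs$g_max)
}

#' Personalize layer conductivities for a subject
#'
#' Scales sigma_inf and sigma_0 of every layer by [personalization_factor()];
#' geometry (thicknesses) is never modified. Pure and deterministic.
#'
#' @param subject a `subject_descriptors`
#' @param baseline list of exactly 4 `tissue_layer`s (outer to inner)
#' @param modifiers coefficient list as in [personalization_factor()]
#' @return list of 4 personalized `tissue_layer`s
#' @export
personalize_layers <- function(subject, baseline,
                               modifiers = list(a1 = 0.15, a2 = -0.05,
                                                a3 = 0.05, g_min = 0.5,
                                                g_max = 1.5)) {
  if (length(baseline) != 4)
    stop("baseline must contain exactly 4 tissue layers")
  g <- personalization_factor(subject, modifiers)
  lapply(baseline, function(L) {
    p <- L$cole_cole
    tissue_layer(L$name, L$thickness_mm,
                 cole_cole_params(g * p$sigma_inf, g * p$sigma_0,
                                  p$tau, p$alpha),
                 rel_permittivity = L$rel_permittivity)
  })
}

#' Default baseline tissue layers
#'
#' Thicknesses are the fixed values 0.029 / 0.089 / 1.380 / 3.500 mm;
#' Cole-Cole baselines are representative low-kHz skin-layer values taken
#' from the dielectric-dispersion literature and stored as data in the
#' package's default configuration file.
#'
#' @param config optional run configuration (see [default_run_config()]);
#'   its `layers` entry supplies the baselines
#' @return list of 4 `tissue_layer`s, outer to inner
#' @export
default_tissue_layers <- function(config = default_run_config()) {
  lapply(config$layers, function(L)
    tissue_layer(L$name, L$thickness_mm,
                 cole_cole_params(L$sigma_inf, L$sigma_0, L$tau, L$alpha),
                 rel_permittivity = L$rel_permittivity))
}

#' Assemble the subject-specific fingertip model
#'
#' @param subject a `subject_descriptors`
#' @param config run configuration (layer baselines, personalization
#'   coefficients, effective frequency, lateral extent)
#' @return a `fingertip_model`: personalized `layers`, `lateral_extent_mm`
#'   (x, y), `subject`, `effective_frequency_hz`
#' @export
fingertip_model <- function(subject, config = default_run_config()) {
  layers <- personalize_layers(subject, default_tissue_layers(config),
                               config$personalization)
  structure(
    list(layers = layers,
         lateral_extent_mm = config$solver$lateral_extent_mm,
         subject = subject,
         effective_frequency_hz = config$effective_frequency_hz),
    class = "fingertip_model")
}

#' @export
print.fingertip_model <- function(x, ...) {
  cat(sprintf(
    "<fingertip_model: 4 layers, depth %.3f mm, extent %g x %g mm, f_eff %g Hz>\n",
    sum(vapply(x$layers, function(L) L$thickness_mm, numeric(1))),
    x$lateral_extent_mm[1], x$lateral_extent_mm[2],
    x$effective_frequency_hz))
  invisible(x)
}
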