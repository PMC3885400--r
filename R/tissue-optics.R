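#' Hemoglobin molar extinction table
#'
#' Loads the packaged molar extinction compilation for oxygenated (HbO) and
#' deoxygenated (HbR) hemoglobin on a 1 nm grid from 450 to 1000 nm, in
#' 1/(mM cm). The table is a synthetic representative compilation: smooth
#' log-spline curves through literature-scale anchor values, with the visible
#' isosbestic point placed exactly at 569 nm and a near-isosbestic crossing
#' around 797 nm, so that the 569 nm band tracks total hemoglobin and the
#' 805 nm band is scattering-dominated.
#'
#' @return A `chromophore_table` (data frame with columns `wavelength_nm`,
#'   `eps_HbO`, `eps_HbR`).
#' @export
#' @examples
#' tab <- hemoglobin_extinction()
#' extinction(tab, 569, "HbO") / extinction(tab, 569, "HbR")
hemoglobin_extinction <- function() {
  path <- system.file("extdata", "hemoglobin_extinction.csv",
                      package = "sdoptics", mustWork = TRUE)
  df <- utils::read.csv(path)
  chromophore_table(df$wavelength_nm, df$eps_HbO, df$eps_HbR)
}

#' Construct a chromophore extinction table
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param eps_HbO,eps_HbR molar extinction of oxy-/deoxyhemoglobin per grid
#'   node, 1/(mM cm); all values must be positive.
#' @return A `chromophore_table`.
#' @export
chromophore_table <- function(wavelength_nm, eps_HbO, eps_HbR) {
  if (length(wavelength_nm) != length(eps_HbO) ||
      length(wavelength_nm) != length(eps_HbR))
    stop("wavelength grid and extinction columns must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(eps_HbO <= 0) || any(eps_HbR <= 0))
    stop("extinction coefficients must be positive")
  structure(
    data.frame(wavelength_nm = wavelength_nm,
               eps_HbO = eps_HbO, eps_HbR = eps_HbR),
    class = c("chromophore_table", "data.frame"))
}

#' Molar extinction at a wavelength
#'
#' Linear interpolation between bracketing grid nodes; exact node values are
#' returned at the nodes.
#'
#' @param table a [chromophore_table()].
#' @param wavelength wavelength(s) in nm, within the grid range.
#' @param species `"HbO"` or `"HbR"`.
#' @return extinction in 1/(mM cm).
#' @export
extinction <- function(table, wavelength, species = c("HbO", "HbR")) {
  species <- match.arg(species)
  rng <- range(table$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf("wavelength outside the tabulated range [%g, %g] nm",
                 rng[1], rng[2]))
  y <- if (species == "HbO") table$eps_HbO else table$eps_HbR
  stats::approx(table$wavelength_nm, y, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Absorption coefficient from hemoglobin concentrations
#'
#' Beer-Lambert assembly of the absorption coefficient,
#' `mu_a = ln(10) (eps_HbO C_HbO + eps_HbR C_HbR)`, converted to 1/mm
#' (extinctions are tabulated per cm).
#'
#' @param C_HbO,C_HbR concentrations in mM (non-negative).
#' @param wavelength wavelength(s) in nm.
#' @param table a [chromophore_table()].
#' @return absorption coefficient in 1/mm.
#' @export
absorption_coefficient <- function(C_HbO, C_HbR, wavelength,
                                   table = hemoglobin_extinction()) {
  if (any(C_HbO < 0) || any(C_HbR < 0))
    stop("hemoglobin concentrations must be non-negative")
  e_o <- extinction(table, wavelength, "HbO")
  e_r <- extinction(table, wavelength, "HbR")
  log(10) * (e_o * C_HbO + e_r * C_HbR) / 10
}

#' Wavelength-dependent reduced scattering law
#'
#' Power law `mu_s'(lambda) = a (lambda / lambda_ref)^(-b)`. The amplitude
#' `a` is the single free scattering parameter recovered by the spectral
#' inversion; the exponent is a typical Mie-like slope for cortical tissue.
#'
#' @param amplitude_a reduced scattering at the reference wavelength, 1/mm.
#' @param exponent_b dimensionless scattering power; default 1.3.
#' @param reference_wavelength nm; default 500.
#' @return a `scattering_law`.
#' @export
scattering_law <- function(amplitude_a, exponent_b = 1.3,
                           reference_wavelength = 500) {
  stop_if_not_scalar(amplitude_a, "amplitude_a")
  if (amplitude_a < 0) stop("scattering amplitude must be non-negative")
  structure(list(amplitude_a = amplitude_a, exponent_b = exponent_b,
                 reference_wavelength = reference_wavelength),
            class = "scattering_law")
}

#' Reduced scattering coefficient at a wavelength
#'
#' @param law a [scattering_law()].
#' @param wavelength wavelength(s) in nm, positive.
#' @return reduced scattering coefficient mu_s' in 1/mm.
#' @export
reduced_scattering <- function(law, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  law$amplitude_a * (wavelength / law$reference_wavelength)^(-law$exponent_b)
}

#' Single tissue layer
#'
#' @param thickness layer thickness in mm; `Inf` for a semi-infinite layer.
#' @param C_HbO,C_HbR hemoglobin concentrations in mM.
#' @param scattering a [scattering_law()].
#' @param anisotropy_g scattering anisotropy, `0 <= g < 1`.
#' @param refractive_index `>= 1`.
#' @param mua_background wavelength-independent baseline absorption (1/mm),
#'   e.g. for bloodless skull; default 0.
#' @param name optional label (`"cortex"` marks the layer whose surface is the
#'   depth reference for [sampling_depth()]).
#' @return a `tissue_layer`.
#' @export
tissue_layer <- function(thickness = Inf, C_HbO = 0, C_HbR = 0,
                         scattering = scattering_law(2),
                         anisotropy_g = 0.9, refractive_index = 1.37,
                         mua_background = 0, name = "cortex") {
  if (!(is.infinite(thickness) || thickness > 0))
    stop("layer thickness must be positive or Inf (semi-infinite)")
  if (anisotropy_g < 0 || anisotropy_g >= 1)
    stop("anisotropy g must satisfy 0 <= g < 1")
  if (refractive_index < 1) stop("refractive index must be >= 1")
  if (C_HbO < 0 || C_HbR < 0) stop("concentrations must be non-negative")
  if (mua_background < 0) stop("mua_background must be non-negative")
  structure(list(thickness = thickness, C_HbO = C_HbO, C_HbR = C_HbR,
                 scattering = scattering, anisotropy_g = anisotropy_g,
                 refractive_index = refractive_index,
                 mua_background = mua_background, name = name),
            class = "tissue_layer")
}

#' Layered tissue model
#'
#' Ordered top-to-bottom list of layers; only the last layer may be
#' semi-infinite.
#'
#' @param ... `tissue_layer` objects, top first.
#' @return a `tissue_model`.
#' @export
tissue_model <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "tissue_layer"))
    layers <- layers[[1]]
  if (!length(layers)) stop("at least one layer is required")
  ok <- vapply(layers, inherits, logical(1), "tissue_layer")
  if (!all(ok)) stop("all layers must be tissue_layer objects")
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  if (any(is.infinite(th[-length(th)])))
    stop("only the last layer may be semi-infinite")
  structure(list(layers = layers), class = "tissue_model")
}

#' Semi-infinite single-layer cortex model
#'
#' The geometry used for the spectral inversion: fibers placed directly on the
#' exposed cortex (measurement through a small skull window).
#'
#' @param C_HbO,C_HbR hemoglobin concentrations, mM.
#' @param a scattering amplitude at 500 nm, 1/mm.
#' @param exponent_b,anisotropy_g,refractive_index optical defaults.
#' @return a `tissue_model`.
#' @export
cortex_model <- function(C_HbO = 0.06, C_HbR = 0.04, a = 2,
                         exponent_b = 1.3, anisotropy_g = 0.9,
                         refractive_index = 1.37) {
  tissue_model(tissue_layer(
    thickness = Inf, C_HbO = C_HbO, C_HbR = C_HbR,
    scattering = scattering_law(a, exponent_b),
    anisotropy_g = anisotropy_g, refractive_index = refractive_index,
    name = "cortex"))
}

#' Two-layer skull plus cortex model
#'
#' Transcranial geometry: a thin bloodless skull layer over a semi-infinite
#' cortex. Skull optical properties are conventional defaults (the measurement
#' they support is qualitative) and are fully overridable.
#'
#' @param skull_thickness mm; rat parietal bone is about 1 mm.
#' @param skull_mua baseline skull absorption, 1/mm.
#' @param skull_a,skull_b skull reduced-scattering power law at 500 nm.
#' @param skull_n skull refractive index.
#' @param C_HbO,C_HbR,a cortex parameters as in [cortex_model()].
#' @return a `tissue_model`.
#' @export
skull_cortex_model <- function(skull_thickness = 1.0, skull_mua = 0.03,
                               skull_a = 2.0, skull_b = 0.65, skull_n = 1.55,
                               C_HbO = 0.06, C_HbR = 0.04, a = 2) {
  tissue_model(
    tissue_layer(thickness = skull_thickness, C_HbO = 0, C_HbR = 0,
                 scattering = scattering_law(skull_a, skull_b),
                 anisotropy_g = 0.9, refractive_index = skull_n,
                 mua_background = skull_mua, name = "skull"),
    tissue_layer(thickness = Inf, C_HbO = C_HbO, C_HbR = C_HbR,
                 scattering = scattering_law(a),
                 anisotropy_g = 0.9, refractive_index = 1.37,
                 name = "cortex"))
}

#' Source-detector fiber pair geometry
#'
#' @param core_diameter_um fiber core diameter, micrometres.
#' @param center_separation_mm centre-to-centre fiber distance, mm.
#' @param numerical_aperture fiber NA; must be below the coupling-medium index.
#' @param coupling_index refractive index of the medium above the tissue
#'   (index-matching gel by default).
#' @return a `fiber_geometry`.
#' @export
fiber_geometry <- function(core_diameter_um = 800, center_separation_mm = 2,
                           numerical_aperture = 0.22, coupling_index = 1.37) {
  if (core_diameter_um <= 0 || center_separation_mm <= 0 ||
      numerical_aperture <= 0)
    stop("fiber geometry values must be positive")
  if (numerical_aperture >= coupling_index)
    stop("numerical aperture must be below the coupling-medium index")
  structure(list(core_diameter_um = core_diameter_um,
                 center_separation_mm = center_separation_mm,
                 numerical_aperture = numerical_aperture,
                 coupling_index = coupling_index),
            class = "fiber_geometry")
}

# per-layer optical properties at one wavelength -> matrix for the MC kernel
layer_matrix <- function(tissue, wavelength, table) {
  rows <- lapply(tissue$layers, function(ly) {
    mua <- ly$mua_background +
      absorption_coefficient(ly$C_HbO, ly$C_HbR, wavelength, table)
    musp <- reduced_scattering(ly$scattering, wavelength)
    mus <- musp / (1 - ly$anisotropy_g)
    c(ly$thickness, mua, mus, ly$anisotropy_g, ly$refractive_index)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("thickness", "mua", "mus", "g", "n")
  m
}

# depth of the top surface of the layer named "cortex" (0 if first layer)
cortex_offset <- function(tissue) {
  names_ <- vapply(tissue$layers, `[[`, character(1), "name")
  i <- match("cortex", names_)
  if (is.na(i) || i == 1) return(0)
  sum(vapply(tissue$layers[seq_len(i - 1)], `[[`, numeric(1), "thickness"))
}
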