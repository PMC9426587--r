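#' Fixed model parameters
#'
#' Assembles the full set of fixed (non-optimized) constants of the trichome
#' model: per-electron yields of linear and alternative photosynthetic electron
#' transport (LPET/AET), ATP and NADPH quotas of N2 fixation, carbon fixation,
#' the CO2-concentrating mechanism (CCM), biosynthesis and respiration, elemental
#' ratios, trichome geometry, O2 diffusion constants and the light forcing.
#'
#' All rates are carbon-specific (per mol cellular C) and in SI seconds; the
#' light period is 12 h and daily quantities are normalized to 1 day = 86400 s.
#'
#' Stoichiometric quotas, `QC`, `O2_far`, `kO2NF`, `epsilon` and `f_D` are the
#' published constants of the model. The light-curve, PET-capacity, storage and
#' geometry constants (`alpha_I`, `I_max`, `vPET_max`, `beta`, `N_max`,
#' `CS_max`, `d_O2`, `R`, `L_g`, `L`, `L_m`) are not printed in the main text;
#' defaults here are standard literature magnitudes, with `vPET_max` pinned by
#' the optimization bound note (maximal PSII O2 production 5.0e-4 =
#' 0.25*vPET_max) and `alpha_I`, `beta`, `N_max`, `CS_max` set by
#' [calibrate_unknowns()] against the published unified-model outcomes. These
#' calibrated defaults are therefore not canonical values; see the methods
#' vignette.
#'
#' @param ... named overrides for any field listed below.
#' @param .validate logical; run [validate_fixed_parameters()] (default TRUE).
#'
#' @section Fields:
#' \describe{
#'   \item{qLPET_ATP, qLPET_NADPH, qLPET_O2}{mol ATP / NADPH / O2 per mol
#'     electron through LPET (0.65, 0.5, 0.25).}
#'   \item{qAET_ATP}{mol ATP per mol electron through AET (0.65; no NADPH, no
#'     net O2).}
#'   \item{qNF_ATP, qNF_NADPH}{mol ATP (9) and NADPH (3) per mol N fixed.}
#'   \item{qCF_ATP, qCF_NADPH, qCCM_ATP}{mol ATP (3), NADPH (2) per fixed C
#'     (Calvin-Benson) plus 0.8 ATP per C for the CCM (50% Ci leakage, 80% Ci
#'     from HCO3-, 0.5 ATP per HCO3-).}
#'   \item{qBIO_ATP, qRESP_ATP}{ATP cost of biosynthesis (2 per C) and ATP
#'     yield of carbohydrate respiration (5 per C).}
#'   \item{gamma_MT}{dimensionless maintenance ATP surcharge (0.10).}
#'   \item{qRP_O2}{mol O2 consumed per mol C respired in respiratory
#'     protection (1; CH2O + O2 -> CO2 + H2O).}
#'   \item{NC_ratio}{Redfield-type mol N per mol C of biomass (0.159).}
#'   \item{QC}{cellular carbon concentration, mol C m-3 (18333).}
#'   \item{O2_far}{far-field O2 concentration, mol m-3 (0.213; air saturation
#'     at 34 PSU, 25 C).}
#'   \item{kO2NF}{half-saturation of O2 inhibition of N2 fixation, mol m-3.}
#'   \item{epsilon}{membrane:seawater O2 diffusivity ratio.}
#'   \item{f_D}{diazocyte fraction of cells (0.15; segregated variant).}
#'   \item{beta}{PET inhibition strength by respiratory protection,
#'     (mol C (mol C)-1 s-1)-1.}
#'   \item{alpha_I}{initial slope of the light curve, (umol m-2 s-1)-1.}
#'   \item{I_max}{peak irradiance, umol photons m-2 s-1.}
#'   \item{vPET_max}{light-saturated PET capacity, mol e- (mol C)-1 s-1.}
#'   \item{N_max, CS_max}{maximal fixed-N and carbon-skeleton storage, mol
#'     (mol C)-1.}
#'   \item{d_O2}{O2 diffusivity in seawater, m2 s-1.}
#'   \item{R, L_g, L_m, L}{cytoplasm radius, membrane thickness, mixed-layer
#'     thickness, trichome length, m.}
#'   \item{k_b}{boundary-layer multiplier; L_b = k_b * (R + L_g).}
#'   \item{L_b}{boundary-layer thickness, m (derived unless overridden).}
#'   \item{V}{trichome volume, m3 (derived as pi R^2 L unless overridden).}
#'   \item{T_light}{light period, s (43200).}
#' }
#' @return a validated list of class `"trd_fixed"`.
#' @export
fixed_parameters <- function(..., .validate = TRUE) {
  p <- list(
    # per-electron PET yields
    qLPET_ATP   = 0.65,
    qLPET_NADPH = 0.5,
    qLPET_O2    = 0.25,
    qAET_ATP    = 0.65,
    # process quotas
    qNF_ATP   = 9,
    qNF_NADPH = 3,
    qCF_ATP   = 3,
    qCF_NADPH = 2,
    qCCM_ATP  = 0.8,
    qBIO_ATP  = 2,
    qRESP_ATP = 5,
    qRP_O2    = 1,
    gamma_MT  = 0.10,
    # elemental / environmental constants
    NC_ratio = 0.159,
    QC       = 18333,
    O2_far   = 0.213,
    kO2NF    = 1e-2,
    epsilon  = 1e-4,
    f_D      = 0.15,
    # light forcing and PET capacity
    T_light  = 43200,
    I_max    = 2000,
    vPET_max = 2.0e-3,
    # calibrated constants (see calibrate_unknowns and the methods vignette)
    alpha_I = 4.6298277e-4,
    beta    = 1.8706926e4,
    N_max   = 0.16543317,
    CS_max  = 7.7575179,
    # geometry and diffusion (R calibrated alongside the constants above)
    d_O2 = 2.1e-9,
    R    = 7.2230311e-6,
    L_g  = 5e-8,
    L_m  = 1e-6,
    L    = 5e-4,
    k_b  = 1024,
    L_b  = NULL,
    V    = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  if (is.null(p$L_b)) p$L_b <- p$k_b * (p$R + p$L_g)
  if (is.null(p$V)) p$V <- pi * p$R^2 * p$L
  class(p) <- "trd_fixed"
  if (.validate) validate_fixed_parameters(p)
  p
}

#' Validate fixed parameters
#'
#' Checks positivity of quotas, concentrations and lengths, that fractions lie
#' in \[0, 1\], and that a user-supplied trichome volume agrees with the
#' cylinder implied by `R` and `L` to within 0.1%.
#'
#' @param p a `"trd_fixed"` list.
#' @return `p`, invisibly; errors name the offending field.
#' @export
validate_fixed_parameters <- function(p) {
  pos <- c(
    "qLPET_ATP", "qLPET_NADPH", "qLPET_O2", "qAET_ATP", "qNF_ATP", "qNF_NADPH",
    "qCF_ATP", "qCF_NADPH", "qCCM_ATP", "qBIO_ATP", "qRESP_ATP", "qRP_O2",
    "NC_ratio", "QC", "O2_far", "kO2NF", "beta", "alpha_I", "I_max",
    "vPET_max", "N_max", "CS_max", "d_O2", "R", "L_g", "L_m", "L", "L_b", "V",
    "T_light", "k_b"
  )
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("fixed parameter '", nm, "' must be a single positive number")
    }
  }
  for (nm in c("gamma_MT", "epsilon", "f_D")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("fixed parameter '", nm, "' must lie in [0, 1]")
    }
  }
  v_cyl <- pi * p$R^2 * p$L
  if (abs(p$V - v_cyl) > 1e-3 * v_cyl) {
    stop("fixed parameter 'V' (", p$V, ") is inconsistent with the cylinder ",
         "volume pi*R^2*L (", v_cyl, ") by more than 0.1%")
  }
  invisible(p)
}

#' Bounds of the optimizable parameters
#'
#' Search ranges of the four free parameters: the half-saturation constants are
#' bounded by the maximal potential of organic carbon fixed over a diurnal
#' cycle, and the two maximal rates by the maximal potential PSII O2 production
#' rate (5.0e-4 mol (mol C)-1 s-1).
#'
#' @return a 2 x 4 matrix with rows `lower`, `upper`.
#' @export
free_parameter_bounds <- function() {
  rbind(
    lower = c(kCSNF = 0, vCS_max = 0,     kCH2O_CS = 0, vRP_max = 0),
    upper = c(kCSNF = 1, vCS_max = 5e-4,  kCH2O_CS = 1, vRP_max = 5e-4)
  )
}

#' Optimizable (free) parameters
#'
#' @param kCSNF half-saturation of carbon skeleton for N2 fixation,
#'   mol C (mol C)-1.
#' @param vCS_max maximal carbon-skeleton synthesis rate, mol C (mol C)-1 s-1.
#' @param kCH2O_CS half-saturation of carbohydrate for carbon-skeleton
#'   synthesis, mol C (mol C)-1.
#' @param vRP_max maximal respiratory-protection rate, mol C (mol C)-1 s-1.
#' @return a validated list of class `"trd_free"`.
#' @export
free_parameters <- function(kCSNF, vCS_max, kCH2O_CS, vRP_max) {
  f <- list(kCSNF = kCSNF, vCS_max = vCS_max,
            kCH2O_CS = kCH2O_CS, vRP_max = vRP_max)
  b <- free_parameter_bounds()
  for (nm in names(f)) {
    v <- f[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("free parameter '", nm, "' must be a single finite number")
    }
    if (v < b["lower", nm] || v > b["upper", nm]) {
      stop("free parameter '", nm, "' = ", v, " outside its bound [",
           b["lower", nm], ", ", b["upper", nm], "]")
    }
  }
  structure(f, class = "trd_free")
}

#' Published optima of the free parameters
#'
#' The growth-maximizing values of the four free parameters: kCSNF = 0.06,
#' vCS_max = 3.7e-6, kCH2O_CS = 0.58, and vRP_max = 4.5e-4 for the unified
#' (non-segregated) trichome or 4.0e-4 when N2 fixation is confined to
#' diazocytes (respiratory protection is in less demand there).
#'
#' @param variant `"unified"` or `"segregated"`.
#' @return a `"trd_free"` list.
#' @export
default_optimized_parameters <- function(variant = c("unified", "segregated")) {
  variant <- match.arg(variant)
  free_parameters(
    kCSNF    = 0.06,
    vCS_max  = 3.7e-6,
    kCH2O_CS = 0.58,
    vRP_max  = if (variant == "unified") 4.5e-4 else 4.0e-4
  )
}

#' Run configuration
#'
#' Experiment switches and numerical settings for one diel integration.
#'
#' @param variant `"unified"` (all cells identical) or `"segregated"`
#'   (N2 fixation confined to diazocytes).
#' @param transfer_loss loss fraction lambda in \[0, 0.8\] applied to materials
#'   transferred between cell types; only meaningful for the segregated
#'   variant.
#' @param ablate_RP disable respiratory protection.
#' @param ablate_AET force the AET electron fraction to zero.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param dt_out output grid spacing, s.
#' @param seed integer seed for stochastic components (optimizer starts).
#' @param n_starts default number of multistart optimizer starts.
#' @return a validated list of class `"trd_config"`.
#' @export
run_config <- function(variant = c("unified", "segregated"),
                       transfer_loss = 0,
                       ablate_RP = FALSE,
                       ablate_AET = FALSE,
                       rtol = 1e-7,
                       atol = 1e-10,
                       dt_out = 60,
                       seed = 42L,
                       n_starts = 64L) {
  variant <- match.arg(variant)
  if (!is.numeric(transfer_loss) || length(transfer_loss) != 1L ||
      transfer_loss < 0 || transfer_loss > 0.8) {
    stop("run parameter 'transfer_loss' must lie in [0, 0.8]")
  }
  if (variant == "unified" && transfer_loss > 0) {
    stop("'transfer_loss' is only meaningful for the segregated variant")
  }
  stopifnot(is.logical(ablate_RP), is.logical(ablate_AET),
            rtol > 0, atol > 0, dt_out > 0, n_starts >= 1)
  structure(list(
    variant = variant, transfer_loss = transfer_loss,
    ablate_RP = isTRUE(ablate_RP), ablate_AET = isTRUE(ablate_AET),
    rtol = rtol, atol = atol, dt_out = dt_out,
    seed = as.integer(seed), n_starts = as.integer(n_starts)
  ), class = "trd_config")
}
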