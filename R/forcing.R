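#' Diel irradiance
#'
#' Sinusoidal 12-h light forcing: `I(t) = I_max * sin(pi * t / T_light)`.
#'
#' @param t time since dawn, s; must lie in \[0, T_light\].
#' @param params fixed parameters.
#' @return irradiance, umol photons m-2 s-1.
#' @export
irradiance <- function(t, params) {
  if (any(t < 0 | t > params$T_light)) {
    stop("t outside the light period [0, ", params$T_light, "] s")
  }
  params$I_max * pmax(0, sin(pi * (t / params$T_light)))
}

#' Light-dependent PET potential
#'
#' Saturating exponential light response of photosynthetic electron transport:
#' `vPET_max * (1 - exp(-alpha_I * I))`.
#'
#' @param I irradiance, umol photons m-2 s-1 (>= 0).
#' @param params fixed parameters.
#' @return electron transport potential, mol e- (mol C)-1 s-1.
#' @export
pet_light_potential <- function(I, params) {
  stopifnot(all(I >= 0))
  params$vPET_max * (1 - exp(-params$alpha_I * I))
}

#' Realized PET rate under respiratory-protection feedback
#'
#' High respiratory protection reduces the plastoquinone pool and feeds back
#' on photosystem II: `V_PET = V_PET_I * exp(-beta * V_RP)`.
#'
#' @param V_PET_I light-dependent PET potential, mol e- (mol C)-1 s-1.
#' @param V_RP respiratory protection rate, mol C (mol C)-1 s-1.
#' @param params fixed parameters.
#' @return realized PET rate, mol e- (mol C)-1 s-1.
#' @export
pet_rate <- function(V_PET_I, V_RP, params) {
  stopifnot(all(V_PET_I >= 0), all(V_RP >= 0))
  V_PET_I * exp(-params$beta * V_RP)
}

#' AET electron fraction required for a given ATP:NADPH demand ratio
#'
#' Linear PET yields ATP and NADPH at 0.65:0.5 = 1.3 per electron; AET yields
#' 0.65 ATP and no NADPH. Routing a fraction `f` of electrons through AET sets
#' the supply ratio to `qLPET_ATP / (qLPET_NADPH * (1 - f))`, so the fraction
#' required to meet a demand ratio `r >= 1.3` is
#' `f = 1 - qLPET_ATP / (qLPET_NADPH * r)`.
#'
#' For the bare process stoichiometries this gives 56.7% at the 3:1 ratio of
#' N2 fixation and 31.6% at the 1.9:1 ratio of carbon fixation. Demand ratios
#' below 1.3 (unreachable without discarding NADPH) return 0, flagged
#' `"NADPH_limited"` in the `"limitation"` attribute.
#'
#' @param r ATP:NADPH demand ratio (vectorized).
#' @param params fixed parameters.
#' @return AET fraction in \[0, 1\] with attribute `"limitation"`.
#' @export
required_aet_fraction <- function(r, params = fixed_parameters()) {
  stopifnot(all(is.finite(r)), all(r > 0))
  r0 <- params$qLPET_ATP / params$qLPET_NADPH
  f <- pmin(pmax(1 - r0 / r, 0), 1)
  attr(f, "limitation") <- ifelse(r < r0, "NADPH_limited", "none")
  f
}

#' Allocate PET energy between N2 fixation and carbon fixation
#'
#' Solves the instantaneous two-currency (ATP, NADPH) balance with N2-fixation
#' priority. ATP and NADPH are not storable, so supply must track demand at
#' every instant:
#' \enumerate{
#'   \item N2 fixation is capped so that its ATP cost, including the
#'     maintenance surcharge `(1 + gamma_MT)` and any transfer-loss inflation
#'     (`nf_cost_factor`), fits within total ATP supply
#'     `qLPET_ATP * V_PET` (equal ATP yield per electron on both pathways).
#'   \item Carbon fixation takes the entire ATP residual:
#'     `(1+gamma_MT) * (qNF_ATP*c*V_NF + (qCF_ATP+qCCM_ATP)*V_CF) =
#'     qLPET_ATP * V_PET`.
#'   \item The AET fraction is then set so NADPH supply exactly matches NADPH
#'     demand: `f_AET = 1 - (qNF_NADPH*c*V_NF + qCF_NADPH*V_CF) /
#'     (qLPET_NADPH * V_PET)`, clipped to \[0, 1\].
#' }
#' With these quotas the ATP constraint always binds first, so both currencies
#' close exactly whenever `V_PET > 0` and `f_AET` is interior. ATP wasted by
#' respiratory protection is not part of this budget.
#'
#' @param V_PET realized PET rate, mol e- (mol C)-1 s-1.
#' @param V_NF_requested kinetically possible N2 fixation rate,
#'   mol N (mol C)-1 s-1.
#' @param params fixed parameters.
#' @param ablate_AET force `f_AET = 0` (model experiment); NADPH then runs a
#'   surplus and carbon fixation stays ATP-limited.
#' @param nf_cost_factor cost inflation `1/(1-lambda)` for energy transferred
#'   into diazocytes (1 for the unified variant).
#' @return a list (energy budget): realized `V_NF`, `V_CF`, `f_AET`,
#'   `ATP_supply`, `NADPH_supply`, per-process demands `ATP_NF`, `ATP_CF_CCM`,
#'   `ATP_MT`, `NADPH_NF`, `NADPH_CF`, `O2_evolution`, and `limitation_flag`
#'   (`"light_limited"`, `"ATP_limited"` or `"NADPH_limited"`).
#' @export
allocate_energy <- function(V_PET, V_NF_requested, params,
                            ablate_AET = FALSE, nf_cost_factor = 1) {
  stopifnot(V_PET >= 0, V_NF_requested >= 0, nf_cost_factor >= 1)
  s <- 1 + params$gamma_MT
  qA <- params$qLPET_ATP
  qN <- params$qLPET_NADPH
  c_nf <- nf_cost_factor

  if (V_PET <= 0) {
    return(list(
      V_NF = 0, V_CF = 0, f_AET = 0,
      ATP_supply = 0, NADPH_supply = 0,
      ATP_NF = 0, ATP_CF_CCM = 0, ATP_MT = 0,
      NADPH_NF = 0, NADPH_CF = 0, O2_evolution = 0,
      limitation_flag = "light_limited"
    ))
  }

  atp_supply <- qA * V_PET
  # N2-fixation priority: ATP cap (binding) and, for safety, the NADPH cap at
  # maximal AET (f such that all residual NADPH feeds NF).
  cap_atp   <- atp_supply / (s * params$qNF_ATP * c_nf)
  cap_nadph <- qN * V_PET / (params$qNF_NADPH * c_nf)
  V_NF <- min(V_NF_requested, cap_atp, cap_nadph)

  # carbon fixation exhausts the ATP residual
  resid <- atp_supply / s - params$qNF_ATP * c_nf * V_NF
  V_CF <- max(0, resid / (params$qCF_ATP + params$qCCM_ATP))

  d_nadph <- params$qNF_NADPH * c_nf * V_NF + params$qCF_NADPH * V_CF

  if (isTRUE(ablate_AET)) {
    f_AET <- 0
    # with f_AET pinned, NADPH may still bind in principle
    if (d_nadph > qN * V_PET) {
      V_CF <- max(0, (qN * V_PET - params$qNF_NADPH * c_nf * V_NF) /
                    params$qCF_NADPH)
      d_nadph <- params$qNF_NADPH * c_nf * V_NF + params$qCF_NADPH * V_CF
      flag <- "NADPH_limited"
    } else {
      flag <- "ATP_limited"
    }
  } else {
    f_raw <- 1 - d_nadph / (qN * V_PET)
    f_AET <- min(max(f_raw, 0), 1)
    flag <- if (f_raw < 0) "NADPH_limited" else "ATP_limited"
  }

  proc_atp <- params$qNF_ATP * c_nf * V_NF +
    (params$qCF_ATP + params$qCCM_ATP) * V_CF
  list(
    V_NF = V_NF, V_CF = V_CF, f_AET = f_AET,
    ATP_supply = atp_supply,
    NADPH_supply = qN * (1 - f_AET) * V_PET,
    ATP_NF = params$qNF_ATP * c_nf * V_NF,
    ATP_CF_CCM = (params$qCF_ATP + params$qCCM_ATP) * V_CF,
    ATP_MT = params$gamma_MT * proc_atp,
    NADPH_NF = params$qNF_NADPH * c_nf * V_NF,
    NADPH_CF = params$qCF_NADPH * V_CF,
    O2_evolution = params$qLPET_O2 * (1 - f_AET) * V_PET,
    limitation_flag = flag
  )
}
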