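#' Maximal (energy-bound) N2 fixation rate
#'
#' The ceiling reached when all PET-derived NADPH and ATP feed N2 fixation,
#' with the AET fraction at the value required by the 3:1 ATP:NADPH demand of
#' nitrogenase plus ammonium assimilation:
#' `V_NF_max = V_PET * (1 - f_AET_NF) * qLPET_NADPH / qNF_NADPH`
#' with `f_AET_NF = 1 - 1.3/3 = 56.7%`.
#'
#' @param V_PET realized PET rate, mol e- (mol C)-1 s-1.
#' @param params fixed parameters.
#' @return maximal N2 fixation rate, mol N (mol C)-1 s-1.
#' @export
nf_max <- function(V_PET, params) {
  stopifnot(all(V_PET >= 0))
  r_nf <- params$qNF_ATP / params$qNF_NADPH
  f_nf <- 1 - (params$qLPET_ATP / params$qLPET_NADPH) / r_nf
  V_PET * (1 - f_nf) * params$qLPET_NADPH / params$qNF_NADPH
}

#' Regulated N2 fixation rate
#'
#' Downregulates the energetic ceiling by carbon-skeleton availability
#' (Michaelis-Menten), by the approach of fixed N to its maximal storage, and
#' by Michaelis-Menten O2 inhibition:
#' `V_NF = V_NF_max * CS/(CS+kCSNF) * (N_max-N)/N_max * kO2NF/(O2+kO2NF)`.
#'
#' @param V_NF_max energetic ceiling from [nf_max()].
#' @param CS carbon-skeleton pool, mol C (mol C)-1.
#' @param N fixed-N pool, mol N (mol C)-1; values above `N_max` give 0.
#' @param O2 intracellular O2, mol m-3.
#' @param params fixed parameters.
#' @param free free parameters (uses `kCSNF`).
#' @return N2 fixation rate, mol N (mol C)-1 s-1.
#' @export
nf_rate <- function(V_NF_max, CS, N, O2, params, free) {
  stopifnot(all(CS >= 0), all(O2 >= 0))
  f_cs <- CS / (CS + free$kCSNF)
  f_n  <- pmax(0, params$N_max - N) / params$N_max
  f_o2 <- 1 - O2 / (O2 + params$kO2NF)
  V_NF_max * f_cs * f_n * f_o2
}

#' Carbon-skeleton synthesis rate
#'
#' Carbohydrate is converted to carbon skeletons without energy cost or carbon
#' loss, stimulated by the carbohydrate pool and inhibited by skeleton
#' accumulation:
#' `V_CS = vCS_max * CH2O/(CH2O+kCH2O_CS) * (CS_max-CS)/CS_max`.
#'
#' @param CH2O carbohydrate pool, mol C (mol C)-1.
#' @param CS carbon-skeleton pool, mol C (mol C)-1; values above `CS_max`
#'   give 0.
#' @param params fixed parameters.
#' @param free free parameters (uses `vCS_max`, `kCH2O_CS`).
#' @return synthesis rate, mol C (mol C)-1 s-1.
#' @export
cs_rate <- function(CH2O, CS, params, free) {
  stopifnot(all(CH2O >= 0))
  free$vCS_max * CH2O / (CH2O + free$kCH2O_CS) *
    pmax(0, params$CS_max - CS) / params$CS_max
}

#' Respiratory protection rate
#'
#' Active respiration of carbohydrate that draws down intracellular O2 to
#' protect nitrogenase; the ATP produced is discarded as heat. RP is
#' stimulated by intracellular O2 and by the potential for N2 fixation (light,
#' carbon skeleton) and fades as N storage fills:
#' `V_RP = vRP_max * O2/(O2+kO2NF) * (1-exp(-alpha_I*I)) * CS/(CS+kCSNF) *
#' (N_max-N)/N_max`.
#'
#' @param O2 intracellular O2, mol m-3.
#' @param I irradiance, umol photons m-2 s-1.
#' @param CS,N pools, mol (mol C)-1.
#' @param params fixed parameters.
#' @param free free parameters (uses `vRP_max`, `kCSNF`).
#' @param ablate_RP if TRUE the rate is 0 (model experiment).
#' @return RP rate, mol C (mol C)-1 s-1.
#' @export
rp_rate <- function(O2, I, CS, N, params, free, ablate_RP = FALSE) {
  if (isTRUE(ablate_RP)) return(0 * O2)
  stopifnot(all(O2 >= 0), all(I >= 0), all(CS >= 0))
  free$vRP_max *
    O2 / (O2 + params$kO2NF) *
    (1 - exp(-params$alpha_I * I)) *
    CS / (CS + free$kCSNF) *
    pmax(0, params$N_max - N) / params$N_max
}
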