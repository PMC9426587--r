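# Assembly of the diel ODE system, its integration, the end-of-day
# biosynthesis solve and the daily accounting.

# Pools can only be consumed while they exist: rates drawing on CH2O are
# scaled by a piecewise-linear limiter that is exactly 1 above `eps` and
# ramps to 0 at an empty pool (numerical guard, see methods vignette).
pool_limiter <- function(x, eps = 1e-6) pmin(1, pmax(0, x / eps))

flag_code <- function(flag) {
  c(light_limited = 0, ATP_limited = 1, NADPH_limited = 2)[[flag]]
}

#' Instantaneous fluxes of the trichome model
#'
#' Evaluates every rate and energy-budget term at one instant, for either
#' model variant. All rates are normalized to total trichome carbon unless
#' suffixed `_P`/`_D` (per photosynthetic-cell / per diazocyte biomass).
#'
#' @param t time since dawn, s.
#' @param state named numeric state: `CH2O`, `CS`, `N`, and `O2` (unified) or
#'   `O2_P`, `O2_D` (segregated), pools in mol (mol C)-1 and O2 in mol m-3.
#' @param params fixed parameters.
#' @param free free parameters.
#' @param config run configuration.
#' @return named list of rates, energy terms and diffusion fluxes.
#' @export
trichome_fluxes <- function(t, state, params, free, config) {
  t <- min(max(t, 0), params$T_light)
  I <- irradiance(t, params)
  CH2O <- max(state[["CH2O"]], 0)
  CS <- max(state[["CS"]], 0)
  N <- max(state[["N"]], 0)
  lim <- pool_limiter(CH2O)
  V_PET_I <- pet_light_potential(I, params)
  V_CS <- cs_rate(CH2O, CS, params, free) * lim

  if (config$variant == "unified") {
    O2 <- max(state[["O2"]], 0)
    V_RP <- rp_rate(O2, I, CS, N, params, free, config$ablate_RP) * lim
    V_PET <- pet_rate(V_PET_I, V_RP, params)
    V_NF_req <- nf_rate(nf_max(V_PET, params), CS, N, O2, params, free)
    al <- allocate_energy(V_PET, V_NF_req, params, config$ablate_AET)
    T_O2 <- o2_exchange_unified(O2, params)
    c(list(
      t = t, I = I, V_PET_I = V_PET_I, V_PET = V_PET, V_CS = V_CS,
      V_RP = V_RP, rp_draw = V_RP,
      O2_rp = params$qRP_O2 * V_RP,
      T_O2 = T_O2, T_O2_env = T_O2,
      nf_credit = al$V_NF,
      limitation = flag_code(al$limitation_flag)
    ), al[setdiff(names(al), "limitation_flag")])
  } else {
    O2_P <- max(state[["O2_P"]], 0)
    O2_D <- max(state[["O2_D"]], 0)
    lam <- config$transfer_loss
    keep <- 1 - lam
    fD <- params$f_D
    V_RP_P <- rp_rate(O2_P, I, CS, N, params, free, config$ablate_RP) * lim
    V_RP_D <- rp_rate(O2_D, I, CS, N, params, free, config$ablate_RP) * lim
    V_PET_P <- pet_rate(V_PET_I, V_RP_P, params)
    V_PET <- (1 - fD) * V_PET_P
    # energy reaching diazocytes is discounted by the transfer loss, both in
    # the kinetic ceiling and in the allocation's cost inflation; at f_D = 0
    # (degenerate limit) N2 fixation falls back to the photosynthetic cells,
    # which recovers the unified model
    O2_NF <- if (fD == 0) O2_P else O2_D
    V_NF_req <- nf_rate(nf_max(V_PET, params) * keep, CS, N, O2_NF,
                        params, free)
    al <- allocate_energy(V_PET, V_NF_req, params, config$ablate_AET,
                          nf_cost_factor = 1 / keep)
    ox <- o2_exchange_segregated(O2_D, O2_P, params)
    V_RP <- (1 - fD) * V_RP_P + fD * V_RP_D        # O2-consuming respiration
    rp_draw <- (1 - fD) * V_RP_P + fD * V_RP_D / keep  # CH2O drawn from pool
    c(list(
      t = t, I = I, V_PET_I = V_PET_I, V_PET = V_PET, V_CS = V_CS,
      V_RP = V_RP, rp_draw = rp_draw,
      O2_rp = params$qRP_O2 * V_RP,
      V_PET_P = V_PET_P, V_RP_P = V_RP_P, V_RP_D = V_RP_D,
      O2_prod_P = params$qLPET_O2 * (1 - al$f_AET) * V_PET_P,
      T_O2_P = ox$flux_P, T_O2_D = ox$flux_D, T_O2_env = ox$flux_env,
      O2_mixed = ox$O2_mixed,
      nf_credit = al$V_NF * (fD + (1 - fD) * keep),
      limitation = flag_code(al$limitation_flag)
    ), al[setdiff(names(al), "limitation_flag")])
  }
}

#' Time derivatives of the diel state
#'
#' Pool balances `dCH2O/dt = V_CF - V_CS - V_RP(draw)`, `dCS/dt = V_CS`,
#' `dN/dt = V_NF` (discounted by transfer losses in the segregated variant)
#' and the O2 balance `dO2/dt = (V_O2 - V_O2RP) * QC + T_O2` per compartment.
#'
#' @inheritParams trichome_fluxes
#' @return list of derivatives in deSolve order.
#' @export
derivatives <- function(t, state, params, free, config) {
  fl <- trichome_fluxes(t, state, params, free, config)
  d <- if (config$variant == "unified") {
    c(CH2O = fl$V_CF - fl$V_CS - fl$rp_draw,
      CS = fl$V_CS,
      N = fl$nf_credit,
      O2 = (fl$O2_evolution - fl$O2_rp) * params$QC + fl$T_O2)
  } else {
    c(CH2O = fl$V_CF - fl$V_CS - fl$rp_draw,
      CS = fl$V_CS,
      N = fl$nf_credit,
      O2_P = (fl$O2_prod_P - params$qRP_O2 * fl$V_RP_P) * params$QC +
        fl$T_O2_P,
      O2_D = (-params$qRP_O2 * fl$V_RP_D) * params$QC + fl$T_O2_D)
  }
  if (any(!is.finite(d))) {
    stop("non-finite derivative at t = ", t, "; state = ",
         paste(sprintf("%s=%.6g", names(state), state), collapse = ", "))
  }
  list(d)
}

#' Integrate one diel cycle
#'
#' Integrates the light-period ODEs with a stiff-capable solver
#' (deSolve `lsoda`) from dawn (all storage pools empty, intracellular O2 at
#' the far-field concentration) to dusk, evaluates every flux on the output
#' grid, forms daily integrals by the trapezoid rule, and performs the
#' end-of-day biosynthesis solve and growth-rate calculation.
#'
#' @param params fixed parameters.
#' @param free free parameters.
#' @param config run configuration.
#' @return an object of class `"trd_diel"`: list with `series` (data.frame of
#'   state and fluxes per grid point), `state_end`, `integrals` (daily
#'   integrals, mol (mol C)-1 day-1 and derived ratios), `bio` (biosynthesis
#'   outcome), `G` (growth rate, day-1), and the inputs.
#' @export
integrate_diel <- function(params = fixed_parameters(),
                           free = default_optimized_parameters(),
                           config = run_config()) {
  y0 <- if (config$variant == "unified") {
    c(CH2O = 0, CS = 0, N = 0, O2 = params$O2_far)
  } else {
    c(CH2O = 0, CS = 0, N = 0, O2_P = params$O2_far, O2_D = params$O2_far)
  }
  times <- seq(0, params$T_light, by = config$dt_out)
  sol <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, parms) derivatives(t, y, params, free, config),
    parms = NULL,
    method = "lsoda", rtol = config$rtol, atol = config$atol
  )
  if (attr(sol, "istate")[1L] < 0) {
    stop("diel integration failed; last state: ",
         paste(sprintf("%.6g", sol[nrow(sol), ]), collapse = ", "))
  }
  states <- sol[, -1L, drop = FALSE]
  if (min(states) < -1e-6) {
    stop("negative pool beyond tolerance during integration (min = ",
         min(states), ")")
  }

  rec <- lapply(seq_len(nrow(sol)), function(i) {
    fl <- trichome_fluxes(sol[i, "time"], pmax(states[i, ], 0),
                          params, free, config)
    fl$limitation_flag <- NULL
    unlist(fl)
  })
  series <- as.data.frame(do.call(rbind, rec))
  series <- cbind(time = sol[, "time"], as.data.frame(states),
                  series[, setdiff(names(series), "t")])

  itg <- function(col) pracma::trapz(series$time, series[[col]])
  state_end <- pmax(states[nrow(states), ], 0)

  integrals <- list(
    gross_C = itg("V_CF"),
    gross_N = itg("V_NF"),
    net_N   = itg("nf_credit"),
    rp_C    = itg("rp_draw"),
    cs_C    = itg("V_CS"),
    electrons = itg("V_PET"),
    o2_production = itg("O2_evolution"),
    o2_rp = itg("O2_rp"),
    o2_diffusion = itg("T_O2_env") / params$QC,
    atp_day = itg("ATP_supply"),
    atp_nf = itg("ATP_NF"),
    atp_cf_ccm = itg("ATP_CF_CCM"),
    atp_mt_day = itg("ATP_MT"),
    nadph_supply = itg("NADPH_supply"),
    nadph_nf = itg("NADPH_NF"),
    nadph_cf = itg("NADPH_CF"),
    atp_aet = params$qAET_ATP *
      pracma::trapz(series$time, series$f_AET * series$V_PET),
    f_AET_daily = pracma::trapz(series$time, series$f_AET * series$V_PET) /
      max(itg("V_PET"), .Machine$double.xmin),
    peak_t_CF = series$time[which.max(series$V_CF)],
    peak_t_NF = series$time[which.max(series$V_NF)]
  )
  integrals$atp_lpet <- integrals$atp_day - integrals$atp_aet
  integrals$CN_ratio <- integrals$gross_C /
    max(integrals$gross_N, .Machine$double.xmin)
  if (config$variant == "unified") {
    integrals$O2_max <- max(series$O2)
    integrals$O2_min <- min(series$O2)
  } else {
    integrals$O2_max <- max(series$O2_P)
    integrals$O2_min <- min(series$O2_D)
  }

  bio <- biosynthesis(state_end[["CH2O"]], state_end[["CS"]],
                      state_end[["N"]], params)
  res <- list(
    series = series, state_end = state_end, integrals = integrals,
    bio = bio, G = growth_rate(bio$Bio),
    params = params, free = free, config = config
  )
  class(res) <- "trd_diel"
  res
}

#' End-of-day biosynthesis solve
#'
#' Biomass is synthesized once, at the end of the light period, from the
#' accumulated pools. The ATP for synthesis comes from respiring part of the
#' carbohydrate: `Bio_C * qBIO_ATP * (1 + gamma_MT) = CH2O_resp * qRESP_ATP`,
#' while the non-respired carbohydrate and all carbon skeletons become
#' biomass: `Bio_C = CH2O - CH2O_resp + CS`. The pair solves in closed form to
#' `Bio_C = (CH2O + CS) / (1 + qBIO_ATP (1+gamma_MT) / qRESP_ATP)` (= 1.44
#' with the default quotas). If the required respiration exceeds the
#' carbohydrate pool, all carbohydrate is respired and synthesis is capped by
#' ATP or by the carbon-skeleton pool (flagged). N-based biomass is
#' `Bio_N = N / NC_ratio`; realized biomass is the smaller of the two.
#'
#' @param CH2O_end,CS_end,N_end end-of-day pools, mol (mol C)-1.
#' @param params fixed parameters.
#' @return list with `Bio`, `Bio_C`, `Bio_N`, `CH2O_resp` (respiration of the
#'   C-based solve), `CH2O_resp_realized` (respiration supporting the realized
#'   biomass), and `capped`.
#' @export
biosynthesis <- function(CH2O_end, CS_end, N_end, params) {
  stopifnot(CH2O_end >= 0, CS_end >= 0, N_end >= 0)
  k <- params$qBIO_ATP * (1 + params$gamma_MT) / params$qRESP_ATP
  Bio_N <- N_end / params$NC_ratio
  Bio_C <- (CH2O_end + CS_end) / (1 + k)
  capped <- FALSE
  if (k * Bio_C > CH2O_end) {
    # energy-limited: respire all carbohydrate, synthesize from skeletons
    Bio_C <- min(CH2O_end / k, CS_end)
    CH2O_resp <- CH2O_end
    capped <- TRUE
  } else {
    CH2O_resp <- k * Bio_C
  }
  Bio <- min(Bio_N, Bio_C)
  list(Bio = Bio, Bio_C = Bio_C, Bio_N = Bio_N,
       CH2O_resp = CH2O_resp,
       CH2O_resp_realized = min(k * Bio, CH2O_end),
       capped = capped)
}

#' Daily growth rate
#'
#' `G = ln(1 + Bio) / (1 day)`; `Bio` is the relative biomass increase over
#' one diel cycle.
#'
#' @param Bio synthesized biomass, mol C (mol C)-1.
#' @return growth rate, day-1.
#' @export
growth_rate <- function(Bio) {
  stopifnot(all(Bio >= 0))
  log(1 + Bio)
}

#' Daily carbon, ATP, NADPH and O2 budgets
#'
#' Partitions the daily integrals of a completed run into closed fraction
#' sets: gross fixed carbon into biomass, respiratory protection, nighttime
#' respiration and unsynthesized remainder; total ATP production (daytime PET
#' plus nighttime respiration) into carbon fixation + CCM, N2 fixation,
#' maintenance and biosynthesis, and by source into LPET, AET and night
#' respiration; NADPH into carbon and N2 fixation; and the O2 budget into
#' photosynthetic production, RP consumption and net diffusion.
#'
#' @param result a `"trd_diel"` object.
#' @return list of named fraction vectors (`carbon`, `atp`, `atp_source`,
#'   `nadph`) plus `o2` (mol O2 (mol C)-1 day-1 terms), `nadph_surplus`, and
#'   absolute totals.
#' @export
daily_budgets <- function(result) {
  stopifnot(inherits(result, "trd_diel"))
  ig <- result$integrals
  p <- result$params
  bio <- result$bio

  night_resp <- bio$CH2O_resp_realized
  atp_night <- p$qRESP_ATP * night_resp
  atp_bio <- p$qBIO_ATP * bio$Bio
  atp_mt <- ig$atp_mt_day + p$gamma_MT * atp_bio
  atp_total <- ig$atp_day + atp_night

  residual_C <- ig$gross_C - bio$Bio - night_resp - ig$rp_C
  carbon <- c(biomass = bio$Bio, rp = ig$rp_C,
              night_respiration = night_resp,
              residual = max(residual_C, 0)) / ig$gross_C
  atp <- c(cf_ccm = ig$atp_cf_ccm, nf = ig$atp_nf,
           maintenance = atp_mt, biosynthesis = atp_bio) / atp_total
  atp_source <- c(lpet = ig$atp_lpet, aet = ig$atp_aet,
                  night_respiration = atp_night) / atp_total
  nadph_used <- ig$nadph_nf + ig$nadph_cf
  nadph <- c(cf = ig$nadph_cf, nf = ig$nadph_nf) / nadph_used

  list(
    carbon = carbon,
    atp = atp,
    atp_source = atp_source,
    nadph = nadph,
    nadph_surplus = (ig$nadph_supply - nadph_used) /
      max(ig$nadph_supply, .Machine$double.xmin),
    o2 = c(production = ig$o2_production, rp = -ig$o2_rp,
           diffusion = ig$o2_diffusion),
    totals = c(gross_C = ig$gross_C, gross_N = ig$gross_N,
               net_N = ig$net_N, atp_total = atp_total,
               f_AET_daily = ig$f_AET_daily, G = result$G)
  )
}

#' @export
print.trd_diel <- function(x, ...) {
  ig <- x$integrals
  cat("Diel trichome simulation (", x$config$variant, " variant)\n", sep = "")
  cat(sprintf("  growth rate G        : %.3f day-1\n", x$G))
  cat(sprintf("  gross C fixation     : %.3f mol C (mol C)-1 day-1\n",
              ig$gross_C))
  cat(sprintf("  gross N2 fixation    : %.4f mol N (mol C)-1 day-1\n",
              ig$gross_N))
  cat(sprintf("  gross C:N            : %.1f\n", ig$CN_ratio))
  cat(sprintf("  daily AET fraction   : %.1f%%\n", 100 * ig$f_AET_daily))
  invisible(x)
}
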