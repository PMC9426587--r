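# Growth-maximizing parameter search: Latin-hypercube multistart over the
# bounded free-parameter space, each start refined by bounded quasi-Newton
# descent on parameters rescaled to [0, 1] (the two maximal rates span orders
# of magnitude; raw scales stall line searches).

rescale_to_unit <- function(x, b) (x - b["lower", ]) / (b["upper", ] - b["lower", ])
rescale_from_unit <- function(u, b) b["lower", ] + u * (b["upper", ] - b["lower", ])

growth_objective <- function(params, config) {
  force(params); force(config)
  function(x_free) {
    free <- tryCatch(do.call(free_parameters, as.list(x_free)),
                     error = function(e) NULL)
    if (is.null(free)) return(NA_real_)
    tryCatch(integrate_diel(params, free, config)$G,
             error = function(e) NA_real_)
  }
}

#' Maximize the daily growth rate over the free parameters
#'
#' Multistart bounded maximization of the daily growth rate `G` returned by
#' [integrate_diel()] over the four free parameters. Start points are drawn by
#' Latin-hypercube sampling over the bounds (deterministic given `seed`); each
#' start is refined with `L-BFGS-B` on unit-rescaled parameters. All starts
#' are returned so multimodality can be inspected.
#'
#' @param params fixed parameters.
#' @param config run configuration.
#' @param bounds 2 x 4 bounds matrix (default [free_parameter_bounds()]).
#' @param n_starts number of starts (default from `config`).
#' @param seed integer seed (default from `config`).
#' @param start_points optional matrix of additional start points (raw scale,
#'   one row per start, named columns).
#' @param control passed to [stats::optim()] (e.g. `maxit`, `factr`).
#' @return list of class `"trd_opt"`: `best_free` (`trd_free`), `best_G`,
#'   `starts` (data.frame: start point, converged point, G, convergence
#'   status), `seed`, `n_starts`.
#' @export
optimize_growth <- function(params = fixed_parameters(),
                            config = run_config(),
                            bounds = free_parameter_bounds(),
                            n_starts = config$n_starts,
                            seed = config$seed,
                            start_points = NULL,
                            control = list(maxit = 40L, factr = 1e9)) {
  obj <- growth_objective(params, config)
  nm <- colnames(bounds)

  set.seed(seed)
  U <- lhs::randomLHS(n_starts, ncol(bounds))
  colnames(U) <- nm
  if (!is.null(start_points)) {
    extra <- t(apply(start_points[, nm, drop = FALSE], 1L,
                     function(x) rescale_to_unit(x, bounds)))
    U <- rbind(U, extra)
  }

  fn_unit <- function(u) {
    g <- obj(rescale_from_unit(pmin(pmax(u, 0), 1), bounds))
    if (is.na(g)) 1e6 else -g
  }

  rows <- lapply(seq_len(nrow(U)), function(i) {
    fit <- tryCatch(
      stats::optim(U[i, ], fn_unit, method = "L-BFGS-B",
                   lower = rep(0, length(nm)), upper = rep(1, length(nm)),
                   control = control),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(data.frame(as.list(stats::setNames(
        c(rescale_from_unit(U[i, ], bounds), rep(NA_real_, length(nm))),
        c(paste0("start_", nm), nm))),
        G = NA_real_, convergence = -1L))
    }
    par <- rescale_from_unit(pmin(pmax(fit$par, 0), 1), bounds)
    data.frame(as.list(stats::setNames(
      c(rescale_from_unit(U[i, ], bounds), par),
      c(paste0("start_", nm), nm))),
      G = -fit$value, convergence = fit$convergence)
  })
  starts <- do.call(rbind, rows)
  ok <- which(is.finite(starts$G))
  if (!length(ok)) {
    stop("all optimizer starts failed; inspect the starts table:\n",
         paste(utils::capture.output(print(starts)), collapse = "\n"))
  }
  ibest <- ok[which.max(starts$G[ok])]
  best_free <- do.call(free_parameters, as.list(starts[ibest, nm]))
  structure(list(
    best_free = best_free, best_G = starts$G[ibest], starts = starts,
    seed = seed, n_starts = n_starts
  ), class = "trd_opt")
}

#' Re-optimize the maximal RP rate for the segregated variant
#'
#' Holding the other three free parameters at the unified optima, performs a
#' 1-D bounded maximization of `G` over `vRP_max` for the spatially segregated
#' trichome (respiratory protection is in less demand there). A grid pre-scan
#' is run first to document the objective's shape and to bracket the best
#' region; an optimum on a bound is flagged.
#'
#' @param params fixed parameters.
#' @param config run configuration (must have `variant = "segregated"`).
#' @param free_base free parameters supplying the three fixed values
#'   (default: unified optima).
#' @param n_grid size of the pre-scan grid.
#' @param tol absolute tolerance on `vRP_max` for [stats::optimize()].
#' @return list: `free` (with re-optimized `vRP_max`), `vRP_max`, `G`,
#'   `grid` (pre-scan data.frame), `at_boundary`.
#' @export
reoptimize_vrp_segregated <- function(params = fixed_parameters(),
                                      config = run_config(variant = "segregated"),
                                      free_base = default_optimized_parameters("unified"),
                                      n_grid = 9L,
                                      tol = 2e-6) {
  stopifnot(config$variant == "segregated")
  b <- free_parameter_bounds()[, "vRP_max"]
  g_of <- function(v) {
    free <- free_parameters(free_base$kCSNF, free_base$vCS_max,
                            free_base$kCH2O_CS, v)
    integrate_diel(params, free, config)$G
  }
  grid_v <- seq(b[1L] + (b[2L] - b[1L]) / (n_grid + 1), b[2L],
                length.out = n_grid)
  grid <- data.frame(vRP_max = grid_v, G = vapply(grid_v, g_of, numeric(1)))
  i0 <- which.max(grid$G)
  lo <- if (i0 > 1L) grid$vRP_max[i0 - 1L] else b[1L]
  hi <- if (i0 < n_grid) grid$vRP_max[i0 + 1L] else b[2L]
  fit <- stats::optimize(g_of, interval = c(lo, hi), maximum = TRUE, tol = tol)
  best_v <- fit$maximum
  best_G <- fit$objective
  if (grid$G[i0] > best_G) {   # coarse grid can beat a narrow bracket
    best_v <- grid$vRP_max[i0]
    best_G <- grid$G[i0]
  }
  at_boundary <- best_v <= b[1L] + 2 * tol || best_v >= b[2L] - 2 * tol
  free <- free_parameters(free_base$kCSNF, free_base$vCS_max,
                          free_base$kCH2O_CS, best_v)
  list(free = free, vRP_max = best_v, G = best_G,
       grid = grid, at_boundary = at_boundary)
}
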